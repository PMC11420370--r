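test_that("estimated missingness weights are count ratios", {
  # 10 phase-two non-cases, 8 with complete data -> w3 = 1.25, sigma3 = 0.16
  n <- 14
  d <- data.frame(subject_id = 1:n, stratum = "a", entry_time = 0,
                  exit_time = seq(1, 14), event = c(rep(1, 4), rep(0, 10)),
                  xi = 1, v = c(rep(1, 4), rep(1, 8), 0, 0),
                  x1 = rnorm(n))
  d$x1[d$v == 0] <- NA
  fr <- cohort_frame(d, covars = "x1")
  p3 <- phase3_weights(fr)
  nc <- which(d$event == 0)
  expect_equal(unique(p3$w3[nc]), 10 / 8)
  expect_equal(unique(p3$sigma3[nc]), 0.8 * 0.2)
  expect_equal(unique(p3$w3[d$event == 1]), 1) # all cases complete here
  expect_equal(unname(exp(p3$gamma)), c(1, 1.25))

  # no missingness: weights 1, variances 0
  d2 <- d; d2$v <- 1; d2$x1 <- rnorm(n)
  fr2 <- cohort_frame(d2, covars = "x1")
  p32 <- phase3_weights(fr2)
  expect_true(all(p32$w3 == 1) && all(p32$sigma3 == 0))

  # a stratum with members but nothing observed is an error
  d3 <- d; d3$v[d3$event == 0] <- 0; d3$x1[d3$v == 0] <- NA
  fr3 <- cohort_frame(d3, covars = "x1")
  expect_error(phase3_weights(fr3), "no complete-data")
})

test_that("V = 1 collapses the three-phase analysis to the two-phase one", {
  fx <- make_cch_frame(n = 60, seed = 23, m_per_stratum = 14)
  fr <- fx$frame
  req <- risk_request(0, 8, rbind(c(1, 0.5), c(-1, 0)))
  p3 <- phase3_weights(fr)
  ftp <- fit_threephase(fr, fx$weights, p3, req)
  fit2 <- cch_fit(fr, fx$weights)
  expect_identical(ftp$fit$beta, fit2$beta)

  i3 <- influence_threephase(fr, fx$weights, p3, ftp$fit, req)
  i2 <- influence_two_phase(fr, fx$weights, fit2, req)
  for (nm in c("beta", "Lambda", "purerisk")) {
    expect_equal(i3[[nm]]$delta, i2[[nm]]$delta, tolerance = 1e-12)
  }
  rule <- pair_rule(fr, fx$weights)
  v22 <- variance_threephase(i3$beta, rule, p3)
  v14 <- variance_twophase(i2$beta, rule)
  expect_lt(max(abs(v22$total - v14$total)), 1e-12)
})

test_that("three-phase influences pass the weight-perturbation oracle", {
  fx <- make_cch_frame(n = 60, seed = 24, m_per_stratum = 16, miss_prob = 0.25)
  fr <- fx$frame
  req <- risk_request(0, 8, rbind(c(1, 0.5), c(-1, 0)))
  p3 <- phase3_weights(fr)
  ftp <- suppressWarnings(fit_threephase(fr, fx$weights, p3, req))
  infl <- influence_threephase(fr, fx$weights, p3, ftp$fit, req)

  # a phase-two subject with missing data still has a deviate (it enters
  # the missingness-weight estimating equation)
  iv0 <- which(fr$xi == 1 & fr$v == 0)
  expect_gt(max(abs(infl$beta$delta[iv0, ])), 0)

  subjects <- c(which(fr$xi * fr$v == 1), iv0)
  fd <- fd_deviates(refit_threephase(fr, fx$weights, req), nrow(fr), subjects)
  expect_fd_match(fd, deviate_rows(infl, subjects), tol = 1e-3)

  # variance is invariant to relabeling the phase-three strata
  rule <- pair_rule(fr, fx$weights)
  v_a <- variance_threephase(infl$beta, rule, p3)
  lab <- ifelse(is_case(fr), "zz_case", "aa_ctrl")
  p3b <- phase3_weights(fr, strata3 = lab)
  ftpb <- suppressWarnings(fit_threephase(fr, fx$weights, p3b, req))
  inflb <- influence_threephase(fr, fx$weights, p3b, ftpb$fit, req)
  v_b <- variance_threephase(inflb$beta, rule, p3b)
  expect_equal(v_a$total, v_b$total, tolerance = 1e-10)
})

test_that("undefined event times are dropped with a warning and counted", {
  # age scale: an early case with missing covariates fails while everyone
  # else is still left-truncated, so no phase-three subject is at risk
  set.seed(25)
  n <- 12
  d <- data.frame(subject_id = 1:n, stratum = "a",
                  entry_time = c(0, rep(2, n - 1)),
                  exit_time = c(1, seq(3, length.out = n - 1, by = 0.5)),
                  event = c(1, 1, 1, rep(0, n - 3)),
                  xi = c(1, 1, 1, 1, 1, 1, rep(0, n - 6)),
                  v = c(0, 1, 1, 1, 1, 1, rep(0, n - 6)),
                  x1 = rnorm(n))
  d$x1[d$xi * d$v == 0] <- NA
  fr <- cohort_frame(d, covars = "x1", timescale = "age")
  dw <- design_weights(fr, c(a = 4))
  p3 <- phase3_weights(fr)
  bad <- undefined_event_times(fr, dw, p3)
  expect_equal(bad, 1)
  expect_warning(ftp <- fit_threephase(fr, dw, p3), "dropped 1 event")
  expect_equal(length(ftp$fit$dropped_times), 1L)
  # without the drop flag the engine refuses
  expect_error(cch_fit(fr, dw$w2 * p3$w3, include = fr$xi * fr$v,
                       num_weights = rep(1, nrow(fr))), "undefined")
  # clean data: grid unchanged
  fx <- make_cch_frame(n = 50, seed = 25, m_per_stratum = 12)
  p3c <- phase3_weights(fx$frame)
  expect_length(undefined_event_times(fx$frame, fx$weights, p3c), 0)
})

test_that("MCAR missingness leaves the estimate unbiased (simulation)", {
  # small-cohort recovery check: 20% missing completely at random
  set.seed(26)
  reps <- 500
  n <- 400
  beta_true <- 0.5
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    x1 <- rnorm(n)
    Tfail <- rexp(n, 0.05 * exp(beta_true * x1))
    C <- rexp(n, 0.03)
    d <- data.frame(subject_id = 1:n, stratum = "a", entry_time = 0,
                    exit_time = pmin(Tfail, C, 12),
                    event = as.numeric(Tfail <= pmin(C, 12)),
                    xi = 0, v = 0, x1 = x1)
    d$xi[sample.int(n, 120)] <- 1
    d$xi[d$event == 1] <- 1
    d$v <- d$xi * rbinom(n, 1, 0.8)
    d$x1[d$xi * d$v == 0] <- NA
    fr <- cohort_frame(d, covars = "x1")
    dw <- design_weights(fr, c(a = 120))
    p3 <- phase3_weights(fr)
    est[r] <- tryCatch(
      suppressWarnings(fit_threephase(fr, dw, p3)$fit$beta),
      error = function(e) NA_real_)
  }
  est <- est[!is.na(est)]
  expect_gt(length(est), 0.95 * reps)
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - beta_true), 2 * mc_se + 0.01)
})
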