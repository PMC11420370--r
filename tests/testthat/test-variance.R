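test_that("pair rule matches exhaustive enumeration (n = 4, m = 2)", {
  # enumerate all C(4,2) = 6 equally likely subcohorts of non-cases
  combos <- combn(4, 2)
  inc <- matrix(0, 4, ncol(combos))
  for (s in seq_len(ncol(combos))) inc[combos[, s], s] <- 1
  p_joint <- mean(inc[1, ] * inc[2, ]) # any pair, by symmetry
  p_marg <- mean(inc[1, ])
  expect_equal(p_marg, 1 / 2)
  expect_equal(p_joint, 1 / 6)
  sigma_enum <- p_joint - p_marg^2
  expect_equal(sigma_enum, -1 / 12)

  d <- data.frame(subject_id = 1:5, stratum = "a", entry_time = 0,
                  exit_time = 1:5, event = c(1, 0, 0, 0, 0), xi = 1, v = 1,
                  x1 = rnorm(5))
  fr <- cohort_frame(d, covars = "x1")
  # stratum has n = 5 incl. one case; the enumeration concerns the 4
  # non-cases, so build a 4-subject non-case stratum instead
  d4 <- d[d$event == 0, ]
  d4$event[1] <- 1 # pair_rule needs a valid frame; use separate stratum
  d4$stratum <- "b"
  frab <- cohort_frame(rbind(d, d4), covars = "x1")
  dw <- design_weights(frab, c(a = 2, b = 2))
  rule <- pair_rule(frab, dw)
  a <- rule$strata[rule$strata$level == "a", ]
  expect_equal(a$n, 5)
  # for the pure 4-subject enumeration: n = 4, m = 2
  d_enum <- data.frame(subject_id = 1:4, stratum = "e", entry_time = 0,
                       exit_time = 1:4, event = 0, xi = c(1, 1, 0, 0), v = c(1, 1, 0, 0),
                       x1 = c(1, 2, NA, NA))
  # need >= 1 event elsewhere for fits, but pair_rule itself is data-free:
  d_enum$event[1] <- 1
  fr_e <- cohort_frame(d_enum, covars = "x1")
  rule_e <- pair_rule(fr_e, design_weights(fr_e, c(e = 2)))
  e <- rule_e$strata
  expect_equal(e$sigma_off, sigma_enum)
  expect_equal(e$w_pair, 4 * 3 / (2 * 1))
  expect_equal(e$sigma_diag, (2 / 4) * (1 - 2 / 4))

  # census: zero covariances, unit pair weights
  d_c <- d_enum
  fr_c <- cohort_frame(d_c, covars = "x1")
  rule_c <- pair_rule(fr_c, design_weights(fr_c, c(e = 4)))
  expect_equal(rule_c$strata$sigma_off, 0)
  expect_equal(rule_c$strata$sigma_diag, 0)
  expect_equal(rule_c$strata$w_pair, 1)

  # bernoulli: all off-diagonal covariances zero
  rule_b <- pair_rule(fr_c, design_weights(fr_c, c(e = 2), mode = "bernoulli"))
  expect_equal(rule_b$strata$sigma_off, 0)
  expect_gt(rule_b$strata$sigma_diag, 0)
})

test_that("variance identities hold to machine precision on random inputs", {
  for (seed in 1:4) {
    fx <- make_cch_frame(n = 50, seed = seed, m_per_stratum = 10)
    fr <- fx$frame
    rule <- pair_rule(fr, fx$weights)
    set.seed(seed + 100)
    d <- 3
    IF2 <- matrix(rnorm(nrow(fr) * d), ncol = d)
    IF2[fr$xi == 0, ] <- 0
    xw <- fr$xi * fx$weights$w2
    infl <- cchcox:::new_influence_set("test", IF2, delta = IF2 * xw)
    vr <- variance_twophase(infl, rule)
    expect_lt(max(abs(vr$robust - (vr$total + vr$difference))), 1e-12)
    expect_equal(vr$robust, variance_robust(infl), tolerance = 1e-14)
    # pair term equals the naive O(n^2) double loop exactly
    expect_lt(max(abs(vr$phase2_component -
                        naive_pair_term(IF2, fr, fx$weights, rule))), 1e-12)

    # calibrated identity with random phase-one parts
    IF1 <- matrix(rnorm(nrow(fr) * d), ncol = d) * 0.3
    inflc <- cchcox:::new_influence_set("test", IF2, if1 = IF1,
                                        delta = IF1 + IF2 * xw)
    vc <- variance_calibrated(inflc, rule)
    expect_lt(max(abs(vc$robust - (vc$total + vc$difference))), 1e-12)

    # IF1 = 0 collapses the calibrated estimator to the two-phase one
    infl0 <- cchcox:::new_influence_set("test", IF2, if1 = IF1 * 0,
                                        delta = IF2 * xw)
    v0 <- variance_calibrated(infl0, rule)
    expect_equal(v0$total, vr$total, tolerance = 1e-14)
    expect_equal(v0$robust, vr$robust, tolerance = 1e-14)
    expect_equal(v0$difference, vr$difference, tolerance = 1e-14)
  }
})

test_that("census sampling zeroes the phase-two component", {
  fr <- make_full_frame(n = 40, seed = 21)
  d <- as.data.frame(fr)
  d$stratum <- rep(c("a", "b"), 20)
  fr <- cohort_frame(d, covars = c("x1", "x2"))
  nj <- table(fr$stratum)
  dw <- design_weights(fr, c(a = nj[["a"]], b = nj[["b"]]))
  fit <- cch_fit(fr, dw)
  infl <- influence_two_phase(fr, dw, fit)
  rule <- pair_rule(fr, dw)
  vr <- variance_twophase(infl$beta, rule)
  expect_true(all(vr$phase2_component == 0))
  n <- nrow(fr)
  expect_equal(vr$total, n / (n - 1) * crossprod(infl$beta$if2),
               tolerance = 1e-14)
})

test_that("variance is invariant to subject order and stratum relabeling", {
  fx <- make_cch_frame(n = 60, seed = 22, m_per_stratum = 12)
  fr <- fx$frame
  fit <- cch_fit(fr, fx$weights)
  infl <- influence_two_phase(fr, fx$weights, fit)
  v1 <- variance_twophase(infl$beta, pair_rule(fr, fx$weights))

  perm <- sample(nrow(fr))
  d2 <- as.data.frame(fr)[perm, ]
  d2$stratum <- c(a = "zebra", b = "ant")[d2$stratum]
  fr2 <- cohort_frame(d2, covars = c("x1", "x2"), proxies = c("xt1", "xt2"))
  dw2 <- design_weights(fr2, c(zebra = 12, ant = 12))
  fit2 <- cch_fit(fr2, dw2)
  infl2 <- influence_two_phase(fr2, dw2, fit2)
  v2 <- variance_twophase(infl2$beta, pair_rule(fr2, dw2))
  expect_equal(v1$total, v2$total, tolerance = 1e-10)
  expect_equal(v1$robust, v2$robust, tolerance = 1e-10)
})

test_that("phase-two component tracks the conditional resampling variance", {
  # one fixed cohort; the empirical variance of beta-hat across repeated
  # subcohort draws is the phase-two (conditional) variance, which the
  # sigma-weighted term of the two-phase estimator targets
  set.seed(31)
  n <- 2000
  strat <- sample(c("a", "b"), n, TRUE)
  x1 <- rnorm(n); x2 <- rnorm(n)
  Tfail <- rexp(n, 0.004 * exp(0.4 * x1 + 0.3 * x2))
  C <- rexp(n, 0.01)
  d <- data.frame(subject_id = 1:n, stratum = strat, entry_time = 0,
                  exit_time = pmin(Tfail, C, 10),
                  event = as.numeric(Tfail <= pmin(C, 10)),
                  xi = 1, v = 1, x1 = x1, x2 = x2)
  fr <- cohort_frame(d, covars = c("x1", "x2"))
  m <- c(a = 150, b = 150)
  reps <- 1000
  est <- matrix(NA_real_, reps, 2)
  p2 <- matrix(0, 2, 2)
  set.seed(32)
  for (r in seq_len(reps)) {
    fs <- sample_design(fr, m)
    dw <- design_weights(fs, m)
    fit <- cch_fit(fs, dw)
    est[r, ] <- fit$beta
    infl <- influence_two_phase(fs, dw, fit)
    p2 <- p2 + variance_twophase(infl$beta, pair_rule(fs, dw))$phase2_component
  }
  p2 <- p2 / reps
  emp <- cov(est)
  expect_lt(max(abs(diag(p2) / diag(emp) - 1)), 0.10)
})

test_that("confidence intervals and the coverage band", {
  # zero variance: degenerate interval
  expect_equal(unname(confidence_interval(1.5, 0)), c(1.5, 1.5))
  expect_error(confidence_interval(1, -0.1), "non-positive")
  # 95% quantile against a high-precision value
  ci <- confidence_interval(0, 1, 0.95)
  expect_equal(unname(ci[2]), 1.959964, tolerance = 1e-6)
  # log-scale formula
  ci_log <- confidence_interval(0.1, 0.2^2, transform = "log")
  z <- qnorm(0.975)
  expect_equal(unname(ci_log),
               c(0.1 * exp(-z * 0.2), 0.1 * exp(z * 0.2)), tolerance = 1e-12)
  expect_equal(round(unname(coverage_band(0.95, 5000)), 4), c(0.9440, 0.9560))
})
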