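test_that("imputation: perfect proxy, OLS oracle, intercept-only", {
  fx <- make_cch_frame(n = 60, seed = 16, m_per_stratum = 15)
  fr <- fx$frame
  d <- as.data.frame(fr)

  # proxy equal to the covariate reproduces it exactly (R^2 = 1)
  d$perfect <- ifelse(is.na(d$x1), d$xt1, d$x1)
  d$perfect[fr$xi == 1] <- d$x1[fr$xi == 1]
  fr_p <- cohort_frame(d, covars = c("x1", "x2"),
                       proxies = c("xt1", "perfect"))
  # x2 has missing entries outside phase two, so impute it too
  imp <- impute_phase2(fr_p, fx$weights,
                       models = list(x1 = "perfect", x2 = "xt2"))
  expect_equal(imp[fr$xi == 1, "x1"], d$x1[fr$xi == 1], tolerance = 1e-10)
  expect_equal(attr(imp, "r2")[["x1"]], 1, tolerance = 1e-10)

  # equal weights reduce to OLS: check against the normal equations
  w1 <- fx$weights
  w1$w2 <- rep(1, nrow(fr))
  imp_ols <- impute_phase2(fr_p, w1, models = list(x1 = "xt1", x2 = "xt2"))
  rows <- which(fr$xi == 1)
  M <- cbind(1, d$xt1[rows])
  coef <- solve(crossprod(M), crossprod(M, d$x1[rows]))
  expect_equal(unname(imp_ols[, "x1"]),
               unname(drop(cbind(1, d$xt1) %*% coef)), tolerance = 1e-10)

  # intercept-only model imputes the weighted phase-two mean
  d$one <- 1
  fr_1 <- cohort_frame(d, covars = c("x1", "x2"),
                       proxies = c("xt1", "one"))
  imp_m <- impute_phase2(fr_1, fx$weights, models = list(x1 = "1", x2 = "1"))
  wmean <- sum((fx$weights$w2 * d$x1)[rows]) / sum(fx$weights$w2[rows])
  expect_equal(unname(imp_m[1, "x1"]), wmean, tolerance = 1e-10)

  # collinear predictors error
  d$xt1b <- d$xt1
  fr_c <- cohort_frame(d, covars = c("x1", "x2"),
                       proxies = c("xt1", "xt1b", "one"))
  expect_error(impute_phase2(fr_c, fx$weights,
                             models = list(x1 = c("xt1", "xt1b"), x2 = "1")),
               "collinear")
})

test_that("auxiliary matrix: block structure and trivial columns", {
  fx <- make_cch_frame(n = 80, seed = 17, m_per_stratum = 20)
  fr <- fx$frame
  req <- risk_request(2, 8, rbind(c(1, 0)))
  imp <- impute_phase2(fr, fx$weights, models = list(x1 = "xt1", x2 = "xt2"))
  aux <- build_auxiliary(fr, fx$weights, imp, req)
  expect_equal(ncol(aux), 2 + 1 + 1) # p influences + risk time + constant
  # the constant column sums to n; the influence columns sum to ~0
  expect_equal(sum(aux[, "const"]), nrow(fr))
  expect_lt(max(abs(colSums(aux[, 1:2]))), 1e-6)
  # no follow-up time in the interval -> zero auxiliary (ii)
  short <- fr$exit_time <= req$tau1
  expect_true(any(short))
  expect_true(all(aux[short, "risktime"] == 0))
})

test_that("raking: closed forms, fixed point, random-system solve", {
  fx <- make_cch_frame(n = 100, seed = 18, m_per_stratum = 25)
  fr <- fx$frame
  n <- nrow(fr)
  w <- fx$weights$w2

  # constant-1 auxiliary: eta = log(n / sum xi w), uniform rescale
  cal1 <- calibrate_weights(fr, fx$weights, matrix(1, n, 1))
  expect_equal(unname(cal1$eta), log(n / sum(fr$xi * w)), tolerance = 1e-10)
  expect_equal(sum(fr$xi * cal1$wstar), n, tolerance = 1e-8)

  # weights already satisfying the constraints are a fixed point: build an
  # auxiliary with sum xi w A = sum A by a one-dimensional adjustment
  set.seed(180)
  u <- rnorm(n); v <- rnorm(n)
  tt <- (sum(u) - sum(fr$xi * w * u)) / (sum(fr$xi * w * v) - sum(v))
  A_fix <- matrix(u + tt * v, n, 1)
  cal_fix <- calibrate_weights(fr, fx$weights, A_fix)
  expect_equal(unname(cal_fix$eta), 0, tolerance = 1e-10)
  expect_equal(cal_fix$wstar, w, tolerance = 1e-12)

  # random q = 3 system: constraints met to 1e-8
  set.seed(181)
  A <- cbind(1, matrix(rnorm(n * 2), n, 2))
  cal <- calibrate_weights(fr, fx$weights, A)
  expect_lt(max(abs(colSums(A * (fr$xi * cal$wstar)) - colSums(A))), 1e-8)
  expect_true(all(cal$wstar > 0))
})

test_that("calibrated estimation and influences pass the oracle", {
  fx <- make_cch_frame(n = 60, seed = 19, m_per_stratum = 14)
  fr <- fx$frame
  req <- risk_request(0, 8, rbind(c(1, 0.5), c(-1, 0)))
  imp <- impute_phase2(fr, fx$weights, models = list(x1 = "xt1", x2 = "xt2"))
  aux <- build_auxiliary(fr, fx$weights, imp, req)
  cal <- calibrate_weights(fr, fx$weights, aux)
  fitc <- fit_calibrated(fr, fx$weights, cal, req)
  infl <- influence_calibrated(fr, fx$weights, cal, fitc$fit, req)

  # score identity under calibrated weights: the plain weighted influences
  # evaluated at w* sum to zero, and so do the total deviates
  if_at_wstar <- if2_beta(fr, cal$wstar, fitc$fit)
  expect_lt(max(abs(colSums(if_at_wstar * (fr$xi * cal$wstar)))), 1e-8)
  expect_lt(max(abs(colSums(infl$beta$delta))), 1e-8)

  # residual property: weighted phase-two score influences are orthogonal
  # to every auxiliary column
  orth <- crossprod(infl$beta$if2 * (fr$xi * fx$weights$w2), aux)
  expect_lt(max(abs(orth)), 1e-6)

  # subjects outside phase two still influence the estimate through eta-hat
  out2 <- which(fr$xi == 0)
  expect_gt(max(abs(infl$beta$if1[out2, ])), 0)
  expect_true(all(infl$beta$if2[out2, ] == 0))

  # finite-difference oracle through the raking solve, all subjects
  subjects <- c(which(fr$xi == 1), out2[1:5])
  fd <- fd_deviates(refit_calibrated(fr, fx$weights, aux, req),
                    nrow(fr), subjects)
  expect_fd_match(fd, deviate_rows(infl, subjects), tol = 1e-3)
})

test_that("calibration against the constant only reproduces design estimates", {
  fx <- make_cch_frame(n = 80, seed = 20, m_per_stratum = 20)
  fr <- fx$frame
  n <- nrow(fr)
  # normalise the design weights so sum xi w = n already
  w_norm <- fx$weights
  w_norm$w2 <- fx$weights$w2 * n / sum(fr$xi * fx$weights$w2)
  cal <- calibrate_weights(fr, w_norm, matrix(1, n, 1))
  expect_equal(cal$wstar, w_norm$w2, tolerance = 1e-10)
  fit_d <- cch_fit(fr, w_norm)
  fit_c <- fit_calibrated(fr, w_norm, cal)$fit
  expect_equal(fit_c$beta, fit_d$beta, tolerance = 1e-9)
})
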