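# Synthetic cohort generator and design-comparison study runner.
#
# The generative model: three covariates X1 ~ N(0,1); X2 in {0,1,2} with
# probabilities that may depend on the sign of X1; X3 ~ N(a1 X1 + a2 X2, 1);
# sampling strata from the phase-one categorical
#   W = 0 I(X1>=0, X2=0) + 1 I(X1<0, X2<2) + 2 I(X1>=0, X2>0)
#     + 3 I(X1<0, X2=2);
# proxies Xt = X + N(0, sd^2) with sd = 0.75 giving corr(Xt, X) = 0.8;
# failure times from a Cox model with constant baseline hazard
#   lambda0 = pY / (E exp(beta'X) * 10)
# (10-year event probability approximately pY); uniform staggered entry on
# [0, 5]; exponential loss to follow-up with 2% pure risk at 10 years, i.e.
# rate -log(0.98)/10; observed time min(T, 10 - E, C) on the study scale.
#
# The subcohort allocation targets K sampled non-cases per expected case:
#   m_j = floor( r_j / (1 - r_j) * E(n_j) * K + 1/2 ),
# with r_j the expected 10-year failure fraction in stratum j. Normalising
# expectations are evaluated by Monte Carlo with a fixed internal seed.

.with_private_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.draw_covariates <- function(n, alpha, pX2) {
  x1 <- stats::rnorm(n)
  if (is.matrix(pX2)) { # rows: X1 < 0, X1 >= 0
    pr <- pX2[(x1 >= 0) + 1L, , drop = FALSE]
    u <- stats::runif(n)
    x2 <- (u > pr[, 1L]) + (u > pr[, 1L] + pr[, 2L])
  } else {
    x2 <- sample.int(3L, n, replace = TRUE,
                     prob = pX2) - 1L
  }
  x3 <- stats::rnorm(n, alpha[1L] * x1 + alpha[2L] * x2, 1)
  W <- ifelse(x1 >= 0 & x2 == 0, 0L,
              ifelse(x1 < 0 & x2 < 2, 1L,
                     ifelse(x1 >= 0 & x2 > 0, 2L, 3L)))
  list(x1 = x1, x2 = as.numeric(x2), x3 = x3, W = W)
}

#' Simulation scenario
#'
#' Fixes the generative parameters and precomputes, by Monte Carlo with a
#' fixed internal seed, the baseline hazard normalisation and the
#' per-stratum quantities used by the subcohort allocation rule.
#'
#' @param n cohort size
#' @param pY target 10-year event probability (0.02, 0.05 or 0.1)
#' @param K non-cases to sample per expected case (2 or 4)
#' @param alpha `(a1, a2)`, the X3 mean coefficients
#' @param beta true log-relative hazards `(b1, b2, b3)`
#' @param pX2 probabilities of X2 = 0, 1, 2; either a length-3 vector or a
#'   2-by-3 matrix with rows for X1 < 0 and X1 >= 0
#' @param proxy_sd proxy noise standard deviation (0.75 gives correlation
#'   0.8 with the true covariate)
#' @param tau1,tau2 risk projection interval
#' @param profiles covariate profiles for pure risk (matrix, one per row)
#' @param mc_draws Monte Carlo draws for the normalising expectations
#' @param mc_seed fixed internal seed for those draws
#' @return object of class `sim_scenario`
#' @export
sim_scenario <- function(n = 5000, pY = 0.02, K = 2,
                         alpha = c(0.5, 0.5), beta = c(0.3, 0.3, 0.3),
                         pX2 = c(1, 1, 1) / 3, proxy_sd = 0.75,
                         tau1 = 0, tau2 = 8,
                         profiles = rbind(c(-1, 1, -0.6), c(1, -1, 0.6),
                                          c(1, 1, 0.6)),
                         mc_draws = 1e6, mc_seed = 20240402L) {
  if (is.matrix(pX2)) {
    if (any(abs(rowSums(pX2) - 1) > 1e-12) || any(pX2 < 0)) {
      stop("invalid probability matrix pX2", call. = FALSE)
    }
  } else if (abs(sum(pX2) - 1) > 1e-12 || any(pX2 < 0)) {
    stop("invalid probability vector pX2", call. = FALSE)
  }
  mc <- .with_private_seed(mc_seed, {
    cv <- .draw_covariates(mc_draws, alpha, pX2)
    e <- exp(beta[1L] * cv$x1 + beta[2L] * cv$x2 + beta[3L] * cv$x3)
    list(Ee = mean(e),
         Ee_W = tapply(e, cv$W, mean),
         pW = as.numeric(table(factor(cv$W, 0:3))) / mc_draws)
  })
  lambda0 <- pY / (mc$Ee * 10)
  r_j <- lambda0 * 10 * mc$Ee_W
  structure(list(n = n, pY = pY, K = K, alpha = alpha, beta = beta,
                 pX2 = pX2, proxy_sd = proxy_sd,
                 tau1 = tau1, tau2 = tau2, profiles = profiles,
                 lambda0 = lambda0, Ee = mc$Ee, r_j = r_j, pW = mc$pW,
                 loss_rate = -log(0.98) / 10,
                 mc_draws = mc_draws, mc_seed = mc_seed),
            class = "sim_scenario")
}

#' Generate a synthetic cohort
#'
#' One cohort under the scenario's generative model, on the time-on-study
#' scale, with sampling strata defined by `W`, proxies `xt1` and `xt3`, and
#' all sampling indicators initialised to 1 (census); use [sample_design()]
#' to draw the case-cohort sample.
#'
#' @param scn a [sim_scenario()]
#' @param seed optional RNG seed
#' @return a [cohort_frame()] with covariates `x1`, `x2`, `x3` and proxies
#'   `xt1`, `xt3`, `W`
#' @export
generate_cohort <- function(scn, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- scn$n
  cv <- .draw_covariates(n, scn$alpha, scn$pX2)
  xt1 <- cv$x1 + stats::rnorm(n, 0, scn$proxy_sd)
  xt3 <- cv$x3 + stats::rnorm(n, 0, scn$proxy_sd)
  rate <- scn$lambda0 * exp(scn$beta[1L] * cv$x1 + scn$beta[2L] * cv$x2 +
                              scn$beta[3L] * cv$x3)
  Tfail <- stats::rexp(n, rate)
  E <- stats::runif(n, 0, 5)
  C <- stats::rexp(n, scn$loss_rate)
  cens <- pmin(10 - E, C)
  exit <- pmin(Tfail, cens)
  d <- data.frame(subject_id = seq_len(n), stratum = as.character(cv$W),
                  entry_time = 0, exit_time = exit,
                  event = as.numeric(Tfail <= cens), xi = 1, v = 1,
                  x1 = cv$x1, x2 = cv$x2, x3 = cv$x3,
                  xt1 = xt1, xt3 = xt3, W = as.character(cv$W),
                  stringsAsFactors = FALSE)
  cohort_frame(d, covars = c("x1", "x2", "x3"),
               proxies = c("xt1", "xt3", "W"))
}

#' Subcohort allocation rule
#'
#' `m_j = floor( r_j/(1 - r_j) * E(n_j) * K + 1/2 )`, where `r_j` is the
#' expected 10-year failure fraction in stratum `j` and `E(n_j)` its
#' expected size; both were evaluated by Monte Carlo when the scenario was
#' built.
#'
#' @param scn a [sim_scenario()]
#' @param K overrides the scenario's non-cases-per-case multiplier
#' @return named integer vector `m` per stratum (labels "0".."3")
#' @export
allocate_subcohort <- function(scn, K = scn$K) {
  if (any(scn$r_j >= 1)) stop("stratum failure fraction r_j >= 1", call. = FALSE)
  m <- floor(scn$r_j / (1 - scn$r_j) * (scn$n * scn$pW) * K + 0.5)
  stats::setNames(as.integer(m), names(scn$r_j))
}

#' Draw the phase-two sampling indicators
#'
#' Simple random samples without replacement of `m_j` subjects per stratum
#' (one stratum if `stratified = FALSE`), independent of case status, after
#' which all cases are added to the phase-two sample.
#'
#' @param frame a [cohort_frame()]
#' @param m per-stratum subcohort sizes (a single total if unstratified)
#' @param seed optional RNG seed
#' @param stratified draw within strata (default) or from the whole cohort
#' @return the frame with `xi` (and `v`) replaced by the drawn indicators
#' @export
sample_design <- function(frame, m, seed = NULL, stratified = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(frame)
  xi <- integer(n)
  if (stratified) {
    levels <- attr(frame, "stratum_levels")
    if (is.null(names(m))) names(m) <- levels
    for (s in levels) {
      idx <- which(frame$stratum == s)
      if (m[[s]] > length(idx)) {
        stop("m^(j) exceeds realised stratum size for stratum ", s,
             call. = FALSE)
      }
      xi[idx[sample.int(length(idx), m[[s]])]] <- 1L
    }
  } else {
    mt <- sum(m)
    if (mt > n) stop("m exceeds cohort size", call. = FALSE)
    xi[sample.int(n, mt)] <- 1L
  }
  xi[frame$event == 1] <- 1L
  out <- frame
  out$xi <- xi
  out$v <- xi
  out
}

# collapse to a single stratum (for the unstratified designs)
unstratify <- function(frame) {
  out <- frame
  out$stratum <- "all"
  attr(out, "stratum_levels") <- "all"
  out
}

# imputation models used by the calibrated methods in the study
.study_imputation <- list(x1 = c("xt1", "W"), x3 = c("xt1", "xt3"))

# analyse one sampled frame with design weights: estimates + variances for
# beta components and log pure risks
.analyse_design <- function(frame, m, request, mode = "without_replacement") {
  dw <- design_weights(frame, m, mode)
  fit <- cch_fit(frame, dw)
  infl <- influence_two_phase(frame, dw, fit, request)
  rule <- pair_rule(frame, dw)
  vb <- variance_twophase(infl$beta, rule)
  vl <- variance_twophase(infl$log_purerisk, rule)
  list(est = c(fit$beta, infl$log_purerisk$estimate),
       var = c(diag(vb$total), diag(vl$total)),
       var_robust = c(diag(vb$robust), diag(vl$robust)))
}

.analyse_calibrated <- function(frame, m, request,
                                mode = "without_replacement") {
  dw <- design_weights(frame, m, mode)
  imp <- impute_phase2(frame, dw, .study_imputation)
  aux <- build_auxiliary(frame, dw, imp, request)
  cal <- calibrate_weights(frame, dw, aux)
  fit <- fit_calibrated(frame, dw, cal, request)$fit
  infl <- influence_calibrated(frame, dw, cal, fit, request)
  rule <- pair_rule(frame, dw)
  vb <- variance_calibrated(infl$beta, rule)
  vl <- variance_calibrated(infl$log_purerisk, rule)
  list(est = c(fit$beta, infl$log_purerisk$estimate),
       var = c(diag(vb$total), diag(vl$total)),
       var_robust = c(diag(vb$robust), diag(vl$robust)))
}

.analyse_cohort <- function(frame, request) {
  n <- nrow(frame)
  ones <- rep(1, n)
  fit <- cch_fit(frame, ones, include = ones, weights_used = "unit")
  infl <- influence_two_phase(frame, ones, fit, request, include = ones)
  # census: phase-two variance is exactly zero; sandwich first block only
  vb <- n / (n - 1) * crossprod(infl$beta$if2)
  vl <- n / (n - 1) * crossprod(infl$log_purerisk$if2)
  list(est = c(fit$beta, infl$log_purerisk$estimate),
       var = c(diag(vb), diag(vl)),
       var_robust = c(diag(vb), diag(vl)))
}

#' True parameter values under a scenario
#'
#' The log-relative hazards and, for each profile, the true log pure risk in
#' the scenario's projection interval (the baseline hazard is constant, so
#' the cumulative baseline hazard is linear in time).
#'
#' @param scn a [sim_scenario()]
#' @return named numeric vector aligned with the study estimands
#' @export
sim_truth <- function(scn) {
  dL <- scn$lambda0 * (scn$tau2 - scn$tau1)
  logpi <- log(1 - exp(-exp(drop(scn$profiles %*% scn$beta)) * dL))
  c(stats::setNames(scn$beta, c("x1", "x2", "x3")),
    stats::setNames(logpi, paste0("logpi", seq_along(logpi))))
}

#' Run the design-comparison simulation study
#'
#' Repeatedly generates cohorts, draws the case-cohort samples and analyses
#' them with the requested methods, then tabulates, per method and estimand:
#' the mean of the design-based and robust variance estimates, the empirical
#' variance of the estimates, 95% confidence-interval coverage (normal
#' theory; log scale for pure risks) under both variance estimates, and the
#' ratio of the full-cohort empirical variance to the method's (a relative
#' efficiency). Replicate `r` uses seed `base_seed + r`; replicate-level
#' failures are excluded with a count.
#'
#' @param scn a [sim_scenario()]
#' @param reps number of replicates
#' @param methods subset of `c("SCC", "SCC.Calib", "USCC", "USCC.Calib",
#'   "Cohort")`
#' @param base_seed integer base seed
#' @param level confidence level
#' @return list with `metrics` (data.frame), `band` (coverage acceptance
#'   band), `m` (allocation used), `n_fail` per method, `truth`
#' @export
run_study <- function(scn, reps = 500,
                      methods = c("SCC", "SCC.Calib", "Cohort"),
                      base_seed = 1L, level = 0.95) {
  methods <- match.arg(methods,
                       c("SCC", "SCC.Calib", "USCC", "USCC.Calib", "Cohort"),
                       several.ok = TRUE)
  m <- allocate_subcohort(scn)
  request <- risk_request(scn$tau1, scn$tau2, scn$profiles)
  truth <- sim_truth(scn)
  d <- length(truth)
  res <- lapply(methods, function(x)
    list(est = matrix(NA_real_, reps, d), var = matrix(NA_real_, reps, d),
         var_robust = matrix(NA_real_, reps, d), fail = 0L))
  names(res) <- methods
  needs_u <- any(c("USCC", "USCC.Calib") %in% methods)
  for (r in seq_len(reps)) {
    set.seed(base_seed + r)
    cohort <- generate_cohort(scn)
    frame_s <- sample_design(cohort, m)
    if (needs_u) {
      frame_u <- sample_design(unstratify(cohort), sum(m), stratified = FALSE)
    }
    for (meth in methods) {
      ans <- tryCatch(switch(meth,
        Cohort = .analyse_cohort(cohort, request),
        SCC = .analyse_design(frame_s, m, request),
        SCC.Calib = .analyse_calibrated(frame_s, m, request),
        USCC = .analyse_design(frame_u, c(all = sum(m)), request),
        USCC.Calib = .analyse_calibrated(frame_u, c(all = sum(m)), request)),
        error = function(e) NULL)
      if (is.null(ans)) {
        res[[meth]]$fail <- res[[meth]]$fail + 1L
      } else {
        res[[meth]]$est[r, ] <- ans$est
        res[[meth]]$var[r, ] <- ans$var
        res[[meth]]$var_robust[r, ] <- ans$var_robust
      }
    }
  }
  z <- stats::qnorm((1 + level) / 2)
  rows <- list()
  emp_cohort <- if ("Cohort" %in% methods) {
    apply(res$Cohort$est, 2L, stats::var, na.rm = TRUE)
  } else rep(NA_real_, d)
  for (meth in methods) {
    ok <- stats::complete.cases(res[[meth]]$est)
    est <- res[[meth]]$est[ok, , drop = FALSE]
    va <- res[[meth]]$var[ok, , drop = FALSE]
    vr <- res[[meth]]$var_robust[ok, , drop = FALSE]
    cover <- function(v) {
      se <- sqrt(v)
      colMeans(abs(est - rep(truth, each = nrow(est))) <= z * se)
    }
    rows[[meth]] <- data.frame(
      method = meth, estimand = names(truth),
      mean_var = colMeans(va), mean_var_robust = colMeans(vr),
      emp_var = apply(est, 2L, stats::var),
      coverage = cover(va), coverage_robust = cover(vr),
      var_ratio_vs_cohort = emp_cohort / apply(est, 2L, stats::var),
      n_used = nrow(est), row.names = NULL)
  }
  list(metrics = do.call(rbind, rows),
       band = coverage_band(level, reps),
       m = m, truth = truth,
       n_fail = vapply(res, function(x) x$fail, integer(1L)))
}
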