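# Independent oracles used by the influence and variance tests.
#
# The generic weight-perturbation oracle scales one subject's "mass" in
# every sum that subject enters (risk sets, score, Breslow numerator,
# calibration constraints, missingness-weight counts), re-solves all
# estimated quantities and differentiates numerically. The resulting
# w * d(theta)/d(w) is the subject's total deviate, and is independent of
# the closed-form influence expressions it checks.

# estimands reported by all oracle refits: beta, interval cumulative
# baseline hazard, pure risks
.oracle_estimands <- function(fit, request) {
  c(fit$beta,
    Lambda = cumulative_baseline(fit, request$tau2) -
      cumulative_baseline(fit, request$tau1),
    purerisk = pure_risk(fit, request))
}

fd_deviates <- function(refit, n, subjects, h = 1e-5) {
  out <- NULL
  for (i in subjects) {
    mass <- rep(1, n)
    mass[i] <- 1 + h
    up <- refit(mass)
    mass[i] <- 1 - h
    dn <- refit(mass)
    out <- rbind(out, (up - dn) / (2 * h))
  }
  rownames(out) <- subjects
  out
}

refit_design <- function(frame, weights, request) {
  function(mass) {
    fit <- cch_fit(frame, weights, mass = mass)
    .oracle_estimands(fit, request)
  }
}

refit_calibrated <- function(frame, weights, aux, request) {
  w2 <- weights$w2
  function(mass) {
    cal <- calibrate_weights(frame, weights, aux, mass = mass)
    fit <- cch_fit(frame, cal$wstar, include = frame$xi,
                   num_weights = frame$xi * w2, mass = mass,
                   weights_used = "calibrated")
    .oracle_estimands(fit, request)
  }
}

refit_threephase <- function(frame, weights, request) {
  w2 <- weights$w2
  n <- nrow(frame)
  function(mass) {
    p3 <- phase3_weights(frame, mass = mass)
    fit <- suppressWarnings(
      cch_fit(frame, w2 * p3$w3, include = frame$xi * frame$v,
              num_weights = rep(1, n), mass = mass, drop_undefined = TRUE,
              weights_used = "phase3"))
    .oracle_estimands(fit, request)
  }
}

# stack the total deviates of an influence-set list in oracle order
deviate_rows <- function(infl, subjects) {
  cbind(infl$beta$delta[subjects, , drop = FALSE],
        infl$Lambda$delta[subjects, , drop = FALSE],
        infl$purerisk$delta[subjects, , drop = FALSE])
}

expect_fd_match <- function(fd, dev, tol = 1e-3) {
  expect_lt(max(abs(fd - dev) / (abs(dev) + 1e-4)), tol)
}

# naive O(n^2) double loop for the sigma-weighted pair term of the
# two-phase variance (the implementation uses rank-one updates)
naive_pair_term <- function(IF, frame, weights, rule) {
  n <- nrow(frame)
  d <- ncol(as.matrix(IF))
  IF <- as.matrix(IF)
  sidx <- stratum_index(frame)
  case <- frame$event == 1
  st <- rule$strata
  out <- matrix(0, d, d)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (sidx[i] != sidx[k] || frame$xi[i] == 0 || frame$xi[k] == 0) next
      if (case[i] || case[k]) next # sigma = 0 for pairs involving a case
      j <- sidx[i]
      if (i == k) {
        wik <- st$w[j]; sik <- st$sigma_diag[j]
      } else {
        wik <- st$w_pair[j]; sik <- st$sigma_off[j]
      }
      out <- out + wik * sik * weights$w2[i] * weights$w2[k] *
        tcrossprod(IF[i, ], IF[k, ])
    }
  }
  out
}

# weighted Breslow log partial likelihood (for the golden-section oracle)
log_partial_likelihood <- function(frame, weights, beta) {
  w <- frame$xi * cchcox:::combined_weights(weights, nrow(frame))
  X <- covariate_matrix(frame)
  lp <- drop(X %*% beta)
  val <- 0
  for (i in which(frame$event == 1)) {
    t <- frame$exit_time[i]
    at_risk <- frame$exit_time >= t & frame$xi == 1
    val <- val + w[i] * (lp[i] - log(sum(w[at_risk] * exp(lp[at_risk]))))
  }
  val
}
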