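# Missing phase-two covariates as a third sampling phase.
#
# Subjects with complete covariate data among the phase-two sample form the
# phase-three sample, with Bernoulli indicators V assumed mutually
# independent (missing at random). Missingness probabilities may differ
# across phase-three strata (default: case status), and the estimated weight
# in a stratum is the ratio of sampled to observed counts,
#   w3 = (# phase-two in stratum) / (# complete-data in stratum),
# the closed-form solution of the estimating equation
#   sum_i { xi_i B_i - exp(gamma'B_i) xi_i V_i B_i } = 0.
# Estimation substitutes xi V for xi and w2 * w3 for w in the weighted Cox
# machinery, keeping the unweighted Breslow numerator (event times are known
# cohort-wide); event times at which a case with missing covariates fails
# with no complete-data subject at risk are dropped with a warning.
#
# Total deviates are Delta = xi IF2 + xi V exp(gamma'B) IF3, where IF2
# (phase-two information, V-free) carries the own-event numerator terms and
# each phase-two subject's contribution to the estimated weights, and IF3
# needs complete covariate data.

#' Phase-three (missingness) weights
#'
#' Estimates per-stratum inverse missingness probabilities from observed
#' counts, or accepts known sampling probabilities.
#'
#' @param frame a [cohort_frame()] with `v` filled for the phase-two sample
#' @param strata3 per-subject phase-three stratum labels; default
#'   (`"case_status"`) stratifies on case status. Need not coincide with the
#'   phase-two strata.
#' @param known_probs optional per-subject known phase-three sampling
#'   probabilities; when given, weights are `1/probs` and no estimation
#'   variability is attributed to them.
#' @param mass internal per-subject multiplier (finite-difference oracle)
#' @return object of class `phase3_weights`: `gamma` (log weights per
#'   stratum), per-subject `w3`, `sigma3`, `strata3`, `v`, `known`, and the
#'   per-stratum phase-two mass `h3` (the estimating-equation Jacobian
#'   diagonal)
#' @export
phase3_weights <- function(frame, strata3 = "case_status",
                           known_probs = NULL, mass = NULL) {
  n <- nrow(frame)
  if (is.null(mass)) mass <- rep(1, n)
  if (identical(strata3, "case_status")) {
    strata3 <- ifelse(is_case(frame), "case", "noncase")
  }
  strata3 <- as.character(strata3)
  levels3 <- sort(unique(strata3))
  s3 <- match(strata3, levels3)
  xi <- frame$xi; v <- frame$v
  if (!is.null(known_probs)) {
    if (any(known_probs <= 0 | known_probs > 1)) {
      stop("known phase-three probabilities must lie in (0, 1]", call. = FALSE)
    }
    w3 <- 1 / known_probs
    return(structure(list(gamma = NULL, strata3 = strata3, w3 = w3,
                          sigma3 = (1 / w3) * (1 - 1 / w3), v = v,
                          known = TRUE, h3 = NULL, levels = levels3),
                     class = "phase3_weights"))
  }
  num <- as.numeric(tapply(mass * xi, factor(s3, seq_along(levels3)), sum,
                           default = 0))
  den <- as.numeric(tapply(mass * xi * v, factor(s3, seq_along(levels3)), sum,
                           default = 0))
  bad <- which(num > 0 & den == 0)
  if (length(bad) > 0L) {
    stop("phase-three stratum with phase-two members but no complete-data ",
         "subject: ", paste(levels3[bad], collapse = ", "), call. = FALSE)
  }
  w3s <- ifelse(num > 0, num / den, 1)
  w3 <- w3s[s3]
  structure(list(gamma = stats::setNames(log(w3s), levels3),
                 strata3 = strata3, w3 = w3,
                 sigma3 = (1 / w3) * (1 - 1 / w3), v = v,
                 known = FALSE, h3 = num, levels = levels3),
            class = "phase3_weights")
}

#' Event times with an empty complete-data risk set
#'
#' Times at which a case fails but no phase-three subject is at risk; the
#' Breslow estimate is undefined there and such times are dropped from all
#' integrals (recommended when they are few).
#'
#' @param frame a [cohort_frame()]
#' @param weights phase-two design weights
#' @param p3 a [phase3_weights()] object
#' @return numeric vector of undefined event times (possibly empty)
#' @export
undefined_event_times <- function(frame, weights, p3) {
  w <- combined_weights(weights, nrow(frame))
  b <- frame$xi * p3$v * w * p3$w3
  times <- sort(unique(frame$exit_time[is_case(frame)]))
  risk <- .grid_sums(frame$entry_time, frame$exit_time, times,
                     matrix(b, ncol = 1L),
                     attr(frame, "timescale") == "age")[, 1L]
  times[risk <= 0]
}

#' Three-phase estimation with estimated missingness weights
#'
#' Fits the weighted Cox score over the complete-data sample with combined
#' weights `w2 * w3`, keeping all cohort events in the Breslow numerator.
#'
#' @param frame a [cohort_frame()]
#' @param weights phase-two design weights
#' @param p3 a [phase3_weights()] object
#' @param request optional [risk_request()]
#' @return list with `fit` (a `cch_fit`; `fit$dropped_times` records ignored
#'   undefined event times) and optionally `pure_risk`
#' @export
fit_threephase <- function(frame, weights, p3, request = NULL) {
  n <- nrow(frame)
  w2 <- combined_weights(weights, n)
  fit <- cch_fit(frame, w2 * p3$w3, include = frame$xi * p3$v,
                 num_weights = rep(1, n), drop_undefined = TRUE,
                 weights_used = "phase3")
  out <- list(fit = fit)
  if (!is.null(request)) out$pure_risk <- pure_risk(fit, request)
  out
}

#' Influence sets under three-phase estimation
#'
#' Total deviates `Delta = xi IF2 + xi V w3 IF3`. `IF2` is phase-two
#' measurable and free of `V`; it collects the own-event Breslow numerator
#' terms and the contribution of each phase-two subject to the estimated
#' missingness weights (so a subject with `xi = 1, V = 0` still has a
#' non-zero deviate). `IF3` requires complete covariate data. With known
#' probabilities the weight-estimation terms are dropped.
#'
#' @param frame a [cohort_frame()]
#' @param weights phase-two design weights
#' @param p3 a [phase3_weights()] object
#' @param fit the three-phase [cch_fit()] from [fit_threephase()]
#' @param request a [risk_request()], or `NULL` for beta only
#' @return named list of `influence_set` objects
#' @export
influence_threephase <- function(frame, weights, p3, fit, request = NULL) {
  n <- nrow(frame)
  w2 <- combined_weights(weights, n)
  xi <- frame$xi; v <- p3$v
  include <- xi * v
  xvw3 <- xi * v * p3$w3
  core <- .influence_core(frame, include, w2 * p3$w3, fit)
  IFb_tilde <- core$IFb

  J3 <- length(p3$levels)
  s3 <- match(p3$strata3, p3$levels)
  B <- outer(s3, seq_len(J3), `==`) * 1

  estimated <- !p3$known
  if (estimated) {
    # D3 H3^{-1} B_i reduces to the per-stratum mean of u IFtilde
    D3b <- crossprod(B, IFb_tilde * xvw3 * w2) / p3$h3 # J3 x p
    gamma_b <- D3b[s3, , drop = FALSE]
  } else {
    gamma_b <- matrix(0, n, fit$p)
  }
  IF2b <- gamma_b * xi # V-free, phase-two members only
  IF3b <- (w2 * IFb_tilde - gamma_b) * include
  out <- list(beta = new_influence_set("beta", IF2b, if3 = IF3b,
                                       delta = IF2b * xi + IF3b * xvw3,
                                       estimate = fit$beta))
  if (is.null(request)) return(out)

  lp <- .lambda_pieces(core, request$tau1, request$tau2)
  coreL <- lp$phi + drop(IFb_tilde %*% lp$gbeta)
  if (estimated) {
    X <- covariate_matrix(frame); X[include == 0, ] <- 0
    rB <- (xvw3 * w2 * exp(drop(X %*% fit$beta))) * B
    SB1 <- .grid_sums(frame$entry_time, frame$exit_time, fit$event_times, rB,
                      fit$timescale == "age")
    dLdgam <- -colSums((fit$jumps * lp$inI / fit$s0) * SB1)
    # (gbeta' D3 + dL/dgamma') H3^{-1}, expanded per phase-three stratum
    ML_over_h3 <- drop(D3b %*% lp$gbeta) + dLdgam / p3$h3
    gamma_L <- ML_over_h3[s3]
  } else {
    gamma_L <- rep(0, n)
  }
  IF2L <- (lp$nu + gamma_L) * xi
  IF3L <- (w2 * coreL - gamma_L) * include
  dL <- .delta_lambda(fit, request$tau1, request$tau2)
  out$Lambda <- new_influence_set("Lambda", IF2L, if3 = IF3L,
                                  delta = IF2L * xi + IF3L * xvw3,
                                  estimate = dL)

  Gn <- nrow(request$profiles)
  IF2P <- matrix(0, n, Gn); IF3P <- matrix(0, n, Gn)
  IF2LP <- matrix(0, n, Gn); IF3LP <- matrix(0, n, Gn)
  est <- numeric(Gn)
  for (g in seq_len(Gn)) {
    gr <- .pure_risk_grad(fit$beta, dL, request$profiles[g, ])
    IF2P[, g] <- drop(IF2b %*% gr$gbeta) + gr$gL * IF2L
    IF3P[, g] <- drop(IF3b %*% gr$gbeta) + gr$gL * IF3L
    IF2LP[, g] <- IF2P[, g] / gr$pi
    IF3LP[, g] <- IF3P[, g] / gr$pi
    est[g] <- gr$pi
  }
  out$purerisk <- new_influence_set("purerisk", IF2P, if3 = IF3P,
                                    delta = IF2P * xi + IF3P * xvw3,
                                    estimate = est)
  out$log_purerisk <- new_influence_set("log_purerisk", IF2LP, if3 = IF3LP,
                                        delta = IF2LP * xi + IF3LP * xvw3,
                                        estimate = log(est))
  out
}
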