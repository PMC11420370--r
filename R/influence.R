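# Empirical influence functions (Taylor deviates) for the weighted Cox
# estimators.
#
# For subject i, the phase-two influence on beta-hat is
#   IF2(beta) = Jbar^{-1} int { X_i - S1/S0 } { dN_i - Y_i e^{beta'X_i}
#               dNbar(t) / S0(t) },
# with Jbar the weighted observed information and dNbar the (score-weighted)
# total event mass at t; for the baseline-hazard jump,
#   IF2(dL0(t)) = S0^{-1} { dN_i(t) - dL0(t) Y_i e^{beta'X_i} }
#               - S0^{-1} dL0(t) S1' IF2(beta);
# the interval cumulative hazard sums these over event times in (tau1, tau2],
# and the pure-risk influence follows by the chain rule through
# pi = 1 - exp{ -e^{beta'x} (L0(tau2) - L0(tau1)) }.
#
# The per-subject total deviate is Delta = xi w IF2 with design weights; the
# calibrated and three-phase modules reuse the "core" pieces computed here
# with their own weights and add the weight-estimation terms.

# Per-subject core pieces shared by all estimands.
# Returns the risk-window cumulative integrals needed by IF2(beta) and the
# at-risk parts of IF2 for cumulative hazards.
.influence_core <- function(frame, include, w, fit, mass = NULL) {
  n <- nrow(frame)
  if (is.null(mass)) mass <- rep(1, n)
  b <- include * w * mass
  X <- covariate_matrix(frame)
  X[include == 0, ] <- 0
  p <- fit$p
  times <- fit$event_times
  age_scale <- fit$timescale == "age"
  S0 <- fit$s0; Z <- fit$s1 / S0
  eb <- exp(drop(X %*% fit$beta))

  pos_exit <- findInterval(frame$exit_time, times)
  pos_entry <- if (age_scale) findInterval(frame$entry_time, times) else
    rep(0L, n)
  wsum <- function(percol) {
    # per-subject at-risk-window sums of a K x C matrix of grid increments
    cs <- rbind(0, apply(as.matrix(percol), 2L, cumsum))
    cs[pos_exit + 1L, , drop = FALSE] - cs[pos_entry + 1L, , drop = FALSE]
  }

  deS0 <- fit$de / S0
  C0 <- wsum(deS0)[, 1L]
  C1 <- wsum(Z * deS0)

  kpos <- match(frame$exit_time, times)
  on_grid_case <- frame$event == 1 & !is.na(kpos)

  # score-type residual: dN part + compensator part
  term <- -eb * (X * C0 - C1)
  sc <- which(on_grid_case & include == 1)
  term[sc, ] <- term[sc, , drop = FALSE] + X[sc, , drop = FALSE] -
    Z[kpos[sc], , drop = FALSE]
  term[include == 0, ] <- 0
  IFb <- t(solve(fit$info, t(term)))
  colnames(IFb) <- fit$covars

  list(IFb = IFb, eb = eb, wsum = wsum, kpos = kpos,
       on_grid_case = on_grid_case, include = include, S0 = S0, Z = Z,
       times = times, jumps = fit$jumps, p = p)
}

# At-risk ("phi") and own-event ("nu", per unit numerator weight) parts of
# the influence on the cumulative baseline hazard over (tau1, tau2], plus the
# beta-gradient. IF2(Lambda) = nu + phi + gbeta' IF2(beta).
.lambda_pieces <- function(core, tau1, tau2) {
  inI <- core$times > tau1 & core$times <= tau2
  jS0 <- ifelse(inI, core$jumps / core$S0, 0)
  phi <- -core$eb * core$wsum(jS0)[, 1L]
  phi[core$include == 0] <- 0
  nu <- numeric(length(core$eb))
  own <- which(core$on_grid_case)
  own <- own[inI[core$kpos[own]]]
  nu[own] <- 1 / core$S0[core$kpos[own]]
  gbeta <- -colSums((core$jumps * inI) * core$Z)
  list(phi = phi, nu = nu, gbeta = gbeta, inI = inI)
}

#' Phase-two influences on the log-relative hazard estimate
#'
#' Per-subject empirical influence vectors for `beta`; zero rows for subjects
#' outside the phase-two sample. The total deviate is `Delta = xi * w *
#' if2_beta(...)`, and the weighted influences sum to zero (the score
#' identity).
#'
#' @param frame a [cohort_frame()]
#' @param weights weights used in the fit (numeric or [design_weights()])
#' @param fit the corresponding [cch_fit()]
#' @param include 0/1 inclusion vector (default `frame$xi`)
#' @return n-by-p matrix of influences
#' @export
if2_beta <- function(frame, weights, fit, include = NULL) {
  n <- nrow(frame)
  w <- combined_weights(weights, n)
  if (is.null(include)) include <- frame$xi
  .influence_core(frame, include, w, fit)$IFb
}

#' Phase-two influences on a baseline-hazard jump
#'
#' @inheritParams if2_beta
#' @param t an observed event time on the fit's grid
#' @param if2b influence matrix from [if2_beta()] (recomputed if omitted)
#' @return n-vector of influences on `dLambda0(t)`
#' @export
if2_dlambda <- function(frame, weights, fit, t, if2b = NULL, include = NULL) {
  n <- nrow(frame)
  w <- combined_weights(weights, n)
  if (is.null(include)) include <- frame$xi
  k <- match(t, fit$event_times)
  if (is.na(k)) stop("t is not an event time on the fit grid", call. = FALSE)
  core <- .influence_core(frame, include, w, fit)
  if (is.null(if2b)) if2b <- core$IFb
  X <- covariate_matrix(frame); X[include == 0, ] <- 0
  atrisk <- frame$exit_time >= t &
    (fit$timescale != "age" | frame$entry_time < t)
  dN <- as.numeric(frame$event == 1 & frame$exit_time == t)
  val <- (dN - fit$jumps[k] * atrisk * core$eb * include) / fit$s0[k] -
    (fit$jumps[k] / fit$s0[k]) * drop(if2b %*% fit$s1[k, ])
  val[include == 0 & dN == 0] <- 0
  val
}

#' Phase-two influences on the cumulative baseline hazard over an interval
#'
#' Sums [if2_dlambda()] over the event times in `(tau1, tau2]` (exact
#' linearity), computed in closed form.
#'
#' @inheritParams if2_dlambda
#' @param tau1,tau2 interval endpoints
#' @return n-vector of influences on `Lambda0(tau2) - Lambda0(tau1)`
#' @export
if2_cumhaz <- function(frame, weights, fit, tau1, tau2, if2b = NULL,
                       include = NULL) {
  n <- nrow(frame)
  w <- combined_weights(weights, n)
  if (is.null(include)) include <- frame$xi
  core <- .influence_core(frame, include, w, fit)
  if (is.null(if2b)) if2b <- core$IFb
  lp <- .lambda_pieces(core, tau1, tau2)
  lp$nu + lp$phi + drop(if2b %*% lp$gbeta)
}

# gradient of pure risk in (beta, DeltaLambda); validated against numeric
# differentiation in the test suite
.pure_risk_grad <- function(beta, dL, x) {
  rr <- exp(sum(beta * x))
  pi_hat <- 1 - exp(-rr * dL)
  list(pi = pi_hat,
       gbeta = (1 - pi_hat) * rr * dL * x,
       gL = (1 - pi_hat) * rr)
}

#' Phase-two influences on covariate-specific pure risk
#'
#' Chain rule through the pure-risk formula; the log-scale variant divides by
#' the estimated risk (used for log-transformed confidence intervals).
#'
#' @inheritParams if2_cumhaz
#' @param request a [risk_request()]
#' @param if2L influence vector from [if2_cumhaz()] for the same interval
#' @param log_scale return influences on `log(pi)` instead of `pi`
#' @return n-by-(number of profiles) matrix
#' @export
if2_purerisk <- function(frame, weights, fit, request, if2b = NULL,
                         if2L = NULL, include = NULL, log_scale = FALSE) {
  n <- nrow(frame)
  w <- combined_weights(weights, n)
  if (is.null(include)) include <- frame$xi
  if (is.null(if2b)) if2b <- if2_beta(frame, w, fit, include)
  if (is.null(if2L)) {
    if2L <- if2_cumhaz(frame, w, fit, request$tau1, request$tau2, if2b, include)
  }
  dL <- .delta_lambda(fit, request$tau1, request$tau2)
  G <- ncol(request$profiles)
  out <- matrix(0, n, nrow(request$profiles))
  for (g in seq_len(nrow(request$profiles))) {
    x <- request$profiles[g, ]
    gr <- .pure_risk_grad(fit$beta, dL, x)
    v <- drop(if2b %*% gr$gbeta) + gr$gL * if2L
    if (log_scale) {
      if (gr$pi <= 0) {
        stop("log-scale influence undefined: estimated pure risk is 0",
             call. = FALSE)
      }
      v <- v / gr$pi
    }
    out[, g] <- v
  }
  out
}

# ---- influence-set container -------------------------------------------

new_influence_set <- function(estimand, if2, if1 = NULL, if3 = NULL,
                              delta, estimate = NULL) {
  if2 <- as.matrix(if2)
  structure(list(estimand = estimand, if1 = if1, if2 = if2, if3 = if3,
                 delta = as.matrix(delta), estimate = estimate),
            class = "influence_set")
}

#' @export
print.influence_set <- function(x, ...) {
  cat("influence_set:", x$estimand, "(", nrow(x$if2), "subjects x",
      ncol(x$if2), ")",
      if (!is.null(x$if1)) "with phase-one part" else "", "\n")
  invisible(x)
}

#' Influence sets for all estimands under design weights
#'
#' Convenience wrapper computing [if2_beta()], [if2_cumhaz()] and
#' [if2_purerisk()] (plain and log scale) in one pass and attaching the total
#' deviates `Delta = xi w IF2`.
#'
#' @inheritParams if2_beta
#' @param request a [risk_request()], or `NULL` for `beta` only
#' @return named list of `influence_set` objects: `beta`, and when a request
#'   is given `Lambda`, `purerisk`, `log_purerisk`
#' @export
influence_two_phase <- function(frame, weights, fit, request = NULL,
                                include = NULL) {
  n <- nrow(frame)
  w <- combined_weights(weights, n)
  if (is.null(include)) include <- frame$xi
  xw <- include * w
  core <- .influence_core(frame, include, w, fit)
  out <- list(beta = new_influence_set("beta", core$IFb,
                                       delta = core$IFb * xw,
                                       estimate = fit$beta))
  if (!is.null(request)) {
    lp <- .lambda_pieces(core, request$tau1, request$tau2)
    ifL <- lp$nu + lp$phi + drop(core$IFb %*% lp$gbeta)
    dL <- .delta_lambda(fit, request$tau1, request$tau2)
    out$Lambda <- new_influence_set("Lambda", ifL, delta = ifL * xw,
                                    estimate = dL)
    Gn <- nrow(request$profiles)
    ifP <- matrix(0, n, Gn); ifLP <- matrix(0, n, Gn)
    est <- numeric(Gn)
    for (g in seq_len(Gn)) {
      gr <- .pure_risk_grad(fit$beta, dL, request$profiles[g, ])
      v <- drop(core$IFb %*% gr$gbeta) + gr$gL * ifL
      ifP[, g] <- v
      ifLP[, g] <- if (gr$pi > 0) v / gr$pi else NA_real_
      est[g] <- gr$pi
    }
    out$purerisk <- new_influence_set("purerisk", ifP, delta = ifP * xw,
                                      estimate = est)
    out$log_purerisk <- new_influence_set("log_purerisk", ifLP,
                                          delta = ifLP * xw,
                                          estimate = log(est))
  }
  out
}

#' Export per-subject influences to delimited text
#'
#' Writes `subject_id`, `estimand`, component and value, one row per
#' subject-by-component, for audit.
#'
#' @param frame a [cohort_frame()]
#' @param infl a single `influence_set` or the list from
#'   [influence_two_phase()]
#' @param path output path (`.csv` or tab separated)
#' @export
write_influences <- function(frame, infl, path) {
  if (inherits(infl, "influence_set")) infl <- list(infl)
  rows <- do.call(rbind, lapply(infl, function(s) {
    d <- s$delta
    data.frame(subject_id = rep(frame$subject_id, ncol(d)),
               estimand = s$estimand,
               component = rep(seq_len(ncol(d)), each = nrow(d)),
               delta = as.vector(d))
  }))
  utils::write.table(rows, path, sep = .delim_for_path(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
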