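# Weighted Cox partial-likelihood engine.
#
# The estimating equation is the weighted score
#   U(beta) = sum_i b_i int { X_i - S1(t)/S0(t) } dN_i(t),
# with risk-set sums S_r(t) = sum_k b_k Y_k(t) exp(beta'X_k) {1, X, XX'} and
# per-subject weights b_k = include_k * w_k (design, calibrated or
# three-phase weights). The Breslow baseline-hazard jump at an event time is
# the (numerator-weighted) event mass divided by S0. The same engine serves
# the full-cohort fit (all weights 1, one stratum) used for calibration
# auxiliaries.

# Sums over risk sets at each grid time, exploiting sorted cumulative sums:
# at-risk at t means exit >= t (and, on the age scale, entry < t), so
#   sum_{i at risk} c_i = sum_{entry < t} c_i - sum_{exit < t} c_i
# (on the study scale the first term is the grand total).
.grid_sums <- function(entry, exit, times, contrib, age_scale) {
  contrib <- as.matrix(contrib)
  K <- length(times)
  oe <- order(exit)
  ce <- rbind(0, apply(contrib[oe, , drop = FALSE], 2L, cumsum))
  pos_exit <- findInterval(times, exit[oe], left.open = TRUE) # exits < t
  below_exit <- ce[pos_exit + 1L, , drop = FALSE]
  if (age_scale) {
    on <- order(entry)
    cn <- rbind(0, apply(contrib[on, , drop = FALSE], 2L, cumsum))
    pos_entry <- findInterval(times, entry[on], left.open = TRUE) # entries < t
    upper <- cn[pos_entry + 1L, , drop = FALSE]
  } else {
    upper <- matrix(rep(ce[nrow(ce), ], each = K), nrow = K)
  }
  upper - below_exit
}

# index pairs for the packed upper triangle of a p x p symmetric matrix
.tri_index <- function(p) {
  idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

.unpack_sym <- function(v, p, tri) {
  m <- matrix(0, p, p)
  m[tri] <- v
  m[tri[, c(2L, 1L), drop = FALSE]] <- v
  m
}

# All engine quantities at a fixed beta on the event-time grid.
# b: per-subject risk-set/score weights (include * weight * mass).
.engine_state <- function(entry, exit, times, X, b, beta, age_scale) {
  p <- ncol(X)
  eb <- exp(drop(X %*% beta))
  r <- b * eb
  tri <- .tri_index(p)
  prods <- X[, tri[, 1L], drop = FALSE] * X[, tri[, 2L], drop = FALSE]
  sums <- .grid_sums(entry, exit, times, cbind(r, r * X, r * prods), age_scale)
  list(S0 = sums[, 1L],
       S1 = sums[, 2L:(p + 1L), drop = FALSE],
       S2p = sums[, (p + 2L):(p + 1L + nrow(tri)), drop = FALSE],
       tri = tri, eb = eb, p = p)
}

#' Weighted risk-set sums at one time point
#'
#' Returns `S0`, `S1` and `S2`, the zeroth to second weighted moments of the
#' covariates over the risk set at time `t` for the supplied coefficient
#' vector: `S_r(t) = sum_i include_i w_i Y_i(t) exp(beta'X_i) {1, X_i,
#' X_i X_i'}`.
#'
#' @param frame a [cohort_frame()]
#' @param weights per-subject weights (numeric or [design_weights()])
#' @param include 0/1 inclusion indicators (defaults to `frame$xi`)
#' @param beta coefficient p-vector
#' @param t time point
#' @return list with scalar `s0`, p-vector `s1`, p-by-p matrix `s2`
#' @export
risk_set_sums <- function(frame, weights, include = NULL, beta, t) {
  n <- nrow(frame)
  w <- combined_weights(weights, n)
  if (is.null(include)) include <- frame$xi
  X <- covariate_matrix(frame)
  act <- include == 1
  if (anyNA(X[act, , drop = FALSE])) {
    stop("missing covariate for an included subject", call. = FALSE)
  }
  X[!act, ] <- 0 # unused rows; avoid NA propagation
  st <- .engine_state(frame$entry_time, frame$exit_time, t, X,
                      include * w, beta,
                      attr(frame, "timescale") == "age")
  list(s0 = unname(st$S0[1L]), s1 = unname(drop(st$S1[1L, ])),
       s2 = .unpack_sym(st$S2p[1L, ], st$p, st$tri))
}

#' Fit the weighted Cox score equation
#'
#' Newton-Raphson with step-halving on the weighted partial-likelihood score.
#' Tied event times are aggregated on a shared grid (Breslow convention).
#' The Breslow numerator (event mass) is weighted by `num_weights`, which
#' defaults to `include * weights`; under the standard design every case has
#' `xi w = 1` so this equals the plain event count.
#'
#' @param frame a [cohort_frame()]
#' @param weights per-subject weights used in the risk-set sums and score
#'   (numeric vector or [design_weights()])
#' @param include 0/1 vector; a subject enters risk sets and the score only
#'   if `include = 1` (defaults to `frame$xi`)
#' @param num_weights per-subject weights for the Breslow numerator; default
#'   `include * weights`. Pass 1 for all cases to keep an unweighted
#'   numerator (three-phase analysis).
#' @param init starting value (default 0)
#' @param tol convergence tolerance on the max-norm of the score
#' @param max_iter maximum Newton iterations
#' @param mass internal per-subject multiplier applied to every sum the
#'   subject enters; used by the finite-difference influence oracle. Default 1.
#' @param drop_undefined drop event times at which no included subject is at
#'   risk (cases with missing covariates); otherwise such times are an error.
#' @param beta_bound divergence guard: an iterate with `max |beta| >
#'   beta_bound` aborts with a monotone-likelihood error.
#' @param weights_used tag recorded on the fit (`"design"`, `"calibrated"`,
#'   `"phase3"`, `"unit"`).
#' @return object of class `cch_fit`
#' @export
cch_fit <- function(frame, weights, include = NULL, num_weights = NULL,
                    init = NULL, tol = 1e-8, max_iter = 25L, mass = NULL,
                    drop_undefined = FALSE, beta_bound = 30,
                    weights_used = "design") {
  n <- nrow(frame)
  w <- combined_weights(weights, n)
  if (is.null(include)) include <- frame$xi
  if (is.null(mass)) mass <- rep(1, n)
  X <- covariate_matrix(frame)
  covars <- attr(frame, "covars")
  p <- ncol(X)
  age_scale <- attr(frame, "timescale") == "age"
  b <- include * w * mass
  if (anyNA(X[b != 0, , drop = FALSE])) {
    stop("missing covariate for an included subject", call. = FALSE)
  }
  X[include == 0, ] <- 0
  if (is.null(num_weights)) num_weights <- include * w
  vnum <- num_weights * mass

  case <- frame$event == 1
  if (!any(case)) stop("no events: at least one event is required", call. = FALSE)
  times <- sort(unique(frame$exit_time[case]))

  # event masses per grid time: numerator mass dn (Breslow) and score-side
  # event mass de (weighted dNbar in the information and influence integrals)
  tf <- factor(frame$exit_time[case], levels = times)
  dn <- as.numeric(tapply(vnum[case], tf, sum, default = 0))
  de <- as.numeric(tapply(b[case], tf, sum, default = 0))

  # at-risk inclusion mass (beta-free) to detect undefined Breslow times
  risk_mass <- .grid_sums(frame$entry_time, frame$exit_time, times,
                          matrix(b, ncol = 1L), age_scale)[, 1L]
  dropped <- times[risk_mass <= 0]
  if (length(dropped) > 0L) {
    if (!drop_undefined) {
      stop("event time(s) with an empty weighted risk set (", length(dropped),
           "); the Breslow estimate is undefined there. ",
           "Use drop_undefined = TRUE to ignore them.", call. = FALSE)
    }
    warning(sprintf("dropped %d event time(s) with empty phase-three risk set",
                    length(dropped)), call. = FALSE)
    keep <- risk_mass > 0
    times <- times[keep]; dn <- dn[keep]; de <- de[keep]
    if (length(times) == 0L) stop("no usable event times left", call. = FALSE)
  }
  K <- length(times)

  # per-case grid position (NA if the case's time was dropped)
  kpos <- match(frame$exit_time, times)
  kpos[!case] <- NA_integer_

  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)
  score_at <- function(st) {
    Z <- st$S1 / st$S0
    sc_case <- which(case & include == 1 & !is.na(kpos))
    U <- colSums(b[sc_case] * (X[sc_case, , drop = FALSE] -
                                 Z[kpos[sc_case], , drop = FALSE]))
    J <- matrix(0, p, p)
    for (k in seq_len(K)) {
      if (de[k] == 0) next
      J <- J + de[k] * (.unpack_sym(st$S2p[k, ], p, st$tri) / st$S0[k] -
                          tcrossprod(Z[k, ]))
    }
    list(U = U, J = J, Z = Z)
  }

  st <- .engine_state(frame$entry_time, frame$exit_time, times, X, b, beta, age_scale)
  if (any(st$S0 <= 0)) stop("empty weighted risk set at an event time", call. = FALSE)
  sc <- score_at(st)
  unorm <- max(abs(sc$U))
  iter <- 0L
  while (unorm > tol && iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(sc$J, sc$U), error = function(e) NULL)
    if (is.null(step)) .stop_singular(sc$J, covars)
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      if (max(abs(cand)) > beta_bound) {
        stop("divergent estimate (monotone likelihood?): |beta| exceeded ",
             beta_bound, call. = FALSE)
      }
      st2 <- .engine_state(frame$entry_time, frame$exit_time, times, X, b,
                           cand, age_scale)
      sc2 <- score_at(st2)
      if (max(abs(sc2$U)) <= unorm || lambda < 1 / 1024) break
      lambda <- lambda / 2
    }
    beta <- cand; st <- st2; sc <- sc2
    unorm <- max(abs(sc$U))
  }
  if (unorm > tol) {
    stop(sprintf("no convergence after %d iterations (|U| = %.3g); last beta: %s",
                 iter, unorm, paste(signif(beta, 6), collapse = ", ")),
         call. = FALSE)
  }
  if (!isTRUE(all(is.finite(sc$J))) || any(diag(sc$J) <= 0) ||
      inherits(tryCatch(chol(sc$J), error = identity), "error")) {
    .stop_singular(sc$J, covars)
  }

  structure(list(beta = stats::setNames(beta, covars),
                 event_times = times,
                 jumps = dn / st$S0,
                 dn = dn, de = de,
                 s0 = st$S0, s1 = st$S1, s2p = st$S2p, tri = st$tri,
                 info = sc$J,
                 score_norm = unorm, iterations = iter,
                 p = p, covars = covars,
                 dropped_times = dropped,
                 timescale = attr(frame, "timescale"),
                 weights_used = weights_used),
            class = "cch_fit")
}

.stop_singular <- function(J, covars) {
  qrj <- qr(J)
  bad <- if (qrj$rank < ncol(J)) {
    covars[qrj$pivot[(qrj$rank + 1L):ncol(J)]]
  } else covars
  stop("singular information matrix; collinear or constant column(s): ",
       paste(bad, collapse = ", "), call. = FALSE)
}

#' @export
print.cch_fit <- function(x, ...) {
  cat("cch_fit (", x$weights_used, " weights): ", length(x$event_times),
      " event times, ", x$iterations, " iterations, |U| = ",
      signif(x$score_norm, 3), "\n", sep = "")
  print(x$beta)
  invisible(x)
}

#' Cumulative baseline hazard
#'
#' Right-continuous step function summing the Breslow jumps at event times
#' `<= t`.
#'
#' @param fit a [cch_fit()]
#' @param t time (may be a vector; `Inf` gives the total mass)
#' @return numeric vector of `Lambda0(t)`
#' @export
cumulative_baseline <- function(fit, t) {
  cs <- c(0, cumsum(fit$jumps))
  cs[findInterval(t, fit$event_times) + 1L]
}

.delta_lambda <- function(fit, tau1, tau2) {
  sum(fit$jumps[fit$event_times > tau1 & fit$event_times <= tau2])
}

#' Covariate-specific pure risk
#'
#' `pi(tau1, tau2; x) = 1 - exp{ -exp(beta'x) (Lambda0(tau2) -
#' Lambda0(tau1)) }`, the absolute probability of the event in the half-open
#' interval `(tau1, tau2]` for profile `x` in the absence of competing
#' censoring.
#'
#' @param fit a [cch_fit()]
#' @param request a [risk_request()] (or `tau1`/`tau2`/`profiles` given
#'   separately)
#' @param tau1,tau2,profiles used when `request` is missing
#' @return numeric vector, one pure risk per profile
#' @export
pure_risk <- function(fit, request = NULL, tau1 = NULL, tau2 = NULL,
                      profiles = NULL) {
  if (is.null(request)) request <- risk_request(tau1, tau2, profiles)
  dL <- .delta_lambda(fit, request$tau1, request$tau2)
  rr <- exp(drop(request$profiles %*% fit$beta))
  unname(1 - exp(-rr * dL))
}
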