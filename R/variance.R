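# Design-based variance estimation from influence deviates.
#
# The variance of an estimate theta-hat is estimated from the per-subject
# deviates Delta via var(sum Delta). Conditional on the cohort, the phase-two
# sampling indicators have known joint moments, giving the two-phase
# estimator
#   n/(n-1) sum xi w IF2 IF2' +
#   sum_j sum_{i,k} w_pair sigma_{ik} w_i w_k xi_i xi_k IF2_i IF2_k',
# the robust estimator sum Delta Delta', and their difference. The
# calibrated and three-phase estimators extend the same decomposition with
# the phase-one (calibration) and phase-three (missingness) influence parts.
#
# The pairwise sigma and joint-weight constants are shared by all non-case
# pairs within a stratum, so the double sum reduces to rank-one updates on
# group sums; exact equality with the naive double loop is part of the test
# contract.

#' Joint sampling weights and indicator covariances per stratum
#'
#' For without-replacement sampling of `m` from `n` per stratum:
#' non-case pairs have joint weight `n(n-1)/(m(m-1))` and indicator
#' covariance `(m/n)((m-1)/(n-1)) - (m/n)^2`; any pair involving a case has
#' zero covariance; the non-case diagonal variance is `(m/n)(1 - m/n)`.
#' Bernoulli sampling zeroes all off-diagonal covariances.
#'
#' @param frame a [cohort_frame()]
#' @param weights a [design_weights()] object (carries `m`, `n`, `mode`)
#' @return object of class `pair_rule` with the per-stratum constants and the
#'   per-subject vectors needed by the variance estimators
#' @export
pair_rule <- function(frame, weights) {
  if (!inherits(weights, "design_weights")) {
    stop("pair_rule needs a design_weights object", call. = FALSE)
  }
  m <- weights$m; nj <- weights$n
  if (weights$mode == "without_replacement" && any(m <= 1)) {
    stop("m^(j) = 1: pairwise weight undefined under without-replacement ",
         "sampling", call. = FALSE)
  }
  f <- m / nj
  if (weights$mode == "without_replacement") {
    w_pair <- nj * (nj - 1) / (m * (m - 1))
    sigma_off <- f * (m - 1) / (nj - 1) - f^2
  } else {
    w_pair <- (nj / m)^2
    sigma_off <- rep(0, length(m))
  }
  structure(list(
    strata = data.frame(level = names(m), n = unname(nj), m = unname(m),
                        w = unname(nj / m), w_pair = unname(w_pair),
                        sigma_off = unname(sigma_off),
                        sigma_diag = unname(f * (1 - f))),
    mode = weights$mode,
    stratum_idx = stratum_index(frame),
    case = is_case(frame),
    xi = frame$xi,
    w2 = weights$w2,
    n_total = nrow(frame)), class = "pair_rule")
}

.sym <- function(A) A + t(A)

# sum_i v_i M_i M_i'  (rows of M, weights v)
.wcross <- function(M, v) crossprod(M, M * v)
.wcross2 <- function(M, N, v) crossprod(M, N * v)

# sigma-weighted double sum over sampled non-case pairs (and optionally the
# diagonal) within each stratum, applied to per-subject rows G (already
# carrying any xi V w factors): returns
#   sum_j [ include_diag * w_diag sigma_diag w^2 sum_i G_i G_i'
#           + w_pair sigma_off w^2 (S S' - sum_i G_i G_i') ]
# `marg` supplies the per-pair marginal factor w_i w_k (w^2 for design-weight
# formulas, 1 for the three-phase block where weights are inside G).
.pair_double_sum <- function(G, rule, include_diag = TRUE, use_marginal = TRUE) {
  d <- ncol(G)
  out <- matrix(0, d, d)
  st <- rule$strata
  for (j in seq_len(nrow(st))) {
    nc <- which(!rule$case & rule$xi == 1 & rule$stratum_idx == j)
    if (length(nc) == 0L) next
    M <- G[nc, , drop = FALSE]
    SS <- crossprod(M)
    S <- colSums(M)
    marg <- if (use_marginal) st$w[j]^2 else 1
    off <- st$w_pair[j] * st$sigma_off[j] * marg * (tcrossprod(S) - SS)
    dia <- if (include_diag) st$w[j] * st$sigma_diag[j] * marg * SS else 0
    out <- out + off + dia
  }
  out
}

new_variance_report <- function(total, robust, phase1, phase2, difference,
                                method, estimate = NULL, extra = list()) {
  structure(c(list(total = total, robust = robust,
                   phase1_component = phase1, phase2_component = phase2,
                   difference = difference, method = method,
                   estimate = estimate), extra),
            class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat("variance_report [", x$method, "]\n", sep = "")
  cat("  total SE:", paste(signif(sqrt(diag(as.matrix(x$total))), 4),
                           collapse = ", "), "\n")
  cat("  robust SE:", paste(signif(sqrt(diag(as.matrix(x$robust))), 4),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Two-phase variance estimator for a case-cohort estimate
#'
#' The first ("superpopulation") block is `n/(n-1)` times the weighted sum of
#' squared phase-two influences; the second block weights products of
#' influences by the joint inclusion weights and indicator covariances, to
#' which only sampled non-cases contribute. Also reports the robust
#' (sum-of-squared-deviates) estimator and the difference diagnostic
#' (`robust - total`, an exact algebraic identity).
#'
#' @param infl an `influence_set` (see [influence_two_phase()])
#' @param rule a [pair_rule()]
#' @return a `variance_report` with `total`, `robust`, `phase1_component`,
#'   `phase2_component` and `difference`
#' @export
variance_twophase <- function(infl, rule) {
  IF2 <- infl$if2
  n <- rule$n_total
  if (nrow(IF2) != n) stop("shape mismatch between influences and rule",
                           call. = FALSE)
  xw <- rule$xi * rule$w2
  first <- n / (n - 1) * .wcross(IF2, xw)
  second <- .pair_double_sum(IF2, rule)
  total <- first + second
  robust <- .wcross(IF2, xw * rule$w2)
  diff <- -(1 / (n - 1) * .wcross(IF2, xw) +
              .pair_double_sum(IF2, rule, include_diag = FALSE))
  new_variance_report(total, robust, first, second, diff,
                      method = "twophase", estimate = infl$estimate)
}

#' Robust (sum of squared deviates) variance estimator
#'
#' `sum_i Delta_i Delta_i'`; valid under with-replacement sampling, upward
#' biased under stratified without-replacement sampling.
#'
#' @param infl an `influence_set`
#' @return matrix estimate
#' @export
variance_robust <- function(infl) crossprod(infl$delta)

#' Calibrated-weight variance estimator
#'
#' Extends the two-phase estimator with the phase-one calibration influences:
#' the superpopulation block sums `IF1 IF1' + 2 xi w IF1 IF2' + xi w IF2
#' IF2'`; the pair block involves the phase-two parts only. The robust
#' estimator is the sum of squared total deviates `Delta = IF1 + xi w IF2`,
#' and the difference diagnostic again satisfies `robust = total +
#' difference` exactly. With `IF1 = 0` everything reduces to
#' [variance_twophase()].
#'
#' @param infl an `influence_set` carrying `if1` and `if2`
#' @param rule a [pair_rule()]
#' @return a `variance_report`
#' @export
variance_calibrated <- function(infl, rule) {
  IF1 <- if (is.null(infl$if1)) 0 * infl$if2 else infl$if1
  IF2 <- infl$if2
  n <- rule$n_total
  xw <- rule$xi * rule$w2
  bracket <- function(v1, v12) {
    .wcross(IF1, v1) + .sym(.wcross2(IF1, IF2, v12)) + .wcross(IF2, v12)
  }
  first <- n / (n - 1) * bracket(rep(1, n), xw)
  second <- .pair_double_sum(IF2, rule)
  total <- first + second
  robust <- crossprod(IF1 + IF2 * xw)
  diff <- -(1 / (n - 1) * bracket(rep(1, n), xw) +
              .pair_double_sum(IF2, rule, include_diag = FALSE))
  new_variance_report(total, robust, first, second, diff,
                      method = "calibrated", estimate = infl$estimate)
}

#' Three-phase variance estimator with estimated missingness weights
#'
#' Four-block estimator for the inverse-probability-weighted analysis of
#' missing phase-two covariates: a superpopulation block with `1/w2`
#' factors, a diagonal phase-two block, an off-diagonal phase-two pair
#' block, and a phase-three block weighted by the estimated missingness
#' indicator variances. With no missingness (`V = 1`) it collapses exactly
#' to [variance_twophase()].
#'
#' @param infl an `influence_set` with `if2` and `if3` (see
#'   [influence_threephase()])
#' @param rule the phase-two [pair_rule()]
#' @param p3 a [phase3_weights()] object
#' @return a `variance_report`
#' @export
variance_threephase <- function(infl, rule, p3) {
  IF2 <- infl$if2; IF3 <- infl$if3
  n <- rule$n_total
  xi <- rule$xi
  xvw3 <- xi * p3$v * p3$w3
  sig2 <- ifelse(rule$case, 0, rule$strata$sigma_diag[rule$stratum_idx])
  bracket <- function(v) {
    .wcross(IF2, v * xi) + .sym(.wcross2(IF2, IF3, v * xvw3)) +
      .wcross(IF3, v * xvw3)
  }
  block1 <- n / (n - 1) * bracket(1 / rule$w2)
  block2 <- bracket(sig2 * rule$w2)
  G <- IF2 * xi + IF3 * xvw3
  block3 <- .pair_double_sum(G, rule, include_diag = FALSE,
                             use_marginal = FALSE)
  block4 <- .wcross(IF3, xvw3 * p3$sigma3 * p3$w3^2)
  total <- block1 + block2 + block3 + block4
  robust <- crossprod(G)
  new_variance_report(total, robust,
                      phase1 = block1, phase2 = block2 + block3,
                      difference = robust - total,
                      method = "threephase", estimate = infl$estimate,
                      extra = list(phase3_component = block4))
}

#' Normal-theory confidence interval
#'
#' `estimate +/- z * sqrt(variance)` on the chosen scale. With `transform =
#' "log"` the estimate is a (pure) risk, `variance` is the variance of its
#' logarithm, and the interval is formed on the log scale and exponentiated.
#'
#' @param estimate point estimate (scalar)
#' @param variance variance of the estimate (or of its log, see above)
#' @param level confidence level (default 0.95)
#' @param transform `"identity"` or `"log"`
#' @return numeric vector `c(lower, upper)`
#' @export
confidence_interval <- function(estimate, variance, level = 0.95,
                                transform = c("identity", "log")) {
  transform <- match.arg(transform)
  if (variance < 0) stop("non-positive variance", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  se <- sqrt(variance)
  if (transform == "identity") {
    c(lower = estimate - z * se, upper = estimate + z * se)
  } else {
    c(lower = estimate * exp(-z * se), upper = estimate * exp(z * se))
  }
}

#' Binomial acceptance band for empirical coverage
#'
#' The interval `level +/- z sqrt(level (1 - level) / reps)` within which the
#' empirical coverage of nominal `level` confidence intervals over `reps`
#' independent replicates is expected to fall.
#'
#' @param level nominal coverage
#' @param reps number of simulation replicates
#' @return numeric vector `c(lower, upper)`
#' @export
coverage_band <- function(level = 0.95, reps) {
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(level * (1 - level) / reps)
  c(lower = level - half, upper = level + half)
}
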