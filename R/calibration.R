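# Survey weight calibration (raking) for case-cohort estimation.
#
# Calibrated weights w* = w exp(eta'A) multiplicatively perturb the design
# weights so that phase-two weighted totals of q auxiliary variables A match
# their cohort totals:
#   sum_i { xi_i w_i exp(eta'A_i) A_i - A_i } = 0.
# Good auxiliaries are cohort-wide variables highly correlated with the
# influences of the target estimator; here they are built from covariates
# imputed by weighted regression on phase-one proxies:
#   (i)  the influences on beta from a full-cohort Cox fit on the imputed
#        covariates,
#   (ii) follow-up time in the risk-projection interval times the imputed
#        relative hazard, with beta estimated from the case-cohort fit using
#        weights calibrated against (i) + (iii), and
#   (iii) the constant 1.
#
# Total deviates under calibration are Delta = IF1 + xi w IF2, where IF1
# (phase-one information only) carries each cohort member's influence on
# eta-hat, and xi w* IF2 are, for the phase-two score part, weighted
# residuals of the fixed-weight influences regressed on the auxiliaries.

#' Impute phase-two covariates from phase-one data
#'
#' Weighted least-squares regressions within the phase-two sample (design
#' weights), with fitted values produced for every cohort member, including
#' those with measured phase-two covariates. Covariates without an imputation
#' model must be observed cohort-wide and are passed through.
#'
#' @param frame a [cohort_frame()]
#' @param weights phase-two design weights
#' @param models named list: covariate name -> character vector of predictor
#'   columns (phase-one variables; character columns enter as factors).
#' @param mass internal per-subject multiplier (finite-difference oracle).
#' @return n-by-p matrix: the covariate matrix with modelled columns replaced
#'   by their imputed values everywhere. Attribute `"r2"` records weighted
#'   in-sample R-squared per modelled column.
#' @export
impute_phase2 <- function(frame, weights, models, mass = NULL) {
  n <- nrow(frame)
  w <- combined_weights(weights, n)
  if (is.null(mass)) mass <- rep(1, n)
  X <- covariate_matrix(frame)
  covars <- attr(frame, "covars")
  bad <- setdiff(names(models), covars)
  if (length(bad) > 0L) {
    stop("config error: imputation model for unknown covariate(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  plain <- setdiff(covars, names(models))
  if (length(plain) > 0L && anyNA(X[, plain])) {
    stop("covariate(s) without an imputation model must be observed ",
         "cohort-wide: ", paste(plain, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(frame)
  r2 <- stats::setNames(numeric(length(models)), names(models))
  for (nm in names(models)) {
    preds <- setdiff(models[[nm]], "1") # "1" or empty: intercept only
    missing_p <- setdiff(preds, names(df))
    if (length(missing_p) > 0L) {
      stop("config error: predictor column(s) not found: ",
           paste(missing_p, collapse = ", "), call. = FALSE)
    }
    if (length(preds) == 0L) {
      mm <- matrix(1, n, 1L)
    } else {
      sub <- df[, preds, drop = FALSE]
      for (cn in names(sub)) if (is.character(sub[[cn]])) sub[[cn]] <- factor(sub[[cn]])
      mm <- stats::model.matrix(~ ., data = sub)
    }
    if (anyNA(mm)) {
      stop("predictor missing for some cohort member in model for '", nm, "'",
           call. = FALSE)
    }
    rows <- which(frame$xi == 1 & !is.na(df[[nm]]))
    wr <- w[rows] * mass[rows]
    Mm <- mm[rows, , drop = FALSE]
    y <- df[[nm]][rows]
    fitq <- qr(Mm * sqrt(wr))
    if (fitq$rank < ncol(Mm)) {
      stop("collinear predictors in imputation model for '", nm, "'",
           call. = FALSE)
    }
    coef <- qr.coef(fitq, y * sqrt(wr))
    fitted_all <- drop(mm %*% coef)
    res <- y - fitted_all[rows]
    mu <- sum(wr * y) / sum(wr)
    r2[nm] <- 1 - sum(wr * res^2) / sum(wr * (y - mu)^2)
    X[, nm] <- fitted_all
  }
  structure(X, r2 = r2)
}

# frame with the covariate columns replaced (used for the imputed-cohort fit)
.with_covariates <- function(frame, X) {
  out <- frame
  for (j in seq_along(attr(frame, "covars"))) {
    out[[attr(frame, "covars")[j]]] <- X[, j]
  }
  out
}

#' Build the calibration auxiliary matrix
#'
#' Implements the two-stage recipe: block (i) are the per-subject influences
#' on beta from a full-cohort Cox fit on the imputed covariates (unit
#' weights); design weights are then calibrated against (i) + (iii) and the
#' resulting case-cohort estimate of beta defines block (ii), follow-up time
#' in `(tau1, tau2]` times the imputed relative hazard; block (iii) is the
#' constant 1.
#'
#' @param frame a [cohort_frame()]
#' @param weights phase-two design weights
#' @param imputed matrix from [impute_phase2()]
#' @param request [risk_request()] giving the risk-projection interval
#' @param blocks subset of `c("i", "ii", "iii")` to include
#' @return n-by-q auxiliary matrix with attribute `"blocks"`
#' @export
build_auxiliary <- function(frame, weights, imputed, request,
                            blocks = c("i", "ii", "iii")) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  n <- nrow(frame)
  frame_imp <- .with_covariates(frame, imputed)
  ones <- rep(1, n)
  fit_full <- cch_fit(frame_imp, weights = ones, include = ones,
                      weights_used = "unit")
  block_i <- if2_beta(frame_imp, ones, fit_full, include = ones)
  colnames(block_i) <- paste0("inf_", attr(frame, "covars"))
  out <- list()
  if ("i" %in% blocks) out$i <- block_i
  if ("ii" %in% blocks) {
    stage1 <- calibrate_weights(frame, weights,
                                cbind(block_i, const = 1))
    w2 <- combined_weights(weights, n)
    fit1 <- cch_fit(frame, stage1$wstar, include = frame$xi,
                    num_weights = frame$xi * w2, weights_used = "calibrated")
    time_in <- pmax(0, pmin(frame$exit_time, request$tau2) - request$tau1)
    out$ii <- cbind(risktime = time_in * exp(drop(imputed %*% fit1$beta)))
  }
  if ("iii" %in% blocks) out$iii <- cbind(const = rep(1, n))
  A <- do.call(cbind, out)
  attr(A, "blocks") <- blocks
  A
}

#' Rake design weights against auxiliary variables
#'
#' Newton solve with step-halving of the calibration equations; near-singular
#' auxiliary cross-products trigger pruning of redundant columns (with a
#' warning) rather than silent regularisation. A calibrated-to-design weight
#' ratio above `ratio_bound` aborts with a suggestion to reduce the
#' auxiliary set.
#'
#' @param frame a [cohort_frame()]
#' @param weights phase-two design weights
#' @param aux n-by-q auxiliary matrix (defined for every cohort member)
#' @param tol max-norm tolerance on the constraint residual
#' @param max_iter Newton iteration cap
#' @param ratio_bound weight-explosion bound on `max(w*/w)`
#' @param mass internal per-subject multiplier (finite-difference oracle)
#' @return object of class `calibrated_weights`: `eta` (q-vector, zeros for
#'   pruned columns), `wstar` (per-subject), `residual_norm`, `kept`
#' @export
calibrate_weights <- function(frame, weights, aux, tol = 1e-10,
                              max_iter = 50L, ratio_bound = 100, mass = NULL) {
  n <- nrow(frame)
  w <- combined_weights(weights, n)
  if (is.null(mass)) mass <- rep(1, n)
  A_full <- as.matrix(aux)
  if (nrow(A_full) != n) stop("aux must have one row per cohort member",
                              call. = FALSE)
  q <- ncol(A_full)
  if (q >= sum(frame$xi)) {
    stop("more auxiliary columns than phase-two subjects", call. = FALSE)
  }
  xi <- frame$xi
  # prune collinear columns (rank of the weighted cross-product)
  qrA <- qr(A_full * sqrt(xi * w * mass), tol = 1e-9)
  kept <- sort(qrA$pivot[seq_len(qrA$rank)])
  if (length(kept) < q) {
    warning(sprintf("pruned %d collinear auxiliary column(s)", q - length(kept)),
            call. = FALSE)
  }
  A <- A_full[, kept, drop = FALSE]
  target <- colSums(A * mass)
  eta <- rep(0, length(kept))
  gfun <- function(eta) {
    e <- exp(drop(A %*% eta))
    g <- colSums(A * (xi * w * mass * e)) - target
    list(g = g, e = e)
  }
  gv <- gfun(eta)
  res <- max(abs(gv$g))
  iter <- 0L
  while (res > tol && iter < max_iter) {
    iter <- iter + 1L
    H <- crossprod(A, A * (xi * w * mass * gv$e))
    step <- tryCatch(solve(H, gv$g), error = function(e) NULL)
    if (is.null(step)) {
      stop("singular calibration system; reduce the auxiliary set",
           call. = FALSE)
    }
    lambda <- 1
    repeat {
      cand <- eta - lambda * step
      gv2 <- gfun(cand)
      if (max(abs(gv2$g)) <= res || lambda < 1 / 1024) break
      lambda <- lambda / 2
    }
    eta <- cand; gv <- gv2; res <- max(abs(gv$g))
  }
  if (res > tol) {
    stop(sprintf("raking did not converge: residual %.3g after %d iterations",
                 res, iter), call. = FALSE)
  }
  if (max(gv$e[xi == 1]) > ratio_bound) {
    stop("calibrated weights exploded (max w*/w > ", ratio_bound,
         "); reduce the auxiliary set", call. = FALSE)
  }
  eta_full <- stats::setNames(rep(0, q),
                              colnames(A_full) %||% paste0("A", seq_len(q)))
  eta_full[kept] <- eta
  structure(list(eta = eta_full, wstar = w * exp(drop(A_full %*% eta_full)),
                 residual_norm = res, kept = kept, iterations = iter,
                 aux = A_full),
            class = "calibrated_weights")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Case-cohort estimation with calibrated weights
#'
#' Fits the weighted Cox score with `w*` replacing the design weights; the
#' Breslow numerator keeps the uncalibrated case contributions (event times
#' are known for all cohort members).
#'
#' @param frame a [cohort_frame()]
#' @param weights phase-two design weights
#' @param cal a [calibrate_weights()] result
#' @param request optional [risk_request()]
#' @return list with elements `fit` (a `cch_fit`), and when a request is
#'   given `pure_risk`
#' @export
fit_calibrated <- function(frame, weights, cal, request = NULL) {
  w <- combined_weights(weights, nrow(frame))
  fit <- cch_fit(frame, cal$wstar, include = frame$xi,
                 num_weights = frame$xi * w, weights_used = "calibrated")
  out <- list(fit = fit)
  if (!is.null(request)) out$pure_risk <- pure_risk(fit, request)
  out
}

#' Influence sets under calibrated weights
#'
#' Total deviates `Delta = IF1 + xi w IF2` for beta, the interval cumulative
#' baseline hazard and pure risk. `IF1` depends only on phase-one information
#' (a subject outside the phase-two sample still influences eta-hat); `IF2`
#' is a multiplicatively reweighted residual of the fixed-weight influence on
#' the auxiliaries, so the weighted phase-two score parts are orthogonal to
#' every auxiliary column.
#'
#' @param frame a [cohort_frame()]
#' @param weights phase-two design weights
#' @param cal a [calibrate_weights()] result
#' @param fit the calibrated [cch_fit()] from [fit_calibrated()]
#' @param request a [risk_request()], or `NULL` for beta only
#' @return named list of `influence_set` objects (`beta`, `Lambda`,
#'   `purerisk`, `log_purerisk`)
#' @export
influence_calibrated <- function(frame, weights, cal, fit, request = NULL) {
  n <- nrow(frame)
  w <- combined_weights(weights, n)
  xi <- frame$xi
  A <- cal$aux[, cal$kept, drop = FALSE]
  wstar <- cal$wstar
  efac <- wstar / w # exp(eta'A)

  core <- .influence_core(frame, xi, wstar, fit)
  IFb_tilde <- core$IFb
  H <- crossprod(A, A * (xi * wstar))
  Hi <- solve(H)
  D <- crossprod(IFb_tilde * (xi * wstar), A) # p x q

  AHD <- A %*% Hi %*% t(D) # n x p, rows = (D H^-1 A_i)'
  IF1b <- AHD
  IF2b <- (IFb_tilde - AHD) * efac
  IF2b[xi == 0, ] <- 0
  out <- list(beta = new_influence_set("beta", IF2b, if1 = IF1b,
                                       delta = IF1b + IF2b * (xi * w),
                                       estimate = fit$beta))
  if (is.null(request)) return(out)

  lp <- .lambda_pieces(core, request$tau1, request$tau2)
  # d Lambda / d eta, through S0* only (the numerator is not calibrated)
  X <- covariate_matrix(frame); X[xi == 0, ] <- 0
  rA <- (xi * wstar * exp(drop(X %*% fit$beta))) * A
  SA1 <- .grid_sums(frame$entry_time, frame$exit_time, fit$event_times, rA,
                    fit$timescale == "age")
  dLdeta <- -colSums((fit$jumps * lp$inI / fit$s0) * SA1)
  ML <- drop(crossprod(lp$gbeta, D)) + dLdeta # q-vector
  MHA <- drop(A %*% (Hi %*% ML)) # n-vector, M' H^-1 A_i
  coreL <- lp$phi + drop(IFb_tilde %*% lp$gbeta)
  IF1L <- MHA
  IF2L <- lp$nu + (coreL - MHA) * efac
  IF2L[xi == 0] <- 0
  dL <- .delta_lambda(fit, request$tau1, request$tau2)
  out$Lambda <- new_influence_set("Lambda", IF2L, if1 = IF1L,
                                  delta = IF1L + IF2L * (xi * w),
                                  estimate = dL)

  Gn <- nrow(request$profiles)
  IF1P <- matrix(0, n, Gn); IF2P <- matrix(0, n, Gn)
  IF1LP <- matrix(0, n, Gn); IF2LP <- matrix(0, n, Gn)
  est <- numeric(Gn)
  for (g in seq_len(Gn)) {
    gr <- .pure_risk_grad(fit$beta, dL, request$profiles[g, ])
    IF1P[, g] <- drop(IF1b %*% gr$gbeta) + gr$gL * IF1L
    IF2P[, g] <- drop(IF2b %*% gr$gbeta) + gr$gL * IF2L
    IF1LP[, g] <- IF1P[, g] / gr$pi
    IF2LP[, g] <- IF2P[, g] / gr$pi
    est[g] <- gr$pi
  }
  out$purerisk <- new_influence_set("purerisk", IF2P, if1 = IF1P,
                                    delta = IF1P + IF2P * (xi * w),
                                    estimate = est)
  out$log_purerisk <- new_influence_set("log_purerisk", IF2LP, if1 = IF1LP,
                                        delta = IF1LP + IF2LP * (xi * w),
                                        estimate = log(est))
  out
}
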