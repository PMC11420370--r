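# Cohort container, validation and delimited text I/O.
#
# A cohort_frame is a data.frame (one row per subject) carrying the phase-one
# follow-up information for the whole cohort, the phase-two / phase-three
# sampling indicators, the covariate columns (possibly missing outside the
# phase-two sample) and the phase-one proxy columns, plus attributes naming
# the covariate and proxy columns and the time scale.

REQUIRED_COLUMNS <- c("subject_id", "stratum", "entry_time", "exit_time",
                      "event", "xi", "v")

#' Construct and validate a cohort frame
#'
#' Bundles subject-level follow-up data, sampling indicators and covariates
#' into the container used by all estimation functions, and enforces the
#' design invariants of the standard case-cohort design: every case is in the
#' phase-two sample (`xi = 1`), follow-up is positive, and phase-two
#' covariates are observed wherever `xi * v = 1`.
#'
#' @param data data.frame with columns `subject_id`, `stratum`, `entry_time`,
#'   `exit_time`, `event` (0/1), `xi` (phase-two sampling indicator, 0/1) and
#'   optionally `v` (phase-three indicator; defaults to `xi`, i.e. complete
#'   phase-two data), plus covariate and proxy columns.
#' @param covars character vector naming the covariate columns (the Cox model
#'   design matrix). Entries may be `NA` for subjects with `xi * v = 0`.
#' @param proxies character vector naming phase-one proxy columns, observed
#'   for every cohort member. May be empty.
#' @param timescale `"time_on_study"` (at risk while `exit_time >= t`) or
#'   `"age"` (at risk while `exit_time >= t > entry_time`, i.e. left
#'   truncation at study entry).
#' @return An object of class `cohort_frame` (a validated data.frame with
#'   attributes `covars`, `proxies`, `timescale`, `stratum_levels`).
#' @export
cohort_frame <- function(data, covars, proxies = character(),
                         timescale = c("time_on_study", "age")) {
  timescale <- match.arg(timescale)
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"v" %in% names(data)) data$v <- data$xi
  missing_cols <- setdiff(c(REQUIRED_COLUMNS, covars, proxies), names(data))
  if (length(missing_cols) > 0L) {
    stop("config error: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data$stratum <- as.character(data$stratum)
  for (col in c("entry_time", "exit_time", "event", "xi", "v")) {
    data[[col]] <- as.numeric(data[[col]])
  }

  if (!all(data$event %in% c(0, 1))) {
    stop("validation error: 'event' must be 0/1", call. = FALSE)
  }
  if (!all(data$xi %in% c(0, 1)) || !all(data$v %in% c(0, 1))) {
    stop("validation error: 'xi' and 'v' must be 0/1", call. = FALSE)
  }
  bad_fu <- which(!(data$exit_time > data$entry_time))
  if (length(bad_fu) > 0L) {
    stop("validation error: non-positive follow-up for subject(s) ",
         paste(utils::head(data$subject_id[bad_fu], 5L), collapse = ", "),
         call. = FALSE)
  }
  bad_case <- which(data$event == 1 & data$xi == 0)
  if (length(bad_case) > 0L) {
    stop("design-violation error: case(s) with xi = 0: ",
         paste(utils::head(data$subject_id[bad_case], 5L), collapse = ", "),
         call. = FALSE)
  }
  bad_v <- which(data$v == 1 & data$xi == 0)
  if (length(bad_v) > 0L) {
    stop("validation error: v = 1 outside the phase-two sample for subject(s) ",
         paste(utils::head(data$subject_id[bad_v], 5L), collapse = ", "),
         call. = FALSE)
  }
  # phase-two covariates must be observed on the complete-data sample
  if (length(covars) > 0L) {
    obs <- data$xi * data$v == 1
    for (col in covars) {
      if (anyNA(data[[col]][obs])) {
        stop("validation error: covariate '", col,
             "' missing for subject(s) with xi*v = 1", call. = FALSE)
      }
    }
  }
  for (col in proxies) {
    if (anyNA(data[[col]])) {
      stop("validation error: proxy '", col,
           "' must be observed for every cohort member", call. = FALSE)
    }
  }

  levels <- sort(unique(data$stratum))
  structure(data,
            covars = covars, proxies = proxies, timescale = timescale,
            stratum_levels = levels,
            class = c("cohort_frame", "data.frame"))
}

#' @export
print.cohort_frame <- function(x, ...) {
  cat("cohort_frame: n =", nrow(x),
      "| strata:", length(attr(x, "stratum_levels")),
      "| cases:", sum(x$event),
      "| phase-two:", sum(x$xi),
      "| timescale:", attr(x, "timescale"), "\n")
  tab <- table(x$stratum)
  cat("  n^(j):", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                        collapse = ", "), "\n")
  invisible(x)
}

is_case <- function(frame) frame$event == 1

#' Stratum index (1..J, sorted label order) for each subject
#' @param frame a [cohort_frame()]
#' @return integer vector of per-subject stratum indices
#' @export
stratum_index <- function(frame) {
  match(frame$stratum, attr(frame, "stratum_levels"))
}

#' Covariate matrix of a cohort frame
#' @param frame a [cohort_frame()]
#' @return numeric matrix, one column per covariate, `NA` where unobserved
#' @export
covariate_matrix <- function(frame) {
  covars <- attr(frame, "covars")
  m <- as.matrix(as.data.frame(frame)[, covars, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, covars)
  m
}

proxy_matrix <- function(frame) {
  proxies <- attr(frame, "proxies")
  m <- as.matrix(as.data.frame(frame)[, proxies, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

.delim_for_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a cohort from a delimited text file
#'
#' The delimiter is chosen from the extension (`.csv` is comma separated,
#' anything else tab separated); a header row is mandatory and empty fields
#' are read as missing values.
#'
#' @param path file path.
#' @param config list with element `columns` (named list or vector mapping the
#'   canonical names `subject_id`, `stratum`, `entry_time`, `exit_time`,
#'   `event`, `xi` and optionally `v` to columns in the file), `covariates`
#'   (character), optional `proxies` (character) and optional `timescale`.
#' @return a validated [cohort_frame()]
#' @export
read_cohort <- function(path, config) {
  if (is.null(config$columns) || is.null(config$covariates)) {
    stop("config error: 'columns' and 'covariates' are required", call. = FALSE)
  }
  cols <- unlist(config$columns)
  raw <- utils::read.table(path, header = TRUE, sep = .delim_for_path(path),
                           na.strings = c("", "NA"), stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols) > 0L) {
    stop("config error: column(s) not in file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (canon in names(cols)) {
    if (cols[[canon]] != canon) {
      raw[[canon]] <- raw[[cols[[canon]]]]
    }
  }
  cohort_frame(raw,
               covars = unlist(config$covariates),
               proxies = if (is.null(config$proxies)) character() else unlist(config$proxies),
               timescale = if (is.null(config$timescale)) "time_on_study" else config$timescale)
}

#' Write a cohort frame to delimited text
#'
#' Uses the same dialect convention as [read_cohort()]; missing values are
#' written as empty fields.
#'
#' @param frame a [cohort_frame()]
#' @param path output file path (`.csv` for comma separated, else tab)
#' @export
write_cohort <- function(frame, path) {
  utils::write.table(as.data.frame(frame), path, sep = .delim_for_path(path),
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Phase-two design weights
#'
#' Standard case-cohort design weights: 1 for cases (all cases are sampled)
#' and `n^(j) / m^(j)` for non-cases in stratum `j`, where `m^(j)` subjects
#' were drawn without replacement from the `n^(j)` in the stratum. Under
#' Bernoulli (independent) sampling the same marginal weight applies with
#' inclusion probability `m^(j) / n^(j)`.
#'
#' @param frame a [cohort_frame()]
#' @param m integer vector of per-stratum subcohort sizes, either named by
#'   stratum label or ordered as the sorted labels.
#' @param mode `"without_replacement"` (default) or `"bernoulli"`.
#' @return object of class `design_weights`: list with per-subject `w2`
#'   (phase-two weight), `w3` (initialised to 1), `mode`, per-stratum `m` and
#'   `n`.
#' @export
design_weights <- function(frame, m,
                           mode = c("without_replacement", "bernoulli")) {
  mode <- match.arg(mode)
  levels <- attr(frame, "stratum_levels")
  n_j <- as.integer(table(factor(frame$stratum, levels = levels)))
  if (is.null(names(m))) {
    if (length(m) != length(levels)) {
      stop("config error: 'm' must have one entry per stratum", call. = FALSE)
    }
    names(m) <- levels
  }
  m <- m[levels]
  if (anyNA(m)) stop("config error: 'm' missing for some stratum", call. = FALSE)
  if (any(m > n_j)) {
    stop("config error: m^(j) exceeds stratum size n^(j)", call. = FALSE)
  }
  if (mode == "without_replacement" && any(m <= 1L)) {
    stop("m^(j) <= 1 with without-replacement sampling: pairwise weight ",
         "n(n-1)/(m(m-1)) is undefined", call. = FALSE)
  }
  idx <- stratum_index(frame)
  w2 <- ifelse(is_case(frame), 1, n_j[idx] / m[idx])
  structure(list(w2 = w2, w3 = rep(1, nrow(frame)), mode = mode,
                 m = stats::setNames(as.numeric(m), levels),
                 n = stats::setNames(as.numeric(n_j), levels)),
            class = "design_weights")
}

# Canonical per-subject weight vector from either a design_weights object or
# a bare numeric vector.
combined_weights <- function(weights, n = NULL) {
  if (inherits(weights, "design_weights")) {
    w <- weights$w2 * weights$w3
  } else {
    w <- as.numeric(weights)
  }
  if (!is.null(n) && length(w) != n) {
    stop("shape mismatch: weight vector of length ", length(w),
         " for ", n, " subjects", call. = FALSE)
  }
  w
}

#' Risk interval and covariate profiles for pure risk
#'
#' @param tau1,tau2 endpoints of the half-open projection interval
#'   `(tau1, tau2]`.
#' @param profiles numeric vector (single profile), matrix or list of numeric
#'   p-vectors, one covariate profile per row/element.
#' @return object of class `risk_request`
#' @export
risk_request <- function(tau1, tau2, profiles) {
  if (!(is.numeric(tau1) && is.numeric(tau2)) || tau1 >= tau2) {
    stop("empty risk interval: need tau1 < tau2", call. = FALSE)
  }
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1L)
  structure(list(tau1 = tau1, tau2 = tau2, profiles = profiles),
            class = "risk_request")
}
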