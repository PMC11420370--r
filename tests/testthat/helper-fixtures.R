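# Shared fixtures: small random case-cohort frames built in code.

# full cohort with everything observed (xi = v = 1)
make_full_frame <- function(n = 50, seed = 1, p = 2, rate0 = 0.08,
                            beta = c(0.4, 0.2), age_scale = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  Tfail <- rexp(n, rate0 * exp(drop(X[, seq_along(beta), drop = FALSE] %*% beta)))
  C <- rexp(n, 0.04)
  d <- data.frame(subject_id = seq_len(n), stratum = "all",
                  entry_time = 0, exit_time = pmin(Tfail, C, 15),
                  event = as.numeric(Tfail <= pmin(C, 15)), xi = 1, v = 1)
  for (j in seq_len(p)) d[[paste0("x", j)]] <- X[, j]
  if (age_scale) d$entry_time <- runif(n, 0, d$exit_time * 0.4)
  cohort_frame(d, covars = paste0("x", seq_len(p)),
               timescale = if (age_scale) "age" else "time_on_study")
}

# stratified case-cohort frame: two strata, m sampled per stratum plus all
# cases; covariates masked outside the phase-two (times phase-three) sample
make_cch_frame <- function(n = 50, seed = 1, m_per_stratum = 10,
                           miss_prob = 0, proxy_sd = 0.75) {
  set.seed(seed)
  strat <- sample(c("a", "b"), n, TRUE)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  xt1 <- x1 + rnorm(n, 0, proxy_sd)
  xt2 <- x2 + rnorm(n, 0, proxy_sd)
  Tfail <- rexp(n, 0.08 * exp(0.4 * x1 + 0.2 * x2))
  C <- rexp(n, 0.04)
  d <- data.frame(subject_id = seq_len(n), stratum = strat, entry_time = 0,
                  exit_time = pmin(Tfail, C, 15),
                  event = as.numeric(Tfail <= pmin(C, 15)),
                  xi = 0, v = 0, x1 = x1, x2 = x2, xt1 = xt1, xt2 = xt2,
                  stringsAsFactors = FALSE)
  for (s in c("a", "b")) {
    idx <- which(d$stratum == s)
    d$xi[idx[sample.int(length(idx), m_per_stratum)]] <- 1
  }
  d$xi[d$event == 1] <- 1
  d$v <- d$xi
  if (miss_prob > 0) {
    d$v <- d$xi * rbinom(n, 1, 1 - miss_prob)
    # keep at least one complete case and non-case
    if (sum(d$v[d$event == 1]) == 0) d$v[which(d$event == 1)[1]] <- 1
    if (sum(d$v[d$event == 0 & d$xi == 1]) == 0) {
      d$v[which(d$event == 0 & d$xi == 1)[1]] <- 1
    }
  }
  d$x1[d$xi * d$v == 0] <- NA
  d$x2[d$xi * d$v == 0] <- NA
  fr <- cohort_frame(d, covars = c("x1", "x2"), proxies = c("xt1", "xt2"))
  list(frame = fr,
       weights = design_weights(fr, c(a = m_per_stratum, b = m_per_stratum)),
       m = c(a = m_per_stratum, b = m_per_stratum))
}

# delimited cohort + JSON config on disk, for the CLI and workflow tests
write_cli_fixture <- function(dir, n = 500, seed = 41, census = FALSE) {
  scn <- sim_scenario(n = n, pY = 0.1, mc_draws = 1e5)
  co <- generate_cohort(scn, seed = seed)
  m <- allocate_subcohort(scn)
  fs <- if (census) co else sample_design(co, m)
  if (census) {
    m <- sapply(attr(co, "stratum_levels"), function(s) sum(co$stratum == s))
  }
  data_path <- file.path(dir, "cohort.csv")
  write_cohort(fs, data_path)
  cfg <- list(
    columns = list(subject_id = "subject_id", stratum = "stratum",
                   entry_time = "entry_time", exit_time = "exit_time",
                   event = "event", xi = "xi", v = "v"),
    covariates = c("x1", "x2", "x3"),
    proxies = c("xt1", "xt3", "W"),
    m = as.list(m), mode = "without_replacement",
    tau1 = 0, tau2 = 8,
    profiles = list(c(-1, 1, -0.6), c(1, 1, 0.6)),
    calibration = list(impute = list(x1 = c("xt1", "W"),
                                     x3 = c("xt1", "xt3"))))
  config_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, config_path, auto_unbox = TRUE)
  list(data = data_path, config = config_path)
}
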