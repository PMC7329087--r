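#' Specification for a synthetic EHR-like survival table
#'
#' Describes a mixed-type table whose outcome follows a Cox
#' proportional-hazards law with an exponential baseline hazard: event time
#' T = -log(U) / (lambda * exp(x'beta)), an independent exponential
#' censoring time calibrated to the requested censoring fraction, duration
#' = min(T, C) and event = 1[T <= C]. The criterion column is the duration
#' itself (a length of stay), recorded in whole days as hospital systems
#' do. Informative numeric covariates are standard normal (stored at one
#' decimal, the precision of typical clinical measurements); informative
#' categorical covariates act through indicator contrasts with per-level
#' log-hazard effects. Date-like and code-like columns are
#' outcome-independent distractors. Missingness is applied completely at
#' random per column.
#'
#' @param n Number of samples (default 2000).
#' @param informative_numeric,informative_categorical Numbers of
#'   informative columns (defaults 2 and 3).
#' @param noise_numeric,noise_categorical,n_date,n_code Numbers of
#'   noise/distractor columns (defaults 6, 5, 2, 2).
#' @param beta_numeric Log-hazard slope per informative numeric column
#'   (recycled; default 1).
#' @param beta_categorical Per-level effects for each informative
#'   categorical column (reference level first; default `c(0, 0.8, 1.6)`).
#' @param lambda Baseline exponential hazard rate per day (default 0.1,
#'   i.e. a 10-day mean stay at the covariate origin).
#' @param censoring Target censoring fraction in `[0, 1)` (default 0.2).
#' @param missingness Per-feature-column MCAR missingness fraction
#'   (default 0.05; never applied to the duration/event columns).
#' @param min_subset Guard replicated from [ss_sample()] (default 10).
#' @param seed Integer random seed.
#' @return An object of class `fsopa_synthspec`.
#' @export
synth_spec <- function(n = 2000, informative_numeric = 2,
                       informative_categorical = 3, noise_numeric = 6,
                       noise_categorical = 5, n_date = 2, n_code = 2,
                       beta_numeric = 1, beta_categorical = c(0, 0.8, 1.6),
                       lambda = 0.1, censoring = 0.2, missingness = 0.05,
                       min_subset = 10, seed = 1) {
  stopifnot(censoring >= 0, censoring < 1, missingness >= 0, missingness < 1,
            lambda > 0)
  if (n < 8 * min_subset)
    stop("n must be at least 8 * min_subset = ", 8 * min_subset)
  structure(as.list(environment()), class = "fsopa_synthspec")
}

random_dates <- function(n) {
  origin <- as.Date("2005-01-01")
  format(origin + sample.int(4017L, n, replace = TRUE) - 1L, "%Y-%m-%d")
}

random_codes <- function(n) {
  sprintf("F%02d.%d", sample(0:99, n, replace = TRUE),
          sample(0:9, n, replace = TRUE))
}

#' Generate a synthetic feature table with known ground truth
#'
#' Draws covariates, simulates the survival outcome under the Cox law of
#' the spec, calibrates the exponential censoring rate so the expected
#' censored fraction matches the request, applies MCAR missingness, and
#' returns the table together with a ground-truth record naming the
#' informative columns and their effects. Fully reproducible from the
#' spec's seed (byte-identical CSV for the same spec).
#'
#' @param spec An [synth_spec()].
#' @return List with `table` (an `fsopa_table` whose config names `los` as
#'   criterion/duration and `event` as event column) and `truth`
#'   (informative column names, betas, lambda, censoring rate used).
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "fsopa_synthspec"))
  set.seed(spec$seed)
  n <- spec$n
  cols <- list(); miss_frac <- list()
  lp <- rep(0, n)
  informative <- character(0)
  betas <- list()
  bn <- rep_len(spec$beta_numeric, max(1L, spec$informative_numeric))
  for (i in seq_len(spec$informative_numeric)) {
    nm <- sprintf("sev%d", i)                # severity-score style covariate
    x <- round(stats::rnorm(n), 1)
    lp <- lp + bn[i] * x
    cols[[nm]] <- as.character(x)
    miss_frac[[nm]] <- spec$missingness
    informative <- c(informative, nm)
    betas[[nm]] <- bn[i]
  }
  lev_effects <- spec$beta_categorical
  lev_names <- paste0("L", seq_along(lev_effects))
  for (i in seq_len(spec$informative_categorical)) {
    nm <- sprintf("diag%d", i)               # diagnosis-group style covariate
    g <- sample.int(length(lev_effects), n, replace = TRUE)
    lp <- lp + lev_effects[g]
    cols[[nm]] <- lev_names[g]
    miss_frac[[nm]] <- spec$missingness
    informative <- c(informative, nm)
    betas[[nm]] <- stats::setNames(lev_effects, lev_names)
  }
  for (i in seq_len(spec$noise_numeric)) {
    nm <- sprintf("lab%d", i)
    cols[[nm]] <- as.character(round(stats::rnorm(n), 1))
    miss_frac[[nm]] <- spec$missingness
  }
  for (i in seq_len(spec$noise_categorical)) {
    nm <- sprintf("adm%d", i)
    cols[[nm]] <- sample(c("A", "B", "C"), n, replace = TRUE)
    miss_frac[[nm]] <- spec$missingness
  }
  for (i in seq_len(spec$n_date)) {
    nm <- sprintf("date%d", i)
    cols[[nm]] <- random_dates(n)
    miss_frac[[nm]] <- spec$missingness
  }
  for (i in seq_len(spec$n_code)) {
    nm <- sprintf("code%d", i)
    cols[[nm]] <- random_codes(n)
    miss_frac[[nm]] <- spec$missingness
  }
  rate <- spec$lambda * exp(lp)
  t_event <- -log(stats::runif(n)) / rate
  if (spec$censoring == 0) {
    duration <- t_event
    event <- rep(1L, n)
    cens_rate <- 0
  } else {
    target <- spec$censoring
    f <- function(lc) mean(lc / (lc + rate)) - target
    lo <- 1e-8; hi <- 1e8
    if (f(lo) > 0 || f(hi) < 0)
      stop("infeasible censoring calibration for fraction ", target)
    cens_rate <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    t_cens <- -log(stats::runif(n)) / cens_rate
    duration <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  los <- ceiling(duration)                   # whole-day length of stay
  cols[["los"]] <- as.character(los)
  cols[["event"]] <- as.character(event)
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in names(miss_frac)) {
    p <- miss_frac[[nm]]
    if (p > 0) {
      hit <- stats::runif(n) < p
      df[[nm]][hit] <- ""
    }
  }
  roles <- stats::setNames(
    rep(c("date", "code"),
        c(spec$n_date, spec$n_code)),
    c(sprintf("date%d", seq_len(spec$n_date)),
      sprintf("code%d", seq_len(spec$n_code))))
  cfg <- role_config(criterion = "los", direction = "minimize",
                     duration = "los", event = "event", roles = roles)
  list(table = feature_table(df, config = cfg),
       truth = list(informative = informative, beta = betas,
                    lambda = spec$lambda, censoring_rate = cens_rate,
                    linear_predictor_sd = stats::sd(lp),
                    event_fraction = mean(event)))
}

#' Hand-built toy phylogram pairs with known sensitivity output
#'
#' Two small best/worst tree pairs used as regression fixtures for the
#' clade-based and target-based procedures. In the `"clade"` pair the
#' cherry (A,B) of the best model is rearranged in the worst model while
#' everything else is preserved, so the clade-based list is {A, B}. In the
#' `"target"` pair the sibling subtree of target A is {B} in the best model
#' and {B, C} in the worst model, so the target-based list for A is
#' {A, B, C}.
#'
#' @param which `"clade"` or `"target"`.
#' @return List with `best`, `worst` (`phylo`), and `expected` (named list
#'   of expected selection sets).
#' @export
toy_phylograms <- function(which = c("clade", "target")) {
  which <- match.arg(which)
  if (which == "clade") {
    best <- ape::read.tree(text = "((A,B),(D,E),((F,G),H));")
    worst <- ape::read.tree(text = "(A,(B,(D,E)),((F,G),H));")
    expected <- list(s1 = c("A", "B"), s2 = character(0),
                     s_clade = c("A", "B"))
  } else {
    best <- ape::read.tree(text = "((A,B),(C,(D,E)),((F,G),H));")
    worst <- ape::read.tree(text = "((A,(B,C)),(D,E),((F,G),H));")
    expected <- list(target = "A", s_criterion = c("A", "B", "C"))
  }
  best$edge.length <- rep(1, nrow(best$edge))
  worst$edge.length <- rep(1, nrow(worst$edge))
  list(best = best, worst = worst, expected = expected)
}
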