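#' Cox model specification
#'
#' Binds an `fsopa_table` to the duration and event columns used by the Cox
#' stage. Durations must be positive where present; events are coded 0/1
#' (1 = event observed, 0 = censored).
#'
#' @param table An `fsopa_table`.
#' @param duration Duration column name; defaults to the configured
#'   `duration` (falling back to the criterion column).
#' @param event Event column name; defaults to the configured `event`.
#' @return An object of class `fsopa_coxspec`.
#' @export
cox_spec <- function(table, duration = NULL, event = NULL) {
  stopifnot(inherits(table, "fsopa_table"))
  cfg <- table$config
  if (is.null(duration))
    duration <- if (!is.null(cfg$duration)) cfg$duration else cfg$criterion
  if (is.null(event)) event <- cfg$event
  if (is.null(duration) || is.null(event))
    stop("duration and event columns must be given or configured")
  for (cn in c(duration, event))
    if (!cn %in% feature_names(table)) stop("unknown column: ", cn)
  dur <- column_values(table, duration)
  if (any(dur[!is.na(dur)] <= 0))
    stop("durations must be strictly positive")
  ev <- column_values(table, event)
  if (!all(ev[!is.na(ev)] %in% c(0, 1)))
    stop("event column must be coded in {0,1}")
  structure(list(table = table, duration = duration, event = event),
            class = "fsopa_coxspec")
}

#' Encode candidate covariates into a model frame
#'
#' Numeric columns pass through; categorical columns become factors with the
#' most frequent level as the reference (so one-hot indicators are emitted
#' for the remaining levels by the model matrix). Rows with any missing
#' value among the used columns are dropped (complete-case); features left
#' with a single level after row filtering are dropped with a warning.
#'
#' @param spec An `fsopa_coxspec`.
#' @param features Character vector of covariate names (must exclude the
#'   duration and event columns themselves).
#' @param extra_complete Additional columns whose missingness also drops
#'   rows (used to keep nested forward-selection fits on a common sample).
#' @return List with `frame` (data.frame including `.time` and `.event`),
#'   `features` (kept covariates), `dropped`, `n_dropped_rows`.
#' @export
encode_covariates <- function(spec, features, extra_complete = character()) {
  stopifnot(inherits(spec, "fsopa_coxspec"))
  table <- spec$table
  if (any(features %in% c(spec$duration, spec$event)))
    stop("covariates must exclude the duration and event columns")
  missing_cols <- setdiff(features, feature_names(table))
  if (length(missing_cols))
    stop("unknown covariates: ", paste(missing_cols, collapse = ", "))
  used <- unique(c(spec$duration, spec$event, features, extra_complete))
  cc <- !apply(table$missing[, used, drop = FALSE], 1L, any)
  if (!any(cc)) stop("no usable rows after complete-case filtering")
  frame <- data.frame(.time = column_values(table, spec$duration)[cc],
                      .event = column_values(table, spec$event)[cc])
  kept <- character(0); dropped <- character(0)
  for (f in features) {
    if (table$kinds[[f]] == "numeric") {
      v <- column_values(table, f)[cc]
      if (length(unique(v)) < 2L) { dropped <- c(dropped, f); next }
      frame[[f]] <- v
    } else {
      v <- table$data[[f]][cc]
      tab <- sort(table(v), decreasing = TRUE)
      if (length(tab) < 2L) { dropped <- c(dropped, f); next }
      frame[[f]] <- factor(v, levels = names(tab))  # reference = modal level
    }
    kept <- c(kept, f)
  }
  if (length(dropped))
    warning("dropped single-level covariates: ",
            paste(dropped, collapse = ", "))
  list(frame = frame, features = kept, dropped = dropped,
       n_dropped_rows = sum(!cc))
}

quote_terms <- function(x) paste0("`", x, "`")

#' Fit a Cox proportional-hazards model and compute its AIC
#'
#' Maximizes the Cox partial likelihood with the Efron approximation for
#' tied event times and reports AIC = -2 logPL + 2k, where k is the number
#' of estimated coefficients after categorical encoding. With no features
#' the null model is returned (k = 0, AIC = -2 logPL0).
#'
#' @param spec An `fsopa_coxspec`.
#' @param features Covariate names (possibly empty).
#' @param label Optional model label.
#' @param extra_complete See [encode_covariates()].
#' @return An object of class `fsopa_model`: `features`, `coef`, `logpl`,
#'   `k`, `aic`, `n`, `label`, `fit` (the underlying fit, `NULL` for the
#'   null model).
#' @export
cox_fit <- function(spec, features = character(), label = NULL,
                    extra_complete = character()) {
  enc <- encode_covariates(spec, features, extra_complete = extra_complete)
  frame <- enc$frame
  surv <- survival::Surv(frame$.time, frame$.event)
  if (length(enc$features) == 0L) {
    fit0 <- survival::coxph(surv ~ 1, data = frame)
    logpl <- fit0$loglik[1L]
    return(structure(list(features = character(0), coef = numeric(0),
                          logpl = logpl, k = 0L, aic = -2 * logpl,
                          n = nrow(frame), label = label, fit = NULL),
                     class = "fsopa_model"))
  }
  fml <- stats::as.formula(paste("surv ~",
                                 paste(quote_terms(enc$features),
                                       collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = frame, ties = "efron",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) stop("cox fit failed to converge: ",
                               conditionMessage(w)),
    error = function(e) stop("cox fit failed: ", conditionMessage(e)))
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("collinear covariates: ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  logpl <- fit$loglik[2L]
  k <- length(beta)
  structure(list(features = enc$features, coef = beta, logpl = logpl,
                 k = k, aic = -2 * logpl + 2 * k, n = nrow(frame),
                 label = label, fit = fit),
            class = "fsopa_model")
}

#' @export
print.fsopa_model <- function(x, ...) {
  cat("<fsopa_model>", if (!is.null(x$label)) paste0(" [", x$label, "]"),
      " ", length(x$features), " features, k = ", x$k,
      ", logPL = ", format(x$logpl, digits = 8),
      ", AIC = ", format(x$aic, digits = 8), "\n", sep = "")
  invisible(x)
}

#' Forward covariate selection by AIC
#'
#' Starts from the null model and scans the candidates in the given order,
#' tentatively adding each and keeping it only if the AIC strictly
#' decreases. All fits use the complete cases of the full candidate set so
#' AIC values are comparable across steps. Candidates that fail to fit are
#' skipped with the reason logged.
#'
#' @param spec An `fsopa_coxspec`.
#' @param candidates Ordered character vector of candidate covariates.
#' @param label Optional label for the final model.
#' @return The final `fsopa_model`, with the per-step log in
#'   `$forward_log` (data.frame: candidate, aic_before, aic_after, kept,
#'   note).
#' @export
forward_aic <- function(spec, candidates, label = NULL) {
  if (length(candidates) == 0L) stop("candidates must be non-empty")
  current <- cox_fit(spec, character(0), extra_complete = candidates)
  kept <- character(0)
  log <- data.frame(candidate = character(0), aic_before = numeric(0),
                    aic_after = numeric(0), kept = logical(0),
                    note = character(0), stringsAsFactors = FALSE)
  for (cand in candidates) {
    trial <- tryCatch(cox_fit(spec, c(kept, cand),
                              extra_complete = candidates),
                      error = function(e) e, warning = function(w) w)
    if (inherits(trial, "condition")) {
      log <- rbind(log, data.frame(candidate = cand,
                                   aic_before = current$aic,
                                   aic_after = NA_real_, kept = FALSE,
                                   note = conditionMessage(trial)))
      next
    }
    accept <- trial$aic < current$aic
    log <- rbind(log, data.frame(candidate = cand, aic_before = current$aic,
                                 aic_after = trial$aic, kept = accept,
                                 note = ""))
    if (accept) {
      current <- trial
      kept <- c(kept, cand)
    }
  }
  current$label <- label
  current$forward_log <- log
  current
}

#' Normalize AIC values of a set of models
#'
#' Divides each model's AIC by a reference value (by default the maximum
#' AIC among the models), giving the normalized AIC used as the second
#' coordinate of the multicriteria comparison.
#'
#' @param points List of `fsopa_model` objects.
#' @param reference Positive number, or `"max"`.
#' @return The list with `$aic_normalized` set on each model.
#' @export
normalize_aic <- function(points, reference = "max") {
  aics <- vapply(points, `[[`, numeric(1), "aic")
  ref <- if (identical(reference, "max")) max(aics) else reference
  if (!is.numeric(ref) || ref <= 0) stop("reference must be positive")
  lapply(points, function(p) { p$aic_normalized <- p$aic / ref; p })
}

#' Tabular summary of a list of models
#' @param points List of `fsopa_model`.
#' @return Data frame: label, n_features, k, logpl, aic, aic_normalized.
#' @export
model_table <- function(points) {
  data.frame(
    label = vapply(points, function(p)
      if (is.null(p$label)) "" else p$label, character(1)),
    n_features = vapply(points, function(p) length(p$features), integer(1)),
    k = vapply(points, function(p) as.integer(p$k), integer(1)),
    logpl = vapply(points, `[[`, numeric(1), "logpl"),
    aic = vapply(points, `[[`, numeric(1), "aic"),
    aic_normalized = vapply(points, function(p)
      if (is.null(p$aic_normalized)) NA_real_ else p$aic_normalized,
      numeric(1)),
    features = vapply(points, function(p)
      paste(p$features, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
}
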