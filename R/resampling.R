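protected_columns <- function(table) {
  keep <- names(table$roles)[table$roles %in% c("criterion", "duration", "event")]
  cfg <- table$config
  if (!is.null(cfg))
    keep <- union(keep, unlist(cfg[c("criterion", "duration", "event")]))
  keep[!is.na(keep)]
}

#' Missing-value column filter (RS1)
#'
#' Drops every column whose missing fraction is strictly greater than the
#' threshold ("more than 85 percent empty"): a column at exactly the
#' threshold is kept. Criterion, duration and event columns are never
#' dropped. Idempotent.
#'
#' @param table An `fsopa_table`.
#' @param threshold Missing-fraction threshold, default 0.85.
#' @return A filtered `fsopa_table`; the dropped names are in
#'   `attr(, "dropped")`.
#' @export
rs1_missing_filter <- function(table, threshold = 0.85) {
  stopifnot(inherits(table, "fsopa_table"))
  frac <- vapply(feature_names(table), function(cn) missing_fraction(table, cn),
                 numeric(1))
  drop <- names(frac)[frac > threshold]
  drop <- setdiff(drop, protected_columns(table))
  keep <- setdiff(feature_names(table), drop)
  if (length(setdiff(keep, protected_columns(table))) == 0L)
    stop("missing-value filter would drop every feature column")
  out <- subset_table(table, columns = keep)
  attr(out, "dropped") <- drop
  out
}

#' Role-based column filter (RS2)
#'
#' Drops columns whose annotated role is in `drop_roles` (by default
#' date-like and code-like columns, which mostly repeat information held
#' elsewhere). Criterion, duration and event columns are protected even if
#' annotated with a dropped role.
#'
#' @param table An `fsopa_table` whose config carries role overrides.
#' @param drop_roles Character vector of roles to drop.
#' @return A filtered `fsopa_table` with `attr(, "dropped")`.
#' @export
rs2_role_filter <- function(table, drop_roles = c("date", "code")) {
  stopifnot(inherits(table, "fsopa_table"))
  drop <- names(table$roles)[table$roles %in% drop_roles]
  drop <- setdiff(drop, protected_columns(table))
  keep <- setdiff(feature_names(table), drop)
  out <- subset_table(table, columns = keep)
  attr(out, "dropped") <- drop
  out
}

clade_side_of <- function(selection, label, feature, shared) {
  cat <- paste0(substr(label, 2, 2), "C")
  split <- if (startsWith(label, "B")) selection$per_category[[cat]]$best_split
           else selection$per_category[[cat]]$worst_split
  side <- if (feature %in% split$c1) split$c1 else split$c2
  sort(intersect(side, shared))
}

#' Features with stable clades across datasets (RS3 criterion)
#'
#' A feature is stable when, across every supplied selection result, it was
#' never selected by SM1 and the leaf set of its containing middle-split
#' clade (restricted to the shared features) is identical in each of the
#' six phylograms. Stable features carry no ranking signal and are
#' candidates for removal.
#'
#' @param selections List of >= 2 `fsopa_selection` objects on datasets
#'   sharing candidate features.
#' @return Sorted character vector of stable feature names.
#' @export
stable_features <- function(selections) {
  if (length(selections) < 2L) stop("need at least 2 selection results")
  shared <- Reduce(intersect, lapply(selections, `[[`, "columns"))
  if (length(shared) == 0L) stop("no shared features across datasets")
  ever_selected <- Reduce(union, lapply(selections, `[[`, "s_clade"))
  stable <- character(0)
  for (f in setdiff(shared, ever_selected)) {
    ok <- TRUE
    for (lab in subset_labels()) {
      sides <- lapply(selections, clade_side_of, lab, f, shared)
      if (!all(vapply(sides[-1], identical, logical(1), sides[[1]]))) {
        ok <- FALSE
        break
      }
    }
    if (ok) stable <- c(stable, f)
  }
  sort(stable)
}

#' Common and novelty feature lists (RS4/RS5) and their union (RS6)
#'
#' A feature selected in at least two of the three resamplings lands in the
#' common list (RS4) when it was also selected from the full dataset, and
#' in the novelty list (RS5) otherwise. RS6 is their union.
#'
#' @param full_r Feature set selected from the full dataset.
#' @param resampled_rs List of three feature sets from the resamplings.
#' @return List with `rs4`, `rs5`, `rs6` (sorted character vectors).
#' @export
common_novelty <- function(full_r, resampled_rs) {
  stopifnot(length(resampled_rs) == 3L)
  all_feats <- sort(unique(unlist(resampled_rs)))
  counts <- vapply(all_feats, function(f)
    sum(vapply(resampled_rs, function(s) f %in% s, logical(1))), integer(1))
  eligible <- all_feats[counts >= 2L]
  rs4 <- sort(intersect(eligible, full_r))
  rs5 <- sort(setdiff(eligible, full_r))
  list(rs4 = rs4, rs5 = rs5, rs6 = sort(union(rs4, rs5)))
}

#' Run the full resampling suite
#'
#' Applies feature selection to the full table and to three
#' column-constrained resamplings derived from it: RS1 (missing-value
#' filter), RS2 (role filter on RS1), RS3 (RS2 minus the stable features
#' determined from the full/RS1/RS2 selections), then derives the common
#' (RS4), novelty (RS5) and union (RS6) lists.
#'
#' @param table An `fsopa_table` with a configured criterion.
#' @param targets Targets for SM2; default the criterion column.
#' @param compressor Compressor name.
#' @param missing_threshold RS1 threshold, default 0.85.
#' @param drop_roles RS2 roles, default `c("date", "code")`.
#' @param min_subset Passed to [ss_sample()].
#' @param stable_drop Optional explicit feature drop-list overriding the
#'   stability criterion for RS3.
#' @return An object of class `fsopa_suite`: `tables`, `selections` (both
#'   named full/rs1/rs2/rs3), `stable`, `rs4`, `rs5`, `rs6`.
#' @export
run_resampling_suite <- function(table, targets = NULL, compressor = "gzip",
                                 missing_threshold = 0.85,
                                 drop_roles = c("date", "code"),
                                 min_subset = 10, stable_drop = NULL) {
  select_on <- function(tab) {
    ss <- ss_sample(tab, min_subset = min_subset)
    select_features(tab, ss, targets = targets, compressor = compressor)
  }
  tables <- list(full = table)
  tables$rs1 <- rs1_missing_filter(table, threshold = missing_threshold)
  tables$rs2 <- rs2_role_filter(tables$rs1, drop_roles = drop_roles)
  selections <- list(full = select_on(tables$full),
                     rs1 = select_on(tables$rs1),
                     rs2 = select_on(tables$rs2))
  stable <- if (is.null(stable_drop))
    stable_features(selections[c("full", "rs1", "rs2")]) else sort(stable_drop)
  keep <- setdiff(feature_names(tables$rs2),
                  setdiff(stable, protected_columns(tables$rs2)))
  if (length(keep) < 2L)
    stop("stable-clade removal left fewer than 2 columns")
  tables$rs3 <- subset_table(tables$rs2, columns = keep)
  attr(tables$rs3, "dropped") <- setdiff(feature_names(tables$rs2), keep)
  selections$rs3 <- select_on(tables$rs3)
  cn <- common_novelty(selections$full$r,
                       lapply(selections[c("rs1", "rs2", "rs3")], `[[`, "r"))
  structure(c(list(tables = tables, selections = selections, stable = stable),
              cn),
            class = "fsopa_suite")
}

#' @export
print.fsopa_suite <- function(x, ...) {
  cat("<fsopa_suite>\n")
  for (nm in names(x$tables))
    cat(sprintf("  %-4s %d columns, r = {%s}\n", nm,
                length(feature_names(x$tables[[nm]])),
                paste(x$selections[[nm]]$r, collapse = ", ")))
  cat("  rs4 (common):  ", paste(x$rs4, collapse = ", "), "\n",
      "  rs5 (novelty): ", paste(x$rs5, collapse = ", "), "\n",
      "  rs6 (union):   ", paste(x$rs6, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Membership matrix of selected features across the suite
#' @param suite An `fsopa_suite`.
#' @return Data frame: one row per feature ever selected, logical columns
#'   full, rs1, rs2, rs3, rs4, rs5, rs6.
#' @export
suite_membership <- function(suite) {
  sets <- c(lapply(suite$selections, `[[`, "r"),
            list(rs4 = suite$rs4, rs5 = suite$rs5, rs6 = suite$rs6))
  feats <- sort(unique(unlist(sets)))
  out <- data.frame(feature = feats, stringsAsFactors = FALSE)
  for (nm in names(sets)) out[[nm]] <- feats %in% sets[[nm]]
  out
}
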