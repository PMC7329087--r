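#' Rank samples by the criterion and form the six best/worst subsets
#'
#' The salient-sampling (SS) step: all samples are ranked by the criterion
#' column (ascending when `direction = "minimize"`, so the head of the rank
#' holds the best samples), and the head and tail of the rank are saved at
#' three selection-pressure levels s in {2, 4, 8}. `B2C`/`W2C` hold the best
#' and worst floor(n/2) samples, `B4C`/`W4C` floor(n/4), `B8C`/`W8C`
#' floor(n/8), so subsets are nested: `B8C` is a subset of `B4C` is a subset
#' of `B2C` (and likewise for the worst tails). Ties in the criterion are
#' broken by original row index, making the rank deterministic.
#'
#' Rows with a missing criterion value are excluded from the rank; the count
#' is recorded in the result.
#'
#' @param table An `fsopa_table`.
#' @param criterion Criterion column name; defaults to the table config.
#' @param direction `"minimize"` or `"maximize"`; defaults to the config.
#' @param min_subset Smallest admissible size for the s = 8 subsets
#'   (default 10); guards against degenerate phylograms.
#'
#' @return An object of class `fsopa_subsets`: list with `rank` (row indices
#'   best to worst), the six index vectors `B2C`, `W2C`, `B4C`, `W4C`,
#'   `B8C`, `W8C`, `n_ranked`, and `n_missing_criterion`.
#' @export
ss_sample <- function(table, criterion = NULL, direction = NULL,
                      min_subset = 10) {
  stopifnot(inherits(table, "fsopa_table"))
  if (is.null(criterion)) {
    if (is.null(table$config)) stop("no criterion column configured")
    criterion <- table$config$criterion
  }
  if (is.null(direction))
    direction <- if (!is.null(table$config)) table$config$direction else "minimize"
  direction <- match.arg(direction, c("minimize", "maximize"))
  if (!criterion %in% names(table$data)) stop("unknown column: ", criterion)
  if (table$kinds[[criterion]] != "numeric")
    stop("criterion column '", criterion, "' is not numeric")
  vals <- column_values(table, criterion)
  keep <- which(!is.na(vals))
  n_missing <- table$n - length(keep)
  n <- length(keep)
  if (n %/% 8L < min_subset)
    stop("insufficient data: floor(n/8) = ", n %/% 8L,
         " < min_subset = ", min_subset)
  v <- vals[keep]
  ord <- order(if (direction == "minimize") v else -v, keep)
  rank <- keep[ord]
  subsets <- list()
  for (s in c(2L, 4L, 8L)) {
    m <- n %/% s
    subsets[[paste0("B", s, "C")]] <- rank[seq_len(m)]
    subsets[[paste0("W", s, "C")]] <- rank[seq.int(n - m + 1L, n)]
  }
  structure(c(list(rank = rank), subsets,
              list(n_ranked = n, n_missing_criterion = n_missing,
                   criterion = criterion, direction = direction,
                   min_subset = min_subset)),
            class = "fsopa_subsets")
}

#' @export
print.fsopa_subsets <- function(x, ...) {
  cat("<fsopa_subsets> criterion '", x$criterion, "' (", x$direction, "), ",
      x$n_ranked, " ranked rows", sep = "")
  if (x$n_missing_criterion > 0)
    cat(" (", x$n_missing_criterion, " with missing criterion excluded)",
        sep = "")
  cat("\n  sizes: B2C/W2C = ", length(x$B2C), ", B4C/W4C = ", length(x$B4C),
      ", B8C/W8C = ", length(x$B8C), "\n", sep = "")
  invisible(x)
}

subset_labels <- function() c("B2C", "W2C", "B4C", "W4C", "B8C", "W8C")

#' Write the six subsets as per-feature text files
#'
#' Mirrors the directory layout used for compression-based model building:
#' one subdirectory per subset (`B2C` ... `W8C`), each holding one
#' newline-delimited file per feature column, plus a JSON manifest of the
#' rank.
#'
#' @param table An `fsopa_table`.
#' @param subsets An `fsopa_subsets` from [ss_sample()].
#' @param dir Output directory (created if needed).
#' @param columns Columns to serialize; default all.
#' @return `dir`, invisibly.
#' @export
write_subsets <- function(table, subsets, dir, columns = NULL) {
  stopifnot(inherits(subsets, "fsopa_subsets"))
  if (is.null(columns)) columns <- feature_names(table)
  for (lab in subset_labels()) {
    d <- file.path(dir, lab)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (col in columns) {
      obj <- serialize_column(table, col, subsets[[lab]])
      writeLines(rawToChar(obj$payload), file.path(d, paste0(col, lab)),
                 sep = "")
    }
  }
  manifest <- list(criterion = subsets$criterion,
                   direction = subsets$direction,
                   rank = subsets$rank,
                   n_missing_criterion = subsets$n_missing_criterion)
  jsonlite::write_json(manifest, file.path(dir, "rank.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
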