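#' Column-role configuration
#'
#' Describes how the columns of a raw table map onto the roles the analysis
#' needs: the ranking criterion, the survival duration and event columns,
#' and free-form role overrides (e.g. marking columns as `"date"` or
#' `"code"` so the role-based resampling filter can drop them).
#'
#' @param criterion Name of the criterion column used for ranking samples.
#' @param direction `"minimize"` (default; e.g. shorter length of stay is
#'   better) or `"maximize"`.
#' @param duration Optional name of the duration column for Cox modeling.
#'   May equal `criterion` (the usual case when the criterion is the
#'   survival time itself).
#' @param event Optional name of the 0/1 event-indicator column.
#' @param id Optional name of a sample-identifier column.
#' @param roles Named character vector of per-column role overrides; values
#'   from `"feature"`, `"date"`, `"code"`, `"id"`.
#' @param sentinels Character vector of cell values treated as missing.
#'
#' @return An object of class `fsopa_roles`.
#' @export
role_config <- function(criterion, direction = c("minimize", "maximize"),
                        duration = NULL, event = NULL, id = NULL,
                        roles = character(), sentinels = c("", "NA")) {
  direction <- match.arg(direction)
  if (!is.character(criterion) || length(criterion) != 1L || !nzchar(criterion))
    stop("`criterion` must be a single column name")
  if (length(roles) && is.null(names(roles)))
    stop("`roles` must be a named character vector (column name -> role)")
  structure(list(criterion = criterion, direction = direction,
                 duration = duration, event = event, id = id,
                 roles = roles, sentinels = as.character(sentinels)),
            class = "fsopa_roles")
}

infer_kind <- function(cells, missing) {
  present <- cells[!missing]
  if (length(present) == 0L) return("categorical")
  suppressWarnings(num <- as.numeric(present))
  if (!anyNA(num)) "numeric" else "categorical"
}

#' Construct a feature table from raw character cells
#'
#' The container for all downstream stages: an n x l table of raw cell
#' strings with a per-cell missing mask, per-column inferred kinds
#' (`numeric`/`categorical`) and roles. Row order is significant and
#' preserved everywhere; it is the alignment key across columns for the
#' compression distances.
#'
#' @param cells A data.frame (or list of equal-length character vectors) of
#'   raw cell values; column names must be unique and non-empty.
#' @param config A [role_config()] naming the criterion column; may be
#'   `NULL` for tables used without ranking.
#'
#' @return An object of class `fsopa_table` with fields `data` (character
#'   data.frame), `missing` (logical matrix), `kinds`, `roles`, `n`,
#'   `config`.
#' @export
feature_table <- function(cells, config = NULL) {
  df <- as.data.frame(cells, stringsAsFactors = FALSE, check.names = FALSE,
                      optional = TRUE)
  nm <- names(df)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("all columns must be named")
  if (anyDuplicated(nm))
    stop("duplicate column names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (nrow(df) < 1L) stop("table must have at least one row")
  df[] <- lapply(df, as.character)
  sentinels <- if (is.null(config)) c("", "NA") else config$sentinels
  miss <- vapply(df, function(col) is.na(col) | col %in% sentinels,
                 logical(nrow(df)))
  miss <- matrix(miss, nrow = nrow(df), dimnames = list(NULL, nm))
  kinds <- vapply(nm, function(j) infer_kind(df[[j]], miss[, j]), character(1))
  roles <- rep("feature", length(nm)); names(roles) <- nm
  if (!is.null(config)) {
    for (special in c("criterion", "duration", "event", "id")) {
      cn <- config[[special]]
      if (!is.null(cn)) {
        if (!cn %in% nm)
          stop("configured ", special, " column '", cn, "' not in table")
        if (special == "duration" && identical(cn, config$criterion)) next
        roles[cn] <- special
      }
    }
    if (length(config$roles)) {
      unknown <- setdiff(names(config$roles), nm)
      if (length(unknown))
        stop("role overrides for unknown columns: ",
             paste(unknown, collapse = ", "))
      plain <- roles[names(config$roles)] == "feature"
      roles[names(config$roles)[plain]] <- config$roles[plain]
    }
    ev <- config$event
    if (!is.null(ev)) {
      vals <- df[[ev]][!miss[, ev]]
      if (length(vals) && !all(vals %in% c("0", "1")))
        stop("event column '", ev, "' must be coded in {0,1}")
    }
  }
  structure(list(data = df, missing = miss, kinds = kinds, roles = roles,
                 n = nrow(df), config = config),
            class = "fsopa_table")
}

#' @export
print.fsopa_table <- function(x, ...) {
  cat("<fsopa_table> ", x$n, " samples x ", ncol(x$data), " columns\n", sep = "")
  cat("  kinds: ", paste(sprintf("%s=%d", names(table(x$kinds)),
                                 table(x$kinds)), collapse = ", "), "\n", sep = "")
  if (!is.null(x$config))
    cat("  criterion: ", x$config$criterion, " (", x$config$direction, ")\n",
        sep = "")
  invisible(x)
}

#' Read a delimited table into a feature table
#'
#' Reads a CSV (RFC-4180 quoting, header required) with every cell kept as a
#' raw string, applies the missing-value sentinels and validates structure.
#' Ragged rows are rejected with the offending row number; duplicate header
#' names are an error.
#'
#' @param path Path to a CSV file with a header row.
#' @param config A [role_config()]; optional.
#' @param sep Field separator, default comma.
#' @return An `fsopa_table`.
#' @export
read_feature_table <- function(path, config = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(nf) < 2L) stop("file has no data rows: ", path)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged input: row ", bad, " has ", nf[bad],
         " fields, expected ", nf[1L])
  }
  header <- utils::read.csv(path, header = FALSE, nrows = 1L, sep = sep,
                            colClasses = "character", check.names = FALSE)
  nm <- as.character(unlist(header, use.names = FALSE))
  if (anyDuplicated(nm))
    stop("duplicate column names in header: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  df <- utils::read.csv(path, header = FALSE, skip = 1L, sep = sep,
                        colClasses = "character", check.names = FALSE,
                        na.strings = character())
  names(df) <- nm
  feature_table(df, config = config)
}

#' Write a feature table back to CSV
#'
#' Canonical writer for derived subsets: same dialect as [read_feature_table()],
#' missing cells emitted as the first configured sentinel. Round-trips
#' cell-exactly on the string representation.
#'
#' @param table An `fsopa_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "fsopa_table"))
  df <- table$data
  sentinel <- missing_sentinel(table)
  for (j in seq_along(df)) df[[j]][table$missing[, j]] <- sentinel
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

missing_sentinel <- function(table) {
  s <- if (!is.null(table$config)) table$config$sentinels else c("", "NA")
  s2 <- s[nzchar(s)]
  if (length(s2)) s2[1L] else "NA"
}

#' Fraction of missing cells in a column
#'
#' @param table An `fsopa_table`.
#' @param column Column name.
#' @return Fraction in `[0, 1]`: masked cells over n.
#' @export
missing_fraction <- function(table, column) {
  stopifnot(inherits(table, "fsopa_table"))
  if (!column %in% colnames(table$missing))
    stop("unknown column: ", column)
  mean(table$missing[, column])
}

#' Numeric view of a column (NA where missing or unparseable)
#' @param table An `fsopa_table`.
#' @param column Column name.
#' @return Numeric vector of length n.
#' @export
column_values <- function(table, column) {
  stopifnot(inherits(table, "fsopa_table"))
  if (!column %in% names(table$data)) stop("unknown column: ", column)
  v <- table$data[[column]]
  v[table$missing[, column]] <- NA
  suppressWarnings(as.numeric(v))
}

#' Restrict a feature table to a subset of columns (and/or rows)
#' @param table An `fsopa_table`.
#' @param columns Character vector of column names to keep (in table order).
#' @param rows Optional integer row indices to keep, in the given order.
#' @return An `fsopa_table`.
#' @export
subset_table <- function(table, columns = NULL, rows = NULL) {
  stopifnot(inherits(table, "fsopa_table"))
  df <- table$data
  if (!is.null(columns)) {
    miss <- setdiff(columns, names(df))
    if (length(miss)) stop("unknown columns: ", paste(miss, collapse = ", "))
    df <- df[, names(df)[names(df) %in% columns], drop = FALSE]
  }
  if (!is.null(rows)) df <- df[rows, , drop = FALSE]
  rownames(df) <- NULL
  cfg <- table$config
  if (!is.null(cfg) && length(cfg$roles))
    cfg$roles <- cfg$roles[names(cfg$roles) %in% names(df)]
  feature_table(df, config = cfg)
}

feature_names <- function(table) names(table$data)
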