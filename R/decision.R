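#' Non-dominated (Pareto) front over feature count and normalized AIC
#'
#' Both coordinates are minimized. Point p dominates q when p is no worse
#' in both coordinates and strictly better in at least one; the front is
#' the set of points dominated by none. Duplicates of a front point are all
#' kept in the front.
#'
#' @param points Data frame (or matrix) with columns `k` (number of
#'   features) and `a` (normalized AIC), one row per model; a list of
#'   `fsopa_model` objects is also accepted.
#' @return An object of class `fsopa_front`: `points` (data.frame with
#'   `k`, `a`, `label`, `on_front`), `front` (row indices of the front, in
#'   input order).
#' @export
pareto_front <- function(points) {
  pts <- as_point_frame(points)
  n <- nrow(pts)
  if (n == 0L) stop("need at least one point")
  # q is dominated iff some point has k' <= k, a' <= a with one strict;
  # equivalently a > min a at its k, or min a at some smaller-or-equal k
  # (strictly smaller k, or equal k via the first clause) is <= a.
  on_front <- logical(n)
  ks <- sort(unique(pts$k))
  min_at <- vapply(ks, function(k) min(pts$a[pts$k == k]), numeric(1))
  prefix_min <- cummin(min_at)
  for (i in seq_len(n)) {
    ki <- match(pts$k[i], ks)
    if (pts$a[i] > min_at[ki]) next
    if (ki > 1L && prefix_min[ki - 1L] <= pts$a[i]) next
    on_front[i] <- TRUE
  }
  pts$on_front <- on_front
  structure(list(points = pts, front = which(on_front)),
            class = "fsopa_front")
}

as_point_frame <- function(points) {
  if (inherits(points, "fsopa_front")) return(points$points)
  if (is.list(points) && length(points) && inherits(points[[1]], "fsopa_model")) {
    return(data.frame(
      k = vapply(points, function(p) length(p$features), integer(1)),
      a = vapply(points, function(p)
        if (is.null(p$aic_normalized)) p$aic else p$aic_normalized,
        numeric(1)),
      label = vapply(points, function(p)
        if (is.null(p$label)) "" else p$label, character(1)),
      stringsAsFactors = FALSE))
  }
  pts <- as.data.frame(points)
  if (!all(c("k", "a") %in% names(pts))) {
    if (ncol(pts) < 2L) stop("points need columns k and a")
    names(pts)[1:2] <- c("k", "a")
  }
  if (is.null(pts$label)) pts$label <- rownames(pts)
  pts
}

#' @export
print.fsopa_front <- function(x, ...) {
  cat("<fsopa_front> ", nrow(x$points), " points, ", length(x$front),
      " non-dominated\n", sep = "")
  print(x$points[x$front, c("label", "k", "a")], row.names = FALSE)
  invisible(x)
}

#' Elbow point of a Pareto front
#'
#' Normalizes both coordinates to [0, 1] over the front and returns the
#' front point closest (Euclidean) to the ideal point (0, 0). Ties are
#' broken toward fewer features, then lower normalized AIC.
#'
#' @param front An `fsopa_front` (or anything [pareto_front()] accepts).
#' @return Row index (into the original points) of the elbow point; the
#'   point itself is in `attr(, "point")`.
#' @export
elbow <- function(front) {
  if (!inherits(front, "fsopa_front")) front <- pareto_front(front)
  idx <- front$front
  pts <- front$points[idx, , drop = FALSE]
  rng <- function(v) if (diff(range(v)) == 0) rep(0, length(v))
                     else (v - min(v)) / diff(range(v))
  d <- sqrt(rng(pts$k)^2 + rng(pts$a)^2)
  ord <- order(d, pts$k, pts$a)
  pick <- idx[ord[1L]]
  structure(pick, point = front$points[pick, , drop = FALSE])
}

#' JSON report of a Pareto front
#' @param front An `fsopa_front`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_front <- function(front, path) {
  el <- elbow(front)
  out <- list(points = front$points,
              front = front$points[front$front, , drop = FALSE],
              elbow = front$points[as.integer(el), , drop = FALSE])
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}
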