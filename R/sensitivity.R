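congruence <- function(a, b) length(intersect(a$leaves, b$leaves))

sym_diff_size <- function(a, b)
  length(setdiff(a$leaves, b$leaves)) + length(setdiff(b$leaves, a$leaves))

pair_key <- function(p)
  paste(paste(p$best$leaves, collapse = ","),
        paste(p$worst$leaves, collapse = ","), sep = "|")

# Evaluate the two possible pairings of one best split with one worst split.
# p1 is the most congruent pair; score the pairing by p1's congruence, with
# ties broken by fewer total symmetric-difference leaves, then by a
# deterministic lexicographic key.
evaluate_pairing <- function(bs, ws) {
  pairings <- list(
    list(a = list(best = bs$c1, worst = ws$c1),
         b = list(best = bs$c2, worst = ws$c2)),
    list(a = list(best = bs$c1, worst = ws$c2),
         b = list(best = bs$c2, worst = ws$c1)))
  best <- NULL
  for (pr in pairings) {
    ca <- congruence(pr$a$best, pr$a$worst)
    cb <- congruence(pr$b$best, pr$b$worst)
    if (cb > ca) { p1 <- pr$b; p2 <- pr$a; c1 <- cb } else {
      p1 <- pr$a; p2 <- pr$b; c1 <- ca
    }
    cand <- list(p1 = p1, p2 = p2, congruence = c1,
                 symdiff = sym_diff_size(p1$best, p1$worst) +
                           sym_diff_size(p2$best, p2$worst),
                 key = pair_key(p1))
    if (is.null(best) || cand$congruence > best$congruence ||
        (cand$congruence == best$congruence &&
         (cand$symdiff < best$symdiff ||
          (cand$symdiff == best$symdiff && cand$key < best$key))))
      best <- cand
  }
  best
}

#' Pair best-model and worst-model clades by congruence
#'
#' Given the candidate middle splits of a best-model phylogram and a
#' worst-model phylogram over the same leaf universe, evaluates every
#' candidate combination and both pairings within each, and keeps the
#' arrangement whose most congruent pair (shared-leaf count) is maximal.
#' Remaining ties are broken by fewer total symmetric-difference leaves and
#' then lexicographically, so the result is deterministic.
#'
#' @param best_splits,worst_splits Candidate lists from [split_middle()]
#'   (or a single split).
#' @return List of class `fsopa_pairing` with `p1`, `p2` (each
#'   `list(best =, worst =)` of `fsopa_clade`), `congruence` (of p1),
#'   `best_split`, `worst_split` (the chosen splits).
#' @export
pair_by_congruence <- function(best_splits, worst_splits) {
  if (!is.null(best_splits$c1)) best_splits <- list(best_splits)
  if (!is.null(worst_splits$c1)) worst_splits <- list(worst_splits)
  ub <- sort(c(best_splits[[1]]$c1$leaves, best_splits[[1]]$c2$leaves))
  uw <- sort(c(worst_splits[[1]]$c1$leaves, worst_splits[[1]]$c2$leaves))
  if (!identical(ub, uw))
    stop("best and worst splits cover different leaf universes")
  best <- NULL
  for (bs in best_splits) {
    for (ws in worst_splits) {
      cand <- evaluate_pairing(bs, ws)
      cand$best_split <- bs
      cand$worst_split <- ws
      if (is.null(best) || cand$congruence > best$congruence ||
          (cand$congruence == best$congruence &&
           (cand$symdiff < best$symdiff ||
            (cand$symdiff == best$symdiff && cand$key < best$key))))
        best <- cand
    }
  }
  class(best) <- "fsopa_pairing"
  best
}

changed_sibling_leaves <- function(pair) {
  common <- intersect(pair$best$leaves, pair$worst$leaves)
  changed <- character(0)
  for (leaf in common) {
    if (!setequal(sibling_set(leaf, pair$best), sibling_set(leaf, pair$worst)))
      changed <- c(changed, leaf)
  }
  sort(changed)
}

#' Clade-based sensitivity (SM1) for one category
#'
#' Splits the best-model and worst-model phylograms at the middle of their
#' longest paths, pairs the resulting clades by congruence, and selects the
#' leaves whose sibling sets differ between the paired best and worst
#' clades. Leaves present in only one clade of a pair cannot be compared
#' and are recorded as unpaired.
#'
#' @param best,worst `fsopa_phylogram` or `phylo` objects over the same
#'   leaf universe.
#' @return List with `s1`, `s2` (changed-sibling leaves from the p1 and p2
#'   pairs), `pairing` (the `fsopa_pairing`), and `unpaired`.
#' @export
sm1 <- function(best, worst) {
  pairing <- pair_by_congruence(split_middle(best), split_middle(worst))
  s1 <- changed_sibling_leaves(pairing$p1)
  s2 <- changed_sibling_leaves(pairing$p2)
  unpaired <- sort(c(
    setdiff(union(pairing$p1$best$leaves, pairing$p1$worst$leaves),
            intersect(pairing$p1$best$leaves, pairing$p1$worst$leaves))))
  list(s1 = s1, s2 = s2, pairing = pairing, unpaired = unpaired)
}

target_selection <- function(clade, target) {
  if (!target %in% clade$leaves) return(NULL)
  sort(union(target, sibling_set(target, clade)))
}

#' Target-based sensitivity (SM2) for one category
#'
#' Reuses the clades found by SM1's middle splits: in the best-model and
#' worst-model clades containing the target feature, selects the target plus
#' every leaf of the subtree rooted at the target's sibling node, and takes
#' the union of the two selections.
#'
#' @param pairing An `fsopa_pairing` from [sm1()]/[pair_by_congruence()],
#'   or `best`/`worst` phylograms may be given directly.
#' @param target Target feature name; must be a leaf of both trees.
#' @param best,worst Optional phylograms, used when `pairing` is missing.
#' @return Sorted character vector: the criterion-based list for this
#'   category.
#' @export
sm2 <- function(pairing = NULL, target, best = NULL, worst = NULL) {
  if (is.null(pairing)) {
    if (is.null(best) || is.null(worst))
      stop("provide either a pairing or both phylograms")
    pairing <- pair_by_congruence(split_middle(best), split_middle(worst))
  }
  bs <- pairing$best_split; ws <- pairing$worst_split
  sel_b <- target_selection(bs$c1, target)
  if (is.null(sel_b)) sel_b <- target_selection(bs$c2, target)
  sel_w <- target_selection(ws$c1, target)
  if (is.null(sel_w)) sel_w <- target_selection(ws$c2, target)
  if (is.null(sel_b) || is.null(sel_w))
    stop("target '", target, "' is not a leaf of both phylograms")
  sort(union(sel_b, sel_w))
}

#' Full feature-sensitivity selection over the six ranked subsets
#'
#' Builds the six phylogram models (one per subset), runs SM1 per category
#' (2C, 4C, 8C) comparing the best-model against the worst-model tree, runs
#' SM2 per target on the same splits, and combines everything: s_clade is
#' the union of the per-category SM1 lists, s_criterion the union of the
#' per-category, per-target SM2 lists, and r their union. Provenance
#' records, for every selected feature, which categories and procedures
#' selected it.
#'
#' @param table An `fsopa_table`.
#' @param subsets An `fsopa_subsets` from [ss_sample()].
#' @param targets Character vector of target features for SM2. Defaults to
#'   the criterion column (when it is among the model columns); pass
#'   `character(0)` for SM1-only mode.
#' @param compressor Compressor name, see [ncd()].
#' @param columns Columns used as model objects; default all.
#' @return An object of class `fsopa_selection`.
#' @export
select_features <- function(table, subsets, targets = NULL,
                            compressor = "gzip", columns = NULL) {
  stopifnot(inherits(table, "fsopa_table"), inherits(subsets, "fsopa_subsets"))
  if (is.null(columns)) columns <- feature_names(table)
  if (is.null(targets)) {
    crit <- if (!is.null(table$config)) table$config$criterion else NULL
    targets <- if (!is.null(crit) && crit %in% columns) crit else character(0)
  }
  models <- lapply(subset_labels(), function(lab)
    build_model(table, subsets[[lab]], compressor = compressor,
                columns = columns, label = lab))
  names(models) <- subset_labels()
  categories <- c("2C", "4C", "8C")
  per_category <- list()
  prov <- list()
  add_prov <- function(features, category, procedure) {
    for (f in features)
      prov[[f]] <<- unique(rbind(prov[[f]],
                                 data.frame(category = category,
                                            procedure = procedure)))
  }
  s_criterion_by_target <- stats::setNames(
    replicate(length(targets), character(0), simplify = FALSE), targets)
  for (cat in categories) {
    best <- models[[paste0("B", substr(cat, 1, 1), "C")]]
    worst <- models[[paste0("W", substr(cat, 1, 1), "C")]]
    res1 <- sm1(best, worst)
    add_prov(res1$s1, cat, "SM1/p1")
    add_prov(res1$s2, cat, "SM1/p2")
    sc <- list()
    for (tg in targets) {
      sel <- sm2(res1$pairing, tg)
      sc[[tg]] <- sel
      s_criterion_by_target[[tg]] <- union(s_criterion_by_target[[tg]], sel)
      add_prov(sel, cat, paste0("SM2[", tg, "]"))
    }
    per_category[[cat]] <- list(
      s1 = res1$s1, s2 = res1$s2, unpaired = res1$unpaired,
      s_criterion = sc,
      best_split = list(c1 = res1$pairing$best_split$c1$leaves,
                        c2 = res1$pairing$best_split$c2$leaves),
      worst_split = list(c1 = res1$pairing$worst_split$c1$leaves,
                         c2 = res1$pairing$worst_split$c2$leaves),
      congruence = res1$pairing$congruence)
  }
  s_clade <- sort(Reduce(union, lapply(per_category, function(x)
    union(x$s1, x$s2)), character(0)))
  s_criterion <- sort(Reduce(union, s_criterion_by_target, character(0)))
  r <- sort(union(s_clade, s_criterion))
  structure(list(per_category = per_category,
                 s_clade = s_clade,
                 s_criterion_by_target = lapply(s_criterion_by_target, sort),
                 s_criterion = s_criterion,
                 r = r,
                 provenance = prov,
                 targets = targets,
                 columns = columns,
                 models = models,
                 compressor = compressor),
            class = "fsopa_selection")
}

#' @export
print.fsopa_selection <- function(x, ...) {
  cat("<fsopa_selection> ", length(x$columns), " candidate features\n",
      "  s_clade     (", length(x$s_clade), "): ",
      paste(x$s_clade, collapse = ", "), "\n",
      "  s_criterion (", length(x$s_criterion), "): ",
      paste(x$s_criterion, collapse = ", "), "\n",
      "  r           (", length(x$r), "): ",
      paste(x$r, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' JSON report of a selection result
#' @param selection An `fsopa_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path) {
  out <- list(
    s_clade = selection$s_clade,
    s_criterion = selection$s_criterion,
    s_criterion_by_target = selection$s_criterion_by_target,
    r = selection$r,
    per_category = lapply(selection$per_category, function(x)
      x[c("s1", "s2", "unpaired", "s_criterion", "best_split",
          "worst_split", "congruence")]),
    provenance = selection$provenance)
  jsonlite::write_json(out, path, auto_unbox = FALSE, dataframe = "rows")
  invisible(path)
}
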