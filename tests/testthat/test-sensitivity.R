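caterpillar <- function(labels) {
  # ((l1,l2),l3,...)-style caterpillar as an unrooted binary tree
  n <- length(labels)
  txt <- paste0("(", labels[1], ",", labels[2], ")")
  for (i in seq(3, n - 1)) txt <- paste0("(", txt, ",", labels[i], ")")
  ape::read.tree(text = paste0(
    "(", substring(txt, 2, nchar(txt) - 1), ",", labels[n], ");"))
}

test_that("longest_path finds the diameter with deterministic tie-breaks", {
  # 2-leaf tree: the single branch
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  p <- longest_path(neighbor_joining(d2))
  expect_equal(length(p) - 1, 2)  # through the degree-2 junction node
  # balanced 4-leaf tree: diameter 3 edges, endpoints from opposite
  # cherries, lexicographically smallest pair is (a, c)
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  tr <- ape::unroot(tr)
  p4 <- longest_path(tr)
  expect_equal(length(p4) - 1, 3)
  expect_equal(tr$tip.label[p4[1]], "a")
  expect_equal(tr$tip.label[p4[length(p4)]], "c")
  # caterpillar on 6 leaves: extremes are the ends; brute-force check
  cat6 <- caterpillar(letters[1:6])
  p6 <- longest_path(cat6)
  adj_lengths <- sapply(seq_along(cat6$tip.label), function(i) {
    b <- fsopa:::bfs_tree(fsopa:::tree_adj(cat6), i)
    max(b$dist[seq_along(cat6$tip.label)], na.rm = TRUE)
  })
  expect_equal(length(p6) - 1, max(adj_lengths))
  # both chain ends tie at the diameter; the lexicographic rule picks (a, e)
  expect_setequal(cat6$tip.label[c(p6[1], p6[length(p6)])], c("a", "e"))
})

test_that("split_middle removes the unique middle edge or returns both
           candidates on even diameters", {
  cat6 <- caterpillar(letters[1:6])   # diameter 5 edges (odd)
  s <- split_middle(cat6)
  expect_length(s, 1)
  expect_setequal(s[[1]]$c1$leaves, c("a", "b", "c"))
  expect_setequal(s[[1]]$c2$leaves, c("d", "e", "f"))
  cat5 <- caterpillar(letters[1:5])   # diameter 4 edges (even)
  s5 <- split_middle(cat5)
  expect_length(s5, 2)
  sizes <- lapply(s5, function(x) sort(c(length(x$c1$leaves),
                                         length(x$c2$leaves))))
  expect_setequal(lapply(sizes, paste, collapse = "-"), c("2-3", "2-3"))
  # 2-leaf tree: clades are the two singletons
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  s2 <- split_middle(neighbor_joining(d2))
  expect_setequal(unlist(lapply(s2, function(x)
    list(x$c1$leaves, x$c2$leaves)), recursive = TRUE), c("a", "b"))
})

test_that("middle splits partition the leaf universe disjointly", {
  for (seed in 1:25) {
    tr <- random_additive_tree(4 + seed %% 9, seed)$tree
    for (s in split_middle(tr)) {
      expect_length(intersect(s$c1$leaves, s$c2$leaves), 0)
      expect_setequal(c(s$c1$leaves, s$c2$leaves), tr$tip.label)
    }
  }
})

test_that("congruence pairing maximizes shared leaves and rejects
           mismatched universes", {
  best <- split_middle(caterpillar(letters[1:6]))
  worst <- split_middle(caterpillar(letters[1:6]))
  pr <- pair_by_congruence(best, worst)
  expect_equal(pr$congruence, 3)            # identical splits: p1 = C1 self-pair
  expect_setequal(pr$p1$best$leaves, pr$p1$worst$leaves)
  expect_setequal(pr$p2$best$leaves, pr$p2$worst$leaves)
  # crossed split {A,B|C,D} vs {A,C|B,D}: best congruence is 1
  t1 <- ape::unroot(ape::read.tree(text = "((A,B),(C,D));"))
  t2 <- ape::unroot(ape::read.tree(text = "((A,C),(B,D));"))
  pr2 <- pair_by_congruence(split_middle(t1), split_middle(t2))
  expect_equal(pr2$congruence, 1)
  t3 <- ape::unroot(ape::read.tree(text = "((P,Q),(R,S));"))
  expect_error(pair_by_congruence(split_middle(t1), split_middle(t3)),
               "universes")
})

test_that("sibling sets read off the rooted clade structure", {
  cat6 <- caterpillar(letters[1:6])
  s <- split_middle(cat6)[[1]]
  left <- if ("a" %in% s$c1$leaves) s$c1 else s$c2
  # clade ((a,b),c) rooted at the cut: cherry partner, and cherry as a
  # sibling subtree
  expect_equal(sibling_set("a", left), "b")
  expect_equal(sibling_set("c", left), c("a", "b"))
  # singleton clade
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  s2 <- split_middle(neighbor_joining(d2))[[1]]
  single <- if (identical(s2$c1$leaves, "a")) s2$c1 else s2$c2
  expect_equal(sibling_set("a", single), character(0))
  expect_error(sibling_set("zzz", left), "not in clade")
})

test_that("sm1 reproduces the reference toy example and is empty on
           identical trees", {
  toy <- toy_phylograms("clade")
  res <- sm1(toy$best, toy$worst)
  expect_equal(res$s1, toy$expected$s1)
  expect_equal(res$s2, toy$expected$s2)
  expect_equal(sort(union(res$s1, res$s2)), toy$expected$s_clade)
  # identical forests select nothing
  same <- sm1(toy$best, toy$best)
  expect_length(c(same$s1, same$s2), 0)
})

test_that("sm1 is symmetric under best/worst exchange and matches a
           brute-force sibling comparison on a cherry swap", {
  labs <- letters[1:6]
  best <- caterpillar(labs)                       # ((a,b),c,d,e,f chain)
  worst <- caterpillar(c("e", "b", "c", "d", "a", "f"))  # a <-> e swapped
  fwd <- sm1(best, worst)
  rev <- sm1(worst, best)
  expect_setequal(union(fwd$s1, fwd$s2), union(rev$s1, rev$s2))
  # brute force: compare sibling sets leaf by leaf inside the paired clades
  pr <- fwd$pairing
  for (pair in list(pr$p1, pr$p2)) {
    for (leaf in intersect(pair$best$leaves, pair$worst$leaves)) {
      changed <- !setequal(sibling_set(leaf, pair$best),
                           sibling_set(leaf, pair$worst))
      expect_equal(leaf %in% c(fwd$s1, fwd$s2), changed, info = leaf)
    }
  }
  # the swapped leaves themselves land on opposite clades, so they are
  # unpaired (skipped by the pairwise comparison), not selected
  expect_setequal(fwd$unpaired, c("a", "e"))
})

test_that("sm2 reproduces the reference target example and degenerate
           cases", {
  toy <- toy_phylograms("target")
  res <- sm1(toy$best, toy$worst)
  expect_equal(sm2(res$pairing, toy$expected$target),
               toy$expected$s_criterion)
  # cherry partner changes from x to y between the models
  b <- ape::read.tree(text = "((t,x),y,(u,v));")
  w <- ape::read.tree(text = "((t,y),x,(u,v));")
  pr <- pair_by_congruence(split_middle(b), split_middle(w))
  expect_setequal(sm2(pr, "t"), c("t", "x", "y"))
  # target isolated as a singleton clade contributes only itself
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("t", "x"),
                                                    c("t", "x")))
  tiny <- neighbor_joining(d2)
  pr1 <- pair_by_congruence(split_middle(tiny), split_middle(tiny))
  expect_equal(sm2(pr1, "t"), "t")
  # mismatched universes are rejected upstream of sm2
  b2 <- caterpillar(c("t", "x", "y", "z"))
  expect_error(pair_by_congruence(split_middle(b2), split_middle(tiny)),
               "universes")
  expect_error(sm2(pr, "absent"), "not a leaf")
})

test_that("sm1 on identical random trees is empty at every category", {
  for (seed in 1:30) {
    tr <- random_additive_tree(4 + seed %% 9, seed + 100)$tree
    res <- sm1(tr, tr)
    expect_length(c(res$s1, res$s2), 0)
  }
})

test_that("select_features combines SM1 and SM2 with full provenance", {
  gen <- generate_table(synth_spec(n = 240, noise_numeric = 3,
                                   noise_categorical = 2, n_date = 1,
                                   n_code = 1, seed = 17))
  tab <- gen$table
  ss <- ss_sample(tab)
  sel <- select_features(tab, ss)
  expect_equal(sel$r, sort(union(sel$s_clade, sel$s_criterion)))
  expect_true(all(sel$r %in% names(tab$data)))
  expect_setequal(names(sel$provenance), sel$r)
  for (cat in c("2C", "4C", "8C")) {
    pc <- sel$per_category[[cat]]
    expect_setequal(c(pc$best_split$c1, pc$best_split$c2), sel$columns)
    expect_length(intersect(pc$best_split$c1, pc$best_split$c2), 0)
  }
  # SM1-only mode
  sel0 <- select_features(tab, ss, targets = character(0))
  expect_length(sel0$s_criterion, 0)
  expect_equal(sel0$r, sel0$s_clade)
  # target selection always contains the target
  expect_true(all(vapply(sel$s_criterion_by_target, function(s)
    "los" %in% s, logical(1))))
})
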