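test_that("column serialization follows subset order and sentinel rule", {
  tab <- feature_table(data.frame(a = c("1", "2", "3"),
                                  b = c("x", "NA", "z")))
  expect_equal(rawToChar(serialize_column(tab, "a", c(1, 3))$payload), "1\n3")
  expect_equal(rawToChar(serialize_column(tab, "b", c(1, 2))$payload),
               "x\nNA")
  # order sensitivity by construction
  expect_false(identical(serialize_column(tab, "a", c(1, 3))$payload,
                         serialize_column(tab, "a", c(3, 1))$payload))
  expect_error(serialize_column(tab, "a", integer(0)), "empty subset")
})

test_that("ncd is symmetric, near 0 on identical payloads and near 1 on
           independent random payloads", {
  x <- fixed_bytes("x", 123)
  x2 <- fixed_bytes("x2", 123)       # same payload, different name
  y <- fixed_bytes("y", 456)
  self <- ncd(x, x2)
  indep <- ncd(x, y)
  expect_lt(self, 0.25)
  expect_gt(indep, 0.8)
  # frozen regression values for the default compressor on these payloads
  expect_equal(self, 0.01498352, tolerance = 1e-6)
  expect_equal(indep, 0.9994007, tolerance = 1e-6)
  expect_identical(ncd(x, y), ncd(y, x))
  expect_identical(ncd(x2, y), ncd(y, x2))
  expect_error(ncd(x, y, compressor = "zip7"), "unknown compressor")
})

test_that("ncd_matrix is symmetric, zero-diagonal and permutation invariant", {
  objs <- lapply(c(a = 1, b = 2, c = 3), function(s) fixed_bytes("t", s))
  for (i in seq_along(objs)) objs[[i]]$name <- names(objs)[i]
  d <- ncd_matrix(objs)
  expect_identical(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_true(all(d >= 0))
  dp <- ncd_matrix(objs[c(3, 1, 2)])
  expect_equal(dp[rownames(d), colnames(d)], d)
  # identical payloads under distinct names -> equal off-diagonals
  same <- lapply(c("p", "q", "r"), function(nm) {
    o <- fixed_bytes(nm, 99); o$name <- nm; o
  })
  ds <- ncd_matrix(same)
  off <- ds[upper.tri(ds)]
  expect_equal(max(off) - min(off), 0)
  expect_error(ncd_matrix(same[c(1, 1)]), "duplicate")
})

test_that("neighbor joining recovers the additive 4-leaf tree exactly", {
  # distances from tree ((A:1,B:2):1,(C:3,D:4))
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  # the matrix is additive: verify the four-point condition first
  sums <- c(d["A", "B"] + d["C", "D"], d["A", "C"] + d["B", "D"],
            d["A", "D"] + d["B", "C"])
  expect_equal(sort(sums)[2], sort(sums)[3])
  tr <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  # split AB|CD present
  expect_true(any(vapply(split_middle(tr), function(s)
    setequal(s$c1$leaves, c("A", "B")) || setequal(s$c1$leaves, c("C", "D")),
    logical(1))))
})

test_that("neighbor joining handles the 2-leaf base case and bad input", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("u", "v"),
                                                       c("u", "v")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$tip.label), c("u", "v"))
  expect_equal(sum(tr$edge.length), 0.4)
  expect_error(neighbor_joining(d[1, 1, drop = FALSE]), "at least 2")
  d[1, 2] <- d[2, 1] <- Inf
  expect_error(neighbor_joining(d), "non-finite")
})

test_that("neighbor joining reproduces random additive matrices entrywise", {
  for (seed in 1:20) {
    l <- 4 + (seed %% 9)
    fix <- random_additive_tree(l, seed)
    tr <- neighbor_joining(fix$d)
    expect_true(all(tr$edge.length >= 0))
    expect_equal(ape::cophenetic.phylo(tr)[rownames(fix$d), colnames(fix$d)],
                 fix$d, tolerance = 1e-9)
  }
})

test_that("fast_newman separates two cliques and never loses to singletons", {
  g <- igraph::make_graph(c(utils::combn(1:4, 2), utils::combn(5:8, 2),
                            1, 5), directed = FALSE)
  res <- fast_newman(g)
  expect_equal(length(unique(res$membership)), 2)
  expect_equal(res$membership[1:4], rep(res$membership[1], 4))
  expect_equal(res$membership[5:8], rep(res$membership[5], 4))
  expect_gte(res$modularity, igraph::modularity(g, seq_len(8)))
  # single edge: one community of both nodes
  g2 <- igraph::make_graph(c(1, 2), directed = FALSE)
  res2 <- fast_newman(g2)
  expect_equal(res2$modularity,
               igraph::modularity(g2, res2$membership))
  expect_error(fast_newman(igraph::make_empty_graph(0, directed = FALSE)),
               "empty graph")
})

test_that("build_model composes serialization, NCD, NJ and communities
           deterministically", {
  set.seed(31)
  base1 <- sample(c("aa", "bb", "cc"), 120, replace = TRUE)
  base2 <- sample(c("xx", "yy"), 120, replace = TRUE)
  df <- data.frame(a1 = base1, a2 = base1, a3 = base1,
                   b1 = base2, b2 = base2, b3 = base2,
                   stringsAsFactors = FALSE)
  tab <- feature_table(df)
  model <- build_model(tab, seq_len(120))
  expect_s3_class(model$tree, "phylo")
  expect_setequal(model$tree$tip.label, names(df))
  # duplicated blocks are separated by one internal edge
  splits <- split_middle(model$tree)
  expect_true(any(vapply(splits, function(s)
    setequal(s$c1$leaves, c("a1", "a2", "a3")) ||
    setequal(s$c1$leaves, c("b1", "b2", "b3")), logical(1))))
  # byte-identical Newick on rerun
  expect_identical(write_newick(build_model(tab, seq_len(120))),
                   write_newick(model))
  # two features -> a single-edge tree
  tab2 <- feature_table(df[, 1:2])
  m2 <- build_model(tab2, seq_len(120))
  expect_equal(length(m2$tree$tip.label), 2)
})

test_that("phylogram leaves always match the table's model columns", {
  gen <- generate_table(synth_spec(n = 160, seed = 5))
  ss <- ss_sample(gen$table)
  for (lab in c("B2C", "W8C")) {
    m <- build_model(gen$table, ss[[lab]], label = lab)
    expect_setequal(m$tree$tip.label, names(gen$table$data))
    # unrooted binary: 2l - 3 edges
    l <- length(m$tree$tip.label)
    expect_equal(nrow(m$tree$edge), 2 * l - 3)
  }
})
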