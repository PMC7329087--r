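# Independent oracles used across the suite. These never call the code
# paths they check.

# Random unrooted binary tree with positive branch lengths and its additive
# (path-length) distance matrix.
random_additive_tree <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.1, 2))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# All set partitions of seq_len(n) as membership vectors (restricted
# growth strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(memb, next_block) {
    i <- length(memb) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- memb; return(invisible()) }
    for (b in seq_len(next_block))
      grow(c(memb, b), max(next_block, b + 1L))
  }
  grow(integer(0), 1L)
  out
}

# Brute-force maximum-modularity partition of a small igraph.
brute_modularity <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 8L)
  best_q <- -Inf; best_m <- NULL
  for (memb in all_partitions(n)) {
    q <- igraph::modularity(g, memb)
    if (q > best_q) { best_q <- q; best_m <- memb }
  }
  list(modularity = best_q, membership = best_m)
}

# Minimal Newton maximizer of the textbook Cox partial likelihood
# (distinct event times assumed; no tie handling needed).
cox_newton_oracle <- function(time, status, X, tol = 1e-12, maxit = 100) {
  X <- as.matrix(X)
  p <- ncol(X)
  events <- which(status == 1)
  logpl <- function(b) {
    eta <- drop(X %*% b)
    sum(vapply(events, function(i) {
      risk <- time >= time[i]
      eta[i] - log(sum(exp(eta[risk])))
    }, numeric(1)))
  }
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta); w <- exp(eta)
    g <- rep(0, p); H <- matrix(0, p, p)
    for (i in events) {
      risk <- which(time >= time[i])
      wr <- w[risk]; sw <- sum(wr)
      xr <- X[risk, , drop = FALSE]
      xbar <- colSums(xr * wr) / sw
      g <- g + X[i, ] - xbar
      xc <- sweep(xr, 2, xbar)
      H <- H + crossprod(xc * wr, xc) / sw
    }
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, logpl = logpl(beta))
}

# O(n^2) all-pairs dominance scan (minimization in both coordinates).
pareto_oracle <- function(k, a) {
  n <- length(k)
  vapply(seq_len(n), function(i) {
    !any(k <= k[i] & a <= a[i] & (k < k[i] | a < a[i]))
  }, logical(1))
}

# Small all-numeric random table with a criterion column.
random_numeric_table <- function(n, l, seed, criterion = "crit") {
  set.seed(seed)
  df <- as.data.frame(matrix(round(stats::runif(n * l), 3), n, l))
  names(df) <- c(criterion, paste0("f", seq_len(l - 1L)))
  df[] <- lapply(df, as.character)
  feature_table(df, config = role_config(criterion = criterion))
}

fixed_bytes <- function(name, seed, size = 10000) {
  set.seed(seed)
  structure(list(name = name,
                 payload = as.raw(sample(0:255, size, replace = TRUE))),
            class = "fsopa_bytes")
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
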