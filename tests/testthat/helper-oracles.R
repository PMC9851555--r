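# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, closed forms, or an
# unrelated library implementation.

# ---- brute-force affine-gap alignment by path enumeration -----------------
# Enumerates every monotone alignment path (diag/up/left) and scores it with
# gap runs costing open + len * extend. Exponential; only for tiny inputs.
brute_align_score <- function(a, b, S, gap_open = 11, gap_extend = 1,
                              local = FALSE) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac)
  m <- length(bc)
  best <- if (local) 0 else -Inf
  rec <- function(i, j, score, state) {
    if (i == n && j == m) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i < n && j < m) {
      rec(i + 1, j + 1, score + S[ac[i + 1], bc[j + 1]], "M")
    }
    if (i < n) {
      pen <- gap_extend + if (state != "U") gap_open else 0
      rec(i + 1, j, score - pen, "U")
    }
    if (j < m) {
      pen <- gap_extend + if (state != "L") gap_open else 0
      rec(i, j + 1, score - pen, "L")
    }
  }
  if (local) {
    # max over all substring pairs of the global score (empty allowed -> 0)
    for (i1 in seq_len(n)) for (i2 in i1:n) {
      for (j1 in seq_len(m)) for (j2 in j1:m) {
        best <- max(best,
                    brute_align_score(paste(ac[i1:i2], collapse = ""),
                                      paste(bc[j1:j2], collapse = ""),
                                      S, gap_open, gap_extend, FALSE))
      }
    }
    return(best)
  }
  rec(0, 0, 0, "start")
  best
}

random_aa <- function(n, seed = NULL) {
  letters20 <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")
  paste(sample(letters20, n, replace = TRUE), collapse = "")
}

# ---- permutations via Heap's algorithm (independent of the package) -------
heap_permutations <- function(n) {
  out <- list()
  a <- seq_len(n)
  rec <- function(k) {
    if (k == 1) {
      out[[length(out) + 1]] <<- a
      return(invisible())
    }
    for (i in seq_len(k)) {
      rec(k - 1)
      if (k %% 2 == 0) {
        tmp <- a[i]; a[i] <<- a[k]; a[k] <<- tmp
      } else {
        tmp <- a[1]; a[1] <<- a[k]; a[k] <<- tmp
      }
    }
  }
  rec(n)
  do.call(rbind, out)
}

# Spearman rho from first principles (no rank/cor shortcuts beyond base
# arithmetic): average ranks, then the covariance formula.
plain_spearman <- function(x, y) {
  r <- function(v) {
    s <- sort(unique(v))
    rk <- numeric(length(v))
    pos <- 1
    for (u in s) {
      idx <- which(v == u)
      rk[idx] <- mean(seq(pos, pos + length(idx) - 1))
      pos <- pos + length(idx)
    }
    rk
  }
  rx <- r(x); ry <- r(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# ---- exhaustive collinear-chain search ------------------------------------
# Maximum chain size over all valid chains among `rows` of an anchor table,
# for one orientation; DFS over successor anchors.
brute_best_chain <- function(an, max_gap) {
  step <- max_gap + 1
  n <- nrow(an)
  if (n == 0) return(0L)
  best <- 1L
  for (sgn in c(1, -1)) {
    succ <- function(u) {
      which(an$idx_a - an$idx_a[u] > 0 & an$idx_a - an$idx_a[u] <= step &
            sgn * (an$idx_b - an$idx_b[u]) > 0 &
            sgn * (an$idx_b - an$idx_b[u]) <= step)
    }
    rec <- function(u, len) {
      best <<- max(best, len)
      for (v in succ(u)) rec(v, len + 1L)
    }
    for (u in seq_len(n)) rec(u, 1L)
  }
  best
}

# ---- tree utilities independent of the package ----------------------------
# Does removing some edge of `tree` split the leaves exactly into `taxa`
# vs complement? BFS over the tree graph minus each edge.
brute_is_monophyletic <- function(tree, taxa) {
  edges <- tree$edge
  n_tip <- length(tree$tip.label)
  n_nodes <- max(edges)
  for (e in seq_len(nrow(edges))) {
    adj <- vector("list", n_nodes)
    for (k in seq_len(nrow(edges))[-e]) {
      adj[[edges[k, 1]]] <- c(adj[[edges[k, 1]]], edges[k, 2])
      adj[[edges[k, 2]]] <- c(adj[[edges[k, 2]]], edges[k, 1])
    }
    comp <- integer(0)
    queue <- edges[e, 2]
    seen <- rep(FALSE, n_nodes)
    seen[queue] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v <= n_tip) comp <- c(comp, v)
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    side <- sort(tree$tip.label[comp])
    if (identical(side, sort(taxa)) ||
        identical(side, sort(setdiff(tree$tip.label, taxa)))) {
      return(TRUE)
    }
  }
  FALSE
}

# ---- shared fixture cache --------------------------------------------------
# One default-scenario fixture + pipeline run per test session.
.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    dir <- file.path(tempdir(), "dupshift-fixture")
    unlink(dir, recursive = TRUE)
    .fixture_cache$fx <- make_fixture(dir, seed = 101)
  }
  .fixture_cache$fx
}

get_pipeline_report <- function() {
  if (is.null(.fixture_cache$report)) {
    .fixture_cache$report <- run_pipeline(
      get_fixture(), params = list(tree = list(n_bootstrap = 200)), seed = 101)
  }
  .fixture_cache$report
}
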