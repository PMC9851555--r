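#' Poisson-corrected protein distances with pairwise deletion
#'
#' For every pair of alignment rows, the proportion of differing residues
#' `p` is computed over the columns where both rows hold an unambiguous
#' residue (pairwise deletion; `X` is treated as missing for distance
#' purposes since it cannot be compared), and corrected to an expected
#' number of substitutions per site `d = -ln(1 - p)` under the
#' equal-rates Poisson model. Saturated pairs (`p >= p_max`) and pairs with
#' fewer than `min_overlap` shared columns are flagged undefined (`NA`)
#' rather than extrapolated.
#'
#' @param msa An [aa_msa] (>= 2 rows).
#' @param min_overlap Minimum number of mutually ungapped columns.
#' @param p_max Saturation guard; `p >= p_max` is undefined.
#' @return A list of class `poisson_dist`: `distance` (symmetric matrix,
#'   zero diagonal), `p` (observed proportions), `valid` (shared-column
#'   counts).
#' @export
poisson_distance <- function(msa, min_overlap = 30, p_max = 0.95) {
  m <- as.matrix(aa_msa(msa))
  if (nrow(m) < 2) stop("need at least two rows", call. = FALSE)
  n <- nrow(m)
  res_ok <- m != "-" & m != "X"
  D <- P <- base::matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  V <- base::matrix(0L, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      both <- res_ok[i, ] & res_ok[j, ]
      nv <- sum(both)
      V[i, j] <- V[j, i] <- nv
      p <- if (nv == 0) NA_real_ else sum(m[i, both] != m[j, both]) / nv
      d <- if (is.na(p) || nv < min_overlap || p >= p_max) NA_real_
           else -log(1 - p)
      P[i, j] <- P[j, i] <- p
      D[i, j] <- D[j, i] <- d
    }
  }
  structure(list(distance = D, p = P, valid = V), class = "poisson_dist")
}

as_dist_matrix <- function(D) {
  if (inherits(D, "poisson_dist")) D <- D$distance
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining. On an additive distance matrix the
#' generating topology and branch lengths are recovered exactly. Negative
#' estimated branch lengths are clamped to zero; ties in the Q criterion
#' are broken by the lowest (row, column) index pair in the current matrix
#' order, so results are reproducible.
#'
#' @param D A symmetric distance matrix with taxon dimnames, a `dist`, or a
#'   [poisson_distance()] result. Undefined (NA) entries are an error.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as_dist_matrix(D)
  if (anyNA(D)) {
    idx <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    pairs <- apply(idx, 1, function(k)
      paste(rownames(D)[k[1]], colnames(D)[k[2]], sep = "~"))
    stop("undefined distances for pairs: ", paste(pairs, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(D)
  if (n < 3) stop("need at least three taxa", call. = FALSE)
  labels <- rownames(D)
  nodes <- labels
  while (n > 3) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    vi <- max(vi, 0); vj <- max(vj, 0)
    new_node <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt_num(vi),
                        nodes[j], fmt_num(vj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    nodes <- c(nodes[keep], new_node)
    rownames(D) <- colnames(D) <- NULL
    n <- n - 1L
  }
  v1 <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  v2 <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  v3 <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt_num(v1),
                 nodes[2], fmt_num(v2), nodes[3], fmt_num(v3))
  ape::read.tree(text = nwk)
}

# Tips subtended by each node (index list over 1..Ntip+Nnode).
node_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  ord <- stats::reorder(tree, "postorder")$edge
  for (e in seq_len(nrow(ord))) {
    p <- ord[e, 1]; ch <- ord[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# Canonical key of the bipartition induced by a tip set: take the side not
# containing the alphabetically first leaf, sort, join.
bipart_key <- function(tips, all_tips) {
  anchor <- min(all_tips)
  side <- if (anchor %in% tips) setdiff(all_tips, tips) else tips
  paste(sort(side), collapse = "|")
}

#' Non-trivial bipartitions of a tree
#'
#' @param tree A `phylo`.
#' @return A tibble with `node` (child node of the defining edge), `key`
#'   (canonical string of the smaller side), and `tips` (list-column of the
#'   subtended leaf labels). Trivial splits (single leaf or all-but-one)
#'   are excluded.
#' @export
tree_bipartitions <- function(tree) {
  all_tips <- tree$tip.label
  n_tip <- length(all_tips)
  sets <- node_tip_sets(tree)
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(n_tip))
  rows <- purrr::map_dfr(internal, function(nd) {
    tp <- sets[[nd]]
    if (length(tp) < 2 || length(tp) > n_tip - 2) return(NULL)
    tibble(node = nd, key = bipart_key(tp, all_tips), tips = list(sort(tp)))
  })
  dplyr::distinct(rows, .data$key, .keep_all = TRUE)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the non-trivial bipartition sets. Both trees
#' must share the same leaf set.
#'
#' @param t1,t2 `phylo` trees.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets", call. = FALSE)
  }
  k1 <- tree_bipartitions(t1)$key
  k2 <- tree_bipartitions(t2)$key
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Test a taxon set for monophyly (unrooted)
#'
#' True iff removing some edge splits the leaves exactly into `taxa` versus
#' the rest. Singletons and complements of singletons are trivially
#' monophyletic via the corresponding leaf edge.
#'
#' @param tree A `phylo`.
#' @param taxa Character vector, a non-empty proper subset of the leaves.
#' @return A list with `monophyletic` (logical) and `key` (the defining
#'   bipartition key, or `NA`).
#' @export
is_monophyletic <- function(tree, taxa) {
  leaves <- tree$tip.label
  unknown <- setdiff(taxa, leaves)
  if (length(unknown)) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(taxa) == 0 || length(taxa) >= length(leaves)) {
    stop("taxa must be a non-empty proper subset of the leaves", call. = FALSE)
  }
  if (length(taxa) == 1 || length(taxa) == length(leaves) - 1) {
    return(list(monophyletic = TRUE, key = bipart_key(taxa, leaves)))
  }
  key <- bipart_key(taxa, leaves)
  found <- key %in% tree_bipartitions(tree)$key
  list(monophyletic = found, key = if (found) key else NA_character_)
}

#' Test whether one clade nests within another
#'
#' Roots the tree on the outgroup, then checks that `inner` is
#' monophyletic, that the MRCA of `outer` already contains the inner clade
#' (so the inner lineage attaches inside the outer clade rather than
#' sister to it), and that every leaf on the ancestor path from
#' MRCA(`inner`) up to MRCA(`inner` + `outer`) belongs to
#' `inner` + `outer`. This is the topology test for a derived gene lineage
#' (e.g. FNS I) arising inside its parent family's clade (F3H).
#'
#' @param tree A `phylo`.
#' @param outgroup,inner,outer Disjoint character vectors of leaf labels;
#'   `outgroup` non-empty and monophyletic in the unrooted tree.
#' @return A list with `nested` (logical), `inner_monophyletic` (logical).
#' @export
nested_within <- function(tree, outgroup, inner, outer) {
  sets <- list(outgroup = outgroup, inner = inner, outer = outer)
  if (length(outgroup) == 0) stop("outgroup must be non-empty", call. = FALSE)
  ids <- unlist(sets)
  if (anyDuplicated(ids)) {
    stop("outgroup, inner and outer sets must be disjoint", call. = FALSE)
  }
  unknown <- setdiff(ids, tree$tip.label)
  if (length(unknown)) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  og_ok <- is_monophyletic(tree, outgroup)$monophyletic
  if (!og_ok) stop("outgroup is not monophyletic in this tree", call. = FALSE)
  rt <- ape::root(ape::unroot(tree), outgroup = outgroup, resolve.root = TRUE)
  sets_by_node <- node_tip_sets(rt)
  tip_index <- function(labels) match(labels, rt$tip.label)
  mrca_of <- function(labels) {
    if (length(labels) == 1) return(tip_index(labels))
    ape::getMRCA(rt, labels)
  }
  m_in <- mrca_of(inner)
  inner_mono <- setequal(sets_by_node[[m_in]], inner)
  if (!inner_mono) return(list(nested = FALSE, inner_monophyletic = FALSE))
  m_union <- mrca_of(c(inner, outer))
  m_outer <- mrca_of(outer)
  # nested: the outer clade's MRCA already contains the inner clade (i.e.
  # the inner lineage attaches inside the outer clade, not sister to it),
  # and no foreign leaf intervenes between the two MRCAs
  nested <- identical(m_union, m_outer) &&
    all(sets_by_node[[m_union]] %in% c(inner, outer))
  list(nested = nested, inner_monophyletic = TRUE)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-distance NJ tree per replicate, and annotates each internal
#' edge of the full-alignment tree with the percentage of retained
#' replicates containing its bipartition. Replicates whose resampled
#' alignment yields an undefined distance pair are dropped and counted;
#' more than 50% dropped is an error.
#'
#' @param msa An [aa_msa].
#' @param n_reps Number of bootstrap replicates (>= 1); the classic choice
#'   is 1000.
#' @param seed Integer seed; the result is a pure function of
#'   (alignment, `n_reps`, `seed`).
#' @inheritParams poisson_distance
#' @return A list with `tree` (`phylo`, supports in `node.label` as
#'   percentages, `NA` on the root), `support` (tibble of bipartition key
#'   and support), and `dropped` (number of discarded replicates).
#' @export
bootstrap_support <- function(msa, n_reps = 1000, seed = 1,
                              min_overlap = 30, p_max = 0.95) {
  stopifnot(n_reps >= 1)
  msa <- aa_msa(msa)
  m <- as.matrix(msa)
  base_tree <- nj_tree(poisson_distance(msa, min_overlap, p_max))
  counts <- new.env(parent = emptyenv())
  dropped <- 0L
  with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      sub <- m[, cols, drop = FALSE]
      rows <- setNames(apply(sub, 1, paste, collapse = ""), rownames(m))
      dd <- poisson_distance(aa_msa(rows), min_overlap, p_max)
      if (anyNA(dd$distance)) {
        dropped <- dropped + 1L
        next
      }
      tr <- nj_tree(dd)
      for (key in tree_bipartitions(tr)$key) {
        counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
      }
    }
  })
  if (dropped > n_reps / 2) {
    stop(sprintf("%d of %d bootstrap replicates had undefined distances",
                 dropped, n_reps), call. = FALSE)
  }
  retained <- n_reps - dropped
  bp <- tree_bipartitions(base_tree)
  bp$support <- vapply(bp$key, function(k) {
    cnt <- counts[[k]]
    100 * (if (is.null(cnt)) 0L else cnt) / retained
  }, 0)
  n_tip <- length(base_tree$tip.label)
  node_lab <- rep(NA_character_, base_tree$Nnode)
  for (r in seq_len(nrow(bp))) {
    node_lab[bp$node[r] - n_tip] <- fmt_num(bp$support[r])
  }
  base_tree$node.label <- node_lab
  list(tree = base_tree,
       support = bp[, c("key", "tips", "support")],
       dropped = dropped)
}

#' Compare clade verdicts across alternative trees
#'
#' Applies the monophyly and nesting tests to each tree (after pruning all
#' trees to their common leaf set) and reports Robinson-Foulds distances
#' against the first tree, mirroring the manual comparison of topologies
#' from alternative inference tools.
#'
#' @param trees A (optionally named) list of `phylo` trees.
#' @param inner,outer,outgroup Leaf-label sets as in [nested_within()].
#' @return A tibble with one row per tree: `tree`, `n_leaves`, `pruned`,
#'   `inner_monophyletic`, `nested`, `rf_vs_first`.
#' @export
consensus_report <- function(trees, inner, outer, outgroup) {
  stopifnot(length(trees) >= 1)
  nm <- names(trees)
  if (is.null(nm)) nm <- paste0("tree", seq_along(trees))
  common <- Reduce(intersect, lapply(trees, function(t) t$tip.label))
  if (length(common) < 4) {
    stop("common leaf set has fewer than 4 taxa", call. = FALSE)
  }
  pruned_any <- any(vapply(trees, function(t)
    length(t$tip.label) > length(common), TRUE))
  trees <- lapply(trees, function(t) {
    if (length(t$tip.label) > length(common)) ape::keep.tip(t, common)
    else t
  })
  inner <- intersect(inner, common)
  outer <- intersect(outer, common)
  outgroup <- intersect(outgroup, common)
  purrr::map_dfr(seq_along(trees), function(k) {
    t <- trees[[k]]
    mono <- is_monophyletic(t, inner)$monophyletic
    nest <- tryCatch(nested_within(t, outgroup, inner, outer)$nested,
                     error = function(e) NA)
    tibble(tree = nm[k], n_leaves = length(common), pruned = pruned_any,
           inner_monophyletic = mono, nested = nest,
           rf_vs_first = rf_distance(trees[[1]], t))
  })
}
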