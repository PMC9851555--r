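#' Multiple-alignment container
#'
#' An alignment is a named character vector of equal-length strings over the
#' amino-acid alphabet plus `-`, carrying class `aa_msa`. Column occupancy is
#' the fraction of rows holding a non-gap character; `X` counts as a residue
#' (it is an amino-acid placeholder, not a gap).
#'
#' @param rows Named character vector of aligned strings.
#' @return An `aa_msa` object.
#' @export
aa_msa <- function(rows) {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("alignment rows must be named", call. = FALSE)
  }
  lens <- nchar(rows)
  if (length(unique(lens)) > 1) {
    off <- names(rows)[lens != lens[1]][1]
    stop(sprintf("ragged alignment: row '%s' has length %d, expected %d",
                 off, nchar(rows[off]), lens[1]), call. = FALSE)
  }
  structure(toupper(rows), class = "aa_msa")
}

#' @export
print.aa_msa <- function(x, ...) {
  cat(sprintf("<aa_msa: %d rows x %d columns>\n", length(x), nchar(x[1])))
  shown <- head(seq_along(x), 8)
  for (i in shown) {
    s <- unclass(x)[i]
    cat(sprintf("  %-20s %s%s\n", names(x)[i], substr(s, 1, 50),
                if (nchar(s) > 50) "..." else ""))
  }
  if (length(x) > 8) cat(sprintf("  ... %d more rows\n", length(x) - 8))
  invisible(x)
}

#' @export
as.matrix.aa_msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(unclass(x), ""))
  rownames(m) <- names(x)
  m
}

#' @rdname aa_msa
#' @param msa An `aa_msa`.
#' @return `occupancy()` returns the per-column fraction of non-gap rows.
#' @export
occupancy <- function(msa) {
  m <- as.matrix(aa_msa(msa))
  colMeans(m != "-")
}

ungap_row <- function(s) gsub("-", "", s, fixed = TRUE)

#' Progressive multiple sequence alignment
#'
#' A deliberately simple progressive aligner used to align simulated or
#' small candidate sets in-repo: pairwise global alignments give percent
#' identities, `1 - identity/100` distances feed a neighbor-joining guide
#' tree, and profiles are merged bottom-up by affine-gap profile-profile
#' dynamic programming with average-of-pairs BLOSUM62 column scores.
#' For exactly three sequences all three join orders are evaluated and the
#' best sum-of-pairs result kept. Externally computed alignments (MAFFT,
#' MUSCLE) are first-class inputs via [import_alignment()] and generally
#' preferable for real data.
#'
#' @param proteins Proteome tibble or named character vector (>= 2 usually).
#' @param guide Optional guide tree (`phylo`); inferred from identity
#'   distances when `NULL`.
#' @inheritParams align_pair
#' @return An [aa_msa] whose rows, once ungapped, reproduce the inputs.
#' @export
build_msa <- function(proteins, guide = NULL, matrix = blosum62_x(),
                      gap_open = 11, gap_extend = 1) {
  pr <- as_proteome(proteins)
  if (nrow(pr) == 1) {
    warning("single sequence: returned unaligned")
    return(aa_msa(setNames(pr$sequence, pr$id)))
  }
  if (is.null(guide) && nrow(pr) >= 4) {
    idm <- percent_identity_matrix(pr, matrix, gap_open, gap_extend)
    D <- 1 - idm / 100
    guide <- nj_tree(D)
  }
  profiles <- lapply(seq_len(nrow(pr)),
                     function(i) setNames(pr$sequence[i], pr$id[i]))
  names(profiles) <- pr$id
  merge2 <- function(ra, rb) {
    pa <- rows_to_profile(ra, matrix)
    pb <- rows_to_profile(rb, matrix)
    path <- align_profiles_cpp(pa, pb, matrix, gap_open, gap_extend)
    merge_rows <- function(rows, pos) {
      chs <- strsplit(rows, "")
      out <- vapply(chs, function(ch) {
        paste(ifelse(is.na(pos), "-", ch[pos]), collapse = "")
      }, "")
      setNames(out, names(rows))
    }
    c(merge_rows(ra, path$a_pos), merge_rows(rb, path$b_pos))
  }
  if (nrow(pr) == 2) {
    return(aa_msa(merge2(profiles[[1]], profiles[[2]])))
  }
  if (nrow(pr) == 3 && is.null(guide)) {
    # exhaustive guide search: only three join orders exist
    cands <- lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 3, 1)), function(ord) {
      aa_msa(merge2(merge2(profiles[[ord[1]]], profiles[[ord[2]]]),
                    profiles[[ord[3]]]))
    })
    sps <- vapply(cands, sum_of_pairs_score, 0, matrix = matrix,
                  gap_open = gap_open, gap_extend = gap_extend)
    return(aa_msa(unclass(cands[[which.max(sps)]])[pr$id]))
  }
  rows <- progressive_merge(guide, profiles, merge2)
  aa_msa(rows[pr$id])
}

# Column frequency profile (nsym x L) from gapped row strings; frequencies
# are counts over non-gap symbols divided by the number of rows.
rows_to_profile <- function(rows, matrix) {
  m <- do.call(rbind, strsplit(rows, ""))
  nsym <- nrow(matrix)
  L <- ncol(m)
  P <- base::matrix(0, nsym, L)
  for (k in seq_len(nsym)) {
    P[k, ] <- colSums(m == AA_ALPHABET_X[k])
  }
  P / nrow(m)
}

# Post-order traversal of the guide tree, merging leaf profiles pairwise.
progressive_merge <- function(guide, profiles, merge2) {
  tr <- guide
  if (!ape::is.rooted(tr)) {
    tr <- ape::root(tr, outgroup = tr$tip.label[1], resolve.root = TRUE)
  }
  tr <- stats::reorder(tr, "postorder")
  n_tip <- length(tr$tip.label)
  store <- vector("list", n_tip + tr$Nnode)
  for (i in seq_len(n_tip)) store[[i]] <- profiles[[tr$tip.label[i]]]
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    store[[parent]] <- if (is.null(store[[parent]])) store[[child]]
                       else merge2(store[[parent]], store[[child]])
  }
  store[[n_tip + 1L]]
}

#' Trim low-occupancy alignment columns
#'
#' Removes every column whose occupancy is strictly below `min_occupancy`
#' (a column at exactly the threshold is kept). Column order is preserved
#' and the returned index map gives, for each retained column, its original
#' 1-based index.
#'
#' @param msa An [aa_msa].
#' @param min_occupancy Occupancy threshold in `[0, 1]`; default 0.10.
#' @return A list with `msa` (trimmed) and `kept` (strictly increasing
#'   integer vector of original column indices).
#' @export
trim_low_occupancy <- function(msa, min_occupancy = 0.10) {
  stopifnot(min_occupancy >= 0, min_occupancy <= 1)
  msa <- aa_msa(msa)
  occ <- occupancy(msa)
  kept <- which(occ >= min_occupancy)
  if (length(kept) == 0) {
    stop(sprintf("all %d columns fall below the %.3g occupancy threshold",
                 length(occ), min_occupancy), call. = FALSE)
  }
  m <- as.matrix(msa)[, kept, drop = FALSE]
  rows <- setNames(apply(m, 1, paste, collapse = ""), names(msa))
  list(msa = aa_msa(rows), kept = as.integer(kept))
}

#' Read and write aligned FASTA
#'
#' `import_alignment()` reads an aligned FASTA, upper-cases residues, and
#' rejects ragged inputs naming the offending record. `write_alignment()`
#' writes one record per row; a write-then-read round trip reproduces the
#' alignment exactly up to line wrapping.
#'
#' @param path File path.
#' @return An [aa_msa]; for the writer, the path invisibly.
#' @export
import_alignment <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  rows <- setNames(toupper(as.character(aas)), sub("\\s.*$", "", names(aas)))
  aa_msa(rows)
}

#' @rdname import_alignment
#' @param msa An [aa_msa].
#' @export
write_alignment <- function(msa, path) {
  msa <- aa_msa(msa)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(unclass(msa), names(msa))), path)
  invisible(path)
}

# Sum-of-pairs score of an alignment under a substitution matrix with
# affine gap costs applied per row pair (used by tests/benchmarks).
sum_of_pairs_score <- function(msa, matrix = blosum62_x(),
                               gap_open = 11, gap_extend = 1) {
  m <- as.matrix(aa_msa(msa))
  n <- nrow(m)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- m[i, ]
      b <- m[j, ]
      keep <- !(a == "-" & b == "-")
      a <- a[keep]
      b <- b[keep]
      both <- a != "-" & b != "-"
      total <- total + sum(matrix[cbind(a[both], b[both])])
      for (row in list(a == "-", b == "-")) {
        r <- rle(row)
        glens <- r$lengths[r$values]
        if (length(glens)) total <- total - sum(gap_open + glens * gap_extend)
      }
    }
  }
  total
}
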