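#' Optimal pairwise alignment of two protein sequences
#'
#' Affine-gap dynamic programming (Gotoh), global (Needleman-Wunsch) or
#' local (Smith-Waterman). A gap of length \eqn{k} costs
#' `gap_open + k * gap_extend`, the BLAST convention, so the defaults 11/1
#' mirror BLASTp. Percent identity is computed over alignment columns where
#' both rows hold a residue: `100 * identical pairs / aligned pairs`;
#' gap-containing columns do not enter the denominator.
#'
#' @param a,b Amino-acid sequences (single strings over the 20 residues + X).
#' @param mode `"global"` or `"local"`.
#' @param matrix Substitution matrix; defaults to [blosum62_x()].
#' @param gap_open,gap_extend Gap penalties (positive numbers).
#' @return A list with `hit`, a one-row tibble (`query`, `subject`, `score`,
#'   `identity`, `aligned_pairs`), and `alignment`, the two aligned strings.
#' @examples
#' align_pair("ACDE", "ACDF")$hit
#' @export
align_pair <- function(a, b, mode = c("global", "local"),
                       matrix = blosum62_x(), gap_open = 11, gap_extend = 1) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty", call. = FALSE)
  ca <- aa_encode(a, "a")
  cb <- aa_encode(b, "b")
  res <- align_pair_cpp(ca, cb, matrix, gap_open, gap_extend, mode == "local")
  ach <- strsplit(toupper(a), "")[[1]]
  bch <- strsplit(toupper(b), "")[[1]]
  arow <- ifelse(is.na(res$a_pos), "-", ach[res$a_pos])
  brow <- ifelse(is.na(res$b_pos), "-", bch[res$b_pos])
  both <- !is.na(res$a_pos) & !is.na(res$b_pos)
  n_pairs <- sum(both)
  n_ident <- sum(both & arow == brow)
  identity <- if (n_pairs == 0) NA_real_ else 100 * n_ident / n_pairs
  list(
    hit = tibble(query = NA_character_, subject = NA_character_,
                 score = res$score, identity = identity,
                 aligned_pairs = n_pairs),
    alignment = c(a = paste(arow, collapse = ""), b = paste(brow, collapse = ""))
  )
}

#' Pairwise percent-identity matrix
#'
#' Global affine-gap alignment of every sequence pair; identity is computed
#' over mutually ungapped columns. Values are kept at full precision; round
#' only for reporting.
#'
#' @param proteins A proteome tibble or named character vector (>= 2 records).
#' @inheritParams align_pair
#' @return A symmetric numeric matrix (percent), 100 on the diagonal.
#' @export
percent_identity_matrix <- function(proteins, matrix = blosum62_x(),
                                    gap_open = 11, gap_extend = 1) {
  pr <- as_proteome(proteins)
  if (nrow(pr) < 2) stop("need at least two sequences", call. = FALSE)
  n <- nrow(pr)
  M <- diag(100, n)
  dimnames(M) <- list(pr$id, pr$id)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      al <- align_pair(pr$sequence[i], pr$sequence[j], "global",
                       matrix, gap_open, gap_extend)
      M[i, j] <- M[j, i] <- al$hit$identity
    }
  }
  M
}

# Best hit of each target sequence against a set of baits.
best_hits <- function(baits, target, mode, matrix, gap_open, gap_extend) {
  purrr::map_dfr(seq_len(nrow(target)), function(i) {
    hits <- purrr::map_dfr(seq_len(nrow(baits)), function(j) {
      al <- align_pair(target$sequence[i], baits$sequence[j], mode,
                       matrix, gap_open, gap_extend)
      dplyr::mutate(al$hit, query = target$id[i], subject = baits$id[j])
    })
    hits[order(-hits$score), ][1, ]
  })
}

#' Find candidate family members in a target proteome
#'
#' Aligns every target protein against every bait and keeps targets whose
#' best bait hit clears both a score and an identity threshold — the
#' package's stand-in for a BLASTp candidate search. Each target appears at
#' most once, with its best bait, ranked by score.
#'
#' @param baits,target Proteome tibbles (or named character vectors).
#' @param min_score,min_identity Inclusion thresholds (>= 0).
#' @inheritParams align_pair
#' @return A tibble (`query`, `subject`, `score`, `identity`,
#'   `aligned_pairs`) sorted by decreasing score; zero rows (with a warning)
#'   for an empty proteome.
#' @export
find_candidates <- function(baits, target, min_score = 80, min_identity = 40,
                            mode = c("global", "local"),
                            matrix = blosum62_x(), gap_open = 11,
                            gap_extend = 1) {
  mode <- match.arg(mode)
  stopifnot(min_score >= 0, min_identity >= 0)
  empty <- tibble(query = character(), subject = character(),
                  score = numeric(), identity = numeric(),
                  aligned_pairs = integer())
  baits <- as_proteome(baits)
  target <- as_proteome(target)
  if (nrow(baits) == 0 || nrow(target) == 0) {
    warning("empty proteome: no candidates searched")
    return(empty)
  }
  hits <- best_hits(baits, target, mode, matrix, gap_open, gap_extend)
  hits <- dplyr::filter(hits, .data$score >= min_score,
                        .data$identity >= min_identity)
  dplyr::arrange(hits[, c("query", "subject", "score", "identity",
                          "aligned_pairs")], dplyr::desc(.data$score))
}

#' Reciprocal best hits between two proteomes
#'
#' `(a, b)` is reported iff `b` is the unique best-scoring hit of `a` in B
#' and `a` is the unique best-scoring hit of `b` in A. Ties for best score
#' disqualify the sequence: a duplicated gene whose two copies score equally
#' produces no pair.
#'
#' @param proteome_a,proteome_b Proteome tibbles (or named character vectors).
#' @param min_score Minimum alignment score for a hit to be considered.
#' @inheritParams align_pair
#' @return A tibble with columns `id_a`, `id_b`, `score`.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b, min_score = 0,
                                 matrix = blosum62_x(), gap_open = 11,
                                 gap_extend = 1) {
  A <- as_proteome(proteome_a)
  B <- as_proteome(proteome_b)
  empty <- tibble(id_a = character(), id_b = character(), score = numeric())
  if (nrow(A) == 0 || nrow(B) == 0) return(empty)
  S <- Matrix_scores(A, B, matrix, gap_open, gap_extend)
  unique_best <- function(scores) {
    best <- max(scores)
    if (best < min_score || sum(scores == best) != 1) NA_integer_
    else which.max(scores)
  }
  best_in_b <- apply(S, 1, unique_best)  # per A row
  best_in_a <- apply(S, 2, unique_best)  # per B column
  pairs <- purrr::map_dfr(seq_len(nrow(A)), function(i) {
    j <- best_in_b[i]
    if (!is.na(j) && !is.na(best_in_a[j]) && best_in_a[j] == i) {
      tibble(id_a = A$id[i], id_b = B$id[j], score = S[i, j])
    } else {
      empty
    }
  })
  pairs
}

# Full score matrix A x B (global alignment scores).
Matrix_scores <- function(A, B, matrix, gap_open, gap_extend) {
  S <- base::matrix(NA_real_, nrow(A), nrow(B),
                    dimnames = list(A$id, B$id))
  enc_a <- lapply(seq_len(nrow(A)), function(i) aa_encode(A$sequence[i], A$id[i]))
  enc_b <- lapply(seq_len(nrow(B)), function(j) aa_encode(B$sequence[j], B$id[j]))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      S[i, j] <- align_pair_cpp(enc_a[[i]], enc_b[[j]], matrix,
                                gap_open, gap_extend, FALSE)$score
    }
  }
  S
}
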