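#' Transcripts-per-million normalization
#'
#' `tpm[g, s] = 1e6 * (counts[g, s] / length[g]) / sum_h (counts[h, s] /
#' length[h])`. Every column of the result sums to one million; an all-zero
#' sample stays all-zero with a warning. Note that subsetting genes after
#' normalization breaks the column-sum property — re-normalization is never
#' done silently.
#'
#' @param counts Non-negative count matrix, genes x samples, with rownames.
#' @param lengths Per-gene effective lengths in bp (named or in row order);
#'   must be strictly positive.
#' @return A TPM matrix of the same shape.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  stopifnot(length(lengths) == nrow(counts))
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    bad <- rownames(counts)[is.na(lengths) | lengths <= 0]
    stop("non-positive effective length for gene(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  rate <- counts / lengths
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero sample(s) left all-zero", sum(zero)))
    denom[zero] <- 1
  }
  sweep(rate, 2, denom, "/") * 1e6
}

#' Exclude outliers by the 3-IQR rule
#'
#' Keeps `x` iff `|x - median| <= 3 * IQR`, the rule used to clean
#' per-tissue TPM distributions before plotting. Quartiles use linear
#' interpolation (R's default type-7 quantiles).
#'
#' @param values Numeric vector (>= 1 value).
#' @return The retained values, in input order.
#' @export
exclude_outliers <- function(values) {
  stopifnot(length(values) >= 1)
  med <- median(values)
  iqr <- unname(diff(quantile(values, c(0.25, 0.75), type = 7)))
  values[abs(values - med) <= 3 * iqr]
}

# All permutations of 1..n (n small), as a matrix of rows.
all_permutations <- function(n) {
  if (n == 1) return(base::matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Spearman rank correlation with small-sample exact p-values
#'
#' Rho is the Pearson correlation of average ranks (ties averaged). The
#' two-sided p-value is exact for `n < 8` (full enumeration of all `n!`
#' orderings of one variable), seeded Monte-Carlo with 1e5 permutations for
#' `8 <= n < 10`, and the t approximation with `n - 2` degrees of freedom
#' for `n >= 10`.
#'
#' @param x,y Paired numeric vectors (>= 4 observations).
#' @param mc_seed Seed for the Monte-Carlo branch.
#' @return A list with `rho`, `p`, and `method`; `rho` is `NA` (with
#'   `method = "undefined"`) when either vector has zero variance.
#' @export
spearman_rho <- function(x, y, mc_seed = 1) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, method = "undefined"))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  tol <- 1e-12
  if (n < 8) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(pp) cor(rx, ry[pp]))
    p <- mean(abs(rhos) >= abs(rho) - tol)
    method <- "exact"
  } else if (n < 10) {
    p <- with_seed(mc_seed, {
      hits <- vapply(seq_len(1e5), function(i) {
        abs(cor(rx, sample(ry))) >= abs(rho) - tol
      }, TRUE)
      mean(hits)
    })
    method <- "monte-carlo"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = min(p, 1), method = method)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `padj_(i) = min_(j >= i) p_(j) * m / j`, capped at 1 and mapped back to
#' the input order (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Thresholded co-expression partners of a focal gene
#'
#' Drops lowly expressed genes (mean TPM below `min_mean_tpm`), computes
#' Spearman rho and p for the focal gene against every retained gene across
#' all samples, adjusts p-values over the tested set (Benjamini-Hochberg by
#' default, Bonferroni optional), and reports exactly the pairs with
#' `rho > rho_min` (strict) and adjusted p below `alpha`, sorted by
#' decreasing rho.
#'
#' @param tpm TPM matrix, genes x samples, with rownames.
#' @param focal Focal gene id.
#' @param min_mean_tpm Low-expression floor on the per-gene mean (default 1).
#' @param rho_min Correlation threshold, strict (default 0.65).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param adjust `"BH"` or `"bonferroni"`.
#' @return A tibble of class `coexpression_result` with columns `gene`,
#'   `rho`, `p`, `padj`; attributes record the focal gene and thresholds.
#' @export
coexpression <- function(tpm, focal, min_mean_tpm = 1, rho_min = 0.65,
                         alpha = 0.05, adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  tpm <- as.matrix(tpm)
  if (!focal %in% rownames(tpm)) stop("focal gene not found", call. = FALSE)
  keep <- rowMeans(tpm) >= min_mean_tpm
  if (!keep[focal]) {
    stop(sprintf("focal gene '%s' falls below the mean-TPM floor (%g)",
                 focal, min_mean_tpm), call. = FALSE)
  }
  genes <- setdiff(rownames(tpm)[keep], focal)
  x <- tpm[focal, ]
  res <- purrr::map_dfr(genes, function(g) {
    sp <- spearman_rho(x, tpm[g, ])
    tibble(gene = g, rho = sp$rho, p = sp$p)
  })
  res <- res[!is.na(res$rho), ]
  res$padj <- if (adjust == "BH") bh_adjust(res$p)
              else pmin(res$p * length(res$p), 1)
  edges <- dplyr::arrange(
    dplyr::filter(res, .data$rho > rho_min, .data$padj < alpha),
    dplyr::desc(.data$rho))
  structure(edges, class = c("coexpression_result", class(edges)),
            focal = focal, n_tested = length(genes),
            min_mean_tpm = min_mean_tpm, rho_min = rho_min, alpha = alpha)
}

#' @export
#' @rdname coexpression
#' @param x A `coexpression_result`.
#' @param ... Unused.
glance.coexpression_result <- function(x, ...) {
  tibble(focal = attr(x, "focal"), n_edges = nrow(x),
         n_tested = attr(x, "n_tested"), rho_min = attr(x, "rho_min"),
         alpha = attr(x, "alpha"))
}

#' Per-tissue expression summaries
#'
#' For each requested gene and tissue, applies the 3-IQR outlier rule to
#' the tissue's TPM values and reports distribution statistics plus the
#' retained values (for violin-style plots). Samples without metadata are
#' excluded; empty tissues are omitted with a warning.
#'
#' @param tpm TPM matrix, genes x samples.
#' @param metadata Tibble with columns `sample` and `tissue`.
#' @param genes Gene ids to summarise.
#' @return A tibble: `gene`, `tissue`, `n`, `n_outliers`, `median`, `q25`,
#'   `q75`, and list-column `values` (retained values).
#' @export
tissue_summary <- function(tpm, metadata, genes) {
  tpm <- as.matrix(tpm)
  metadata <- as_tibble(metadata)
  stopifnot(all(c("sample", "tissue") %in% names(metadata)))
  metadata <- metadata[metadata$sample %in% colnames(tpm), ]
  tissues <- unique(metadata$tissue)
  missing_genes <- setdiff(genes, rownames(tpm))
  if (length(missing_genes)) {
    stop("genes not in matrix: ", paste(missing_genes, collapse = ", "),
         call. = FALSE)
  }
  out <- purrr::map_dfr(genes, function(g) {
    purrr::map_dfr(tissues, function(ts) {
      smp <- metadata$sample[metadata$tissue == ts]
      if (length(smp) == 0) {
        warning(sprintf("tissue '%s' has no samples; omitted", ts))
        return(NULL)
      }
      v <- tpm[g, smp]
      kept <- exclude_outliers(v)
      q <- quantile(kept, c(0.25, 0.5, 0.75), type = 7)
      tibble(gene = g, tissue = ts, n = length(kept),
             n_outliers = length(v) - length(kept),
             median = unname(q[2]), q25 = unname(q[1]), q75 = unname(q[3]),
             values = list(unname(kept)))
    })
  })
  out
}

#' Read a genes-x-samples TSV expression matrix
#'
#' @param path TSV with a header row of sample ids and gene ids in the
#'   first column.
#' @return A numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tb[, -1])
  rownames(m) <- dplyr::pull(tb, 1)
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param m Matrix to write.
#' @export
write_expression_tsv <- function(m, path) {
  tb <- dplyr::bind_cols(tibble(gene = rownames(m)), as_tibble(m))
  readr::write_tsv(tb, path)
  invisible(path)
}
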