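#' Read gene order from a GFF3 annotation
#'
#' Imports `gene` features, sorts them by start within each chromosome and
#' assigns 1-based order indices along each chromosome. Overlapping genes
#' are allowed but flagged.
#'
#' @param path GFF3 file path.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `order` and `overlaps_previous`.
#' @export
read_gene_order <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID
  if (is.null(ids)) ids <- names(gr)
  tb <- tibble(gene_id = as.character(ids),
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)))
  tb <- dplyr::arrange(tb, .data$chrom, .data$start, .data$end)
  tb <- dplyr::group_by(tb, .data$chrom)
  tb <- dplyr::mutate(tb,
    order = dplyr::row_number(),
    overlaps_previous = dplyr::coalesce(
      .data$start <= dplyr::lag(cummax(.data$end)), FALSE))
  dplyr::ungroup(tb)
}

#' Chain collinear anchors into microsynteny blocks
#'
#' Dynamic programming over anchor pairs sorted by their order index in
#' genome A: consecutive anchors of a chain must advance strictly in both
#' genomes by at most `max_gap + 1` ranks (parallel orientation) or advance
#' in A while receding in B under the mirrored bound (antiparallel). Chains
#' are extracted greedily by score (number of anchors; ties broken by the
#' leftmost A index), each anchor joins at most one block, and blocks with
#' fewer than `min_anchors` anchors are dropped.
#'
#' @param anchors A tibble/data.frame with columns `id_a`, `id_b`, `idx_a`,
#'   `idx_b` (1-based order indices). Duplicated pairs are deduplicated
#'   with a warning.
#' @param max_gap Maximum number of intervening genes between consecutive
#'   anchors (default 5).
#' @param min_anchors Minimum anchors per reported block (default 3).
#' @return A tibble of blocks: `block`, `orientation`, `n_anchors`,
#'   `span_a`, `span_b`, and a list-column `anchors` holding each block's
#'   anchor table in chain order.
#' @export
chain_anchors <- function(anchors, max_gap = 5, min_anchors = 3) {
  stopifnot(max_gap >= 0, min_anchors >= 1)
  an <- as_tibble(anchors)
  stopifnot(all(c("id_a", "id_b", "idx_a", "idx_b") %in% names(an)))
  dup <- duplicated(an[, c("idx_a", "idx_b")])
  if (any(dup)) {
    warning(sprintf("%d duplicate anchor pairs removed", sum(dup)))
    an <- an[!dup, ]
  }
  an <- dplyr::arrange(an, .data$idx_a, .data$idx_b)
  out <- tibble(block = integer(), orientation = character(),
                n_anchors = integer(), span_a = integer(),
                span_b = integer(), anchors = list())
  if (nrow(an) == 0) return(out)
  avail <- rep(TRUE, nrow(an))
  step <- max_gap + 1
  block_id <- 0L
  repeat {
    idx <- which(avail)
    if (length(idx) == 0) break
    best <- NULL
    for (orient in c("parallel", "antiparallel")) {
      sgn <- if (orient == "parallel") 1 else -1
      ia <- an$idx_a[idx]
      ib <- an$idx_b[idx]
      k <- length(idx)
      dp <- rep(1L, k)
      prev <- rep(NA_integer_, k)
      for (u in seq_len(k)) {
        for (v in seq_len(u - 1)) {
          da <- ia[u] - ia[v]
          db <- sgn * (ib[u] - ib[v])
          if (da > 0 && da <= step && db > 0 && db <= step &&
              dp[v] + 1L > dp[u]) {
            dp[u] <- dp[v] + 1L
            prev[u] <- v
          }
        }
      }
      u <- which.max(dp)  # ties: lowest position = leftmost idx_a
      chain <- integer()
      while (!is.na(u)) {
        chain <- c(u, chain)
        u <- prev[u]
      }
      cand <- list(score = max(dp), rows = idx[chain], orientation = orient,
                   left = ia[chain[1]])
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && cand$left < best$left)) {
        best <- cand
      }
    }
    if (best$score < min_anchors) break
    block_id <- block_id + 1L
    rows <- an[best$rows, ]
    out <- dplyr::bind_rows(out, tibble(
      block = block_id, orientation = best$orientation,
      n_anchors = nrow(rows),
      span_a = max(rows$idx_a) - min(rows$idx_a) + 1L,
      span_b = max(rows$idx_b) - min(rows$idx_b) + 1L,
      anchors = list(rows)))
    avail[best$rows] <- FALSE
  }
  out
}

#' Presence/absence of a gene family across syntenic regions
#'
#' Given microsynteny blocks of each query genome against a reference
#' genome and the family member ids per genome, reports whether a family
#' member lies inside (or within `max_gap` genes of) the block syntenic to
#' the reference's family region, and whether two family members sit in
#' tandem (adjacent order indices) in that genome. A family id missing
#' from a genome's annotation is reported as `absent_from_annotation`,
#' distinct from annotated-but-outside-the-block.
#'
#' @param blocks Named list of [chain_anchors()] results, one per query
#'   genome (A side = reference genome).
#' @param family_ids Named list: for the reference genome and each query
#'   genome, the character vector of family gene ids (possibly empty).
#' @param gene_orders Named list of [read_gene_order()] tibbles per genome.
#' @param reference Name of the reference genome.
#' @param max_gap Slack, in genes, around the block span (default 5).
#' @return A tibble with one row per genome: `genome`, `in_annotation`,
#'   `in_syntenic_block`, `tandem`, `n_family`.
#' @export
locate_family <- function(blocks, family_ids, gene_orders, reference,
                          max_gap = 5) {
  ref_order <- gene_orders[[reference]]
  ref_fam <- family_ids[[reference]]
  ref_idx <- ref_order$order[ref_order$gene_id %in% ref_fam]
  if (length(ref_idx) == 0) {
    warning("no family member annotated in the reference genome")
  }
  genomes <- names(gene_orders)
  purrr::map_dfr(genomes, function(g) {
    go <- gene_orders[[g]]
    fam <- family_ids[[g]]
    fam_rows <- go[go$gene_id %in% fam, ]
    in_annot <- nrow(fam_rows) > 0
    tandem <- nrow(fam_rows) >= 2 && any(diff(sort(fam_rows$order)) == 1)
    if (g == reference) {
      return(tibble(genome = g, in_annotation = in_annot,
                    in_syntenic_block = in_annot, tandem = tandem,
                    n_family = nrow(fam_rows)))
    }
    bl <- blocks[[g]]
    in_block <- FALSE
    if (!is.null(bl) && nrow(bl) > 0 && in_annot && length(ref_idx) > 0) {
      for (r in seq_len(nrow(bl))) {
        anc <- bl$anchors[[r]]
        a_lo <- min(anc$idx_a) - max_gap
        a_hi <- max(anc$idx_a) + max_gap
        if (!any(ref_idx >= a_lo & ref_idx <= a_hi)) next
        b_lo <- min(anc$idx_b) - max_gap
        b_hi <- max(anc$idx_b) + max_gap
        if (any(fam_rows$order >= b_lo & fam_rows$order <= b_hi)) {
          in_block <- TRUE
          break
        }
      }
    }
    if (is.null(bl) || nrow(bl) == 0) {
      warning(sprintf("no synteny blocks for genome '%s'", g))
    }
    tibble(genome = g, in_annotation = in_annot,
           in_syntenic_block = in_block, tandem = tandem,
           n_family = nrow(fam_rows))
  })
}

# Six-frame translations of one chromosome sequence. Returns a tibble of
# open segments (between stop codons) with their genomic anchoring.
six_frame_segments <- function(dna, min_len = 10) {
  L <- nchar(dna)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") Biostrings::DNAString(dna)
         else Biostrings::reverseComplement(Biostrings::DNAString(dna))
    for (off in 0:2) {
      n_cod <- (L - off) %/% 3
      if (n_cod < min_len) next
      aa <- as.character(suppressWarnings(Biostrings::translate(
        Biostrings::subseq(s, off + 1, off + 3 * n_cod),
        if.fuzzy.codon = "X")))
      segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
      pos <- 1L
      for (seg in segs) {
        if (nchar(seg) >= min_len) {
          res[[length(res) + 1]] <- tibble(
            strand = strand, frame = off + 1L,
            aa_start = pos, seq = seg)
        }
        pos <- pos + nchar(seg) + 1L
      }
    }
  }
  dplyr::bind_rows(res)
}

#' Six-frame translated scan of a genome with a protein query
#'
#' Translates all six reading frames (stop codons break segments), locally
#' aligns the protein query against every open segment, and reports hits at
#' or above `min_score` with genomic coordinates back-converted through
#' frame and strand, mirroring a TBLASTN search for gene copies missing
#' from the annotation.
#'
#' @param genome Named character vector of chromosome sequences (DNA), or a
#'   FASTA path.
#' @param query Protein sequence (single string).
#' @param min_score Minimum local alignment score to report.
#' @inheritParams align_pair
#' @return A tibble: `chrom`, `start`, `end` (1-based inclusive genomic),
#'   `strand`, `frame` (1..3 on +, -1..-3 on -), `score`, `identity`,
#'   sorted by decreasing score.
#' @export
translated_scan <- function(genome, query, min_score = 100,
                            matrix = blosum62_x(), gap_open = 11,
                            gap_extend = 1) {
  if (length(genome) == 1 && file.exists(genome[1]) && is.null(names(genome))) {
    dss <- Biostrings::readDNAStringSet(genome)
    genome <- setNames(as.character(dss), sub("\\s.*$", "", names(dss)))
  }
  qc <- aa_encode(query, "query")
  hits <- list()
  for (chrom in names(genome)) {
    dna <- toupper(genome[[chrom]])
    L <- nchar(dna)
    segs <- six_frame_segments(dna)
    if (nrow(segs) == 0) next
    for (k in seq_len(nrow(segs))) {
      seg <- segs[k, ]
      sc <- aa_encode(gsub("[^A-Z]", "X", seg$seq), "segment")
      al <- align_pair_cpp(qc, sc, matrix, gap_open, gap_extend, TRUE)
      if (al$score < min_score || length(al$b_pos) == 0) next
      bpos <- al$b_pos[!is.na(al$b_pos)]
      aa_lo <- seg$aa_start + min(bpos) - 1L
      aa_hi <- seg$aa_start + max(bpos) - 1L
      # nt coordinates on the (possibly reverse-complemented) strand
      nt_lo <- (seg$frame - 1L) + 3L * (aa_lo - 1L) + 1L
      nt_hi <- (seg$frame - 1L) + 3L * aa_hi
      if (seg$strand == "+") {
        gstart <- nt_lo; gend <- nt_hi
      } else {
        gstart <- L - nt_hi + 1L; gend <- L - nt_lo + 1L
      }
      both <- !is.na(al$a_pos) & !is.na(al$b_pos)
      qch <- strsplit(toupper(query), "")[[1]][al$a_pos[both]]
      sch <- strsplit(seg$seq, "")[[1]][al$b_pos[both]]
      hits[[length(hits) + 1]] <- tibble(
        chrom = chrom, start = gstart, end = gend, strand = seg$strand,
        frame = if (seg$strand == "+") seg$frame else -seg$frame,
        score = al$score,
        identity = 100 * sum(qch == sch) / sum(both))
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), frame = integer(), score = numeric(),
                  identity = numeric()))
  }
  dplyr::arrange(out, dplyr::desc(.data$score))
}

#' Hits falling outside annotated gene models
#'
#' A hit is "outside" iff it shares no overlapping base pair (1-based
#' inclusive intervals, strand-agnostic) with any gene model on its
#' chromosome — the filter used to spot unannotated gene copies in a
#' translated genome scan.
#'
#' @param hits A tibble with `chrom`, `start`, `end` (e.g. from
#'   [translated_scan()]).
#' @param gene_models A tibble with `chrom`, `start`, `end` (e.g. from
#'   [read_gene_order()]).
#' @return The subset of `hits` overlapping no gene model.
#' @export
hits_outside_models <- function(hits, gene_models) {
  hits <- as_tibble(hits)
  gene_models <- as_tibble(gene_models)
  if (nrow(hits) == 0) return(hits)
  if (nrow(gene_models) == 0) return(hits)
  h <- GenomicRanges::GRanges(hits$chrom,
                              IRanges::IRanges(hits$start, hits$end))
  g <- GenomicRanges::GRanges(gene_models$chrom,
                              IRanges::IRanges(gene_models$start,
                                               gene_models$end))
  ov <- GenomicRanges::countOverlaps(h, g, ignore.strand = TRUE)
  hits[ov == 0, ]
}
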