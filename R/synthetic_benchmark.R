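#' Published diagnostic residues of the carrot and celery candidates
#'
#' The published residue grid for the seven *Daucus carota* and *Apium
#' graveolens* FNS I / F3H candidate proteins at the eight diagnostic
#' positions (AAP57393.1 numbering), with their reported classes.
#'
#' @return A tibble with columns `sequence`, `name`, `p106` ... `p216`,
#'   `class`.
#' @export
apiaceae_residue_grid <- function() {
  readr::read_tsv(system.file("extdata", "apiaceae_diagnostic_residues.tsv",
                              package = "dupshift"),
                  show_col_types = FALSE)
}

#' Synthetic residue-mapping benchmark set
#'
#' Builds a SYNTHETIC stand-in for the deposited candidate sequences: the
#' real deposited FASTA is not redistributed here, so this constructs an
#' artificial sequence family that embeds exactly the published residue
#' grid ([apiaceae_residue_grid()]) at the correctly mapped reference
#' positions. The set contains a synthetic AAP57393.1-numbering reference
#' (carrying the FNS I profile), a synthetic PaFNSI-numbering reference
#' with a 5-residue insertion and Y at its own position 240 (the Apiaceae
#' rows carry the conserved P at the corresponding column), the seven grid
#' sequences (one with an internal deletion, to exercise gap-aware position
#' bookkeeping), and is returned both pre-aligned and as ungapped
#' sequences. It validates reference-position mapping and classification,
#' not sequence divergence: the synthetic sequences are near-identical
#' outside the diagnostic sites.
#'
#' @param seed Seed for the synthetic background sequence.
#' @return A list: `alignment` (an [aa_msa]), `proteome` (ungapped tibble),
#'   `grid` (the published residue grid), `profile` (a
#'   [diagnostic_profile()] pointing at the synthetic reference).
#' @export
synthetic_residue_benchmark <- function(seed = 42) {
  grid <- apiaceae_residue_grid()
  prof <- diagnostic_profile()
  base_len <- 320L
  ins_after <- 50L   # 5-column insertion (PaFNSI only) after this position
  ins_len <- 5L
  width <- base_len + ins_len
  base <- with_seed(seed, sample(AA_LETTERS, base_len, replace = TRUE))
  # conserved P at the column that PaFNSI numbers 240
  pa240_base_pos <- 240L - ins_len
  base[pa240_base_pos] <- "P"
  col_of_base <- function(pos) ifelse(pos <= ins_after, pos, pos + ins_len)
  make_row <- function(residues_at = NULL, gap_at = NULL) {
    row <- rep("-", width)
    row[col_of_base(seq_len(base_len))] <- base
    if (!is.null(residues_at)) {
      row[col_of_base(prof$positions)] <- residues_at
    }
    if (!is.null(gap_at)) row[col_of_base(gap_at)] <- "-"
    paste(row, collapse = "")
  }
  rows <- c("AAP57393.1_synthetic" = make_row(prof$fnsi_residues))
  # PaFNSI-numbering reference: fills every column (owns the insertion),
  # Y at its own ungapped position 240
  pa <- rep("-", width)
  pa[col_of_base(seq_len(base_len))] <- base
  pa[(ins_after + 1):(ins_after + ins_len)] <-
    with_seed(seed + 1, sample(AA_LETTERS, ins_len, replace = TRUE))
  pa[240L] <- "Y"
  rows["PaFNSI_synthetic"] <- paste(pa, collapse = "")
  for (k in seq_len(nrow(grid))) {
    res <- unlist(grid[k, paste0("p", prof$positions)])
    gap <- if (grid$sequence[k] == "DCAR_009487") 10:12 else NULL
    rows[grid$sequence[k]] <- make_row(res, gap_at = gap)
  }
  aln <- aa_msa(rows)
  prof$reference_id <- "AAP57393.1_synthetic"
  prof$aux_position$reference_id <- "PaFNSI_synthetic"
  proteome <- tibble(id = names(aln), species = NA_character_,
                     sequence = vapply(unclass(aln), ungap_row, ""))
  list(alignment = aln, proteome = proteome, grid = grid, profile = prof)
}
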