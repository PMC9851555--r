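#' Diagnostic residue profile
#'
#' Loads the diagnostic-position profile that separates FNS I from F3H
#' within the Apiaceae: eight active-site positions numbered on the
#' *Petroselinum crispum* FNS I reference (AAP57393.1), the expected FNS I
#' and F3H residues at each, two sufficiency sets known to confer FNS I
#' activity, and the auxiliary P/Y site at position 240 (PaFNSI numbering).
#'
#' @param path Path to a YAML profile; defaults to the profile shipped with
#'   the package.
#' @return A list of class `diagnostic_profile` with elements
#'   `reference_id`, `positions`, `fnsi_residues`, `f3h_residues`,
#'   `sufficiency_sets`, `aux_position`.
#' @export
diagnostic_profile <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "diagnostic_profile.yml",
                        package = "dupshift")
  }
  prof <- yaml::read_yaml(path)
  prof$positions <- as.integer(prof$positions)
  stopifnot(all(diff(prof$positions) > 0),
            length(prof$fnsi_residues) == length(prof$positions),
            length(prof$f3h_residues) == length(prof$positions))
  prof$sufficiency_sets <- lapply(prof$sufficiency_sets, function(s) {
    setNames(unlist(s), names(s))
  })
  structure(prof, class = "diagnostic_profile")
}

#' Map reference-numbered positions through an alignment
#'
#' For each 1-based ungapped position `r` of the reference row, locates the
#' alignment column holding the reference's `r`-th residue and reports, for
#' every row, the character found there (residue or `-`) together with that
#' row's own 1-based ungapped position (NA at a gap).
#'
#' @param msa An [aa_msa] containing the reference row.
#' @param reference_id Row name of the reference sequence.
#' @param positions Integer vector of 1-based reference positions.
#' @return A tibble with columns `id`, `ref_position`, `column`, `residue`,
#'   `own_position`.
#' @export
map_reference_positions <- function(msa, reference_id, positions) {
  msa <- aa_msa(msa)
  if (!reference_id %in% names(msa)) {
    stop(sprintf("reference '%s' not found in alignment", reference_id),
         call. = FALSE)
  }
  m <- as.matrix(msa)
  ref <- m[reference_id, ]
  ref_res_cols <- which(ref != "-")
  if (any(positions < 1) || any(positions > length(ref_res_cols))) {
    stop(sprintf("position beyond reference length (%d ungapped residues)",
                 length(ref_res_cols)), call. = FALSE)
  }
  cols <- ref_res_cols[positions]
  own_pos <- apply(m != "-", 1, cumsum)  # columns x rows
  purrr::map_dfr(seq_along(positions), function(k) {
    col <- cols[k]
    res <- m[, col]
    tibble(id = rownames(m),
           ref_position = positions[k],
           column = col,
           residue = unname(res),
           own_position = unname(ifelse(res == "-", NA_integer_,
                                        own_pos[col, ])))
  })
}

#' Classify a sequence from its diagnostic residues
#'
#' The minimal rule consistent with the published residue grid: all
#' positions matching the FNS I profile gives `FNS_I`; all matching the F3H
#' profile gives `F3H`; at least one FNS I match without all eight gives
#' `FNS_I_LIKE`; no FNS I match and not a full F3H profile gives
#' `UNCLASSIFIED`. Gaps are non-matches, never errors, so truncated gene
#' models degrade visibly.
#'
#' @param residues Character vector of observed residues (or `-`), one per
#'   profile position, in profile order.
#' @param profile A [diagnostic_profile()].
#' @return One of `"FNS_I"`, `"F3H"`, `"FNS_I_LIKE"`, `"UNCLASSIFIED"`.
#' @export
classify_sequence <- function(residues, profile = diagnostic_profile()) {
  stopifnot(length(residues) == length(profile$positions))
  fnsi_match <- residues == profile$fnsi_residues
  f3h_match <- residues == profile$f3h_residues
  if (all(fnsi_match)) "FNS_I"
  else if (all(f3h_match)) "F3H"
  else if (any(fnsi_match)) "FNS_I_LIKE"
  else "UNCLASSIFIED"
}

#' Evaluate the FNS-activity sufficiency sets
#'
#' @param residues Named character vector: names are reference positions
#'   (as characters), values the observed residues.
#' @param profile A [diagnostic_profile()].
#' @return Named logical vector, one flag per sufficiency set; a flag is
#'   true iff every residue of the set is observed at its position.
#' @export
check_sufficiency_sets <- function(residues, profile = diagnostic_profile()) {
  flags <- vapply(profile$sufficiency_sets, function(s) {
    all(residues[names(s)] == s, na.rm = FALSE) %in% TRUE
  }, TRUE)
  names(flags) <- vapply(profile$sufficiency_sets, function(s) {
    paste0(names(s), s, collapse = "+")
  }, "")
  flags
}

#' Inspect the auxiliary P/Y site (position 240, PaFNSI numbering)
#'
#' Maps position 240 of the PaFNSI-numbering reference through the
#' alignment and reports the residue each sequence carries there. Apiaceae
#' FNS I and F3H are both expected to retain P; any other character (or a
#' gap) raises a flag. If the numbering reference is absent the check is
#' skipped with a warning.
#'
#' @param msa An [aa_msa].
#' @param profile A [diagnostic_profile()] (supplies the reference id,
#'   position and expected residue).
#' @return A tibble (`id`, `residue`, `flag`), or `NULL` when skipped.
#' @export
check_position240 <- function(msa, profile = diagnostic_profile()) {
  aux <- profile$aux_position
  msa <- aa_msa(msa)
  if (!aux$reference_id %in% names(msa)) {
    warning(sprintf("position-%d reference '%s' absent; check skipped",
                    aux$position, aux$reference_id))
    return(NULL)
  }
  mp <- map_reference_positions(msa, aux$reference_id, aux$position)
  dplyr::mutate(mp[, c("id", "residue")],
                flag = .data$residue != aux$expected &
                       .data$id != aux$reference_id)
}

#' Diagnostic-residue report table
#'
#' Builds the residue-grid report: one row per sequence (alignment order),
#' one column per diagnostic position, plus the class call and sufficiency
#' flags — the shape used to present FNS I / F3H candidate inspection.
#'
#' @param msa An [aa_msa] containing the numbering reference.
#' @param profile A [diagnostic_profile()].
#' @param include_reference Keep the reference row in the report?
#' @return A tibble with columns `id`, `p<position>`..., `class`,
#'   one logical column per sufficiency set, and `aux240` when the
#'   auxiliary reference is present.
#' @export
build_residue_table <- function(msa, profile = diagnostic_profile(),
                                include_reference = FALSE) {
  msa <- aa_msa(msa)
  mp <- map_reference_positions(msa, profile$reference_id, profile$positions)
  wide <- tidyr::pivot_wider(mp[, c("id", "ref_position", "residue")],
                             names_from = "ref_position",
                             values_from = "residue", names_prefix = "p")
  wide <- wide[match(names(msa), wide$id), ]
  pos_cols <- paste0("p", profile$positions)
  calls <- purrr::map_dfr(seq_len(nrow(wide)), function(i) {
    res <- unlist(wide[i, pos_cols])
    named <- setNames(res, profile$positions)
    flags <- check_sufficiency_sets(named, profile)
    out <- tibble(id = wide$id[i], class = classify_sequence(res, profile))
    for (k in seq_along(flags)) out[[names(flags)[k]]] <- flags[k]
    out
  })
  out <- dplyr::left_join(wide, calls, by = "id")
  aux <- suppressWarnings(check_position240(msa, profile))
  if (!is.null(aux)) {
    out <- dplyr::left_join(
      out, setNames(aux[, c("id", "residue")], c("id", "aux240")), by = "id")
  }
  if (!include_reference) {
    refs <- c(profile$reference_id, profile$aux_position$reference_id)
    out <- out[!out$id %in% refs, ]
  }
  out
}
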