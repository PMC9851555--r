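write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

write_dna_fasta <- function(dna, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(dna), path)
  invisible(path)
}

#' Emit the default duplication-scenario fixture
#'
#' Generates the four-species synthetic dataset (family proteins, annotated
#' genomes, expression matrix) with full ground truth and writes it as
#' plain-text files: per-species protein FASTA and GFF3 + genome FASTA,
#' a TSV expression matrix with sample metadata, truth tables, and the
#' resolved configuration.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param config Optional [simulation_config()]; `seed` overrides its seed.
#' @return Invisibly, a list with `config`, `family`, `genomes`,
#'   `expression` and `paths`.
#' @export
make_fixture <- function(out_dir, seed = 1, config = NULL) {
  if (is.null(config)) config <- simulation_config(seed = as.integer(seed))
  else config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  family <- simulate_gene_family(config)
  genomes <- simulate_genomes(config, family)
  expr <- simulate_expression(config, family)
  species <- ape::read.tree(text = config$species_tree)$tip.label
  paths <- list()
  for (sp in species) {
    g <- genomes[[sp]]
    paths[[paste0("proteins_", sp)]] <-
      write_proteome(g$proteins, file.path(out_dir, paste0(sp, ".faa")))
    paths[[paste0("genome_", sp)]] <-
      write_dna_fasta(g$genome, file.path(out_dir, paste0(sp, ".fna")))
    paths[[paste0("gff_", sp)]] <-
      write_gff3(g$genes, file.path(out_dir, paste0(sp, ".gff3")))
  }
  paths$family <- write_proteome(family$proteome,
                                 file.path(out_dir, "family.faa"))
  paths$expression <- write_expression_tsv(expr$tpm,
                                           file.path(out_dir, "expression.tsv"))
  paths$metadata <- readr::write_tsv(expr$metadata,
                                     file.path(out_dir, "metadata.tsv"))
  paths$truth_classes <- readr::write_tsv(
    family$truth$classes, file.path(out_dir, "truth_classes.tsv"))
  paths$truth_modules <- readr::write_tsv(
    expr$truth, file.path(out_dir, "truth_modules.tsv"))
  writeLines(family$truth$gene_tree, file.path(out_dir, "truth_gene_tree.nwk"))
  cfg <- unclass(config)
  cfg$expression$log_mean <- as.list(cfg$expression$log_mean)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yml"))
  invisible(list(config = config, family = family, genomes = genomes,
                 expression = expr, paths = paths, out_dir = out_dir))
}

default_pipeline_params <- function() {
  list(
    search = list(min_score = 80, min_identity = 40),
    trim = list(min_occupancy = 0.10),
    tree = list(n_bootstrap = 200, min_overlap = 30),
    synteny = list(max_gap = 5, min_anchors = 3),
    coexpress = list(min_mean_tpm = 1, rho_min = 0.65, alpha = 0.05)
  )
}

#' Run the full duplication-inference pipeline on a fixture
#'
#' Orchestrates the evidence chain on a dataset produced by
#' [make_fixture()] (or laid out identically): candidate search, multiple
#' alignment and occupancy trimming, neighbor-joining tree with bootstrap
#' supports, clade monophyly/nesting verdicts, diagnostic-residue
#' classification, microsynteny presence/absence with tandem flags, and
#' thresholded co-expression. Each stage writes its table into
#' `<out_dir>/report` before the next starts; existing stage outputs are
#' reused on rerun (delete the report directory for a fresh run).
#'
#' @param fixture A [make_fixture()] result, or the path of a fixture
#'   directory.
#' @param params Nested list of stage parameters; defaults from
#'   `default_pipeline_params()` are echoed into the resolved
#'   configuration.
#' @param seed Seed for the bootstrap stage.
#' @return A list of class `dupshift_report`: `candidates`, `alignment`
#'   stats, `tree`, `clades`, `residue_table`, `synteny`, `coexpression`,
#'   plus `params` and `out_dir`.
#' @export
run_pipeline <- function(fixture, params = list(), seed = 1) {
  if (is.character(fixture)) fixture <- load_fixture(fixture)
  p <- utils::modifyList(default_pipeline_params(), params)
  report_dir <- file.path(fixture$out_dir, "report")
  dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)
  config <- fixture$config
  species <- ape::read.tree(text = config$species_tree)$tip.label
  ref_sp <- config$duplication_branch[1]
  stage_file <- function(name) file.path(report_dir, paste0(name, ".tsv"))
  stage <- function(name, compute) {
    f <- stage_file(name)
    if (file.exists(f)) {
      return(readr::read_tsv(f, show_col_types = FALSE))
    }
    out <- compute()
    readr::write_tsv(out, f)
    out
  }

  # 1. candidate search: baits = the reference species' focal family
  baits <- fixture$family$proteome[fixture$family$proteome$species == ref_sp, ]
  candidates <- stage("candidates", function() {
    purrr::map_dfr(species, function(sp) {
      hits <- find_candidates(baits, fixture$genomes[[sp]]$proteins,
                              min_score = p$search$min_score,
                              min_identity = p$search$min_identity)
      dplyr::mutate(hits, species = sp)
    })
  })

  # 2. alignment + trimming of the candidate set
  cand_prot <- fixture$family$proteome[
    fixture$family$proteome$id %in% candidates$query, ]
  msa <- build_msa(cand_prot)
  trimmed <- trim_low_occupancy(msa, p$trim$min_occupancy)
  aln_stats <- stage("alignment", function() {
    tibble(n_rows = length(trimmed$msa),
           n_columns_in = nchar(unclass(msa)[1]),
           n_columns_kept = length(trimmed$kept),
           min_occupancy = p$trim$min_occupancy)
  })

  # 3. NJ tree with bootstrap supports
  bs <- bootstrap_support(trimmed$msa, n_reps = p$tree$n_bootstrap,
                          seed = seed, min_overlap = p$tree$min_overlap)
  ape::write.tree(bs$tree, file.path(report_dir, "nj_tree.nwk"))

  # 4. residue classification (numbering on the reference species' FNS I,
  # falling back to its F3H when no duplicate exists)
  prof <- diagnostic_profile()
  ref_fnsi <- cand_prot$id[cand_prot$species == ref_sp &
                             cand_prot$class == "FNS_I"]
  prof$reference_id <- if (length(ref_fnsi)) ref_fnsi[1] else cand_prot$id[1]
  residue_table <- stage("residues", function() {
    tb <- suppressWarnings(
      build_residue_table(trimmed$msa, prof, include_reference = TRUE))
    dplyr::select(tb, !dplyr::any_of("aux240"))
  })

  # 5. clade verdicts: inner = duplicate-lineage calls, outer = parent
  # calls outside the outgroup; the outgroup species is the tip attached
  # directly to the species-tree root
  sp_tree <- ape::read.tree(text = config$species_tree)
  root_kids <- sp_tree$edge[sp_tree$edge[, 1] == length(species) + 1L, 2]
  outgroup_sp <- sp_tree$tip.label[root_kids[root_kids <= length(species)]][1]
  og <- cand_prot$id[cand_prot$species == outgroup_sp]
  inner <- residue_table$id[residue_table$class %in% c("FNS_I", "FNS_I_LIKE")]
  outer <- setdiff(residue_table$id[residue_table$class == "F3H"], og)
  clades <- stage("clades", function() {
    mono <- is_monophyletic(bs$tree, inner)
    nest <- nested_within(bs$tree, og, inner, outer)
    key <- mono$key
    supp <- bs$support$support[bs$support$key == key]
    tibble(inner_monophyletic = mono$monophyletic,
           nested_within_parent = nest$nested,
           inner_clade_support = if (length(supp)) supp else NA_real_)
  })

  # 6. microsynteny vs the reference species
  orders <- lapply(species, function(sp) {
    go <- fixture$genomes[[sp]]$genes
    dplyr::mutate(go, order = dplyr::row_number())
  })
  names(orders) <- species
  fam_ids <- lapply(species, function(sp) {
    candidates$query[candidates$species == sp &
                       candidates$query %in% fixture$family$proteome$id]
  })
  names(fam_ids) <- species
  # duplicate-lineage members only (the Fig-3-style presence call is about
  # the derived copy, not the ubiquitous parent)
  dup_ids <- lapply(fam_ids, function(ids) {
    cls <- residue_table$class[match(ids, residue_table$id)]
    ids[!is.na(cls) & cls %in% c("FNS_I", "FNS_I_LIKE")]
  })
  blocks <- list()
  for (sp in setdiff(species, ref_sp)) {
    rbh <- reciprocal_best_hits(fixture$genomes[[ref_sp]]$proteins,
                                fixture$genomes[[sp]]$proteins)
    anchors <- dplyr::mutate(
      rbh,
      idx_a = orders[[ref_sp]]$order[match(rbh$id_a,
                                           orders[[ref_sp]]$gene_id)],
      idx_b = orders[[sp]]$order[match(rbh$id_b, orders[[sp]]$gene_id)])
    blocks[[sp]] <- chain_anchors(anchors, max_gap = p$synteny$max_gap,
                                  min_anchors = p$synteny$min_anchors)
  }
  synteny <- stage("synteny", function() {
    dup_loc <- suppressWarnings(locate_family(blocks, dup_ids, orders, ref_sp,
                                              max_gap = p$synteny$max_gap))
    fam_loc <- suppressWarnings(locate_family(blocks, fam_ids, orders, ref_sp,
                                              max_gap = p$synteny$max_gap))
    tibble(genome = dup_loc$genome,
           duplicate_in_annotation = dup_loc$in_annotation,
           duplicate_in_block = dup_loc$in_syntenic_block,
           parent_region_in_block = fam_loc$in_syntenic_block,
           tandem = fam_loc$tandem,
           n_family = fam_loc$n_family)
  })

  # 7. co-expression around the duplicate
  focal <- fam_ids[[ref_sp]][grepl("FNSI$", fam_ids[[ref_sp]])]
  coexpr <- NULL
  if (length(focal) == 1 && !is.null(fixture$expression)) {
    coexpr <- stage("coexpression", function() {
      ed <- coexpression(fixture$expression$tpm, focal,
                         min_mean_tpm = p$coexpress$min_mean_tpm,
                         rho_min = p$coexpress$rho_min,
                         alpha = p$coexpress$alpha)
      as_tibble(ed)
    })
  }

  resolved <- list(params = p, seed = seed, package_version =
                     as.character(utils::packageVersion("dupshift")))
  yaml::write_yaml(resolved, file.path(report_dir, "resolved_config.yml"))
  structure(list(candidates = candidates, alignment = aln_stats,
                 tree = bs$tree, support = bs$support, clades = clades,
                 residue_table = residue_table, synteny = synteny,
                 coexpression = coexpr, params = p, out_dir = fixture$out_dir),
            class = "dupshift_report")
}

# Reload a fixture directory written by make_fixture().
load_fixture <- function(dir) {
  cfg_raw <- yaml::read_yaml(file.path(dir, "config.yml"))
  cfg_raw$expression$log_mean <- unlist(cfg_raw$expression$log_mean)
  cfg_raw$diagnostic_positions <- as.integer(cfg_raw$diagnostic_positions)
  config <- do.call(simulation_config, cfg_raw[setdiff(names(cfg_raw), "")])
  species <- ape::read.tree(text = config$species_tree)$tip.label
  fam_prot <- read_proteome(file.path(dir, "family.faa"))
  classes <- readr::read_tsv(file.path(dir, "truth_classes.tsv"),
                             show_col_types = FALSE)
  fam_prot$species <- classes$species[match(fam_prot$id, classes$id)]
  fam_prot$class <- classes$class[match(fam_prot$id, classes$id)]
  family <- list(proteome = fam_prot,
                 truth = list(
                   classes = classes,
                   gene_tree = readLines(file.path(dir,
                                                   "truth_gene_tree.nwk"))))
  genomes <- list()
  for (sp in species) {
    dss <- Biostrings::readDNAStringSet(file.path(dir, paste0(sp, ".fna")))
    genomes[[sp]] <- list(
      genome = setNames(as.character(dss), sub("\\s.*$", "", names(dss))),
      genes = read_gene_order(file.path(dir, paste0(sp, ".gff3"))),
      proteins = read_proteome(file.path(dir, paste0(sp, ".faa")),
                               species = sp))
  }
  tpm <- read_expression_tsv(file.path(dir, "expression.tsv"))
  expr <- list(
    tpm = tpm,
    metadata = readr::read_tsv(file.path(dir, "metadata.tsv"),
                               show_col_types = FALSE),
    truth = readr::read_tsv(file.path(dir, "truth_modules.tsv"),
                            show_col_types = FALSE))
  list(config = config, family = family, genomes = genomes,
       expression = expr, out_dir = dir)
}

#' @export
print.dupshift_report <- function(x, ...) {
  cat("dupshift pipeline report\n")
  cat(sprintf("  candidates: %d hits across %d species\n",
              nrow(x$candidates), length(unique(x$candidates$species))))
  cat(sprintf("  alignment: %d columns kept of %d\n",
              x$alignment$n_columns_kept, x$alignment$n_columns_in))
  cat(sprintf("  clades: monophyletic=%s nested=%s support=%.1f\n",
              x$clades$inner_monophyletic, x$clades$nested_within_parent,
              x$clades$inner_clade_support))
  cat(sprintf("  synteny: duplicate inside syntenic block for %d genome(s), tandem in %d\n",
              sum(x$synteny$duplicate_in_block), sum(x$synteny$tandem)))
  if (!is.null(x$coexpression)) {
    cat(sprintf("  co-expression: %d partner(s) reported\n",
                nrow(x$coexpression)))
  }
  invisible(x)
}
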