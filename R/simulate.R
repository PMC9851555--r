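#' Simulation configuration for the duplication scenario
#'
#' Assembles and validates the parameters of the synthetic study system:
#' a four-species tree (outgroup, basal lineage, two ingroup sisters), a
#' tandem duplication of the parent gene (F3H) on the ingroup stem with
#' neofunctionalizing substitutions at the diagnostic positions (creating
#' FNS I), a later species-specific duplication producing an FNS I-like
#' copy, conserved gene-order blocks with the duplicate inserted next to
#' its parent, and an expression matrix with rank-correlated modules.
#'
#' Defaults encode the study conditions of the Apiaceae FNS I scenario:
#' terminal ingroup branches of 0.112 substitutions/site with the
#' duplication placed near the end of the ingroup stem, so that the
#' within-species FNS I vs F3H identity is ~78% and cross-species FNS I
#' identity ~80%; 146 expression samples with within-module Spearman
#' rho 0.8.
#'
#' @param species_tree Newick string with branch lengths in
#'   substitutions/site.
#' @param duplication_branch Character vector of tip labels: the clade
#'   whose stem edge carries the duplication.
#' @param duplication_at Fraction along that edge (0 = parent end) at
#'   which the duplicate arises.
#' @param like_event `NULL`, or a list with `species`, `at` (fraction
#'   along that species' terminal branch) and `profile` (residues at the
#'   diagnostic positions for the FNS I-like copy).
#' @param n_sites Protein length in residues.
#' @param rate_scale Global rate multiplier.
#' @param diagnostic_positions Strictly increasing 1-based positions
#'   (<= `n_sites`).
#' @param ancestral_profile,derived_profile Residues at those positions for
#'   the parent (F3H) and the neofunctionalized (FNS I) copy.
#' @param aux_position,aux_residue A single always-conserved site (the P of
#'   the 240 P/Y contrast); `NULL` to disable.
#' @param genome_block Ordered family labels shared by every genome; must
#'   contain `"F3H"`.
#' @param intergenic Intergenic spacer length in bp.
#' @param flank_len Length of flanking-family proteins (aa).
#' @param expression List: `n_samples`, `rho_within`, `log_sd`,
#'   `module_size`, `n_null`, `tissues`, and per-class log-scale means.
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    species_tree = paste0("((Casiatica:0.15,(Dcarota:0.112,",
                          "Agraveolens:0.112):0.10):0.05,Pginseng:0.22);"),
    duplication_branch = c("Dcarota", "Agraveolens"),
    duplication_at = 0.98,
    like_event = list(species = "Dcarota", at = 0.3,
                      profile = c("T", "T", "V", "F", "E", "I", "V", "R")),
    n_sites = 360,
    rate_scale = 1,
    diagnostic_positions = c(106L, 115L, 116L, 131L, 195L, 200L, 215L, 216L),
    ancestral_profile = c("M", "I", "V", "I", "D", "V", "L", "K"),
    derived_profile = c("T", "T", "I", "F", "E", "I", "V", "R"),
    aux_position = 240L,
    aux_residue = "P",
    genome_block = c(paste0("G0", 1:5), "F3H", paste0("G", c("06", "07", "08", "09", "10"))),
    intergenic = 200L,
    flank_len = 250L,
    expression = list(n_samples = 146L, rho_within = 0.8, log_sd = 1,
                      module_size = 8L, n_null = 30L,
                      tissues = c("flower", "leaf", "phloem", "petiole",
                                  "root", "callus"),
                      log_mean = c(F3H = 3.5, FNS_I = 3.0,
                                   FNS_I_LIKE = -1.5, partner = 2.5,
                                   null = 1.0)),
    seed = 1L) {
  tree <- ape::read.tree(text = species_tree)
  if (is.null(tree)) stop("species_tree is not valid Newick", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch length", call. = FALSE)
  stopifnot(length(diagnostic_positions) >= 1,
            all(diff(diagnostic_positions) > 0),
            max(diagnostic_positions) <= n_sites,
            length(ancestral_profile) == length(diagnostic_positions),
            length(derived_profile) == length(diagnostic_positions),
            rate_scale >= 0, n_sites >= 1)
  if (!is.null(like_event)) {
    stopifnot(length(like_event$profile) == length(diagnostic_positions),
              like_event$species %in% tree$tip.label)
  }
  if (!"F3H" %in% genome_block) stop("genome_block must contain F3H",
                                     call. = FALSE)
  if (!is.null(expression$rho_within)) {
    stopifnot(expression$rho_within >= -1, expression$rho_within <= 1)
  }
  if (!is.null(expression$n_samples) && expression$n_samples <= 0) {
    stop("n_samples must be positive", call. = FALSE)
  }
  structure(as.list(environment())[c(
    "species_tree", "duplication_branch", "duplication_at", "like_event",
    "n_sites", "rate_scale", "diagnostic_positions", "ancestral_profile",
    "derived_profile", "aux_position", "aux_residue", "genome_block",
    "intergenic", "flank_len", "expression", "seed")],
    class = "simulation_config")
}

# Masked sites: diagnostic positions (class-determined) + the conserved
# auxiliary site. These never change in the stochastic process.
masked_sites <- function(config) {
  ms <- config$diagnostic_positions
  if (!is.null(config$aux_position) && config$aux_position <= config$n_sites) {
    ms <- sort(unique(c(ms, config$aux_position)))
  }
  ms
}

# Evolve a residue vector along a branch of length d (substitutions/site):
# per-site Poisson(d) replacement counts, each replacement drawn uniformly
# from the 19 other residues. Masked sites are frozen.
evolve_seq <- function(seq, d, masked) {
  if (d <= 0) return(seq)
  k <- rpois(length(seq), d)
  k[masked] <- 0L
  idx <- which(k > 0)
  for (i in idx) {
    for (rep_i in seq_len(k[i])) {
      cur <- seq[i]
      seq[i] <- sample(AA_LETTERS[AA_LETTERS != cur], 1)
    }
  }
  seq
}

# Locate the edge whose child clade's tip set equals `tips`.
find_clade_edge <- function(tree, tips) {
  sets <- node_tip_sets(tree)
  for (e in seq_len(nrow(tree$edge))) {
    if (setequal(sets[[tree$edge[e, 2]]], tips)) return(e)
  }
  stop("duplication_branch does not match any edge of the species tree",
       call. = FALSE)
}

short_label <- c(F3H = "F3H", FNS_I = "FNSI", FNS_I_LIKE = "FNSIlike")

#' Simulate the gene family along the species tree
#'
#' Evolves a root protein down the species tree under an i.i.d.-site
#' Poisson replacement process. At the duplication edge the gene is copied;
#' the copy's diagnostic positions are set to the derived (FNS I) profile
#' and both copies are inherited by all descendants. An optional later
#' species-specific duplication spawns an FNS I-like copy with a partial
#' profile. Diagnostic positions are deterministic per copy class, so
#' ground-truth class labels are exact by construction.
#'
#' @param config A [simulation_config()].
#' @return A list with `proteome` (tibble: `id`, `species`, `sequence`,
#'   `class`), `truth` (list: `classes` tibble, `gene_tree` Newick with the
#'   duplication nodes labelled `DUP`, `duplication_edge` index), and
#'   `root_sequence`.
#' @export
simulate_gene_family <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- ape::read.tree(text = config$species_tree)
  dup_edge <- find_clade_edge(tree, config$duplication_branch)
  masked <- masked_sites(config)
  n <- config$n_sites
  rs <- config$rate_scale
  profiles <- list(F3H = config$ancestral_profile,
                   FNS_I = config$derived_profile,
                   FNS_I_LIKE = if (!is.null(config$like_event))
                     config$like_event$profile else NULL)

  with_seed(config$seed, {
    root_seq <- sample(AA_LETTERS, n, replace = TRUE)
    root_seq[config$diagnostic_positions] <- config$ancestral_profile
    if (!is.null(config$aux_position) && config$aux_position <= n) {
      root_seq[config$aux_position] <- config$aux_residue
    }
    records <- list()
    n_tip <- length(tree$tip.label)

    rec <- function(node, copies) {
      # copies: named list class -> residue vector
      if (node <= n_tip) {
        sp <- tree$tip.label[node]
        nwk <- character(0)
        for (cl in names(copies)) {
          gid <- paste(sp, short_label[[cl]], sep = "_")
          seq <- copies[[cl]]
          seq[config$diagnostic_positions] <- profiles[[cl]]
          records[[gid]] <<- tibble(id = gid, species = sp,
                                    sequence = paste(seq, collapse = ""),
                                    class = cl)
          nwk[cl] <- gid
        }
        return(nwk)
      }
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      child_maps <- list()
      for (child in kids) {
        e <- which(tree$edge[, 1] == node & tree$edge[, 2] == child)[1]
        len <- tree$edge.length[e]
        events <- list()
        if (e == dup_edge) {
          events <- c(events, list(list(at = config$duplication_at,
                                        source = "F3H", new = "FNS_I")))
        }
        le <- config$like_event
        if (!is.null(le) && child <= n_tip &&
            tree$tip.label[child] == le$species) {
          events <- c(events, list(list(at = le$at, source = "FNS_I",
                                        new = "FNS_I_LIKE")))
        }
        events <- events[order(vapply(events, `[[`, 0, "at"))]
        cc <- copies
        t_cur <- 0
        birth <- setNames(rep(0, length(cc)), names(cc))
        for (ev in events) {
          seg <- (ev$at - t_cur) * len
          for (cl in names(cc)) cc[[cl]] <- evolve_seq(cc[[cl]], seg * rs,
                                                       masked)
          t_cur <- ev$at
          if (!ev$source %in% names(cc)) {
            stop(sprintf("event source copy '%s' absent on this edge",
                         ev$source), call. = FALSE)
          }
          newseq <- cc[[ev$source]]
          newseq[config$diagnostic_positions] <- profiles[[ev$new]]
          cc[[ev$new]] <- newseq
          birth[ev$new] <- ev$at
        }
        seg <- (1 - t_cur) * len
        for (cl in names(cc)) cc[[cl]] <- evolve_seq(cc[[cl]], seg * rs,
                                                     masked)
        nm <- rec(child, cc)
        # fold events back into newick strings, most recent first
        for (ev in rev(events)) {
          tail_len <- (1 - ev$at) * len
          nm[ev$source] <- sprintf("(%s:%s,%s:%s)DUP",
                                   nm[ev$source], fmt_num(tail_len),
                                   nm[ev$new], fmt_num(tail_len))
          nm <- nm[names(nm) != ev$new]
        }
        attach_len <- vapply(names(nm), function(cl) {
          ev_at <- vapply(events, function(ev)
            if (ev$source == cl) ev$at else NA_real_, 0)
          ev_at <- ev_at[!is.na(ev_at)]
          len * (if (length(ev_at)) min(ev_at) else 1)
        }, 0)
        child_maps[[as.character(child)]] <-
          setNames(sprintf("%s:%s", nm, fmt_num(attach_len)), names(nm))
      }
      all_classes <- unique(unlist(lapply(child_maps, names)))
      out <- character(0)
      for (cl in all_classes) {
        subs <- unlist(lapply(child_maps, function(mp) mp[[cl]]))
        out[cl] <- if (length(subs) == 1) subs
                   else sprintf("(%s)", paste(subs, collapse = ","))
      }
      out
    }

    root <- n_tip + 1L
    root_map <- rec(root, list(F3H = root_seq))
    gene_tree <- paste0(root_map[["F3H"]], ";")
    proteome <- dplyr::bind_rows(records)
    list(proteome = proteome,
         truth = list(classes = proteome[, c("id", "species", "class")],
                      gene_tree = gene_tree,
                      duplication_edge = dup_edge),
         root_sequence = paste(root_seq, collapse = ""))
  })
}

# First codon (in standard-code table order) for each amino acid.
first_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  aas <- unique(gc)
  setNames(names(gc)[match(aas, gc)], aas)
}

back_translate <- function(protein, codon_table = first_codon_table()) {
  aa <- strsplit(protein, "")[[1]]
  cod <- codon_table[aa]
  if (anyNA(cod)) stop("cannot back-translate residue(s): ",
                       paste(unique(aa[is.na(cod)]), collapse = ", "),
                       call. = FALSE)
  paste(cod, collapse = "")
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Simulate annotated genomes with a conserved gene-order block
#'
#' Each species receives the shared ordered block of flanking gene
#' families plus the focal parent gene; species descending from the
#' duplication additionally carry the duplicate immediately downstream of
#' its parent (tandem), and the FNS I-like copy next to the duplicate in
#' its species. Flanking-family proteins are evolved along the species
#' tree with the same replacement process, so cross-species reciprocal
#' best hits recover the collinear anchors. Coding sequences back-translate
#' each protein with the first standard-code codon per residue; genes are
#' separated by random intergenic spacers and alternate strands.
#'
#' @param config A [simulation_config()].
#' @param family A [simulate_gene_family()] result for the focal family.
#' @return A list per species: `genome` (named DNA string), `genes`
#'   (tibble: `gene_id`, `chrom`, `start`, `end`, `strand`, `family`),
#'   `proteins` (proteome tibble of all genes incl. flanking), plus a
#'   `truth` element with the per-genome true gene order.
#' @export
simulate_genomes <- function(config, family) {
  tree <- ape::read.tree(text = config$species_tree)
  species <- tree$tip.label
  masked <- integer(0)
  flank_labels <- setdiff(config$genome_block, "F3H")
  codon_table <- first_codon_table()

  with_seed(config$seed + 1L, {
    # flanking families: one gene per species, evolved along the tree
    flank <- list()
    for (fam in flank_labels) {
      root_seq <- sample(AA_LETTERS, config$flank_len, replace = TRUE)
      seqs <- list()
      n_tip <- length(species)
      rec <- function(node, s) {
        if (node <= n_tip) {
          seqs[[species[node]]] <<- paste(s, collapse = "")
          return(invisible())
        }
        for (child in tree$edge[tree$edge[, 1] == node, 2]) {
          e <- which(tree$edge[, 1] == node & tree$edge[, 2] == child)[1]
          rec(child, evolve_seq(s, tree$edge.length[e] * config$rate_scale,
                                masked))
        }
      }
      rec(n_tip + 1L, root_seq)
      flank[[fam]] <- seqs
    }

    fam_by_sp <- split(family$proteome, family$proteome$species)
    out <- list()
    for (sp in species) {
      fams <- character(0)
      ids <- character(0)
      prots <- character(0)
      for (lab in config$genome_block) {
        if (lab == "F3H") {
          rows <- fam_by_sp[[sp]]
          ord <- match(c("F3H", "FNS_I", "FNS_I_LIKE"), rows$class)
          ord <- ord[!is.na(ord)]
          rows <- rows[ord, ]
          fams <- c(fams, rows$class)
          ids <- c(ids, rows$id)
          prots <- c(prots, rows$sequence)
        } else {
          fams <- c(fams, lab)
          ids <- c(ids, paste(sp, lab, sep = "_"))
          prots <- c(prots, flank[[lab]][[sp]])
        }
      }
      strands <- rep(c("+", "-"), length.out = length(ids))
      pieces <- character(0)
      gene_rows <- list()
      pos <- 1L
      for (k in seq_along(ids)) {
        spacer <- paste(sample(c("A", "C", "G", "T"), config$intergenic,
                               replace = TRUE), collapse = "")
        pieces <- c(pieces, spacer)
        pos <- pos + config$intergenic
        cds <- back_translate(prots[k], codon_table)
        gene_dna <- if (strands[k] == "+") cds else revcomp(cds)
        pieces <- c(pieces, gene_dna)
        gene_rows[[k]] <- tibble(gene_id = ids[k], chrom = "chr1",
                                 start = pos,
                                 end = pos + nchar(gene_dna) - 1L,
                                 strand = strands[k], family = fams[k])
        pos <- pos + nchar(gene_dna)
      }
      tail_spacer <- paste(sample(c("A", "C", "G", "T"), config$intergenic,
                                  replace = TRUE), collapse = "")
      genome <- setNames(paste(c(pieces, tail_spacer), collapse = ""), "chr1")
      genes <- dplyr::bind_rows(gene_rows)
      if (any(genes$start > genes$end)) stop("overlapping coordinates")
      out[[sp]] <- list(
        genome = genome,
        genes = genes,
        proteins = tibble(id = ids, species = sp, sequence = prots))
    }
    out$truth <- lapply(out[species], function(x) x$genes$gene_id)
    out
  })
}

#' Simulate an expression matrix with planted co-expression modules
#'
#' Gaussian-copula construction: genes of a module load on a shared latent
#' factor with loading `sqrt(2 sin(pi rho/6))`, so every within-module pair
#' has population Spearman correlation `rho` after the monotone transform
#' to the log-normal TPM scale; between-module pairs are independent
#' (Spearman 0 in expectation). Focal genes receive class-specific
#' log-scale means reproducing the observed expression ranking (parent and
#' duplicate well expressed, FNS I-like copies low). Samples carry cycling
#' tissue labels, and one marker gene per first tissue is expressed in
#' that tissue only.
#'
#' @param config A [simulation_config()].
#' @param family Optional [simulate_gene_family()] result; its ingroup
#'   reference-species genes become the focal module seeds.
#' @return A list: `tpm` (matrix genes x samples), `metadata` (tibble
#'   `sample`, `tissue`), `truth` (tibble `gene`, `module`).
#' @export
simulate_expression <- function(config, family = NULL) {
  ex <- config$expression
  if (is.null(ex$n_samples) || ex$n_samples <= 0) {
    stop("n_samples must be positive", call. = FALSE)
  }
  rho <- ex$rho_within
  loading <- sqrt(2 * sin(pi * rho / 6))
  lm <- ex$log_mean

  focal <- NULL
  if (!is.null(family)) {
    ref_sp <- config$duplication_branch[1]
    focal <- family$proteome[family$proteome$species == ref_sp, ]
  }
  with_seed(config$seed + 2L, {
    ns <- ex$n_samples
    genes <- list()
    add_gene <- function(name, module, mu, z) {
      genes[[name]] <<- list(module = module, mu = mu, z = z)
    }
    z_f3h <- rnorm(ns)
    z_fnsi <- rnorm(ns)
    mix <- function(zm) loading * zm + sqrt(1 - loading^2) * rnorm(ns)
    if (!is.null(focal)) {
      for (k in seq_len(nrow(focal))) {
        cl <- focal$class[k]
        zm <- if (cl == "F3H") z_f3h else z_fnsi
        module <- if (cl == "F3H") "module_f3h" else
                  if (cl == "FNS_I") "module_fnsi" else "none"
        z <- if (cl == "FNS_I_LIKE") rnorm(ns) else mix(zm)
        add_gene(focal$id[k], module,
                 lm[[if (cl == "FNS_I_LIKE") "FNS_I_LIKE" else cl]], z)
      }
    }
    f3h_partners <- c("CHS", "CHI", "F3pH", "DFR", "LDOX", "GT1", "GT2",
                      "ANTtrans")[seq_len(ex$module_size)]
    fnsi_partners <- c("FLS1", "UGT78", "UGT73", "OMT1", "MYB12", "RBOH1",
                       "PAL2", "C4H2")[seq_len(ex$module_size)]
    for (g in f3h_partners) add_gene(g, "module_f3h", lm[["partner"]],
                                     mix(z_f3h))
    for (g in fnsi_partners) add_gene(g, "module_fnsi", lm[["partner"]],
                                      mix(z_fnsi))
    for (k in seq_len(ex$n_null)) {
      add_gene(sprintf("NULL%03d", k), "none", lm[["null"]], rnorm(ns))
    }
    meta <- tibble(sample = sprintf("S%03d", seq_len(ns)),
                   tissue = rep(ex$tissues, length.out = ns))
    tpm <- do.call(rbind, lapply(genes, function(g) {
      exp(g$mu + ex$log_sd * g$z)
    }))
    rownames(tpm) <- names(genes)
    colnames(tpm) <- meta$sample
    # tissue marker: expressed in the first tissue only
    marker <- rep(0, ns)
    in_t <- meta$tissue == ex$tissues[1]
    marker[in_t] <- exp(lm[["partner"]] + ex$log_sd * rnorm(sum(in_t)))
    tpm <- rbind(tpm, MARKER_T1 = marker)
    truth <- tibble(gene = rownames(tpm),
                    module = c(vapply(genes, `[[`, "", "module"), "none"))
    list(tpm = tpm, metadata = meta, truth = truth)
  })
}
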