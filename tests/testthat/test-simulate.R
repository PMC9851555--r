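test_that("config validation rejects inconsistent parameters", {
  expect_error(simulation_config(n_sites = 100,
                                 diagnostic_positions = c(50L, 150L)))
  expect_error(simulation_config(duplication_branch = c("Dcarota", "Nope")) |>
                 simulate_gene_family(), "does not match")
  expect_error(simulation_config(derived_profile = c("T", "T")))
  expect_error(simulation_config(
    expression = list(n_samples = 0, rho_within = 0.5)), "positive")
})

test_that("zero-rate simulation reproduces the root everywhere but the
           derived profile", {
  cfg <- simulation_config(rate_scale = 0, seed = 5L)
  fam <- simulate_gene_family(cfg)
  root <- fam$root_sequence
  pr <- fam$proteome
  expect_true(all(pr$sequence[pr$class == "F3H"] == root))
  fnsi <- pr$sequence[pr$id == "Dcarota_FNSI"]
  diffs <- which(strsplit(fnsi, "")[[1]] != strsplit(root, "")[[1]])
  expect_equal(diffs, cfg$diagnostic_positions)
})

test_that("the generators are byte-identical under a fixed seed", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  make_fixture(d1, seed = 77)
  make_fixture(d2, seed = 77)
  for (f in c("family.faa", "Dcarota.fna", "Dcarota.gff3",
              "expression.tsv", "truth_gene_tree.nwk")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  d3 <- file.path(tempdir(), "det3")
  unlink(d3, recursive = TRUE)
  fx3 <- make_fixture(d3, seed = 78)
  expect_false(identical(readBin(file.path(d1, "family.faa"), "raw", 1e6),
                         readBin(file.path(d3, "family.faa"), "raw", 1e6)))
  # different sequences, same truth topology
  t1 <- ape::read.tree(file.path(d1, "truth_gene_tree.nwk"))
  t3 <- ape::read.tree(file.path(d3, "truth_gene_tree.nwk"))
  expect_equal(rf_distance(t1, t3), 0L)
})

test_that("observed p-distance matches the Poisson expectation", {
  # two taxa at total path 0.1, 2000 sites: within 3 binomial SDs of
  # 1 - exp(-0.1)
  cfg <- simulation_config(
    species_tree = "(A:0.05,B:0.05);",
    duplication_branch = "A", duplication_at = 0.5,
    like_event = NULL, n_sites = 2000L,
    diagnostic_positions = c(1L, 2L),
    ancestral_profile = c("M", "I"), derived_profile = c("T", "T"),
    aux_position = NULL, seed = 13L)
  fam <- simulate_gene_family(cfg)
  a <- strsplit(fam$proteome$sequence[fam$proteome$id == "A_F3H"], "")[[1]]
  b <- strsplit(fam$proteome$sequence[fam$proteome$id == "B_F3H"], "")[[1]]
  free <- setdiff(seq_len(2000), cfg$diagnostic_positions)
  p_obs <- mean(a[free] != b[free])
  p_exp <- 1 - exp(-0.1)
  sd3 <- 3 * sqrt(p_exp * (1 - p_exp) / length(free))
  expect_lt(abs(p_obs - p_exp), sd3)
})

test_that("mean p-distance over 100 replicate blocks calibrates within 2%", {
  cfg_base <- simulation_config(
    species_tree = "(A:0.1,B:0.1);",
    duplication_branch = "A", duplication_at = 0.5,
    like_event = NULL, n_sites = 500L,
    diagnostic_positions = c(1L, 2L),
    ancestral_profile = c("M", "I"), derived_profile = c("T", "T"),
    aux_position = NULL)
  ps <- vapply(1:100, function(s) {
    cfg <- cfg_base
    cfg$seed <- s
    fam <- simulate_gene_family(cfg)
    a <- strsplit(fam$proteome$sequence[fam$proteome$id == "A_F3H"], "")[[1]]
    b <- strsplit(fam$proteome$sequence[fam$proteome$id == "B_F3H"], "")[[1]]
    mean(a[-(1:2)] != b[-(1:2)])
  }, 0)
  p_exp <- 1 - exp(-0.2)
  expect_lt(abs(mean(ps) - p_exp) / p_exp, 0.02)
})

test_that("every emitted gene appears exactly once in the ground truth", {
  fx <- get_fixture()
  fam <- fx$family
  expect_equal(sort(fam$proteome$id), sort(fam$truth$classes$id))
  expect_equal(anyDuplicated(fam$truth$classes$id), 0L)
  gt <- ape::read.tree(text = fam$truth$gene_tree)
  expect_setequal(gt$tip.label, fam$proteome$id)
  # genome truth covers every annotated gene
  for (sp in names(fx$genomes)[1:4]) {
    genes <- fx$genomes[[sp]]$genes
    expect_equal(genes$gene_id, fx$genomes$truth[[sp]])
    expect_equal(anyDuplicated(genes$gene_id), 0L)
  }
  # expression truth covers every matrix row
  expect_setequal(rownames(fx$expression$tpm), fx$expression$truth$gene)
})

test_that("the true gene tree marks the duplication and carries both copies", {
  fx <- get_fixture()
  gt <- ape::read.tree(text = fx$family$truth$gene_tree)
  expect_true("DUP" %in% gt$node.label)
  expect_true(is_monophyletic(gt, c("Dcarota_FNSI", "Dcarota_FNSIlike",
                                    "Agraveolens_FNSI"))$monophyletic)
})

test_that("genomes place the duplicate adjacent to its parent, ingroup only", {
  fx <- get_fixture()
  for (sp in c("Dcarota", "Agraveolens")) {
    genes <- fx$genomes[[sp]]$genes
    i_par <- which(genes$family == "F3H")
    i_dup <- which(genes$family == "FNS_I")
    expect_equal(i_dup, i_par + 1L)
  }
  for (sp in c("Casiatica", "Pginseng")) {
    expect_false(any(fx$genomes[[sp]]$genes$family %in%
                       c("FNS_I", "FNS_I_LIKE")))
  }
  # coordinates: 1-based, non-overlapping, strand-annotated, CDS
  # back-translates its protein
  g <- fx$genomes$Casiatica
  expect_true(all(g$genes$start >= 1))
  expect_true(all(g$genes$start <= g$genes$end))
  expect_true(all(g$genes$start[-1] > g$genes$end[-nrow(g$genes)]))
  expect_true(all(g$genes$strand %in% c("+", "-")))
  k <- which(g$genes$gene_id == "Casiatica_G02")
  cds <- substr(g$genome[[1]], g$genes$start[k], g$genes$end[k])
  if (g$genes$strand[k] == "-") cds <- dupshift:::revcomp(cds)
  expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(cds))),
               g$proteins$sequence[g$proteins$id == "Casiatica_G02"])
})

test_that("a comonotone module has sample Spearman exactly 1", {
  cfg <- simulation_config(seed = 9L)
  cfg$expression$rho_within <- 1
  ex <- simulate_expression(cfg)
  mods <- ex$truth$gene[ex$truth$module == "module_fnsi"]
  r <- cor(ex$tpm[mods[1], ], ex$tpm[mods[2], ], method = "spearman")
  expect_equal(r, 1)
})

test_that("null gene pairs have near-zero correlations at n = 200", {
  cfg <- simulation_config(seed = 10L)
  cfg$expression$n_samples <- 200L
  cfg$expression$n_null <- 40L
  ex <- simulate_expression(cfg)
  nulls <- ex$truth$gene[ex$truth$module == "none" &
                           !grepl("MARKER", ex$truth$gene)]
  combos <- combn(nulls, 2)
  rhos <- vapply(seq_len(min(300, ncol(combos))), function(k) {
    cor(ex$tpm[combos[1, k], ], ex$tpm[combos[2, k], ], method = "spearman")
  }, 0)
  expect_gte(mean(abs(rhos) < 0.2), 0.95)
})

test_that("within-module sample correlations concentrate on the target", {
  fx <- get_fixture()
  mods <- fx$expression$truth$gene[fx$expression$truth$module ==
                                     "module_f3h"]
  combos <- combn(mods, 2)
  rhos <- vapply(seq_len(ncol(combos)), function(k) {
    cor(fx$expression$tpm[combos[1, k], ], fx$expression$tpm[combos[2, k], ],
        method = "spearman")
  }, 0)
  expect_lt(abs(mean(rhos) - 0.8), 0.05)
})
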