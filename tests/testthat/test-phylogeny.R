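test_that("poisson distance follows the closed form and pairwise deletion", {
  m <- aa_msa(c(a = "AAAA", b = "AAAA"))
  expect_equal(poisson_distance(m, min_overlap = 1)$distance["a", "b"], 0)
  m2 <- aa_msa(c(a = "AAAACCCC", b = "AAAADDDD"))
  d <- poisson_distance(m2, min_overlap = 1)
  expect_equal(d$p["a", "b"], 0.5)
  expect_equal(d$distance["a", "b"], -log(0.5), tolerance = 1e-12)
})

test_that("gappy pairs are compared only over mutually ungapped columns", {
  set.seed(31)
  for (rep in 1:10) {
    nc <- 50
    mk <- function() paste(sample(c("A", "C", "D", "E", "-", "X"), nc,
                                  replace = TRUE), collapse = "")
    m <- aa_msa(c(a = mk(), b = mk()))
    d <- poisson_distance(m, min_overlap = 1)
    ca <- strsplit(unclass(m)[["a"]], "")[[1]]
    cb <- strsplit(unclass(m)[["b"]], "")[[1]]
    both <- ca != "-" & ca != "X" & cb != "-" & cb != "X"
    expect_equal(d$valid["a", "b"], sum(both))
    expect_equal(d$p["a", "b"], sum(ca[both] != cb[both]) / sum(both))
  }
})

test_that("saturated or thin pairs are undefined and refuse tree building", {
  m <- aa_msa(c(a = "ACDEFGHIKL", b = "LKIHGFEDCA", c = "ACDEFGHIKL"))
  d <- poisson_distance(m, min_overlap = 1, p_max = 0.9)
  expect_true(is.na(d$distance["a", "b"]))
  expect_error(nj_tree(d), "a~b")
  d2 <- poisson_distance(m, min_overlap = 20)
  expect_true(all(is.na(d2$distance[upper.tri(d2$distance)])))
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(cd[rownames(D), colnames(D)], D, tolerance = 1e-9)
  # v_a = (d_ab + d_ac - d_bc)/2 = 1
  a_edge <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")]
  expect_equal(a_edge, 1)
})

test_that("NJ exactly recovers random additive trees (consistency)", {
  set.seed(41)
  for (rep in 1:100) {
    n <- sample(5:10, 1)
    true <- ape::rtree(n, rooted = FALSE,
                       br = function(k) runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(true)
    est <- nj_tree(D)
    expect_equal(rf_distance(ape::unroot(true), est), 0L)
    expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("Q-matrix ties join the lowest-index pair", {
  # four equidistant taxa: every Q entry ties; (1,2) must be joined first,
  # giving the ab|cd split
  D <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  tr <- nj_tree(D)
  expect_true(is_monophyletic(tr, c("a", "b"))$monophyletic)
})

test_that("negative branch-length estimates are clamped to zero", {
  D <- matrix(c(0, 1, 5, 5,
                1, 0, 1, 5,
                5, 1, 0, 1,
                5, 5, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)  # wildly non-additive
  expect_true(all(tr$edge.length >= 0))
})

test_that("monophyly agrees with exhaustive edge-removal on random trees", {
  set.seed(51)
  for (rep in 1:25) {
    tr <- ape::rtree(8, rooted = FALSE)
    taxa <- sample(tr$tip.label, sample(2:6, 1))
    expect_equal(is_monophyletic(tr, taxa)$monophyletic,
                 brute_is_monophyletic(tr, taxa),
                 info = paste(sort(taxa), collapse = ","))
  }
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(is_monophyletic(tr, c("A", "B"))$monophyletic)
  expect_false(is_monophyletic(tr, c("A", "C"))$monophyletic)
  expect_error(is_monophyletic(tr, c("A", "Z")), "Z")
})

test_that("RF distance equals phangorn on random pairs and 0 on identity", {
  set.seed(61)
  for (rep in 1:20) {
    t1 <- ape::rtree(6, rooted = FALSE)
    t2 <- ape::rtree(6, rooted = FALSE, tip.label = t1$tip.label)
    expect_equal(rf_distance(t1, t2),
                 as.integer(phangorn::RF.dist(t1, t2)))
  }
  t1 <- ape::rtree(7, rooted = FALSE)
  expect_equal(rf_distance(t1, t1), 0L)
})

test_that("nesting verdict distinguishes embedded from outside clades", {
  # inner clade (I1,I2) sister to an outer member inside the outer clade
  tr <- ape::read.tree(
    text = "(OG1,(O1,(O2,((I1,I2),O3))),O4x);")
  expect_true(nested_within(tr, "OG1", c("I1", "I2"),
                            c("O1", "O2", "O3"))$nested)
  # inner attached outside the outer clade
  tr2 <- ape::read.tree(text = "(OG1,((I1,I2),(O1,(O2,O3))),O4x);")
  expect_false(nested_within(tr2, "OG1", c("I1", "I2"),
                             c("O1", "O2", "O3"))$nested)
  # broken inner monophyly
  tr3 <- ape::read.tree(text = "(OG1,(O1,(I1,(O2,I2))),O4x);")
  res <- nested_within(tr3, "OG1", c("I1", "I2"), c("O1", "O2"))
  expect_false(res$inner_monophyletic)
  expect_false(res$nested)
  expect_error(nested_within(tr, "OG1", c("I1"), c("I1", "O1")), "disjoint")
})

test_that("bootstrap supports are deterministic, bounded, and saturate on
           duplicated-column alignments", {
  rows <- c(a = "AAAACCCCKKKK", b = "AAAACCCCKKKW", c = "AAADCCCCKKKK",
            d = "AAAACCDDKKKK", e = "AAAACCDCKKKK")
  m <- aa_msa(rows)
  b1 <- bootstrap_support(m, n_reps = 50, seed = 9, min_overlap = 1)
  b2 <- bootstrap_support(m, n_reps = 50, seed = 9, min_overlap = 1)
  expect_identical(b1$support$support, b2$support$support)
  expect_true(all(b1$support$support >= 0 & b1$support$support <= 100))
  # an alignment of two duplicated column patterns supports its two splits
  # in every replicate
  shared <- strrep("K", 30)  # keeps every pair below saturation
  inv <- aa_msa(c(a = paste0(strrep("A", 30), strrep("G", 30), shared),
                  b = paste0(strrep("A", 30), strrep("G", 30), shared),
                  c = paste0(strrep("C", 30), strrep("G", 30), shared),
                  d = paste0(strrep("C", 30), strrep("W", 30), shared),
                  e = paste0(strrep("C", 30), strrep("W", 30), shared)))
  bs <- bootstrap_support(inv, n_reps = 30, seed = 1, min_overlap = 1)
  expect_true(all(bs$support$support == 100))
})

test_that("support of the true split rises with alignment length", {
  quartet <- function(n_sites, seed) {
    cfg <- simulation_config(
      species_tree = "((A:0.4,B:0.4):0.04,(C:0.4,D:0.4):0.04);",
      duplication_branch = c("A", "B"), duplication_at = 0.99,
      like_event = NULL, n_sites = n_sites,
      diagnostic_positions = c(5L, 10L),
      ancestral_profile = c("M", "I"), derived_profile = c("T", "T"),
      aux_position = NULL, seed = seed)
    fam <- simulate_gene_family(cfg)
    pr <- fam$proteome[fam$proteome$class == "F3H", ]
    msa <- aa_msa(setNames(pr$sequence, pr$id))
    bs <- bootstrap_support(msa, n_reps = 100, seed = seed, min_overlap = 10)
    key_row <- bs$support[vapply(bs$support$tips, function(tp)
      setequal(tp, c("A_F3H", "B_F3H")) | setequal(tp, c("C_F3H", "D_F3H")),
      TRUE), ]
    if (nrow(key_row) == 0) 0 else max(key_row$support)
  }
  short_sup <- mean(vapply(1:3, function(s) quartet(120L, s), 0))
  long_sup <- mean(vapply(1:3, function(s) quartet(1500L, s), 0))
  expect_gt(long_sup, short_sup)
  expect_gt(long_sup, 70)
})

test_that("consensus report flags a broken inner clade and RF against first", {
  t1 <- ape::read.tree(text = "(OG,(A,(B,(C,(I1,I2)))));")
  t2 <- t1
  t3 <- ape::read.tree(text = "(OG,(A,(I1,(C,(B,I2)))));")
  rep <- consensus_report(list(ml = t1, nj = t2, alt = t3),
                          inner = c("I1", "I2"),
                          outer = c("A", "B", "C"), outgroup = "OG")
  expect_equal(rep$inner_monophyletic, c(TRUE, TRUE, FALSE))
  expect_equal(rep$rf_vs_first[1:2], c(0L, 0L))
  expect_gt(rep$rf_vs_first[3], 0L)
  expect_error(consensus_report(list(ape::rtree(3)), "a", "b", "c"),
               "fewer than 4")
})
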