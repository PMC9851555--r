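test_that("gene order reading sorts, indexes, and round-trips", {
  genes <- tibble::tibble(
    gene_id = c("g3", "g1", "g2"), chrom = "chr1",
    start = c(500L, 10L, 200L), end = c(600L, 100L, 300L),
    strand = c("+", "-", "+"))
  f <- tempfile(fileext = ".gff3")
  dupshift:::write_gff3(genes, f)
  go <- read_gene_order(f)
  expect_equal(go$gene_id, c("g1", "g2", "g3"))  # sorted by start
  expect_equal(go$order, 1:3)
  expect_false(any(go$overlaps_previous))
  expect_equal(go$strand, c("-", "+", "+"))
  # overlap flagged
  genes2 <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                           start = c(1L, 50L), end = c(100L, 120L),
                           strand = "+")
  dupshift:::write_gff3(genes2, f)
  expect_true(read_gene_order(f)$overlaps_previous[2])
})

test_that("anchor chaining finds parallel and antiparallel blocks", {
  an <- tibble::tibble(id_a = paste0("a", 1:3), id_b = paste0("b", 1:3),
                       idx_a = 1:3, idx_b = 1:3)
  bl <- chain_anchors(an, max_gap = 2, min_anchors = 3)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$orientation, "parallel")
  expect_equal(bl$n_anchors, 3L)
  an2 <- tibble::tibble(id_a = paste0("a", 1:3), id_b = paste0("b", 3:1),
                        idx_a = 1:3, idx_b = 3:1)
  bl2 <- chain_anchors(an2, max_gap = 2, min_anchors = 3)
  expect_equal(bl2$orientation, "antiparallel")
  expect_equal(bl2$n_anchors, 3L)
  # gap constraint: a jump of max_gap+2 breaks the chain
  an3 <- tibble::tibble(id_a = c("x", "y"), id_b = c("u", "v"),
                        idx_a = c(1L, 5L), idx_b = c(1L, 5L))
  expect_equal(nrow(chain_anchors(an3, max_gap = 2, min_anchors = 2)), 0L)
  expect_equal(nrow(chain_anchors(an3, max_gap = 3, min_anchors = 2)), 1L)
  expect_warning(chain_anchors(dplyr::bind_rows(an, an[1, ]), 2, 3),
                 "duplicate")
})

test_that("chaining matches exhaustive search on 200 random instances", {
  set.seed(81)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    an <- tibble::tibble(id_a = paste0("a", seq_len(n)),
                         id_b = paste0("b", seq_len(n)),
                         idx_a = sample(20, n),
                         idx_b = sample(20, n))
    an <- an[!duplicated(an[, c("idx_a", "idx_b")]), ]
    max_gap <- sample(0:3, 1)
    got <- chain_anchors(an, max_gap = max_gap, min_anchors = 1)
    # greedy rounds: each reported block must match the brute-force best
    # chain among the anchors still available at its round
    avail <- an
    for (r in seq_len(nrow(got))) {
      expect_equal(got$n_anchors[r], brute_best_chain(avail, max_gap),
                   info = sprintf("rep %d round %d", rep, r))
      used <- got$anchors[[r]]
      avail <- avail[!paste(avail$idx_a, avail$idx_b) %in%
                       paste(used$idx_a, used$idx_b), ]
    }
    if (nrow(avail) > 0) {
      expect_lte(1L, brute_best_chain(avail, max_gap))
    }
  }
})

test_that("chained anchor indices are strictly monotone within blocks", {
  set.seed(82)
  an <- tibble::tibble(id_a = paste0("a", 1:12), id_b = paste0("b", 1:12),
                       idx_a = sample(15, 12), idx_b = sample(15, 12))
  bl <- chain_anchors(an, max_gap = 3, min_anchors = 2)
  for (r in seq_len(nrow(bl))) {
    anc <- bl$anchors[[r]]
    expect_true(all(diff(anc$idx_a) > 0))
    if (bl$orientation[r] == "parallel") {
      expect_true(all(diff(anc$idx_b) > 0))
    } else {
      expect_true(all(diff(anc$idx_b) < 0))
    }
  }
})

test_that("family location reports presence, tandem flags and annotation gaps", {
  rep <- get_pipeline_report()
  syn <- rep$synteny
  expect_equal(syn$duplicate_in_block[syn$genome %in%
                 c("Dcarota", "Agraveolens")], c(TRUE, TRUE))
  expect_equal(syn$duplicate_in_block[syn$genome %in%
                 c("Casiatica", "Pginseng")], c(FALSE, FALSE))
  expect_false(any(syn$duplicate_in_annotation[syn$genome %in%
                 c("Casiatica", "Pginseng")]))
  expect_true(all(syn$tandem[syn$genome %in% c("Dcarota", "Agraveolens")]))
  expect_true(all(syn$parent_region_in_block))
  # empty block list: absent with warning
  fx <- get_fixture()
  orders <- lapply(fx$genomes[c("Dcarota", "Agraveolens")], function(g)
    dplyr::mutate(g$genes, order = dplyr::row_number()))
  fam_ids <- list(Dcarota = "Dcarota_FNSI", Agraveolens = "Agraveolens_FNSI")
  expect_warning(
    loc <- locate_family(list(), fam_ids, orders, "Dcarota"),
    "no synteny blocks")
  expect_false(loc$in_syntenic_block[loc$genome == "Agraveolens"])
})

test_that("translated scan finds planted genes on both strands", {
  fx <- get_fixture()
  g <- fx$genomes$Agraveolens
  for (gid in c("Agraveolens_FNSI", "Agraveolens_G03")) {
    prot <- g$proteins$sequence[g$proteins$id == gid]
    ann <- g$genes[g$genes$gene_id == gid, ]
    hits <- translated_scan(g$genome, prot, min_score = 200)
    top <- hits[1, ]
    expect_equal(top$start, ann$start)
    expect_equal(top$end, ann$end)
    expect_equal(top$strand, ann$strand)
    expect_equal(top$identity, 100)
  }
})

test_that("strand symmetry: reverse-complementing the genome mirrors hits", {
  fx <- get_fixture()
  g <- fx$genomes$Pginseng
  prot <- g$proteins$sequence[g$proteins$id == "Pginseng_F3H"]
  hits <- translated_scan(g$genome, prot, min_score = 500)
  L <- nchar(g$genome[[1]])
  rc <- setNames(dupshift:::revcomp(g$genome[[1]]), names(g$genome))
  hits_rc <- translated_scan(rc, prot, min_score = 500)
  expect_equal(hits_rc$start[1], L - hits$end[1] + 1L)
  expect_equal(hits_rc$end[1], L - hits$start[1] + 1L)
  expect_true(hits$strand[1] != hits_rc$strand[1])
  expect_equal(hits$score[1], hits_rc$score[1])
})

test_that("shuffled genomes yield no hits above threshold", {
  fx <- get_fixture()
  g <- fx$genomes$Casiatica
  prot <- g$proteins$sequence[g$proteins$id == "Casiatica_F3H"]
  chars <- strsplit(substr(g$genome[[1]], 1, 4000), "")[[1]]
  set.seed(91)
  n_hit <- 0L
  for (k in 1:20) {
    shuf <- paste(sample(chars), collapse = "")
    hits <- translated_scan(setNames(shuf, "chr1"), prot, min_score = 100)
    if (nrow(hits) > 0) n_hit <- n_hit + 1L
  }
  expect_lte(n_hit, 1L)  # >= 95% of shuffles are clean
})

test_that("hits outside gene models follow the any-overlap boundary rule", {
  models <- tibble::tibble(chrom = "chr1", start = c(100L, 500L),
                           end = c(200L, 600L))
  hits <- tibble::tibble(chrom = "chr1",
                         start = c(150L, 201L, 90L, 601L, 450L),
                         end = c(160L, 300L, 100L, 700L, 499L))
  out <- hits_outside_models(hits, models)
  # inside -> excluded; 1 bp past the end -> included; touching -> excluded
  expect_equal(out$start, c(201L, 601L, 450L))
  # brute-force O(n*m) oracle on random intervals
  set.seed(92)
  for (rep in 1:20) {
    h <- tibble::tibble(chrom = sample(c("c1", "c2"), 30, TRUE),
                        start = sample(1000, 30))
    h$end <- h$start + sample(0:50, 30, TRUE)
    m <- tibble::tibble(chrom = sample(c("c1", "c2"), 10, TRUE),
                        start = sample(1000, 10))
    m$end <- m$start + sample(0:100, 10, TRUE)
    keep_oracle <- vapply(seq_len(nrow(h)), function(i) {
      !any(m$chrom == h$chrom[i] & m$start <= h$end[i] & m$end >= h$start[i])
    }, TRUE)
    expect_equal(hits_outside_models(h, m)$start, h$start[keep_oracle])
  }
})

test_that("re-translating a reported hit interval reproduces protein sequence", {
  fx <- get_fixture()
  g <- fx$genomes$Dcarota
  prot <- g$proteins$sequence[g$proteins$id == "Dcarota_G06"]
  hits <- translated_scan(g$genome, prot, min_score = 500)
  top <- hits[1, ]
  sub <- substr(g$genome[[1]], top$start, top$end)
  if (top$strand == "-") sub <- dupshift:::revcomp(sub)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub)))
  expect_equal(aa, prot)
})
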