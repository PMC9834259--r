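dmr_frame <- function(chrom, start, end) {
  structure(data.frame(chrom = chrom, start = start, end = end,
                       name = sprintf("%s:%d-%d", chrom, start, end)),
            class = c("dmr_set", "data.frame"))
}

test_that("gene association respects the inclusive 10 kb boundary", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      symbol = c("G1", "G2", "G3"),
                      chrom = "chr1",
                      start = c(6000L, 20000L, 40000L),
                      end = c(8000L, 21000L, 41000L),
                      strand = "+")
  dmrs <- dmr_frame("chr1", 0L, 1000L)
  # gap to g1 = 5000, to g2 = 19000, to g3 = 39000
  a <- associate_genes(dmrs, genes)
  expect_equal(a$gene_id, "g1")
  expect_equal(a$distance_bp, 5000L)
  # boundary: gap exactly 10000 is associated
  dmrs2 <- dmr_frame("chr1", 0L, 10000L)  # gap to g2 = 10000
  a2 <- associate_genes(dmrs2, genes)
  expect_setequal(a2$gene_id, c("g1", "g2"))
  expect_equal(a2$distance_bp[a2$gene_id == "g2"], 10000L)
  expect_equal(a2$distance_bp[a2$gene_id == "g1"], 0L)  # overlap
  # gap 15000 is not
  dmrs3 <- dmr_frame("chr1", 0L, 5000L)  # gap to g2 = 15000
  expect_false("g2" %in% associate_genes(dmrs3, genes)$gene_id)
})

test_that("gene association agrees with a brute-force all-pairs scan", {
  set.seed(33)
  for (rep in 1:20) {
    nd <- sample(1:8, 1)
    ng <- sample(1:8, 1)
    ds <- sort(sample(0:200, nd)) * 1000L
    gs <- sort(sample(0:200, ng)) * 1000L
    dmrs <- dmr_frame(sample(c("c1", "c2"), nd, TRUE), ds, ds + 2000L)
    genes <- data.frame(gene_id = sprintf("g%d", seq_len(ng)),
                        symbol = sprintf("g%d", seq_len(ng)),
                        chrom = sample(c("c1", "c2"), ng, TRUE),
                        start = gs, end = gs + 3000L, strand = "+")
    got <- associate_genes(dmrs, genes, max_distance = 10000L)
    want <- 0L
    for (i in seq_len(nd)) for (j in seq_len(ng)) {
      if (dmrs$chrom[i] != genes$chrom[j]) next
      gap <- max(0L, max(genes$start[j] - dmrs$end[i],
                         dmrs$start[i] - genes$end[j]))
      if (gap <= 10000L) {
        want <- want + 1L
        row <- got[got$dmr == dmrs$name[i] & got$gene_id == genes$gene_id[j], ]
        expect_equal(nrow(row), 1L)
        expect_equal(row$distance_bp, gap)
      }
    }
    expect_equal(nrow(got), want)
  }
})

test_that("gene models are read from GFF3 into 0-based coordinates", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t1001\t3000\t.\t+\t.\tID=geneA;Name=ALPHA",
               "chr1\ttest\texon\t1001\t1500\t.\t+\t.\tID=exonA;Parent=geneA",
               "chr2\ttest\tgene\t501\t900\t.\t-\t.\tID=geneB;Name=BETA"),
             gff)
  g <- read_gene_models(gff)
  expect_equal(nrow(g), 2L)  # exon feature dropped
  expect_equal(g$start[g$gene_id == "geneA"], 1000L)
  expect_equal(g$end[g$gene_id == "geneA"], 3000L)
  expect_equal(g$symbol, c("ALPHA", "BETA"))
  expect_equal(g$strand[g$gene_id == "geneB"], "-")
})

test_that("Venn overlap handles identical, disjoint and mixed sets", {
  A <- dmr_frame("chr1", c(0L, 5000L), c(1000L, 6000L))
  idAB <- venn_overlap(list(A = A, B = A))
  expect_equal(unname(idAB$pairwise["A", "B"]), 2L)
  expect_equal(unname(idAB$sizes), c(2L, 2L))
  expect_true(all(idAB$regions$pattern == "A&B"))

  C <- dmr_frame("chr1", 20000L, 21000L)
  dis <- venn_overlap(list(A = A, C = C))
  expect_equal(unname(dis$pairwise["A", "C"]), 0L)
  expect_equal(unname(dis$pairwise["C", "A"]), 0L)

  # A=[0,1000), B=[999,2000), C=[5000,6000): only A and B share a base
  a <- dmr_frame("chr1", 0L, 1000L)
  b <- dmr_frame("chr1", 999L, 2000L)
  cc <- dmr_frame("chr1", 5000L, 6000L)
  v <- venn_overlap(list(A = a, B = b, C = cc))
  expect_equal(unname(v$pairwise["A", "B"]), 1L)
  expect_equal(unname(v$pairwise["A", "C"]), 0L)
  expect_equal(unname(v$pairwise["B", "C"]), 0L)
  # region counts per perspective sum to the set sizes
  sums <- tapply(v$regions$count, v$regions$set, sum)
  expect_equal(as.vector(sums[names(v$sizes)]), unname(v$sizes))

  expect_error(venn_overlap(list(a = a)), "2-4")
  expect_error(venn_overlap(list(a, b)), "named")
})

test_that("extended overlap of a set with its own relaxed calls is 100%", {
  set.seed(44)
  p <- 10^runif(300, -9, 0)
  tr <- p_track(p)
  strict <- call_dmrs(tr)
  expect_gt(nrow(strict), 0)
  eo <- extended_overlap(strict, tr, p_relaxed = 0.05)
  expect_equal(eo$percentage, 100)
  expect_equal(eo$count, nrow(strict))
})

test_that("extended overlap is 0% against a flat comparison and warns on empty", {
  strict <- dmr_frame("chr1", 0L, 2000L)
  flat <- p_track(rep(0.6, 50))
  eo <- extended_overlap(strict, flat)
  expect_equal(eo$percentage, 0)
  empty <- strict[0, ]
  expect_warning(eo2 <- extended_overlap(empty, flat), "empty")
  expect_equal(eo2$percentage, 0)
})

test_that("extended overlap exceeds strict Venn overlap on shared signal", {
  # two comparisons sharing some true regions: relaxation is monotone
  cfg1 <- simulation_config(n_chromosomes = 2L, chromosome_length = 100000L,
                            n_spiked_regions = 10L, rng_seed = 15L,
                            n_case_samples = 6L, n_control_samples = 6L,
                            spike_log2fc_magnitude = 2)
  g <- generate_genome(cfg1)
  simA <- simulate_counts(g, cfg1)
  # comparison B: same genome, independent spikes and noise; the
  # inequality holds structurally because every strict-threshold DMR span
  # is also a relaxed-threshold DMR span
  cfg2 <- cfg1
  cfg2$rng_seed <- 16L
  simB <- simulate_counts(g, cfg2)
  twA <- test_windows(simA$counts)
  twB <- test_windows(simB$counts)
  strictA <- call_dmrs(twA)
  strictB <- call_dmrs(twB)
  venn_ct <- if (nrow(strictA) && nrow(strictB))
    sum(overlaps_dmr(strictA, strictB)) else 0L
  eo <- extended_overlap(strictA, twB)
  expect_gte(eo$count, venn_ct)
})

test_that("RPKM is definitional, length-aware and scale-invariant", {
  counts <- rbind(c(10L, 10L), c(10L, 20L))
  windows <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                        end = c(1000L, 1500L), index = 0:1)
  cm <- medip_counts(windows, matrix(counts, 2, 2,
                                     dimnames = list(NULL, c("a", "b"))),
                     data.frame(sample = c("a", "b"),
                                group = c("case", "control")),
                     library_sizes = c(a = 1e6, b = 2e6))
  r <- rpkm_matrix(cm)
  expect_equal(r[1, "a"], 10)        # 10 reads / (1 kb x 1 M)
  expect_equal(r[2, "a"], 20)        # 500 bp window: length scaling
  expect_equal(r[1, "b"], 5)         # doubled library halves RPKM
  # doubling counts and library together changes nothing
  cm2 <- medip_counts(windows, cm$counts * 2L, cm$design,
                      library_sizes = cm$library_sizes * 2)
  expect_equal(rpkm_matrix(cm2), r)
  expect_error(rpkm_matrix(medip_counts(windows, cm$counts, cm$design,
                                        library_sizes = c(a = 0, b = 1))),
               "library size")
})

test_that("RPKM conservation: sum over all windows of RPKM x kb = 1e6", {
  cfg <- simulation_config(n_chromosomes = 1L, chromosome_length = 30000L,
                           n_spiked_regions = 2L, rng_seed = 8L)
  sim <- simulate_counts(generate_genome(cfg), cfg)
  r <- rpkm_matrix(sim$counts)
  len_kb <- (sim$counts$windows$end - sim$counts$windows$start) / 1000
  expect_equal(unname(colSums(r * len_kb)), rep(1e6, ncol(r)))
})

test_that("PCA on identical samples gives zero scores and variance", {
  rpkm <- matrix(rep(c(3, 7, 1, 9), 4), nrow = 4,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
  pc <- dmr_pca(rpkm)
  expect_equal(max(abs(pc$scores)), 0)
  expect_equal(pc$explained_variance, c(0, 0))
  expect_error(dmr_pca(rpkm[, 1:2]), "3 samples")
})

test_that("explained-variance fractions are ordered and bounded", {
  set.seed(55)
  rpkm <- matrix(rexp(200), nrow = 20)
  colnames(rpkm) <- sprintf("s%d", 1:10)
  pc <- dmr_pca(rpkm)
  expect_true(pc$explained_variance[1] >= pc$explained_variance[2])
  expect_lte(sum(pc$explained_variance), 1)
  # deterministic up to nothing: repeated runs identical (sign fixed)
  expect_identical(pc$scores, dmr_pca(rpkm)$scores)
})

test_that("groups separate linearly in PC space on spiked data", {
  cfg <- simulation_config(n_chromosomes = 2L, chromosome_length = 100000L,
                           n_spiked_regions = 12L, rng_seed = 23L,
                           n_case_samples = 6L, n_control_samples = 6L,
                           spike_log2fc_magnitude = 2)
  g <- generate_genome(cfg)
  sim <- simulate_counts(g, cfg)
  tw <- test_windows(sim$counts)
  dmrs <- call_dmrs(tw)
  expect_gt(nrow(dmrs), 0)
  dw <- sim$counts$windows[overlaps_dmr(sim$counts$windows, dmrs), ]
  pc <- dmr_pca(rpkm_matrix(sim$counts, dw), groups = sim$counts$design$group)
  expect_true(perceptron_separable(pc$scores, sim$counts$design$group))
})
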