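test_that("ES is maximal when all hits lead the list", {
  genes <- sprintf("g%02d", 1:10)
  ranked <- data.frame(gene = genes, rank = rep(1, 10))  # ties -> name order
  res <- gsea_preranked(ranked, genes[1:3], n_perm = 500, seed = 1)
  expect_equal(res$es, 1.0, tolerance = 1e-12)
  expect_equal(sort(res$leading_edge), genes[1:3])
  expect_lt(res$p, 0.05)
})

test_that("uniformly interleaved hits give a near-zero ES", {
  genes <- sprintf("g%02d", 1:12)
  ranked <- data.frame(gene = genes, rank = 12:1)
  res <- gsea_preranked(ranked, genes[c(3, 6, 9, 12)], weight_exp = 0,
                        n_perm = 50, seed = 1)
  expect_lt(abs(res$es), 0.3)
})

test_that("ES equals the brute-force running sum on all small instances", {
  set.seed(77)
  for (n in 2:10) {
    r <- sort(rnorm(n), decreasing = TRUE)
    genes <- sprintf("g%02d", seq_len(n))
    for (nh in seq_len(min(4, n - 1))) {
      hits_sets <- utils::combn(n, nh, simplify = FALSE)
      for (hs in hits_sets) {
        hit <- seq_len(n) %in% hs
        expected <- bf_gsea_es(r, hit, weight_exp = 1)
        res <- gsea_preranked(setNames(r, genes), genes[hs],
                              n_perm = 2, seed = 1)
        expect_equal(res$es, expected, tolerance = 1e-12)
      }
    }
  }
})

test_that("ES is invariant under positive rescaling of the ranks", {
  set.seed(78)
  r <- setNames(rnorm(30), sprintf("g%02d", 1:30))
  set_g <- sample(names(r), 5)
  e1 <- gsea_preranked(r, set_g, n_perm = 2, seed = 1)$es
  e2 <- gsea_preranked(r * 17.3, set_g, n_perm = 2, seed = 1)$es
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("ES agrees with an independent GSEA implementation", {
  set.seed(79)
  n <- 50
  r <- sort(rnorm(n), decreasing = TRUE)
  genes <- sprintf("g%02d", 1:n)
  hs <- sort(sample.int(n, 6))
  ours <- gsea_preranked(setNames(r, genes), genes[hs], n_perm = 2,
                         seed = 1)$es
  ref <- fgsea::calcGseaStat(r, selectedStats = hs, gseaParam = 1)
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("permutation p-values are reproducible and null-calibrated", {
  set.seed(80)
  r <- setNames(rnorm(60), sprintf("g%02d", 1:60))
  set_g <- sample(names(r), 5)
  p1 <- gsea_preranked(r, set_g, n_perm = 200, seed = 5)$p
  p2 <- gsea_preranked(r, set_g, n_perm = 200, seed = 5)$p
  expect_identical(p1, p2)
  expect_gt(p1, 0)
  expect_lte(p1, 1)

  # null sets: p below 0.1 about 10% of the time (95% binomial envelope)
  set.seed(81)
  n_null <- 100
  ps <- vapply(seq_len(n_null), function(i) {
    rr <- setNames(rnorm(40), sprintf("g%02d", 1:40))
    gsea_preranked(rr, sample(names(rr), 4), n_perm = 200, seed = i)$p
  }, numeric(1))
  hits <- sum(ps <= 0.1)
  env <- qbinom(c(0.025, 0.975), n_null, 0.1)
  expect_gte(hits, env[1])
  expect_lte(hits, env[2])
})

test_that("gsea rejects degenerate inputs", {
  r <- setNames(3:1, c("a", "b", "c"))
  expect_error(gsea_preranked(r, "zz", n_perm = 2), "no gene-set member")
  expect_error(gsea_preranked(r, c("a", "b", "c"), n_perm = 2),
               "entire list")
})

test_that("any-bp overlap respects half-open boundaries", {
  a <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  b_touch <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  b_over <- data.frame(chrom = "chr1", start = 99L, end = 200L)
  expect_equal(overlap_regions(a, b_touch)$n_overlap, 0)
  expect_equal(overlap_regions(a, b_over)$n_overlap, 1)
  expect_warning(
    overlap_regions(a, data.frame(chrom = "1", start = 0L, end = 50L)),
    "no shared chromosome")
})

test_that("overlap counts match the quadratic brute force", {
  set.seed(83)
  mk <- function(n) {
    s <- sample.int(50000, n)
    data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
               start = s, end = s + sample.int(500, n))
  }
  a <- mk(200); b <- mk(300)
  ov <- overlap_regions(a, b)
  expect_equal(ov$n_overlap, bf_overlap_count(a, b))
  expect_equal(ov$n_a_only, nrow(a) - bf_overlap_count(a, b))
  expect_equal(ov$n_b_only, nrow(b) - bf_overlap_count(b, a))
})

test_that("gene-label overlap is a symmetric set intersection", {
  ov <- overlap_regions(c("a", "b", "c"), c("b", "c", "d", "e"),
                        mode = "gene_label")
  expect_equal(ov$n_overlap, 2)
  expect_equal(ov$n_a_only, 1)
  expect_equal(ov$n_b_only, 2)
  ov_rev <- overlap_regions(c("b", "c", "d", "e"), c("a", "b", "c"),
                            mode = "gene_label")
  expect_equal(ov_rev$n_overlap, ov$n_overlap)
})

test_that("binomial enrichment equals the exact tail sum", {
  set.seed(84)
  genome <- 1e6
  for (i in 1:20) {
    n_reg <- sample(5:40, 1)
    dom_w <- sample.int(2e5, 1)
    dom <- data.frame(chrom = "chr1", start = 0L, end = dom_w)
    s <- sample.int(genome - 600, n_reg)
    regions <- data.frame(chrom = "chr1", start = s, end = s + 500L)
    res <- binomial_region_enrichment(regions, list(term = dom), genome)
    p_term <- dom_w / genome
    mids <- s + 250L
    k <- sum(mids >= 0 & mids < dom_w)
    expect_equal(res$n_hits, k)
    # independent closed form: sum of binomial pmf terms
    tail_sum <- if (k == 0) 1 else
      sum(choose(n_reg, k:n_reg) * p_term^(k:n_reg) *
            (1 - p_term)^(n_reg - (k:n_reg)))
    expect_equal(res$p, tail_sum, tolerance = 1e-12)
  }
})

test_that("binomial enrichment edge cases behave", {
  regions <- data.frame(chrom = "chr1", start = c(0L, 100L),
                        end = c(50L, 150L))
  whole <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  res <- binomial_region_enrichment(regions, list(all = whole), 1000)
  expect_equal(res$p_term, 1)
  expect_equal(res$p, 1)
  none <- data.frame(chrom = "chr2", start = 0L, end = 100L)
  res0 <- binomial_region_enrichment(regions, list(off = none), 1e6)
  expect_equal(res0$n_hits, 0)
  expect_equal(res0$p, 1)
})

test_that("basal domains are strand-aware and clipped", {
  genes <- data.frame(gene = c("gA", "gB"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(2000L, 500L))
  dom <- basal_domains(genes, up = 5000, down = 1000,
                       chrom_lengths = c(chr1 = 10000L))
  expect_equal(dom$start[1], 0L)          # clipped at chromosome start
  expect_equal(dom$end[1], 3000L)
  expect_equal(dom$start[2], 0L)
  expect_equal(dom$end[2], 5501L)
})

test_that("GMT and RNK files parse and round-trip", {
  gmt <- withr::local_tempfile(
    lines = c("cell_cycle\tdesc\tCdkn2a\tCdkn2b\tMdm2",
              "other\tdesc\tRb1"))
  sets <- read_gmt(gmt)
  expect_equal(names(sets), c("cell_cycle", "other"))
  expect_equal(sets$cell_cycle, c("Cdkn2a", "Cdkn2b", "Mdm2"))
  rnk <- data.frame(gene = c("a", "b"), rank = c(2.5, -1.25))
  f <- withr::local_tempfile(fileext = ".rnk")
  write_rnk(rnk, f)
  expect_equal(read_rnk(f), rnk)
})
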