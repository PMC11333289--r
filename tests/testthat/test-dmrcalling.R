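test_that("site test is null at equality and extreme at full separation", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 200L))
  tot <- matrix(20L, 2, 6)
  meth_eq <- matrix(8L, 2, 6)
  cm <- cpg_counts(sites, meth_eq, tot, samples = paste0("s", 1:6))
  st <- test_sites(cm, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(st$z, c(0, 0))
  expect_equal(st$p, c(1, 1))

  meth_sep <- cbind(matrix(0L, 2, 3), matrix(20L, 2, 3))
  cm2 <- cpg_counts(sites, meth_sep, tot, samples = paste0("s", 1:6))
  st2 <- test_sites(cm2, paste0("s", 1:3), paste0("s", 4:6))
  expect_true(all(abs(st2$z) > 5))
  expect_true(all(st2$p < 1e-6))
  # orientation: positive z = gain in group B
  expect_true(all(st2$z > 0))
  expect_equal(sign(st2$z), sign(st2$tmean_b - st2$tmean_a))
})

test_that("site test guards its preconditions", {
  cm <- tiny_counts()
  expect_error(test_sites(cm, "s1", c("s2", "s3")), "at least 2")
  expect_error(test_sites(cm, c("s1", "s2"), c("s2", "s3")), "disjoint")
  expect_error(test_sites(cm, c("s1", "nope"), c("s2", "s3")), "unknown")
})

test_that("null type-I error is calibrated near the candidate threshold", {
  # no planted differences: both groups drawn from the same surface
  cfg <- sim_config(two_group_samples(divisions_a = 0, divisions_b = 0),
                    n_sites = 20000L, frac_gain = 0, frac_loss = 0,
                    frac_hostage = 0, seed = 7L)
  sim <- simulate_cohort(cfg)
  cm <- filter_coverage(sim$counts)
  st <- test_sites(cm, sim$samples$sample_id[1:3], sim$samples$sample_id[4:6])
  frac <- mean(st$p < 0.01)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.02)
})

test_that("segmentation follows the gap, sign, and size rules", {
  # no candidate -> empty
  st0 <- make_stats("chr1", c(100, 200), z = c(1, -1))
  expect_equal(nrow(call_dmrs(st0)), 0)

  # 8 consecutive candidates, z = +3, 50 bp apart -> one region, area 24
  st1 <- make_stats("chr1", 100 + 50 * (0:7), z = rep(3, 8))
  d1 <- call_dmrs(st1)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$n_cpgs, 8L)
  expect_equal(d1$area_stat, 24.0, tolerance = 1e-12)
  expect_equal(d1$direction, "gain")
  expect_equal(d1$start, 100L)
  expect_equal(d1$end, 451L)

  # two runs separated by 1 kb never merge
  st2 <- make_stats("chr1", c(100, 150, 200, 1200, 1250, 1300),
                    z = rep(4, 6))
  expect_equal(nrow(call_dmrs(st2)), 2)

  # opposite-sign candidates split runs
  st3 <- make_stats("chr1", c(100, 150, 200, 250, 300, 350),
                    z = c(3, 3, 3, -3, -3, -3))
  d3 <- call_dmrs(st3)
  expect_equal(d3$direction, c("gain", "loss"))

  # min_cpg prunes short runs
  st4 <- make_stats("chr1", c(100, 150), z = c(5, 5))
  expect_equal(nrow(call_dmrs(st4, min_cpg = 3)), 0)
  expect_equal(nrow(call_dmrs(st4, min_cpg = 2)), 1)

  # nearby same-sign survivors merge; members of both runs are pooled
  st5 <- make_stats("chr1", c(100, 150, 200, 600, 650, 700),
                    z = rep(2.8, 6))
  d5 <- call_dmrs(st5, max_gap_bp = 300, merge_dist_bp = 500)
  expect_equal(nrow(d5), 1)
  expect_equal(d5$n_cpgs, 6L)
  expect_equal(d5$area_stat, 6 * 2.8, tolerance = 1e-12)

  expect_error(call_dmrs(make_stats("chr1", c(200, 100), z = c(3, 3))),
               "sorted")
})

test_that("area statistics equal the brute-force sum of member z", {
  for (seed in 1:5) {
    sim <- simulate_cohort(sim_config(two_group_samples(), n_sites = 1500L,
                                      seed = seed))
    cm <- filter_coverage(sim$counts)
    st <- test_sites(cm, sim$samples$sample_id[1:3],
                     sim$samples$sample_id[4:6])
    dmrs <- call_dmrs(st)
    p_thresh <- attr(dmrs, "params")$p_thresh
    for (i in seq_len(nrow(dmrs))) {
      members <- st$p < p_thresh & !is.na(st$p) &
        st$chrom == dmrs$chrom[i] &
        st$pos >= dmrs$start[i] & st$pos < dmrs$end[i] &
        sign(st$z) == ifelse(dmrs$direction[i] == "gain", 1, -1)
      expect_equal(dmrs$area_stat[i], sum(st$z[members]), tolerance = 1e-12)
      expect_equal(dmrs$n_cpgs[i], sum(members))
    }
  }
})

test_that("segmentation is invariant to chromosome processing order", {
  st <- rbind(make_stats("chr2", c(100, 150, 200), z = rep(4, 3)),
              make_stats("chr1", c(100, 150, 200), z = rep(-4, 3)))
  st <- st[order(st$chrom, st$pos), ]
  d <- call_dmrs(st)
  expect_equal(d$chrom, c("chr1", "chr2"))
  expect_equal(d$direction, c("loss", "gain"))
})

test_that("top-K selection sorts by |area| with coordinate tie-breaks", {
  dmrs <- data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr1", "chr1"),
    start = c(500L, 100L, 50L, 900L, 1300L),
    end = c(600L, 200L, 150L, 1000L, 1400L),
    n_cpgs = 3L,
    area_stat = c(9, -7, 7, 3, 1),
    direction = c("gain", "loss", "gain", "gain", "gain"),
    mean_diff = c(0.3, -0.2, 0.2, 0.1, 0.05),
    stringsAsFactors = FALSE
  )
  top <- select_top(dmrs, k = 3)
  expect_equal(abs(top$dmrs$area_stat), c(9, 7, 7))
  # |area| tie between chr1:100 and chr2:50 resolves by coordinate
  expect_equal(top$dmrs$chrom[2:3], c("chr1", "chr2"))
  gain_only <- select_top(dmrs, k = 150, direction = "gain")
  expect_equal(nrow(gain_only$dmrs), 4)
  expect_true(all(gain_only$dmrs$direction == "gain"))
  k139 <- select_top(dmrs, k = 139)
  expect_equal(k139$k, 139L)
})

test_that("gene ranks use the signed -log10 region p and keep one DMR per gene", {
  z3 <- sqrt(3) * stats::qnorm(1 - 0.01 / 2)   # area/sqrt(n) giving p = 0.01
  dmrs <- data.frame(
    chrom = "chr1", start = c(100L, 500L, 900L),
    end = c(200L, 600L, 1000L), n_cpgs = 3L,
    area_stat = c(z3, -sqrt(3) * stats::qnorm(1 - 0.001 / 2), z3),
    direction = c("gain", "loss", "gain"),
    mean_diff = c(0.2, -0.2, 0.2),
    gene = c("Cdkn2a", "Cdkn2a", "Mdm2"),
    stringsAsFactors = FALSE
  )
  r <- rank_metric(dmrs)
  # the gene with ranks (+2, -3) is represented by -3
  expect_equal(r$rank[r$gene == "Cdkn2a"], -3, tolerance = 1e-9)
  expect_equal(r$rank[r$gene == "Mdm2"], 2, tolerance = 1e-9)
  expect_equal(r$gene, c("Mdm2", "Cdkn2a"))   # descending rank order
  expect_error(rank_metric(dmrs[, setdiff(names(dmrs), "gene")]), "gene")
})

test_that("region scores pool counts over member CpGs", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 150L, 5000L))
  cm <- cpg_counts(sites, matrix(c(5L, 15L, 2L), 3, 1),
                   matrix(c(10L, 20L, 4L), 3, 1), samples = "s1")
  reg <- data.frame(chrom = "chr1", start = 90L, end = 200L)
  sc <- score_regions(cm, reg)
  expect_equal(unname(sc$region_meth[1, 1]), 20 / 30)
  expect_equal(unname(sc$sample_score), 20 / 30)

  # all-unmethylated counts give score zero
  cm0 <- cpg_counts(sites, matrix(0L, 3, 1), matrix(10L, 3, 1),
                    samples = "s1")
  expect_equal(unname(score_regions(cm0, reg)$sample_score), 0)
  expect_error(score_regions(cm, reg[0, ]), "empty")
})

test_that("splitting a region preserves the pooled-count identity", {
  sim <- small_cohort()
  cm <- filter_coverage(sim$counts)
  reg <- sim$truth$regions[1, ]
  mid <- reg$start + (reg$end - reg$start) %/% 2
  halves <- data.frame(chrom = reg$chrom, start = c(reg$start, mid),
                       end = c(mid, reg$end))
  whole <- score_regions(cm, reg)
  parts <- score_regions(cm, halves)
  # pooled counts across both halves reproduce the whole-region value
  gr <- sim$counts$sites$chrom == reg$chrom &
    sim$counts$sites$pos >= reg$start & sim$counts$sites$pos < reg$end
  ids <- sim$counts$sites$id[gr]
  ids <- intersect(ids, cm$sites$id)
  pooled <- colSums(cm$meth[ids, , drop = FALSE]) /
    colSums(cm$total[ids, , drop = FALSE])
  expect_equal(unname(whole$region_meth[1, ]), unname(pooled),
               tolerance = 1e-12)
  # but the unweighted mean over the two halves differs in general
  expect_false(isTRUE(all.equal(unname(parts$sample_score),
                                unname(whole$sample_score),
                                tolerance = 1e-12)))
})

test_that("signature scores increase along the division ladder", {
  sim <- cached_cohort("ladder", function() {
    simulate_cohort(sim_config(ladder_samples(), seed = 1L))
  })
  cm <- filter_coverage(sim$counts)
  s <- sim$samples
  st <- test_sites(cm, s$sample_id[s$divisions == 0],
                   s$sample_id[s$divisions == 16])
  sig <- select_top(call_dmrs(st), k = 150, direction = "gain")
  sc <- score_regions(cm, sig)$sample_score
  per_rung <- tapply(sc, s$divisions, mean)
  expect_true(all(diff(per_rung[order(as.numeric(names(per_rung)))]) > 0))
})

test_that("DMR BED export re-imports losslessly", {
  sim <- small_cohort()
  cm <- filter_coverage(sim$counts)
  st <- test_sites(cm, sim$samples$sample_id[1:3],
                   sim$samples$sample_id[4:6])
  dmrs <- call_dmrs(st)
  f <- withr::local_tempfile(fileext = ".bed")
  write_dmr_bed(dmrs, f)
  back <- read_dmr_bed(f)
  expect_equal(back, as.data.frame(dmrs)[names(back)], ignore_attr = TRUE)

  dir <- withr::local_tempdir()
  sig <- select_top(dmrs, 10, "gain", label = "sig10")
  paths <- write_signature(sig, dir)
  side <- jsonlite::read_json(paths[["sidecar"]])
  expect_equal(side$k, 10)
  expect_equal(side$n_dmrs, nrow(sig$dmrs))
})
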