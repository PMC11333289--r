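# Shared fixtures (built in code) and independent brute-force oracles.

.cohort_cache <- new.env(parent = emptyenv())

# Memoized simulated cohorts so multiple test files can reuse them.
cached_cohort <- function(key, builder) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, builder(), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

small_cohort <- function() {
  cached_cohort("small", function() {
    simulate_cohort(sim_config(two_group_samples(), n_sites = 2000L,
                               seed = 42L))
  })
}

recovery_cohort <- function() {
  cached_cohort("recovery", function() {
    simulate_cohort(sim_config(two_group_samples(), seed = 1L))
  })
}

# Hand-built count matrix: 4 sites x 3 samples.
tiny_counts <- function() {
  sites <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                      pos = c(100L, 200L, 300L, 50L))
  total <- matrix(c(10L, 20L, 10L,
                    6L, 6L, 6L,
                    6L, 5L, 6L,
                    0L, 8L, 8L), nrow = 4, byrow = TRUE)
  meth <- matrix(c(5L, 15L, 0L,
                   6L, 0L, 3L,
                   2L, 2L, 2L,
                   0L, 8L, 4L), nrow = 4, byrow = TRUE)
  cpg_counts(sites, meth, total, samples = c("s1", "s2", "s3"))
}

# Synthetic site-statistic table (sorted) for segmentation tests.
make_stats <- function(chrom, pos, z, p = 2 * pnorm(-abs(z)),
                       delta = sign(z) * 0.1) {
  data.frame(chrom = chrom, pos = as.integer(pos),
             id = paste0(chrom, ":", pos),
             mean_a = 0.2, mean_b = 0.2 + delta,
             tmean_a = 0.5, tmean_b = 0.5 + sign(z) * 0.1,
             delta = delta, z = z, p = p, stringsAsFactors = FALSE)
}

## ---- independent oracles --------------------------------------------------

# Running-sum GSEA enrichment score computed directly from the definition.
bf_gsea_es <- function(ranks_desc, hit, weight_exp = 1) {
  n <- length(ranks_desc)
  w <- abs(ranks_desc)^weight_exp
  nr <- sum(w[hit])
  nh <- sum(hit)
  step <- ifelse(hit,
                 if (nr == 0) rep(1 / nh, n) else w / nr,
                 -1 / (n - nh))
  run <- cumsum(step)
  run[which.max(abs(run))]
}

# O(n^2) any-bp overlap count (half-open), once per a-region.
bf_overlap_count <- function(a, b) {
  sum(vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1)))
}

# Exhaustive per-region precedence scan for feature classification.
bf_classify_feature <- function(region, genes, exons,
                                promoter_up = 2000, promoter_down = 500) {
  mid <- region$start + (region$end - region$start) %/% 2
  in_iv <- function(lo, hi) mid >= lo & mid < hi
  cand <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    if (g$chrom != region$chrom) next
    tss <- if (g$strand == "+") g$tx_start else g$tx_end - 1
    prom <- if (g$strand == "+") c(tss - promoter_up, tss + promoter_down)
            else c(tss - promoter_down + 1, tss + promoter_up + 1)
    ex <- exons[exons$gene == g$gene, , drop = FALSE]
    in_exon <- any(in_iv(ex$start, ex$end))
    lvl <- NULL
    if (in_iv(max(prom[1], 0), prom[2])) {
      lvl <- "promoter"
    } else if (!is.na(g$cds_start) && in_exon) {
      before_cds <- mid < g$cds_start
      after_cds <- mid >= g$cds_end
      if (before_cds) lvl <- if (g$strand == "+") "utr5" else "utr3"
      else if (after_cds) lvl <- if (g$strand == "+") "utr3" else "utr5"
      else lvl <- "exon"
    } else if (in_exon) {
      lvl <- "exon"
    } else if (in_iv(g$tx_start, g$tx_end)) {
      lvl <- "intron"
    }
    if (!is.null(lvl)) {
      cand[[length(cand) + 1]] <- list(lvl = lvl, gene = g$gene,
                                       d = abs(mid - tss))
    }
  }
  if (!length(cand)) return("intergenic")
  prec <- c(promoter = 1, utr5 = 2, utr3 = 3, exon = 4, intron = 5)
  ranks <- vapply(cand, function(x) prec[[x$lvl]], numeric(1))
  cand[[which.min(ranks)]]$lvl
}

# Distance-based CpG-context scan against merged islands.
bf_classify_context <- function(region, islands, shore_bp = 2000,
                                shelf_bp = 2000) {
  mid <- region$start + (region$end - region$start) %/% 2
  isl <- islands[islands$chrom == region$chrom, , drop = FALSE]
  if (nrow(isl) == 0) return("open_sea")
  if (any(mid >= isl$start & mid < isl$end)) return("island")
  in_band <- function(lo_off, hi_off) {
    any((mid >= isl$start - hi_off & mid < isl$start - lo_off) |
          (mid >= isl$end + lo_off & mid < isl$end + hi_off))
  }
  if (in_band(0, shore_bp)) return("shore")
  if (in_band(shore_bp, shore_bp + shelf_bp)) return("shelf")
  "open_sea"
}

# Toy genome annotation with known feature placement.
toy_annotation <- function() {
  genes <- data.frame(
    gene = c("geneA", "geneB", "geneC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tx_start = c(10000L, 40000L, 5000L),
    tx_end = c(20000L, 50000L, 9000L),
    cds_start = c(11000L, 42000L, NA),
    cds_end = c(18000L, 48000L, NA),
    stringsAsFactors = FALSE
  )
  exons <- data.frame(
    gene = c("geneA", "geneA", "geneA", "geneB", "geneB", "geneC"),
    start = c(10000L, 13000L, 17000L, 40000L, 47000L, 5000L),
    end = c(12000L, 14000L, 20000L, 43000L, 50000L, 6000L)
  )
  islands <- data.frame(chrom = c("chr1", "chr2"),
                        start = c(9500L, 4800L), end = c(11500L, 5200L))
  genome_annotation(genes, exons, islands,
                    chrom_lengths = c(chr1 = 100000L, chr2 = 50000L))
}
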