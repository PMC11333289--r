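#' Per-CpG two-group differential methylation test
#'
#' A Wald test on arcsine-square-root transformed methylation proportions:
#' per sample, `y = asin(sqrt((meth + 0.5) / (total + 1)))`; group means are
#' coverage-weighted; the per-observation variance combines the known
#' binomial sampling term `1 / (4 (total + 0.5))` (averaged within group)
#' with a pooled moment-estimated biological variance floored at `1e-4`;
#' `z = (ybar_B - ybar_A) / sqrt(var_A / n_A + var_B / n_B)` with a
#' two-sided normal p-value.  Positive `z` means higher methylation in
#' group B (by convention the older / multi-lifetime group), i.e. gain of
#' methylation with age.
#'
#' Sites should be coverage-filtered first ([filter_coverage()]); a site
#' with zero total in every sample of a group gets a missing statistic.
#'
#' @param cm A [cpg_counts()] object.
#' @param group_a,group_b Sample ids of the two groups (each at least 2).
#' @return `data.frame` with one row per site: `chrom`, `pos`, `id`, raw
#'   pooled group means `mean_a`/`mean_b`, transformed weighted means
#'   `tmean_a`/`tmean_b`, `delta` (raw B - A), `z`, `p`.
#' @export
test_sites <- function(cm, group_a, group_b) {
  stopifnot(inherits(cm, "cpg_counts"))
  ia <- match(group_a, cm$samples); ib <- match(group_b, cm$samples)
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample id in group definition")
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  n_a <- length(ia); n_b <- length(ib)
  if (n_a < 2 || n_b < 2) stop("each group needs at least 2 samples")

  meth <- cm$meth; total <- cm$total
  y <- asin(sqrt((meth + 0.5) / (total + 1)))
  samp_var <- 1 / (4 * (total + 0.5))

  wmean <- function(cols) {
    w <- total[, cols, drop = FALSE]
    rowSums(y[, cols, drop = FALSE] * w) / rowSums(w)
  }
  ybar_a <- wmean(ia); ybar_b <- wmean(ib)

  row_var <- function(cols) {
    m <- y[, cols, drop = FALSE]
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (length(cols) - 1)
  }
  s2_pool <- ((n_a - 1) * row_var(ia) + (n_b - 1) * row_var(ib)) /
    (n_a + n_b - 2)
  samp_all <- rowMeans(samp_var[, c(ia, ib), drop = FALSE])
  bio <- pmax(s2_pool - samp_all, 1e-4)

  var_a <- rowMeans(samp_var[, ia, drop = FALSE]) + bio
  var_b <- rowMeans(samp_var[, ib, drop = FALSE]) + bio
  z <- (ybar_b - ybar_a) / sqrt(var_a / n_a + var_b / n_b)
  p <- 2 * stats::pnorm(-abs(z))

  sum_a_t <- rowSums(total[, ia, drop = FALSE])
  sum_b_t <- rowSums(total[, ib, drop = FALSE])
  mean_a <- rowSums(meth[, ia, drop = FALSE]) / sum_a_t
  mean_b <- rowSums(meth[, ib, drop = FALSE]) / sum_b_t
  dead <- sum_a_t == 0 | sum_b_t == 0
  z[dead] <- NA_real_; p[dead] <- NA_real_

  data.frame(
    chrom = cm$sites$chrom, pos = cm$sites$pos, id = cm$sites$id,
    mean_a = mean_a, mean_b = mean_b,
    tmean_a = ybar_a, tmean_b = ybar_b,
    delta = mean_b - mean_a, z = unname(z), p = unname(p),
    stringsAsFactors = FALSE
  )
}

#' Segment candidate CpGs into differentially methylated regions
#'
#' Candidates are sites with `p < p_thresh`.  Maximal runs of same-sign
#' candidates whose consecutive genomic gaps are at most `max_gap_bp` form
#' proto-regions; runs with fewer than `min_cpg` candidates are dropped;
#' surviving same-sign regions closer than `merge_dist_bp` are merged.  The
#' signed **area statistic** of a region is the sum of its candidate
#' members' `z` values -- a Stouffer-style measure of strong, consistent
#' differential methylation.  Members are all same-sign candidates
#' contained in the final interval, so the statistic is recomputable from
#' the region coordinates alone.  Region `end` is the last member
#' position + 1 (half-open).
#'
#' @param stats Site statistics from [test_sites()], sorted by (chrom, pos).
#' @param p_thresh Candidate p-value threshold.
#' @param max_gap_bp Maximal gap between consecutive candidates of a run.
#' @param min_cpg Minimal candidate CpGs per region.
#' @param merge_dist_bp Merge same-sign regions separated by less than this.
#' @return `data.frame` of regions: `chrom`, `start`, `end`, `n_cpgs`,
#'   `area_stat`, `direction` (`"gain"`/`"loss"`), `mean_diff`; derivation
#'   parameters are attached as attribute `"params"`.
#' @export
call_dmrs <- function(stats, p_thresh = 0.01, max_gap_bp = 300L,
                      min_cpg = 3L, merge_dist_bp = 100L) {
  stop_if_not_sorted_sites(stats$chrom, stats$pos, "site statistics")
  params <- list(p_thresh = p_thresh, max_gap_bp = max_gap_bp,
                 min_cpg = min_cpg, merge_dist_bp = merge_dist_bp)
  ok <- !is.na(stats$p)
  cand <- stats[ok & stats$p < p_thresh, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpgs = integer(0),
                      area_stat = numeric(0), direction = character(0),
                      mean_diff = numeric(0), stringsAsFactors = FALSE)
  attr(empty, "params") <- params
  if (nrow(cand) == 0) return(empty)

  sgn <- sign(cand$z)
  new_run <- c(TRUE,
               cand$chrom[-1] != cand$chrom[-nrow(cand)] |
                 cand$pos[-1] - cand$pos[-nrow(cand)] > max_gap_bp |
                 sgn[-1] != sgn[-nrow(cand)])
  run <- cumsum(new_run)

  regions <- lapply(split(seq_len(nrow(cand)), run), function(m) {
    list(chrom = cand$chrom[m[1]], start = cand$pos[m[1]],
         end = cand$pos[m[length(m)]] + 1L, members = m)
  })
  regions <- Filter(function(r) length(r$members) >= min_cpg, regions)
  if (length(regions) == 0) return(empty)

  # merge nearby same-sign survivors, left to right (chains allowed)
  merged <- list(regions[[1]])
  for (r in regions[-1]) {
    last <- merged[[length(merged)]]
    same_sign <- sgn[r$members[1]] == sgn[last$members[1]]
    if (r$chrom == last$chrom && same_sign &&
        r$start - last$end < merge_dist_bp) {
      last$end <- r$end
      last$members <- c(last$members, r$members)
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1L]] <- r
    }
  }

  out <- do.call(rbind, lapply(merged, function(r) {
    # members: every same-sign candidate inside the final interval (after a
    # merge this may pick up candidates from short runs the interval spans)
    m <- which(cand$chrom == r$chrom & cand$pos >= r$start &
                 cand$pos < r$end & sgn == sgn[r$members[1]])
    area <- sum(cand$z[m])
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               n_cpgs = length(m), area_stat = area,
               direction = if (area > 0) "gain" else "loss",
               mean_diff = mean(cand$delta[m]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- params
  out
}

#' Select the top-K DMRs by absolute area statistic
#'
#' Filters by direction, sorts by descending `|area_stat|` (ties by
#' chromosome then start) and truncates to `k`, yielding a signature
#' program -- the ordered region set whose mean methylation acts as an
#' experiential-age clock score.
#'
#' @param dmrs Regions from [call_dmrs()].
#' @param k Signature cardinality (150 for pathway-analysis programs; 139
#'   reproduces the senescence-resistance program cardinality).
#' @param direction `"both"`, `"gain"` or `"loss"`.
#' @param label Free-text provenance label.
#' @return A `signature_program`: list with `dmrs`, `k`, `direction`,
#'   `params`, `label`.
#' @export
select_top <- function(dmrs, k = 150L, direction = c("both", "gain", "loss"),
                       label = "signature") {
  direction <- match.arg(direction)
  d <- dmrs
  if (direction != "both") d <- d[d$direction == direction, , drop = FALSE]
  o <- order(-abs(d$area_stat), d$chrom, d$start, method = "radix")
  d <- d[o, , drop = FALSE][seq_len(min(k, nrow(d))), , drop = FALSE]
  rownames(d) <- NULL
  structure(list(dmrs = d, k = as.integer(k), direction = direction,
                 params = attr(dmrs, "params"), label = label),
            class = "signature_program")
}

#' @export
print.signature_program <- function(x, ...) {
  cat("Signature program '", x$label, "': ", nrow(x$dmrs), " DMRs (k = ",
      x$k, ", direction = ", x$direction, ")\n", sep = "")
  if (nrow(x$dmrs)) {
    cat("  |area| range:", format(range(abs(x$dmrs$area_stat)), digits = 4),
        "\n")
  }
  invisible(x)
}

#' Per-gene rank metric for preranked GSEA
#'
#' Each DMR gets a region-level p-value from the normal tail of
#' `area_stat / sqrt(n_cpgs)` and a rank
#' `sign(mean_diff) * (-log10 p)`; a gene represented by several DMRs keeps
#' only the one with the largest absolute rank.  Zero p-values are clamped
#' to the smallest positive double before taking logs.
#'
#' @param dmrs Regions from [call_dmrs()] carrying a `gene` column (see
#'   [annotate_dmrs()]).
#' @return `data.frame` (`gene`, `rank`) sorted by descending rank, ties
#'   broken by gene name -- ready for [gsea_preranked()].
#' @export
rank_metric <- function(dmrs) {
  if (is.null(dmrs$gene)) stop("dmrs need a 'gene' column; annotate first")
  d <- dmrs[!is.na(dmrs$gene), , drop = FALSE]
  p <- 2 * stats::pnorm(-abs(d$area_stat / sqrt(d$n_cpgs)))
  p <- pmax(p, .Machine$double.xmin)
  rank_v <- sign(d$mean_diff) * (-log10(p))
  # one DMR per gene: largest |rank|; coordinate order breaks ties
  o <- order(d$gene, -abs(rank_v), d$chrom, d$start, method = "radix")
  keep <- o[!duplicated(d$gene[o])]
  out <- data.frame(gene = d$gene[keep], rank = rank_v[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rank, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Region-level methylation and signature scores
#'
#' For every sample and region, pooled methylation
#' `sum(meth) / sum(total)` over the CpGs falling in the region; the
#' per-sample signature score is the unweighted mean of its region-level
#' values, skipping regions with no covered CpG in that sample.
#'
#' @param cm A [cpg_counts()] object.
#' @param regions `data.frame` with `chrom`, `start`, `end` (half-open), or
#'   a `signature_program`.
#' @return List with `region_meth` (regions x samples matrix) and
#'   `sample_score` (named numeric).
#' @export
score_regions <- function(cm, regions) {
  stopifnot(inherits(cm, "cpg_counts"))
  if (inherits(regions, "signature_program")) regions <- regions$dmrs
  if (nrow(regions) == 0) stop("empty region set")
  gr_reg <- regions_to_granges(regions)
  gr_site <- points_to_granges(cm$sites$chrom, cm$sites$pos)
  hits <- GenomicRanges::findOverlaps(gr_site, gr_reg)
  reg_names <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  n_reg <- nrow(regions)
  meth_sum <- matrix(0, n_reg, length(cm$samples))
  tot_sum <- matrix(0, n_reg, length(cm$samples))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ms <- rowsum(cm$meth[qi, , drop = FALSE], si)
    ts <- rowsum(cm$total[qi, , drop = FALSE], si)
    ridx <- as.integer(rownames(ms))
    meth_sum[ridx, ] <- ms
    tot_sum[ridx, ] <- ts
  }
  region_meth <- meth_sum / tot_sum
  region_meth[tot_sum == 0] <- NA_real_
  dimnames(region_meth) <- list(reg_names, cm$samples)
  score <- apply(region_meth, 2, function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  list(region_meth = region_meth, sample_score = score)
}

#' Export DMRs as BED6+ and re-import them
#'
#' BED columns: chrom, start, end, name (`dmr_<i>` in file order), score
#' (`|area_stat|` clamped to 0-1000), strand (`.`), then `n_cpgs`,
#' `mean_diff`, `area_stat`, `direction`.  Numeric extras are written in
#' full precision so [read_dmr_bed()] round-trips losslessly.
#'
#' @param dmrs Regions from [call_dmrs()] (or a `signature_program`'s
#'   `dmrs`).
#' @param path Output BED file.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (inherits(dmrs, "signature_program")) dmrs <- dmrs$dmrs
  df <- data.frame(
    chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    name = sprintf("dmr_%d", seq_len(nrow(dmrs))),
    score = round(pmin(pmax(abs(dmrs$area_stat), 0), 1000)),
    strand = ".",
    n_cpgs = dmrs$n_cpgs,
    mean_diff = sprintf("%.17g", dmrs$mean_diff),
    area_stat = sprintf("%.17g", dmrs$area_stat),
    direction = dmrs$direction
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dmr_bed
#' @export
read_dmr_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpgs = integer(0),
                      area_stat = numeric(0), direction = character(0),
                      mean_diff = numeric(0)))
  }
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character",
                                         "integer", "numeric", "numeric",
                                         "character"))
  names(df) <- c("chrom", "start", "end", "name", "score", "strand",
                 "n_cpgs", "mean_diff", "area_stat", "direction")
  df[, c("chrom", "start", "end", "n_cpgs", "area_stat", "direction",
         "mean_diff")]
}

#' Write a signature program: BED plus JSON sidecar
#'
#' @param sig A `signature_program` from [select_top()].
#' @param dir Output directory.
#' @export
write_signature <- function(sig, dir) {
  stopifnot(inherits(sig, "signature_program"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bed <- file.path(dir, paste0(sig$label, ".bed"))
  write_dmr_bed(sig$dmrs, bed)
  side <- file.path(dir, paste0(sig$label, ".json"))
  jsonlite::write_json(
    list(label = sig$label, k = sig$k, direction = sig$direction,
         n_dmrs = nrow(sig$dmrs), params = sig$params),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(bed = bed, sidecar = side))
}
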