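#' Preranked gene set enrichment (weighted Kolmogorov-Smirnov)
#'
#' Walks the ranked gene list from top to bottom, incrementing a running
#' sum at gene-set hits proportionally to `|rank|^weight_exp` (normalized
#' over hits) and decrementing by `1 / (N - Nh)` at misses.  The enrichment
#' score (ES) is the running-sum value of largest absolute magnitude; its
#' significance comes from gene-label permutation (rank values fixed,
#' labels shuffled): permuted ES at least as extreme with the same sign,
#' normalized over the same-sign permutations with the +1 Monte-Carlo
#' correction, so the p-value is never exactly 0 and is calibrated under
#' the null.  The leading edge comprises
#' the hits at or before the extremum (at or after, for negative ES).
#'
#' @param ranked `data.frame` (`gene`, `rank`) as from [rank_metric()], or
#'   a named numeric vector of ranks.  Sorted descending, ties broken by
#'   gene name.
#' @param gene_set Character vector of member genes.
#' @param weight_exp Hit-weight exponent (1 = classic weighted statistic,
#'   0 = unweighted Kolmogorov-Smirnov).
#' @param n_perm Number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return List of class `enrichment_result`: `es`, `p`, `n_perm`,
#'   `leading_edge`, `n_hits`, `seed`.
#' @export
gsea_preranked <- function(ranked, gene_set, weight_exp = 1,
                           n_perm = 1000L, seed = 1L) {
  if (is.data.frame(ranked)) {
    genes <- ranked$gene; r <- ranked$rank
  } else {
    genes <- names(ranked); r <- unname(ranked)
  }
  if (anyDuplicated(genes)) stop("genes in the ranked list must be unique")
  o <- order(-r, genes, method = "radix")
  genes <- genes[o]; r <- r[o]
  hit <- genes %in% unique(gene_set)
  n <- length(genes); nh <- sum(hit)
  if (nh == 0) stop("no gene-set member present in the ranked list")
  if (nh >= n) stop("gene set covers the entire list")

  w <- abs(r)^weight_exp
  es_core <- function(hit_v) {
    inc <- numeric(n)
    wh <- w[hit_v]
    nr <- sum(wh)
    if (nr == 0) {
      inc[hit_v] <- 1 / sum(hit_v)   # all hit weights zero: equal increments
    } else {
      inc[hit_v] <- wh / nr
    }
    inc[!hit_v] <- -1 / (n - sum(hit_v))
    run <- cumsum(inc)
    run[which.max(abs(run))]
  }

  run_inc <- numeric(n)
  nr <- sum(w[hit])
  if (nr == 0) run_inc[hit] <- 1 / nh else run_inc[hit] <- w[hit] / nr
  run_inc[!hit] <- -1 / (n - nh)
  run <- cumsum(run_inc)
  ext <- which.max(abs(run))
  es <- run[ext]
  leading <- if (es >= 0) genes[hit & seq_len(n) <= ext]
             else genes[hit & seq_len(n) >= ext]

  perm_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    hp <- logical(n)
    hp[sample.int(n, nh)] <- TRUE
    es_core(hp)
  }, numeric(1)))
  # one-sided Monte-Carlo p conditional on the observed sign, with the +1
  # correction: permuted ES of the opposite sign carry no evidence about an
  # enrichment in this direction, so they are excluded from both counts
  same_sign <- if (es >= 0) perm_es >= 0 else perm_es < 0
  extreme <- if (es >= 0) perm_es >= es else perm_es <= es
  p <- (1 + sum(extreme & same_sign)) / (1 + sum(same_sign))

  structure(list(es = es, p = p, n_perm = as.integer(n_perm),
                 leading_edge = leading, n_hits = nh,
                 seed = as.integer(seed)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.4f, p = %.4g (%d permutations, %d hits, %d leading-edge genes)\n",
              x$es, x$p, x$n_perm, x$n_hits, length(x$leading_edge)))
  invisible(x)
}

#' Overlap two region (or gene) lists
#'
#' `any_bp` counts, once per `a`-region, the `a`-regions sharing at least
#' one base with some `b`-region (half-open coordinates); `gene_label`
#' intersects gene label sets and is symmetric.
#'
#' @param a,b Region `data.frame`s (`chrom`, `start`, `end`, and `gene`
#'   for `gene_label` mode) or, in `gene_label` mode, character vectors.
#' @param mode `"any_bp"` or `"gene_label"`.
#' @return List of class `overlap_result`: `n_a_only`, `n_b_only`,
#'   `n_overlap`, plus the overlapping identities (`a` row indices /
#'   shared labels).
#' @export
overlap_regions <- function(a, b, mode = c("any_bp", "gene_label")) {
  mode <- match.arg(mode)
  if (mode == "gene_label") {
    la <- unique(if (is.data.frame(a)) a$gene else as.character(a))
    lb <- unique(if (is.data.frame(b)) b$gene else as.character(b))
    shared <- intersect(la, lb)
    return(structure(list(
      n_a_only = length(setdiff(la, lb)), n_b_only = length(setdiff(lb, la)),
      n_overlap = length(shared), shared = sort(shared), mode = mode
    ), class = "overlap_result"))
  }
  ca <- unique(a$chrom); cb <- unique(b$chrom)
  if (length(ca) && length(cb) && !length(intersect(ca, cb))) {
    warning("no shared chromosome names; unmatched: ",
            paste(unique(c(ca, cb)), collapse = ", "))
  }
  gra <- regions_to_granges(a); grb <- regions_to_granges(b)
  # disjoint seqlevel sets already raise our own warning above
  a_hit <- suppressWarnings(GenomicRanges::countOverlaps(gra, grb) > 0)
  b_hit <- suppressWarnings(GenomicRanges::countOverlaps(grb, gra) > 0)
  structure(list(
    n_a_only = sum(!a_hit), n_b_only = sum(!b_hit), n_overlap = sum(a_hit),
    a_overlapping = which(a_hit), b_overlapping = which(b_hit), mode = mode
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap (%s): A-only %d, B-only %d, overlapping %d\n",
              x$mode, x$n_a_only, x$n_b_only, x$n_overlap))
  invisible(x)
}

#' One-sided binomial enrichment of regions in term domains
#'
#' For each annotation term with a genomic domain set: the background hit
#' probability is the merged domain span divided by the genome size, the
#' observed count is the number of query regions whose midpoint falls in a
#' domain, and the p-value is the exact upper binomial tail
#' `P(X >= k), X ~ Bin(n_regions, p_term)`, with no multiple-testing
#' adjustment.
#'
#' @param regions Query regions (`chrom`, `start`, `end`, half-open).
#' @param term_domains Named list of region `data.frame`s, one per term.
#' @param genome_size Total genome size in bp.
#' @return `data.frame`: `term`, `n_hits`, `p_term`, `fold`, `p`.
#' @export
binomial_region_enrichment <- function(regions, term_domains, genome_size) {
  stopifnot(genome_size > 0, length(term_domains) > 0)
  n <- nrow(regions)
  mid <- regions$start + (regions$end - regions$start) %/% 2L
  gr_mid <- points_to_granges(regions$chrom, mid)
  out <- lapply(names(term_domains), function(term) {
    dom <- term_domains[[term]]
    gr_dom <- GenomicRanges::reduce(regions_to_granges(dom))
    bp <- sum(GenomicRanges::width(gr_dom))
    if (bp > genome_size) stop("term '", term, "' domains exceed genome size")
    p_term <- bp / genome_size
    k <- sum(suppressWarnings(
      GenomicRanges::countOverlaps(gr_mid, gr_dom)) > 0)
    if (p_term == 0 && k > 0) {
      stop("term '", term, "': zero-span domains but ", k, " hits")
    }
    pval <- if (k == 0) 1 else stats::pbinom(k - 1L, n, p_term,
                                             lower.tail = FALSE)
    data.frame(term = term, n_hits = k, p_term = p_term,
               fold = if (p_term > 0) (k / n) / p_term else NA_real_,
               p = pval, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Basal regulatory domains around transcription start sites
#'
#' Builds per-gene basal domains (default TSS -5 kb / +1 kb, strand-aware,
#' clipped at chromosome ends) as a simple regulatory-domain model for
#' [binomial_region_enrichment()].
#'
#' @param genes `data.frame` with `gene`, `chrom`, `strand` (`"+"`/`"-"`),
#'   `tss` (0-based).
#' @param up,down Basal extent upstream / downstream of the TSS (bp).
#' @param chrom_lengths Named chromosome lengths for clipping.
#' @return Region `data.frame` (`chrom`, `start`, `end`, `gene`).
#' @export
basal_domains <- function(genes, up = 5000L, down = 1000L,
                          chrom_lengths = NULL) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - up, genes$tss - down + 1L)
  end <- ifelse(plus, genes$tss + down, genes$tss + up + 1L)
  start <- pmax(start, 0L)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[genes$chrom]
    end <- pmin(end, lim)
  }
  data.frame(chrom = genes$chrom, start = as.integer(start),
             end = as.integer(end), gene = genes$gene,
             stringsAsFactors = FALSE)
}

#' Read GMT gene-set collections; read / write RNK ranked lists
#'
#' GMT: one set per line, `name<TAB>description<TAB>gene...`.  RNK: a
#' two-column headerless TSV of gene and rank value.
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character vectors; `read_rnk()`:
#'   `data.frame` (`gene`, `rank`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  sets
}

#' @rdname read_gmt
#' @export
read_rnk <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("gene", "rank"))
  df
}

#' @rdname read_gmt
#' @param ranked `data.frame` (`gene`, `rank`).
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(
    data.frame(gene = ranked$gene, rank = sprintf("%.17g", ranked$rank)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
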