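#' Genome annotation container
#'
#' Holds the gene models, CpG islands and chromosome lengths used to
#' classify DMRs.  All intervals are 0-based half-open.  UTRs are derived
#' from CDS versus transcript bounds; genes without a CDS (`NA` cds)
#' contribute exon/intron classes only.
#'
#' @param genes `data.frame`: `gene`, `chrom`, `strand` (`"+"`/`"-"`),
#'   `tx_start`, `tx_end`, and optional `cds_start`, `cds_end`.
#' @param exons `data.frame`: `gene`, `start`, `end` (within tx bounds).
#' @param islands CpG island regions (`chrom`, `start`, `end`); merged and
#'   sorted internally.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return A `genome_annotation` object.
#' @export
genome_annotation <- function(genes, exons, islands, chrom_lengths) {
  genes <- as.data.frame(genes); exons <- as.data.frame(exons)
  stopifnot(all(c("gene", "chrom", "strand", "tx_start", "tx_end") %in%
                  names(genes)),
            all(c("gene", "start", "end") %in% names(exons)))
  if (is.null(genes$cds_start)) genes$cds_start <- NA_integer_
  if (is.null(genes$cds_end)) genes$cds_end <- NA_integer_
  if (anyDuplicated(genes$gene)) stop("gene ids must be unique")
  if (any(genes$tx_end <= genes$tx_start)) stop("tx_end must exceed tx_start")
  ex_g <- match(exons$gene, genes$gene)
  if (anyNA(ex_g)) stop("exon refers to unknown gene")
  if (any(exons$start < genes$tx_start[ex_g]) ||
      any(exons$end > genes$tx_end[ex_g])) {
    stop("exons must lie within transcript bounds")
  }
  lim <- chrom_lengths[genes$chrom]
  if (anyNA(lim) || any(genes$tx_end > lim) || any(genes$tx_start < 0)) {
    stop("gene intervals must lie within chromosome lengths")
  }
  isl <- GenomicRanges::reduce(regions_to_granges(islands))
  structure(list(genes = genes, exons = exons, islands = isl,
                 chrom_lengths = chrom_lengths),
            class = "genome_annotation")
}

# strand-aware TSS (0-based position of the first transcribed base)
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
}

# Feature interval sets per precedence level, each a data.frame
# (chrom, start, end, gene_idx).  Half-open coordinates.
feature_levels <- function(ann, promoter_up, promoter_down) {
  g <- ann$genes
  tss <- gene_tss(g)
  plus <- g$strand == "+"
  prom <- data.frame(
    chrom = g$chrom,
    start = ifelse(plus, tss - promoter_up, tss - promoter_down + 1L),
    end = ifelse(plus, tss + promoter_down, tss + promoter_up + 1L),
    gene_idx = seq_len(nrow(g))
  )
  prom$start <- pmax(prom$start, 0L)

  ex <- ann$exons
  ex_g <- match(ex$gene, g$gene)
  exon <- data.frame(chrom = g$chrom[ex_g], start = ex$start, end = ex$end,
                     gene_idx = ex_g)

  # UTRs: exonic sequence outside the CDS, 5' or 3' by strand
  has_cds <- !is.na(g$cds_start[ex_g]) & !is.na(g$cds_end[ex_g])
  clip <- function(lo, hi) {
    s <- pmax(ex$start, lo); e <- pmin(ex$end, hi)
    keep <- has_cds & s < e
    data.frame(chrom = g$chrom[ex_g][keep], start = s[keep], end = e[keep],
               gene_idx = ex_g[keep])
  }
  left <- clip(g$tx_start[ex_g], g$cds_start[ex_g])   # 5' on +, 3' on -
  right <- clip(g$cds_end[ex_g], g$tx_end[ex_g])      # 3' on +, 5' on -
  lplus <- g$strand[left$gene_idx] == "+"
  rplus <- g$strand[right$gene_idx] == "+"
  utr5 <- rbind(left[lplus, ], right[!rplus, ])
  utr3 <- rbind(right[rplus, ], left[!lplus, ])

  tx <- data.frame(chrom = g$chrom, start = g$tx_start, end = g$tx_end,
                   gene_idx = seq_len(nrow(g)))
  list(promoter = prom, utr5 = utr5, utr3 = utr3, exon = exon, intron = tx)
}

#' Classify regions by genomic feature
#'
#' Each region is classified by its midpoint with precedence
#' promoter > 5' UTR > 3' UTR > exon > intron > intergenic.  The promoter
#' window is strand-aware (`[TSS - up, TSS + down)` on the plus strand).
#' The assigned gene is the precedence-winning gene (nearest TSS among
#' equal-precedence candidates); intergenic regions get the nearest-TSS
#' gene.  `tss_dist` is the strand-aware signed distance from the midpoint
#' to the assigned gene's TSS (positive downstream).
#'
#' @param regions Region `data.frame` (`chrom`, `start`, `end`).
#' @param ann A [genome_annotation()].
#' @param promoter_up,promoter_down Promoter window around the TSS (bp).
#' @return `data.frame`: `feature`, `gene`, `tss_dist`, one row per region.
#' @export
classify_feature <- function(regions, ann, promoter_up = 2000L,
                             promoter_down = 500L) {
  stopifnot(inherits(ann, "genome_annotation"))
  unknown <- setdiff(unique(regions$chrom), names(ann$chrom_lengths))
  if (length(unknown)) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  n <- nrow(regions)
  mid <- regions$start + (regions$end - regions$start) %/% 2L
  gr_mid <- points_to_granges(regions$chrom, mid)
  g <- ann$genes
  tss <- gene_tss(g)

  tss_dist_to <- function(region_i, gene_i) {
    d <- mid[region_i] - tss[gene_i]
    ifelse(g$strand[gene_i] == "+", d, -d)
  }

  feature <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  tdist <- rep(NA_real_, n)
  unassigned <- rep(TRUE, n)

  levels <- feature_levels(ann, promoter_up, promoter_down)
  for (lv in names(levels)) {
    iv <- levels[[lv]]
    if (!nrow(iv) || !any(unassigned)) next
    hits <- GenomicRanges::findOverlaps(gr_mid, regions_to_granges(iv))
    qi <- S4Vectors::queryHits(hits); gi <- iv$gene_idx[S4Vectors::subjectHits(hits)]
    use <- unassigned[qi]
    qi <- qi[use]; gi <- gi[use]
    if (!length(qi)) next
    # nearest TSS, then gene id, decides among equal-precedence candidates
    o <- order(qi, abs(tss_dist_to(qi, gi)), g$gene[gi], method = "radix")
    qi <- qi[o]; gi <- gi[o]
    first <- !duplicated(qi)
    ri <- qi[first]; wi <- gi[first]
    feature[ri] <- lv
    gene[ri] <- g$gene[wi]
    tdist[ri] <- tss_dist_to(ri, wi)
    unassigned[ri] <- FALSE
  }

  if (any(unassigned) && nrow(g)) {
    for (ri in which(unassigned)) {
      same <- which(g$chrom == regions$chrom[ri])
      if (!length(same)) next
      d <- abs(tss_dist_to(rep(ri, length(same)), same))
      wi <- same[order(d, g$gene[same], method = "radix")[1]]
      gene[ri] <- g$gene[wi]
      tdist[ri] <- tss_dist_to(ri, wi)
    }
  }
  data.frame(feature = feature, gene = gene, tss_dist = tdist,
             stringsAsFactors = FALSE)
}

#' Classify regions by CpG context
#'
#' Midpoint-based: island if inside a (merged) CpG island, shore within
#' `shore_bp` of an island edge, shelf within the next `shelf_bp`,
#' otherwise open sea.  Shore and shelf bands are constructed as half-open
#' intervals flanking the merged islands, so they never overlap an island.
#'
#' @param regions Region `data.frame` (`chrom`, `start`, `end`).
#' @param islands Island regions or a [genome_annotation()].
#' @param shore_bp,shelf_bp Band widths (bp).
#' @return Character vector: `"island"`, `"shore"`, `"shelf"`, `"open_sea"`.
#' @export
classify_cpg_context <- function(regions, islands, shore_bp = 2000L,
                                 shelf_bp = 2000L) {
  isl <- if (inherits(islands, "genome_annotation")) islands$islands
         else GenomicRanges::reduce(regions_to_granges(islands))
  mid <- regions$start + (regions$end - regions$start) %/% 2L
  gr_mid <- points_to_granges(regions$chrom, mid)

  band <- function(extra_lo, extra_hi) {
    up <- GenomicRanges::flank(isl, width = extra_hi, start = TRUE)
    dn <- GenomicRanges::flank(isl, width = extra_hi, start = FALSE)
    full <- GenomicRanges::reduce(c(up, dn))
    full <- GenomicRanges::setdiff(full, isl)
    if (extra_lo > 0) {
      inner_up <- GenomicRanges::flank(isl, width = extra_lo, start = TRUE)
      inner_dn <- GenomicRanges::flank(isl, width = extra_lo, start = FALSE)
      full <- GenomicRanges::setdiff(
        full, GenomicRanges::reduce(c(inner_up, inner_dn)))
    }
    full
  }
  shore <- band(0L, shore_bp)
  shelf <- band(shore_bp, shore_bp + shelf_bp)

  ctx <- rep("open_sea", nrow(regions))
  in_isl <- GenomicRanges::countOverlaps(gr_mid, isl) > 0
  in_shore <- !in_isl & GenomicRanges::countOverlaps(gr_mid, shore) > 0
  in_shelf <- !in_isl & !in_shore &
    GenomicRanges::countOverlaps(gr_mid, shelf) > 0
  ctx[in_isl] <- "island"; ctx[in_shore] <- "shore"; ctx[in_shelf] <- "shelf"
  ctx
}

#' Annotate DMRs with feature class, gene and CpG context
#'
#' @param dmrs Regions from [call_dmrs()] or a `signature_program`.
#' @param ann A [genome_annotation()].
#' @inheritParams classify_feature
#' @inheritParams classify_cpg_context
#' @return The input regions with `feature`, `gene`, `tss_dist` and
#'   `cpg_context` columns appended.
#' @export
annotate_dmrs <- function(dmrs, ann, promoter_up = 2000L,
                          promoter_down = 500L, shore_bp = 2000L,
                          shelf_bp = 2000L) {
  if (inherits(dmrs, "signature_program")) dmrs <- dmrs$dmrs
  fc <- classify_feature(dmrs, ann, promoter_up, promoter_down)
  out <- cbind(dmrs, fc)
  out$cpg_context <- classify_cpg_context(dmrs, ann, shore_bp, shelf_bp)
  out
}

#' Fraction tables of annotated DMRs, split by direction
#'
#' Returns, per DMR direction, the fraction of regions in each feature
#' class and each CpG context; fractions sum to 1 within every direction
#' for each axis.
#'
#' @param annotated Output of [annotate_dmrs()] (needs `direction`,
#'   `feature`, `cpg_context` columns).
#' @return List with `feature` and `cpg_context` fraction matrices
#'   (direction x class).
#' @export
annotation_summary <- function(annotated) {
  if (nrow(annotated) == 0) stop("nonempty input required")
  feat_lv <- c("promoter", "utr5", "utr3", "exon", "intron", "intergenic")
  ctx_lv <- c("island", "shore", "shelf", "open_sea")
  f <- table(annotated$direction, factor(annotated$feature, levels = feat_lv))
  cx <- table(annotated$direction,
              factor(annotated$cpg_context, levels = ctx_lv))
  list(feature = prop.table(f, margin = 1),
       cpg_context = prop.table(cx, margin = 1))
}
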