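#' Per-CpG methylation count matrices
#'
#' `cpg_counts` is the raw substrate of every analysis stage: parallel
#' integer matrices of methylated and total read counts over a sorted site
#' table.  Coordinates are 0-based half-open internally; Bismark-coverage
#' I/O converts at the boundary.
#'
#' @param sites `data.frame` with columns `chrom`, `pos` (0-based) and
#'   optionally `id`; rows are sorted by (chrom, pos) if not already.
#' @param meth,total Integer matrices, sites by samples, with
#'   `meth <= total` elementwise.
#' @param samples Sample ids (column names).
#' @return A `cpg_counts` object.
#' @export
cpg_counts <- function(sites, meth, total, samples = colnames(total)) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  if (is.null(sites$id)) sites$id <- site_id(sites$chrom, sites$pos)
  meth <- as.matrix(meth); total <- as.matrix(total)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(total)))
  stopifnot(nrow(meth) == nrow(sites), identical(dim(meth), dim(total)),
            ncol(meth) == length(samples))
  if (any(sites$pos < 0)) stop("positions must be nonnegative")
  if (anyDuplicated(sites$id)) stop("site ids must be unique")
  if (any(meth > total)) stop("meth > total at some (site, sample)")
  if (any(meth < 0) || any(total < 0)) stop("counts must be nonnegative")
  if (any(meth != round(meth)) || any(total != round(total))) {
    stop("counts must be integers")
  }
  storage.mode(meth) <- "integer"
  storage.mode(total) <- "integer"
  o <- site_order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  meth <- meth[o, , drop = FALSE]
  total <- total[o, , drop = FALSE]
  rownames(sites) <- NULL
  dimnames(meth) <- dimnames(total) <- list(sites$id, samples)
  structure(list(sites = sites, meth = meth, total = total,
                 samples = samples),
            class = "cpg_counts")
}

#' @export
print.cpg_counts <- function(x, ...) {
  cat("CpG count matrix:", nrow(x$sites), "sites x", length(x$samples),
      "samples\n")
  cat("  chroms:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  cov <- x$total[x$total > 0]
  if (length(cov)) cat("  median covered depth:", stats::median(cov), "\n")
  invisible(x)
}

#' @export
dim.cpg_counts <- function(x) dim(x$total)

#' Subset a count matrix by site index
#' @noRd
subset_sites <- function(cm, keep) {
  cm$sites <- cm$sites[keep, , drop = FALSE]
  rownames(cm$sites) <- NULL
  cm$meth <- cm$meth[keep, , drop = FALSE]
  cm$total <- cm$total[keep, , drop = FALSE]
  cm
}

#' Read Bismark-coverage-style count files
#'
#' One file per sample with six whitespace-separated columns: chrom,
#' start (1-based), end (1-based inclusive), percent methylation,
#' count methylated, count unmethylated.  Positions are converted to the
#' internal 0-based convention; the site set is the union across files and
#' absent (site, sample) pairs get `total = 0`.  Input is assumed
#' strand-collapsed per CpG dyad; no strand merging is performed.
#'
#' @param paths Files, one per sample.
#' @param sample_ids Sample ids, parallel to `paths`; defaults to file
#'   basenames without extension.
#' @return A [cpg_counts()] object.
#' @export
read_coverage <- function(paths, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  stopifnot(length(paths) == length(sample_ids))
  per <- lapply(seq_along(paths), function(i) {
    df <- tryCatch(
      utils::read.table(paths[i], stringsAsFactors = FALSE,
                        colClasses = c("character", "integer", "integer",
                                       "numeric", "integer", "integer")),
      error = function(e) stop("malformed coverage file ", paths[i], ": ",
                               conditionMessage(e), call. = FALSE)
    )
    if (ncol(df) != 6) {
      stop("coverage file ", paths[i], " must have 6 columns", call. = FALSE)
    }
    names(df) <- c("chrom", "start", "end", "pct", "n_meth", "n_unmeth")
    bad <- which(df$n_meth < 0 | df$n_unmeth < 0)
    if (length(bad)) {
      stop("negative count in ", paths[i], " line ", bad[1], call. = FALSE)
    }
    df
  })
  all_sites <- unique(do.call(rbind, lapply(per, function(d) {
    data.frame(chrom = d$chrom, pos = d$start - 1L, stringsAsFactors = FALSE)
  })))
  all_sites <- all_sites[site_order(all_sites$chrom, all_sites$pos), ,
                         drop = FALSE]
  all_sites$id <- site_id(all_sites$chrom, all_sites$pos)
  n <- nrow(all_sites)
  meth <- matrix(0L, n, length(paths))
  total <- matrix(0L, n, length(paths))
  for (i in seq_along(per)) {
    d <- per[[i]]
    ix <- match(site_id(d$chrom, d$start - 1L), all_sites$id)
    meth[ix, i] <- d$n_meth
    total[ix, i] <- d$n_meth + d$n_unmeth
  }
  cpg_counts(all_sites, meth, total, samples = sample_ids)
}

#' Write Bismark-coverage-style count files, one per sample
#'
#' Sites with zero coverage in a sample are omitted from that sample's
#' file, mirroring what alignment pipelines emit.  Writing then re-reading
#' reproduces the counts exactly.
#'
#' @param cm A [cpg_counts()] object.
#' @param dir Output directory.
#' @return Invisibly, the written paths (named by sample).
#' @export
write_coverage <- function(cm, dir) {
  stopifnot(inherits(cm, "cpg_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(cm$samples))
  for (i in seq_along(cm$samples)) {
    covered <- cm$total[, i] > 0
    m <- cm$meth[covered, i]; t <- cm$total[covered, i]
    df <- data.frame(
      chrom = cm$sites$chrom[covered],
      start = cm$sites$pos[covered] + 1L,
      end = cm$sites$pos[covered] + 1L,
      pct = formatC(100 * m / t, format = "f", digits = 6),
      n_meth = m,
      n_unmeth = t - m
    )
    paths[i] <- file.path(dir, paste0(cm$samples[i], ".cov"))
    utils::write.table(df, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(stats::setNames(paths, cm$samples))
}

#' Beta values from counts
#'
#' `beta = meth / total`, `NA` exactly where `total = 0`; no smoothing and
#' no pseudocount.  The site table travels along as an attribute.
#'
#' @param cm A [cpg_counts()] object.
#' @return Numeric matrix (sites x samples) with attribute `"sites"`.
#' @export
compute_beta <- function(cm) {
  stopifnot(inherits(cm, "cpg_counts"))
  beta <- cm$meth / cm$total
  beta[cm$total == 0] <- NA_real_
  attr(beta, "sites") <- cm$sites
  beta
}

#' Site table attached to a beta matrix
#' @param bm Beta matrix from [compute_beta()].
#' @export
beta_sites <- function(bm) {
  s <- attr(bm, "sites")
  if (is.null(s)) {
    ids <- rownames(bm)
    s <- data.frame(chrom = sub(":.*$", "", ids),
                    pos = as.integer(sub("^.*:", "", ids)), id = ids,
                    stringsAsFactors = FALSE)
  }
  s
}

#' Coverage filter: sites covered in every sample
#'
#' Keeps exactly the sites whose total read count is strictly greater than
#' `min_exclusive` in *all* samples (default: "higher than five reads"),
#' preserving site order.  Idempotent; larger thresholds give subsets.
#'
#' @param cm A [cpg_counts()] object.
#' @param min_exclusive Exclusive lower bound on per-sample coverage.
#' @return Filtered [cpg_counts()].
#' @export
filter_coverage <- function(cm, min_exclusive = 5L) {
  stopifnot(inherits(cm, "cpg_counts"), min_exclusive >= 0)
  keep <- rowSums(cm$total > min_exclusive) == length(cm$samples)
  if (!any(keep)) warning("no site passes the coverage filter")
  subset_sites(cm, keep)
}

#' Per-sample global methylation summary
#'
#' Unweighted mean and median of the nonmissing beta values of each sample;
#' a sample with no covered site gets `NA` summaries.
#'
#' @param bm Beta matrix from [compute_beta()].
#' @return `data.frame` with `sample_id`, `mean_beta`, `median_beta`,
#'   `n_sites`.
#' @export
global_methylation <- function(bm) {
  data.frame(
    sample_id = colnames(bm),
    mean_beta = apply(bm, 2, function(x) {
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }),
    median_beta = apply(bm, 2, function(x) {
      if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE)
    }),
    n_sites = colSums(!is.na(bm)),
    row.names = NULL
  )
}

#' PCA on the most variable CpG sites
#'
#' Ranks complete (no missing value) sites by across-sample variance, takes
#' the top `n_top` (ties broken by genomic coordinate), centers each site
#' (no unit-variance scaling) and computes principal components by singular
#' value decomposition.  Each component's loading vector is oriented so its
#' sum is nonnegative.
#'
#' @param bm Beta matrix from [compute_beta()] (apply [filter_coverage()]
#'   first so the candidate sites have no missing values).
#' @param n_top Number of top-variance sites (all if fewer are available).
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x components), `var_explained`
#'   (fraction of selected-site variance per component), `sites` (ids used)
#'   and `loadings`.
#' @export
variable_site_pca <- function(bm, n_top = 3000L, n_components = 2L) {
  if (ncol(bm) < 2) stop("PCA needs at least 2 samples")
  complete <- rowSums(is.na(bm)) == 0
  bm_c <- bm[complete, , drop = FALSE]
  sites <- beta_sites(bm)[complete, , drop = FALSE]
  v <- apply(bm_c, 1, stats::var)
  # rank by variance descending; site order (already coordinate-sorted)
  # breaks ties deterministically
  o <- order(-v, seq_along(v))
  take <- o[seq_len(min(n_top, length(o)))]
  x <- t(bm_c[take, , drop = FALSE])          # samples x sites
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)
  k <- min(n_components, length(sv$d))
  load <- sv$v[, seq_len(k), drop = FALSE]
  flip <- ifelse(colSums(load) < 0, -1, 1)
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                            k, k),
                  2, flip, `*`)
  dimnames(scores) <- list(colnames(bm), paste0("PC", seq_len(k)))
  tot_var <- sum(sv$d^2)
  list(
    scores = scores,
    var_explained = if (tot_var > 0) (sv$d^2 / tot_var)[seq_len(k)]
                    else rep(0, k),
    sites = sites$id[take],
    loadings = load
  )
}

#' Write a sample's beta values as bedGraph
#'
#' @param bm Beta matrix.
#' @param sample Sample id (column of `bm`).
#' @param path Output file.
#' @export
write_bedgraph <- function(bm, sample, path) {
  stopifnot(sample %in% colnames(bm))
  s <- beta_sites(bm)
  b <- bm[, sample]
  ok <- !is.na(b)
  df <- data.frame(chrom = s$chrom[ok], start = s$pos[ok],
                   end = s$pos[ok] + 1L,
                   beta = formatC(b[ok], format = "f", digits = 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
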