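# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so library functions do not perturb user randomness.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a reproducible per-stage seed from a master seed
#'
#' Stage names are hashed so that inserting a new stage does not reshuffle the
#' randomness of stages downstream of it.  The result is always a valid
#' 32-bit integer seed.
#'
#' @param seed Master integer seed.
#' @param stage Character stage name.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, length(stage) == 1L)
  chars <- utf8ToInt(stage)
  h <- 0
  for (c in chars) h <- (h * 131 + c) %% 1999999973
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

site_id <- function(chrom, pos) paste0(chrom, ":", pos)

# Order used for every site table: chromosome name lexicographic, then position.
site_order <- function(chrom, pos) order(chrom, pos, method = "radix")

stop_if_not_sorted_sites <- function(chrom, pos, what = "input") {
  o <- site_order(chrom, pos)
  if (!identical(o, seq_along(chrom))) {
    stop(what, " must be sorted by (chrom, pos)", call. = FALSE)
  }
}

# data.frame of half-open regions -> GRanges (1-based closed internally).
regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

points_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos + 1L, width = 1L)
  )
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "", ...)
}
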