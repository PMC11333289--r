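#' Synthetic WGBS cohorts with planted experiential-age methylation drift
#'
#' The simulator emulates the design of a serial-transplant / iterative-boost
#' T cell aging study: each sample carries both a cumulative division count
#' `divisions` (the lineage's experiential age) and a host chronological age
#' `host_age` (months), and the two are decoupled.  Three classes of CpG
#' sites drift:
#'
#' * **gain** sites start hypomethylated and gain methylation with divisions
#'   following a saturating exponential, `mu = b + (1 - b) (1 - exp(-k D))`;
#'   they are planted in contiguous runs so that region callers can find them;
#' * **loss** sites start hypermethylated and decay with divisions,
#'   `mu = b exp(-r D)`, producing the global demethylation seen in aged
#'   lineages;
#' * **hostage** sites drift (weakly) with host age only,
#'   `mu = b + (1 - b) (1 - exp(-r A))`.
#'
#' All remaining sites are stable.  Coverage is negative-binomial and
#' methylated counts are beta-binomial around the drift surface with
#' overdispersion `bio_dispersion`.
#'
#' @name simdata
NULL

#' Saturating gain rate for a target methylation change
#'
#' Solves `(1 - baseline) * (1 - exp(-k * divisions)) = delta` for the
#' per-division rate `k`, i.e. the rate at which gain-class loci must
#' saturate so that a lineage with the given division count shows the given
#' beta-value increase over baseline.
#'
#' @param delta Target increase in mean methylation (beta scale).
#' @param divisions Division count at which the target is reached.
#' @param baseline Baseline methylation of the gain loci.
#' @return Per-division rate (1/divisions).
#' @export
#' @examples
#' gain_rate_for_delta(0.4, 16, 0.05)
gain_rate_for_delta <- function(delta, divisions, baseline = 0.05) {
  stopifnot(delta > 0, delta < 1 - baseline, divisions > 0)
  -log(1 - delta / (1 - baseline)) / divisions
}

#' Drift surfaces for the three site classes
#'
#' Closed-form expected methylation as a function of divisions `D` (gain,
#' loss) or host age `A` in months (hostage).
#'
#' @param baseline Baseline methylation in `[0, 1]`.
#' @param rate Nonnegative drift rate.
#' @param divisions,host_age Nonnegative drift coordinate.
#' @return Expected beta in `[0, 1]`.
#' @export
mu_gain <- function(baseline, rate, divisions) {
  baseline + (1 - baseline) * (1 - exp(-rate * divisions))
}

#' @rdname mu_gain
#' @export
mu_loss <- function(baseline, rate, divisions) {
  baseline * exp(-rate * divisions)
}

#' @rdname mu_gain
#' @export
mu_hostage <- function(baseline, rate, host_age) {
  baseline + (1 - baseline) * (1 - exp(-rate * host_age))
}

#' Simulation configuration
#'
#' Bundles and validates all generator parameters.  Defaults encode the
#' package's reference study conditions: 20,000 CpG sites of which 8% are
#' gain-class loci planted as 200 contiguous runs of 8 CpGs within 400 bp,
#' a gain rate calibrated so that the gain loci rise by delta-beta = 0.4
#' between 0 and 16 divisions, 30% slowly demethylating loss loci, 1%
#' host-age loci moving at most ~0.1 beta over a 30-month lifespan,
#' negative-binomial coverage with mean 20 and dispersion (size) 5, and
#' beta-binomial biological overdispersion phi = 0.02.
#'
#' @param samples Sample sheet, e.g. from [two_group_samples()],
#'   [ladder_samples()], [crossed_samples()] or [rest_design_samples()].
#' @param n_sites Total CpG sites.
#' @param n_chroms Number of chromosomes the sites are spread over.
#' @param frac_gain,frac_loss,frac_hostage Fractions of sites in the
#'   gain / loss / host-age drift classes; must sum to at most 1.
#' @param gain_rate Per-division saturation rate of gain loci.
#' @param loss_rate Per-division decay rate of loss loci.
#' @param hostage_rate Per-month rate of host-age loci.
#' @param baseline_beta_gain Baseline methylation of gain (and host-age) loci.
#' @param gain_run_length CpGs per planted gain run.
#' @param gain_run_span_bp Maximal genomic span of a planted run.
#' @param coverage_mean,coverage_dispersion Negative-binomial coverage model
#'   (mean and size).
#' @param bio_dispersion Beta-binomial overdispersion phi in `[0, 0.5)`;
#'   0 gives pure binomial counts.
#' @param seed RNG seed; identical seeds give bit-identical cohorts.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(samples,
                       n_sites = 20000L,
                       n_chroms = 2L,
                       frac_gain = 0.08,
                       frac_loss = 0.30,
                       frac_hostage = 0.01,
                       gain_rate = gain_rate_for_delta(0.4, 16, 0.05),
                       loss_rate = 0.015,
                       hostage_rate = 0.0037,
                       baseline_beta_gain = 0.05,
                       gain_run_length = 8L,
                       gain_run_span_bp = 400L,
                       coverage_mean = 20,
                       coverage_dispersion = 5,
                       bio_dispersion = 0.02,
                       seed = 1L) {
  samples <- as.data.frame(samples)
  required <- c("sample_id", "group", "divisions", "host_age")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("sample sheet lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(samples) == 0L) stop("at least one sample is required")
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique")
  if (any(samples$divisions < 0) || any(samples$host_age < 0)) {
    stop("divisions and host_age must be nonnegative")
  }
  fr <- c(frac_gain, frac_loss, frac_hostage)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("class fractions must lie in [0, 1] and sum to at most 1")
  }
  if (n_sites <= 0) stop("n_sites must be positive")
  if (gain_rate < 0 || loss_rate < 0 || hostage_rate < 0) {
    stop("drift rates must be nonnegative")
  }
  if (coverage_mean < 1) stop("coverage_mean must be >= 1")
  if (bio_dispersion < 0 || bio_dispersion >= 0.5) {
    stop("bio_dispersion must lie in [0, 0.5)")
  }
  if (gain_run_length < 1) stop("gain_run_length must be >= 1")
  cfg <- list(
    samples = samples, n_sites = as.integer(n_sites),
    n_chroms = as.integer(n_chroms),
    frac_gain = frac_gain, frac_loss = frac_loss, frac_hostage = frac_hostage,
    gain_rate = gain_rate, loss_rate = loss_rate, hostage_rate = hostage_rate,
    baseline_beta_gain = baseline_beta_gain,
    gain_run_length = as.integer(gain_run_length),
    gain_run_span_bp = as.integer(gain_run_span_bp),
    coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion,
    bio_dispersion = bio_dispersion, seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Sample-sheet builders for common designs
#'
#' Convenience constructors for the designs exercised throughout the
#' package: a two-group comparison (young vs multi-lifetime), a division
#' ladder, a crossed divisions-by-host-age design for decoupling analyses,
#' and a rest-period design in which arms undergo the same number of boost
#' cycles but accumulate different division counts per cycle.
#'
#' @param divisions_a,divisions_b Division counts of the two groups.
#' @param n_per_group,n_rep Replicates per group / per condition.
#' @param host_age Host chronological age in months.
#' @return A sample sheet `data.frame` with columns `sample_id`, `group`,
#'   `divisions`, `host_age`, `rest_days`, `replicate`.
#' @export
two_group_samples <- function(divisions_a = 0, divisions_b = 16,
                              n_per_group = 3, host_age = 3) {
  rbind(
    make_samples("young", divisions_a, host_age, n_per_group),
    make_samples("ml", divisions_b, host_age, n_per_group)
  )
}

#' @rdname two_group_samples
#' @param divisions Vector of division counts, one rung per value.
#' @export
ladder_samples <- function(divisions = c(0, 2, 4, 8, 16), n_rep = 3,
                           host_age = 3) {
  do.call(rbind, lapply(divisions, function(d) {
    make_samples(paste0("D", d), d, host_age, n_rep)
  }))
}

#' @rdname two_group_samples
#' @export
crossed_samples <- function(divisions = c(0, 16), host_age = c(3, 30),
                            n_rep = 3) {
  grid <- expand.grid(divisions = divisions, host_age = host_age)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    d <- grid$divisions[i]; a <- grid$host_age[i]
    make_samples(sprintf("D%g_A%g", d, a), d, a, n_rep)
  }))
}

#' @rdname two_group_samples
#' @param n_boosts Boost cycles undergone by every arm.
#' @param divisions_per_boost Named numeric: divisions accumulated per boost
#'   cycle for each rest length (names are rest days).  Longer rests allow
#'   fuller expansion, hence more divisions per cycle.
#' @export
rest_design_samples <- function(n_boosts = 5,
                                divisions_per_boost = c("30" = 7, "60" = 10),
                                n_rep = 3, host_age = 12) {
  do.call(rbind, lapply(names(divisions_per_boost), function(rd) {
    s <- make_samples(paste0("rest", rd),
                      n_boosts * divisions_per_boost[[rd]], host_age, n_rep)
    s$rest_days <- as.integer(rd)
    s
  }))
}

make_samples <- function(group, divisions, host_age, n_rep) {
  data.frame(
    sample_id = paste0(group, "_r", seq_len(n_rep)),
    group = group,
    divisions = divisions,
    host_age = host_age,
    rest_days = NA_integer_,
    replicate = seq_len(n_rep),
    stringsAsFactors = FALSE
  )
}

#' Simulate a WGBS-like cohort with planted drift loci
#'
#' Generates per-CpG (methylated, total) counts for every sample in the
#' configuration, together with the planted ground truth: per-site class
#' labels, the full expected-methylation surface `mu[site, sample]`, and the
#' coordinates of the planted gain runs.  Identical seeds give bit-identical
#' cohorts.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (a [cpg_counts()] object),
#'   `samples` (the sample sheet) and `truth` (class `sim_truth`: site
#'   classes, baselines, `mu` surface, planted `regions`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_sites
  run_len <- cfg$gain_run_length
  n_runs <- as.integer(floor(cfg$frac_gain * n / run_len))

  ## --- site layout -------------------------------------------------------
  per_chrom <- diff(floor(seq(0, n, length.out = cfg$n_chroms + 1)))
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  runs_per_chrom <- diff(floor(seq(0, n_runs, length.out = cfg$n_chroms + 1)))

  chrom_v <- rep(chroms, per_chrom)
  pos_v <- integer(n)
  class_v <- rep("stable", n)
  run_id <- integer(n)  # 0 = not in a run
  # spacing within a planted run keeps the run inside gain_run_span_bp
  run_gap <- max(1L, as.integer(floor(cfg$gain_run_span_bp / max(1L, run_len - 1L))))

  regions <- list()
  offset <- 0L
  run_counter <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    nc <- per_chrom[ci]
    idx <- offset + seq_len(nc)
    # background CpG spacing: 80-200 bp
    gaps <- sample(80:200, nc, replace = TRUE)
    nr <- runs_per_chrom[ci]
    if (nr > 0 && nc >= nr * (run_len + 4L)) {
      # one run per equal-width index segment, at a random offset inside it
      seg <- floor(seq(0, nc, length.out = nr + 1))
      for (ri in seq_len(nr)) {
        lo <- seg[ri] + 2L
        hi <- seg[ri + 1] - run_len - 2L
        if (hi < lo) next
        start_i <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        members <- start_i + seq_len(run_len) - 1L
        class_v[offset + members] <- "gain"
        run_counter <- run_counter + 1L
        run_id[offset + members] <- run_counter
        # tighten intra-run spacing (gap before members 2..len)
        gaps[members[-1]] <- run_gap
      }
    }
    pos_v[idx] <- 1000L + cumsum(gaps)
    offset <- offset + nc
  }

  ## --- remaining class assignment ---------------------------------------
  free <- which(class_v == "stable")
  n_loss <- min(length(free), round(cfg$frac_loss * n))
  loss_idx <- sample(free, n_loss)
  class_v[loss_idx] <- "loss"
  free <- setdiff(free, loss_idx)
  n_host <- min(length(free), round(cfg$frac_hostage * n))
  host_idx <- if (n_host > 0) sample(free, n_host) else integer(0)
  class_v[host_idx] <- "hostage"

  ## --- baselines ---------------------------------------------------------
  baseline <- numeric(n)
  baseline[class_v == "gain"] <- cfg$baseline_beta_gain
  baseline[class_v == "hostage"] <- cfg$baseline_beta_gain
  nl <- sum(class_v == "loss")
  baseline[class_v == "loss"] <- stats::rbeta(nl, 16, 4)
  ns <- sum(class_v == "stable")
  comp <- sample.int(3L, ns, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  bs <- numeric(ns)
  bs[comp == 1] <- stats::rbeta(sum(comp == 1), 16, 4)
  bs[comp == 2] <- stats::rbeta(sum(comp == 2), 2, 18)
  bs[comp == 3] <- stats::rbeta(sum(comp == 3), 4, 4)
  baseline[class_v == "stable"] <- bs

  ## --- expected methylation surface --------------------------------------
  smp <- cfg$samples
  n_s <- nrow(smp)
  mu <- matrix(baseline, nrow = n, ncol = n_s)
  gi <- class_v == "gain"; li <- class_v == "loss"; hi <- class_v == "hostage"
  for (j in seq_len(n_s)) {
    D <- smp$divisions[j]; A <- smp$host_age[j]
    mu[gi, j] <- mu_gain(baseline[gi], cfg$gain_rate, D)
    mu[li, j] <- mu_loss(baseline[li], cfg$loss_rate, D)
    mu[hi, j] <- mu_hostage(baseline[hi], cfg$hostage_rate, A)
  }
  dimnames(mu) <- list(site_id(chrom_v, pos_v), smp$sample_id)

  ## --- counts -------------------------------------------------------------
  total <- matrix(stats::rnbinom(n * n_s, mu = cfg$coverage_mean,
                                 size = cfg$coverage_dispersion),
                  nrow = n, ncol = n_s)
  mu_c <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  phi <- cfg$bio_dispersion
  if (phi > 0) {
    conc <- 1 / phi - 1
    p <- matrix(stats::rbeta(n * n_s, mu_c * conc, (1 - mu_c) * conc),
                nrow = n, ncol = n_s)
  } else {
    p <- mu_c
  }
  meth <- matrix(stats::rbinom(n * n_s, total, p), nrow = n, ncol = n_s)
  dimnames(total) <- dimnames(meth) <- dimnames(mu)

  sites <- data.frame(chrom = chrom_v, pos = pos_v,
                      id = site_id(chrom_v, pos_v), stringsAsFactors = FALSE)
  counts <- cpg_counts(sites, meth, total, samples = smp$sample_id)

  ## --- planted regions ----------------------------------------------------
  if (run_counter > 0) {
    reg <- do.call(rbind, lapply(seq_len(run_counter), function(r) {
      m <- which(run_id == r)
      data.frame(chrom = chrom_v[m[1]], start = pos_v[m[1]],
                 end = pos_v[m[length(m)]] + 1L, class = "gain",
                 stringsAsFactors = FALSE)
    }))
    reg <- reg[order(reg$chrom, reg$start, method = "radix"), , drop = FALSE]
    rownames(reg) <- NULL
  } else {
    reg <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), class = character(0))
  }

  truth <- structure(
    list(site_classes = stats::setNames(class_v, sites$id),
         baseline = stats::setNames(baseline, sites$id),
         mu = mu, regions = reg, config = cfg),
    class = "sim_truth"
  )
  list(counts = counts, samples = smp, truth = truth)
}

#' Write / read planted ground truth
#'
#' Planted regions are emitted as a 4-column BED file (0-based half-open,
#' sorted by chromosome then start) and per-site classes as a TSV with
#' columns `chrom`, `pos`, `class`.  [read_truth_regions()] round-trips the
#' BED losslessly.
#'
#' @param truth A `sim_truth` object from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bed <- file.path(dir, "planted_regions.bed")
  reg <- truth$regions
  reg <- reg[order(reg$chrom, reg$start, method = "radix"), , drop = FALSE]
  utils::write.table(reg[, c("chrom", "start", "end", "class")], bed,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  tsv <- file.path(dir, "site_classes.tsv")
  sc <- data.frame(
    chrom = sub(":.*$", "", names(truth$site_classes)),
    pos = as.integer(sub("^.*:", "", names(truth$site_classes))),
    class = unname(truth$site_classes), stringsAsFactors = FALSE
  )
  write_tsv_plain(sc, tsv)
  invisible(c(regions = bed, sites = tsv))
}

#' @rdname write_truth
#' @param path BED file written by [write_truth()].
#' @export
read_truth_regions <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), class = character(0)))
  }
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "class")[seq_len(ncol(df))]
  df
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Planted simulation truth\n")
  cat("  sites:", length(x$site_classes), "\n")
  tab <- table(x$site_classes)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  planted regions:", nrow(x$regions), "\n")
  invisible(x)
}
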