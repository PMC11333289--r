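#' Run the end-to-end experiential-age analysis
#'
#' Orchestrates the full analysis from a single configuration: simulate a
#' cohort (or read coverage files), apply the coverage filter, compute
#' global methylation and the variable-site PCA, test sites between the
#' two groups, segment DMRs, select the top-K signature, score every
#' sample, regress scores on divisions and on host age, optionally fit the
#' plateau model, and compare groups.  A single master seed drives
#' per-stage derived substreams ([stage_seed()]), so inserting a stage does
#' not reshuffle downstream randomness; identical config + seed gives an
#' identical report.
#'
#' @param config Named list or path to a YAML file (see
#'   [read_run_config()]).  Must contain exactly one of `simulate` (design
#'   block) or `inputs` (coverage paths + sample sheet), plus `groups`
#'   (`a`, `b`: group labels of the comparison).  Optional blocks `filter`,
#'   `pca`, `dmr`, `top`, `regress`, `plateau` override stage defaults.
#' @param outdir Optional output directory; when given, all intermediate
#'   artifacts are written (coverage files, sample sheet, truth BED/TSV,
#'   site statistics, DMR BED, signature BED + JSON sidecar, score and fit
#'   TSVs, report JSON).
#' @param verbose Log one line per stage.
#' @return A `run_report`: per-stage record counts and parameters, the
#'   signature score table, regression/plateau/group-comparison fits, seed
#'   and package version stamp.
#' @export
run_pipeline <- function(config, outdir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    stop("config must contain exactly one of 'simulate' or 'inputs'")
  }
  if (is.null(config$groups$a) || is.null(config$groups$b)) {
    stop("config$groups must name the two comparison groups (a, b)")
  }
  seed <- as.integer(config$seed %||% 1L)
  say <- function(...) if (verbose) message("[eaclock] ", ...)
  stages <- list()
  note <- function(name, ...) {
    stages[[name]] <<- list(...)
  }
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }

  ## --- input stage -------------------------------------------------------
  truth <- NULL
  if (has_sim) {
    sb <- config$simulate
    samples <- build_design(sb)
    sim_args <- sb[setdiff(names(sb), c("design", "divisions", "host_age",
                                        "n_per_group", "n_rep", "n_boosts",
                                        "divisions_per_boost"))]
    cfg <- do.call(sim_config, c(list(samples = samples), sim_args,
                                 list(seed = stage_seed(seed, "simulate"))))
    sim <- simulate_cohort(cfg)
    cm <- sim$counts; samples <- sim$samples; truth <- sim$truth
    say("simulate: ", nrow(cm$sites), " sites x ", length(cm$samples),
        " samples")
    note("simulate", n_sites = nrow(cm$sites), n_samples = length(cm$samples),
         n_planted = nrow(truth$regions))
    if (!is.null(outdir)) {
      write_coverage(cm, file.path(outdir, "coverage"))
      write_truth(truth, file.path(outdir, "truth"))
      write_tsv_plain(samples, file.path(outdir, "samples.tsv"))
    }
  } else {
    inp <- config$inputs
    samples <- read_tsv_plain(inp$samples_tsv)
    cm <- read_coverage(inp$coverage, inp$sample_ids %||% samples$sample_id)
    missing_s <- setdiff(samples$sample_id, cm$samples)
    if (length(missing_s)) {
      stop("sample sheet names samples without coverage files: ",
           paste(missing_s, collapse = ", "))
    }
    say("read: ", nrow(cm$sites), " sites x ", length(cm$samples), " samples")
    note("read", n_sites = nrow(cm$sites), n_samples = length(cm$samples))
  }

  ## --- filter ------------------------------------------------------------
  min_cov <- config$filter$min_cov %||% 5L
  cm_f <- filter_coverage(cm, min_cov)
  say("filter (> ", min_cov, " reads in all samples): ", nrow(cm_f$sites),
      " sites kept")
  note("filter", min_cov = min_cov, n_sites = nrow(cm_f$sites))
  bm <- compute_beta(cm_f)

  ## --- global methylation / PCA -----------------------------------------
  glob <- global_methylation(bm)
  note("global_methylation", n_samples = nrow(glob))
  pca <- NULL
  if (!isFALSE(config$pca)) {
    pca <- variable_site_pca(bm, n_top = config$pca$n_top %||% 3000L,
                             n_components = config$pca$n_components %||% 2L)
    note("pca", n_top = length(pca$sites),
         var_explained = pca$var_explained)
  }

  ## --- differential methylation -----------------------------------------
  ga <- samples$sample_id[samples$group %in% config$groups$a]
  gb <- samples$sample_id[samples$group %in% config$groups$b]
  if (length(ga) < 2 || length(gb) < 2) {
    stop("comparison groups must each contain at least 2 samples")
  }
  stats <- test_sites(cm_f, ga, gb)
  note("test", n_sites = nrow(stats), group_a = config$groups$a,
       group_b = config$groups$b)

  dp <- config$dmr %||% list()
  dmrs <- call_dmrs(stats, p_thresh = dp$p_thresh %||% 0.01,
                    max_gap_bp = dp$max_gap_bp %||% 300L,
                    min_cpg = dp$min_cpg %||% 3L,
                    merge_dist_bp = dp$merge_dist_bp %||% 100L)
  say("dmrs: ", nrow(dmrs), " regions")
  note("call_dmrs", n_dmrs = nrow(dmrs), params = attr(dmrs, "params"))

  tp <- config$top %||% list()
  sig <- select_top(dmrs, k = tp$k %||% 150L,
                    direction = tp$direction %||% "gain",
                    label = tp$label %||% "ea_signature")
  note("select_top", k = sig$k, direction = sig$direction,
       n_selected = nrow(sig$dmrs))

  ## --- scoring and clock fits -------------------------------------------
  if (nrow(sig$dmrs) == 0) stop("stage select_top produced no regions")
  sc <- score_regions(cm_f, sig)
  score_tab <- data.frame(sample_id = names(sc$sample_score),
                          score = unname(sc$sample_score),
                          stringsAsFactors = FALSE)
  score_tab <- merge(score_tab, samples, by = "sample_id", sort = FALSE)
  score_tab <- score_tab[match(samples$sample_id, score_tab$sample_id), ]
  rownames(score_tab) <- NULL
  note("score", n_regions = nrow(sig$dmrs), n_samples = nrow(score_tab))

  fits <- list()
  if (stats::var(score_tab$divisions) > 0) {
    fits$divisions <- fit_age_regression(score_tab$score,
                                         score_tab$divisions)
  }
  if (stats::var(score_tab$host_age) > 0) {
    fits$host_age <- fit_age_regression(score_tab$score, score_tab$host_age)
  }
  note("regress", fitted = names(fits))

  plateau <- NULL
  if (isTRUE(config$plateau) &&
      length(unique(score_tab$divisions)) >= 3) {
    plateau <- fit_plateau(score_tab$score, score_tab$divisions)
    note("plateau", converged = plateau$converged,
         delta_aic = plateau$delta_aic)
  }

  cmp <- compare_groups(score_tab$score[score_tab$group %in%
                                          c(config$groups$a, config$groups$b)],
                        score_tab$group[score_tab$group %in%
                                          c(config$groups$a, config$groups$b)])
  note("compare_groups", n_pairs = nrow(cmp))

  report <- structure(list(
    seed = seed,
    version = as.character(utils::packageVersion("eaclock")),
    stages = stages,
    global_methylation = glob,
    pca_scores = if (!is.null(pca)) pca$scores else NULL,
    scores = score_tab,
    regressions = lapply(fits, function(f) {
      list(slope = f$slope, intercept = f$intercept, pearson_r = f$pearson_r,
           n = f$n)
    }),
    plateau = if (!is.null(plateau)) {
      plateau[c("a", "b", "c", "delta_aic", "saturation_age", "converged")]
    } else NULL,
    group_comparison = cmp,
    signature = sig
  ), class = "run_report")

  if (!is.null(outdir)) {
    write_tsv_plain(stats, file.path(outdir, "site_stats.tsv"))
    write_dmr_bed(dmrs, file.path(outdir, "dmrs.bed"))
    write_signature(sig, outdir)
    write_tsv_plain(score_tab, file.path(outdir, "scores.tsv"))
    write_tsv_plain(glob, file.path(outdir, "global_methylation.tsv"))
    write_report(report, file.path(outdir, "report.json"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("eaclock run report (seed ", x$seed, ", version ", x$version, ")\n",
      sep = "")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    flat <- vapply(st, function(v) paste(format(unlist(v), digits = 4),
                                         collapse = ","), character(1))
    cat("  ", nm, ": ", paste(names(flat), flat, sep = "=",
                              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a run report as JSON
#'
#' Deterministic (no timestamps): identical runs give byte-identical files.
#'
#' @param report A `run_report`.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  out <- report
  out$signature <- list(label = out$signature$label, k = out$signature$k,
                        direction = out$signature$direction,
                        n_dmrs = nrow(out$signature$dmrs))
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring the `config` list of [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

# Sample-sheet construction from a config 'simulate' block.
build_design <- function(sb) {
  design <- sb$design %||% "two_group"
  switch(
    design,
    two_group = two_group_samples(
      divisions_a = (sb$divisions %||% c(0, 16))[1],
      divisions_b = (sb$divisions %||% c(0, 16))[2],
      n_per_group = sb$n_per_group %||% 3,
      host_age = sb$host_age %||% 3),
    ladder = ladder_samples(divisions = sb$divisions %||% c(0, 2, 4, 8, 16),
                            n_rep = sb$n_rep %||% 3,
                            host_age = sb$host_age %||% 3),
    crossed = crossed_samples(divisions = sb$divisions %||% c(0, 16),
                              host_age = sb$host_age %||% c(3, 30),
                              n_rep = sb$n_rep %||% 3),
    rest = rest_design_samples(
      n_boosts = sb$n_boosts %||% 5,
      divisions_per_boost = unlist(sb$divisions_per_boost %||%
                                     c("30" = 7, "60" = 10)),
      n_rep = sb$n_rep %||% 3),
    stop("unknown design: ", design)
  )
}
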