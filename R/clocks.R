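#' Epigenetic clock models
#'
#' Two kinds of clock are supported.  A **weighted** clock is a linear age
#' estimator, `score = intercept + sum_i w_i * beta_i`, the form of
#' published penalized-regression clocks; such scores are age estimates and
#' may legitimately be negative.  A **mean** clock is the unweighted mean
#' beta over a site panel, the form used for mean-of-sites mouse panels and
#' for DMR-signature scores.
#'
#' @param kind `"weighted"` or `"mean"`.
#' @param sites CpG site ids (`"chrom:pos"` or array probe ids -- any ids
#'   resolvable against the beta-matrix rownames).
#' @param weights One weight per site (weighted kind only).
#' @param intercept Model intercept (weighted kind only).
#' @param reference Optional named per-site reference mean betas used to
#'   impute missing sites.
#' @param name Clock name.
#' @return A `clock_model` object.
#' @export
clock_model <- function(kind = c("weighted", "mean"), sites, weights = NULL,
                        intercept = NULL, reference = NULL, name = "clock") {
  kind <- match.arg(kind)
  sites <- as.character(sites)
  if (anyDuplicated(sites)) stop("clock sites must be unique")
  if (kind == "weighted") {
    if (is.null(weights) || length(weights) != length(sites)) {
      stop("weighted clock needs one weight per site")
    }
    if (is.null(intercept)) stop("weighted clock needs an intercept")
  } else {
    if (!is.null(weights) || !is.null(intercept)) {
      stop("mean clock takes no weights or intercept")
    }
  }
  if (!is.null(reference)) {
    stopifnot(!is.null(names(reference)))
    reference <- reference[names(reference) %in% sites]
  }
  structure(list(kind = kind, sites = sites, weights = weights,
                 intercept = intercept, reference = reference, name = name),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("Clock model '", x$name, "' (", x$kind, "), ", length(x$sites),
      " sites", sep = "")
  if (x$kind == "weighted") cat(", intercept ", format(x$intercept), sep = "")
  cat("\n")
  invisible(x)
}

#' Read / write clock weight tables
#'
#' TSV with header `site_id<TAB>weight` and the intercept on a
#' `#intercept=<value>` comment line; a file without weights column or
#' intercept line is read as a mean-of-sites clock.
#'
#' @param path Weight table file.
#' @param name Clock name (defaults to the file basename).
#' @return A [clock_model()].
#' @export
read_clock_tsv <- function(path, name = NULL) {
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  int_line <- grep("^#intercept=", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (length(int_line) && "weight" %in% names(df)) {
    clock_model("weighted", df$site_id, weights = df$weight,
                intercept = as.numeric(sub("^#intercept=", "", int_line[1])),
                name = name)
  } else {
    clock_model("mean", df$site_id, name = name)
  }
}

#' @rdname read_clock_tsv
#' @param model A [clock_model()].
#' @export
write_clock_tsv <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  con <- file(path, "w")
  on.exit(close(con))
  if (model$kind == "weighted") {
    writeLines(sprintf("#intercept=%.17g", model$intercept), con)
    writeLines("site_id\tweight", con)
    writeLines(sprintf("%s\t%.17g", model$sites, model$weights), con)
  } else {
    writeLines("site_id", con)
    writeLines(model$sites, con)
  }
  invisible(path)
}

#' Apply a clock to a beta matrix
#'
#' Resolves the model's sites against the matrix rownames and computes one
#' score per sample.  Missing values (sites absent from the matrix, or
#' uncovered in a sample) are handled per `missing_policy`: `"impute"`
#' substitutes the model's reference mean (or the cohort mean of the site
#' when no reference is shipped), `"drop"` silently drops missing sites
#' sample-wise, `"error"` refuses.  Under `"impute"`/`"error"` the missing
#' fraction must not exceed `max_missing_frac`.
#'
#' @param bm Beta matrix from [compute_beta()].
#' @param model A [clock_model()].
#' @param missing_policy `"impute"`, `"drop"` or `"error"`.
#' @param max_missing_frac Maximal tolerated missing site fraction.
#' @return `data.frame`: `sample_id`, `score`, `clock`, `n_sites_used`,
#'   `n_sites_imputed`.
#' @export
apply_clock <- function(bm, model,
                        missing_policy = c("impute", "drop", "error"),
                        max_missing_frac = 0.2) {
  stopifnot(inherits(model, "clock_model"))
  missing_policy <- match.arg(missing_policy)
  ix <- match(model$sites, rownames(bm))
  b <- matrix(NA_real_, length(model$sites), ncol(bm),
              dimnames = list(model$sites, colnames(bm)))
  b[!is.na(ix), ] <- bm[ix[!is.na(ix)], , drop = FALSE]

  miss_frac <- colMeans(is.na(b))
  if (missing_policy == "error" && any(miss_frac > 0)) {
    stop("missing clock sites: ",
         sum(is.na(ix)), " absent from matrix; per-sample missing fraction up to ",
         format(max(miss_frac), digits = 3))
  }
  if (missing_policy == "impute" && any(miss_frac > max_missing_frac)) {
    stop("missing site fraction ", format(max(miss_frac), digits = 3),
         " exceeds max_missing_frac = ", max_missing_frac)
  }

  n_imputed <- integer(ncol(b))
  if (missing_policy == "impute" && anyNA(b)) {
    fill <- rowMeans(b, na.rm = TRUE)                     # cohort means
    if (!is.null(model$reference)) {
      ref <- model$reference[rownames(b)]
      fill[!is.na(ref)] <- ref[!is.na(ref)]
    }
    for (j in seq_len(ncol(b))) {
      na_j <- is.na(b[, j])
      usable <- na_j & !is.na(fill)
      b[usable, j] <- fill[usable]
      n_imputed[j] <- sum(usable)
    }
  }

  if (model$kind == "weighted") {
    w <- model$weights
    score <- vapply(seq_len(ncol(b)), function(j) {
      use <- !is.na(b[, j])
      model$intercept + sum(w[use] * b[use, j])
    }, numeric(1))
  } else {
    score <- vapply(seq_len(ncol(b)), function(j) {
      use <- !is.na(b[, j])
      if (!any(use)) NA_real_ else mean(b[use, j])
    }, numeric(1))
  }
  data.frame(
    sample_id = colnames(bm), score = score, clock = model$name,
    n_sites_used = colSums(!is.na(b)), n_sites_imputed = n_imputed,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Ordinary least squares of clock score on age
#'
#' Fits `score ~ age`, reports the Pearson correlation and the standard
#' error of the fitted mean at each observation (for a
#' `mean +/- 1.96 * SE` band).
#'
#' @param scores Numeric scores, or a `data.frame` from [apply_clock()]
#'   (its `score` column is used, matched to `ages` by `sample_id` when
#'   `ages` is named).
#' @param ages Numeric ages (any unit: months, lifetimes, divisions).
#' @return List of class `age_regression`: `slope`, `intercept`,
#'   `pearson_r`, `n`, `se_fit` (per observation), `fitted`, `fit` (the
#'   `lm` object).
#' @export
fit_age_regression <- function(scores, ages) {
  if (is.data.frame(scores)) {
    if (!is.null(names(ages))) ages <- ages[scores$sample_id]
    scores <- scores$score
  }
  ok <- !is.na(scores) & !is.na(ages)
  scores <- scores[ok]; ages <- as.numeric(ages[ok])
  if (length(scores) < 3) stop("need at least 3 paired observations")
  if (stats::var(ages) == 0) stop("zero age variance: slope undefined")
  fit <- stats::lm(scores ~ ages)
  pr <- stats::predict(fit, se.fit = TRUE)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    pearson_r = stats::cor(ages, scores),
    n = length(scores),
    se_fit = unname(pr$se.fit),
    fitted = unname(pr$fit),
    fit = fit
  ), class = "age_regression")
}

#' @export
print.age_regression <- function(x, ...) {
  cat(sprintf("score ~ age: slope %.4g, intercept %.4g, Pearson r %.3f (n = %d)\n",
              x$slope, x$intercept, x$pearson_r, x$n))
  invisible(x)
}

#' Pairwise two-sided t-tests of clock scores between groups
#'
#' Welch's unequal-variance t-test by default; `pooled = TRUE` gives the
#' classic equal-variance Student variant.
#'
#' @param scores Numeric scores or [apply_clock()] output.
#' @param groups Group labels, parallel to the scores.
#' @param pooled Use the pooled-variance test instead of Welch.
#' @return `data.frame` with one row per group pair: `group_a`, `group_b`,
#'   `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @export
compare_groups <- function(scores, groups, pooled = FALSE) {
  if (is.data.frame(scores)) scores <- scores$score
  groups <- as.character(groups)
  stopifnot(length(scores) == length(groups))
  lev <- unique(groups)
  tab <- table(groups)
  if (any(tab < 2)) stop("each group needs at least 2 observations")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    xa <- scores[groups == pr[1]]; xb <- scores[groups == pr[2]]
    tt <- stats::t.test(xa, xb, var.equal = pooled)
    data.frame(group_a = pr[1], group_b = pr[2],
               mean_a = mean(xa), mean_b = mean(xb),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
}

#' Saturation (plateau) diagnostics of a clock
#'
#' Fits the bounded drift model `score = a + b * (1 - exp(-c * age))`
#' (nonlinear least squares, `c >= 0`, Levenberg-Marquardt from five fixed
#' starting rates) alongside a linear model, and compares them by AIC.
#' `delta_aic < 0` favors the saturating model; `saturation_age`
#' (`-log(0.05) / c`) is the age at which 95% of the asymptotic change is
#' reached -- a clock trained on a short age range plateaus near there and
#' stops counting.
#'
#' @param scores Numeric scores or [apply_clock()] output.
#' @param ages Ages, parallel to scores.
#' @return List of class `plateau_fit`: `a`, `b`, `c`, `linear`
#'   (slope/intercept), `delta_aic` (saturating minus linear),
#'   `saturation_age`, `converged`.
#' @export
fit_plateau <- function(scores, ages) {
  if (is.data.frame(scores)) scores <- scores$score
  ok <- !is.na(scores) & !is.na(ages)
  scores <- scores[ok]; ages <- as.numeric(ages[ok])
  if (length(scores) < 5) stop("need at least 5 observations")
  rng <- diff(range(ages))
  if (rng == 0) stop("degenerate age range")
  n <- length(scores)

  lin <- stats::lm(scores ~ ages)
  rss_lin <- sum(stats::resid(lin)^2)
  aic <- function(rss, k) n * log(max(rss, 1e-300) / n) + 2 * k
  aic_lin <- aic(rss_lin, 2L)

  starts <- c(5, 2, 1, 0.5, 0.1) / rng
  best <- NULL
  for (c0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        scores ~ a + b * (1 - exp(-cc * ages)),
        start = list(a = min(scores), b = diff(range(scores)), cc = c0),
        lower = c(a = -Inf, b = -Inf, cc = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }

  if (is.null(best)) {
    return(structure(list(
      a = NA_real_, b = NA_real_, c = NA_real_,
      linear = list(slope = unname(stats::coef(lin)[2]),
                    intercept = unname(stats::coef(lin)[1])),
      delta_aic = NA_real_, saturation_age = NA_real_, converged = FALSE
    ), class = "plateau_fit"))
  }

  cf <- stats::coef(best$fit)
  cc <- unname(cf["cc"])
  structure(list(
    a = unname(cf["a"]), b = unname(cf["b"]), c = cc,
    linear = list(slope = unname(stats::coef(lin)[2]),
                  intercept = unname(stats::coef(lin)[1])),
    delta_aic = aic(best$rss, 3L) - aic_lin,
    saturation_age = if (cc > 0) -log(0.05) / cc else Inf,
    converged = TRUE
  ), class = "plateau_fit")
}

#' @export
print.plateau_fit <- function(x, ...) {
  if (!x$converged) {
    cat("plateau fit: saturating model did not converge; linear slope",
        format(x$linear$slope, digits = 4), "\n")
    return(invisible(x))
  }
  cat(sprintf("score = %.4g + %.4g (1 - exp(-%.4g age)); dAIC (sat - lin) = %.2f\n",
              x$a, x$b, x$c, x$delta_aic))
  cat(sprintf("  95%% saturation at age %.3g\n", x$saturation_age))
  invisible(x)
}
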