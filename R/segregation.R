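# Mendelian segregation model tests: Pearson chi-squared goodness-of-fit
# against named genetic ratios, Bartlett's variance-homogeneity test from
# summary statistics, and the B-locus genotype-conditioned analysis.

#' B-locus genotype levels
#'
#' The three codominant genotypes at the cannabinoid synthase locus complex,
#' ordered by expected F_dicyclic (homozygote THCAS lowest).
#'
#' @return Character vector of genotype labels.
#' @export
b_genotype_levels <- function() {
  c("THCAS/THCAS", "THCAS/CBDAS", "CBDAS/CBDAS")
}

.new_ratio <- function(name, terms, n_loci, gene_effect) {
  stopifnot(length(terms) >= 1, all(terms > 0))
  structure(list(name = name, terms = as.integer(terms),
                 n_loci = as.integer(n_loci), gene_effect = gene_effect),
            class = "segregation_ratio")
}

#' Registry of genetic segregation ratios
#'
#' The named F2 segregation models testable by goodness-of-fit:
#' monogenic codominant 1:2:1, digenic additive 1:4:6:4:1, digenic
#' dominant 9:3:3:1, and the dominant + partially dominant epistatic 7:6:3.
#'
#' @return Named list of `segregation_ratio` objects with fields `name`,
#'   `terms`, `n_loci` and `gene_effect`.
#' @export
#' @examples
#' names(segregation_ratios())
segregation_ratios <- function() {
  list(
    monogenic_codominant = .new_ratio("monogenic codominant", c(1, 2, 1),
                                      1, "codominant"),
    digenic_additive = .new_ratio("digenic additive", c(1, 4, 6, 4, 1),
                                  2, "additive"),
    digenic_dominant = .new_ratio("digenic dominant", c(9, 3, 3, 1),
                                  2, "dominant"),
    epistatic_7_6_3 = .new_ratio("epistatic 7:6:3", c(7, 6, 3), 2,
                                 "dominant, partially dominant")
  )
}

#' @export
print.segregation_ratio <- function(x, ...) {
  cat(sprintf("%s (%d loci, %s): %s\n", x$name, x$n_loci, x$gene_effect,
              paste(x$terms, collapse = ":")))
  invisible(x)
}

#' Upper-tail chi-squared critical value
#'
#' @param df Degrees of freedom, `>= 1`.
#' @param alpha Significance level in `(0, 1]`.
#' @return The upper-tail quantile `q` such that `P(X > q) = alpha`.
#' @export
#' @examples
#' chi_square_critical(3, 0.05)  # 7.815
#' chi_square_critical(2, 0.05)  # 5.991
chi_square_critical <- function(df, alpha) {
  if (!is.numeric(df) || any(df < 1)) stop("df must be >= 1", call. = FALSE)
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha > 1)) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  stats::qchisq(alpha, df = df, lower.tail = FALSE)
}

#' Pearson chi-squared goodness-of-fit to a segregation ratio
#'
#' Tests observed category counts against expected counts proportional to
#' the ratio terms. The statistic is `sum((O - E)^2 / E)` with no
#' continuity correction and `df = k - 1`. Expected counts below 5 are
#' permitted (with a warning noting the classical guideline), matching
#' standard practice for F2 ratio tests with small tail classes.
#'
#' @param observed Integer vector of category counts, ordered by increasing
#'   fraction value, with `sum(observed) > 0`.
#' @param ratio A `segregation_ratio` object or a numeric vector of positive
#'   ratio terms, same length as `observed`.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `gof_result`: list with `observed`,
#'   `expected`, `ratio_name`, `terms`, `chi2`, `df`, `alpha`,
#'   `critical_value`, `p_value` and `h0_accepted`
#'   (`chi2 <= critical_value`).
#' @export
#' @examples
#' chi_square_gof(c(26, 6, 7, 5), segregation_ratios()$digenic_dominant)
chi_square_gof <- function(observed, ratio, alpha = 0.05) {
  if (inherits(ratio, "segregation_ratio")) {
    terms <- ratio$terms
    rname <- ratio$name
  } else {
    terms <- as.numeric(ratio)
    rname <- paste(terms, collapse = ":")
  }
  if (any(terms <= 0)) stop("ratio terms must be positive", call. = FALSE)
  observed <- as.numeric(observed)
  if (length(observed) != length(terms)) {
    stop(sprintf(
      "observed has %d categories but ratio %s has %d terms",
      length(observed), paste(terms, collapse = ":"), length(terms)),
      call. = FALSE)
  }
  if (any(observed < 0) || sum(observed) <= 0) {
    stop("observed counts must be >= 0 and sum > 0", call. = FALSE)
  }
  n <- sum(observed)
  expected <- n * terms / sum(terms)
  if (any(expected < 5)) {
    warning("some expected counts are below 5; the chi-squared ",
            "approximation may be inaccurate", call. = FALSE)
  }
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  crit <- chi_square_critical(df, alpha)
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  structure(list(observed = observed, expected = expected,
                 ratio_name = rname, terms = terms,
                 chi2 = chi2, df = df, alpha = alpha,
                 critical_value = crit, p_value = p,
                 h0_accepted = chi2 <= crit),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("Goodness-of-fit vs %s (%s)\n", x$ratio_name,
              paste(x$terms, collapse = ":")))
  cat(sprintf("  observed: %s\n", paste(x$observed, collapse = ", ")))
  cat(sprintf("  expected: %s\n",
              paste(sprintf("%.2f", x$expected), collapse = ", ")))
  cat(sprintf("  chi2 = %.2f on %d df (critical %.2f at alpha %.2g): H0 %s\n",
              x$chi2, x$df, x$critical_value, x$alpha,
              if (x$h0_accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Bartlett's test of variance homogeneity from summary statistics
#'
#' Computes Bartlett's chi-squared statistic from per-group sample variances
#' and degrees of freedom (n - 1), as used when only summary tables are
#' available. With pooled variance `s_p^2 = sum(df_i s_i^2) / sum(df_i)`,
#' the statistic is
#' `[sum(df_i) log(s_p^2) - sum(df_i log(s_i^2))] / C` with
#' `C = 1 + (sum(1/df_i) - 1/sum(df_i)) / (3 (k - 1))`, on `k - 1` df.
#'
#' @param variances Numeric vector of group sample variances, `>= 0`.
#' @param dfs Integer vector of within-group degrees of freedom, `>= 1`.
#' @return List with `chi2`, `df` and `p_value`.
#' @export
#' @examples
#' bartlett_from_summaries(c(160.4, 185.2, 138.0), c(33, 15, 26))
bartlett_from_summaries <- function(variances, dfs) {
  variances <- as.numeric(variances)
  dfs <- as.numeric(dfs)
  k <- length(variances)
  if (k < 2 || length(dfs) != k) {
    stop("need >= 2 groups with matching variance and df vectors",
         call. = FALSE)
  }
  if (any(dfs < 1)) stop("each group df must be >= 1", call. = FALSE)
  if (any(variances < 0)) stop("variances must be >= 0", call. = FALSE)
  if (any(variances == 0)) {
    if (all(variances == 0)) {
      return(list(chi2 = 0, df = k - 1, p_value = 1))
    }
    stop("zero variance in one group with non-zero in another: ",
         "log-variance undefined", call. = FALSE)
  }
  N <- sum(dfs)
  sp2 <- sum(dfs * variances) / N
  num <- N * log(sp2) - sum(dfs * log(variances))
  C <- 1 + (sum(1 / dfs) - 1 / N) / (3 * (k - 1))
  chi2 <- num / C
  df <- k - 1
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Test B-locus genotype counts against the monogenic codominant 1:2:1 ratio
#'
#' @param genotype_counts Counts ordered
#'   `[CBDAS/CBDAS, THCAS/CBDAS, THCAS/THCAS]`.
#' @param alpha Significance level (default 0.05).
#' @return A `gof_result` (see [chi_square_gof()]).
#' @export
#' @examples
#' b_locus_monogenic_test(c(44, 116, 50))  # chi2 = 2.65, accepted
b_locus_monogenic_test <- function(genotype_counts, alpha = 0.05) {
  if (length(genotype_counts) != 3) {
    stop("expected three genotype counts ",
         "[CBDAS/CBDAS, THCAS/CBDAS, THCAS/THCAS]", call. = FALSE)
  }
  chi_square_gof(genotype_counts, segregation_ratios()$monogenic_codominant,
                 alpha)
}

#' Run a plan of segregation models on per-group category counts
#'
#' @param counts_by_group Named list of observed category-count vectors.
#' @param plan Named list (same names) of lists of ratios (see
#'   [segregation_ratios()]) to test on each group.
#' @param alpha Significance level (default 0.05).
#' @return Named list per group, each a list of `gof_result` objects (or a
#'   character condition message where the model shape does not match the
#'   observed number of categories).
#' @export
run_model_plan <- function(counts_by_group, plan, alpha = 0.05) {
  stopifnot(is.list(counts_by_group), is.list(plan))
  out <- lapply(names(plan), function(g) {
    counts <- counts_by_group[[g]]
    if (is.null(counts)) return(list())
    ratios <- plan[[g]]
    if (inherits(ratios, "segregation_ratio")) ratios <- list(ratios)
    lapply(ratios, function(r) {
      tryCatch(suppressWarnings(chi_square_gof(counts, r, alpha)),
               error = function(e) conditionMessage(e))
    })
  })
  stats::setNames(out, names(plan))
}

#' Genotype-conditioned segregation analysis
#'
#' Splits F_C3 values by B-locus genotype, re-derives chemotype categories
#' within each genotype subset (or reuses global category boundaries), and
#' tests each subset's category counts against the segregation models listed
#' for that genotype. Plants without a genotype call are excluded (their
#' number is reported); genotype classes with fewer than `min_n` plants are
#' skipped with a warning because expected counts would be too small.
#'
#' @param values Numeric vector of per-plant F_C3 values (percent).
#' @param genotypes Character vector aligned with `values`; levels from
#'   [b_genotype_levels()], `NA` for unscored plants.
#' @param model_plan Named list mapping genotype level to a list of ratios
#'   to test (see [segregation_ratios()]).
#' @param mode `"per-subset"` (default) re-runs KDE demarcation within each
#'   genotype; `"global"` tabulates the subset against `categories`.
#' @param categories Required when `mode = "global"`: a
#'   `chemotype_categories` object from the full population.
#' @param alpha Significance level (default 0.05).
#' @param min_support,valley_depth_frac Passed to [demarcate()].
#' @param min_n Minimum genotype-class size for testing (default 8).
#' @return Object of class `conditioned_segregation`: per-genotype list with
#'   `n`, `counts`, `categories` (per-subset mode) and `fits`; attribute
#'   `n_unscored` counts excluded plants.
#' @export
genotype_conditioned_segregation <- function(values, genotypes, model_plan,
                                             mode = c("per-subset", "global"),
                                             categories = NULL, alpha = 0.05,
                                             min_support = 2,
                                             valley_depth_frac = 0.05,
                                             min_n = 8) {
  mode <- match.arg(mode)
  stopifnot(length(values) == length(genotypes))
  if (mode == "global" && !inherits(categories, "chemotype_categories")) {
    stop("global mode requires `categories` from the full population",
         call. = FALSE)
  }
  unscored <- sum(is.na(genotypes))
  results <- lapply(names(model_plan), function(gl) {
    sel <- which(!is.na(genotypes) & genotypes == gl)
    if (length(sel) < min_n) {
      warning(sprintf(
        "genotype %s has n = %d < %d: tests skipped (expected counts too small)",
        gl, length(sel), min_n), call. = FALSE)
      return(list(n = length(sel), skipped = TRUE))
    }
    v <- values[sel]
    if (mode == "per-subset") {
      cats <- tryCatch({
        kde <- estimate_density(v, sj_bandwidth(v))
        demarcate(kde, min_support = min_support,
                  valley_depth_frac = valley_depth_frac)
      }, error = function(e) NULL)
      if (is.null(cats)) {
        counts <- stats::setNames(length(v), "I")
        cats_out <- NULL
      } else {
        counts <- cats$counts
        cats_out <- cats
      }
    } else {
      lab <- assign_categories(v, categories)
      counts <- stats::setNames(
        tabulate(match(lab, categories$labels),
                 nbins = length(categories$labels)),
        categories$labels)
      cats_out <- categories
    }
    ratios <- model_plan[[gl]]
    if (inherits(ratios, "segregation_ratio")) ratios <- list(ratios)
    fits <- lapply(ratios, function(r) {
      tryCatch(suppressWarnings(chi_square_gof(as.numeric(counts), r, alpha)),
               error = function(e) conditionMessage(e))
    })
    list(n = length(sel), counts = counts, categories = cats_out,
         fits = fits, skipped = FALSE)
  })
  structure(stats::setNames(results, names(model_plan)),
            class = "conditioned_segregation", n_unscored = unscored)
}

#' @export
print.conditioned_segregation <- function(x, ...) {
  cat("Genotype-conditioned segregation analysis\n")
  if (attr(x, "n_unscored") > 0) {
    cat(sprintf("  (%d plants without genotype call excluded)\n",
                attr(x, "n_unscored")))
  }
  for (gl in names(x)) {
    r <- x[[gl]]
    if (isTRUE(r$skipped)) {
      cat(sprintf("  %s: n = %d, skipped\n", gl, r$n))
      next
    }
    cat(sprintf("  %s: n = %d, counts [%s]\n", gl, r$n,
                paste(r$counts, collapse = ", ")))
    for (f in r$fits) {
      if (is.character(f)) {
        cat(sprintf("    not testable: %s\n", f))
      } else {
        cat(sprintf("    %s: chi2 = %.2f, df = %d, H0 %s\n", f$ratio_name,
                    f$chi2, f$df,
                    if (f$h0_accepted) "accepted" else "rejected"))
      }
    }
  }
  invisible(x)
}
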