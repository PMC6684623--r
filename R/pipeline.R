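# End-to-end pipeline: plant-table I/O, fractions -> KDE demarcation (F_C3
# and F_dicyclic axes) -> B-locus 1:2:1 test -> genotype-conditioned
# segregation, with a structured report.

#' Read a plant table from delimited text
#'
#' Accepts comma- or tab-separated text with a header. Required columns:
#' `plant_id`, `generation`; recognised optional columns: `replicate`,
#' `b_genotype` (values among [b_genotype_levels()]), `sex`, `family`, and
#' analyte columns named by canonical abbreviation. Unknown columns are
#' preserved. Malformed numeric cells (including comma decimal separators)
#' are rejected with their row numbers.
#'
#' @param path Path to the file.
#' @return Data frame of plant records.
#' @export
read_plant_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tbl <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  req <- c("plant_id", "generation")
  missing_cols <- setdiff(req, names(tbl))
  if (length(missing_cols)) {
    stop("plant table missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- intersect(c(.analyte_names(), "replicate",
                          "CBN", "CBG", "CBGA", "CBC"), names(tbl))
  for (cc in num_cols) {
    raw <- tbl[[cc]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & nzchar(trimws(raw)))
    if (length(bad)) {
      stop(sprintf("column `%s` has malformed numeric cells at row(s) %s",
                   cc, paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
    }
    tbl[[cc]] <- val
  }
  if (!"replicate" %in% names(tbl)) tbl$replicate <- 1L
  key <- paste(tbl$plant_id, tbl$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate plant_id + replicate records in ", path, call. = FALSE)
  }
  if ("b_genotype" %in% names(tbl)) {
    bg <- tbl$b_genotype
    known <- bg %in% c(b_genotype_levels(), "", NA)
    if (any(!known)) {
      stop("unrecognised b_genotype value(s): ",
           paste(unique(bg[!known]), collapse = ", "), call. = FALSE)
    }
    tbl$b_genotype[!nzchar(bg)] <- NA
  }
  tbl
}

#' Write a plant table as tab-separated text
#'
#' @param tbl Data frame of plant records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plant_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default genotype-conditioned model plan
#'
#' The plan tested in the study: digenic dominant 9:3:3:1 within each
#' synthase homozygote/heterozygote class except the THCAS homozygotes,
#' where the tripartite distribution is tested against the epistatic 7:6:3.
#'
#' @return Named list mapping genotype level to a list of
#'   `segregation_ratio` objects.
#' @export
default_model_plan <- function() {
  r <- segregation_ratios()
  list("CBDAS/CBDAS" = list(r$digenic_dominant),
       "THCAS/CBDAS" = list(r$digenic_dominant),
       "THCAS/THCAS" = list(r$epistatic_7_6_3))
}

.gen_summary <- function(fr_tbl) {
  gens <- unique(fr_tbl$generation)
  do.call(rbind, lapply(gens, function(g) {
    s <- fr_tbl[fr_tbl$generation == g, ]
    data.frame(generation = g, n = nrow(s),
               F_C3_min = min(s$F_C3), F_C3_max = max(s$F_C3),
               F_C3_median = stats::median(s$F_C3),
               F_dicyclic_min = min(s$F_dicyclic),
               F_dicyclic_max = max(s$F_dicyclic),
               F_dicyclic_median = stats::median(s$F_dicyclic),
               stringsAsFactors = FALSE)
  }))
}

#' Run the chemotype inheritance analysis pipeline
#'
#' Orchestrates the full analysis: replicate averaging and chemotype
#' fractions, KDE demarcation of the F2 F_C3 and F_dicyclic axes, the
#' B-locus monogenic 1:2:1 test from genotype counts, the overall additive
#' 1:4:6:4:1 test on the global F_C3 categories, and the
#' genotype-conditioned segregation analysis. Deterministic for fixed
#' inputs.
#'
#' @param input A plant table path, a plant-table data frame, or an
#'   `f2_study` from [simulate_f2_study()].
#' @param alpha Significance level for all tests (default 0.05).
#' @param min_support,valley_depth_frac Passed to [demarcate()].
#' @param grid_points KDE grid resolution (default 512).
#' @param conditioning `"per-subset"` (default) or `"global"` category
#'   boundaries for the genotype-conditioned analysis.
#' @param model_plan Genotype-to-models plan (default
#'   [default_model_plan()]).
#' @param forced_counts Optional named list of category-count vectors (name
#'   `"All"` plus genotype levels) that bypasses KDE demarcation for the
#'   goodness-of-fit stage (fixtures mode).
#' @return Object of class `chemotype_report`.
#' @export
run_pipeline <- function(input, alpha = 0.05, min_support = 2,
                         valley_depth_frac = 0.05, grid_points = 512,
                         conditioning = c("per-subset", "global"),
                         model_plan = default_model_plan(),
                         forced_counts = NULL) {
  conditioning <- match.arg(conditioning)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  tbl <- if (is.character(input)) read_plant_table(input)
  else if (inherits(input, "f2_study")) input$table
  else if (is.data.frame(input)) input
  else stop("input must be a path, a data frame, or an f2_study",
            call. = FALSE)

  avg <- average_replicates(tbl)
  profiles <- avg$profiles
  totals <- rowSums(profiles[, intersect(.analyte_names(), names(profiles)),
                             drop = FALSE])
  zero <- which(totals <= 0)
  if (length(zero)) {
    warning(sprintf("excluding %d plant(s) with all-zero cannabinoid totals",
                    length(zero)), call. = FALSE)
    note("excluded %d all-zero plants: %s", length(zero),
         paste(profiles$plant_id[zero], collapse = ", "))
    profiles <- profiles[-zero, , drop = FALSE]
  }
  fr <- cbind(profiles[, intersect(c("plant_id", "generation", "b_genotype",
                                     "sex", "family"), names(profiles)),
                       drop = FALSE],
              .fractions_rows(profiles))

  f2 <- fr[fr$generation == "F2", , drop = FALSE]
  if (nrow(f2) == 0) {
    note("no F2 plants: demarcation and segregation stages skipped")
  }

  demarc_axis <- function(vals, axis) {
    tryCatch({
      h <- sj_bandwidth(vals)
      kde <- estimate_density(vals, h, grid_points = grid_points)
      cats <- demarcate(kde, min_support = min_support,
                        valley_depth_frac = valley_depth_frac)
      note("%s: h = %.3f, %d categories, boundaries [%s]", axis, h,
           length(cats$labels),
           paste(sprintf("%.1f", cats$boundaries), collapse = ", "))
      if (length(cats$unresolved_valleys)) {
        note("%s: unresolved antimodes at [%s]", axis,
             paste(sprintf("%.1f", cats$unresolved_valleys), collapse = ", "))
      }
      list(kde = kde, categories = cats)
    }, error = function(e) {
      note("%s demarcation unavailable: %s", axis, conditionMessage(e))
      NULL
    })
  }
  dem_fc3 <- if (nrow(f2) >= 2) demarc_axis(f2$F_C3, "F_C3") else NULL
  dem_fdi <- if (nrow(f2) >= 2) demarc_axis(f2$F_dicyclic, "F_dicyclic")
  else NULL

  # B-locus monogenic test from genotype counts
  b_test <- NULL
  cond <- NULL
  if ("b_genotype" %in% names(f2) && nrow(f2) > 0 &&
      any(!is.na(f2$b_genotype))) {
    cts <- vapply(c("CBDAS/CBDAS", "THCAS/CBDAS", "THCAS/THCAS"),
                  function(g) sum(f2$b_genotype == g, na.rm = TRUE),
                  numeric(1))
    if (!is.null(forced_counts$b_locus)) cts <- forced_counts$b_locus
    b_test <- suppressWarnings(b_locus_monogenic_test(cts, alpha))
    note("B locus 1:2:1: chi2 = %.2f, H0 %s", b_test$chi2,
         if (b_test$h0_accepted) "accepted" else "rejected")
    if (!is.null(forced_counts)) {
      plan_counts <- forced_counts[intersect(names(forced_counts),
                                             names(model_plan))]
      cond <- run_model_plan(plan_counts, model_plan[names(plan_counts)],
                             alpha)
    } else {
      cond <- withCallingHandlers(
        genotype_conditioned_segregation(
          f2$F_C3, f2$b_genotype, model_plan, mode = conditioning,
          categories = if (conditioning == "global" && !is.null(dem_fc3))
            dem_fc3$categories else NULL,
          alpha = alpha, min_support = min_support,
          valley_depth_frac = valley_depth_frac),
        warning = function(w) {
          note("conditioned analysis: %s", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }
  } else {
    note("no b_genotype calls: genotype-conditioned stages skipped")
  }

  # overall F_C3 test against the digenic additive expectation
  overall <- NULL
  all_counts <- if (!is.null(forced_counts$All)) forced_counts$All
  else if (!is.null(dem_fc3)) as.numeric(dem_fc3$categories$counts)
  else NULL
  if (!is.null(all_counts)) {
    overall <- tryCatch(
      suppressWarnings(chi_square_gof(
        all_counts, segregation_ratios()$digenic_additive, alpha)),
      error = function(e) conditionMessage(e))
    if (is.character(overall)) note("overall additive test: %s", overall)
  }

  # F1 family variance homogeneity, when several families are recorded
  variance_tbl <- NULL
  bartlett <- NULL
  if ("family" %in% names(fr)) {
    f1 <- fr[fr$generation == "F1" & !is.na(fr$family), , drop = FALSE]
    fams <- unique(f1$family)
    if (length(fams) >= 2) {
      variance_tbl <- do.call(rbind, lapply(fams, function(fm) {
        v <- f1$F_C3[f1$family == fm]
        data.frame(family = fm, variance_F_C3 = stats::var(v),
                   df = length(v) - 1, stringsAsFactors = FALSE)
      }))
      ok <- variance_tbl$df >= 1
      if (sum(ok) >= 2) {
        bartlett <- bartlett_from_summaries(variance_tbl$variance_F_C3[ok],
                                            variance_tbl$df[ok])
        note("Bartlett (F1 families): chi2 = %.2f on %d df", bartlett$chi2,
             bartlett$df)
      }
    }
  }

  structure(list(
    config = list(alpha = alpha, min_support = min_support,
                  valley_depth_frac = valley_depth_frac,
                  grid_points = grid_points, conditioning = conditioning),
    n = list(records = nrow(tbl), plants = nrow(fr), f2 = nrow(f2),
             excluded_zero_total = length(zero)),
    repeatability_r2 = avg$repeatability_r2,
    fractions = fr,
    generation_summary = .gen_summary(fr),
    demarcation_F_C3 = if (!is.null(dem_fc3)) dem_fc3$categories else NULL,
    demarcation_F_dicyclic = if (!is.null(dem_fdi)) dem_fdi$categories
    else NULL,
    kde_F_C3 = if (!is.null(dem_fc3)) dem_fc3$kde else NULL,
    kde_F_dicyclic = if (!is.null(dem_fdi)) dem_fdi$kde else NULL,
    b_locus_test = b_test,
    conditioned = cond,
    overall_additive = overall,
    variance_table = variance_tbl,
    bartlett = bartlett,
    log = log), class = "chemotype_report")
}

.fmt_gof_row <- function(label, n, counts, f) {
  if (is.character(f)) {
    sprintf("  %-14s n=%-4d [%s]  not testable: %s", label, n,
            paste(counts, collapse = ","), f)
  } else {
    sprintf("  %-14s n=%-4d [%s]  %s  chi2=%6.2f df=%d crit=%.2f  H0 %s",
            label, n, paste(counts, collapse = ","),
            paste(f$terms, collapse = ":"), f$chi2, f$df, f$critical_value,
            if (f$h0_accepted) "accepted" else "rejected")
  }
}

#' @export
print.chemotype_report <- function(x, ...) {
  cat("== Chemotype inheritance analysis ==\n")
  cat(sprintf("Plants: %d (%d records; %d F2; %d excluded all-zero)\n",
              x$n$plants, x$n$records, x$n$f2, x$n$excluded_zero_total))
  if (!all(is.na(x$repeatability_r2))) {
    cat(sprintf("Replicate repeatability r2: F_C3 = %.4f, F_dicyclic = %.4f\n",
                x$repeatability_r2[["F_C3"]],
                x$repeatability_r2[["F_dicyclic"]]))
  }
  cat("\n-- Generation summary (percent of total cannabinoid fraction) --\n")
  gs <- x$generation_summary
  for (i in seq_len(nrow(gs))) {
    cat(sprintf("  %-3s n=%-4d F_C3 %.1f-%.1f [%.1f]  F_dicyclic %.1f-%.1f [%.1f]\n",
                gs$generation[i], gs$n[i], gs$F_C3_min[i], gs$F_C3_max[i],
                gs$F_C3_median[i], gs$F_dicyclic_min[i],
                gs$F_dicyclic_max[i], gs$F_dicyclic_median[i]))
  }
  if (!is.null(x$demarcation_F_C3)) {
    cat("\n-- F_C3 demarcation (F2) --\n")
    print(x$demarcation_F_C3)
  }
  if (!is.null(x$demarcation_F_dicyclic)) {
    cat("\n-- F_dicyclic demarcation (F2) --\n")
    print(x$demarcation_F_dicyclic)
  }
  if (!is.null(x$b_locus_test)) {
    cat("\n-- B locus monogenic codominant test --\n")
    print(x$b_locus_test)
  }
  if (!is.null(x$overall_additive)) {
    cat("\n-- Overall F_C3 vs digenic additive --\n")
    if (is.character(x$overall_additive)) {
      cat("  not testable:", x$overall_additive, "\n")
    } else {
      print(x$overall_additive)
    }
  }
  if (!is.null(x$conditioned)) {
    cat("\n")
    if (inherits(x$conditioned, "conditioned_segregation")) {
      print(x$conditioned)
    } else {
      cat("-- Genotype-conditioned tests (forced counts) --\n")
      for (gl in names(x$conditioned)) {
        for (f in x$conditioned[[gl]]) {
          cat(.fmt_gof_row(gl, if (is.character(f)) NA_integer_
                           else sum(f$observed),
                           if (is.character(f)) "" else f$observed, f), "\n")
        }
      }
    }
  }
  if (!is.null(x$bartlett)) {
    cat(sprintf("\n-- F1 family variance homogeneity --\n  Bartlett chi2 = %.2f on %d df (p = %.3f)\n",
                x$bartlett$chi2, x$bartlett$df, x$bartlett$p_value))
  }
  if (length(x$log)) {
    cat("\n-- Log --\n")
    cat(paste0("  ", x$log, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write an analysis report to a text file
#'
#' Writes the formatted report; optionally also writes machine-readable
#' density tables for the two demarcated axes alongside it.
#'
#' @param report A `chemotype_report`.
#' @param path Output path for the text report.
#' @param density_tables If `TRUE`, write `<path>_fc3_density.tsv` and
#'   `<path>_fdicyclic_density.tsv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, density_tables = FALSE) {
  stopifnot(inherits(report, "chemotype_report"))
  txt <- utils::capture.output(print(report))
  writeLines(txt, path)
  if (density_tables) {
    if (!is.null(report$kde_F_C3)) {
      utils::write.table(density_table(report$kde_F_C3),
                         paste0(path, "_fc3_density.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(report$kde_F_dicyclic)) {
      utils::write.table(density_table(report$kde_F_dicyclic),
                         paste0(path, "_fdicyclic_density.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
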