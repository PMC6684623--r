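# Chemotype fractions: F_C3/F_C5 (alkyl side-chain) and F_dicyclic/F_tricyclic
# (ring type) as percentages of the total cannabinoid fraction, computed from
# acid-equivalent pools of the eight fraction-relevant analytes.

.analyte_names <- function() .analyte_def$analyte

# validate and normalise a profile to a full named vector over the 8 analytes;
# unknown analytes (CBN, CBG, CBGA, CBC, ...) are ignored for the pools.
.profile_contents <- function(content) {
  if (is.data.frame(content)) content <- unlist(content[1, , drop = TRUE])
  if (is.null(names(content))) {
    stop("cannabinoid contents must be a named vector (analyte abbreviations)",
         call. = FALSE)
  }
  keep <- intersect(.analyte_names(), names(content))
  x <- suppressWarnings(as.numeric(content[keep]))
  names(x) <- keep
  if (any(!is.finite(x))) {
    stop("cannabinoid contents must all be finite", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("cannabinoid contents must all be >= 0", call. = FALSE)
  }
  full <- stats::setNames(numeric(8), .analyte_names())
  full[keep] <- x
  full
}

#' Compute chemotype fractions from a cannabinoid profile
#'
#' Pools the eight fraction-relevant cannabinoids into propyl (C3) versus
#' pentyl (C5) alkyl side-chain and dicyclic (CBD-type) versus tricyclic
#' (THC-type) ring classes, after expressing the neutral forms (CBDV, THCV,
#' CBD, THC) as acid equivalents. Each fraction is the pool as a percentage
#' of the total cannabinoid fraction, so `F_C3 + F_C5 = 100` and
#' `F_dicyclic + F_tricyclic = 100`.
#'
#' @param content Named numeric vector of fresh-weight contents (mg per g)
#'   for some or all of CBDVA, THCVA, CBDA, THCA, CBDV, THCV, CBD, THC.
#'   Analytes outside these eight (e.g. CBG, CBN) are accepted but excluded
#'   from all pools.
#' @return Named numeric vector `c(F_C3, F_C5, F_dicyclic, F_tricyclic)`,
#'   percentages in `[0, 100]`.
#' @export
#' @examples
#' compute_fractions(c(THCVA = 3, THCA = 1))  # F_C3 = 75, F_tricyclic = 100
compute_fractions <- function(content) {
  x <- .profile_contents(content)
  if (sum(x) <= 0) {
    stop("all-zero cannabinoid profile: chemotype fractions are undefined",
         call. = FALSE)
  }
  def <- .analyte_def
  eq <- x
  for (a in def$analyte[def$form == "neutral"]) {
    eq[[a]] <- acid_equivalent(x[[a]], a)
  }
  c3 <- sum(eq[def$alkyl == "C3"])
  c5 <- sum(eq[def$alkyl == "C5"])
  di <- sum(eq[def$ring == "dicyclic"])
  tri <- sum(eq[def$ring == "tricyclic"])
  total <- c3 + c5
  c(F_C3 = 100 * c3 / total,
    F_C5 = 100 * c5 / total,
    F_dicyclic = 100 * di / total,
    F_tricyclic = 100 * tri / total)
}

# fractions for every row of a plant table; returns a data.frame aligned with tbl
.fractions_rows <- function(tbl) {
  cols <- intersect(.analyte_names(), names(tbl))
  out <- t(vapply(seq_len(nrow(tbl)), function(i) {
    compute_fractions(unlist(tbl[i, cols, drop = FALSE]))
  }, numeric(4)))
  as.data.frame(out)
}

#' Average extraction replicates and assess repeatability
#'
#' Collapses a plant table with repeated extraction records to one mean
#' profile per plant (analyte-wise arithmetic mean) and, when plants carry
#' exactly two replicates, computes the repeatability of the derived
#' fraction axes as the coefficient of determination (r^2) between the
#' replicate-1 and replicate-2 fraction values across the plant set.
#'
#' @param tbl Data frame with columns `plant_id`, `generation`, optionally
#'   `replicate`, `b_genotype`, `sex`, and analyte columns named by
#'   canonical abbreviation.
#' @return A list with `profiles` (one row per plant: metadata plus mean
#'   analyte contents) and `repeatability_r2` (named numeric, `F_C3` and
#'   `F_dicyclic` axes; `NA` when fewer than three plants have exactly two
#'   replicates or an axis is degenerate).
#' @export
average_replicates <- function(tbl) {
  stopifnot(is.data.frame(tbl))
  if (!all(c("plant_id", "generation") %in% names(tbl))) {
    stop("plant table requires `plant_id` and `generation` columns",
         call. = FALSE)
  }
  if (!"replicate" %in% names(tbl)) tbl$replicate <- 1L
  key <- paste(tbl$plant_id, tbl$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate plant_id + replicate records: ",
         paste(unique(tbl$plant_id[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  }
  meta_cols <- intersect(c("generation", "b_genotype", "sex", "family"),
                         names(tbl))
  for (mc in meta_cols) {
    n_lev <- tapply(tbl[[mc]], tbl$plant_id, function(v) length(unique(v)))
    if (any(n_lev > 1)) {
      stop("plant_id mapped to conflicting `", mc, "` values: ",
           paste(names(n_lev)[n_lev > 1], collapse = ", "), call. = FALSE)
    }
  }
  cols <- intersect(.analyte_names(), names(tbl))
  if (length(cols) == 0) {
    stop("no recognised analyte columns in plant table", call. = FALSE)
  }
  ids <- unique(tbl$plant_id)
  first <- tbl[match(ids, tbl$plant_id), c("plant_id", meta_cols), drop = FALSE]
  means <- do.call(rbind, lapply(ids, function(id) {
    colMeans(as.matrix(tbl[tbl$plant_id == id, cols, drop = FALSE]))
  }))
  profiles <- cbind(first, as.data.frame(means))
  rownames(profiles) <- NULL

  # repeatability across plants with exactly two replicates
  r2 <- c(F_C3 = NA_real_, F_dicyclic = NA_real_)
  n_rep <- table(tbl$plant_id)
  dup_ids <- names(n_rep)[n_rep == 2]
  if (length(dup_ids) >= 3) {
    sub <- tbl[tbl$plant_id %in% dup_ids, , drop = FALSE]
    sub <- sub[order(sub$plant_id, sub$replicate), , drop = FALSE]
    fr <- .fractions_rows(sub)
    odd <- seq(1, nrow(sub), by = 2)
    for (ax in c("F_C3", "F_dicyclic")) {
      a <- fr[[ax]][odd]
      b <- fr[[ax]][odd + 1]
      if (stats::sd(a) > 0 && stats::sd(b) > 0) {
        r2[[ax]] <- stats::cor(a, b)^2
      } else if (all(a == b)) {
        r2[[ax]] <- 1
      }
    }
  }
  list(profiles = profiles, repeatability_r2 = r2)
}

#' Mid-parent value
#'
#' Arithmetic mean of two parental trait values, the additive-inheritance
#' expectation for hybrid progeny.
#'
#' @param p1,p2 Parental values in percent, each in `[0, 100]`.
#' @return `(p1 + p2) / 2`.
#' @export
#' @examples
#' midparent(0.9, 96.1)   # 48.5
#' midparent(88.3, 0.8)   # 44.55
midparent <- function(p1, p2) {
  if (!is.numeric(p1) || !is.numeric(p2) ||
      any(p1 < 0 | p1 > 100) || any(p2 < 0 | p2 > 100)) {
    stop("parental values must lie in [0, 100]", call. = FALSE)
  }
  (p1 + p2) / 2
}
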