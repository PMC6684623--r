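# Kernel density demarcation: Sheather-Jones bandwidth, Gaussian KDE on a
# uniform grid, mode detection, and baseline peak integration into ordered
# chemotype categories.

# Gaussian kernel derivative polynomials: phi^(4) and phi^(6)
.phi4 <- function(u) (u^4 - 6 * u^2 + 3) * stats::dnorm(u)
.phi6 <- function(u) (u^6 - 15 * u^4 + 45 * u^2 - 15) * stats::dnorm(u)

# density-derivative functional psi_r(g) over all ordered pairs (diagonal
# included); d = vector of |x_i - x_j| for i < j
.psi_hat <- function(phi, d, n, g, r) {
  (2 * sum(phi(d / g)) + n * phi(0)) / (n^2 * g^(r + 1))
}

#' Sheather-Jones plug-in bandwidth
#'
#' Solve-the-equation plug-in bandwidth of Sheather and Jones for a Gaussian
#' kernel. Density-derivative functionals are estimated with the standard
#' two-stage pilot bandwidths; the root is located by `uniroot` on a
#' geometric bracket expanded from the normal-reference bandwidth
#' `1.059 * lambda * n^(-1/5)` (scale `lambda = min(sd, IQR/1.349)`). If no
#' root can be bracketed within `[h_ref/100, 100 * h_ref]` the function
#' falls back, with a warning, to the normal-reference bandwidth.
#'
#' @param values Numeric vector of observations, `n >= 4`, not all equal.
#' @return Bandwidth `h > 0` in the units of `values`.
#' @export
#' @examples
#' set.seed(1)
#' sj_bandwidth(rnorm(200, 50, 5))
sj_bandwidth <- function(values) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("values must be finite", call. = FALSE)
  n <- length(x)
  if (n < 4) {
    stop("need at least 4 observations for bandwidth selection; ",
         "treat the group as a single category", call. = FALSE)
  }
  sdx <- stats::sd(x)
  scale0 <- max(1, abs(mean(x)))
  if (!is.finite(sdx) || sdx <= 1e-10 * scale0) {
    stop("zero variance in values; treat the group as a single category",
         call. = FALSE)
  }
  iqr <- stats::IQR(x)
  lambda <- if (iqr > 0) min(sdx, iqr / 1.349) else sdx

  d <- as.vector(stats::dist(x))
  a <- 1.241 * lambda * n^(-1 / 7)   # pilot for psi_4
  b <- 1.230 * lambda * n^(-1 / 9)   # pilot for psi_6
  psi6 <- .psi_hat(.phi6, d, n, b, 6)
  h_ref <- 1.059 * lambda * n^(-1 / 5)
  if (!is.finite(psi6) || psi6 >= 0) {
    warning("Sheather-Jones functional estimate degenerate; ",
            "falling back to normal-reference bandwidth")
    return(h_ref)
  }
  td <- -psi6
  psi4_a <- .psi_hat(.phi4, d, n, a, 4)
  if (!is.finite(psi4_a) || psi4_a <= 0) {
    warning("Sheather-Jones functional estimate degenerate; ",
            "falling back to normal-reference bandwidth")
    return(h_ref)
  }
  alpha2 <- function(h) 1.357 * (psi4_a / td)^(1 / 7) * h^(5 / 7)
  f <- function(h) {
    psi4 <- .psi_hat(.phi4, d, n, alpha2(h), 4)
    if (!is.finite(psi4) || psi4 <= 0) return(NA_real_)
    (1 / (2 * sqrt(pi) * n * psi4))^(1 / 5) - h
  }

  lo <- h_ref / 10
  hi <- h_ref * 10
  flo <- f(lo)
  fhi <- f(hi)
  while ((!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) &&
         lo > h_ref / 100) {
    lo <- lo / sqrt(10)
    hi <- hi * sqrt(10)
    flo <- f(lo)
    fhi <- f(hi)
  }
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    warning("no Sheather-Jones root bracketed in [h_ref/100, 100*h_ref]; ",
            "falling back to normal-reference bandwidth")
    return(h_ref)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-9 * h_ref)$root
}

#' Gaussian kernel density estimate on a uniform grid
#'
#' Evaluates the Gaussian KDE of fraction values (percent) on a uniform grid
#' spanning the data range padded by `padding` bandwidths and clipped to
#' `[0, 100]`. The density is computed exactly (no binning approximation).
#'
#' @param values Numeric vector of observed fractions (percent).
#' @param h Bandwidth, `> 0`; defaults to [sj_bandwidth()].
#' @param grid_points Number of grid points, `>= 64` (default 512).
#' @param padding Grid padding in multiples of `h` (default 3).
#' @return An object of class `fraction_kde`: a list with `values`, `n`,
#'   `h`, `grid` and `density`.
#' @export
estimate_density <- function(values, h = sj_bandwidth(values),
                             grid_points = 512, padding = 3) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("values must be finite", call. = FALSE)
  if (!is.finite(h) || h <= 0) stop("bandwidth must be > 0", call. = FALSE)
  if (grid_points < 64) stop("grid_points must be >= 64", call. = FALSE)
  lo <- max(0, min(x) - padding * h)
  hi <- min(100, max(x) + padding * h)
  if (lo >= hi) stop("degenerate grid: values must span part of [0, 100]",
                     call. = FALSE)
  grid <- seq(lo, hi, length.out = grid_points)
  dens <- rowMeans(stats::dnorm(outer(grid, x, "-") / h)) / h
  structure(list(values = x, n = length(x), h = h, grid = grid,
                 density = dens),
            class = "fraction_kde")
}

#' @export
print.fraction_kde <- function(x, ...) {
  cat(sprintf("Gaussian KDE: n = %d, h = %.4g, grid [%.2f, %.2f] (%d points)\n",
              x$n, x$h, min(x$grid), max(x$grid), length(x$grid)))
  invisible(x)
}

#' Export a KDE as a density table
#'
#' @param kde A `fraction_kde` object.
#' @return Data frame with columns `grid` and `density`, suitable for
#'   plotting or delimited-text export.
#' @export
density_table <- function(kde) {
  stopifnot(inherits(kde, "fraction_kde"))
  data.frame(grid = kde$grid, density = kde$density)
}

# trapezoidal integral of density over grid indices a..b
.trapz <- function(grid, dens, a = 1, b = length(grid)) {
  i <- a:(b - 1)
  sum((dens[i] + dens[i + 1]) / 2 * diff(grid[a:b]))
}

#' Locate modes and antimodes of a density estimate
#'
#' Local maxima and minima are found from sign changes of the first
#' differences of the density; plateaus are collapsed to their midpoint and
#' boundary grid points may carry maxima. Antimodes (valleys) are retained
#' only between adjacent peaks.
#'
#' @param kde A `fraction_kde` object.
#' @return An object of class `mode_set`: list with integer grid indices
#'   `peaks` and `valleys` (alternating, valleys strictly between peaks)
#'   and `support_counts`, the number of observations falling in each peak
#'   interval.
#' @export
find_modes <- function(kde) {
  stopifnot(inherits(kde, "fraction_kde"))
  d <- kde$density
  m <- length(d)
  s <- sign(diff(d))
  nz <- which(s != 0)
  peaks <- integer(0)
  valleys <- integer(0)
  if (length(nz) == 0) {
    peaks <- as.integer(round((1 + m) / 2))  # flat density: single plateau
  } else {
    ss <- s[nz]
    if (ss[1] < 0) {
      peaks <- c(peaks, as.integer(floor((1 + nz[1]) / 2)))
    }
    k <- length(nz)
    if (k >= 2) {
      for (i in seq_len(k - 1)) {
        mid <- as.integer(floor((nz[i] + 1 + nz[i + 1]) / 2))
        if (ss[i] > 0 && ss[i + 1] < 0) peaks <- c(peaks, mid)
        if (ss[i] < 0 && ss[i + 1] > 0) valleys <- c(valleys, mid)
      }
    }
    if (ss[k] > 0) {
      peaks <- c(peaks, as.integer(floor((nz[k] + 1 + m) / 2)))
    }
  }
  # valleys before the first peak or after the last are boundary minima,
  # not category boundaries
  if (length(peaks) > 0) {
    valleys <- valleys[valleys > min(peaks) & valleys < max(peaks)]
  }
  support <- tabulate(.interval_index(kde$values, kde$grid[valleys]),
                      nbins = length(peaks))
  structure(list(peaks = peaks, valleys = valleys,
                 support_counts = support),
            class = "mode_set")
}

# category index per value for boundary vector b: 1 + number of boundaries
# strictly below the value (left-open/right-closed; first interval closed)
.interval_index <- function(values, b) {
  if (length(b) == 0) return(rep.int(1L, length(values)))
  idx <- rowSums(outer(values, b, ">")) + 1L
  as.integer(idx)
}

#' Demarcate a fraction distribution into ordered chemotype categories
#'
#' Baseline peak integration of a KDE: peak intervals are delimited by their
#' flanking antimodes (or the grid ends). Antimodes whose depth below the
#' smaller flanking peak is less than `valley_depth_frac` of that peak
#' height are treated as unresolvable and merged across (reported in the
#' result). Any interval supported by fewer than `min_support` observations
#' is merged into the adjacent interval whose shared antimode has the higher
#' density (ties merge toward the interval with larger support), and
#' boundaries are re-derived. Categories are labelled with Roman numerals in
#' order of increasing fraction value.
#'
#' @param kde A `fraction_kde` object.
#' @param min_support Minimum observations per retained category (default 2,
#'   i.e. kernels supported by a single observation are not considered).
#' @param valley_depth_frac Minimum antimode depth, as a fraction of the
#'   smaller flanking peak height, for a boundary to be considered resolved
#'   (default 0.05).
#' @return An object of class `chemotype_categories`: list with
#'   `boundaries` (cut points, percent), `labels`, `counts`, `assignment`
#'   (label per observation), `areas` (integrated density per category),
#'   `h`, `n` and `unresolved_valleys` (positions merged across).
#' @export
demarcate <- function(kde, min_support = 2, valley_depth_frac = 0.05) {
  stopifnot(inherits(kde, "fraction_kde"))
  values <- kde$values
  n <- length(values)
  g <- kde$grid
  d <- kde$density
  if (n < 2) {
    warning("fewer than 2 observations: returning a single category")
    return(.make_categories(kde, peaks = which.max(d), valleys = integer(0),
                            unresolved = numeric(0)))
  }
  m <- find_modes(kde)
  peaks <- m$peaks
  valleys <- m$valleys
  unresolved <- numeric(0)

  # 1) merge across unresolvable (too shallow) antimodes
  repeat {
    if (length(valleys) == 0) break
    depth_ok <- vapply(seq_along(valleys), function(i) {
      pk <- min(d[peaks[i]], d[peaks[i + 1]])
      (pk - d[valleys[i]]) >= valley_depth_frac * pk
    }, logical(1))
    if (all(depth_ok)) break
    i <- which(!depth_ok)[1]
    unresolved <- c(unresolved, g[valleys[i]])
    peaks[i] <- if (d[peaks[i]] >= d[peaks[i + 1]]) peaks[i] else peaks[i + 1]
    peaks <- peaks[-(i + 1)]
    valleys <- valleys[-i]
  }

  # 2) merge intervals with insufficient observation support
  if (min_support > 1) {
    repeat {
      counts <- tabulate(.interval_index(values, g[valleys]),
                         nbins = length(peaks))
      bad <- which(counts < min_support)
      if (length(bad) == 0 || length(peaks) == 1) break
      i <- bad[which.min(counts[bad])]
      if (i == 1) {
        j <- 2L
      } else if (i == length(peaks)) {
        j <- i - 1L
      } else {
        vl <- d[valleys[i - 1]]
        vr <- d[valleys[i]]
        j <- if (vr > vl) i + 1L
        else if (vl > vr) i - 1L
        else if (counts[i + 1] >= counts[i - 1]) i + 1L else i - 1L
      }
      vshared <- min(i, j)           # valley between intervals i and j
      lo <- min(i, j)
      peaks[lo] <- if (d[peaks[i]] >= d[peaks[j]]) peaks[i] else peaks[j]
      peaks <- peaks[-(lo + 1)]
      valleys <- valleys[-vshared]
    }
  }
  .make_categories(kde, peaks, valleys, unresolved)
}

.make_categories <- function(kde, peaks, valleys, unresolved) {
  g <- kde$grid
  d <- kde$density
  values <- kde$values
  boundaries <- g[valleys]
  k <- length(peaks)
  labels <- as.character(utils::as.roman(seq_len(k)))
  idx <- .interval_index(values, boundaries)
  counts <- tabulate(idx, nbins = k)
  seg <- c(1L, valleys, length(g))
  areas <- vapply(seq_len(k), function(i) {
    .trapz(g, d, seg[i], seg[i + 1])
  }, numeric(1))
  structure(list(boundaries = boundaries, labels = labels,
                 counts = stats::setNames(counts, labels),
                 assignment = labels[idx],
                 areas = stats::setNames(areas, labels),
                 peak_positions = g[peaks],
                 h = kde$h, n = length(values),
                 unresolved_valleys = unresolved),
            class = "chemotype_categories")
}

#' @export
print.chemotype_categories <- function(x, ...) {
  cat(sprintf("Chemotype demarcation: %d categories (h = %.3g, n = %d)\n",
              length(x$labels), x$h, x$n))
  if (length(x$boundaries)) {
    cat("  boundaries:", paste(sprintf("%.1f", x$boundaries), collapse = ", "),
        "\n")
  }
  cat("  counts:",
      paste(sprintf("%s = %d", x$labels, x$counts), collapse = ", "), "\n")
  if (length(x$unresolved_valleys)) {
    cat("  unresolved antimodes at:",
        paste(sprintf("%.1f", x$unresolved_valleys), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assign fraction values to demarcated categories
#'
#' Intervals are left-open/right-closed, except the first which is closed at
#' both ends, so a value lying exactly on a boundary joins the
#' lower-fraction category.
#'
#' @param values Numeric vector of fractions (percent), each in `[0, 100]`.
#' @param categories A `chemotype_categories` object or a numeric vector of
#'   ordered boundaries (possibly empty).
#' @return Character vector of category labels, one per value.
#' @export
assign_categories <- function(values, categories) {
  b <- if (inherits(categories, "chemotype_categories")) {
    categories$boundaries
  } else {
    as.numeric(categories)
  }
  if (is.unsorted(b, strictly = TRUE) && length(b) > 1) {
    stop("category boundaries must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0 | values > 100)) {
    stop("values must lie in [0, 100]", call. = FALSE)
  }
  labels <- if (inherits(categories, "chemotype_categories")) {
    categories$labels
  } else {
    as.character(utils::as.roman(seq_len(length(b) + 1)))
  }
  labels[.interval_index(values, b)]
}
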