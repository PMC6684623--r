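# Analyte constants: the eight cannabinoids entering the chemotype fractions.
# Molecular weights are derived from molecular formulas using standard atomic
# weights so the decarboxylation correction is auditable to the formula level.

.atomic_weights <- c(C = 12.011, H = 1.008, O = 15.999)

.formula_mw <- function(C, H, O) {
  C * .atomic_weights[["C"]] + H * .atomic_weights[["H"]] + O * .atomic_weights[["O"]]
}

# columns: analyte, form (acid/neutral), alkyl (C3/C5), ring (dicyclic/tricyclic),
# atom counts. Order is the canonical column order for plant tables.
.analyte_def <- data.frame(
  analyte = c("CBDVA", "THCVA", "CBDA", "THCA", "CBDV", "THCV", "CBD", "THC"),
  form    = c("acid", "acid", "acid", "acid",
              "neutral", "neutral", "neutral", "neutral"),
  alkyl   = c("C3", "C3", "C5", "C5", "C3", "C3", "C5", "C5"),
  ring    = c("dicyclic", "tricyclic", "dicyclic", "tricyclic",
              "dicyclic", "tricyclic", "dicyclic", "tricyclic"),
  C = c(20L, 20L, 22L, 22L, 19L, 19L, 21L, 21L),
  H = c(26L, 26L, 30L, 30L, 26L, 26L, 30L, 30L),
  O = c(4L, 4L, 4L, 4L, 2L, 2L, 2L, 2L),
  stringsAsFactors = FALSE
)
.analyte_def$mw <- .formula_mw(.analyte_def$C, .analyte_def$H, .analyte_def$O)

.neutral_to_acid <- c(CBDV = "CBDVA", THCV = "THCVA", CBD = "CBDA", THC = "THCA")

#' Cannabinoid analyte reference table
#'
#' The eight analytes used to compute chemotype fractions, with molecular
#' formulas, average molecular weights (standard atomic weights C 12.011,
#' H 1.008, O 15.999), alkyl side-chain class (propyl C3 / pentyl C5) and
#' ring class (dicyclic CBD-type / tricyclic THC-type).
#'
#' @return A data frame with one row per analyte: `analyte`, `form`
#'   (`"acid"` or `"neutral"`), `alkyl`, `ring`, atom counts `C`, `H`, `O`
#'   and average molecular weight `mw` (g/mol).
#' @export
#' @examples
#' analyte_table()
analyte_table <- function() .analyte_def

#' Neutral/acid analyte pairs for decarboxylation correction
#'
#' The four neutral cannabinoids are expressed as their carboxylic-acid
#' precursors by a molecular-weight ratio; carboxylation adds one CO2
#' (44.009 g/mol) to each neutral form.
#'
#' @return A data frame with columns `neutral_name`, `acid_name`,
#'   `neutral_mw`, `acid_mw` and the correction `factor` (acid over neutral
#'   molecular weight, > 1).
#' @export
#' @examples
#' analyte_pairs()
analyte_pairs <- function() {
  neutral <- names(.neutral_to_acid)
  acid <- unname(.neutral_to_acid)
  nmw <- .analyte_def$mw[match(neutral, .analyte_def$analyte)]
  amw <- .analyte_def$mw[match(acid, .analyte_def$analyte)]
  data.frame(
    neutral_name = neutral, acid_name = acid,
    neutral_mw = nmw, acid_mw = amw, factor = amw / nmw,
    stringsAsFactors = FALSE
  )
}

#' Express a neutral cannabinoid content as its acid equivalent
#'
#' Multiplies a neutral (decarboxylated) cannabinoid fresh-weight content by
#' the acid/neutral molecular-weight ratio, so that all analytes are pooled
#' on the carboxylated-acid scale before fractions are computed.
#'
#' @param neutral_content Numeric vector of fresh-weight contents (mg per g),
#'   all finite and non-negative.
#' @param pair Either the neutral analyte name (`"CBDV"`, `"THCV"`, `"CBD"`
#'   or `"THC"`) or a list with elements `neutral_mw` and `acid_mw`.
#' @return Acid-equivalent content (mg per g), `neutral_content *
#'   acid_mw / neutral_mw`.
#' @export
#' @examples
#' acid_equivalent(10, "THC")   # 11.40 mg/g
#' acid_equivalent(10, "THCV")  # 11.54 mg/g
acid_equivalent <- function(neutral_content, pair) {
  if (!is.numeric(neutral_content) || any(!is.finite(neutral_content))) {
    stop("`neutral_content` must be finite numeric", call. = FALSE)
  }
  if (any(neutral_content < 0)) {
    stop("`neutral_content` must be >= 0", call. = FALSE)
  }
  if (is.character(pair)) {
    pairs <- analyte_pairs()
    i <- match(pair, pairs$neutral_name)
    if (is.na(i)) {
      stop("unknown neutral analyte: ", pair, call. = FALSE)
    }
    fac <- pairs$factor[i]
  } else if (is.list(pair)) {
    if (is.null(pair$neutral_mw) || is.null(pair$acid_mw)) {
      stop("`pair` must supply `neutral_mw` and `acid_mw`", call. = FALSE)
    }
    fac <- pair$acid_mw / pair$neutral_mw
  } else {
    stop("`pair` must be an analyte name or a list of molecular weights",
         call. = FALSE)
  }
  neutral_content * fac
}
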