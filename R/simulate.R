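# F2 cross simulator: meiosis with two-point recombination (no interference),
# gene-action models mapping two-locus A genotypes to alkyl phenotype classes,
# the codominant B locus for ring-type composition, and emission of plant
# tables in the pipeline's input format.

#' Define a locus for the cross simulator
#'
#' @param name Locus name (`"A1"`, `"A2"`, `"B"`, or a marker name).
#' @param alleles Character vector of the two allele labels.
#' @param linkage_group Linkage-group identifier; loci on different groups
#'   segregate independently (effective r = 0.5).
#' @param recomb_to_prev Recombination fraction to the previous locus in the
#'   ordered locus list, in `[0, 0.5]`. Ignored for the first locus.
#' @return A `locus_spec` object.
#' @export
locus_spec <- function(name, alleles, linkage_group = "LG1",
                       recomb_to_prev = 0.5) {
  if (length(alleles) != 2) stop("a locus carries two alleles", call. = FALSE)
  if (!is.numeric(recomb_to_prev) || recomb_to_prev < 0 ||
      recomb_to_prev > 0.5) {
    stop("recomb_to_prev must lie in [0, 0.5]", call. = FALSE)
  }
  structure(list(name = name, alleles = as.character(alleles),
                 linkage_group = linkage_group,
                 recomb_to_prev = recomb_to_prev),
            class = "locus_spec")
}

#' Default three-locus map: A1, A2 (alkyl) and B (synthase complex)
#'
#' @param r_a1_a2 Recombination fraction between A1 and A2 (default 0.5,
#'   unlinked).
#' @param r_a2_b Recombination fraction between A2 and B (default 0.5).
#' @return Ordered list of `locus_spec` objects.
#' @export
default_loci <- function(r_a1_a2 = 0.5, r_a2_b = 0.5) {
  list(
    locus_spec("A1", c("C3", "C5"), "LG1", 0.5),
    locus_spec("A2", c("C3", "C5"), "LG1", r_a1_a2),
    locus_spec("B", c("THCAS", "CBDAS"), "LG1", r_a2_b)
  )
}

.loci_names <- function(loci) vapply(loci, `[[`, character(1), "name")

# effective recombination fraction between locus l and l-1
.effective_r <- function(loci, l) {
  if (loci[[l]]$linkage_group != loci[[l - 1]]$linkage_group) return(0.5)
  loci[[l]]$recomb_to_prev
}

#' Construct a plant genotype
#'
#' @param plant_id Identifier.
#' @param mat,pat Named character vectors: allele per locus on the maternal
#'   and paternal haplotype.
#' @param sex Sex label (recorded only; no genetic effect).
#' @param generation Generation label (P1/P2/F1/F2).
#' @return A `plant_genotype` object.
#' @export
plant_genotype <- function(plant_id, mat, pat, sex = "U", generation = NA) {
  if (!identical(sort(names(mat)), sort(names(pat)))) {
    stop("maternal and paternal haplotypes must cover the same loci",
         call. = FALSE)
  }
  structure(list(plant_id = plant_id, mat = mat, pat = pat[names(mat)],
                 sex = sex, generation = generation),
            class = "plant_genotype")
}

# n gametes from one parent: matrix n x L of allele labels.
# First locus drawn from either haplotype with probability 1/2; each
# subsequent locus switches source haplotype with probability r.
.sim_gametes <- function(genotype, loci, n) {
  nm <- .loci_names(loci)
  H <- rbind(genotype$mat[nm], genotype$pat[nm])
  L <- length(loci)
  src <- matrix(0L, n, L)
  src[, 1] <- stats::rbinom(n, 1L, 0.5)
  if (L > 1) {
    for (l in 2:L) {
      sw <- stats::rbinom(n, 1L, .effective_r(loci, l))
      src[, l] <- (src[, l - 1] + sw) %% 2L
    }
  }
  out <- matrix("", n, L, dimnames = list(NULL, nm))
  for (l in seq_len(L)) out[, l] <- H[src[, l] + 1L, l]
  out
}

#' Draw one gamete from a parent
#'
#' Standard meiosis with two-point recombination and no crossover
#' interference: the first locus allele comes from either haplotype with
#' probability 1/2 and each subsequent locus switches source haplotype with
#' its `recomb_to_prev` probability. Uses R's global random number stream.
#'
#' @param genotype A `plant_genotype`.
#' @param loci Ordered list of `locus_spec` objects.
#' @return Named character vector: allele per locus.
#' @export
make_gamete <- function(genotype, loci) {
  .sim_gametes(genotype, loci, 1L)[1, ]
}

#' Cross two plants
#'
#' Each offspring combines one maternal and one paternal gamete.
#'
#' @param mother,father `plant_genotype` objects.
#' @param n_offspring Number of offspring, `>= 1`.
#' @param loci Ordered list of `locus_spec` objects.
#' @param id_prefix Prefix for offspring identifiers (default `"F2"`).
#' @param generation Generation label for the offspring.
#' @return List of `plant_genotype` objects; sexes assigned at random
#'   (recorded only).
#' @export
cross <- function(mother, father, n_offspring, loci, id_prefix = "F2",
                  generation = id_prefix) {
  stopifnot(n_offspring >= 1)
  gm <- .sim_gametes(mother, loci, n_offspring)
  gp <- .sim_gametes(father, loci, n_offspring)
  sexes <- ifelse(stats::rbinom(n_offspring, 1, 0.5) == 1, "F", "M")
  lapply(seq_len(n_offspring), function(i) {
    plant_genotype(sprintf("%s_%03d", id_prefix, i),
                   mat = gm[i, ], pat = gp[i, ],
                   sex = sexes[i], generation = generation)
  })
}

#' Define a gene-action model for alkyl phenotype classes
#'
#' Maps two-locus A genotypes to an ordered phenotype class and attaches the
#' phenotype model: class mean F_C3 values plus Gaussian within-class noise,
#' and B-genotype mean F_dicyclic values.
#'
#' * `additive`: class = number of C3-type alleles over A1 + A2 (5 classes,
#'   expected F2 ratio 1:4:6:4:1).
#' * `digenic_dominant`: C5-type alleles dominant at both loci; the four
#'   dominance classes (both dominant, A1-only, A2-only, double recessive)
#'   give the 9:3:3:1 ratio, with the double C3 recessive the F_C3 maximum.
#' * `epistatic_7_6_3`: the C3 allele is dominant at A1 and the A1
#'   homozygous-recessive genotype is epistatic to A2; otherwise the class
#'   follows A2 C3-allele dosage with a distinguishable heterozygote
#'   (partial dominance), giving 7:6:3 (low:mid:high F_C3).
#'
#' @param kind One of `"additive"`, `"digenic_dominant"`,
#'   `"epistatic_7_6_3"`.
#' @param class_means_FC3 Strictly increasing mean F_C3 per class (percent);
#'   defaults anchor the extremes at the parental values 0.8 and 88.3.
#' @param noise_sd Within-class standard deviation of F_C3 (percent,
#'   default 4.5).
#' @param b_class_means_Fdi Mean F_dicyclic for the three B genotypes
#'   ordered `THCAS/THCAS`, `THCAS/CBDAS`, `CBDAS/CBDAS` (default
#'   `c(0.9, 48.5, 96.1)`: parental anchors with the incomplete-dominance
#'   mid-parent heterozygote).
#' @param b_noise_sd Within-genotype standard deviation of F_dicyclic
#'   (default 4.5).
#' @param skew If `TRUE`, phenotype noise is applied on the logit scale,
#'   producing distributions skewed toward the boundary-near class means
#'   (default `FALSE`, so Mendelian class expectations stay exact).
#' @param skew_sd Logit-scale noise standard deviation used when
#'   `skew = TRUE` (default 0.35).
#' @return A `gene_action_model` object.
#' @export
gene_action_model <- function(kind = c("additive", "digenic_dominant",
                                       "epistatic_7_6_3"),
                              class_means_FC3 = NULL, noise_sd = 4.5,
                              b_class_means_Fdi = c(0.9, 48.5, 96.1),
                              b_noise_sd = 4.5, skew = FALSE,
                              skew_sd = 0.35) {
  kind <- match.arg(kind)
  n_classes <- switch(kind, additive = 5L, digenic_dominant = 4L,
                      epistatic_7_6_3 = 3L)
  if (is.null(class_means_FC3)) {
    class_means_FC3 <- switch(
      kind,
      additive = seq(0.8, 88.3, length.out = 5),
      digenic_dominant = c(0.8, 30, 60, 88.3),
      epistatic_7_6_3 = c(0.8, 44.55, 88.3)
    )
  }
  if (length(class_means_FC3) != n_classes) {
    stop(sprintf("%s gene action requires %d class means", kind, n_classes),
         call. = FALSE)
  }
  if (is.unsorted(class_means_FC3, strictly = TRUE) ||
      any(class_means_FC3 < 0 | class_means_FC3 > 100)) {
    stop("class means must be strictly increasing within [0, 100]",
         call. = FALSE)
  }
  if (length(b_class_means_Fdi) != 3 ||
      is.unsorted(b_class_means_Fdi, strictly = TRUE)) {
    stop("b_class_means_Fdi must be three increasing F_dicyclic means ",
         "(THCAS/THCAS lowest)", call. = FALSE)
  }
  if (noise_sd < 0 || b_noise_sd < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(kind = kind, n_classes = n_classes,
                 class_means_FC3 = class_means_FC3, noise_sd = noise_sd,
                 b_class_means_Fdi = b_class_means_Fdi,
                 b_noise_sd = b_noise_sd, skew = skew, skew_sd = skew_sd),
            class = "gene_action_model")
}

.c3_dosage <- function(genotype, locus) {
  (genotype$mat[[locus]] == "C3") + (genotype$pat[[locus]] == "C3")
}

#' Phenotype class of a genotype under a gene-action model
#'
#' @param genotype A `plant_genotype` covering loci A1 and A2.
#' @param model A `gene_action_model`.
#' @return Integer class index (1 = lowest F_C3 class).
#' @export
phenotype_class <- function(genotype, model) {
  stopifnot(inherits(model, "gene_action_model"))
  d1 <- .c3_dosage(genotype, "A1")
  d2 <- .c3_dosage(genotype, "A2")
  switch(model$kind,
    additive = 1L + d1 + d2,
    digenic_dominant = {
      dom1 <- d1 < 2  # carries a dominant C5 allele at A1
      dom2 <- d2 < 2
      if (dom1 && dom2) 1L else if (dom1) 2L else if (dom2) 3L else 4L
    },
    epistatic_7_6_3 = {
      if (d1 == 0) 1L else c(1L, 2L, 3L)[d2 + 1L]
    },
    stop("unknown gene-action kind", call. = FALSE)
  )
}

#' Enumerate F2 phenotype-class probabilities exactly
#'
#' Brute-force enumeration of all 16 equally likely two-locus gamete
#' combinations from an F1 x F1 cross (both parents heterozygous at A1 and
#' A2), in integer arithmetic.
#'
#' @param kind Gene-action kind (see [gene_action_model()]).
#' @return Integer vector of class counts out of 16, ordered by class.
#' @export
#' @examples
#' enumerate_f2_classes("epistatic_7_6_3")  # 7 6 3
enumerate_f2_classes <- function(kind) {
  model <- gene_action_model(kind)
  counts <- integer(model$n_classes)
  als <- c("C3", "C5")
  for (m1 in als) for (m2 in als) for (p1 in als) for (p2 in als) {
    gt <- plant_genotype("enum",
                         mat = c(A1 = m1, A2 = m2, B = "THCAS"),
                         pat = c(A1 = p1, A2 = p2, B = "THCAS"))
    k <- phenotype_class(gt, model)
    counts[k] <- counts[k] + 1L
  }
  counts
}

# truncated-normal draw via inverse CDF (seed-stable, no rejection loop);
# vectorized over `mean`
.rtnorm <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd == 0) return(rep_len(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# vectorized phenotype draw for a list of plants
.phenotypes <- function(plants, model) {
  n <- length(plants)
  cls <- vapply(plants, phenotype_class, integer(1), model = model)
  bcl <- vapply(plants, .b_class, integer(1))
  mu <- model$class_means_FC3[cls]
  bmu <- model$b_class_means_Fdi[bcl]
  if (isTRUE(model$skew)) {
    sq <- function(m) {
      100 * stats::plogis(stats::qlogis(pmin(pmax(m, 1e-6), 100 - 1e-6) /
                                          100) +
                            stats::rnorm(n, 0, model$skew_sd))
    }
    fc3 <- sq(mu)
    fdi <- sq(bmu)
  } else {
    fc3 <- .rtnorm(n, mu, model$noise_sd)
    fdi <- .rtnorm(n, bmu, model$b_noise_sd)
  }
  data.frame(F_C3 = fc3, F_dicyclic = fdi, class_alkyl = cls, class_b = bcl)
}

.b_class <- function(genotype) {
  1L + (genotype$mat[["B"]] == "CBDAS") + (genotype$pat[["B"]] == "CBDAS")
}

#' Simulate the chemotype phenotype of a plant
#'
#' F_C3 is the gene-action class mean plus Gaussian noise truncated to
#' `[0, 100]` (or logit-scale noise in skew mode); `F_C5 = 100 - F_C3`.
#' F_dicyclic follows analogously from the B genotype.
#'
#' @param genotype A `plant_genotype`.
#' @param model A `gene_action_model`.
#' @return Named numeric vector `c(F_C3, F_C5, F_dicyclic, F_tricyclic,
#'   class_alkyl, class_b)`.
#' @export
phenotype <- function(genotype, model) {
  k <- phenotype_class(genotype, model)
  bk <- .b_class(genotype)
  mu <- model$class_means_FC3[k]
  bmu <- model$b_class_means_Fdi[bk]
  if (isTRUE(model$skew)) {
    fc3 <- 100 * stats::plogis(stats::qlogis(pmin(pmax(mu, 1e-6), 100 - 1e-6) /
                                               100) +
                                 stats::rnorm(1, 0, model$skew_sd))
    fdi <- 100 * stats::plogis(stats::qlogis(pmin(pmax(bmu, 1e-6),
                                                  100 - 1e-6) / 100) +
                                 stats::rnorm(1, 0, model$skew_sd))
  } else {
    fc3 <- .rtnorm(1, mu, model$noise_sd)
    fdi <- .rtnorm(1, bmu, model$b_noise_sd)
  }
  c(F_C3 = fc3, F_C5 = 100 - fc3, F_dicyclic = fdi, F_tricyclic = 100 - fdi,
    class_alkyl = k, class_b = bk)
}

#' SCAR marker call for the B locus
#'
#' With `marker_r = 0` the call equals the true B genotype; otherwise each
#' haplotype's marker allele derives from a marker locus co-simulated at
#' recombination fraction `marker_r` from B (per-meiosis discordance
#' `marker_r`).
#'
#' @param genotype A `plant_genotype` covering locus B.
#' @param marker_r Marker-to-B recombination fraction in `[0, 0.5]`.
#' @return Genotype call string, one of [b_genotype_levels()].
#' @export
scar_genotype <- function(genotype, marker_r = 0) {
  if (marker_r < 0 || marker_r > 0.5) {
    stop("marker_r must lie in [0, 0.5]", call. = FALSE)
  }
  flip <- function(a) if (a == "THCAS") "CBDAS" else "THCAS"
  call_one <- function(a) {
    if (marker_r > 0 && stats::runif(1) < marker_r) flip(a) else a
  }
  al <- c(call_one(genotype$mat[["B"]]), call_one(genotype$pat[["B"]]))
  paste(sort(al, decreasing = TRUE), collapse = "/")  # THCAS sorts first
}

#' Configuration for an F2 chemotype study simulation
#'
#' Defaults reproduce the study design: homozygous divergent parents
#' (F_C3 anchors 88.3 and 0.8; F_dicyclic anchors 0.9 and 96.1), an F1
#' family of 35, and an F2 of 210 from a single F1 x F1 cross, with
#' duplicate extraction replicates per plant.
#'
#' @param gene_action Gene-action kind or a [gene_action_model()] object
#'   (default `"additive"`, the pentapartite expectation).
#' @param n_f1,n_f2 Family sizes (defaults 35 and 210).
#' @param n_replicates Extraction replicates per plant (default 2).
#' @param loci Ordered locus list (default [default_loci()], unlinked).
#' @param marker_r SCAR marker-to-B recombination fraction (default 0).
#' @param total_content Median total acid-equivalent cannabinoid content
#'   (mg per g fresh weight, default 20).
#' @param total_content_cv Lognormal coefficient of variation of total
#'   content between plants (default 0.25).
#' @param neutral_fraction Share of each pool present as the decarboxylated
#'   neutral form (default 0.1).
#' @param replicate_cv Multiplicative measurement noise per analyte per
#'   replicate (lognormal sd on the log scale, default 0.02).
#' @return Validated `f2_sim_config` object.
#' @export
simulation_config <- function(gene_action = "additive", n_f1 = 35,
                              n_f2 = 210, n_replicates = 2,
                              loci = default_loci(), marker_r = 0,
                              total_content = 20, total_content_cv = 0.25,
                              neutral_fraction = 0.1, replicate_cv = 0.02) {
  model <- if (inherits(gene_action, "gene_action_model")) gene_action
  else gene_action_model(gene_action)
  bad <- character(0)
  if (!is.numeric(n_f1) || n_f1 < 1) bad <- c(bad, "n_f1")
  if (!is.numeric(n_f2) || n_f2 < 1) bad <- c(bad, "n_f2")
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    bad <- c(bad, "n_replicates")
  }
  if (!is.list(loci) || !all(vapply(loci, inherits, logical(1),
                                    "locus_spec")) ||
      !all(c("A1", "A2", "B") %in% .loci_names(loci))) {
    bad <- c(bad, "loci")
  }
  if (!is.numeric(marker_r) || marker_r < 0 || marker_r > 0.5) {
    bad <- c(bad, "marker_r")
  }
  if (!is.numeric(total_content) || total_content <= 0) {
    bad <- c(bad, "total_content")
  }
  if (!is.numeric(total_content_cv) || total_content_cv < 0) {
    bad <- c(bad, "total_content_cv")
  }
  if (!is.numeric(neutral_fraction) || neutral_fraction < 0 ||
      neutral_fraction >= 1) {
    bad <- c(bad, "neutral_fraction")
  }
  if (!is.numeric(replicate_cv) || replicate_cv < 0) {
    bad <- c(bad, "replicate_cv")
  }
  if (length(bad)) {
    stop("invalid simulation config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(model = model, n_f1 = as.integer(n_f1),
                 n_f2 = as.integer(n_f2),
                 n_replicates = as.integer(n_replicates), loci = loci,
                 marker_r = marker_r, total_content = total_content,
                 total_content_cv = total_content_cv,
                 neutral_fraction = neutral_fraction,
                 replicate_cv = replicate_cv),
            class = "f2_sim_config")
}

# split target fractions into the eight analyte contents; compute_fractions
# recovers (fc3, fdi) exactly for any total and neutral share
.contents_from_fractions <- function(fc3, fdi, total, neutral_fraction) {
  p3 <- fc3 / 100
  pdi <- fdi / 100
  eq <- c(CBDVA = total * p3 * pdi, THCVA = total * p3 * (1 - pdi),
          CBDA = total * (1 - p3) * pdi, THCA = total * (1 - p3) * (1 - pdi))
  pairs <- analyte_pairs()
  fac <- stats::setNames(pairs$factor, pairs$acid_name)
  neutral <- eq * neutral_fraction / fac[names(eq)]
  names(neutral) <- pairs$neutral_name[match(names(eq), pairs$acid_name)]
  c(eq * (1 - neutral_fraction), neutral)
}

#' Simulate a full F2 chemotype inheritance study
#'
#' Builds homozygous divergent parents (P1: C3/tricyclic extreme, P2:
#' C5/dicyclic extreme), an F1 family, and an F2 population from a single
#' F1 male x F1 female cross; phenotypes each plant under the configured
#' gene-action model; calls the SCAR genotype; and emits a plant table in
#' the pipeline's delimited input format with per-replicate analyte
#' contents. Deterministic given `seed`.
#'
#' @param config An `f2_sim_config` (default [simulation_config()]).
#' @param seed Integer seed for all randomness (default 1).
#' @return Object of class `f2_study`: list with `config`, `seed`,
#'   `parents`, `f1`, `f2` (lists of `plant_genotype`), `truth` (per-plant
#'   true classes and fractions) and `table` (the plant table, one row per
#'   plant per replicate).
#' @export
simulate_f2_study <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "f2_sim_config"))
  set.seed(seed)
  model <- config$model
  loci <- config$loci
  nm <- .loci_names(loci)

  hap <- function(a, b_allele) {
    stats::setNames(ifelse(nm == "B", b_allele, a), nm)
  }
  p1 <- plant_genotype("P1", hap("C3", "THCAS"), hap("C3", "THCAS"),
                       sex = "F", generation = "P1")
  p2 <- plant_genotype("P2", hap("C5", "CBDAS"), hap("C5", "CBDAS"),
                       sex = "M", generation = "P2")
  f1 <- cross(p1, p2, config$n_f1, loci, id_prefix = "F1")
  # a single female and male F1 plant serve as F2 parents
  sex_f1 <- vapply(f1, `[[`, character(1), "sex")
  i_f <- which(sex_f1 == "F")[1]
  i_m <- which(sex_f1 == "M")[1]
  if (is.na(i_f)) i_f <- 1L
  if (is.na(i_m)) i_m <- if (length(f1) > 1) 2L else 1L
  f2 <- cross(f1[[i_f]], f1[[i_m]], config$n_f2, loci, id_prefix = "F2")

  plants <- c(list(p1, p2), f1, f2)
  n <- length(plants)
  ph <- .phenotypes(plants, model)
  scar <- vapply(plants, scar_genotype, character(1),
                 marker_r = config$marker_r)
  totals <- config$total_content *
    exp(stats::rnorm(n, 0, config$total_content_cv))
  contents <- t(vapply(seq_len(n), function(i) {
    .contents_from_fractions(ph$F_C3[i], ph$F_dicyclic[i], totals[i],
                             config$neutral_fraction)
  }, numeric(8)))

  truth <- data.frame(
    plant_id = vapply(plants, `[[`, character(1), "plant_id"),
    generation = vapply(plants, `[[`, character(1), "generation"),
    sex = vapply(plants, `[[`, character(1), "sex"),
    class_alkyl = ph$class_alkyl, class_b = ph$class_b,
    b_genotype_true = vapply(plants, function(p) {
      paste(sort(c(p$mat[["B"]], p$pat[["B"]]), decreasing = TRUE),
            collapse = "/")
    }, character(1)),
    F_C3 = ph$F_C3, F_dicyclic = ph$F_dicyclic,
    stringsAsFactors = FALSE)

  reps <- config$n_replicates
  ridx <- rep(seq_len(n), each = reps)
  obs <- contents[ridx, , drop = FALSE] *
    exp(matrix(stats::rnorm(n * reps * 8, 0, config$replicate_cv),
               nrow = n * reps))
  tbl <- data.frame(plant_id = truth$plant_id[ridx],
                    generation = truth$generation[ridx],
                    replicate = rep(seq_len(reps), times = n),
                    sex = truth$sex[ridx], b_genotype = scar[ridx],
                    stringsAsFactors = FALSE)
  tbl[, colnames(contents)] <- obs
  rownames(tbl) <- NULL

  structure(list(config = config, seed = seed,
                 parents = list(P1 = p1, P2 = p2), f1 = f1, f2 = f2,
                 truth = truth, table = tbl),
            class = "f2_study")
}

#' @export
print.f2_study <- function(x, ...) {
  cat(sprintf(
    "Simulated F2 chemotype study (seed %d): %s gene action\n",
    x$seed, x$config$model$kind))
  cat(sprintf("  P1/P2 + %d F1 + %d F2 plants, %d replicate(s) each\n",
              length(x$f1), length(x$f2), x$config$n_replicates))
  invisible(x)
}
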