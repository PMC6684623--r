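# Cross simulator: meiosis, linkage, gene action, phenotype noise, SCAR
# marker calls and whole-study generation.

test_that("gametes respect the linkage limits", {
  # homozygous parent: gamete identical at every locus regardless of r
  loci <- default_loci()
  hom <- plant_genotype("P", c(A1 = "C3", A2 = "C3", B = "THCAS"),
                        c(A1 = "C3", A2 = "C3", B = "THCAS"))
  set.seed(31)
  for (i in 1:20) {
    expect_equal(unname(make_gamete(hom, loci)), c("C3", "C3", "THCAS"))
  }

  # complete linkage: alleles co-segregate in every gamete
  linked <- list(locus_spec("A1", c("C3", "C5"), "LG1"),
                 locus_spec("A2", c("C3", "C5"), "LG2"),
                 locus_spec("B", c("THCAS", "CBDAS"), "LG2", 0))
  het <- f1_het(loci = linked)
  set.seed(32)
  for (i in 1:100) {
    g <- make_gamete(het, linked)
    expect_true((g[["A2"]] == "C3") == (g[["B"]] == "THCAS"))
  }
})

test_that("unlinked loci co-segregate at frequency 1/2", {
  set.seed(33)
  het <- f1_het()
  g <- alkylseg:::.sim_gametes(het, default_loci(), 10000)
  parental <- (g[, "A1"] == "C3") == (g[, "B"] == "THCAS")
  expect_lt(abs(mean(parental) - 0.5), 0.02)
})

test_that("configured recombination fractions are recovered from meioses", {
  r_true <- 0.2
  loci <- list(locus_spec("A1", c("C3", "C5"), "LG1"),
               locus_spec("A2", c("C3", "C5"), "LG2"),
               locus_spec("B", c("THCAS", "CBDAS"), "LG2", r_true))
  set.seed(34)
  g <- alkylseg:::.sim_gametes(f1_het(loci = loci), loci, 10000)
  recomb <- (g[, "A2"] == "C3") != (g[, "B"] == "THCAS")
  se <- sqrt(r_true * (1 - r_true) / 10000)
  expect_lt(abs(mean(recomb) - r_true), 3 * se)
})

test_that("crosses produce legal offspring with Mendelian frequencies", {
  loci <- default_loci()
  p1 <- plant_genotype("P1", c(A1 = "C3", A2 = "C3", B = "THCAS"),
                       c(A1 = "C3", A2 = "C3", B = "THCAS"), sex = "F")
  p2 <- plant_genotype("P2", c(A1 = "C5", A2 = "C5", B = "CBDAS"),
                       c(A1 = "C5", A2 = "C5", B = "CBDAS"), sex = "M")
  set.seed(35)
  f1 <- cross(p1, p2, 30, loci, id_prefix = "F1")
  for (pl in f1) {
    expect_equal(unname(pl$mat), c("C3", "C3", "THCAS"))
    expect_equal(unname(pl$pat), c("C5", "C5", "CBDAS"))
  }

  # F1 x F1: genotype frequencies 1:2:1 at an unlinked biallelic locus
  set.seed(36)
  f2 <- cross(f1[[1]], f1[[2]], 10000, loci)
  dosage <- vapply(f2, function(p) {
    (p$mat[["B"]] == "CBDAS") + (p$pat[["B"]] == "CBDAS")
  }, numeric(1))
  counts <- tabulate(dosage + 1, nbins = 3)
  f <- chi_square_gof(counts, c(1, 2, 1), alpha = 0.01)
  expect_true(f$h0_accepted)
})

test_that("complete A1-B linkage pins the A1 genotype of B homozygotes", {
  loci <- list(locus_spec("A2", c("C3", "C5"), "LG2"),
               locus_spec("A1", c("C3", "C5"), "LG1"),
               locus_spec("B", c("THCAS", "CBDAS"), "LG1", 0))
  set.seed(37)
  f2 <- cross(f1_het("m", loci), f1_het("f", loci), 500, loci)
  for (pl in f2) {
    if (pl$mat[["B"]] == "CBDAS" && pl$pat[["B"]] == "CBDAS") {
      expect_equal(unname(c(pl$mat[["A1"]], pl$pat[["A1"]])), c("C5", "C5"))
    }
  }
})

test_that("enumerated gene-action class probabilities are the named ratios", {
  expect_identical(enumerate_f2_classes("additive"), c(1L, 4L, 6L, 4L, 1L))
  expect_identical(enumerate_f2_classes("digenic_dominant"),
                   c(9L, 3L, 3L, 1L))
  expect_identical(enumerate_f2_classes("epistatic_7_6_3"), c(7L, 6L, 3L))
})

test_that("double homozygotes sit in the extreme phenotype classes", {
  hi <- plant_genotype("hi", c(A1 = "C3", A2 = "C3", B = "THCAS"),
                       c(A1 = "C3", A2 = "C3", B = "THCAS"))
  lo <- plant_genotype("lo", c(A1 = "C5", A2 = "C5", B = "CBDAS"),
                       c(A1 = "C5", A2 = "C5", B = "CBDAS"))
  for (kind in c("additive", "digenic_dominant", "epistatic_7_6_3")) {
    m <- gene_action_model(kind)
    expect_equal(phenotype_class(hi, m), m$n_classes)
    expect_equal(phenotype_class(lo, m), 1L)
  }
})

test_that("noise-free phenotypes equal the class means and noise is truncated", {
  m0 <- gene_action_model("additive", noise_sd = 0, b_noise_sd = 0)
  het <- f1_het()
  ph <- phenotype(het, m0)
  expect_equal(ph[["F_C3"]], m0$class_means_FC3[3])
  expect_equal(ph[["F_C5"]], 100 - m0$class_means_FC3[3])
  expect_equal(ph[["F_dicyclic"]], m0$b_class_means_Fdi[2])

  # a near-boundary class never produces negative fractions
  mlow <- gene_action_model("epistatic_7_6_3", noise_sd = 2)
  lo <- plant_genotype("lo", c(A1 = "C5", A2 = "C5", B = "CBDAS"),
                       c(A1 = "C5", A2 = "C5", B = "CBDAS"))
  set.seed(38)
  draws <- replicate(500, phenotype(lo, mlow)[["F_C3"]])
  expect_true(all(draws >= 0 & draws <= 100))
})

test_that("per-class phenotype means are recovered for interior classes", {
  # interior class means avoid truncation bias at the [0, 100] bounds
  m <- gene_action_model("additive", class_means_FC3 = seq(10, 90, 20),
                         noise_sd = 3,
                         b_class_means_Fdi = c(20, 50, 80), b_noise_sd = 3)
  set.seed(39)
  f2 <- cross(f1_het("a"), f1_het("b"), 210, default_loci())
  cls <- vapply(f2, phenotype_class, integer(1), model = m)
  fc3 <- vapply(f2, function(p) phenotype(p, m)[["F_C3"]], numeric(1))
  for (k in 1:5) {
    nk <- sum(cls == k)
    if (nk >= 5) {
      expect_lt(abs(mean(fc3[cls == k]) - m$class_means_FC3[k]),
                3 * 3 / sqrt(nk))
    }
  }
})

test_that("SCAR calls track the B locus at the configured marker distance", {
  het <- f1_het()
  expect_equal(scar_genotype(het, 0), "THCAS/CBDAS")
  hom <- plant_genotype("h", c(A1 = "C3", A2 = "C3", B = "THCAS"),
                        c(A1 = "C3", A2 = "C3", B = "THCAS"))
  expect_equal(scar_genotype(hom, 0), "THCAS/THCAS")
  # calls are always one of the three genotype levels
  set.seed(40)
  calls <- replicate(50, scar_genotype(hom, 0.5))
  expect_true(all(calls %in% b_genotype_levels()))

  # per-meiosis discordance equals marker_r
  set.seed(41)
  n <- 5000
  discordant <- replicate(n, {
    cl <- scar_genotype(hom, 0.1)
    sum(strsplit(cl, "/", fixed = TRUE)[[1]] == "CBDAS")
  })
  rate <- sum(discordant) / (2 * n)
  expect_lt(abs(rate - 0.1), 0.01)
})

test_that("a default study has the published population structure", {
  study <- simulate_f2_study(seed = 42)
  expect_equal(length(study$f2), 210)
  expect_equal(length(study$f1), 35)
  expect_equal(sum(study$truth$generation == "F2"), 210)
  expect_equal(nrow(study$table), 2 * (2 + 35 + 210))
  # parents anchored near the divergent chemotype extremes
  p1 <- study$truth$F_C3[study$truth$generation == "P1"]
  p2 <- study$truth$F_C3[study$truth$generation == "P2"]
  expect_lt(abs(p1 - 88.3), 3 * 4.5)
  expect_lt(abs(p2 - 0.8), 3 * 4.5)
  # every F2 haplotype allele is a parental allele
  for (pl in study$f2[1:20]) {
    expect_true(all(pl$mat[c("A1", "A2")] %in% c("C3", "C5")))
    expect_true(all(c(pl$mat[["B"]], pl$pat[["B"]]) %in%
                      c("THCAS", "CBDAS")))
  }
})

test_that("studies are deterministic given the seed", {
  s1 <- simulate_f2_study(seed = 43)
  s2 <- simulate_f2_study(seed = 43)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_f2_study(seed = 44)
  expect_false(identical(s1$table, s3$table))
})

test_that("F2 allele frequencies are conserved near one half", {
  for (seed in 1:5) {
    study <- simulate_f2_study(simulation_config(n_f1 = 10, n_replicates = 1),
                               seed = seed)
    se <- sqrt(0.25 / (2 * 210))
    for (locus in c("A1", "A2", "B")) {
      ref <- if (locus == "B") "THCAS" else "C3"
      freq <- mean(vapply(study$f2, function(p) {
        ((p$mat[[locus]] == ref) + (p$pat[[locus]] == ref)) / 2
      }, numeric(1)))
      expect_lt(abs(freq - 0.5), 3 * se + 1e-9)
    }
  }
})

test_that("alkyl class and B genotype factorize when loci are unlinked", {
  set.seed(45)
  m <- gene_action_model("digenic_dominant")
  rejections <- 0
  for (i in 1:10) {
    f2 <- cross(f1_het("a"), f1_het("b"), 10000, default_loci())
    cls <- vapply(f2, phenotype_class, integer(1), model = m)
    bcl <- vapply(f2, alkylseg:::.b_class, integer(1))
    p <- suppressWarnings(stats::chisq.test(table(cls, bcl))$p.value)
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 1)
})

test_that("tight A1-B linkage distorts genotype-conditioned class ratios", {
  loci <- list(locus_spec("A2", c("C3", "C5"), "LG2"),
               locus_spec("A1", c("C3", "C5"), "LG1"),
               locus_spec("B", c("THCAS", "CBDAS"), "LG1", 0.01))
  m <- gene_action_model("epistatic_7_6_3")
  set.seed(46)
  f2 <- cross(f1_het("a", loci), f1_het("b", loci), 4000, loci)
  cls <- vapply(f2, phenotype_class, integer(1), model = m)
  bcl <- vapply(f2, alkylseg:::.b_class, integer(1))
  # within THCAS homozygotes, A1 is almost always C3/C3 (coupling), so the
  # pooled 7:6:3 expectation collapses toward the A2-driven 1:2:1
  counts <- tabulate(cls[bcl == 1], nbins = 3)
  f <- suppressWarnings(chi_square_gof(counts,
                                       segregation_ratios()$epistatic_7_6_3))
  expect_false(f$h0_accepted)
  f121 <- chi_square_gof(counts, c(1, 2, 1), alpha = 0.01)
  expect_true(f121$h0_accepted)
})

test_that("invalid simulation configurations name the offending fields", {
  expect_error(simulation_config(n_f2 = 0), "n_f2")
  expect_error(simulation_config(marker_r = 0.7), "marker_r")
  expect_error(simulation_config(neutral_fraction = 1), "neutral_fraction")
  expect_error(gene_action_model("additive", class_means_FC3 = c(1, 2)),
               "5 class means")
  expect_error(gene_action_model("additive",
                                 class_means_FC3 = c(5, 4, 3, 2, 1)),
               "increasing")
})
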