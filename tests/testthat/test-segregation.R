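# Segregation model tests: Pearson goodness-of-fit, critical values,
# Bartlett from summaries, and the genotype-conditioned analysis.

test_that("the ratio registry holds exactly the four genetic models", {
  r <- segregation_ratios()
  expect_setequal(names(r), c("monogenic_codominant", "digenic_additive",
                              "digenic_dominant", "epistatic_7_6_3"))
  expect_equal(r$monogenic_codominant$terms, c(1L, 2L, 1L))
  expect_equal(r$digenic_additive$terms, c(1L, 4L, 6L, 4L, 1L))
  expect_equal(r$digenic_dominant$terms, c(9L, 3L, 3L, 1L))
  expect_equal(r$epistatic_7_6_3$terms, c(7L, 6L, 3L))
})

test_that("goodness-of-fit has the Pearson form with df = k - 1", {
  # counts exactly proportional to the terms
  f <- chi_square_gof(c(90, 30, 30, 10), segregation_ratios()$digenic_dominant)
  expect_equal(f$chi2, 0)
  expect_true(f$h0_accepted)
  expect_equal(f$df, 3)
  expect_equal(sum(f$expected), sum(f$observed), tolerance = 1e-12)

  # invariant to scaling the ratio terms
  f1 <- suppressWarnings(chi_square_gof(c(26, 6, 7, 5), c(9, 3, 3, 1)))
  f2 <- suppressWarnings(chi_square_gof(c(26, 6, 7, 5), c(18, 6, 6, 2)))
  expect_equal(f1$chi2, f2$chi2)

  # shape mismatch is an error, not a silent aggregation
  expect_error(chi_square_gof(c(1, 2, 3, 4),
                              segregation_ratios()$epistatic_7_6_3),
               "4 categories")
  expect_error(chi_square_gof(numeric(0), c(1, 2)), "categories")
  expect_warning(chi_square_gof(c(26, 6, 7, 5), c(9, 3, 3, 1)), "below 5")
})

test_that("decisions are consistent across chi2, p-value and critical value", {
  set.seed(21)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    terms <- sample(1:9, k, replace = TRUE)
    obs <- stats::rmultinom(1, 120, terms / sum(terms))[, 1]
    f <- suppressWarnings(chi_square_gof(obs, terms))
    expect_equal(f$h0_accepted, f$p_value >= f$alpha)
    expect_equal(f$h0_accepted, f$chi2 <= f$critical_value)
    expect_gte(f$chi2, 0)
  }
})

test_that("chi2 grows as a count moves from its expectation", {
  # hold N fixed by compensating in the last cell
  base <- c(50, 100, 50)
  prev <- -1
  for (shift in c(0, 5, 10, 20)) {
    obs <- base + c(shift, 0, -shift)
    f <- chi_square_gof(obs, c(1, 2, 1))
    expect_gt(f$chi2, prev)
    prev <- f$chi2
  }
})

test_that("critical values match tabulated chi-squared quantiles", {
  expect_equal(round(chi_square_critical(3, 0.05), 3), 7.815)
  expect_equal(round(chi_square_critical(2, 0.05), 3), 5.991)
  expect_equal(chi_square_critical(1, 1), 0)
  expect_error(chi_square_critical(0, 0.05), ">= 1")
  expect_error(chi_square_critical(2, 0), "alpha")
})

test_that("Bartlett from summaries matches the raw-data computation", {
  set.seed(22)
  g <- factor(rep(1:4, times = c(35, 34, 16, 27)))
  x <- stats::rnorm(length(g), 0, c(1, 1.4, 1.2, 2)[as.integer(g)])
  raw <- stats::bartlett.test(x, g)
  vs <- tapply(x, g, stats::var)
  dfs <- tabulate(g) - 1
  b <- bartlett_from_summaries(vs, dfs)
  expect_equal(b$chi2, unname(raw$statistic), tolerance = 1e-9)
  expect_equal(b$df, unname(raw$parameter))
  expect_equal(b$p_value, raw$p.value, tolerance = 1e-9)
})

test_that("Bartlett degenerate and error cases behave", {
  expect_equal(bartlett_from_summaries(c(3, 3, 3), c(10, 20, 5))$chi2, 0)
  expect_error(bartlett_from_summaries(c(0, 2), c(5, 5)), "zero variance")
  expect_error(bartlett_from_summaries(c(1), c(5)), ">= 2 groups")
  expect_error(bartlett_from_summaries(c(1, 2), c(0, 5)), ">= 1")
})

test_that("the B-locus monogenic test is the 1:2:1 goodness-of-fit", {
  f <- b_locus_monogenic_test(c(25, 50, 25))
  expect_equal(f$chi2, 0)
  f2 <- b_locus_monogenic_test(c(0, 0, 100))
  expect_equal(f2$chi2, 300)
  expect_false(f2$h0_accepted)
  expect_error(b_locus_monogenic_test(c(1, 2)), "three genotype counts")
})

test_that("a model plan on forced counts reproduces per-genotype decisions", {
  counts <- list("CBDAS/CBDAS" = c(26, 6, 7, 5),
                 "THCAS/CBDAS" = c(44, 42, 9, 21),
                 "THCAS/THCAS" = c(21, 22, 7))
  res <- run_model_plan(counts, default_model_plan())
  decisions <- vapply(res, function(r) r[[1]]$h0_accepted, logical(1))
  expect_equal(unname(decisions), c(TRUE, FALSE, TRUE))
  # 7:6:3 on a quadripartite subset must surface as a shape condition
  res2 <- run_model_plan(list("THCAS/CBDAS" = c(44, 42, 9, 21)),
                         list("THCAS/CBDAS" =
                                segregation_ratios()$epistatic_7_6_3))
  expect_type(res2[["THCAS/CBDAS"]][[1]], "character")
})

test_that("conditioning on a single genotype reduces to the global analysis", {
  set.seed(23)
  vals <- mixture_sample(c(10, 40, 70), 2.5, 20)
  geno <- rep("THCAS/THCAS", length(vals))
  plan <- list("THCAS/THCAS" = segregation_ratios()$epistatic_7_6_3)
  cond <- genotype_conditioned_segregation(vals, geno, plan)
  global <- demarcate(estimate_density(vals))
  expect_equal(as.numeric(cond[["THCAS/THCAS"]]$counts),
               as.numeric(global$counts))
  f <- cond[["THCAS/THCAS"]]$fits[[1]]
  expect_s3_class(f, "gof_result")
  expect_equal(f$observed, as.numeric(global$counts))
})

test_that("small genotype classes are skipped and unscored plants excluded", {
  set.seed(24)
  vals <- c(mixture_sample(c(20, 70), 2, 10), stats::rnorm(3, 50, 2))
  geno <- c(rep("CBDAS/CBDAS", 20), rep("THCAS/THCAS", 2), NA)
  plan <- list("CBDAS/CBDAS" = segregation_ratios()$monogenic_codominant,
               "THCAS/THCAS" = segregation_ratios()$epistatic_7_6_3)
  expect_warning(
    cond <- genotype_conditioned_segregation(vals, geno, plan),
    "skipped")
  expect_true(cond[["THCAS/THCAS"]]$skipped)
  expect_equal(attr(cond, "n_unscored"), 1)
})

test_that("global-mode conditioning reuses population boundaries", {
  set.seed(25)
  vals <- mixture_sample(c(15, 85), 2, 30)
  geno <- rep(c("CBDAS/CBDAS", "THCAS/THCAS"), 30)
  cats <- demarcate(estimate_density(vals))
  plan <- list("CBDAS/CBDAS" = segregation_ratios()$monogenic_codominant)
  cond <- genotype_conditioned_segregation(vals, geno, plan, mode = "global",
                                           categories = cats)
  expect_equal(sum(cond[["CBDAS/CBDAS"]]$counts), 30)
  expect_error(genotype_conditioned_segregation(vals, geno, plan,
                                                mode = "global"),
               "requires `categories`")
})
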