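# Shared fixtures: all synthetic, generated in code under fixed seeds.

# Gaussian mixture sample with equal component sizes
mixture_sample <- function(means, sd, n_per) {
  unlist(lapply(means, function(m) stats::rnorm(n_per, m, sd)))
}

# nearest-component-mean classification oracle
nearest_mean_class <- function(values, means) {
  vapply(values, function(v) which.min(abs(v - means)), integer(1))
}

# minimal plant table where F_C3 equals `fc3` and F_dicyclic equals `fdi`
# exactly (acid forms only, so no decarboxylation correction enters)
make_plant_table <- function(fc3, fdi, generation = "F2",
                             ids = sprintf("PL%03d", seq_along(fc3)),
                             replicate = 1L, b_genotype = NULL) {
  total <- 20
  p3 <- fc3 / 100
  pdi <- fdi / 100
  tbl <- data.frame(plant_id = ids, generation = generation,
                    replicate = replicate,
                    CBDVA = total * p3 * pdi,
                    THCVA = total * p3 * (1 - pdi),
                    CBDA = total * (1 - p3) * pdi,
                    THCA = total * (1 - p3) * (1 - pdi),
                    CBDV = 0, THCV = 0, CBD = 0, THC = 0,
                    stringsAsFactors = FALSE)
  if (!is.null(b_genotype)) tbl$b_genotype <- b_genotype
  tbl
}

# F1 x F1 double heterozygote (coupling phase C3-THCAS on the maternal side)
f1_het <- function(id = "F1", loci = default_loci()) {
  nm <- vapply(loci, `[[`, character(1), "name")
  mat <- setNames(ifelse(nm == "B", "THCAS", "C3"), nm)
  pat <- setNames(ifelse(nm == "B", "CBDAS", "C5"), nm)
  plant_genotype(id, mat, pat)
}
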