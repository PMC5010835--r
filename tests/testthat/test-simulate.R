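canon_gt <- function(s) {
  vapply(strsplit(s, "/", fixed = TRUE),
         function(x) paste(sort(x), collapse = "/"), character(1))
}

test_that("mendelian_transmit draws each parental allele with probability
           one half", {
  n <- 10000
  set.seed(101)
  # autosome, mother 0/1 x father 0/0 -> child 0/0 or 0/1, each 1/2
  kids <- replicate(n, sum(mendelian_transmit(c(0L, 1L), c(0L, 0L),
                                              "1", "female")))
  p <- mean(kids == 1)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / n))
  # X, mother 0/1, father 0: daughter het with prob 1/2, son alt with prob 1/2
  daughters <- replicate(n, sum(mendelian_transmit(c(0L, 1L), 0L,
                                                   "X", "female")))
  expect_lt(abs(mean(daughters == 1) - 0.5), 3 * sqrt(0.25 / n))
  sons <- replicate(n, mendelian_transmit(c(0L, 1L), 0L, "X", "male"))
  expect_true(all(lengths(replicate(5, mendelian_transmit(c(0L, 1L), 0L, "X",
                                                          "male"),
                                    simplify = FALSE)) == 1))
  expect_lt(abs(mean(sons == 1) - 0.5), 3 * sqrt(0.25 / n))
  # forced transmission
  expect_equal(mendelian_transmit(c(1L, 1L), c(1L, 1L), "2", "male"),
               c(1L, 1L))
  # contract violations
  expect_error(mendelian_transmit(c(0L, 1L), c(0L, 1L), "X", "female"),
               class = "quadprio_invalid_transmit")
  expect_error(mendelian_transmit(c(0L, NA), c(0L, 0L), "1", "male"),
               class = "quadprio_invalid_transmit")
})

test_that("simulate_quad is byte-identical for a fixed seed", {
  p <- simulation_params(n_background_sites = 120, seed = 33)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  s1 <- simulate_quad(p, d1)
  s2 <- simulate_quad(p, d2)
  for (f in names(s1$paths)) {
    expect_identical(readLines(s1$paths[[f]]), readLines(s2$paths[[f]]))
  }
  s3 <- simulate_quad(simulation_params(n_background_sites = 120, seed = 34),
                      file.path(tempdir(), "simC"))
  expect_false(identical(readLines(s1$paths$vcf), readLines(s3$paths$vcf)))
})

test_that("every planted variant appears exactly once in the emitted VCF and
           its gene is on the emitted gene list", {
  sim <- simulate_quad(simulation_params(n_background_sites = 200,
                                         planted = c(dominant_de_novo = 2,
                                                     autosomal_recessive = 1,
                                                     compound_het = 2,
                                                     x_linked = 1),
                                         seed = 5),
                       file.path(tempdir(), "simD"))
  vcf <- readLines(sim$paths$vcf)
  body <- vcf[!startsWith(vcf, "#")]
  cols <- strsplit(body, "\t", fixed = TRUE)
  keys <- vapply(cols, function(x)
    sprintf("%s:%s:%s>%s", x[1], x[2], x[4], x[5]), character(1))
  expect_equal(nrow(sim$truth), 2 + 1 + 4 + 1)
  for (k in sim$truth$key) expect_equal(sum(keys == k), 1L)
  genes <- readLines(sim$paths$genes)
  expect_true(all(sim$truth$gene %in% genes))
})

test_that("error-free emission matches the truth genotypes; degenerate error
           rate 1 still runs", {
  sim <- simulate_quad(simulation_params(n_background_sites = 150,
                                         genotype_error_rate = 0,
                                         missing_rate = 0, seed = 8),
                       file.path(tempdir(), "simE"))
  for (r in c("proband", "mother", "father", "sibling")) {
    em <- canon_gt(quadprio:::geno_string(sim$emitted, r))
    expect_identical(em, canon_gt(sim$truth_geno[, r]))
  }
  expect_no_error(simulate_quad(
    simulation_params(n_background_sites = 50, genotype_error_rate = 1,
                      seed = 9),
    file.path(tempdir(), "simF")))
})

test_that("simulated inputs round-trip through the pipeline loaders", {
  sim <- simulate_quad(simulation_params(n_background_sites = 80, seed = 21),
                       file.path(tempdir(), "simG"))
  ped <- load_pedigree(sim$paths$ped)
  expect_equal(ped["proband", "sex"], "female")
  expect_equal(ped["sibling", "sex"], "male")
  qv <- read_quad_vcf(sim$paths$vcf, ped)
  expect_equal(nrow(qv$sites), 80 + nrow(sim$truth))
  lookup <- load_annotation_table(sim$paths$annotations)
  av <- annotate(qv, lookup)
  expect_equal(sum(is.na(av$ann$gene)), 0L)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_params(genotype_error_rate = 1.5),
               class = "quadprio_invalid_params")
  expect_error(simulation_params(n_background_sites = -1),
               class = "quadprio_invalid_params")
  expect_error(simulation_params(planted = c(bogus_model = 1)),
               class = "quadprio_invalid_params")
  expect_error(simulation_params(mean_depth = 0),
               class = "quadprio_invalid_params")
})
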