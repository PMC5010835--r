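test_that("multiallelic sites decompose into biallelic records that conserve
           alt alleles", {
  df <- data.frame(chrom = "1", pos = 100, ref = "A", alt = "G,T",
                   gt_proband = "1/2", gt_mother = "0/1", gt_father = "2/2",
                   gt_sibling = "0/0", stringsAsFactors = FALSE)
  qv <- read_test_quad(df)
  expect_equal(qv_n <- nrow(qv$sites), 2L)
  expect_equal(qv$sites$alt, c("G", "T"))
  # A->G record: proband carries {1, missing}; A->T record: {missing, 1}
  g <- which(qv$sites$alt == "G"); t <- which(qv$sites$alt == "T")
  expect_equal(unname(c(qv$a1[g, "proband"], qv$a2[g, "proband"])),
               c(1L, NA_integer_))
  expect_equal(unname(c(qv$a1[t, "proband"], qv$a2[t, "proband"])),
               c(NA_integer_, 1L))
  # father 2/2 -> hom-alt in the T record, fully missing in the G record
  expect_equal(unname(c(qv$a1[t, "father"], qv$a2[t, "father"])), c(1L, 1L))
  expect_true(all(is.na(c(qv$a1[g, "father"], qv$a2[g, "father"]))))

  # property: each sample's non-missing alt allele lands in exactly one record
  set.seed(11)
  gts <- c("0/0", "0/1", "0/2", "1/1", "1/2", "2/2")
  for (i in 1:15) {
    df2 <- data.frame(chrom = "1", pos = 500, ref = "A", alt = "C,G",
                      gt_proband = sample(gts, 1), gt_mother = sample(gts, 1),
                      gt_father = sample(gts, 1), gt_sibling = sample(gts, 1),
                      stringsAsFactors = FALSE)
    qv2 <- read_test_quad(df2)
    for (role in c("proband", "mother", "father", "sibling")) {
      raw <- strsplit(df2[[paste0("gt_", role)]], "/")[[1]]
      n_alt_in <- sum(raw %in% c("1", "2"))
      n_alt_out <- sum(c(qv2$a1[, role], qv2$a2[, role]) == 1L, na.rm = TRUE)
      expect_equal(n_alt_out, n_alt_in)
    }
  }
})

test_that("male chrX calls normalize to the full hemizygosity table", {
  male_gts <- c("0/0", "0/1", "1/0", "1/1", "0", "1", ".", "./.", "0|1")
  # expected normalized (allele, ploidy): het male X is invalid -> missing
  expected_allele <- c(0L, NA, NA, 1L, 0L, 1L, NA, NA, NA)
  df <- data.frame(chrom = "X", pos = seq_along(male_gts) * 100,
                   ref = "G", alt = "A",
                   gt_proband = "0/1", gt_mother = "0/1",
                   gt_father = male_gts, gt_sibling = "0",
                   stringsAsFactors = FALSE)
  qv <- suppressWarnings(read_test_quad(df))
  ord <- order(df$pos)
  expect_equal(unname(qv$a1[, "father"]), expected_allele[ord])
  expect_true(all(qv$ploidy[, "father"] == 1L))
  expect_true(all(is.na(qv$a2[, "father"])))
  # female proband stays diploid on X
  expect_true(all(qv$ploidy[, "proband"] == 2L))
  expect_warning(read_test_quad(df), "invalid for sample sex")
})

test_that("chromosome labels normalize and records come back sorted", {
  df <- data.frame(chrom = c("chrX", "chr2", "2", "chr10"),
                   pos = c(50, 900, 100, 70), ref = "A", alt = "G",
                   gt_proband = "0/1", gt_mother = "0/0", gt_father = "0/0",
                   gt_sibling = "0/0", stringsAsFactors = FALSE)
  qv <- read_test_quad(df)
  expect_equal(qv$sites$chrom, c("2", "2", "10", "X"))
  expect_equal(qv$sites$pos, c(100L, 900L, 70L, 50L))
})

test_that("read -> write -> read is the identity on normalized records", {
  df <- data.frame(chrom = c("1", "7", "X", "X"), pos = c(10, 20, 30, 40),
                   id = c("rs1", ".", "rs3", "."), ref = c("A", "C", "G", "T"),
                   alt = c("G", "T", "A", "C"),
                   gt_proband = c("0/1", "1/1", "0/1", "0/0"),
                   gt_mother = c("0/0", "0/1", "0/1", "0/1"),
                   gt_father = c("0/1", "0/1", "0", "1"),
                   gt_sibling = c("./.", "0/1", "1", "0"),
                   stringsAsFactors = FALSE)
  qv <- read_test_quad(df)
  path <- tempfile(fileext = ".vcf")
  write_quad_vcf(qv, path)
  back <- read_quad_vcf(path, test_ped())
  for (f in c("sites", "a1", "a2", "ploidy", "gq", "dp"))
    expect_identical(back[[f]], qv[[f]])
})

test_that("genotype_equal is an unordered comparison where missing never
           matches", {
  expect_true(genotype_equal(c(0, 1), c(1, 0)))
  expect_false(genotype_equal(c(0, 1), c(1, 1)))
  expect_false(genotype_equal(c(0, NA), c(0, 1)))
  expect_false(genotype_equal(c(0), c(0, 0)))   # ploidy mismatch
  # symmetry and reflexivity on missing-free calls
  calls <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L), 0L, 1L)
  for (a in calls) for (b in calls) {
    expect_identical(genotype_equal(a, b), genotype_equal(b, a))
  }
  for (a in calls) expect_true(genotype_equal(a, a))
})

test_that("missing samples and absent GT are classed errors; symbolic alleles
           are skipped", {
  df <- data.frame(chrom = "1", pos = 1, ref = "A", alt = "G",
                   gt_proband = "0/1", gt_mother = "0/0", gt_father = "0/0",
                   gt_sibling = "0/0", stringsAsFactors = FALSE)
  path <- write_test_vcf(df)
  other <- quad_pedigree(c("NOPE", "MOTHER", "FATHER", "SIB"),
                         c("proband", "mother", "father", "sibling"),
                         c("female", "female", "male", "male"),
                         c(TRUE, FALSE, FALSE, FALSE))
  expect_error(read_quad_vcf(path, other), class = "quadprio_sample_not_in_vcf")

  nogt <- tempfile(fileext = ".vcf")
  lines <- readLines(path)
  lines[length(lines)] <- gsub("GT:GQ:DP", "GQ:DP", gsub("0/[01]:", "",
                                                         lines[length(lines)]))
  writeLines(lines, nogt)
  expect_error(read_quad_vcf(nogt, test_ped()), class = "quadprio_gt_required")

  sym <- data.frame(chrom = "1", pos = c(5, 9), ref = "A",
                    alt = c("<DEL>", "G"),
                    gt_proband = c("0/1", "0/1"), gt_mother = "0/0",
                    gt_father = "0/0", gt_sibling = "0/0",
                    stringsAsFactors = FALSE)
  expect_warning(qv <- read_test_quad(sym), "symbolic")
  expect_equal(nrow(qv$sites), 1L)
  expect_equal(qv$sites$alt, "G")
})

test_that("an empty VCF yields an empty record set", {
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf_header(test_ped()$sample_id), path)
  qv <- read_quad_vcf(path, test_ped())
  expect_equal(nrow(qv$sites), 0L)
})
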