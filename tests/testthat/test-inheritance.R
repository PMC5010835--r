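quad_gts <- function(p, m, f, s, chrom = "1", pos = 10, gene = "GENE1",
                     maf = ".") {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
             gt_proband = p, gt_mother = m, gt_father = f, gt_sibling = s,
             gene = gene, maf = maf, stringsAsFactors = FALSE)
}

test_that("dominant de novo: proband het, everyone else hom-ref", {
  expect_true(classify_dominant_de_novo(
    annotated_quad(quad_gts("0/1", "0/0", "0/0", "0/0"))))
  expect_false(classify_dominant_de_novo(
    annotated_quad(quad_gts("0/1", "0/0", "0/1", "0/0"))))  # inherited
  expect_false(classify_dominant_de_novo(
    annotated_quad(quad_gts("1/1", "0/0", "0/0", "0/0"))))  # not het
  expect_error(classify_dominant_de_novo(
    annotated_quad(quad_gts("0/1", "0/1", "0", "0", chrom = "X"))),
    class = "quadprio_non_autosomal")
})

test_that("autosomal recessive: hom-alt proband, carrier parents, sibling not
           hom-alt", {
  expect_true(classify_recessive(
    annotated_quad(quad_gts("1/1", "0/1", "0/1", "0/1"))))
  expect_false(classify_recessive(
    annotated_quad(quad_gts("1/1", "0/1", "0/1", "1/1"))))  # sibling shares
  expect_false(classify_recessive(
    annotated_quad(quad_gts("0/1", "0/1", "0/1", "0/0"))))  # proband het
})

test_that("X-linked: carrier mother, hemizygous-ref father, branching on
           proband sex", {
  x <- function(p, m, f, s, psex = "female", ssex = "male")
    annotated_quad(quad_gts(p, m, f, s, chrom = "X"),
                   ped = test_ped(proband_sex = psex, sibling_sex = ssex))
  expect_true(classify_x_linked(x("0/1", "0/1", "0", "0")))
  expect_false(classify_x_linked(x("0/1", "0/1", "1", "0"))) # carrier father
  expect_false(classify_x_linked(x("0/1", "0/0", "0", "0"))) # de novo, not inherited
  expect_false(classify_x_linked(x("1/1", "0/1", "0", "0"))) # hom proband
  # male proband: hemizygous alternate, carrier mother
  expect_true(classify_x_linked(x("1", "0/1", "0", "0", psex = "male")))
  expect_false(classify_x_linked(x("0", "0/1", "0", "0", psex = "male")))
  # female sibling must not be homozygous alternate
  expect_true(classify_x_linked(x("1", "0/1", "0", "0/1", psex = "male",
                                  ssex = "female")))
  expect_false(classify_x_linked(x("1", "0/1", "0", "1/1", psex = "male",
                                   ssex = "female")))
  expect_error(classify_x_linked(annotated_quad(quad_gts("0/1", "0/1", "0/0",
                                                         "0/0"))),
               class = "quadprio_non_x")
})

ch_gene <- function(gt_list, gene = "NRAP") {
  df <- do.call(rbind, lapply(seq_along(gt_list), function(i) {
    g <- gt_list[[i]]
    quad_gts(g[1], g[2], g[3], g[4], pos = i * 100, gene = gene)
  }))
  suppressMessages(annotated_quad(df))
}

test_that("compound het: one paternal plus two maternal variants pair up", {
  av <- ch_gene(list(c("0/1", "0/0", "0/1", "0/0"),    # paternal
                     c("0/1", "0/1", "0/0", "0/0"),    # maternal
                     c("0/1", "0/1", "0/0", "0/0")))   # maternal
  ch <- find_compound_het(av)
  expect_equal(nrow(ch), 3L)
  keys <- qv_keys <- with(av$sites, sprintf("%s:%d:%s>%s", chrom, pos, ref, alt))
  pat <- ch[ch$origin == "paternal", ]
  expect_equal(nrow(pat), 1L)
  expect_setequal(strsplit(pat$partners, ",")[[1]], keys[2:3])
  for (i in 2:3)
    expect_equal(ch$partners[ch$key == keys[i]], keys[1])
})

test_that("a gene with variants from only one parent has no trans pair", {
  av <- ch_gene(list(c("0/1", "0/1", "0/0", "0/0"),
                     c("0/1", "0/1", "0/0", "0/0")))
  expect_equal(nrow(find_compound_het(av)), 0L)
})

test_that("ambiguous-origin variants cannot anchor a pair", {
  av <- ch_gene(list(c("0/1", "0/1", "0/1", "0/0"),    # both parents carry
                     c("0/1", "0/1", "0/0", "0/0")))
  expect_equal(nrow(find_compound_het(av)), 0L)
})

test_that("sibling exclusion: pairs fully carried by the unaffected sibling
           are dropped (brute force over sibling genotypes)", {
  for (s1 in DIPLOID_GTS) for (s2 in DIPLOID_GTS) {
    av <- ch_gene(list(c("0/1", "0/0", "0/1", s1),     # paternal
                       c("0/1", "0/1", "0/0", s2)))    # maternal
    ch <- find_compound_het(av)
    sib_carries_both <- gt_alt_count(s1) >= 1 && gt_alt_count(s2) >= 1
    if (sib_carries_both) {
      expect_equal(nrow(ch), 0L)
    } else {
      expect_equal(nrow(ch), 2L)
    }
  }
})

test_that("find_compound_het is invariant to input record order", {
  gts <- list(c("0/1", "0/0", "0/1", "0/0"),
              c("0/1", "0/1", "0/0", "0/0"),
              c("0/1", "0/1", "0/0", "0/0"),
              c("0/1", "0/1", "0/1", "0/0"))
  av <- ch_gene(gts)
  ref <- find_compound_het(av)
  ref <- ref[order(ref$key), ]
  set.seed(5)
  for (i in 1:5) {
    perm <- sample(length(gts))
    av2 <- ch_gene(gts[perm])
    got <- find_compound_het(av2)
    got <- got[order(got$key), ]
    rownames(ref) <- rownames(got) <- NULL
    # keys differ (positions follow input order), so compare structure
    expect_equal(nrow(got), nrow(ref))
    expect_setequal(got$origin, ref$origin)
  }
})

test_that("rarity: gene-level at-least-one-rare rescue for compound sets,
           strict per-variant cut otherwise", {
  cands <- data.frame(
    key = c("k1", "k2", "k3"), gene = "NRAP",
    maf = c(0.0004, 0.25, 0.27),
    models = "compound_het", stringsAsFactors = FALSE)
  kept <- apply_rarity(cands, rarity_rule(0.01))
  expect_equal(kept$key, c("k1", "k2", "k3"))  # rescued by the rare member

  no_rare <- cands[2:3, ]
  expect_equal(nrow(apply_rarity(no_rare, rarity_rule(0.01))), 0L)

  dn <- data.frame(key = "d1", gene = "BAG3", maf = NA_real_,
                   models = "dominant_de_novo", stringsAsFactors = FALSE)
  expect_equal(nrow(apply_rarity(dn, rarity_rule(0.01))), 1L)  # novel = rare

  common_dn <- data.frame(key = "d2", gene = "CRYAB", maf = 0.05,
                          models = "dominant_de_novo", stringsAsFactors = FALSE)
  expect_equal(nrow(apply_rarity(common_dn, rarity_rule(0.01))), 0L)
  # boundary: MAF exactly at the threshold is not rare (strictly below)
  at <- data.frame(key = "d3", gene = "G", maf = 0.01,
                   models = "dominant_de_novo", stringsAsFactors = FALSE)
  expect_equal(nrow(apply_rarity(at, rarity_rule(0.01))), 0L)
})

test_that("apply_rarity is monotone in max_maf on random candidate sets", {
  set.seed(9)
  for (i in 1:10) {
    n <- 20
    cands <- data.frame(
      key = sprintf("k%02d", 1:n),
      gene = sample(c("G1", "G2", "G3"), n, replace = TRUE),
      maf = ifelse(runif(n) < 0.2, NA, runif(n, 0, 0.3)),
      models = sample(c("dominant_de_novo", "autosomal_recessive",
                        "compound_het"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    thresholds <- sort(runif(3, 0, 0.3))
    prev <- character(0)
    for (t in thresholds) {
      kept <- apply_rarity(cands, rarity_rule(t))$key
      expect_true(all(prev %in% kept))
      prev <- kept
    }
  }
})

test_that("no genotype configuration satisfies both de novo and recessive", {
  combos <- expand.grid(p = DIPLOID_GTS, m = DIPLOID_GTS, f = DIPLOID_GTS,
                        s = DIPLOID_GTS, stringsAsFactors = FALSE)
  df <- data.frame(chrom = "1", pos = seq_len(nrow(combos)) * 10,
                   ref = "A", alt = "G",
                   gt_proband = combos$p, gt_mother = combos$m,
                   gt_father = combos$f, gt_sibling = combos$s,
                   stringsAsFactors = FALSE)
  av <- annotated_quad(df)
  expect_false(any(classify_dominant_de_novo(av) & classify_recessive(av)))
})
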