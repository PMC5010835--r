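# Quad-pedigree genotype simulator: Hardy-Weinberg parental genotypes,
# Mendelian transmission to a female proband and a male sibling, male X
# hemizygosity, planted variants for each inheritance model, and a
# two-level GQ / Poisson DP error model. Everything is deterministic given
# the seed, and a truth table records each planted variant's model and
# pre-error genotypes for recovery scoring.

#' Simulation parameters
#'
#' Defaults emulate a quad exome call set: site allele frequencies drawn
#' from a rare-skewed Beta distribution, mean depth 46x (typical exome
#' coverage), genotype quality 99 for concordant calls and 30 (below the
#' 50 cut) for error-perturbed ones, and small genotyping-error and
#' missingness rates.
#'
#' @param n_background_sites Number of background (non-planted) sites.
#' @param maf_spec Either a numeric vector of fixed site MAFs (recycled), or
#'   a list `list(dist = "beta", shape1 =, shape2 =)` describing a sampling
#'   distribution over (0, 1).
#' @param planted Named integer vector of planted counts per model:
#'   `dominant_de_novo`, `autosomal_recessive`, `compound_het` (number of
#'   compound genes, two sites each), `x_linked`.
#' @param genotype_error_rate Per-genotype probability of re-drawing the
#'   call uniformly from the legal genotype space (the redraw may restore
#'   the true genotype, so realized discordance is 2/3 of this rate for
#'   diploid and 1/2 for hemizygous calls).
#' @param missing_rate Per-genotype missingness probability.
#' @param mean_depth Mean of the Poisson read-depth distribution.
#' @param gq_high,gq_low GQ assigned to concordant vs error-perturbed calls.
#' @param x_fraction Fraction of background sites placed on chromosome X.
#' @param seed Integer seed; fixes all randomness in [simulate_quad()].
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_background_sites = 1000L,
                              maf_spec = list(dist = "beta", shape1 = 0.7,
                                              shape2 = 6),
                              planted = c(dominant_de_novo = 1L,
                                          autosomal_recessive = 1L,
                                          compound_het = 1L,
                                          x_linked = 1L),
                              genotype_error_rate = 0.005,
                              missing_rate = 0.002,
                              mean_depth = 46,
                              gq_high = 99L, gq_low = 30L,
                              x_fraction = 0.05,
                              seed = 1L) {
  n_background_sites <- as.integer(n_background_sites)
  full <- c(dominant_de_novo = 0L, autosomal_recessive = 0L,
            compound_het = 0L, x_linked = 0L)
  bad <- setdiff(names(planted), names(full))
  if (length(bad) > 0)
    qp_stop("invalid_params", "unknown planted model(s): %s",
            paste(bad, collapse = ", "))
  full[names(planted)] <- as.integer(planted)
  probs <- c(genotype_error_rate, missing_rate, x_fraction)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    qp_stop("invalid_params", "rates and fractions must lie in [0, 1]")
  if (n_background_sites < 0L || any(full < 0L))
    qp_stop("invalid_params", "site counts must be >= 0")
  if (!is.numeric(mean_depth) || mean_depth <= 0)
    qp_stop("invalid_params", "mean_depth must be > 0")
  structure(list(n_background_sites = n_background_sites,
                 maf_spec = maf_spec, planted = full,
                 genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate, mean_depth = mean_depth,
                 gq_high = as.integer(gq_high), gq_low = as.integer(gq_low),
                 x_fraction = x_fraction, seed = as.integer(seed)),
            class = "simulation_params")
}

#' Transmit parental alleles to a child
#'
#' Mendelian transmission for one site. On autosomes the child receives one
#' uniformly chosen allele from each parent. On chromosome X a daughter
#' receives the father's single X allele plus one uniformly chosen maternal
#' allele; a son receives one uniformly chosen maternal allele and is
#' hemizygous. Draws use the current R random number generator state.
#'
#' @param mother Integer vector of two maternal allele indices.
#' @param father Integer vector of paternal allele indices: two on
#'   autosomes, one on X.
#' @param chrom Chromosome label (autosome or `"X"`).
#' @param child_sex `"male"` or `"female"`.
#' @return Integer vector of child allele indices: length 2, or length 1
#'   for a son on X.
#' @export
mendelian_transmit <- function(mother, father, chrom, child_sex) {
  chrom <- normalize_chrom(chrom)
  if (anyNA(mother) || anyNA(father))
    qp_stop("invalid_transmit", "parental calls must be non-missing")
  if (length(mother) != 2L)
    qp_stop("invalid_transmit", "mother must carry two alleles")
  if (chrom == "X") {
    if (length(father) != 1L)
      qp_stop("invalid_transmit",
              "male X calls must be hemizygous (one allele)")
    m_allele <- mother[sample.int(2L, 1L)]
    if (child_sex == "male") return(m_allele)
    return(c(m_allele, father[1L]))
  }
  if (length(father) != 2L)
    qp_stop("invalid_transmit", "father must carry two alleles on autosomes")
  c(mother[sample.int(2L, 1L)], father[sample.int(2L, 1L)])
}

# Vectorized transmission used by the simulator (children: female proband,
# male sibling). m1/m2/f1/f2 are parental allele vectors; f2 is ignored on X.
transmit_quad <- function(m1, m2, f1, f2, on_x) {
  n <- length(m1)
  pick <- function(a, b) ifelse(stats::runif(n) < 0.5, a, b)
  pro1 <- pick(m1, m2)                     # maternal allele to proband
  sib1 <- pick(m1, m2)                     # maternal allele to sibling
  pro2 <- ifelse(on_x, f1, pick(f1, f2))   # paternal: single X or drawn
  sib2 <- ifelse(on_x, NA_integer_, pick(f1, f2))  # son is hemizygous on X
  list(pro1 = pro1, pro2 = pro2, sib1 = sib1, sib2 = sib2)
}

sim_pedigree <- function() {
  quad_pedigree(sample_id = c("PROBAND", "MOTHER", "FATHER", "BROTHER"),
                role = QP_ROLES,
                sex = c("female", "female", "male", "male"),
                affected = c(TRUE, FALSE, FALSE, FALSE))
}

draw_mafs <- function(spec, n) {
  if (is.numeric(spec)) {
    if (length(spec) == 0) qp_stop("invalid_params", "empty fixed MAF list")
    if (any(spec < 0 | spec > 1))
      qp_stop("invalid_params", "fixed MAFs must lie in [0, 1]")
    return(rep_len(spec, n))
  }
  if (!is.list(spec) || !identical(spec$dist, "beta"))
    qp_stop("invalid_params",
            "maf_spec must be a numeric vector or list(dist='beta', ...)")
  pmin(pmax(stats::rbeta(n, spec$shape1, spec$shape2), 1e-4), 0.5)
}

random_bases <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  list(ref = ref, alt = unname(alt))
}

#' Simulate a quad exome call set with known ground truth
#'
#' Generates background sites (parental genotypes at Hardy-Weinberg
#' equilibrium for the site MAF, children by Mendelian transmission, male X
#' hemizygosity) plus planted variants in the defining genotype
#' configuration of each inheritance model, then applies genotyping error,
#' missingness, Poisson read depth and two-level GQ, and writes the five
#' pipeline inputs to `out_dir`:
#' `quad.vcf`, `quad.ped`, `annotations.tsv`, `genes.txt`, `truth.tsv`.
#'
#' Planted variants are annotated `nonsynonymous` in distinct
#' muscle-gene-list genes (compound genes get two sites of opposite
#' unambiguous parental origin, at least one rare); background sites carry
#' per-site synthetic gene symbols outside the muscle list and a mixture of
#' functional classes. Sites are independent — there is no linkage map, so
#' compound-heterozygous trans configurations are planted explicitly.
#'
#' @param params A [simulation_params] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (the five files), `truth` (the
#'   planted-variant truth table), `pedigree`, `truth_geno` (pre-error
#'   genotype strings for all sites, for error-rate diagnostics) and
#'   `emitted` (the post-error `quad_variants` object).
#' @export
simulate_quad <- function(params, out_dir) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  ped <- sim_pedigree()

  n_bg <- params$n_background_sites
  n_x <- as.integer(round(n_bg * params$x_fraction))
  n_auto <- n_bg - n_x

  chrom <- c(sample(QP_AUTOSOMES, n_auto, replace = TRUE), rep("X", n_x))
  maf <- draw_mafs(params$maf_spec, n_bg)
  on_x <- chrom == "X"

  # Parents at Hardy-Weinberg equilibrium: independent Bernoulli(maf) alleles
  m1 <- stats::rbinom(n_bg, 1L, maf)
  m2 <- stats::rbinom(n_bg, 1L, maf)
  f1 <- stats::rbinom(n_bg, 1L, maf)
  f2 <- ifelse(on_x, NA_integer_, stats::rbinom(n_bg, 1L, maf))
  kids <- transmit_quad(m1, m2, f1, f2, on_x)

  bg <- data.frame(chrom = chrom, maf = maf,
                   gene = sprintf("BG%05d", seq_len(n_bg)),
                   functional_class = sample(
                     c("nonsynonymous", "synonymous", "intronic",
                       "intergenic", "splicing", "other_exonic", "stopgain"),
                     n_bg, replace = TRUE,
                     prob = c(0.40, 0.30, 0.12, 0.05, 0.05, 0.06, 0.02)),
                   model = NA_character_,
                   p1 = kids$pro1, p2 = kids$pro2,
                   m1 = m1, m2 = m2, f1 = f1, f2 = f2,
                   s1 = kids$sib1, s2 = kids$sib2,
                   stringsAsFactors = FALSE)

  # Planted variants: defining genotype configuration per model.
  planted <- list()
  add_planted <- function(chrom, maf, gene, model,
                          p1, p2, m1, m2, f1, f2, s1, s2) {
    planted[[length(planted) + 1L]] <<- data.frame(
      chrom = chrom, maf = maf, gene = gene,
      functional_class = "nonsynonymous", model = model,
      p1 = p1, p2 = p2, m1 = m1, m2 = m2, f1 = f1, f2 = f2,
      s1 = s1, s2 = s2, stringsAsFactors = FALSE)
  }
  k <- params$planted
  for (i in seq_len(k[["dominant_de_novo"]]))
    add_planted(sample(QP_AUTOSOMES, 1L), NA_real_,
                sprintf("MUSDN%02d", i), "dominant_de_novo",
                0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L)
  for (i in seq_len(k[["autosomal_recessive"]]))
    add_planted(sample(QP_AUTOSOMES, 1L), stats::runif(1, 0, 0.005),
                sprintf("MUSAR%02d", i), "autosomal_recessive",
                1L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)
  for (i in seq_len(k[["compound_het"]])) {
    ch_chrom <- sample(QP_AUTOSOMES, 1L)
    gene <- sprintf("MUSCH%02d", i)
    # paternal member, rare; maternal member, common: the at-least-one-rare
    # gene-level rule must rescue the pair
    add_planted(ch_chrom, stats::runif(1, 0, 0.005), gene, "compound_het",
                0L, 1L, 0L, 0L, 0L, 1L, 0L, 0L)
    add_planted(ch_chrom, stats::runif(1, 0.05, 0.4), gene, "compound_het",
                1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L)
  }
  for (i in seq_len(k[["x_linked"]]))
    add_planted("X", stats::runif(1, 0, 0.005),
                sprintf("MUSXL%02d", i), "x_linked",
                0L, 1L, 0L, 1L, 0L, NA_integer_, 0L, NA_integer_)

  sites <- if (length(planted) > 0) {
    rbind(bg, do.call(rbind, planted))
  } else bg
  n <- nrow(sites)
  sites$is_planted <- c(rep(FALSE, n_bg), rep(TRUE, n - n_bg))

  # unique positions per chromosome, then canonical sort
  pos <- integer(n)
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    pos[i] <- sort(sample.int(2e8L, length(i)))
  }
  sites$pos <- pos
  alle <- random_bases(n)
  sites$ref <- alle$ref
  sites$alt <- alle$alt
  ord <- order(chrom_rank(sites$chrom), sites$pos, sites$alt)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  sites$key <- variant_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  on_x <- sites$chrom == "X"

  # truth genotype matrices (pre-error); male roles hemizygous on X
  a1 <- cbind(proband = sites$p1, mother = sites$m1, father = sites$f1,
              sibling = sites$s1)
  a2 <- cbind(proband = sites$p2, mother = sites$m2, father = sites$f2,
              sibling = sites$s2)
  ploidy <- matrix(2L, n, 4L, dimnames = list(NULL, QP_ROLES))
  ploidy[on_x, c("father", "sibling")] <- 1L
  a2[on_x, c("father", "sibling")] <- NA_integer_
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"

  truth_qv <- new_quad_variants(
    sites = data.frame(chrom = sites$chrom, pos = sites$pos,
                       id = rep(".", n), ref = sites$ref, alt = sites$alt,
                       stringsAsFactors = FALSE),
    a1 = a1, a2 = a2, ploidy = ploidy,
    phased = matrix(FALSE, n, 4L, dimnames = list(NULL, QP_ROLES)),
    gq = matrix(params$gq_high, n, 4L, dimnames = list(NULL, QP_ROLES)),
    dp = matrix(NA_integer_, n, 4L, dimnames = list(NULL, QP_ROLES)),
    pedigree = ped)
  truth_geno <- vapply(QP_ROLES, function(r) geno_string(truth_qv, r),
                       character(n))
  if (n == 1L) truth_geno <- matrix(truth_geno, nrow = 1L,
                                    dimnames = list(NULL, QP_ROLES))

  # --- error model -----------------------------------------------------------
  emitted <- truth_qv
  eps <- params$genotype_error_rate
  if (eps > 0) {
    for (r in QP_ROLES) {
      hit <- stats::runif(n) < eps
      if (any(hit)) {
        dip <- hit & emitted$ploidy[, r] == 2L
        hap <- hit & emitted$ploidy[, r] == 1L
        # uniform redraw over the legal unordered genotype space
        g <- sample.int(3L, sum(dip), replace = TRUE)  # 1=0/0, 2=0/1, 3=1/1
        emitted$a1[dip, r] <- as.integer(g >= 3L)
        emitted$a2[dip, r] <- as.integer(g >= 2L)
        emitted$a1[hap, r] <- sample(0:1, sum(hap), replace = TRUE)
        emitted$gq[hit, r] <- params$gq_low
      }
    }
  }
  if (params$missing_rate > 0) {
    for (r in QP_ROLES) {
      miss <- stats::runif(n) < params$missing_rate
      emitted$a1[miss, r] <- NA_integer_
      emitted$a2[miss & emitted$ploidy[, r] == 2L, r] <- NA_integer_
    }
  }
  for (r in QP_ROLES)
    emitted$dp[, r] <- stats::rpois(n, params$mean_depth)

  # --- outputs ---------------------------------------------------------------
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(out_dir, "quad.vcf"),
                ped = file.path(out_dir, "quad.ped"),
                annotations = file.path(out_dir, "annotations.tsv"),
                genes = file.path(out_dir, "genes.txt"),
                truth = file.path(out_dir, "truth.tsv"))
  write_quad_vcf(emitted, paths$vcf,
                 extra_header = sprintf("##quadprio_simulation_seed=%d",
                                        params$seed))
  write_ped(ped, paths$ped)

  ann <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                    alt = sites$alt, gene = sites$gene,
                    functional_class = sites$functional_class,
                    maf_1kg = format_maf(sites$maf),
                    hgvs_c = ".", hgvs_p = ".", predicted_deleterious = ".",
                    stringsAsFactors = FALSE)
  utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")

  gene_list <- c(sort(unique(sites$gene[sites$is_planted])),
                 "DES", "CRYAB", "MYOT", "LDB3", "FLNC", "TTN")
  writeLines(gene_list, paths$genes)

  pl <- sites$is_planted
  truth <- data.frame(key = sites$key[pl], gene = sites$gene[pl],
                      model = sites$model[pl],
                      maf = sites$maf[pl],
                      gt_proband = truth_geno[pl, "proband"],
                      gt_mother = truth_geno[pl, "mother"],
                      gt_father = truth_geno[pl, "father"],
                      gt_sibling = truth_geno[pl, "sibling"],
                      stringsAsFactors = FALSE)
  truth_out <- truth
  truth_out$maf <- format_maf(truth_out$maf)
  utils::write.table(truth_out, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")

  invisible(list(paths = paths, truth = truth, pedigree = ped,
                 truth_geno = truth_geno, emitted = emitted,
                 params = params))
}
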