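# Classification of variants under the four Mendelian inheritance models of
# a quad with one affected child and three unaffected relatives, plus the
# population-rarity rule with its gene-level relaxation for compound
# heterozygotes.

assert_autosomal <- function(qv, what) {
  bad <- !is_autosome(qv$sites$chrom)
  if (any(bad))
    qp_stop("non_autosomal", "%s requires autosomal variants; found %s",
            what, paste(unique(qv$sites$chrom[bad]), collapse = ", "))
}

#' Classify variants as dominant de novo
#'
#' An autosomal variant fits the dominant de novo model when the affected
#' proband is heterozygous while mother, father and sibling are all
#' homozygous reference. With both parents unaffected, a dominant-acting
#' allele in the proband can only have arisen de novo, so the dominant model
#' reduces to this configuration.
#'
#' @param qv An (annotated) `quad_variants` object; all records must be
#'   autosomal.
#' @return Logical vector, one verdict per record.
#' @export
classify_dominant_de_novo <- function(qv) {
  stopifnot(inherits(qv, "quad_variants"))
  assert_autosomal(qv, "classify_dominant_de_novo")
  is_het(qv, "proband") & is_hom_ref(qv, "mother") &
    is_hom_ref(qv, "father") & is_hom_ref(qv, "sibling")
}

#' Classify variants as autosomal recessive
#'
#' An autosomal variant fits the recessive model when the proband is
#' homozygous for the alternate allele, both parents are heterozygous
#' carriers, and the unaffected sibling is not homozygous alternate.
#'
#' @inheritParams classify_dominant_de_novo
#' @return Logical vector, one verdict per record.
#' @export
classify_recessive <- function(qv) {
  stopifnot(inherits(qv, "quad_variants"))
  assert_autosomal(qv, "classify_recessive")
  is_hom_alt(qv, "proband") & is_het(qv, "mother") & is_het(qv, "father") &
    !geno_missing(qv, "sibling") & !is_hom_alt(qv, "sibling")
}

#' Classify chromosome-X variants under the X-linked model
#'
#' Branches on proband sex. For a female proband the configuration is a
#' heterozygous proband with a heterozygous carrier mother, a hemizygous
#' reference father and an unaffected sibling who does not carry the
#' variant homozygously (a male sibling must be hemizygous reference).
#' For a male proband: hemizygous alternate proband, carrier (heterozygous)
#' mother, hemizygous-reference father, and a male sibling hemizygous
#' reference or a female sibling not homozygous alternate.
#'
#' @inheritParams classify_dominant_de_novo
#' @return Logical vector, one verdict per record. All records must lie on
#'   chromosome X; anything else is a precondition violation.
#' @export
classify_x_linked <- function(qv) {
  stopifnot(inherits(qv, "quad_variants"))
  if (any(qv$sites$chrom != "X"))
    qp_stop("non_x", "classify_x_linked requires chromosome-X variants")
  ped <- qv$pedigree
  sib_ok <- if (ped_sex(ped, "sibling") == "male") {
    is_hap_ref(qv, "sibling")
  } else {
    !geno_missing(qv, "sibling") & !is_hom_alt(qv, "sibling")
  }
  proband_ok <- if (ped_sex(ped, "proband") == "female") {
    is_het(qv, "proband")
  } else {
    is_hap_alt(qv, "proband")
  }
  proband_ok & is_het(qv, "mother") & is_hap_ref(qv, "father") & sib_ok
}

# Parental origin of the proband's alternate allele, inferred from parental
# carriage (no read-backed phasing):
#   paternal   father carries the alternate, mother is hom-ref
#   maternal   mother carries the alternate, father is hom-ref
#   both       both parents carry it (ambiguous for phasing purposes)
#   de_novo    neither parent carries it
parental_origin <- function(qv) {
  f_alt <- carries_alt(qv, "father")
  m_alt <- carries_alt(qv, "mother")
  f_ref <- is_hom_ref(qv, "father") | is_hap_ref(qv, "father")
  m_ref <- is_hom_ref(qv, "mother") | is_hap_ref(qv, "mother")
  out <- rep("ambiguous", qv_n(qv))
  out[f_alt & m_ref] <- "paternal"
  out[m_alt & f_ref] <- "maternal"
  out[f_alt & m_alt] <- "both"
  out[f_ref & m_ref] <- "de_novo"
  out
}

#' Find compound-heterozygous candidates without phase
#'
#' Groups autosomal proband-heterozygous variants by gene and infers the
#' parental origin of each from the parents' genotypes (no phasing is
#' available): a variant is unambiguously paternal when the father carries
#' the alternate allele and the mother is homozygous reference, and vice
#' versa; variants carried by both parents are ambiguous and can never
#' anchor a trans pair.
#'
#' A gene yields compound-heterozygous candidates only when it contains at
#' least one unambiguously paternal and one unambiguously maternal
#' proband-het variant. Candidate partners are the opposite-origin variants,
#' with one restriction consistent with the sibling's unaffected status: a
#' trans pair jointly carried by the sibling is excluded (applied pairwise),
#' and a variant left with no surviving partner is not a candidate.
#'
#' @param qv An `annotated_quad_variants` object (gene symbols are taken
#'   from the annotation); all records must be autosomal.
#' @return A data frame with one row per candidate: `key`, `gene`, `origin`
#'   (`"paternal"`/`"maternal"`), and `partners` (comma-joined keys of the
#'   opposite-origin partners). Zero rows when no gene has a trans pair.
#' @export
find_compound_het <- function(qv) {
  stopifnot(inherits(qv, "annotated_quad_variants"))
  assert_autosomal(qv, "find_compound_het")
  empty <- data.frame(key = character(), gene = character(),
                      origin = character(), partners = character(),
                      stringsAsFactors = FALSE)
  if (qv_n(qv) == 0) return(empty)

  keys <- qv_keys(qv)
  het <- is_het(qv, "proband")
  origin <- parental_origin(qv)
  sib_alt <- carries_alt(qv, "sibling")
  eligible <- het & origin %in% c("paternal", "maternal") & !is.na(qv$ann$gene)
  if (!any(eligible)) return(empty)

  idx <- which(eligible)
  out <- empty
  for (g in unique(qv$ann$gene[idx])) {
    in_gene <- idx[qv$ann$gene[idx] == g]
    pat <- in_gene[origin[in_gene] == "paternal"]
    mat <- in_gene[origin[in_gene] == "maternal"]
    if (length(pat) == 0 || length(mat) == 0) next
    # pairwise sibling exclusion: a trans pair the unaffected sibling also
    # carries in full cannot be causal
    pairs <- expand.grid(p = pat, m = mat)
    keep <- !(sib_alt[pairs$p] & sib_alt[pairs$m])
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0) next
    members <- sort(unique(c(pairs$p, pairs$m)))
    partners <- vapply(members, function(i) {
      opp <- sort(unique(c(pairs$m[pairs$p == i], pairs$p[pairs$m == i])))
      paste(keys[opp], collapse = ",")
    }, character(1))
    out <- rbind(out, data.frame(key = keys[members], gene = g,
                                 origin = origin[members],
                                 partners = partners,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Population rarity rule
#'
#' @param max_maf Maximum population minor-allele frequency (exclusive); the
#'   default 0.01 keeps variants with MAF strictly below 1%.
#' @return An object of class `rarity_rule`.
#' @export
rarity_rule <- function(max_maf = 0.01) {
  max_maf <- as.numeric(max_maf)
  if (is.na(max_maf) || max_maf < 0 || max_maf > 1)
    qp_stop("invalid_rarity", "max_maf must lie in [0, 1]")
  structure(list(max_maf = max_maf), class = "rarity_rule")
}

is_rare <- function(maf, rule) is.na(maf) | maf < rule$max_maf

#' Apply the rarity rule to classified candidates
#'
#' Non-compound candidates are kept only if their population MAF is below
#' the threshold; a missing MAF means the variant is absent from the
#' reference population and therefore rare (kept). For the
#' compound-heterozygous model the rule is relaxed to the gene set: the
#' whole set is kept when at least one member is rare, and removed
#' otherwise. A candidate supported by several models keeps the models that
#' survive; candidates with no surviving model are dropped. Raising
#' `max_maf` never removes a candidate.
#'
#' @param candidates A candidate data frame as produced by the model
#'   classification stage of [prioritize()]: columns `key`, `gene`, `maf`,
#'   `models` (comma-joined model names) are required.
#' @param rule A [rarity_rule].
#' @return The surviving candidate rows with `models` reduced to the
#'   surviving models.
#' @export
apply_rarity <- function(candidates, rule = rarity_rule()) {
  stopifnot(inherits(rule, "rarity_rule"),
            all(c("key", "gene", "maf", "models") %in% names(candidates)))
  if (nrow(candidates) == 0) return(candidates)
  model_list <- strsplit(candidates$models, ",", fixed = TRUE)
  rare <- is_rare(candidates$maf, rule)

  has_ch <- vapply(model_list, function(m) "compound_het" %in% m, logical(1))
  gene_rescued <- tapply(rare[has_ch], candidates$gene[has_ch], any)

  surviving <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    keep <- character()
    for (m in model_list[[i]]) {
      ok <- if (m == "compound_het") {
        isTRUE(gene_rescued[[candidates$gene[i]]])
      } else {
        rare[i]
      }
      if (ok) keep <- c(keep, m)
    }
    surviving[[i]] <- keep
  }
  n_models <- lengths(surviving)
  out <- candidates[n_models > 0, , drop = FALSE]
  out$models <- vapply(surviving[n_models > 0],
                       function(m) paste(sort(m), collapse = ","),
                       character(1))
  rownames(out) <- NULL
  out
}
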