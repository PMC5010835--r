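# Pre-model filtering cascade: genotype quality, functional class,
# family-genotype discard rule and muscle-expressed gene restriction.
#
# Every filter returns one verdict per record: a data frame with columns
# `key`, `pass` and `reason` (NA where the record passes). A record fails
# with exactly one machine-readable reason (the first failing check), so
# passes plus per-reason failures always sum to the input count.

#' Genotype quality thresholds
#'
#' Per-genotype thresholds applied to all four family members. The defaults
#' discard genotypes with quality below 50 or coverage below 7x; the
#' boundary values themselves (GQ = 50, DP = 7) pass.
#'
#' @param min_gq Minimum Phred-scaled genotype quality (integer >= 0).
#' @param min_dp Minimum read depth (integer >= 0).
#' @return An object of class `quality_thresholds`.
#' @export
quality_thresholds <- function(min_gq = 50L, min_dp = 7L) {
  min_gq <- as.integer(min_gq); min_dp <- as.integer(min_dp)
  if (is.na(min_gq) || is.na(min_dp) || min_gq < 0L || min_dp < 0L)
    qp_stop("invalid_thresholds", "min_gq and min_dp must be integers >= 0")
  structure(list(min_gq = min_gq, min_dp = min_dp),
            class = "quality_thresholds")
}

filter_result <- function(qv, pass, reason) {
  data.frame(key = qv_keys(qv), pass = pass, reason = reason,
             stringsAsFactors = FALSE)
}

#' Per-sample genotype quality filter
#'
#' A record passes only if every quad member has a fully called genotype with
#' `GQ >= min_gq` and `DP >= min_dp`. Inheritance inference compares all four
#' genotypes, so a low-confidence or missing call in any member discards the
#' variant; missing genotypes are hard failures, never imputed. Members are
#' checked in the order proband, mother, father, sibling and the first
#' failure is reported, as `missing-genotype:<role>`,
#' `missing-quality:<role>` (absent GQ/DP fields) or `quality:<role>`.
#'
#' @param qv A `quad_variants` or `annotated_quad_variants` object.
#' @param thresholds A [quality_thresholds] object.
#' @return A data frame with columns `key`, `pass`, `reason`.
#' @export
quality_filter <- function(qv, thresholds = quality_thresholds()) {
  stopifnot(inherits(qv, "quad_variants"),
            inherits(thresholds, "quality_thresholds"))
  n <- qv_n(qv)
  pass <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  for (role in QP_ROLES) {
    miss_gt <- geno_missing(qv, role)
    miss_q <- is.na(qv$gq[, role]) | is.na(qv$dp[, role])
    low <- !miss_q & (qv$gq[, role] < thresholds$min_gq |
                        qv$dp[, role] < thresholds$min_dp)
    fail_now <- pass & (miss_gt | miss_q | low)
    reason[fail_now] <- ifelse(
      miss_gt[fail_now], paste0("missing-genotype:", role),
      ifelse(miss_q[fail_now], paste0("missing-quality:", role),
             paste0("quality:", role)))
    pass <- pass & !fail_now
  }
  filter_result(qv, pass, reason)
}

#' Functional-class filter
#'
#' Keeps protein-changing variants only: `nonsynonymous`, `stopgain` and
#' `stoploss`. Intergenic, intronic, synonymous, splicing, other-exonic and
#' unannotated (`unknown`) records fail; the reason names the failing class
#' (`class:<functional_class>`).
#'
#' @param qv An `annotated_quad_variants` object.
#' @return A data frame with columns `key`, `pass`, `reason`.
#' @export
functional_filter <- function(qv) {
  stopifnot(inherits(qv, "annotated_quad_variants"))
  pass <- qv$ann$functional_class %in% QP_DAMAGING_CLASSES
  filter_result(qv, pass,
                ifelse(pass, NA_character_,
                       paste0("class:", qv$ann$functional_class)))
}

#' Family-genotype discard rule
#'
#' Discards variants whose genotype configuration cannot distinguish the
#' affected proband from her unaffected relatives: the record fails if the
#' proband is homozygous for the reference allele (`hom-ref`), if the
#' proband's genotype is identical to the sibling's (`shared-with-sibling`),
#' or if it is identical to both parents' (`shared-with-parents`).
#' Comparisons follow [genotype_equal()]: missing data never asserts
#' identity. Intended to run on records that already passed
#' [quality_filter()], which guarantees fully called genotypes.
#'
#' @param qv A `quad_variants` or `annotated_quad_variants` object.
#' @return A data frame with columns `key`, `pass`, `reason`.
#' @export
family_genotype_filter <- function(qv) {
  stopifnot(inherits(qv, "quad_variants"))
  hom_ref <- is_hom_ref(qv, "proband") | is_hap_ref(qv, "proband")
  shared_sib <- geno_equal_roles(qv, "proband", "sibling")
  shared_par <- geno_equal_roles(qv, "proband", "mother") &
    geno_equal_roles(qv, "proband", "father")
  pass <- !(hom_ref | shared_sib | shared_par)
  reason <- rep(NA_character_, qv_n(qv))
  reason[shared_par] <- "shared-with-parents"
  reason[shared_sib] <- "shared-with-sibling"
  reason[hom_ref] <- "hom-ref"
  filter_result(qv, pass, reason)
}

#' Muscle-expressed gene restriction
#'
#' Keeps variants whose gene symbol appears in a user-supplied list of genes
#' mainly expressed in skeletal and cardiac muscle (exact, case-insensitive
#' match). Records without a gene symbol fail with reason `no-gene`.
#'
#' @param qv An `annotated_quad_variants` object.
#' @param gene_list Character vector of gene symbols (non-empty).
#' @return A data frame with columns `key`, `pass`, `reason`.
#' @seealso [load_gene_list()]
#' @export
muscle_gene_filter <- function(qv, gene_list) {
  stopifnot(inherits(qv, "annotated_quad_variants"))
  if (length(gene_list) == 0 || all(!nzchar(gene_list)))
    qp_stop("empty_gene_list", "the muscle gene list must be non-empty")
  genes <- toupper(trimws(gene_list))
  no_gene <- is.na(qv$ann$gene)
  pass <- !no_gene & toupper(qv$ann$gene) %in% genes
  reason <- ifelse(pass, NA_character_,
                   ifelse(no_gene, "no-gene", "not-in-gene-list"))
  filter_result(qv, pass, reason)
}

#' Load a gene list from a plain-text file
#'
#' One gene symbol per line; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path Path to the gene-list file.
#' @return Character vector of gene symbols.
#' @export
load_gene_list <- function(path) {
  if (!file.exists(path))
    qp_stop("io", "gene list not found: %s", path)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0)
    qp_stop("empty_gene_list", "the muscle gene list must be non-empty")
  unique(x)
}
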