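# Per-variant annotation: gene symbol, functional class and population MAF
# from a tab-separated table (the stand-in for an annotator's output).

ANN_REQUIRED_COLS <- c("chrom", "pos", "ref", "alt", "gene",
                       "functional_class", "maf_1kg")
ANN_OPTIONAL_COLS <- c("hgvs_c", "hgvs_p", "predicted_deleterious")

#' Load a variant annotation table
#'
#' Reads a tab-separated table with header columns `chrom`, `pos`, `ref`,
#' `alt`, `gene`, `functional_class`, `maf_1kg` and optionally `hgvs_c`,
#' `hgvs_p`, `predicted_deleterious`. `"."` and the empty string both denote
#' a missing cell.
#'
#' The MAF column holds the population frequency of the record's alternate
#' (derived) allele as a fraction in \[0, 1\]; no minor/major folding is
#' performed. HGVS strings are kept as opaque text and never parsed. The
#' functional class must come from the closed vocabulary
#' `r paste(QP_FUNCTIONAL_CLASSES, collapse = ", ")`.
#'
#' Chromosome labels are normalized exactly as in [read_quad_vcf()], so a
#' table keyed on `"chr10"` matches records on `"10"`.
#'
#' @param tsv_path Path to the annotation TSV.
#' @return An object of class `annotation_table` keyed by
#'   (chrom, pos, ref, alt); duplicate keys are an error.
#' @export
load_annotation_table <- function(tsv_path) {
  if (!file.exists(tsv_path))
    qp_stop("io", "annotation table not found: %s", tsv_path)
  tab <- utils::read.delim(tsv_path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = NULL,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(ANN_REQUIRED_COLS, names(tab))
  if (length(missing_cols) > 0)
    qp_stop("annotation_columns", "annotation table lacks column(s): %s",
            paste(missing_cols, collapse = ", "))
  for (col in ANN_OPTIONAL_COLS) if (is.null(tab[[col]])) tab[[col]] <- "."

  blank <- function(x) is.na(x) | x == "" | x == "."
  tab$chrom <- normalize_chrom(tab$chrom)
  tab$pos <- suppressWarnings(as.integer(tab$pos))
  if (anyNA(tab$pos) || any(tab$pos < 1L))
    qp_stop("annotation_pos", "annotation pos must be a positive integer")

  bad_class <- !tab$functional_class %in% QP_FUNCTIONAL_CLASSES
  if (any(bad_class))
    qp_stop("unknown_functional_class",
            "unknown functional_class token(s): %s",
            paste(unique(tab$functional_class[bad_class]), collapse = ", "))

  maf_txt <- tab$maf_1kg
  maf <- rep(NA_real_, nrow(tab))
  has <- !blank(maf_txt)
  maf[has] <- suppressWarnings(as.numeric(maf_txt[has]))
  if (anyNA(maf[has]))
    qp_stop("malformed_maf", "non-numeric maf_1kg value(s): %s",
            paste(unique(maf_txt[has][is.na(maf[has])]), collapse = ", "))
  if (any(maf[has] < 0 | maf[has] > 1))
    qp_stop("malformed_maf", "maf_1kg out of [0, 1]: %s",
            paste(unique(maf_txt[has][maf[has] < 0 | maf[has] > 1]),
                  collapse = ", "))
  tab$maf <- maf

  deleterious <- rep(NA, nrow(tab))
  has_del <- !blank(tab$predicted_deleterious)
  truthy <- tolower(tab$predicted_deleterious) %in% c("1", "true", "yes", "t")
  deleterious[has_del] <- truthy[has_del]
  tab$predicted_deleterious <- deleterious

  tab$gene[blank(tab$gene)] <- NA_character_
  tab$hgvs_c[blank(tab$hgvs_c)] <- NA_character_
  tab$hgvs_p[blank(tab$hgvs_p)] <- NA_character_

  tab$key <- variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)
  dup <- duplicated(tab$key)
  if (any(dup))
    qp_stop("duplicate_annotation_key", "duplicate annotation key(s): %s",
            paste(unique(tab$key[dup]), collapse = ", "))

  out <- tab[, c("key", "chrom", "pos", "ref", "alt", "gene",
                 "functional_class", "maf", "hgvs_c", "hgvs_p",
                 "predicted_deleterious")]
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Attach annotations to variant records
#'
#' Joins an [load_annotation_table()] lookup onto a `quad_variants` object by
#' (chrom, pos, ref, alt). Records without a matching row receive
#' `functional_class = "unknown"`, missing gene and missing MAF; the number
#' of unannotated records is reported as a message. Annotation never drops or
#' duplicates records and is independent of table row order.
#'
#' @param qv A `quad_variants` object from [read_quad_vcf()].
#' @param lookup An `annotation_table`.
#' @return `qv` with an `ann` data frame added, classed
#'   `annotated_quad_variants`.
#' @export
annotate <- function(qv, lookup) {
  stopifnot(inherits(qv, "quad_variants"), inherits(lookup, "annotation_table"))
  idx <- match(qv_keys(qv), lookup$key)
  n_un <- sum(is.na(idx))
  if (n_un > 0)
    message(sprintf("%d record(s) without an annotation row", n_un))
  ann <- data.frame(
    gene = lookup$gene[idx],
    functional_class = ifelse(is.na(idx), "unknown",
                              lookup$functional_class[idx]),
    maf = lookup$maf[idx],
    hgvs_c = lookup$hgvs_c[idx],
    hgvs_p = lookup$hgvs_p[idx],
    predicted_deleterious = lookup$predicted_deleterious[idx],
    stringsAsFactors = FALSE)
  qv$ann <- ann
  class(qv) <- unique(c("annotated_quad_variants", class(qv)))
  qv
}
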