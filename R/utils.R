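# Internal helpers shared across modules.

QP_ROLES <- c("proband", "mother", "father", "sibling")
QP_CHROMS <- c(as.character(1:22), "X", "Y", "MT")
QP_AUTOSOMES <- as.character(1:22)
QP_FUNCTIONAL_CLASSES <- c("intergenic", "intronic", "synonymous",
                           "nonsynonymous", "stopgain", "stoploss",
                           "splicing", "other_exonic", "unknown")
QP_DAMAGING_CLASSES <- c("nonsynonymous", "stopgain", "stoploss")
QP_MODELS <- c("dominant_de_novo", "autosomal_recessive", "compound_het",
               "x_linked")

#' Raise a classed quadprio error
#'
#' All validation failures in the package carry a condition class of the form
#' `quadprio_<what>` (plus `quadprio_error`) so callers can distinguish them
#' programmatically.
#' @noRd
qp_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(paste0("quadprio_", class), "quadprio_error")))
}

#' Normalize a chromosome label
#'
#' Strips any "chr" prefix, upper-cases X/Y/M and maps "M" to "MT". Labels
#' outside 1-22/X/Y/MT are returned stripped but otherwise untouched; callers
#' decide whether to reject them.
#' @noRd
normalize_chrom <- function(x) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(x))
  x <- toupper(x)
  x[x == "M"] <- "MT"
  x
}

# Ordering rank for sorting records: 1..22, X, Y, MT, then anything else.
chrom_rank <- function(x) {
  r <- match(x, QP_CHROMS)
  r[is.na(r)] <- length(QP_CHROMS) + 1L
  r
}

is_autosome <- function(x) x %in% QP_AUTOSOMES

#' Canonical variant key "chrom:pos:ref>alt"
#' @noRd
variant_key <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s>%s", chrom, as.integer(pos), ref, alt)
}

# Deterministic text formatting for MAF values in reports ("." for missing).
format_maf <- function(maf) {
  out <- ifelse(is.na(maf), ".",
                sub("0+$", "", sub("\\.$", ".0",
                                   format(maf, scientific = FALSE, trim = TRUE))))
  out[!is.na(maf) & maf == 0] <- "0"
  out[!is.na(maf) & maf == 1] <- "1"
  out
}
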