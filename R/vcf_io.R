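# VCF input/output and the internal quad-genotype container.
#
# Genotypes are held column-wise per role (proband, mother, father, sibling)
# in integer allele-slot matrices so that every downstream filter and
# classifier is vectorized over sites:
#   a1, a2   allele indices (0 = ref, 1 = alt, NA = missing slot)
#   ploidy   1 (hemizygous) or 2; a2 is NA wherever ploidy == 1
#   gq, dp   per-genotype quality and depth (NA = absent)
# Coordinates are VCF-native: 1-based, fully closed, never converted.

new_quad_variants <- function(sites, a1, a2, ploidy, phased, gq, dp, pedigree) {
  n <- nrow(sites)
  for (m in list(a1, a2, ploidy, gq, dp))
    stopifnot(is.matrix(m), nrow(m) == n, ncol(m) == 4L)
  structure(list(sites = sites, a1 = a1, a2 = a2, ploidy = ploidy,
                 phased = phased, gq = gq, dp = dp, pedigree = pedigree),
            class = "quad_variants")
}

empty_role_matrix <- function(n, data = NA_integer_) {
  matrix(data, nrow = n, ncol = 4L, dimnames = list(NULL, QP_ROLES))
}

qv_n <- function(qv) nrow(qv$sites)

qv_keys <- function(qv) {
  with(qv$sites, variant_key(chrom, pos, ref, alt))
}

qv_subset <- function(qv, i) {
  out <- qv
  out$sites <- qv$sites[i, , drop = FALSE]
  rownames(out$sites) <- NULL
  for (f in c("a1", "a2", "ploidy", "phased", "gq", "dp"))
    out[[f]] <- qv[[f]][i, , drop = FALSE]
  if (!is.null(out$ann)) {
    out$ann <- qv$ann[i, , drop = FALSE]
    rownames(out$ann) <- NULL
  }
  out
}

# --- per-role genotype predicates (vectorized over sites) -------------------

geno_missing <- function(qv, role) {
  is.na(qv$a1[, role]) | (qv$ploidy[, role] == 2L & is.na(qv$a2[, role]))
}

# Number of alternate alleles carried; NA where the call is (partly) missing.
n_alt <- function(qv, role) {
  n <- qv$a1[, role] + ifelse(qv$ploidy[, role] == 2L, qv$a2[, role], 0L)
  n[geno_missing(qv, role)] <- NA_integer_
  n
}

is_hom_ref <- function(qv, role) !geno_missing(qv, role) & n_alt(qv, role) == 0L
is_het <- function(qv, role) {
  !geno_missing(qv, role) & qv$ploidy[, role] == 2L & n_alt(qv, role) == 1L
}
is_hom_alt <- function(qv, role) {
  !geno_missing(qv, role) & qv$ploidy[, role] == 2L & n_alt(qv, role) == 2L
}
is_hap_ref <- function(qv, role) {
  !geno_missing(qv, role) & qv$ploidy[, role] == 1L & qv$a1[, role] == 0L
}
is_hap_alt <- function(qv, role) {
  !geno_missing(qv, role) & qv$ploidy[, role] == 1L & qv$a1[, role] == 1L
}
carries_alt <- function(qv, role) !geno_missing(qv, role) & n_alt(qv, role) >= 1L

# Row-wise unordered genotype identity between two roles. Missing data never
# asserts identity; hemizygous vs diploid calls are never identical.
geno_equal_roles <- function(qv, role_a, role_b) {
  ma <- geno_missing(qv, role_a)
  mb <- geno_missing(qv, role_b)
  same_ploidy <- qv$ploidy[, role_a] == qv$ploidy[, role_b]
  eq_dip <- pmin(qv$a1[, role_a], qv$a2[, role_a]) ==
              pmin(qv$a1[, role_b], qv$a2[, role_b]) &
            pmax(qv$a1[, role_a], qv$a2[, role_a]) ==
              pmax(qv$a1[, role_b], qv$a2[, role_b])
  eq_hap <- qv$a1[, role_a] == qv$a1[, role_b]
  eq <- ifelse(qv$ploidy[, role_a] == 1L, eq_hap, eq_dip)
  out <- !ma & !mb & same_ploidy & eq
  out[is.na(out)] <- FALSE
  out
}

geno_string <- function(qv, role) {
  a1 <- qv$a1[, role]; a2 <- qv$a2[, role]
  sep <- ifelse(qv$phased[, role], "|", "/")
  s1 <- ifelse(is.na(a1), ".", as.character(a1))
  s2 <- ifelse(is.na(a2), ".", as.character(a2))
  ifelse(qv$ploidy[, role] == 1L, s1, paste0(s1, sep, s2))
}

#' Compare two genotype calls for identity
#'
#' Unordered allele-multiset equality, as used by the family-genotype discard
#' rule ("identical to the sibling or to both parents"). Any missing allele in
#' either call makes the comparison `FALSE`: a comparison against missing data
#' never asserts identity. Calls of different ploidy (a hemizygous male X call
#' vs a diploid call) are never equal.
#'
#' @param a,b Integer vectors of allele indices (0 = reference, 1 = alternate,
#'   `NA` = missing), length 1 (hemizygous) or 2 (diploid).
#' @return `TRUE` or `FALSE`.
#' @examples
#' genotype_equal(c(0, 1), c(1, 0))  # TRUE: unordered
#' genotype_equal(c(0, 1), c(1, 1))  # FALSE
#' genotype_equal(c(0, NA), c(0, 1)) # FALSE: missing never matches
#' @export
genotype_equal <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (anyNA(a) || anyNA(b)) return(FALSE)
  identical(sort(as.integer(a)), sort(as.integer(b)))
}

# --- reading ----------------------------------------------------------------

parse_gt_token <- function(gt) {
  # Returns list(alleles = integer vector of raw allele indices (NA for '.'),
  #              phased = logical). gt may be NA (missing field).
  if (is.na(gt) || gt == "." || gt == "") {
    return(list(alleles = NA_integer_, phased = FALSE))
  }
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[/|]")[[1]]
  alle <- suppressWarnings(as.integer(ifelse(parts == ".", NA, parts)))
  list(alleles = alle, phased = phased)
}

#' Read a multi-sample VCF into the quad genotype model
#'
#' Reads a VCF v4.x file (plain or bgzipped) containing the four pedigree
#' members and normalizes it into biallelic, sex-consistent records:
#'
#' * multiallelic sites are decomposed into one biallelic record per
#'   alternate allele; genotypes are recoded so the chosen alternate becomes
#'   allele 1 and alleles belonging to any *other* alternate become missing,
#' * chromosome labels are normalized (the `"chr"` prefix is stripped,
#'   `"M"` becomes `"MT"`),
#' * male calls on chromosome X/Y are normalized to hemizygous: `0/0` becomes
#'   `0`, `1/1` becomes `1`, and a heterozygous male X call (impossible
#'   outside pseudoautosomal regions, which are not modeled) is flagged
#'   invalid-for-sex and treated as missing,
#' * records are returned sorted by (chromosome, position, alternate allele).
#'
#' Symbolic alleles (`<DEL>`, breakends, `*`) are skipped with a warning.
#' Per-sample `GT` is required; `GQ` and `DP` are consumed when present.
#'
#' @param vcf_path Path to the VCF file.
#' @param pedigree A [quad_pedigree]; its sample ids must all be present in
#'   the VCF (extra samples are ignored).
#' @return An object of class `quad_variants`.
#' @export
read_quad_vcf <- function(vcf_path, pedigree) {
  stopifnot(inherits(pedigree, "quad_pedigree"))
  if (!file.exists(vcf_path))
    qp_stop("io", "VCF file not found: %s", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)

  fix <- v@fix
  gt <- v@gt
  n_in <- nrow(fix)
  samples <- colnames(gt)[-1]
  missing_samples <- setdiff(pedigree$sample_id, samples)
  if (length(missing_samples) > 0)
    qp_stop("sample_not_in_vcf", "sample not in VCF: %s",
            paste(missing_samples, collapse = ", "))

  if (n_in == 0L) {
    sites <- data.frame(chrom = character(), pos = integer(),
                        id = character(), ref = character(),
                        alt = character(), stringsAsFactors = FALSE)
    z <- empty_role_matrix(0L)
    return(new_quad_variants(sites, z, z, z, empty_role_matrix(0L, NA), z, z,
                             pedigree))
  }

  # Per-sample FORMAT fields parsed directly from the genotype matrix
  # (robust to duplicate IDs and per-record FORMAT layouts).
  fmt_split <- strsplit(gt[, "FORMAT"], ":", fixed = TRUE)
  sample_split <- lapply(pedigree$sample_id,
                         function(s) strsplit(gt[, s], ":", fixed = TRUE))
  extract_field <- function(el) {
    idx <- vapply(fmt_split, function(f) match(el, f), integer(1))
    vapply(sample_split, function(ss) {
      mapply(function(x, i) {
        if (is.na(i) || length(x) < i || is.na(x[1])) NA_character_ else x[i]
      }, ss, idx, USE.NAMES = FALSE)
    }, character(n_in))
  }
  gt_idx <- vapply(fmt_split, function(f) match("GT", f), integer(1))
  if (anyNA(gt_idx))
    qp_stop("gt_required", "GT required: every record needs a GT FORMAT field")
  as_int <- function(m) {
    matrix(suppressWarnings(as.integer(as.numeric(m))), nrow = n_in)
  }
  gt_raw <- matrix(extract_field("GT"), nrow = n_in)
  gq_raw <- as_int(extract_field("GQ"))
  dp_raw <- as_int(extract_field("DP"))

  chrom_in <- normalize_chrom(fix[, "CHROM"])
  pos_in <- as.integer(fix[, "POS"])
  id_in <- ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"])
  ref_in <- fix[, "REF"]
  alt_in <- fix[, "ALT"]

  # Decompose multiallelic sites: one biallelic record per alternate allele.
  alt_split <- strsplit(alt_in, ",", fixed = TRUE)
  n_alts <- lengths(alt_split)
  i_vec <- rep.int(seq_len(n_in), n_alts)
  k_vec <- unlist(lapply(n_alts, seq_len), use.names = FALSE)
  alt_vec <- unlist(alt_split, use.names = FALSE)
  symbolic <- grepl("<", alt_vec, fixed = TRUE) |
    grepl("[", alt_vec, fixed = TRUE) | grepl("]", alt_vec, fixed = TRUE) |
    alt_vec == "*" | alt_vec == "."
  if (any(symbolic)) {
    warning(sprintf("skipped %d symbolic/spanning alternate allele(s)",
                    sum(symbolic)))
    i_vec <- i_vec[!symbolic]; k_vec <- k_vec[!symbolic]
    alt_vec <- alt_vec[!symbolic]
  }

  n <- length(i_vec)
  sites <- data.frame(chrom = chrom_in[i_vec], pos = pos_in[i_vec],
                      id = id_in[i_vec], ref = ref_in[i_vec], alt = alt_vec,
                      stringsAsFactors = FALSE)

  a1 <- empty_role_matrix(n); a2 <- empty_role_matrix(n)
  ploidy <- empty_role_matrix(n); phased <- empty_role_matrix(n, NA)
  gq <- empty_role_matrix(n); dp <- empty_role_matrix(n)

  # Genotype recoding: the chosen alternate (allele index k) becomes 1,
  # alleles of other alternates become missing. Each distinct (GT string, k)
  # pair is parsed once and broadcast by lookup.
  recode <- function(a, k) ifelse(is.na(a), NA_integer_,
                                  ifelse(a == 0L, 0L,
                                         ifelse(a == k, 1L, NA_integer_)))
  for (r in if (n > 0) seq_along(QP_ROLES) else integer(0)) {
    g <- gt_raw[i_vec, r]
    pair <- paste(ifelse(is.na(g), ".", g), k_vec)
    first <- which(!duplicated(pair))
    parsed <- lapply(first, function(j) {
      p <- parse_gt_token(g[j])
      alle <- recode(p$alleles, k_vec[j])
      pl <- length(alle)
      if (pl > 2L) { alle <- c(NA_integer_, NA_integer_); pl <- 2L }
      c(a1 = alle[1], a2 = if (pl == 2L) alle[2] else NA_integer_,
        ploidy = pl, phased = as.integer(p$phased))
    })
    tab <- do.call(rbind, parsed)
    idx <- match(pair, pair[first])
    a1[, r] <- tab[idx, "a1"]
    a2[, r] <- tab[idx, "a2"]
    ploidy[, r] <- tab[idx, "ploidy"]
    phased[, r] <- as.logical(tab[idx, "phased"])
    gq[, r] <- gq_raw[i_vec, r]
    dp[, r] <- dp_raw[i_vec, r]
  }

  qv <- new_quad_variants(sites, a1, a2, ploidy, phased, gq, dp, pedigree)
  qv <- normalize_sex_chrom_calls(qv)
  ord <- order(chrom_rank(qv$sites$chrom), qv$sites$pos, qv$sites$alt)
  qv_subset(qv, ord)
}

# Enforce sex-consistent ploidy after decomposition. All of chrX is treated
# as non-pseudoautosomal.
normalize_sex_chrom_calls <- function(qv) {
  male <- QP_ROLES[qv$pedigree$sex == "male"]
  female <- setdiff(QP_ROLES, male)
  on_x <- qv$sites$chrom == "X"
  on_y <- qv$sites$chrom == "Y"
  n_invalid <- 0L
  for (r in male) {
    hemi <- on_x | on_y
    dip <- hemi & qv$ploidy[, r] == 2L
    het <- dip & !is.na(qv$a1[, r]) & !is.na(qv$a2[, r]) &
      qv$a1[, r] != qv$a2[, r]
    n_invalid <- n_invalid + sum(het)
    # homozygous diploid -> hemizygous of that allele; het/partial -> missing
    new_a1 <- ifelse(het | is.na(qv$a1[, r]) | is.na(qv$a2[, r]) |
                       qv$a1[, r] != qv$a2[, r],
                     NA_integer_, qv$a1[, r])
    qv$a1[dip, r] <- new_a1[dip]
    qv$a2[hemi, r] <- NA_integer_
    qv$ploidy[hemi, r] <- 1L
  }
  for (r in female) {
    # hemizygous calls for a female (or on an autosome, below) are invalid
    hap_x <- on_x & qv$ploidy[, r] == 1L
    if (any(hap_x)) {
      n_invalid <- n_invalid + sum(hap_x)
      qv$a1[hap_x, r] <- NA_integer_
      qv$a2[hap_x, r] <- NA_integer_
      qv$ploidy[hap_x, r] <- 2L
    }
    if (any(on_y)) { # females carry no Y
      qv$a1[on_y, r] <- NA_integer_
      qv$a2[on_y, r] <- NA_integer_
      qv$ploidy[on_y, r] <- 2L
    }
  }
  auto <- !(on_x | on_y)
  for (r in QP_ROLES) {
    hap_auto <- auto & qv$ploidy[, r] == 1L
    if (any(hap_auto)) {
      n_invalid <- n_invalid + sum(hap_auto)
      qv$a1[hap_auto, r] <- NA_integer_
      qv$a2[hap_auto, r] <- NA_integer_
      qv$ploidy[hap_auto, r] <- 2L
    }
  }
  if (n_invalid > 0)
    warning(sprintf(
      "%d genotype call(s) invalid for sample sex/ploidy treated as missing",
      n_invalid))
  qv
}

# --- writing ----------------------------------------------------------------

#' Write quad variant records as a VCF file
#'
#' Emits a plain-text VCF v4.2 with the four pedigree samples (columns in
#' role order proband, mother, father, sibling) and FORMAT `GT:GQ:DP`,
#' plus provenance header lines. Reading the result back with
#' [read_quad_vcf()] recovers the same records.
#'
#' @param qv A `quad_variants` object.
#' @param path Output path.
#' @param extra_header Optional character vector of additional `##` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_quad_vcf <- function(qv, path, extra_header = character()) {
  stopifnot(inherits(qv, "quad_variants"))
  ped <- qv$pedigree
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=quadprio-%s",
            as.character(utils::packageVersion("quadprio"))),
    extra_header,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ped$sample_id), collapse = "\t"))
  fmt_int <- function(x) ifelse(is.na(x), ".", as.character(x))
  sample_cols <- lapply(QP_ROLES, function(r) {
    paste(geno_string(qv, r), fmt_int(qv$gq[, r]), fmt_int(qv$dp[, r]),
          sep = ":")
  })
  body <- do.call(paste, c(list(qv$sites$chrom, qv$sites$pos, qv$sites$id,
                                qv$sites$ref, qv$sites$alt, ".", ".", ".",
                                "GT:GQ:DP"),
                           sample_cols, list(sep = "\t")))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @export
print.quad_variants <- function(x, ...) {
  cat(sprintf("quad_variants: %d biallelic record(s), 4 samples\n", qv_n(x)))
  if (qv_n(x) > 0) {
    df <- x$sites
    for (r in QP_ROLES) df[[r]] <- geno_string(x, r)
    print(utils::head(df, 10), row.names = FALSE)
    if (qv_n(x) > 10) cat(sprintf("  ... and %d more\n", qv_n(x) - 10))
  }
  invisible(x)
}
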