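# Worked-example fixture: a deterministic quad call set whose five expected
# candidates exercise all four inheritance models — a de novo BAG3 missense
# change, a compound-heterozygous trio in NRAP (one rare paternal member,
# two common maternal members rescued by the at-least-one-rare rule) and a
# rare X-linked FHL1 variant inherited from the carrier mother — plus one
# decoy per filter stage. Genomic positions (except the FHL1 site) are
# synthetic placeholders; genotypes, rsIDs, genes and population MAFs follow
# the reported family.

worked_example_table <- function() {
  # columns: chrom pos id ref alt gene class maf hgvs_c hgvs_p
  #          gt P/M/F/S, proband GQ override, expected fate
  v <- rbind(
    c("10", "121436625", ".", "C", "T", "BAG3", "nonsynonymous", NA,
      "c.626C>T", "p.P209L", "0/1", "0/0", "0/0", "0/0", NA, "candidate"),
    c("10", "115371950", "rs200747403", "G", "A", "NRAP", "nonsynonymous",
      "0.0004", "c.3674G>A", "p.A1225V", "0/1", "0/0", "0/1", "0/0", NA,
      "candidate"),
    c("10", "115384060", "rs2270182", "T", "A", "NRAP", "nonsynonymous",
      "0.25", "c.1556T>A", "p.N519I", "0/1", "0/1", "0/0", "0/0", NA,
      "candidate"),
    c("10", "115399470", "rs2275799", "C", "T", "NRAP", "nonsynonymous",
      "0.27", "c.844C>T", "p.A282T", "0/1", "0/1", "0/0", "0/0", NA,
      "candidate"),
    c("X", "135291325", "rs151315725", "G", "A", "FHL1", "nonsynonymous",
      "0.0048", "c.823G>A", "p.D275N", "0/1", "0/1", "0", "0", NA,
      "candidate"),
    # one decoy per stage, each violating exactly that stage's rule
    c("2", "179400000", ".", "G", "A", "TTN", "nonsynonymous", "0.001",
      ".", ".", "0/1", "0/0", "0/0", "0/0", "30", "quality"),
    c("2", "220283000", ".", "C", "T", "DES", "synonymous", "0.001",
      ".", ".", "0/1", "0/0", "0/0", "0/0", NA, "functional"),
    c("5", "137221000", ".", "A", "G", "MYOT", "nonsynonymous", "0.002",
      ".", ".", "0/1", "0/0", "0/0", "0/1", NA, "family"),
    c("11", "111780000", ".", "G", "A", "CRYAB", "nonsynonymous", "0.05",
      ".", ".", "0/1", "0/0", "0/0", "0/0", NA, "rarity"),
    c("4", "74270000", ".", "C", "A", "ALB", "nonsynonymous", "0.0001",
      ".", ".", "0/1", "0/0", "0/0", "0/0", NA, "muscle_gene"))
  df <- as.data.frame(v, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "pos", "id", "ref", "alt", "gene",
                 "functional_class", "maf", "hgvs_c", "hgvs_p",
                 "gt_proband", "gt_mother", "gt_father", "gt_sibling",
                 "gq_proband", "fate")
  df$pos <- as.integer(df$pos)
  df
}

#' Write the worked-example quad fixture
#'
#' Emits a complete, deterministic input set for [prioritize()]: a VCF with
#' the four family members, the PED file, the annotation table, and a
#' muscle-expressed gene list. It contains the five expected candidate
#' variants — a heterozygous de novo BAG3 missense change (absent from the
#' reference population), three NRAP variants forming a compound
#' heterozygote (rare paternal rs200747403, MAF 0.0004; common maternal
#' rs2270182 and rs2275799, MAF 0.25 and 0.27, retained through the
#' gene-level at-least-one-rare rule) and the X-linked FHL1 variant
#' rs151315725 (MAF 0.0048, heterozygous carrier mother,
#' hemizygous-reference father and brother) — plus five decoys, each built
#' to fail exactly one cascade stage (low proband GQ; synonymous class;
#' shared with the sibling; common at MAF 0.05 under a de novo pattern; a
#' non-muscle gene). The unaffected brother is set homozygous/hemizygous
#' reference at the candidate sites, the only configuration consistent with
#' the family discard rule and his unaffected status.
#'
#' Positions other than the FHL1 site are synthetic placeholders; the
#' fixture is for validating the cascade, not for genome-coordinate lookup.
#'
#' @param out_dir Output directory (created if needed).
#' @return A list with `paths` (vcf, ped, annotations, genes), the
#'   `pedigree`, and `expected`: a data frame of the fixture's variants
#'   with their intended fate (`"candidate"` or the name of the stage each
#'   decoy fails).
#' @export
make_worked_example <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- worked_example_table()
  ped <- quad_pedigree(
    sample_id = c("PATIENT", "MOTHER", "FATHER", "BROTHER"),
    role = QP_ROLES,
    sex = c("female", "female", "male", "male"),
    affected = c(TRUE, FALSE, FALSE, FALSE))

  paths <- list(vcf = file.path(out_dir, "quad.vcf"),
                ped = file.path(out_dir, "quad.ped"),
                annotations = file.path(out_dir, "annotations.tsv"),
                genes = file.path(out_dir, "genes.txt"))

  write_ped(ped, paths$ped)

  gq <- ifelse(is.na(tab$gq_proband), "99", tab$gq_proband)
  fmt <- function(gt, q) paste(gt, q, "50", sep = ":")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=quadprio worked-example fixture (synthetic positions)",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ped$sample_id), collapse = "\t"))
  ord <- order(chrom_rank(tab$chrom), tab$pos, tab$alt)
  tabo <- tab[ord, , drop = FALSE]
  gqo <- gq[ord]
  body <- paste(tabo$chrom, tabo$pos, tabo$id, tabo$ref, tabo$alt, ".", ".",
                ".", "GT:GQ:DP",
                fmt(tabo$gt_proband, gqo), fmt(tabo$gt_mother, "99"),
                fmt(tabo$gt_father, "99"), fmt(tabo$gt_sibling, "99"),
                sep = "\t")
  writeLines(c(header, body), paths$vcf)

  ann <- data.frame(chrom = tab$chrom, pos = tab$pos, ref = tab$ref,
                    alt = tab$alt, gene = tab$gene,
                    functional_class = tab$functional_class,
                    maf_1kg = ifelse(is.na(tab$maf), ".", tab$maf),
                    hgvs_c = tab$hgvs_c, hgvs_p = tab$hgvs_p,
                    predicted_deleterious = ".",
                    stringsAsFactors = FALSE)
  utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")

  writeLines(c("BAG3", "NRAP", "FHL1", "DES", "CRYAB", "MYOT", "LDB3",
               "FLNC", "TTN", "MYH10"), paths$genes)

  expected <- tab[, c("chrom", "pos", "ref", "alt", "id", "gene", "fate")]
  expected$key <- variant_key(expected$chrom, expected$pos, expected$ref,
                              expected$alt)
  list(paths = paths, pedigree = ped, expected = expected)
}
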