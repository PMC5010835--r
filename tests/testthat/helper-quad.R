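# Shared fixture builders: in-code VCF/PED/annotation writers so every test
# input is generated at run time.

test_ped <- function(proband_sex = "female", sibling_sex = "male") {
  quad_pedigree(
    sample_id = c("PATIENT", "MOTHER", "FATHER", "SIB"),
    role = c("proband", "mother", "father", "sibling"),
    sex = c(proband_sex, "female", "male", sibling_sex),
    affected = c(TRUE, FALSE, FALSE, FALSE))
}

vcf_header <- function(sample_ids) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
}

# df columns: chrom, pos, ref, alt, gt_proband, gt_mother, gt_father,
# gt_sibling; optional id, and per-role gq_*/dp_* (defaults 99/50).
write_test_vcf <- function(df, ped = test_ped(),
                           path = tempfile(fileext = ".vcf")) {
  g <- function(col, default) {
    if (is.null(df[[col]])) rep(default, nrow(df)) else df[[col]]
  }
  cell <- function(role) {
    paste(df[[paste0("gt_", role)]], g(paste0("gq_", role), "99"),
          g(paste0("dp_", role), "50"), sep = ":")
  }
  body <- paste(df$chrom, df$pos, g("id", "."), df$ref, df$alt, ".", ".",
                ".", "GT:GQ:DP", cell("proband"), cell("mother"),
                cell("father"), cell("sibling"), sep = "\t")
  writeLines(c(vcf_header(ped$sample_id), body), path)
  path
}

read_test_quad <- function(df, ped = test_ped()) {
  read_quad_vcf(write_test_vcf(df, ped), ped)
}

# Annotation table writer; df columns chrom, pos, ref, alt plus optional
# gene, functional_class, maf (character), hgvs_c, hgvs_p.
write_test_annotations <- function(df, path = tempfile(fileext = ".tsv")) {
  g <- function(col, default) {
    if (is.null(df[[col]])) rep(default, nrow(df)) else df[[col]]
  }
  out <- data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref,
                    alt = df$alt, gene = g("gene", "GENE1"),
                    functional_class = g("functional_class", "nonsynonymous"),
                    maf_1kg = g("maf", "."),
                    hgvs_c = g("hgvs_c", "."), hgvs_p = g("hgvs_p", "."),
                    predicted_deleterious = ".", stringsAsFactors = FALSE)
  for (cl in names(out)) out[[cl]][is.na(out[[cl]])] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# One-call builder: variants + matching annotations -> annotated container.
annotated_quad <- function(df, ped = test_ped()) {
  qv <- read_test_quad(df, ped)
  annotate(qv, load_annotation_table(write_test_annotations(df)))
}

write_test_genes <- function(genes, path = tempfile(fileext = ".txt")) {
  writeLines(genes, path)
  path
}

write_test_ped_file <- function(ped = test_ped(),
                                path = tempfile(fileext = ".ped")) {
  write_ped(ped, path)
}

# All three diploid genotypes and the hemizygous pair, for enumerations.
DIPLOID_GTS <- c("0/0", "0/1", "1/1")
HAPLOID_GTS <- c("0", "1")
gt_alt_count <- function(gt) {
  vapply(strsplit(gt, "/", fixed = TRUE),
         function(x) sum(x == "1"), integer(1))
}
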