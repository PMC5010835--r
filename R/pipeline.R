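# End-to-end orchestration: quality -> functional -> family -> inheritance
# models -> rarity -> muscle genes, with a per-variant filter trace, stage
# count conservation, and diff-able TSV outputs.

REPORT_COLUMNS <- c("key", "rsid", "gene", "functional_class", "hgvs_c",
                    "hgvs_p", "maf", "models", "parental_origin",
                    "compound_partners", "gt_proband", "gt_mother",
                    "gt_father", "gt_sibling")

#' Assemble a run configuration
#'
#' Collects the input paths and tunable parameters of one prioritization
#' run. All referenced paths must exist.
#'
#' @param vcf,ped,annotations,genes Paths to the multi-sample VCF, the
#'   6-column PED file, the tab-separated annotation table and the
#'   muscle-expressed gene list.
#' @param out_dir Output directory for the report, filter trace and
#'   candidate VCF; `NULL` to skip writing files.
#' @param thresholds A [quality_thresholds] object.
#' @param rarity A [rarity_rule] object.
#' @return An object of class `run_config`.
#' @export
run_config <- function(vcf, ped, annotations, genes, out_dir = NULL,
                       thresholds = quality_thresholds(),
                       rarity = rarity_rule()) {
  for (p in c(vcf, ped, annotations, genes))
    if (!file.exists(p)) qp_stop("io", "input path does not exist: %s", p)
  stopifnot(inherits(thresholds, "quality_thresholds"),
            inherits(rarity, "rarity_rule"))
  structure(list(vcf = vcf, ped = ped, annotations = annotations,
                 genes = genes, out_dir = out_dir, thresholds = thresholds,
                 rarity = rarity),
            class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' Recognized keys: `vcf`, `ped`, `annotations`, `genes`, `out_dir`,
#' `min_gq`, `min_dp`, `max_maf`. Arguments passed via `...` override the
#' file (mirroring command-line flags overriding the config file).
#'
#' @param json_path Path to the JSON configuration.
#' @param ... Overrides for any recognized key.
#' @return A [run_config] object.
#' @export
load_run_config <- function(json_path, ...) {
  if (!file.exists(json_path))
    qp_stop("io", "config file not found: %s", json_path)
  cfg <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  dots <- list(...)
  for (k in names(dots)) cfg[[k]] <- dots[[k]]
  needed <- c("vcf", "ped", "annotations", "genes")
  missing_keys <- setdiff(needed, names(cfg))
  if (length(missing_keys) > 0)
    qp_stop("config", "config lacks key(s): %s",
            paste(missing_keys, collapse = ", "))
  run_config(vcf = cfg$vcf, ped = cfg$ped, annotations = cfg$annotations,
             genes = cfg$genes, out_dir = cfg$out_dir,
             thresholds = quality_thresholds(
               min_gq = if (is.null(cfg$min_gq)) 50L else cfg$min_gq,
               min_dp = if (is.null(cfg$min_dp)) 7L else cfg$min_dp),
             rarity = rarity_rule(
               max_maf = if (is.null(cfg$max_maf)) 0.01 else cfg$max_maf))
}

# Stage order is fixed; rarity runs after model assignment because the
# compound-het rarity relaxation is model-dependent.
QP_STAGES <- c("quality", "functional", "family", "model", "rarity",
               "muscle_gene")

#' Prioritize candidate variants in a family quad
#'
#' Runs the full cascade on a quad exome call set: per-sample genotype
#' quality filtering, restriction to protein-changing variants, the
#' family-genotype discard rule, classification under the four inheritance
#' models (dominant de novo, autosomal recessive, compound heterozygous,
#' X-linked), the population rarity rule (with the gene-level
#' at-least-one-rare relaxation for compound heterozygotes) and finally the
#' muscle-expressed gene restriction.
#'
#' The run is deterministic: two runs on identical inputs produce
#' byte-identical outputs. When `config$out_dir` is set, three files are
#' written there: `candidate_report.tsv`, `filter_trace.tsv` and
#' `candidates.vcf`. An empty candidate set is a valid outcome.
#'
#' Chromosome Y and MT variants support none of the four models and are set
#' aside at the model stage with a notice.
#'
#' @param config A [run_config] object.
#' @return An object of class `candidate_report` with elements
#'   `candidates` (one row per candidate, sorted by chromosome, position,
#'   alternate allele), `summary` (per-stage counts satisfying
#'   input = passes + failures), `trace` (per-variant verdicts), and
#'   `paths` (output files, if written).
#' @export
prioritize <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ped <- load_pedigree(config$ped)
  qv <- read_quad_vcf(config$vcf, ped)
  lookup <- load_annotation_table(config$annotations)
  gene_list <- load_gene_list(config$genes)
  av <- annotate(qv, lookup)

  n0 <- qv_n(av)
  keys <- qv_keys(av)
  stage <- rep(NA_character_, n0)   # stage at which the record failed
  reason <- rep(NA_character_, n0)
  alive <- rep(TRUE, n0)
  summary_rows <- list()

  note_stage <- function(name, verdict) {
    idx <- which(alive)
    fail <- idx[!verdict$pass]
    stage[fail] <<- name
    reason[fail] <<- verdict$reason[!verdict$pass]
    alive[fail] <<- FALSE
    summary_rows[[name]] <<- data.frame(
      stage = name, n_in = length(idx), n_pass = sum(verdict$pass),
      n_fail = sum(!verdict$pass), stringsAsFactors = FALSE)
  }

  note_stage("quality", quality_filter(qv_subset(av, which(alive)),
                                       config$thresholds))
  note_stage("functional", functional_filter(qv_subset(av, which(alive))))
  note_stage("family", family_genotype_filter(qv_subset(av, which(alive))))

  # --- model classification stage ------------------------------------------
  surv <- qv_subset(av, which(alive))
  n_surv <- qv_n(surv)
  chrom <- surv$sites$chrom
  auto <- is_autosome(chrom)
  on_x <- chrom == "X"
  excluded <- !auto & !on_x
  if (any(excluded))
    message(sprintf(
      "%d variant(s) on chrY/MT excluded from inheritance models",
      sum(excluded)))

  models <- rep("", n_surv)
  origin <- rep(NA_character_, n_surv)
  partners <- rep(NA_character_, n_surv)

  if (any(auto)) {
    qa <- qv_subset(surv, which(auto))
    dn <- classify_dominant_de_novo(qa)
    ar <- classify_recessive(qa)
    ch <- find_compound_het(qa)
    m_auto <- character(qv_n(qa))
    m_auto[dn] <- "dominant_de_novo"
    m_auto[ar] <- paste0(ifelse(m_auto[ar] == "", "",
                                paste0(m_auto[ar], ",")),
                         "autosomal_recessive")
    o_auto <- rep(NA_character_, qv_n(qa))
    o_auto[dn] <- "de_novo"
    o_auto[ar] <- "both"
    p_auto <- rep(NA_character_, qv_n(qa))
    if (nrow(ch) > 0) {
      i_ch <- match(ch$key, qv_keys(qa))
      m_auto[i_ch] <- ifelse(m_auto[i_ch] == "", "compound_het",
                             paste0(m_auto[i_ch], ",compound_het"))
      o_auto[i_ch] <- ch$origin
      p_auto[i_ch] <- ch$partners
    }
    models[auto] <- m_auto
    origin[auto] <- o_auto
    partners[auto] <- p_auto
  }
  if (any(on_x)) {
    qx <- qv_subset(surv, which(on_x))
    xl <- classify_x_linked(qx)
    m_x <- character(qv_n(qx))
    m_x[xl] <- "x_linked"
    o_x <- rep(NA_character_, qv_n(qx))
    o_x[xl] <- "maternal"   # carrier mother, hemizygous-reference father
    models[on_x] <- m_x
    origin[on_x] <- o_x
  }
  model_pass <- models != ""
  note_stage("model",
             data.frame(key = qv_keys(surv), pass = model_pass,
                        reason = ifelse(model_pass, NA_character_,
                                        ifelse(excluded,
                                               "chrom-not-modeled",
                                               "no-model")),
                        stringsAsFactors = FALSE))

  # --- rarity stage ---------------------------------------------------------
  cand_idx <- which(model_pass)
  candidates <- data.frame(
    key = qv_keys(surv)[cand_idx],
    gene = surv$ann$gene[cand_idx],
    maf = surv$ann$maf[cand_idx],
    models = models[cand_idx],
    origin = origin[cand_idx],
    partners = partners[cand_idx],
    stringsAsFactors = FALSE)
  kept <- apply_rarity(candidates, config$rarity)
  rare_pass <- candidates$key %in% kept$key
  note_stage("rarity",
             data.frame(key = candidates$key, pass = rare_pass,
                        reason = ifelse(rare_pass, NA_character_,
                                        "common-variant"),
                        stringsAsFactors = FALSE))
  # surviving model sets may have shrunk
  candidates <- kept

  # --- muscle gene stage ----------------------------------------------------
  surv2 <- qv_subset(av, which(alive))
  gene_verdict <- muscle_gene_filter(surv2, gene_list)
  note_stage("muscle_gene", gene_verdict)
  candidates <- candidates[candidates$key %in% gene_verdict$key[gene_verdict$pass], ,
                           drop = FALSE]

  # --- assemble report ------------------------------------------------------
  final <- qv_subset(av, which(alive))
  stopifnot(identical(sort(qv_keys(final)), sort(candidates$key)))
  ord <- match(qv_keys(final), candidates$key)
  report <- data.frame(
    key = qv_keys(final),
    rsid = final$sites$id,
    gene = final$ann$gene,
    functional_class = final$ann$functional_class,
    hgvs_c = ifelse(is.na(final$ann$hgvs_c), ".", final$ann$hgvs_c),
    hgvs_p = ifelse(is.na(final$ann$hgvs_p), ".", final$ann$hgvs_p),
    maf = format_maf(final$ann$maf),
    models = candidates$models[ord],
    parental_origin = candidates$origin[ord],
    compound_partners = ifelse(is.na(candidates$partners[ord]), ".",
                               candidates$partners[ord]),
    gt_proband = geno_string(final, "proband"),
    gt_mother = geno_string(final, "mother"),
    gt_father = geno_string(final, "father"),
    gt_sibling = geno_string(final, "sibling"),
    stringsAsFactors = FALSE)
  report$maf_value <- final$ann$maf

  trace <- data.frame(
    key = keys,
    stage = ifelse(alive, "report", stage),
    verdict = ifelse(alive, "pass", "fail"),
    reason = ifelse(alive, ".", reason),
    stringsAsFactors = FALSE)

  summary <- do.call(rbind, summary_rows[QP_STAGES])
  rownames(summary) <- NULL

  out <- structure(list(candidates = report, summary = summary,
                        trace = trace, n_input = n0,
                        pedigree = ped, paths = NULL),
                   class = "candidate_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      report = file.path(config$out_dir, "candidate_report.tsv"),
      trace = file.path(config$out_dir, "filter_trace.tsv"),
      vcf = file.path(config$out_dir, "candidates.vcf"))
    utils::write.table(report[, REPORT_COLUMNS], paths$report, sep = "\t",
                       quote = FALSE, row.names = FALSE, eol = "\n")
    utils::write.table(trace, paths$trace, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    write_quad_vcf(final, paths$vcf,
                   extra_header = "##quadprio=prioritized candidate set")
    out$paths <- paths
  }
  out
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("Quad prioritization report: %d candidate(s) from %d record(s)\n",
              nrow(x$candidates), x$n_input))
  if (nrow(x$candidates) > 0) {
    cols <- c("key", "rsid", "gene", "models", "parental_origin", "maf")
    print(x$candidates[, cols], row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.candidate_report <- function(object, ...) {
  cat(sprintf("Input records: %d\n", object$n_input))
  print(object$summary, row.names = FALSE)
  fails <- object$trace[object$trace$verdict == "fail", ]
  if (nrow(fails) > 0) {
    cat("Failure reasons:\n")
    tab <- as.data.frame(table(stage = fails$stage, reason = fails$reason))
    print(tab[tab$Freq > 0, c("stage", "reason", "Freq")], row.names = FALSE)
  }
  invisible(object$summary)
}

#' Score candidate recovery against a simulation truth table
#'
#' Compares a [prioritize()] report with the ground truth of a simulated
#' data set: per model, the sensitivity (planted variants recovered with the
#' correct model label, over planted) and the number of model-labeled false
#' positives (reported candidates carrying that model that were not planted
#' with it).
#'
#' @param report A `candidate_report`.
#' @param truth A truth table as written by [simulate_quad()] (or read back
#'   from its `truth.tsv`): columns `key` and `model` are required.
#' @return A data frame of class `recovery_metrics` with one row per model:
#'   `model`, `n_planted`, `n_recovered`, `sensitivity`, `false_positives`.
#' @export
evaluate_recovery <- function(report, truth) {
  stopifnot(inherits(report, "candidate_report"),
            all(c("key", "model") %in% names(truth)))
  bad_models <- setdiff(unique(truth$model), QP_MODELS)
  if (length(bad_models) > 0)
    qp_stop("truth_models", "unknown model(s) in truth table: %s",
            paste(bad_models, collapse = ", "))
  rep_models <- strsplit(report$candidates$models, ",", fixed = TRUE)
  out <- do.call(rbind, lapply(QP_MODELS, function(m) {
    planted <- truth$key[truth$model == m]
    labeled <- report$candidates$key[vapply(rep_models,
                                            function(x) m %in% x,
                                            logical(1))]
    n_rec <- sum(planted %in% labeled)
    data.frame(model = m, n_planted = length(planted), n_recovered = n_rec,
               sensitivity = if (length(planted) > 0)
                 n_rec / length(planted) else NA_real_,
               false_positives = sum(!labeled %in% planted),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("recovery_metrics", "data.frame")
  out
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat("Per-model recovery against simulation truth\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
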