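#' Construct a quad pedigree
#'
#' A quad pedigree is a nuclear family of four: an affected proband, two
#' unaffected parents and one unaffected sibling. It anchors every
#' genotype-comparison rule in the prioritization cascade: the family-genotype
#' discard rule, the four inheritance-model classifiers and male X
#' hemizygosity all look up members by role and sex through this object.
#'
#' The proband may be of either sex (the X-linked classifier branches on it);
#' the mother must be female and the father male, and the three relatives must
#' be unaffected.
#'
#' @param sample_id Character vector of four unique sample identifiers.
#' @param role Character vector: one each of `"proband"`, `"mother"`,
#'   `"father"`, `"sibling"`.
#' @param sex Character vector of `"male"`/`"female"`.
#' @param affected Logical vector; exactly the proband must be `TRUE`.
#' @return An object of class `quad_pedigree`: a data frame with one row per
#'   role (ordered proband, mother, father, sibling).
#' @examples
#' quad_pedigree(
#'   sample_id = c("PATIENT", "MOTHER", "FATHER", "BROTHER"),
#'   role      = c("proband", "mother", "father", "sibling"),
#'   sex       = c("female", "female", "male", "male"),
#'   affected  = c(TRUE, FALSE, FALSE, FALSE))
#' @export
quad_pedigree <- function(sample_id, role, sex, affected) {
  if (length(sample_id) != 4L || length(role) != 4L ||
      length(sex) != 4L || length(affected) != 4L)
    qp_stop("quad_required", "a quad pedigree has exactly four members")
  role <- as.character(role)
  sex <- as.character(sex)
  if (!setequal(role, QP_ROLES) || anyDuplicated(role))
    qp_stop("invalid_roles",
            "roles must be exactly {proband, mother, father, sibling}")
  if (!all(sex %in% c("male", "female")))
    qp_stop("invalid_sex", "sex must be 'male' or 'female'")
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id) || any(!nzchar(sample_id)) || anyNA(sample_id))
    qp_stop("invalid_sample_id", "sample ids must be non-empty and unique")
  ped <- data.frame(sample_id = sample_id, role = role, sex = sex,
                    affected = as.logical(affected),
                    stringsAsFactors = FALSE)
  ped <- ped[match(QP_ROLES, ped$role), , drop = FALSE]
  rownames(ped) <- ped$role
  if (ped["mother", "sex"] != "female")
    qp_stop("invalid_parent_sex", "mother must be female")
  if (ped["father", "sex"] != "male")
    qp_stop("invalid_parent_sex", "father must be male")
  if (!isTRUE(ped["proband", "affected"]))
    qp_stop("no_proband", "the proband must be affected")
  if (any(ped[c("mother", "father", "sibling"), "affected"]))
    qp_stop("affected_relative",
            "mother, father and sibling must be unaffected")
  class(ped) <- c("quad_pedigree", "data.frame")
  ped
}

ped_sample <- function(ped, role) ped[role, "sample_id"]
ped_sex <- function(ped, role) ped[role, "sex"]

#' Load a quad pedigree from a PED file
#'
#' Reads a standard whitespace-delimited 6-column PED file (FamilyID,
#' IndividualID, PaternalID, MaternalID, Sex, Phenotype) describing exactly one
#' nuclear family of four. Roles are inferred from the parent pointers and the
#' affection column: the two founders are the parents (assigned mother/father
#' by sex), the affected child is the proband, the unaffected child the
#' sibling.
#'
#' Affection coding is strict: 2 = affected, 1 = unaffected; 0 or -9
#' (unknown) are rejected rather than guessed. Sex must be coded 1 (male) or
#' 2 (female).
#'
#' @param ped_path Path to the PED file.
#' @return A [quad_pedigree] object.
#' @seealso [write_ped()]
#' @export
load_pedigree <- function(ped_path) {
  if (!file.exists(ped_path))
    qp_stop("io", "PED file not found: %s", ped_path)
  tab <- utils::read.table(ped_path, header = FALSE, colClasses = "character",
                           col.names = c("fid", "iid", "pat", "mat", "sex",
                                         "pheno"),
                           stringsAsFactors = FALSE)
  if (nrow(tab) != 4L)
    qp_stop("quad_required",
            "quad required: PED file must contain exactly 4 samples, found %d",
            nrow(tab))
  if (length(unique(tab$fid)) != 1L)
    qp_stop("multiple_families", "PED file must describe a single family")
  if (!all(tab$sex %in% c("1", "2")))
    qp_stop("invalid_sex", "PED sex codes must be 1 (male) or 2 (female)")
  if (!all(tab$pheno %in% c("1", "2")))
    qp_stop("ambiguous_affection",
            "PED phenotype must be 1 (unaffected) or 2 (affected); 0/-9 are rejected")

  founder <- tab$pat == "0" & tab$mat == "0"
  if (sum(founder) != 2L)
    qp_stop("missing_parent_pointers",
            "expected exactly two founders (parents), found %d", sum(founder))
  parents <- tab[founder, , drop = FALSE]
  children <- tab[!founder, , drop = FALSE]
  if (any(children$pat == "0" | children$mat == "0"))
    qp_stop("missing_parent_pointers",
            "children must have both parent pointers set")
  father_id <- parents$iid[parents$sex == "1"]
  mother_id <- parents$iid[parents$sex == "2"]
  if (length(father_id) != 1L || length(mother_id) != 1L)
    qp_stop("invalid_parent_sex", "founders must be one male and one female")
  if (!all(children$pat == father_id) || !all(children$mat == mother_id))
    qp_stop("missing_parent_pointers",
            "child parent pointers must reference the two founders")
  if (any(parents$pheno == "2"))
    qp_stop("affected_relative", "parents must be unaffected")
  affected_child <- children$pheno == "2"
  if (sum(affected_child) > 1L)
    qp_stop("multiple_probands",
            "multiple probands: exactly one child may be affected")
  if (sum(affected_child) == 0L)
    qp_stop("no_proband", "no proband: one child must be affected")

  proband <- children[affected_child, , drop = FALSE]
  sibling <- children[!affected_child, , drop = FALSE]
  sex_label <- function(code) ifelse(code == "1", "male", "female")
  quad_pedigree(
    sample_id = c(proband$iid, mother_id, father_id, sibling$iid),
    role = QP_ROLES,
    sex = c(sex_label(proband$sex), "female", "male", sex_label(sibling$sex)),
    affected = c(TRUE, FALSE, FALSE, FALSE))
}

#' Write a quad pedigree to a PED file
#'
#' Emits the standard 6-column PED representation (tab-delimited, family id
#' `FAM1`). `load_pedigree(write_ped(p))` recovers `p`.
#'
#' @param ped A [quad_pedigree].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  stopifnot(inherits(ped, "quad_pedigree"))
  sex_code <- function(s) ifelse(s == "male", "1", "2")
  father <- ped_sample(ped, "father")
  mother <- ped_sample(ped, "mother")
  rows <- c(
    paste("FAM1", father, "0", "0", "1", "1", sep = "\t"),
    paste("FAM1", mother, "0", "0", "2", "1", sep = "\t"),
    paste("FAM1", ped_sample(ped, "proband"), father, mother,
          sex_code(ped_sex(ped, "proband")), "2", sep = "\t"),
    paste("FAM1", ped_sample(ped, "sibling"), father, mother,
          sex_code(ped_sex(ped, "sibling")), "1", sep = "\t"))
  writeLines(rows, path)
  invisible(path)
}

#' @export
print.quad_pedigree <- function(x, ...) {
  cat("Quad pedigree (1 family, 4 members)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
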