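#' @title Amino-acid alphabets
#' @description One-letter codes of the 20 canonical amino acids, and the
#'   three-letter to one-letter lookup used when normalizing HGVS protein
#'   notation.
#' @keywords internal
#' @name aa-alphabet
NULL

AA_ONE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
              Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
              Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
              Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

norm_aa <- function(x, what = "residue") {
  out <- character(length(x))
  three <- nchar(x) == 3L
  key <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3)))
  out[three] <- unname(AA_THREE[key[three]])
  out[!three] <- toupper(x[!three])
  bad <- is.na(out) | !(out %in% AA_ONE)
  if (any(bad)) {
    stop(sprintf("unknown %s code: %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Parse HGVS-style protein variant notation
#'
#' Parses strings such as `"p.P103Q"` or `"p.Pro103Gln"` into their
#' reference residue, 1-based protein position and alternate residue.
#' Three-letter residue codes are normalized to one-letter codes.
#' Synonymous changes (reference equal to alternate) are rejected: the
#' package models missense variants only.
#'
#' @param text character vector of HGVS-like protein changes
#'   (`p.<ref><pos><alt>`; the `p.` prefix is optional).
#' @return a data.frame with columns `ref_aa`, `position`, `alt_aa`.
#' @examples
#' parse_protein_variant(c("p.P103Q", "p.Ala5Gly"))
#' @export
parse_protein_variant <- function(text) {
  stopifnot(is.character(text), length(text) >= 1L)
  body <- sub("^p\\.", "", text)
  pat <- "^([A-Za-z]{1}|[A-Za-z]{3})([0-9]+)([A-Za-z]{1}|[A-Za-z]{3})$"
  ok <- grepl(pat, body)
  if (any(!ok)) {
    stop("malformed protein variant notation: ",
         paste(unique(text[!ok]), collapse = ", "), call. = FALSE)
  }
  ref <- norm_aa(sub(pat, "\\1", body), "reference residue")
  alt <- norm_aa(sub(pat, "\\3", body), "alternate residue")
  pos <- as.integer(sub(pat, "\\2", body))
  if (any(pos < 1L)) stop("protein positions are 1-based", call. = FALSE)
  syn <- ref == alt
  if (any(syn)) {
    stop("synonymous change (reference residue equals alternate) is not a ",
         "missense variant: ", paste(unique(text[syn]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(ref_aa = ref, position = pos, alt_aa = alt,
             stringsAsFactors = FALSE)
}

#' Format protein variants back to HGVS-style notation
#' @param variants data.frame with `ref_aa`, `position`, `alt_aa` columns.
#' @return character vector of `p.<ref><pos><alt>` strings.
#' @export
format_protein_variant <- function(variants) {
  paste0("p.", variants$ref_aa, variants$position, variants$alt_aa)
}

HGMD_LEVELS <- c("absent", "no_phenotype_dbSNP", "disease_causing",
                 "dm_questionable", "other")
CLINVAR_LEVELS <- c("absent", "benign", "likely_benign",
                    "benign_or_likely_benign", "vus", "pathogenic",
                    "likely_pathogenic", "other")
ENSEMBL_LEVELS <- c("absent", "present_no_phenotype",
                    "present_with_phenotype")
PATTERN_LEVELS <- c("single_disease", "two_opposite", "two_severity")
SEVERITY_LEVELS <- c("complete", "partial")
CLINVAR_BENIGNISH <- c("benign", "likely_benign", "benign_or_likely_benign")
CLASS_LEVELS <- c("DIS", "PART", "NO_PHEN", "EXCL")

check_enum <- function(x, levels, field) {
  x <- as.character(x)
  bad <- which(!(x %in% levels) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("invalid %s value(s) '%s' (row %s); expected one of: %s",
                 field, paste(unique(x[bad]), collapse = "', '"),
                 paste(head(bad, 5L), collapse = ", "),
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  x
}

validate_annotations <- function(records) {
  required <- c("hgmd_status", "clinvar_status", "ensembl_phenotype",
                "gene_disease_pattern")
  miss <- setdiff(required, names(records))
  if (length(miss)) {
    stop("annotation table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  records$hgmd_status <- check_enum(records$hgmd_status, HGMD_LEVELS,
                                    "hgmd_status")
  records$clinvar_status <- check_enum(records$clinvar_status,
                                       CLINVAR_LEVELS, "clinvar_status")
  records$ensembl_phenotype <- check_enum(records$ensembl_phenotype,
                                          ENSEMBL_LEVELS, "ensembl_phenotype")
  records$gene_disease_pattern <- check_enum(records$gene_disease_pattern,
                                             PATTERN_LEVELS,
                                             "gene_disease_pattern")
  if (is.null(records$severity_role)) records$severity_role <- NA_character_
  records$severity_role[records$severity_role %in% c("", "NA")] <-
    NA_character_
  records$severity_role <- check_enum(records$severity_role, SEVERITY_LEVELS,
                                      "severity_role")
  two_sev <- records$gene_disease_pattern == "two_severity"
  if (any(two_sev & is.na(records$severity_role))) {
    stop("severity_role must be given when gene_disease_pattern is ",
         "'two_severity' (row ",
         paste(head(which(two_sev & is.na(records$severity_role)), 5L),
               collapse = ", "), ")", call. = FALSE)
  }
  if (any(!two_sev & !is.na(records$severity_role))) {
    stop("severity_role is only meaningful when gene_disease_pattern is ",
         "'two_severity'", call. = FALSE)
  }
  if (!is.null(records$allele_frequency)) {
    if (any(records$allele_frequency < 0, na.rm = TRUE)) {
      stop("allele_frequency must be nonnegative", call. = FALSE)
    }
  }
  records
}

#' Assign clinical classes with the database classification key
#'
#' Walks the numbered clinical classification key over HGMD-, ClinVar- and
#' Ensembl-style annotation fields and assigns each variant one of four
#' classes: `DIS` (disease-associated, a DAV), `PART` (associated with the
#' milder of two severity-graded phenotypes), `NO_PHEN` (no
#' phenotype-associated, an NPAV) or `EXCL` (ambiguous, excluded).
#'
#' The walk is: step 1 on `hgmd_status` (absent or unspecific statuses go to
#' step 2, a dbSNP "no phenotype" entry is `NO_PHEN`, a disease-causing
#' entry goes to step 4); step 2 on `clinvar_status` (benign, likely benign
#' or VUS entries are `NO_PHEN`, anything else goes to step 3); step 3 on
#' `ensembl_phenotype` (present without phenotype is `NO_PHEN`, present with
#' phenotype goes to step 5); step 4 re-checks ClinVar for a
#' benign/likely-benign conflict with the disease-causing HGMD status
#' (conflict is `EXCL`, otherwise step 5); step 5 resolves the gene's
#' disease pattern (a single Mendelian disease or two opposite diseases are
#' `DIS`; two severity-graded diseases are `DIS` for the complete phenotype
#' and `PART` for the partial one).
#'
#' A variant that reaches step 3 while absent from the Ensembl-style source
#' has no phenotype evidence in any of the three sources; the key does not
#' cover this combination and such records are classified `EXCL` with an
#' explanatory reason (see the methods vignette).
#'
#' @param records data.frame of annotation records with columns
#'   `hgmd_status`, `clinvar_status`, `ensembl_phenotype`,
#'   `gene_disease_pattern` and (for `two_severity` genes) `severity_role`.
#' @param detail if `TRUE`, return a data.frame with the class, the path of
#'   key rows taken (e.g. `"1a-2b-3b-5a"`) and the exclusion reason;
#'   otherwise a factor of classes.
#' @return factor with levels `DIS`, `PART`, `NO_PHEN`, `EXCL`, or a
#'   data.frame when `detail = TRUE`.
#' @examples
#' classify_clinical(data.frame(hgmd_status = "absent",
#'   clinvar_status = "vus", ensembl_phenotype = "absent",
#'   gene_disease_pattern = "single_disease"))
#' @export
classify_clinical <- function(records, detail = FALSE) {
  records <- validate_annotations(records)
  n <- nrow(records)
  class <- character(n)
  path <- character(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    hgmd <- records$hgmd_status[i]
    clinvar <- records$clinvar_status[i]
    ensembl <- records$ensembl_phenotype[i]
    pattern <- records$gene_disease_pattern[i]
    severity <- records$severity_role[i]
    steps <- character(0)

    step5 <- function() {
      if (pattern == "single_disease") list("5a", "DIS")
      else if (pattern == "two_opposite") list("5b", "DIS")
      else if (severity == "complete") list("5c", "DIS")
      else list("5d", "PART")
    }

    if (hgmd == "no_phenotype_dbSNP") {
      steps <- "1b"; cls <- "NO_PHEN"
    } else if (hgmd == "disease_causing") {
      steps <- "1c"
      if (clinvar %in% CLINVAR_BENIGNISH) {
        steps <- c(steps, "4a"); cls <- "EXCL"
        reason[i] <- "HGMD disease-causing vs ClinVar benign/likely benign"
      } else {
        s5 <- step5()
        steps <- c(steps, "4b", s5[[1]]); cls <- s5[[2]]
      }
    } else {
      steps <- if (hgmd == "absent") "1a" else "1d"
      if (clinvar %in% c(CLINVAR_BENIGNISH, "vus")) {
        steps <- c(steps, "2a"); cls <- "NO_PHEN"
      } else if (ensembl == "present_no_phenotype") {
        steps <- c(steps, "2b", "3a"); cls <- "NO_PHEN"
      } else if (ensembl == "present_with_phenotype") {
        s5 <- step5()
        steps <- c(steps, "2b", "3b", s5[[1]]); cls <- s5[[2]]
      } else {
        steps <- c(steps, "2b", "3-"); cls <- "EXCL"
        reason[i] <- "no phenotype evidence in HGMD, ClinVar or Ensembl"
      }
    }
    class[i] <- cls
    path[i] <- paste(steps, collapse = "-")
  }
  cls <- factor(class, levels = CLASS_LEVELS)
  if (!detail) return(cls)
  data.frame(clinical_class = cls, key_path = path,
             exclusion_reason = reason, stringsAsFactors = FALSE)
}

#' Curation configuration
#'
#' Thresholds and switches for [apply_exclusion_filters()].  The population
#' frequency cutoff corresponds to the ExAC-style `f > 8` rule used to drop
#' benign variants with abundant high-quality data; the source does not
#' state its units, so it is kept configurable (see the methods vignette).
#'
#' @param freq_cutoff drop ClinVar benign/likely-benign variants whose
#'   `allele_frequency` exceeds this value (default 8).
#' @param drop_likely_nonphenotypic drop records flagged
#'   `likely_nonphenotypic` (e.g. hemoglobin variants listed as likely
#'   non-phenotypic); kept as a switch because the appropriate handling is
#'   dataset-dependent.
#' @return a list of class `curation_config`.
#' @export
curation_config <- function(freq_cutoff = 8,
                            drop_likely_nonphenotypic = FALSE) {
  stopifnot(is.numeric(freq_cutoff), freq_cutoff >= 0)
  structure(list(freq_cutoff = freq_cutoff,
                 drop_likely_nonphenotypic = drop_likely_nonphenotypic),
            class = "curation_config")
}

#' Apply curation exclusion filters
#'
#' Applies the pre-classification exclusion rules used when assembling a
#' clinical score dataset.  A record is dropped when any of the following
#' holds (rules are disjunctive, so order does not matter):
#'
#' 1. its evidence is limited to non-Mendelian disease (column
#'    `non_mendelian_only`, if present);
#' 2. it is ClinVar benign/likely benign with population frequency above
#'    `config$freq_cutoff`;
#' 3. its HGMD status is the questionable `DM?` category
#'    (`dm_questionable`);
#' 4. HGMD calls it disease-causing while ClinVar calls it benign or likely
#'    benign;
#' 5. optionally, it is flagged `likely_nonphenotypic` and the config says
#'    to drop such records.
#'
#' @param records annotation data.frame (see [classify_clinical()]); the
#'   optional logical columns `non_mendelian_only` and
#'   `likely_nonphenotypic` default to `FALSE`, and `allele_frequency`
#'   defaults to 0.
#' @param config a [curation_config()].
#' @return data.frame with logical `keep` and character `reason` (empty for
#'   kept records).
#' @examples
#' apply_exclusion_filters(data.frame(hgmd_status = "dm_questionable",
#'   clinvar_status = "absent", ensembl_phenotype = "absent",
#'   gene_disease_pattern = "single_disease"))
#' @export
apply_exclusion_filters <- function(records, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"))
  records <- validate_annotations(records)
  n <- nrow(records)
  freq <- if (is.null(records$allele_frequency)) rep(0, n) else
    records$allele_frequency
  freq[is.na(freq)] <- 0
  nonmend <- if (is.null(records$non_mendelian_only)) rep(FALSE, n) else
    isTRUE_vec(records$non_mendelian_only)
  likely_np <- if (is.null(records$likely_nonphenotypic)) rep(FALSE, n) else
    isTRUE_vec(records$likely_nonphenotypic)
  benignish <- records$clinvar_status %in% CLINVAR_BENIGNISH

  reason <- character(n)
  hit <- function(cond, msg) {
    new <- cond & reason == ""
    reason[new] <<- msg
  }
  hit(nonmend, "evidence limited to non-Mendelian disease")
  hit(benignish & freq > config$freq_cutoff,
      "benign/likely benign with high population frequency")
  hit(records$hgmd_status == "dm_questionable",
      "HGMD DM? (questionable disease-causing status)")
  hit(records$hgmd_status == "disease_causing" & benignish,
      "HGMD disease-causing vs ClinVar benign/likely benign")
  if (config$drop_likely_nonphenotypic) {
    hit(likely_np, "flagged likely non-phenotypic")
  }
  data.frame(keep = reason == "", reason = reason, stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Curate an annotation table into classified variant records
#'
#' Convenience wrapper chaining [apply_exclusion_filters()] and
#' [classify_clinical()]: records dropped by a filter are classified `EXCL`
#' with the filter's reason; the rest are classified by the key.
#'
#' @inheritParams apply_exclusion_filters
#' @return the input data.frame with `clinical_class`, `key_path` and
#'   `exclusion_reason` columns appended; `clinical_class` is `EXCL` exactly
#'   when `exclusion_reason` is non-empty.
#' @export
curate_variants <- function(records, config = curation_config()) {
  filt <- apply_exclusion_filters(records, config)
  keyed <- classify_clinical(records, detail = TRUE)
  cls <- as.character(keyed$clinical_class)
  path <- keyed$key_path
  reason <- keyed$exclusion_reason
  dropped <- !filt$keep
  cls[dropped] <- "EXCL"
  reason[dropped] <- filt$reason[dropped]
  path[dropped] <- "filtered"
  records$clinical_class <- factor(cls, levels = CLASS_LEVELS)
  records$key_path <- path
  records$exclusion_reason <- reason
  records
}
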