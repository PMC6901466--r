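#' Read a clinical annotation table
#'
#' Reads a tab-separated annotation table with columns `gene`, `hgvs_p`,
#' `hgmd_status`, `clinvar_status`, `ensembl_phenotype`,
#' `gene_disease_pattern`, `severity_role`, `allele_frequency` and
#' (optionally) `acmg_label`, `non_mendelian_only`, `likely_nonphenotypic`.
#' Enum columns are validated with row numbers; the HGVS column is parsed
#' and normalized into `ref_aa`, `position`, `alt_aa`.
#'
#' @param path path to a TSV file.
#' @return validated annotation data.frame.
#' @export
read_annotations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("gene", "hgvs_p", "hgmd_status", "clinvar_status",
                "ensembl_phenotype", "gene_disease_pattern",
                "severity_role", "allele_frequency")
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop("annotation file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) return(validate_annotations(tab))
  if (!is.numeric(tab$allele_frequency)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$allele_frequency))) &
                   !is.na(tab$allele_frequency))
    if (length(bad)) {
      stop("non-numeric allele_frequency on line ",
           paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
    }
    tab$allele_frequency <- as.numeric(tab$allele_frequency)
  }
  tab$allele_frequency[is.na(tab$allele_frequency)] <- 0
  parsed <- parse_protein_variant(tab$hgvs_p)
  tab$ref_aa <- parsed$ref_aa
  tab$position <- parsed$position
  tab$alt_aa <- parsed$alt_aa
  validate_annotations(tab)
}

#' Read a predictor score table
#'
#' Reads a tab-separated score table with columns `gene`, `hgvs_p`,
#' `predictor`, `score`.  Scores must be numeric; offending lines are
#' reported by number.
#'
#' @param path path to a TSV file.
#' @return data.frame with the four columns, `score` numeric.
#' @export
read_scores <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = list(score = "character"))
  required <- c("gene", "hgvs_p", "predictor", "score")
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop("score file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  num <- suppressWarnings(as.numeric(tab$score))
  bad <- which(is.na(num))
  if (length(bad)) {
    stop("non-numeric score on line ", paste(bad + 1L, collapse = ", "),
         " of ", path, call. = FALSE)
  }
  tab$score <- num
  if (nrow(tab)) parse_protein_variant(tab$hgvs_p)  # validates notation
  tab
}

#' Write classified variant records to TSV
#'
#' Writes the output of [curate_variants()] (or any annotation data.frame)
#' as a TSV that [read_records()] reads back field-exactly.
#'
#' @param records data.frame of (classified) records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records
  for (col in names(out)) {
    if (is.factor(out[[col]])) out[[col]] <- as.character(out[[col]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read classified variant records written by [write_records()]
#' @param path path to a TSV file.
#' @return data.frame; a `clinical_class` column, if present, is restored
#'   as a factor with the standard class levels.
#' @export
read_records <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  if (!is.null(tab$clinical_class)) {
    tab$clinical_class <- factor(tab$clinical_class, levels = CLASS_LEVELS)
  }
  for (col in c("key_path", "exclusion_reason")) {
    if (!is.null(tab[[col]])) tab[[col]][is.na(tab[[col]])] <- ""
  }
  tab
}

#' Write a fitted threshold set as JSON
#'
#' Serializes the threshold table of a [fit_thresholds()] model, one entry
#' per (gene, predictor), with thresholds, pool medians, SDs and sizes.
#'
#' @param fit a `vthresh` model object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_threshold_report <- function(fit, path) {
  stopifnot(inherits(fit, "vthresh"))
  jsonlite::write_json(
    list(scope = fit$scope,
         thresholds = fit$thresholds,
         skipped = fit$skipped),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
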