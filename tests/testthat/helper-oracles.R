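# Independent oracles used by the unit and acceptance tests.  These are
# deliberately written as brute-force or flat-rule re-derivations, not
# calls into the package internals.

# -- clinical classification key, re-stated as flat decision rules -------
table1_oracle <- function(hgmd, clinvar, ensembl, pattern, severity) {
  benignish <- clinvar %in% c("benign", "likely_benign",
                              "benign_or_likely_benign")
  leaf5 <- if (pattern == "two_severity" && identical(severity, "partial"))
    "PART" else "DIS"
  if (hgmd == "no_phenotype_dbSNP") return("NO_PHEN")
  if (hgmd == "disease_causing") {
    return(if (benignish) "EXCL" else leaf5)
  }
  # remaining HGMD statuses (absent / DM? / other) defer to ClinVar
  if (benignish || clinvar == "vus") return("NO_PHEN")
  if (ensembl == "present_no_phenotype") return("NO_PHEN")
  if (ensembl == "absent") return("EXCL")  # no evidence anywhere
  leaf5
}

# every valid combination of the classification-key enums (severity_role
# present exactly when the gene has two severity-graded diseases)
all_key_inputs <- function() {
  hgmd <- c("absent", "no_phenotype_dbSNP", "disease_causing",
            "dm_questionable", "other")
  clinvar <- c("absent", "benign", "likely_benign",
               "benign_or_likely_benign", "vus", "pathogenic",
               "likely_pathogenic", "other")
  ensembl <- c("absent", "present_no_phenotype", "present_with_phenotype")
  pat <- rbind(
    data.frame(gene_disease_pattern = c("single_disease", "two_opposite"),
               severity_role = NA_character_, stringsAsFactors = FALSE),
    data.frame(gene_disease_pattern = "two_severity",
               severity_role = c("complete", "partial"),
               stringsAsFactors = FALSE))
  grid <- expand.grid(hgmd_status = hgmd, clinvar_status = clinvar,
                      ensembl_phenotype = ensembl, pi = seq_len(nrow(pat)),
                      stringsAsFactors = FALSE)
  cbind(grid[names(grid) != "pi"], pat[grid$pi, ], row.names = NULL)
}

# -- genetic code brute force -------------------------------------------
codon_table_oracle <- function() {
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  # codon order matching the string above: b1 slow, b2 mid, b3 fast
  codons <- character(64)
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
}

nt_diff <- function(c1, c2) {
  sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
}

is_possible_oracle <- function(ref_aa, alt_aa, codon = NULL) {
  code <- codon_table_oracle()
  ref_codons <- if (is.null(codon)) names(code)[code == ref_aa] else codon
  alt_codons <- names(code)[code == alt_aa]
  for (rc in ref_codons) {
    for (ac in alt_codons) {
      if (nt_diff(rc, ac) == 1L) return(TRUE)
    }
  }
  FALSE
}

# -- percentile: sort-and-interpolate, written from the definition -------
percentile_oracle <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(x)
  h <- (n - 1) * q / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# -- p-distance by direct counting --------------------------------------
pdistance_oracle <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  keep <- a != "-" & b != "-"
  mean(a[keep] != b[keep])
}

# -- widely reproduced integer Grantham matrix anchors -------------------
# value: the printed matrix entry.  print_offset: entries of the printed
# matrix known to differ from exact recomputation with the published
# constants by one unit (print-era rounding).
grantham_anchors <- function() {
  data.frame(
    a = c("S", "S", "S", "S", "S", "S", "S", "S", "S", "S",
          "R", "R", "R", "L", "L", "L", "D", "F", "G", "M",
          "N", "H", "A", "T", "C", "F", "P", "W"),
    b = c("T", "A", "I", "F", "C", "H", "Q", "N", "K", "W",
          "L", "K", "Q", "I", "F", "V", "E", "Y", "W", "I",
          "D", "Q", "G", "M", "Y", "W", "A", "C"),
    value = c(58, 99, 142, 155, 112, 89, 68, 46, 121, 177,
              102, 26, 43, 5, 22, 32, 45, 22, 184, 10,
              23, 24, 60, 81, 194, 40, 27, 215),
    stringsAsFactors = FALSE)
}
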