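#' Sense codons of an amino acid
#'
#' All codons translating to a residue under the standard genetic code
#' (61 sense codons; stop codons are never returned and the stop symbol
#' is rejected — the package models missense variation only).
#'
#' @param aa one-letter residue code.
#' @return character vector of codons (DNA alphabet).
#' @examples
#' codons_of("M")  # "ATG"
#' @export
codons_of <- function(aa) {
  stopifnot(length(aa) == 1L)
  if (!aa %in% AA_ONE) {
    stop("not a canonical amino acid (stop codons are excluded): ", aa,
         call. = FALSE)
  }
  code <- Biostrings::GENETIC_CODE
  names(code)[code == aa]
}

codon_neighbors <- function(codon) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (i in 1:3) {
    for (b in setdiff(bases, substr(codon, i, i))) {
      x <- codon
      substr(x, i, i) <- b
      out <- c(out, x)
    }
  }
  out
}

# single-nucleotide accessibility of each ordered residue pair under the
# any-codon basis, memoized (computed once per session)
.vs_cache <- new.env(parent = emptyenv())

aa_adjacency <- function() {
  if (!is.null(.vs_cache$adj)) return(.vs_cache$adj)
  code <- Biostrings::GENETIC_CODE
  adj <- matrix(FALSE, 20, 20, dimnames = list(AA_ONE, AA_ONE))
  for (ref in AA_ONE) {
    reachable <- unique(unlist(lapply(codons_of(ref), function(cd) {
      code[codon_neighbors(cd)]
    })))
    reachable <- setdiff(reachable, c("*", ref))
    adj[ref, reachable] <- TRUE
  }
  .vs_cache$adj <- adj
  adj
}

#' Is an amino-acid substitution reachable by one nucleotide change?
#'
#' Substitutions requiring two or three nucleotide changes in the codon
#' are "impossible" as single-nucleotide variants; those reachable by a
#' single change are "possible".  With no codon given (`any_codon`
#' basis), a pair is possible when *some* codon of the reference residue
#' has a single-nucleotide neighbor encoding the alternate residue.  With
#' the actual codon given, only that codon's nine neighbors count.
#'
#' @param ref_aa,alt_aa one-letter residue codes, `ref_aa != alt_aa`.
#' @param codon optional actual codon of the reference residue.
#' @return logical.
#' @examples
#' is_possible("M", "V")  # TRUE  (ATG -> GTG)
#' is_possible("M", "P")  # FALSE (needs >= 2 changes)
#' @export
is_possible <- function(ref_aa, alt_aa, codon = NULL) {
  stopifnot(length(ref_aa) == 1L, length(alt_aa) == 1L)
  if (!ref_aa %in% AA_ONE || !alt_aa %in% AA_ONE) {
    stop("residues must be canonical amino acids", call. = FALSE)
  }
  if (ref_aa == alt_aa) {
    stop("ref and alt residues are identical (not a missense change)",
         call. = FALSE)
  }
  if (is.null(codon)) {
    return(unname(aa_adjacency()[ref_aa, alt_aa]))
  }
  codon <- toupper(codon)
  if (Biostrings::GENETIC_CODE[[codon]] != ref_aa) {
    stop("codon ", codon, " does not encode ", ref_aa, call. = FALSE)
  }
  alt_aa %in% Biostrings::GENETIC_CODE[codon_neighbors(codon)]
}

#' Enumerate theoretical missense variants of a protein
#'
#' All `19 * L` single-residue substitutions over the covered region,
#' minus the clinically observed ones, each flagged possible/impossible
#' (see [is_possible()]).  When a coding sequence is supplied it must
#' translate exactly to the protein, and possibility is then judged from
#' each position's actual codon (`actual_codon` basis); otherwise the
#' `any_codon` basis is used.
#'
#' @param protein_seq protein sequence (string of one-letter residues).
#' @param observed optional observed variants: a data.frame with
#'   `position`, `ref_aa`, `alt_aa` (e.g. from [parse_protein_variant()])
#'   or a character vector of HGVS-like strings.  Observed reference
#'   residues must match the sequence.
#' @param cdna optional coding DNA sequence (string, length `3 * L`).
#' @param range optional `c(first, last)` restriction to the region with
#'   structural coverage.
#' @return data.frame with `position`, `ref_aa`, `alt_aa`, `possible`,
#'   `basis`.
#' @export
enumerate_theoretical <- function(protein_seq, observed = NULL,
                                  cdna = NULL, range = NULL) {
  stopifnot(is.character(protein_seq), length(protein_seq) == 1L)
  res <- strsplit(toupper(protein_seq), "")[[1]]
  if (!all(res %in% AA_ONE)) {
    stop("protein sequence contains non-canonical residues: ",
         paste(unique(res[!res %in% AA_ONE]), collapse = ", "),
         call. = FALSE)
  }
  L <- length(res)
  codons <- NULL
  if (!is.null(cdna)) {
    cdna <- toupper(gsub("\\s", "", cdna))
    if (nchar(cdna) != 3L * L) {
      stop("cDNA length ", nchar(cdna), " does not match 3 x ", L,
           call. = FALSE)
    }
    codons <- substring(cdna, seq(1, 3 * L, by = 3), seq(3, 3 * L, by = 3))
    translated <- unname(Biostrings::GENETIC_CODE[codons])
    if (any(translated != res)) {
      stop("cDNA does not translate to the protein sequence (first ",
           "mismatch at position ", which(translated != res)[1], ")",
           call. = FALSE)
    }
  }
  positions <- seq_len(L)
  if (!is.null(range)) {
    stopifnot(length(range) == 2L, range[1] >= 1L, range[2] <= L)
    positions <- seq.int(range[1], range[2])
  }
  if (!is.null(observed)) {
    if (is.character(observed)) observed <- parse_protein_variant(observed)
    mism <- observed$ref_aa != res[observed$position]
    if (any(mism)) {
      stop("observed variant reference residue mismatch at position ",
           paste(observed$position[mism], collapse = ", "), call. = FALSE)
    }
    obs_key <- paste(observed$position, observed$alt_aa)
  } else {
    obs_key <- character(0)
  }
  grid <- expand.grid(position = positions, alt_aa = AA_ONE,
                      stringsAsFactors = FALSE)
  grid$ref_aa <- res[grid$position]
  grid <- grid[grid$ref_aa != grid$alt_aa, ]
  grid <- grid[!(paste(grid$position, grid$alt_aa) %in% obs_key), ]
  basis <- if (is.null(codons)) "any_codon" else "actual_codon"
  adj <- aa_adjacency()
  if (is.null(codons)) {
    grid$possible <- adj[cbind(grid$ref_aa, grid$alt_aa)]
  } else {
    reach <- lapply(positions, function(i) {
      setdiff(unique(unname(
        Biostrings::GENETIC_CODE[codon_neighbors(codons[i])])), "*")
    })
    names(reach) <- positions
    grid$possible <- mapply(function(p, alt) alt %in% reach[[as.character(p)]],
                            grid$position, grid$alt_aa)
  }
  grid$basis <- basis
  grid <- grid[order(grid$position, grid$alt_aa),
               c("position", "ref_aa", "alt_aa", "possible", "basis")]
  rownames(grid) <- NULL
  grid
}

#' Linear-interpolation percentile
#'
#' The percentile convention used throughout the package: linear
#' interpolation between closest order statistics ([stats::quantile()]
#' type 7, `h = (n - 1) q / 100`).  Pinned here so the negative-selection
#' scan is convention-stable.
#'
#' @param x numeric vector (NAs dropped).
#' @param q percentile in `[0, 100]`.
#' @return the interpolated percentile.
#' @examples
#' percentile(1:100, 10)  # 10.9
#' @export
percentile <- function(x, q) {
  stopifnot(is.numeric(x), length(q) == 1L, q >= 0, q <= 100)
  x <- x[!is.na(x)]
  if (!length(x)) stop("no scores to take a percentile of", call. = FALSE)
  unname(quantile(x, probs = q / 100, type = 7, names = FALSE))
}

#' Scan genes for variants under negative selection
#'
#' Compares, per gene and predictor, the deleterious-tail percentile of
#' clinically observed DAV scores with the same percentile of possible
#' theoretical variant scores.  The tail is the 10th percentile for
#' smaller-is-deleterious predictors (EVmutation-like) and the 90th for
#' larger-is-deleterious ones (SNAP2-like).  The reported difference is
#' `delta = p_dav - p_theoretical`; a gene is flagged when the observed
#' DAV tail reaches *beyond* the theoretical tail (negative delta for a
#' 10th-percentile predictor, positive for a 90th-percentile one),
#' signalling that the most deleterious accessible variants are depleted
#' from the clinical record.
#'
#' @param dav_scores data.frame with `gene`, `predictor`, `score` for
#'   observed DAVs.
#' @param theoretical_scores same layout for theoretical variants; rows
#'   with a logical `possible` column equal to `FALSE` are dropped
#'   (impossible variants are excluded from the scan).
#' @param predictors list of [predictor_config()] covering the predictors
#'   present.
#' @return object of class `selection_scan` with `results` (one row per
#'   (gene, predictor): `tail_percentile`, `p_dav`, `p_theoretical`,
#'   `delta`, `flagged`), `heatmap` (genes x predictors matrix of deltas
#'   on the flag-strength scale, rows sorted most-flagged first) and
#'   `skipped`.
#' @export
selection_scan <- function(dav_scores, theoretical_scores,
                           predictors = default_predictors()) {
  predictors <- as_predictor_list(predictors)
  for (nm in c("gene", "predictor", "score")) {
    stopifnot(nm %in% names(dav_scores), nm %in% names(theoretical_scores))
  }
  if (!is.null(theoretical_scores$possible)) {
    theoretical_scores <-
      theoretical_scores[isTRUE_vec(theoretical_scores$possible), ]
  }
  preds <- intersect(names(predictors),
                     union(unique(dav_scores$predictor),
                           unique(theoretical_scores$predictor)))
  genes <- union(unique(dav_scores$gene), unique(theoretical_scores$gene))
  rows <- list()
  skipped <- list()
  for (pred in preds) {
    cfg <- predictors[[pred]]
    tail_q <- if (cfg$orientation < 0) 10 else 90
    for (g in genes) {
      dav <- dav_scores$score[dav_scores$gene == g &
                                dav_scores$predictor == pred]
      theo <- theoretical_scores$score[theoretical_scores$gene == g &
                                         theoretical_scores$predictor == pred]
      if (!length(dav) || !length(theo)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          gene = g, predictor = pred,
          reason = "empty DAV or theoretical pool", stringsAsFactors = FALSE)
        next
      }
      p_dav <- percentile(dav, tail_q)
      p_theo <- percentile(theo, tail_q)
      delta <- p_dav - p_theo
      flagged <- if (tail_q == 10) delta < 0 else delta > 0
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, predictor = pred, tail_percentile = tail_q,
        p_dav = p_dav, p_theoretical = p_theo, delta = delta,
        flagged = flagged, stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), predictor = character(0),
               tail_percentile = numeric(0), p_dav = numeric(0),
               p_theoretical = numeric(0), delta = numeric(0),
               flagged = logical(0))
  # flag strength: positive = evidence of depletion, regardless of tail side
  results$flag_strength <- ifelse(results$tail_percentile == 10,
                                  -results$delta, results$delta)
  hm <- NULL
  if (nrow(results)) {
    genes_seen <- unique(results$gene)
    hm <- matrix(NA_real_, length(genes_seen), length(preds),
                 dimnames = list(genes_seen, preds))
    hm[cbind(results$gene, results$predictor)] <- results$flag_strength
    ord <- order(-apply(hm, 1, max, na.rm = TRUE))
    hm <- hm[ord, , drop = FALSE]
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(gene = character(0), predictor = character(0),
               reason = character(0))
  structure(list(results = results, heatmap = hm, skipped = skipped),
            class = "selection_scan")
}

#' @export
print.selection_scan <- function(x, ...) {
  n_flag <- sum(x$results$flagged)
  cat(sprintf("negative-selection scan: %d (gene, predictor) cells, %d flagged\n",
              nrow(x$results), n_flag))
  if (n_flag) {
    print(x$results[x$results$flagged,
                    c("gene", "predictor", "tail_percentile", "delta")],
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.selection_scan <- function(x, ...) {
  hm <- x$heatmap
  if (is.null(hm)) stop("nothing to plot", call. = FALSE)
  # flag-strength heatmap, most strongly flagged genes on top
  image(seq_len(ncol(hm)), seq_len(nrow(hm)), t(hm[rev(seq_len(nrow(hm))), ,
                                                   drop = FALSE]),
        col = grDevices::hcl.colors(25, "Blue-Red 3"),
        axes = FALSE, xlab = "", ylab = "", ...)
  axis(1, seq_len(ncol(hm)), colnames(hm), las = 1, tick = FALSE)
  axis(2, seq_len(nrow(hm)), rev(rownames(hm)), las = 2, tick = FALSE)
  invisible(x)
}
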