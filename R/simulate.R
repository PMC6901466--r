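#' Default synthetic score specification
#'
#' One row per (gene, predictor, class) describing the generating
#' distribution of [gen_scores()].  The defaults restate the summary
#' statistics of the reference clinical dataset where they are known:
#' EVmutation DAVs centred at -6.58 (SD 2.23) and NPAVs at -3.86
#' (SD 2.41); SNAP2 DAVs at 61 (SD 46.51) and NPAVs at -12.57 (SD 55.85,
#' the benign/likely-benign summary); possible theoretical pools at
#' -4.83 (SD 2.49) for EVmutation and 18 (SD 56) for SNAP2.
#' Partial-phenotype pools reuse the DAV location.  Default pool sizes
#' are the per-gene averages of that dataset (103 DAVs, 7 partial, 48
#' NPAVs, 1448 possible theoretical variants per gene).  All values are
#' overridable; the distribution family is `normal` with an optional
#' `skew_normal` (shape column) for heavy one-sided pools.
#'
#' @param genes character vector of gene labels.
#' @param n_dav,n_part,n_npav,n_theoretical pool sizes per gene.
#' @return data.frame with columns `gene`, `predictor`, `class`,
#'   `location`, `scale`, `n`, `family`, `shape`.
#' @export
default_score_spec <- function(genes = paste0("G", 1:5),
                               n_dav = 103, n_part = 7, n_npav = 48,
                               n_theoretical = 1448) {
  base <- data.frame(
    predictor = rep(c("EVmutation", "SNAP2"), each = 4),
    class = rep(c("DAV", "PART", "NPAV", "theoretical"), 2),
    location = c(-6.58, -6.58, -3.86, -4.83,
                 61, 61, -12.57, 18),
    scale = c(2.23, 2.23, 2.41, 2.49,
              46.51, 46.51, 55.85, 56),
    n = rep(c(n_dav, n_part, n_npav, n_theoretical), 2),
    family = "normal", shape = 0,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(genes, function(g) cbind(gene = g, base)))
  rownames(out) <- NULL
  out
}

rskewnorm <- function(n, location, scale, shape) {
  # Azzalini's representation: delta|U0| + sqrt(1-delta^2) U1
  delta <- shape / sqrt(1 + shape^2)
  u0 <- abs(rnorm(n))
  u1 <- rnorm(n)
  location + scale * (delta * u0 + sqrt(1 - delta^2) * u1)
}

#' Generate a labelled synthetic score table
#'
#' Draws per-class predictor scores from the distributions declared in a
#' spec (see [default_score_spec()]).  Variants are shared across
#' predictors: each (gene, class) pool gets stable variant identifiers
#' and every predictor draws one score per variant, so consensus calling
#' across predictors is exercised.  All (gene, class) pools must
#' therefore declare the same `n` for every predictor.  Deterministic
#' under `seed`.
#'
#' @param spec data.frame as returned by [default_score_spec()].
#' @param seed RNG seed (caller's RNG state restored).
#' @return data.frame with columns `gene`, `hgvs_p` (synthetic stable
#'   variant id), `class` (truth label), `predictor`, `score`.
#' @export
gen_scores <- function(spec, seed = NULL) {
  required <- c("gene", "predictor", "class", "location", "scale", "n")
  miss <- setdiff(required, names(spec))
  if (length(miss)) stop("spec is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(spec$family)) spec$family <- "normal"
  if (is.null(spec$shape)) spec$shape <- 0
  bad <- setdiff(unique(spec$family), c("normal", "skew_normal"))
  if (length(bad)) stop("unknown distribution family: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(all(spec$scale > 0), all(spec$n >= 0))
  cell <- paste(spec$gene, spec$class)
  if (any(tapply(spec$n, cell, function(v) length(unique(v))) > 1L)) {
    stop("all predictors of a (gene, class) pool must declare the same n",
         call. = FALSE)
  }
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(spec)), function(i) {
      s <- spec[i, ]
      if (s$n == 0L) return(NULL)
      draw <- if (s$family == "normal") rnorm(s$n, s$location, s$scale)
      else rskewnorm(s$n, s$location, s$scale, s$shape)
      data.frame(gene = s$gene,
                 hgvs_p = sprintf("%s_%s_%d", s$gene, s$class, seq_len(s$n)),
                 class = s$class, predictor = s$predictor, score = draw,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame(gene = character(0),
                                        hgvs_p = character(0),
                                        class = character(0),
                                        predictor = character(0),
                                        score = numeric(0))
    rownames(out) <- NULL
    out
  })
}

# one representative annotation template per classification-key branch;
# unreached fields hold neutral values so each template exercises exactly
# the intended path
annotation_templates <- function() {
  t <- function(path, hgmd, clinvar, ensembl, pattern, severity, class) {
    data.frame(key_path = path, hgmd_status = hgmd, clinvar_status = clinvar,
               ensembl_phenotype = ensembl, gene_disease_pattern = pattern,
               severity_role = severity, intended_class = class,
               stringsAsFactors = FALSE)
  }
  rbind(
    t("1b", "no_phenotype_dbSNP", "absent", "absent", "single_disease",
      NA, "NO_PHEN"),
    t("1a-2a", "absent", "benign", "absent", "single_disease", NA, "NO_PHEN"),
    t("1a-2a", "absent", "vus", "absent", "single_disease", NA, "NO_PHEN"),
    t("1d-2a", "other", "likely_benign", "absent", "single_disease", NA,
      "NO_PHEN"),
    t("1a-2b-3a", "absent", "absent", "present_no_phenotype",
      "single_disease", NA, "NO_PHEN"),
    t("1d-2b-3a", "other", "pathogenic", "present_no_phenotype",
      "single_disease", NA, "NO_PHEN"),
    t("1a-2b-3-", "absent", "absent", "absent", "single_disease", NA,
      "EXCL"),
    t("1a-2b-3b-5a", "absent", "absent", "present_with_phenotype",
      "single_disease", NA, "DIS"),
    t("1a-2b-3b-5b", "absent", "other", "present_with_phenotype",
      "two_opposite", NA, "DIS"),
    t("1a-2b-3b-5c", "absent", "absent", "present_with_phenotype",
      "two_severity", "complete", "DIS"),
    t("1a-2b-3b-5d", "absent", "absent", "present_with_phenotype",
      "two_severity", "partial", "PART"),
    t("1c-4a", "disease_causing", "likely_benign", "present_with_phenotype",
      "single_disease", NA, "EXCL"),
    t("1c-4b-5a", "disease_causing", "pathogenic", "present_with_phenotype",
      "single_disease", NA, "DIS"),
    t("1c-4b-5b", "disease_causing", "absent", "present_with_phenotype",
      "two_opposite", NA, "DIS"),
    t("1c-4b-5c", "disease_causing", "vus", "present_with_phenotype",
      "two_severity", "complete", "DIS"),
    t("1c-4b-5d", "disease_causing", "absent", "present_with_phenotype",
      "two_severity", "partial", "PART"))
}

#' Generate a synthetic clinical annotation table
#'
#' Builds annotation records whose fields walk every branch of the
#' clinical classification key, either in branch-coverage mode (each
#' branch template exactly once) or by sampling the requested number of
#' records per intended class.  The `intended_class` and `key_path`
#' columns are truth labels: passing the records through
#' [classify_clinical()] reproduces `intended_class` exactly (tested).
#'
#' @param n named integer vector of record counts per class, e.g.
#'   `c(DIS = 10, PART = 2, NO_PHEN = 5, EXCL = 1)`.
#' @param seed RNG seed.
#' @param branch_coverage if `TRUE`, ignore `n` and emit every key branch
#'   once.
#' @return annotation data.frame with truth columns `intended_class` and
#'   `key_path`, plus `gene`, `hgvs_p` and `allele_frequency` fields.
#' @export
gen_annotations <- function(n = c(DIS = 4, PART = 2, NO_PHEN = 4, EXCL = 2),
                            seed = NULL, branch_coverage = FALSE) {
  tpl <- annotation_templates()
  picked <- if (branch_coverage) {
    tpl
  } else {
    stopifnot(all(n >= 0), all(names(n) %in% CLASS_LEVELS))
    with_seed(seed, {
      do.call(rbind, lapply(names(n), function(cl) {
        pool <- tpl[tpl$intended_class == cl, ]
        if (n[[cl]] == 0L) return(NULL)
        pool[sample.int(nrow(pool), n[[cl]], replace = TRUE), ]
      }))
    })
  }
  if (is.null(picked) || nrow(picked) == 0L) {
    picked <- tpl[0, ]
  }
  out <- picked
  k <- nrow(out)
  out$gene <- rep("SYNGENE", k)
  refs <- rep_len(c("A", "G", "L", "R", "S"), k)
  alts <- rep_len(c("V", "D", "P", "H", "F"), k)
  out$hgvs_p <- sprintf("p.%s%d%s", refs, seq_len(k), alts)
  out$allele_frequency <- rep(0, k)
  rownames(out) <- NULL
  out[c("gene", "hgvs_p", "hgmd_status", "clinvar_status",
        "ensembl_phenotype", "gene_disease_pattern", "severity_role",
        "allele_frequency", "intended_class", "key_path")]
}

#' Generate a synthetic tiered protein alignment
#'
#' Emulates the ortholog alignments used for GV scoring: a random
#' reference sequence, copied into taxonomic tiers whose sequences
#' substitute residues at a per-tier probability, restricted to the
#' columns marked variable.  Conserved columns (mask `TRUE`) receive no
#' substitutions anywhere; every variable column is guaranteed at least
#' one substitution somewhere (so the GV conserved/variable call recovers
#' the mask exactly).  No gaps are generated.
#'
#' @param width alignment length (columns).
#' @param tiers data.frame with columns `tier`, `n_seqs`, `p_sub`
#'   (per-site substitution probability from the reference), ordered from
#'   closest to most distant.  A `reference` tier with `p_sub = 0` holds
#'   exact copies of the reference sequence.
#' @param conserved_mask logical vector (length `width`); `TRUE` columns
#'   are immutable.  Default: no conserved columns.
#' @param seed RNG seed.
#' @return list with `msa` (a [protein_msa()] whose groups are the
#'   tiers), `truth` (the mask and the tier substitution probabilities).
#' @export
gen_msa <- function(width,
                    tiers = data.frame(
                      tier = c("reference", "tier1"),
                      n_seqs = c(2, 8),
                      p_sub = c(0, 0.1)),
                    conserved_mask = rep(FALSE, width),
                    seed = NULL) {
  stopifnot(width >= 1L, nrow(tiers) >= 1L,
            all(c("tier", "n_seqs", "p_sub") %in% names(tiers)),
            length(conserved_mask) == width,
            all(tiers$p_sub >= 0 & tiers$p_sub <= 1))
  with_seed(seed, {
    ref <- sample(AA_ONE, width, replace = TRUE)
    labels <- character(0)
    groups <- character(0)
    seqs <- list()
    for (i in seq_len(nrow(tiers))) {
      for (s in seq_len(tiers$n_seqs[i])) {
        x <- ref
        if (tiers$p_sub[i] > 0) {
          mutable <- which(!conserved_mask)
          hit <- mutable[runif(length(mutable)) < tiers$p_sub[i]]
          for (j in hit) x[j] <- sample(setdiff(AA_ONE, ref[j]), 1L)
        }
        lab <- sprintf("%s_%d", tiers$tier[i], s)
        labels <- c(labels, lab)
        groups <- c(groups, tiers$tier[i])
        seqs[[lab]] <- x
      }
    }
    mat <- do.call(rbind, seqs)
    rownames(mat) <- labels
    # guarantee every variable column varies somewhere (otherwise the
    # planted mask is not recoverable from the realized alignment) -- but
    # only when some tier mutates at all: an all-zero substitution spec
    # legitimately yields a fully conserved alignment
    mutated_rows <- which(tiers$p_sub[match(groups, tiers$tier)] > 0)
    if (length(mutated_rows)) {
      for (j in which(!conserved_mask)) {
        if (length(unique(mat[, j])) == 1L) {
          r <- mutated_rows[sample.int(length(mutated_rows), 1L)]
          mat[r, j] <- sample(setdiff(AA_ONE, ref[j]), 1L)
        }
      }
    }
    msa <- protein_msa(mat, labels = labels,
                       groups = setNames(groups, labels))
    list(msa = msa,
         truth = list(conserved_mask = conserved_mask,
                      reference = paste(ref, collapse = ""),
                      tiers = tiers))
  })
}

#' Generate a random protein and a consistent coding sequence
#'
#' @param width protein length (residues).
#' @param composition either `NULL` (uniform over the 20 residues), a
#'   single residue (homopolymer), or a named probability vector over
#'   residues.
#' @param seed RNG seed.
#' @return list with `protein` and `cdna` strings; the cDNA translates
#'   exactly to the protein under the standard code (codons drawn
#'   uniformly among each residue's synonymous codons).
#' @export
gen_sequences <- function(width, composition = NULL, seed = NULL) {
  stopifnot(width >= 1L)
  with_seed(seed, {
    res <- if (is.null(composition)) {
      sample(AA_ONE, width, replace = TRUE)
    } else if (is.character(composition) && length(composition) == 1L) {
      rep(norm_aa(composition), width)
    } else {
      stopifnot(!is.null(names(composition)),
                all(names(composition) %in% AA_ONE))
      sample(names(composition), width, replace = TRUE,
             prob = composition)
    }
    codons <- vapply(res, function(aa) {
      cc <- codons_of(aa)
      cc[sample.int(length(cc), 1L)]
    }, character(1))
    list(protein = paste(res, collapse = ""),
         cdna = paste(codons, collapse = ""))
  })
}
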