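#' Construct a protein multiple sequence alignment object
#'
#' The alignment container used by the conservation functions: a
#' character matrix of one-letter residues (rows = sequences, columns =
#' alignment positions) with sequence labels and an optional label->group
#' assignment (taxonomic tiers).  All sequences must have identical
#' aligned length and use the 20 canonical residues plus the gap symbol.
#'
#' @param sequences character vector of aligned sequences (equal length),
#'   or an already-built character matrix.
#' @param labels sequence identifiers (defaults to names of `sequences`).
#' @param groups optional named character vector mapping labels to group
#'   names.
#' @return object of class `protein_msa`.
#' @export
protein_msa <- function(sequences, labels = names(sequences),
                        groups = NULL) {
  if (is.matrix(sequences)) {
    mat <- sequences
    if (is.null(labels)) labels <- rownames(mat)
  } else {
    stopifnot(is.character(sequences), length(sequences) >= 1L)
    widths <- nchar(sequences)
    if (length(unique(widths)) != 1L) {
      stop("aligned sequences must all have the same length", call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  }
  if (is.null(labels)) labels <- paste0("seq", seq_len(nrow(mat)))
  rownames(mat) <- labels
  ok <- mat %in% c(AA_ONE, "-", ".")
  if (!all(ok)) {
    stop("alignment contains non-residue symbol(s): ",
         paste(unique(mat[!ok]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(groups)) {
    miss <- setdiff(labels, names(groups))
    if (length(miss)) {
      stop("no group assignment for sequence(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    groups <- groups[labels]
  }
  structure(list(matrix = mat, labels = labels, groups = groups),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("protein MSA: %d sequences x %d columns%s\n",
              nrow(x$matrix), ncol(x$matrix),
              if (is.null(x$groups)) "" else
                sprintf(" (%d groups)", length(unique(x$groups)))))
  invisible(x)
}

#' Read an aligned FASTA file into a `protein_msa`
#'
#' @param path aligned FASTA file (gap `-`).
#' @param groups optional path to a two-column TSV (`label`, `group`) or a
#'   named character vector.
#' @return a [protein_msa()] object.
#' @export
read_msa <- function(path, groups = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    tab <- read.delim(groups, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("group file needs two columns", call. = FALSE)
    groups <- setNames(as.character(tab[[2]]), tab[[1]])
  }
  protein_msa(as.character(seqs), labels = names(seqs), groups = groups)
}

#' Write a `protein_msa` as aligned FASTA
#' @param msa a [protein_msa()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  stopifnot(inherits(msa, "protein_msa"))
  seqs <- apply(msa$matrix, 1, paste, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(seqs, msa$labels)), path)
  invisible(path)
}

#' Per-column GV profile of an alignment
#'
#' Scores every alignment column with [gv_score()] and flags conserved
#' columns (GV exactly 0, i.e. a single distinct non-gap residue).
#' Positions are reported both in 1-based alignment coordinates and in
#' 1-based coordinates of a designated reference sequence (columns where
#' the reference has a gap get `NA`).
#'
#' @param msa a [protein_msa()].
#' @param reference label of the reference sequence (default: first).
#' @param table Grantham constants, from [grantham_table()].
#' @return data.frame with `alignment_pos`, `ref_pos`, `ref_aa`, `gv`,
#'   `conserved`.  All-gap columns get `NA` gv and conserved.
#' @export
gv_profile <- function(msa, reference = NULL, table = grantham_table()) {
  stopifnot(inherits(msa, "protein_msa"))
  mat <- msa$matrix
  if (is.null(reference)) reference <- msa$labels[1L]
  if (!reference %in% msa$labels) {
    stop("reference sequence '", reference, "' is not in the alignment",
         call. = FALSE)
  }
  ref <- mat[reference, ]
  gap <- c("-", ".")
  ref_pos <- cumsum(!(ref %in% gap))
  ref_pos[ref %in% gap] <- NA_integer_
  gv <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    gv[j] <- if (all(col %in% gap)) NA_real_ else gv_score(col, table, gap)
  }
  data.frame(alignment_pos = seq_len(ncol(mat)),
             ref_pos = ref_pos,
             ref_aa = ifelse(ref %in% gap, NA_character_, ref),
             gv = gv,
             conserved = !is.na(gv) & gv == 0,
             stringsAsFactors = FALSE)
}

#' Between-group sequence divergence with bootstrap SE
#'
#' Mean proportion of differing sites over all cross-group sequence
#' pairs, computed on the gap-free columns of the sequences involved
#' (complete deletion).  The standard error is the SD of the statistic
#' over site-resampled bootstrap replicates.  This is the uncorrected
#' p-distance; model-corrected (maximum-likelihood) distances are out of
#' scope, so criteria defined on corrected distances should be adjusted
#' by the caller.
#'
#' @param msa a [protein_msa()].
#' @param group_a,group_b character vectors of sequence labels, or single
#'   group names resolved through `msa$groups`.
#' @param bootstrap_reps number of bootstrap replicates (default 1000; 0
#'   skips the bootstrap and returns `se = NA`).
#' @param seed RNG seed for the bootstrap (caller's RNG state restored).
#' @return list of class `divergence_result` with `distance`, `se`,
#'   `replicates`, `n_sites` (gap-free columns used) and `n_pairs`.
#' @export
group_divergence <- function(msa, group_a, group_b,
                             bootstrap_reps = 1000, seed = NULL) {
  stopifnot(inherits(msa, "protein_msa"))
  resolve <- function(g) {
    if (all(g %in% msa$labels)) return(g)
    if (!is.null(msa$groups) && all(g %in% msa$groups)) {
      return(msa$labels[msa$groups %in% g])
    }
    stop("cannot resolve group: ", paste(g, collapse = ", "), call. = FALSE)
  }
  la <- resolve(group_a)
  lb <- resolve(group_b)
  if (!length(la) || !length(lb)) stop("empty group", call. = FALSE)
  mat <- msa$matrix[union(la, lb), , drop = FALSE]
  gapfree <- colSums(mat == "-" | mat == ".") == 0L
  sites <- which(gapfree)
  if (!length(sites)) {
    stop("no gap-free columns to compare under complete deletion",
         call. = FALSE)
  }
  pairs <- expand.grid(a = la, b = lb, stringsAsFactors = FALSE)
  # per-pair mismatch indicator over retained sites
  mm <- vapply(seq_len(nrow(pairs)), function(k) {
    msa$matrix[pairs$a[k], sites] != msa$matrix[pairs$b[k], sites]
  }, logical(length(sites)))
  mm <- matrix(mm, nrow = length(sites))
  stat <- function(idx) mean(colMeans(mm[idx, , drop = FALSE]))
  dist <- stat(seq_along(sites))
  se <- NA_real_
  if (bootstrap_reps > 0) {
    reps <- with_seed(seed, {
      vapply(seq_len(bootstrap_reps), function(r) {
        stat(sample.int(length(sites), replace = TRUE))
      }, numeric(1))
    })
    se <- sd(reps)
  }
  structure(list(distance = dist, se = se, replicates = bootstrap_reps,
                 n_sites = length(sites), n_pairs = nrow(pairs)),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf(
    "between-group divergence: %.4f substitutions/site (SE %.4f, %d bootstrap reps, %d sites, %d pairs)\n",
    x$distance, x$se, x$replicates, x$n_sites, x$n_pairs))
  invisible(x)
}

#' Select how many taxonomic tiers an alignment needs
#'
#' Highly conserved proteins show no variation among close orthologs, so
#' their alignments are deepened tier by tier (e.g. primates, other
#' mammals, sauropsids, fish, invertebrates) until the pooled non-reference
#' sequences reach a minimum divergence from the reference group —
#' by default 0.1 substitutions per amino acid.
#'
#' @param msa a [protein_msa()] with a `groups` assignment.
#' @param tiers character vector of group names ordered from closest to
#'   most distant (excluding the reference group).
#' @param reference_group name of the reference group (e.g. `"primates"`).
#' @param min_divergence divergence target (default 0.1).
#' @param bootstrap_reps,seed passed to [group_divergence()] (bootstrap
#'   off by default here; the decision uses the point estimate).
#' @return list with `tiers_used` (the minimal prefix), `divergence`
#'   (named vector of achieved divergence after each prefix), `reached`
#'   (logical; `FALSE` means all tiers were used without reaching the
#'   target).
#' @export
select_taxon_depth <- function(msa, tiers, reference_group,
                               min_divergence = 0.1,
                               bootstrap_reps = 0, seed = NULL) {
  stopifnot(inherits(msa, "protein_msa"), !is.null(msa$groups))
  div <- setNames(numeric(length(tiers)), tiers)
  reached_at <- NA_integer_
  for (k in seq_along(tiers)) {
    pooled <- tiers[seq_len(k)]
    d <- group_divergence(msa, reference_group, pooled,
                          bootstrap_reps = bootstrap_reps, seed = seed)
    div[k] <- d$distance
    if (is.na(reached_at) && d$distance >= min_divergence) reached_at <- k
  }
  reached <- !is.na(reached_at)
  list(tiers_used = tiers[seq_len(if (reached) reached_at else
    length(tiers))],
    divergence = div, reached = reached)
}
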