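---
title: "Evidence-based calibration of variant-effect-predictor thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-based calibration of variant-effect-predictor thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varthresh)
```

## The problem and the model

Variant-effect predictors assign each missense variant a numeric score,
shipped with an arbitrary cutoff (e.g. zero for EVmutation-style
epistatic scores). Against clinical labels such cutoffs are nearly
perfectly sensitive — almost all disease-associated variants (DAVs) fall
on the deleterious side — but barely specific, because most variants
with conclusive evidence of *no* phenotype (NPAVs) fall there too.

varthresh replaces the single arbitrary cutoff with a pair of
*evidence-based* thresholds estimated from labelled score pools. With
orientation $o \in \{+1,-1\}$ ($+1$ when larger raw scores are more
deleterious), on the raw score scale:

$$t_{\mathrm{sens}} = \operatorname{median}(S_{\mathrm{DAV}}) - o\,2\,\mathrm{SD}(S_{\mathrm{DAV}}),
\qquad
t_{\mathrm{spec}} = \operatorname{median}(S_{\mathrm{NPAV}}) + o\,2\,\mathrm{SD}(S_{\mathrm{NPAV}}).$$

Under an approximately symmetric unimodal pool, roughly 95% of DAVs lie
on the deleterious side of $t_{\mathrm{sens}}$ and 95% of NPAVs on the
benign side of $t_{\mathrm{spec}}$ — hence the names. A score strictly
beyond $t_{\mathrm{spec}}$ (deleterious direction) and not on the benign
side of $t_{\mathrm{sens}}$ is called *pathogenic*; the mirror case is
*benign*; everything between is *unresolved*. Consensus over several
predictors (`combine_calls()`) is unanimous-vote: all-pathogenic,
all-benign, *contradictory* when both directions occur, otherwise
unresolved (partial or all).

Assumptions worth stating: the pools are treated per (gene, predictor)
cell as exchangeable samples; the 2-SD offset presumes the spread is
meaningfully summarized by a standard deviation (heavily skewed pools —
thermostability-style scores are the known offender — yield thresholds
that can escape the opposing pool's range entirely, which is why the
`conflicting` value exists); and clinical labels are taken as ground
truth, so label noise propagates into the thresholds.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `scope` | `"gene"` | gene-specific pools; `"general"` pools all genes |
| `min_dav`, `min_npav` | 9, 6 | minimum pool sizes per (gene, predictor); mirrors the gene-selection floor of the reference dataset (at least nine DAVs, six NPAVs); undersized cells are skipped and listed |
| `include_partial` | `FALSE` | partial-phenotype records are excluded from both pools; the sensitivity/specificity construction is defined on DAVs and NPAVs only, while partial records remain available for evaluation |
| `orientation` | per predictor | $+1$ for SNAP2-/PoPMuSiC-style, $-1$ for EVmutation-style scores |
| `freq_cutoff` (curation) | 8 | population-frequency cutoff for dropping ClinVar-benign variants; the source states "f > 8" without units, so the value is configurable rather than baked in |
| `drop_likely_nonphenotypic` | `FALSE` | curation switch for records flagged likely non-phenotypic (the appropriate handling of such hemoglobin-style records changed during the original study, so it is a switch, not a rule) |
| `min_divergence` (taxon depth) | 0.1 | substitutions per amino acid required between the reference group and the pooled deeper tiers |
| `mode` (weights) | `"harmonized"` | see below |

## The clinical classification key

`classify_clinical()` walks a numbered key over HGMD-, ClinVar- and
Ensembl-style fields, yielding `DIS`, `PART`, `NO_PHEN` or `EXCL`; the
`detail = TRUE` form records the path taken (e.g. `"1a-2b-3b-5d"`). The
key as published has no row for a variant that reaches the Ensembl step
while *absent* from that source (its two rows presume presence). Such a
record has, at that point, no phenotype evidence in any of the three
sources; we classify it `EXCL` with an explicit reason rather than guess
a phenotype, keeping the classifier total over the whole input space.
The exclusion filters (`apply_exclusion_filters()`) are disjunctive
drops — non-Mendelian-only evidence, benign with high population
frequency, questionable `DM?` status, HGMD/ClinVar conflict — so their
order can never matter; this is tested by permutation.

VUS records classify as `NO_PHEN` (the key's row 2a) but retain their
`clinvar_status`, so downstream group comparisons such as VUS vs benign
stay possible.

## Numerical conventions

* **SD** is the sample standard deviation ($n-1$ denominator); the
  source does not specify. Thresholds are always computed from data —
  never from rounded printed summaries (where printed summaries are
  re-used, as in the worked-example tests, small print-rounding
  differences like $-8.68$ vs a figure's $-8.81$, or a printed $-1.00$
  for an exact $-0.99$, are expected and documented).
* **Ties**: the call inequalities are strict; a score exactly on a
  threshold is unresolved. No tie convention is stated in the source, and
  strictness is the conservative choice.
* **Crossed thresholds**: in a poorly separated cell $t_{\mathrm{spec}}$
  can lie on the benign side of $t_{\mathrm{sens}}$; scores in the
  overlap satisfy both gates and get the distinct value `conflicting`.
  In consensus combination a `conflicting` call contributes evidence in
  both directions and therefore forces `contradictory`.
* **Percentile** is linear interpolation between closest order
  statistics (`stats::quantile` type 7); the convention is pinned by an
  independent oracle test so the negative-selection scan is stable.
* **Percentages** are stored at full precision and rounded only when
  printed (half away from zero, one decimal).
* **Weight rescaling** maps a raw score to $[-100, 100]$ piecewise
  linearly, threshold $\mapsto 0$ and range ends $\mapsto \pm 100$. The
  literal published mapping sends the observed *maximum* to $+100$,
  which makes $+100$ benign for a smaller-is-deleterious predictor while
  $+100$ is deleterious for the others; averaging such weights mixes
  directions. The default `harmonized` mode therefore sends the
  *deleterious* extreme to $+100$ for every predictor; `literal` mode is
  kept for fidelity. Which variant the original averaging used is not
  stated.

## Conservation: GV scores and alignment depth

`gv_score()` measures the physicochemical spread of an alignment column
with Grantham's difference formula applied to the max–min range of each
property (composition, polarity, volume) over the *distinct* non-gap
residues. GV $= 0$ exactly when one distinct residue occupies the
column; the binary conserved/variable call uses exact zero (no epsilon)
because property values are exact table lookups. For a two-residue
column GV equals the pairwise Grantham distance; for larger columns GV
*dominates* the maximal pairwise distance, since the per-property ranges
may combine extremes from different residue pairs. Plain max–min ranges
are used throughout; the composition-deviation refinement found in some
GV implementations is a possible extension, not implemented.

A note on constants: the package evaluates the published formula
($\alpha = 1.833$, $\beta = 0.1018$, $\gamma = 0.000399$,
$\rho = 50.723$). A minority of entries in the widely reproduced printed
integer matrix differ from exact recomputation by one unit (the printed
Trp–Cys 215 recomputes to 214.36; Ser–Arg 110 to 109.21) — print-era
rounding in the 1974 source. The formula value is authoritative here;
tests pin a set of published anchors to within that one unit.

Gap policy: for GV, gaps within a column are ignored (the source is
silent; an all-gap column is an error). For between-group divergence,
complete deletion — any column containing a gap among the involved
sequences is excluded. Divergence itself is the uncorrected
proportion-of-differences (p-distance) averaged over all cross-group
sequence pairs, with a site-resampling bootstrap SE. The original
analysis used maximum-likelihood corrected distances (substitution-model
fitting is out of scope here); since p-distance underestimates corrected
distance, the 0.1 substitutions-per-site criterion of
`select_taxon_depth()` is exposed as a parameter so users can
compensate.

## Theoretical variants and the negative-selection scan

`enumerate_theoretical()` lists all $19L$ substitutions over the covered
region minus the observed ones (all observed records are excluded,
whether DAV or NPAV — "not clinically observed" is read literally).
Accessibility is judged against the standard genetic code: with no
coding sequence supplied, a substitution is *possible* when some codon
of the reference residue has a single-nucleotide neighbour encoding the
alternate (`any_codon` basis); when a cDNA is supplied and validated by
translation, only the actual codon's nine neighbours count. Stop-gained
changes are excluded throughout.

`selection_scan()` compares, per gene and predictor, the
deleterious-tail percentile of observed DAV scores with the same
percentile of *possible* theoretical scores: the 10th percentile for
smaller-is-deleterious predictors, the 90th for larger-is-deleterious
ones. The reported difference is $\Delta = p_{\mathrm{DAV}} -
p_{\mathrm{theor}}$, and a gene is flagged when the observed tail
reaches beyond the theoretical tail ($\Delta < 0$ for a 10th-percentile
predictor, $\Delta > 0$ for a 90th-percentile one) — the sign convention
of the original figure captions. The original running text is partially
inconsistent with its own captions about which ordering signals
depletion; the package exposes $\Delta$ with this explicit definition
and leaves interpretation to the user. A direct consequence, exercised
in the acceptance tests: truncating the deleterious tail of a gene's
observed pool at the theoretical tail cutoff deterministically *clears*
its flag, while pools drawn from the (deeper) disease-associated
distributions flag.

## What the synthetic generators emulate — and what they do not

`gen_scores()` draws per-class normal (optionally skew-normal) pools.
The defaults restate printed summaries of the reference dataset where
available: EVmutation DAV $-6.58 \pm 2.23$, NPAV $-3.86 \pm 2.41$,
possible-theoretical $-4.83 \pm 2.49$; SNAP2 DAV $61 \pm 46.51$ and
possible-theoretical $18 \pm 56$. No SNAP2 NPAV summary is printed; the
closest printed NPAV-like statistic — the benign/likely-benign SNAP2
summary $-12.57 \pm 55.85$ — was adopted once and not revisited.
Default per-gene pool sizes (103 DAV, 7 partial, 48 NPAV, 1448 possible
theoretical) are the dataset totals divided by its 44 genes. Scores are
drawn independently across predictors for shared variant identifiers,
so the generator underestimates the between-predictor correlation of
real scores; consensus precision on synthetic data is therefore
optimistic about independence, and a green end-to-end test establishes
parameter recovery and plumbing, not real-data performance. Skewness,
multimodality from mixed disease mechanisms, per-gene score-range
truncation and annotation label noise are likewise not emulated.

`gen_msa()` plants a conservation mask: conserved columns receive no
substitutions anywhere; each variable column is guaranteed at least one
substitution (when any tier mutates at all), so the GV binary call can
recover the mask exactly — a property of the generator, not of real
alignments, where a variable site can happen to show no variation at a
given sampling depth. Tiers diverge independently from a single
reference sequence; within-tier phylogenetic structure and indels are
not modelled (no gaps are generated).

`gen_annotations()` emits one template per classification-key branch
(16 templates) or samples among them per requested class, with the
intended class and key path as truth columns.

## Known limitations

* No ROC-style threshold optimization: the 2-SD rule is the model.
* No transcript/genome coordinate handling; protein coordinates are
  1-based on the supplied isoform.
* The full ACMG point-based classifier is out of scope; ACMG category
  labels are carried as data fields only.
* Divergence is uncorrected p-distance (see above), bounded by 1, so
  deep-taxon saturation compresses differences.
* Predictors themselves are never run; score tables are inputs.
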