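test_that("codon lookup follows the standard genetic code", {
  expect_equal(codons_of("M"), "ATG")
  expect_length(codons_of("L"), 6L)
  expect_length(codons_of("W"), 1L)
  expect_error(codons_of("*"), "canonical")
  expect_error(codons_of("B"), "canonical")
})

test_that("single-nucleotide accessibility matches the brute-force oracle", {
  expect_true(is_possible("M", "V"))   # ATG -> GTG
  expect_false(is_possible("M", "P"))  # needs two changes
  expect_false(is_possible("W", "F"))  # none of TGG's neighbors is Phe

  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (ref in aas) {
    for (alt in setdiff(aas, ref)) {
      expect_equal(is_possible(ref, alt), is_possible_oracle(ref, alt),
                   info = paste(ref, alt))
      # adjacency of codon sets is symmetric
      expect_equal(is_possible(ref, alt), is_possible(alt, ref))
    }
  }
})

test_that("actual-codon basis restricts accessibility to the codon in hand", {
  # CTG (Leu) reaches Val via GTG but CTA does not reach Phe
  expect_true(is_possible("L", "V", codon = "CTG"))
  expect_false(is_possible("L", "F", codon = "CTA"))
  expect_true(is_possible("L", "F", codon = "CTT"))  # TTT is Phe
  expect_error(is_possible("L", "V", codon = "ATG"), "does not encode")

  # spot-check the oracle on every codon of serine
  for (cd in codons_of("S")) {
    for (alt in c("A", "R", "T", "W")) {
      expect_equal(is_possible("S", alt, codon = cd),
                   is_possible_oracle("S", alt, codon = cd),
                   info = paste(cd, alt))
    }
  }
})

test_that("theoretical enumeration covers 19 substitutions per position", {
  th <- enumerate_theoretical("MK")
  expect_equal(nrow(th), 38L)
  expect_equal(unique(th$basis), "any_codon")

  obs <- data.frame(position = c(1L, 1L, 2L), ref_aa = c("M", "M", "K"),
                    alt_aa = c("V", "T", "R"))
  th2 <- enumerate_theoretical("MK", observed = obs)
  expect_equal(nrow(th2), 35L)
  # conservation: theoretical + observed-in-range = 19 * L
  expect_equal(nrow(th2) + nrow(obs), 19L * 2L)

  expect_error(enumerate_theoretical("MK",
    observed = data.frame(position = 1L, ref_aa = "K", alt_aa = "R")),
    "mismatch")

  # range restriction
  th3 <- enumerate_theoretical("MKLV", range = c(2, 3))
  expect_equal(sort(unique(th3$position)), 2:3)
  expect_equal(nrow(th3), 38L)
})

test_that("poly-Met possible sets equal the single-change neighbors of ATG", {
  th <- enumerate_theoretical(strrep("M", 10))
  atg_neighbors <- sort(c("I", "L", "V", "T", "K", "R"))
  for (p in 1:10) {
    poss <- sort(th$alt_aa[th$position == p & th$possible])
    expect_equal(poss, atg_neighbors)
  }

  # with an explicit cDNA the answer is the same for ATG codons
  seqs <- gen_sequences(10, composition = "M", seed = 2)
  th_cdna <- enumerate_theoretical(seqs$protein, cdna = seqs$cdna)
  expect_equal(unique(th_cdna$basis), "actual_codon")
  expect_equal(sort(th_cdna$alt_aa[th_cdna$position == 3 & th_cdna$possible]),
               atg_neighbors)
})

test_that("a cDNA that does not translate to the protein is rejected", {
  expect_error(enumerate_theoretical("MK", cdna = "ATGATG"), "translate")
  expect_error(enumerate_theoretical("MK", cdna = "ATGAA"), "length")
})

test_that("percentile uses linear interpolation between closest ranks", {
  expect_equal(percentile(1:100, 10), 10.9)
  expect_equal(percentile(42, 37), 42)
  expect_equal(percentile(c(3, 1, 2), 100), 3)
  expect_equal(percentile(c(3, 1, 2), 0), 1)
  expect_error(percentile(numeric(0), 50), "no scores")

  set.seed(23)
  for (i in 1:60) {
    x <- runif(sample(2:40, 1), -50, 50)
    q <- runif(1, 0, 100)
    expect_equal(percentile(x, q), percentile_oracle(x, q))
  }
})

test_that("the negative-selection scan flags per the tail-side sign rule", {
  cfgs <- default_predictors()
  dav <- data.frame(gene = c("g1", "g2", "g3"),
                    predictor = c("EVmutation", "EVmutation", "SNAP2"),
                    score = c(-9, -9, 80))
  theo <- data.frame(gene = c("g1", "g2", "g3"),
                     predictor = c("EVmutation", "EVmutation", "SNAP2"),
                     score = c(-8, -9.5, 85))
  scan <- selection_scan(dav, theo, cfgs)
  res <- scan$results
  # EVmutation uses the 10th percentile: negative delta flags
  g1 <- res[res$gene == "g1", ]
  expect_equal(g1$tail_percentile, 10)
  expect_equal(g1$delta, -1)
  expect_true(g1$flagged)
  g2 <- res[res$gene == "g2", ]
  expect_equal(g2$delta, 0.5)
  expect_false(g2$flagged)
  # SNAP2 uses the 90th percentile: only positive delta flags
  g3 <- res[res$gene == "g3", ]
  expect_equal(g3$tail_percentile, 90)
  expect_equal(g3$delta, -5)
  expect_false(g3$flagged)

  # identical pools: zero delta, unflagged
  scan0 <- selection_scan(dav[1, ], dav[1, ], cfgs)
  expect_equal(scan0$results$delta, 0)
  expect_false(scan0$results$flagged)
})

test_that("impossible theoretical variants are excluded and empty pools skipped", {
  dav <- data.frame(gene = "g1", predictor = "EVmutation", score = -9)
  theo <- data.frame(gene = "g1", predictor = "EVmutation",
                     score = c(-8, -20), possible = c(TRUE, FALSE))
  scan <- selection_scan(dav, theo)
  # the extreme impossible score is dropped, so the gene is flagged
  expect_equal(scan$results$p_theoretical, -8)
  expect_true(scan$results$flagged)

  theo_empty <- data.frame(gene = "g1", predictor = "EVmutation",
                           score = -8, possible = FALSE)
  scan2 <- selection_scan(dav, theo_empty)
  expect_equal(nrow(scan2$results), 0L)
  expect_equal(scan2$skipped$reason, "empty DAV or theoretical pool")
})

test_that("scan flags survive padding the body of the distribution", {
  set.seed(51)
  dav_scores <- c(rnorm(200, -7, 1.5), -12, -12.5)  # heavy observed tail
  theo_scores <- rnorm(2000, -6, 1.5)
  dav <- data.frame(gene = "g", predictor = "EVmutation",
                    score = dav_scores)
  theo <- data.frame(gene = "g", predictor = "EVmutation",
                     score = theo_scores)
  base <- selection_scan(dav, theo)
  expect_true(base$results$flagged)
  # add mass strictly inside the inter-percentile body
  pad <- data.frame(gene = "g", predictor = "EVmutation",
                    score = rep(median(dav_scores), 50))
  padded <- selection_scan(rbind(dav, pad), theo)
  expect_true(padded$results$flagged)
})

test_that("the heatmap orders genes by flag strength", {
  dav <- data.frame(gene = c("weak", "strong"), predictor = "EVmutation",
                    score = c(-8.1, -10))
  theo <- data.frame(gene = c("weak", "strong"), predictor = "EVmutation",
                     score = c(-8, -8))
  scan <- selection_scan(dav, theo)
  expect_equal(rownames(scan$heatmap), c("strong", "weak"))
  expect_equal(scan$heatmap["strong", "EVmutation"], 2)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(scan))
})
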