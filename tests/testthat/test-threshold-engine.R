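ev_cfg <- default_predictors()$EVmutation
snap_cfg <- default_predictors()$SNAP2
pop_cfg <- default_predictors("PoPMuSiC")$PoPMuSiC

test_that("median +/- 2 SD thresholds reproduce the printed worked examples", {
  # SNAP2 general sensitivity threshold: 61 - 2 x 46.51
  expect_equal(threshold_from_stats(61, 46.51, +1, "sensitivity"), -32.02)
  # EVmutation general sensitivity threshold: -6.57 + 2 x 2.22
  expect_equal(threshold_from_stats(-6.57, 2.22, -1, "sensitivity"), -2.13)
  # EVmutation specificity threshold from the NPAV summary stats
  expect_equal(threshold_from_stats(-3.86, 2.41, -1, "specificity"), -8.68)
  # PoPMuSiC: 1.17 - 2 x 1.08 is -0.99 by exact arithmetic
  expect_equal(threshold_from_stats(1.17, 1.08, +1, "sensitivity"), -0.99)
})

test_that("compute_threshold derives median and sample SD from the pool", {
  res <- compute_threshold(c(1, 2, 3), "sensitivity", snap_cfg)
  expect_equal(res$center, 2)
  expect_equal(res$spread, 1)  # n-1 denominator
  expect_equal(res$threshold, 0)
  expect_equal(res$n, 3L)

  # zero spread collapses the threshold onto the median
  res0 <- compute_threshold(c(5, 5, 5), "specificity", snap_cfg)
  expect_equal(res0$threshold, 5)

  expect_error(compute_threshold(7, "sensitivity", snap_cfg),
               "at least 2")
})

test_that("gene-specific thresholds recover the generating distribution", {
  spec <- data.frame(gene = "G1", predictor = "EVmutation",
                     class = c("DAV", "NPAV"),
                     location = c(-7, -4), scale = 2, n = 2000)
  d <- gen_scores(spec, seed = 11)
  fit <- fit_thresholds(d, ev_cfg)
  th <- fit$thresholds
  # orientation -1: t_sens = med_DAV + 2 SD, t_spec = med_NPAV - 2 SD
  expect_equal(th$t_sens, -3.0, tolerance = 0.15 / 3)
  expect_equal(th$t_spec, -8.0, tolerance = 0.15 / 8)
})

test_that("genes with missing or undersized pools are skipped with a reason", {
  d <- data.frame(gene = rep(c("A", "B"), each = 12),
                  predictor = "EVmutation",
                  score = rnorm(24),
                  class = c(rep(c("DAV", "NPAV"), 6),  # gene A: both pools
                            rep("DAV", 12)))           # gene B: DAVs only
  fit <- fit_thresholds(d, ev_cfg, min_dav = 5, min_npav = 5)
  expect_equal(fit$thresholds$gene, "A")
  expect_equal(fit$skipped$gene, "B")
  expect_match(fit$skipped$reason, "pool too small")

  # one gene, two predictors -> two threshold pairs
  d2 <- rbind(d[d$gene == "A", ],
              transform(d[d$gene == "A", ], predictor = "SNAP2"))
  fit2 <- fit_thresholds(d2, default_predictors(), min_dav = 5,
                         min_npav = 5)
  expect_equal(nrow(fit2$thresholds), 2L)
})

test_that("dual classification follows the strict two-gate rule", {
  # thresholds from the printed general EVmutation calibration
  calls <- classify_dual(c(-10, -5, -2.13, -1, 0.5),
                         t_sens = -2.13, t_spec = -8.68, ev_cfg)
  expect_equal(as.character(calls),
               c("pathogenic", "unresolved", "unresolved", "benign",
                 "benign"))
  # crossed thresholds create a conflicting zone
  crossed <- classify_dual(0, t_sens = 2, t_spec = -2, snap_cfg)
  expect_equal(as.character(crossed), "conflicting")
})

test_that("calls are equivariant under score negation with flipped orientation", {
  flipped <- predictor_config("flipped", orientation = +1,
                              observed_min = -ev_cfg$observed_max,
                              observed_max = -ev_cfg$observed_min)
  scores <- seq(-12, 3, by = 0.37)
  a <- classify_dual(scores, -2.13, -8.68, ev_cfg)
  b <- classify_dual(-scores, 2.13, 8.68, flipped)
  expect_equal(as.character(a), as.character(b))
})

test_that("increasing deleteriousness never demotes a call towards benign", {
  scores <- seq(-12, 3, length.out = 200)
  calls <- classify_dual(scores, -2.13, -8.68, ev_cfg)
  rank <- c(benign = 1, unresolved = 2, conflicting = 2, pathogenic = 3)
  u_order <- order(ev_cfg$orientation * scores)
  expect_true(all(diff(rank[as.character(calls)[u_order]]) >= 0))
})

test_that("consensus combination follows the all-agree rule", {
  expect_equal(as.character(combine_calls(c("pathogenic", "pathogenic"))),
               "pathogenic")
  expect_equal(as.character(combine_calls(c("benign", "benign", "benign"))),
               "benign")
  expect_equal(as.character(combine_calls(c("pathogenic", "benign"))),
               "contradictory")
  expect_equal(as.character(combine_calls(c("unresolved", "unresolved"))),
               "unresolved_all")
  expect_equal(as.character(combine_calls(c("pathogenic", "unresolved"))),
               "unresolved_partial")
  expect_error(combine_calls(character(0)), "no per-predictor calls")

  # permutation invariance over random call vectors
  set.seed(42)
  for (i in 1:25) {
    calls <- sample(c("pathogenic", "benign", "unresolved", "conflicting"),
                    sample(1:5, 1), replace = TRUE)
    expect_equal(combine_calls(calls), combine_calls(sample(calls)))
  }
})

test_that("evidence-based thresholds retain ~95% of their defining pools", {
  spec <- default_score_spec("G1", n_dav = 2000, n_npav = 2000)
  d <- gen_scores(spec, seed = 7)
  d <- d[d$class %in% c("DAV", "NPAV"), ]
  fit <- fit_thresholds(d, default_predictors())
  pr <- predict(fit, d)
  for (pred in c("EVmutation", "SNAP2")) {
    dav <- pr$predictor == pred & d$class == "DAV"
    npav <- pr$predictor == pred & d$class == "NPAV"
    # beyond median - 2 SD lies ~2.3% of a normal pool
    expect_gte(mean(pr$call[dav] != "benign"), 0.95)
    expect_gte(mean(pr$call[npav] != "pathogenic"), 0.95)
  }
})

test_that("weight rescaling maps threshold to 0 and range ends to +/-100", {
  expect_equal(rescale_to_weight(3.8104, 0, ev_cfg, mode = "literal"), 100)
  expect_equal(rescale_to_weight(-12.933, 0, ev_cfg, mode = "literal"),
               -100)
  expect_equal(rescale_to_weight(0, 0, ev_cfg, mode = "literal"), 0)
  # harmonized mode flips the smaller-is-deleterious predictor so +100 is
  # always the deleterious extreme
  expect_equal(rescale_to_weight(-12.933, 0, ev_cfg), 100)
  expect_equal(rescale_to_weight(99, 0, snap_cfg), 100)
  # piecewise linearity on each side of the threshold
  expect_equal(rescale_to_weight(1.9052, 0, ev_cfg, mode = "literal"), 50)
  expect_warning(w <- rescale_to_weight(10, 0, ev_cfg, mode = "literal"),
                 "clamped")
  expect_equal(w, 100)
  expect_error(rescale_to_weight(1, -50, ev_cfg), "inside the observed")
})

test_that("weighted mean averages per-predictor weights", {
  expect_equal(weighted_mean_score(c(a = 100, b = -100)), 0)
  expect_equal(weighted_mean_score(c(a = 40)), 40)
  expect_equal(weighted_mean_score(c(a = 30, b = 60, c = -30)), 20)
  expect_error(weighted_mean_score(numeric(0)), "no weights")
})

test_that("the fitted model object supports the standard methods", {
  d <- gen_scores(default_score_spec(c("A", "B")), seed = 3)
  d <- d[d$class != "theoretical", ]
  fit <- fit_thresholds(d, default_predictors())
  expect_s3_class(fit, "vthresh")
  expect_output(print(fit), "dual-threshold")
  expect_named(coef(fit), c("gene", "predictor", "t_sens", "t_spec"))
  s <- summary(fit)
  expect_s3_class(s, "summary.vthresh")
  expect_true("separation" %in% names(s$table))

  pr <- predict(fit, d, type = "combined")
  expect_true(all(table(pr$n_predictors) > 0))
  expect_equal(nrow(pr), length(unique(paste(d$gene, d$hgvs_p))))

  sim <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sim, 2L)
  expect_named(sim[[1]], c("gene", "predictor", "score", "class"))
  sim2 <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(sim, sim2)

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, d))
})

test_that("general scope pools all genes into one threshold pair per predictor", {
  d <- gen_scores(default_score_spec(c("A", "B", "C")), seed = 9)
  d <- d[d$class != "theoretical", ]
  fit <- fit_thresholds(d, default_predictors(), scope = "general")
  expect_equal(sort(unique(fit$thresholds$gene)), "(all)")
  expect_equal(nrow(fit$thresholds), 2L)
  pr <- predict(fit, d)
  expect_false(anyNA(pr$call))
})
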