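ev_cfg <- default_predictors()$EVmutation

# build a call/class table with exact category counts
make_calls <- function(path_dav, path_npav, ben_dav, ben_npav,
                       rest_dav = 0, rest_npav = 0,
                       rest_call = "unresolved_all") {
  calls <- c(rep("pathogenic", path_dav + path_npav),
             rep("benign", ben_dav + ben_npav),
             rep(rest_call, rest_dav + rest_npav))
  class <- c(rep(c("DAV", "NPAV"), c(path_dav, path_npav)),
             rep(c("DAV", "NPAV"), c(ben_dav, ben_npav)),
             rep(c("DAV", "NPAV"), c(rest_dav, rest_npav)))
  list(calls = calls, class = class)
}

test_that("gate counts reproduce the printed precision percentages", {
  # combined EVmutation+SNAP2 outcome: 763 pathogenic (752 DAV, 11 NPAV),
  # 622 benign (102 DAV, 520 NPAV) out of 6639 evaluable
  x <- make_calls(752, 11, 102, 520, rest_dav = 4546 - 854,
                  rest_npav = 2093 - 531)
  rep <- evaluate_calls(x$calls, x$class)
  expect_equal(rep$n_evaluated, 6639)
  expect_equal(round(rep$precision_pathogenic, 1), 98.6)
  expect_equal(round(rep$precision_benign, 1), 83.6)
  expect_equal(round(rep$predictable_fraction), 21)

  # EVmutation alone: 1236 pathogenic (1188 DAV), 807 benign (643 NPAV)
  y <- make_calls(1188, 48, 164, 643, rest_dav = 4546 - 1352,
                  rest_npav = 2093 - 691)
  rep_ev <- evaluate_calls(y$calls, y$class)
  expect_equal(round(rep_ev$precision_pathogenic, 1), 96.1)
  expect_equal(round(rep_ev$precision_benign, 1), 79.7)
  expect_equal(round(rep_ev$predictable_fraction), 31)

  # SNAP2 alone: 1390 pathogenic (1343 DAV), 1365 benign (962 NPAV)
  z <- make_calls(1343, 47, 403, 962, rest_dav = 4546 - 1746,
                  rest_npav = 2093 - 1009)
  rep_sn <- evaluate_calls(z$calls, z$class)
  expect_equal(round(rep_sn$precision_pathogenic, 1), 96.6)
  expect_equal(round(rep_sn$precision_benign, 1), 70.5)
  expect_equal(round(rep_sn$predictable_fraction), 41)
})

test_that("a perfectly called fixture scores 100% on both axes", {
  calls <- c(rep("pathogenic", 6), rep("benign", 4))
  class <- c(rep("DIS", 6), rep("NO_PHEN", 4))
  rep <- evaluate_calls(calls, class)
  expect_equal(rep$sensitivity, 100)
  expect_equal(rep$specificity, 100)
  expect_equal(rep$predictable_fraction, 100)
})

test_that("PART and EXCL records never enter the denominators", {
  calls <- c("pathogenic", "pathogenic", "benign", "unresolved_all",
             "pathogenic")
  class <- c("DIS", "NO_PHEN", "NO_PHEN", "DIS", "PART")
  rep <- evaluate_calls(calls, class)
  expect_equal(rep$n_evaluated, 4L)
  expect_equal(rep$n_pass_spec, 2L)  # the PART pathogenic call is ignored
  expect_error(evaluate_calls(c("pathogenic"), c("EXCL")), "no evaluable")
})

test_that("percentages are invariant under record duplication", {
  x <- make_calls(37, 3, 11, 45, rest_dav = 60, rest_npav = 20,
                  rest_call = "unresolved_partial")
  r1 <- evaluate_calls(x$calls, x$class)
  r3 <- evaluate_calls(rep(x$calls, 3), rep(x$class, 3))
  for (f in c("precision_pathogenic", "precision_benign", "sensitivity",
              "specificity", "predictable_fraction")) {
    expect_equal(r3[[f]], r1[[f]], info = f)
  }
})

test_that("every evaluable record lands in exactly one outcome category", {
  set.seed(12)
  calls <- sample(c("pathogenic", "benign", "contradictory",
                    "unresolved_partial", "unresolved_all", "conflicting"),
                  200, replace = TRUE)
  class <- sample(c("DAV", "NPAV"), 200, replace = TRUE)
  rep <- evaluate_calls(calls, class)
  expect_equal(rep$n_pass_spec + rep$n_pass_sens +
                 sum(rep$category_breakdown), rep$n_evaluated)
  expect_equal(rep$n_pass_spec, rep$n_pass_spec_dav + rep$n_pass_spec_npav)
  expect_equal(rep$n_pass_sens, rep$n_pass_sens_dav + rep$n_pass_sens_npav)
})

test_that("fixed-threshold accuracy counts strict deleterious-side fractions", {
  out <- evaluate_fixed_threshold(c(-5, -1), c("DAV", "DAV"), -2.13, ev_cfg)
  expect_equal(out[["DAV"]], 50)
  expect_true(is.na(out[["NPAV"]]))  # empty class reported as NA, never 0

  all_beyond <- evaluate_fixed_threshold(c(-5, -6, -7), rep("DIS", 3), -2.13,
                                         ev_cfg)
  expect_equal(all_beyond[["DAV"]], 100)

  # NPAVs are correct on the non-deleterious side (tie counts as correct)
  npav <- evaluate_fixed_threshold(c(-1, -2.13, -4), rep("NPAV", 3), -2.13,
                                   ev_cfg)
  expect_equal(npav[["NPAV"]], 100 * 2 / 3)
})

test_that("the 95% sensitivity threshold keeps >=95% of its defining pool", {
  d <- gen_scores(default_score_spec("G1", n_dav = 3000), seed = 21)
  dav <- d[d$class == "DAV" & d$predictor == "EVmutation", ]
  th <- compute_threshold(dav$score, "sensitivity", ev_cfg)
  acc <- evaluate_fixed_threshold(dav$score, dav$class, th$threshold, ev_cfg)
  expect_gte(acc[["DAV"]], 95)
})

test_that("group comparisons delegate to the standard tests", {
  set.seed(5)
  a <- rnorm(50)
  b <- rnorm(50, mean = 3)
  cmp <- compare_groups(a, b, test = "t_test")
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$direction, -1)

  same <- rnorm(30)
  cmp0 <- compare_groups(same, same, test = "t_test")
  expect_equal(cmp0$statistic, 0)
  expect_gt(cmp0$p_value, 0.99)

  kw <- compare_groups(a, b, test = "kruskal_wallis")
  expect_lt(kw$p_value, 0.001)

  chi <- compare_groups(matrix(c(50, 50, 50, 50), 2), test = "chi_square")
  expect_equal(chi$statistic, 0)

  expect_error(compare_groups(rep(1, 5), rep(2, 5), test = "t_test"),
               "zero variance")
  expect_error(compare_groups(1, c(1, 2), test = "t_test"), "at least 2")
})

test_that("one-tailed direction can be requested", {
  set.seed(8)
  a <- rnorm(40, 1)
  b <- rnorm(40)
  one <- compare_groups(a, b, test = "t_test", alternative = "greater")
  two <- compare_groups(a, b, test = "t_test")
  expect_lt(one$p_value, two$p_value)
})

test_that("stratified reports flag small strata and compare the rest", {
  set.seed(31)
  n <- 120
  strata <- c(rep("domain", 58), rep("outside", 59), rep("tiny", 3))
  class <- sample(c("DAV", "NPAV"), n, replace = TRUE)
  calls <- ifelse(class == "DAV", "pathogenic", "benign")
  score <- rnorm(n) + (strata == "domain") * 2
  rep <- stratified_report(calls, class, strata, score = score)
  expect_named(rep$reports, c("domain", "outside", "tiny"))
  expect_equal(rep$flagged, "tiny")
  expect_equal(nrow(rep$comparisons), 1L)  # tiny stratum excluded
  expect_lt(rep$comparisons$p_value, 0.001)
  expect_equal(rep$comparisons$p_adjusted,
               pmin(1, rep$comparisons$p_value * nrow(rep$comparisons)))

  # identical strata are not significantly different
  rep2 <- stratified_report(calls[1:100], class[1:100],
                            rep(c("x", "y"), 50),
                            score = rep(rnorm(50), each = 2))
  expect_gt(rep2$comparisons$p_value, 0.05)
})
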