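test_that("ROC handles separation, the 4-point example, and ties", {
  sep <- rocCurve(c(1, 2, 3, 10, 11, 12), c("F", "F", "F", "nF", "nF", "nF"))
  expect_equal(sep@orientation, "positive_if_less")
  expect_equal(aucWithCi(sep)$auc, 1)
  expect_true(any(sep@fpr == 0 & sep@tpr == 1))

  four <- rocCurve(c(0.1, 0.4, 0.35, 0.8), c("n", "n", "p", "p"),
                   positive = "p", orientation = "positive_if_greater")
  expect_equal(aucWithCi(four)$auc, 0.75)

  same <- rocCurve(rep(5, 8), rep(c("F", "nF"), 4))
  expect_equal(aucWithCi(same)$auc, 0.5)
})

test_that("curves always contain the (0,0) and (1,1) sentinels", {
  set.seed(2)
  rc <- rocCurve(rnorm(30), rep(c("F", "nF"), 15))
  expect_true(any(rc@fpr == 0 & rc@tpr == 0))
  expect_true(any(rc@fpr == 1 & rc@tpr == 1))
  ord <- order(rc@fpr, rc@tpr)
  expect_true(all(diff(rc@fpr[ord]) >= 0))
  expect_true(all(diff(rc@tpr[ord]) >= 0))
  expect_error(rocCurve(1:4, rep("F", 4)), "both classes")
})

test_that("trapezoid AUC equals the Mann-Whitney estimator", {
  for (s in 1:10) {
    set.seed(s)
    xPos <- rnorm(12, 1)
    xNeg <- rnorm(15, 0)
    rc <- rocCurve(c(xPos, xNeg), rep(c("F", "nF"), c(12, 15)),
                   orientation = "positive_if_greater")
    u <- wilcox.test(xPos, xNeg, exact = FALSE)$statistic
    expect_equal(aucWithCi(rc)$auc, unname(u) / (12 * 15),
                 tolerance = 1e-12)
  }
  # midrank estimator under ties
  v <- c(1, 2, 2, 3, 1, 2, 3, 3)
  l <- rep(c("F", "nF"), each = 4)
  rc <- rocCurve(v, l, orientation = "positive_if_greater")
  u <- wilcox.test(v[1:4], v[5:8], exact = FALSE)$statistic
  expect_equal(aucWithCi(rc)$auc, unname(u) / 16, tolerance = 1e-12)
})

test_that("AUC confidence machinery behaves at the binormal benchmark", {
  set.seed(31)
  scores <- c(rnorm(200, 1), rnorm(200, 0))
  labels <- rep(c("F", "nF"), each = 200)
  a <- aucWithCi(rocCurve(scores, labels))
  expect_lt(abs(a$auc - pnorm(1 / sqrt(2))), 0.03)
  expect_true(a$ci_lo < a$auc && a$auc < a$ci_hi)
  expect_lt(a$p_value, 0.001)
  # zero-SE at full separation with tiny n
  asep <- aucWithCi(rocCurve(c(1, 2, 10, 11), c("nF", "nF", "F", "F")))
  expect_equal(asep$ci_hi, 1)
  expect_true(asep$unreliable == FALSE || asep$n_pos >= 2)
})

test_that("cross-check against an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  v <- rnorm(40)
  l <- rep(c("F", "nF"), 20)
  mine <- aucWithCi(rocCurve(v, l))$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(l == "F", v)))
  expect_equal(mine, as.numeric(ref), tolerance = 1e-9)
})

test_that("orthogonal cut-off resolves the documented tie to higher sensitivity", {
  four <- rocCurve(c(0.1, 0.4, 0.35, 0.8), c("n", "n", "p", "p"),
                   positive = "p", orientation = "positive_if_greater")
  cut <- bestCutoffOrthogonal(four)
  expect_equal(cut$distance, 0.5)
  expect_equal(cut$sens_at_cut, 1)
  expect_equal(cut$cutoff, 0.35)
  sep <- rocCurve(c(1, 2, 10, 11), c("nF", "nF", "F", "F"))
  expect_equal(bestCutoffOrthogonal(sep)$distance, 0)
})

test_that("cut-off selection equals the exhaustive scan on 100 seeded sets", {
  for (s in 1:100) {
    set.seed(s)
    n1 <- sample(5:15, 1)
    n2 <- sample(5:15, 1)
    v <- c(rnorm(n1, 0.8), rnorm(n2))
    l <- rep(c("F", "nF"), c(n1, n2))
    rc <- rocCurve(v, l)
    cut <- bestCutoffOrthogonal(rc)
    expect_equal(cut$distance,
                 oracleMinRocDistance(v, l, "F", rc@orientation),
                 tolerance = 1e-12)
    # the reported operating point is consistent with its own distance
    expect_equal(cut$distance,
                 sqrt((1 - cut$spec_at_cut)^2 + (1 - cut$sens_at_cut)^2),
                 tolerance = 1e-12)
  }
})

test_that("confusion counts equal a direct loop over subjects", {
  set.seed(77)
  v <- rnorm(60)
  l <- sample(c("F", "nF"), 60, replace = TRUE, prob = c(0.6, 0.4))
  cm <- confusionAtCutoff(v, l, 0.2, "positive_if_greater", positive = "F")
  tp <- fn <- fp <- tn <- 0
  for (i in seq_along(v)) {
    pred <- v[i] >= 0.2
    if (l[i] == "F" && pred) tp <- tp + 1
    if (l[i] == "F" && !pred) fn <- fn + 1
    if (l[i] != "F" && pred) fp <- fp + 1
    if (l[i] != "F" && !pred) tn <- tn + 1
  }
  expect_equal(cm, list(tp = tp, fn = fn, fp = fp, tn = tn))
  expect_equal(cm$tp + cm$fn, sum(l == "F"))
  # degenerate cut-offs
  all_pos <- confusionAtCutoff(v, l, min(v) - 1, "positive_if_greater")
  expect_equal(all_pos$fn, 0)
  expect_equal(all_pos$tn, 0)
})

test_that("reversing labels mirrors the ROC geometry", {
  set.seed(9)
  v <- rnorm(30)
  l <- rep(c("F", "nF"), 15)
  a <- aucWithCi(rocCurve(v, l, orientation = "positive_if_greater"))$auc
  flipped <- ifelse(l == "F", "nF", "F")
  b <- aucWithCi(rocCurve(v, flipped,
                          orientation = "positive_if_greater"))$auc
  expect_equal(a, 1 - b, tolerance = 1e-12)
})

test_that("Wald intervals reproduce their defining arithmetic", {
  perf <- diagnosticPerformanceWald(tp = 10, fn = 0, fp = 3, tn = 7)
  sens <- perf[perf$metric == "sensitivity", ]
  expect_equal(sens$estimate, 100)
  expect_equal(sens$lo, 100)
  expect_equal(sens$hi, 100)
  half <- diagnosticPerformanceWald(tp = 50, fn = 50, fp = 0, tn = 1)
  s2 <- half[half$metric == "sensitivity", ]
  expect_equal(s2$estimate, 50)
  expect_equal(s2$lo, 50 - 100 * 1.959964 * sqrt(0.25 / 100),
               tolerance = 1e-6)
  expect_error(diagnosticPerformanceWald(0, 0, 0, 0), "all-zero")
  nodenom <- diagnosticPerformanceWald(0, 0, 2, 3)
  expect_true(is.na(nodenom$estimate[nodenom$metric == "sensitivity"]))
})

test_that("Wald interval width shrinks as one over root n", {
  w <- function(k) {
    p <- diagnosticPerformanceWald(18 * k, 7 * k, 5 * k, 12 * k)
    p$hi - p$lo
  }
  expect_equal(w(2), w(1) / sqrt(2), tolerance = 1e-9)
})

test_that("group comparison is null-safe and detects a planted shift", {
  base <- data.frame(value = rep(c(1, 2, 3, 4, 5), 4),
                     group = rep(c("F", "nF"), each = 10))
  nullCase <- compareGroups(base, "value", "group")
  expect_gt(nullCase$omnibus$p_value, 0.05)
  expect_equal(nullCase$omnibus$test, "mann_whitney")
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    d <- data.frame(value = c(rnorm(30, 60, 12), rnorm(30, 80, 12)),
                    group = rep(c("F", "nF"), each = 30))
    if (compareGroups(d, "value", "group")$omnibus$p_value < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("three-group comparisons run Kruskal-Wallis plus pairwise tests", {
  set.seed(4)
  d <- data.frame(value = c(rnorm(15, 0), rnorm(15, 0.2), rnorm(15, 2)),
                  group = rep(c("C1", "C2", "F"), each = 15))
  cg <- compareGroups(d, "value", "group")
  expect_equal(cg$omnibus$test, "kruskal_wallis")
  expect_equal(nrow(cg$pairwise), 3)
  expect_equal(cg$descriptives$n, rep(15, 3))
  expect_true(all(c("median", "p25", "p75", "shapiro_p") %in%
                    names(cg$descriptives)))
})

test_that("paired contrasts use the signed-rank test on aligned subjects", {
  set.seed(6)
  d <- data.frame(id = rep(1:20, 2),
                  value = c(rnorm(20, 10), rnorm(20, 12)),
                  phase = rep(c("baseline", "recovery"), each = 20))
  cg <- compareGroups(d, "value", "phase", paired = TRUE, id = "id")
  expect_equal(cg$omnibus$test, "wilcoxon_signed_rank")
  ref <- wilcox.test(d$value[1:20], d$value[21:40], paired = TRUE,
                     exact = FALSE)
  expect_equal(cg$omnibus$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("nominal comparisons follow the expected-cell-count rule", {
  d <- data.frame(outcome = rep(c("yes", "no", "yes", "no"), c(9, 1, 2, 8)),
                  group = rep(c("F", "nF"), each = 10))
  cg <- compareGroups(d, "outcome", "group", type = "nominal")
  expect_equal(cg$omnibus$test, "fisher_exact")
  tab <- table(d$group, d$outcome)
  expect_equal(cg$omnibus$p_value, oracleFisher2x2(tab), tolerance = 1e-9)
  big <- data.frame(outcome = rep(c("yes", "no", "yes", "no"),
                                  c(40, 20, 20, 40)),
                    group = rep(c("F", "nF"), each = 60))
  expect_equal(compareGroups(big, "outcome", "group",
                             type = "nominal")$omnibus$test, "chi_squared")
})

test_that("evaluateBiomarkers assembles both result tables with n", {
  set.seed(44)
  d <- data.frame(lf_nu = c(rnorm(20, 60, 10), rnorm(15, 82, 8)),
                  delta_t = c(rnorm(20, 120, 25), rnorm(15, 55, 15)),
                  group = rep(c("F", "nF"), c(20, 15)))
  ev <- evaluateBiomarkers(d, c("lf_nu", "delta_t"))
  expect_equal(nrow(ev$roc), 2)
  expect_true(all(c("auc", "ci_lo", "ci_hi", "cutoff", "inequality",
                    "n_pos", "n_neg") %in% names(ev$roc)))
  expect_gt(ev$roc$auc[ev$roc$index == "lf_nu"], 0.8)
  expect_true(grepl("<=", ev$roc$inequality[ev$roc$index == "lf_nu"]))
  expect_true(grepl(">=", ev$roc$inequality[ev$roc$index == "delta_t"]))
  expect_equal(nrow(ev$performance), 8)
  expect_true(all(ev$performance$n > 0))
})
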