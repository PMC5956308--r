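# Group statistics: ANOVA/Tukey, ROC, stepwise selection and LOOCV.

make_tab <- function(values, groups) {
  data.frame(subject_id = sprintf("S%02d", seq_along(values)),
             group = groups, v = values, stringsAsFactors = FALSE)
}

test_that("one-way ANOVA with Tukey reproduces hand-computed cases", {
  tab <- make_tab(c(1, 2, 3, 2, 3, 4, 5, 6, 7),
                  rep(c("HC", "PRP", "SSc"), each = 3))
  res <- anova_tukey(tab, "v")
  # SSB = 26, SSW = 6 -> F = (26/2)/(6/6) = 13
  expect_equal(res$F, 13, tolerance = 1e-9)
  expect_lt(res$p, 0.05)

  # all values identical: F defined as 0, nothing significant
  tab0 <- make_tab(rep(2, 9), rep(c("HC", "PRP", "SSc"), each = 3))
  res0 <- anova_tukey(tab0, "v")
  expect_identical(res0$F, 0)
  expect_false(any(res0$flags))

  # two identical groups and one far-shifted: exactly the two pairs
  # involving the shifted group are flagged
  set.seed(2)
  base <- rnorm(8)
  tab2 <- make_tab(c(base, base, base + 50),
                   rep(c("HC", "PRP", "SSc"), each = 8))
  res2 <- anova_tukey(tab2, "v")
  expect_identical(unname(res2$flags),
                   c(FALSE, TRUE, TRUE))   # PRP-HC, SSc-HC, SSc-PRP

  expect_error(anova_tukey(make_tab(1:3, c("HC", "HC", "SSc")), "v"),
               class = "nailfold_invalid_input")
  expect_error(anova_tukey(tab, "nope"), class = "nailfold_schema_error")
})

test_that("ANOVA F equals t^2 on two-group data", {
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(15, 0.5)
    tab <- make_tab(c(x, y), rep(c("HC", "SSc"), c(12, 15)))
    res <- anova_tukey(tab, "v")
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
  }
})

test_that("ROC area: exact small cases and the pairwise-counting oracle", {
  expect_equal(roc_auc(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(3, 6), rep(c(TRUE, FALSE), 3),
                       direction = ">")$auc, 0.5)
  r <- roc_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)   # 3 wins of 4 pairs

  pair_oracle <- function(s, l) {
    pos <- s[l]; neg <- s[!l]
    tot <- 0
    for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  set.seed(12)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    l <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    s <- sample.int(8, n, replace = TRUE)
    expect_identical(roc_auc(s, l, direction = ">")$auc, pair_oracle(s, l))
  }
})

test_that("ROC curve geometry, orientation and the complement identity", {
  set.seed(4)
  s <- rnorm(40)
  l <- runif(40) < 0.4
  r <- roc_auc(s, l, direction = ">")
  expect_identical(r$curve[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  # trapezoidal area under the curve equals the rank-based area
  trap <- sum(diff(r$curve$fpr) *
                (head(r$curve$tpr, -1) + tail(r$curve$tpr, -1)) / 2)
  expect_equal(trap, r$auc, tolerance = 1e-12)
  # flipping the labels complements the area (fixed orientation)
  expect_equal(roc_auc(s, !l, direction = ">")$auc, 1 - r$auc,
               tolerance = 1e-12)
  # auto orientation reports >= 0.5 and records the direction used
  rauto <- roc_auc(-s, l)
  expect_gte(rauto$auc, 0.5)
  expect_error(roc_auc(s, rep(TRUE, 40)), class = "nailfold_invalid_input")
})

test_that("Hanley-McNeil SE matches the closed form", {
  r <- roc_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))
  a <- 0.75; q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (q1 - a^2) + (q2 - a^2)) / 4)
  expect_equal(r$se, se, tolerance = 1e-12)
})

test_that("stepwise selection matches step() on an initial linear fit", {
  set.seed(42)
  for (i in 1:12) {
    n <- 40 + 5 * i
    X <- matrix(rnorm(n * 5), n)
    colnames(X) <- paste0("x", 1:5)
    y <- as.numeric(runif(n) < plogis(X[, 1] - 0.5 * X[, 3]))
    Xz <- scale(X)
    mine <- nailfold:::stepwise_select(Xz, y)
    ref <- attr(terms(stats::step(lm(y ~ ., data.frame(y = y, Xz)),
                                  direction = "both", trace = 0)),
                "term.labels")
    expect_setequal(mine, ref)
  }
})

test_that("stepwise logistic: duplicated and informative candidates", {
  set.seed(8)
  n <- 200
  tab <- data.frame(subject_id = sprintf("S%03d", 1:n),
                    a = rnorm(n), b = rnorm(n), c = rnorm(n))
  tab$dup <- tab$a + rnorm(n, 0, 1e-8)    # near-exact duplicate of `a`
  y <- runif(n) < plogis(3 * tab$a)
  tab$group <- ifelse(y, "SSc", "HC")
  fit <- stepwise_logistic(tab, c("a", "dup", "b", "c"))
  expect_true(sum(c("a", "dup") %in% fit$selected_terms) <= 1)
  expect_true(any(c("a", "dup") %in% fit$selected_terms))

  # informative parameter among noise is found; coefficients on the
  # original scale preserve the predicted ranking
  hits <- 0
  for (sd in 1:20) {
    set.seed(sd)
    X <- data.frame(subject_id = sprintf("S%03d", 1:n),
                    x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                    x4 = rnorm(n), x5 = rnorm(n))
    yy <- runif(n) < plogis(2.5 * X$x1)
    f <- stepwise_logistic(X, paste0("x", 1:5), labels = yy)
    hits <- hits + ("x1" %in% f$selected_terms)
  }
  expect_gte(hits, 18)

  # labels carrying no information: selections stay minimal
  sizes <- sapply(1:20, function(sd) {
    set.seed(sd + 100)
    X <- data.frame(x1 = rnorm(60), x2 = rnorm(60), x3 = rnorm(60),
                    x4 = rnorm(60))
    length(stepwise_logistic(X, paste0("x", 1:4),
                             labels = runif(60) < 0.5)$selected_terms)
  })
  expect_lte(median(sizes), 1)

  expect_error(stepwise_logistic(tab, "a"),
               class = "nailfold_invalid_input")
  tab$const <- 1
  expect_error(stepwise_logistic(tab, c("a", "const")),
               class = "nailfold_invalid_input")
})

test_that("perfect separation falls back to a penalised fit and is flagged", {
  n <- 30
  tab <- data.frame(x1 = c(rnorm(15, -4), rnorm(15, 4)), x2 = rnorm(n))
  y <- tab$x1 > 0
  fit <- stepwise_logistic(tab, c("x1", "x2"), labels = y)
  expect_true(fit$separated)
  expect_true(all(is.finite(fit$coefficients)))
  p <- nailfold:::predict_model_fit(fit, tab)
  expect_gt(min(p[y]), max(p[!y]))
})

test_that("LOOCV produces one out-of-fold score per subject and is exact on
           separable cohorts", {
  tab <- simulate_cohort(5, 0, 5, effect_scale = 4, seed = 3)
  res <- loocv_roc(tab)
  expect_length(res$loocv_scores, 10)
  expect_true(all(is.finite(res$loocv_scores)))
  expect_identical(res$combined_roc$n_pos + res$combined_roc$n_neg, 10L)
  expect_error(loocv_roc(tab[1:3, ]), class = "nailfold_invalid_input")
})

test_that("cohort report mirrors the results-table layout and is invariant
           to row order", {
  tab <- simulate_cohort(12, 6, 12, seed = 5)
  rep1 <- cohort_report(tab)
  expect_identical(rep1$table$parameter,
                   c("density", "mean_width", "max_width", "shape",
                     "derangement", "flow", "combined_structure",
                     "combined_structure_flow"))
  expect_true(all(is.finite(rep1$table$az)))
  expect_true(all(rep1$table$az >= 0.5 & rep1$table$az <= 1))
  # permuting the rows changes nothing
  set.seed(1)
  rep2 <- cohort_report(tab[sample(nrow(tab)), ])
  expect_identical(rep1$table, rep2$table)
  expect_identical(rep1$combined_full$loocv_scores,
                   rep2$combined_full$loocv_scores)
  # determinism: identical input -> identical report
  expect_identical(rep1$table, cohort_report(tab)$table)
  expect_error(cohort_report(tab[, -3]), class = "nailfold_schema_error")
})

test_that("synthetic cohorts have the documented shape and ranges", {
  tab <- simulate_cohort(seed = 2)
  expect_identical(nrow(tab), 112L)
  expect_identical(as.vector(table(factor(tab$group,
                                          c("HC", "PRP", "SSc")))),
                   c(50L, 12L, 50L))
  expect_true(all(tab$shape >= 0 & tab$shape <= 1))
  expect_true(all(tab$derangement >= 0 & tab$derangement <= 1))
  expect_true(all(tab$mean_width > 0 & tab$flow > 0 & tab$density > 0))
  expect_true(all(tab$max_width >= tab$mean_width))
  expect_identical(tab, simulate_cohort(seed = 2))
  # SSc group is wider and slower on average, as constructed
  expect_gt(mean(tab$mean_width[tab$group == "SSc"]),
            mean(tab$mean_width[tab$group == "HC"]))
  expect_lt(mean(tab$flow[tab$group == "SSc"]),
            mean(tab$flow[tab$group == "HC"]))
  # a null cohort carries no group information by construction
  tn <- simulate_null_cohort(40, seed = 1)
  expect_identical(nrow(tn), 40L)
  expect_identical(sort(unique(tn$group)), c("HC", "SSc"))
})
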