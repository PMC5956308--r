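# Group statistics: one-way ANOVA with Tukey's range test, and ROC analysis
# of SSc vs pooled HC/PRP.

NF_PAIRS <- c("PRP-HC", "SSc-HC", "SSc-PRP")

as_positive_label <- function(labels) {
  if (is.logical(labels)) return(labels)
  as.character(labels) == "SSc"
}

#' One-way ANOVA and Tukey's range test for one parameter
#'
#' Standard one-way decomposition across the HC / PRP / SSc groups followed
#' by Tukey's HSD on the studentized range, with the Tukey-Kramer adjustment
#' for unequal group sizes. Pairwise significance flags use the convention
#' `#` = PRP vs HC, `†` = SSc vs HC, `‡` = SSc vs PRP.
#'
#' @param table cohort data.frame with `group` and the parameter column.
#' @param parameter column name to test.
#' @param alpha significance level.
#' @return list with `F`, `p`, `tukey` (the adjusted pairwise table) and
#'   `flags`, a named logical vector over `PRP-HC`, `SSc-HC`, `SSc-PRP`.
#' @export
anova_tukey <- function(table, parameter, alpha = 0.05) {
  v <- table[[parameter]]
  if (is.null(v)) {
    nf_error("nailfold_schema_error",
             sprintf("parameter column `%s` is missing", parameter))
  }
  g <- factor(as.character(table$group),
              levels = intersect(NF_GROUPS, unique(table$group)))
  tabn <- table(g)
  if (length(tabn) < 2 || any(tabn < 2)) {
    nf_error("nailfold_invalid_input",
             "ANOVA needs >= 2 groups with >= 2 subjects each")
  }
  flags <- setNames(rep(FALSE, length(NF_PAIRS)), NF_PAIRS)
  if (var(v) == 0) {
    return(list(F = 0, p = 1, tukey = NULL, flags = flags))
  }
  fit <- aov(v ~ g)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  present <- intersect(NF_PAIRS, rownames(tk))
  flags[present] <- tk[present, "p adj"] < alpha
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1], tukey = tk,
       flags = flags)
}

#' ROC curve and area (A_z)
#'
#' The area under the ROC curve computed by the rank (Mann-Whitney)
#' statistic with half credit for ties, equal to the trapezoidal area under
#' the empirical curve. With `direction = "auto"` the scores are flipped
#' when needed so the reported area is >= 0.5, and the orientation used is
#' recorded. The standard error is the Hanley-McNeil estimate.
#'
#' @param scores numeric per-subject scores.
#' @param labels logical (TRUE = positive) or a group vector in which `SSc`
#'   is the positive class.
#' @param direction `"auto"`, `">"` (higher score = positive) or `"<"`.
#' @return a `roc_result`: `auc`, `se`, `curve` (data.frame `fpr`, `tpr`
#'   from (0,0) to (1,1)), `n_pos`, `n_neg`, `direction` (the orientation
#'   actually used).
#' @export
roc_auc <- function(scores, labels, direction = c("auto", ">", "<")) {
  direction <- match.arg(direction)
  pos <- as_positive_label(labels)
  if (length(scores) != length(pos)) {
    nf_error("nailfold_invalid_input", "scores and labels differ in length")
  }
  keep <- is.finite(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) {
    nf_error("nailfold_invalid_input", "both classes must be present")
  }
  auc_of <- function(s) {
    r <- rank(s)
    (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  }
  used <- if (direction == "<") "<" else ">"
  s <- if (used == "<") -scores else scores
  a <- auc_of(s)
  if (direction == "auto" && a < 0.5) {
    used <- "<"; s <- -scores; a <- auc_of(s)
  }
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(s[pos] >= t) / np, 0))
  fpr <- c(0, vapply(thr, function(t) sum(s[!pos] >= t) / nn, 0))
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + (np - 1) * (q1 - a^2) + (nn - 1) * (q2 - a^2)) /
               (np * nn))
  structure(list(auc = a, se = se,
                 curve = data.frame(fpr = fpr, tpr = tpr),
                 n_pos = np, n_neg = nn, direction = used),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC A_z = %.3f +/- %.3f (%d pos, %d neg)\n",
              x$auc, x$se, x$n_pos, x$n_neg))
  invisible(x)
}
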