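# The cohort report: group means +/- SE, pairwise flags, per-parameter and
# combined-model ROC areas, in the layout of a capillaroscopy results table.

#' Full cohort statistical report
#'
#' For each of the six parameters: per-group mean and standard error,
#' ANOVA/Tukey pairwise significance flags, and the single-parameter ROC
#' area (SSc vs pooled HC/PRP, auto-oriented) with its Hanley-McNeil SE.
#' Two combined models follow: the five structural parameters
#' (density, mean width, max width, shape, derangement), and structure plus
#' flow, each selected by stepwise logistic regression and scored by
#' leave-one-out cross-validated ROC. The report is a deterministic function
#' of the input table and is invariant to row order.
#'
#' @param table cohort data.frame (see [cohort_table()] /
#'   [simulate_cohort()]).
#' @param alpha significance level for the pairwise flags.
#' @return a `cohort_report`: `table` (the formatted per-parameter
#'   data.frame plus the two combined rows), `rocs` (per-parameter
#'   `roc_result`s), `anova`, `combined_structure` and `combined_full`
#'   (`model_fit`s with LOOCV scores and ROCs), `n` per group.
#' @export
cohort_report <- function(table, alpha = 0.05) {
  missing_cols <- setdiff(c("subject_id", "group", NF_PARAMS), names(table))
  if (length(missing_cols)) {
    nf_error("nailfold_schema_error",
             paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  table <- table[order(table$subject_id), , drop = FALSE]
  rownames(table) <- NULL
  groups <- intersect(NF_GROUPS, unique(table$group))
  labels <- as_positive_label(table$group)

  mark <- c("PRP-HC" = "#", "SSc-HC" = "†", "SSc-PRP" = "‡")
  rows <- list()
  rocs <- list()
  anovas <- list()
  for (p in NF_PARAMS) {
    v <- table[[p]]
    m <- tapply(v, table$group, mean)[groups]
    se <- tapply(v, table$group, function(x) sd(x) / sqrt(length(x)))[groups]
    an <- if (length(groups) >= 2) anova_tukey(table, p, alpha) else NULL
    anovas[[p]] <- an
    flags <- if (is.null(an)) "" else paste(mark[an$flags], collapse = "")
    roc <- roc_auc(v, labels)
    rocs[[p]] <- roc
    row <- data.frame(parameter = p, stringsAsFactors = FALSE)
    for (g in groups) {
      row[[paste0("mean_", g)]] <- unname(m[g])
      row[[paste0("se_", g)]] <- unname(se[g])
    }
    row$pairwise <- flags
    row$az <- roc$auc
    row$az_se <- roc$se
    rows[[p]] <- row
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  comb_s <- loocv_roc(table, NF_STRUCTURE_PARAMS, labels = labels)
  comb_f <- loocv_roc(table, NF_PARAMS, labels = labels)
  add_row <- function(tab, name, fit) {
    row <- tab[1, , drop = FALSE]
    row[1, ] <- NA
    row$parameter <- name
    row$pairwise <- ""
    row$az <- fit$combined_roc$auc
    row$az_se <- fit$combined_roc$se
    rbind(tab, row)
  }
  tab <- add_row(tab, "combined_structure", comb_s)
  tab <- add_row(tab, "combined_structure_flow", comb_f)
  rownames(tab) <- NULL

  structure(list(
    table = tab,
    rocs = rocs,
    anova = anovas,
    combined_structure = comb_s,
    combined_full = comb_f,
    n = table(factor(table$group, levels = groups)),
    alpha = alpha
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, digits = 3, ...) {
  cat("Cohort report (", paste(sprintf("%s n=%d", names(x$n), x$n),
                               collapse = ", "), ")\n", sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  cat("structure model terms:",
      paste(x$combined_structure$selected_terms, collapse = ", "), "\n")
  cat("structure+flow model terms:",
      paste(x$combined_full$selected_terms, collapse = ", "), "\n")
  invisible(x)
}
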