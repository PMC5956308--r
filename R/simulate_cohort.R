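# Synthetic participant-level cohorts for validating the statistics chain.
# Group profiles mimic a typical capillaroscopy cohort: healthy controls and
# primary Raynaud's subjects with normal, well-organised capillaries, and
# systemic sclerosis subjects with fewer, wider, more tortuous and more
# deranged capillaries carrying slower flow.

nf_group_profiles <- function() {
  means <- rbind(
    HC  = c(density = 6.73, mean_width = 11.8, max_width = 16.5,
            shape = 0.312, derangement = 0.649, flow = 0.311),
    PRP = c(density = 7.28, mean_width = 12.7, max_width = 21.4,
            shape = 0.325, derangement = 0.689, flow = 0.383),
    SSc = c(density = 5.52, mean_width = 15.0, max_width = 27.4,
            shape = 0.249, derangement = 0.540, flow = 0.235)
  )
  # between-subject SDs (SE x sqrt(n) for cohort sizes 50 / 12 / 50)
  sds <- rbind(
    HC  = c(2.40, 1.63, 6.43, 0.141, 0.212, 0.354),
    PRP = c(1.87, 2.56, 10.18, 0.104, 0.173, 0.346),
    SSc = c(2.97, 5.02, 16.83, 0.071, 0.212, 0.283)
  )
  colnames(sds) <- colnames(means)
  list(means = means, sds = sds)
}

#' Simulate a participant-level cohort table
#'
#' Draws the six per-participant parameters for HC, PRP and SSc groups from
#' correlated multivariate normals whose group means and between-subject SDs
#' follow typical published capillaroscopy cohorts (mean width is strongly
#' correlated with max width, and shape with derangement). `effect_scale`
#' interpolates every group mean between the HC profile (0: a null cohort
#' whose parameters carry no group information) and the nominal profile (1),
#' or exaggerates the separation (> 1). Draws are clipped to their valid
#' ranges (positive widths/density/flow, scores in \[0, 1\]).
#'
#' @param n_hc,n_prp,n_ssc group sizes.
#' @param effect_scale group-difference multiplier (see above).
#' @param seed RNG seed.
#' @return a cohort data.frame as produced by [cohort_table()].
#' @export
simulate_cohort <- function(n_hc = 50, n_prp = 12, n_ssc = 50,
                            effect_scale = 1, seed = 1) {
  prof <- nf_group_profiles()
  p <- length(NF_PARAMS)
  cor_m <- diag(p)
  dimnames(cor_m) <- list(NF_PARAMS, NF_PARAMS)
  cor_m[lower.tri(cor_m)] <- 0.15
  cor_m[upper.tri(cor_m)] <- 0.15
  cor_m["mean_width", "max_width"] <- cor_m["max_width", "mean_width"] <- 0.8
  cor_m["shape", "derangement"] <- cor_m["derangement", "shape"] <- 0.8
  ns <- c(HC = n_hc, PRP = n_prp, SSc = n_ssc)
  with_seed(seed, {
    rows <- lapply(names(ns)[ns > 0], function(gr) {
      mu <- prof$means["HC", ] +
        effect_scale * (prof$means[gr, ] - prof$means["HC", ])
      sig <- diag(prof$sds[gr, ]) %*% cor_m %*% diag(prof$sds[gr, ])
      X <- MASS::mvrnorm(ns[[gr]], mu, sig)
      colnames(X) <- NF_PARAMS
      X[, "density"] <- pmax(X[, "density"], 0.5)
      X[, "mean_width"] <- pmax(X[, "mean_width"], 3)
      X[, "max_width"] <- pmax(X[, "max_width"], X[, "mean_width"])
      X[, "shape"] <- pmin(pmax(X[, "shape"], 0.01), 0.99)
      X[, "derangement"] <- pmin(pmax(X[, "derangement"], 0.01), 0.99)
      X[, "flow"] <- pmax(X[, "flow"], 0.005)
      data.frame(group = gr, X, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(df))), df,
                stringsAsFactors = FALSE)
    rownames(df) <- NULL
    df
  })
}

#' Simulate a null cohort
#'
#' All subjects are drawn from the healthy-control parameter distribution
#' and labels are assigned at random, so the parameters carry no information
#' about the group: the reference case for checking that cross-validated
#' classification is calibrated (combined A_z near 0.5).
#'
#' @param n total subjects (half labelled SSc at random).
#' @param seed RNG seed.
#' @return a cohort data.frame.
#' @export
simulate_null_cohort <- function(n = 100, seed = 1) {
  df <- simulate_cohort(n_hc = n, n_prp = 0, n_ssc = 0, effect_scale = 0,
                        seed = seed)
  with_seed(seed + 1L, {
    ssc <- sample(n, n %/% 2)
    df$group[ssc] <- "SSc"
    df$group[-ssc] <- "HC"
  })
  df
}
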