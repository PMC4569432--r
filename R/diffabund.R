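# Species-level differential abundance: per-cluster Welch's t-test on
# relative abundances, Benjamini-Hochberg correction, log10 case/control
# fold change with the not-detected -> 1-read rule, and longitudinal
# fold-change consistency validation.

#' Welch's t-test
#'
#' Two-sample comparison with unequal variances (Welch-Satterthwaite
#' degrees of freedom, two-sided).  When both groups have zero variance and
#' equal means the statistic is undefined; by convention `t = 0`, `p = 1`,
#' flagged `degenerate`.
#'
#' @param x,y numeric vectors (each length >= 2, finite).
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0,
                degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1,
#' returned in the original order.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Log10 fold change with the not-detected rule
#'
#' Ratio of case to control group-mean relative abundances on the log10
#' scale.  A group in which the cluster was not detected (mean count
#' exactly 0) is assigned 1 read (i.e. `1/depth` relative abundance) before
#' the ratio, which keeps the fold change finite.
#'
#' @param mean_case,mean_control group-mean relative abundances.
#' @param depth fixed per-sample read depth (default 3000).
#' @return log10(case / control), vectorised.
#' @export
log10_fold_change <- function(mean_case, mean_control, depth = 3000L) {
  floor_rel <- 1 / depth
  mc <- ifelse(mean_case == 0, floor_rel, mean_case)
  mh <- ifelse(mean_control == 0, floor_rel, mean_control)
  log10(mc / mh)
}

#' Differential abundance between two groups
#'
#' Welch's t-test per cluster on relative abundances, BH-adjusted q-values,
#' and log10 fold change under the not-detected rule.  The significance
#' flag uses the raw p-value at `alpha`, with q reported alongside.
#'
#' @param tab an `abundance_table` (cross-sectional samples).
#' @param case_group,control_group group labels in the sheet.
#' @param alpha significance level on the raw p-value.
#' @return data.frame `cluster_id`, `kind`, `mean_rel_case`,
#'   `mean_rel_control`, `log10_fc`, `t`, `df`, `p`, `q`, `significant`.
#' @export
diff_abundance <- function(tab, case_group = "MS", control_group = "HC",
                           alpha = 0.05) {
  stopifnot(inherits(tab, "abundance_table"))
  grp <- tab$sheet$group[match(colnames(tab$counts), tab$sheet$sample_id)]
  rel <- relative_abundance(tab)
  xs <- rel[, grp == case_group, drop = FALSE]
  ys <- rel[, grp == control_group, drop = FALSE]
  if (ncol(xs) < 2 || ncol(ys) < 2) stop("each group needs >= 2 samples")
  rows <- lapply(seq_len(nrow(rel)), function(i) {
    wt <- welch_test(xs[i, ], ys[i, ])
    data.frame(cluster_id = rownames(rel)[i], kind = tab$kind[i],
               mean_rel_case = mean(xs[i, ]), mean_rel_control = mean(ys[i, ]),
               log10_fc = log10_fold_change(mean(xs[i, ]), mean(ys[i, ]),
                                            tab$depth),
               t = wt$t, df = wt$df, p = wt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$p < alpha
  out
}

#' Longitudinal fold-change validation
#'
#' For each (typically significant) cluster and each longitudinal
#' timepoint, computes the log10 fold change between the cross-sectional
#' case mean and the longitudinal control mean at that timepoint (subjects
#' averaged; a subject missing a timepoint is omitted from that mean), with
#' the not-detected rule.  Sign consistency is the fraction of timepoints
#' whose fold-change sign matches the cross-sectional one.
#'
#' @param diff result of [diff_abundance()] (supplies case means and the
#'   cross-sectional fold-change sign).
#' @param long_tab `abundance_table` of the longitudinal samples (sheet has
#'   `subject_id`, `timepoint`).
#' @param clusters cluster ids to validate (default: significant ones).
#' @param depth read depth for the not-detected rule.
#' @return list with `per_timepoint` (data.frame `cluster_id`, `timepoint`,
#'   `log10_fc`) and `consistency` (data.frame `cluster_id`,
#'   `cross_sectional_fc`, `sign_consistency`).
#' @export
longitudinal_validation <- function(diff, long_tab, clusters = NULL,
                                    depth = long_tab$depth) {
  stopifnot(inherits(long_tab, "abundance_table"))
  if (is.null(clusters)) clusters <- diff$cluster_id[diff$significant]
  clusters <- intersect(clusters, diff$cluster_id)
  sheet <- long_tab$sheet[match(colnames(long_tab$counts),
                                long_tab$sheet$sample_id), ]
  if (all(is.na(sheet$timepoint))) stop("longitudinal sheet lacks timepoints")
  rel <- relative_abundance(long_tab)
  tps <- sort(unique(sheet$timepoint[!is.na(sheet$timepoint)]))
  case_mean <- stats::setNames(diff$mean_rel_case, diff$cluster_id)
  cross_fc <- stats::setNames(diff$log10_fc, diff$cluster_id)

  per_tp <- list()
  for (cl in clusters) {
    v <- if (cl %in% rownames(rel)) rel[cl, ] else
      stats::setNames(rep(0, ncol(rel)), colnames(rel))
    for (tp in tps) {
      sel <- sheet$timepoint == tp & !is.na(sheet$timepoint)
      # subject mean first, then mean over subjects
      subj <- tapply(v[sel], sheet$subject_id[sel], mean)
      tp_mean <- mean(subj)
      per_tp[[length(per_tp) + 1]] <- data.frame(
        cluster_id = cl, timepoint = tp,
        log10_fc = log10_fold_change(case_mean[[cl]], tp_mean, depth),
        stringsAsFactors = FALSE)
    }
  }
  per_tp <- do.call(rbind, per_tp)
  consistency <- do.call(rbind, lapply(clusters, function(cl) {
    fc <- per_tp$log10_fc[per_tp$cluster_id == cl]
    data.frame(cluster_id = cl, cross_sectional_fc = cross_fc[[cl]],
               sign_consistency = mean(sign(fc) == sign(cross_fc[[cl]])),
               stringsAsFactors = FALSE)
  }))
  list(per_timepoint = per_tp, consistency = consistency)
}
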