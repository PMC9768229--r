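## TPM normalization, fold changes and the negative-binomial Wald screen.

#' Tags-per-million normalization
#'
#' `tpm_i = count_i / sum(counts) * 1e6` per sample; for fixed-length small
#' RNAs no length normalization is applied. Every normalized column sums to
#' one million.
#'
#' @param counts Numeric matrix or data frame, tags x samples.
#' @return Matrix of the same shape.
#' @export
#' @examples
#' compute_tpm(matrix(c(1, 1, 2), ncol = 1))
compute_tpm <- function(counts) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' Group-mean TPM with a zero floor
#'
#' Arithmetic mean of the replicate TPMs; a mean of exactly zero is replaced
#' by `floor` so downstream log2 fold changes are finite.
#'
#' @param tpm Numeric vector (one tag, replicates of one group) or matrix
#'   (tags x replicates).
#' @param floor Replacement for a zero mean.
#' @return Mean TPM (vector when `tpm` is a matrix).
#' @export
#' @examples
#' group_mean_floor(c(0, 0, 0))
#' group_mean_floor(c(100, 200, 300))
group_mean_floor <- function(tpm, floor = 0.01) {
  m <- if (is.matrix(tpm)) rowMeans(tpm) else mean(tpm)
  ifelse(m == 0, floor, m)
}

#' Log2 fold change of floored group means
#'
#' Direction fixed as log2(`mean_b` / `mean_a`): positive values mean higher
#' expression in group B (the second group).
#'
#' @param mean_a,mean_b Positive (post-floor) group-mean TPMs.
#' @return log2(mean_b / mean_a).
#' @export
#' @examples
#' log2_fold_change(164.3288, 375.8126)
#' log2_fold_change(565.937, 0.01)
log2_fold_change <- function(mean_a, mean_b) {
  if (any(mean_a <= 0) || any(mean_b <= 0)) {
    stop("group means must be positive (apply the zero floor first)",
         call. = FALSE)
  }
  log2(mean_b / mean_a)
}

## Median-of-ratios size factors (computed on tags with all-positive counts).
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts == 0) == 0
  if (!any(pos)) {
    ## fall back to library-size factors when no tag is always observed
    sf <- colSums(counts)
    return(sf / exp(mean(log(sf))))
  }
  lg <- log(counts[pos, , drop = FALSE])
  geo <- exp(rowMeans(lg))
  apply(counts[pos, , drop = FALSE], 2, function(cc) median(cc / geo))
}

#' Negative-binomial Wald test for two groups of count replicates
#'
#' Counts are normalized by median-of-ratios size factors; each tag gets a
#' method-of-moments common-scale dispersion estimate (floored at 1e-8)
#' from the pooled within-group variance of normalized counts; the Wald
#' statistic contrasts the log2 group means with a delta-method standard
#' error and is referred to a t distribution with `nA + nB - 2` degrees of
#' freedom (the small-replicate reference that keeps the test calibrated at
#' n = 3 per group).
#'
#' @param counts Integer matrix, tags x samples (rownames = tag ids).
#' @param group Factor/character vector over columns with exactly two
#'   levels; the first level is the reference (denominator) group.
#' @param min_mu Floor on a group mean inside the statistic, in normalized
#'   counts (guards log of zero; the reported p for all-zero groups relies
#'   on it).
#' @return Data frame: `tag_id`, `log2fc_counts` (normalized-count log2
#'   ratio used by the statistic), `dispersion`, `stat`, `p_value`. Tags
#'   with zero counts everywhere are excluded.
#' @export
de_test <- function(counts, group, min_mu = 0.5) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required", call. = FALSE)
  if (min(table(group)) < 2L) {
    stop("at least two replicates per group required", call. = FALSE)
  }
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  sf <- size_factors(counts)
  q <- sweep(counts, 2, sf, "/")
  ia <- which(group == levels(group)[1])
  ib <- which(group == levels(group)[2])
  na <- length(ia); nb <- length(ib)

  ma <- rowMeans(q[, ia, drop = FALSE])
  mb <- rowMeans(q[, ib, drop = FALSE])
  va <- apply(q[, ia, drop = FALSE], 1, var)
  vb <- apply(q[, ib, drop = FALSE], 1, var)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  mu <- (na * ma + nb * mb) / (na + nb)
  ## MoM: Var(q) ~ mu * mean(1/sf) + alpha * mu^2
  alpha <- pmax((s2 - mu * mean(1 / sf)) / mu^2, 1e-8)

  ma_f <- pmax(ma, min_mu)
  mb_f <- pmax(mb, min_mu)
  var_ma <- (ma_f * sum(1 / sf[ia]) / na^2) + alpha * ma_f^2 / na
  var_mb <- (mb_f * sum(1 / sf[ib]) / nb^2) + alpha * mb_f^2 / nb
  se_log2 <- sqrt(var_ma / ma_f^2 + var_mb / mb_f^2) / log(2)
  lfc <- log2(mb_f / ma_f)
  stat <- lfc / se_log2
  p <- 2 * pt(-abs(stat), df = na + nb - 2)

  data.frame(tag_id = rownames(counts) %||% sprintf("t%05d",
                                                    seq_len(nrow(counts))),
             log2fc_counts = lfc, dispersion = alpha, stat = stat,
             p_value = p, stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag significant tags by p-value and fold-change thresholds
#'
#' A tag is significant when `p_value < p_cut` and its absolute fold change
#' exceeds `fc_cut` (`|log2fc| > log2(fc_cut)`). Up-regulated means higher
#' in group B (positive log2fc).
#'
#' @param results Data frame with `log2fc` and `p_value` columns.
#' @param p_cut,fc_cut Screening thresholds.
#' @return `results` with a logical `significant` column and a `direction`
#'   column (`up`, `down`, or `ns`).
#' @export
screen_de <- function(results, p_cut = 0.05, fc_cut = 1.5) {
  sig <- results$p_value < p_cut & abs(results$log2fc) > log2(fc_cut)
  results$significant <- sig
  results$direction <- ifelse(!sig, "ns",
                              ifelse(results$log2fc > 0, "up", "down"))
  results
}

#' TPM-based differential expression screen for two groups
#'
#' The full screen: TPM normalization (per-sample sums of one million),
#' floored group-mean TPMs, log2 fold change of the group means (group B
#' over group A), per-tag negative-binomial Wald p-values computed on the
#' raw counts, and the significance rule `p < p_cut & FC > fc_cut`. The
#' reported fold change comes from the floored TPM means (so worked
#' examples reproduce exactly) while the test statistic uses the counts.
#'
#' @param counts Integer matrix, tags x samples.
#' @param group Two-level grouping over the columns; first level =
#'   reference group A.
#' @param p_cut,fc_cut Screening thresholds.
#' @param floor Zero floor for group-mean TPMs.
#' @param fdr Also append a Benjamini-Hochberg adjusted p column.
#' @return Data frame: `tag_id`, `mean_tpm_a`, `mean_tpm_b`, `log2fc`,
#'   `p_value`, `significant`, `direction` (and `padj` when `fdr = TRUE`).
#' @export
run_diffexp <- function(counts, group, p_cut = 0.05, fc_cut = 1.5,
                        floor = 0.01, fdr = FALSE) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  tpm <- compute_tpm(counts)
  ia <- which(group == levels(group)[1])
  ib <- which(group == levels(group)[2])
  mean_a <- group_mean_floor(tpm[, ia, drop = FALSE], floor)
  mean_b <- group_mean_floor(tpm[, ib, drop = FALSE], floor)
  lfc <- log2_fold_change(mean_a, mean_b)
  tst <- de_test(counts, group)
  out <- data.frame(
    tag_id = rownames(counts) %||% sprintf("t%05d", seq_len(nrow(counts))),
    mean_tpm_a = mean_a, mean_tpm_b = mean_b, log2fc = lfc,
    stringsAsFactors = FALSE, row.names = NULL)
  out$p_value <- tst$p_value[match(out$tag_id, tst$tag_id)]
  out$p_value[is.na(out$p_value)] <- 1      # all-zero tags: no evidence
  out <- screen_de(out, p_cut, fc_cut)
  if (fdr) out$padj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
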