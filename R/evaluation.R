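#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive outranks
#' a random negative, with ties counted 1/2 — equivalent to trapezoidal
#' integration of the ROC curve.
#'
#' @param scores Numeric score vector (higher = more positive).
#' @param labels 0/1 (or logical) class labels, same length.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step interpolation (average precision): walking down the unique score
#' thresholds, each increment in recall contributes that threshold's
#' precision. No linear interpolation between recall points is used, since
#' precision does not interpolate linearly.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in (0, 1].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  if (n1 == 0L) stop("no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

# DeLong structural components: for each positive, the mean of
# psi(pos, neg) over negatives (V10), and symmetrically V01.
delong_components <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' One-sided DeLong test for paired ROC curves
#'
#' Tests whether score vector \code{a} has a larger AUC than \code{b} on the
#' same labelled genes, using DeLong's structural-components estimate of the
#' variance of the paired AUC difference.
#'
#' @param scores_a,scores_b Two score vectors over the same genes.
#' @param labels Shared 0/1 class labels.
#' @return List with \code{auc_a}, \code{auc_b}, \code{z}, and \code{p_value}
#'   for the alternative AUC(a) > AUC(b).
#' @export
delong_one_sided <- function(scores_a, scores_b, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m == 0L || n == 0L) stop("both classes must be present")
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (v <= .Machine$double.eps) {
    # no sampling variability in the paired difference: equal AUCs are
    # uninformative (p = 0.5); a nonzero difference is maximally extreme
    if (d != 0) warning("degenerate DeLong variance with nonzero AUC difference")
    p <- if (d > 0) 0 else if (d < 0) 1 else 0.5
    return(list(auc_a = ca$auc, auc_b = cb$auc,
                z = if (d == 0) 0 else sign(d) * Inf, p_value = p))
  }
  z <- d / sqrt(v)
  list(auc_a = ca$auc, auc_b = cb$auc, z = z,
       p_value = stats::pnorm(z, lower.tail = FALSE))
}

#' Fisher enrichment of a benchmark set in the top-K ranked genes
#'
#' Builds the 2x2 table (top-K vs rest) x (in benchmark vs not) over the
#' evaluated genes — the ranked table with training (seed/background) genes
#' already depleted — and reports the sample odds ratio with a two-sided
#' Fisher exact p-value. When a zero cell occurs, the odds ratio uses the
#' Haldane-Anscombe 0.5 correction and the result is flagged.
#'
#' @param ranked Ranked score table (from [rank_genes()]) or a character
#'   vector of evaluated genes in rank order.
#' @param benchmark Benchmark gene set.
#' @param k Top-K cut.
#' @param alternative Sidedness of the Fisher test (default two-sided).
#' @return List with \code{k}, \code{table} (2x2 counts), \code{odds_ratio},
#'   \code{p_value}, \code{corrected} flag.
#' @export
topk_enrichment <- function(ranked, benchmark, k,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  genes <- if (is.data.frame(ranked)) ranked$gene else as.character(ranked)
  stopifnot(k >= 1, k <= length(genes))
  bench <- intersect(benchmark, genes)
  if (length(bench) == 0L) stop("benchmark set is disjoint from the evaluated genes")
  top <- genes[seq_len(k)]
  rest <- genes[-seq_len(k)]
  a <- sum(top %in% bench); b <- k - a
  cc <- sum(rest %in% bench); d <- length(rest) - cc
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("topK", "rest"), c("bench", "other")))
  corrected <- any(tab == 0)
  if (corrected) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    or <- (a * d) / (b * cc)
  }
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  list(k = k, table = tab, odds_ratio = or, p_value = p,
       corrected = corrected)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; input order is preserved.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Benchmark one or more score vectors against a gold-standard gene set
#'
#' Labels the evaluated (training-depleted) genes by benchmark membership
#' and reports ROC-AUC, PR-AUC and top-K Fisher enrichment for each score
#' column, with BH adjustment across the enrichment tests.
#'
#' @param ranked Ranked candidate table from [rank_genes()], or a data.frame
#'   with a \code{gene} column and one or more score columns.
#' @param benchmark Benchmark gene set.
#' @param score_cols Score columns to evaluate (default
#'   \code{"log10_posterior_odds"}).
#' @param topk Vector of K values for enrichment (default c(100, 1000),
#'   trimmed to the table size).
#' @return List with \code{labels}, \code{auc} (data.frame per score column)
#'   and \code{enrichment} (data.frame per score column x K with BH-adjusted
#'   p-values).
#' @export
evaluate_scores <- function(ranked, benchmark,
                            score_cols = "log10_posterior_odds",
                            topk = c(100L, 1000L)) {
  genes <- ranked$gene
  labels <- as.integer(genes %in% benchmark)
  if (sum(labels) == 0L || sum(labels) == length(labels)) {
    stop("benchmark labelling is single-class on the evaluated genes")
  }
  topk <- topk[topk <= length(genes)]
  auc <- do.call(rbind, lapply(score_cols, function(sc) {
    s <- ranked[[sc]]
    s[!is.finite(s)] <- min(s[is.finite(s)]) - 1
    data.frame(score = sc, roc_auc = roc_auc(s, labels),
               pr_auc = pr_auc(s, labels))
  }))
  enr <- do.call(rbind, lapply(score_cols, function(sc) {
    ord <- order(-ranked[[sc]], ranked$gene, method = "radix")
    g <- genes[ord]
    do.call(rbind, lapply(topk, function(k) {
      e <- topk_enrichment(g, benchmark, k)
      data.frame(score = sc, k = k, odds_ratio = e$odds_ratio,
                 p_value = e$p_value, corrected = e$corrected)
    }))
  }))
  if (!is.null(enr) && nrow(enr)) enr$bh_adjusted_p <- bh_adjust(enr$p_value)
  list(labels = stats::setNames(labels, genes), auc = auc, enrichment = enr)
}
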