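#' Pre-select binary annotations enriched in seed genes
#'
#' For each binary annotation, builds the 2x2 table of seed/background
#' membership against presence/absence (missing cells excluded) and runs a
#' one-sided Fisher's exact test for enrichment in the seed group. An
#' annotation is selected when p < \code{alpha_level}. No multiplicity
#' correction is applied at this screening step.
#'
#' @param B Binary annotation matrix (genes x annotations, values 0/1/NA).
#' @param seeds,background Gene sets defining the two groups.
#' @param alpha_level Selection threshold on the p-value (default 0.05).
#' @return data.frame with columns annotation, kind, statistic (seed odds
#'   ratio estimate), p_value, selected, flagged.
#' @export
select_binary_annotations <- function(B, seeds, background,
                                      alpha_level = 0.05) {
  stopifnot(is.matrix(B), !is.null(rownames(B)))
  sg <- intersect(seeds, rownames(B))
  bg <- intersect(background, rownames(B))
  out <- lapply(colnames(B), function(a) {
    vs <- B[sg, a]; vb <- B[bg, a]
    vs <- vs[!is.na(vs)]; vb <- vb[!is.na(vb)]
    if (length(vs) == 0L || length(vb) == 0L) {
      return(data.frame(annotation = a, kind = "binary", statistic = NA_real_,
                        p_value = NA_real_, selected = FALSE, flagged = TRUE))
    }
    tab <- matrix(c(sum(vs == 1), sum(vs == 0),
                    sum(vb == 1), sum(vb == 0)), nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tab, alternative = "greater")
    data.frame(annotation = a, kind = "binary",
               statistic = unname(ft$estimate), p_value = ft$p.value,
               selected = ft$p.value < alpha_level, flagged = FALSE)
  })
  do.call(rbind, out)
}

#' Pre-select continuous annotations differing between seed and background
#'
#' Two-sided Welch t-test per annotation; selected when p < \code{alpha_level}.
#' Annotations that are constant in both groups get p = 1 (equal means) or
#' p = 0 (different means) and are flagged.
#'
#' @inheritParams select_binary_annotations
#' @param C Continuous annotation matrix (genes x annotations).
#' @return data.frame with columns annotation, kind, statistic (t), p_value,
#'   selected, flagged.
#' @export
select_continuous_annotations <- function(C, seeds, background,
                                          alpha_level = 0.05) {
  stopifnot(is.matrix(C), !is.null(rownames(C)))
  sg <- intersect(seeds, rownames(C))
  bg <- intersect(background, rownames(C))
  out <- lapply(colnames(C), function(a) {
    vs <- C[sg, a]; vb <- C[bg, a]
    vs <- vs[!is.na(vs)]; vb <- vb[!is.na(vb)]
    if (length(vs) < 2L || length(vb) < 2L) {
      return(data.frame(annotation = a, kind = "continuous",
                        statistic = NA_real_, p_value = NA_real_,
                        selected = FALSE, flagged = TRUE))
    }
    res <- tryCatch(stats::t.test(vs, vb), error = function(e) NULL)
    if (is.null(res)) {  # essentially constant data
      p <- if (isTRUE(all.equal(mean(vs), mean(vb)))) 1 else 0
      return(data.frame(annotation = a, kind = "continuous",
                        statistic = 0, p_value = p,
                        selected = p < alpha_level, flagged = TRUE))
    }
    data.frame(annotation = a, kind = "continuous",
               statistic = unname(res$statistic), p_value = res$p.value,
               selected = res$p.value < alpha_level, flagged = FALSE)
  })
  do.call(rbind, out)
}

#' Fit Beta hyperparameters for a binary annotation
#'
#' Empirical-Bayes fit of the Beta prior on the Bernoulli rate from the
#' annotation's counts in a gene group: with \eqn{k} of \eqn{n} genes
#' carrying the annotation, \eqn{\tilde\alpha = k + 1},
#' \eqn{\tilde\beta = n - k + 1} (the conjugate update of a uniform prior).
#' The implied single-gene marginal \eqn{(k+1)/(n+2)} tracks the group
#' frequency while never reaching 0 or 1, so degenerate groups remain usable.
#'
#' @param B Binary annotation matrix, or \code{NULL} if \code{k}/\code{n}
#'   are given directly.
#' @param annotation Annotation (column) name.
#' @param group Gene set the model is fitted from (seeds for M1, background
#'   for M0).
#' @param model Model label, 1 (risk) or 0 (non-risk); stored for bookkeeping.
#' @param k,n Optional direct counts, bypassing the matrix lookup.
#' @return A \code{beta_hyperparams}: list(annotation, model, alpha, beta,
#'   n_fit, k_fit).
#' @export
fit_beta_hyperparams <- function(B = NULL, annotation = NULL, group = NULL,
                                 model = 1L, k = NULL, n = NULL) {
  if (is.null(k) || is.null(n)) {
    v <- B[intersect(group, rownames(B)), annotation]
    v <- v[!is.na(v)]
    n <- length(v)
    k <- sum(v == 1)
  }
  stopifnot(n >= 1, k >= 0, k <= n)
  structure(list(annotation = annotation, model = model,
                 alpha = k + 1, beta = n - k + 1,
                 n_fit = as.integer(n), k_fit = as.integer(k)),
            class = "beta_hyperparams")
}

#' Beta-Bernoulli marginal likelihood
#'
#' Marginal probability of observing \eqn{k} successes in \eqn{n} Bernoulli
#' draws with the rate integrated out against a Beta(\eqn{\alpha,\beta})
#' prior: \eqn{B(\alpha + k, n - k + \beta) / B(\alpha, \beta)} (no binomial
#' coefficient: the draws are a fixed labelled sequence). Computed via
#' log-gamma for numerical stability.
#'
#' @param k Number of successes, \eqn{0 \le k \le n}.
#' @param n Number of draws.
#' @param hp A \code{beta_hyperparams}, or a list with \code{alpha}/\code{beta}.
#' @param log If TRUE return the log marginal.
#' @return Marginal likelihood in (0, 1] (or its log).
#' @export
binary_marginal <- function(k, n, hp, log = FALSE) {
  a <- hp$alpha; b <- hp$beta
  if (a <= 0 || b <= 0) stop("alpha and beta must be positive")
  stopifnot(k >= 0, k <= n, n >= 0)
  lm <- lbeta(a + k, n - k + b) - lbeta(a, b)
  if (log) lm else exp(lm)
}

#' Bayes factor of a single binary annotation value
#'
#' Ratio of the single-draw Beta-Bernoulli marginals of the observed value
#' under the risk (M1) and non-risk (M0) hyperparameters. A missing value is
#' evidence-neutral: BF = 1.
#'
#' @param d Observed value 0, 1, or NA.
#' @param hp1,hp0 \code{beta_hyperparams} fitted under M1 and M0.
#' @return List with \code{bf}, \code{log_bf} (natural log), and
#'   \code{missing} flag.
#' @export
binary_bf <- function(d, hp1, hp0) {
  if (is.na(d)) return(list(bf = 1, log_bf = 0, missing = TRUE))
  stopifnot(d %in% c(0, 1))
  lb <- binary_marginal(d, 1L, hp1, log = TRUE) -
        binary_marginal(d, 1L, hp0, log = TRUE)
  list(bf = exp(lb), log_bf = lb, missing = FALSE)
}

#' Fit Normal-Inverse-Gamma hyperparameters for a continuous annotation
#'
#' Moment-matching empirical-Bayes fit from a gene group with sample mean
#' \eqn{\bar{x}} and variance \eqn{v}: \eqn{\tilde\mu_0 = \bar{x}},
#' \eqn{\tilde\kappa = n}, \eqn{\tilde\nu = n - 1}, and
#' \eqn{\tilde\sigma^2 = v\,(\tilde\nu - 2)/\tilde\nu \cdot
#' \tilde\kappa/(1 + \tilde\kappa)}, chosen so the implied marginal
#' (a non-standardized t, see [continuous_bf()]) has mean \eqn{\bar{x}} and
#' variance exactly \eqn{v}. Requires \eqn{n \ge 4} (so \eqn{\nu > 2} and the
#' marginal variance exists) and \eqn{v > 0}.
#'
#' @inheritParams fit_beta_hyperparams
#' @param C Continuous annotation matrix, or \code{NULL} if \code{values}
#'   are given directly.
#' @param values Optional numeric vector bypassing the matrix lookup.
#' @return A \code{nig_hyperparams}: list(annotation, model, mu0, kappa, nu,
#'   sigma2, n_fit).
#' @export
fit_nig_hyperparams <- function(C = NULL, annotation = NULL, group = NULL,
                                model = 1L, values = NULL) {
  if (is.null(values)) {
    values <- C[intersect(group, rownames(C)), annotation]
  }
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 4L) stop("need >= 4 non-missing values to fit NIG hyperparameters")
  v <- stats::var(values)
  if (v <= 0) stop("zero sample variance; NIG moment matching undefined")
  nu <- n - 1
  kappa <- n
  sigma2 <- v * (nu - 2) / nu * kappa / (1 + kappa)
  structure(list(annotation = annotation, model = model,
                 mu0 = mean(values), kappa = kappa, nu = nu, sigma2 = sigma2,
                 n_fit = as.integer(n)),
            class = "nig_hyperparams")
}

#' Non-standardized t density
#'
#' Density of \eqn{t_\nu(\mu, s^2)}: a Student t with \eqn{\nu} degrees of
#' freedom, location \eqn{\mu} and squared scale \eqn{s^2}.
#'
#' @param x Evaluation points.
#' @param nu Degrees of freedom.
#' @param mu Location.
#' @param s2 Squared scale.
#' @param log If TRUE return the log density.
#' @return Density values.
#' @export
dt_ns <- function(x, nu, mu, s2, log = FALSE) {
  stopifnot(nu > 0, s2 > 0)
  s <- sqrt(s2)
  ld <- stats::dt((x - mu) / s, df = nu, log = TRUE) - base::log(s)
  if (log) ld else exp(ld)
}

#' Bayes factor of a single continuous annotation value
#'
#' Under the Normal-Inverse-Gamma prior the marginal of one observation is a
#' non-standardized t, \eqn{t_\nu(\mu_0, \sigma^2 (1+\kappa)/\kappa)}. The
#' Bayes factor is the ratio of these densities under the M1 and M0
#' hyperparameters, computed in log space. A missing value gives BF = 1.
#'
#' @param d Observed value (numeric or NA).
#' @param hp1,hp0 \code{nig_hyperparams} fitted under M1 and M0.
#' @return List with \code{bf}, \code{log_bf} (natural log), \code{missing}.
#' @export
continuous_bf <- function(d, hp1, hp0) {
  if (is.na(d)) return(list(bf = 1, log_bf = 0, missing = TRUE))
  stopifnot(is.finite(d))
  l1 <- dt_ns(d, hp1$nu, hp1$mu0, hp1$sigma2 * (1 + hp1$kappa) / hp1$kappa,
              log = TRUE)
  l0 <- dt_ns(d, hp0$nu, hp0$mu0, hp0$sigma2 * (1 + hp0$kappa) / hp0$kappa,
              log = TRUE)
  list(bf = exp(l1 - l0), log_bf = l1 - l0, missing = FALSE)
}

#' Fit both models' hyperparameters for the selected annotations
#'
#' Convenience wrapper: for every selected annotation, fits M1 hyperparameters
#' from the seed genes and M0 from the background genes.
#'
#' @param B,C Binary and continuous annotation matrices (either may be NULL).
#' @param selection data.frame from the two \code{select_*_annotations}
#'   functions (rows with \code{selected == TRUE} are used).
#' @param seeds,background Fitting groups for M1 and M0.
#' @return List with elements \code{binary} and \code{continuous}, each a
#'   named list of \code{list(hp1, hp0)} per annotation.
#' @export
fit_annotation_models <- function(B = NULL, C = NULL, selection, seeds,
                                  background) {
  sel <- selection[selection$selected, , drop = FALSE]
  models <- list(binary = list(), continuous = list())
  for (i in seq_len(nrow(sel))) {
    a <- sel$annotation[i]
    if (sel$kind[i] == "binary") {
      models$binary[[a]] <- list(
        hp1 = fit_beta_hyperparams(B, a, seeds, model = 1L),
        hp0 = fit_beta_hyperparams(B, a, background, model = 0L))
    } else {
      models$continuous[[a]] <- list(
        hp1 = fit_nig_hyperparams(C, a, seeds, model = 1L),
        hp0 = fit_nig_hyperparams(C, a, background, model = 0L))
    }
  }
  models
}

#' Per-gene total Bayes factor over selected annotations
#'
#' Annotations are assumed independent under both models, so the gene-level
#' Bayes factor is the product over annotations — accumulated in log space.
#' Missing annotation values contribute log BF = 0 (evidence-neutral), which
#' keeps the score defined genome-wide.
#'
#' @param genes Character vector of genes to score.
#' @param B,C Binary and continuous annotation matrices (either may be NULL;
#'   genes absent from a matrix count as missing).
#' @param models Fitted hyperparameter sets from [fit_annotation_models()].
#' @return Matrix of natural-log Bayes factors, genes x (annotations +
#'   \code{".total"} column).
#' @export
gene_bayes_factor <- function(genes, B = NULL, C = NULL, models) {
  anns <- c(names(models$binary), names(models$continuous))
  out <- matrix(0, nrow = length(genes), ncol = length(anns) + 1L,
                dimnames = list(genes, c(anns, ".total")))
  for (a in names(models$binary)) {
    hp1 <- models$binary[[a]]$hp1; hp0 <- models$binary[[a]]$hp0
    d <- rep(NA_real_, length(genes))
    if (!is.null(B) && a %in% colnames(B)) {
      hit <- match(genes, rownames(B))
      d[!is.na(hit)] <- B[hit[!is.na(hit)], a]
    }
    # vectorized single-draw log BF: value-dependent constant
    l1 <- ifelse(d == 1,
                 base::log(hp1$alpha / (hp1$alpha + hp1$beta)),
                 base::log(hp1$beta / (hp1$alpha + hp1$beta)))
    l0 <- ifelse(d == 1,
                 base::log(hp0$alpha / (hp0$alpha + hp0$beta)),
                 base::log(hp0$beta / (hp0$alpha + hp0$beta)))
    lb <- ifelse(is.na(d), 0, l1 - l0)
    out[, a] <- lb
  }
  for (a in names(models$continuous)) {
    hp1 <- models$continuous[[a]]$hp1; hp0 <- models$continuous[[a]]$hp0
    d <- rep(NA_real_, length(genes))
    if (!is.null(C) && a %in% colnames(C)) {
      hit <- match(genes, rownames(C))
      d[!is.na(hit)] <- C[hit[!is.na(hit)], a]
    }
    ok <- !is.na(d)
    lb <- numeric(length(genes))
    if (any(ok)) {
      s21 <- hp1$sigma2 * (1 + hp1$kappa) / hp1$kappa
      s20 <- hp0$sigma2 * (1 + hp0$kappa) / hp0$kappa
      lb[ok] <- dt_ns(d[ok], hp1$nu, hp1$mu0, s21, log = TRUE) -
                dt_ns(d[ok], hp0$nu, hp0$mu0, s20, log = TRUE)
    }
    out[, a] <- lb
  }
  out[, ".total"] <- if (length(anns)) rowSums(out[, anns, drop = FALSE]) else 0
  out
}
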