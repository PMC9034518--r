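#' Fold-change ranks of genes for a target condition
#'
#' For the target condition and every other condition \eqn{k}, computes each
#' gene's fold change \eqn{(E_{target,g} + pc) / (E_{k,g} + pc)} and ranks it
#' across genes, rank 1 for the largest fold change (most target-enriched),
#' ties averaged. The pseudocount \eqn{pc} guards against division by zero
#' in sparse expression data.
#'
#' @param E Expression matrix, genes x conditions, nonnegative.
#' @param target Target condition (column name or index).
#' @param pseudocount Added to numerator and denominator (default 1e-8).
#' @return Matrix of ranks, genes x other conditions.
#' @export
fold_change_ranks <- function(E, target, pseudocount = 1e-8) {
  stopifnot(is.matrix(E), ncol(E) >= 2L, all(E >= 0))
  if (is.character(target)) target <- match(target, colnames(E))
  stopifnot(!is.na(target), target >= 1, target <= ncol(E))
  others <- setdiff(seq_len(ncol(E)), target)
  num <- E[, target] + pseudocount
  r <- vapply(others, function(k) {
    fc <- num / (E[, k] + pseudocount)
    rank(-fc, ties.method = "average")
  }, numeric(nrow(E)))
  dimnames(r) <- list(rownames(E), colnames(E)[others])
  r
}

#' Specificity index (SI)
#'
#' A gene's SI for the target condition is its average fold-change rank over
#' the other \eqn{m - 1} conditions,
#' \eqn{SI_g = \sum_{k \ne target} R_{k,g} / (m - 1)}. SI ranges from 1
#' (top-ranked in every comparison: fully condition-specific) to the number
#' of genes; lower is more specific.
#'
#' @inheritParams fold_change_ranks
#' @return Named numeric vector of SI per gene.
#' @export
specificity_index <- function(E, target, pseudocount = 1e-8) {
  r <- fold_change_ranks(E, target, pseudocount)
  rowMeans(r)
}

#' Permutation p-value of the specificity index (pSI)
#'
#' Raw SI values are not comparable across conditions, so each gene's SI is
#' referred to a permutation null: in each of \code{n_perm} rounds every
#' gene's expression vector is shuffled across conditions independently
#' (preserving each gene's magnitude distribution) and SI is recomputed.
#' \deqn{pSI(g) = (1 + \#\{SI^{null}_g \le SI^{obs}_g\}) / (n_{perm} + 1)}
#' so the smallest attainable value is \eqn{1/(n_{perm}+1)}. Smaller pSI =
#' more condition-specific. With \code{scheme = "within_condition"} the
#' shuffle instead permutes genes within each condition column.
#'
#' @inheritParams fold_change_ranks
#' @param n_perm Number of permutation rounds (default 1000).
#' @param rng_seed Integer seed for reproducibility.
#' @param scheme Permutation unit: \code{"within_gene"} (default) shuffles
#'   each gene's values across conditions; \code{"within_condition"}
#'   shuffles each condition across genes.
#' @return Named vector of pSI per gene, in (0, 1].
#' @export
psi <- function(E, target, n_perm = 1000L, rng_seed = NULL,
                pseudocount = 1e-8,
                scheme = c("within_gene", "within_condition")) {
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 1)
  obs <- specificity_index(E, target, pseudocount)
  if (!is.null(rng_seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(rng_seed)
  }
  G <- nrow(E); m <- ncol(E)
  hits <- numeric(G)
  for (b in seq_len(n_perm)) {
    if (scheme == "within_gene") {
      Eb <- t(apply(E, 1L, sample, size = m))
    } else {
      Eb <- apply(E, 2L, sample, size = G)
    }
    dimnames(Eb) <- dimnames(E)
    null_si <- specificity_index(Eb, target, pseudocount)
    hits <- hits + (null_si <= obs)
  }
  stats::setNames((1 + hits) / (n_perm + 1), rownames(E))
}

#' Condition-specific gene list from pSI values
#'
#' @param psi_values Named vector of pSI per gene (see [psi()]), or a matrix
#'   with conditions in columns.
#' @param threshold Genes with pSI strictly below this are kept
#'   (default 0.05).
#' @return For a vector, a \code{gene_set}; for a matrix, a named list of
#'   \code{gene_set}s per condition.
#' @export
specific_gene_list <- function(psi_values, threshold = 0.05) {
  if (is.matrix(psi_values)) {
    out <- lapply(colnames(psi_values), function(cond) {
      gene_set(rownames(psi_values)[psi_values[, cond] < threshold],
               name = cond, role = "benchmark")
    })
    names(out) <- colnames(psi_values)
    return(out)
  }
  gene_set(names(psi_values)[psi_values < threshold], name = "specific",
           role = "benchmark")
}

#' Average replicate columns of an expression matrix
#'
#' Collapses replicate columns of the same condition to their mean before
#' specificity analysis (e.g. averaging RPKM across tissue replicates).
#'
#' @param E Expression matrix, genes x samples.
#' @param conditions Condition label per column of \code{E}.
#' @return Matrix genes x unique conditions (first-seen order).
#' @export
average_replicates <- function(E, conditions) {
  stopifnot(length(conditions) == ncol(E))
  conds <- unique(conditions)
  out <- vapply(conds, function(cc) {
    rowMeans(E[, conditions == cc, drop = FALSE])
  }, numeric(nrow(E)))
  dimnames(out) <- list(rownames(E), conds)
  out
}
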