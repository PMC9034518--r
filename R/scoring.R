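#' Combine prior odds and Bayes factors into posterior odds
#'
#' Posterior odds = prior odds x total Bayes factor, accumulated in log10
#' space. Genes with zero prior get posterior 0 (log10 = -Inf) regardless of
#' their Bayes factor. Both inputs must cover exactly the same genes.
#'
#' @param prior Named vector of prior odds per gene.
#' @param log_bf_total Named vector of total natural-log Bayes factors.
#' @param roles Optional named character vector of role flags per gene
#'   (\code{"candidate"}, \code{"seed"}, \code{"background"}).
#' @return data.frame (one row per gene): gene, role, prior_odds,
#'   log10_bf_total, log10_posterior_odds, posterior_odds.
#' @export
posterior_odds <- function(prior, log_bf_total, roles = NULL) {
  asym <- c(setdiff(names(prior), names(log_bf_total)),
            setdiff(names(log_bf_total), names(prior)))
  if (length(asym)) {
    stop("genes present in only one input: ",
         paste(utils::head(asym, 10), collapse = ", "))
  }
  genes <- names(prior)
  lbf10 <- log_bf_total[genes] / base::log(10)
  lprior10 <- ifelse(prior > 0, log10(prior), -Inf)
  lpost10 <- lprior10 + lbf10
  if (is.null(roles)) roles <- stats::setNames(rep("candidate", length(genes)),
                                               genes)
  data.frame(gene = genes,
             role = unname(roles[genes]),
             prior_odds = unname(prior),
             log10_bf_total = unname(lbf10),
             log10_posterior_odds = unname(lpost10),
             posterior_odds = unname(10^lpost10),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank a gene score table by posterior odds
#'
#' Sorts descending by posterior odds with ties broken lexicographically by
#' gene identifier so the ranking is deterministic. Seed and background
#' (training) genes are excluded from the candidate ranking unless
#' \code{include_training = TRUE}.
#'
#' @param table Score table from [posterior_odds()].
#' @param include_training Keep seed/background genes in the ranking?
#' @return The filtered table, sorted, with a \code{rank} column (1 = best).
#' @export
rank_genes <- function(table, include_training = FALSE) {
  if (!include_training) {
    table <- table[table$role == "candidate", , drop = FALSE]
  }
  ord <- order(-table$log10_posterior_odds, table$gene, method = "radix")
  table <- table[ord, , drop = FALSE]
  table$rank <- seq_len(nrow(table))
  rownames(table) <- NULL
  table
}

#' Fit the full Bayesian network-and-annotation gene prioritization model
#'
#' End-to-end fit: (1) computes each gene's network prior odds from its
#' average random-walk-with-restart reaching probability to the seed genes;
#' (2) screens binary annotations by one-sided Fisher enrichment and
#' continuous annotations by Welch t-test between seeds and background;
#' (3) fits conjugate hyperparameters for each selected annotation under the
#' risk model (from seeds) and the non-risk model (from background) and
#' turns each gene's annotation values into Bayes factors; (4) multiplies
#' prior odds by the product of Bayes factors into posterior odds and ranks
#' the candidate genes.
#'
#' @param universe Ordered gene namespace (see [gene_universe()]).
#' @param seeds Seed (known risk) gene set.
#' @param background Background gene set for the null model; if NULL, drawn
#'   by [sample_background()] with \code{n_background} and \code{rng_seed}.
#' @param binary,continuous Annotation matrices (genes x annotations; either
#'   may be NULL).
#' @param network A \code{gene_network} (or NULL to use a flat prior equal
#'   to the constant ratio for every gene).
#' @param restart RWR restart probability (default 0.5).
#' @param n_risk,n_total Assumed genome-wide risk/total gene counts for the
#'   prior constant (defaults 1000/18000).
#' @param prior_mode \code{"literal"} or \code{"mean_normalized"}; see
#'   [prior_odds()].
#' @param alpha_level Annotation screening threshold (default 0.05).
#' @param n_background Background size when sampling (default 500).
#' @param rng_seed Seed for background sampling.
#' @param missing_prior Prior odds assigned to genes absent from the network
#'   (default 0, the literal reading; set e.g. a percentile value to avoid
#'   annihilating annotation evidence).
#' @return An object of class \code{bnscore}: list with \code{scores} (full
#'   per-gene table), \code{ranked} (candidate ranking), \code{selection},
#'   \code{models}, \code{p_ns}, \code{seeds}, \code{background}, and
#'   \code{call}.
#' @examples
#' sim <- simulate_universe(simulation_config(n_genes = 300, n_risk = 30,
#'                                            n_seeds_observed = 15,
#'                                            rng_seed = 1))
#' fit <- bnscore(sim$universe, sim$seeds, binary = sim$binary,
#'                continuous = sim$continuous, network = sim$network,
#'                rng_seed = 1, n_background = 100)
#' head(fit$ranked)
#' @export
bnscore <- function(universe, seeds, background = NULL, binary = NULL,
                    continuous = NULL, network = NULL, restart = 0.5,
                    n_risk = 1000, n_total = 18000,
                    prior_mode = c("literal", "mean_normalized"),
                    alpha_level = 0.05, n_background = 500L, rng_seed = NULL,
                    missing_prior = 0) {
  prior_mode <- match.arg(prior_mode)
  cl <- match.call()
  universe <- gene_universe(universe)
  seeds <- intersect(as.character(seeds), universe)
  if (length(seeds) == 0L) stop("no seed gene is in the universe")
  if (is.null(background)) {
    background <- sample_background(universe, seeds, n = n_background,
                                    rng_seed = rng_seed)
  }
  background <- setdiff(intersect(as.character(background), universe), seeds)
  if (length(background) == 0L) stop("background set is empty")

  # (1) network prior
  if (!is.null(network)) {
    tm <- to_transition_matrix(network, universe = universe)
    p_ns_net <- avg_reach_to_seeds(tm, seeds, restart = restart)
    p_ns <- stats::setNames(rep(NA_real_, length(universe)), universe)
    p_ns[names(p_ns_net)] <- p_ns_net
    scored <- !is.na(p_ns)
    pri <- stats::setNames(rep(missing_prior, length(universe)), universe)
    pri[scored] <- prior_odds(p_ns[scored], n_risk = n_risk,
                              n_total = n_total, mode = prior_mode)
  } else {
    p_ns <- stats::setNames(rep(NA_real_, length(universe)), universe)
    pri <- stats::setNames(rep(n_risk / (n_total - n_risk), length(universe)),
                           universe)
  }

  # (2) annotation screening
  selection <- rbind(
    if (!is.null(binary))
      select_binary_annotations(binary, seeds, background, alpha_level),
    if (!is.null(continuous))
      select_continuous_annotations(continuous, seeds, background, alpha_level)
  )
  if (is.null(selection)) {
    selection <- data.frame(annotation = character(0), kind = character(0),
                            statistic = numeric(0), p_value = numeric(0),
                            selected = logical(0), flagged = logical(0))
  }

  # (3) empirical-Bayes fits and per-gene Bayes factors
  models <- fit_annotation_models(binary, continuous, selection,
                                  seeds, background)
  log_bf <- gene_bayes_factor(universe, binary, continuous, models)

  # (4) posterior odds and ranking
  roles <- stats::setNames(rep("candidate", length(universe)), universe)
  roles[seeds] <- "seed"
  roles[background] <- "background"
  scores <- posterior_odds(pri, log_bf[, ".total"], roles = roles)
  per_ann <- log_bf[, setdiff(colnames(log_bf), ".total"), drop = FALSE] /
    base::log(10)
  structure(list(scores = scores, ranked = rank_genes(scores),
                 log10_bf = per_ann, selection = selection, models = models,
                 p_ns = p_ns, seeds = seeds, background = background,
                 restart = restart, n_risk = n_risk, n_total = n_total,
                 prior_mode = prior_mode, call = cl),
            class = "bnscore")
}

#' @export
print.bnscore <- function(x, ...) {
  cat("Bayesian gene prioritization fit\n")
  cat(sprintf("  universe: %d genes (%d seeds, %d background, %d candidates)\n",
              nrow(x$scores), length(x$seeds), length(x$background),
              nrow(x$ranked)))
  nsel <- sum(x$selection$selected)
  cat(sprintf("  annotations: %d screened, %d selected (%d binary, %d continuous)\n",
              nrow(x$selection), nsel,
              length(x$models$binary), length(x$models$continuous)))
  cat(sprintf("  prior: %s mode, constant %d/%d, restart r = %.2f\n",
              x$prior_mode, x$n_risk, x$n_total - x$n_risk, x$restart))
  cat("  top candidates:\n")
  print(utils::head(x$ranked[, c("gene", "log10_posterior_odds", "rank")], 5L),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.bnscore <- function(object, ...) {
  r <- object$ranked
  sel <- object$selection
  out <- list(
    n_candidates = nrow(r),
    n_selected = sum(sel$selected),
    selection = sel,
    score_quartiles = stats::quantile(
      r$log10_posterior_odds[is.finite(r$log10_posterior_odds)],
      c(0, .25, .5, .75, 1)),
    top = utils::head(r, 10L))
  class(out) <- "summary.bnscore"
  out
}

#' @export
print.summary.bnscore <- function(x, ...) {
  cat(sprintf("%d candidate genes ranked; %d annotations selected\n",
              x$n_candidates, x$n_selected))
  cat("log10 posterior odds quartiles (finite scores):\n")
  print(round(x$score_quartiles, 3))
  cat("top 10 candidates:\n")
  print(x$top[, c("gene", "prior_odds", "log10_bf_total",
                  "log10_posterior_odds", "rank")], row.names = FALSE)
  invisible(x)
}

#' Fitted hyperparameters of a prioritization model
#'
#' @param object A \code{bnscore} fit.
#' @param ... Unused.
#' @return data.frame of per-annotation hyperparameters under both models
#'   (Beta alpha/beta for binary, NIG mu0/kappa/nu/sigma2 for continuous).
#' @export
coef.bnscore <- function(object, ...) {
  rows <- list()
  for (a in names(object$models$binary)) {
    for (m in c("hp1", "hp0")) {
      h <- object$models$binary[[a]][[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        annotation = a, kind = "binary", model = h$model,
        alpha = h$alpha, beta = h$beta, mu0 = NA_real_, kappa = NA_real_,
        nu = NA_real_, sigma2 = NA_real_)
    }
  }
  for (a in names(object$models$continuous)) {
    for (m in c("hp1", "hp0")) {
      h <- object$models$continuous[[a]][[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        annotation = a, kind = "continuous", model = h$model,
        alpha = NA_real_, beta = NA_real_, mu0 = h$mu0, kappa = h$kappa,
        nu = h$nu, sigma2 = h$sigma2)
    }
  }
  if (length(rows) == 0L) return(data.frame())
  do.call(rbind, rows)
}

#' Score new genes with a fitted prioritization model
#'
#' Applies the fitted annotation models (and, when the gene was part of the
#' original network solve, its network prior) to annotation values supplied
#' for new or existing genes. Genes without a network reach get the
#' flat-missing prior used at fit time.
#'
#' @param object A \code{bnscore} fit.
#' @param binary,continuous Annotation matrices covering the genes to score.
#' @param genes Genes to score (default: union of the matrices' rownames).
#' @param ... Unused.
#' @return Score table as in [posterior_odds()].
#' @export
predict.bnscore <- function(object, binary = NULL, continuous = NULL,
                            genes = NULL, ...) {
  if (is.null(genes)) {
    genes <- unique(c(rownames(binary), rownames(continuous)))
  }
  if (length(genes) == 0L) stop("no genes to score")
  lbf <- gene_bayes_factor(genes, binary, continuous, object$models)
  pri <- stats::setNames(rep(0, length(genes)), genes)
  pri[genes %in% object$scores$gene] <-
    object$scores$prior_odds[match(genes[genes %in% object$scores$gene],
                                   object$scores$gene)]
  posterior_odds(pri, lbf[, ".total"])
}

#' Plot the score distribution of a prioritization fit
#'
#' Histogram of finite log10 posterior odds over candidate genes, with the
#' top-ranked genes marked in the rug.
#'
#' @param x A \code{bnscore} fit.
#' @param top Number of top genes to mark (default 20).
#' @param ... Passed to [graphics::hist()].
#' @export
plot.bnscore <- function(x, top = 20L, ...) {
  s <- x$ranked$log10_posterior_odds
  s <- s[is.finite(s)]
  graphics::hist(s, breaks = 40, col = "grey85", border = "white",
                 main = "Candidate gene scores",
                 xlab = "log10 posterior odds", ...)
  graphics::rug(utils::head(x$ranked$log10_posterior_odds, top),
                col = "firebrick", lwd = 1.5)
  invisible(x)
}

#' Write a score table to TSV
#'
#' @param table Ranked score table (see [rank_genes()]).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_score_table <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1))
  out <- table
  for (j in which(num)) out[[j]] <- vapply(table[[j]], format, character(1),
                                           digits = 17)
  lines <- c(paste(colnames(out), collapse = "\t"),
             do.call(paste, c(unname(as.list(out)), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}
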