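#' Build a weighted gene functional network from gene-to-term assignments
#'
#' Connects every pair of genes that shares at least one functional term
#' (e.g. GO annotations). The edge weight is the summed information content
#' of the shared terms, \eqn{w(i,j) = \sum_t -\log_2 f_t}, where \eqn{f_t} is
#' the fraction of input genes annotated with term \eqn{t}: sharing more and
#' rarer terms yields heavier edges. A term carried by every gene contributes
#' nothing. This is one standard instantiation of a shared-annotation
#' likelihood-ratio network; a precomputed edge list (see [read_edge_list()])
#' can always be supplied instead.
#'
#' @param gene_terms Named list: gene identifier -> character vector of term
#'   identifiers. Genes with empty term sets become isolated nodes.
#' @param min_weight Edges lighter than this are omitted (default 0 keeps all
#'   positive-weight edges).
#' @return A \code{gene_network}: list with \code{nodes} (character) and
#'   \code{edges} (data.frame gene1, gene2, weight).
#' @export
build_go_network <- function(gene_terms, min_weight = 0) {
  stopifnot(is.list(gene_terms), !is.null(names(gene_terms)))
  genes <- names(gene_terms)
  with_terms <- genes[lengths(gene_terms) > 0L]
  if (length(with_terms) < 2L) stop("need >= 2 genes with >= 1 term each")
  n <- length(genes)
  term_tab <- table(unlist(lapply(gene_terms, unique)))
  ic <- -log2(as.numeric(term_tab) / n)
  names(ic) <- names(term_tab)
  e1 <- character(0); e2 <- character(0); w <- numeric(0)
  for (i in seq_along(with_terms)[-length(with_terms)]) {
    gi <- with_terms[i]
    ti <- unique(gene_terms[[gi]])
    for (j in seq((i + 1L), length(with_terms))) {
      gj <- with_terms[j]
      shared <- intersect(ti, unique(gene_terms[[gj]]))
      if (length(shared) == 0L) next
      wij <- sum(ic[shared])
      if (wij >= min_weight && wij > 0) {
        e1 <- c(e1, gi); e2 <- c(e2, gj); w <- c(w, wij)
      }
    }
  }
  gene_network(data.frame(gene1 = e1, gene2 = e2, weight = w,
                          stringsAsFactors = FALSE), nodes = genes)
}

#' Construct a weighted undirected gene network from an edge table
#'
#' @param edges data.frame with columns gene1, gene2, weight.
#' @param nodes Optional node universe; defaults to the genes appearing in
#'   the edge table. Nodes without edges are retained as isolated.
#' @return A \code{gene_network} object.
#' @export
gene_network <- function(edges, nodes = NULL) {
  stopifnot(all(c("gene1", "gene2", "weight") %in% colnames(edges)))
  edges$gene1 <- as.character(edges$gene1)
  edges$gene2 <- as.character(edges$gene2)
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0)) {
    stop("edge weights must be finite and nonnegative")
  }
  self <- edges$gene1 == edges$gene2
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped")
    edges <- edges[!self, , drop = FALSE]
  }
  # canonical orientation, then sum duplicate pairs
  flip <- edges$gene1 > edges$gene2
  tmp <- edges$gene1[flip]
  edges$gene1[flip] <- edges$gene2[flip]
  edges$gene2[flip] <- tmp
  key <- paste(edges$gene1, edges$gene2, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate edge pair(s) summed")
    agg <- rowsum(edges$weight, key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    edges <- data.frame(gene1 = vapply(parts, `[`, "", 1L),
                        gene2 = vapply(parts, `[`, "", 2L),
                        weight = agg[, 1L], stringsAsFactors = FALSE)
  }
  edges <- edges[edges$weight > 0, , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene1, edges$gene2)))
  nodes <- unique(as.character(nodes))
  missing <- setdiff(unique(c(edges$gene1, edges$gene2)), nodes)
  if (length(missing)) stop("edges reference genes outside the node set: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a weighted undirected edge list from TSV
#'
#' Expects columns gene1, gene2, weight (with header). Duplicate pairs are
#' summed with a warning; self-edges are dropped.
#'
#' @param path Path to the TSV file.
#' @param nodes Optional node universe (isolated genes retained).
#' @return A \code{gene_network} object.
#' @export
read_edge_list <- function(path, nodes = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, comment.char = "",
                          colClasses = c("character", "character", "numeric"))
  colnames(df)[1:3] <- c("gene1", "gene2", "weight")
  gene_network(df, nodes = nodes)
}

#' Write a network's edge list to TSV
#' @param net A \code{gene_network}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(net, path) {
  e <- net$edges
  lines <- c("gene1\tgene2\tweight",
             paste(e$gene1, e$gene2,
                   vapply(e$weight, format, character(1), digits = 17),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene-to-term assignments from a two-column TSV
#' @param path TSV with header columns gene, term.
#' @return Named list gene -> character vector of terms.
#' @export
read_gene_terms <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, comment.char = "",
                          colClasses = "character")
  split(df[[2L]], factor(df[[1L]], levels = unique(df[[1L]])))
}

#' Row-stochastic transition matrix of a weighted network
#'
#' Each row of the returned matrix is the node's edge weights normalised to
#' sum to one; zero-degree (isolated) nodes receive a unit self-loop so the
#' matrix stays stochastic. Genes of the universe absent from the network are
#' excluded and recorded in the \code{missing} element.
#'
#' @param net A \code{gene_network}.
#' @param universe Optional gene universe; defaults to the network's nodes.
#' @return A \code{transition_matrix}: list with \code{W} (sparse
#'   row-stochastic \code{Matrix}), \code{nodes}, and \code{missing} (universe
#'   genes not in the network).
#' @export
to_transition_matrix <- function(net, universe = NULL) {
  nodes <- net$nodes
  if (!is.null(universe)) {
    missing <- setdiff(universe, nodes)
    nodes <- intersect(nodes, universe)
    if (length(nodes) == 0L) stop("no universe gene is present in the network")
  } else {
    missing <- character(0)
  }
  idx <- stats::setNames(seq_along(nodes), nodes)
  e <- net$edges
  keep <- e$gene1 %in% nodes & e$gene2 %in% nodes
  e <- e[keep, , drop = FALSE]
  i <- c(idx[e$gene1], idx[e$gene2])
  j <- c(idx[e$gene2], idx[e$gene1])
  x <- c(e$weight, e$weight)
  n <- length(nodes)
  A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  iso <- which(deg == 0)
  if (length(iso)) {
    A <- A + Matrix::sparseMatrix(i = iso, j = iso, x = 1, dims = c(n, n))
    deg[iso] <- 1
  }
  W <- Matrix::Diagonal(x = 1 / deg) %*% A
  W <- methods::as(W, "CsparseMatrix")
  dimnames(W) <- list(nodes, nodes)
  structure(list(W = W, nodes = nodes, missing = missing),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix over %d nodes (%d universe genes absent)\n",
              length(x$nodes), length(x$missing)))
  invisible(x)
}

#' Random walk with restart from a source gene
#'
#' Iterates \eqn{p \leftarrow (1-r)\,W^\top p + r\,e_{source}} to its unique
#' fixed point, the stationary distribution of a walker that at each step
#' follows the row-stochastic transition matrix but teleports back to the
#' source with probability \eqn{r}. Entry \eqn{p^*(v)} is the reaching
#' probability from the source to node \eqn{v}.
#'
#' @param tm A \code{transition_matrix}.
#' @param source Source gene (must be a node).
#' @param restart Restart probability \eqn{r \in (0, 1]} (default 0.5).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter Maximum iterations before failing (default 1000).
#' @return A \code{reach_profile}: list with \code{source} and
#'   \code{probabilities} (named vector summing to 1).
#' @export
rwr <- function(tm, source, restart = 0.5, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(tm, "transition_matrix"),
            restart > 0, restart <= 1, tol > 0, max_iter >= 1)
  n <- length(tm$nodes)
  s <- match(source, tm$nodes)
  if (is.na(s)) stop("source gene '", source, "' is not in the network")
  e <- numeric(n); e[s] <- 1
  if (restart == 1) {
    p <- e
  } else {
    Wt <- Matrix::t(tm$W)
    p <- e
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      p_new <- as.numeric((1 - restart) * (Wt %*% p)) + restart * e
      delta <- sum(abs(p_new - p))
      p <- p_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      stop(sprintf("RWR did not converge in %d iterations (L1 residual %.3g)",
                   max_iter, delta))
    }
  }
  names(p) <- tm$nodes
  structure(list(source = source, probabilities = p), class = "reach_profile")
}

#' Average reaching probability to the seed genes
#'
#' For each gene \eqn{g}, \eqn{P(N_s)(g)} is the mean over seed genes of the
#' random-walk-with-restart reaching probability from \eqn{g} to the seed.
#' The default path computes all genes at once through a single sparse linear
#' solve of \eqn{(I - (1-r)W)\,v = r\,\bar{e}_S} (with \eqn{\bar{e}_S} the
#' uniform seed indicator), which is algebraically identical to averaging the
#' per-source fixed points; \code{method = "iterative"} runs one [rwr()] per
#' gene instead. A list of precomputed \code{reach_profile}s may also be
#' supplied directly.
#'
#' @param x A \code{transition_matrix}, or a list of \code{reach_profile}s
#'   (one per scored gene).
#' @param seeds Seed gene set (character vector).
#' @param restart Restart probability (ignored when profiles are supplied).
#' @param method \code{"solve"} (batched, default) or \code{"iterative"}.
#' @param tol,max_iter Passed to [rwr()] when \code{method = "iterative"}.
#' @return Named numeric vector of \eqn{P(N_s)} over network nodes (or over
#'   the profiled genes).
#' @export
avg_reach_to_seeds <- function(x, seeds, restart = 0.5, method = c("solve",
                               "iterative"), tol = 1e-10, max_iter = 1000L) {
  method <- match.arg(method)
  if (is.list(x) && !inherits(x, "transition_matrix")) {
    stopifnot(all(vapply(x, inherits, logical(1), "reach_profile")))
    node_names <- names(x[[1L]]$probabilities)
    eff <- intersect(seeds, node_names)
    if (length(eff) == 0L) stop("no seed gene is present in the network")
    if (length(eff) < length(seeds)) {
      warning(length(seeds) - length(eff), " seed gene(s) absent from the ",
              "network were skipped")
    }
    out <- vapply(x, function(pr) mean(pr$probabilities[eff]), numeric(1))
    names(out) <- vapply(x, `[[`, character(1), "source")
    return(out)
  }
  tm <- x
  stopifnot(inherits(tm, "transition_matrix"))
  eff <- intersect(seeds, tm$nodes)
  if (length(eff) == 0L) stop("no seed gene is present in the network")
  if (length(eff) < length(seeds)) {
    warning(length(seeds) - length(eff), " seed gene(s) absent from the ",
            "network were skipped")
  }
  n <- length(tm$nodes)
  if (method == "iterative") {
    out <- vapply(tm$nodes, function(g) {
      mean(rwr(tm, g, restart, tol, max_iter)$probabilities[eff])
    }, numeric(1))
    return(out)
  }
  # mean_s p*_g(s) = r [ (I - (1-r)W)^{-1} (1_S / |S|) ]_g
  s_vec <- numeric(n)
  s_vec[match(eff, tm$nodes)] <- 1 / length(eff)
  A <- Matrix::Diagonal(n) - (1 - restart) * tm$W
  v <- as.numeric(Matrix::solve(A, restart * s_vec))
  stats::setNames(pmax(v, 0), tm$nodes)
}

#' Network prior odds of being a risk gene
#'
#' Converts the average seed-reaching probability \eqn{P(N_s)} into prior
#' odds \eqn{P(M_1)/P(M_0) = c \cdot P(N_s)} with
#' \eqn{c = n_{risk} / (n_{total} - n_{risk})}, the assumed genome-wide ratio
#' of risk to non-risk genes (defaults 1000 of 18000). In
#' \code{"mean_normalized"} mode \eqn{P(N_s)} is first divided by its mean
#' over the scored genes so the average prior odds equals \eqn{c} exactly;
#' the literal mode multiplies the raw reaching probability as stated.
#'
#' @param p_ns Named vector of \eqn{P(N_s)} per gene.
#' @param n_risk Assumed number of risk genes in the genome (default 1000).
#' @param n_total Assumed genome size (default 18000).
#' @param mode \code{"literal"} (default) or \code{"mean_normalized"}.
#' @return Named vector of prior odds, same genes and order as \code{p_ns}.
#' @export
prior_odds <- function(p_ns, n_risk = 1000, n_total = 18000,
                       mode = c("literal", "mean_normalized")) {
  mode <- match.arg(mode)
  stopifnot(n_total > n_risk, n_risk > 0, all(p_ns >= 0))
  const <- n_risk / (n_total - n_risk)
  if (mode == "mean_normalized") {
    mu <- mean(p_ns)
    if (mu == 0) stop("all reaching probabilities are zero; cannot normalize")
    p_ns <- p_ns / mu
  }
  const * p_ns
}
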