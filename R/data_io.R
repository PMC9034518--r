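#' Read a gene set from a plain-text or GMT file
#'
#' Plain format is one gene identifier per line; GMT is the standard
#' tab-separated format (set name, description, then members). Identifiers
#' are whitespace-trimmed and deduplicated; they are treated as opaque,
#' case-sensitive strings throughout the package.
#'
#' @param path Path to the file.
#' @param format Either \code{"plain"} or \code{"gmt"}. For GMT files with
#'   several lines, only the first set is returned unless \code{set} names one.
#' @param set Optional set name to pick from a multi-set GMT file.
#' @param role Role label attached to the returned set; one of
#'   \code{"seed"}, \code{"background"}, \code{"benchmark"}, \code{"candidate"}.
#' @return A \code{gene_set}: a character vector of unique members with
#'   attributes \code{name} and \code{role}.
#' @examples
#' tf <- tempfile()
#' writeLines(c("SCN2A", "CHD8", "CHD8"), tf)
#' read_gene_set(tf)  # duplicate dropped with a warning
#' @export
read_gene_set <- function(path, format = c("plain", "gmt"), set = NULL,
                          role = "candidate") {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty gene set file: ", path)
  if (format == "plain") {
    members <- trimws(lines)
    name <- sub("\\.[^.]*$", "", basename(path))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    names(fields) <- vapply(fields, function(f) trimws(f[[1L]]), character(1))
    if (!is.null(set)) {
      if (!set %in% names(fields)) stop("set '", set, "' not found in ", path)
      rec <- fields[[set]]
    } else {
      rec <- fields[[1L]]
    }
    if (length(rec) < 3L) stop("GMT line has no members: ", rec[[1L]])
    members <- trimws(rec[-(1:2)])
    members <- members[nzchar(members)]
    name <- trimws(rec[[1L]])
  }
  if (anyDuplicated(members)) {
    warning(sum(duplicated(members)), " duplicate member(s) removed from '",
            name, "'")
    members <- unique(members)
  }
  gene_set(members, name = name, role = role)
}

#' Construct a gene set
#'
#' @param members Character vector of gene identifiers.
#' @param name Set name.
#' @param role One of \code{"seed"}, \code{"background"}, \code{"benchmark"},
#'   \code{"candidate"}.
#' @return A character vector of class \code{gene_set}.
#' @export
gene_set <- function(members, name = "set",
                     role = c("candidate", "seed", "background", "benchmark")) {
  role <- match.arg(role)
  members <- unique(as.character(members))
  structure(members, name = name, role = role, class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (role: %s), %d genes\n",
              attr(x, "name"), attr(x, "role"), length(x)))
  show <- utils::head(unclass(x), 6L)
  cat(" ", paste(show, collapse = ", "),
      if (length(x) > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Define a gene universe
#'
#' The universe fixes the ordered namespace over which priors, Bayes factors
#' and ranks are defined.
#'
#' @param genes Character vector of gene identifiers (duplicates dropped).
#' @return Character vector of unique identifiers, in first-seen order.
#' @export
gene_universe <- function(genes) {
  genes <- as.character(genes)
  genes <- genes[nzchar(genes)]
  genes <- unique(genes)
  if (length(genes) < 3L) stop("gene universe must contain at least 3 genes")
  genes
}

#' Read a gene-by-annotation matrix from TSV
#'
#' The file must have a header row of annotation names with the first column
#' holding gene identifiers; empty cells are missing. Binary matrices accept
#' only 0, 1 and missing; continuous matrices accept any finite decimal.
#'
#' @param path Path to a TSV file.
#' @param kind \code{"binary"} or \code{"continuous"}.
#' @return A numeric matrix with gene rownames and annotation colnames;
#'   missing cells are \code{NA}.
#' @seealso [write_annotation_matrix()] for the lossless inverse.
#' @export
read_annotation_matrix <- function(path, kind = c("binary", "continuous")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          na.strings = "", comment.char = "")
  if (ncol(df) < 2L) stop("annotation matrix needs a gene column plus >= 1 annotation")
  genes <- df[[1L]]
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in ", path)
  ann <- colnames(df)[-1L]
  if (anyDuplicated(ann)) stop("duplicate annotation names in ", path)
  m <- matrix(NA_real_, nrow = nrow(df), ncol = length(ann),
              dimnames = list(genes, ann))
  for (j in seq_along(ann)) {
    raw <- df[[j + 1L]]
    filled <- !is.na(raw)
    val <- suppressWarnings(as.numeric(raw[filled]))
    if (anyNA(val)) {
      bad <- which(filled)[which(is.na(val))[1L]]
      stop(sprintf("non-numeric cell at gene '%s', annotation '%s' in %s",
                   genes[bad], ann[j], path))
    }
    if (kind == "binary" && !all(val %in% c(0, 1))) {
      bad <- which(filled)[which(!val %in% c(0, 1))[1L]]
      stop(sprintf("binary annotation '%s' has non-0/1 value at gene '%s'",
                   ann[j], genes[bad]))
    }
    if (!all(is.finite(val))) {
      bad <- which(filled)[which(!is.finite(val))[1L]]
      stop(sprintf("non-finite value at gene '%s', annotation '%s'",
                   genes[bad], ann[j]))
    }
    m[filled, j] <- val
  }
  m
}

#' Write a gene-by-annotation matrix to TSV
#'
#' Inverse of [read_annotation_matrix()]: values are printed with full
#' precision (up to 17 significant digits) so a write/read round trip is
#' lossless; \code{NA} becomes the empty cell.
#'
#' @param m Numeric matrix with gene rownames and annotation colnames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  fmt <- function(x) ifelse(is.na(x), "", vapply(x, format, character(1),
                                                 digits = 17))
  body <- apply(m, 1L, fmt)
  body <- if (is.null(dim(body))) matrix(body, nrow = 1L) else t(body)
  lines <- c(paste(c("gene", colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix (genes x conditions) from TSV
#'
#' Same layout as [read_annotation_matrix()] but missing values and negative
#' expression are errors: the specificity index is undefined on them.
#'
#' @param path Path to a TSV file.
#' @return Nonnegative numeric matrix, genes in rows, conditions in columns.
#' @export
read_expression_matrix <- function(path) {
  m <- read_annotation_matrix(path, kind = "continuous")
  if (ncol(m) < 2L) stop("expression matrix needs >= 2 conditions")
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (any(m < 0)) stop("expression values must be nonnegative")
  m
}

#' Sample background genes
#'
#' Draws \code{n} genes uniformly without replacement from the universe,
#' excluding the seed genes. Background genes anchor the null model M0; the
#' default size of 500 balances genomic representativeness against
#' heterogeneity.
#'
#' @param universe Character vector of gene identifiers (see [gene_universe()]).
#' @param seeds Seed gene set (character vector).
#' @param n Number of background genes to draw (default 500).
#' @param rng_seed Integer seed making the draw reproducible.
#' @return A \code{gene_set} with role \code{"background"}.
#' @export
sample_background <- function(universe, seeds, n = 500L, rng_seed = NULL) {
  pool <- setdiff(universe, seeds)
  if (n > length(pool)) {
    stop("requested ", n, " background genes but only ", length(pool),
         " non-seed genes are available")
  }
  if (!is.null(rng_seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(rng_seed)
  }
  gene_set(sample(pool, n), name = "background", role = "background")
}

#' Write a gene set as plain text
#'
#' @param x Character vector of genes.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_set <- function(x, path) {
  writeLines(as.character(x), path)
  invisible(path)
}
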