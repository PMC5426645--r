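#' Construct an expression matrix
#'
#' Genes-by-samples matrix of expression levels.  At least two samples
#' are required, gene identifiers must be unique, and (by default)
#' values must be finite.
#'
#' @param values numeric matrix, genes in rows.
#' @param genes gene identifiers; defaults to `rownames(values)`.
#' @return Object of class `expression_matrix` (a numeric matrix with
#'   gene rownames).
#' @export
expression_matrix <- function(values, genes = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(genes)) stop("gene identifiers are required")
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  if (ncol(values) < 2L) stop("need at least 2 samples")
  rownames(values) <- as.character(genes)
  storage.mode(values) <- "double"
  structure(values, class = c("expression_matrix", "matrix", "array"))
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample names and the gene identifier in the
#' first column.
#'
#' @param path path to the file.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  expression_matrix(as.matrix(df[, -1L, drop = FALSE]), genes = df[[1L]])
}

#' Pearson correlation of two expression profiles
#'
#' Computed directly from the definition: the mean product of the two
#' standardised profiles with the sample (n - 1) standard deviation,
#' `sum(zx * zy) / (n - 1)`.  Returns `NA` (the undefined marker) when
#' either profile has zero variance.
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
#' @examples
#' pcc(c(1, 2, 3), c(3, 2, 1))  # -1
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0)
    return(NA_real_)
  sum(((x - mean(x)) / sx) * ((y - mean(y)) / sy)) / (n - 1)
}

# rows standardised to mean 0, sample sd 1; zero-variance or non-finite
# rows become all-NA so their correlations are undefined
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  z <- (m - mu) / sdv
  bad <- !is.finite(sdv) | sdv == 0 | !apply(m, 1L, function(r) all(is.finite(r)))
  z[bad, ] <- NA_real_
  z
}

# full gene-gene Pearson matrix for the given genes, blockwise on the
# standardised matrix; genes missing from expr (or undefined) give NA rows.
# missing = "undefined" treats any non-finite entry as making the whole
# gene undefined; "pairwise" drops samples pairwise-complete instead.
pcc_matrix <- function(expr, genes, missing = c("undefined", "pairwise")) {
  missing <- match.arg(missing)
  n <- ncol(expr)
  present <- intersect(genes, rownames(expr))
  out <- matrix(NA_real_, length(genes), length(genes),
                dimnames = list(genes, genes))
  if (length(present) >= 1L) {
    if (missing == "pairwise") {
      m <- expr[present, , drop = FALSE]
      m[!is.finite(m)] <- NA_real_
      cc <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
    } else {
      z <- standardize_rows(expr[present, , drop = FALSE])
      cc <- tcrossprod(z) / (n - 1)
    }
    out[present, present] <- cc
  }
  out
}

#' Pearson correlation for all unlinked pairs of a network
#'
#' Scores every unlinked canonical pair among the network's nodes.
#' Pairs where either gene is absent from the expression matrix, or
#' where the correlation is undefined (zero variance, non-finite
#' values), are assigned score 0 so that any positive threshold
#' excludes them.
#'
#' @param net a [ppi_network()].
#' @param expr an [expression_matrix()].
#' @param missing how non-finite expression entries are handled:
#'   `"undefined"` (default) makes every correlation of the affected
#'   gene undefined (score 0); `"pairwise"` drops samples
#'   pairwise-complete.
#' @return Data frame with columns `u`, `v`, `pcc` over all unlinked
#'   pairs (linked pairs never appear).
#' @export
pair_pcc <- function(net, expr, missing = c("undefined", "pairwise")) {
  pairs <- unlinked_pairs(net)
  if (!nrow(pairs))
    return(data.frame(u = character(), v = character(), pcc = numeric()))
  cm <- pcc_matrix(expr, net$nodes, missing = match.arg(missing))
  val <- cm[cbind(pairs[, 1L], pairs[, 2L])]
  val[!is.finite(val)] <- 0
  data.frame(u = pairs[, 1L], v = pairs[, 2L], pcc = val,
             stringsAsFactors = FALSE)
}
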