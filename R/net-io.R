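#' Read a PPI edge list or a confidence-scored reference set
#'
#' Reads whitespace/tab-separated interaction files.  The plain
#' two-column dialect yields a [ppi_network()]; the scored three-column
#' dialect (`u<TAB>v<TAB>confidence`, STRING-style) yields a
#' `reference_set`.  Lines starting with `#` and blank lines are
#' ignored.  Self-interactions are dropped and duplicate interactions
#' collapsed; for the scored dialect the maximum confidence of a
#' duplicated pair is kept (evidence union).  The number of dropped
#' lines is reported with `message()`.
#'
#' @param path path to the file.
#' @param dialect `"two-column"` or `"scored"`.
#' @return A `ppi_network` or, for `dialect = "scored"`, an object of
#'   class `reference_set`: list with `pairs` (n x 2 character matrix,
#'   canonical) and `confidence` (numeric in `[0, 1]`).
#' @export
read_edge_list <- function(path, dialect = c("two-column", "scored")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  need <- if (dialect == "scored") 3L else 2L
  bad <- which(nf < need)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected >= %d fields",
                 lineno[bad[1L]], path, need))
  u <- vapply(fields, `[[`, "", 1L)
  v <- vapply(fields, `[[`, "", 2L)
  if (dialect == "two-column") {
    cp <- canonical_pairs(u, v)
    self <- cp[, 1L] == cp[, 2L]
    dup <- duplicated(pair_key(cp[, 1L], cp[, 2L])) & !self
    if (any(self) || any(dup))
      message(sprintf("read_edge_list: dropped %d self-interaction(s) and %d duplicate(s)",
                      sum(self), sum(dup)))
    # a protein mentioned only in a dropped self-interaction stays a node
    return(ppi_network(cp, nodes = unique(c(u, v))))
  }
  conf <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(conf))
    stop(sprintf("malformed line %d in %s: confidence does not parse as a number",
                 lineno[which(is.na(conf))[1L]], path))
  if (any(conf < 0 | conf > 1))
    stop(sprintf("line %d in %s: confidence outside [0, 1]",
                 lineno[which(conf < 0 | conf > 1)[1L]], path))
  reference_set(u, v, conf, .report_drops = TRUE)
}

#' Construct a reference interaction set
#'
#' @param u,v endpoint identifiers.
#' @param confidence numeric confidences in `[0, 1]`.
#' @param .report_drops message the number of dropped lines.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(u, v, confidence, .report_drops = FALSE) {
  stopifnot(length(u) == length(v), length(u) == length(confidence))
  if (any(confidence < 0 | confidence > 1)) stop("confidence outside [0, 1]")
  cp <- canonical_pairs(u, v)
  self <- cp[, 1L] == cp[, 2L]
  cp <- cp[!self, , drop = FALSE]
  confidence <- confidence[!self]
  key <- pair_key(cp[, 1L], cp[, 2L])
  # duplicate pairs keep the maximum confidence
  if (anyDuplicated(key)) {
    best <- tapply(confidence, key, max)
    first <- !duplicated(key)
    cp2 <- cp[first, , drop = FALSE]
    conf2 <- as.numeric(best[pair_key(cp2[, 1L], cp2[, 2L])])
    ndrop <- length(key) - nrow(cp2)
    cp <- cp2; confidence <- conf2
  } else ndrop <- 0L
  if (.report_drops && (sum(self) || ndrop))
    message(sprintf("reference_set: dropped %d self-interaction(s), collapsed %d duplicate(s)",
                    sum(self), ndrop))
  o <- order(cp[, 1L], cp[, 2L])
  structure(list(pairs = cp[o, , drop = FALSE], confidence = confidence[o]),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d scored interactions (confidence %.2f-%.2f)\n",
              nrow(x$pairs),
              if (nrow(x$pairs)) min(x$confidence) else NA,
              if (nrow(x$pairs)) max(x$confidence) else NA))
  invisible(x)
}

#' Read a protein list (one identifier per line)
#'
#' Blank lines and `#` comments are allowed; duplicates are removed
#' keeping the first occurrence.
#'
#' @param path path to the file.
#' @return Character vector of identifiers (possibly empty, with a
#'   warning for an empty file).
#' @export
read_protein_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  ids <- lines[!grepl("^(#|$)", lines)]
  ids <- ids[!duplicated(ids)]
  if (!length(ids)) warning("protein list is empty: ", path)
  ids
}

#' Write a network or reference set as a tab-separated edge list
#'
#' @param x a [ppi_network()] or `reference_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  if (inherits(x, "ppi_network")) {
    utils::write.table(x$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else if (inherits(x, "reference_set")) {
    utils::write.table(cbind(x$pairs, format(x$confidence, digits = 15)),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else stop("cannot write object of class ", class(x)[1L])
  invisible(path)
}
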