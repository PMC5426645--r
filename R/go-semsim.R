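#' Parse a Gene Ontology file in OBO 1.2 format
#'
#' Captures `is_a` and `relationship: part_of` parent links, the
#' namespace of each term, obsolete flags and alternate identifiers.
#' Parent links crossing namespaces are dropped.  The parent graph must
#' be acyclic; a cycle is an error naming a term on it.
#'
#' @param path path to the `.obo` file.
#' @param weights semantic contribution factors per relation, strictly
#'   between 0 and 1.  The customary constants of the Wang-style measure
#'   are 0.8 for `is_a` and 0.6 for `part_of`.
#' @return Object of class `go_dag`: list with `terms` (per-term list of
#'   `namespace`, `parents`, `relation`, `obsolete`), `alt` (named
#'   vector mapping alternate to primary identifiers) and `weights`.
#' @export
parse_obo <- function(path, weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  go_dag_from_lines(lines, weights)
}

# shared by parse_obo and the synthetic ontology builder
go_dag_from_lines <- function(lines, weights = c(is_a = 0.8, part_of = 0.6)) {
  if (any(weights <= 0 | weights >= 1))
    stop("relation weights must lie strictly between 0 and 1")
  starts <- grep("^\\[", lines)
  term_starts <- starts[lines[starts] == "[Term]"]
  bounds <- c(starts, length(lines) + 1L)
  terms <- list(); alt <- character()
  for (s in term_starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[s:e]
    tag <- function(t) sub(paste0("^", t, ":\\s*"), "",
                           grep(paste0("^", t, ":"), block, value = TRUE))
    id <- tag("id")[1L]
    if (is.na(id) || !nzchar(id)) next
    isa <- sub("\\s*!.*$", "", tag("is_a"))
    rel <- sub("\\s*!.*$", "", tag("relationship"))
    rel <- rel[grepl("^part_of\\s", rel)]
    partof <- trimws(sub("^part_of\\s+", "", rel))
    parents <- c(isa, partof)
    relation <- c(rep("is_a", length(isa)), rep("part_of", length(partof)))
    obo_ns <- tag("namespace")[1L]
    ns <- switch(if (is.na(obo_ns)) "" else obo_ns,
                 biological_process = "BP", cellular_component = "CC",
                 molecular_function = "MF", obo_ns)
    alt_ids <- tag("alt_id")
    if (length(alt_ids)) alt[alt_ids] <- id
    terms[[id]] <- list(namespace = ns,
                        parents = trimws(parents), relation = relation,
                        obsolete = isTRUE(any(tag("is_obsolete") == "true")))
  }
  # drop parent links to unknown terms or across namespaces
  for (id in names(terms)) {
    tm <- terms[[id]]
    ok <- tm$parents %in% names(terms)
    ok[ok] <- vapply(tm$parents[ok], function(p)
      identical(terms[[p]]$namespace, tm$namespace), logical(1L))
    terms[[id]]$parents <- tm$parents[ok]
    terms[[id]]$relation <- tm$relation[ok]
  }
  dag <- structure(list(terms = terms, alt = alt, weights = weights),
                   class = "go_dag")
  assert_acyclic(dag)
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  ns <- vapply(x$terms, `[[`, "", "namespace")
  cat(sprintf("go_dag: %d terms (%s), %d alternate ids\n",
              length(x$terms),
              paste(sprintf("%s: %d", names(table(ns)), table(ns)),
                    collapse = ", "),
              length(x$alt)))
  invisible(x)
}

# Kahn's topological sort over child -> parent links; leftovers are on cycles
assert_acyclic <- function(dag) {
  ids <- names(dag$terms)
  np <- vapply(dag$terms, function(t) length(t$parents), integer(1L))
  children <- split(
    rep(ids, np),
    unlist(lapply(dag$terms, `[[`, "parents"), use.names = FALSE))
  outdeg <- np  # number of unresolved parents per term
  queue <- ids[outdeg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[t]]) {
      outdeg[[ch]] <- outdeg[[ch]] - 1L
      if (outdeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    on_cycle <- ids[outdeg > 0L][1L]
    stop("ontology parent graph contains a cycle involving term ", on_cycle)
  }
  invisible(TRUE)
}

# resolve an identifier through the alternate-id table
resolve_term <- function(id, dag) {
  if (id %in% names(dag$terms)) id
  else if (id %in% names(dag$alt)) dag$alt[[id]]
  else NA_character_
}

#' Read protein annotations from a GAF 2.x file
#'
#' Keeps rows of the requested aspect, drops `NOT`-qualified rows, maps
#' alternate identifiers to primary ones and drops rows annotating
#' obsolete or unknown terms (with a logged count).  A malformed row is
#' skipped with a warning, never an abort.
#'
#' @param path path to the GAF file (`!` comment lines allowed).
#' @param namespace one of `"BP"`, `"CC"`, `"MF"`.
#' @param dag a [parse_obo()] ontology.
#' @param exclude_iea drop IEA evidence rows (off by default).
#' @return Named list mapping protein identifier to a character vector
#'   of term identifiers (an `annotation_map`).
#' @export
read_gaf <- function(path, namespace = c("BP", "CC", "MF"), dag,
                     exclude_iea = FALSE) {
  namespace <- match.arg(namespace)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(!|$)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 15L
  if (any(bad)) {
    warning(sprintf("read_gaf: skipped %d unparseable row(s)", sum(bad)))
    fields <- fields[!bad]
  }
  if (!length(fields)) return(structure(list(), class = "annotation_map"))
  gene <- vapply(fields, `[[`, "", 2L)
  qualifier <- vapply(fields, `[[`, "", 4L)
  term <- vapply(fields, `[[`, "", 5L)
  evidence <- vapply(fields, `[[`, "", 7L)
  aspect <- vapply(fields, `[[`, "", 9L)
  want <- c(BP = "P", CC = "C", MF = "F")[[namespace]]
  keep <- aspect == want & !grepl("\\bNOT\\b", qualifier)
  if (exclude_iea) keep <- keep & evidence != "IEA"
  gene <- gene[keep]; term <- term[keep]
  term <- vapply(term, resolve_term, "", dag = dag)
  known <- !is.na(term) & nzchar(term)
  obs <- known & vapply(term, function(t)
    !is.na(t) && nzchar(t) && isTRUE(dag$terms[[t]]$obsolete), logical(1L))
  drop <- !known | obs
  if (any(drop))
    message(sprintf("read_gaf: dropped %d row(s) with unknown or obsolete terms",
                    sum(drop)))
  gene <- gene[!drop]; term <- term[!drop]
  ann <- lapply(split(term, gene), function(x) sort(unique(unname(x))))
  structure(ann, class = "annotation_map")
}

#' Build an annotation map in code
#'
#' @param x named list: protein identifier to character vector of term
#'   identifiers.
#' @param dag a `go_dag`; annotations to unknown or obsolete terms are
#'   an error.
#' @return An `annotation_map`.
#' @export
annotation_map <- function(x, dag) {
  x <- lapply(x, function(ts) {
    ts <- vapply(as.character(ts), resolve_term, "", dag = dag)
    if (anyNA(ts)) stop("annotation to unknown term")
    if (any(vapply(ts, function(t) dag$terms[[t]]$obsolete, logical(1L))))
      stop("annotation to obsolete term")
    sort(unique(unname(ts)))
  })
  structure(x, class = "annotation_map")
}

#' S-values of a term and its ancestors
#'
#' The semantic contribution `S_A(t)` of every ancestor `t` of anchor
#' term `A`: `S_A(A) = 1`, and walking up the DAG each parent receives
#' the maximum over its children (on paths toward `A`) of the child's
#' S-value times the relation weight.  Computed by best-first relaxation
#' over the ancestor subgraph (a max-product shortest path).
#'
#' @param term anchor term identifier (alternate ids resolve).
#' @param dag a `go_dag`.
#' @return Named numeric vector over the anchor and all its ancestors,
#'   values in `(0, 1]`, anchor first.
#' @export
svalues <- function(term, dag) {
  a <- resolve_term(term, dag)
  if (is.na(a)) stop("unknown term: ", term)
  if (isTRUE(dag$terms[[a]]$obsolete)) stop("obsolete term: ", term)
  s <- c(1); names(s) <- a
  queue <- a
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    tm <- dag$terms[[t]]
    if (!length(tm$parents)) next
    cand <- s[[t]] * dag$weights[tm$relation]
    for (i in seq_along(tm$parents)) {
      p <- tm$parents[[i]]
      if (is.na(s[p]) || cand[[i]] > s[[p]]) {
        s[p] <- cand[[i]]
        queue <- c(queue, p)
      }
    }
  }
  s
}

#' Wang-style semantic similarity of two terms
#'
#' The ratio of the summed S-values over the common ancestors (counted
#' from both sides) to the total S-value mass of the two terms.
#'
#' @param a,b term identifiers in the same namespace.
#' @param dag a `go_dag`.
#' @return Similarity in `(0, 1]`; symmetric in `a` and `b`.
#' @export
term_sim <- function(a, b, dag) {
  ra <- resolve_term(a, dag); rb <- resolve_term(b, dag)
  if (is.na(ra)) stop("unknown term: ", a)
  if (is.na(rb)) stop("unknown term: ", b)
  if (!identical(dag$terms[[ra]]$namespace, dag$terms[[rb]]$namespace))
    stop("terms belong to different namespaces: ", ra, " vs ", rb)
  sa <- svalues(ra, dag); sb <- svalues(rb, dag)
  common <- intersect(names(sa), names(sb))
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

# semantic profile of a protein: max S-value over its annotated anchors,
# keyed by the union of the anchors' ancestor closures
protein_profile <- function(terms, dag) {
  prof <- numeric()
  for (t in terms) {
    s <- svalues(t, dag)
    new <- setdiff(names(s), names(prof))
    upd <- intersect(names(s), names(prof))
    prof[new] <- s[new]
    if (length(upd)) prof[upd] <- pmax(prof[upd], s[upd])
  }
  prof
}

#' GO semantic similarity between two proteins
#'
#' Set-based similarity over the proteins' term sets.  With the default
#' `aggregate = "ancestor-union"` the term set of a protein is the
#' ancestor closure of all its annotated terms, each ancestor carrying
#' the maximum S-value over the annotated anchors, and the similarity is
#' the common mass counted from both sides over the total mass.  The
#' `"bma"` alternative is the best-match average of pairwise
#' [term_sim()] values.  Proteins with no annotation score 0.
#'
#' @param u,v protein identifiers.
#' @param ann an `annotation_map`.
#' @param dag a `go_dag`.
#' @param aggregate `"ancestor-union"` (default) or `"bma"`.
#' @return Similarity in `[0, 1]`; symmetric.
#' @export
protein_go_sim <- function(u, v, ann, dag,
                           aggregate = c("ancestor-union", "bma")) {
  aggregate <- match.arg(aggregate)
  tu <- ann[[u]]; tv <- ann[[v]]
  if (is.null(tu) || !length(tu) || is.null(tv) || !length(tv)) return(0)
  if (aggregate == "bma") {
    m <- outer(tu, tv, Vectorize(function(a, b) term_sim(a, b, dag)))
    return((mean(apply(m, 1L, max)) + mean(apply(m, 2L, max))) / 2)
  }
  pu <- protein_profile(tu, dag)
  pv <- protein_profile(tv, dag)
  common <- intersect(names(pu), names(pv))
  sum(pu[common] + pv[common]) / (sum(pu) + sum(pv))
}

# profile cache used by the stage-1 scorer: named list protein -> profile
profile_cache <- function(proteins, ann, dag) {
  out <- vector("list", length(proteins)); names(out) <- proteins
  for (p in proteins) {
    ts <- ann[[p]]
    out[[p]] <- if (is.null(ts) || !length(ts)) numeric()
                else protein_profile(ts, dag)
  }
  out
}

# similarity from two cached profiles (0 if either empty)
profile_sim <- function(pu, pv) {
  if (!length(pu) || !length(pv)) return(0)
  common <- intersect(names(pu), names(pv))
  sum(pu[common] + pv[common]) / (sum(pu) + sum(pv))
}
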