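# Fixtures and independent oracles shared across the suite.
# Oracles are deliberately naive (brute force / closed form / library
# cross-check) and never reuse the code paths they verify.

# --- graphs ----------------------------------------------------------------

triangle_net <- function() {
  ppi_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
}

path_net <- function(ids = c("A", "B", "C")) {
  ppi_network(cbind(ids[-length(ids)], ids[-1L]))
}

# Erdos-Renyi graph on labelled nodes (isolated nodes retained)
random_net <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  idx <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(idx)) < p
  ppi_network(cbind(ids[idx[1L, keep]], ids[idx[2L, keep]]), nodes = ids)
}

dense_adj <- function(net) {
  n <- length(net$nodes)
  a <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(nrow(net$edges))) {
    a[net$edges[i, 1L], net$edges[i, 2L]] <- 1
    a[net$edges[i, 2L], net$edges[i, 1L]] <- 1
  }
  a
}

# --- ontologies ------------------------------------------------------------

# build a go_dag from a compact parent spec:
#   list(t1 = character(), t2 = c(is_a = "t1"), t3 = c(part_of = "t2"), ...)
dag_from_spec <- function(spec, namespace = "biological_process",
                          weights = c(is_a = 0.8, part_of = 0.6)) {
  lines <- c("format-version: 1.2")
  for (id in names(spec)) {
    lines <- c(lines, "", "[Term]", paste0("id: ", id),
               paste0("name: ", id), paste0("namespace: ", namespace))
    parents <- spec[[id]]
    for (i in seq_along(parents)) {
      rel <- names(parents)[[i]]
      lines <- c(lines, if (identical(rel, "part_of"))
        paste0("relationship: part_of ", parents[[i]])
        else paste0("is_a: ", parents[[i]]))
    }
  }
  edgefill:::go_dag_from_lines(lines, weights)
}

# random DAG spec with <= n terms; parents drawn among earlier terms
random_dag_spec <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(n))
  spec <- list()
  spec[[ids[[1L]]]] <- character()
  for (i in 2:n) {
    k <- sample(1:min(3L, i - 1L), 1L)
    parents <- sample(ids[seq_len(i - 1L)], k)
    rels <- sample(c("is_a", "part_of"), k, replace = TRUE)
    spec[[ids[[i]]]] <- stats::setNames(parents, rels)
  }
  spec
}

# brute-force S-values: exhaustive enumeration of every upward path
brute_svalues <- function(anchor, dag) {
  best <- c(1); names(best) <- anchor
  recurse <- function(t, prod) {
    tm <- dag$terms[[t]]
    for (i in seq_along(tm$parents)) {
      p <- tm$parents[[i]]
      np <- prod * dag$weights[[tm$relation[[i]]]]
      if (is.na(best[p]) || np > best[[p]]) best[p] <<- np
      recurse(p, np)
    }
  }
  recurse(anchor, 1)
  best
}

# Eq-style protein similarity computed naively from brute-force S-values
brute_protein_sim <- function(u, v, ann, dag) {
  prof <- function(terms) {
    out <- numeric()
    for (t in terms) {
      s <- brute_svalues(t, dag)
      for (nm in names(s))
        out[nm] <- if (is.na(out[nm])) s[[nm]] else max(out[[nm]], s[[nm]])
    }
    out
  }
  tu <- ann[[u]]; tv <- ann[[v]]
  if (is.null(tu) || !length(tu) || is.null(tv) || !length(tv)) return(0)
  pu <- prof(tu); pv <- prof(tv)
  common <- intersect(names(pu), names(pv))
  sum(pu[common] + pv[common]) / (sum(pu) + sum(pv))
}

# --- text fixtures ---------------------------------------------------------

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal 17-column GAF row
gaf_row <- function(gene, term, aspect = "P", qualifier = "",
                    evidence = "IDA") {
  f <- rep("", 17L)
  f[1L] <- "DB"; f[2L] <- gene; f[3L] <- gene; f[4L] <- qualifier
  f[5L] <- term; f[6L] <- "REF:1"; f[7L] <- evidence; f[9L] <- aspect
  f[12L] <- "protein"; f[13L] <- "taxon:4932"; f[14L] <- "20160305"
  f[15L] <- "DB"
  paste(f, collapse = "\t")
}

# expression matrix with exact planted profiles
expr_from_rows <- function(rows) {
  expression_matrix(do.call(rbind, rows), genes = names(rows))
}
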