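#' Generate a seeded synthetic benchmark scenario
#'
#' Builds a planted-truth benchmark exercising every stage of the
#' pipeline without external downloads: a truth network, a hidden edge
#' set (the observed network is truth minus hidden), expression
#' profiles correlated along hidden edges, a toy GO DAG with
#' annotations enriched along truth edges, a confidence-scored
#' reference set, and a designated essential set (the top decile of
#' truth degree).
#'
#' Hidden edges are organised into *modules* sharing one latent
#' expression factor and a triplet of deep sibling ontology leaves
#' (protein complexes co-express and share specific annotations).
#' Under the default `hide_policy = "matching"` each module is a single
#' hidden edge and no node belongs to two modules, so every hidden pair
#' has population expression correlation `rho_edge`.  Under
#' `"essential-biased"` the modules are stars centred on mid-tier
#' essential proteins whose edges are preferentially hidden (all but
#' `keep_edges` of each seed's incident edges) — the scenario in which
#' stage 2's rescued-candidate selection is exercised.
#'
#' Annotation coherence: every protein has a "home" subtree of the toy
#' DAG (its module's subtree when it belongs to one) and all its leaf
#' annotations are drawn there, mirroring the functional coherence of
#' real annotation sets.  Module members receive the module's leaf
#' triplet with probability `annotation_overlap`; observed truth-edge
#' pairs additionally share a fresh leaf with the same probability.
#'
#' Reference confidences: truth edges draw `Uniform(0.7, 1)` except a
#' `ref_false_negative` fraction drawing `Uniform(0, 0.7)`; an equal
#' number of decoy non-edges draw `Uniform(0, 0.7)`, so the 0.7
#' confidence filter is exercised in both directions.
#'
#' @param n_nodes number of proteins (default 300).
#' @param model `"scale-free"` (preferential attachment, 2 links per
#'   arriving node) or `"ER"` (Erdos-Renyi with matching edge count).
#' @param hide_fraction fraction of truth edges hidden under the
#'   matching policy (default 0.1).
#' @param n_samples expression samples (default 36).
#' @param rho_edge population correlation planted on hidden-module
#'   pairs (default 0.99).
#' @param rho_background baseline correlation between all other pairs
#'   (default 0); must satisfy `rho_background < rho_edge`.
#' @param dag_depth depth of each ontology subtree (default 6).
#' @param annotation_overlap probability that a module member receives
#'   the module's annotation triplet, and that an observed truth edge
#'   shares a leaf (default 0.9).
#' @param hide_policy `"matching"` (default) or `"essential-biased"`.
#' @param n_seed_modules number of essential seed stars under the
#'   biased policy (default 5).
#' @param keep_edges observed edges retained per seed under the biased
#'   policy (default 2).
#' @param ref_false_negative fraction of truth edges scored below the
#'   0.7 confidence cut (default 0.05).
#' @param seed master seed; the scenario is a deterministic function of
#'   the configuration and this seed.
#' @return Object of class `synthetic_scenario`: list with `truth`,
#'   `observed` (both [ppi_network()]), `hidden` (matrix), `modules`
#'   (list of member vectors), `expr`, `dag`, `ann`, `reference`,
#'   `essential`, `config`.
#' @export
synthetic_scenario <- function(n_nodes = 300L,
                               model = c("scale-free", "ER"),
                               hide_fraction = 0.1,
                               n_samples = 36L,
                               rho_edge = 0.99,
                               rho_background = 0,
                               dag_depth = 6L,
                               annotation_overlap = 0.9,
                               hide_policy = c("matching", "essential-biased"),
                               n_seed_modules = 5L,
                               keep_edges = 2L,
                               ref_false_negative = 0.05,
                               seed = 1L) {
  model <- match.arg(model)
  hide_policy <- match.arg(hide_policy)
  stopifnot(hide_fraction > 0, hide_fraction < 1,
            rho_edge > rho_background, rho_edge < 1, rho_background >= 0,
            n_samples >= 2L, n_nodes >= 20L)
  config <- list(n_nodes = n_nodes, model = model,
                 hide_fraction = hide_fraction, n_samples = n_samples,
                 rho_edge = rho_edge, rho_background = rho_background,
                 dag_depth = dag_depth,
                 annotation_overlap = annotation_overlap,
                 hide_policy = hide_policy, n_seed_modules = n_seed_modules,
                 keep_edges = keep_edges,
                 ref_false_negative = ref_false_negative, seed = seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  ids <- sprintf("P%04d", seq_len(n_nodes))
  g <- if (model == "scale-free") {
    igraph::sample_pa(n_nodes, m = 2L, directed = FALSE)
  } else {
    igraph::sample_gnm(n_nodes, 2L * n_nodes - 3L)
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  # identifiers are assigned by a random permutation so lexicographic
  # tie-breaks are independent of degree structure
  perm <- sample(ids)
  truth <- ppi_network(cbind(perm[el[, 1L]], perm[el[, 2L]]), nodes = ids)

  deg <- node_degrees(truth)
  n_ess <- max(1L, floor(n_nodes / 10))
  essential <- names(sort(deg, decreasing = TRUE))[seq_len(n_ess)]
  essential <- essential[order(-deg[essential], essential)]

  modules <- plant_hidden_modules(truth, essential, config)
  hidden <- modules$hidden
  observed <- ppi_network(
    truth$edges[!(edge_keys(truth) %in% pair_key(hidden[, 1L], hidden[, 2L])), ,
                drop = FALSE],
    nodes = truth$nodes)

  dag_parts <- build_toy_ontology(n_subtrees = 8L, depth = dag_depth,
                                  leaves_per_subtree = 12L)
  ann <- annotate_scenario(truth, observed, modules$modules, dag_parts, config)
  expr <- simulate_expression(truth$nodes, modules$modules, config)
  reference <- simulate_reference(truth, config)

  structure(list(truth = truth, observed = observed, hidden = hidden,
                 modules = modules$modules, expr = expr,
                 dag = dag_parts$dag, ann = ann, reference = reference,
                 essential = essential, config = config),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_scenario (seed %d, %s hiding): %d proteins, %d truth edges,\n",
    "  %d hidden in %d modules; %d expression samples; %d essential proteins\n"),
    x$config$seed, x$config$hide_policy, length(x$truth$nodes),
    nrow(x$truth$edges), nrow(x$hidden), length(x$modules),
    ncol(x$expr), length(x$essential)))
  invisible(x)
}

# choose hidden edges and group them into latent modules
plant_hidden_modules <- function(truth, essential, config) {
  deg <- node_degrees(truth)
  if (config$hide_policy == "matching") {
    target <- floor(config$hide_fraction * nrow(truth$edges))
    ord <- sample(nrow(truth$edges))
    used <- character()
    take <- integer()
    for (i in ord) {
      u <- truth$edges[i, 1L]; v <- truth$edges[i, 2L]
      if (u %in% used || v %in% used) next
      if (deg[[u]] < 2L || deg[[v]] < 2L) next    # never isolate a node
      take <- c(take, i); used <- c(used, u, v)
      if (length(take) == target) break
    }
    if (length(take) < target)
      stop("infeasible configuration: cannot hide ", target,
           " edges as a matching without isolating nodes")
    hidden <- truth$edges[take, , drop = FALSE]
    modules <- lapply(seq_len(nrow(hidden)), function(i)
      as.character(hidden[i, ]))
    return(list(hidden = hidden, modules = modules))
  }
  # essential-biased: star modules on mid-tier essential seeds (the very
  # top hubs keep too much degree after hiding to ever leave the top ranks)
  start <- min(10L, max(2L, floor(length(essential) / 3)))
  seeds <- essential[seq(start, length.out = config$n_seed_modules)]
  seeds <- seeds[!is.na(seeds)]
  if (!length(seeds))
    stop("infeasible configuration: no essential seeds available")
  adj <- split(c(truth$edges[, 2L], truth$edges[, 1L]),
               c(truth$edges[, 1L], truth$edges[, 2L]))
  taken <- character()
  hidden <- matrix(character(), ncol = 2L)
  modules <- list()
  for (s in seeds) {
    nb <- setdiff(adj[[s]], c(seeds, taken))
    nb <- nb[deg[nb] >= 2L]                       # partner keeps >= 1 edge
    if (length(nb) <= config$keep_edges) next
    partners <- sample(nb, length(nb) - config$keep_edges)
    hidden <- rbind(hidden, canonical_pairs(rep(s, length(partners)), partners))
    modules <- c(modules, list(c(s, partners)))
    taken <- c(taken, partners, s)
  }
  if (!nrow(hidden))
    stop("infeasible configuration: biased hiding produced no modules")
  list(hidden = hidden, modules = modules)
}

# latent-factor expression: module members load sqrt(rho_edge - rho_bg)
# on their module factor; everyone loads sqrt(rho_bg) on a global factor
simulate_expression <- function(nodes, modules, config) {
  n <- length(nodes); s <- config$n_samples
  rho_e <- config$rho_edge; rho_b <- config$rho_background
  x <- matrix(stats::rnorm(n * s), n, s, dimnames = list(nodes, NULL))
  member <- stats::setNames(rep(FALSE, n), nodes)
  for (m in modules) member[m] <- TRUE
  noise_sd <- ifelse(member, sqrt(1 - rho_e), sqrt(1 - rho_b))
  x <- x * noise_sd
  if (rho_b > 0)
    x <- x + rep(sqrt(rho_b) * stats::rnorm(s), each = n)
  for (m in modules) {
    f <- stats::rnorm(s)
    x[m, ] <- x[m, ] + rep(sqrt(rho_e - rho_b) * f, each = length(m))
  }
  colnames(x) <- sprintf("S%02d", seq_len(s))
  expression_matrix(x)
}

# toy single-namespace ontology: a root, n_subtrees internal chains of
# the given depth, each ending in a fan of sibling leaves; one chain
# edge per subtree is part_of, the rest is_a
build_toy_ontology <- function(n_subtrees, depth, leaves_per_subtree) {
  lines <- c("format-version: 1.2", "",
             "[Term]", "id: GO:0000001", "name: biological_process",
             "namespace: biological_process")
  counter <- 1L
  nxt <- function() {
    counter <<- counter + 1L
    sprintf("GO:%07d", counter)
  }
  subtree_leaves <- list()
  subtree_roots <- character()
  for (s in seq_len(n_subtrees)) {
    chain <- character(depth)
    for (d in seq_len(depth)) chain[[d]] <- nxt()
    subtree_roots[[s]] <- chain[[1L]]
    for (d in seq_len(depth)) {
      parent <- if (d == 1L) "GO:0000001" else chain[[d - 1L]]
      rel <- if (d == 3L) sprintf("relationship: part_of %s", parent)
             else sprintf("is_a: %s", parent)
      lines <- c(lines, "", "[Term]", sprintf("id: %s", chain[[d]]),
                 sprintf("name: subtree%d level%d", s, d),
                 "namespace: biological_process", rel)
    }
    leaves <- character(leaves_per_subtree)
    for (l in seq_len(leaves_per_subtree)) {
      leaves[[l]] <- nxt()
      lines <- c(lines, "", "[Term]", sprintf("id: %s", leaves[[l]]),
                 sprintf("name: subtree%d leaf%d", s, l),
                 "namespace: biological_process",
                 sprintf("is_a: %s", chain[[depth]]))
    }
    subtree_leaves[[s]] <- leaves
  }
  list(dag = go_dag_from_lines(lines), obo_lines = lines,
       subtree_leaves = subtree_leaves, subtree_roots = subtree_roots)
}

# annotations: per-protein home subtree, module leaf triplets, one own
# leaf each, and shared leaves along observed truth edges
annotate_scenario <- function(truth, observed, modules, dag_parts, config) {
  nodes <- truth$nodes
  n_sub <- length(dag_parts$subtree_leaves)
  home <- stats::setNames(sample.int(n_sub, length(nodes), replace = TRUE),
                          nodes)
  module_sub <- sample.int(n_sub, length(modules), replace = TRUE)
  ann <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(modules)) {
    sub <- module_sub[[i]]
    members <- modules[[i]]
    home[members] <- sub
    triplet <- sample(dag_parts$subtree_leaves[[sub]], 3L)
    for (p in members)
      if (stats::runif(1) < config$annotation_overlap)
        ann[[p]] <- c(ann[[p]], triplet)
  }
  for (p in nodes)
    ann[[p]] <- c(ann[[p]], sample(dag_parts$subtree_leaves[[home[[p]]]], 1L))
  if (nrow(observed$edges)) for (i in seq_len(nrow(observed$edges))) {
    if (stats::runif(1) >= config$annotation_overlap) next
    u <- observed$edges[i, 1L]; v <- observed$edges[i, 2L]
    leaf <- sample(dag_parts$subtree_leaves[[home[[u]]]], 1L)
    ann[[u]] <- c(ann[[u]], leaf); ann[[v]] <- c(ann[[v]], leaf)
  }
  annotation_map(lapply(ann, unique), dag_parts$dag)
}

# confidence-scored reference: truth edges mostly >= 0.7, decoys below
simulate_reference <- function(truth, config) {
  ne <- nrow(truth$edges)
  fn <- stats::runif(ne) < config$ref_false_negative
  conf <- ifelse(fn, stats::runif(ne, 0, 0.7), stats::runif(ne, 0.7, 1))
  nodes <- truth$nodes
  decoys <- matrix(character(), ncol = 2L)
  guard <- 0L
  while (nrow(decoys) < ne && guard < 50L) {
    guard <- guard + 1L
    cand <- canonical_pairs(sample(nodes, ne, replace = TRUE),
                            sample(nodes, ne, replace = TRUE))
    cand <- cand[cand[, 1L] != cand[, 2L], , drop = FALSE]
    cand <- rbind(decoys, cand)
    keep <- !(pair_key(cand[, 1L], cand[, 2L]) %in% edge_keys(truth)) &
      !duplicated(pair_key(cand[, 1L], cand[, 2L]))
    decoys <- cand[keep, , drop = FALSE]
  }
  decoys <- decoys[seq_len(min(ne, nrow(decoys))), , drop = FALSE]
  dconf <- stats::runif(nrow(decoys), 0, 0.7)
  reference_set(c(truth$edges[, 1L], decoys[, 1L]),
                c(truth$edges[, 2L], decoys[, 2L]),
                c(conf, dconf))
}

#' Precision and recall of predicted links against the hidden truth
#'
#' @param predicted two-column matrix of predicted pairs.
#' @param scenario a [synthetic_scenario()].
#' @return List with `n_predicted`, `n_hidden`, `true_positive`,
#'   `precision` (`NA` with a warning when nothing was predicted) and
#'   `recall`.
#' @export
truth_precision <- function(predicted, scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  hid <- pair_key(scenario$hidden[, 1L], scenario$hidden[, 2L])
  n <- NROW(predicted)
  if (n == 0L) {
    warning("no predicted links; precision undefined")
    return(list(n_predicted = 0L, n_hidden = length(hid),
                true_positive = 0L, precision = NA_real_, recall = 0))
  }
  cp <- canonical_pairs(predicted[, 1L], predicted[, 2L])
  tp <- sum(pair_key(cp[, 1L], cp[, 2L]) %in% hid)
  list(n_predicted = n, n_hidden = length(hid), true_positive = tp,
       precision = tp / n, recall = tp / length(hid))
}

#' Write all scenario inputs in the standard on-disk dialects
#'
#' Emits the observed network, expression TSV, OBO, GAF, essential list
#' and scored reference set into a directory, in exactly the formats the
#' readers of this package consume.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    observed = file.path(dir, "observed_ppi.tsv"),
    truth = file.path(dir, "truth_ppi.tsv"),
    expression = file.path(dir, "expression.tsv"),
    obo = file.path(dir, "ontology.obo"),
    gaf = file.path(dir, "annotations.gaf"),
    essential = file.path(dir, "essential.txt"),
    reference = file.path(dir, "reference.tsv"))
  write_edge_list(scenario$observed, paths[["observed"]])
  write_edge_list(scenario$truth, paths[["truth"]])
  expr_df <- data.frame(gene = rownames(scenario$expr),
                        scenario$expr, check.names = FALSE)
  utils::write.table(expr_df, paths[["expression"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # regenerate the OBO text of the scenario's toy ontology
  ob <- build_obo_lines_from_dag(scenario$dag)
  writeLines(ob, paths[["obo"]])
  writeLines(gaf_lines_from_annotation(scenario$ann), paths[["gaf"]])
  writeLines(scenario$essential, paths[["essential"]])
  write_edge_list(scenario$reference, paths[["reference"]])
  paths
}

build_obo_lines_from_dag <- function(dag) {
  lines <- c("format-version: 1.2")
  ns_long <- c(BP = "biological_process", CC = "cellular_component",
               MF = "molecular_function")
  for (id in names(dag$terms)) {
    tm <- dag$terms[[id]]
    rel <- character()
    for (i in seq_along(tm$parents)) {
      rel <- c(rel, if (tm$relation[[i]] == "is_a")
        sprintf("is_a: %s", tm$parents[[i]])
        else sprintf("relationship: part_of %s", tm$parents[[i]]))
    }
    lines <- c(lines, "", "[Term]", sprintf("id: %s", id),
               sprintf("name: %s", id),
               sprintf("namespace: %s",
                       if (tm$namespace %in% names(ns_long))
                         ns_long[[tm$namespace]] else tm$namespace),
               rel,
               if (tm$obsolete) "is_obsolete: true")
  }
  lines
}

gaf_lines_from_annotation <- function(ann) {
  rows <- character()
  for (p in names(ann)) for (t in ann[[p]]) {
    f <- rep("", 17L)
    f[1L] <- "EDGEFILL"; f[2L] <- p; f[3L] <- p; f[5L] <- t
    f[6L] <- "SYN:0000000"; f[7L] <- "IEA"; f[9L] <- "P"; f[12L] <- "protein"
    f[13L] <- "taxon:4932"; f[14L] <- "20260101"; f[15L] <- "EDGEFILL"
    rows <- c(rows, paste(f, collapse = "\t"))
  }
  c("!gaf-version: 2.1", rows)
}
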