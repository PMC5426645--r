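#' Run the full two-stage pipeline
#'
#' Orchestrates predict, augment, rank (original plus two augmented
#' networks), top-K set-difference tables, rescued-candidate selection,
#' incident-edge selection, reference validation and the random-walk
#' baseline comparison, writing every intermediate artifact to
#' `out_dir`.  Identical configuration and seed give identical outputs.
#'
#' The configuration mirrors the two-network design of the method: by
#' default network 1 applies only the correlation threshold (0.98) and
#' network 2 combines a lower correlation threshold (0.95) with a GO
#' similarity threshold (0.5).
#'
#' @param config a named list or the path of a YAML file with entries:
#'   `network`, `expression`, `obo`, `gaf`, `essential`, `reference`
#'   (input paths); `namespace` (default `"BP"`); `network1` and
#'   `network2` (each a list `pcc_threshold`, `go_threshold`); `K`
#'   (default 200), `R` (default 1000), `methods` (default DC, NC, SC);
#'   `baselines` (list `restart`, `steps`); `out_dir`; `seed`.
#' @return Object of class `stage_two_report` (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    namespace = "BP",
    network1 = list(pcc_threshold = 0.98, go_threshold = 0),
    network2 = list(pcc_threshold = 0.95, go_threshold = 0.5),
    K = 200L, R = 1000L, methods = c("DC", "NC", "SC"),
    baselines = list(restart = 0.8, steps = 3L),
    min_conf = 0.7, seed = 1L), config)
  for (f in c("network", "expression", "essential", "reference", "out_dir"))
    if (is.null(cfg[[f]])) stop("config entry missing: ", f)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s (artifacts so far: %s)",
                   name, conditionMessage(e),
                   paste(list.files(cfg$out_dir), collapse = ", ")),
           call. = FALSE)
    })
  }

  net <- stage("read inputs", read_edge_list(cfg$network))
  expr <- stage("read inputs", read_expression(cfg$expression))
  essential <- stage("read inputs", read_protein_list(cfg$essential))
  reference <- stage("read inputs", read_edge_list(cfg$reference, "scored"))
  need_go <- cfg$network1$go_threshold > 0 || cfg$network2$go_threshold > 0
  dag <- ann <- NULL
  if (need_go) {
    if (is.null(cfg$obo) || is.null(cfg$gaf))
      stop("GO thresholds require `obo` and `gaf` config entries")
    dag <- stage("read inputs", parse_obo(cfg$obo))
    ann <- stage("read inputs", read_gaf(cfg$gaf, cfg$namespace, dag))
  }
  message(sprintf("[predict] network: %d proteins, %d edges",
                  length(net$nodes), nrow(net$edges)))

  fits <- stage("predict", lapply(list(cfg$network1, cfg$network2), function(tc)
    predict_links(net, expr, ann, dag,
                  pcc_threshold = tc$pcc_threshold,
                  go_threshold = tc$go_threshold)))
  preds <- lapply(fits, `[[`, "predicted")
  for (i in 1:2) {
    message(sprintf("[predict] network %d: %d predicted links (proportion %.5f)",
                    i, nrow(preds[[i]]),
                    added_proportion(preds[[i]], net)))
    utils::write.table(preds[[i]],
                       file.path(cfg$out_dir, sprintf("predicted_net%d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  nets <- stage("augment", lapply(preds, function(p) augment_network(net, p)))
  for (i in 1:2)
    write_edge_list(nets[[i]],
                    file.path(cfg$out_dir, sprintf("network%d.tsv", i)))

  rank_all <- function(g) {
    out <- lapply(cfg$methods, function(m)
      rank_centrality(centrality(g, m), m))
    names(out) <- cfg$methods
    out
  }
  ranks <- stage("rank", list(ori = rank_all(net),
                              new1 = rank_all(nets[[1L]]),
                              new2 = rank_all(nets[[2L]])))
  for (nm in names(ranks)) for (m in cfg$methods)
    utils::write.table(ranks[[nm]][[m]],
                       file.path(cfg$out_dir,
                                 sprintf("ranking_%s_%s.tsv", nm, m)),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  sdt <- stage("set differences", do.call(rbind, lapply(cfg$methods, function(m) {
    rows <- lapply(1:2, function(i)
      cbind(method = m, network = sprintf("new%d", i),
            set_difference_table(ranks$ori[[m]],
                                 ranks[[sprintf("new%d", i)]][[m]],
                                 K = cfg$K, essential = essential)))
    do.call(rbind, rows)
  })))
  utils::write.table(sdt, file.path(cfg$out_dir, "set_differences.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cand <- stage("select candidates",
                select_candidates(ranks$ori, ranks$new1, ranks$new2,
                                  methods = cfg$methods, K = cfg$K, R = cfg$R,
                                  essential = essential))
  deep <- cand$protein[cand$deep_ranked]
  message(sprintf("[stage2] %d qualifying candidates, %d deep-ranked",
                  nrow(cand), length(deep)))
  utils::write.table(cand, file.path(cfg$out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  selected <- stage("select edges", lapply(preds, function(p)
    suppressWarnings(incident_predicted_edges(deep, p))))
  validation <- stage("validate", lapply(1:2, function(i) {
    tot <- suppressWarnings(validate_edges(preds[[i]], reference, cfg$min_conf))
    sel <- suppressWarnings(validate_edges(selected[[i]], reference, cfg$min_conf))
    # an empty reference set cannot define a confirmation fraction
    if (nrow(reference$pairs) == 0L) tot$fraction <- sel$fraction <- NA_real_
    list(network = sprintf("new%d", i),
         total = tot[c("n", "confirmed", "fraction")],
         selected = sel[c("n", "confirmed", "fraction")])
  }))

  prop1 <- added_proportion(preds[[1L]], net)
  baselines <- stage("baselines", {
    sims <- list(RWR = rwr_scores(net, restart = cfg$baselines$restart),
                 LRW = lrw_scores(net, steps = cfg$baselines$steps))
    lapply(sims, function(s) {
      bp <- predict_by_proportion(s, net, prop1)
      v <- suppressWarnings(validate_edges(bp, reference, cfg$min_conf))
      list(n = v$n, confirmed = v$confirmed, fraction = v$fraction)
    })
  })

  report <- structure(list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    n_nodes = length(net$nodes), n_edges = nrow(net$edges),
    n_predicted = vapply(preds, nrow, 0L),
    proportions = vapply(preds, added_proportion, 0, original = net),
    set_differences = sdt,
    candidates = cand, deep_ranked = deep,
    validation = validation, baselines = baselines),
    class = "stage_two_report")
  jsonlite::write_json(report_to_list(report),
                       file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

report_to_list <- function(report) {
  r <- unclass(report)
  r$set_differences <- as.list(as.data.frame(r$set_differences))
  r$candidates <- as.list(as.data.frame(r$candidates))
  r
}

#' @export
print.stage_two_report <- function(x, ...) {
  cat(sprintf("stage_two_report: %d proteins, %d edges\n",
              x$n_nodes, x$n_edges))
  cat(sprintf("predicted links: network 1 %d (%.4f), network 2 %d (%.4f)\n",
              x$n_predicted[[1L]], x$proportions[[1L]],
              x$n_predicted[[2L]], x$proportions[[2L]]))
  cat(sprintf("candidates: %d qualifying, %d deep-ranked\n",
              nrow(x$candidates), length(x$deep_ranked)))
  for (v in x$validation)
    cat(sprintf("%s: total %d/%d (%.3f), selected %d/%d (%.3f)\n",
                v$network, v$total$confirmed, v$total$n, v$total$fraction,
                v$selected$confirmed, v$selected$n, v$selected$fraction))
  for (b in names(x$baselines))
    cat(sprintf("baseline %s: %d/%d (%.3f)\n", b,
                x$baselines[[b]]$confirmed, x$baselines[[b]]$n,
                x$baselines[[b]]$fraction))
  invisible(x)
}
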