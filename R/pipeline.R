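#' Run the full analysis pipeline
#'
#' Wires the stages together: ingest (or simulate) a multi-condition
#' inhibition tensor, build the union network, compute global statistics,
#' hierarchy scores and levels, the cross-condition conservation summary,
#' optional permutation null tests, and write a machine-readable report
#' plus exchange files.
#'
#' @param config either a path to a YAML file or a list, with elements:
#'   \describe{
#'     \item{input}{list(`format` = "wide"/"long", `paths` = named
#'       condition -> path mapping (wide) or path(s) (long), optional
#'       `metadata`, `strains`, `conditions`, `delim`).}
#'     \item{simulate}{alternative to `input`: arguments for
#'       [synthetic_config()]; `fixture = TRUE` uses
#'       [paper_scale_fixture()] instead.}
#'     \item{k_top}{top-producer count (default 4).}
#'     \item{levels}{`"tertile"` (default) or numeric thresholds
#'       `c(high, medium)`.}
#'     \item{nulls}{optional list(`statistic`, `family`, `n_perm`, `seed`,
#'       `k`) or a list of such lists.}
#'     \item{seed}{default seed for simulation/nulls.}
#'   }
#' @param out_dir output directory; created if needed. Writes
#'   `report.json`, `hierarchy.tsv`, `venn.tsv`, `network.sif`,
#'   `network.graphml`. `NULL` skips all file output.
#' @return invisibly, the report as a list (`analysis_report`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  if (!is.null(config$input)) {
    inp <- config$input
    tensor <- read_tensor(inp$paths, format = inp$format %||% "wide",
                          strains = inp$strains, conditions = inp$conditions,
                          delim = inp$delim, metadata = inp$metadata)
  } else if (!is.null(config$simulate)) {
    sim <- config$simulate
    tensor <- if (isTRUE(sim$fixture)) {
      paper_scale_fixture(seed = sim$seed %||% seed)
    } else {
      sim$fixture <- NULL
      sim$seed <- sim$seed %||% seed
      generate_tensor(do.call(synthetic_config, sim))$tensor
    }
  } else stop("config must contain either `input` or `simulate`")

  network <- union_network(tensor)
  k_top <- config$k_top %||% 4
  stats <- network_stats(network, k_top = k_top)
  hier <- hierarchy_scores(network)
  hier <- if (is.numeric(config$levels))
    assign_levels(hier, "thresholds", thresholds = config$levels)
  else assign_levels(hier, "tertile")
  cons <- conservation_summary(tensor)
  recl <- classify_reciprocal(network)
  nonh <- if (n_edges(network) > 0) nonhierarchical_fraction(network)
          else list(edge_count = 0L, fraction = NA_real_,
                    percent = NA_integer_)

  null_cfgs <- config$nulls
  if (!is.null(null_cfgs) && !is.null(null_cfgs$statistic))
    null_cfgs <- list(null_cfgs)
  null_results <- lapply(null_cfgs, function(nc) {
    null_test(network,
              statistic = nc$statistic %||% "top_k_share",
              family = nc$family %||% "both-margins",
              n_perm = nc$n_perm %||% 999,
              seed = nc$seed %||% seed,
              k = nc$k %||% k_top,
              direction = nc$direction %||% "greater")
  })

  report <- list(
    schema_version = "1.0",
    provenance = list(
      tool = "inhibnet",
      version = as.character(utils::packageVersion("inhibnet")),
      seed = seed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      input = if (!is.null(config$input)) config$input$paths else "simulated"),
    stats = list(
      n_strains = stats$n_strains,
      n_edges = stats$n_edges,
      connectance = stats$connectance,
      connectance_rounded = round(stats$connectance, 2),
      asymmetry_q = stats$asymmetry_q,
      mean_partners = stats$mean_partners,
      mean_partners_rounded = round(stats$mean_partners, 1),
      out_degree = stats$degrees$out_degree,
      in_degree = stats$degrees$in_degree,
      n_reciprocal_pairs = nrow(stats$reciprocal_pairs),
      nonhierarchical_percent = nonh$percent,
      top_k = stats$top_k),
    hierarchy = hier$table,
    conservation = list(
      support_histogram = as.list(cons$support_histogram),
      venn_counts = as.list(cons$venn_counts),
      conserved_at_least = cons$conserved_at_least),
    reciprocal_classes = recl,
    null_tests = lapply(null_results, function(r)
      r[c("statistic", "observed", "p_value", "direction", "family",
          "n_perm", "n_excluded", "seed")])
  )
  class(report) <- "analysis_report"

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    utils::write.table(hier$table, file.path(out_dir, "hierarchy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(subset = names(cons$venn_counts),
                 count = as.integer(cons$venn_counts)),
      file.path(out_dir, "venn.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_sif(network, file.path(out_dir, "network.sif"))
    write_graphml(network, file.path(out_dir, "network.graphml"),
                  hierarchy = hier)
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.analysis_report <- function(x, ...) {
  cat("Inhibition-network analysis report (schema", x$schema_version, ")\n")
  cat(sprintf("  %d strains, %d edges; C = %.2f; Q = %s\n",
              x$stats$n_strains, x$stats$n_edges, x$stats$connectance,
              ifelse(is.na(x$stats$asymmetry_q), "undefined",
                     sprintf("%.2f", x$stats$asymmetry_q))))
  cat(sprintf("  top-%d producers: %d edges (%d%%); nonhierarchical %s%%\n",
              x$stats$top_k$k, x$stats$top_k$edge_count,
              x$stats$top_k$percent, x$stats$nonhierarchical_percent))
  if (length(x$null_tests))
    for (nt in x$null_tests)
      cat(sprintf("  null %s vs %s: p = %.4g\n", nt$statistic, nt$family,
                  nt$p_value))
  invisible(x)
}
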