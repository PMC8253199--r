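#' Pipeline configuration
#'
#' Assembles and validates the full set of analysis choices for
#' [run_pipeline()], so that every decision point of a run (lag order,
#' significance level, variance estimator, weight mode, multiplicity
#' correction, stationarity handling, seed) is explicit, serializable and
#' echoed into the output bundle. Either `input` (a [panel_dataset()] or a
#' file path readable by [read_panel()]) or `preset` (a diet-condition name
#' for [diet_study_preset()]) must be given.
#'
#' @param input a [panel_dataset()], or a path to a long-layout panel file.
#' @param preset `"regular"`, `"low"` or `"high"`: generate input from
#'   [diet_study_preset()] instead of reading it.
#' @param conditions condition filter (default: all conditions present).
#' @param lag_order Granger lag order.
#' @param alpha significance threshold for edges and stationarity tests.
#' @param variance `"clustered"` or `"bootstrap"`.
#' @param n_boot bootstrap draws when `variance = "bootstrap"`.
#' @param weight_mode adjacency weight mode (see [build_adjacency()]).
#' @param correction `"none"` or `"BH"` multiplicity correction.
#' @param moments LLC moments mode (`"simulated"` or `"tabulated"`).
#' @param llc_nrep calibration replicates for simulated LLC moments.
#' @param max_diff maximum differencing rounds in [ensure_stationary()].
#' @param skip_stationarity bypass the stationarity screen (used for
#'   graph-layer self-consistency checks).
#' @param seed integer seed governing every stochastic step of the run.
#' @param out_dir output directory (created if needed); `NULL` for an
#'   in-memory run without file outputs.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, preset = NULL, conditions = NULL,
                            lag_order = 1L, alpha = 0.05,
                            variance = c("clustered", "bootstrap"),
                            n_boot = 199L,
                            weight_mode = c("wald", "one_minus_p", "coef"),
                            correction = c("none", "BH"),
                            moments = c("simulated", "tabulated"),
                            llc_nrep = 2000L, max_diff = 2L,
                            skip_stationarity = FALSE,
                            seed = 1L, out_dir = NULL) {
  if (is.null(input) && is.null(preset)) stop_("one of `input` or `preset` is required")
  if (!is.null(preset)) preset <- match.arg(preset, c("regular", "low", "high"))
  cfg <- list(input = input, preset = preset, conditions = conditions,
              lag_order = as.integer(lag_order), alpha = alpha,
              variance = match.arg(variance), n_boot = as.integer(n_boot),
              weight_mode = match.arg(weight_mode),
              correction = match.arg(correction),
              moments = match.arg(moments), llc_nrep = as.integer(llc_nrep),
              max_diff = as.integer(max_diff),
              skip_stationarity = isTRUE(skip_stationarity),
              seed = as.integer(seed), out_dir = out_dir)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_("`alpha` must be in (0, 1)")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML or JSON file
#'
#' @param path file path (`.json` parsed as JSON, otherwise YAML).
#' @param ... overrides applied on top of the file's values.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

config_echo <- function(cfg) {
  out <- unclass(cfg)
  out$input <- if (inherits(cfg$input, "panel_dataset")) "<in-memory panel_dataset>" else cfg$input
  out
}

#' Run the full network-inference pipeline
#'
#' Executes, per condition: load or generate the panel, enforce
#' stationarity (LLC screen with differencing, unless bypassed), test all
#' ordered variable pairs for panel Granger causality, threshold into a
#' weighted adjacency network, and compute the centrality report. When
#' `out_dir` is set, each condition's bundle is written under
#' `out_dir/<condition>/`: `stationarity_log.tsv`, `pairwise.tsv`,
#' `adjacency.tsv`, `centrality.tsv`, `density.json`, `network.graphml`,
#' `edges.tsv`, plus a shared `config.json` and `run_log.txt` recording
#' test and edge counts. Two runs with the same configuration and seed
#' produce identical bundles.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list of per-condition bundles, each with `panel`
#'   (post-transformation), `stationarity_log`, `pairwise` (`granger_set`),
#'   `network`, `report` ([centrality_report()]), `hubs`, plus attribute
#'   fields `config` and `truth` (preset runs only).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$preset)) {
    spec <- diet_study_preset(config$preset, seed = config$seed)
    sim <- simulate_panel_var(spec, condition = config$preset)
    panel <- sim$panel
    truth <- sim$truth
  } else if (inherits(config$input, "panel_dataset")) {
    panel <- config$input
  } else {
    panel <- read_panel(config$input, layout = "long")
  }
  conditions <- config$conditions %||% panel$conditions
  log_lines <- c(sprintf("phosnet pipeline (seed %d)", config$seed))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  bundles <- list()
  for (cond in conditions) {
    stage <- "load"
    bundle <- tryCatch({
      pc <- if (length(panel$conditions) > 1L) filter_condition(panel, cond) else panel
      stage <- "stationarity"
      if (config$skip_stationarity) {
        st <- list(panel = pc,
                   log = data.frame(variable = pc$variables, diff_order = 0L,
                                    p_value_final = NA_real_, stationary = NA,
                                    stringsAsFactors = FALSE))
      } else {
        st <- ensure_stationary(pc, alpha = config$alpha,
                                max_diff = config$max_diff,
                                moments = config$moments,
                                nrep = config$llc_nrep, seed = config$seed)
      }
      stage <- "granger"
      gs <- pairwise_granger(st$panel, p = config$lag_order,
                             variance = config$variance,
                             n_boot = config$n_boot, seed = config$seed)
      stage <- "network"
      net <- suppressWarnings(
        build_adjacency(gs, alpha = config$alpha,
                        weight_mode = config$weight_mode,
                        correction = config$correction,
                        nodes = st$panel$variables))
      rep_ <- centrality_report(net)
      list(condition = cond, panel = st$panel, stationarity_log = st$log,
           pairwise = gs, network = net, report = rep_,
           hubs = hub_report(rep_))
    }, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(sprintf("FAILED at stage '%s' (condition %s): %s",
                           stage, cond, conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      stop_("pipeline stage '%s' failed for condition '%s': %s",
            stage, cond, conditionMessage(e))
    })
    n_tests <- length(bundle$pairwise$results)
    n_sig <- edge_count(bundle$network)
    log_lines <- c(log_lines,
                   sprintf("condition %s: %d Granger tests, %d significant edge(s), density %.4f",
                           cond, n_tests, n_sig, bundle$report$density))
    if (!is.null(out_dir)) {
      cdir <- file.path(out_dir, cond)
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      write_tsv <- function(df, name) {
        utils::write.table(df, file.path(cdir, name), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      write_tsv(bundle$stationarity_log, "stationarity_log.tsv")
      write_tsv(as.data.frame(bundle$pairwise), "pairwise.tsv")
      adj <- as.data.frame(bundle$network$weights)
      adj <- cbind(cause = rownames(bundle$network$weights), adj)
      write_tsv(adj, "adjacency.tsv")
      write_tsv(bundle$report$table, "centrality.tsv")
      jsonlite::write_json(list(condition = cond,
                                density = bundle$report$density,
                                edge_count = bundle$report$edge_count,
                                n_tests = n_tests),
                           file.path(cdir, "density.json"),
                           auto_unbox = TRUE, digits = NA)
      export_graph(bundle$network, file.path(cdir, "network.graphml"), "graphml")
      export_graph(bundle$network, file.path(cdir, "edges.tsv"), "edgelist-tsv")
    }
    bundles[[cond]] <- bundle
  }
  if (!is.null(out_dir)) {
    jsonlite::write_json(config_echo(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  structure(bundles, config = config, truth = truth, log = log_lines,
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (ln in attr(x, "log")) cat(" ", ln, "\n")
  invisible(x)
}

#' Edge-set precision, recall and F1 against a ground-truth network
#'
#' Compares the support (nonzero cells) of an inferred [causal_network()]
#' with a ground-truth network over the same nodes.
#'
#' @param inferred,truth [causal_network()] objects with identical node
#'   sets.
#' @return named numeric vector `c(tp, fp, fn, precision, recall, f1)`.
#'   With an empty truth and empty inference, F1 is defined as 1.
#' @export
edge_f1 <- function(inferred, truth) {
  stopifnot(inherits(inferred, "causal_network"), inherits(truth, "causal_network"))
  if (!identical(sort(inferred$nodes), sort(truth$nodes))) {
    stop_("node sets differ")
  }
  A <- binary_adj(inferred)
  B <- binary_adj(truth)[inferred$nodes, inferred$nodes]
  tp <- sum(A == 1 & B == 1)
  fp <- sum(A == 1 & B == 0)
  fn <- sum(A == 0 & B == 1)
  prec <- if (tp + fp == 0) 1 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1)
}
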