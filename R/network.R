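#' Weighted directed causal network
#'
#' An `n x n` weighted adjacency matrix over named nodes with a zero
#' diagonal; row index is the cause, column index the effect. A weight of 0
#' means no edge; larger weights mean stronger evidence of Granger
#' causality. All weights are nonnegative.
#'
#' @param weights square numeric matrix (rownames/colnames used as node
#'   names if present).
#' @param nodes optional character vector of node names.
#' @param alpha the significance threshold the network was built at
#'   (`NA` for e.g. ground-truth networks).
#' @param weight_mode how weights were derived: `"wald"` (Wald statistic),
#'   `"one_minus_p"` (1 - p-value), `"coef"` (absolute lag-1 coefficient),
#'   or `"binary"`.
#' @return an object of class `causal_network` with fields `nodes`,
#'   `weights`, `alpha`, `weight_mode`.
#' @export
causal_network <- function(weights, nodes = NULL, alpha = NA_real_,
                           weight_mode = "wald") {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop_("`weights` must be square")
  n <- nrow(weights)
  if (is.null(nodes)) nodes <- rownames(weights) %||% paste0("v", seq_len(n))
  stopifnot(length(nodes) == n, !anyDuplicated(nodes))
  dimnames(weights) <- list(nodes, nodes)
  if (any(!is.finite(weights))) stop_("weights must be finite")
  if (any(weights < 0)) stop_("weights must be nonnegative")
  if (any(diag(weights) != 0)) stop_("diagonal (self-loop) weights must be zero")
  structure(list(nodes = nodes, weights = weights, alpha = alpha,
                 weight_mode = weight_mode),
            class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf("<causal_network> %d nodes, %d edge(s), density %.3f (weight mode: %s)\n",
              length(x$nodes), edge_count(x), graph_density(x), x$weight_mode))
  invisible(x)
}

edge_count <- function(net) sum(net$weights > 0)

binary_adj <- function(net) (net$weights > 0) * 1L

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights, mode = "directed",
                                      weighted = TRUE, diag = FALSE)
}

#' Build a weighted adjacency network from pairwise Granger results
#'
#' Thresholds a set of ordered-pair Granger tests at significance level
#' `alpha` and records, for each significant pair, a nonnegative strength:
#' the Wald statistic (default, "the larger the stronger"), `1 - p`, or the
#' absolute bias-corrected first cross-lag coefficient. Non-significant
#' pairs get weight 0. Optional Benjamini-Hochberg correction is applied
#' across the supplied family of tests before thresholding.
#'
#' @param results list of `granger_pair` results (see [granger_test()]), or
#'   a `granger_set` from [pairwise_granger()].
#' @param alpha significance threshold (per-pair by default).
#' @param weight_mode `"wald"`, `"one_minus_p"` or `"coef"`.
#' @param correction `"none"` (default) or `"BH"`.
#' @param nodes optional node ordering; defaults to order of appearance.
#' @return a [causal_network()].
#' @export
build_adjacency <- function(results, alpha = 0.05,
                            weight_mode = c("wald", "one_minus_p", "coef"),
                            correction = c("none", "BH"), nodes = NULL) {
  weight_mode <- match.arg(weight_mode)
  correction <- match.arg(correction)
  if (inherits(results, "granger_set")) results <- results$results
  stopifnot(length(results) > 0)
  cause <- vapply(results, `[[`, "", "cause")
  effect <- vapply(results, `[[`, "", "effect")
  pval <- vapply(results, `[[`, 0, "p_value")
  if (anyDuplicated(paste(cause, effect, sep = "\r"))) {
    stop_("duplicate (cause, effect) pair in results")
  }
  if (is.null(nodes)) nodes <- unique(c(rbind(cause, effect)))
  n <- length(nodes)
  expected <- n * (n - 1L)
  if (length(results) < expected) {
    warning(sprintf("results cover %d of %d ordered pairs; missing pairs treated as absent edges",
                    length(results), expected), call. = FALSE)
  }
  padj <- if (correction == "BH") stats::p.adjust(pval, "BH") else pval
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_along(results)) {
    if (is.na(padj[i]) || padj[i] >= alpha) next
    r <- results[[i]]
    w <- switch(weight_mode,
                wald = r$wald,
                one_minus_p = 1 - r$p_value,
                coef = abs(r$theta_hpj[r$lag_order + 1L]))
    W[r$cause, r$effect] <- w
  }
  net <- causal_network(W, nodes = nodes, alpha = alpha, weight_mode = weight_mode)
  net$correction <- correction
  net
}

#' In/out degree centralities of a causal network
#'
#' Degree centrality divides the number of incoming (resp. outgoing) edges
#' of each node by `n - 1`, the number of possible counterpart nodes, so
#' both centralities lie in `[0, 1]`. Computed on the binary (thresholded)
#' graph; full precision is returned, rounding is a report-layer concern.
#'
#' @param net a [causal_network()].
#' @return data.frame with columns `node`, `in_count`, `out_count`,
#'   `indegree_centrality`, `outdegree_centrality`.
#' @export
degree_centralities <- function(net) {
  stopifnot(inherits(net, "causal_network"))
  B <- binary_adj(net)
  n <- nrow(B)
  if (n < 2L) stop_("need at least 2 nodes")
  data.frame(node = net$nodes,
             in_count = unname(colSums(B)),
             out_count = unname(rowSums(B)),
             indegree_centrality = unname(colSums(B)) / (n - 1),
             outdegree_centrality = unname(rowSums(B)) / (n - 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Directed betweenness centrality
#'
#' Unweighted (edge-presence) shortest-path betweenness on the directed
#' graph: for each node `v`, the sum over ordered pairs `(s, t)` of the
#' fraction of shortest directed `s -> t` paths passing through `v`
#' (pairs with no connecting path contribute 0), normalized by
#' `(n-1)(n-2)` so values lie in `[0, 1]`. Set `normalized = FALSE` for the
#' raw pair-fraction sums.
#'
#' @param net a [causal_network()].
#' @param normalized divide by `(n-1)(n-2)`? Default `TRUE`.
#' @return named numeric vector of per-node betweenness values.
#' @export
betweenness_centrality <- function(net, normalized = TRUE) {
  stopifnot(inherits(net, "causal_network"))
  n <- length(net$nodes)
  g <- igraph::graph_from_adjacency_matrix(binary_adj(net), mode = "directed")
  b <- igraph::betweenness(g, directed = TRUE, weights = NULL, normalized = FALSE)
  if (normalized && n > 2L) b <- b / ((n - 1) * (n - 2))
  stats::setNames(as.numeric(b), net$nodes)
}

#' Density of a directed graph
#'
#' The number of realized directed edges divided by the `n(n-1)` possible
#' ones — the standard summary of overall network complexity.
#'
#' @param net a [causal_network()].
#' @return a probability in `[0, 1]`.
#' @export
graph_density <- function(net) {
  stopifnot(inherits(net, "causal_network"))
  n <- length(net$nodes)
  if (n < 2L) stop_("need at least 2 nodes")
  edge_count(net) / (n * (n - 1))
}

#' @export
density.causal_network <- function(x, ...) graph_density(x)

#' Per-node centrality report for a causal network
#'
#' Bundles betweenness, in/out degree centralities, edge count and density,
#' with per-metric rankings (ties reported as ties via min-rank).
#'
#' @param net a [causal_network()].
#' @return an object of class `centrality_report`: list with `table`
#'   (data.frame: node, betweenness, outdegree_centrality,
#'   indegree_centrality, in_count, out_count), `density`, `edge_count`,
#'   `n_nodes`, and `rankings` (list of node orderings per metric).
#' @export
centrality_report <- function(net) {
  stopifnot(inherits(net, "causal_network"))
  deg <- degree_centralities(net)
  btw <- betweenness_centrality(net)
  tab <- data.frame(node = net$nodes,
                    betweenness = as.numeric(btw[net$nodes]),
                    outdegree_centrality = deg$outdegree_centrality,
                    indegree_centrality = deg$indegree_centrality,
                    out_count = deg$out_count,
                    in_count = deg$in_count,
                    row.names = NULL, stringsAsFactors = FALSE)
  rank_of <- function(v) net$nodes[order(-v, seq_along(v))]
  structure(list(
    table = tab,
    density = graph_density(net),
    edge_count = edge_count(net),
    n_nodes = length(net$nodes),
    rankings = list(betweenness = rank_of(tab$betweenness),
                    outdegree = rank_of(tab$outdegree_centrality),
                    indegree = rank_of(tab$indegree_centrality))
  ), class = "centrality_report")
}

#' @export
print.centrality_report <- function(x, digits = 2, ...) {
  cat(sprintf("<centrality_report> %d nodes, %d edges, density %s\n",
              x$n_nodes, x$edge_count, format(round_half_up(x$density, digits))))
  tab <- x$table
  tab$betweenness <- round_half_up(tab$betweenness, digits)
  tab$outdegree_centrality <- round_half_up(tab$outdegree_centrality, digits)
  tab$indegree_centrality <- round_half_up(tab$indegree_centrality, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Top-ranked (hub) nodes per centrality metric
#'
#' Names the top node for each metric in a [centrality_report()]; exact
#' ties at the top are reported jointly.
#'
#' @param report a [centrality_report()].
#' @return data.frame with columns `metric`, `top_nodes`
#'   (comma-joined when tied), `value`.
#' @export
hub_report <- function(report) {
  stopifnot(inherits(report, "centrality_report"))
  tab <- report$table
  one <- function(metric, v) {
    mx <- max(v)
    data.frame(metric = metric,
               top_nodes = paste(tab$node[v == mx], collapse = ", "),
               value = mx, stringsAsFactors = FALSE)
  }
  rbind(one("betweenness", tab$betweenness),
        one("outdegree", tab$outdegree_centrality),
        one("indegree", tab$indegree_centrality))
}

#' Realize a directed graph with prescribed in/out degree sequences
#'
#' Constructs a simple digraph (no self-loops, no multi-edges) whose node
#' `i` has exactly `out_counts[i]` outgoing and `in_counts[i]` incoming
#' edges, via the standard maximum-flow bipartite construction (source ->
#' out-copies with capacity `out_counts`, in-copies -> sink with capacity
#' `in_counts`, unit arcs between distinct copies). Deterministic given the
#' input order; errors when the sequence is infeasible.
#'
#' @param out_counts,in_counts integer vectors of equal length `n` with
#'   equal sums and entries in `0..n-1`.
#' @param nodes optional node names.
#' @return a binary-weight [causal_network()].
#' @export
realize_degree_sequence <- function(out_counts, in_counts, nodes = NULL) {
  out_counts <- as.integer(out_counts); in_counts <- as.integer(in_counts)
  n <- length(out_counts)
  if (length(in_counts) != n) stop_("out_counts and in_counts must have equal length")
  if (is.null(nodes)) nodes <- paste0("v", seq_len(n))
  if (any(out_counts < 0L) || any(in_counts < 0L) ||
      any(out_counts > n - 1L) || any(in_counts > n - 1L)) {
    stop_("infeasible degree sequence: each count must lie in 0..n-1 (no self-loops or multi-edges)")
  }
  m <- sum(out_counts)
  if (m != sum(in_counts)) {
    stop_("infeasible degree sequence: sum(out) = %d differs from sum(in) = %d",
          m, sum(in_counts))
  }
  W <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  if (m > 0L) {
    # vertices: 1 = source, 2..n+1 = out-copies, n+2..2n+1 = in-copies, 2n+2 = sink
    src <- 1L; snk <- 2L * n + 2L
    mid_from <- integer(0); mid_to <- integer(0)
    for (i in seq_len(n)) {
      js <- setdiff(seq_len(n), i)
      mid_from <- c(mid_from, rep(1L + i, n - 1L))
      mid_to <- c(mid_to, n + 1L + js)
    }
    edges <- rbind(cbind(rep(src, n), 1L + seq_len(n)),
                   cbind(mid_from, mid_to),
                   cbind(n + 1L + seq_len(n), rep(snk, n)))
    caps <- c(out_counts, rep(1L, length(mid_from)), in_counts)
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    fl <- igraph::max_flow(g, source = src, target = snk, capacity = caps)
    if (abs(fl$value - m) > 1e-9) {
      stop_("infeasible degree sequence: maximum realizable edge count is %d of the requested %d (Gale-Ryser condition violated)",
            as.integer(round(fl$value)), m)
    }
    midx <- n + seq_len(length(mid_from))
    used <- fl$flow[midx] > 0.5
    W[cbind(mid_from[used] - 1L, mid_to[used] - n - 1L)] <- 1L
  }
  causal_network(W, nodes = nodes, alpha = NA_real_, weight_mode = "binary")
}

#' Export a causal network to a file
#'
#' `edgelist-tsv` writes a tab-separated edge list (`cause`, `effect`,
#' `weight`) preceded by a `# nodes:` comment line recording the full node
#' set (so isolated nodes survive a round trip via [read_edgelist()]);
#' `graphml` and `dot` delegate to [igraph::write_graph()] with node names
#' and edge weights attached.
#'
#' @param net a [causal_network()].
#' @param path output file path.
#' @param format `"edgelist-tsv"`, `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("edgelist-tsv", "graphml", "dot")) {
  stopifnot(inherits(net, "causal_network"))
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_("unknown export format '%s'", format[1]))
  if (format == "edgelist-tsv") {
    idx <- which(net$weights > 0, arr.ind = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# nodes: ", paste(net$nodes, collapse = "\t")), con)
    writeLines("cause\teffect\tweight", con)
    if (nrow(idx)) {
      ord <- order(idx[, 1], idx[, 2])
      idx <- idx[ord, , drop = FALSE]
      writeLines(sprintf("%s\t%s\t%s", net$nodes[idx[, 1]], net$nodes[idx[, 2]],
                         formatC(net$weights[idx], digits = 17, format = "g")), con)
    }
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = if (format == "graphml") "graphml" else "dot")
  }
  invisible(path)
}

#' Read a causal network from an edge-list TSV written by [export_graph()]
#'
#' @param path file path.
#' @param alpha,weight_mode metadata to attach to the reconstructed network.
#' @return a [causal_network()].
#' @export
read_edgelist <- function(path, alpha = NA_real_, weight_mode = "wald") {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# nodes:")) {
    stop_("not an edge-list file written by export_graph(): %s", path)
  }
  nodes <- strsplit(sub("^# nodes: ", "", lines[1]), "\t")[[1]]
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (length(lines) > 2L) {
    df <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    W[cbind(match(df$cause, nodes), match(df$effect, nodes))] <- df$weight
  }
  causal_network(W, nodes = nodes, alpha = alpha, weight_mode = weight_mode)
}
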