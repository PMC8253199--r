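fake_pair <- function(cause, effect, p, wald = 5, beta = 0.4) {
  structure(list(cause = cause, effect = effect, lag_order = 1L,
                 theta_within = c(0.1, beta), theta_hpj = c(0.1, beta),
                 wald = wald, df = 1L, p_value = p, n_effective = 48L,
                 variance_mode = "clustered"),
            class = "granger_pair")
}

test_that("adjacency construction thresholds and weights as documented", {
  rs <- list(fake_pair("a", "b", p = 0.008, wald = 7.1),
             fake_pair("b", "a", p = 0.20, wald = 1.1),
             fake_pair("a", "c", p = 0.51, wald = 0.2),
             fake_pair("c", "a", p = 0.03, wald = 4.9, beta = 0.33),
             fake_pair("b", "c", p = 0.70, wald = 0.1),
             fake_pair("c", "b", p = 0.90, wald = 0.0))
  net <- build_adjacency(rs, alpha = 0.05, weight_mode = "wald")
  expect_equal(net$weights["a", "b"], 7.1)
  expect_equal(net$weights["c", "a"], 4.9)
  expect_equal(sum(net$weights > 0), 2L)
  expect_equal(diag(net$weights), c(a = 0, b = 0, c = 0))
  # one_minus_p weights of significant edges exceed 1 - alpha
  net2 <- build_adjacency(rs, alpha = 0.05, weight_mode = "one_minus_p")
  w <- net2$weights[net2$weights > 0]
  expect_true(all(w > 0.95 & w <= 1))
  net3 <- build_adjacency(rs, alpha = 0.05, weight_mode = "coef")
  expect_equal(net3$weights["c", "a"], 0.33)
  # all p >= alpha -> zero matrix
  net0 <- build_adjacency(rs, alpha = 0.001)
  expect_equal(sum(net0$weights), 0)
  # BH correction can only remove edges
  netbh <- build_adjacency(rs, alpha = 0.05, correction = "BH")
  expect_true(all(netbh$weights[net$weights == 0] == 0))
  expect_error(build_adjacency(c(rs, list(fake_pair("a", "b", 0.01)))),
               "duplicate")
  expect_warning(build_adjacency(rs[1:3]), "missing pairs")
})

test_that("degree centralities divide the counts the panel-study way", {
  W <- matrix(0, 8, 8)
  W[1:5, 8] <- 1   # node 8 receives 5 of its 7 possible incoming edges
  W[2, 1:6] <- 1; W[2, 2] <- 0
  net <- causal_network(W, weight_mode = "binary")
  deg <- degree_centralities(net)
  expect_equal(round_half_up(deg$indegree_centrality[8], 2), 0.71)
  W2 <- matrix(0, 8, 8); W2[2:7, 1] <- 1
  expect_equal(round_half_up(
    degree_centralities(causal_network(W2))$indegree_centrality[1], 2), 0.86)
  # isolated node
  expect_equal(deg$indegree_centrality[7], 0)
  expect_equal(deg$outdegree_centrality[7], 0)
  # conservation: total in = total out = edge count
  expect_equal(sum(deg$in_count), sum(deg$out_count))
  expect_equal(sum(deg$in_count), sum(net$weights > 0))
})

test_that("betweenness handles the canonical small cases", {
  path3 <- causal_network(rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)),
                          nodes = c("a", "b", "c"))
  expect_equal(betweenness_centrality(path3),
               c(a = 0, b = 0.5, c = 0))
  expect_equal(unname(betweenness_centrality(path3, normalized = FALSE)),
               c(0, 1, 0))
  full <- causal_network(1 - diag(4))
  expect_equal(unname(betweenness_centrality(full)), rep(0, 4))
})

test_that("betweenness matches the exhaustive shortest-path oracle", {
  withr::local_seed(41)
  for (i in 1:30) {
    n <- 8
    B <- matrix(rbinom(n * n, 1, 0.25), n, n); diag(B) <- 0
    net <- causal_network(B)
    expect_equal(unname(betweenness_centrality(net)), oracle_betweenness(B),
                 tolerance = 1e-12)
  }
})

test_that("density is the edge fraction and agrees with mean degree centrality", {
  prof <- diet_centrality_profiles()
  reg <- prof[prof$condition == "regular", ]
  net <- realize_degree_sequence(round(reg$out_degree * 7), round(reg$in_degree * 7),
                                 nodes = reg$variable)
  expect_equal(round_half_up(graph_density(net), 2), 0.46)
  deg <- degree_centralities(net)
  expect_equal(graph_density(net), mean(deg$indegree_centrality))
  expect_equal(graph_density(net), mean(deg$outdegree_centrality))
  expect_equal(graph_density(causal_network(matrix(0, 3, 3))), 0)
  expect_equal(graph_density(causal_network(1 - diag(3))), 1)
  expect_equal(density(net), graph_density(net))  # S3 convenience
})

test_that("degree-sequence realization is exact, deterministic, and honest about infeasibility", {
  net <- realize_degree_sequence(c(1, 0), c(0, 1))
  expect_equal(net$weights, matrix(c(0, 0, 1, 0), 2, 2,
                                   dimnames = list(c("v1", "v2"), c("v1", "v2"))))
  # 2-cycle forced by the no-self-loop constraint
  cyc <- realize_degree_sequence(c(1, 1), c(1, 1))
  expect_equal(unname(cyc$weights), rbind(c(0, 1), c(1, 0)))
  withr::local_seed(42)
  for (i in 1:20) {
    n <- 8
    B <- matrix(rbinom(n * n, 1, 0.3), n, n); diag(B) <- 0
    r <- realize_degree_sequence(rowSums(B), colSums(B))
    deg <- degree_centralities(r)
    expect_equal(deg$out_count, unname(rowSums(B)))
    expect_equal(deg$in_count, unname(colSums(B)))
  }
  r1 <- realize_degree_sequence(c(2, 1, 0, 1), c(1, 1, 1, 1))
  r2 <- realize_degree_sequence(c(2, 1, 0, 1), c(1, 1, 1, 1))
  expect_identical(r1$weights, r2$weights)
  expect_error(realize_degree_sequence(c(3, 0), c(0, 3)), "0..n-1")
  expect_error(realize_degree_sequence(c(1, 1), c(0, 1)), "differs")
  # sums match but the no-self-loop structure cannot host it
  expect_error(realize_degree_sequence(c(2, 0, 0), c(0, 2, 0), nodes = letters[1:3]),
               "infeasible|Gale")
})

test_that("hub report names top nodes and reports exact ties jointly", {
  zero <- centrality_report(causal_network(matrix(0, 3, 3), nodes = c("a", "b", "c")))
  h <- hub_report(zero)
  expect_equal(h$top_nodes[h$metric == "betweenness"], "a, b, c")
  one <- centrality_report(causal_network(rbind(c(0, 2.5), c(0, 0)),
                                          nodes = c("src", "snk")))
  h1 <- hub_report(one)
  expect_equal(h1$top_nodes[h1$metric == "outdegree"], "src")
  expect_equal(h1$top_nodes[h1$metric == "indegree"], "snk")
  withr::local_seed(43)
  B <- matrix(rbinom(64, 1, 0.4), 8, 8); diag(B) <- 0
  rep_ <- centrality_report(causal_network(B))
  hh <- hub_report(rep_)
  top_in <- strsplit(hh$top_nodes[hh$metric == "indegree"], ", ")[[1]]
  expect_true(all(colSums(B)[match(top_in, rep_$table$node)] == max(colSums(B))))
})

test_that("graph export round-trips and emits well-formed files", {
  withr::local_seed(44)
  W <- matrix(0, 5, 5)
  W[cbind(c(1, 2, 4), c(3, 5, 1))] <- c(2.25, 7.5, 0.125)
  net <- causal_network(W, nodes = letters[1:5], alpha = 0.05)
  dir <- withr::local_tempdir()
  ep <- file.path(dir, "edges.tsv")
  export_graph(net, ep, "edgelist-tsv")
  back <- read_edgelist(ep)
  expect_identical(back$weights, net$weights)
  # empty graph: header plus node list only
  empty <- causal_network(matrix(0, 3, 3))
  export_graph(empty, ep, "edgelist-tsv")
  expect_length(readLines(ep), 2L)
  expect_identical(read_edgelist(ep)$weights, empty$weights)
  gp <- file.path(dir, "net.graphml")
  export_graph(net, gp, "graphml")
  doc <- xml2::read_xml(gp)  # well-formed XML with all nodes present
  expect_equal(length(xml2::xml_find_all(doc, ".//d1:node", xml2::xml_ns(doc))), 5L)
  dp <- file.path(dir, "net.dot")
  export_graph(net, dp, "dot")
  dot <- readLines(dp)
  expect_match(paste(dot, collapse = "\n"), "digraph")
  expect_equal(sum(grepl("->", dot)), 3L)
  expect_error(export_graph(net, ep, "gexf"), "unknown")
})
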