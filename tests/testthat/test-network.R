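test_that("pairwise_correlations: duplicated metabolite correlates at 1", {
  set.seed(61)
  v <- rnorm(30, 10, 1)
  mat <- cbind(a = v, b = v + rnorm(30, 0, 0.01), dup = v)
  pairs <- pairwise_correlations(mat)
  expect_equal(nrow(pairs), 3)
  r_dup <- pairs$weight[pairs$m1 == "a" & pairs$m2 == "dup"]
  expect_equal(r_dup, 1.0, tolerance = 1e-6)
})

test_that("pairwise_correlations on independent columns stays near zero", {
  set.seed(62)
  mat <- matrix(rnorm(500 * 16), 500, 16,
                dimnames = list(NULL, sprintf("m%02d", 1:16)))
  pairs <- pairwise_correlations(mat)
  expect_gte(mean(abs(pairs$weight) < 0.15), 0.95)
})

test_that("short or degenerate pairs are flagged, not dropped", {
  mat <- cbind(a = c(1, 2, NA, NA), b = c(NA, NA, 1, 2), c = c(1, 2, 3, 4))
  pairs <- pairwise_correlations(mat)
  ab <- pairs[pairs$m1 == "a" & pairs$m2 == "b", ]
  expect_false(ab$ok)
  expect_true(is.na(ab$weight))
  expect_equal(ab$n_obs, 0)
})

test_that("planted block members correlate more than cross-block pairs", {
  m <- 20
  blocks <- c(rep("B1", 5), rep(NA, m - 5))
  rho <- rep(0.5, m)
  cfg <- simulation_config(n_glioma = 60, n_control = 40, n_metabolites = m,
                           rho_by_group = data.frame(rho_patient = rho,
                                                     rho_control = rho),
                           block_assignment = blocks, block_loading = 0.95,
                           seed = 63)
  flt <- filter_detected(ln_transform(average_replicates(
    simulate_dataset(cfg)$dataset)), 0.8)
  pairs <- pairwise_correlations(pooled_matrix(flt))
  in_b1 <- function(x) x %in% sprintf("met%03d", 1:5)
  within <- pairs$weight[in_b1(pairs$m1) & in_b1(pairs$m2)]
  cross <- pairs$weight[xor(in_b1(pairs$m1), in_b1(pairs$m2))]
  cmp <- outer(within, cross, ">")
  expect_gte(mean(cmp), 0.9)
})

test_that("build_graph applies the edge rule and keeps isolated vertices", {
  pairs <- data.frame(m1 = c("a", "a", "b"), m2 = c("b", "c", "c"),
                      weight = c(0.9, -0.8, 0.5),
                      p = c(0.001, 0.001, 0.2),
                      n_obs = 10L, ok = TRUE)
  g <- build_graph(pairs, edge_alpha = 0.05)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)        # only a-b: significant & positive
  g_abs <- build_graph(pairs, edge_alpha = 0.05, use_abs = TRUE)
  expect_equal(igraph::ecount(g_abs), 2)    # a-c re-enters
  g_all <- build_graph(pairs, edge_alpha = 1.0, positive_only = FALSE)
  expect_equal(igraph::ecount(g_all), 3)    # complete graph on 3 vertices
})

test_that("null-simulation edge count sits in the binomial band", {
  set.seed(64)
  n <- 400; m <- 12
  mat <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("m", 1:m)))
  pairs <- pairwise_correlations(mat)
  g <- build_graph(pairs, edge_alpha = 0.05, positive_only = TRUE)
  n_pairs <- choose(m, 2)
  expected <- 0.05 * n_pairs / 2          # sign filter halves the null rate
  band <- qbinom(c(0.005, 0.995), n_pairs, 0.025)
  expect_gte(igraph::ecount(g), band[1])
  expect_lte(igraph::ecount(g), band[2])
})

test_that("DC-SBM greedy fit matches exhaustive search on the two-clique instance", {
  g <- igraph::make_full_graph(10) + igraph::make_full_graph(10)
  g <- igraph::add_edges(g, c(1, 11))
  igraph::V(g)$name <- sprintf("v%02d", 1:20)
  orc <- oracle_dcsbm_exhaustive(g)
  fit <- fit_dcsbm(g, n_blocks = 2, n_restarts = 20, seed = 1)
  expect_equal(fit$description_length, orc$dl, tolerance = 1e-10)
  expect_equal(oracle_ari(unname(fit$membership), orc$membership), 1.0)
  # the optimum is the two cliques
  expect_equal(oracle_ari(orc$membership, rep(1:2, each = 10)), 1.0)
  # package DL function agrees with the oracle formula on this partition
  expect_equal(dcsbm_description_length(g, orc$membership), orc$dl,
               tolerance = 1e-10)
})

test_that("DC-SBM single-block DL is closed-form and ER graphs resist splitting", {
  set.seed(65)
  g <- igraph::sample_gnp(40, 0.15)
  igraph::V(g)$name <- paste0("v", 1:40)
  deg <- igraph::degree(g); E <- igraph::ecount(g); n <- 40
  # closed-form single-block DL written out independently
  S1 <- -E - sum(lgamma(deg + 1)) - 0.5 * (2 * E) * log((2 * E) / (2 * E)^2)
  dl1_oracle <- S1 + lchoose(E, E) + lchoose(n + 2 * E - 1, 2 * E) +
    lchoose(n - 1, 0) + 0
  expect_equal(dcsbm_description_length(g, rep(1, 40)), dl1_oracle,
               tolerance = 1e-10)
  # on ER graphs a 2-block fit should rarely beat the single block
  wins <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    ger <- igraph::sample_gnp(40, 0.15)
    igraph::V(ger)$name <- paste0("v", 1:40)
    fit2 <- fit_dcsbm(ger, 2, n_restarts = 5, seed = s)
    dl1 <- dcsbm_description_length(ger, rep(1, 40))
    if (fit2$description_length < dl1 - 1e-9 &&
        fit2$n_blocks_effective == 2) wins <- wins + 1
  }
  expect_lte(wins, 1)   # >= 90% of seeds stay single-block
})

test_that("DC-SBM recovers planted blocks and descends monotonically", {
  pg <- make_planted_graph(n_per_block = 30, p_in = 0.4, p_out = 0.05,
                           seed = 66)
  fit <- fit_dcsbm(pg$graph, 2, n_restarts = 10, seed = 2)
  expect_gte(oracle_ari(unname(fit$membership), pg$labels), 0.9)
  # the returned optimum is no worse than any restart and beats random
  expect_true(all(fit$restart_dl >= fit$description_length - 1e-9))
  set.seed(3)
  rand_dl <- replicate(50, dcsbm_description_length(
    pg$graph, sample(1:2, 60, replace = TRUE)))
  expect_lt(fit$description_length, min(rand_dl))
})

test_that("edgeless graphs yield a flagged single-block partition", {
  g <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(g)$name <- paste0("v", 1:5)
  fit <- fit_dcsbm(g, 2, seed = 1)
  expect_equal(fit$n_blocks_effective, 1)
  expect_match(fit$flag, "edgeless")
})

test_that("percentile_subgraph thresholds by interpolated percentile", {
  g <- igraph::make_ring(100)
  igraph::V(g)$name <- paste0("v", 1:100)
  igraph::E(g)$weight <- sample(1:100)
  ps <- percentile_subgraph(g, 0.95)
  expect_equal(ps$threshold, 95.05)
  expect_setequal(igraph::E(ps$graph)$weight, 96:100)
  # retained edge set is exactly {weight > threshold}
  ps2 <- percentile_subgraph(g, 0.5)
  expect_equal(ps2$threshold, 50.5)
  expect_setequal(igraph::E(ps2$graph)$weight, 51:100)
})

test_that("percentile_subgraph is monotone in q", {
  set.seed(67)
  g <- igraph::sample_gnp(30, 0.3)
  igraph::V(g)$name <- paste0("v", 1:30)
  igraph::E(g)$weight <- runif(igraph::ecount(g))
  edge_key <- function(gr) {
    el <- igraph::as_edgelist(gr)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  e50 <- edge_key(percentile_subgraph(g, 0.5)$graph)
  e80 <- edge_key(percentile_subgraph(g, 0.8)$graph)
  e95 <- edge_key(percentile_subgraph(g, 0.95)$graph)
  expect_true(all(e95 %in% e80))
  expect_true(all(e80 %in% e50))
})

test_that("connected_components agrees with a union-find oracle and has no cross edges", {
  # two triangles plus an isolated edge
  g <- igraph::graph_from_edgelist(
    rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6), c(7, 8)),
    directed = FALSE)
  igraph::V(g)$name <- paste0("v", 1:8)
  cs <- connected_components(g, min_vertices = 3)
  expect_length(cs$members, 2)
  expect_equal(cs$n_total, 3)
  # random graphs vs oracle
  for (s in 1:10) {
    set.seed(200 + s)
    n <- sample(8:25, 1)
    gr <- igraph::sample_gnp(n, runif(1, 0.05, 0.3))
    igraph::V(gr)$name <- sprintf("v%02d", 1:n)
    el <- igraph::as_edgelist(gr, names = FALSE)
    lab <- oracle_components(n, el)
    cs <- connected_components(gr, min_vertices = 1)
    oracle_sets <- lapply(split(sprintf("v%02d", 1:n), lab), sort)
    expect_setequal(vapply(cs$members, paste, "", collapse = ","),
                    unname(vapply(oracle_sets, paste, "", collapse = ",")))
    # literal cross-edge assertion
    memb <- rep(seq_along(cs$members), lengths(cs$members))
    names(memb) <- unlist(cs$members)
    if (nrow(el) > 0) {
      vn <- igraph::V(gr)$name
      expect_true(all(memb[vn[el[, 1]]] == memb[vn[el[, 2]]]))
    }
  }
})
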