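# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately written from first principles, separate
# from the package's own code paths.

# --- plain-loop Huber IRLS, solved via QR of the weighted design ------------
oracle_irls <- function(x, y, k = 1.345, tol = 1e-8, max_iter = 50) {
  X <- cbind(1, x)
  beta <- qr.solve(X, y)
  for (it in seq_len(max_iter)) {
    e <- as.numeric(y - X %*% beta)
    s <- median(abs(e - median(e))) / 0.6745
    if (s <= 0) s <- mean(abs(e - median(e))) / 0.7979
    if (s <= 0) return(list(intercept = unname(beta[1]), slope = unname(beta[2]), iter = it))
    w <- pmin(1, k * s / abs(e))
    w[e == 0] <- 1
    beta_new <- qr.solve(X * sqrt(w), y * sqrt(w))
    if (max(abs(beta_new - beta)) < tol)
      return(list(intercept = unname(beta_new[1]), slope = unname(beta_new[2]),
                  iter = it))
    beta <- beta_new
  }
  list(intercept = unname(beta[1]), slope = unname(beta[2]), iter = max_iter)
}

# --- brute-force weighted Pearson -------------------------------------------
oracle_weighted_cor <- function(x, y, w) {
  wt <- w / sum(w)
  mx <- sum(wt * x); my <- sum(wt * y)
  num <- sum(wt * (x - mx) * (y - my))
  num / sqrt(sum(wt * (x - mx)^2) * sum(wt * (y - my)^2))
}

# --- adjusted Rand index -----------------------------------------------------
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sc <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  N <- choose(sum(tab), 2)
  e <- sa * sb / N
  (sc - e) / ((sa + sb) / 2 - e)
}

# --- union-find connected components ----------------------------------------
oracle_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges) > 0) for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, numeric(1))
  match(roots, unique(roots))   # canonical component labels
}

# --- linear-interpolation percentile, written out by hand -------------------
oracle_percentile <- function(v, q) {
  v <- sort(v)
  h <- (length(v) - 1) * q + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# --- hypergeometric upper tail by exhaustive enumeration of draws -----------
# enumerate every n-subset of 1..N, treating 1..K as pathway members
oracle_hyper_tail_enum <- function(k, n, K, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  subsets <- combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# --- Benjamini-Hochberg step-up applied by hand -----------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# --- mean silhouette width on 2 clusters, euclidean -------------------------
oracle_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  n <- nrow(coords)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(d[i, own])
    b <- mean(d[i, !own & seq_len(n) != i])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# --- exhaustive DC-SBM description length over all 2-partitions -------------
# vertex 1 fixed in block 1 (label symmetry); returns best membership and DL.
# The DL formula is re-derived here independently of the package.
oracle_dcsbm_exhaustive <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  E <- igraph::ecount(g)
  n <- igraph::vcount(g)
  stopifnot(n <= 20)
  ids <- 0:(2^(n - 1) - 1)
  memb2 <- matrix(FALSE, length(ids), n)
  for (j in 2:n)
    memb2[, j] <- bitwAnd(ids, bitwShiftL(1L, j - 2L)) > 0
  n2 <- rowSums(memb2); n1 <- n - n2
  e22 <- e12 <- rep(0, length(ids))
  for (kk in seq_len(E)) {
    a <- memb2[, el[kk, 1]]; b <- memb2[, el[kk, 2]]
    e22 <- e22 + (a & b)
    e12 <- e12 + xor(a, b)
  }
  e11 <- E - e22 - e12
  er1 <- 2 * e11 + e12; er2 <- 2 * e22 + e12
  term <- function(v, x, y) ifelse(v > 0, v * log(v / (x * y)), 0)
  lgsum <- term(2 * e11, er1, er1) + term(2 * e22, er2, er2) +
    2 * term(e12, er1, er2)
  S <- -E - sum(lgamma(deg + 1)) - 0.5 * lgsum
  B <- ifelse(n2 == 0 | n1 == 0, 1, 2)
  L_ers <- lchoose(B * (B + 1) / 2 + E - 1, E)
  L_deg <- ifelse(B == 1, lchoose(n + 2 * E - 1, 2 * E),
                  lchoose(n1 + er1 - 1, er1) + lchoose(n2 + er2 - 1, er2))
  L_part <- lchoose(n - 1, B - 1) + lgamma(n + 1) -
    lgamma(n1 + 1) - lgamma(n2 + 1)
  dl <- S + L_ers + L_deg + L_part
  best <- which.min(dl)
  list(membership = ifelse(memb2[best, ], 2L, 1L), dl = dl[best])
}

# --- planted 2-block random graph -------------------------------------------
make_planted_graph <- function(n_per_block = 50, p_in = 0.4, p_out = 0.05,
                               seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_block
  lab <- rep(1:2, each = n_per_block)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- ifelse(lab[pairs[, 1]] == lab[pairs[, 2]], p_in, p_out)
  keep <- rbinom(nrow(pairs), 1, p) == 1
  g <- igraph::graph_from_edgelist(pairs[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
  list(graph = g, labels = lab)
}

# --- tiny literal datasets ---------------------------------------------------
toy_long_csv <- function(path, rows) {
  writeLines(c("subject,group,fluid,replicate,metabolite,peak_area", rows),
             path)
  path
}

# quick simulated paired table for module tests
sim_paired <- function(cfg) {
  sim <- simulate_dataset(cfg)
  paired <- suppressWarnings(
    build_paired_table(ln_transform(average_replicates(sim$dataset))))
  list(paired = paired, truth = sim$truth, dataset = sim$dataset)
}
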