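#' Pairwise robust correlations between metabolites
#'
#' For every unordered pair of columns of the pooled (subject, fluid) ln
#' matrix, fits [huber_irls()] on the pairwise-complete observations and
#' reports the Huber-weighted correlation with the robust slope-test p-value
#' of [huber_slope_pvalue()].
#' Pairs with fewer than 3 complete observations or a degenerate design are
#' emitted with `NA` statistics and `ok = FALSE` rather than dropped.
#'
#' @param mat numeric matrix, observations in rows, metabolites in columns
#'   (see [pooled_matrix()]).
#' @param tuning_const,tol,max_iter passed to [huber_irls()].
#' @return data.frame with columns `m1`, `m2`, `weight`, `p`, `n_obs`, `ok`.
#' @export
pairwise_correlations <- function(mat, tuning_const = 1.345, tol = 1e-8,
                                  max_iter = 50L) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  m <- ncol(mat)
  n_pairs <- m * (m - 1L) / 2L
  m1 <- character(n_pairs); m2 <- character(n_pairs)
  weight <- rep(NA_real_, n_pairs); pval <- rep(NA_real_, n_pairs)
  n_obs <- integer(n_pairs); ok <- logical(n_pairs)
  k <- 0L
  for (i in seq_len(m - 1L)) {
    xi <- mat[, i]
    for (j in seq((i + 1L), m)) {
      k <- k + 1L
      m1[k] <- colnames(mat)[i]; m2[k] <- colnames(mat)[j]
      yj <- mat[, j]
      use <- is.finite(xi) & is.finite(yj)
      n_obs[k] <- sum(use)
      res <- tryCatch({
        fit <- huber_irls(xi[use], yj[use], tuning_const, tol, max_iter)
        r <- weighted_correlation(xi[use], yj[use], fit$weights)
        c(r, as.numeric(huber_slope_pvalue(fit, xi[use], yj[use],
                                           tuning_const)))
      }, error = function(e) NULL)
      if (!is.null(res)) {
        weight[k] <- res[1]; pval[k] <- res[2]; ok[k] <- TRUE
      }
    }
  }
  data.frame(m1 = m1, m2 = m2, weight = weight, p = pval,
             n_obs = n_obs, ok = ok, stringsAsFactors = FALSE)
}

#' Build the metabolite correlation graph
#'
#' Vertices are all metabolites (isolated ones included); an undirected edge
#' joins a pair when its correlation is defined, `p < edge_alpha`, and the
#' sign filter passes. The default keeps positive correlations only, since
#' the percentile-subgraph analysis thresholds a positive weight
#' distribution; set `use_abs = TRUE` to keep strong correlations of either
#' sign (filtering on `|weight|`).
#'
#' @param pairs output of [pairwise_correlations()].
#' @param edge_alpha p-value threshold for edge inclusion.
#' @param positive_only keep only edges with `weight > 0`.
#' @param use_abs apply the significance/sign rule to `|weight|` and ignore
#'   `positive_only`.
#' @param vertices optional character vector fixing the vertex set (defaults
#'   to every metabolite mentioned in `pairs`).
#' @return igraph object with edge attributes `weight` and `p`.
#' @export
build_graph <- function(pairs, edge_alpha = 0.05, positive_only = TRUE,
                        use_abs = FALSE, vertices = NULL) {
  stopifnot(all(c("m1", "m2", "weight", "p", "ok") %in% names(pairs)))
  if (is.null(vertices)) vertices <- sort(unique(c(pairs$m1, pairs$m2)))
  keep <- pairs$ok & !is.na(pairs$p) & pairs$p < edge_alpha
  if (use_abs) {
    # sign-free variant: any significant correlation becomes an edge
  } else if (positive_only) {
    keep <- keep & pairs$weight > 0
  }
  e <- pairs[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = e$m1, to = e$m2, weight = e$weight, p = e$p,
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = vertices, stringsAsFactors = FALSE))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = "first")
}

#' Microcanonical description length of a degree-corrected SBM partition
#'
#' Computes, in nats, the description length of a simple undirected graph
#' under a flat degree-corrected stochastic block model: the microcanonical
#' entropy
#' `S = -E - sum_i ln k_i! - 1/2 sum_rs e_rs ln(e_rs / (e_r e_s))`
#' (with `e_rs` twice the internal edge count on the diagonal and `e_r` the
#' total degree of block r) plus uniform-prior encoding costs for the block
#' edge-count matrix, the per-block degree sequences, and the partition
#' itself. Blocks are counted by occupancy, so partitions that leave a block
#' empty are scored as the smaller model.
#'
#' @param graph igraph object (undirected, simple).
#' @param membership integer/character vector of block labels, one per
#'   vertex in `igraph::V(graph)` order.
#' @return description length in nats (scalar).
#' @export
dcsbm_description_length <- function(graph, membership) {
  n <- igraph::vcount(graph)
  stopifnot(length(membership) == n)
  pre <- dcsbm_precompute(graph)
  .dcsbm_dl(as.integer(factor(membership)), pre)
}

dcsbm_precompute <- function(graph) {
  deg <- igraph::degree(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  list(n = igraph::vcount(graph), E = igraph::ecount(graph),
       el = el, deg = deg, lkfact = sum(lgamma(deg + 1)))
}

# description length for an occupancy-relabelled membership b (1..B)
.dcsbm_dl <- function(b, pre) {
  b <- as.integer(factor(b))
  B <- max(b, 1L)
  n <- pre$n; E <- pre$E
  if (E > 0) {
    r <- b[pre$el[, 1]]; s <- b[pre$el[, 2]]
    lo <- pmin(r, s); hi <- pmax(r, s)
    m <- matrix(tabulate(hi + (lo - 1L) * B, nbins = B * B), B, B)
    ers <- m + t(m)                      # diagonal = 2 x internal edges
  } else {
    ers <- matrix(0, B, B)
  }
  e_r <- rowSums(ers)
  n_r <- tabulate(b, nbins = B)
  pos <- ers > 0
  lg <- sum(ers[pos] * log(ers[pos] / outer(e_r, e_r)[pos]))
  S <- -E - pre$lkfact - 0.5 * lg
  L_ers <- lchoose(B * (B + 1) / 2 + E - 1, E)
  L_deg <- sum(lchoose(n_r + e_r - 1, e_r))
  L_part <- lchoose(n - 1, B - 1) + lgamma(n + 1) - sum(lgamma(n_r + 1))
  S + L_ers + L_deg + L_part
}

#' Fit a flat degree-corrected SBM by greedy description-length descent
#'
#' Partitions the vertices into at most `n_blocks` groups by minimizing
#' [dcsbm_description_length()]: starting from a random assignment, sweeps
#' vertices in random order and applies any single-vertex move that lowers
#' the description length, until a full sweep makes no move; the best of
#' `n_restarts` seeded restarts is returned. Blocks may empty out, so the
#' effective number of blocks can be smaller than `n_blocks`. Deterministic
#' given `seed`.
#'
#' @param graph igraph object.
#' @param n_blocks maximum number of blocks.
#' @param n_restarts random restarts.
#' @param seed integer seed.
#' @return list with `membership` (named integer vector, labels 1..),
#'   `description_length` (nats), `n_blocks_effective`, `flag` (`NA` or an
#'   explanation for degenerate inputs), `restart_dl` (best DL per restart).
#' @export
fit_dcsbm <- function(graph, n_blocks = 2L, n_restarts = 20L, seed = 1L) {
  stopifnot(n_blocks >= 1, n_restarts >= 1)
  n <- igraph::vcount(graph)
  vnames <- igraph::V(graph)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(n))
  if (igraph::ecount(graph) == 0) {
    memb <- setNames(rep(1L, n), vnames)
    return(list(membership = memb,
                description_length = dcsbm_description_length(graph, memb),
                n_blocks_effective = 1L,
                flag = "edgeless graph: single-block partition",
                restart_dl = numeric(0)))
  }
  set.seed(seed)
  pre <- dcsbm_precompute(graph)
  best <- NULL
  restart_dl <- numeric(n_restarts)
  for (rs in seq_len(n_restarts)) {
    b <- sample.int(n_blocks, n, replace = TRUE)
    dl <- .dcsbm_dl(b, pre)
    repeat {
      moved <- FALSE
      for (v in sample.int(n)) {
        cur <- b[v]
        for (cand in seq_len(n_blocks)) {
          if (cand == cur) next
          b[v] <- cand
          dl_new <- .dcsbm_dl(b, pre)
          if (dl_new < dl - 1e-12) {
            dl <- dl_new
            cur <- cand
            moved <- TRUE
          } else {
            b[v] <- cur
          }
        }
      }
      if (!moved) break
    }
    restart_dl[rs] <- dl
    if (is.null(best) || dl < best$dl) best <- list(b = b, dl = dl)
  }
  memb <- setNames(as.integer(factor(best$b)), vnames)
  list(membership = memb, description_length = best$dl,
       n_blocks_effective = length(unique(memb)),
       flag = NA_character_, restart_dl = restart_dl)
}

#' Upper-percentile subgraph of the correlation graph
#'
#' Computes the `q`-th percentile of all edge weights (linear interpolation,
#' i.e. R's default quantile type 7) and keeps the edges whose weight lies
#' strictly above it; vertices left isolated are dropped.
#'
#' @param graph igraph object with a `weight` edge attribute.
#' @param q percentile in (0, 1), default 0.95.
#' @return list with `graph` (the filtered igraph) and `threshold`.
#' @export
percentile_subgraph <- function(graph, q = 0.95) {
  stopifnot(q > 0, q < 1)
  if (igraph::ecount(graph) == 0) stop("graph has no edges")
  w <- igraph::E(graph)$weight
  thr <- as.numeric(quantile(w, probs = q, type = 7, names = FALSE))
  g <- igraph::subgraph_from_edges(graph, igraph::E(graph)[w > thr],
                                   delete.vertices = TRUE)
  list(graph = g, threshold = thr)
}

#' Connected components above a size floor
#'
#' Standard undirected connected components, keeping those with at least
#' `min_vertices` vertices ("more than a pair of vertices") and ordering
#' them by decreasing size, ties broken by the lexicographically smallest
#' member.
#'
#' @param graph igraph object.
#' @param min_vertices minimum component size retained.
#' @return list of class `ComponentSet`: `members` (list of sorted vertex
#'   name vectors), `subgraphs` (list of igraph objects), `n_total`
#'   (component count before the size filter).
#' @export
connected_components <- function(graph, min_vertices = 3L) {
  comp <- igraph::components(graph)
  ids <- seq_len(comp$no)
  members <- lapply(ids, function(i)
    sort(igraph::V(graph)$name[comp$membership == i]))
  keep <- vapply(members, length, integer(1)) >= min_vertices
  members <- members[keep]
  ord <- order(-vapply(members, length, integer(1)),
               vapply(members, `[`, character(1), 1))
  members <- members[ord]
  subgraphs <- lapply(members, function(vs)
    igraph::induced_subgraph(graph, vs))
  structure(list(members = members, subgraphs = subgraphs,
                 n_total = comp$no),
            class = "ComponentSet")
}

#' @export
print.ComponentSet <- function(x, ...) {
  cat(sprintf("ComponentSet: %d component(s) kept (of %d total)\n",
              length(x$members), x$n_total))
  for (i in seq_along(x$members))
    cat(sprintf("  C%d (%d): %s\n", i, length(x$members[[i]]),
                paste(head(x$members[[i]], 6), collapse = ", ")))
  invisible(x)
}
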