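#' Read a pathway collection from a GMT file
#'
#' Each line is `id<TAB>description<TAB>member1<TAB>member2...`. Lines with
#' fewer than three fields (i.e. no members) are rejected with a warning
#' naming the line number; duplicate member IDs within a line are collapsed
#' with a warning. The universe defaults to the union of all members.
#'
#' @param path GMT file path.
#' @return list of class `PathwayCollection`: `pathways` (list of lists with
#'   `id`, `name`, `members`) and `universe` (character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  pathways <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      warning("GMT line ", i, " has fewer than 3 fields; rejected")
      next
    }
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("GMT line ", i, " (", f[1], ") has duplicate members; deduplicated")
      members <- unique(members)
    }
    if (length(members) == 0) {
      warning("GMT line ", i, " has no members; rejected")
      next
    }
    pathways[[length(pathways) + 1L]] <-
      list(id = f[1], name = f[2], members = members)
  }
  structure(list(pathways = pathways,
                 universe = sort(unique(unlist(lapply(pathways,
                                                      `[[`, "members"))))),
            class = "PathwayCollection")
}

#' Write a pathway collection to GMT
#'
#' @param collection a `PathwayCollection`.
#' @param path output file path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "PathwayCollection"))
  lines <- vapply(collection$pathways, function(p)
    paste(c(p$id, p$name, p$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` where `X` counts the query members falling in a pathway of
#' size `K` when `n` items are drawn without replacement from a universe of
#' size `N` — the standard one-sided overrepresentation p-value, evaluated
#' through `stats::phyper` (log-space stable).
#'
#' @param k observed overlap.
#' @param n query size.
#' @param K pathway size.
#' @param N universe size.
#' @export
hypergeom_tail <- function(k, n, K, N) {
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > n || n > N || K > N ||
      k > K)
    stop("invalid hypergeometric parameters: need 0 <= k <= min(n, K), n <= N, K <= N")
  if (k == 0) return(1)
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input vector.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(is.na(pvalues) | (pvalues > 0 & pvalues <= 1)))
  p.adjust(pvalues, method = "BH")
}

#' Read a metabolite-name to compound-ID mapping
#'
#' Two-column delimited file (header `metabolite`, `compound_id`) used to
#' harmonize metabolite names with the compound accessions of a pathway
#' collection. No fuzzy matching is attempted.
#'
#' @param path file path.
#' @return named character vector (names = metabolite, values = compound ID).
#' @export
read_id_map <- function(path) {
  dt <- data.table::fread(path, colClasses = "character")
  if (!all(c("metabolite", "compound_id") %in% names(dt)))
    stop("mapping file needs columns 'metabolite' and 'compound_id'")
  setNames(dt$compound_id, dt$metabolite)
}

#' Map metabolite names to compound IDs
#'
#' @param metabolites character vector of metabolite names.
#' @param id_map named character vector from [read_id_map()].
#' @return character vector of compound IDs; unmapped names dropped with a
#'   warning.
#' @export
map_ids <- function(metabolites, id_map) {
  ids <- unname(id_map[metabolites])
  n_miss <- sum(is.na(ids))
  if (n_miss > 0)
    warning(n_miss, " metabolite(s) without a compound ID dropped from the query")
  ids[!is.na(ids)]
}

#' Overrepresentation analysis of a compound set
#'
#' For every pathway, counts the overlap between the (harmonized) query and
#' the pathway membership restricted to the universe, computes the one-sided
#' hypergeometric p-value and Benjamini-Hochberg FDR across all tested
#' pathways, then drops pathways with overlap below `min_found`. Query IDs
#' absent from the universe are dropped with a warning.
#'
#' @param query character vector of compound IDs.
#' @param collection a `PathwayCollection`.
#' @param min_found minimum overlap for a reported row (the study's "more
#'   than one metabolite found" corresponds to `min_found = 2`).
#' @param universe optional custom universe (e.g. the analyzed panel);
#'   defaults to the collection's universe.
#' @return data.frame sorted by (fdr, p, id) with columns `id`, `name`, `k`,
#'   `n`, `K`, `N`, `p`, `fdr`, `found_members`.
#' @export
enrich <- function(query, collection, min_found = 1L, universe = NULL) {
  stopifnot(inherits(collection, "PathwayCollection"))
  if (is.null(universe)) universe <- collection$universe
  universe <- unique(universe)
  query <- unique(query)
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0)
    warning(length(dropped), " query ID(s) not in the universe dropped")
  query <- intersect(query, universe)
  if (length(query) == 0) {
    warning("empty harmonized query; no enrichment computed")
    return(data.frame(id = character(0), name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), fdr = numeric(0),
                      found_members = character(0), stringsAsFactors = FALSE))
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(collection$pathways, function(pw) {
    mem <- intersect(pw$members, universe)
    K <- length(mem)
    if (K == 0) return(NULL)
    found <- intersect(query, mem)
    k <- length(found)
    data.frame(id = pw$id, name = pw$name, k = k, n = n, K = K, N = N,
               p = hypergeom_tail(k, n, K, N),
               found_members = paste(sort(found), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0) return(res)
  res$fdr <- bh_fdr(res$p)
  res <- res[res$k >= min_found, , drop = FALSE]
  res <- res[order(res$fdr, res$p, res$id), ]
  rownames(res) <- NULL
  res[, c("id", "name", "k", "n", "K", "N", "p", "fdr", "found_members")]
}
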