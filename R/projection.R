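#' Principal component scores of sample profiles
#'
#' Column-centers the matrix and takes scores from the singular value
#' decomposition. Component signs follow the convention that the loading
#' with the largest magnitude is positive, making scores reproducible across
#' SVD implementations.
#'
#' @param mat numeric matrix, samples in rows, metabolites in columns, no
#'   missing values (see [impute_column_means()]).
#' @param n_components number of components returned.
#' @return list of class `EmbeddingResult`: `coordinates`
#'   (samples x n_components), `method = "pca"`, `explained_variance`
#'   (fractions, all components), `seed = NA`.
#' @export
pca_embed <- function(mat, n_components = 2L) {
  stopifnot(is.matrix(mat), n_components >= 1)
  if (nrow(mat) < 3) stop("need at least 3 samples")
  if (ncol(mat) < 2) stop("need at least 2 features")
  if (anyNA(mat)) stop("matrix contains missing values; impute first")
  x <- scale(mat, center = TRUE, scale = FALSE)
  sv <- svd(x)
  if (sv$d[min(n_components, length(sv$d))] < 1e-10 * sv$d[1])
    stop("matrix rank below requested number of components")
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(n_components), drop = FALSE] %*%
                    diag(sv$d[seq_len(n_components)], n_components),
                  2, flip, "*")
  rownames(scores) <- rownames(mat)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(coordinates = scores, method = "pca",
                 explained_variance = sv$d^2 / sum(sv$d^2),
                 seed = NA_integer_),
            class = "EmbeddingResult")
}

#' Replace missing cells by their column means
#'
#' Minimal imputation for embedding inputs; columns that are entirely
#' missing are dropped with a warning.
#'
#' @param mat numeric matrix.
#' @export
impute_column_means <- function(mat) {
  stopifnot(is.matrix(mat))
  all_na <- colSums(!is.na(mat)) == 0
  if (any(all_na)) {
    warning(sum(all_na), " all-missing column(s) dropped")
    mat <- mat[, !all_na, drop = FALSE]
  }
  for (j in which(colSums(is.na(mat)) > 0)) {
    v <- mat[, j]
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    mat[, j] <- v
  }
  mat
}

#' Two-dimensional UMAP embedding (delegated)
#'
#' Thin contract wrapper around the `uwot` package: the guarantees are shape
#' (one coordinate pair per sample), finiteness, and determinism for a fixed
#' seed. The embedding itself is a delegated nonlinear method used for
#' visualization, not an inferential statistic of this package.
#'
#' @param mat numeric matrix, samples in rows (>= 10), no missing values.
#' @param seed integer seed.
#' @param n_neighbors UMAP neighborhood size (capped at n - 1).
#' @return an `EmbeddingResult` with `method = "umap"`.
#' @export
umap_embed <- function(mat, seed = 1L, n_neighbors = 15L) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 10)
    stop("UMAP needs at least 10 samples")
  if (anyNA(mat)) stop("matrix contains missing values; impute first")
  if (!requireNamespace("uwot", quietly = TRUE))
    stop("package 'uwot' is not available; use pca_embed() as a fallback")
  set.seed(seed)
  coords <- uwot::umap(mat, n_neighbors = min(n_neighbors, nrow(mat) - 1L),
                       n_components = 2L, n_threads = 1L,
                       n_sgd_threads = 0L)
  rownames(coords) <- rownames(mat)
  colnames(coords) <- c("UMAP1", "UMAP2")
  structure(list(coordinates = coords, method = "umap",
                 explained_variance = NULL, seed = as.integer(seed)),
            class = "EmbeddingResult")
}

#' OPLS-DA: single-component PLS after orthogonal signal correction
#'
#' Two-class orthogonal projections to latent structures discriminant
#' analysis. The class vector is coded -1/+1 and centered; the matrix is
#' column-centered (and optionally unit-variance scaled). `n_orth` rounds of
#' orthogonal signal correction each remove the X-variation component that is
#' orthogonal to y (Trygg-Wold filtering), then a one-component PLS1
#' regression on the filtered matrix provides the predictive direction.
#' Class assignment thresholds the predicted score at 0, and performance is
#' estimated by k-fold cross-validation in which the full OSC + PLS chain is
#' refit on every training split.
#'
#' @param mat numeric matrix, samples in rows, no missing values.
#' @param labels two-level factor/character/logical vector of class labels.
#' @param n_orth number of orthogonal components removed (0 = plain PLS1).
#' @param cv_folds number of cross-validation folds.
#' @param scale unit-variance scale columns.
#' @param seed seed controlling the CV fold shuffle.
#' @return list of class `OplsModel`: `weights` (predictive), `loadings`,
#'   `scores_pred`, `scores_orth` (matrix, may have 0 columns),
#'   `orth_loadings`, `cv_accuracy`, `q2`, `levels`, `n_orth`.
#' @export
opls_da_fit <- function(mat, labels, n_orth = 1L, cv_folds = 7L,
                        scale = TRUE, seed = 1L) {
  stopifnot(is.matrix(mat), nrow(mat) == length(labels), n_orth >= 0,
            cv_folds >= 2)
  if (anyNA(mat)) stop("matrix contains missing values; impute first")
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2) stop("labels must contain exactly two classes")
  yv <- ifelse(as.character(labels) == lev[2], 1, -1)

  fit_chain <- function(X, y) {
    mu <- colMeans(X)
    sdev <- if (scale) apply(X, 2, sd) else rep(1, ncol(X))
    sdev[sdev == 0] <- 1
    Xc <- sweep(sweep(X, 2, mu, "-"), 2, sdev, "/")
    yc <- y - mean(y)
    w_orth_list <- list(); p_orth_list <- list(); t_orth <- NULL
    Xf <- Xc
    for (a in seq_len(n_orth)) {
      w <- drop(crossprod(Xf, yc)); w <- w / sqrt(sum(w^2))
      t <- drop(Xf %*% w)
      p <- drop(crossprod(Xf, t)) / sum(t^2)
      wo <- p - drop(crossprod(w, p)) * w
      nwo <- sqrt(sum(wo^2))
      if (nwo < 1e-12) break              # no orthogonal variation left
      wo <- wo / nwo
      to <- drop(Xf %*% wo)
      po <- drop(crossprod(Xf, to)) / sum(to^2)
      Xf <- Xf - tcrossprod(to, po)
      w_orth_list[[a]] <- wo; p_orth_list[[a]] <- po
      t_orth <- cbind(t_orth, to)
    }
    w <- drop(crossprod(Xf, yc)); w <- w / sqrt(sum(w^2))
    t <- drop(Xf %*% w)
    p <- drop(crossprod(Xf, t)) / sum(t^2)
    q <- sum(yc * t) / sum(t^2)
    list(mu = mu, sdev = sdev, w_orth = w_orth_list, p_orth = p_orth_list,
         w = w, p = p, q = q, t = t, t_orth = t_orth, y_mean = mean(y))
  }
  predict_chain <- function(fit, X) {
    Xc <- sweep(sweep(X, 2, fit$mu, "-"), 2, fit$sdev, "/")
    for (a in seq_along(fit$w_orth)) {
      to <- drop(Xc %*% fit$w_orth[[a]])
      Xc <- Xc - tcrossprod(to, fit$p_orth[[a]])
    }
    drop(Xc %*% fit$w) * fit$q + fit$y_mean
  }

  full <- fit_chain(mat, yv)

  set.seed(seed)
  n <- nrow(mat)
  folds <- sample(rep(seq_len(cv_folds), length.out = n))
  pred <- numeric(n)
  for (f in seq_len(cv_folds)) {
    te <- folds == f
    if (length(unique(yv[!te])) < 2) next   # degenerate split: skip fold fit
    ft <- fit_chain(mat[!te, , drop = FALSE], yv[!te])
    pred[te] <- predict_chain(ft, mat[te, , drop = FALSE])
  }
  cv_accuracy <- mean((pred > 0) == (yv > 0))
  q2 <- 1 - sum((yv - pred)^2) / sum((yv - mean(yv))^2)

  structure(list(weights = full$w, loadings = full$p,
                 scores_pred = full$t, scores_orth = full$t_orth,
                 orth_loadings = full$p_orth, q = full$q,
                 cv_accuracy = cv_accuracy, q2 = q2, levels = lev,
                 n_orth = length(full$w_orth)),
            class = "OplsModel")
}
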