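#' Huber M-estimate of a simple linear regression by IRLS
#'
#' Fits `y = intercept + slope * x` by iteratively reweighted least squares
#' with the Huber psi function. At each iteration the residual scale is
#' re-estimated as `MAD(e)/0.6745` (median absolute deviation about the
#' residual median, i.e. a consistent robust sigma under normality; when the
#' MAD collapses to zero with nonzero residuals, the centered mean absolute
#' deviation over 0.7979 is used instead) and each
#' observation receives weight 1 when its standardized residual is within
#' `tuning_const`, and `tuning_const * scale / |e|` beyond it. Iteration stops
#' when the largest coefficient change drops below `tol`.
#'
#' The default tuning constant 1.345 gives 95% efficiency at the Gaussian
#' model while bounding the influence of gross outliers.
#'
#' @param x,y numeric vectors of paired observations (NAs dropped pairwise).
#' @param tuning_const Huber tuning constant k.
#' @param tol convergence tolerance on coefficients.
#' @param max_iter iteration cap.
#' @return An object of class `RobustFit`: list with `slope`, `intercept`,
#'   `scale`, `weights` (in (0, 1], aligned with the used observations),
#'   `n_obs`, `n_iter`, `converged`, and `used` (logical mask of the input
#'   positions that entered the fit).
#' @export
huber_irls <- function(x, y, tuning_const = 1.345, tol = 1e-8, max_iter = 50L) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            tuning_const > 0, tol > 0, max_iter >= 1)
  used <- is.finite(x) & is.finite(y)
  xs <- x[used]; ys <- y[used]
  n <- length(xs)
  if (n < 3)
    stop(insufficient_data_error(
      sprintf("need at least 3 paired observations, got %d", n)))
  if (max(xs) - min(xs) == 0)
    stop(degenerate_design_error("predictor is constant"))

  wls <- function(w) {
    sw <- sum(w)
    mx <- sum(w * xs) / sw; my <- sum(w * ys) / sw
    sxx <- sum(w * (xs - mx)^2)
    if (sxx <= 0) stop(degenerate_design_error("zero weighted predictor variance"))
    b <- sum(w * (xs - mx) * (ys - my)) / sxx
    c(my - b * mx, b)
  }

  coef <- wls(rep(1, n))
  w <- rep(1, n)
  scale <- NA_real_
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    e <- ys - coef[1] - coef[2] * xs
    scale <- mad(e, center = median(e)) / 1.4826 / 0.6745  # = MAD(e)/0.6745
    if (!is.finite(scale) || scale <= 0) {
      # MAD collapses when over half the residuals tie (e.g. points exactly
      # on a line plus outliers); fall back to the centered mean absolute
      # deviation (consistency constant 0.7979 under normality)
      scale <- mean(abs(e - median(e))) / 0.7979
    }
    if (!is.finite(scale) || scale <= 0) {
      # genuinely perfect fit: every point already on the line
      w <- rep(1, n); scale <- .Machine$double.eps
      converged <- TRUE
      break
    }
    r <- abs(e) / scale
    w <- ifelse(r <= tuning_const, 1, tuning_const * scale / abs(e))
    new_coef <- wls(w)
    if (max(abs(new_coef - coef)) < tol) {
      coef <- new_coef
      converged <- TRUE
      break
    }
    coef <- new_coef
  }
  structure(list(slope = coef[2], intercept = coef[1], scale = scale,
                 weights = w, n_obs = n, n_iter = iter,
                 converged = converged, used = used),
            class = "RobustFit")
}

insufficient_data_error <- function(msg) {
  structure(class = c("insufficient_data_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

degenerate_design_error <- function(msg) {
  structure(class = c("degenerate_design_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Weighted Pearson correlation coefficient
#'
#' Correlation under observation weights, normally the Huber weights of a
#' robust fit: with normalized weights `w~ = w / sum(w)`, weighted means
#' `xbar = sum(w~ x)`, the coefficient is
#' `sum(w~ (x - xbar)(y - ybar)) / sqrt(sum(w~ (x - xbar)^2) sum(w~ (y - ybar)^2))`.
#' With equal weights this reduces exactly to the ordinary Pearson r.
#'
#' @param x,y numeric vectors.
#' @param weights non-negative weights, not all zero.
#' @return correlation in `[-1, 1]`.
#' @export
weighted_correlation <- function(x, y, weights) {
  stopifnot(length(x) == length(y), length(weights) == length(x))
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative and not all zero")
  w <- weights / sum(weights)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0)
    stop("undefined correlation: zero weighted variance")
  r <- sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  min(1, max(-1, r))
}

#' Two-sided p-value for a correlation coefficient
#'
#' Student-t approximation: `t = r sqrt((n - 2)/(1 - r^2))` on `n - 2`
#' degrees of freedom. For weighted (Huber) correlations this treats the
#' nominal number of observations as the sample size, i.e. it ignores the
#' reduction in effective sample size caused by downweighting; the p-values
#' are therefore approximate.
#'
#' @param r correlation in `[-1, 1]`.
#' @param n_obs number of paired observations (>= 3).
#' @return two-sided p-value in `(0, 1]`; exactly 0 (with attribute
#'   `exact = TRUE`) when `|r| = 1`.
#' @export
correlation_pvalue <- function(r, n_obs) {
  stopifnot(is.finite(r), abs(r) <= 1 + 1e-12, n_obs >= 3)
  r <- min(1, max(-1, r))
  if (abs(r) == 1) return(structure(0, exact = TRUE))
  t <- r * sqrt((n_obs - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n_obs - 2)
}

#' Significance of the Huber regression slope
#'
#' Two-sided p-value for the null hypothesis of zero slope, using the
#' standard M-estimation (sandwich) variance of a Huber fit: with
#' standardized residuals `u = e / scale` and the clipped psi function
#' `psi(u) = max(-k, min(k, u))`,
#' `se(b)^2 = K^2 scale^2 sum(psi^2) / ((n - 2) mean(psi')^2 Sxx)`
#' where `K` is Huber's small-sample correction
#' `1 + (2/n) var(psi') / mean(psi')^2` and `Sxx = sum((x - xbar)^2)`; the
#' statistic `b / se(b)` is referred to a t distribution on `n - 2` degrees
#' of freedom. When no observation is clipped this reduces exactly to the
#' ordinary least-squares slope t-test. Unlike the t-approximation applied
#' to the weighted correlation itself, this test stays calibrated when the
#' weights are estimated from the data, which is why correlation records use
#' it for `p_huber`.
#'
#' @param fit a `RobustFit` from [huber_irls()].
#' @param x,y the observations the fit was computed from (complete pairs).
#' @param tuning_const the Huber constant used in the fit.
#' @return two-sided p-value; exactly 0 (attribute `exact = TRUE`) for a
#'   perfect noiseless fit with nonzero slope.
#' @export
huber_slope_pvalue <- function(fit, x, y, tuning_const = 1.345) {
  stopifnot(inherits(fit, "RobustFit"))
  n <- fit$n_obs
  e <- y - fit$intercept - fit$slope * x
  if (all(abs(e) < 1e-12 * max(1, abs(fit$slope)))) {
    # exact fit: zero residual variance
    return(structure(if (fit$slope == 0) 1 else 0, exact = TRUE))
  }
  s <- fit$scale
  u <- e / s
  psi <- pmax(-tuning_const, pmin(tuning_const, u))
  dpsi <- as.numeric(abs(u) <= tuning_const)
  md <- mean(dpsi)
  if (md == 0) return(1)                   # everything clipped: no information
  K <- 1 + (2 / n) * stats::var(dpsi) / md^2
  sxx <- sum((x - mean(x))^2)
  se2 <- K^2 * s^2 * sum(psi^2) / (n - 2) / md^2 / sxx
  tstat <- fit$slope / sqrt(se2)
  2 * pt(-abs(tstat), df = n - 2)
}

empty_correlation_record <- function(metabolite, scope, n_obs, reason) {
  data.frame(metabolite = metabolite, scope = scope,
             r_huber = NA_real_, p_huber = NA_real_,
             r_ols = NA_real_, p_ols = NA_real_,
             n_obs = n_obs, converged = NA, ok = FALSE,
             flag = reason, stringsAsFactors = FALSE)
}

#' Robust and ordinary plasma-CSF correlation for one metabolite
#'
#' Restricts the paired table to the subjects of a scope (`combined`,
#' `patients` = glioma, `controls`), takes pairwise-complete (ln plasma,
#' ln CSF) observations, fits [huber_irls()] of CSF on plasma, and reports
#' the Huber-weighted correlation with the robust slope-test p-value of
#' [huber_slope_pvalue()] alongside the unweighted Pearson r/p (t-test,
#' [correlation_pvalue()]). Metabolites with fewer than 3 complete pairs
#' or a degenerate design yield a flagged record with `NA` statistics rather
#' than being dropped, so result tables keep a stable shape.
#'
#' @param paired a `PairedProfileTable`.
#' @param metabolite metabolite ID (must be present in the table).
#' @param scope one of `"combined"`, `"patients"`, `"controls"`.
#' @param tuning_const,tol,max_iter passed to [huber_irls()].
#' @return one-row data.frame (a `CorrelationRecord`).
#' @export
correlate_metabolite <- function(paired, metabolite,
                                 scope = c("combined", "patients", "controls"),
                                 tuning_const = 1.345, tol = 1e-8,
                                 max_iter = 50L) {
  stopifnot(inherits(paired, "PairedProfileTable"))
  scope <- match.arg(scope)
  j <- match(metabolite, paired$metabolites)
  if (is.na(j)) stop("unknown metabolite: ", metabolite)
  rows <- scope_rows(paired, scope)
  ok_cell <- paired$mask[, j] & rows
  x <- paired$s_pl[ok_cell, j]
  y <- paired$s_csf[ok_cell, j]
  n <- length(x)
  fit <- tryCatch(huber_irls(x, y, tuning_const, tol, max_iter),
                  insufficient_data_error = function(e) e,
                  degenerate_design_error = function(e) e)
  if (inherits(fit, "condition"))
    return(empty_correlation_record(metabolite, scope, n,
                                    conditionMessage(fit)))
  r_h <- tryCatch(weighted_correlation(x, y, fit$weights),
                  error = function(e) NA_real_)
  if (is.na(r_h))
    return(empty_correlation_record(metabolite, scope, n,
                                    "undefined weighted correlation"))
  p_h <- as.numeric(huber_slope_pvalue(fit, x, y, tuning_const))
  sy <- sd(y)
  if (sy == 0)
    return(empty_correlation_record(metabolite, scope, n, "constant response"))
  r_o <- cor(x, y)
  p_o <- as.numeric(correlation_pvalue(r_o, n))
  data.frame(metabolite = metabolite, scope = scope,
             r_huber = r_h, p_huber = p_h, r_ols = r_o, p_ols = p_o,
             n_obs = n, converged = fit$converged, ok = TRUE,
             flag = NA_character_, stringsAsFactors = FALSE)
}

#' Correlation records for all metabolites and scopes
#'
#' @param paired a `PairedProfileTable`.
#' @param scopes character vector of scopes to evaluate.
#' @param ... passed to [correlate_metabolite()].
#' @return data.frame with one `CorrelationRecord` row per metabolite x scope.
#' @export
correlate_all <- function(paired,
                          scopes = c("combined", "patients", "controls"),
                          ...) {
  stopifnot(inherits(paired, "PairedProfileTable"))
  out <- vector("list", length(scopes) * length(paired$metabolites))
  i <- 0L
  for (sc in scopes) {
    for (m in paired$metabolites) {
      i <- i + 1L
      out[[i]] <- correlate_metabolite(paired, m, sc, ...)
    }
  }
  do.call(rbind, out)
}

#' Scale regression residuals to unit sum of squares
#'
#' Residuals `e_i = y_i - (intercept + slope x_i)` of a robust fit are
#' divided by `sqrt(sum(e^2))` so their squares sum to one; the squared
#' scaled residuals then partition total lack-of-fit across subjects, and
#' summing them within the patient and control groups gives each group's
#' share of the total residual mass.
#'
#' @param fit a `RobustFit`.
#' @param x,y the observations the fit was computed from.
#' @param groups character vector of group labels aligned with `x`.
#' @return list of class `ResidualProfile`: `scaled_residuals`,
#'   `group_share_patients`, `group_share_controls`, `flag`.
#' @export
scale_residuals <- function(fit, x, y, groups) {
  stopifnot(inherits(fit, "RobustFit"), length(x) == length(y),
            length(groups) == length(x))
  e <- y - (fit$intercept + fit$slope * x)
  ss <- sum(e^2)
  is_pat <- groups == "glioma"
  if (ss == 0) {
    n <- length(e)
    return(structure(list(scaled_residuals = rep(0, n),
                          group_share_patients = mean(is_pat),
                          group_share_controls = mean(!is_pat),
                          flag = "zero residuals; shares are group fractions"),
                     class = "ResidualProfile"))
  }
  s <- e / sqrt(ss)
  structure(list(scaled_residuals = s,
                 group_share_patients = sum(s[is_pat]^2),
                 group_share_controls = sum(s[!is_pat]^2),
                 flag = NA_character_),
            class = "ResidualProfile")
}

#' Normalize a residual matrix to unit sum of squares by row or column
#'
#' Matrix variant of [scale_residuals()] for the alternative reading of the
#' scaling rule: `margin = "metabolite"` scales each metabolite's residual
#' vector across subjects (the package default elsewhere), while
#' `margin = "subject"` scales each subject's residual vector across
#' metabolites. All-zero slices are left at zero.
#'
#' @param e residual matrix, subjects in rows and metabolites in columns.
#' @param margin which slice gets unit sum of squares.
#' @export
scale_residual_matrix <- function(e, margin = c("metabolite", "subject")) {
  margin <- match.arg(margin)
  stopifnot(is.matrix(e))
  if (margin == "metabolite") {
    nrm <- sqrt(colSums(e^2, na.rm = TRUE))
    nrm[nrm == 0] <- 1
    sweep(e, 2, nrm, "/")
  } else {
    nrm <- sqrt(rowSums(e^2, na.rm = TRUE))
    nrm[nrm == 0] <- 1
    sweep(e, 1, nrm, "/")
  }
}

#' Correlation between mean plasma and mean CSF metabolic profiles
#'
#' For each metabolite, the mean ln peak area across the scope's subjects is
#' computed separately in plasma and CSF; the returned value is the ordinary
#' Pearson correlation across metabolites between these two mean profiles
#' (the profile-similarity statistic plotted metabolite-per-point).
#'
#' @param paired a `PairedProfileTable`.
#' @param scope `"combined"`, `"patients"` or `"controls"`.
#' @export
mean_profile_correlation <- function(paired,
                                     scope = c("combined", "patients",
                                               "controls")) {
  stopifnot(inherits(paired, "PairedProfileTable"))
  scope <- match.arg(scope)
  rows <- scope_rows(paired, scope)
  if (length(paired$metabolites) < 3)
    stop("need at least 3 metabolites")
  pl <- paired$s_pl[rows, , drop = FALSE]
  cs <- paired$s_csf[rows, , drop = FALSE]
  mpl <- colMeans(pl, na.rm = TRUE)
  mcs <- colMeans(cs, na.rm = TRUE)
  keep <- is.finite(mpl) & is.finite(mcs)
  cor(mpl[keep], mcs[keep])
}
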