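#' Significant-correlation sets per scope and their intersection
#'
#' Splits a [correlate_all()] record table by scope and collects the
#' metabolites whose Huber-correlation p-value is below `alpha` in the
#' combined cohort, in patients, and in controls, plus the three-way
#' intersection. The default uses raw p-values (the study reports raw
#' p < 0.05 across the metabolite panel); Benjamini-Hochberg adjustment
#' within each scope is available behind `adjust = "BH"`.
#'
#' @param records data.frame of correlation records covering the scopes
#'   `combined`, `patients`, `controls`.
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return list with character vectors `S_comb`, `S_pat`, `S_ctrl`,
#'   `S_shared` and an integer vector `sizes`.
#' @export
significant_sets <- function(records, alpha = 0.05,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("combined", "patients", "controls") %in% records$scope))
  pick <- function(sc) {
    r <- records[records$scope == sc, ]
    p <- r$p_huber
    if (adjust == "BH") p <- p.adjust(p, method = "BH")
    sort(r$metabolite[!is.na(p) & p < alpha])
  }
  s_comb <- pick("combined"); s_pat <- pick("patients"); s_ctrl <- pick("controls")
  shared <- intersect(intersect(s_comb, s_pat), s_ctrl)
  list(S_comb = s_comb, S_pat = s_pat, S_ctrl = s_ctrl, S_shared = shared,
       sizes = c(combined = length(s_comb), patients = length(s_pat),
                 controls = length(s_ctrl), shared = length(shared)))
}

#' Classify metabolites whose plasma-CSF correlation is lost in one group
#'
#' A metabolite is "lost in patients" when its correlation is significant and
#' strong in controls (`p_ctrl < alpha` and `|r_ctrl| >= min_abs_r`) but not
#' significant in patients (`p_pat >= alpha`); "lost in controls" is the
#' mirror image. Each list is ranked by the significant scope's p-value,
#' ascending, with ties broken by metabolite ID. The `min_abs_r` floor keeps
#' borderline-significant weak correlations out of the lists.
#'
#' @param records data.frame of correlation records with scopes `patients`
#'   and `controls`.
#' @param alpha significance level.
#' @param min_abs_r minimum |Huber R| in the scope where the correlation is
#'   retained.
#' @return list with data.frames `lost_in_patients` and `lost_in_controls`
#'   (columns metabolite, r_pat, p_pat, r_ctrl, p_ctrl), each ranked.
#' @export
classify_lost <- function(records, alpha = 0.05, min_abs_r = 0.7) {
  stopifnot(all(c("patients", "controls") %in% records$scope))
  pat <- records[records$scope == "patients", ]
  ctl <- records[records$scope == "controls", ]
  mets <- intersect(pat$metabolite, ctl$metabolite)
  pat <- pat[match(mets, pat$metabolite), ]
  ctl <- ctl[match(mets, ctl$metabolite), ]
  tab <- data.frame(metabolite = mets,
                    r_pat = pat$r_huber, p_pat = pat$p_huber,
                    r_ctrl = ctl$r_huber, p_ctrl = ctl$p_huber,
                    stringsAsFactors = FALSE)
  ok <- complete.cases(tab[, c("p_pat", "p_ctrl", "r_pat", "r_ctrl")])
  lip <- tab[ok & tab$p_ctrl < alpha & abs(tab$r_ctrl) >= min_abs_r &
               tab$p_pat >= alpha, ]
  lic <- tab[ok & tab$p_pat < alpha & abs(tab$r_pat) >= min_abs_r &
               tab$p_ctrl >= alpha, ]
  lip <- lip[order(lip$p_ctrl, lip$metabolite), ]
  lic <- lic[order(lic$p_pat, lic$metabolite), ]
  rownames(lip) <- rownames(lic) <- NULL
  list(lost_in_patients = lip, lost_in_controls = lic)
}

#' Mean profiles ranked by plasma abundance
#'
#' Per-metabolite mean ln plasma and CSF values across all subjects of the
#' paired table, sorted by increasing plasma mean (ties broken by metabolite
#' ID) — the ranked-profile view of the two fluids.
#'
#' @param paired a `PairedProfileTable`.
#' @return data.frame with columns `metabolite`, `mean_ln_plasma`,
#'   `mean_ln_csf`, `rank`.
#' @export
ranked_profile_export <- function(paired) {
  stopifnot(inherits(paired, "PairedProfileTable"))
  mpl <- colMeans(paired$s_pl, na.rm = TRUE)
  mcs <- colMeans(paired$s_csf, na.rm = TRUE)
  out <- data.frame(metabolite = paired$metabolites,
                    mean_ln_plasma = mpl, mean_ln_csf = mcs,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_ln_plasma, out$metabolite), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
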