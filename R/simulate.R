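#' Configuration of the matched-biofluid cohort simulator
#'
#' Defaults describe a cohort shaped like the glioma study: 20 glioma and 11
#' control subjects, plasma and CSF per subject, three replicate MRM
#' measurements, and 101 quantified metabolites. The default planted
#' plasma-CSF correlation structure mirrors the reported set structure:
#' 16 metabolites significantly correlated in every scope (rho 0.8 in both
#' groups), 7 with the correlation lost in patients (rho 0 in patients, 0.9
#' in controls), 53 with the correlation lost in controls (0.9 / 0), and 25
#' weakly correlated background metabolites (0.2 / 0.2).
#'
#' @param n_glioma,n_control subjects per group (each >= 2).
#' @param n_replicates replicate measurements per (subject, fluid).
#' @param n_metabolites quantified metabolites.
#' @param rho_by_group matrix/data.frame with columns `rho_patient`,
#'   `rho_control` (one row per metabolite), or `NULL` for the default
#'   planted scheme described above (requires `n_metabolites >= 4`; the four
#'   class sizes are scaled proportionally when `n_metabolites != 101`).
#' @param outlier_fraction fraction of (subject, metabolite) latent pairs
#'   whose CSF value is perturbed (must be < 0.5).
#' @param outlier_scale size of the perturbation in units of the
#'   metabolite's CSF standard deviation (> 1).
#' @param replicate_cv coefficient of variation of multiplicative replicate
#'   noise on the peak-area scale.
#' @param block_assignment character/integer vector of per-metabolite block
#'   labels (`NA` = no block), `NULL` for the default two planted blocks of
#'   8 metabolites, or `"none"` for no blocks at all.
#' @param block_loading loading of the shared per-(subject, block) factor in
#'   (0, 1); within-block same-fluid metabolite pairs correlate at
#'   `block_loading^2`.
#' @param n_extra_undetected additional screened-but-poorly-detected
#'   metabolites appended to emulate the screened panel (present in only
#'   ~30% of CSF samples, so a 0.8 dual-detection filter removes them).
#' @param seed integer seed; all randomness derives from it.
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_glioma = 20L, n_control = 11L,
                              n_replicates = 3L, n_metabolites = 101L,
                              rho_by_group = NULL,
                              outlier_fraction = 0, outlier_scale = 5,
                              replicate_cv = 0.1,
                              block_assignment = NULL, block_loading = 0.9,
                              n_extra_undetected = 0L, seed = 1L) {
  stopifnot(n_glioma >= 2, n_control >= 2, n_replicates >= 1,
            n_metabolites >= 1, outlier_fraction >= 0, outlier_fraction < 0.5,
            outlier_scale > 1, replicate_cv > 0,
            block_loading > 0, block_loading < 1, n_extra_undetected >= 0)
  if (is.null(rho_by_group)) {
    rho_by_group <- default_rho_scheme(n_metabolites)
  } else {
    rho_by_group <- as.data.frame(rho_by_group)
    stopifnot(all(c("rho_patient", "rho_control") %in% names(rho_by_group)),
              nrow(rho_by_group) == n_metabolites)
  }
  if (any(abs(rho_by_group$rho_patient) > 1) ||
      any(abs(rho_by_group$rho_control) > 1))
    stop("planted correlations must lie in [-1, 1]")
  if (is.null(block_assignment)) {
    block_assignment <- rep(NA_character_, n_metabolites)
    # two planted blocks of 8, one inside the shared-significant class and
    # one inside the weak background class (so targets stay exactly attainable)
    cls <- attr(rho_by_group, "class_of")
    if (!is.null(cls)) {
      b1 <- which(cls == "shared")[seq_len(min(8, sum(cls == "shared")))]
      b2 <- which(cls == "weak")[seq_len(min(8, sum(cls == "weak")))]
      block_assignment[b1] <- "B1"
      block_assignment[b2] <- "B2"
    }
  } else if (identical(block_assignment, "none")) {
    block_assignment <- rep(NA_character_, n_metabolites)
  } else {
    stopifnot(length(block_assignment) == n_metabolites)
    block_assignment <- as.character(block_assignment)
  }
  structure(list(n_glioma = as.integer(n_glioma),
                 n_control = as.integer(n_control),
                 n_replicates = as.integer(n_replicates),
                 n_metabolites = as.integer(n_metabolites),
                 rho_by_group = rho_by_group,
                 outlier_fraction = outlier_fraction,
                 outlier_scale = outlier_scale,
                 replicate_cv = replicate_cv,
                 block_assignment = block_assignment,
                 block_loading = block_loading,
                 n_extra_undetected = as.integer(n_extra_undetected),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# Planted-correlation classes sized after the study's reported sets
# (16 shared / 7 lost-in-patients / 53 lost-in-controls / 25 weak at M=101),
# scaled proportionally for other panel sizes.
default_rho_scheme <- function(m) {
  base <- c(shared = 16, lost_pat = 7, lost_ctrl = 53, weak = 25)
  if (m == 101) {
    sizes <- base
  } else if (m < 4) {
    stop("the default correlation scheme needs n_metabolites >= 4; ",
         "supply rho_by_group explicitly for smaller panels")
  } else {
    sizes <- pmax(round(base * m / 101), 1)   # pmax(x, 1) keeps names
    while (sum(sizes) > m) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1
    sizes["weak"] <- sizes["weak"] + (m - sum(sizes))
  }
  cls <- rep(names(sizes), times = sizes)
  rho <- data.frame(
    rho_patient = c(shared = 0.8, lost_pat = 0.0, lost_ctrl = 0.9,
                    weak = 0.2)[cls],
    rho_control = c(shared = 0.8, lost_pat = 0.9, lost_ctrl = 0.0,
                    weak = 0.2)[cls])
  rownames(rho) <- NULL
  attr(rho, "class_of") <- cls
  rho
}

#' Simulate a matched plasma/CSF replicate-level dataset
#'
#' Generative model, per subject s in group g and metabolite m: the latent
#' ln-scale pair (plasma, CSF) is bivariate normal with metabolite-specific
#' means and standard deviations and group-specific correlation
#' `rho_{g,m}`. Metabolites sharing a block additionally load (with loading
#' lambda) on a per-(subject, block) factor pair whose plasma-CSF correlation
#' equals the block's mean target rho per group; the idiosyncratic pair
#' correlation is solved so the total plasma-CSF correlation hits the target
#' (clamped to [-1, 1] when a crossing block makes a target unattainable; the
#' achieved value is recorded in the truth object). A fraction
#' `outlier_fraction` of (subject, metabolite) pairs has the latent CSF value
#' shifted by `outlier_scale` CSF standard deviations (random sign) — the
#' contamination Huber weighting is meant to suppress. Replicate peak areas
#' are `exp(latent)` times mean-one log-normal noise with coefficient of
#' variation `replicate_cv`.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `dataset` (replicate-level
#'   `MetabolomicsDataset`) and `truth` (`SyntheticTruth`: data.frame `rho`
#'   with planted and achieved correlations and outlier counts, the planted
#'   sets `lost_in_patients`, `lost_in_controls`, `shared_significant`,
#'   `blocks`, and `detected`, the IDs of the quantified panel).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  n_sub <- cfg$n_glioma + cfg$n_control
  m <- cfg$n_metabolites
  subjects <- sprintf("S%02d", seq_len(n_sub))
  groups <- rep(c("glioma", "control"), c(cfg$n_glioma, cfg$n_control))

  met_ids <- sprintf("met%03d", seq_len(m))
  compound <- sprintf("C%05d", seq_len(m))
  mu_pl <- runif(m, 8, 16)
  mu_cs <- mu_pl - runif(m, 0, 2)
  sd_pl <- runif(m, 0.4, 1.0)
  sd_cs <- runif(m, 0.4, 1.0)

  rho_pat <- cfg$rho_by_group$rho_patient
  rho_ctl <- cfg$rho_by_group$rho_control
  lam <- cfg$block_loading
  blocks <- cfg$block_assignment
  blk_ids <- unique(blocks[!is.na(blocks)])

  # per-group block-factor correlation = mean target rho of members
  blk_rho <- function(rho) vapply(blk_ids, function(b)
    mean(rho[which(blocks == b)]), numeric(1))
  blk_rho_pat <- blk_rho(rho_pat)
  blk_rho_ctl <- blk_rho(rho_ctl)

  # idiosyncratic correlation solving lam^2 * rho_blk + (1-lam^2) * rho_e = rho
  solve_rho_e <- function(target, in_block, rho_blk_of_m) {
    out <- target
    i <- which(in_block)
    out[i] <- (target[i] - lam^2 * rho_blk_of_m[i]) / (1 - lam^2)
    pmin(1, pmax(-1, out))
  }
  in_blk <- !is.na(blocks)
  rho_blk_pat_m <- ifelse(in_blk, blk_rho_pat[match(blocks, blk_ids)], 0)
  rho_blk_ctl_m <- ifelse(in_blk, blk_rho_ctl[match(blocks, blk_ids)], 0)
  rho_e_pat <- solve_rho_e(rho_pat, in_blk, rho_blk_pat_m)
  rho_e_ctl <- solve_rho_e(rho_ctl, in_blk, rho_blk_ctl_m)
  ach_pat <- ifelse(in_blk, lam^2 * rho_blk_pat_m + (1 - lam^2) * rho_e_pat,
                    rho_e_pat)
  ach_ctl <- ifelse(in_blk, lam^2 * rho_blk_ctl_m + (1 - lam^2) * rho_e_ctl,
                    rho_e_ctl)

  # latent (subject x metabolite) matrices, unit scale
  u_pl <- matrix(0, n_sub, m)
  u_cs <- matrix(0, n_sub, m)
  is_pat <- groups == "glioma"
  # block factors: one (plasma, csf) pair per subject per block
  if (length(blk_ids) > 0) {
    g_pl <- matrix(rnorm(n_sub * length(blk_ids)), n_sub)
    g_cs <- matrix(NA_real_, n_sub, length(blk_ids))
    for (b in seq_along(blk_ids)) {
      rb <- ifelse(is_pat, blk_rho_pat[b], blk_rho_ctl[b])
      g_cs[, b] <- rb * g_pl[, b] + sqrt(1 - rb^2) * rnorm(n_sub)
    }
  }
  for (j in seq_len(m)) {
    e_pl <- rnorm(n_sub)
    rho_e <- ifelse(is_pat, rho_e_pat[j], rho_e_ctl[j])
    e_cs <- rho_e * e_pl + sqrt(1 - rho_e^2) * rnorm(n_sub)
    if (in_blk[j]) {
      b <- match(blocks[j], blk_ids)
      u_pl[, j] <- lam * g_pl[, b] + sqrt(1 - lam^2) * e_pl
      u_cs[, j] <- lam * g_cs[, b] + sqrt(1 - lam^2) * e_cs
    } else {
      u_pl[, j] <- e_pl
      u_cs[, j] <- e_cs
    }
  }
  z_pl <- sweep(sweep(u_pl, 2, sd_pl, "*"), 2, mu_pl, "+")
  z_cs <- sweep(sweep(u_cs, 2, sd_cs, "*"), 2, mu_cs, "+")

  # CSF outliers on the latent scale
  n_out_cells <- round(cfg$outlier_fraction * n_sub * m)
  outlier_mask <- matrix(FALSE, n_sub, m)
  if (n_out_cells > 0) {
    cells <- sample.int(n_sub * m, n_out_cells)
    outlier_mask[cells] <- TRUE
    shift <- sample(c(-1, 1), n_out_cells, replace = TRUE) * cfg$outlier_scale
    z_cs[cells] <- z_cs[cells] + shift * sd_cs[(cells - 1) %/% n_sub + 1]
  }

  # replicate-level peak areas with multiplicative log-normal noise (mean 1)
  sig <- sqrt(log(1 + cfg$replicate_cv^2))
  n_rep <- cfg$n_replicates
  samp <- expand.grid(replicate = seq_len(n_rep), fluid = FLUIDS,
                      subject = subjects, stringsAsFactors = FALSE)
  samp <- samp[, c("subject", "fluid", "replicate")]
  samp$group <- groups[match(samp$subject, subjects)]
  n_row <- nrow(samp)
  area <- matrix(NA_real_, n_row, m)
  sub_i <- match(samp$subject, subjects)
  lat <- ifelse(samp$fluid == "plasma", 1, 2)
  for (j in seq_len(m)) {
    base <- ifelse(lat == 1, z_pl[cbind(sub_i, j)], z_cs[cbind(sub_i, j)])
    area[, j] <- exp(base) * exp(sig * rnorm(n_row) - sig^2 / 2)
  }

  # optional screened-but-undetected extras: sparse in CSF
  n_x <- cfg$n_extra_undetected
  if (n_x > 0) {
    x_ids <- sprintf("scr%03d", seq_len(n_x))
    x_area <- matrix(NA_real_, n_row, n_x)
    mu_x <- runif(n_x, 6, 10)
    present_csf <- matrix(rbinom(n_sub * n_x, 1, 0.3) == 1, n_sub, n_x)
    for (j in seq_len(n_x)) {
      v <- exp(rnorm(n_row, mu_x[j], 0.6))
      drop <- lat == 2 & !present_csf[cbind(sub_i, j)]
      v[drop] <- NA_real_
      x_area[, j] <- v
    }
    area <- cbind(area, x_area)
    met_ids_all <- c(met_ids, x_ids)
    compound_all <- c(compound, rep(NA_character_, n_x))
  } else {
    met_ids_all <- met_ids
    compound_all <- compound
  }

  ds <- metabolomics_dataset(
    samples = samp[, c("subject", "group", "fluid", "replicate")],
    metabolites = data.frame(metabolite = met_ids_all,
                             compound_id = compound_all,
                             stringsAsFactors = FALSE),
    peak_area = area)

  cls <- attr(cfg$rho_by_group, "class_of")
  truth <- structure(list(
    rho = data.frame(metabolite = met_ids, compound_id = compound,
                     rho_patient = rho_pat, rho_control = rho_ctl,
                     achieved_rho_patient = ach_pat,
                     achieved_rho_control = ach_ctl,
                     block = blocks,
                     n_outliers = colSums(outlier_mask),
                     stringsAsFactors = FALSE),
    lost_in_patients   = if (!is.null(cls)) met_ids[cls == "lost_pat"] else character(0),
    lost_in_controls   = if (!is.null(cls)) met_ids[cls == "lost_ctrl"] else character(0),
    shared_significant = if (!is.null(cls)) met_ids[cls == "shared"] else character(0),
    blocks = setNames(blocks, met_ids),
    detected = met_ids,
    outlier_mask = outlier_mask,
    seed = cfg$seed), class = "SyntheticTruth")
  list(dataset = ds, truth = truth)
}

#' Write a synthetic pathway collection in GMT format
#'
#' Produces a plain-text GMT fixture keyed by the simulator's compound IDs.
#' Half of the requested pathways are planted as enriched: at least 50% of
#' their members come from one planted correlation block (falling back to
#' the shared-significant set when no blocks exist). The rest are uniform
#' random draws from the compound universe. Set sizes are drawn between
#' `size_range[1]` and `min(size_range[2], universe size)`.
#'
#' @param path output file path.
#' @param n_pathways number of sets to write.
#' @param truth a `SyntheticTruth` from [simulate_dataset()].
#' @param size_range inclusive bounds on pathway sizes.
#' @param seed integer seed.
#' @return invisibly, a data.frame describing the written sets (`id`,
#'   `planted`, `block`).
#' @export
write_fixture_gmt <- function(path, n_pathways, truth,
                              size_range = c(5L, 165L), seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"), n_pathways >= 1)
  set.seed(seed)
  universe <- truth$rho$compound_id
  names(universe) <- truth$rho$metabolite
  blk <- truth$blocks[!is.na(truth$blocks)]
  blk_ids <- unique(blk)
  smax <- min(size_range[2], length(universe))
  smin <- min(size_range[1], smax)
  lines <- character(n_pathways)
  meta <- data.frame(id = sprintf("PW%03d", seq_len(n_pathways)),
                     planted = FALSE, block = NA_character_,
                     stringsAsFactors = FALSE)
  n_planted <- floor(n_pathways / 2)
  for (i in seq_len(n_pathways)) {
    if (i <= n_planted && (length(blk_ids) > 0 ||
                           length(truth$shared_significant) > 0)) {
      if (length(blk_ids) > 0) {
        b <- blk_ids[1 + (i - 1) %% length(blk_ids)]
        core_mets <- names(blk)[blk == b]
        meta$block[i] <- b
      } else {
        core_mets <- truth$shared_significant
        meta$block[i] <- "shared"
      }
      core <- universe[core_mets]
      # >= 50% of members from the block caps planted sizes at 2x block size
      pmax_size <- max(smin, min(smax, 2L * length(core)))
      size <- if (smin == pmax_size) smin
              else sample(seq(smin, pmax_size), 1)
      n_core <- min(length(core), size - floor(size / 2))
      members <- sample(core, n_core)
      filler <- setdiff(universe, members)
      n_fill <- min(length(filler), max(0, size - n_core))
      if (n_fill > 0) members <- c(members, sample(filler, n_fill))
      meta$planted[i] <- TRUE
    } else {
      size <- if (smin == smax) smin else sample(seq(smin, smax), 1)
      members <- sample(universe, min(size, length(universe)))
    }
    lines[i] <- paste(c(meta$id[i],
                        sprintf("synthetic pathway %d", i),
                        members), collapse = "\t")
  }
  writeLines(lines, path)
  invisible(meta)
}
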