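PIPELINE_DEFAULTS <- list(
  input = NULL,               # long-format peak table (required)
  gmt = NULL,                 # optional pathway collection
  id_map = NULL,              # optional metabolite -> compound mapping CSV
  out_dir = NULL,             # output directory (required)
  pseudocount = 0,
  detection_fraction = 0.8,
  alpha = 0.05,
  min_abs_r = 0.7,
  edge_alpha = 0.05,
  positive_edges_only = TRUE,
  q = 0.95,
  n_blocks = 2L,
  n_restarts = 20L,
  min_component_size = 3L,
  min_found = 1L,
  bh_across_metabolites = FALSE,
  residual_scaling = "metabolite",
  n_orth = 1L,
  cv_folds = 7L,
  seed = 1L)

#' Validate a pipeline configuration
#'
#' Merges user settings over the package defaults, rejecting unknown keys.
#' Accepts a named list or the path of a JSON file.
#'
#' @param config named list or JSON file path.
#' @return validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, config)
  if (is.null(cfg$input) || is.null(cfg$out_dir))
    stop("configuration must set 'input' and 'out_dir'")
  stopifnot(cfg$pseudocount >= 0,
            cfg$detection_fraction >= 0, cfg$detection_fraction <= 1,
            cfg$alpha > 0, cfg$alpha <= 1,
            cfg$edge_alpha > 0, cfg$edge_alpha <= 1,
            cfg$q > 0, cfg$q < 1, cfg$n_blocks >= 1,
            cfg$residual_scaling %in% c("metabolite", "subject"))
  class(cfg) <- "PipelineConfig"
  cfg
}

write_table_out <- function(df, path) {
  data.table::fwrite(df, path, quote = FALSE, na = "NA")
  path
}

#' Run the complete matched-biofluid analysis
#'
#' Executes every stage on one input table: replicate averaging, ln
#' transformation, dual-fluid detection filtering, paired-profile assembly,
#' mean-profile correlations, per-metabolite robust correlation records in
#' all three scopes, significant-set / lost-set classification, the pooled
#' pairwise correlation network with DC-SBM blocks, percentile subgraph and
#' connected components, optional pathway overrepresentation for the derived
#' metabolite sets, and PCA/UMAP/OPLS-DA projections of the replicate-level
#' profiles. All outputs are plain-text files under `cfg$out_dir`, listed
#' with MD5 checksums in `manifest.csv`; `summary.json` carries the headline
#' numbers and full provenance (seed, config, package version).
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the summary list.
#' @export
run_all <- function(cfg) {
  if (!inherits(cfg, "PipelineConfig")) cfg <- pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ds <- stage("read", read_peak_table(cfg$input))
  flt <- stage("preprocess", {
    avg <- average_replicates(ds)
    lnd <- ln_transform(avg, cfg$pseudocount)
    filter_detected(lnd, cfg$detection_fraction)
  })
  paired <- stage("pair", build_paired_table(flt))

  mean_r <- stage("mean-profiles", vapply(
    c("combined", "patients", "controls"),
    function(sc) mean_profile_correlation(paired, sc), numeric(1)))

  records <- stage("correlate", correlate_all(paired))
  write_table_out(records, out("correlations.csv"))

  adjust <- if (isTRUE(cfg$bh_across_metabolites)) "BH" else "none"
  sets <- stage("sets", significant_sets(records, cfg$alpha, adjust))
  lost <- stage("lost", classify_lost(records, cfg$alpha, cfg$min_abs_r))
  write_table_out(lost$lost_in_patients, out("lost_in_patients.csv"))
  write_table_out(lost$lost_in_controls, out("lost_in_controls.csv"))
  write_table_out(ranked_profile_export(paired), out("ranked_profiles.csv"))

  pooled <- stage("pool", pooled_matrix(flt))
  pairs <- stage("pairwise", pairwise_correlations(pooled))
  write_table_out(pairs, out("pairwise_correlations.csv"))
  g <- stage("graph", build_graph(pairs, cfg$edge_alpha,
                                  positive_only = cfg$positive_edges_only))
  sbm <- stage("sbm", fit_dcsbm(g, cfg$n_blocks, cfg$n_restarts, cfg$seed))
  igraph::V(g)$block <- as.integer(sbm$membership[igraph::V(g)$name])
  igraph::write_graph(g, out("network.graphml"), format = "graphml")
  sub <- stage("subgraph", percentile_subgraph(g, cfg$q))
  comps <- stage("components",
                 connected_components(sub$graph, cfg$min_component_size))
  comp_df <- do.call(rbind, lapply(seq_along(comps$members), function(i)
    data.frame(component = paste0("C", i), metabolite = comps$members[[i]],
               stringsAsFactors = FALSE)))
  if (is.null(comp_df))
    comp_df <- data.frame(component = character(0), metabolite = character(0))
  write_table_out(comp_df, out("components.csv"))

  enr_files <- character(0)
  if (!is.null(cfg$gmt)) {
    collection <- stage("gmt", read_gmt(cfg$gmt))
    to_ids <- if (!is.null(cfg$id_map)) {
      idm <- read_id_map(cfg$id_map)
      function(mets) map_ids(mets, idm)
    } else {
      cid <- setNames(flt$metabolites$compound_id, flt$metabolites$metabolite)
      function(mets) {
        v <- cid[mets]
        v[!is.na(v)]
      }
    }
    queries <- c(list(shared_significant = sets$S_shared,
                      lost_in_patients = lost$lost_in_patients$metabolite,
                      lost_in_controls = lost$lost_in_controls$metabolite),
                 split(names(sbm$membership),
                       paste0("block_", sbm$membership)),
                 setNames(comps$members,
                          paste0("component_", seq_along(comps$members))))
    for (qn in names(queries)) {
      ids <- suppressWarnings(to_ids(queries[[qn]]))
      res <- suppressWarnings(
        stage(paste0("enrich-", qn), enrich(ids, collection, cfg$min_found)))
      f <- out(sprintf("enrichment_%s.csv", qn))
      write_table_out(res, f)
      enr_files <- c(enr_files, f)
    }
  }

  proj <- stage("project", {
    repl_ln <- ln_transform(ds, cfg$pseudocount)
    keep <- flt$metabolites$metabolite
    m <- repl_ln$peak_area[, keep, drop = FALSE]
    rownames(m) <- paste(repl_ln$samples$subject, repl_ln$samples$fluid,
                         repl_ln$samples$replicate, sep = ":")
    m <- impute_column_means(m)
    pca <- pca_embed(m)
    coords <- data.frame(sample = rownames(m),
                         group = repl_ln$samples$group,
                         fluid = repl_ln$samples$fluid,
                         PC1 = pca$coordinates[, 1],
                         PC2 = pca$coordinates[, 2],
                         stringsAsFactors = FALSE)
    um <- tryCatch(umap_embed(m, seed = cfg$seed), error = function(e) NULL)
    if (!is.null(um)) {
      coords$UMAP1 <- um$coordinates[, 1]
      coords$UMAP2 <- um$coordinates[, 2]
    }
    opls <- opls_da_fit(m, repl_ln$samples$group, n_orth = cfg$n_orth,
                        cv_folds = cfg$cv_folds, seed = cfg$seed)
    coords$opls_score <- opls$scores_pred
    write_table_out(coords, out("embedding.csv"))
    list(pca_var = pca$explained_variance[1:2],
         umap = !is.null(um),
         opls_cv_accuracy = opls$cv_accuracy, opls_q2 = opls$q2)
  })

  summary <- list(
    package_version = as.character(utils::packageVersion("metabopair")),
    seed = cfg$seed,
    config = unclass(cfg),
    n_samples = nrow(ds$samples),
    n_metabolites_input = nrow(ds$metabolites),
    n_metabolites_analyzed = nrow(flt$metabolites),
    n_subjects_paired = nrow(paired$subjects),
    mean_profile_r = as.list(mean_r),
    set_sizes = as.list(sets$sizes),
    n_lost_in_patients = nrow(lost$lost_in_patients),
    n_lost_in_controls = nrow(lost$lost_in_controls),
    graph = list(vertices = igraph::vcount(g), edges = igraph::ecount(g),
                 description_length = sbm$description_length,
                 n_blocks_effective = sbm$n_blocks_effective,
                 percentile_threshold = sub$threshold,
                 n_components = length(comps$members)),
    projection = proj)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  files <- setdiff(list.files(cfg$out_dir, full.names = TRUE),
                   out("manifest.csv"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_table_out(manifest, out("manifest.csv"))
  invisible(summary)
}
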