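#' @importFrom stats mad median pt cor quantile rnorm runif rbinom sd phyper
#'   p.adjust complete.cases setNames
#' @importFrom utils head combn
NULL

GROUPS <- c("glioma", "control")
FLUIDS <- c("plasma", "csf")

#' Construct a targeted-metabolomics peak-area dataset
#'
#' The central container of the package: an intensity matrix of integrated
#' MRM peak areas (samples in rows, metabolites in columns) together with the
#' sample metadata that defines the matched-biofluid design. Each sample is a
#' (subject, fluid, replicate) measurement; each subject belongs to exactly
#' one group (`glioma` or `control`). Missing measurements are `NA` cells.
#'
#' @param samples data.frame with columns `subject`, `group` (`glioma` or
#'   `control`), `fluid` (`plasma` or `csf`), `replicate` (positive integer).
#' @param metabolites data.frame with columns `metabolite` (unique IDs) and
#'   optionally `compound_id` (e.g. KEGG compound accession, may be `NA`).
#' @param peak_area numeric matrix `[nrow(samples) x nrow(metabolites)]` of
#'   non-negative intensities; `NA` marks a missing cell.
#' @return An object of class `MetabolomicsDataset`.
#' @export
metabolomics_dataset <- function(samples, metabolites, peak_area) {
  stopifnot(is.data.frame(samples), is.data.frame(metabolites),
            is.matrix(peak_area))
  req <- c("subject", "group", "fluid", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0)
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!"metabolite" %in% names(metabolites))
    stop("metabolite table lacks column 'metabolite'")
  if (!"compound_id" %in% names(metabolites))
    metabolites$compound_id <- NA_character_
  samples$subject   <- as.character(samples$subject)
  samples$group     <- as.character(samples$group)
  samples$fluid     <- as.character(samples$fluid)
  samples$replicate <- as.integer(samples$replicate)
  bad_g <- setdiff(unique(samples$group), GROUPS)
  if (length(bad_g) > 0)
    stop("unknown group label(s): ", paste(bad_g, collapse = ", "))
  bad_f <- setdiff(unique(samples$fluid), FLUIDS)
  if (length(bad_f) > 0)
    stop("unknown fluid label(s): ", paste(bad_f, collapse = ", "))
  if (any(samples$replicate < 1L))
    stop("replicate indices must be positive")
  key <- paste(samples$subject, samples$fluid, samples$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate sample key (subject, fluid, replicate): ",
         gsub("\r", "/", key[duplicated(key)][1]))
  gx <- tapply(samples$group, samples$subject, function(g) length(unique(g)))
  if (any(gx > 1))
    stop("subject assigned to more than one group: ",
         names(gx)[which(gx > 1)[1]])
  if (anyDuplicated(metabolites$metabolite))
    stop("duplicate metabolite ID: ",
         metabolites$metabolite[duplicated(metabolites$metabolite)][1])
  if (nrow(peak_area) != nrow(samples) || ncol(peak_area) != nrow(metabolites))
    stop("peak_area dimensions do not match sample/metabolite tables")
  if (any(peak_area < 0, na.rm = TRUE))
    stop("peak areas must be non-negative")
  dimnames(peak_area) <- list(NULL, metabolites$metabolite)
  rownames(samples) <- NULL
  rownames(metabolites) <- NULL
  structure(list(samples = samples, metabolites = metabolites,
                 peak_area = peak_area, log_scale = FALSE),
            class = "MetabolomicsDataset")
}

#' @export
print.MetabolomicsDataset <- function(x, ...) {
  ns <- nrow(x$samples)
  cat(sprintf("MetabolomicsDataset: %d samples x %d metabolites (%s scale)\n",
              ns, nrow(x$metabolites), if (x$log_scale) "ln" else "area"))
  cat(sprintf("  subjects: %d (%d glioma, %d control); fluids: %s; replicates: %s\n",
              length(unique(x$samples$subject)),
              length(unique(x$samples$subject[x$samples$group == "glioma"])),
              length(unique(x$samples$subject[x$samples$group == "control"])),
              paste(sort(unique(x$samples$fluid)), collapse = "/"),
              paste(range(x$samples$replicate), collapse = "-")))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x$peak_area)),
              100 * mean(is.na(x$peak_area))))
  invisible(x)
}

#' Read a long-format peak-area table
#'
#' Expects a delimited file with columns `subject`, `group`, `fluid`,
#' `replicate`, `metabolite`, `peak_area` (one row per measurement) and an
#' optional `compound_id` column. Unparseable peak areas become missing
#' cells; absent (subject, fluid, replicate, metabolite) combinations are
#' also missing.
#'
#' @param path file path (CSV or TSV; delimiter sniffed by `data.table::fread`).
#' @param sep optional explicit field separator.
#' @return A [metabolomics_dataset()].
#' @export
read_peak_table <- function(path, sep = "auto") {
  hdr <- names(data.table::fread(path, sep = sep, nrows = 0L))
  dt <- data.table::fread(path, sep = sep, colClasses = list(
    character = intersect(c("subject", "group", "fluid", "metabolite",
                            "compound_id", "peak_area"), hdr)))
  req <- c("subject", "group", "fluid", "replicate", "metabolite", "peak_area")
  miss <- setdiff(req, names(dt))
  if (length(miss) > 0)
    stop("input table lacks required column(s): ", paste(miss, collapse = ", "))
  key <- paste(dt$subject, dt$fluid, dt$replicate, dt$metabolite, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate measurement row for key (subject/fluid/replicate/metabolite): ",
         key[duplicated(key)][1])
  area <- suppressWarnings(as.numeric(dt$peak_area))
  n_bad <- sum(is.na(area) & !is.na(dt$peak_area) &
                 !(trimws(as.character(dt$peak_area)) %in% c("", "NA", "NaN")))
  if (n_bad > 0)
    message(n_bad, " peak_area value(s) unparseable; masked as missing")

  samples <- unique(data.frame(subject = dt$subject, group = dt$group,
                               fluid = dt$fluid,
                               replicate = as.integer(dt$replicate),
                               stringsAsFactors = FALSE))  # first-appearance order
  mets <- unique(data.frame(
    metabolite = dt$metabolite,
    compound_id = if ("compound_id" %in% names(dt)) dt$compound_id else NA_character_,
    stringsAsFactors = FALSE))
  mets <- mets[!duplicated(mets$metabolite), ]
  mets <- mets[order(match(mets$metabolite, unique(dt$metabolite))), ]

  skey <- paste(samples$subject, samples$fluid, samples$replicate, sep = "\r")
  ri <- match(paste(dt$subject, dt$fluid, dt$replicate, sep = "\r"), skey)
  ci <- match(dt$metabolite, mets$metabolite)
  mat <- matrix(NA_real_, nrow(samples), nrow(mets))
  mat[cbind(ri, ci)] <- area
  message("read_peak_table: ", nrow(dt), " rows -> ",
          nrow(samples), " samples x ", nrow(mets), " metabolites")
  metabolomics_dataset(samples, mets, mat)
}

#' Write a dataset back to a long-format delimited table
#'
#' Inverse of [read_peak_table()]: cells (including missing ones, written as
#' `NA`) are emitted one row per measurement with full decimal precision so
#' that a read/write round trip preserves every value exactly.
#'
#' @param ds a `MetabolomicsDataset`.
#' @param path output path; `.tsv` extension selects tab separation.
#' @export
write_peak_table <- function(ds, path) {
  stopifnot(inherits(ds, "MetabolomicsDataset"))
  n_m <- nrow(ds$metabolites)
  long <- data.frame(
    subject    = rep(ds$samples$subject, each = n_m),
    group      = rep(ds$samples$group, each = n_m),
    fluid      = rep(ds$samples$fluid, each = n_m),
    replicate  = rep(ds$samples$replicate, each = n_m),
    metabolite = rep(ds$metabolites$metabolite, times = nrow(ds$samples)),
    compound_id = rep(ds$metabolites$compound_id, times = nrow(ds$samples)),
    peak_area  = sprintf("%.17g", t(ds$peak_area)),
    stringsAsFactors = FALSE)
  long$peak_area[long$peak_area %in% c("NA", "nan")] <- "NA"
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  data.table::fwrite(long, path, sep = sep, quote = FALSE, na = "NA")
  invisible(path)
}

#' Average replicate measurements
#'
#' Collapses the replicate dimension: every (subject, fluid) keeps a single
#' sample whose cell value is the arithmetic mean of the replicate peak areas
#' that are present. A cell is missing only when all replicates are missing.
#' Averaging is done on the raw area scale; apply [ln_transform()] afterwards.
#'
#' @param ds a `MetabolomicsDataset`.
#' @return A `MetabolomicsDataset` with one sample per (subject, fluid) and
#'   `replicate = 1`.
#' @export
average_replicates <- function(ds) {
  stopifnot(inherits(ds, "MetabolomicsDataset"))
  gid <- paste(ds$samples$subject, ds$samples$fluid, sep = "\r")
  ug <- unique(gid)
  idx <- match(gid, ug)
  n_m <- nrow(ds$metabolites)
  mat <- matrix(NA_real_, length(ug), n_m)
  for (j in seq_len(n_m)) {
    v <- ds$peak_area[, j]
    s <- tapply(v, idx, function(z) if (all(is.na(z))) NA_real_
                else mean(z, na.rm = TRUE))
    mat[as.integer(names(s)), j] <- as.numeric(s)
  }
  first <- match(ug, gid)
  samples <- ds$samples[first, , drop = FALSE]
  samples$replicate <- 1L
  out <- metabolomics_dataset(samples, ds$metabolites, mat)
  out$log_scale <- ds$log_scale
  out
}

#' Natural-log transform peak areas
#'
#' Replaces each cell by `ln(peak_area + pseudocount)`. Cells where
#' `peak_area + pseudocount <= 0` (e.g. exact zeros with the default
#' pseudocount of 0) are masked missing rather than producing `-Inf`.
#'
#' @param ds a `MetabolomicsDataset` on the raw area scale.
#' @param pseudocount non-negative offset added before taking logs.
#' @export
ln_transform <- function(ds, pseudocount = 0) {
  stopifnot(inherits(ds, "MetabolomicsDataset"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0)
    stop("pseudocount must be a single non-negative number")
  if (ds$log_scale) stop("dataset is already ln-transformed")
  v <- ds$peak_area + pseudocount
  v[!is.na(v) & v <= 0] <- NA_real_
  ds$peak_area <- log(v)
  ds$log_scale <- TRUE
  ds
}

#' Filter metabolites by detection rate in both fluids
#'
#' Keeps a metabolite only when its fraction of non-missing cells is at least
#' `min_fraction_per_fluid` among plasma samples AND among CSF samples. This
#' is the stand-in rule reducing the screened panel to the dually-detected
#' analysis panel; the threshold is deliberately exposed because no published
#' rule exists for that reduction.
#'
#' @param ds a `MetabolomicsDataset` (normally replicate-averaged).
#' @param min_fraction_per_fluid required presence fraction in each fluid.
#' @export
filter_detected <- function(ds, min_fraction_per_fluid = 0.8) {
  stopifnot(inherits(ds, "MetabolomicsDataset"),
            min_fraction_per_fluid >= 0, min_fraction_per_fluid <= 1)
  keep <- rep(TRUE, nrow(ds$metabolites))
  for (f in FLUIDS) {
    rows <- ds$samples$fluid == f
    if (!any(rows)) next
    frac <- colMeans(!is.na(ds$peak_area[rows, , drop = FALSE]))
    keep <- keep & (frac >= min_fraction_per_fluid)
  }
  ds$metabolites <- ds$metabolites[keep, , drop = FALSE]
  rownames(ds$metabolites) <- NULL
  ds$peak_area <- ds$peak_area[, keep, drop = FALSE]
  ds
}

#' Build the per-subject paired plasma/CSF profile table
#'
#' Rearranges an averaged, ln-transformed dataset into matched per-subject
#' profiles: `s_pl[i, m]` and `s_csf[i, m]` hold subject i's ln mean peak
#' area of metabolite m in plasma and CSF. Subjects lacking either fluid are
#' dropped with a warning. The `mask` is `TRUE` only where both fluid values
#' are present; downstream regressions use pairwise-complete cells.
#'
#' @param ds an averaged, ln-transformed `MetabolomicsDataset` containing
#'   both fluids.
#' @return An object of class `PairedProfileTable` with elements `subjects`
#'   (data.frame subject/group), `metabolites`, `s_pl`, `s_csf`, `mask`.
#' @export
build_paired_table <- function(ds) {
  stopifnot(inherits(ds, "MetabolomicsDataset"))
  if (!ds$log_scale)
    warning("building paired table from a dataset not ln-transformed")
  key <- paste(ds$samples$subject, ds$samples$fluid, sep = "\r")
  if (anyDuplicated(key))
    stop("dataset has several samples per (subject, fluid); average replicates first")
  subs <- unique(ds$samples$subject)
  has_pl <- subs %in% ds$samples$subject[ds$samples$fluid == "plasma"]
  has_cs <- subs %in% ds$samples$subject[ds$samples$fluid == "csf"]
  dropped <- subs[!(has_pl & has_cs)]
  if (length(dropped) > 0)
    warning("dropping subject(s) lacking a fluid: ",
            paste(dropped, collapse = ", "))
  subs <- subs[has_pl & has_cs]
  if (length(subs) == 0) stop("no subject has both plasma and CSF samples")
  ip <- match(paste(subs, "plasma", sep = "\r"), key)
  ic <- match(paste(subs, "csf", sep = "\r"), key)
  s_pl <- ds$peak_area[ip, , drop = FALSE]
  s_csf <- ds$peak_area[ic, , drop = FALSE]
  subjects <- data.frame(subject = subs,
                         group = ds$samples$group[ip],
                         stringsAsFactors = FALSE)
  structure(list(subjects = subjects,
                 metabolites = ds$metabolites$metabolite,
                 compound_id = ds$metabolites$compound_id,
                 s_pl = s_pl, s_csf = s_csf,
                 mask = !is.na(s_pl) & !is.na(s_csf)),
            class = "PairedProfileTable")
}

#' @export
print.PairedProfileTable <- function(x, ...) {
  cat(sprintf("PairedProfileTable: %d subjects (%d glioma, %d control) x %d metabolites\n",
              nrow(x$subjects), sum(x$subjects$group == "glioma"),
              sum(x$subjects$group == "control"), length(x$metabolites)))
  invisible(x)
}

# Rows of a paired table belonging to a scope ("combined", "patients", "controls").
scope_rows <- function(paired, scope) {
  scope <- match.arg(scope, c("combined", "patients", "controls"))
  switch(scope,
         combined = rep(TRUE, nrow(paired$subjects)),
         patients = paired$subjects$group == "glioma",
         controls = paired$subjects$group == "control")
}

#' Pooled sample-by-metabolite matrix
#'
#' Stacks both fluids and both groups of an averaged, ln-transformed dataset
#' into a single matrix with one row per (subject, fluid) observation — the
#' input of the pairwise metabolite correlation network.
#'
#' @param ds an averaged, ln-transformed `MetabolomicsDataset`.
#' @return numeric matrix with rownames `subject:fluid`.
#' @export
pooled_matrix <- function(ds) {
  stopifnot(inherits(ds, "MetabolomicsDataset"))
  key <- paste(ds$samples$subject, ds$samples$fluid, sep = ":")
  if (anyDuplicated(key))
    stop("dataset has several samples per (subject, fluid); average replicates first")
  m <- ds$peak_area
  rownames(m) <- key
  m
}
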