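#' Run the full DAR analysis pipeline
#'
#' Orchestrates extraction, metrics, clustering, PCA, cohort summaries and
#' the size model end to end, either on provided tracks/metadata or on a
#' freshly simulated archetype cohort. When `out_dir` is given, writes the
#' output tables (metrics, labels, wss curve, loadings, cluster summary) as
#' CSV and a machine-readable JSON run report.
#'
#' @param tracks named list of track data frames (ignored with
#'   `simulate = TRUE`).
#' @param metadata metadata data frame.
#' @param config a [dar_config()] list.
#' @param simulate simulate a cohort instead of using `tracks`.
#' @param cohort_spec individual specs for [generate_cohort()] (default: the
#'   one-per-archetype spec with 50 nights).
#' @param fit_model also fit the mixed-effects size model (needs >= 2 sex
#'   and age levels among selected individuals).
#' @param out_dir optional output directory.
#' @return A list with `dars`, `metrics`, `matrix`, `tree`, `curves`,
#'   `k_candidates`, `labels`, `pca`, `summary`, `records`, `size_model`
#'   (NULL unless fitted), `truth` (simulation only) and `report`.
#' @export
run_all <- function(tracks = NULL, metadata = NULL, config = dar_config(),
                    simulate = FALSE, cohort_spec = archetype_cohort_spec(),
                    fit_model = FALSE, out_dir = NULL) {
  truth <- NULL
  if (simulate) {
    sim <- generate_cohort(cohort_spec, seed = config$seed,
                           tz = config$timezone)
    tracks <- sim$tracks
    metadata <- sim$metadata
    truth <- sim$truth
  }
  if (is.null(tracks) || !length(tracks)) stop("no tracks to process")

  ext <- build_dars(tracks, metadata, config)
  if (!length(ext$dars)) stop("extraction produced no DARs")
  metrics <- compute_metrics_table(ext$dars)
  mat <- make_matrix(metrics)
  tree <- ward_linkage(mat)
  curves <- wss_curve(mat, tree, config$k_max)
  cand <- suggest_k(curves)
  labels <- cut_tree(tree, config$k)
  pca <- run_pca(mat)

  cm <- metrics[match(mat$dar_ids, metrics$dar_id), ]
  summary_tab <- summarize_clusters(labels, cm,
                                    open_lo = config$openness_breaks[1],
                                    open_hi = config$openness_breaks[2],
                                    transverse_ratio = config$transverse_ratio)

  # cohort records: one per clustered DAR
  dars <- ext$dars[mat$dar_ids]
  records <- data.frame(
    dar_id = mat$dar_ids,
    individual_id = vapply(dars, `[[`, character(1), "individual_id"),
    night_date = as.Date(vapply(dars, function(d)
      as.character(d$night_date), character(1))),
    cluster = as.integer(labels),
    stringsAsFactors = FALSE)
  q <- assign_quadrimester(records$night_date)
  records$quadrimester <- q$quadrimester
  records$cycle_year <- q$cycle_year
  if (!is.null(metadata)) {
    mi <- match(records$individual_id, metadata$individual_id)
    records$sex <- metadata$sex[mi]
    records$age_class <- metadata$age_class[mi]
  }
  starts <- t(vapply(dars, function(d)
    if (is.null(d$start_point)) c(NA_real_, NA_real_) else d$start_point,
    numeric(2)))
  if (sum(stats::complete.cases(starts)) >= 3) {
    loc <- cluster_start_locations(starts, k = 3,
                                   nstart = config$kmeans_restarts,
                                   seed = config$seed)
    records$start_location <- NA_integer_
    records$start_location[stats::complete.cases(starts)] <- loc$labels
  }

  size_model <- NULL
  if (fit_model) {
    records$size <- composite_size(cm, pca)
    keep <- !vapply(dars, function(d) isTRUE(d$quality$no_flight), logical(1))
    size_model <- fit_size_model(records[keep & !is.na(records$size), ])
  }

  report <- c(ext$report,
              list(n_metric_rows = nrow(metrics),
                   n_dropped_incomplete = mat$n_dropped,
                   k = config$k,
                   k_candidates = cand$k,
                   variance_fraction = unname(pca$variance_fraction),
                   config = config[!vapply(config, is.list, logical(1))]))

  out <- list(dars = ext$dars, metrics = metrics, matrix = mat, tree = tree,
              curves = curves, k_candidates = cand, labels = labels,
              pca = pca, summary = summary_tab, records = records,
              size_model = size_model, truth = truth, report = report)
  if (!is.null(out_dir)) write_outputs(out, out_dir)
  out
}

write_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table(out$metrics, file.path(out_dir, "metrics.csv"))
  write_table(data.frame(dar_id = names(out$labels),
                         cluster = as.integer(out$labels)),
              file.path(out_dir, "labels.csv"))
  write_table(out$curves, file.path(out_dir, "wss_curve.csv"))
  load_df <- data.frame(metric = rownames(out$pca$loadings),
                        out$pca$loadings)
  write_table(load_df, file.path(out_dir, "pca_loadings.csv"))
  write_table(out$summary, file.path(out_dir, "cluster_summary.csv"))
  write_table(out$records, file.path(out_dir, "cohort_records.csv"))
  jsonlite::write_json(out$report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null", na = "null")
  invisible(out_dir)
}
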