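#' Default pipeline configuration
#'
#' Returns the full set of thresholds and options used by the extraction,
#' clustering and cohort modules. Defaults are the published study values:
#' accuracy filter STD > 50 m, speed filter 15 m/s, diel boundary 10:00 local,
#' complete nights require more than 1000 fixes, a first fix before 21:00 and
#' a last fix after 02:00 (next day), individuals require more than 30
#' complete nights, endpoints average n = 20 fixes, and trajectories are
#' subsampled to one fix per 300 s.
#'
#' @param ... named overrides for any default; unknown names are an error.
#'
#' @return A named list of class `dar_config`.
#' @examples
#' cfg <- dar_config(subsample_s = 120)
#' cfg$max_speed
#' @export
dar_config <- function(...) {
  cfg <- list(
    # column mapping for relocation tables
    columns = list(id = "individual_id", time = "timestamp",
                   x = "x", y = "y", std = "accuracy_std"),
    meta_columns = list(id = "individual_id", sex = "sex", age = "age_class",
                        birth_date = "birth_date", family = "family_id"),
    delim = ",",
    timezone = "Asia/Jerusalem",
    # fix filtering
    max_std = 50,            # m; drop fixes with accuracy STD above this
    max_speed = 15,          # m/s; drop fixes implying faster movement
    # diel segmentation and night quality
    boundary_hour = 10,      # local clock hour opening each diel window
    min_fixes = 1000,        # complete nights have strictly more fixes
    latest_start = "21:00",  # first fix must be before this local time
    earliest_end = "02:00",  # last fix must be after this (next day)
    count_after_filter = TRUE,
    min_nights = 30,         # individuals need strictly more complete nights
    # flight/stop segmentation
    seg_window_s = 60,       # sliding window for the median speed
    seg_speed = 2,           # m/s; move when median speed exceeds this
    seg_min_run_s = 60,      # runs shorter than this merge into neighbors
    # endpoints and subsampling
    endpoint_n = 20,         # fixes averaged before/after the flight phase
    subsample_s = 300,       # s between retained fixes
    # clustering / summaries
    k = 7,
    k_max = 15,
    openness_breaks = c(0.25, 2.0),  # km; closed < lo <= partially open < hi
    transverse_ratio = 0.25,         # transverse when width < ratio * diameter
    # start-location k-means
    kmeans_restarts = 25,
    seed = 1
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      stop("unknown config option(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "dar_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Values present in the file override the defaults of [dar_config()];
#' everything else keeps its default.
#'
#' @param path path to a YAML file.
#' @return A `dar_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(dar_config, vals)
}

#' @export
print.dar_config <- function(x, ...) {
  cat("DAR pipeline configuration:\n")
  flat <- x[!vapply(x, is.list, logical(1))]
  for (nm in names(flat))
    cat(sprintf("  %-18s %s\n", nm, paste(format(flat[[nm]]), collapse = ", ")))
  invisible(x)
}
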