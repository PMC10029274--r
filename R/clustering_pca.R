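METRIC_COLS <- c("net_displacement", "max_displacement",
                 "max_diameter", "max_width")

#' Standardized metric matrix
#'
#' Drops rows with any missing metric (these arise when a flight segment
#' starts right at the diel boundary and the averaged endpoint cannot be
#' computed), then z-scores each of the four metric columns. The column
#' means and SDs are retained so raw values can be mapped into the
#' standardized space later.
#'
#' @param metrics a metrics data frame from [compute_metrics_table()].
#' @return A list of class `dar_matrix`: `x` (numeric matrix, rows named by
#'   dar_id), `dar_ids`, `center`, `scale`, `n_dropped`.
#' @export
make_matrix <- function(metrics) {
  if (nrow(metrics) == 0L) stop("empty metrics table")
  ok <- stats::complete.cases(metrics[METRIC_COLS])
  m <- metrics[ok, ]
  m <- m[order(m$dar_id), ]       # fixed row order for determinism
  x <- as.matrix(m[METRIC_COLS])
  rownames(x) <- m$dar_id
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance metric column(s): ",
         paste(METRIC_COLS[sds == 0], collapse = ", "))
  xs <- scale(x)
  structure(list(x = xs[, , drop = FALSE],
                 dar_ids = m$dar_id,
                 center = attr(xs, "scaled:center"),
                 scale = attr(xs, "scaled:scale"),
                 n_dropped = sum(!ok)),
            class = "dar_matrix")
}

#' Ward hierarchical clustering of DARs
#'
#' Agglomerative clustering on Euclidean distances in the standardized
#' metric space under Ward's minimum-variance criterion (the `ward.D2`
#' form, which applies the criterion to the distances themselves).
#'
#' @param mat a `dar_matrix` from [make_matrix()].
#' @return An [stats::hclust] tree.
#' @export
ward_linkage <- function(mat) {
  if (nrow(mat$x) < 2L) stop("need at least 2 rows to cluster")
  stats::hclust(stats::dist(mat$x), method = "ward.D2")
}

#' Cut the tree into k clusters
#'
#' @param tree an [stats::hclust] tree from [ward_linkage()].
#' @param k number of clusters, between 1 and the number of rows.
#' @return Integer labels 1..k, numbered in order of first row occurrence.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1L || k > n) stop("k out of range [1, ", n, "]")
  lab <- stats::cutree(tree, k = k)
  relabel_first_occurrence(lab)
}

relabel_first_occurrence <- function(lab) {
  u <- unique(lab)
  out <- match(lab, u)
  names(out) <- names(lab)
  out
}

#' Within-sum-of-squares curve and slope heuristic
#'
#' For each k, wss(k) is the sum over clusters of squared Euclidean
#' distances of members to their cluster centroid in the standardized
#' space, with the clusters taken from the tree cut at k. The slope is
#' s(k) = wss(k+1) - wss(k) and the relative change in slope is
#' f(k) = (s(k-1) - s(k)) / s(k-1); values of k where f jumps above its
#' predecessor are elbow candidates (see [suggest_k()]).
#'
#' @param mat a `dar_matrix`.
#' @param tree the Ward tree.
#' @param k_max largest k evaluated (default 15).
#' @return A data frame with columns `k`, `wss`, `s`, `f` (s undefined at
#'   `k_max`, f undefined at k = 1 and `k_max`).
#' @export
wss_curve <- function(mat, tree, k_max = 15) {
  n <- nrow(mat$x)
  k_max <- min(k_max, n)
  wss <- vapply(seq_len(k_max), function(k) {
    lab <- stats::cutree(tree, k = k)
    sum(vapply(split(seq_len(n), lab), function(idx) {
      xs <- mat$x[idx, , drop = FALSE]
      ctr <- colMeans(xs)
      sum(sweep(xs, 2, ctr)^2)
    }, numeric(1)))
  }, numeric(1))
  slope_heuristic(wss)
}

#' Slope and relative slope change of a wss sequence
#'
#' Given wss values at k = 1, 2, ..., computes the slope
#' s(k) = wss(k+1) - wss(k) and the relative change in slope
#' f(k) = (s(k-1) - s(k)) / s(k-1). s is undefined at the last k, f at
#' k = 1 and the last k (and wherever s(k-1) is 0).
#'
#' @param wss numeric vector of within-sum-of-squares values for
#'   k = 1..length(wss).
#' @return A data frame with columns `k`, `wss`, `s`, `f`.
#' @export
slope_heuristic <- function(wss) {
  k_max <- length(wss)
  s <- c(diff(wss), NA_real_)
  f <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    if (k >= 2 && k < k_max && !is.na(s[k - 1]) && s[k - 1] != 0)
      f[k] <- (s[k - 1] - s[k]) / s[k - 1]
  }
  data.frame(k = seq_len(k_max), wss = wss, s = s, f = f)
}

#' Elbow candidates for the number of clusters
#'
#' Returns the values of k whose relative slope change f(k) is larger than
#' the preceding point's (treated as 0 at k = 2, where no predecessor
#' exists), ranked by f(k) descending. The final choice of k is the
#' caller's: the heuristic flags candidates, the trade-off between cluster
#' diversity and per-cluster sample size is a study decision.
#'
#' @param curves the data frame from [wss_curve()].
#' @return A data frame with `k` and `f`, ranked by `f` descending; zero
#'   rows when the wss decline is linear (f identically 0).
#' @export
suggest_k <- function(curves) {
  f <- curves$f
  prev <- c(NA_real_, f[-length(f)])
  prev[is.na(prev)] <- 0
  cand <- which(!is.na(f) & f > prev & f > 0)
  out <- data.frame(k = curves$k[cand], f = f[cand])
  out[order(-out$f), , drop = FALSE]
}

#' Principal components of the metric matrix
#'
#' Eigendecomposition of the correlation structure of the four standardized
#' metrics. Components are ordered by variance explained and each is
#' sign-flipped so its loading sum is positive; PC1 then has all-positive
#' loadings and is the composite "extent" (size) factor, PC2 separates open
#' from closed routines ("openness"), PC3 contrasts length against width
#' ("elongation").
#'
#' @param mat a `dar_matrix` from [make_matrix()].
#' @return A list of class `dar_pca`: `loadings` (4x4, columns PC1..PC4),
#'   `variance_fraction` (sums to 1), `scores` (rows named by dar_id),
#'   `interpretation` (tags for the first three components).
#' @export
run_pca <- function(mat) {
  pc <- stats::prcomp(mat$x, center = FALSE, scale. = FALSE)
  flip <- ifelse(colSums(pc$rotation) < 0, -1, 1)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = loadings,
                 variance_fraction = varfrac,
                 scores = scores,
                 interpretation = c(PC1 = "extent", PC2 = "openness",
                                    PC3 = "elongation")),
            class = "dar_pca")
}

#' Composite DAR size
#'
#' A nonnegative scale variable for each DAR, suitable for a square-root
#' transformed mixed model. The default combines the raw (km) metrics with
#' the all-positive PC1 loadings, so the score is a nonnegative weighted
#' length; the alternative uses the standardized PC1 score shifted by its
#' minimum (rank-equivalent, but anchored to the sample).
#'
#' @param metrics a metrics data frame (raw km values).
#' @param pca a `dar_pca` from [run_pca()].
#' @param method `"loading"` (default) or `"score"`.
#' @return Named numeric vector of nonnegative sizes (names = dar_id).
#' @export
composite_size <- function(metrics, pca, method = c("loading", "score")) {
  method <- match.arg(method)
  if (method == "loading") {
    w <- pca$loadings[, 1]
    x <- as.matrix(metrics[METRIC_COLS])
    x[is.na(x)] <- NA_real_
    size <- drop(x %*% w)
    if (any(size < -1e-9, na.rm = TRUE))
      stop("negative composite size: PC1 loadings must be all-positive")
    size <- pmax(size, 0)
  } else {
    sc <- pca$scores[, 1]
    size <- sc - min(sc)
    size <- size[match(metrics$dar_id, rownames(pca$scores))]
  }
  names(size) <- metrics$dar_id
  size
}

#' Per-cluster summaries
#'
#' Cluster sizes, metric means and SDs (km), plus descriptive tags: an
#' openness label from the mean net displacement (closed below `open_lo`,
#' wide open at or above `open_hi`, partially open between), a transverse
#' flag when the mean width falls below `transverse_ratio` times the mean
#' diameter, and a size rank by mean diameter (1 = smallest).
#'
#' @param labels integer cluster labels (aligned with `metrics` rows).
#' @param metrics metrics data frame (raw km values, complete rows).
#' @param open_lo,open_hi openness thresholds in km (defaults 0.25 and 2).
#' @param transverse_ratio width/diameter ratio below which a cluster is
#'   transverse (default 0.25).
#' @return A data frame with one row per cluster: `cluster`, `n`, `percent`,
#'   `<metric>_mean`, `<metric>_sd` for the four metrics, `openness`,
#'   `transverse`, `size_rank`.
#' @export
summarize_clusters <- function(labels, metrics, open_lo = 0.25, open_hi = 2.0,
                               transverse_ratio = 0.25) {
  stopifnot(length(labels) == nrow(metrics))
  rows <- lapply(sort(unique(labels)), function(cl) {
    m <- metrics[labels == cl, ]
    out <- data.frame(cluster = cl, n = nrow(m),
                      percent = 100 * nrow(m) / nrow(metrics))
    for (col in METRIC_COLS) {
      out[[paste0(col, "_mean")]] <- mean(m[[col]])
      out[[paste0(col, "_sd")]] <- stats::sd(m[[col]])
    }
    out
  })
  sm <- do.call(rbind, rows)
  sm$openness <- cut(sm$net_displacement_mean,
                     breaks = c(-Inf, open_lo, open_hi, Inf),
                     labels = c("closed", "partially open", "wide open"),
                     right = FALSE)
  sm$openness <- as.character(sm$openness)
  sm$transverse <- sm$max_width_mean < sm$max_diameter_mean * transverse_ratio
  sm$size_rank <- rank(sm$max_diameter_mean, ties.method = "first")
  sm
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to relabeling), about 0 for independent ones.
#' Used to score cluster recovery against generator ground truth.
#'
#' @param a,b label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
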