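# Shared fixtures and independent oracles for the test suite.

# Brute-force diameter oracle: exhaustive pairwise scan via dist().
bf_diameter <- function(points) {
  p <- cbind(points[, 1], points[, 2])
  if (nrow(p) < 2) return(0)
  max(stats::dist(p)) / 1000
}

# Exhaustive signed-offset width oracle about the line through points i, j.
bf_width <- function(points, pair) {
  p <- cbind(points[, 1], points[, 2])
  a <- p[pair[1], ]; b <- p[pair[2], ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len == 0) return(0)
  off <- vapply(seq_len(nrow(p)), function(i) {
    q <- p[i, ]
    (ab[1] * (q[2] - a[2]) - ab[2] * (q[1] - a[1])) / len
  }, numeric(1))
  (max(c(off[off > 0], 0)) + max(c(-off[off < 0], 0))) / 1000
}

# Minimal track data frame from vectors (UTC timestamps in seconds).
make_track <- function(t, x, y, std = NA_real_, id = "owl1") {
  data.frame(individual_id = rep(id, length(t)),
             timestamp = as.POSIXct(t, origin = "2021-03-01 00:00:00",
                                    tz = "UTC"),
             x = x, y = y,
             accuracy_std = rep_len(std, length(t)),
             stringsAsFactors = FALSE)
}

# A night segment built directly (for segmenter/endpoint unit tests):
# positions given per fix at a fixed cadence.
make_night <- function(x, y, cadence_s = 8, date = as.Date("2021-03-01"),
                       start_utc = "2021-03-01 16:00:00", id = "owl1") {
  n <- length(x)
  t <- as.POSIXct(start_utc, tz = "UTC") + cadence_s * (seq_len(n) - 1)
  list(individual_id = id, night_date = date,
       fixes = data.frame(individual_id = id, timestamp = t, x = x, y = y,
                          accuracy_std = 10, stringsAsFactors = FALSE))
}

# Random point cloud generators with varied geometry.
random_point_set <- function(n, kind = c("uniform", "gaussian", "clustered",
                                         "near_collinear")) {
  kind <- match.arg(kind)
  switch(kind,
    uniform = cbind(runif(n, 0, 5000), runif(n, 0, 5000)),
    gaussian = cbind(rnorm(n, 0, 1500), rnorm(n, 0, 600)),
    clustered = {
      ctr <- matrix(runif(6, 0, 8000), 3, 2)
      g <- sample(1:3, n, TRUE)
      cbind(ctr[g, 1] + rnorm(n, 0, 200), ctr[g, 2] + rnorm(n, 0, 200))
    },
    near_collinear = {
      u <- runif(n, 0, 4000)
      cbind(u, 0.5 * u + rnorm(n, 0, 2))
    })
}
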