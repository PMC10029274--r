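#' Assign annual-cycle quadrimesters
#'
#' The annual cycle is split into three 4-month blocks: quadrimester 1
#' (February-May, the local breeding season), 2 (June-September, rearing /
#' post-breeding) and 3 (October-January, fall-winter recovery). January is
#' attached to the cycle that began the previous October, so the cycle year
#' of 10 January 2022 is 2021.
#'
#' @param dates a Date vector (or anything coercible with [as.Date()]).
#' @return A data frame with `quadrimester` (1-3) and `cycle_year`.
#' @export
assign_quadrimester <- function(dates) {
  d <- as.Date(dates)
  mo <- as.integer(format(d, "%m"))
  yr <- as.integer(format(d, "%Y"))
  q <- ifelse(mo >= 2 & mo <= 5, 1L, ifelse(mo >= 6 & mo <= 9, 2L, 3L))
  cy <- ifelse(mo == 1L, yr - 1L, yr)
  data.frame(quadrimester = q, cycle_year = cy)
}

#' Age class at a DAR's date
#'
#' Cluster-distribution comparisons use the age class assigned at the start
#' of data collection, but the size model evaluates age at the night the
#' routine was executed: an individual with a known birth date is "young"
#' up to one year of age and "adult" after, so one bird can contribute young
#' records early in a study and adult records later. When the birth date is
#' unknown the assignment class is kept.
#'
#' @param birth_date Date vector (NA = unknown).
#' @param dar_date Date vector of the nights evaluated.
#' @param assignment_age character vector of age classes at assignment,
#'   used as fallback.
#' @return Character vector of "young"/"adult".
#' @export
age_at_dar <- function(birth_date, dar_date, assignment_age) {
  birth_date <- as.Date(birth_date)
  dar_date <- as.Date(dar_date)
  out <- ifelse(dar_date < birth_date + 365, "young", "adult")
  out[is.na(birth_date)] <- assignment_age[is.na(birth_date)]
  out
}

#' Cluster DAR start locations
#'
#' k-means on the (x, y) start points, with multiple restarts under a fixed
#' seed for determinism. A wss-versus-k curve is returned so the number of
#' location clusters can be chosen by the elbow heuristic (the study used
#' three: west, center, east).
#'
#' @param start_points two-column (x, y) matrix or data frame in meters.
#' @param k number of location clusters (default 3).
#' @param k_max largest k evaluated for the wss curve (default 10).
#' @param nstart k-means restarts (default 25).
#' @param seed RNG seed (default 1).
#' @return A list with `labels`, `centers`, and `wss` (data frame k, wss).
#' @export
cluster_start_locations <- function(start_points, k = 3, k_max = 10,
                                    nstart = 25, seed = 1) {
  p <- as_point_matrix(start_points)
  p <- p[stats::complete.cases(p), , drop = FALSE]
  if (nrow(p) < k) stop("fewer start points (", nrow(p), ") than k = ", k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  k_max <- min(k_max, nrow(unique(p)))
  wss <- vapply(seq_len(k_max), function(kk)
    stats::kmeans(p, centers = kk, nstart = nstart,
                  iter.max = 100)$tot.withinss, numeric(1))
  set.seed(seed)
  km <- stats::kmeans(p, centers = k, nstart = nstart, iter.max = 100)
  list(labels = km$cluster, centers = km$centers,
       wss = data.frame(k = seq_len(k_max), wss = wss))
}

#' DAR-type distributions by group
#'
#' Cross-tabulates cohort records (one per DAR, with a cluster label and
#' grouping attributes) into group-by-type counts and row-normalized
#' frequencies, plus the per-individual mean and SD of type frequencies
#' within each group.
#'
#' @param records a data frame with columns `individual_id`, `cluster`, and
#'   the grouping column.
#' @param by grouping column name: one of `"sex"`, `"age"`, `"location"`,
#'   `"quadrimester"`, `"individual"` (or any column present in `records`;
#'   `age`/`location`/`individual` map to `age_class`, `start_location`,
#'   `individual_id` when those columns exist).
#' @return A list with `counts` (group x type matrix), `freq` (row-
#'   normalized), and `individual_summary` (group, cluster, mean_freq,
#'   sd_freq across individuals).
#' @export
distribution_table <- function(records, by) {
  alias <- c(age = "age_class", location = "start_location",
             individual = "individual_id")
  col <- if (by %in% names(records)) by
         else if (by %in% names(alias) && alias[[by]] %in% names(records))
           alias[[by]]
         else stop("unknown grouping key: ", by)
  if (nrow(records) == 0L) stop("no records")
  counts <- table(group = records[[col]], cluster = records$cluster)
  freq <- prop.table(counts, margin = 1)
  per_ind <- table(records$individual_id, records$cluster)
  per_ind_freq <- prop.table(per_ind, margin = 1)
  ind_group <- records[[col]][match(rownames(per_ind), records$individual_id)]
  rows <- list()
  for (g in rownames(counts)) {
    sub <- per_ind_freq[ind_group == g, , drop = FALSE]
    for (cl in colnames(counts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, cluster = cl,
        mean_freq = mean(sub[, cl]),
        sd_freq = if (nrow(sub) > 1) stats::sd(sub[, cl]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(counts = unclass(counts), freq = unclass(freq),
       individual_summary = do.call(rbind, rows))
}

#' Pearson chi-squared contingency test
#'
#' Independence test of a group-by-type count table, without continuity
#' correction. A flag is raised when any expected count falls below 5
#' (where the chi-squared approximation weakens).
#'
#' @param tab a matrix of nonnegative counts with at least 2 rows and
#'   2 columns.
#' @return A list with `observed`, `expected`, `statistic`, `df`,
#'   `p_value`, `low_expected` (logical).
#' @export
chi_squared_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2x2 table")
  if (any(tab < 0)) stop("negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal total")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(observed = tab,
       expected = ct$expected,
       statistic = unname(ct$statistic),
       df = unname(ct$parameter),
       p_value = unname(ct$p.value),
       low_expected = any(ct$expected < 5))
}

#' Per-individual temporal DAR-type sequence
#'
#' Calendar-ordered sequence of DAR types for one individual, with explicit
#' NA markers for nights inside the individual's tracking span that yielded
#' no classified DAR (incomplete nights or missing metrics), and
#' quadrimester annotations.
#'
#' @param records cohort records with `individual_id`, `night_date`,
#'   `cluster`.
#' @param individual_id the individual to extract.
#' @param all_dates optional Date vector bounding the sequence; defaults to
#'   the individual's first-to-last recorded night.
#' @return A data frame with `night_date`, `cluster` (NA for gap nights),
#'   `quadrimester`, `cycle_year`; dates strictly increasing.
#' @export
temporal_sequence <- function(records, individual_id, all_dates = NULL) {
  sub <- records[records$individual_id == individual_id, ]
  if (nrow(sub) == 0L) stop("unknown individual: ", individual_id)
  span <- if (is.null(all_dates))
    seq(min(sub$night_date), max(sub$night_date), by = "day")
  else sort(unique(as.Date(all_dates)))
  cl <- sub$cluster[match(span, sub$night_date)]
  q <- assign_quadrimester(span)
  data.frame(night_date = span, cluster = cl,
             quadrimester = q$quadrimester, cycle_year = q$cycle_year)
}

#' Mixed-effects model of DAR size
#'
#' Fits a linear mixed model to the square-root transformed size variable
#' with fixed effects for sex and age and random intercepts for individual
#' (repeated measures) and calendar night (shared temporal conditions):
#' `sqrt(size) ~ sex + age_class + (1 | individual_id) + (1 | night_date)`.
#' The size variable is typically the PC1 composite ([composite_size()]) or
#' a single metric such as maximum displacement. With
#' `include_interaction`, the sex-by-age cross-product model is also fitted
#' (by maximum likelihood) and compared on AIC.
#'
#' @param records a data frame with columns `size` (nonnegative), `sex`,
#'   `age_class`, `individual_id`, `night_date`; each fixed factor needs at
#'   least 2 levels.
#' @param include_interaction also fit and compare the sex x age model.
#' @return A list of class `dar_sizemodel`: `fixed` (term, estimate, se, df,
#'   p_value), `ranef_var` (named variances incl. residual), `aic`,
#'   `interaction` (NULL, or list with `aic_main`, `aic_interaction`,
#'   `preferred`), `residuals`, `fitted`, `model` (the merMod fit).
#' @export
fit_size_model <- function(records, include_interaction = FALSE) {
  need <- c("size", "sex", "age_class", "individual_id", "night_date")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(records$size)) || any(records$size < 0))
    stop("size must be nonnegative and non-missing")
  d <- records
  d$sex <- factor(d$sex)
  d$age_class <- factor(d$age_class)
  d$individual_id <- factor(d$individual_id)
  d$night_date <- factor(as.character(d$night_date))
  if (nlevels(d$sex) < 2L || nlevels(d$age_class) < 2L)
    stop("sex and age_class each need at least 2 levels")
  d$.y <- sqrt(d$size)
  form <- .y ~ sex + age_class + (1 | individual_id) + (1 | night_date)
  fit <- lmerTest::lmer(form, data = d)
  co <- stats::coef(summary(fit))
  fixed <- data.frame(term = rownames(co),
                      estimate = co[, "Estimate"],
                      se = co[, "Std. Error"],
                      df = co[, "df"],
                      p_value = co[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ranef_var <- stats::setNames(vc$vcov, vc$grp)
  interaction <- NULL
  if (include_interaction) {
    f_main <- stats::update(form, . ~ .)
    f_int <- .y ~ sex * age_class + (1 | individual_id) + (1 | night_date)
    m_main <- lme4::lmer(f_main, data = d, REML = FALSE)
    m_int <- lme4::lmer(f_int, data = d, REML = FALSE)
    interaction <- list(aic_main = stats::AIC(m_main),
                        aic_interaction = stats::AIC(m_int),
                        preferred = if (stats::AIC(m_int) < stats::AIC(m_main) - 2)
                          "interaction" else "main")
  }
  structure(list(fixed = fixed, ranef_var = ranef_var,
                 aic = stats::AIC(fit), interaction = interaction,
                 residuals = stats::residuals(fit),
                 fitted = stats::fitted(fit), model = fit),
            class = "dar_sizemodel")
}

#' Residual diagnostics for the size model
#'
#' @param fit a `dar_sizemodel` from [fit_size_model()].
#' @return A list with `residual_summary` (mean, sd), `qq` (data frame of
#'   theoretical and sample quantiles), and `quintile_sd` (residual SD by
#'   fitted-value quintile, a heteroscedasticity check).
#' @export
model_diagnostics <- function(fit) {
  r <- fit$residuals
  qq <- stats::qqnorm(r, plot.it = FALSE)
  quint <- cut(fit$fitted,
               breaks = stats::quantile(fit$fitted, probs = seq(0, 1, 0.2)),
               include.lowest = TRUE, labels = FALSE)
  list(residual_summary = c(mean = mean(r), sd = stats::sd(r)),
       qq = data.frame(theoretical = sort(qq$x), sample = sort(qq$y)),
       quintile_sd = tapply(r, quint, stats::sd))
}

#' Simulate a size cohort for model calibration
#'
#' Generates DAR sizes from the size model's own data-generating process:
#' sqrt(size) = intercept + beta_sex (males) + beta_age (young) +
#' individual intercept + date intercept + noise, with sizes returned on
#' the squared (original) scale. Used for type-I-error and
#' coverage/parameter-recovery checks of [fit_size_model()].
#'
#' @param n_individuals,dars_per_ind cohort dimensions.
#' @param beta_sex,beta_age fixed effects on the sqrt scale.
#' @param sd_individual,sd_date,sd_noise random-effect and residual SDs.
#' @param intercept sqrt-scale intercept (large enough that negative draws
#'   are negligible).
#' @param n_dates number of distinct calendar nights shared across
#'   individuals.
#' @return A records data frame suitable for [fit_size_model()], with the
#'   true parameters in attribute `"truth"`.
#' @export
simulate_size_data <- function(n_individuals = 40, dars_per_ind = 100,
                               beta_sex = 0.2, beta_age = 0.5,
                               sd_individual = 0.3, sd_date = 0.2,
                               sd_noise = 0.5, intercept = 3,
                               n_dates = dars_per_ind) {
  ids <- sprintf("ind%02d", seq_len(n_individuals))
  sex <- rep(c("female", "male"), length.out = n_individuals)
  age <- rep(c("adult", "adult", "young", "young"),
             length.out = n_individuals)
  u_ind <- stats::rnorm(n_individuals, 0, sd_individual)
  dates <- as.Date("2021-01-01") + seq_len(n_dates) - 1
  u_date <- stats::rnorm(n_dates, 0, sd_date)
  rows <- data.frame(
    individual_id = rep(ids, each = dars_per_ind),
    sex = rep(sex, each = dars_per_ind),
    age_class = rep(age, each = dars_per_ind),
    night_date = rep(dates, length.out = n_individuals * dars_per_ind),
    stringsAsFactors = FALSE)
  di <- match(rows$night_date, dates)
  ii <- match(rows$individual_id, ids)
  y <- intercept +
    beta_sex * (rows$sex == "male") +
    beta_age * (rows$age_class == "young") +
    u_ind[ii] + u_date[di] +
    stats::rnorm(nrow(rows), 0, sd_noise)
  y <- pmax(y, 0)
  rows$size <- y^2
  attr(rows, "truth") <- c(intercept = intercept, beta_sex = beta_sex,
                           beta_age = beta_age)
  rows
}
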