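# The five mean-structure models for the PSD contrast d (uV^2/Hz), all with
# a common residual scale sigma:
#   M1: d ~ N(0, sigma)                    (no contrast anywhere)
#   M2: d ~ N(m, sigma)                    (one shared contrast)
#   M3: d ~ N(m[group], sigma)             (contrast differs per group)
#   M4: d ~ N(m[region], sigma)            (contrast differs per region)
#   M5: d ~ N(m[group x region], sigma)
# The default parameterization is treatment coding (intercept + offsets,
# the convention of regression-style Bayesian model fitters), each
# coefficient carrying an independent copy of the mean prior. The
# alternative "cellmeans" parameterization puts the prior on each cell
# mean directly.

#' Model specification
#'
#' @param id Model id, 1 to 5.
#' @return A `model_spec` list with the id, a label, the factors entering
#'   the mean structure, and the number of mean parameters.
#' @export
model_spec <- function(id) {
  id <- as.integer(id)
  stopifnot(id %in% 1:5)
  info <- list(
    list(label = "Model 1", terms = character(0), n_par = 0L),
    list(label = "Model 2", terms = "1", n_par = 1L),
    list(label = "Model 3", terms = "group", n_par = 2L),
    list(label = "Model 4", terms = "region", n_par = 6L),
    list(label = "Model 5", terms = c("region", "group"), n_par = 12L)
  )[[id]]
  structure(c(list(id = id), info), class = "model_spec")
}

# treatment-coded design matrix (NULL for model 1)
model_design <- function(model, table) {
  if (!inherits(model, "model_spec")) model <- model_spec(model)
  if (model$id == 1L) return(NULL)
  df <- data.frame(group = factor(table$group, levels = c(1L, 2L)),
                   region = factor(table$region, levels = regions()))
  form <- switch(model$id, NULL, ~1, ~group, ~region, ~region * group)
  stats::model.matrix(form, df)
}

#' Cell partition and sufficient statistics
#'
#' Partitions the observations into the cells implied by a model's mean
#' structure (M1/M2: one cell; M3: per group; M4: per region; M5: per
#' group x region) and returns, per cell, the count, sample mean and
#' within-cell sum of squared deviations -- the sufficient statistics of
#' the normal likelihood with common sigma.
#'
#' @param table A [contrast_table()].
#' @param model A [model_spec()] or model id.
#' @return Data frame with columns `cell`, `n`, `mean`, `ss`.
#' @export
cell_stats <- function(table, model) {
  if (!inherits(model, "model_spec")) model <- model_spec(model)
  key <- switch(model$id,
    rep("all", nrow(table)),
    rep("all", nrow(table)),
    paste0("group", table$group),
    table$region,
    paste0(table$region, ".group", table$group))
  sp <- split(table$contrast, key)
  if (any(lengths(sp) == 0L)) stop("empty cell in model partition")
  data.frame(cell = names(sp),
             n = lengths(sp),
             mean = vapply(sp, mean, 0),
             ss = vapply(sp, function(d) sum((d - mean(d))^2), 0),
             row.names = NULL)
}

#' Prior specification
#'
#' One point of the 3 x 3 sensitivity grid: a diffuse prior for the mean
#' parameters (each parameter gets an independent copy) and one for the
#' residual scale sigma.
#'
#' @param mean_prior `"normal"` (N(0,1)), `"cauchy"` (Cauchy(0,1)) or
#'   `"uniform"` (U(-8, 8)).
#' @param sigma_prior `"uniform"` (U(0, 5)), `"halfnormal"` (half-normal
#'   with scale 2) or `"gamma"` (Gamma(shape 2, rate 2)).
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(mean_prior = c("normal", "cauchy", "uniform"),
                       sigma_prior = c("uniform", "halfnormal", "gamma")) {
  structure(list(mean_prior = match.arg(mean_prior),
                 sigma_prior = match.arg(sigma_prior)),
            class = "prior_spec")
}

#' All nine prior combinations of the sensitivity grid
#'
#' @return List of nine [prior_spec()] objects, mean prior varying slowest.
#' @export
prior_grid <- function() {
  out <- list()
  for (m in c("normal", "uniform", "cauchy")) {
    for (s in c("uniform", "gamma", "halfnormal")) {
      out[[paste(m, s, sep = "_")]] <- prior_spec(m, s)
    }
  }
  out
}

prior_label <- function(prior) {
  m <- c(normal = "Normal (0,1)", cauchy = "Cauchy (0,1)",
         uniform = "Uniform (-8,8)")[[prior$mean_prior]]
  s <- c(uniform = "Uniform (0,5)", halfnormal = "Half-normal (0,2)",
         gamma = "Gamma (2,2)")[[prior$sigma_prior]]
  c(mean = m, sigma = s)
}

# log density of the mean prior, vectorized
mean_log_density <- function(x, prior) {
  switch(prior$mean_prior,
    normal = stats::dnorm(x, log = TRUE),
    cauchy = stats::dcauchy(x, log = TRUE),
    uniform = ifelse(abs(x) <= 8, -log(16), -Inf))
}

# log density of the sigma prior (support sigma > 0)
sigma_log_density <- function(s, prior) {
  out <- switch(prior$sigma_prior,
    uniform = ifelse(s > 0 & s <= 5, -log(5), -Inf),
    halfnormal = log(2) + stats::dnorm(s, 0, 2, log = TRUE),
    gamma = stats::dgamma(s, 2, 2, log = TRUE))
  out[s <= 0] <- -Inf
  out
}

# upper truncation of the sigma integration range: the prior's support, or
# a point beyond which prior mass is negligible (< 1e-8)
sigma_upper <- function(prior) {
  switch(prior$sigma_prior, uniform = 5, halfnormal = 12, gamma = 12)
}
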