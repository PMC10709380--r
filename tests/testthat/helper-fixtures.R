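# Shared fixtures: desk-scale simulator configurations and synthetic
# contrast tables generated in code.

desk_config <- function(...) {
  sim_config(sampling_rate = 250, ...)
}

desk_schedule <- list(washout_s = 0, n_cycles = 2, break_range = c(2, 4))

# a minimal recording wrapper around a raw channel x time matrix
raw_recording <- function(X, rate, label = "EO", channels = rownames(X)) {
  structure(list(samples = X, rate = rate, channels = channels,
                 annotations = data.frame(label = label, onset = 1L,
                                          n_samples = ncol(X),
                                          rf_on = FALSE),
                 metadata = list()),
            class = "recording")
}

# contrast table with normal observations: per-group means, common sigma
random_contrast_table <- function(n_subjects = 32L, m = c(0, 0),
                                  sigma = 0.8, seed = 1L,
                                  subject_sd = 0) {
  stopifnot(n_subjects %% 2L == 0L)
  set.seed(seed)
  half <- n_subjects %/% 2L
  rows <- lapply(seq_len(n_subjects), function(i) {
    g <- if (i <= half) 1L else 2L
    u <- if (subject_sd > 0) rnorm(1, 0, subject_sd) else 0
    data.frame(subject = i, group = g, region = regions(),
               contrast = rnorm(6, m[g] + u, sigma))
  })
  contrast_table(do.call(rbind, rows))
}

# brute-force log evidence by direct Riemann sums over (means, sigma),
# cellmeans parameterization; tractable for models 1-3 on small tables
riemann_log_evidence <- function(table, model, prior,
                                 n_m = 601L, n_s = 801L, m_span = 12) {
  cs <- cell_stats(table, model)
  s_hi <- switch(prior$sigma_prior, uniform = 5, halfnormal = 10, gamma = 10)
  sg <- seq(1e-3, s_hi, length.out = n_s)
  ds <- sg[2] - sg[1]
  lp_s <- switch(prior$sigma_prior,
    uniform = ifelse(sg <= 5, -log(5), -Inf),
    halfnormal = log(2) + dnorm(sg, 0, 2, log = TRUE),
    gamma = dgamma(sg, 2, 2, log = TRUE))
  tot <- lp_s + log(ds)
  for (i in seq_len(nrow(cs))) {
    n <- cs$n[i]; mb <- cs$mean[i]; ss <- cs$ss[i]
    base <- -n / 2 * log(2 * pi * sg^2) - ss / (2 * sg^2)
    if (model == 1 || inherits(model, "model_spec") && model$id == 1L) {
      tot <- tot + base - n * mb^2 / (2 * sg^2)
    } else {
      lj <- vapply(sg, function(s) {
        se <- s / sqrt(n)
        lo <- mb - m_span * se; hi <- mb + m_span * se
        if (prior$mean_prior == "uniform") { lo <- max(lo, -8); hi <- min(hi, 8) }
        if (prior$mean_prior %in% c("normal", "cauchy")) {
          lo <- min(lo, -6); hi <- max(hi, 6)  # cover the prior bulk
        }
        m <- seq(lo, hi, length.out = n_m)
        lf <- -(m - mb)^2 / (2 * se^2) + switch(prior$mean_prior,
          normal = dnorm(m, log = TRUE),
          cauchy = dcauchy(m, log = TRUE),
          uniform = -log(16))
        mx <- max(lf)
        mx + log(sum(exp(lf - mx)) * (m[2] - m[1]))
      }, 0)
      tot <- tot + base + lj
    }
  }
  mx <- max(tot[is.finite(tot)])
  mx + log(sum(exp(tot - mx)))
}

desk_sched <- function(...) utils::modifyList(desk_schedule, list(...))
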