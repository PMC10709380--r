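# Marginal likelihood (evidence) computation. The evidence of a model is
#   Z = int p(sigma) [ int p(beta) N(y | X beta, sigma^2 I) dbeta ] dsigma,
# computed by deterministic 1-D quadrature over sigma with the inner
# beta-integral evaluated per sigma:
#   * Normal mean prior: exact (Gaussian marginal, Cholesky).
#   * Uniform(-8,8): exact Gaussian integral times a box-mass factor.
#   * Cauchy(0,1): Gauss-Hermite tensor quadrature for <= 2 parameters,
#     importance sampling with a posterior-shaped multivariate-t proposal
#     (fixed internal seed, standard error reported) for more.
# Everything is carried in the log domain via log-sum-exp.

logsumexp <- function(x) {
  x <- x[is.finite(x) | x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

gauss_hermite <- function(n) {
  i <- seq_len(n - 1L)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1L, ]^2)
}

sigma_quad_grid <- function(prior, n_sigma) {
  hi <- sigma_upper(prior)
  n_log <- min(200L, n_sigma %/% 8L)
  g <- c(exp(seq(log(1e-3), log(0.1), length.out = n_log)),
         seq(0.1005, hi, length.out = n_sigma - n_log))
  w <- numeric(length(g))
  w[1L] <- (g[2L] - g[1L]) / 2
  w[length(g)] <- (g[length(g)] - g[length(g) - 1L]) / 2
  w[2:(length(g) - 1L)] <- (g[3:length(g)] - g[1:(length(g) - 2L)]) / 2
  list(sigma = g, logw = log(w))
}

# sufficient statistics of the regression likelihood
design_stats <- function(X, y) {
  n <- length(y)
  if (is.null(X)) {
    return(list(n = n, p = 0L, yy = sum(y^2), rss = sum(y^2)))
  }
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  beta_hat <- solve(XtX, Xty)
  rss <- sum(y^2) - sum(Xty * beta_hat)
  list(n = n, p = ncol(X), X = X, XtX = XtX, Xty = Xty, yy = sum(y^2),
       beta_hat = beta_hat, rss = max(rss, 0),
       XtX_inv = solve(XtX), ld_XtX = determinant(XtX)$modulus[1])
}

# log of int p(beta) N(y | X beta, sigma^2) dbeta, vectorized over sigma
log_inner_beta <- function(ds, sigma, prior, gh = NULL) {
  n <- ds$n
  if (ds$p == 0L) {
    return(-n / 2 * log(2 * pi * sigma^2) - ds$yy / (2 * sigma^2))
  }
  p <- ds$p
  if (prior$mean_prior == "normal") {
    vapply(sigma, function(s) {
      B <- s^2 * diag(p) + ds$XtX
      cB <- chol(B)
      quad <- (ds$yy - sum(ds$Xty * backsolve(cB, forwardsolve(t(cB), ds$Xty)))) / s^2
      -0.5 * (n * log(2 * pi) + (n - p) * log(s^2) +
                2 * sum(log(diag(cB))) + quad)
    }, 0)
  } else if (prior$mean_prior == "uniform") {
    sd_j <- sqrt(diag(ds$XtX_inv))
    base <- -(n - p) / 2 * log(2 * pi * sigma^2) - 0.5 * ds$ld_XtX -
      ds$rss / (2 * sigma^2) - p * log(16)
    box <- vapply(sigma, function(s) {
      sum(log(pmax(stats::pnorm((8 - ds$beta_hat) / (s * sd_j)) -
                     stats::pnorm((-8 - ds$beta_hat) / (s * sd_j)),
                   .Machine$double.xmin)))
    }, 0)
    base + box
  } else {  # cauchy, p <= 2 (tensor Gauss-Hermite); larger p handled by IS
    if (is.null(gh)) gh <- gauss_hermite(40L)
    L <- t(chol(ds$XtX_inv))  # lower triangular
    if (p == 1L) {
      nodes <- matrix(gh$x, ncol = 1L)
      wts <- gh$w
    } else {
      nodes <- as.matrix(expand.grid(gh$x, gh$x))
      wts <- as.vector(outer(gh$w, gh$w))
    }
    offs <- nodes %*% t(L) * sqrt(2)   # per unit sigma
    vapply(sigma, function(s) {
      B <- sweep(offs * s, 2L, ds$beta_hat, "+")
      lp <- rowSums(stats::dcauchy(B, log = TRUE))
      -n / 2 * log(2 * pi * s^2) - ds$rss / (2 * s^2) +
        p / 2 * log(2 * s^2) - 0.5 * ds$ld_XtX +
        logsumexp(log(wts) + lp)
    }, 0)
  }
}

# importance-sampling evidence for Cauchy priors with p > 2 coefficients
log_evidence_is <- function(ds, prior, n_draws, seed, n_sigma) {
  # sigma proposal: posterior under the Normal mean prior (cheap, exact)
  grid <- sigma_quad_grid(prior, max(400L, n_sigma %/% 8L))
  lg <- sigma_log_density(grid$sigma, prior) +
    log_inner_beta(ds, grid$sigma, prior_spec("normal", prior$sigma_prior)) +
    grid$logw
  lg[!is.finite(lg)] <- -Inf
  wq <- exp(lg - max(lg)); wq <- wq / sum(wq)
  widths <- exp(grid$logw)
  with_seed(seed, {
    idx <- sample.int(length(grid$sigma), n_draws, replace = TRUE, prob = wq)
    sig <- grid$sigma[idx] + (stats::runif(n_draws) - 0.5) * widths[idx]
    sig <- pmin(pmax(sig, 1e-4), sigma_upper(prior))
    lq_sigma <- log(wq[idx]) - log(widths[idx])
    # beta | sigma: multivariate t (df 7) at the GLS mode, inflated scale
    p <- ds$p; df_t <- 7; infl <- 1.3
    L <- t(chol(ds$XtX_inv)) * infl
    Zn <- matrix(stats::rnorm(n_draws * p), n_draws, p)
    u <- stats::rchisq(n_draws, df_t)
    Tz <- Zn * sqrt(df_t / u)
    B <- sweep((Tz %*% t(L)) * sig, 2L, ds$beta_hat, "+")
    # mvt log density with scale matrix sig^2 * (L L')
    ld_scale <- 2 * sum(log(diag(L))) + 2 * p * log(sig)
    qf <- rowSums(Tz^2)  # (B - mode)' Sigma^-1 (B - mode) in t coords
    lq_beta <- lgamma((df_t + p) / 2) - lgamma(df_t / 2) -
      p / 2 * log(df_t * pi) - 0.5 * ld_scale -
      (df_t + p) / 2 * log1p(qf / df_t)
    # likelihood via RSS + GLS quadratic form
    D <- B - matrix(ds$beta_hat, n_draws, p, byrow = TRUE)
    qlik <- rowSums((D %*% ds$XtX) * D)
    ll <- -ds$n / 2 * log(2 * pi * sig^2) - (ds$rss + qlik) / (2 * sig^2)
    lw <- sigma_log_density(sig, prior) +
      rowSums(stats::dcauchy(B, log = TRUE)) + ll - lq_sigma - lq_beta
    lw <- lw[is.finite(lw)]
    m <- max(lw)
    w <- exp(lw - m)
    est <- m + log(mean(w))
    se <- stats::sd(w) / (mean(w) * sqrt(length(w)))
    list(log_evidence = est, se = se, ess = sum(w)^2 / sum(w^2))
  })
}

#' Log marginal likelihood of one model under one prior
#'
#' Integrates the normal likelihood of the observed contrasts over the
#' prior on the mean parameters and on sigma ("averaging over the prior
#' assumption on the parameters"). The outer sigma integral is a
#' deterministic trapezoid quadrature on the prior's support; the inner
#' mean-parameter integral is exact or quadrature-based depending on the
#' prior (see Details).
#'
#' @details With the default `"treatment"` parameterization, mean
#'   structures are coded as intercept + offsets (regression convention)
#'   and every coefficient carries an independent copy of the mean prior.
#'   `"cellmeans"` instead places the prior on each cell mean, in which
#'   case the inner integral factorizes over cells. For Cauchy priors with
#'   more than two coefficients the inner integral has no closed form or
#'   low-dimensional grid; it is estimated by importance sampling with a
#'   posterior-shaped multivariate-t proposal and a fixed internal seed,
#'   with the standard error reported in the diagnostics.
#'
#' @param table A [contrast_table()].
#' @param model A [model_spec()] or id 1-5.
#' @param prior A [prior_spec()].
#' @param parameterization `"treatment"` (default) or `"cellmeans"`.
#' @param n_sigma Number of sigma quadrature points.
#' @param n_draws Importance-sampling draws (Cauchy prior, p > 2 only).
#' @param seed Seed for the importance-sampling path; `NULL` uses a fixed
#'   internal seed so results are reproducible by default.
#' @return An `evidence_result`: list with `log_evidence` (natural log)
#'   and `diagnostics` (method, grid sizes, quadrature error estimate from
#'   grid halving, and IS standard error / effective sample size when
#'   applicable).
#' @export
log_evidence <- function(table, model, prior,
                         parameterization = c("treatment", "cellmeans"),
                         n_sigma = 4000L, n_draws = 40000L, seed = NULL) {
  parameterization <- match.arg(parameterization)
  if (!inherits(model, "model_spec")) model <- model_spec(model)
  stopifnot(inherits(prior, "prior_spec"))
  is_out <- NULL

  if (parameterization == "treatment" && prior$mean_prior == "cauchy" &&
      model$n_par > 2L) {
    ds <- design_stats(model_design(model, table), table$contrast)
    if (is.null(seed)) seed <- sub_seed(48561L, model$id, 7L)
    is_out <- log_evidence_is(ds, prior, n_draws, seed, n_sigma)
    lz <- is_out$log_evidence
    err <- is_out$se
  } else {
    inner <- function(sig) {
      if (parameterization == "treatment") {
        ds <- design_stats(model_design(model, table), table$contrast)
        log_inner_beta(ds, sig, prior)
      } else {
        cs <- cell_stats(table, model)
        acc <- numeric(length(sig))
        for (i in seq_len(nrow(cs))) {
          acc <- acc + inner_cell_vec(cs$n[i], cs$mean[i], cs$ss[i], sig,
                                      prior, fixed_zero = (model$id == 1L))
        }
        acc
      }
    }
    quad <- function(ns) {
      g <- sigma_quad_grid(prior, ns)
      lg <- sigma_log_density(g$sigma, prior) + inner(g$sigma) + g$logw
      logsumexp(lg)
    }
    lz <- quad(n_sigma)
    err <- abs(lz - quad(n_sigma %/% 2L))
  }
  structure(list(model = model$id, prior = prior,
                 parameterization = parameterization,
                 log_evidence = lz,
                 diagnostics = list(
                   method = if (is.null(is_out)) "quadrature" else "importance",
                   n_sigma = n_sigma, err_est = err,
                   is_se = is_out$se, ess = is_out$ess)),
            class = "evidence_result")
}

# vectorized (over sigma) inner mean-integral for one cell, cellmeans path
inner_cell_vec <- function(n, mbar, ss, sigma, prior, fixed_zero = FALSE,
                           gh = NULL) {
  base <- -n / 2 * log(2 * pi * sigma^2) - ss / (2 * sigma^2)
  if (fixed_zero) return(base - n * mbar^2 / (2 * sigma^2))
  s <- sigma / sqrt(n)
  lj <- switch(prior$mean_prior,
    normal = 0.5 * log(2 * pi * s^2) +
      stats::dnorm(mbar, 0, sqrt(1 + s^2), log = TRUE),
    uniform = 0.5 * log(2 * pi * s^2) - log(16) +
      log(pmax(stats::pnorm((8 - mbar) / s) - stats::pnorm((-8 - mbar) / s),
               .Machine$double.xmin)),
    cauchy = {
      if (is.null(gh)) gh <- gauss_hermite(60L)
      vapply(s, function(si) {
        0.5 * log(2 * pi * si^2) +
          log(sum(gh$w * stats::dcauchy(mbar + sqrt(2) * si * gh$x)) / sqrt(pi))
      }, 0)
    })
  base + lj
}

#' Inner mean-parameter integral for one cell
#'
#' Reference implementation of
#' `log int p(m) prod_i N(d_i | m, sigma) dm` for a single cell with
#' sufficient statistics `(n, mean, ss)`: the conjugate closed form for
#' the Normal(0,1) prior, adaptive Gauss-Kronrod quadrature (recentered at
#' the cell mean, width sigma/sqrt(n)) for Cauchy and Uniform priors.
#'
#' @param n,mean,ss Cell count, sample mean, within-cell sum of squares.
#' @param sigma Residual scale (> 0), scalar.
#' @param prior A [prior_spec()] (only its mean prior is used).
#' @return Scalar log integral.
#' @export
inner_mean_integral <- function(n, mean, ss, sigma, prior) {
  stopifnot(length(sigma) == 1L, is.finite(sigma), sigma > 0,
            is.finite(mean), is.finite(ss), n >= 1L)
  base <- -n / 2 * log(2 * pi * sigma^2) - ss / (2 * sigma^2)
  s <- sigma / sqrt(n)
  if (prior$mean_prior == "normal") {
    return(base + 0.5 * log(2 * pi * s^2) +
             stats::dnorm(mean, 0, sqrt(1 + s^2), log = TRUE))
  }
  # log-domain scaled integrand: peak value 1 at m = mean
  f <- function(m) exp(-(m - mean)^2 / (2 * s^2) + mean_log_density(m, prior))
  lim <- if (prior$mean_prior == "uniform") c(-8, 8) else c(-Inf, Inf)
  lo <- max(lim[1], mean - 12 * s); hi <- min(lim[2], mean + 12 * s)
  val <- stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 0)$value
  if (prior$mean_prior == "cauchy") {
    # add prior tails outside the likelihood window
    if (lim[1] < lo) val <- val + stats::integrate(f, -Inf, lo)$value
    if (hi < lim[2]) val <- val + stats::integrate(f, hi, Inf)$value
  } else {
    if (-8 < lo) val <- val + stats::integrate(f, -8, lo)$value
    if (hi < 8) val <- val + stats::integrate(f, hi, 8)$value
  }
  base + log(val)
}

#' Pairwise likelihood-ratio matrix for the five models
#'
#' Entry (row r, column c) is `evidence(model c) / evidence(model r)`: a
#' value greater than 1 means the column model explains the data better
#' than the row model.
#'
#' @inheritParams log_evidence
#' @param ... Passed to [log_evidence()].
#' @return An `lr_matrix`: 5 x 5 matrix with the log-evidences as
#'   attribute `log_evidence` and the prior as attribute `prior`.
#' @export
lr_matrix <- function(table, prior, ...) {
  ev <- vapply(1:5, function(m)
    log_evidence(table, m, prior, ...)$log_evidence, 0)
  lab <- paste("Model", 1:5)
  M <- exp(outer(ev, ev, function(r, c) c - r))
  dimnames(M) <- list(lab, lab)
  L10 <- outer(ev, ev, function(r, c) c - r) / log(10)
  dimnames(L10) <- list(lab, lab)
  structure(M, log_evidence = stats::setNames(ev, lab), log10 = L10,
            prior = prior, class = c("lr_matrix", "matrix"))
}

#' Likelihood-ratio matrices for the whole prior grid
#'
#' @inheritParams lr_matrix
#' @return Named list of nine [lr_matrix()] results, one per
#'   [prior_grid()] combination.
#' @export
all_lr_matrices <- function(table, ...) {
  lapply(prior_grid(), function(pr) lr_matrix(table, pr, ...))
}

#' @export
print.lr_matrix <- function(x, ...) {
  pl <- prior_label(attr(x, "prior"))
  cat("likelihood ratios (column model over row model)\n")
  cat("  priors: contrast", pl[["mean"]], "| sigma", pl[["sigma"]], "\n")
  print(matrix(sprintf("%.3g", x), 5, 5, dimnames = dimnames(x)), quote = FALSE)
  best <- names(which.max(attr(x, "log_evidence")))
  cat("highest evidence:", best, "\n")
  invisible(x)
}

#' Prior-sampling importance estimate of the evidence (cross-check oracle)
#'
#' Draws parameters from the priors and averages the likelihood
#' (log-sum-exp), the direct "simulation approximation" to the evidence.
#' Only practical for small data sets (the prior is a poor proposal when
#' the likelihood is concentrated); used to cross-check the quadrature
#' engine, never as the primary method.
#'
#' @inheritParams log_evidence
#' @param n_draws Number of prior draws (>= 1000).
#' @param seed Integer seed (required: the estimate is stochastic).
#' @return List with `log_evidence`, `se` (delta-method standard error of
#'   the log estimate) and `ess` (effective sample size; a warning is
#'   given below 50).
#' @export
evidence_mc_oracle <- function(table, model, prior, n_draws = 1e5, seed,
                               parameterization = c("treatment", "cellmeans")) {
  parameterization <- match.arg(parameterization)
  stopifnot(n_draws >= 1000)
  if (!inherits(model, "model_spec")) model <- model_spec(model)
  y <- table$contrast
  X <- if (parameterization == "treatment") {
    model_design(model, table)
  } else if (model$id > 1L) {
    cs_key <- cell_stats(table, model)$cell
    key <- switch(model$id, NULL, rep("all", nrow(table)),
                  paste0("group", table$group), table$region,
                  paste0(table$region, ".group", table$group))
    stats::model.matrix(~ 0 + factor(key, levels = cs_key))
  } else NULL
  p <- if (is.null(X)) 0L else ncol(X)
  with_seed(seed, {
    sig <- switch(prior$sigma_prior,
      uniform = stats::runif(n_draws, 0, 5),
      halfnormal = abs(stats::rnorm(n_draws, 0, 2)),
      gamma = stats::rgamma(n_draws, 2, 2))
    ll <- if (p == 0L) {
      -length(y) / 2 * log(2 * pi * sig^2) - sum(y^2) / (2 * sig^2)
    } else {
      B <- switch(prior$mean_prior,
        normal = matrix(stats::rnorm(n_draws * p), n_draws, p),
        cauchy = matrix(stats::rcauchy(n_draws * p), n_draws, p),
        uniform = matrix(stats::runif(n_draws * p, -8, 8), n_draws, p))
      R <- tcrossprod(B, X)  # n_draws x n fitted means
      rss <- rowSums((matrix(y, n_draws, length(y), byrow = TRUE) - R)^2)
      -length(y) / 2 * log(2 * pi * sig^2) - rss / (2 * sig^2)
    }
    m <- max(ll)
    w <- exp(ll - m)
    est <- m + log(mean(w))
    ess <- sum(w)^2 / sum(w^2)
    if (ess < 50) warning("effective sample size ", round(ess, 1),
                          " < 50: oracle estimate unreliable")
    list(log_evidence = est, se = stats::sd(w) / (mean(w) * sqrt(n_draws)),
         ess = ess)
  })
}
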