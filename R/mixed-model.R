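#' Random-intercept mixed model of the contrasts
#'
#' The frequentist companion to the two-group Bayesian model: a linear
#' mixed model of the per-region contrasts with group as fixed effect and
#' a per-subject random intercept (each subject contributes six
#' observations), fit by REML. The group effect is parameterized as
#' mean(group 1) - mean(group 2), and its t statistic and two-sided
#' p-value use Satterthwaite degrees of freedom (which equal the
#' between-subject degrees of freedom, n_subjects - 2, in this balanced
#' design).
#'
#' @param table A [contrast_table()] with at least two subjects per group
#'   and two observations per subject.
#' @return An `lmm_fit` list: `estimate` (group 1 minus group 2), `se`,
#'   `t_value`, `df`, `p_value`, `intercept`, and the REML variance
#'   components `var_subject` and `var_residual`.
#' @export
fit_random_intercept <- function(table) {
  stopifnot(inherits(table, "contrast_table"))
  df <- data.frame(contrast = table$contrast,
                   group = factor(table$group, levels = c(2L, 1L)),
                   subject = factor(table$subject))
  if (stats::var(df$contrast) == 0) {
    stop("all contrasts identical: group effect 0 with zero residual ",
         "variance, t statistic undefined")
  }
  fit <- lmerTest::lmer(contrast ~ group + (1 | subject), data = df,
                        REML = TRUE)
  co <- stats::coef(summary(fit))["group1", ]
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    estimate = unname(co[["Estimate"]]),
    se = unname(co[["Std. Error"]]),
    t_value = unname(co[["t value"]]),
    df = unname(co[["df"]]),
    p_value = unname(co[["Pr(>|t|)"]]),
    intercept = unname(lme4::fixef(fit)[["(Intercept)"]]),
    var_subject = vc$vcov[vc$grp == "subject"],
    var_residual = vc$vcov[vc$grp == "Residual"]
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("random-intercept mixed model (REML)\n")
  cat(sprintf("  group effect (g1 - g2): %.4f  SE %.4f  t = %.3f  df = %.1f  p = %.3g\n",
              x$estimate, x$se, x$t_value, x$df, x$p_value))
  cat(sprintf("  variance components: subject %.4f, residual %.4f\n",
              x$var_subject, x$var_residual))
  invisible(x)
}
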