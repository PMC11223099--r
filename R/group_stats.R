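#' Significance tier for a p-value
#'
#' The caption convention used for treatment comparisons:
#' `N.S.` (> 0.05), `*` (<= 0.05), `**` (<= 0.01), `***` (<= 0.001).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of tiers.
#' @export
sig_tier <- function(p) {
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
                ifelse(p <= 0.05, "*", "N.S.")))
}

#' Group significance tests for per-cell statistics
#'
#' The statistical battery applied to per-cell readouts across treatment
#' conditions: one-way ANOVA with a post hoc Tukey HSD across all groups,
#' plus pairwise two-sample t tests (pooled-variance Student's t by
#' default; Welch behind `var_equal = FALSE`). Each p-value is annotated
#' with its significance tier.
#'
#' @param data data.frame of per-cell rows.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping (condition) column.
#' @param var_equal Pooled-variance t test if `TRUE` (default).
#' @return A `group_test_report`: list with `anova` (data.frame: F, df, p,
#'   tier), `tukey` (data.frame of pairwise adjusted p), `t_tests`
#'   (data.frame of pairwise t statistics and p), `groups`.
#' @export
group_tests <- function(data, value, group, var_equal = TRUE) {
  y <- data[[value]]
  gvec <- factor(data[[group]])
  ok <- is.finite(y) & !is.na(gvec)
  y <- y[ok]; gvec <- droplevels(gvec[ok])
  counts <- table(gvec)
  if (nlevels(gvec) < 2 || any(counts < 2)) {
    srs_error("srsphasor_insufficient_data",
              "need >= 2 groups with >= 2 observations each")
  }
  fit <- stats::aov(y ~ gvec)
  s <- summary(fit)[[1]]
  anova_df <- data.frame(F = s[1, "F value"],
                         df_between = s[1, "Df"], df_within = s[2, "Df"],
                         p = s[1, "Pr(>F)"])
  anova_df$tier <- sig_tier(anova_df$p)
  tk <- stats::TukeyHSD(fit)$gvec
  tukey_df <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         p_adj = tk[, "p adj"], tier = sig_tier(tk[, "p adj"]),
                         row.names = NULL)
  lev <- levels(gvec)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  t_rows <- lapply(pairs, function(pr) {
    tt <- stats::t.test(y[gvec == pr[1]], y[gvec == pr[2]],
                        var.equal = var_equal)
    data.frame(group1 = pr[1], group2 = pr[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, tier = sig_tier(tt$p.value))
  })
  structure(list(anova = anova_df, tukey = tukey_df,
                 t_tests = do.call(rbind, t_rows),
                 groups = as.data.frame(counts,
                                        responseName = "n"),
                 var_equal = var_equal),
            class = "group_test_report")
}

#' @export
print.group_test_report <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.3g (%s)\n",
              x$anova$df_between, x$anova$df_within, x$anova$F,
              x$anova$p, x$anova$tier))
  cat("Tukey HSD:\n"); print(x$tukey, digits = 3)
  cat(sprintf("pairwise %s t tests:\n",
              if (x$var_equal) "Student (pooled)" else "Welch"))
  print(x$t_tests, digits = 3)
  invisible(x)
}
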