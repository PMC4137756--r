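# Inferential layer: one-sample t-tests on log-ratios, multiplicity
# adjustment, and the Group x Lab (Type II) ANOVA.

#' One-sample t-test
#'
#' Tests whether the mean of `values` (typically log10 freezing ratios
#' across participants) differs from `mu0`; two-sided, sample (n-1) SD.
#' Degenerate zero-variance input is handled explicitly: if all values
#' equal `mu0` the statistic is 0 with p = 1; if they are constant but
#' different from `mu0` the test is undefined and an error is raised.
#'
#' @param values numeric vector, n >= 2, finite.
#' @param mu0 null mean (default 0, i.e. no freezing effect).
#' @return list with `t`, `df`, `p`, `mean`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("one_sample_t needs at least 2 values")
  if (any(!is.finite(values))) stop("one_sample_t: values must be finite")
  s <- stats::sd(values)
  if (s == 0) {
    if (abs(mean(values) - mu0) < .Machine$double.eps^0.5) {
      return(list(t = 0, df = length(values) - 1L, p = 1,
                  mean = mean(values)))
    }
    stop("one_sample_t: zero variance with mean != mu0; t undefined")
  }
  ht <- stats::t.test(values, mu = mu0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(values))
}

#' Adjust p-values for multiple comparisons
#'
#' Monotone step-down Holm adjustment by default;
#' Benjamini-Hochberg available for exploratory use. Adjusted values are
#' never smaller than the raw ones and preserve their order.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @param method `"holm"` (default) or `"BH"`.
#' @return adjusted p-values, same length/order as the input.
#' @export
adjust_p <- function(pvals, method = c("holm", "BH")) {
  method <- match.arg(method)
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = method)
}

#' Group effect from a Type-II Group x Lab ANOVA
#'
#' Between-subject ANOVA with factors Group and Lab and their interaction,
#' using Type-II sums of squares (to control for the group/lab confound of
#' an unbalanced two-lab design); only the Group main effect is extracted.
#'
#' @param values numeric response (one freezing effect per participant).
#' @param group,lab factors (or coercible) of the same length as `values`;
#'   each needs at least 2 levels and every occupied cell at least one
#'   observation.
#' @return list with `F_group`, `df`, `df_resid`, `p_group`.
#' @export
anova_group_lab <- function(values, group, lab) {
  df <- data.frame(value = as.numeric(values),
                   group = factor(group), lab = factor(lab))
  if (nlevels(df$group) < 2 || nlevels(df$lab) < 2) {
    stop("group and lab each need at least 2 levels")
  }
  if (any(!is.finite(df$value))) stop("values must be finite")
  fit <- stats::lm(value ~ group * lab, data = df)
  tab <- tryCatch(car::Anova(fit, type = 2),
                  error = function(e) {
                    stop("Type-II ANOVA not estimable: ", conditionMessage(e))
                  })
  i <- match("group", rownames(tab))
  r <- match("Residuals", rownames(tab))
  list(F_group = tab[i, "F value"],
       df = tab[i, "Df"],
       df_resid = tab[r, "Df"],
       p_group = tab[i, "Pr(>F)"])
}

#' Group-level statistics for a cohort of freezing effects
#'
#' Reproduces the study's inferential structure on a table of per-participant
#' freezing effects: (i) within each group, one-sample t-tests of the log10
#' ratios against 0 for every joint x direction cell, Holm-adjusted within
#' the family of the 6 cells (3 joints x 2 directions) of each group x
#' measure; (ii) per joint x measure x direction, the Group main effect from
#' the Type-II Group x Lab ANOVA, Holm-adjusted within each measure's 6
#' cells.
#'
#' @param effects data frame with columns `participant_id`, `group`, `lab`,
#'   `joint`, `measure`, `direction`, `log10_ratio` (one row per participant
#'   and cell), e.g. from [run_study()].
#' @param adjust_method passed to [adjust_p()].
#' @return list of data frames `t_tests` and `group_anova`.
#' @export
freeze_stats <- function(effects, adjust_method = "holm") {
  need <- c("group", "lab", "joint", "measure", "direction", "log10_ratio")
  stopifnot(all(need %in% names(effects)))
  eff <- effects[is.finite(effects$log10_ratio), , drop = FALSE]

  cells <- unique(eff[c("group", "joint", "measure", "direction")])
  trows <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- cells[i, ]
    v <- eff$log10_ratio[eff$group == cc$group & eff$joint == cc$joint &
                           eff$measure == cc$measure &
                           eff$direction == cc$direction]
    if (length(v) < 2) return(NULL)
    res <- one_sample_t(v)
    data.frame(group = cc$group, joint = cc$joint, measure = cc$measure,
               direction = cc$direction, n = length(v),
               mean_log10_ratio = res$mean, t = res$t, df = res$df,
               p = res$p, stringsAsFactors = FALSE)
  })
  t_tests <- do.call(rbind, trows)
  if (!is.null(t_tests)) {
    t_tests$p_adj <- NA_real_
    for (g in unique(t_tests$group)) {
      for (m in unique(t_tests$measure)) {
        fam <- t_tests$group == g & t_tests$measure == m
        t_tests$p_adj[fam] <- adjust_p(t_tests$p[fam], adjust_method)
      }
    }
  }

  acells <- unique(eff[c("joint", "measure", "direction")])
  arows <- lapply(seq_len(nrow(acells)), function(i) {
    cc <- acells[i, ]
    sub <- eff[eff$joint == cc$joint & eff$measure == cc$measure &
                 eff$direction == cc$direction, , drop = FALSE]
    if (length(unique(sub$group)) < 2 || length(unique(sub$lab)) < 2) {
      return(NULL)
    }
    res <- tryCatch(anova_group_lab(sub$log10_ratio, sub$group, sub$lab),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(joint = cc$joint, measure = cc$measure,
               direction = cc$direction, n = nrow(sub),
               F_group = res$F_group, df = res$df,
               df_resid = res$df_resid, p = res$p_group,
               stringsAsFactors = FALSE)
  })
  group_anova <- do.call(rbind, arows)
  if (!is.null(group_anova)) {
    group_anova$p_adj <- NA_real_
    for (m in unique(group_anova$measure)) {
      fam <- group_anova$measure == m
      group_anova$p_adj[fam] <- adjust_p(group_anova$p[fam], adjust_method)
    }
  }
  list(t_tests = t_tests, group_anova = group_anova)
}
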