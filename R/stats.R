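#' Remove 1.5 x IQR outliers
#'
#' Values beyond 1.5 interquartile ranges above the upper quartile or
#' below the lower quartile are removed, in a single pass. Quartiles use
#' linear interpolation (R's default type-7 convention; alternative
#' conventions are selectable). Fewer than 4 values pass through
#' unchanged with a warning, since quartile fences are not meaningful.
#'
#' @param values Finite numeric vector.
#' @param k Fence multiplier (default 1.5).
#' @param type Quartile algorithm passed to [stats::quantile()]
#'   (default 7).
#' @return A list with `kept` and `removed` numeric vectors.
#' @export
iqr_outlier_filter <- function(values, k = 1.5, type = 7) {
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("iqr_outlier_filter: values must be finite numeric",
         call. = FALSE)
  if (length(values) < 4L) {
    warning("fewer than 4 values: outlier filter passed through unchanged")
    return(list(kept = values, removed = numeric(0)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  keep <- values >= q[1] - k * iqr & values <= q[2] + k * iqr
  list(kept = values[keep], removed = values[!keep])
}

#' Fold change of group means
#'
#' `mean(treated) / mean(control)`, by default after applying the
#' 1.5 x IQR outlier filter to each group separately (matching the
#' assay's reporting of fold changes on filtered per-chip values). A
#' value below 1 is a fold decrease; its reciprocal is the "x-fold
#' decrease" a report would quote.
#'
#' @param treated,control Numeric vectors of per-chip metric values.
#' @param filter_outliers Apply [iqr_outlier_filter()] to each group
#'   first (default `TRUE`).
#' @return A single number.
#' @export
fold_change <- function(treated, control, filter_outliers = TRUE) {
  if (filter_outliers) {
    treated <- suppressWarnings(iqr_outlier_filter(treated)$kept)
    control <- suppressWarnings(iqr_outlier_filter(control)$kept)
  }
  mc <- mean(control)
  if (!is.finite(mc) || mc == 0)
    stop("fold_change: control mean is zero or non-finite", call. = FALSE)
  if (mc < 0)
    warning("fold_change: negative control mean; interpret with care")
  mean(treated) / mc
}

#' One-way ANOVA with Dunnett's comparison against a control group
#'
#' Fits a one-way ANOVA across all groups and adjusts the two-sided
#' comparisons of every non-control group against the control with
#' Dunnett's single-step multivariate-t procedure (via
#' \pkg{multcomp}; the quantile computation is seeded for
#' reproducibility). With exactly one non-control group the adjusted
#' p-value equals the pooled-variance two-sided t-test, which is
#' computed directly in that case.
#'
#' @param values Numeric vector of per-chip metric values.
#' @param group Group label per value (character or factor).
#' @param control Label of the control group.
#' @param seed Integer seed for the multivariate-t quantile routine.
#' @return A list with `anova_F`, `anova_p`, and a data frame
#'   `comparisons` (`group, estimate, p_adj`).
#' @export
compare_to_control <- function(values, group, control, seed = 20240617) {
  group <- as.character(group)
  if (!control %in% group)
    stop("compare_to_control: control label '", control,
         "' not present in groups", call. = FALSE)
  tab <- table(group)
  if (length(tab) < 2L)
    stop("compare_to_control: need >= 2 groups", call. = FALSE)
  if (any(tab < 2L))
    stop("compare_to_control: every group needs n >= 2", call. = FALSE)
  g <- stats::relevel(factor(group), ref = control)
  d <- data.frame(y = values, g = g)
  fit <- stats::aov(y ~ g, data = d)
  s <- summary(fit)[[1]]
  anova_F <- s[["F value"]][1]
  anova_p <- s[["Pr(>F)"]][1]
  others <- setdiff(levels(g), control)
  if (length(others) == 1L) {
    tt <- stats::t.test(values[group == others], values[group == control],
                        var.equal = TRUE)
    cmp <- data.frame(group = others,
                      estimate = unname(diff(rev(tt$estimate))),
                      p_adj = tt$p.value, stringsAsFactors = FALSE)
  } else {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(gl, test = multcomp::adjusted("single-step"))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    cmp <- data.frame(group = others,
                      estimate = as.numeric(sm$test$coefficients),
                      p_adj = as.numeric(sm$test$pvalues),
                      stringsAsFactors = FALSE)
  }
  list(anova_F = anova_F, anova_p = anova_p, comparisons = cmp)
}

#' Per-group summary statistics
#'
#' Sample size, mean, and SD (n-1 denominator) per group, plus the
#' conventional `mean +/- SD` display string with two decimals. Groups
#' of one report `NA` SD.
#'
#' @param values Numeric vector.
#' @param group Group label per value.
#' @return A data frame with `group, n, mean, sd, label`.
#' @export
summarize_groups <- function(values, group) {
  group <- as.character(group)
  out <- do.call(rbind, lapply(split(values, group), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  }))
  out$group <- rownames(out)
  rownames(out) <- NULL
  out$label <- ifelse(is.na(out$sd),
                      sprintf("%.2f", out$mean),
                      sprintf("%.2f ± %.2f", out$mean, out$sd))
  out[, c("group", "n", "mean", "sd", "label")]
}

#' Significance label at the assay's reporting thresholds
#'
#' `#` for p < .10, `*` < .05, `**` < .01, `***` < .001, `****` < .0001,
#' `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of labels.
#' @export
significance_label <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, 0.1, Inf),
      labels = c("****", "***", "**", "*", "#", "ns"),
      right = FALSE) |> as.character()
}
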