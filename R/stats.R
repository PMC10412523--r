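# Inferential layer: one-way and factorial ANOVA with partial eta squared,
# paired t with Cohen's d, Tukey HSD and Bonferroni post hocs. Model fitting
# is delegated to stats::aov / stats::t.test; this layer adds the effect
# sizes and the reporting container.

new_stat_result <- function(statistic, df1, df2, p, effect_size, method,
                            effect = NA_character_) {
  structure(
    list(statistic = statistic, df1 = df1, df2 = df2, p = p,
      effect_size = effect_size, method = method, effect = effect),
    class = "cb_stat"
  )
}

#' @export
print.cb_stat <- function(x, ...) {
  lab <- if (grepl("t-test", x$method)) {
    sprintf("t(%g) = %.3f, p = %s, d = %.3f",
      x$df1, x$statistic, format.pval(x$p, digits = 3), x$effect_size)
  } else {
    sprintf("F(%g, %g) = %.3f, p = %s, partial eta^2 = %.3f",
      x$df1, x$df2, x$statistic, format.pval(x$p, digits = 3),
      x$effect_size)
  }
  eff <- if (!is.na(x$effect)) sprintf(" [%s]", x$effect) else ""
  cat(sprintf("<cb_stat> %s%s (%s)\n", lab, eff, x$method))
  invisible(x)
}

#' One-way between-groups ANOVA with partial eta squared
#'
#' @param groups List of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return A `cb_stat` with the F statistic, degrees of freedom, p value and
#'   partial eta squared `SS_effect / (SS_effect + SS_error)`.
#' @export
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
anova_oneway <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort_argument("need at least 2 groups with at least 2 values each")
  }
  d <- data.frame(
    y = unlist(groups),
    g = factor(rep(seq_along(groups), lengths(groups)))
  )
  fit <- aov(y ~ g, data = d)
  s <- summary(fit)[[1]]
  ss_eff <- s[1, "Sum Sq"]
  ss_err <- s[2, "Sum Sq"]
  f <- s[1, "F value"]
  if (ss_eff + ss_err <= 0) { # all values identical
    f <- 0
  }
  new_stat_result(
    statistic = if (is.nan(f)) 0 else f,
    df1 = s[1, "Df"], df2 = s[2, "Df"],
    p = if (is.nan(f)) 1 else s[1, "Pr(>F)"],
    effect_size = if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else 0,
    method = "one-way ANOVA"
  )
}

#' Factorial (fully crossed, balanced) ANOVA
#'
#' Fits `response ~ A * B` on a balanced design table and reports each main
#' effect and the interaction with partial eta squared. Balanced designs
#' make the Type I/II/III sums of squares coincide, so the classical
#' sequential decomposition from [stats::aov()] is used. An empty cell is an
#' error.
#'
#' @param data Data frame holding the response and two factor columns.
#' @param response Name of the response column.
#' @param factors Character vector of the two factor column names.
#' @return Named list of `cb_stat` (one per main effect, one for the
#'   interaction).
#' @export
anova_factorial <- function(data, response, factors) {
  if (length(factors) != 2) {
    abort_argument("exactly two factors are supported")
  }
  if (!all(c(response, factors) %in% names(data))) {
    abort_argument("response/factor columns not found in data")
  }
  a <- factor(data[[factors[1]]])
  b <- factor(data[[factors[2]]])
  counts <- table(a, b)
  if (any(counts == 0)) {
    abort_argument("design has an empty cell; balanced designs only")
  }
  d <- data.frame(y = data[[response]], A = a, B = b)
  fit <- aov(y ~ A * B, data = d)
  s <- summary(fit)[[1]]
  terms <- rownames(s)
  ss_err <- s[nrow(s), "Sum Sq"]
  df_err <- s[nrow(s), "Df"]
  out <- list()
  labels <- c(factors, paste(factors, collapse = " x "))
  for (i in seq_len(nrow(s) - 1)) {
    ss <- s[i, "Sum Sq"]
    out[[labels[i]]] <- new_stat_result(
      statistic = s[i, "F value"], df1 = s[i, "Df"], df2 = df_err,
      p = s[i, "Pr(>F)"],
      effect_size = if (ss + ss_err > 0) ss / (ss + ss_err) else 0,
      method = "factorial ANOVA", effect = labels[i]
    )
  }
  out
}

#' Paired t-test with Cohen's d
#'
#' Cohen's d for paired data is `mean(diff) / sd(diff)`. Differences with
#' zero variance and zero mean (identical inputs) return a null result
#' (t = 0, d = 0, p = 1); zero variance with a nonzero mean is a degenerate
#' input and errors.
#'
#' @param a,b Numeric vectors of equal length (>= 2).
#' @return A `cb_stat`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3), c(3, 2, 1))
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    abort_argument("a and b must have equal length >= 2")
  }
  d <- a - b
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(new_stat_result(0, length(d) - 1, NA_real_, 1, 0,
        "paired t-test"))
    }
    abort_argument("differences have zero variance but a nonzero mean")
  }
  tt <- t.test(a, b, paired = TRUE)
  new_stat_result(
    statistic = unname(tt$statistic), df1 = unname(tt$parameter),
    df2 = NA_real_, p = tt$p.value,
    effect_size = mean(d) / sd(d), method = "paired t-test"
  )
}

#' Pairwise post-hoc comparisons
#'
#' Tukey HSD (via the studentised range, [stats::TukeyHSD()]) or Bonferroni
#' (raw pooled-variance pairwise t-test p values multiplied by the number
#' of comparisons, capped at 1). Raw pairwise p values are reported
#' alongside the adjusted ones.
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @param method `"tukey_hsd"` or `"bonferroni"`.
#' @return Tibble `comparison, diff, p_raw, p_adj`.
#' @export
posthoc <- function(groups, method = c("tukey_hsd", "bonferroni")) {
  method <- match.arg(method)
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort_argument("need at least 2 groups with at least 2 values each")
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  d <- data.frame(
    y = unlist(groups),
    g = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  k <- length(groups)
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1))) /
    (nrow(d) - k)
  combs <- combn(names(groups), 2)
  raw_t_p <- function(g1, g2) {
    # pooled-variance t using the omnibus MSE
    se <- sqrt(mse * (1 / length(groups[[g1]]) + 1 / length(groups[[g2]])))
    if (se == 0) return(c(0, 1))
    tval <- (mean(groups[[g1]]) - mean(groups[[g2]])) / se
    c(tval, 2 * pt(-abs(tval), nrow(d) - k))
  }
  raw <- apply(combs, 2, function(cc) raw_t_p(cc[1], cc[2])[2])
  diffs <- apply(combs, 2,
    function(cc) mean(groups[[cc[1]]]) - mean(groups[[cc[2]]]))
  comparison <- apply(combs, 2, function(cc) paste(cc[1], "-", cc[2]))

  p_adj <- switch(method,
    bonferroni = pmin(1, raw * ncol(combs)),
    tukey_hsd = {
      tk <- TukeyHSD(aov(y ~ g, data = d))$g
      key <- paste(combs[2, ], combs[1, ], sep = "-")
      unname(tk[match(key, rownames(tk)), "p adj"])
    }
  )
  tibble::tibble(
    comparison = comparison, diff = diffs, p_raw = raw, p_adj = p_adj
  )
}
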