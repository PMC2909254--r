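#' Two-group one-way ANOVA from summary statistics
#'
#' Standard (equal-variance) one-way ANOVA recovered from per-group mean,
#' sd and n: within-group mean square pooled from the sds, between-group
#' mean square from the means, `F` on `(1, n1 + n2 - 2)` degrees of
#' freedom. With two groups `F` equals the square of the pooled
#' two-sample t statistic. A Welch variant is available for wildly
#' unequal variances.
#'
#' @param summary data.frame with columns `group`, `mean`, `sd`, `n`
#'   (exactly two rows) and optionally `parameter`.
#' @param alpha significance level for the flag (default 0.05).
#' @param welch use the Welch (unequal-variance) statistic instead.
#' @return list of class `anova_result`: `parameter`, `F`, `df1`, `df2`,
#'   `p`, `significant`, `degenerate`.
#' @export
anova_two_group <- function(summary, alpha = 0.05, welch = FALSE) {
  stopifnot(nrow(summary) == 2,
            all(c("mean", "sd", "n") %in% names(summary)))
  if (any(summary$sd < 0)) stop_ecm("negative sd")
  if (any(summary$n < 2)) stop_ecm("each group needs n >= 2")
  m <- summary$mean; s <- summary$sd; n <- summary$n
  param <- summary$parameter[1] %||% NA_character_
  if (all(s == 0) && m[1] == m[2]) {
    return(structure(list(parameter = param, F = NaN, df1 = 1L,
                          df2 = sum(n) - 2L, p = 1, significant = FALSE,
                          degenerate = TRUE), class = "anova_result"))
  }
  if (welch) {
    se2 <- s^2 / n
    Fv <- (m[1] - m[2])^2 / sum(se2)
    df2 <- sum(se2)^2 / sum(se2^2 / (n - 1))
  } else {
    grand <- sum(n * m) / sum(n)
    ssb <- sum(n * (m - grand)^2)
    ssw <- sum((n - 1) * s^2)
    df2 <- sum(n) - 2
    Fv <- (ssb / 1) / (ssw / df2)
    if (!is.finite(Fv)) Fv <- Inf  # ssw == 0, means differ
  }
  p <- pf(Fv, 1, df2, lower.tail = FALSE)
  p <- max(p, .Machine$double.xmin)  # keep p in (0, 1]
  structure(list(parameter = param, F = Fv, df1 = 1L, df2 = df2, p = p,
                 significant = p < alpha, degenerate = !is.finite(Fv)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA%s: F(%d, %.3g) = %.4g, p = %.4g%s\n",
              if (is.na(x$parameter)) "" else paste0(" [", x$parameter, "]"),
              x$df1, x$df2, x$F, x$p, if (x$significant) " *" else ""))
  invisible(x)
}

summarise_raw <- function(raw) {
  stopifnot(all(c("parameter", "group", "value") %in% names(raw)))
  agg <- do.call(rbind, lapply(
    split(raw, list(raw$parameter, raw$group), drop = TRUE),
    function(d) data.frame(parameter = d$parameter[1], group = d$group[1],
                           mean = mean(d$value), sd = sd(d$value),
                           n = nrow(d), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg
}

#' Per-parameter two-group soil comparisons
#'
#' Accepts either raw replicates (columns `parameter`, `group`, `value`)
#' or printed summaries (columns `parameter`, `group`, `mean`, `sd`, `n`);
#' raw data are first reduced to summaries, so both paths give identical
#' F statistics. p-values are unadjusted by default (per-parameter
#' significance), with an optional Holm correction.
#'
#' @param x data.frame in either form.
#' @param alpha significance level (default 0.05).
#' @param holm apply Holm adjustment to the p-values.
#' @param welch use Welch ANOVA.
#' @return data.frame: `parameter`, `F`, `df1`, `df2`, `p`, `significant`.
#' @export
compare_soils <- function(x, alpha = 0.05, holm = FALSE, welch = FALSE) {
  summ <- if ("value" %in% names(x)) summarise_raw(x) else x
  stopifnot(all(c("parameter", "group", "mean", "sd", "n") %in% names(summ)))
  out <- do.call(rbind, lapply(split(summ, summ$parameter), function(d) {
    if (nrow(d) != 2)
      stop_ecm("parameter ", d$parameter[1], " does not have exactly ",
               "two groups")
    a <- anova_two_group(d, alpha = alpha, welch = welch)
    data.frame(parameter = a$parameter, F = a$F, df1 = a$df1, df2 = a$df2,
               p = a$p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out <- out[order(out$parameter), , drop = FALSE]
  out$p_adj <- if (holm) stats::p.adjust(out$p, "holm") else out$p
  out$significant <- out$p_adj < alpha
  out
}
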