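# Replicate-level statistics: Welch's unequal-variance t-test, two-way
# ANOVA with Type II sums of squares, and condition-comparison report
# tables. Tests are two-sided throughout; no multiple-testing correction
# is applied (comparisons are reported per metric, as in per-panel
# figure statistics).

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Welch's two-sample t-test
#'
#' Unpaired t-test assuming unequal variances:
#' `t = (mean_x - mean_y) / sqrt(sx^2/nx + sy^2/ny)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. The
#' degenerate case of zero variance in both groups with equal means is
#' defined as `t = 0, p = 1`.
#'
#' @param x,y replicate values (each of length >= 2, finite).
#' @return Object of class `ComparisonResult`: list with `mean_x`,
#'   `mean_y`, `sd_x`, `sd_y`, `n_x`, `n_y`, `t`, `df`, `p`, `stars`.
#' @export
welch_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in input")
  }
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    tstat <- 0
    df <- nx + ny - 2
    p <- 1
  } else {
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  structure(list(mean_x = mean(x), mean_y = mean(y),
                 sd_x = sqrt(vx), sd_y = sqrt(vy),
                 n_x = nx, n_y = ny,
                 t = tstat, df = df, p = p, stars = p_stars(p)),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf(
    "Welch t-test: %.4g +/- %.3g (n=%d) vs %.4g +/- %.3g (n=%d)\n",
    x$mean_x, x$sd_x, x$n_x, x$mean_y, x$sd_y, x$n_y))
  cat(sprintf("  t = %.4g, df = %.3g, p = %.4g %s\n",
              x$t, x$df, x$p, x$stars))
  invisible(x)
}

rss_of <- function(y, mm) {
  fit <- qr.fitted(qr(mm), y)
  sum((y - fit)^2)
}

rank_of <- function(mm) qr(mm)$rank

#' Two-way ANOVA with Type II sums of squares
#'
#' Tests the main effects of two factors and their interaction. Main
#' effects use Type II sums of squares (each main effect adjusted for the
#' other, ignoring the interaction), which coincide with the classical
#' balanced-design decomposition when the design is balanced; the
#' interaction is tested against the full model. F statistics use the full
#' model's residual mean square.
#'
#' @param values numeric response.
#' @param factorA,factorB factors (e.g. pH label and variant), each with
#'   >= 2 levels; every factor-level combination needs >= 2 observations.
#' @return data.frame with rows A, B, A:B and columns `df`, `sum_sq`,
#'   `mean_sq`, `F`, `p`.
#' @export
two_way_anova <- function(values, factorA, factorB) {
  y <- as.numeric(values)
  a <- factor(factorA); b <- factor(factorB)
  stopifnot(length(y) == length(a), length(y) == length(b))
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stop("each factor needs at least 2 levels")
  }
  cell_n <- table(a, b)
  if (any(cell_n < 2L)) {
    stop("every factor combination needs at least 2 observations")
  }
  tss <- sum((y - mean(y))^2)
  if (tss <= 1e-12 * max(1, sum(y^2))) {
    # degenerate constant response: no effects anywhere
    return(data.frame(term = c("A", "B", "A:B"),
                      df = c(nlevels(a) - 1L, nlevels(b) - 1L,
                             (nlevels(a) - 1L) * (nlevels(b) - 1L)),
                      sum_sq = 0, mean_sq = 0, F = 0, p = 1))
  }
  mm <- function(formula) stats::model.matrix(formula,
                                              data.frame(a = a, b = b))
  m_a <- mm(~a); m_b <- mm(~b); m_ab <- mm(~a + b); m_full <- mm(~a * b)
  rss_full <- rss_of(y, m_full)
  df_resid <- length(y) - rank_of(m_full)
  ss <- c(A = rss_of(y, m_b) - rss_of(y, m_ab),
          B = rss_of(y, m_a) - rss_of(y, m_ab),
          `A:B` = rss_of(y, m_ab) - rss_full)
  df <- c(A = nlevels(a) - 1L, B = nlevels(b) - 1L,
          `A:B` = (nlevels(a) - 1L) * (nlevels(b) - 1L))
  ms <- ss / df
  ms_resid <- rss_full / df_resid
  if (ms_resid == 0) {
    # degenerate no-variance data: absent effects give F = 0, p = 1
    fstat <- ifelse(abs(ss) < 1e-12, 0, Inf)
    p <- ifelse(abs(ss) < 1e-12, 1, 0)
  } else {
    fstat <- ms / ms_resid
    p <- stats::pf(fstat, df, df_resid, lower.tail = FALSE)
  }
  out <- data.frame(term = names(ss), df = as.integer(df), sum_sq = ss,
                    mean_sq = ms, F = fstat, p = p,
                    row.names = NULL)
  attr(out, "df_resid") <- df_resid
  attr(out, "rss_resid") <- rss_full
  out
}

#' Condition-comparison report
#'
#' For each metric, pools replicate averages per condition according to
#' the pooling map (subunit-level metrics count each subunit of each
#' trajectory as a replicate; whole-channel metrics count each trajectory
#' once) and compares high vs low pH within each variant with
#' [welch_t_test()].
#'
#' @param replicates named list: `metric -> variant -> pH_label -> numeric
#'   vector of replicate averages` (as produced by stacking
#'   [replicate_averages()] across trajectories).
#' @return data.frame with one row per metric x variant: group means, sds,
#'   ns, t, df, p and significance stars.
#' @export
condition_report <- function(replicates) {
  rows <- list()
  for (metric in names(replicates)) {
    for (variant in names(replicates[[metric]])) {
      groups <- replicates[[metric]][[variant]]
      if (!all(c("high", "low") %in% names(groups))) {
        stop(sprintf("metric '%s' variant '%s' lacks a high or low group",
                     metric, variant))
      }
      cmp <- welch_t_test(groups$high, groups$low)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, variant = variant,
        mean_high = cmp$mean_x, sd_high = cmp$sd_x, n_high = cmp$n_x,
        mean_low = cmp$mean_y, sd_low = cmp$sd_y, n_low = cmp$n_y,
        t = cmp$t, df = cmp$df, p = cmp$p, stars = cmp$stars,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
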