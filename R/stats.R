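#' Group sample
#'
#' @param values Finite numeric values (n >= 1).
#' @param label Group label.
#' @param unit Measurement unit string.
#' @return A `group_sample`.
#' @export
group_sample <- function(values, label = "group", unit = "") {
  values <- as.numeric(values)
  if (length(values) < 1 || any(!is.finite(values)))
    stop("a group sample needs >= 1 finite values", call. = FALSE)
  structure(list(label = label, values = values, unit = unit),
            class = "group_sample")
}

#' Two-sided Mann-Whitney(-Wilcoxon) test
#'
#' Rank-based two-sample comparison used for all group contrasts
#' (branch lengths, apparent stiffness, speed and bulk flow). The exact
#' null distribution is enumerated for small tie-free samples
#' (`n1, n2 <= 8`); otherwise the normal approximation with tie and
#' continuity correction is used.
#'
#' @param a,b `group_sample`s or numeric vectors.
#' @return A `mw_test_result`: list with `U` (statistic of the first
#'   sample), `p_two_sided`, `n1`, `n2`, `method`.
#' @export
mann_whitney <- function(a, b) {
  av <- if (inherits(a, "group_sample")) a$values else as.numeric(a)
  bv <- if (inherits(b, "group_sample")) b$values else as.numeric(b)
  if (length(av) < 1 || length(bv) < 1)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- any(duplicated(c(av, bv)))
  use_exact <- length(av) <= 8 && length(bv) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    av, bv, alternative = "two.sided",
    exact = use_exact, correct = TRUE))
  structure(
    list(U = unname(wt$statistic), p_two_sided = wt$p.value,
         n1 = length(av), n2 = length(bv),
         method = if (use_exact) "exact"
                  else "normal-approx (tie/continuity corrected)"),
    class = "mw_test_result")
}

#' @export
print.mw_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g [%s]\n",
              x$U, x$n1, x$n2, x$p_two_sided, x$method))
  invisible(x)
}

#' Descriptive summary of a group sample
#'
#' Mean, SD, SEM, median, min/max and the 5th/95th percentiles
#' (linear-interpolation quantiles) used for box-plot whiskers.
#'
#' @param s A `group_sample` or numeric vector.
#' @return One-row data frame; a single-value sample reports SD 0 with
#'   `degenerate = TRUE`.
#' @export
summarize_group <- function(s) {
  v <- if (inherits(s, "group_sample")) s$values else as.numeric(s)
  n <- length(v)
  q <- stats::quantile(v, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  data.frame(
    label = if (inherits(s, "group_sample")) s$label else "group",
    n = n,
    mean = mean(v),
    sd = if (n > 1) stats::sd(v) else 0,
    sem = if (n > 1) stats::sd(v) / sqrt(n) else 0,
    median = q[2], min = min(v), max = max(v),
    p05 = q[1], p95 = q[3],
    degenerate = n == 1)
}

#' Render an analysis report bundle
#'
#' Writes CSV tables of the group summaries and test results, a JSON
#' summary, and (optionally, when `ggplot2` is available) box-plot figures.
#' The report is a pure function of its inputs.
#'
#' @param groups Named list of `group_sample`s.
#' @param tests Optional named list of `mw_test_result`s.
#' @param out_dir Output directory (created if needed).
#' @param figures Write box-plot figures? Default `FALSE` (tables only).
#' @return Invisibly, the list of written file paths.
#' @export
render_report <- function(groups, tests = NULL, out_dir, figures = FALSE) {
  if (length(groups) == 0) stop("no analysis outputs to report", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  summ <- do.call(rbind, lapply(groups, summarize_group))
  rownames(summ) <- NULL
  p <- file.path(out_dir, "group_summary.csv")
  utils::write.csv(summ, p, row.names = FALSE)
  paths <- c(paths, p)
  raw <- do.call(rbind, lapply(groups, function(g) {
    data.frame(label = g$label, value = g$values, unit = g$unit)
  }))
  p <- file.path(out_dir, "group_values.csv")
  utils::write.csv(raw, p, row.names = FALSE)
  paths <- c(paths, p)
  report <- list(schema_version = "1.0",
                 quantile_convention = "linear interpolation (type 7)",
                 groups = summ)
  if (!is.null(tests)) {
    tdf <- do.call(rbind, lapply(names(tests), function(nm) {
      t <- tests[[nm]]
      data.frame(comparison = nm, U = t$U, p_two_sided = t$p_two_sided,
                 n1 = t$n1, n2 = t$n2, method = t$method)
    }))
    p <- file.path(out_dir, "tests.csv")
    utils::write.csv(tdf, p, row.names = FALSE)
    paths <- c(paths, p)
    report$tests <- tdf
  }
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths <- c(paths, p)
  if (figures && requireNamespace("ggplot2", quietly = TRUE)) {
    df <- raw
    gg <- ggplot2::ggplot(df, ggplot2::aes(x = label, y = value)) +
      ggplot2::geom_boxplot(outlier.size = 0.6) +
      ggplot2::labs(x = NULL, y = unique(df$unit)[1])
    p <- file.path(out_dir, "groups_boxplot.png")
    suppressMessages(ggplot2::ggsave(p, gg, width = 4, height = 3, dpi = 150))
    paths <- c(paths, p)
  }
  invisible(paths)
}
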