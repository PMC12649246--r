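#' Frozen/thawed volume-pair table
#'
#' Per-scan volume pairs of one object segmented under two conditions
#' (condition A = frozen, condition B = thawed), the input to the paired
#' volumetric comparison.
#'
#' @param scan_id vector of unique scan identifiers.
#' @param frozen,thawed positive volumes in mm^3, paired by position.
#' @return A `data.frame` of class `volume_pair_table` with columns
#'   `scan_id`, `frozen`, `thawed`.
#' @export
volume_pair_table <- function(scan_id, frozen, thawed) {
  if (length(frozen) != length(thawed) || length(scan_id) != length(frozen))
    stop("scan_id, frozen and thawed must have equal length", call. = FALSE)
  if (anyDuplicated(scan_id)) stop("scan ids must be unique", call. = FALSE)
  if (any(frozen <= 0) || any(thawed <= 0))
    stop("volumes must be positive", call. = FALSE)
  structure(data.frame(scan_id = scan_id, frozen = as.numeric(frozen),
                       thawed = as.numeric(thawed)),
            class = c("volume_pair_table", "data.frame"))
}

#' Per-scan relative volume differences
#'
#' Adds the derived difference columns and their summary. The per-scan
#' signed relative difference is `100 * (thawed - frozen) / thawed` (the
#' thawed volume is the denominator); the printed-style column is its
#' absolute value. The summary mean is the mean of the SIGNED values, while
#' the summary SD of the relative differences uses the population convention
#' (divisor n) — both conventions are recorded in the result.
#'
#' @param table a [volume_pair_table()].
#' @return A list of class `relative_differences`: `table` (with columns
#'   `rel_diff_signed_pct`, `rel_diff_abs_pct` appended), `mean_signed_pct`,
#'   `sd_population_pct`, `sd_sample_pct`.
#' @export
relative_differences <- function(table) {
  stopifnot(inherits(table, "volume_pair_table"))
  if (any(table$frozen <= 0) || any(table$thawed <= 0))
    stop("volumes must be positive", call. = FALSE)
  signed <- 100 * (table$thawed - table$frozen) / table$thawed
  out <- table
  out$rel_diff_signed_pct <- signed
  out$rel_diff_abs_pct <- abs(signed)
  n <- length(signed)
  structure(list(table = out,
                 mean_signed_pct = mean(signed),
                 sd_population_pct = sqrt(mean((signed - mean(signed))^2)),
                 sd_sample_pct = if (n > 1) stats::sd(signed) else 0),
            class = "relative_differences")
}

#' @export
print.relative_differences <- function(x, ...) {
  cat("<relative_differences> signed mean ",
      sprintf("%.2f%%", x$mean_signed_pct), " (population SD ",
      sprintf("%.2f%%", x$sd_population_pct), ")\n", sep = "")
  invisible(x)
}

#' Paired t-test with confidence interval and effect size
#'
#' Two-sided paired t-test on differences `d = b - a`: `t = mean(d) /
#' (s_d / sqrt(n))` with `df = n - 1` and sample-convention `s_d`; 95%
#' confidence interval `mean(d) +/- t_{0.975, df} * s_d / sqrt(n)`; Cohen's
#' d for paired data `mean(d) / s_d`. When every difference is exactly zero
#' the test is defined as `t = 0`, `p = 1` (zero effect measured with zero
#' variance).
#'
#' @param a,b paired measurement vectors of equal length `n >= 2` (`a` =
#'   condition A / frozen, `b` = condition B / thawed).
#' @param conf_level confidence level of the interval.
#' @return An object of class `paired_test_result` with fields
#'   `mean_difference`, `sd_difference`, `t`, `df`, `p_value`, `conf_int`,
#'   `cohens_d`, `n`.
#' @export
paired_t_test <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b))
    stop("a and b must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- b - a
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1
  q <- stats::qt(1 - (1 - conf_level) / 2, df)
  if (s == 0) {
    if (m == 0) {
      tstat <- 0; p <- 1; ci <- c(0, 0); cd <- 0
    } else {
      tstat <- sign(m) * Inf; p <- 0; ci <- c(m, m); cd <- sign(m) * Inf
    }
  } else {
    se <- s / sqrt(n)
    tstat <- m / se
    p <- 2 * stats::pt(-abs(tstat), df)
    ci <- m + c(-1, 1) * q * se
    cd <- m / s
  }
  structure(list(mean_difference = m, sd_difference = s, t = tstat, df = df,
                 p_value = p, conf_int = ci, cohens_d = cd, n = n,
                 conf_level = conf_level),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(
    "Paired t-test: mean difference %.2f (s_d %.2f), t(%d) = %.2f, p = %.2f\n",
    x$mean_difference, x$sd_difference, x$df, x$t, x$p_value))
  cat(sprintf("  %g%% CI [%.2f, %.2f], Cohen's d = %.2f\n",
              100 * x$conf_level, x$conf_int[1], x$conf_int[2], x$cohens_d))
  invisible(x)
}

#' Column mean and standard deviation
#'
#' Arithmetic mean and SAMPLE-convention (divisor n-1) standard deviation of
#' a volume column, the convention of per-condition summary rows.
#'
#' @param volumes numeric vector, `n >= 2`.
#' @return A list with `mean` and `sd`.
#' @export
column_summary <- function(volumes) {
  if (length(volumes) < 2)
    stop("need at least 2 values for a column SD", call. = FALSE)
  list(mean = mean(volumes), sd = stats::sd(volumes))
}

#' Full frozen-vs-thawed comparison report
#'
#' Runs the complete paired volumetric comparison, either on a pre-built
#' [volume_pair_table()] or on two paired lists of meshes (volumes computed
#' via [mesh_volume()]): per-scan relative differences, column summaries,
#' and the paired t-test with confidence interval and Cohen's d.
#'
#' @param table a [volume_pair_table()]; or
#' @param meshes_a,meshes_b paired lists of closed [triangle_mesh()] objects.
#' @param scan_id optional ids when meshes are given.
#' @return An object of class `volume_comparison`: `table` (with derived
#'   columns), `test` (a `paired_test_result`), `relative` (a
#'   `relative_differences`), `summary_a`, `summary_b`.
#' @export
run_comparison <- function(table = NULL, meshes_a = NULL, meshes_b = NULL,
                           scan_id = NULL) {
  if (is.null(table)) {
    if (is.null(meshes_a) || is.null(meshes_b))
      stop("provide either a table or both mesh lists", call. = FALSE)
    if (length(meshes_a) != length(meshes_b))
      stop("mesh lists must be paired (equal length)", call. = FALSE)
    va <- vapply(meshes_a, mesh_volume, numeric(1))
    vb <- vapply(meshes_b, mesh_volume, numeric(1))
    if (is.null(scan_id)) scan_id <- seq_along(va)
    table <- volume_pair_table(scan_id, va, vb)
  }
  stopifnot(inherits(table, "volume_pair_table"))
  rel <- relative_differences(table)
  test <- paired_t_test(table$frozen, table$thawed)
  structure(list(table = rel$table, test = test, relative = rel,
                 summary_a = column_summary(table$frozen),
                 summary_b = column_summary(table$thawed)),
            class = "volume_comparison")
}

#' @export
print.volume_comparison <- function(x, ...) {
  cat("Frozen vs thawed volume comparison (n = ", x$test$n, ")\n", sep = "")
  cat(sprintf("  column means: %.2f / %.2f mm^3 (SD %.2f / %.2f)\n",
              x$summary_a$mean, x$summary_b$mean, x$summary_a$sd,
              x$summary_b$sd))
  print(x$test)
  cat(sprintf("  mean signed relative difference %.2f%% (population SD %.2f%%)\n",
              x$relative$mean_signed_pct, x$relative$sd_population_pct))
  invisible(x)
}

#' Read a volume-pair table from CSV
#'
#' Expects columns `scan_id`, `frozen`, `thawed`. The packaged example
#' fixture can be located with
#' `system.file("extdata", "table1.csv", package = "carposeg")`.
#'
#' @param path CSV file path.
#' @return A [volume_pair_table()].
#' @export
read_volume_pairs <- function(path) {
  df <- utils::read.csv(path)
  need <- c("scan_id", "frozen", "thawed")
  if (!all(need %in% names(df)))
    stop("CSV must have columns scan_id, frozen, thawed", call. = FALSE)
  volume_pair_table(df$scan_id, df$frozen, df$thawed)
}
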