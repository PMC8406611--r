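# Quality control.
#
# Three checks guard a CNV result: (1) the query's mean depth must sit
# close to the selected pool's mean depth (percentage deviation vs a lab
# cutoff, e.g. 5%); (2) the pool's members must have uniform depth
# (coefficient of variation of member means); (3) scores from the static
# pool are cross-checked against scores from a run-wise pool built from
# the query's own sequencing run.

#' Percentage deviation of query mean depth from pool mean depth
#'
#' @param query_mean Query sample mean depth (reads per position).
#' @param pool_mean Selected pool mean depth (> 0).
#' @return `100 * |query_mean - pool_mean| / pool_mean`.
#' @examples
#' percent_deviation(210, 200)  # 5
#' @export
percent_deviation <- function(query_mean, pool_mean) {
  if (any(pool_mean <= 0)) {
    stop("pool mean depth must be positive to compute percentage deviation",
         call. = FALSE)
  }
  100 * abs(query_mean - pool_mean) / pool_mean
}

#' Uniformity of a pool's member depths
#'
#' Coefficient of variation (percent, n-1 denominator) of the member
#' sample mean depths. Large values mean the pool averages samples of
#' unlike depth and its per-window reference is noisy.
#'
#' @param pool A `static_pool`.
#' @param member_means Optional explicit member mean depths (defaults to
#'   those stored in the pool).
#' @return CV in percent.
#' @export
pool_uniformity <- function(pool, member_means = pool$member_mean_depths) {
  if (length(member_means) < 2L) {
    stop("pool CV undefined for fewer than 2 members", call. = FALSE)
  }
  100 * stats::sd(member_means) / mean(member_means)
}

#' Compare static-pool and run-wise-pool score profiles
#'
#' Per-window absolute score differences on windows called in both
#' profiles; windows whose difference exceeds `delta_threshold` (log2
#' units) are flagged as pool-dependent and deserve scrutiny.
#'
#' @param static_profile,runwise_profile Two [score_sample()] profiles of
#'   the same sample on the same template.
#' @param delta_threshold Flagging threshold in log2 units (default 0.3).
#' @return List with `max_delta`, `mean_delta`, `n_compared`, `n_above`,
#'   `flagged` (window row indices) and the `delta` vector (`NA` where
#'   either profile is a no-call).
#' @export
compare_static_vs_runwise <- function(static_profile, runwise_profile,
                                      delta_threshold = 0.3) {
  a <- static_profile$table
  b <- runwise_profile$table
  if (nrow(a) != nrow(b) || !all(a$start == b$start) || !all(a$chrom == b$chrom)) {
    stop("profiles are on different window templates", call. = FALSE)
  }
  if (static_profile$sample_id != runwise_profile$sample_id) {
    stop("profiles belong to different samples (",
         static_profile$sample_id, " vs ", runwise_profile$sample_id, ")",
         call. = FALSE)
  }
  both <- !a$no_call & !b$no_call
  delta <- rep(NA_real_, nrow(a))
  delta[both] <- abs(a$score[both] - b$score[both])
  flagged <- which(!is.na(delta) & delta > delta_threshold)
  list(max_delta = if (any(both)) max(delta[both]) else NA_real_,
       mean_delta = if (any(both)) mean(delta[both]) else NA_real_,
       n_compared = sum(both),
       n_above = length(flagged),
       flagged = flagged,
       delta = delta)
}

#' Run all quality checks for one scored sample
#'
#' @param query The query [sample_coverage()].
#' @param pool The selected `static_pool`.
#' @param static_profile The [score_sample()] profile from the static pool.
#' @param runwise_profile Optional profile from a run-wise pool for the
#'   cross-check.
#' @param deviation_cutoff_pct Maximum allowed percentage deviation of
#'   query vs pool mean depth (default 5, the usual lab cutoff).
#' @param max_pool_cv Maximum allowed pool member-depth CV in percent
#'   (default 15).
#' @param delta_threshold Static-vs-run-wise flag threshold, log2 units.
#' @return An object of class `cnv_qc` with the deviation, pool CV,
#'   run-wise comparison summary and per-check pass booleans; `pass` is
#'   the conjunction of the hard checks (deviation and pool CV).
#' @export
qc_sample <- function(query, pool, static_profile, runwise_profile = NULL,
                      deviation_cutoff_pct = 5, max_pool_cv = 15,
                      delta_threshold = 0.3) {
  dev <- percent_deviation(query$mean_depth, pool$pool_mean_depth)
  cv <- pool_uniformity(pool)
  runwise <- if (!is.null(runwise_profile)) {
    compare_static_vs_runwise(static_profile, runwise_profile, delta_threshold)
  }
  structure(
    list(sample_id = query$sample_id, pool_id = pool$pool_id,
         pct_deviation = dev,
         deviation_pass = dev <= deviation_cutoff_pct,
         deviation_cutoff_pct = deviation_cutoff_pct,
         pool_cv = cv,
         pool_cv_pass = cv <= max_pool_cv,
         max_pool_cv = max_pool_cv,
         runwise_delta = runwise,
         pass = dev <= deviation_cutoff_pct && cv <= max_pool_cv),
    class = "cnv_qc"
  )
}

#' @export
print.cnv_qc <- function(x, ...) {
  cat("cnv_qc:", x$sample_id, "vs pool", x$pool_id, "\n")
  cat(sprintf("  depth deviation %.2f%% (cutoff %.1f%%): %s\n", x$pct_deviation,
              x$deviation_cutoff_pct, if (x$deviation_pass) "pass" else "FAIL"))
  cat(sprintf("  pool member CV %.2f%% (max %.1f%%): %s\n", x$pool_cv,
              x$max_pool_cv, if (x$pool_cv_pass) "pass" else "FAIL"))
  if (!is.null(x$runwise_delta)) {
    cat(sprintf("  static vs run-wise: %d/%d windows differ by > threshold (max %.3f)\n",
                x$runwise_delta$n_above, x$runwise_delta$n_compared,
                x$runwise_delta$max_delta))
  }
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param qc A [qc_sample()] object.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_qc_tsv <- function(qc, path) {
  out <- data.frame(
    sample_id = qc$sample_id, pool_id = qc$pool_id,
    pct_deviation = qc$pct_deviation, deviation_pass = qc$deviation_pass,
    pool_cv = qc$pool_cv, pool_cv_pass = qc$pool_cv_pass,
    runwise_n_above = if (is.null(qc$runwise_delta)) NA_integer_ else qc$runwise_delta$n_above,
    runwise_max_delta = if (is.null(qc$runwise_delta)) NA_real_ else qc$runwise_delta$max_delta,
    pass = qc$pass,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
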