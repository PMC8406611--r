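# logCNR scoring.
#
# For each sliding window the query's mean depth is divided by the
# selected pool's mean depth for the same window (mean_TRSW) and the
# ratio is taken to log2 scale. Theoretical values: 0.0 for two alleles,
# -1.0 for a heterozygous deletion (depth halved), +0.58 for a
# heterozygous duplication (depth x 1.5); a mosaic single-allele deletion
# in a fraction f of cells is expected at log2(1 - f/2).

#' Log copy-number-ratio of a window
#'
#' `log2(query_window_mean / pool_window_mean)`, with two guard rules so
#' that no infinite score is ever emitted:
#' * a pool mean below `min_pool_depth` makes the window a no-call
#'   (returned as `NA`) — low-coverage reference windows are where
#'   read-depth callers produce their false positives, so they are
#'   masked rather than scored;
#' * a query mean of 0 against an adequately covered pool returns the
#'   `floor_score` cap (an extreme deletion signal consistent with a
#'   homozygous deletion) instead of `-Inf`.
#'
#' @param query_window_mean Query mean depth(s), reads per position
#'   (vectorised).
#' @param pool_window_mean Pool mean depth(s), same length.
#' @param min_pool_depth Pool-depth floor below which a window is a
#'   no-call (default 20).
#' @param floor_score Capped score for zero query depth (default -6).
#' @return Numeric vector of log2 ratios; `NA` marks no-calls.
#' @examples
#' logcnr(100, 200)  # -1.0, heterozygous deletion
#' logcnr(300, 200)  # +0.585, heterozygous duplication
#' @export
logcnr <- function(query_window_mean, pool_window_mean,
                   min_pool_depth = 20, floor_score = -6) {
  if (anyNA(query_window_mean) || anyNA(pool_window_mean) ||
      any(query_window_mean < 0) || any(pool_window_mean < 0)) {
    stop("window means must be non-negative and non-missing", call. = FALSE)
  }
  no_call <- pool_window_mean < min_pool_depth
  score <- ifelse(no_call, NA_real_,
                  ifelse(query_window_mean == 0, floor_score,
                         log2(query_window_mean / pool_window_mean)))
  score
}

#' Score a query sample against a selected pool
#'
#' Applies [logcnr()] to every template window: the query's window mean
#' (numerator) against the pool's stored per-window mean (`mean_trsw`,
#' denominator).
#'
#' @param query A [sample_coverage()] object.
#' @param pool A `static_pool` (from [select_pool()] or
#'   [build_runwise_pool()]).
#' @param template The shared [build_template()] object.
#' @inheritParams logcnr
#' @return An object of class `logcnr_profile`: list with `sample_id`,
#'   `pool_id`, `table` (window coordinates, gene, region label, query
#'   and pool means, `score`, `no_call`, `flag`), `window_len`,
#'   `slide_len` and a `qc` slot (filled by [qc_sample()]).
#' @export
score_sample <- function(query, pool, template,
                         min_pool_depth = 20, floor_score = -6) {
  stopifnot(inherits(query, "sample_coverage"), inherits(pool, "static_pool"),
            inherits(template, "window_template"))
  if (length(pool$mean_trsw) != nrow(template$windows)) {
    stop("pool mean_trsw has ", length(pool$mean_trsw), " windows but the ",
         "template has ", nrow(template$windows),
         "; pool and template are misaligned", call. = FALSE)
  }
  qm <- window_means(query, template)
  pm <- pool$mean_trsw
  score <- logcnr(qm, pm, min_pool_depth, floor_score)
  no_call <- is.na(score)
  flag <- rep("", length(score))
  flag[!no_call & qm == 0] <- "possible_homozygous_deletion"

  w <- template$windows
  tab <- data.frame(
    gene = w$gene, region_label = w$region_label, region_id = w$region_id,
    chrom = w$chrom, start = w$start, end = w$end,
    window_index = w$window_index,
    query_mean = qm, pool_mean = pm,
    score = score, no_call = no_call, flag = flag,
    stringsAsFactors = FALSE
  )
  structure(
    list(sample_id = query$sample_id, pool_id = pool$pool_id,
         query_mean_depth = query$mean_depth,
         pool_mean_depth = pool$pool_mean_depth,
         table = tab,
         window_len = template$window_len, slide_len = template$slide_len,
         min_pool_depth = min_pool_depth, floor_score = floor_score,
         qc = NULL),
    class = "logcnr_profile"
  )
}

#' @export
print.logcnr_profile <- function(x, ...) {
  called <- !x$table$no_call
  cat("logcnr_profile:", x$sample_id, "vs pool", x$pool_id, "-",
      sum(called), "of", nrow(x$table), "windows called\n")
  if (any(called)) {
    cat(sprintf("  score range [%.2f, %.2f], median %.3f\n",
                min(x$table$score[called]), max(x$table$score[called]),
                stats::median(x$table$score[called])))
  }
  invisible(x)
}

#' Write a per-sample logCNR table
#'
#' One row per sliding window: gene, region label, window coordinates,
#' query/pool means, score and no-call flag. Positions are written
#' 1-based inclusive (`pos_start`/`pos_end`) alongside the 0-based
#' half-open `start`/`end`.
#'
#' @param profile A [score_sample()] profile.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_logcnr_tsv <- function(profile, path) {
  tab <- profile$table
  tab$pos_start <- tab$start + 1L
  tab$pos_end <- tab$end
  out <- tab[, c("gene", "region_label", "chrom", "start", "end",
                 "pos_start", "pos_end", "window_index",
                 "query_mean", "pool_mean", "score", "no_call", "flag")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
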