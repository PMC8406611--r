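# Static pools of normal samples.
#
# Normals (CNV-free samples above a mean-depth cutoff) are sorted by
# increasing mean depth; pool j holds samples j..j+K-1 of that list, so
# N normals yield M = N - K + 1 overlapping pools and consecutive pools
# share K - 1 members. Each pool stores the per-window mean of its
# members' window means (mean_TRSW), the reference the query is scored
# against. Pools carry the capture-kit lot so that cross-lot comparisons
# (batch effects) are refused unless explicitly allowed.

#' Select and sort normal samples for pooling
#'
#' Keeps samples whose mean depth exceeds `min_mean_depth` and orders them
#' by increasing mean depth (ties broken by `sample_id` so the order is
#' reproducible).
#'
#' @param samples List of [sample_coverage()] objects.
#' @param min_mean_depth Mean-depth cutoff in reads per position
#'   (default 100).
#' @return List of `sample_coverage` objects, sorted.
#' @export
select_normals <- function(samples, min_mean_depth = 100) {
  stopifnot(length(samples) > 0L)
  means <- vapply(samples, function(s) s$mean_depth, 0)
  ids <- vapply(samples, function(s) s$sample_id, "")
  keep <- means > min_mean_depth
  if (!any(keep)) {
    stop("no eligible normal samples: all ", length(samples),
         " mean depths are <= the ", min_mean_depth, "x cutoff", call. = FALSE)
  }
  ord <- order(means[keep], ids[keep])
  samples[keep][ord]
}

#' Build overlapping static pools from sorted normals
#'
#' @param normals List of `sample_coverage` objects sorted by increasing
#'   mean depth (from [select_normals()]).
#' @param K Pool size (number of samples per pool, `K >= 2`).
#' @param template The shared [build_template()] object.
#' @param lot_id Capture-kit lot the pools belong to; defaults to the
#'   members' common lot when they agree.
#' @return An object of class `pool_set`: list with `pools` (each a
#'   `static_pool` carrying `pool_id`, `members`, `member_mean_depths`,
#'   `pool_mean_depth`, `lot_id`, `mean_trsw`), `K`, `N`, `lot_id`.
#' @export
build_static_pools <- function(normals, K, template, lot_id = NULL) {
  check_positive_scalar(K, "K")
  if (K < 2L) stop("pool size K must be at least 2", call. = FALSE)
  N <- length(normals)
  if (N < K) {
    stop("insufficient normal samples: N = ", N, " < K = ", K, call. = FALSE)
  }
  means <- vapply(normals, function(s) s$mean_depth, 0)
  if (is.unsorted(means)) {
    stop("`normals` must be sorted by increasing mean depth (use select_normals())",
         call. = FALSE)
  }
  lots <- unique(vapply(normals, function(s) s$lot_id, ""))
  if (is.null(lot_id)) lot_id <- if (length(lots) == 1L) lots else NA_character_

  wm <- vapply(normals, window_means, numeric(nrow(template$windows)),
               template = template)      # windows x N
  ids <- vapply(normals, function(s) s$sample_id, "")

  M <- N - K + 1L
  pools <- lapply(seq_len(M), function(j) {
    cols <- j:(j + K - 1L)
    structure(
      list(pool_id = j,
           members = ids[cols],
           member_mean_depths = means[cols],
           pool_mean_depth = mean(means[cols]),
           lot_id = lot_id,
           mean_trsw = rowMeans(wm[, cols, drop = FALSE])),
      class = "static_pool"
    )
  })
  structure(list(pools = pools, K = as.integer(K), N = N, lot_id = lot_id),
            class = "pool_set")
}

#' @export
print.pool_set <- function(x, ...) {
  cat("pool_set:", length(x$pools), "pools of K =", x$K, "from N =", x$N,
      "normals (lot", x$lot_id, ")\n")
  cat("  pool mean depths:",
      paste(sprintf("%.1f", vapply(x$pools, function(p) p$pool_mean_depth, 0)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Select the static pool nearest a query's mean depth
#'
#' Picks the pool whose mean depth (mean of member sample means) is
#' closest to the query's mean depth; ties go to the lower-depth pool.
#' A query from a different capture-kit lot than the pools is refused
#' unless `allow_cross_lot = TRUE` (batch effects make cross-lot depth
#' comparison unreliable).
#'
#' @param query A [sample_coverage()] object.
#' @param pools A [build_static_pools()] pool set.
#' @param allow_cross_lot Permit lot mismatch between query and pools?
#' @return The selected `static_pool`.
#' @export
select_pool <- function(query, pools, allow_cross_lot = FALSE) {
  stopifnot(inherits(pools, "pool_set"))
  if (length(pools$pools) == 0L) stop("empty pool set", call. = FALSE)
  if (!allow_cross_lot && !is.na(pools$lot_id) && !is.na(query$lot_id) &&
      query$lot_id != pools$lot_id) {
    stop("query lot '", query$lot_id, "' differs from pool lot '", pools$lot_id,
         "'; capture-kit batch effects make cross-lot comparison unreliable ",
         "(use allow_cross_lot = TRUE to override)", call. = FALSE)
  }
  pm <- vapply(pools$pools, function(p) p$pool_mean_depth, 0)
  d <- abs(pm - query$mean_depth)
  best <- order(d, pm)[1L]    # tie -> lower-depth pool
  pools$pools[[best]]
}

#' Build a run-wise pool for a query sample
#'
#' Uses all samples of the query's sequencing run except the query itself
#' as a single reference pool, computed exactly like a static pool. Used
#' to cross-check static-pool results.
#'
#' @param run_samples List of `sample_coverage` objects from one run
#'   (may include the query).
#' @param query_id Sample id of the query, excluded from the pool.
#' @param template The shared [build_template()] object.
#' @return A `static_pool` (pool_id 0, labelled run-wise).
#' @export
build_runwise_pool <- function(run_samples, query_id, template) {
  ids <- vapply(run_samples, function(s) s$sample_id, "")
  members <- run_samples[ids != query_id]
  if (length(members) < 3L) {
    stop("insufficient run samples for a run-wise pool: need >= 3 non-query ",
         "samples, have ", length(members), call. = FALSE)
  }
  means <- vapply(members, function(s) s$mean_depth, 0)
  ord <- order(means, vapply(members, function(s) s$sample_id, ""))
  members <- members[ord]
  ps <- build_static_pools(members, K = length(members), template)
  pool <- ps$pools[[1L]]
  pool$pool_id <- 0L
  pool$runwise <- TRUE
  pool
}

#' Write a pool set to a directory
#'
#' Serialises a pool set as `manifest.tsv` (pool_id, comma-joined members
#' and member mean depths, pool mean depth, K, lot) plus `mean_trsw.tsv`
#' (window coordinates and one column of per-window mean depths per pool).
#'
#' @param pools A [build_static_pools()] pool set.
#' @param template The template the pools were built on.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_pool_set <- function(pools, template, dir) {
  stopifnot(inherits(pools, "pool_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(
    pool_id = vapply(pools$pools, function(p) p$pool_id, 0),
    members = vapply(pools$pools, function(p) paste(p$members, collapse = ","), ""),
    member_mean_depths = vapply(pools$pools, function(p)
      paste(format(p$member_mean_depths, digits = 10), collapse = ","), ""),
    pool_mean_depth = vapply(pools$pools, function(p) p$pool_mean_depth, 0),
    K = pools$K, N = pools$N, lot_id = pools$lot_id,
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  trsw <- template$windows[, c("chrom", "start", "end")]
  for (p in pools$pools) trsw[[paste0("pool_", p$pool_id)]] <- p$mean_trsw
  utils::write.table(trsw, file.path(dir, "mean_trsw.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a pool set written by [write_pool_set()]
#'
#' @param dir Pool-store directory.
#' @param template Template to validate window alignment against.
#' @return A `pool_set`.
#' @export
read_pool_set <- function(dir, template) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  trsw <- utils::read.table(file.path(dir, "mean_trsw.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  w <- template$windows
  if (nrow(trsw) != nrow(w) || !all(trsw$start == w$start) ||
      !all(trsw$end == w$end) || !all(trsw$chrom == w$chrom)) {
    stop("pool store in ", dir, " does not match the window template", call. = FALSE)
  }
  pools <- lapply(seq_len(nrow(manifest)), function(i) {
    structure(
      list(pool_id = manifest$pool_id[i],
           members = strsplit(manifest$members[i], ",", fixed = TRUE)[[1L]],
           member_mean_depths = as.numeric(
             strsplit(manifest$member_mean_depths[i], ",", fixed = TRUE)[[1L]]),
           pool_mean_depth = manifest$pool_mean_depth[i],
           lot_id = as.character(manifest$lot_id[i]),
           mean_trsw = trsw[[paste0("pool_", manifest$pool_id[i])]]),
      class = "static_pool"
    )
  })
  structure(list(pools = pools, K = manifest$K[1L], N = manifest$N[1L],
                 lot_id = as.character(manifest$lot_id[1L])),
            class = "pool_set")
}
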