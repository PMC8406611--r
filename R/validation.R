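# In-silico validation study.
#
# Re-runs the pipeline end to end on simulated cohorts and measures the
# quantities a panel validation reports: event-level sensitivity over the
# canonical CNV classes, window-level specificity on event-free samples,
# mosaic signal recovery, breakpoint resolution, and exactness of the
# score under noise-free conditions. The detection metrics are measured
# on the scoring path (pool selection -> scoring -> flagging); the
# depth-deviation QC gate is a sample-acceptance step evaluated
# separately, since large CNVs legitimately shift a sample's own mean
# depth.

# overlap-based hit test between candidates and one truth interval
cands_hit <- function(cands, truth_row) {
  if (is.null(cands) || nrow(cands) == 0L) return(FALSE)
  dir <- if (truth_row$copy_ratio < 1) "deletion" else "duplication"
  any(cands$chrom == truth_row$chrom & cands$direction == dir &
        cands$start < truth_row$end & cands$end > truth_row$start)
}

score_query <- function(q, pools, template, config = cnv_config()) {
  pool <- select_pool(q, pools, allow_cross_lot = TRUE)
  score_sample(q, pool, template,
               min_pool_depth = config$min_pool_depth,
               floor_score = config$floor_score)
}

#' Run the simulated validation study
#'
#' Builds a deep-panel cohort (126 regions over 21 genes, 20 normal
#' samples, 200x target depth, 5% multiplicative coverage noise), injects
#' the ten canonical CNV events of [example_event_set()], builds K = 8
#' static pools and measures:
#'
#' * `event_sensitivity_pct` — events recovered by the default candidate
#'   flagger, out of 10;
#' * `window_specificity_pct` and `false_positive_candidates` — over five
#'   depth-matched event-free query samples scored against the pools;
#' * `mosaic_mean_logcnr` — mean in-span score of a 30% mosaic multi-exon
#'   deletion simulated at 500x in a depth-matched cohort (expected
#'   log2(0.85) = -0.234), plus whether the low-stringency mosaic pass
#'   flags it;
#' * `breakpoint_max_error_nt` — worst refined-edge error for a
#'   partial-exon deletion with an intra-exon breakpoint;
#' * `zero_noise_max_abs_error` — largest deviation of scores from
#'   log2(copy ratio) when every noise term is zero.
#'
#' The mosaic, breakpoint and zero-noise sub-studies use depth-matched
#' queries (no per-sample depth scaling) so the measured signal is the
#' event's own, mirroring what the depth-deviation QC gate enforces on
#' real samples.
#'
#' @param seed Integer seed governing all randomness.
#' @param n_specificity_samples Event-free query samples for the
#'   specificity estimate.
#' @return A list of the measurements above, plus bookkeeping counts
#'   (`n_events`, `n_windows_specificity`, `n_pools`).
#' @export
validation_study <- function(seed = 1L, n_specificity_samples = 5L) {
  config <- cnv_config()

  # -- main cohort: sensitivity and specificity -----------------------------
  sc <- sim_config(seed = seed)
  sc$events <- example_event_set(simulate_panel(sc))
  co <- simulate_cohort(sc)
  normals <- select_normals(co$samples[co$manifest$role == "normal"], 100)
  pools <- build_static_pools(normals, 8L, co$template)

  truth <- co$truth
  event_ids <- unique(truth$sample_id)
  hits <- vapply(event_ids, function(id) {
    prof <- score_query(co$samples[[id]], pools, co$template, config)
    cands <- flag_candidates(prof, config$del_threshold, config$dup_threshold,
                             config$min_consecutive)
    all(vapply(which(truth$sample_id == id), function(k)
      cands_hit(cands, truth[k, ]), TRUE))
  }, TRUE)

  n_flagged <- 0L
  n_called <- 0L
  n_fp_spans <- 0L
  for (j in seq_len(n_specificity_samples)) {
    res <- simulate_sample(co$panel, co$template, sc, sprintf("QRY%02d", j),
                           seed = sc$seed + 5000L + j)
    prof <- score_query(res$coverage, pools, co$template, config)
    cands <- flag_candidates(prof, config$del_threshold, config$dup_threshold,
                             config$min_consecutive)
    n_fp_spans <- n_fp_spans + nrow(cands)
    called <- !prof$table$no_call
    sc_called <- prof$table$score[called]
    n_called <- n_called + length(sc_called)
    n_flagged <- n_flagged + sum(sc_called <= config$del_threshold |
                                   sc_called >= config$dup_threshold)
  }

  # -- mosaic recovery at 500x, depth-matched -------------------------------
  sc_mos <- sim_config(seed = seed + 1L, base_depth = 500, sample_depth_sd = 0)
  panel_mos <- simulate_panel(sc_mos)
  # first gene whose first three regions hold enough windows for the pass
  tmpl_mos <- build_template(panel_mos$regions)
  mos_gene <- NULL
  for (g in unique(panel_mos$regions$gene)) {
    rr <- panel_mos$regions[panel_mos$regions$gene == g, ]
    if (nrow(rr) >= 3L) {
      n_win <- length(windows_fully_inside(tmpl_mos, rr$chrom[1L],
                                           rr$start[1L], rr$end[3L]))
      if (n_win >= 12L) { mos_gene <- g; break }
    }
  }
  sc_mos$events <- list(cnv_event("MOS01", 0.85, gene = mos_gene, regions = 1:3))
  co_mos <- simulate_cohort(sc_mos)
  normals_mos <- select_normals(co_mos$samples[co_mos$manifest$role == "normal"], 100)
  pools_mos <- build_static_pools(normals_mos, 8L, co_mos$template)
  prof_mos <- score_query(co_mos$samples[["MOS01"]], pools_mos, co_mos$template, config)
  tr <- co_mos$truth[1, ]
  in_span <- windows_fully_inside(co_mos$template, tr$chrom, tr$start, tr$end)
  mosaic_mean <- mean(prof_mos$table$score[in_span])
  cands_mos <- flag_candidates(prof_mos, include_mosaic = TRUE)
  mosaic_flagged <- cands_hit(cands_mos[cands_mos$class == "possible_mosaic", ], tr) ||
    cands_hit(cands_mos, tr)

  # -- breakpoint resolution: partial-exon deletion -------------------------
  sc_bp <- sim_config(seed = seed + 2L, sample_depth_sd = 0)
  panel_bp <- simulate_panel(sc_bp)
  rr <- panel_bp$regions[panel_bp$regions$end - panel_bp$regions$start >= 300, ]
  reg <- rr[1, ]
  bp <- reg$start + (reg$end - reg$start) %/% 3L
  sc_bp$events <- list(cnv_event("BPT01", 0.5, chrom = reg$chrom,
                                 start = bp, end = reg$end))
  co_bp <- simulate_cohort(sc_bp)
  normals_bp <- select_normals(co_bp$samples[co_bp$manifest$role == "normal"], 100)
  pools_bp <- build_static_pools(normals_bp, 8L, co_bp$template)
  prof_bp <- score_query(co_bp$samples[["BPT01"]], pools_bp, co_bp$template, config)
  cands_bp <- refine_breakpoints(prof_bp, flag_candidates(prof_bp))
  cands_bp <- cands_bp[cands_bp$chrom == reg$chrom & cands_bp$direction == "deletion" &
                         cands_bp$start < reg$end & cands_bp$end > bp, , drop = FALSE]
  breakpoint_err <- if (nrow(cands_bp) == 0L) NA_real_ else {
    max(abs(cands_bp$refined_start[1L] - bp), abs(cands_bp$refined_end[1L] - reg$end))
  }

  # -- zero-noise exactness -------------------------------------------------
  sc0 <- sim_config(seed = seed + 3L, capture_efficiency_sd = 0,
                    lot_effect_sd = 0, sample_depth_sd = 0, noise_cv = 0,
                    n_normals = 8L)
  panel0 <- simulate_panel(sc0)
  sc0$events <- list(cnv_event("Z01", 0.5, gene = "GENE001"),
                     cnv_event("Z02", 1.5, gene = "GENE002", regions = 2L),
                     cnv_event("Z03", 0.0, gene = "GENE003", regions = 1:2))
  co0 <- simulate_cohort(sc0)
  normals0 <- select_normals(co0$samples[co0$manifest$role == "normal"], 100)
  pools0 <- build_static_pools(normals0, 8L, co0$template)
  zero_err <- 0
  for (id in c("Z01", "Z02", "Z03")) {
    prof <- score_query(co0$samples[[id]], pools0, co0$template, config)
    tr <- co0$truth[co0$truth$sample_id == id, ]
    in_span <- windows_fully_inside(co0$template, tr$chrom, tr$start, tr$end)
    expected <- rep(0, nrow(prof$table))
    expected[in_span] <- if (tr$copy_ratio == 0) config$floor_score else log2(tr$copy_ratio)
    zero_err <- max(zero_err, max(abs(prof$table$score - expected)))
  }

  list(
    event_sensitivity_pct = 100 * mean(hits),
    n_events = length(hits),
    window_specificity_pct = 100 * (1 - n_flagged / n_called),
    n_windows_specificity = n_called,
    false_positive_candidates = n_fp_spans,
    mosaic_mean_logcnr = mosaic_mean,
    mosaic_flagged = mosaic_flagged,
    n_mosaic_windows = length(in_span),
    breakpoint_max_error_nt = breakpoint_err,
    zero_noise_max_abs_error = zero_err,
    n_pools = length(pools$pools),
    n_windows = nrow(co$template$windows)
  )
}

# template window rows fully inside [start, end) on chrom
windows_fully_inside <- function(template, chrom, start, end) {
  w <- template$windows
  which(w$chrom == chrom & w$start >= start & w$end <= end)
}
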