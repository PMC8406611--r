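# Output interpretation: per-gene score tables and plots, merged per-run
# overlays, and an advisory candidate flagger.
#
# The primary interface for interpretation is the table and plot of
# logCNR scores per gene (reference lines at -1.0 and +0.58 mark the
# expected heterozygous deletion and duplication levels). The candidate
# flagger is a machine-readable shortlist on top of that: maximal runs of
# consecutive windows beyond a threshold. It is advisory and never
# replaces the full table or plot.

#' Per-gene logCNR table
#'
#' Rows of the profile restricted to one gene, in genomic order and
#' grouped by region, so exon junctions are identifiable.
#'
#' @param profile A [score_sample()] profile.
#' @param gene Gene symbol.
#' @return Data frame of that gene's windows with scores and no-call
#'   flags.
#' @export
gene_table <- function(profile, gene) {
  tab <- profile$table
  if (!gene %in% tab$gene) {
    stop("gene '", gene, "' is not in the panel; panel genes: ",
         paste(sort(unique(tab$gene)), collapse = ", "), call. = FALSE)
  }
  out <- tab[tab$gene == gene, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

save_plot <- function(p, path, width = 9, height = 4) {
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = 120)
  invisible(path)
}

#' Plot logCNR scores for one gene
#'
#' Window scores in genomic window order, with horizontal reference
#' lines at -1.0 and +0.58 (expected single-allele deletion and
#' duplication scores) and vertical marks at region boundaries. No-call
#' windows are rendered as gaps, never as zeros. A sidecar TSV with the
#' plotted data is written next to the image (`<path>.data.tsv`) so plot
#' content can be compared without parsing the image.
#'
#' @inheritParams gene_table
#' @param path Output image path (`.png` or `.pdf`).
#' @return Invisibly, the path.
#' @export
gene_plot <- function(profile, gene, path) {
  tab <- gene_table(profile, gene)
  tab$ord <- seq_len(nrow(tab))
  region_starts <- tab$ord[!duplicated(tab$region_id)]
  plt <- tab[!tab$no_call, , drop = FALSE]
  p <- ggplot2::ggplot(plt, ggplot2::aes(x = .data$ord, y = .data$score)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(-1, 0.58), colour = "firebrick",
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = region_starts - 0.5, colour = "grey85",
                        linewidth = 0.2) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.6) +
    ggplot2::labs(title = paste0(gene, " - ", profile$sample_id),
                  x = "sliding window (genomic order)", y = "logCNR score") +
    ggplot2::theme_minimal(base_size = 10)
  sidecar <- tab[, c("gene", "region_label", "chrom", "start", "end",
                     "score", "no_call")]
  utils::write.table(sidecar, paste0(path, ".data.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  save_plot(p, path)
}

#' Overlay logCNR traces of all samples of a run for one gene
#'
#' With `anonymize = TRUE` (the default) sample identifiers are replaced
#' by neutral trace labels and the legend is dropped, so merged per-run
#' review cannot produce incidental findings by name.
#'
#' @param profiles List of [score_sample()] profiles on one template.
#' @param gene Gene symbol.
#' @param path Output image path.
#' @param anonymize Suppress sample identifiers?
#' @return Invisibly, the path.
#' @export
merged_run_plot <- function(profiles, gene, path, anonymize = TRUE) {
  if (length(profiles) < 2L) stop("need at least 2 profiles to merge", call. = FALSE)
  first <- profiles[[1L]]$table
  tabs <- lapply(seq_along(profiles), function(i) {
    tab <- profiles[[i]]$table
    if (nrow(tab) != nrow(first) || !all(tab$start == first$start)) {
      stop("profiles are on different window templates", call. = FALSE)
    }
    tab <- gene_table(profiles[[i]], gene)
    tab$ord <- seq_len(nrow(tab))
    tab$trace <- if (anonymize) sprintf("trace_%02d", i) else profiles[[i]]$sample_id
    tab
  })
  all_tab <- do.call(rbind, tabs)
  plt <- all_tab[!all_tab$no_call, , drop = FALSE]
  p <- ggplot2::ggplot(plt, ggplot2::aes(x = .data$ord, y = .data$score,
                                         group = .data$trace, colour = .data$trace)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(-1, 0.58), colour = "firebrick",
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.7) +
    ggplot2::labs(title = gene, x = "sliding window (genomic order)",
                  y = "logCNR score") +
    ggplot2::theme_minimal(base_size = 10)
  if (anonymize) p <- p + ggplot2::guides(colour = "none")
  sidecar <- all_tab[, c("trace", "gene", "chrom", "start", "end", "score", "no_call")]
  utils::write.table(sidecar, paste0(path, ".data.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  save_plot(p, path)
}

# maximal runs of TRUE in a logical vector (NA treated as FALSE)
runs_of <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(from = starts[keep], to = ends[keep])
}

#' Flag candidate CNV segments in a score profile
#'
#' Maximal runs of at least `min_consecutive` consecutive called windows
#' with score at or below `del_threshold` (deletions) or at or above
#' `dup_threshold` (duplications), per gene. The duplication threshold
#' sits proportionally closer to 0 because the theoretical duplication
#' signal (+0.58) is weaker than the deletion signal (-1.0). An optional
#' low-stringency second pass (score <= `mosaic_del_threshold` over >=
#' `mosaic_min_consecutive` windows) targets mosaic deletions, whose
#' expected score for a 30% cell fraction is only about -0.23; its hits
#' are labelled `possible_mosaic` and suppressed where they only restate
#' a standard deletion call. No-call windows break runs. Candidate spans
#' never cross gene boundaries and their breakpoint resolution is the
#' sliding length.
#'
#' @param profile A [score_sample()] profile.
#' @param del_threshold Deletion score threshold (default -0.5).
#' @param dup_threshold Duplication score threshold (default +0.3).
#' @param min_consecutive Minimum run length in windows (default 3).
#' @param include_mosaic Run the mosaic pass as well?
#' @param mosaic_del_threshold,mosaic_min_consecutive Mosaic-pass
#'   parameters (defaults -0.15 and 10).
#' @return Data frame of candidates: `gene`, `chrom`, `start`, `end`
#'   (0-based half-open union of run windows), `direction`,
#'   `mean_score`, `n_windows`, `breakpoint_resolution`, `class`
#'   (`standard` or `possible_mosaic`), plus `w1`/`w2` (first/last
#'   window row in `profile$table`). Zero rows when nothing is flagged.
#' @export
flag_candidates <- function(profile, del_threshold = -0.5, dup_threshold = 0.3,
                            min_consecutive = 3L, include_mosaic = FALSE,
                            mosaic_del_threshold = -0.15,
                            mosaic_min_consecutive = 10L) {
  if (!(del_threshold < 0 && dup_threshold > 0)) {
    stop("need del_threshold < 0 < dup_threshold", call. = FALSE)
  }
  tab <- profile$table
  empty <- data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(),
                      direction = character(), mean_score = numeric(),
                      n_windows = integer(), breakpoint_resolution = integer(),
                      class = character(), w1 = integer(), w2 = integer(),
                      stringsAsFactors = FALSE)

  scan_gene <- function(rows, threshold, direction, min_run, cls) {
    sc <- tab$score[rows]
    hit <- if (direction == "deletion") sc <= threshold else sc >= threshold
    hit[tab$no_call[rows]] <- FALSE
    rr <- runs_of(hit)
    rr <- rr[rr$to - rr$from + 1L >= min_run, , drop = FALSE]
    if (nrow(rr) == 0L) return(empty)
    do.call(rbind, lapply(seq_len(nrow(rr)), function(k) {
      idx <- rows[rr$from[k]:rr$to[k]]
      data.frame(gene = tab$gene[idx[1L]], chrom = tab$chrom[idx[1L]],
                 start = min(tab$start[idx]), end = max(tab$end[idx]),
                 direction = direction,
                 mean_score = mean(tab$score[idx]),
                 n_windows = length(idx),
                 breakpoint_resolution = profile$slide_len,
                 class = cls, w1 = idx[1L], w2 = idx[length(idx)],
                 stringsAsFactors = FALSE)
    }))
  }

  genes <- unique(tab$gene)
  out <- empty
  for (g in genes) {
    rows <- which(tab$gene == g)
    out <- rbind(out,
                 scan_gene(rows, del_threshold, "deletion", min_consecutive, "standard"),
                 scan_gene(rows, dup_threshold, "duplication", min_consecutive, "standard"))
    if (include_mosaic) {
      mos <- scan_gene(rows, mosaic_del_threshold, "deletion",
                       mosaic_min_consecutive, "possible_mosaic")
      if (nrow(mos) > 0L) {
        std_del <- out[out$gene == g & out$direction == "deletion" &
                         out$class == "standard", , drop = FALSE]
        keep <- vapply(seq_len(nrow(mos)), function(k) {
          !any(std_del$start <= mos$start[k] & std_del$end >= mos$end[k])
        }, TRUE)
        out <- rbind(out, mos[keep, , drop = FALSE])
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Refine candidate breakpoints by ramp interpolation
#'
#' A window whose midpoint sits exactly on a CNV breakpoint carries half
#' the event's depth signal, because half its bases are inside the
#' event. Each candidate edge is therefore refined by locating, on the
#' depth-ratio scale (`2^score`, linear in the affected base fraction),
#' where the ratio crosses the midpoint between baseline (1) and the
#' candidate's plateau, interpolating linearly between window midpoints.
#' This recovers breakpoints inside a region to about the sliding
#' length. Edges that coincide with a region boundary (no ramp to
#' interpolate) keep the flagged-window union coordinate.
#'
#' @param profile The [score_sample()] profile the candidates came from.
#' @param candidates A [flag_candidates()] data frame.
#' @return The candidates with `refined_start` and `refined_end` columns
#'   (0-based half-open, rounded to integer).
#' @export
refine_breakpoints <- function(profile, candidates) {
  tab <- profile$table
  if (nrow(candidates) == 0L) {
    candidates$refined_start <- integer()
    candidates$refined_end <- integer()
    return(candidates)
  }
  mid <- (tab$start + tab$end) / 2

  # baseline ratio from windows away from any candidate (margin of one
  # window length): robust to overall depth shifts without being dragged
  # toward the event plateau when events span much of the profile
  margin <- profile$window_len
  near_cand <- rep(FALSE, nrow(tab))
  for (i in seq_len(nrow(candidates))) {
    near_cand <- near_cand | (tab$chrom == candidates$chrom[i] &
                                tab$start < candidates$end[i] + margin &
                                tab$end > candidates$start[i] - margin)
  }
  base_rows <- !tab$no_call & !near_cand
  baseline <- if (sum(base_rows) >= 5L) {
    stats::median(2^tab$score[base_rows])
  } else 1

  refine_edge <- function(cand, side) {
    edge_row <- if (side == "left") cand$w1 else cand$w2
    region <- tab$region_id[edge_row]
    in_region <- which(tab$region_id == region & !tab$no_call)
    run_rows <- cand$w1:cand$w2
    # plateau from the run core, trimming the ramp windows at either end
    k <- min((length(run_rows) - 1L) %/% 2L,
             ceiling(profile$window_len / profile$slide_len))
    core <- run_rows[seq.int(1L + k, length(run_rows) - k)]
    plateau <- 2^stats::median(tab$score[core])
    # signal normalised to 0 (baseline) .. 1 (plateau)
    sig <- (2^tab$score[in_region] - baseline) / (plateau - baseline)
    x <- mid[in_region]
    if (side == "left") {
      before <- which(in_region < cand$w1)
      if (length(before) == 0L) return(cand$start)   # edge at region boundary
      ks <- c(before, which(in_region >= cand$w1))
      cross <- which(sig[ks[-length(ks)]] < 0.5 & sig[ks[-1L]] >= 0.5)
      if (length(cross) == 0L) return(cand$start)
      k <- ks[max(cross)]
    } else {
      after <- which(in_region > cand$w2)
      if (length(after) == 0L) return(cand$end)
      ks <- c(which(in_region <= cand$w2), after)
      cross <- which(sig[ks[-length(ks)]] >= 0.5 & sig[ks[-1L]] < 0.5)
      if (length(cross) == 0L) return(cand$end)
      k <- ks[min(cross)]
    }
    x1 <- x[k]; x2 <- x[k + 1L]; s1 <- sig[k]; s2 <- sig[k + 1L]
    x1 + (0.5 - s1) * (x2 - x1) / (s2 - s1)
  }

  candidates$refined_start <- vapply(seq_len(nrow(candidates)), function(i) {
    as.integer(round(refine_edge(candidates[i, ], "left")))
  }, 0L)
  candidates$refined_end <- vapply(seq_len(nrow(candidates)), function(i) {
    as.integer(round(refine_edge(candidates[i, ], "right")))
  }, 0L)
  candidates
}

#' Write candidates as TSV and BED
#'
#' @param candidates A [flag_candidates()] data frame.
#' @param tsv_path Output TSV path (full columns).
#' @param bed_path Optional BED path (0-based half-open; name column
#'   `gene|direction`, score column the mean logCNR scaled by 100).
#' @return Invisibly, `tsv_path`.
#' @export
write_candidates <- function(candidates, tsv_path, bed_path = NULL) {
  utils::write.table(candidates, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(candidates$chrom, candidates$start, candidates$end,
                      paste0(candidates$gene, "|", candidates$direction),
                      as.integer(round(100 * candidates$mean_score)))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv_path)
}
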