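# Target-region-based sliding windows (TRSW).
#
# Every captured interval (exon/UTR +- intronic flank) is tiled with
# fixed-size windows that advance by a fixed sliding length; the remainder
# of a region that is shorter than one slide is absorbed into the last
# window, and regions shorter than the window size get a single window of
# the region's own length.  Coordinates are 0-based half-open (BED
# convention) throughout; 1-based positions only appear at I/O boundaries.

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop("`", name, "` must be a positive integer, got ", deparse(substitute(x)),
         " = ", paste(x, collapse = ","), call. = FALSE)
  }
  invisible(as.integer(x))
}

check_window_params <- function(window_len, slide_len) {
  check_positive_scalar(window_len, "window_len")
  check_positive_scalar(slide_len, "slide_len")
  if (slide_len > window_len) {
    stop("`slide_len` (", slide_len, ") must not exceed `window_len` (",
         window_len, ")", call. = FALSE)
  }
  invisible(NULL)
}

#' Number of sliding windows for a target region
#'
#' A region of length `region_len` is tiled with windows of `window_len`
#' nucleotides advancing by `slide_len`; the count is
#' `floor((region_len - window_len) / slide_len) + 1`. A region no longer
#' than the window size yields exactly one window (of the region's length).
#'
#' @param region_len Region length(s) in nucleotides (vectorised).
#' @param window_len Window size in nucleotides (default 75).
#' @param slide_len Sliding length in nucleotides (default 10); must not
#'   exceed `window_len`.
#' @return Integer vector of window counts, one per region length.
#' @examples
#' count_windows(134, 75, 10)  # 6
#' count_windows(50, 75, 10)   # short region: 1
#' @export
count_windows <- function(region_len, window_len = 75L, slide_len = 10L) {
  check_window_params(window_len, slide_len)
  if (length(region_len) == 0 || !is.numeric(region_len) ||
      anyNA(region_len) || any(region_len < 1) || any(region_len != floor(region_len))) {
    stop("`region_len` must contain positive integers", call. = FALSE)
  }
  region_len <- as.numeric(region_len)
  ifelse(region_len <= window_len, 1L,
         as.integer((region_len - window_len) %/% slide_len + 1))
}

#' Tile one target region with sliding windows
#'
#' Windows are anchored at the region start and never cross the region
#' boundary. All windows have length `window_len` except the last, which
#' absorbs the remainder `(region_len - window_len) %% slide_len` so that
#' the union of windows equals the region exactly.
#'
#' @param region A one-row data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `gene`, `label`, and optionally `region_id`.
#' @inheritParams count_windows
#' @return Data frame of windows with columns `chrom`, `start`, `end`,
#'   `gene`, `region_label`, `region_id`, `window_index` (0-based within
#'   the region) and `length`.
#' @export
build_region_windows <- function(region, window_len = 75L, slide_len = 10L) {
  check_window_params(window_len, slide_len)
  stopifnot(is.data.frame(region), nrow(region) == 1L)
  region_len <- region$end - region$start
  if (region_len < 1) stop("region has non-positive length", call. = FALSE)

  n <- count_windows(region_len, window_len, slide_len)
  if (region_len <= window_len) {
    starts <- region$start
    ends <- region$end
  } else {
    starts <- region$start + (seq_len(n) - 1L) * slide_len
    ends <- starts + window_len
    ends[n] <- region$end   # last window absorbs (region_len - window_len) %% slide_len
  }
  data.frame(
    chrom = region$chrom,
    start = starts,
    end = ends,
    gene = region$gene,
    region_label = region$label,
    region_id = if ("region_id" %in% names(region)) region$region_id else 1L,
    window_index = seq_len(n) - 1L,
    length = ends - starts,
    stringsAsFactors = FALSE
  )
}

#' Build the panel-wide sliding-window template
#'
#' Concatenates the windows of every target region in region order. The
#' resulting template also carries the ordered vector of all targeted
#' positions, so per-base coverage vectors and window means can be mapped
#' onto it efficiently.
#'
#' @param regions Data frame of target regions as returned by
#'   [read_panel_bed()] (columns `chrom`, `start`, `end`, `gene`, `label`;
#'   non-overlapping within a chromosome).
#' @inheritParams count_windows
#' @return An object of class `window_template`: a list with elements
#'   `window_len`, `slide_len`, `regions`, `windows` (one row per sliding
#'   window, with position-index bounds `i1`/`i2` into the targeted
#'   position vector), `n_positions`, `pos_chrom`, `pos_pos`.
#' @export
build_template <- function(regions, window_len = 75L, slide_len = 10L) {
  check_window_params(window_len, slide_len)
  if (!is.data.frame(regions) || nrow(regions) == 0L) {
    stop("`regions` must be a non-empty data frame of target regions", call. = FALSE)
  }
  need <- c("chrom", "start", "end", "gene", "label")
  if (!all(need %in% names(regions))) {
    stop("`regions` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(regions$end <= regions$start)) {
    stop("all regions must satisfy end > start", call. = FALSE)
  }
  regions$region_id <- seq_len(nrow(regions))
  regions$length <- regions$end - regions$start

  win_list <- lapply(seq_len(nrow(regions)), function(i) {
    build_region_windows(regions[i, , drop = FALSE], window_len, slide_len)
  })
  windows <- do.call(rbind, win_list)
  rownames(windows) <- NULL

  # targeted positions, in region order; regions are non-overlapping so each
  # window maps to a contiguous slice of the position vector
  reg_off <- cumsum(c(0L, regions$length))
  pos_pos <- unlist(lapply(seq_len(nrow(regions)), function(i) {
    seq.int(regions$start[i], regions$end[i] - 1L)
  }), use.names = FALSE)
  pos_chrom <- rep(regions$chrom, regions$length)

  rstart <- regions$start[windows$region_id]
  windows$i1 <- reg_off[windows$region_id] + (windows$start - rstart) + 1L
  windows$i2 <- reg_off[windows$region_id] + (windows$end - rstart)

  structure(
    list(window_len = as.integer(window_len),
         slide_len = as.integer(slide_len),
         regions = regions,
         windows = windows,
         n_positions = length(pos_pos),
         pos_chrom = pos_chrom,
         pos_pos = pos_pos),
    class = "window_template"
  )
}

#' @export
print.window_template <- function(x, ...) {
  cat("window_template:", nrow(x$windows), "windows over", nrow(x$regions),
      "regions (", length(unique(x$regions$gene)), "genes ),",
      x$n_positions, "targeted positions\n")
  cat("  window_len =", x$window_len, "nt, slide_len =", x$slide_len, "nt\n")
  invisible(x)
}

# "chrom:pos0" keys for the template's targeted positions
template_position_key <- function(template) {
  paste0(template$pos_chrom, ":", template$pos_pos)
}

#' Read a target-panel BED file
#'
#' Reads a BED file (3+ columns; column 4, when present, is parsed as
#' `"GENE|label"`, e.g. `"BRCA2|exon3"`). Adjacent or overlapping intervals
#' of the same gene are merged so duplicate capture probes cannot produce
#' double-counted windows; merged labels are joined with `"+"`. Regions are
#' sorted by chromosome (order of first appearance) and start.
#'
#' @param path Path to the BED file.
#' @return Data frame of regions: `chrom`, `start`, `end` (0-based
#'   half-open), `gene`, `label`.
#' @export
read_panel_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("BED file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(fields))
  if (ncol_min < 3L) stop("BED file needs at least 3 columns: ", path, call. = FALSE)

  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) stop("non-numeric BED coordinates in ", path, call. = FALSE)
  if (any(end <= start)) stop("BED intervals must satisfy end > start", call. = FALSE)

  if (ncol_min >= 4L) {
    name <- vapply(fields, `[[`, "", 4L)
    parts <- strsplit(name, "|", fixed = TRUE)
    gene <- vapply(parts, `[[`, "", 1L)
    label <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "", "")
  } else {
    gene <- paste0("region_", seq_along(chrom))
    label <- ""
  }

  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  merged <- lapply(split(seq_along(gr), gene), function(idx) {
    red <- GenomicRanges::reduce(gr[idx], with.revmap = TRUE)
    lab <- vapply(S4Vectors_mcols_revmap(red), function(rm) {
      labs <- unique(label[idx][rm])
      paste(labs[nzchar(labs)], collapse = "+")
    }, "")
    data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
               start = GenomicRanges::start(red) - 1L,
               end = GenomicRanges::end(red),
               gene = gene[idx][1L] , label = lab,
               stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, merged)
  # fix per-gene gene assignment (split() ordering by gene name)
  regions$gene <- rep(names(merged), vapply(merged, nrow, 0L))
  regions <- regions[order(match(regions$chrom, unique(chrom)), regions$start), ]
  rownames(regions) <- NULL

  # after the per-gene merge, same-chromosome regions must not overlap
  by_chr <- split(regions, regions$chrom)
  for (rr in by_chr) {
    if (nrow(rr) > 1L && any(rr$start[-1L] < rr$end[-nrow(rr)])) {
      stop("overlapping target regions from different genes on ", rr$chrom[1L],
           "; fix the panel BED", call. = FALSE)
    }
  }
  regions
}

# revmap accessor kept separate so the mcols import stays localised
S4Vectors_mcols_revmap <- function(red) {
  as.list(GenomicRanges::mcols(red)$revmap)
}

#' Write the window template as a TSV audit table
#'
#' @param template A [build_template()] object.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_template_tsv <- function(template, path) {
  w <- template$windows
  out <- w[, c("chrom", "start", "end", "gene", "region_label", "window_index")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
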