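# Per-base coverage over the target panel.
#
# A sample's coverage is an integer depth vector aligned to the template's
# targeted-position vector; window means and the sample mean are derived
# from it. The on-disk dialect is the per-locus table produced by standard
# depth-of-coverage tools: "chrom:pos" (1-based) and a total-depth column.

#' Construct a sample coverage object
#'
#' @param depth Integer vector of per-base depths, one entry per targeted
#'   position of `template` (in template order).
#' @param template A [build_template()] object.
#' @param sample_id Sample identifier.
#' @param run_id Sequencing-run identifier (optional).
#' @param lot_id Capture-kit lot identifier (optional); used to enforce
#'   same-lot pooling.
#' @return An object of class `sample_coverage` with fields `sample_id`,
#'   `run_id`, `lot_id`, `depth` and `mean_depth`.
#' @export
sample_coverage <- function(depth, template, sample_id,
                            run_id = NA_character_, lot_id = NA_character_) {
  stopifnot(inherits(template, "window_template"))
  if (length(depth) != template$n_positions) {
    stop("depth vector has ", length(depth), " entries but template has ",
         template$n_positions, " targeted positions", call. = FALSE)
  }
  if (anyNA(depth) || any(depth < 0)) {
    stop("depths must be non-negative and non-missing", call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id),
         run_id = as.character(run_id),
         lot_id = as.character(lot_id),
         depth = as.numeric(depth),
         mean_depth = mean(depth)),
    class = "sample_coverage"
  )
}

#' @export
print.sample_coverage <- function(x, ...) {
  cat("sample_coverage:", x$sample_id,
      sprintf("(run %s, lot %s) mean depth %.1fx over %d positions\n",
              x$run_id, x$lot_id, x$mean_depth, length(x$depth)))
  invisible(x)
}

#' Load per-locus coverage for one sample
#'
#' Reads a per-locus depth table (header line; first column `Locus` as
#' 1-based `"chrom:pos"`, second column `Total_Depth`; extra columns
#' ignored) and restricts it to the template's targeted positions.
#' Targeted positions missing from the file are set to depth 0 with a
#' warning; file positions outside the targets are ignored (count
#' reported via a message).
#'
#' @param path Path to the per-locus TSV.
#' @param template A [build_template()] object.
#' @param sample_id Sample identifier; defaults to the file name stem.
#' @inheritParams sample_coverage
#' @return A [sample_coverage()] object.
#' @export
read_per_locus_coverage <- function(path, template,
                                    sample_id = sub("\\..*$", "", basename(path)),
                                    run_id = NA_character_, lot_id = NA_character_) {
  if (!file.exists(path)) stop("coverage file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("per-locus file needs >= 2 columns: ", path, call. = FALSE)
  locus_col <- which(tolower(names(df)) == "locus")
  depth_col <- which(tolower(names(df)) %in% c("total_depth", "total depth"))
  locus <- as.character(df[[if (length(locus_col)) locus_col[1L] else 1L]])
  depth_in <- df[[if (length(depth_col)) depth_col[1L] else 2L]]

  parts <- strsplit(locus, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) == 0L) {
    pos1 <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
    bad <- which(is.na(pos1))
  }
  if (length(bad) > 0L) {
    stop("malformed locus string '", locus[bad[1L]], "' at line ",
         bad[1L] + 1L, " of ", path, call. = FALSE)   # +1 for the header
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  key_file <- paste0(chrom, ":", pos1 - 1L)           # convert to 0-based

  idx <- match(template_position_key(template), key_file)
  if (all(is.na(idx))) {
    stop("no targeted positions found in ", path,
         "; check chromosome naming and coordinates", call. = FALSE)
  }
  depth <- ifelse(is.na(idx), 0, as.numeric(depth_in[idx]))
  n_missing <- sum(is.na(idx))
  if (n_missing > 0L) {
    warning(n_missing, " targeted position(s) missing from ", basename(path),
            "; set to depth 0", call. = FALSE)
  }
  n_extra <- length(key_file) - sum(!is.na(idx))
  if (n_extra > 0L) {
    message(n_extra, " position(s) in ", basename(path), " fall outside the targets; ignored")
  }
  sample_coverage(depth, template, sample_id, run_id, lot_id)
}

#' Compute per-base coverage from an indexed BAM file
#'
#' Pileup over the template's targeted positions, honouring a mapping
#' quality floor and the duplicate flag. Defaults match deduplicated
#' alignment preprocessing: duplicates excluded, `min_mapq = 20`.
#'
#' @param path Path to an indexed BAM aligned to the same reference build
#'   as the panel BED.
#' @param template A [build_template()] object.
#' @param min_mapq Minimum mapping quality for a read to count.
#' @param count_duplicates Include reads flagged as PCR/optical duplicates?
#' @inheritParams sample_coverage
#' @return A [sample_coverage()] object.
#' @export
compute_bam_coverage <- function(path, template, min_mapq = 20L,
                                 count_duplicates = FALSE,
                                 sample_id = sub("\\.bam$", "", basename(path)),
                                 run_id = NA_character_, lot_id = NA_character_) {
  if (!file.exists(path)) stop("BAM file not found: ", path, call. = FALSE)
  bai <- c(paste0(path, ".bai"), sub("\\.bam$", ".bai", path))
  if (!any(file.exists(bai))) {
    stop("BAM index not found for ", path,
         "; create it with samtools index or Rsamtools::indexBam()", call. = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1L]]$targets
  bam_chroms <- names(hdr)
  tmpl_chroms <- unique(template$regions$chrom)
  if (!any(tmpl_chroms %in% bam_chroms)) {
    strip <- function(x) sub("^chr", "", x)
    if (any(strip(tmpl_chroms) %in% strip(bam_chroms))) {
      stop("contig naming mismatch: panel uses '", tmpl_chroms[1L],
           "' but BAM uses '", bam_chroms[1L],
           "'; harmonise the chr prefix", call. = FALSE)
    }
    stop("no panel chromosome found in BAM header of ", path, call. = FALSE)
  }

  keep <- template$regions$chrom %in% bam_chroms
  which_gr <- GenomicRanges::GRanges(
    template$regions$chrom[keep],
    IRanges::IRanges(template$regions$start[keep] + 1L, template$regions$end[keep])
  )
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isDuplicate = if (count_duplicates) NA else FALSE
  )
  pp <- Rsamtools::PileupParam(
    max_depth = 1000000L, min_base_quality = 0L, min_mapq = as.integer(min_mapq),
    min_nucleotide_depth = 1L, distinguish_strands = FALSE,
    distinguish_nucleotides = FALSE, include_deletions = FALSE
  )
  res <- Rsamtools::pileup(path,
                           scanBamParam = Rsamtools::ScanBamParam(flag = flag, which = which_gr),
                           pileupParam = pp)
  depth <- numeric(template$n_positions)
  if (nrow(res) > 0L) {
    key_res <- paste0(as.character(res$seqnames), ":", res$pos - 1L)
    # which = overlapping ranges can emit a position once per range; targets are
    # non-overlapping here, but guard with aggregation anyway
    agg <- tapply(res$count, key_res, sum)
    idx <- match(template_position_key(template), names(agg))
    depth[!is.na(idx)] <- as.numeric(agg[idx[!is.na(idx)]])
  }
  sample_coverage(depth, template, sample_id, run_id, lot_id)
}

#' Per-window mean depths of a sample
#'
#' Arithmetic mean of per-base depth over each sliding window's actual
#' span (the last window of a region may be longer than `window_len`).
#'
#' @param cov A [sample_coverage()] object.
#' @param template The template the coverage is aligned to.
#' @return Numeric vector, one mean depth per template window.
#' @export
window_means <- function(cov, template) {
  stopifnot(inherits(cov, "sample_coverage"), inherits(template, "window_template"))
  cs <- cumsum(c(0, cov$depth))
  w <- template$windows
  (cs[w$i2 + 1L] - cs[w$i1]) / (w$i2 - w$i1 + 1L)
}

#' Mean depth of a single sliding window
#'
#' @inheritParams window_means
#' @param window Window row index in `template$windows` (1-based).
#' @return Mean depth (reads per position) of that window.
#' @export
window_mean_depth <- function(cov, template, window) {
  stopifnot(length(window) == 1L, window >= 1L, window <= nrow(template$windows))
  w <- template$windows[window, ]
  mean(cov$depth[w$i1:w$i2])
}

#' Sample-level mean depth
#'
#' Mean over unique targeted positions (not over windows, which overlap
#' and would multiply-count interior bases).
#'
#' @param cov A [sample_coverage()] object.
#' @return Mean depth in reads per position.
#' @export
sample_mean_depth <- function(cov) {
  stopifnot(inherits(cov, "sample_coverage"))
  cov$mean_depth
}

#' Write a sample's coverage in the per-locus dialect
#'
#' Emits the same `Locus`/`Total_Depth` TSV that
#' [read_per_locus_coverage()] consumes (1-based positions).
#'
#' @inheritParams window_means
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_per_locus_coverage <- function(cov, template, path) {
  out <- data.frame(
    Locus = paste0(template$pos_chrom, ":", template$pos_pos + 1L),
    Total_Depth = as.integer(round(cov$depth)),
    Average_Depth_sample = as.integer(round(cov$depth)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
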