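# In-code fixtures: small panels, coverage vectors and hand-built pools.

# regions of the given lengths, consecutive genes on one chromosome with
# 1 kb gaps
make_regions <- function(lens, genes = paste0("G", seq_along(lens)),
                         chrom = "chr1", gap = 1000L) {
  start <- integer(length(lens))
  cursor <- 10000L
  for (i in seq_along(lens)) {
    start[i] <- cursor + gap
    cursor <- start[i] + lens[i]
  }
  data.frame(chrom = chrom, start = start, end = start + lens,
             gene = genes, label = paste0("exon", seq_along(lens)),
             stringsAsFactors = FALSE)
}

make_template <- function(lens, window_len = 75L, slide_len = 10L, ...) {
  build_template(make_regions(lens, ...), window_len, slide_len)
}

# constant-or-vector depth coverage
make_cov <- function(template, depth, sample_id = "S1", run_id = "run01",
                     lot_id = "lot01") {
  if (length(depth) == 1L) depth <- rep(depth, template$n_positions)
  sample_coverage(depth, template, sample_id, run_id, lot_id)
}

# a static pool built directly from member coverages (bypasses the sort
# requirement so tests can craft arbitrary pools)
make_pool <- function(covs, template, pool_id = 1L, lot_id = "lot01") {
  wm <- vapply(covs, window_means, numeric(nrow(template$windows)),
               template = template)
  means <- vapply(covs, function(s) s$mean_depth, 0)
  structure(
    list(pool_id = pool_id,
         members = vapply(covs, function(s) s$sample_id, ""),
         member_mean_depths = means,
         pool_mean_depth = mean(means),
         lot_id = lot_id,
         mean_trsw = rowMeans(as.matrix(wm))),
    class = "static_pool"
  )
}

# multiply depth by `ratio` over the positions inside [start, end)
apply_event <- function(cov, template, chrom, start, end, ratio,
                        sample_id = cov$sample_id) {
  depth <- cov$depth
  hit <- template$pos_chrom == chrom & template$pos_pos >= start &
    template$pos_pos < end
  depth[hit] <- depth[hit] * ratio
  sample_coverage(depth, template, sample_id, cov$run_id, cov$lot_id)
}

# rows of template windows lying fully inside an interval
windows_inside <- function(template, chrom, start, end) {
  w <- template$windows
  which(w$chrom == chrom & w$start >= start & w$end <= end)
}
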