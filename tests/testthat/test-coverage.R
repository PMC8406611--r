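# Per-base coverage loading and window/sample means.

test_that("per-locus files are parsed, zero-filled and restricted to targets", {
  tmpl <- make_template(c(100, 60))
  key_chrom <- tmpl$pos_chrom
  key_pos1 <- tmpl$pos_pos + 1L          # file dialect is 1-based

  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(Locus = paste0(key_chrom, ":", key_pos1),
                         Total_Depth = 100L),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  cov <- read_per_locus_coverage(f, tmpl, sample_id = "S1")
  expect_equal(cov$mean_depth, 100)
  expect_equal(length(cov$depth), tmpl$n_positions)

  # missing 10% of targeted positions -> zero-filled with a warning
  n <- tmpl$n_positions
  drop <- seq_len(n %/% 10)
  write.table(data.frame(Locus = paste0(key_chrom, ":", key_pos1)[-drop],
                         Total_Depth = 100L),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(cov2 <- read_per_locus_coverage(f, tmpl), "16 targeted position")
  expect_true(all(cov2$depth[drop] == 0))
  expect_true(all(cov2$depth[-drop] == 100))

  # off-target positions are ignored, with a count
  write.table(data.frame(Locus = c(paste0(key_chrom, ":", key_pos1),
                                   paste0("chr9:", 1:7)),
                         Total_Depth = 100L),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(cov3 <- read_per_locus_coverage(f, tmpl), "7 position")
  expect_equal(cov3$mean_depth, 100)

  # malformed locus -> parse error naming the line
  writeLines(c("Locus\tTotal_Depth", "chr1:10\t5", "oops\t5"), f)
  expect_error(read_per_locus_coverage(f, tmpl), "line 3")

  # no overlap at all
  write.table(data.frame(Locus = "chrZ:1", Total_Depth = 5L),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_per_locus_coverage(f, tmpl), "no targeted positions")
})

test_that("window means equal a per-position summation oracle", {
  tmpl <- make_template(c(134, 85, 40))
  set.seed(3)
  depth <- rpois(tmpl$n_positions, 200)
  cov <- make_cov(tmpl, depth)
  wm <- window_means(cov, tmpl)
  w <- tmpl$windows
  for (i in seq_len(nrow(w))) {
    hit <- tmpl$pos_chrom == w$chrom[i] & tmpl$pos_pos >= w$start[i] &
      tmpl$pos_pos < w$end[i]
    expect_equal(wm[i], sum(depth[hit]) / sum(hit), tolerance = 1e-9)
    expect_equal(window_mean_depth(cov, tmpl, i), wm[i], tolerance = 1e-12)
  }
})

test_that("window means honour the extended last window", {
  tmpl <- make_template(134)                 # last window is 84 nt
  w <- tmpl$windows
  expect_equal(w$length[nrow(w)], 84)
  depth <- rep(0, tmpl$n_positions)
  depth[tmpl$n_positions] <- 1               # one covered base in the last window
  cov <- make_cov(tmpl, depth)
  expect_equal(window_mean_depth(cov, tmpl, nrow(w)), 1 / 84, tolerance = 1e-12)

  # constant and split-depth sanity
  tmpl2 <- make_template(75)
  expect_equal(window_mean_depth(make_cov(tmpl2, 200), tmpl2, 1), 200)
  half <- rep(c(100, 300), each = 38)[1:75]
  half <- c(rep(100, 37), 200, rep(300, 37))  # odd length: symmetric around centre
  expect_equal(window_mean_depth(make_cov(tmpl2, half), tmpl2, 1), 200)
})

test_that("sample mean depth is position-weighted and window-agnostic", {
  tmpl <- make_template(c(120, 120))
  cov <- make_cov(tmpl, rep(c(100, 200), each = 120))
  expect_equal(sample_mean_depth(cov), 150)
  # invariant to window parameters
  tmpl2 <- build_template(tmpl$regions[, c("chrom", "start", "end", "gene", "label")],
                          30, 5)
  cov2 <- sample_coverage(cov$depth, tmpl2, "S1")
  expect_equal(sample_mean_depth(cov2), 150)
  # brute-force oracle on random depths
  set.seed(5)
  d <- rpois(tmpl$n_positions, 150)
  expect_equal(sample_mean_depth(make_cov(tmpl, d)), sum(d) / length(d),
               tolerance = 1e-12)
})

test_that("zero-filling missing positions can only lower means", {
  tmpl <- make_template(c(100, 80))
  set.seed(9)
  d <- rpois(tmpl$n_positions, 120) + 1
  full <- make_cov(tmpl, d)
  d2 <- d
  d2[sample(length(d2), 30)] <- 0
  dropped <- make_cov(tmpl, d2)
  expect_true(all(window_means(dropped, tmpl) <= window_means(full, tmpl)))
  expect_lte(sample_mean_depth(dropped), sample_mean_depth(full))
})

# --- BAM pileup ---------------------------------------------------------

write_test_bam <- function(reads, dir = tempfile()) {
  dir.create(dir)
  sam <- file.path(dir, "t.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               "@SQ\tSN:chr1\tLN:100000", reads), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "t"), overwrite = TRUE)
  bam
}

sam_read <- function(id, pos1, mapq = 60, flag = 0, len = 75) {
  paste(id, flag, "chr1", pos1, mapq, paste0(len, "M"), "*", 0, 0,
        paste(rep("A", len), collapse = ""),
        paste(rep("I", len), collapse = ""), sep = "\t")
}

test_that("BAM pileup respects mapping quality and the duplicate flag", {
  regions <- data.frame(chrom = "chr1", start = 1000L, end = 1075L,
                        gene = "G1", label = "exon1", stringsAsFactors = FALSE)
  tmpl <- build_template(regions, 75, 10)
  # 5 reads fully covering the region (1-based alignment start 1001)
  bam <- write_test_bam(vapply(1:5, function(i) sam_read(paste0("r", i), 1001), ""))
  cov <- compute_bam_coverage(bam, tmpl)
  expect_true(all(cov$depth == 5))

  # MAPQ floor above all reads -> zero depth
  cov0 <- compute_bam_coverage(bam, tmpl, min_mapq = 99)
  expect_true(all(cov0$depth == 0))

  # duplicate-flagged reads are excluded unless requested (pileup oracle:
  # 3 plain reads + 2 duplicates)
  bam2 <- write_test_bam(c(
    vapply(1:3, function(i) sam_read(paste0("p", i), 1001), ""),
    vapply(4:5, function(i) sam_read(paste0("d", i), 1001, flag = 1024), "")))
  expect_true(all(compute_bam_coverage(bam2, tmpl)$depth == 3))
  expect_true(all(compute_bam_coverage(bam2, tmpl, count_duplicates = TRUE)$depth == 5))
})

test_that("BAM loading fails usefully on missing index and contig mismatch", {
  regions <- data.frame(chrom = "chr1", start = 1000L, end = 1075L,
                        gene = "G1", label = "exon1", stringsAsFactors = FALSE)
  tmpl <- build_template(regions, 75, 10)
  bam <- write_test_bam(sam_read("r1", 1001))
  file.remove(paste0(bam, ".bai"))
  expect_error(compute_bam_coverage(bam, tmpl), "index")

  # panel says '1', BAM says 'chr1' -> explicit dialect error
  regions_nochr <- regions
  regions_nochr$chrom <- "1"
  tmpl2 <- build_template(regions_nochr, 75, 10)
  bam2 <- write_test_bam(sam_read("r1", 1001))
  expect_error(compute_bam_coverage(bam2, tmpl2), "chr")
})
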