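# Gene tables, plots and the candidate flagger.

# a 3-gene profile with an injected heterozygous deletion of G2's exon
make_del_profile <- function(lens = c(200, 300, 250), del_gene = 2,
                             ratio = 0.5, depth = 200) {
  tmpl <- make_template(lens)
  members <- lapply(1:4, function(i) make_cov(tmpl, depth, sprintf("M%d", i)))
  pool <- make_pool(members, tmpl)
  r <- tmpl$regions[del_gene, ]
  q <- apply_event(make_cov(tmpl, depth, "Q"), tmpl, r$chrom, r$start, r$end, ratio)
  list(tmpl = tmpl, pool = pool,
       profile = score_sample(q, pool, tmpl), region = r)
}

test_that("gene tables are genomic-ordered, region-grouped and validated", {
  fx <- make_del_profile()
  tab <- gene_table(fx$profile, "G1")
  expect_true(all(tab$gene == "G1"))
  expect_true(!is.unsorted(tab$start))
  expect_true(all(tab$score == 0))                  # event-free gene

  del_tab <- gene_table(fx$profile, "G2")
  expect_true(all(del_tab$score == -1))             # the deleted gene

  expect_error(gene_table(fx$profile, "NOPE"), "G1, G2, G3")
})

test_that("candidate flagging finds exactly the injected deletion span", {
  fx <- make_del_profile()
  cands <- flag_candidates(fx$profile)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$gene, "G2")
  expect_equal(cands$direction, "deletion")
  expect_equal(cands$start, fx$region$start)
  expect_equal(cands$end, fx$region$end)
  expect_equal(cands$mean_score, -1)
  expect_equal(cands$breakpoint_resolution, 10L)
  expect_gte(cands$n_windows, 3L)

  # an all-normal profile yields nothing
  fx0 <- make_del_profile(ratio = 1)
  expect_equal(nrow(flag_candidates(fx0$profile)), 0L)

  # duplication direction
  fxd <- make_del_profile(ratio = 1.5)
  cd <- flag_candidates(fxd$profile)
  expect_equal(cd$direction, "duplication")
  expect_equal(round(cd$mean_score, 2), 0.58)

  expect_error(flag_candidates(fx$profile, del_threshold = 0.2), "del_threshold < 0")
})

test_that("no-call windows break candidate runs and never appear as scores", {
  fx <- make_del_profile()
  prof <- fx$profile
  del_rows <- which(prof$table$gene == "G2")
  mid <- del_rows[ceiling(length(del_rows) / 2)]
  prof$table$no_call[mid] <- TRUE
  prof$table$score[mid] <- NA_real_
  cands <- flag_candidates(prof)
  expect_equal(nrow(cands), 2L)                     # run split in two
  expect_true(all(cands$gene == "G2"))
})

test_that("flagging is monotone in thresholds and respects gene boundaries", {
  tmpl <- make_template(rep(150, 6))
  members <- lapply(1:4, function(i) make_cov(tmpl, 200, sprintf("M%d", i)))
  pool <- make_pool(members, tmpl)
  set.seed(101)
  q <- make_cov(tmpl, pmax(1, rpois(tmpl$n_positions, 200) *
                             sample(c(0.5, 1, 1.5), tmpl$n_positions,
                                    replace = TRUE, prob = c(.2, .6, .2))), "Q")
  prof <- score_sample(q, pool, tmpl)

  n_cand <- function(del, dup, mc) nrow(flag_candidates(prof, del, dup, mc))
  base <- n_cand(-0.5, 0.3, 3)
  expect_lte(n_cand(-0.8, 0.5, 3), base)            # stricter thresholds
  expect_lte(n_cand(-0.5, 0.3, 5), base)            # longer runs required

  cands <- flag_candidates(prof)
  if (nrow(cands) > 0) {
    for (i in seq_len(nrow(cands))) {
      g <- tmpl$regions$gene[tmpl$regions$gene == cands$gene[i]]
      r <- tmpl$regions[tmpl$regions$gene == cands$gene[i], ]
      expect_gte(cands$start[i], min(r$start))      # span inside its gene
      expect_lte(cands$end[i], max(r$end))
    }
  }
})

test_that("the mosaic pass flags weak long deletions and defers to standard calls", {
  # 30% mosaic deletion across three regions: expected score log2(0.85)
  tmpl <- make_template(rep(200, 5), genes = c("GA", "GA", "GA", "GB", "GB"))
  members <- lapply(1:4, function(i) make_cov(tmpl, 400, sprintf("M%d", i)))
  pool <- make_pool(members, tmpl)
  span_start <- tmpl$regions$start[1]
  span_end <- tmpl$regions$end[3]
  q <- apply_event(make_cov(tmpl, 400, "Q"), tmpl, "chr1", span_start, span_end, 0.85)
  prof <- score_sample(q, pool, tmpl)

  expect_equal(nrow(flag_candidates(prof)), 0L)     # invisible to default pass
  cands <- flag_candidates(prof, include_mosaic = TRUE)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$class, "possible_mosaic")
  expect_equal(cands$mean_score, log2(0.85), tolerance = 1e-9)

  # a full heterozygous deletion is reported once, as standard
  q2 <- apply_event(make_cov(tmpl, 400, "Q2"), tmpl, "chr1", span_start, span_end, 0.5)
  prof2 <- score_sample(q2, pool, tmpl)
  cands2 <- flag_candidates(prof2, include_mosaic = TRUE)
  expect_equal(nrow(cands2), 1L)
  expect_equal(cands2$class, "standard")
})

test_that("breakpoints inside a region are refined to sliding-length accuracy", {
  # deletion starting inside a 600 nt region, running to the region end
  tmpl <- make_template(c(600, 300))
  members <- lapply(1:4, function(i) make_cov(tmpl, 300, sprintf("M%d", i)))
  pool <- make_pool(members, tmpl)
  r <- tmpl$regions[1, ]
  for (offset in c(137, 252, 399)) {
    bp <- r$start + offset
    q <- apply_event(make_cov(tmpl, 300, "Q"), tmpl, r$chrom, bp, r$end, 0.5)
    prof <- score_sample(q, pool, tmpl)
    cands <- refine_breakpoints(prof, flag_candidates(prof))
    expect_equal(nrow(cands), 1L)
    expect_lte(abs(cands$refined_start - bp), tmpl$slide_len)
    expect_equal(cands$refined_end, r$end)          # boundary edge kept exact
  }
  # region-aligned event: both edges stay on the region boundaries
  q <- apply_event(make_cov(tmpl, 300, "Q"), tmpl, r$chrom, r$start, r$end, 0.5)
  prof <- score_sample(q, pool, tmpl)
  cands <- refine_breakpoints(prof, flag_candidates(prof))
  expect_equal(cands$refined_start, r$start)
  expect_equal(cands$refined_end, r$end)
})

test_that("gene plots and sidecars render no-calls as gaps", {
  fx <- make_del_profile()
  prof <- fx$profile
  prof$table$no_call[2] <- TRUE
  png_path <- tempfile(fileext = ".png")
  gene_plot(prof, "G1", png_path)
  expect_true(file.exists(png_path))
  sidecar <- read.table(paste0(png_path, ".data.tsv"), header = TRUE, sep = "\t")
  expect_true(sidecar$no_call[2])
  expect_equal(nrow(sidecar), sum(prof$table$gene == "G1"))
})

test_that("merged run plots anonymise sample identities on request", {
  fx <- make_del_profile()
  tmpl <- fx$tmpl
  profs <- lapply(1:5, function(i) {
    q <- make_cov(tmpl, 200, sprintf("PATIENT_%d", i))
    score_sample(q, fx$pool, tmpl)
  })
  png_path <- tempfile(fileext = ".png")
  merged_run_plot(profs, "G1", png_path, anonymize = TRUE)
  sidecar <- read.table(paste0(png_path, ".data.tsv"), header = TRUE, sep = "\t")
  expect_false(any(grepl("PATIENT", sidecar$trace)))

  merged_run_plot(profs, "G1", png_path, anonymize = FALSE)
  sidecar <- read.table(paste0(png_path, ".data.tsv"), header = TRUE, sep = "\t")
  expect_true(any(grepl("PATIENT", sidecar$trace)))

  expect_error(merged_run_plot(profs[1], "G1", png_path), "at least 2")
})

test_that("candidate output round-trips as TSV and BED", {
  fx <- make_del_profile()
  cands <- refine_breakpoints(fx$profile, flag_candidates(fx$profile))
  tsv <- tempfile(fileext = ".tsv")
  bed <- tempfile(fileext = ".bed")
  write_candidates(cands, tsv, bed)
  back <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(back$start, cands$start)
  bed_tab <- read.table(bed, sep = "\t")
  expect_equal(bed_tab$V2, cands$start)              # BED stays 0-based
  expect_match(bed_tab$V4, "G2\\|deletion")
})
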