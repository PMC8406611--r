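# Synthetic deep-panel coverage.
#
# Emulates the statistical structure the pipeline assumes: deep capture
# coverage (hundreds x) with region-specific capture efficiency shared by
# all samples, per-lot capture batch effects, per-sample depth scaling,
# multiplicative per-base noise, and injected CNV events that multiply
# depth by the copy ratio (0.5 heterozygous deletion, 1.5 heterozygous
# duplication, 0 homozygous deletion, 1 - f/2 for a mosaic deletion in a
# fraction f of cells). Every draw is governed by one seed, so a fixed
# configuration reproduces byte-identical fixtures.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults describe a realistic deep gene-panel validation cohort: 126
#' target regions across 21 genes, 20 normal samples over 2 runs of one
#' capture-kit lot, 200x target depth, a log-scale capture-efficiency
#' spread of 0.3 between regions, 10% per-sample depth scaling and 5%
#' multiplicative per-base noise.
#'
#' @param seed RNG seed governing every draw.
#' @param n_regions Number of target regions in the panel.
#' @param n_genes Number of genes the regions are distributed over.
#' @param region_length_range Integer min/max region length (nt);
#'   captured regions are exons/UTRs plus ~25 nt intronic flanks.
#' @param n_normals Number of event-free normal samples.
#' @param n_runs Number of sequencing runs the cohort is spread over.
#' @param n_lots Number of capture-kit lots.
#' @param base_depth Target mean depth (reads per position).
#' @param capture_efficiency_sd Log-scale sd of per-region capture
#'   efficiency (shared by all samples).
#' @param lot_effect_sd Log-scale sd of per-lot per-region multipliers
#'   (batch effect).
#' @param sample_depth_sd Log-scale sd of per-sample depth scaling.
#' @param noise_cv Coefficient of variation of multiplicative per-base
#'   noise.
#' @param events List of [cnv_event()] specifications.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_regions = 126L, n_genes = 21L,
                       region_length_range = c(90L, 400L),
                       n_normals = 20L, n_runs = 2L, n_lots = 1L,
                       base_depth = 200, capture_efficiency_sd = 0.3,
                       lot_effect_sd = 0.05, sample_depth_sd = 0.1,
                       noise_cv = 0.05, events = list()) {
  if (n_regions < 1L) stop("n_regions must be >= 1", call. = FALSE)
  if (n_genes < 1L || n_genes > n_regions) {
    stop("need 1 <= n_genes <= n_regions", call. = FALSE)
  }
  if (length(region_length_range) != 2L ||
      region_length_range[1L] > region_length_range[2L] ||
      region_length_range[1L] < 1L) {
    stop("region_length_range must be an increasing pair of positive lengths",
         call. = FALSE)
  }
  if (base_depth <= 0) stop("base_depth must be positive", call. = FALSE)
  sds <- c(capture_efficiency_sd, lot_effect_sd, sample_depth_sd, noise_cv)
  if (any(sds < 0)) stop("spread parameters must be >= 0", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_regions = as.integer(n_regions),
         n_genes = as.integer(n_genes),
         region_length_range = as.integer(region_length_range),
         n_normals = as.integer(n_normals), n_runs = as.integer(n_runs),
         n_lots = as.integer(n_lots), base_depth = base_depth,
         capture_efficiency_sd = capture_efficiency_sd,
         lot_effect_sd = lot_effect_sd, sample_depth_sd = sample_depth_sd,
         noise_cv = noise_cv, events = events),
    class = "sim_config"
  )
}

#' Specify a CNV event for the simulator
#'
#' The event span is either an explicit genomic interval (`chrom`,
#' `start`, `end`; supports breakpoints inside a region) or a set of
#' whole regions of one gene (`gene` plus `regions`, 1-based exon
#' ordinals within the gene; `regions = NULL` means the whole gene).
#'
#' @param sample_id Sample the event is injected into.
#' @param copy_ratio Expected depth multiplier: 0.5 heterozygous
#'   deletion, 1.5 heterozygous duplication, 0 homozygous deletion,
#'   `1 - f/2` for a mosaic single-allele deletion in cell fraction `f`.
#' @param gene,regions Region-based span (see above).
#' @param chrom,start,end Explicit interval (0-based half-open).
#' @return A `cnv_event` list.
#' @export
cnv_event <- function(sample_id, copy_ratio, gene = NULL, regions = NULL,
                      chrom = NULL, start = NULL, end = NULL) {
  if (copy_ratio < 0) stop("copy_ratio must be >= 0", call. = FALSE)
  explicit <- !is.null(chrom)
  if (explicit && (is.null(start) || is.null(end) || end <= start)) {
    stop("explicit event interval needs chrom, start < end", call. = FALSE)
  }
  if (!explicit && is.null(gene)) {
    stop("event needs either a gene or an explicit interval", call. = FALSE)
  }
  structure(list(sample_id = sample_id, copy_ratio = copy_ratio,
                 gene = gene, regions = regions,
                 chrom = chrom, start = start, end = end),
            class = "cnv_event")
}

# resolve an event to an explicit interval against a panel
resolve_event <- function(event, panel) {
  if (!is.null(event$chrom)) {
    hit <- panel$regions$chrom == event$chrom &
      panel$regions$start < event$end & panel$regions$end > event$start
    if (!any(hit)) stop("event interval ", event$chrom, ":", event$start, "-",
                        event$end, " does not overlap the panel", call. = FALSE)
    return(event)
  }
  rr <- panel$regions[panel$regions$gene == event$gene, , drop = FALSE]
  if (nrow(rr) == 0L) stop("event gene '", event$gene, "' not in panel", call. = FALSE)
  if (!is.null(event$regions)) {
    if (any(event$regions < 1L) || any(event$regions > nrow(rr))) {
      stop("event regions out of range for gene ", event$gene, call. = FALSE)
    }
    rr <- rr[sort(event$regions), , drop = FALSE]
  }
  event$chrom <- rr$chrom[1L]
  event$start <- min(rr$start)
  event$end <- max(rr$end)
  event
}

#' Simulate a target panel
#'
#' Region lengths are drawn uniformly from the configured range; regions
#' are distributed over genes in contiguous blocks (exon01, exon02, ...),
#' genes over chromosomes, with 0.2-2 kb gaps between neighbouring
#' regions. Deterministic for a fixed seed. Per-region capture
#' efficiencies and per-lot batch multipliers are drawn here so that all
#' samples of a cohort share them.
#'
#' @param config A [sim_config()].
#' @return A `sim_panel`: list with `regions` (BED-style data frame plus
#'   per-region `efficiency`), `lot_effects` (lots x regions matrix) and
#'   the `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_regions
    lens <- sample(seq.int(config$region_length_range[1L],
                           config$region_length_range[2L]), n, replace = TRUE)
    gene_of <- sort(rep_len(seq_len(config$n_genes), n))
    gene_names <- sprintf("GENE%03d", seq_len(config$n_genes))
    chrom_of_gene <- paste0("chr", 1L + (seq_len(config$n_genes) - 1L) %% 22L)

    gaps <- sample(200:2000, n, replace = TRUE)
    start <- integer(n); end <- integer(n)
    cursor <- stats::setNames(rep(10000L, 22L), paste0("chr", 1:22))
    label <- integer(n)
    for (i in seq_len(n)) {
      chr <- chrom_of_gene[gene_of[i]]
      start[i] <- cursor[chr] + gaps[i]
      end[i] <- start[i] + lens[i]
      cursor[chr] <- end[i]
      label[i] <- sum(gene_of[seq_len(i)] == gene_of[i])
    }
    regions <- data.frame(
      chrom = chrom_of_gene[gene_of], start = start, end = end,
      gene = gene_names[gene_of], label = sprintf("exon%02d", label),
      efficiency = exp(stats::rnorm(n, 0, config$capture_efficiency_sd)),
      stringsAsFactors = FALSE
    )
    regions <- regions[order(match(regions$chrom, unique(regions$chrom)),
                             regions$start), ]
    rownames(regions) <- NULL
    lot_effects <- matrix(
      exp(stats::rnorm(config$n_lots * n, 0, config$lot_effect_sd)),
      nrow = config$n_lots,
      dimnames = list(sprintf("lot%02d", seq_len(config$n_lots)), NULL)
    )
    structure(list(regions = regions, lot_effects = lot_effects,
                   config = config),
              class = "sim_panel")
  })
}

#' Write a simulated panel as BED
#'
#' @param panel A [simulate_panel()] object.
#' @param path Output BED path (name column `GENE|label`).
#' @return Invisibly, the path.
#' @export
write_panel_bed <- function(panel, path) {
  r <- panel$regions
  bed <- data.frame(r$chrom, r$start, r$end, paste0(r$gene, "|", r$label))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate per-base coverage for one sample
#'
#' Depth at every targeted position is
#' `base_depth * sample_scale * region_efficiency * lot_effect *
#' copy_ratio(pos) * noise(pos)`, rounded half-up to an integer. CNV
#' events multiply depth only over the in-span positions, so
#' partial-region events produce breakpoints inside a region.
#'
#' @param panel A [simulate_panel()] object.
#' @param template A [build_template()] built on `panel$regions`.
#' @param config The [sim_config()] (noise and scaling parameters).
#' @param sample_id,run_id,lot_id Sample annotations; `lot_id` must be a
#'   row name of `panel$lot_effects`.
#' @param events List of [cnv_event()]s for this sample.
#' @param seed Seed for this sample's draws (derive from the cohort seed
#'   for reproducibility).
#' @param sample_scale Optional fixed per-sample depth scaling; drawn
#'   log-normally when `NULL`.
#' @return List with `coverage` (a [sample_coverage()]) and `truth`
#'   (data frame of resolved event intervals and copy ratios).
#' @export
simulate_sample <- function(panel, template, config, sample_id,
                            run_id = "run01", lot_id = "lot01",
                            events = list(), seed = config$seed,
                            sample_scale = NULL) {
  stopifnot(inherits(panel, "sim_panel"), inherits(template, "window_template"))
  lot_row <- match(lot_id, rownames(panel$lot_effects))
  if (is.na(lot_row)) stop("unknown lot_id '", lot_id, "'", call. = FALSE)
  with_seed(seed, {
    if (is.null(sample_scale)) {
      sample_scale <- exp(stats::rnorm(1, 0, config$sample_depth_sd))
    }
    reg <- panel$regions
    reg_len <- reg$end - reg$start
    per_pos_mult <- rep(reg$efficiency * panel$lot_effects[lot_row, ], reg_len)
    depth <- config$base_depth * sample_scale * per_pos_mult

    truth <- NULL
    for (ev in events) {
      ev <- resolve_event(ev, panel)
      in_span <- template$pos_chrom == ev$chrom &
        template$pos_pos >= ev$start & template$pos_pos < ev$end
      depth[in_span] <- depth[in_span] * ev$copy_ratio
      truth <- rbind(truth, data.frame(
        sample_id = sample_id, chrom = ev$chrom, start = ev$start, end = ev$end,
        copy_ratio = ev$copy_ratio, stringsAsFactors = FALSE))
    }
    if (config$noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      depth <- depth * stats::rlnorm(length(depth), -sdlog^2 / 2, sdlog)
    }
    depth <- floor(depth + 0.5)
    list(coverage = sample_coverage(depth, template, sample_id, run_id, lot_id),
         truth = truth)
  })
}

#' Simulate a full cohort
#'
#' Generates `n_normals` event-free samples spread round-robin over runs
#' and lots, plus one sample per distinct `sample_id` in
#' `config$events`. Optionally writes per-locus coverage files, the
#' panel BED, a manifest and the truth set to a directory.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @param window_len,slide_len Window parameters for the internal
#'   template (positions do not depend on them).
#' @return List with `panel`, `template`, `samples` (named list of
#'   [sample_coverage()]), `manifest` (sample_id, run_id, lot_id, role)
#'   and `truth` (all injected events).
#' @export
simulate_cohort <- function(config, dir = NULL, window_len = 75L, slide_len = 10L) {
  stopifnot(inherits(config, "sim_config"))
  panel <- simulate_panel(config)
  template <- build_template(panel$regions, window_len, slide_len)

  event_ids <- unique(vapply(config$events, function(e) e$sample_id, ""))
  normal_ids <- sprintf("NORM%03d", seq_len(config$n_normals))
  if (any(event_ids %in% normal_ids)) {
    stop("event sample ids must not collide with NORMxxx ids", call. = FALSE)
  }
  all_ids <- c(normal_ids, event_ids)
  runs <- sprintf("run%02d", 1L + (seq_along(all_ids) - 1L) %% config$n_runs)
  lots <- sprintf("lot%02d", 1L + (seq_along(all_ids) - 1L) %% config$n_lots)

  samples <- vector("list", length(all_ids))
  names(samples) <- all_ids
  truth <- NULL
  for (i in seq_along(all_ids)) {
    id <- all_ids[i]
    evs <- Filter(function(e) e$sample_id == id, config$events)
    res <- simulate_sample(panel, template, config, id, runs[i], lots[i],
                           events = evs, seed = config$seed + 1000L + i)
    samples[[i]] <- res$coverage
    truth <- rbind(truth, res$truth)
  }
  manifest <- data.frame(
    sample_id = all_ids, run_id = runs, lot_id = lots,
    role = c(rep("normal", length(normal_ids)), rep("event", length(event_ids))),
    stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_panel_bed(panel, file.path(dir, "panel.bed"))
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(truth)) {
      utils::write.table(truth, file.path(dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (id in all_ids) {
      write_per_locus_coverage(samples[[id]], template,
                               file.path(dir, paste0(id, ".coverage.tsv")))
    }
  }
  list(panel = panel, template = template, samples = samples,
       manifest = manifest, truth = truth)
}

#' Canonical validation event set
#'
#' Ten CNV events spanning the classes a panel validation exercises:
#' whole-gene, multi-exon and single-exon heterozygous deletions and
#' duplications, a homozygous whole-gene deletion, and a partial-exon
#' deletion whose breakpoint falls inside an exon. Genes are chosen
#' deterministically from the panel (multi-exon genes with enough
#' regions).
#'
#' @param panel A [simulate_panel()] object.
#' @return List of 10 [cnv_event()]s for samples `EVT01`..`EVT10`.
#' @export
example_event_set <- function(panel) {
  reg <- panel$regions
  genes <- unique(reg$gene)
  n_reg <- vapply(genes, function(g) sum(reg$gene == g), 0L)
  multi <- genes[n_reg >= 4L]
  if (length(multi) < 10L) stop("panel too small for the validation event set",
                                call. = FALSE)
  # partial-exon deletion: from inside exon 2 to the end of exon 3
  g10 <- multi[10L]
  rr <- reg[reg$gene == g10, , drop = FALSE]
  bp <- rr$start[2L] + (rr$end[2L] - rr$start[2L]) %/% 3L
  list(
    cnv_event("EVT01", 0.5, gene = multi[1L]),                      # whole-gene het del
    cnv_event("EVT02", 0.5, gene = multi[2L], regions = 2:4),       # multi-exon het del
    cnv_event("EVT03", 0.5, gene = multi[3L], regions = 2L),        # single-exon het del
    cnv_event("EVT04", 1.5, gene = multi[4L]),                      # whole-gene het dup
    cnv_event("EVT05", 1.5, gene = multi[5L], regions = 1:3),       # multi-exon het dup
    cnv_event("EVT06", 1.5, gene = multi[6L], regions = 3L),        # single-exon het dup
    cnv_event("EVT07", 0.0, gene = multi[7L]),                      # homozygous del
    cnv_event("EVT08", 0.5, gene = multi[8L], regions = 1:2),       # multi-exon het del
    cnv_event("EVT09", 1.5, gene = multi[9L], regions = 2L),        # single-exon het dup
    cnv_event("EVT10", 0.5, chrom = rr$chrom[1L], start = bp,
              end = rr$end[3L])                                     # partial-exon del
  )
}
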