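# Pipeline wiring and command-line interface.
#
# One configuration object carries every tunable; run_score() executes
# pool selection -> scoring -> QC -> reporting for one query sample. A
# deviation failure (query mean depth too far from every pool) is first
# retried against a fallback pool set and then surfaced as a hard QC
# failure with the documented escalation guidance. The `panelcnv`
# Rscript under inst/cli/ exposes the subcommands simulate, make-pools,
# score, qc and report on top of these functions.

#' Pipeline configuration
#'
#' @param window_len,slide_len Sliding-window geometry in nt (defaults
#'   75 and 10: half a 150 nt read, with 65 nt overlap between adjacent
#'   windows).
#' @param pool_size Pool size K (required for pool building; no silent
#'   default — the documented example uses K = 8).
#' @param min_normal_depth Mean-depth cutoff for normals (default 100x).
#' @param deviation_cutoff_pct Query-vs-pool deviation cutoff, percent.
#' @param max_pool_cv Pool member-depth CV limit, percent.
#' @param delta_threshold Static-vs-run-wise flag threshold, log2 units.
#' @param min_pool_depth No-call floor for pool window depth.
#' @param floor_score Capped score for zero query depth.
#' @param del_threshold,dup_threshold,min_consecutive Candidate-flagger
#'   thresholds.
#' @param allow_cross_lot Permit cross-lot pool selection?
#' @return A `cnv_config` list.
#' @export
cnv_config <- function(window_len = 75L, slide_len = 10L, pool_size = NULL,
                       min_normal_depth = 100, deviation_cutoff_pct = 5,
                       max_pool_cv = 15, delta_threshold = 0.3,
                       min_pool_depth = 20, floor_score = -6,
                       del_threshold = -0.5, dup_threshold = 0.3,
                       min_consecutive = 3L, allow_cross_lot = FALSE) {
  check_window_params(window_len, slide_len)
  structure(as.list(environment()), class = "cnv_config")
}

#' Load a YAML pipeline configuration
#'
#' Unknown keys are rejected; omitted keys keep their [cnv_config()]
#' defaults. Explicit arguments in `...` override the file.
#'
#' @param path YAML file path.
#' @param ... Overrides passed to [cnv_config()].
#' @return A `cnv_config` list.
#' @export
load_config <- function(path, ...) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(cnv_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(cnv_config, vals)
}

#' Score one query sample end to end
#'
#' Selects the nearest-depth pool, scores the query, runs QC, and flags
#' candidates. If the query/pool depth deviation exceeds the cutoff the
#' selection is retried against `fallback_pools` (an updated, larger
#' pool set) when provided; a persistent failure returns `status = 2`
#' with escalation guidance (re-sequencing or an orthogonal test such as
#' MLPA) and no candidate list, but still returns the profile for
#' inspection.
#'
#' @param query A [sample_coverage()] query.
#' @param pools A [build_static_pools()] pool set.
#' @param template The shared [build_template()] object.
#' @param config A [cnv_config()].
#' @param runwise_profile Optional run-wise [score_sample()] profile for
#'   the QC cross-check.
#' @param fallback_pools Optional updated pool set tried after a
#'   deviation failure.
#' @param out_dir Optional directory for the logCNR table, QC report,
#'   candidate TSV/BED and per-gene plots.
#' @param plots Write per-gene plots when `out_dir` is set?
#' @return List with `status` (0 ok, 2 QC failure), `profile`, `qc`,
#'   `candidates`, `pool` and `message`.
#' @export
run_score <- function(query, pools, template, config = cnv_config(),
                      runwise_profile = NULL, fallback_pools = NULL,
                      out_dir = NULL, plots = FALSE) {
  stopifnot(inherits(config, "cnv_config"))
  attempt <- function(ps) {
    pool <- select_pool(query, ps, allow_cross_lot = config$allow_cross_lot)
    profile <- score_sample(query, pool, template,
                            min_pool_depth = config$min_pool_depth,
                            floor_score = config$floor_score)
    qc <- qc_sample(query, pool, profile, runwise_profile,
                    deviation_cutoff_pct = config$deviation_cutoff_pct,
                    max_pool_cv = config$max_pool_cv,
                    delta_threshold = config$delta_threshold)
    profile$qc <- qc
    list(pool = pool, profile = profile, qc = qc)
  }
  res <- attempt(pools)
  used_fallback <- FALSE
  if (!res$qc$deviation_pass && !is.null(fallback_pools)) {
    res <- attempt(fallback_pools)
    used_fallback <- TRUE
  }
  if (!res$qc$deviation_pass) {
    msg <- sprintf(paste0(
      "QC failure for %s: query mean depth deviates %.1f%% from the nearest ",
      "pool (cutoff %.1f%%)%s. Re-analyse with a larger, updated static pool ",
      "set; if the deviation persists, escalate to re-sequencing or an ",
      "orthogonal test (e.g. MLPA)."),
      query$sample_id, res$qc$pct_deviation, config$deviation_cutoff_pct,
      if (used_fallback) " even after the fallback pool set" else "")
    return(list(status = 2L, profile = res$profile, qc = res$qc,
                candidates = NULL, pool = res$pool, message = msg))
  }
  cands <- flag_candidates(res$profile,
                           del_threshold = config$del_threshold,
                           dup_threshold = config$dup_threshold,
                           min_consecutive = config$min_consecutive,
                           include_mosaic = TRUE)
  cands <- refine_breakpoints(res$profile, cands)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pre <- file.path(out_dir, query$sample_id)
    write_logcnr_tsv(res$profile, paste0(pre, ".logcnr.tsv"))
    write_qc_tsv(res$qc, paste0(pre, ".qc.tsv"))
    write_candidates(cands, paste0(pre, ".candidates.tsv"),
                     paste0(pre, ".candidates.bed"))
    if (plots) {
      for (g in unique(res$profile$table$gene)) {
        gene_plot(res$profile, g, paste0(pre, ".", g, ".png"))
      }
    }
  }
  list(status = 0L, profile = res$profile, qc = res$qc, candidates = cands,
       pool = res$pool, message = "ok")
}

# ---- command-line interface -------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: panelcnv <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate    --out DIR [--config FILE] [--seed N]",
    "  make-pools  --bed FILE --coverage-dir DIR --out DIR --pool-size K",
    "              [--min-depth N] [--lot ID] [--config FILE]",
    "  score       --bed FILE --query FILE --pools DIR --out DIR",
    "              [--fallback-pools DIR] [--config FILE] [--plots]",
    "  report      --bed FILE --query FILE --pools DIR --out DIR",
    "              [--genes G1,G2] [--anonymize] [--config FILE]",
    "",
    "exit codes: 0 ok, 2 QC failure, 3 input error",
    sep = "\n")
}

cli_parse_args <- function(argv) {
  opts <- list(flags = character())
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i < length(argv) && !grepl("^--", argv[i + 1L])) {
        opts[[key]] <- argv[i + 1L]
        i <- i + 2L
      } else {
        opts$flags <- c(opts$flags, key)
        i <- i + 1L
      }
    } else {
      stop("unexpected argument: ", a, call. = FALSE)
    }
  }
  opts
}

cli_need <- function(opts, keys) {
  miss <- setdiff(keys, names(opts))
  if (length(miss) > 0L) {
    stop("missing required option(s): ", paste0("--", miss, collapse = ", "),
         call. = FALSE)
  }
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `make-pools`, `score` and `report`
#' subcommands; used by the `panelcnv` Rscript installed under
#' `inst/cli/`. Runs fully in-process so it is testable without
#' spawning an interpreter.
#'
#' @param argv Character vector of command-line arguments (without the
#'   program name).
#' @return Integer exit status: 0 ok, 2 QC failure, 3 input error.
#' @export
cnv_cli_main <- function(argv) {
  if (length(argv) == 0L || argv[1L] %in% c("-h", "--help", "help")) {
    cat(cli_usage(), "\n")
    return(0L)
  }
  sub <- argv[1L]
  status <- tryCatch({
    opts <- cli_parse_args(argv[-1L])
    cfg <- load_config(opts$config)
    switch(sub,
      "simulate" = {
        cli_need(opts, "out")
        seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else 1L
        sc <- sim_config(seed = seed)
        sc$events <- example_event_set(simulate_panel(sc))
        simulate_cohort(sc, dir = opts$out,
                        window_len = cfg$window_len, slide_len = cfg$slide_len)
        message("cohort written to ", opts$out)
        0L
      },
      "make-pools" = {
        cli_need(opts, c("bed", "coverage-dir", "out", "pool-size"))
        regions <- read_panel_bed(opts$bed)
        template <- build_template(regions, cfg$window_len, cfg$slide_len)
        files <- list.files(opts[["coverage-dir"]], pattern = "\\.coverage\\.tsv$",
                            full.names = TRUE)
        if (length(files) == 0L) stop("no *.coverage.tsv files in ",
                                      opts[["coverage-dir"]], call. = FALSE)
        lot <- if (!is.null(opts$lot)) opts$lot else NA_character_
        covs <- lapply(files, read_per_locus_coverage, template = template,
                       lot_id = lot)
        min_depth <- if (!is.null(opts[["min-depth"]])) {
          as.numeric(opts[["min-depth"]])
        } else cfg$min_normal_depth
        normals <- select_normals(covs, min_depth)
        pools <- build_static_pools(normals, as.integer(opts[["pool-size"]]),
                                    template, lot_id = lot)
        write_pool_set(pools, template, opts$out)
        message(length(pools$pools), " pools written to ", opts$out)
        0L
      },
      "score" = ,
      "report" = {
        cli_need(opts, c("bed", "query", "pools", "out"))
        regions <- read_panel_bed(opts$bed)
        template <- build_template(regions, cfg$window_len, cfg$slide_len)
        query <- read_per_locus_coverage(opts$query, template)
        pools <- read_pool_set(opts$pools, template)
        fallback <- if (!is.null(opts[["fallback-pools"]])) {
          read_pool_set(opts[["fallback-pools"]], template)
        }
        res <- run_score(query, pools, template, cfg,
                         fallback_pools = fallback, out_dir = opts$out,
                         plots = "plots" %in% opts$flags || sub == "report")
        if (sub == "report") {
          genes <- if (!is.null(opts$genes)) {
            strsplit(opts$genes, ",", fixed = TRUE)[[1L]]
          } else unique(res$profile$table$gene)
          for (g in genes) {
            gene_plot(res$profile, g,
                      file.path(opts$out, paste0(query$sample_id, ".", g, ".png")))
          }
        }
        if (res$status != 0L) message(res$message)
        res$status
      },
      stop("unknown subcommand '", sub, "'\n", cli_usage(), call. = FALSE)
    )
  }, error = function(e) {
    message("panelcnv error [", sub, "]: ", conditionMessage(e))
    3L
  })
  status
}
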