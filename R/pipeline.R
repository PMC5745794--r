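# End-to-end synthetic reproduction pipeline: simulate -> filter -> windowed
# statistics -> SFS -> demographic fit + model choice -> sweep scans +
# calibration -> consensus regions -> QTL demo. Config-driven, deterministic
# per seed, every artifact checksummed into a manifest.

#' Default pipeline configuration
#'
#' A reduced-budget configuration that exercises every stage on one CPU in
#' minutes: sample sizes 86/25 haplotypes (the two-population resequencing
#' design), a short chromosome, and small fit/scan budgets. Any entry can be
#' overridden via `...`.
#'
#' @param ... Named overrides of config entries.
#' @return A list of class `run_config`.
#' @examples
#' cfg <- pipeline_config(seed = 42, sequence_length = 2e5)
#' cfg$seed
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    model = "M4",
    n_per_deme = c(86, 25),
    sequence_length = 5e5,
    with_recombination = TRUE,
    window_size = 2e5,
    step = 1e4,
    fit_models = c("M1", "M4"),
    fit_free = list(t_div = c(5e3, 2e5)),
    fit_n_runs = 3,
    fit_n_cycles = 4,
    fit_n_sims = 5e3,
    fit_n_snps = 5e4,
    scan_grid_interval = 1e4,
    scan_minwin = 1e4,
    scan_maxwin = 1e5,
    scan_n_null = 20,
    scan_null_length = 1e5,
    scan_fpr = 0.01,
    qtl_n = 86,
    qtl_n_perm = 200,
    stages = c("simulate", "filter", "stats", "fit", "scan", "qtl"),
    full_null_budget = 10000   # reference full-scale null count, for warnings
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

stage_log <- function(lines, stage, msg) {
  c(lines, sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the enabled stages in dependency order, writing every
#' intermediate artifact under `outdir` and returning (and writing) a
#' manifest of files with MD5 checksums, effective configuration and seeds.
#' Identical configurations yield identical artifacts and manifests.
#' Disabling a stage skips it and its dependents with explicit notice.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Writable output directory.
#' @return A list of class `run_manifest`: `files` (tibble `stage`, `file`,
#'   `md5`), `config`, `skipped`, `log`, `results` (in-memory stage
#'   outputs).
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir) {
  stopifnot(inherits(cfg, "run_config"))
  if (missing(outdir)) abort("outdir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) abort("outdir is not writable")
  log <- character()
  files <- list()
  results <- list()
  skipped <- character()
  add_file <- function(stage, path) {
    files[[length(files) + 1]] <<- tibble::tibble(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path))
    )
  }
  on <- function(stage) stage %in% cfg$stages
  deps <- list(filter = "simulate", stats = "simulate", fit = "simulate",
               scan = "simulate", qtl = character())
  enabled <- function(stage) {
    need <- deps[[stage]] %||% character()
    on(stage) && all(vapply(need, enabled, logical(1)))
  }

  models <- yangtze_demographic_models()
  if (!cfg$model %in% names(models)) abort("unknown model in config")

  panel <- NULL
  if (enabled("simulate")) {
    log <- stage_log(log, "simulate", sprintf(
      "model %s, n = (%s), L = %g, seed = %d", cfg$model,
      paste(cfg$n_per_deme, collapse = "/"), cfg$sequence_length, cfg$seed))
    panel <- simulate_panel(models[[cfg$model]], cfg$n_per_deme,
                            cfg$sequence_length, seed = derive_seed(cfg$seed, 1),
                            with_recombination = cfg$with_recombination)
    f <- file.path(outdir, "panel.vcf")
    write_panel_vcf(panel, f)
    add_file("simulate", f)
    results$panel <- panel
  } else {
    skipped <- c(skipped, "simulate")
  }

  if (enabled("filter")) {
    kept <- density_filter(panel$positions)
    keep_cols <- panel$positions %in% kept
    filtered <- hap_panel(panel$matrix[, keep_cols, drop = FALSE],
                          panel$positions[keep_cols], panel$sequence_length,
                          panel$pop_labels)
    log <- stage_log(log, "filter", sprintf(
      "density filter removed %d of %d SNPs",
      ncol(panel$matrix) - ncol(filtered$matrix), ncol(panel$matrix)))
    f <- file.path(outdir, "panel_filtered.vcf")
    write_panel_vcf(filtered, f)
    add_file("filter", f)
    results$panel_filtered <- filtered
    panel <- filtered
  } else if (on("filter")) {
    skipped <- c(skipped, "filter")
  } else {
    skipped <- c(skipped, "filter")
  }

  if (enabled("stats")) {
    pi_w <- nucleotide_diversity(panel, cfg$window_size, cfg$step)
    th_w <- watterson_theta(panel, cfg$window_size, cfg$step)
    fst_w <- hudson_fst(panel, cfg$window_size, cfg$step)
    stats_tbl <- dplyr::left_join(
      dplyr::left_join(pi_w, th_w[, c("start", "end", "theta_w")],
                       by = c("start", "end")),
      fst_w[, c("start", "end", "fst")], by = c("start", "end"))
    f <- file.path(outdir, "window_stats.tsv")
    readr::write_tsv(tibble::as_tibble(stats_tbl), f, progress = FALSE)
    add_file("stats", f)
    sfs <- joint_folded_sfs(panel)
    f2 <- file.path(outdir, "joint_sfs.txt")
    write_sfs(sfs, f2)
    add_file("stats", f2)
    results$window_stats <- stats_tbl
    results$sfs <- sfs
    log <- stage_log(log, "stats", sprintf("%d windows, %d SNPs in SFS",
                                           nrow(stats_tbl), sum(sfs$counts)))
  } else {
    skipped <- c(skipped, "stats")
  }

  if (enabled("fit") && "sfs" %in% names(results)) {
    if (cfg$fit_n_sims < 1e5)
      log <- stage_log(log, "fit", sprintf(
        "NOTE: %g sims/evaluation is below the 1e5-1e6 full schedule",
        cfg$fit_n_sims))
    fits <- lapply(cfg$fit_models, function(mn) {
      fit_model(results$sfs, models[[mn]], bounds = cfg$fit_free,
                n_runs = cfg$fit_n_runs,
                sims_schedule = c(cfg$fit_n_sims, cfg$fit_n_sims),
                n_cycles = cfg$fit_n_cycles,
                seed = derive_seed(cfg$seed, 2), min_support = 10)
    })
    cmp <- compare_models(fits)
    f <- file.path(outdir, "model_comparison.tsv")
    readr::write_tsv(tibble::as_tibble(cmp), f, progress = FALSE)
    add_file("fit", f)
    est <- dplyr::bind_rows(lapply(fits, function(x) {
      dplyr::mutate(tidy(x), model = x$model_id)
    }))
    f2 <- file.path(outdir, "fit_estimates.tsv")
    readr::write_tsv(est, f2, progress = FALSE)
    add_file("fit", f2)
    results$fits <- fits
    results$comparison <- cmp
    log <- stage_log(log, "fit", sprintf("best model: %s", cmp$model[1]))
  } else {
    skipped <- c(skipped, "fit")
  }

  if (enabled("scan")) {
    if (cfg$scan_n_null < cfg$full_null_budget)
      log <- stage_log(log, "scan", sprintf(
        "NOTE: %d null datasets is below the %d full-scale budget",
        cfg$scan_n_null, cfg$full_null_budget))
    nulls <- simulate_null_set(models[[cfg$model]], cfg$scan_n_null,
                               cfg$scan_null_length, cfg$n_per_deme,
                               seed = derive_seed(cfg$seed, 3),
                               with_recombination = cfg$with_recombination)
    bg <- folded_marginal_sfs(panel)
    bg <- pmax(bg, 0.5)  # smooth empty background classes for the nulls
    clr_null <- lapply(nulls, function(p) {
      try(clr_scan(p, background = bg,
                   grid_interval = cfg$scan_grid_interval), silent = TRUE)
    })
    clr_null <- clr_null[!vapply(clr_null, inherits, logical(1), "try-error")]
    om_null <- lapply(nulls, function(p) {
      omega_scan(p, grid_interval = cfg$scan_grid_interval,
                 minwin = cfg$scan_minwin, maxwin = cfg$scan_maxwin)
    })
    clr <- clr_scan(panel, background = bg,
                    grid_interval = cfg$scan_grid_interval)
    om <- omega_scan(panel, grid_interval = cfg$scan_grid_interval,
                     minwin = cfg$scan_minwin, maxwin = cfg$scan_maxwin)
    clr <- set_cutoff(clr, calibrate_cutoff(clr_null, cfg$scan_fpr),
                      cfg$scan_fpr)
    om <- set_cutoff(om, calibrate_cutoff(om_null, cfg$scan_fpr),
                     cfg$scan_fpr)
    rc <- merge_regions(clr)
    ro <- merge_regions(om)
    consensus <- intersect_methods(rc, ro)
    for (nm in c("clr", "omega")) {
      f <- file.path(outdir, paste0("scan_", nm, ".tsv"))
      write_scan_tsv(if (nm == "clr") clr else om, f)
      add_file("scan", f)
    }
    f <- file.path(outdir, "consensus_regions.bed")
    write_regions_bed(consensus, f)
    add_file("scan", f)
    results$clr <- clr
    results$omega <- om
    results$consensus <- consensus
    log <- stage_log(log, "scan", sprintf(
      "cutoffs: CLR %.2f, omega %.2f; %d consensus regions",
      attr(clr, "cutoff"), attr(om, "cutoff"), nrow(consensus)))
  } else {
    skipped <- c(skipped, "scan")
  }

  if (enabled("qtl")) {
    cross <- simulate_f2(cfg$qtl_n, genetic_map(), flowering_qtl_model(),
                         seed = derive_seed(cfg$seed, 4))
    lodc <- interval_mapping(cross)
    thr <- permutation_threshold(cross, n_perm = cfg$qtl_n_perm,
                                 seed = derive_seed(cfg$seed, 5))
    peaks <- dplyr::slice_max(dplyr::group_by(lodc, .data$chr), .data$lod,
                              n = 1, with_ties = FALSE)
    peaks <- dplyr::ungroup(peaks)
    peaks <- peaks[peaks$lod > thr, , drop = FALSE]
    pve <- if (nrow(peaks)) {
      variance_explained(cross, peaks[, c("chr", "pos")])
    } else {
      tibble::tibble(chr = character(), pos = double(), lod = double(),
                     pve = double())
    }
    f <- file.path(outdir, "qtl_lod.tsv")
    readr::write_tsv(tibble::as_tibble(lodc), f, progress = FALSE)
    add_file("qtl", f)
    f2 <- file.path(outdir, "qtl_summary.tsv")
    readr::write_tsv(dplyr::mutate(pve, threshold = as.numeric(thr)), f2,
                     progress = FALSE)
    add_file("qtl", f2)
    results$cross <- cross
    results$lod <- lodc
    results$lod_threshold <- as.numeric(thr)
    results$pve <- pve
    log <- stage_log(log, "qtl", sprintf(
      "threshold %.2f; %d significant QTLs", thr, nrow(pve)))
  } else {
    skipped <- c(skipped, "qtl")
  }

  skipped <- setdiff(unique(skipped), cfg$stages[
    vapply(cfg$stages, enabled, logical(1))])
  manifest <- structure(
    list(files = dplyr::bind_rows(files), config = unclass(cfg),
         skipped = skipped, log = log, results = results, outdir = outdir),
    class = "run_manifest"
  )
  cfg_out <- file.path(outdir, "config.yml")
  yaml::write_yaml(unclass(cfg), cfg_out)
  readr::write_tsv(manifest$files, file.path(outdir, "manifest.tsv"),
                   progress = FALSE)
  writeLines(log, file.path(outdir, "pipeline.log"))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d files in %s; skipped: %s\n",
              nrow(x$files), x$outdir,
              if (length(x$skipped)) paste(x$skipped, collapse = ", ")
              else "none"))
  print(x$files)
  invisible(x)
}

#' Human-readable pipeline report
#'
#' Deterministically renders a run manifest into a text report: fitted
#' parameters (with truth columns for synthetic runs), AIC model ranking,
#' sweep cutoffs and regions, and QTL peaks. Missing artifacts are listed
#' and the report is still produced. Regenerating the report from the same
#' manifest gives byte-identical output.
#'
#' @param manifest A `run_manifest` from [run_pipeline()].
#' @param path Optional file to write the report to.
#' @return Character vector of report lines (invisibly if `path` given).
#' @export
make_report <- function(manifest, path = NULL) {
  stopifnot(inherits(manifest, "run_manifest"))
  r <- manifest$results
  cfg <- manifest$config
  out <- c("== coalsweep pipeline report ==",
           sprintf("seed: %d | model: %s | L = %g bp | n = (%s)",
                   cfg$seed, cfg$model, cfg$sequence_length,
                   paste(cfg$n_per_deme, collapse = "/")), "")
  missing <- character()
  if (!is.null(r$comparison)) {
    out <- c(out, "-- model comparison (AIC) --",
             utils::capture.output(as.data.frame(r$comparison)), "")
  } else {
    missing <- c(missing, "model comparison")
  }
  if (!is.null(r$fits)) {
    truth <- model_params(yangtze_demographic_models()[[cfg$model]])
    est <- dplyr::bind_rows(lapply(r$fits, function(x) {
      df <- tidy(x)
      df$model <- x$model_id
      df$truth <- unname(truth[df$term])
      df
    }))
    out <- c(out, "-- fitted parameters (synthetic truth shown) --",
             utils::capture.output(as.data.frame(est)), "")
  } else {
    missing <- c(missing, "fits")
  }
  if (!is.null(r$clr)) {
    out <- c(out, "-- sweep scans --",
             sprintf("CLR cutoff %.3f (FPR %g); omega cutoff %.3f",
                     attr(r$clr, "cutoff"), attr(r$clr, "fpr"),
                     attr(r$omega, "cutoff")),
             sprintf("consensus regions: %d", nrow(r$consensus)), "")
  } else {
    missing <- c(missing, "sweep scans")
  }
  if (!is.null(r$lod)) {
    g <- glance(r$lod)
    out <- c(out, "-- QTL demo --",
             sprintf("max LOD %.2f at %s %.1f cM (threshold %.2f)",
                     g$max_lod, g$chr, g$pos, r$lod_threshold),
             if (nrow(r$pve))
               utils::capture.output(as.data.frame(r$pve)), "")
  } else {
    missing <- c(missing, "QTL")
  }
  if (length(missing))
    out <- c(out, paste("missing artifacts:", paste(missing, collapse = ", ")))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
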