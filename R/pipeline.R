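# End-to-end orchestration: simulate -> BSA scan -> fine map -> panel ->
# machine-readable summary.

#' Configuration for a full pipeline run
#'
#' Collects the simulator configuration and the per-stage analysis
#' parameters.  Stage seeds are derived deterministically from the master
#' seed, so one integer reproduces the whole run.
#'
#' @param seed Master seed.
#' @param sim A [sim_config()]; its own seed is overridden by `seed`.
#' @param bsa List of BSA parameters: `gq_min`, `window_bp`, `step_bp`,
#'   `min_sites`, `threshold_mode` (`"quantile"` or `"simulate"`),
#'   `n_sims`, `level` (`"99"`/`"95"`), `ed2_min` (or `NULL`).
#' @param finemap List: `n_f3`, `n_markers`, `region_width_bp`,
#'   `region_cM` (the fine-map region is laid around the simulated causal
#'   position).
#' @param panel List: `n_green`, `n_yellow`, `discordant`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       sim = sim_config(),
                       bsa = list(),
                       finemap = list(),
                       panel = list()) {
  sim$seed <- as.integer(seed)
  validate_sim_config(sim)
  bsa_def <- list(gq_min = 50, window_bp = 200000, step_bp = 100000,
                  min_sites = 1L, threshold_mode = "fixed",
                  n_sims = 2000L, level = "99", ed2_min = 0.5,
                  merge_gap_bp = 500000)
  fm_def <- list(n_f3 = 847L, n_markers = 21L, region_width_bp = 117840,
                 region_cM = 1.0)
  pn_def <- list(n_green = 26L, n_yellow = 19L, discordant = 0L)
  merge <- function(def, user) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown)) stop("unknown option(s): ", paste(unknown, collapse = ", "))
    def[names(user)] <- user
    def
  }
  structure(
    list(seed = as.integer(seed), sim = sim, bsa = merge(bsa_def, bsa),
         finemap = merge(fm_def, finemap), panel = merge(pn_def, panel)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file whose top-level keys mirror the `run_config`
#'   arguments (`seed`, `sim`, `bsa`, `finemap`, `panel`).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- if (is.null(y$sim)) list() else y$sim
  run_config(
    seed = if (is.null(y$seed)) 1L else y$seed,
    sim = do.call(sim_config, sim_args),
    bsa = if (is.null(y$bsa)) list() else y$bsa,
    finemap = if (is.null(y$finemap)) list() else y$finemap,
    panel = if (is.null(y$panel)) list() else y$panel
  )
}

#' Run the full bulked-segregant mapping pipeline
#'
#' Executes, in order: F2 simulation and bulk construction; pooled-depth
#' sampling and VCF/TSV export; variant filtering and the window scan with
#' peak calling; the Mendelian segregation test; F3 fine mapping
#' (recombinant identification and interval delimitation, plus a regional
#' two-point map length); and the diagnostic-panel concordance test.
#' Writes per-site and per-window TSVs, a BED of called intervals, the
#' filter report, the F3 genotype table, the panel table and a JSON
#' summary into `out_dir`.  Identical config and seed give byte-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The run summary, invisibly (also written to `summary.json`).
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sim <- config$sim
  bsa <- config$bsa

  pop <- stage("simulate", {
    simulate_f2(sim)
  })
  bulks <- stage("simulate", build_bulks(pop, seed = derive_seed(sim$seed, 2L)))
  variants <- stage("simulate", sample_pool_depths(pop, bulks))
  contigs <- setNames(rep(sim$chrom_length_bp, sim$n_chromosomes),
                      paste0("chr", seq_len(sim$n_chromosomes)))
  write_vcf(variants, pth("variants.vcf"), contigs = contigs)
  write_phenotypes(setNames(pop$phenotype, pop$ids), pth("phenotypes.tsv"))

  scan <- stage("bsa", {
    flt <- filter_variants(variants, gq_min = bsa$gq_min)
    sites <- site_stats(flt$variants)
    windows <- sliding_windows(sites, chrom_lengths = contigs,
                               window_bp = bsa$window_bp,
                               step_bp = bsa$step_bp,
                               min_sites = bsa$min_sites)
    thr <- bsa_thresholds(windows, sites = sites, mode = bsa$threshold_mode,
                          pool_size = sim$bulk_size, n_sims = bsa$n_sims,
                          seed = derive_seed(sim$seed, 3L),
                          seq_error = sim$seq_error_rate,
                          window_bp = bsa$window_bp, step_bp = bsa$step_bp)
    peaks <- call_peaks(windows, thr, level = bsa$level, ed2_min = bsa$ed2_min,
                        merge_gap_bp = bsa$merge_gap_bp)
    list(flt = flt, sites = sites, windows = attr(peaks, "windows"),
         thr = thr, peaks = peaks)
  })
  write.table(scan$sites, pth("site_stats.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(scan$windows, pth("window_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(scan$flt$report, pth("filter_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bed(scan$peaks, pth("peaks.bed"))

  seg <- stage("segregation", {
    chisq_segregation(sum(pop$phenotype == "green"),
                      sum(pop$phenotype == "yellow"))
  })

  fm <- stage("finemap", {
    fmc <- config$finemap
    causal <- sim$causal_pos_bp
    start <- round(causal - 0.55 * fmc$region_width_bp)
    markers <- finemap_markers(paste0("chr", sim$causal_chrom), start,
                               start + fmc$region_width_bp,
                               n_markers = fmc$n_markers,
                               region_cM = fmc$region_cM)
    fam <- simulate_f3_family(markers, n_offspring = fmc$n_f3,
                              causal_pos_bp = causal,
                              seed = derive_seed(sim$seed, 4L),
                              dominance = sim$dominance)
    write_genotype_table(fam, pth("f3_genotypes.tsv"))
    rec <- find_recombinants(fam, markers$label[1L],
                             markers$label[nrow(markers)])
    iv <- delimit_interval(rec, fam)
    rf <- recombination_fractions(fam)
    list(markers = markers, fam = fam, rec = rec, interval = iv,
         map_length_cM = attr(rf, "map_length_cM"))
  })
  write_bed(fm$interval, pth("finemap_interval.bed"))

  pan <- stage("panel", {
    pnc <- config$panel
    panel <- simulate_panel(pnc$n_green, pnc$n_yellow, pnc$discordant,
                            seed = derive_seed(sim$seed, 5L))
    write.table(panel, pth("panel.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    c(list(panel = panel), panel_concordance(panel))
  })

  summary <- list(
    seed = config$seed,
    n_f2 = sim$n_f2,
    segregation = c(list(n_green = sum(pop$phenotype == "green"),
                         n_yellow = sum(pop$phenotype == "yellow")),
                    seg[c("chi2", "p_value")]),
    filter = as.list(scan$flt$report),
    thresholds = list(mode = bsa$threshold_mode,
                      thr95 = scan$thr$thr95[1L],
                      thr99 = scan$thr$thr99[1L]),
    peaks = scan$peaks[, c("chrom", "start", "end", "max_mean_delta",
                           "max_mean_ed2")],
    finemap = list(
      n_recombinants = nrow(fm$rec),
      left_marker = fm$interval$left_marker,
      right_marker = fm$interval$right_marker,
      start = fm$interval$start,
      end = fm$interval$end,
      width_bp = interval_width(fm$interval),
      map_length_cM = fm$map_length_cM
    ),
    panel = pan[c("n_concordant", "n_total", "perfect", "fisher_p")],
    files = list(
      vcf = "variants.vcf", phenotypes = "phenotypes.tsv",
      site_stats = "site_stats.tsv", window_stats = "window_stats.tsv",
      filter_report = "filter_report.tsv", peaks_bed = "peaks.bed",
      f3_genotypes = "f3_genotypes.tsv",
      finemap_interval = "finemap_interval.bed", panel = "panel.tsv"
    )
  )
  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Replicated parameter-recovery study of the BSA scan
#'
#' Repeats the simulate-and-scan pipeline (F2, bulks, pooled depths,
#' filtering, windows, thresholds, peak calling) across independent seeded
#' replicates at the configured study conditions, recording for each
#' replicate the window-mean statistics at the causal locus and whether
#' the called intervals recover it.
#'
#' @param config A [sim_config()] describing the study conditions.
#' @param n_reps Number of replicates.
#' @param seed Master seed; replicate seeds are derived from it.
#' @param gq_min,window_bp,step_bp,level,threshold_mode,n_sims,ed2_min,merge_gap_bp
#'   Scan parameters as in [run_config()].
#' @return Data frame with one row per replicate: `causal_delta` and
#'   `causal_ed2` (window means at the best window containing the causal
#'   position), `contains_causal` (a called interval on the causal
#'   chromosome covers the causal position), `n_false_chroms` (peaks
#'   called on non-causal chromosomes), `interval_width_bp` (width of the
#'   covering interval, `NA` when none).
#' @export
bsa_power_study <- function(config = sim_config(), n_reps = 50L, seed = 1L,
                            gq_min = 50, window_bp = 200000,
                            step_bp = 100000, level = "99",
                            threshold_mode = "fixed", n_sims = 2000L,
                            ed2_min = 0.5, merge_gap_bp = 500000) {
  causal_chrom <- paste0("chr", config$causal_chrom)
  contigs <- setNames(rep(config$chrom_length_bp, config$n_chromosomes),
                      paste0("chr", seq_len(config$n_chromosomes)))
  out <- lapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(seed, r)
    pop <- simulate_f2(cfg)
    bulks <- build_bulks(pop, seed = derive_seed(cfg$seed, 2L))
    variants <- sample_pool_depths(pop, bulks)
    flt <- filter_variants(variants, gq_min = gq_min)
    sites <- site_stats(flt$variants)
    windows <- sliding_windows(sites, chrom_lengths = contigs,
                               window_bp = window_bp, step_bp = step_bp)
    thr <- bsa_thresholds(windows, sites = sites, mode = threshold_mode,
                          pool_size = cfg$bulk_size, n_sims = n_sims,
                          seed = derive_seed(cfg$seed, 3L),
                          seq_error = cfg$seq_error_rate,
                          window_bp = window_bp, step_bp = step_bp)
    peaks <- call_peaks(windows, thr, level = level, ed2_min = ed2_min,
                        merge_gap_bp = merge_gap_bp)
    at_causal <- windows$chrom == causal_chrom &
      windows$start <= cfg$causal_pos_bp & windows$end >= cfg$causal_pos_bp &
      !is.na(windows$mean_delta)
    best <- which(at_causal)[which.max(windows$mean_delta[at_causal])]
    cover <- peaks$chrom == causal_chrom & peaks$start <= cfg$causal_pos_bp &
      peaks$end >= cfg$causal_pos_bp
    data.frame(
      rep = r,
      n_peaks = nrow(peaks),
      causal_delta = if (any(at_causal)) windows$mean_delta[best] else NA_real_,
      causal_ed2 = if (any(at_causal)) windows$mean_ed2[best] else NA_real_,
      contains_causal = any(cover),
      n_false_chroms = length(unique(peaks$chrom[peaks$chrom != causal_chrom])),
      interval_width_bp = if (any(cover)) {
        interval_width(peaks[which(cover)[1L], ])
      } else {
        NA_real_
      }
    )
  })
  do.call(rbind, out)
}
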