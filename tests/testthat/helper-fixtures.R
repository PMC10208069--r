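# Shared fixtures: all built in code, seeded.

# A small, fast simulation configuration (3 chromosomes) used where the
# full 11-chromosome study conditions are not required.
small_config <- function(seed = 1L, ...) {
  sim_config(
    n_chromosomes = 3L, chrom_length_bp = 10e6, chrom_length_cM = 40,
    n_variants_per_chrom = 150L, n_f2 = 200L, bulk_size = 30L,
    mean_depth = 30, seq_error_rate = 0.01, causal_chrom = 2L,
    causal_pos_bp = 5e6, seed = seed, ...
  )
}

# Hand-built variant table: one row per entry of `spec`, a list of lists
# with per-role gt / ad / gq (defaults: clean segregating site).
make_vt <- function(spec) {
  roles <- c("parent_green", "parent_yellow", "pool_green", "pool_yellow")
  defaults <- list(
    parent_green = list(gt = "0/0", ad = c(30L, 0L), gq = 99L),
    parent_yellow = list(gt = "1/1", ad = c(0L, 30L), gq = 99L),
    pool_green = list(gt = "0/1", ad = c(20L, 10L), gq = 99L),
    pool_yellow = list(gt = "1/1", ad = c(2L, 28L), gq = 99L)
  )
  rows <- lapply(seq_along(spec), function(i) {
    row <- list(chrom = "chr1", pos = i * 1000, ref = "A", alt = "G")
    for (r in roles) {
      s <- utils::modifyList(defaults[[r]], spec[[i]][[r]] %||% list())
      row[[paste0(r, "_gt")]] <- s$gt
      row[[paste0(r, "_ad_ref")]] <- s$ad[1L]
      row[[paste0(r, "_ad_alt")]] <- s$ad[2L]
      row[[paste0(r, "_gq")]] <- s$gq
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  as_variant_table(do.call(rbind, rows), samples = roles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random fuzzed variant table with positive pool depths.
random_vt <- function(n, seed) {
  set.seed(seed)
  spec <- replicate(n, {
    list(
      pool_green = list(ad = c(sample(0:60, 1L), sample(1:60, 1L))),
      pool_yellow = list(ad = c(sample(1:60, 1L), sample(0:60, 1L)))
    )
  }, simplify = FALSE)
  vt <- make_vt(spec)
  vt$chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  vt <- vt[order(vt$chrom, vt$pos), ]
  vt$pos <- ave(vt$pos, vt$chrom, FUN = function(p) sort(sample.int(3e6, length(p))))
  rownames(vt) <- NULL
  as_variant_table(vt, vt_samples(vt))
}

# Naive per-window recomputation of window means (independent oracle for
# sliding_windows): enumerate every window and average sites inside it.
brute_force_windows <- function(stats, chrom_lengths, window_bp, step_bp) {
  out <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    k <- 0:floor((len - 1) / step_bp)
    do.call(rbind, lapply(k, function(kk) {
      lo <- kk * step_bp + 1
      hi <- min(kk * step_bp + window_bp, len)
      inside <- stats$chrom == ch & stats$pos >= lo & stats$pos <= hi
      data.frame(
        chrom = ch, start = lo, end = hi, n_sites = sum(inside),
        mean_delta = if (any(inside)) mean(stats$delta_snp_index[inside]) else NA_real_,
        mean_ed2 = if (any(inside)) mean(stats$ed2[inside]) else NA_real_,
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(out) <- NULL
  out
}
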