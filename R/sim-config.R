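#' Simulation configuration for a biparental F2 mapping study
#'
#' Bundles the genome, population and sequencing parameters used by the
#' simulator.  Defaults describe the study conditions this package is built
#' around: a bitter-gourd-scale genome (11 chromosomes of 30 Mb / 120 cM),
#' an F2 of 241 individuals from two inbred parents, phenotype-selected
#' bulks of 30 plants each sequenced to a mean depth of 53.83x, and a
#' single dominant causal locus at 23.8 Mb on chromosome 6.
#'
#' The causal allele of parent A (the green-stigma parent) is dominant:
#' with `dominance = TRUE` an individual is phenotyped `"green"` iff it
#' carries at least one A allele at the causal locus, `"yellow"` otherwise.
#' Parent B's allele is always written as the VCF ALT allele, which fixes
#' the orientation of the SNP-index to count the yellow-parent allele.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Physical length of each chromosome (bp).
#' @param chrom_length_cM Genetic length of each chromosome (centimorgan).
#' @param n_variants_per_chrom Number of uniformly spaced variants per
#'   chromosome.
#' @param n_f2 Number of F2 individuals.
#' @param bulk_size Number of individuals pooled per phenotype bulk.
#' @param mean_depth Expected sequencing depth per site per sample
#'   (Poisson mean).
#' @param seq_error_rate Per-read probability that the sampled allele is
#'   misread as the other allele; must lie in `[0, 0.5)`.
#' @param causal_chrom Index of the chromosome carrying the causal locus.
#' @param causal_pos_bp Physical position of the causal locus (bp).
#' @param dominance Logical; `TRUE` (default) makes the A allele dominant
#'   (green iff >= 1 A allele), `FALSE` makes it recessive (green iff AA).
#' @param gq_fail_rate Fraction of simulated genotype calls drawn with the
#'   low genotype quality value (GQ 20) instead of the passing value
#'   (GQ 99); exercises the GQ filter deterministically.
#' @param seed Integer seed; all randomness in the simulator flows from
#'   seeds passed explicitly.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_f2 = 50, n_variants_per_chrom = 20, seed = 1)
#' cfg$mean_depth
#' @export
sim_config <- function(n_chromosomes = 11L,
                       chrom_length_bp = 30e6,
                       chrom_length_cM = 120,
                       n_variants_per_chrom = 400L,
                       n_f2 = 241L,
                       bulk_size = 30L,
                       mean_depth = 53.83,
                       seq_error_rate = 0.01,
                       causal_chrom = 6L,
                       causal_pos_bp = 23.8e6,
                       dominance = TRUE,
                       gq_fail_rate = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    chrom_length_cM = as.numeric(chrom_length_cM),
    n_variants_per_chrom = as.integer(n_variants_per_chrom),
    n_f2 = as.integer(n_f2),
    bulk_size = as.integer(bulk_size),
    mean_depth = as.numeric(mean_depth),
    seq_error_rate = as.numeric(seq_error_rate),
    causal_chrom = as.integer(causal_chrom),
    causal_pos_bp = as.numeric(causal_pos_bp),
    dominance = isTRUE(dominance),
    gq_fail_rate = as.numeric(gq_fail_rate),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param x A `sim_config` object.
#' @export
validate_sim_config <- function(x) {
  stopifnot(inherits(x, "sim_config"))
  bad <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  counts <- c(
    n_chromosomes = x$n_chromosomes, n_variants_per_chrom = x$n_variants_per_chrom,
    n_f2 = x$n_f2
  )
  if (any(!is.finite(counts)) || any(counts <= 0L)) {
    bad("all counts must be positive")
  }
  if (x$bulk_size < 0L) bad("bulk_size must be non-negative")
  if (!is.finite(x$chrom_length_bp) || x$chrom_length_bp <= 0) {
    bad("chrom_length_bp must be positive")
  }
  if (!is.finite(x$chrom_length_cM) || x$chrom_length_cM < 0) {
    bad("chrom_length_cM must be non-negative")
  }
  if (!is.finite(x$mean_depth) || x$mean_depth <= 0) bad("mean_depth must be positive")
  if (x$seq_error_rate < 0 || x$seq_error_rate >= 0.5) {
    bad("seq_error_rate must lie in [0, 0.5)")
  }
  if (x$causal_chrom < 1L || x$causal_chrom > x$n_chromosomes) {
    bad("causal_chrom outside the genome")
  }
  if (x$causal_pos_bp < 1 || x$causal_pos_bp > x$chrom_length_bp) {
    bad("causal_pos_bp outside its chromosome")
  }
  if (x$gq_fail_rate < 0 || x$gq_fail_rate > 1) bad("gq_fail_rate must lie in [0, 1]")
  if (is.na(x$seed)) bad("seed must be an integer")
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  genome: %d chromosomes x %.3g Mb (%.4g cM), %d variants/chrom\n",
    x$n_chromosomes, x$chrom_length_bp / 1e6, x$chrom_length_cM,
    x$n_variants_per_chrom
  ))
  cat(sprintf(
    "  population: F2 n=%d, bulks %d+%d, depth %.2fx, error %.3g\n",
    x$n_f2, x$bulk_size, x$bulk_size, x$mean_depth, x$seq_error_rate
  ))
  cat(sprintf(
    "  causal locus: chromosome %d @ %.6g bp (%s), seed %d\n",
    x$causal_chrom, x$causal_pos_bp,
    if (x$dominance) "A dominant" else "A recessive", x$seed
  ))
  invisible(x)
}

# Deterministic derived seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 31 + 1000003 * k) %% 2147483647)
}
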