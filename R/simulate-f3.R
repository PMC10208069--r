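# F3 fine-mapping families and the diagnostic-marker panel.

#' Build a regional marker map for fine mapping
#'
#' Lays out `n_markers` uniformly spaced markers across a physical region
#' with a given genetic length (linear cM within the region), the setting
#' of a regional fine-map where flanking markers from the primary scan
#' bound a candidate interval of ~100 kb.
#'
#' @param chrom Chromosome label.
#' @param start,end Physical bounds of the region (1-based inclusive bp).
#' @param n_markers Number of markers.
#' @param region_cM Genetic length of the region in centimorgan.
#' @param prefix Marker label prefix (default `"ST"`).
#' @return Data frame with `label`, `chrom`, `pos`, `cM`.
#' @examples
#' finemap_markers("chr6", 23740000, 23857840, n_markers = 5, region_cM = 1)
#' @export
finemap_markers <- function(chrom, start, end, n_markers = 21L, region_cM = 1.0,
                            prefix = "ST") {
  stopifnot(end > start, n_markers >= 2L, region_cM >= 0)
  pos <- round(seq(start, end, length.out = n_markers))
  data.frame(
    label = paste0(prefix, seq_len(n_markers)),
    chrom = chrom,
    pos = pos,
    cM = (pos - pos[1L]) / (pos[n_markers] - pos[1L]) * region_cM,
    stringsAsFactors = FALSE
  )
}

# Allele of a parental haplotype (vector over markers) at an arbitrary cM
# position: the allele of the nearest marker (left marker on ties).
.hap_at <- function(hap, marker_cM, at_cM) {
  hap[which.min(abs(marker_cM - at_cM))]
}

#' Simulate an F3 family by selfing a marker-heterozygous F2 plant
#'
#' Offspring are produced by selfing: two independent gametes drawn from
#' the parent's haplotype pair with the same Poisson/Haldane crossover
#' process as [simulate_f2()], restricted to the regional marker map.
#' The default parent is heterozygous across the whole region (one intact
#' haplotype from each grandparent), the configuration of the F2 plants
#' selected for fine-mapping.
#'
#' @param markers Regional marker map from [finemap_markers()] (columns
#'   `label`, `chrom`, `pos`, `cM`).
#' @param n_offspring Number of F3 individuals.
#' @param causal_pos_bp Physical position of the causal locus; must lie
#'   within the marker span.
#' @param seed Integer seed.
#' @param parent_hap1,parent_hap2 Optional integer vectors (0 = A allele,
#'   1 = B allele, one entry per marker) giving the parent's two regional
#'   haplotypes; default is fully heterozygous (all 0 / all 1).
#' @param dominance Passed to [assign_phenotype()].
#' @return A [genotype_matrix()] with codes `A`/`H`/`B` and phenotypes,
#'   plus attribute `causal_pos_bp`.
#' @examples
#' mk <- finemap_markers("chr6", 1e6, 1.1e6, n_markers = 4, region_cM = 1)
#' fam <- simulate_f3_family(mk, n_offspring = 8, causal_pos_bp = 1.05e6, seed = 1)
#' fam$codes
#' @export
simulate_f3_family <- function(markers, n_offspring, causal_pos_bp, seed,
                               parent_hap1 = NULL, parent_hap2 = NULL,
                               dominance = TRUE) {
  m <- nrow(markers)
  stopifnot(m >= 2L, all(diff(markers$pos) > 0))
  if (causal_pos_bp < markers$pos[1L] || causal_pos_bp > markers$pos[m]) {
    stop("causal_pos_bp must lie within the marker span")
  }
  if (is.null(parent_hap1)) parent_hap1 <- rep(0L, m)
  if (is.null(parent_hap2)) parent_hap2 <- rep(1L, m)
  stopifnot(length(parent_hap1) == m, length(parent_hap2) == m)
  if (all(parent_hap1 == parent_hap2)) {
    warning("parent is homozygous at every marker; offspring will be uniform")
  }
  set.seed(seed)
  causal_cM <- stats::approx(markers$pos, markers$cM, xout = causal_pos_bp,
                             rule = 2)$y
  span <- markers$cM[m] - markers$cM[1L]
  query <- c(markers$cM, causal_cM)
  h1c <- c(parent_hap1, .hap_at(parent_hap1, markers$cM, causal_cM))
  h2c <- c(parent_hap2, .hap_at(parent_hap2, markers$cM, causal_cM))

  codes <- matrix(NA_character_, n_offspring, m)
  dosage <- integer(n_offspring)
  k <- length(query)
  for (i in seq_len(n_offspring)) {
    s1 <- .gamete_alleles(query, span)
    s2 <- .gamete_alleles(query, span)
    a1 <- ifelse(s1 == 0L, h1c, h2c)
    a2 <- ifelse(s2 == 0L, h1c, h2c)
    d <- a1 + a2
    dosage[i] <- d[k]
    codes[i, ] <- c("A", "H", "B")[d[-k] + 1L]
  }
  gm <- genotype_matrix(
    ids = sprintf("F3_%04d", seq_len(n_offspring)),
    markers = markers[, c("label", "chrom", "pos")],
    codes = codes,
    phenotype = if (n_offspring > 0L) assign_phenotype(dosage, dominance) else character(0)
  )
  attr(gm, "causal_pos_bp") <- causal_pos_bp
  gm
}

#' Simulate a diagnostic-marker inbred panel
#'
#' Emulates genotyping a panel of inbred lines for a 15 bp diagnostic
#' insertion expected to co-segregate with the yellow phenotype: yellow
#' lines carry the insertion and green lines lack it, except for
#' `discordant` randomly chosen lines whose insertion status is flipped.
#'
#' @param n_green,n_yellow Number of green / yellow phenotype lines.
#' @param discordant Number of lines with flipped insertion status.
#' @param seed Integer seed.
#' @return Data frame with `id`, `phenotype`, `insertion` (logical).
#' @examples
#' simulate_panel(n_green = 3, n_yellow = 2, discordant = 1, seed = 1)
#' @export
simulate_panel <- function(n_green = 26L, n_yellow = 19L, discordant = 0L,
                           seed = 1L) {
  n <- n_green + n_yellow
  stopifnot(n >= 1L, discordant >= 0L, discordant <= n)
  set.seed(seed)
  phenotype <- c(rep("green", n_green), rep("yellow", n_yellow))
  insertion <- phenotype == "yellow"
  flip <- sample.int(n, discordant)
  insertion[flip] <- !insertion[flip]
  data.frame(
    id = sprintf("IL_%02d", seq_len(n)),
    phenotype = phenotype,
    insertion = insertion,
    stringsAsFactors = FALSE
  )
}
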