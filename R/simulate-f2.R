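# F2 population simulation: gametes are produced by a crossover process
# along the genetic map (Haldane model, no interference): the number of
# crossovers per chromosome is Poisson(length_cM / 100) and breakpoints
# fall uniformly on the cM scale.

# Allele carried by one gamete at each queried cM position.  The F1 parent
# haplotypes are the two inbred parental haplotypes, coded 0 (A, green
# parent) and 1 (B, yellow parent), so the allele equals the haplotype
# index after an odd/even number of crossovers.
.gamete_alleles <- function(pos_cM, length_cM) {
  n_x <- rpois(1L, length_cM / 100)
  brk <- if (n_x > 0L) sort(runif(n_x, 0, length_cM)) else numeric(0)
  start <- sample(0:1, 1L)
  as.integer((start + findInterval(pos_cM, brk)) %% 2L)
}

# Variant map shared by all individuals of one simulated study:
# n uniformly spaced biallelic variants per chromosome, REF = green-parent
# base, ALT = yellow-parent base.
.variant_map <- function(config) {
  nv <- config$n_variants_per_chrom
  nc <- config$n_chromosomes
  pos <- round(seq_len(nv) * config$chrom_length_bp / (nv + 1))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv * nc, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  data.frame(
    chrom = rep(paste0("chr", seq_len(nc)), each = nv),
    pos = rep(pos, nc),
    cM = rep(pos / config$chrom_length_bp * config$chrom_length_cM, nc),
    ref = ref,
    alt = unname(alt),
    stringsAsFactors = FALSE
  )
}

#' Simulate an F2 population from two inbred parents
#'
#' Each F2 individual is formed from two independent F1 gametes produced by
#' a Poisson crossover process on the genetic map (Haldane map function, no
#' interference).  Genotypes are stored as the dosage of the B (yellow
#' parent) allele, 0/1/2 for AA/AB/BB.  The phenotype is a deterministic
#' function of the genotype at the causal locus: under dominance, green iff
#' the individual carries at least one A allele.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `f2_pop`: a list with elements
#'   * `ids` — individual labels;
#'   * `variants` — data frame of the variant map (`chrom`, `pos`, `cM`,
#'     `ref`, `alt`);
#'   * `hap1`, `hap2` — integer matrices (individuals x variants) of the
#'     two inherited haplotypes, 0 = A allele, 1 = B allele;
#'   * `geno` — `hap1 + hap2`, the B-allele dosage;
#'   * `causal_dosage` — B dosage at the causal locus itself (which need
#'     not coincide with a variant);
#'   * `phenotype` — `"green"` or `"yellow"` per individual;
#'   * `config` — the configuration used.
#' @examples
#' pop <- simulate_f2(sim_config(n_f2 = 40, n_chromosomes = 2,
#'                               n_variants_per_chrom = 10, causal_chrom = 1,
#'                               seed = 1))
#' table(pop$phenotype)
#' @export
simulate_f2 <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  variants <- .variant_map(config)
  n <- config$n_f2
  m <- nrow(variants)
  hap1 <- matrix(0L, n, m)
  hap2 <- matrix(0L, n, m)
  causal_dosage <- integer(n)
  causal_cM <- config$causal_pos_bp / config$chrom_length_bp * config$chrom_length_cM
  chroms <- unique(variants$chrom)
  causal_chrom <- paste0("chr", config$causal_chrom)
  for (ch in chroms) {
    idx <- which(variants$chrom == ch)
    pos_cM <- variants$cM[idx]
    query <- pos_cM
    has_causal <- identical(ch, causal_chrom)
    if (has_causal) query <- c(pos_cM, causal_cM)
    for (i in seq_len(n)) {
      g1 <- .gamete_alleles(query, config$chrom_length_cM)
      g2 <- .gamete_alleles(query, config$chrom_length_cM)
      if (has_causal) {
        k <- length(query)
        causal_dosage[i] <- g1[k] + g2[k]
        g1 <- g1[-k]
        g2 <- g2[-k]
      }
      hap1[i, idx] <- g1
      hap2[i, idx] <- g2
    }
  }
  phenotype <- assign_phenotype(causal_dosage, config$dominance)
  structure(
    list(
      ids = sprintf("F2_%03d", seq_len(n)),
      variants = variants,
      hap1 = hap1,
      hap2 = hap2,
      geno = hap1 + hap2,
      causal_dosage = causal_dosage,
      phenotype = phenotype,
      config = config
    ),
    class = "f2_pop"
  )
}

# Phenotype from B-allele dosage at the causal locus.
assign_phenotype <- function(dosage, dominance = TRUE) {
  if (dominance) {
    ifelse(dosage <= 1L, "green", "yellow") # >=1 A allele -> green
  } else {
    ifelse(dosage == 0L, "green", "yellow") # A recessive variant model
  }
}

#' @export
print.f2_pop <- function(x, ...) {
  cat(sprintf(
    "<f2_pop> %d individuals, %d variants on %d chromosomes (%s)\n",
    length(x$ids), nrow(x$variants), length(unique(x$variants$chrom)),
    paste(names(table(x$phenotype)), table(x$phenotype),
      sep = "=", collapse = ", "
    )
  ))
  invisible(x)
}

#' Select phenotype-extreme DNA bulks from an F2 population
#'
#' Draws `bulk_size` individuals per phenotype class by simple random
#' sampling without replacement, mirroring the construction of two pooled
#' DNA bulks each mixing equal amounts of DNA from 30 green- and 30
#' yellow-phenotype plants.
#'
#' @param pop An `f2_pop` object.
#' @param bulk_size Individuals per bulk (default from the population's
#'   configuration).
#' @param seed Integer seed.
#' @return A list with character vectors `green` and `yellow` of selected
#'   individual ids (disjoint by construction).
#' @examples
#' pop <- simulate_f2(sim_config(n_f2 = 60, n_chromosomes = 1,
#'                               n_variants_per_chrom = 5, causal_chrom = 1,
#'                               seed = 2))
#' bulks <- build_bulks(pop, bulk_size = 10, seed = 3)
#' lengths(bulks)
#' @export
build_bulks <- function(pop, bulk_size = pop$config$bulk_size, seed = pop$config$seed) {
  stopifnot(inherits(pop, "f2_pop"))
  bulk_size <- as.integer(bulk_size)
  if (bulk_size < 0L) stop("bulk_size must be non-negative")
  set.seed(seed)
  out <- lapply(c(green = "green", yellow = "yellow"), function(ph) {
    members <- pop$ids[pop$phenotype == ph]
    if (length(members) < bulk_size) {
      stop(sprintf(
        "cannot sample a bulk of %d from %d '%s' individuals",
        bulk_size, length(members), ph
      ), call. = FALSE)
    }
    sort(sample(members, bulk_size))
  })
  out
}

#' Sample pooled sequencing depths for the two bulks
#'
#' Generative model for the pooled whole-genome resequencing of the two
#' bulks: at every variant the bulk's B-allele frequency is
#' `f_B = (# B alleles in the bulk) / (2 * bulk_size)`; the total read
#' depth is Poisson(`mean_depth`) and the number of ALT-supporting reads is
#' Binomial(depth, `f_B (1 - e) + (1 - f_B) e`) with sequencing error `e`.
#' The two parents are emitted as fixed homozygotes (`0/0` green, `1/1`
#' yellow).  Genotype qualities are drawn from a two-point mixture (99
#' pass / 20 fail) with mixing fraction `gq_fail_rate`.
#'
#' @param pop An `f2_pop` object.
#' @param bulks A list with `green` and `yellow` id vectors, from
#'   [build_bulks()].
#' @param config A [sim_config()]; defaults to the population's.
#' @param seed Integer seed (defaults to a value derived from the config
#'   seed so the draw does not replay the population's stream).
#' @return A `variant_table` data frame (see [read_vcf()] for the column
#'   layout) with samples `parent_green`, `parent_yellow`, `pool_green`,
#'   `pool_yellow`.
#' @export
sample_pool_depths <- function(pop, bulks, config = pop$config,
                               seed = derive_seed(config$seed, 1L)) {
  stopifnot(inherits(pop, "f2_pop"))
  if (length(bulks$green) == 0L || length(bulks$yellow) == 0L) {
    stop("bulks must be non-empty")
  }
  validate_sim_config(config)
  set.seed(seed)
  m <- nrow(pop$variants)
  e <- config$seq_error_rate
  tab <- pop$variants[, c("chrom", "pos", "ref", "alt")]

  pool_draw <- function(ids) {
    rows <- match(ids, pop$ids)
    f_b <- colSums(pop$geno[rows, , drop = FALSE]) / (2 * length(ids))
    depth <- rpois(m, config$mean_depth)
    f_obs <- f_b * (1 - e) + (1 - f_b) * e
    alt <- rbinom(m, depth, f_obs)
    list(ref = depth - alt, alt = alt, depth = depth)
  }
  call_gt <- function(ref, alt) {
    tot <- ref + alt
    frac <- ifelse(tot > 0L, alt / pmax(tot, 1L), NA_real_)
    ifelse(tot == 0L, "./.",
      ifelse(frac >= 0.9, "1/1", ifelse(frac <= 0.1, "0/0", "0/1"))
    )
  }
  draw_gq <- function() {
    ifelse(runif(m) < config$gq_fail_rate, 20L, 99L)
  }

  dp_pg <- rpois(m, config$mean_depth)
  dp_py <- rpois(m, config$mean_depth)
  g <- pool_draw(bulks$green)
  y <- pool_draw(bulks$yellow)

  tab$parent_green_gt <- ifelse(dp_pg > 0L, "0/0", "./.")
  tab$parent_green_ad_ref <- dp_pg
  tab$parent_green_ad_alt <- 0L
  tab$parent_green_gq <- draw_gq()
  tab$parent_yellow_gt <- ifelse(dp_py > 0L, "1/1", "./.")
  tab$parent_yellow_ad_ref <- 0L
  tab$parent_yellow_ad_alt <- dp_py
  tab$parent_yellow_gq <- draw_gq()
  tab$pool_green_gt <- call_gt(g$ref, g$alt)
  tab$pool_green_ad_ref <- as.integer(g$ref)
  tab$pool_green_ad_alt <- as.integer(g$alt)
  tab$pool_green_gq <- draw_gq()
  tab$pool_yellow_gt <- call_gt(y$ref, y$alt)
  tab$pool_yellow_ad_ref <- as.integer(y$ref)
  tab$pool_yellow_ad_alt <- as.integer(y$alt)
  tab$pool_yellow_gq <- draw_gq()
  as_variant_table(tab, samples = c(
    "parent_green", "parent_yellow",
    "pool_green", "pool_yellow"
  ))
}
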