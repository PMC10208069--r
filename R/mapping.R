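# Segregation testing, regional two-point linkage, recombinant-driven
# fine mapping, and diagnostic-panel concordance.

#' Chi-square test of a Mendelian segregation ratio
#'
#' Pearson goodness-of-fit of observed dominant:recessive counts against
#' an expected ratio (3:1 by default), df = 1, no continuity correction.
#'
#' @param n_dominant,n_recessive Observed class counts.
#' @param ratio Expected ratio, default `c(3, 1)`.
#' @return List with `chi2`, `p_value`, `df`, `expected`.
#' @examples
#' chisq_segregation(191, 50) # chi2 ~ 2.33, p ~ 0.13
#' @export
chisq_segregation <- function(n_dominant, n_recessive, ratio = c(3, 1)) {
  if (n_dominant < 0 || n_recessive < 0) stop("counts must be non-negative")
  if (n_dominant + n_recessive == 0) stop("at least one observation required")
  ht <- suppressWarnings(
    chisq.test(c(n_dominant, n_recessive), p = ratio / sum(ratio),
               correct = FALSE)
  )
  list(
    chi2 = unname(ht$statistic),
    p_value = ht$p.value,
    df = unname(ht$parameter),
    expected = unname(ht$expected)
  )
}

# Known recombinant-gamete counts for the 3x3 F2 two-point classes
# (rows/cols indexed by B dosage 0/1/2); the double heterozygote is
# ambiguous (parental/parental vs recombinant/recombinant) and handled by
# EM.
.REC_COUNT <- matrix(c(0, 1, 2,
                       1, NA, 1,
                       2, 1, 0), 3L, 3L, byrow = TRUE)

# EM estimate of the recombination fraction for one adjacent F2 codominant
# marker pair with known (coupling) phase.
.em_rf <- function(tab, tol = 1e-10, max_iter = 200L) {
  n <- sum(tab)
  if (n == 0L) return(NA_real_)
  known <- sum(tab * .REC_COUNT, na.rm = TRUE)
  n_dh <- tab[2L, 2L]
  r <- 0.25
  for (i in seq_len(max_iter)) {
    e_dh <- if (n_dh > 0L) 2 * r^2 / (r^2 + (1 - r)^2) else 0
    r_new <- (known + n_dh * e_dh) / (2 * n)
    r_new <- min(max(r_new, 1e-12), 0.5)
    if (abs(r_new - r) < tol) {
      r <- r_new
      break
    }
    r <- r_new
  }
  r
}

#' Two-point recombination fractions between adjacent markers
#'
#' Estimates the recombination fraction for every adjacent marker pair of
#' an F2 codominant genotype matrix by EM (the double-heterozygote class
#' mixes parental and double-recombinant gamete pairs), converts to map
#' distance with the Haldane (default) or Kosambi inverse, and sums the
#' finite adjacent distances into a regional map length.  Marker order is
#' taken from physical position; no ordering search is performed.
#'
#' @param gm A [genotype_matrix()] with codominant codes.
#' @param map_function `"haldane"` (d = -50 ln(1 - 2r)) or `"kosambi"`.
#' @return Data frame with one row per adjacent pair: `marker_left`,
#'   `marker_right`, `n` (individuals scored at both), `r`, `cM`
#'   (infinite when r >= 0.5, flagged and excluded from the map length).
#'   The total is attached as attribute `map_length_cM`.
#' @export
recombination_fractions <- function(gm, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  m <- nrow(gm$markers)
  if (m < 2L) stop("at least two markers required")
  dosage <- matrix(match(gm$codes, c("A", "H", "B")) - 1L,
                   nrow = length(gm$ids))
  to_cM <- function(r) {
    if (map_function == "haldane") -50 * log(1 - 2 * r) else 25 * log((1 + 2 * r) / (1 - 2 * r))
  }
  out <- do.call(rbind, lapply(seq_len(m - 1L), function(j) {
    g1 <- dosage[, j]
    g2 <- dosage[, j + 1L]
    ok <- !is.na(g1) & !is.na(g2)
    tab <- matrix(0L, 3L, 3L)
    for (i in which(ok)) tab[g1[i] + 1L, g2[i] + 1L] <- tab[g1[i] + 1L, g2[i] + 1L] + 1L
    r <- .em_rf(tab)
    data.frame(
      marker_left = gm$markers$label[j], marker_right = gm$markers$label[j + 1L],
      n = sum(ok), r = r,
      cM = if (!is.na(r) && r < 0.5) to_cM(r) else Inf,
      stringsAsFactors = FALSE
    )
  }))
  if (any(is.infinite(out$cM))) {
    warning("recombination fraction >= 0.5 for ",
            sum(is.infinite(out$cM)),
            " pair(s); excluded from the map length")
  }
  attr(out, "map_length_cM") <- sum(out$cM[is.finite(out$cM)])
  out
}

#' Find recombinants between two flanking markers
#'
#' Individuals whose (non-missing) genotype codes differ between the two
#' named markers are recombinant between them; each call carries the
#' breakpoint interval(s), localised by scanning all intervening markers
#' for consecutive informative code changes.
#'
#' @param gm A [genotype_matrix()].
#' @param left_marker,right_marker Marker labels present in `gm`.
#' @return Data frame with `id`, `phenotype`, `code_left`, `code_right`
#'   and a list-column `breakpoints` of data frames (`left`, `right`
#'   marker labels bounding each breakpoint).
#' @export
find_recombinants <- function(gm, left_marker, right_marker) {
  j1 <- match(left_marker, gm$markers$label)
  j2 <- match(right_marker, gm$markers$label)
  if (is.na(j1) || is.na(j2)) {
    stop("marker not found: ",
         paste(c(left_marker, right_marker)[c(is.na(j1), is.na(j2))],
               collapse = ", "))
  }
  if (j1 > j2) {
    tmp <- j1
    j1 <- j2
    j2 <- tmp
  }
  c1 <- gm$codes[, j1]
  c2 <- gm$codes[, j2]
  rec <- which(!is.na(c1) & !is.na(c2) & c1 != c2)
  breakpoints <- lapply(rec, function(i) {
    codes <- gm$codes[i, j1:j2]
    inf <- which(!is.na(codes))
    chg <- which(codes[inf][-1L] != codes[inf][-length(inf)])
    data.frame(
      left = gm$markers$label[j1 - 1L + inf[chg]],
      right = gm$markers$label[j1 - 1L + inf[chg + 1L]],
      stringsAsFactors = FALSE
    )
  })
  out <- data.frame(
    id = gm$ids[rec],
    phenotype = if (!is.null(gm$phenotype)) gm$phenotype[rec] else NA_character_,
    code_left = unname(c1[rec]),
    code_right = unname(c2[rec]),
    stringsAsFactors = FALSE
  )
  out$breakpoints <- breakpoints
  out
}

# Consistency of each candidate causal segment with one individual's
# ordered codes and phenotype under the dominant model.  Segments are the
# m marker points and the m-1 open intervals between adjacent markers
# (2m - 1 segments, odd = marker, even = interval).  A position inherits
# the nearest flanking non-missing codes; if the two flanks disagree (a
# crossover interval) or a flank is absent, the genotype is ambiguous and
# cannot exclude the position.
.consistent_segments <- function(codes, phenotype) {
  m <- length(codes)
  seg_geno <- rep(NA_character_, 2L * m - 1L)
  inf <- which(!is.na(codes))
  seg_geno[2L * inf - 1L] <- codes[inf]
  if (length(inf) >= 1L) {
    for (s in which(is.na(seg_geno))) {
      # segment s spans positions (s+1)/2 (marker) or s/2..s/2+1 (interval)
      if (s %% 2L == 1L) {
        j_left <- (s + 1L) / 2L - 1L
        j_right <- (s + 1L) / 2L + 1L
      } else {
        j_left <- s / 2L
        j_right <- s / 2L + 1L
      }
      left <- inf[inf <= j_left]
      right <- inf[inf >= j_right]
      if (length(left) && length(right)) {
        cl <- codes[max(left)]
        cr <- codes[min(right)]
        if (cl == cr) seg_geno[s] <- cl
      }
    }
  }
  if (identical(phenotype, "yellow")) {
    is.na(seg_geno) | seg_geno == "B"
  } else if (identical(phenotype, "green")) {
    is.na(seg_geno) | seg_geno %in% c("A", "H")
  } else {
    rep(TRUE, 2L * m - 1L) # unknown phenotype imposes no constraint
  }
}

#' Delimit the causal interval from recombinant genotypes and phenotypes
#'
#' For every supplied individual, the candidate causal positions
#' consistent with its phenotype under the dominant model (yellow iff BB;
#' green iff AA or AB) are the marker points / marker intervals where its
#' inherited genotype is `B` (yellow) or `A`/`H` (green); intervals whose
#' flanking codes disagree are crossover intervals and cannot exclude a
#' position.  The final interval is the intersection over all individuals,
#' reported as the bounding marker pair (the nearest excluded markers, or
#' the outermost markers) and their physical span.
#'
#' @param recombinants Output of [find_recombinants()], or a character
#'   vector of individual ids; all listed individuals (plus any
#'   non-recombinant informative individuals included) constrain the
#'   interval.
#' @param gm The [genotype_matrix()] holding their codes and phenotypes.
#' @param model Inheritance model; only `"dominant"` is implemented.
#' @return A [genomic_interval()] with extra columns `left_marker`,
#'   `right_marker`, and attribute `n_used` (individuals that imposed at
#'   least one exclusion).
#' @export
delimit_interval <- function(recombinants, gm, model = "dominant") {
  stopifnot(identical(model, "dominant"))
  ids <- if (is.character(recombinants)) recombinants else recombinants$id
  if (is.null(gm$phenotype)) stop("phenotypes required for delimitation")
  m <- nrow(gm$markers)
  consistent <- rep(TRUE, 2L * m - 1L)
  n_used <- 0L
  if (length(ids) == 0L) {
    warning("no recombinants supplied; interval is the full marker span")
  }
  for (id in ids) {
    i <- match(id, gm$ids)
    if (is.na(i)) stop("individual not found: ", id)
    ci <- .consistent_segments(gm$codes[i, ], gm$phenotype[i])
    if (!any(ci)) {
      stop("individual ", id, " is inconsistent with the dominant model ",
           "at every position (phenotyping or genotyping error?)")
    }
    if (!all(ci)) n_used <- n_used + 1L
    updated <- consistent & ci
    if (!any(updated)) {
      stop("empty intersection: individual ", id,
           " conflicts with the interval implied by the others ",
           "(phenotyping/genotyping error or two-locus genetics)")
    }
    consistent <- updated
  }
  s1 <- which(consistent)[1L]
  s2 <- rev(which(consistent))[1L]
  left <- if (s1 %% 2L == 1L) max((s1 + 1L) / 2L - 1L, 1L) else s1 / 2L
  right <- if (s2 %% 2L == 1L) min((s2 + 1L) / 2L + 1L, m) else s2 / 2L + 1L
  iv <- genomic_interval(gm$markers$chrom[1L], gm$markers$pos[left],
                         gm$markers$pos[right])
  iv$left_marker <- gm$markers$label[left]
  iv$right_marker <- gm$markers$label[right]
  attr(iv, "n_used") <- n_used
  iv
}

#' Concordance of a diagnostic marker with phenotype in an inbred panel
#'
#' Scores agreement with the rule "insertion iff yellow" and tests
#' association with a two-sided Fisher exact test on the 2x2
#' phenotype-by-genotype table.  With a degenerate margin (all one
#' phenotype or all one genotype) the Fisher p is reported as 1 with a
#' warning.
#'
#' @param panel Data frame with `phenotype` (`"green"`/`"yellow"`) and
#'   `insertion` (logical), as from [simulate_panel()].
#' @return List with `n_concordant`, `n_total`, `perfect`, `fisher_p`.
#' @examples
#' panel_concordance(simulate_panel(26, 19, discordant = 0, seed = 1))
#' @export
panel_concordance <- function(panel) {
  stopifnot(nrow(panel) >= 1L)
  concordant <- (panel$phenotype == "yellow" & panel$insertion) |
    (panel$phenotype == "green" & !panel$insertion)
  tab <- table(factor(panel$phenotype, c("green", "yellow")),
               factor(panel$insertion, c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    warning("degenerate 2x2 margin; Fisher p reported as 1")
    p <- 1
  } else {
    p <- fisher.test(tab)$p.value
  }
  list(
    n_concordant = sum(concordant),
    n_total = nrow(panel),
    perfect = all(concordant),
    fisher_p = p
  )
}
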