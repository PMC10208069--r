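---
title: "Bulked-segregant mapping of a single dominant locus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulked-segregant mapping of a single dominant locus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkmap)
```

## The problem

A qualitative trait — here, green versus yellow stigma color in a
cucurbit — segregates in an F2 population derived from two inbred
parents, with the green allele dominant.  Bulked-segregant analysis
(BSA-seq) locates the causal locus by pooling DNA from the two phenotypic
extremes (30 plants per bulk), resequencing both pools and both parents,
and scanning the genome for sites where the pooled allele frequencies
diverge.  Fine mapping then narrows the candidate interval using
recombinants from a larger F3 family, and a diagnostic marker is
validated on a panel of unrelated inbred lines.  `bulkmap` implements
this entire workflow, together with a seeded simulator that generates
every input, so the whole analysis is reproducible and testable without
any external data.

## Per-site statistics

With the recessive (yellow) parent's allele written as the VCF ALT
allele, each pool's **SNP-index** at a site is

$$\mathrm{SNP\text{-}index} = \frac{AD_{alt}}{AD_{ref} + AD_{alt}},$$

the fraction of its reads carrying the yellow-parent allele, and

$$\Delta(\mathrm{SNP\text{-}index}) =
  \mathrm{SNP\text{-}index}_{\mathrm{yellow}} -
  \mathrm{SNP\text{-}index}_{\mathrm{green}}.$$

Under phenotype selection with a single dominant locus, the yellow bulk
is fixed for the ALT allele at the causal site (index 1) while the green
class is 1 AA : 2 AB (index 1/3), so the expected peak value of
$\Delta$ is $2/3$; at unlinked sites both indices center on $1/2$ and
$\Delta$ on 0.  The second track is the squared Euclidean distance
between the pools' four-base proportion vectors,

$$ED^2 = \sum_{b \in \{A,C,G,T\}} (p_{b,\mathrm{yellow}} - p_{b,\mathrm{green}})^2,$$

which for a biallelic site equals twice the squared difference in ALT
proportion (peak expectation $(2/3)^2 + (2/3)^2 = 8/9$).  Sites enter
the scan only after filtering: genotype quality at least 50 in all four
samples, parents homozygous for different alleles, and non-zero depth in
both pools — each removed site is attributed to the first failing rule
so the filter report sums exactly to the input count.

Both statistics are averaged in sliding windows of 200 kb advancing in
100 kb steps (1-based inclusive bounds, the last window of each
chromosome truncated).  Windows with fewer than `min_sites` sites are
reported with `NA` means.

## Significance thresholds: a design decision

The confidence-interval construction behind "significant windows" is the
one genuinely open methodological choice, and the package exposes three
modes in `bsa_thresholds()`:

* **`simulate`** — a per-window Monte-Carlo null: bulk genotypes are
  redrawn without phenotype selection, reads resampled at the observed
  per-site depths, and the 95%/99% quantiles of the null |window mean|
  taken.  This null treats sites as independent, but real sites in a
  window — and windows along a chromosome — share the bulks' sampled
  genotype composition, so the null spread shrinks with the site count
  while the real spread does not.  At the study conditions the resulting
  thresholds are exceeded by several percent of truly null windows:
  applied genome-wide they over-call hundreds of kilobases of background.
* **`quantile`** — genome-wide empirical quantiles of the observed
  |window means| (the "top 5% / top 1%" of windows).  This is robust to
  the correlation structure, but when windows hold only a few sites the
  top-1% cut lands *inside* the broadly linked region's own value
  distribution, so the called windows scatter and fragment the single
  true peak.
* **`fixed`** (default for interval calling) — a constant magnitude
  criterion: window-mean $\Delta \ge 0.5$ co-required with window-mean
  $ED^2 \ge 0.5$.  At realistic depths (~54x) and bulk sizes (30), the
  no-linkage null for |window-mean $\Delta$| stays below ~0.4 even at its
  genome-wide maximum, while windows tightly linked to a dominant causal
  locus approach $2/3$; the 0.5 criterion therefore separates the two
  regimes with a margin on both sides.  It is also the conventional
  peak-reporting criterion in BSA-seq practice for strong single loci.

Runs of significant windows that overlap or touch are merged into
candidate intervals; the pipeline additionally bridges sub-threshold
dips of up to 500 kb inside a run (`merge_gap_bp`), well below the
megabase scale over which linkage to a single locus decays, so one locus
is reported as one interval rather than a broken chain.

## The simulator

The generator reproduces the study design rather than any particular
dataset:

* **Genome** — 11 chromosomes of 30 Mb and 120 cM each (a bitter-gourd
  scale genome with a typical plant map density of ~4 cM/Mb), with 400
  uniformly spaced biallelic variants per chromosome so that every 200 kb
  window is populated.
* **Population** — an F2 of 241 from two inbred parents.  Gametes are
  produced by a Poisson crossover process on the cM scale (the Haldane
  model: no crossover interference, the simplest generative choice);
  the causal locus sits at 23.8 Mb on
  chromosome 6 and the phenotype is a deterministic dominance function of
  the causal genotype, giving the expected 3:1 ratio.
* **Bulks and depths** — 30 plants per phenotype class, drawn by simple
  random sampling within class; pool depths are Poisson with mean 53.83,
  ALT reads
  binomial at the bulk allele frequency perturbed by a 1% per-read error.
  Parents are emitted as fixed homozygotes.  Genotype qualities come from
  a two-point 99/20 mixture with a 5% failure fraction, so the GQ >= 50
  filter removes a deterministic, testable slice of sites.
* **F3 fine mapping** — selfing a regionally heterozygous F2 plant:
  21 markers uniformly spanning a 117.84 kb region of 1 cM around the
  causal position, 847 offspring.  At ~1 cM between the outer flanking
  markers the expected recombinant count among 847 selfed offspring is
  in the tens — the scale at which marker-bounded delimitation to a few
  tens of kilobases becomes possible.
* **Panel** — 26 green and 19 yellow inbred lines scored for a
  diagnostic 15 bp insertion, with a configurable number of discordant
  lines (0 by default).

What the simulator does **not** emulate: read-level artifacts
(mapping bias, indel realignment), multi-allelic or clustered variants,
non-uniform marker spacing, segregation distortion, phenotyping error
and two-locus genetics.  Passing tests therefore demonstrate that the
statistics, thresholds and delimitation logic behave correctly under the
study's idealized genetic model — not that the pipeline is robust to
every artifact of real resequencing data.

## Fine-mapping delimitation

`delimit_interval()` treats each candidate causal position (marker
points and the open intervals between adjacent markers) as consistent
with an individual when the genotype it would inherit there — the code
of the nearest flanking non-missing markers, ambiguous when they
disagree — can produce the observed phenotype under the dominant model
(yellow only from BB; green from AA or AB).  The reported interval is
the intersection of consistent regions over all supplied individuals,
bounded by the nearest excluded markers.  Because it is an intersection,
adding recombinants can only keep or shrink the interval, and with
error-free genotypes and phenotypes it always contains the true
position; a conflicting individual (empty intersection) raises an error
naming it rather than voting it down, mirroring the assumption of
error-free scored recombinants.  Heterozygous codes are green-consistent
and yellow-inconsistent; missing codes impose no constraint.

Regional map lengths come from adjacent-pair recombination fractions
estimated by EM for F2 codominant data (the double-heterozygote class
mixes parental and double-recombinant gamete pairs), converted with the
Haldane inverse $d = -50\ln(1-2r)$ (Kosambi available); marker order is
taken from physical position, so no ordering search is performed — a
deliberate replacement for full linkage-map construction, which the
regional setting does not need.

## Numerical choices and degenerate inputs

* Quantiles everywhere use R's default interpolated type, so thresholds
  are deterministic across platforms; ties at a threshold do not flag
  (significance is strict `>`).
* SNP-index and $ED^2$ are undefined at zero pool depth; such sites are
  rejected by the filter and the statistics error rather than return
  `NaN` if handed one.
* An estimated recombination fraction of exactly 0.5 maps to an infinite
  cM distance; it is flagged, warned about and excluded from map-length
  sums.
* Fisher's exact test on a panel with a degenerate margin reports p = 1
  with a warning.
* The EM recombination estimator is clamped to $[10^{-12}, 0.5]$ and
  iterated to $10^{-10}$.
* All randomness flows through explicit integer seeds; derived stage
  seeds stay inside the 32-bit range, and a fixed seed reproduces every
  output byte for byte.

## Expression and coding-sequence utilities

`translate_cds()` applies the standard genetic code, stopping at the
first stop codon and flagging stops before the final codon — the
signature of the 15 bp insertion that truncates the candidate gene's
GLK domain.  `synthetic_aprr2_cds()` builds an *illustrative, synthetic*
allele pair mirroring the reported consequence structure (a clean
1560 bp ORF of 519 aa; a 39 bp in-frame insertion adding 13 residues; a
15 bp stop-carrying insertion that shortens the effective ORF to
1152 bp); the real deposited sequences are not reproduced.
`ddct_fold_change()` implements $2^{-\Delta\Delta C_T}$ relative
expression with replicates paired by index (the standard plate layout)
and a Welch t-test against the calibrator by default — with n = 3
replicates the unequal-variance test is the safer choice, and a pooled
flag is provided.

## Problem sizes used by the test suite

The packaged checks run the full study conditions where the claim is
about the study design (50 scan replicates at n = 241 / 30+30 bulks /
53.83x; 100 fine-mapping replicates at n = 847 with 21 markers; 200
seeds for the Mendelian segregation property) and reduced genomes
(2–4 chromosomes, shallower depth) where only the mechanics of an
operation are under test.  These sizes are the package's own choices,
balancing statistical resolution against a test suite that completes in
about a minute.

## Known limitations

* The significance machinery assumes a single causal locus of full
  penetrance; polygenic or partially penetrant traits will blunt the
  $\Delta$ peak below the fixed criterion.
* The fixed 0.5 criterion is calibrated for dominant selection with
  complete bulks; smaller bulks, weaker selection or recessive scoring
  change both the peak expectation and the null spread, and the
  `quantile`/`simulate` modes should be consulted alongside it.
* Interval delimitation has no tolerance for phenotyping error: one
  mis-scored recombinant either widens the interval silently (if
  consistent) or raises a conflict error (if not).
* The VCF reader supports exactly the biallelic GT:AD:GQ dialect the
  simulator writes; multi-allelic records are skipped, not split.
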