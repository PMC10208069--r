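# CDS-level consequence analysis and qPCR relative expression.

#' Translate a coding sequence
#'
#' Standard genetic code; translation stops at the first stop codon.  A
#' stop before the final codon flags a premature stop (the signature of a
#' frame-preserving insertion carrying an in-frame terminator).  A missing
#' ATG start or a length not divisible by three is flagged, not fatal
#' (trailing bases beyond the last complete codon are ignored).
#'
#' @param cds DNA string over `A`/`C`/`G`/`T` (case-insensitive), or a
#'   list with elements `id` and `seq`.
#' @return List with `protein` (string, stop excluded), `length_aa`,
#'   `premature_stop` (logical), `stop_codon` (1-based codon index of the
#'   first stop, or `NA` if none), `starts_with_atg`, `in_frame`.
#' @examples
#' translate_cds("ATGTAA")    # "M", no premature stop
#' translate_cds("ATGTAAGGG") # premature stop at codon 2
#' @export
translate_cds <- function(cds) {
  seq <- toupper(if (is.list(cds)) cds$seq else cds)
  if (nchar(seq) == 0L) stop("empty coding sequence")
  if (grepl("[^ACGT]", seq)) stop("coding sequence contains non-ACGT characters")
  n_codon <- nchar(seq) %/% 3L
  if (n_codon == 0L) stop("coding sequence shorter than one codon")
  codons <- substring(seq, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_at <- which(aa == "*")[1L]
  length_aa <- if (is.na(stop_at)) n_codon else stop_at - 1L
  list(
    protein = paste(aa[seq_len(length_aa)], collapse = ""),
    length_aa = length_aa,
    premature_stop = !is.na(stop_at) && stop_at < n_codon,
    stop_codon = stop_at,
    starts_with_atg = codons[1L] == "ATG",
    in_frame = nchar(seq) %% 3L == 0L
  )
}

#' Insert a sequence into a CDS
#'
#' Places `insert` immediately after 1-based position `pos` (`pos = 0`
#' prepends).  An insertion of length divisible by three preserves the
#' downstream reading frame, so any premature stop it causes must lie
#' inside the insert or be created at a junction.
#'
#' @param cds DNA string (or list with `seq`).
#' @param pos 1-based offset after which to insert, `0 <= pos <= length`.
#' @param insert DNA string to insert (may be empty).
#' @return The modified sequence (character string).
#' @examples
#' apply_insertion("ATGAAATAA", 3, "CCC")
#' @export
apply_insertion <- function(cds, pos, insert) {
  seq <- if (is.list(cds)) cds$seq else cds
  n <- nchar(seq)
  if (pos < 0 || pos > n) stop("insertion position out of range [0, ", n, "]")
  if (grepl("[^ACGTacgt]", insert)) stop("insert contains non-ACGT characters")
  paste0(substr(seq, 1L, pos), insert, substr(seq, pos + 1L, n))
}

#' Synthetic APRR2-like CDS pair (illustrative)
#'
#' Builds a synthetic stand-in for the two parental alleles of the
#' candidate transcription-factor gene: a clean 1560 bp ORF (519 aa) for
#' the green (functional) allele, and the yellow allele derived from it by
#' two insertions — a 39 bp in-frame insertion near the 5' end (+13
#' residues) and a 15 bp insertion carrying an in-frame TGA placed so the
#' yellow allele's effective ORF is 1152 bp (383 aa + stop).  The real
#' deposited sequences are not reproduced; this fixture only mirrors their
#' reported lengths and consequence structure.
#'
#' @param seed Integer seed for the random non-stop codons.
#' @return List with `green` (1560 bp CDS), `yellow` (both insertions
#'   applied), `insertion_39` and `insertion_15` (each a list with `pos`
#'   on the green allele and `seq`).
#' @export
synthetic_aprr2_cds <- function(seed = 1L) {
  set.seed(seed)
  codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                              c("T", "C", "A", "G")), 1L, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  green <- paste0("ATG", paste(sample(sense, 518L, replace = TRUE), collapse = ""),
                  "TAA")
  ins39 <- list(pos = 99L, seq = paste(rep("GCT", 13L), collapse = ""))
  ins15 <- list(pos = 1110L, seq = "TGATCCGGTTCAGTT")
  with39 <- apply_insertion(green, ins39$pos, ins39$seq)
  yellow <- apply_insertion(with39, ins15$pos + nchar(ins39$seq), ins15$seq)
  list(green = green, yellow = yellow,
       insertion_39 = ins39, insertion_15 = ins15)
}

#' Read / write CDS FASTA
#'
#' Thin wrappers around Biostrings FASTA IO returning plain named
#' character vectors.
#'
#' @param path FASTA path.
#' @return `read_cds_fasta()`: named character vector of sequences.
#' @export
read_cds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_cds_fasta
#' @param seqs Named character vector of DNA sequences.
#' @export
write_cds_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Relative expression by the 2^-ddCt method
#'
#' For every sample, delta-Ct is the target Ct minus the reference-gene Ct
#' with replicates paired by index (the standard plate layout); the
#' delta-delta-Ct is the sample's mean delta-Ct minus the calibrator's,
#' and the fold change is `2^-ddCt`.  Significance against the calibrator
#' uses a two-sided t test on the replicate delta-Ct values — Welch by
#' default, pooled-variance via `var_equal = TRUE`.
#'
#' @param ct Data frame with columns `sample`, `gene` (`"target"` or
#'   `"reference"`) and `ct` (cycles, > 0); replicate order within each
#'   (sample, gene) defines the pairing.
#' @param calibrator Sample label used as the baseline.
#' @param var_equal Use the pooled-variance t test instead of Welch.
#' @return Data frame with `sample`, `n_rep`, `mean_dct`, `ddct`, `fold`,
#'   `p_value` (`NA` for the calibrator itself).
#' @export
ddct_fold_change <- function(ct, calibrator, var_equal = FALSE) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  if (!all(ct$gene %in% c("target", "reference"))) {
    stop("gene must be 'target' or 'reference'")
  }
  samples <- unique(ct$sample)
  if (!calibrator %in% samples) stop("calibrator sample not found: ", calibrator)
  dct <- lapply(setNames(samples, samples), function(s) {
    tg <- ct$ct[ct$sample == s & ct$gene == "target"]
    rf <- ct$ct[ct$sample == s & ct$gene == "reference"]
    if (length(rf) == 0L) stop("missing reference gene for sample ", s)
    if (length(tg) == 0L) stop("missing target gene for sample ", s)
    if (length(tg) != length(rf)) {
      stop("unequal target/reference replicate counts for sample ", s)
    }
    tg - rf
  })
  cal <- dct[[calibrator]]
  out <- do.call(rbind, lapply(samples, function(s) {
    d <- dct[[s]]
    ddct <- mean(d) - mean(cal)
    p <- if (s == calibrator) {
      NA_real_
    } else if (length(d) < 2L || length(cal) < 2L) {
      warning("fewer than 2 replicates; p value unavailable for ", s)
      NA_real_
    } else {
      t.test(d, cal, var.equal = var_equal)$p.value
    }
    data.frame(sample = s, n_rep = length(d), mean_dct = mean(d),
               ddct = ddct, fold = 2^(-ddct), p_value = p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
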