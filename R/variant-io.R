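# Readers/writers for the formats the pipeline touches.  Internal
# coordinates are 1-based inclusive everywhere (the VCF convention); BED
# output converts to 0-based half-open at the boundary.

#' Genomic interval (1-based inclusive)
#'
#' @param chrom Chromosome label.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return A one-row data frame of class `genomic_interval`.
#' @examples
#' iv <- genomic_interval("chr6", 21410000, 26350000)
#' interval_width(iv)
#' @export
genomic_interval <- function(chrom, start, end) {
  if (any(end < start)) stop("interval end < start")
  if (any(start < 1)) stop("interval start must be >= 1")
  structure(
    data.frame(
      chrom = chrom, start = as.numeric(start), end = as.numeric(end),
      stringsAsFactors = FALSE
    ),
    class = c("genomic_interval", "data.frame")
  )
}

#' @rdname genomic_interval
#' @param x A `genomic_interval` (or any data frame with `start`/`end`).
#' @return `interval_width()`: width in bp under the 1-based inclusive
#'   convention, `end - start + 1`.
#' @export
interval_width <- function(x) {
  x$end - x$start + 1
}

#' Construct / validate a variant table
#'
#' A `variant_table` is a data frame with one row per biallelic site:
#' columns `chrom`, `pos`, `ref`, `alt`, and for every sample `s` the four
#' columns `<s>_gt` (genotype string `0/0`, `0/1`, `1/1` or `./.`),
#' `<s>_ad_ref`, `<s>_ad_alt` (allele depths) and `<s>_gq` (genotype
#' quality).  The sample set is carried in the `samples` attribute.
#'
#' @param x Data frame in the layout above.
#' @param samples Character vector of sample names.
#' @return `x` with class `variant_table` and the `samples` attribute set.
#' @export
as_variant_table <- function(x, samples) {
  need <- c("chrom", "pos", "ref", "alt",
            as.vector(outer(samples, c("_gt", "_ad_ref", "_ad_alt", "_gq"),
                            paste0)))
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("variant_table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(x$pos < 1)) stop("variant positions must be >= 1")
  ad <- unlist(x[paste0(rep(samples, each = 2), c("_ad_ref", "_ad_alt"))],
               use.names = FALSE)
  if (any(ad < 0, na.rm = TRUE)) stop("allele depths must be non-negative")
  attr(x, "samples") <- samples
  class(x) <- c("variant_table", "data.frame")
  x
}

#' @rdname as_variant_table
#' @export
vt_samples <- function(x) attr(x, "samples")

#' Write a variant table as VCF 4.2
#'
#' Writes the minimal dialect this package uses: biallelic sites with
#' FORMAT `GT:AD:GQ`.  Missing AD/GQ values are written as `.`.
#'
#' @param x A `variant_table`.
#' @param path Output path.
#' @param contigs Optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, contigs = NULL) {
  samples <- vt_samples(x)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=bulkmap",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs))
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  fmt_num <- function(v) ifelse(is.na(v), ".", as.character(v))
  sample_fields <- lapply(samples, function(s) {
    gt <- x[[paste0(s, "_gt")]]
    gt[is.na(gt)] <- "./."
    ad_r <- x[[paste0(s, "_ad_ref")]]
    ad_a <- x[[paste0(s, "_ad_alt")]]
    ad <- ifelse(is.na(ad_r) | is.na(ad_a), ".",
                 paste0(ad_r, ",", ad_a))
    paste(gt, ad, fmt_num(x[[paste0(s, "_gq")]]), sep = ":")
  })
  body <- do.call(paste, c(
    list(x$chrom, format(x$pos, scientific = FALSE, trim = TRUE), ".",
         x$ref, x$alt, ".", "PASS", ".", "GT:AD:GQ"),
    sample_fields,
    sep = "\t"
  ))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF file into a variant table
#'
#' Parses the subset of VCF 4.2 this package writes: biallelic records
#' with per-sample `GT`, `AD` (ref,alt) and `GQ`.  Multi-allelic records
#' are skipped with a warning and counted in the `n_multiallelic`
#' attribute.  Missing `AD`/`GQ` fields become `NA`.
#'
#' @param path VCF path.
#' @return A `variant_table` (see [as_variant_table()]).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#CHROM\t", lines)
  if (length(hdr_idx) != 1L) stop("malformed VCF: no #CHROM header line")
  fmt_decl <- grepl("^##FORMAT=<ID=(GT|AD|GQ),", lines[seq_len(hdr_idx - 1L)])
  if (sum(fmt_decl) < 3L) {
    stop("malformed VCF header: FORMAT declarations for GT, AD and GQ required")
  }
  cols <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1L]]
  samples <- cols[-(1:9)]
  if (length(samples) == 0L) stop("malformed VCF: no sample columns")
  body <- lines[-seq_len(hdr_idx)]
  body <- body[nzchar(body)]

  empty <- data.frame(
    chrom = character(0), pos = numeric(0), ref = character(0),
    alt = character(0), stringsAsFactors = FALSE
  )
  for (s in samples) {
    empty[[paste0(s, "_gt")]] <- character(0)
    empty[[paste0(s, "_ad_ref")]] <- integer(0)
    empty[[paste0(s, "_ad_alt")]] <- integer(0)
    empty[[paste0(s, "_gq")]] <- integer(0)
  }
  if (length(body) == 0L) {
    return(as_variant_table(empty, samples))
  }

  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L + length(samples))) {
    stop("malformed VCF line ", hdr_idx + which(nf != 9L + length(samples))[1L],
         ": wrong field count")
  }
  mat <- matrix(unlist(parts), ncol = 9L + length(samples), byrow = TRUE)
  multi <- grepl(",", mat[, 5L], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    mat <- mat[!multi, , drop = FALSE]
  }
  if (nrow(mat) == 0L) {
    out <- empty
    attr(out, "n_multiallelic") <- sum(multi)
    return(as_variant_table(out, samples))
  }
  pos <- suppressWarnings(as.numeric(mat[, 2L]))
  if (anyNA(pos)) {
    stop("malformed VCF line ", hdr_idx + which(is.na(pos))[1L],
         ": non-numeric POS")
  }
  out <- data.frame(
    chrom = mat[, 1L], pos = pos, ref = mat[, 4L], alt = mat[, 5L],
    stringsAsFactors = FALSE
  )
  fmt_keys <- strsplit(mat[, 9L], ":", fixed = TRUE)
  for (j in seq_along(samples)) {
    fields <- strsplit(mat[, 9L + j], ":", fixed = TRUE)
    gt <- ad_r <- ad_a <- gq <- rep(NA_character_, nrow(mat))
    for (i in seq_len(nrow(mat))) {
      f <- setNames(fields[[i]], fmt_keys[[i]][seq_along(fields[[i]])])
      gt[i] <- if ("GT" %in% names(f)) f[["GT"]] else "./."
      if ("AD" %in% names(f) && f[["AD"]] != ".") {
        ad <- strsplit(f[["AD"]], ",", fixed = TRUE)[[1L]]
        ad_r[i] <- ad[1L]
        ad_a[i] <- ad[2L]
      }
      if ("GQ" %in% names(f) && f[["GQ"]] != ".") gq[i] <- f[["GQ"]]
    }
    out[[paste0(samples[j], "_gt")]] <- gt
    out[[paste0(samples[j], "_ad_ref")]] <- as.integer(ad_r)
    out[[paste0(samples[j], "_ad_alt")]] <- as.integer(ad_a)
    out[[paste0(samples[j], "_gq")]] <- as.integer(gq)
  }
  attr(out, "n_multiallelic") <- sum(multi)
  as_variant_table(out, samples)
}

#' Write intervals as BED3
#'
#' Converts from the internal 1-based inclusive convention to BED's
#' 0-based half-open coordinates (`start - 1`, `end`).
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' write_bed(genomic_interval("chr6", 21410000, 26350000), f)
#' readLines(f)
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(
    sprintf("%s\t%s\t%s", intervals$chrom,
            format(intervals$start - 1, scientific = FALSE, trim = TRUE),
            format(intervals$end, scientific = FALSE, trim = TRUE)),
    path
  )
  invisible(path)
}

#' Genotype matrix of individuals by ordered markers
#'
#' Codes are `A` (green-parent homozygote), `B` (yellow-parent
#' homozygote), `H` (heterozygote) and `-` / `NA` (missing).  Markers are
#' ordered by strictly increasing physical position.
#'
#' @param ids Individual ids (unique).
#' @param markers Data frame with `label`, `chrom`, `pos` (strictly
#'   increasing).
#' @param codes Character matrix, individuals x markers.
#' @param phenotype Optional character vector (`"green"`/`"yellow"`) per
#'   individual.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(ids, markers, codes, phenotype = NULL) {
  codes[codes == "-"] <- NA_character_
  if (anyDuplicated(ids)) stop("duplicate individual id(s)")
  if (any(diff(markers$pos) <= 0)) stop("marker positions must be strictly increasing")
  bad <- !(codes %in% c("A", "B", "H")) & !is.na(codes)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("unknown genotype code '%s' (individual %s, marker %s)",
                 codes[bad][1L], ids[ij[1L]], markers$label[ij[2L]]))
  }
  if (!is.null(phenotype)) {
    bad_ph <- !(phenotype %in% c("green", "yellow")) & !is.na(phenotype)
    if (any(bad_ph)) {
      stop("unknown phenotype '", phenotype[bad_ph][1L], "' (individual ",
           ids[bad_ph][1L], ")")
    }
  }
  dimnames(codes) <- list(ids, markers$label)
  structure(
    list(ids = ids, markers = markers, codes = codes, phenotype = phenotype),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d markers (%s..%s)\n",
              length(x$ids), nrow(x$markers),
              x$markers$label[1L], x$markers$label[nrow(x$markers)]))
  invisible(x)
}

#' Read / write marker-genotype and phenotype TSV tables
#'
#' The genotype table is tab-delimited with an `id` column followed by one
#' column per marker (codes `A`/`B`/`H`/`-`); marker physical positions
#' are carried in a companion `markers` table or supplied separately.  The
#' phenotype table has columns `id` and `phenotype`.
#'
#' @param path File path.
#' @param markers Data frame with `label`, `chrom`, `pos` for every marker
#'   column in the file.
#' @return `read_genotype_table()`: a [genotype_matrix()];
#'   `read_phenotypes()`: a named character vector of phenotypes.
#' @export
read_genotype_table <- function(path, markers) {
  tab <- read.delim(path, colClasses = "character", check.names = FALSE)
  if (names(tab)[1L] != "id") stop("genotype table must start with an 'id' column")
  labels <- names(tab)[-1L]
  if (!identical(labels, markers$label)) {
    stop("marker columns do not match the supplied marker table")
  }
  codes <- as.matrix(tab[, -1L, drop = FALSE])
  genotype_matrix(ids = tab$id, markers = markers, codes = codes)
}

#' @rdname read_genotype_table
#' @param gm A `genotype_matrix`.
#' @export
write_genotype_table <- function(gm, path) {
  codes <- gm$codes
  codes[is.na(codes)] <- "-"
  out <- data.frame(id = gm$ids, codes, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_genotype_table
#' @export
read_phenotypes <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  if (!all(c("id", "phenotype") %in% names(tab))) {
    stop("phenotype table must have 'id' and 'phenotype' columns")
  }
  if (anyDuplicated(tab$id)) stop("duplicate individual id(s) in phenotype table")
  bad <- !(tab$phenotype %in% c("green", "yellow"))
  if (any(bad)) {
    stop("unknown phenotype '", tab$phenotype[bad][1L], "' at row ",
         which(bad)[1L])
  }
  setNames(tab$phenotype, tab$id)
}

#' @rdname read_genotype_table
#' @param phenotypes Named character vector of phenotypes.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(
    data.frame(id = names(phenotypes), phenotype = unname(phenotypes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
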