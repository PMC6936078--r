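#' Per-SNP allele counts for one sample
#'
#' Container aligning reference-matching (`m`) and non-matching (`n`) read
#' counts to a panel by index.
#'
#' @param sample_id sample identifier.
#' @param m,n non-negative integer vectors of equal length: reads whose base
#'   at the SNP equals the panel reference allele, and reads whose base
#'   differs from it.
#' @return an object of class `allele_counts`.
#' @export
allele_counts <- function(sample_id, m, n) {
  m <- as.integer(m); n <- as.integer(n)
  stopifnot(length(m) == length(n), all(m >= 0), all(n >= 0),
            is.character(sample_id), length(sample_id) == 1L)
  structure(list(sample_id = sample_id, m = m, n = n),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele counts for '%s': %d SNPs, %d covered, mean depth %.2f\n",
              x$sample_id, length(x$m), sum(x$m + x$n > 0),
              mean(x$m + x$n)))
  invisible(x)
}

#' Pileup filters for allele counting
#'
#' @param min_mapping_quality,min_base_quality minimum qualities for a read /
#'   base call to be counted.
#' @param exclude_duplicates,exclude_secondary,exclude_supplementary,exclude_qcfail
#'   skip reads with the corresponding SAM flag.
#' @param max_depth per-site depth cap.
#' @return an object of class `counting_filters`.
#' @export
counting_filters <- function(min_mapping_quality = 0L,
                             min_base_quality = 0L,
                             exclude_duplicates = TRUE,
                             exclude_secondary = TRUE,
                             exclude_supplementary = TRUE,
                             exclude_qcfail = TRUE,
                             max_depth = 100000L) {
  stopifnot(min_mapping_quality >= 0, min_base_quality >= 0, max_depth >= 1)
  structure(list(min_mapping_quality = as.integer(min_mapping_quality),
                 min_base_quality = as.integer(min_base_quality),
                 exclude_duplicates = isTRUE(exclude_duplicates),
                 exclude_secondary = isTRUE(exclude_secondary),
                 exclude_supplementary = isTRUE(exclude_supplementary),
                 exclude_qcfail = isTRUE(exclude_qcfail),
                 max_depth = as.integer(max_depth)),
            class = "counting_filters")
}

# map panel chromosome names onto the alignment header's, tolerating a
# "chr" prefix mismatch; NA where no header sequence matches
normalize_chroms <- function(panel_chroms, header_chroms) {
  out <- ifelse(panel_chroms %in% header_chroms, panel_chroms, NA_character_)
  miss <- is.na(out)
  if (any(miss)) {
    flipped <- ifelse(grepl("^chr", panel_chroms[miss]),
                      sub("^chr", "", panel_chroms[miss]),
                      paste0("chr", panel_chroms[miss]))
    hit <- flipped %in% header_chroms
    if (any(hit))
      warning("normalizing chromosome names to match the alignment header ",
              "(\"chr\" prefix mismatch)", call. = FALSE)
    out[miss][hit] <- flipped[hit]
  }
  out
}

#' Count reference and non-reference reads at panel SNPs
#'
#' Pileup over one alignment file restricted to the panel positions. For each
#' SNP, `m` counts passing reads presenting the panel reference base and `n`
#' counts passing reads presenting any other base (A/C/G/T); reads showing
#' "N", a deletion or a reference skip at the position contribute to neither.
#' Counting any non-reference base toward `n` conflates sequencing errors
#' toward third alleles with true alternate evidence; the homozygous-
#' reference beta prior tolerates that low error fraction. `strict_alt`
#' restricts `n` to the panel alternate base.
#'
#' Chromosome names are reconciled against the alignment header, tolerating a
#' "chr" prefix mismatch with a warning; panel SNPs on chromosomes absent
#' from the header get zero counts with a one-time warning.
#'
#' @param alignment_source path to a coordinate-sorted BAM (or CRAM) with an
#'   index next to it, or a SAM file (converted and indexed on the fly).
#' @param panel a `snp_panel`.
#' @param filters a [counting_filters()] object.
#' @param sample_id sample label; defaults to the file base name.
#' @param strict_alt count only the panel alternate base toward `n`.
#' @return an `allele_counts` object aligned to `panel`.
#' @export
count_alleles <- function(alignment_source, panel,
                          filters = counting_filters(),
                          sample_id = NULL, strict_alt = FALSE) {
  stopifnot(inherits(panel, "snp_panel"), inherits(filters, "counting_filters"))
  if (is.null(sample_id))
    sample_id <- sub("\\.(bam|sam|cram)$", "", basename(alignment_source),
                     ignore.case = TRUE)
  path <- alignment_source
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = TRUE)
  } else {
    idx <- paste0(path, ".bai")
    idx2 <- sub("\\.bam$", ".bai", path, ignore.case = TRUE)
    if (!file.exists(idx) && !file.exists(idx2))
      stop("no index found for '", path,
           "'; the alignment must be coordinate-sorted and indexed")
  }
  bf <- Rsamtools::BamFile(path)
  header_chroms <- names(Rsamtools::scanBamHeader(bf)$targets)
  mapped <- normalize_chroms(panel$chrom, header_chroms)
  if (nrow(panel) > 0 && all(is.na(mapped)))
    stop("no panel chromosome matches the alignment header (panel: ",
         paste(utils::head(unique(panel$chrom), 3), collapse = ", "),
         "; header: ", paste(utils::head(header_chroms, 3), collapse = ", "),
         ")")
  if (anyNA(mapped))
    warning(length(unique(panel$chrom[is.na(mapped)])),
            " panel chromosome(s) absent from the alignment header; ",
            "their SNPs get zero counts", call. = FALSE)
  m <- integer(nrow(panel))
  n <- integer(nrow(panel))
  use <- !is.na(mapped)
  if (any(use)) {
    which_gr <- GenomicRanges::GRanges(
      mapped[use], IRanges::IRanges(start = panel$pos[use], width = 1L))
    flag <- Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = if (filters$exclude_secondary) FALSE else NA,
      isSupplementaryAlignment = if (filters$exclude_supplementary) FALSE else NA,
      isNotPassingQualityControls = if (filters$exclude_qcfail) FALSE else NA,
      isDuplicate = if (filters$exclude_duplicates) FALSE else NA)
    sbp <- Rsamtools::ScanBamParam(which = which_gr, flag = flag)
    pp <- Rsamtools::PileupParam(
      max_depth = filters$max_depth,
      min_base_quality = filters$min_base_quality,
      min_mapq = filters$min_mapping_quality,
      min_nucleotide_depth = 0L,
      distinguish_strands = FALSE,
      distinguish_nucleotides = TRUE,
      ignore_query_Ns = TRUE,
      include_deletions = FALSE,
      include_insertions = FALSE)
    pu <- Rsamtools::pileup(bf, scanBamParam = sbp, pileupParam = pp)
    if (nrow(pu) > 0) {
      key <- paste(as.character(pu$seqnames), pu$pos)
      panel_key <- paste(mapped, panel$pos)
      idx <- match(key, panel_key)
      ok <- !is.na(idx) & pu$nucleotide %in% c("A", "C", "G", "T")
      pu <- pu[ok, , drop = FALSE]
      idx <- idx[ok]
      nuc <- as.character(pu$nucleotide)
      is_ref <- nuc == panel$ref[idx]
      counts_to_n <- if (strict_alt) nuc == panel$alt[idx] else !is_ref
      m_add <- tapply(pu$count[is_ref], idx[is_ref], sum)
      n_add <- tapply(pu$count[counts_to_n], idx[counts_to_n], sum)
      m[as.integer(names(m_add))] <- as.integer(m_add)
      n[as.integer(names(n_add))] <- as.integer(n_add)
    }
  }
  allele_counts(sample_id, m, n)
}

#' Read and write per-SNP count tables
#'
#' The counts TSV carries one row per panel SNP in panel order, with columns
#' chrom, pos, ref, alt, q, m, n, and the sample id in a `#sample=` header
#' comment. `read_counts()` checks the coordinate columns against `panel`
#' when one is supplied.
#'
#' @param counts an `allele_counts` object.
#' @param panel the `snp_panel` the counts are aligned to.
#' @param destination,source file paths.
#' @return `write_counts()` returns the path invisibly; `read_counts()`
#'   returns an `allele_counts` object.
#' @export
write_counts <- function(counts, panel, destination) {
  stopifnot(inherits(counts, "allele_counts"), inherits(panel, "snp_panel"),
            length(counts$m) == nrow(panel))
  con <- file(destination, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#sample=%s", counts$sample_id),
               paste(c("chrom", "pos", "ref", "alt", "q", "m", "n"),
                     collapse = "\t")), con)
  if (nrow(panel) > 0)
    utils::write.table(
      data.frame(panel$chrom, panel$pos, panel$ref, panel$alt,
                 format(panel$q, digits = 17, trim = TRUE),
                 counts$m, counts$n),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(destination)
}

#' @rdname write_counts
#' @export
read_counts <- function(source, panel = NULL) {
  lines <- readLines(source)
  sample_id <- sub("^#sample=", "", grep("^#sample=", lines, value = TRUE)[1])
  if (is.na(sample_id)) sample_id <- basename(source)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "snp_panel"))
    if (nrow(df) != nrow(panel) ||
        !all(df$chrom == panel$chrom & df$pos == panel$pos))
      stop("counts file does not match the supplied panel")
  }
  allele_counts(sample_id, df$m, df$n)
}
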