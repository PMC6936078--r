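#' Construct a SNP panel
#'
#' A SNP panel is the coordinate system of the identity fingerprint: a fixed
#' set of biallelic single-nucleotide variants, each with a population
#' alternate-allele frequency q strictly inside (0, 1). Records are stored
#' coordinate-sorted with no duplicate positions.
#'
#' @param chrom,pos,ref,alt,q,id vectors of equal length: chromosome name,
#'   1-based position, reference and alternate single-nucleotide alleles,
#'   population alternate-allele frequency in (0, 1), and an optional SNP
#'   identifier ("." when absent).
#' @param genome free-text reference build label (e.g. "hg19").
#' @return an object of class `snp_panel` (a data frame).
#' @export
snp_panel <- function(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      q = numeric(), id = rep(".", length(pos)),
                      genome = "unknown") {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   q = as.numeric(q), id = as.character(id),
                   stringsAsFactors = FALSE)
  bad <- validate_snp_records(df)
  if (any(bad != ""))
    stop("invalid SNP record(s): ",
         paste(utils::head(paste0(df$chrom[bad != ""], ":", df$pos[bad != ""],
                                  " (", bad[bad != ""], ")"), 5L),
               collapse = "; "))
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  if (anyDuplicated(df[c("chrom", "pos")]))
    stop("duplicate (chrom, pos) in panel")
  rownames(df) <- NULL
  attr(df, "genome") <- genome
  class(df) <- c("snp_panel", "data.frame")
  df
}

# per-record reason string, "" when valid
validate_snp_records <- function(df) {
  nt <- c("A", "C", "G", "T")
  reason <- character(nrow(df))
  reason[!(df$ref %in% nt) | !(df$alt %in% nt)] <- "alleles must be single nucleotides A/C/G/T"
  reason[reason == "" & df$ref == df$alt] <- "ref and alt alleles identical"
  reason[reason == "" & (is.na(df$q) | df$q <= 0 | df$q >= 1)] <-
    "allele frequency must lie strictly inside (0, 1)"
  reason[reason == "" & (is.na(df$pos) | df$pos < 1)] <- "position must be >= 1"
  reason
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("SNP panel: %d records, genome '%s'\n",
              nrow(x), attr(x, "genome")))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Hash binding fingerprints to a panel
#'
#' Digest of the panel's positions, alleles and frequencies. Fingerprints
#' carry this hash so that comparisons across mismatched panels fail loudly.
#'
#' @param panel a `snp_panel`.
#' @return a character scalar.
#' @export
panel_hash <- function(panel) {
  stopifnot(inherits(panel, "snp_panel"))
  rlang::hash(list(panel$chrom, panel$pos, panel$ref, panel$alt,
                   signif(panel$q, 12)))
}

#' Load a SNP panel from VCF
#'
#' Reads a VCF (plain or bgzipped) whose INFO field carries a population
#' alternate-allele frequency per record, keeping biallelic single-nucleotide
#' records with frequency strictly inside (0, 1). For multiallelic records
#' only the first ALT allele and the first frequency value are considered.
#' Rejected records are reported via warning with the reason.
#'
#' @param vcf_source path to a VCF file.
#' @param af_field INFO key holding the alternate-allele frequency.
#' @param genome reference build label to attach.
#' @return a `snp_panel`.
#' @export
load_panel <- function(vcf_source, af_field = "AF", genome = "unknown") {
  v <- vcfR::read.vcfR(vcf_source, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L)
    return(snp_panel(genome = genome))
  alt_full <- as.character(fix[, "ALT"])
  alt1 <- vapply(strsplit(alt_full, ",", fixed = TRUE),
                 function(x) if (length(x)) x[[1]] else NA_character_,
                 character(1))
  af_raw <- vcfR::extract.info(v, element = af_field)
  af1 <- suppressWarnings(as.numeric(vapply(
    strsplit(ifelse(is.na(af_raw), "", af_raw), ",", fixed = TRUE),
    function(x) if (length(x)) x[[1]] else NA_character_, character(1))))
  df <- data.frame(chrom = as.character(fix[, "CHROM"]),
                   pos = as.integer(fix[, "POS"]),
                   ref = toupper(as.character(fix[, "REF"])),
                   alt = toupper(alt1),
                   q = af1,
                   id = ifelse(is.na(fix[, "ID"]), ".",
                               as.character(fix[, "ID"])),
                   stringsAsFactors = FALSE)
  # records with a parseable record but no AF at all are a hard error: a
  # panel without frequencies cannot drive the genotype priors
  nt <- c("A", "C", "G", "T")
  shape_ok <- df$ref %in% nt & df$alt %in% nt & df$ref != df$alt
  if (any(shape_ok & is.na(df$q))) {
    i <- which(shape_ok & is.na(df$q))[1]
    stop("record ", df$chrom[i], ":", df$pos[i], " has no '", af_field,
         "' INFO value; every panel record needs an allele frequency")
  }
  reason <- validate_snp_records(df)
  if (any(reason != "")) {
    drop <- reason != ""
    warning(sum(drop), " record(s) rejected: ",
            paste(utils::head(paste0(df$chrom[drop], ":", df$pos[drop], " - ",
                                     reason[drop]), 5L), collapse = "; "),
            call. = FALSE)
    df <- df[!drop, , drop = FALSE]
  }
  if (is.unsorted(order(df$chrom, df$pos)) &&
      !identical(order(df$chrom, df$pos), seq_len(nrow(df))))
    warning("input VCF not coordinate-sorted; sorting", call. = FALSE)
  snp_panel(df$chrom, df$pos, df$ref, df$alt, df$q, df$id, genome = genome)
}

#' Write a SNP panel to VCF
#'
#' Emits a minimal VCFv4.2 file with the allele frequency in the INFO column,
#' such that [load_panel()] round-trips all fields.
#'
#' @param panel a `snp_panel`.
#' @param destination output path.
#' @param af_field INFO key to write the frequency under.
#' @return `destination`, invisibly.
#' @export
write_panel <- function(panel, destination, af_field = "AF") {
  stopifnot(inherits(panel, "snp_panel"))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##reference=%s", attr(panel, "genome")),
    sprintf(paste0("##INFO=<ID=%s,Number=A,Type=Float,",
                   "Description=\"Alternate allele frequency\">"), af_field),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(panel) > 0) {
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s=%s",
            panel$chrom, panel$pos, panel$id, panel$ref, panel$alt,
            af_field, format(panel$q, digits = 17, scientific = FALSE,
                             trim = TRUE))
  } else character()
  writeLines(c(header, body), destination)
  invisible(destination)
}

#' Load capture regions from BED
#'
#' Reads a BED3+ file (0-based half-open intervals), drops malformed
#' intervals with a warning, and returns the merged, sorted region set as a
#' `GRanges`.
#'
#' @param bed_source path to a BED file.
#' @return a `GRanges` of disjoint, sorted intervals.
#' @export
load_regions <- function(bed_source) {
  lines <- readLines(bed_source)
  lines <- lines[nzchar(trimws(lines)) &
                 !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  raw <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE)[, 1:3]
  names(raw) <- c("chrom", "start", "end")
  raw$start <- as.numeric(raw$start)
  raw$end <- as.numeric(raw$end)
  bad <- raw$start >= raw$end
  if (any(bad)) {
    warning(sum(bad), " interval(s) with start >= end rejected",
            call. = FALSE)
    raw <- raw[!bad, , drop = FALSE]
  }
  if (nrow(raw) == 0L) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(raw$chrom,
                               IRanges::IRanges(start = raw$start + 1,
                                                end = raw$end))
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

empty_region_set <- function() GenomicRanges::GRanges()

panel_granges <- function(panel) {
  GenomicRanges::GRanges(panel$chrom,
                         IRanges::IRanges(start = panel$pos, width = 1L))
}

#' Select a fingerprint panel from candidate SNPs
#'
#' Applies the three panel-design rules: (i) keep candidates with population
#' alternate-allele frequency strictly between `min_af` and `max_af` (common
#' SNPs are the informative ones); (ii) keep candidates inside the supplied
#' capture region sets, requiring membership in all sets (`region_mode =
#' "all"`, maximizing the chance of coverage across assay types) or in any
#' one (`"any"`); (iii) thin the survivors so that no two retained SNPs on a
#' chromosome are closer than `min_spacing`, to suppress linkage
#' disequilibrium between panel SNPs.
#'
#' Thinning is exact and deterministic: per chromosome a dynamic program
#' retains the spacing-feasible subset that maximizes the number of SNPs
#' and, among those, minimizes the total distance of the allele frequencies
#' from 1/2 (ties broken toward lower coordinates) - when two SNPs conflict,
#' the one with frequency closest to 1/2 survives, since it carries the most
#' identity information per read.
#'
#' @param candidates a `snp_panel` of candidate SNPs.
#' @param region_sets list of `GRanges` from [load_regions()]; empty list
#'   disables the region filter.
#' @param min_af,max_af open allele-frequency window, defaults (0.1, 0.9).
#' @param min_spacing minimum distance in bp between retained SNPs on one
#'   chromosome, default 100 kb.
#' @param region_mode `"all"` (intersection of region sets) or `"any"`
#'   (union).
#' @return a `snp_panel` satisfying the window, region and spacing rules.
#' @export
select_panel <- function(candidates, region_sets = list(),
                         min_af = 0.1, max_af = 0.9,
                         min_spacing = 100000L,
                         region_mode = c("all", "any")) {
  stopifnot(inherits(candidates, "snp_panel"), min_af < max_af)
  region_mode <- match.arg(region_mode)
  keep <- candidates$q > min_af & candidates$q < max_af
  df <- candidates[keep, , drop = FALSE]
  if (length(region_sets) > 0 && nrow(df) > 0) {
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(start = df$pos, width = 1L))
    hits <- vapply(region_sets, function(rs)
      IRanges::overlapsAny(gr, rs), logical(nrow(df)))
    if (nrow(df) == 1L) hits <- matrix(hits, nrow = 1L)
    inside <- if (region_mode == "all") rowSums(hits) == length(region_sets)
              else rowSums(hits) > 0
    df <- df[inside, , drop = FALSE]
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  kept <- unlist(lapply(split(seq_len(nrow(df)), df$chrom), function(idx) {
    idx[thin_by_spacing(df$pos[idx], df$q[idx], min_spacing)]
  }), use.names = FALSE)
  df <- df[sort(kept), , drop = FALSE]
  if (nrow(df) == 0L)
    warning("panel selection produced no SNPs", call. = FALSE)
  out <- snp_panel(df$chrom, df$pos, df$ref, df$alt, df$q, df$id,
                   genome = attr(candidates, "genome"))
  out
}

# Exact spacing thinning by dynamic programming over positions sorted
# ascending: among all subsets with consecutive retained positions >=
# min_spacing apart, retain the one maximizing the count and, among those,
# minimizing the total distance of the frequencies from 1/2 (ties broken
# toward earlier positions). Linear scan with a prefix-best pointer since
# the eligible predecessors of each SNP form a prefix.
thin_by_spacing <- function(pos, q, min_spacing) {
  n <- length(pos)
  if (n <= 1L) return(rep(TRUE, n))
  pen <- abs(q - 0.5)
  cnt <- integer(n); tot <- numeric(n); prev <- integer(n)
  better <- function(c1, t1, c2, t2) c1 > c2 || (c1 == c2 && t1 < t2)
  bp <- 0L   # best chain end among the eligible prefix
  j <- 0L
  for (i in seq_len(n)) {
    while (j + 1L <= n && pos[j + 1L] <= pos[i] - min_spacing) {
      j <- j + 1L
      if (bp == 0L || better(cnt[j], tot[j], cnt[bp], tot[bp])) bp <- j
    }
    if (bp > 0L) {
      cnt[i] <- cnt[bp] + 1L; tot[i] <- tot[bp] + pen[i]; prev[i] <- bp
    } else {
      cnt[i] <- 1L; tot[i] <- pen[i]; prev[i] <- 0L
    }
  }
  end <- 1L
  for (i in seq_len(n)[-1L])
    if (better(cnt[i], tot[i], cnt[end], tot[end])) end <- i
  keep <- rep(FALSE, n)
  while (end > 0L) {
    keep[end] <- TRUE
    end <- prev[end]
  }
  keep
}
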