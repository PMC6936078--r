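#' Simulation configuration
#'
#' Describes a synthetic cohort matching the statistical assumptions of the
#' identity model: Hardy-Weinberg genotypes at panel allele frequencies,
#' per-SNP read depth from a Poisson (or negative-binomial, emulating
#' expression-driven coverage heterogeneity in RNA-Seq) distribution, and
#' binomially sampled alternate reads with a symmetric per-base miscall
#' probability.
#'
#' @param n_snps number of panel SNPs.
#' @param af_range open interval the panel allele frequencies are drawn
#'   uniformly from; default (0.1, 0.9), the window common fingerprint SNPs
#'   are selected in.
#' @param n_individuals number of unrelated individuals.
#' @param samples_per_individual replicate samples per individual.
#' @param mean_coverage mean reads per SNP per sample.
#' @param coverage_model `"poisson"` or `"negative_binomial"`.
#' @param coverage_dispersion negative-binomial dispersion (size parameter is
#'   `1 / coverage_dispersion`); ignored for Poisson.
#' @param error_rate per-read probability of presenting the wrong allele,
#'   in [0, 0.5); default 0.01, consistent with the Beta(1, 30) homozygous
#'   prior whose mean error tolerance is about 0.032.
#' @param seed master seed; all per-operation seeds are derived from it
#'   deterministically.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_snps = 6000L, af_range = c(0.1, 0.9),
                       n_individuals = 20L, samples_per_individual = 2L,
                       mean_coverage = 5, coverage_model = c("poisson",
                                                             "negative_binomial"),
                       coverage_dispersion = 0.5, error_rate = 0.01,
                       seed = 1L) {
  coverage_model <- match.arg(coverage_model)
  stopifnot(n_snps >= 1, n_individuals >= 1, samples_per_individual >= 1,
            mean_coverage >= 0, error_rate >= 0, error_rate < 0.5,
            length(af_range) == 2L, af_range[1] > 0, af_range[2] < 1,
            af_range[1] <= af_range[2])
  structure(list(n_snps = as.integer(n_snps), af_range = af_range,
                 n_individuals = as.integer(n_individuals),
                 samples_per_individual = as.integer(samples_per_individual),
                 mean_coverage = mean_coverage,
                 coverage_model = coverage_model,
                 coverage_dispersion = coverage_dispersion,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# run expr under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic child seed, kept inside 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Simulate a SNP panel
#'
#' Places `n_snps` SNPs on synthetic chromosomes (500 SNPs per chromosome)
#' with consecutive SNPs at least `spacing` apart, alleles drawn at random
#' and allele frequencies uniform on `af_range`.
#'
#' @param n_snps number of SNPs.
#' @param af_range open allele-frequency interval to draw from.
#' @param seed RNG seed.
#' @param spacing minimum distance between neighbouring SNPs, default 100 kb.
#' @return a `snp_panel`.
#' @export
simulate_panel <- function(n_snps, af_range = c(0.1, 0.9), seed = 1L,
                           spacing = 100000L) {
  stopifnot(n_snps >= 1)
  with_seed(seed, {
    per_chrom <- 500L
    chrom_idx <- (seq_len(n_snps) - 1L) %/% per_chrom + 1L
    within <- (seq_len(n_snps) - 1L) %% per_chrom + 1L
    pos <- as.integer(1000L + (within - 1L) * (spacing + 1000L) +
                        sample.int(1000L, n_snps, replace = TRUE))
    nt <- c("A", "C", "G", "T")
    ref <- sample(nt, n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1))
    q <- runif(n_snps, af_range[1], af_range[2])
    if (af_range[1] == af_range[2]) q <- rep(af_range[1], n_snps)
    snp_panel(sprintf("sim%d", chrom_idx), pos, ref, alt, q,
              sprintf("snp%06d", seq_len(n_snps)), genome = "synthetic")
  })
}

#' Simulate genotypes
#'
#' `simulate_individual()` draws one genotype per panel SNP from the
#' Hardy-Weinberg proportions ((1-q)^2, 2q(1-q), q^2) at that SNP's allele
#' frequency. `simulate_child()` applies Mendelian transmission: at each SNP
#' the child receives one uniformly chosen allele from each parent.
#' Genotypes are encoded as the alternate-allele dose 0 (WW), 1 (WA), 2 (AA).
#'
#' @param panel a `snp_panel`.
#' @param seed RNG seed.
#' @return an integer vector of alternate-allele doses over the panel.
#' @export
simulate_individual <- function(panel, seed = 1L) {
  stopifnot(inherits(panel, "snp_panel"))
  with_seed(seed, {
    u <- runif(nrow(panel))
    p_ww <- (1 - panel$q)^2
    p_wa <- 2 * panel$q * (1 - panel$q)
    as.integer((u >= p_ww) + (u >= p_ww + p_wa))
  })
}

#' @rdname simulate_individual
#' @param parent_a,parent_b parental genotype vectors over the same panel.
#' @export
simulate_child <- function(parent_a, parent_b, seed = 1L) {
  stopifnot(length(parent_a) == length(parent_b))
  with_seed(seed, {
    allele_a <- rbinom(length(parent_a), 1L, parent_a / 2)
    allele_b <- rbinom(length(parent_b), 1L, parent_b / 2)
    as.integer(allele_a + allele_b)
  })
}

#' Simulate read counts for one sample
#'
#' Per SNP the depth is drawn from the configured coverage model, and the
#' non-reference read count is Binomial(depth, p) with p equal to
#' `error_rate` for WW, 1/2 for WA and `1 - error_rate` for AA: sequencing
#' is a binomial process around the genotype's apparent alternate-allele
#' fraction.
#'
#' @param genotypes integer dose vector from [simulate_individual()].
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param sample_id label for the resulting counts.
#' @return an `allele_counts` object.
#' @export
simulate_counts <- function(genotypes, config, seed = 1L,
                            sample_id = "sim_sample") {
  stopifnot(inherits(config, "sim_config"),
            all(genotypes %in% 0:2))
  n_snps <- length(genotypes)
  with_seed(seed, {
    depth <- if (config$mean_coverage == 0) {
      integer(n_snps)
    } else if (config$coverage_model == "poisson") {
      rpois(n_snps, config$mean_coverage)
    } else {
      rnbinom(n_snps, size = 1 / config$coverage_dispersion,
              mu = config$mean_coverage)
    }
    p_alt <- c(config$error_rate, 0.5, 1 - config$error_rate)[genotypes + 1L]
    n <- rbinom(n_snps, depth, p_alt)
    allele_counts(sample_id, depth - n, n)
  })
}

#' Simulate a labeled cohort
#'
#' Generates a panel, genotypes for unrelated individuals (plus optional
#' nuclear families), and `samples_per_individual` independent count sets per
#' individual, recording the sample-to-individual truth labels and any
#' pedigree edges. All randomness derives from `config$seed`, so cohorts are
#' reproducible component-wise.
#'
#' @param config a [sim_config()]; `n_individuals` counts only the unrelated
#'   individuals, family members are additional.
#' @param n_families number of nuclear families (mother, father, children)
#'   to append.
#' @param children_per_family children per family.
#' @param panel optionally reuse an existing `snp_panel` instead of
#'   simulating one.
#' @return an object of class `sim_cohort`: list with `panel`, `counts`
#'   (named list of `allele_counts`), `truth` (a [truth_labels()]),
#'   `genotypes` (individuals x SNPs integer matrix), `pedigree` (data frame
#'   of child, mother, father ids; NULL without families) and `config`.
#' @export
simulate_cohort <- function(config, n_families = 0L, children_per_family = 2L,
                            panel = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(panel))
    panel <- simulate_panel(config$n_snps, config$af_range,
                            seed = child_seed(config$seed, 0L))
  ind_ids <- sprintf("ind%02d", seq_len(config$n_individuals))
  genotypes <- lapply(seq_along(ind_ids), function(i)
    simulate_individual(panel, seed = child_seed(config$seed, i)))
  names(genotypes) <- ind_ids
  pedigree <- NULL
  if (n_families > 0) {
    ped <- list()
    for (f in seq_len(n_families)) {
      base <- 10000L + f * 100L
      mo <- sprintf("fam%02d_mother", f)
      fa <- sprintf("fam%02d_father", f)
      genotypes[[mo]] <- simulate_individual(
        panel, seed = child_seed(config$seed, base + 1L))
      genotypes[[fa]] <- simulate_individual(
        panel, seed = child_seed(config$seed, base + 2L))
      for (k in seq_len(children_per_family)) {
        ch <- sprintf("fam%02d_child%d", f, k)
        genotypes[[ch]] <- simulate_child(
          genotypes[[mo]], genotypes[[fa]],
          seed = child_seed(config$seed, base + 2L + k))
        ped[[length(ped) + 1L]] <- data.frame(
          child = ch, mother = mo, father = fa, stringsAsFactors = FALSE)
      }
    }
    pedigree <- do.call(rbind, ped)
  }
  all_ids <- names(genotypes)
  counts <- list()
  truth_s <- character()
  truth_i <- character()
  k <- 0L
  for (id in all_ids) {
    for (s in seq_len(config$samples_per_individual)) {
      k <- k + 1L
      sid <- sprintf("%s_s%d", id, s)
      counts[[sid]] <- simulate_counts(
        genotypes[[id]], config, seed = child_seed(config$seed, 20000L + k),
        sample_id = sid)
      truth_s <- c(truth_s, sid)
      truth_i <- c(truth_i, id)
    }
  }
  gmat <- do.call(rbind, genotypes)
  rownames(gmat) <- all_ids
  structure(list(panel = panel, counts = counts,
                 truth = truth_labels(truth_s, truth_i),
                 genotypes = gmat, pedigree = pedigree, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "simulated cohort: %d SNPs, %d individuals, %d samples%s\n",
    nrow(x$panel), nrow(x$genotypes), length(x$counts),
    if (is.null(x$pedigree)) "" else
      sprintf(", %d pedigree children", nrow(x$pedigree))))
  invisible(x)
}

#' Emit alignment fixtures reproducing a cohort's counts
#'
#' Writes a synthetic reference FASTA and, per sample, a coordinate-sorted,
#' indexed BAM whose pileup at every panel SNP reproduces the cohort's
#' (m, n) exactly: m reads carry the reference base and n reads the
#' alternate base at the SNP, as 50 bp single-end reads centered on the SNP
#' with mapping quality 60 and base quality 30. Intended for fixture-scale
#' panels (tens of SNPs). With `decoy_duplicates`, extra duplicate-flagged
#' alternate-carrying reads are added at every SNP; they must not change the
#' counts when duplicate filtering is on.
#'
#' @param cohort a `sim_cohort`.
#' @param destination output directory (created if needed).
#' @param read_length read length in bp.
#' @param decoy_duplicates add duplicate-flagged decoy reads.
#' @return list with `reference` (FASTA path) and `bam` (named vector of BAM
#'   paths).
#' @export
emit_alignments <- function(cohort, destination, read_length = 50L,
                            decoy_duplicates = FALSE) {
  stopifnot(inherits(cohort, "sim_cohort"))
  panel <- cohort$panel
  if (!dir.exists(destination)) dir.create(destination, recursive = TRUE)
  chroms <- unique(panel$chrom)
  chrom_len <- vapply(chroms, function(cc)
    max(panel$pos[panel$chrom == cc]) + read_length + 10L, numeric(1))
  # reference: uniform background with the panel reference base planted at
  # each SNP; only the base at the SNP matters for pileup counting
  ref_path <- file.path(destination, "reference.fa")
  con <- file(ref_path, "w")
  for (cc in chroms) {
    seq <- rep("A", chrom_len[[cc]])
    on_c <- panel$chrom == cc
    seq[panel$pos[on_c]] <- panel$ref[on_c]
    writeLines(c(paste0(">", cc),
                 vapply(split(seq, ceiling(seq_along(seq) / 70)),
                        paste0, character(1), collapse = "")), con)
  }
  close(con)
  half <- read_length %/% 2L
  bams <- character()
  for (sid in names(cohort$counts)) {
    cts <- cohort$counts[[sid]]
    sam_path <- file.path(destination, paste0(sid, ".sam"))
    con <- file(sam_path, "w")
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 sprintf("@SQ\tSN:%s\tLN:%d", chroms,
                         as.integer(chrom_len[chroms])),
                 sprintf("@RG\tID:%s\tSM:%s", sid, sid)), con)
    rn <- 0L
    for (i in seq_len(nrow(panel))) {
      depth <- cts$m[i] + cts$n[i]
      n_decoy <- if (decoy_duplicates) 2L else 0L
      if (depth + n_decoy == 0L) next
      start <- max(1L, panel$pos[i] - half)
      offset <- panel$pos[i] - start + 1L
      base_read <- rep("A", read_length)
      make_read <- function(base, flag) {
        rd <- base_read
        rd[offset] <- base
        rn <<- rn + 1L
        sprintf("r%06d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                rn, flag, panel$chrom[i], start, read_length,
                paste0(rd, collapse = ""),
                paste0(rep("?", read_length), collapse = ""))
      }
      lines <- c(
        vapply(seq_len(cts$m[i]), function(j)
          make_read(panel$ref[i], 0L), character(1)),
        vapply(seq_len(cts$n[i]), function(j)
          make_read(panel$alt[i], 0L), character(1)),
        vapply(seq_len(n_decoy), function(j)
          make_read(panel$alt[i], 1024L), character(1)))
      writeLines(lines, con)
    }
    close(con)
    bam <- Rsamtools::asBam(sam_path, file.path(destination, sid),
                            overwrite = TRUE, indexDestination = TRUE)
    unlink(sam_path)
    bams[sid] <- bam
  }
  list(reference = ref_path, bam = bams)
}

#' Write cohort artifacts to a directory
#'
#' Emits the panel VCF, one counts TSV per sample and the truth labels TSV.
#'
#' @param cohort a `sim_cohort`.
#' @param destination output directory.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, destination) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(destination)) dir.create(destination, recursive = TRUE)
  write_panel(cohort$panel, file.path(destination, "panel.vcf"))
  for (sid in names(cohort$counts))
    write_counts(cohort$counts[[sid]], cohort$panel,
                 file.path(destination, paste0(sid, ".counts.tsv")))
  utils::write.table(
    data.frame(sample_id = cohort$truth$sample_id,
               individual_id = cohort$truth$individual_id),
    file.path(destination, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$pedigree))
    utils::write.table(cohort$pedigree,
                       file.path(destination, "pedigree.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(destination)
}
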