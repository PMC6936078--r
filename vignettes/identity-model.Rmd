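---
title: "The snpmatchr identity model: evidence, priors, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The snpmatchr identity model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmatchr)
```

## The problem

Sample swaps and mislabelings are a persistent failure mode of sequencing
studies: two libraries that are supposed to come from the same patient (say,
a tumor RNA-Seq and a matched exome) may in fact derive from different
individuals, and vice versa. `snpmatchr` decides, for any two aligned
sequencing samples, whether they derive from the same human individual. It
does so without genotype calling: it counts, at a fixed panel of common
SNPs, how many reads match the reference base and how many do not, and feeds
those counts into a small Bayesian model. Because the panel is fixed, each
sample reduces to a reusable *fingerprint* and any two fingerprints can be
compared later without touching the alignments again.

## The model

At SNP $s$ with population alternate-allele frequency $q_s$, let $m_s$ be
the number of reads matching the reference base and $n_s$ the number not
matching it. Sequencing is modeled as a binomial process around a latent
apparent alternate-allele fraction $f$:

$$P(m, n \mid f) = \binom{n+m}{n} f^n (1-f)^m.$$

The fraction $f$ depends on the genotype $h \in \{WW, WA, AA\}$ (homozygous
wild type, heterozygous, homozygous alternate): near 0 for $WW$ (but not
exactly 0, because of sequencing error), near $1/2$ for $WA$, near 1 for
$AA$. Each genotype gets a beta prior $f \mid h \sim
\mathrm{Beta}(\alpha_h, \beta_h)$ with defaults

| genotype | $\alpha_h$ | $\beta_h$ | prior mean of $f$ |
|----------|-----------:|----------:|------------------:|
| WW       | 1          | 30        | 0.032             |
| WA       | 2          | 2         | 0.5               |
| AA       | 30         | 1         | 0.968             |

The $\mathrm{Beta}(1, 30)$ shape says: a homozygous-reference sample is
expected to show a few percent of non-reference reads, which is what
Illumina-scale error rates produce. Integrating $f$ out analytically gives
the per-genotype evidence

$$Q(m, n \mid h) = \binom{n+m}{n}
  \frac{B(\alpha_h + n, \beta_h + m)}{B(\alpha_h, \beta_h)},$$

computed in `log_evidence()` via log-gamma, stable to depths beyond $10^6$.
The binomial coefficient is identical across genotypes and across the two
hypotheses below, so it cancels; `snpmatchr` drops it by default
(`model_params(keep_binomial = TRUE)` restores it, and a test asserts the
posterior is unchanged to $10^{-12}$ relative).

Two samples either come from the same individual ($x = I$, prior $\pi_I$,
default 0.01) or from different individuals ($x = D$). Under $x = I$ both
samples share one genotype drawn from the Hardy-Weinberg proportions
$v = ((1-q)^2,\, 2q(1-q),\, q^2)$; under $x = D$ the genotypes are two
independent Hardy-Weinberg draws. Arranging the evidence values of the two
samples into $\widehat Q_{h,h'} = Q(m,n \mid h)\, Q(m',n' \mid h')$ and the
genotype-pair priors into $\widehat I = \mathrm{diag}(v)$ and
$\widehat D = v v^\top$, the posterior probability of identity is

$$\Pr\{x = I \mid \text{data}\} =
  \frac{\pi_I \prod_s \mathrm{Tr}(\widehat Q_s \widehat I_s)}
       {\pi_D \prod_s \mathrm{Tr}(\widehat Q_s \widehat D_s) +
        \pi_I \prod_s \mathrm{Tr}(\widehat Q_s \widehat I_s)}.$$

Two identities make this cheap: $\mathrm{Tr}(\widehat Q \widehat I) =
\sum_h Q_a(h) Q_b(h) v_h$, and $\mathrm{Tr}(\widehat Q \widehat D) =
\left(\sum_h Q_a(h) v_h\right)\left(\sum_h Q_b(h) v_h\right)$ — the
different-individuals factor separates per sample, which is why a stored
fingerprint (the three $\log Q$ values per SNP) is sufficient for all
future comparisons.

### Numerical choices

All accumulation is in natural-log space. On real cohorts the likelihood
ratio spans hundreds of orders of magnitude (posteriors like $10^{-300}$
are routine for different-individual pairs at full coverage), far beyond
double range in probability space; each per-SNP trace is a log-sum-exp of
three terms. Alongside the posterior, `posterior_same()` and
`compare_all()` report the $\log_{10}$ likelihood ratio, because both
"numerically 1" and "numerically 0" posteriors still rank correctly in
log-odds. The summation order is arranged so that swapping the two samples
is bit-for-bit symmetric.

A SNP covered in only one sample has evidence triple $(1,1,1)$ in the
uncovered sample, which makes its same- and different-individual factors
equal; such SNPs are skipped. If *no* SNP is covered in both samples the
pair is reported as `NOTEST` rather than as a number (with no data the
posterior would just restate the prior); NOTEST pairs are excluded from ROC
evaluation. The prior $\pi_I$ is configurable and a regression test checks
that classification at the 0.95 threshold is identical for $\pi_I \in
\{0.001, 0.01, 0.1\}$ on a simulated cohort.

## Panel construction

`select_panel()` implements the three design rules for a fingerprint panel:
keep candidate SNPs with $0.1 < q < 0.9$ (rare variants carry little
pairwise information), keep SNPs inside supplied capture region sets, and
enforce a minimum spacing of 100 kb between retained SNPs on a chromosome
to suppress linkage disequilibrium.

Two of these were genuinely open design points:

* **Region combination.** With several capture kits' BED files, membership
  could mean "in any kit" or "in all kits". The default is *all*: a SNP
  inside every kit's target regions is the most likely to have coverage
  across exome, RNA-Seq and MethylCap-Seq libraries, which is the point of
  the panel. `region_mode = "any"` switches to the union.
* **Spacing thinning.** When SNPs conflict under the 100 kb rule, the rule
  "keep the allele frequency closest to 1/2" does not by itself define
  which subset survives. `snpmatchr` solves the selection exactly: per
  chromosome a dynamic program retains the spacing-feasible subset that
  first maximizes the number of SNPs and then minimizes
  $\sum_s |q_s - 1/2|$, with ties broken toward lower coordinates. A greedy
  drop-the-worse-of-the-closest-pair sweep was considered and rejected: on
  small instances enumerated exhaustively it fails to maximize the retained
  count (two good outer SNPs can both be lost to one middle SNP), while the
  dynamic program provably attains the optimum and is $O(n)$ after sorting.
  The tests compare it against brute-force enumeration on random small
  instances.

Coordinate conventions: the panel and VCF are 1-based; BED regions are
0-based half-open; a SNP at 1-based position $p$ is inside $[start, end)$
iff $start \le p-1 < end$. Chromosome naming ("chr1" vs "1") is normalized
against each alignment's header at counting time, with a warning.

## Allele counting

`count_alleles()` wraps an indexed-BAM pileup restricted to the panel
positions. Any A/C/G/T base different from the panel reference counts
toward $n$ — including third alleles. This is the literal reading of
"reads that do not match the reference", and it deliberately conflates
sequencing errors toward non-alternate bases with alternate-allele
evidence; the $\mathrm{Beta}(1,30)$ homozygous prior absorbs that small
error fraction. `strict_alt = TRUE` restricts $n$ to the panel alternate
base. Reads showing a deletion, a reference skip, or an N at the position
count toward neither $m$ nor $n$. Default filters exclude unmapped,
secondary, supplementary, QC-fail and duplicate reads, with quality floors
of 0 and a per-site depth cap of 100000 — ordinary pileup conventions, all
configurable. Overlapping mate pairs are counted independently (each read
is a read).

## What the simulator emulates — and what it does not

The `simulate` module generates data *from the model's own assumptions*:
genotypes are independent Hardy-Weinberg draws at each SNP's frequency,
children receive one uniformly chosen allele per parent, depth is Poisson
(or negative-binomial with configurable dispersion, emulating
expression-driven coverage variance in RNA-Seq), and alternate reads are
binomial with $p$ equal to the error rate for $WW$, $1/2$ for $WA$ and one
minus the error rate for $AA$. Default error rate is 0.01. The alignment
writer emits 50 bp single-end reads centered on each SNP (mapping quality
60, base quality 30) whose pileup reproduces the simulated counts exactly,
plus optional duplicate-flagged decoys for filter testing.

Real data violate these assumptions in ways the simulator does not model:
linkage disequilibrium between panel SNPs (mitigated in practice by the
100 kb spacing), population stratification of allele frequencies,
reference-alignment bias toward $m$, context-dependent and strand-dependent
error, PCR duplicates beyond flagged ones, allele-specific expression in
RNA-Seq, and bisulfite chemistry (bisulfite data are unsupported: C-to-T
conversion is indistinguishable from genotype signal at C/T SNPs). Passing
the simulation-based tests therefore demonstrates the *statistical engine*
is correct under its stated model, not that the model is exhaustive of
real-data artifacts; the method's robustness on real cross-modality data is
an empirical property established elsewhere.

## Study designs used by the test suite and acceptance script

Chosen once as representative desk-scale designs and documented here:

* **High-quality cohort**: 20 individuals x 2 samples, 6000 SNPs (the size
  of a realistic fingerprint panel), mean coverage 5, error 0.01. Expected
  behaviour, asserted by the tests: every same-individual pair above the
  0.95 threshold, every different-individual pair below it, AUC exactly 1.
* **Coverage sweep**: 20 replicate cohorts (6 individuals x 2 samples, 200
  SNPs) per mean-coverage arm in {5, 1, 0.3, 0.1} reads/SNP. The small
  panel makes the low-coverage arms informative: median AUC must be
  non-increasing and NOTEST counts non-decreasing as coverage falls.
* **Family cohorts**: per replicate, two unrelated individuals plus two
  nuclear families (mother, father, two children), two samples each, 6000
  SNPs at coverage 5. First-degree relatives share enough genotypes that
  their log-odds sit between unrelated pairs and same-individual pairs, and
  some sibling pairs cross the 0.95 threshold — the documented caveat that
  this test must not be used to distinguish family members.

Comparisons between relationship classes are made on log-odds rather than
posterior, because same-individual posteriors saturate to 1 in double
precision while their log-odds still discriminate.

## Known limitations

* The hypothesis space is {same individual, different unrelated
  individuals}; relatedness is not modeled, so first-degree relatives can
  exceed the 0.95 threshold (by design, documented above).
* Bisulfite-converted libraries are unsupported.
* The posterior is exactly calibrated only under the model's assumptions;
  on real data it is a well-behaved ranking score with a validated 0.95
  operating point rather than a frequency-calibrated probability.
* Exact numeric agreement with any particular historical pileup
  implementation on real BAMs is not promised: pileup filter defaults
  (depth caps, quality floors) are documented package choices.
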