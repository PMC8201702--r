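---
title: "Methods: pedigree-based GWAS and allele-frequency trajectories in divergent selection lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-based GWAS and allele-frequency trajectories in divergent selection lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`divselgwas` implements the analysis of a classical livestock divergent
selection experiment: two lines selected from a common base population in
opposite directions on residual feed intake (RFI), with genotyped breeding
animals ("breeders") and phenotyped but ungenotyped sibs ("response
animals") measured every generation. The package covers the whole chain —
simulating such an experiment, genotype quality control, predicting
response-animal genotypes from parental averages, mixed-model association,
multiple-testing thresholds, QTL-region assembly, and the classification of
allele-frequency trajectories against a neutral drift baseline. This
vignette explains the models, the defaults, and the choices made where the
design was genuinely open.

## The experimental design being modelled

The simulated design mirrors a two-line divergent selection scheme: lines
founded from 30 founder matings; at G0 a common pool of 116 tested males
supplies the 6 most extreme males of each tail as founding sires, and about
40 dams per line are chosen at random; in each later generation 96 males
per line are phenotyped and the 6 most extreme are kept (high tail in the
HRFI line, low tail in LRFI), while 40 dams are again random ("no selection
on females"); this runs for 9 generations. Response cohorts of 96 animals
per line per generation (G1–G5) and 175 (G6–G9) carry phenotypes for a
24-trait panel but no genotypes. These counts are the simulator defaults
(`sim_config()`); every one of them can be scaled.

The genome default (18 autosomes, 100 Mb each, 100 SNPs per chromosome) is
deliberately far sparser than a real SNP chip: the methods exercised here
(kinship-based association, PCA-based effective tests, 1-Mb windows) do not
need chip density, and desk-scale genomes keep every stage testable in
seconds. Founders are drawn with independent per-SNP allele frequencies
(minor allele frequency uniform on a configurable interval); there is no
ancestral linkage disequilibrium — LD accrues from the pedigree bottleneck,
which is the dominant source of LD in a closed line within ten
generations. Gametes recombine with Poisson crossover counts per
chromosome (1 cM/Mb by default, Haldane mapping, no interference).

### Trait model

All traits are simulated on a standardised scale: phenotypic variance 1
before fixed effects, so heritabilities and QTL allelic effects are in
phenotypic standard deviations. The selected trait decomposes as

\[ y = \sum_j a_j x_j + u\,\sigma_u + e, \qquad
   \sigma_u^2 = h^2 - \sum_j 2 p_j q_j a_j^2, \]

with planted QTL dosages \(x_j\), a pedigree polygenic factor \(u\)
(founders \(N(0,1)\); offspring receive the parental mean plus a Mendelian
deviation with variance \(0.5\,(1 - (F_s + F_d)/2)\), using the parents'
inbreeding coefficients tracked during the simulation), and residual
variance \(1 - h^2\). A configuration whose QTL variance exceeds the
selected trait's \(h^2\) is rejected.

Correlated traits use a single shared factor: trait \(t\) has genetic value
\(r_t \sqrt{h_t^2/h_s^2}\, g_s + w_t\), with \(w_t\) an independent
pedigree factor scaled so the total genetic variance is \(h_t^2\). This
reproduces the stated genetic correlations \(r_t\) to the selected trait
exactly and implies pleiotropy of planted QTL onto correlated traits in
proportion to \(r_t\). The default trait panel (`divsel_trait_table()`)
carries the experiment's 24 traits with their heritabilities and realised
G9 line differences; genetic correlations to RFI are not part of that
table, so the default derives them from correlated-response theory as the
ratio of each trait's realised response (in its own genetic standard
deviations) to the RFI response, capped at 0.9. That is the package's own
modelling choice, documented here because experiments of this kind report
realised responses rather than the underlying genetic correlations.

Response phenotypes also carry simulated fixed effects — a sex effect and
contemporary-group effects (two birth batches per generation). Contemporary
groups contain animals of *both* lines, as in a station-tested design where
lines are raised together; this matters, because adjusting phenotypes for a
group factor nested within line would silently remove the between-line
genetic signal that the association analysis and the trajectory
classification rely on.

What the generator does **not** emulate: ancestral LD and realistic MAF
spectra, mutation, crossover interference, sex chromosomes, maternal and
litter environmental effects, residual correlations among traits, and
genotyping error. Passing tests therefore demonstrate the correctness of
the pipeline's algorithms under the design's pedigree structure, not
robustness to all features of real chip data.

## Genotype handling

Dosages count a fixed *counted allele* per SNP, chosen at load time (by
default the major allele, so 0 = homozygote for the minor allele) and never
re-polarised after subsetting — frequencies must track one fixed allele
across generations for trajectories to be meaningful.

Quality control runs in a fixed order: unmapped/non-autosomal SNPs,
individual call rate (< 90% discarded), SNP call frequency (< 95%), minor
allele frequency (< 1%), and a two-sided exact Hardy–Weinberg test
(p < 1e-10), the last computed only on observed genotypes — parental
averages are dosage expectations, not genotypes, and are never HWE-tested.
One caveat documented deliberately: applying the HWE filter to the *pooled*
lines late in the experiment can remove exactly the loci most strongly
driven apart by selection (a Wahlund heterozygote deficit), which is why
the planted-QTL validation runs operate on the simulator's clean genotypes
without the pooled-line HWE step, and why on real data the filter belongs
upstream, per genotyping batch.

Response animals receive the average of their parents' dosages
(\((g_s + g_d)/2 \in \{0, 0.5, 1, 1.5, 2\}\)); all full sibs share a row.
Each cell gets a certainty class — certain for matings of two homozygotes,
half-certain for het × het (value 1, true genotype 0/1/2), uncertain for
hom × het — and certainty summaries count half-certain cells with weight
0.5. Animals with an ungenotyped parent are excluded, missing parental
calls give missing cells.

## Association model

Adjusted phenotypes (ordinary least-squares residuals from the stated
fixed-effect model, fitted in full per trait without significance-based
term selection) enter a single-marker linear mixed model

\[ y = x\beta + Zu + \varepsilon, \quad u \sim N(0, A\lambda\tau^{-1}),
   \quad \varepsilon \sim N(0, I\tau^{-1}), \quad Z = I, \]

with \(A\) the pedigree numerator relationship matrix built by the tabular
method over the full ancestral pedigree and subset to the analysed animals.
The variance ratio \(\lambda\) is estimated once per trait per analysis on
the null model by REML, profiling over \(\lambda \in [10^{-5}, 10^5]\) via
the eigen-decomposition of \(A\); each marker is then tested by generalized
least squares under \(V = \lambda A + I\) with a per-marker residual
variance, giving a 1-df Wald chi-square. Estimating \(\lambda\) once (not
per marker) trades a negligible change in the statistics for a large
speed-up; the dense-V oracle tests bound the numerical error of the
rotation itself at 1e-8. REML is the default (an ML option exists); a flat
likelihood in \(\lambda\) — e.g. \(A = I\) — is flagged and returned at the
boundary. The three analyses (global, HRFI, LRFI) differ only in the id
subset; \(A\), \(\lambda\) and the genomic-control factor are re-derived
per subset.

Genomic control estimates the inflation factor as the through-origin
regression slope of the sorted observed chi-squares on theoretical
\(\chi^2_1\) quantiles (a median-based estimator is selectable; untrimmed,
and not floored at 1 by default, so deflation is visible) and divides every
statistic by it.

Average genotypes enter as continuous dosages without uncertainty
weighting: the within-litter sharing of predicted genotypes is a design
feature of the data, and the relationship matrix — in which full sibs
remain distinct — carries the corresponding dependence.

## Thresholds, windows, regions

The effective number of independent tests per chromosome is the number of
leading principal components of the inter-marker Pearson correlation matrix
needed to reach 99.6% of its total variance, computed on observed breeder
genotypes (whose LD the tests inherit), with the dual individual-space
decomposition used when SNPs outnumber animals. The genome-wide threshold
is \(-\log_{10}(0.05 / \sum_c M_c)\), conventionally reported at one
decimal; the suggestive threshold is fixed at 3.

Significant SNPs are binned into 1-Mb windows (`floor(bp/1e6)`, 0-based
half-open — no convention is universal here, so one was fixed and
documented), adjacent windows merge per trait, windows fuse across traits
within an analysis into QTL-regions, and per (trait × region) the most
significant SNP — ties broken by position then id — tags the association
("SNP-QTL") with its allelic substitution effect. Regions are compared
across analyses by any chromosomal overlap, fusing per analysis first.

## Trajectories and drift

For each SNP-QTL and line, allele frequencies are computed cumulatively
(G1 animals only, then G1–G2, ... up to G1–G9) from the predicted dosages,
and frequency is regressed on generation number. The slope is reported in
frequency per generation; its Wald test uses a t reference with \(n-2\)
degrees of freedom by default, with a normal-reference option (with nine
points the two differ noticeably, so the choice is explicit). Cumulative
frequencies autocorrelate the regression errors — the
package's own test measures the resulting rejection-rate inflation under
pure drift rather than assuming nominal calibration, and a per-generation
option exists for sensitivity analysis.

Two significant slopes of the same sign mean *co-selected*, opposite signs
*opposite*, one significant slope *one line only*, none *no change*. The
evolution score is `9 × (|slope_HRFI| + |slope_LRFI|)` over significant
slopes only, approximating the total frequency change over the experiment;
per-trait mean scores are correlated with the realised G9 line differences.

The neutral reference is the idealised Wright–Fisher population (panmixia,
no selection, N = 40): closed form
\(\sqrt{p_0(1-p_0)(1-(1-\tfrac{1}{2N})^t)}\) — 0.164 for \(p_0 = 0.5\),
\(t = 9\) — plus a binomial-resampling Monte-Carlo companion used to verify
it.

## Numerical choices and problem sizes

Eigenvalues of relationship and correlation matrices are clamped at zero
before use; monomorphic markers are skipped, not scored; markers with
missing dosages fall back to an explicit dense-V GLS on complete cases;
degenerate trajectory fits (zero variance) return slope 0 with p = 1; an
exactly linear trajectory has its standard error floored at machine
epsilon. All randomness flows from one master seed through fixed
per-stage/per-generation substreams, so per-line outputs are reproducible
independently and identical seeds give byte-identical pipeline summaries.

Test and validation runs use scaled designs chosen once: pedigree-only
inbreeding checks run the full breeding scheme (it is cheap); the
planted-QTL recovery runs use the full response cohorts (≈1180 per line —
power at the genome-wide threshold needs the design's real sample size)
with a 2-chromosome, 120-SNP genome and a single QTL explaining ≈9–10% of
phenotypic variance, near the ceiling that RFI's heritability (0.13)
allows for one locus; null-calibration runs use smaller cohorts since they
measure a rate, not power. The between-line component of a QTL's signal is
largely absorbed by the relationship matrix, so single-locus power comes
from within-line dosage variance — noticeably less than a naive
\(nR^2\) calculation suggests, which is why the full cohort sizes are used
for recovery checks.

## Known limitations

Founder LD and realistic allele-frequency spectra are not simulated;
imputation of genotypes (an external tool's role in the original design)
is out of scope — the simulator provides complete breeder genotypes and
missingness only enters through an explicit injection utility; the RFI
index coefficients are fixed constants, not re-estimated; genomic (marker)
relationship matrices and formal selection-signature statistics are beyond
the analysis implemented here.
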