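---
title: "Methods: windowed genome scans, haplotype-block genotyping and geographic clines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed genome scans, haplotype-block genotyping and geographic clines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`divscan` analyses population pairs that are almost undifferentiated
genome-wide but segregate a few large, mutually non-recombining haplotype
blocks — the situation found across avian migratory divides, where two
phenotypes that winter on different continents meet and hybridise. This
vignette explains the statistical machinery, the synthetic-data generator
used to validate it, and the design choices that were genuinely open.

## Windowed statistics

All windowed statistics operate on non-overlapping 10 kb windows
(configurable) in 0-based half-open coordinates; VCF positions (1-based)
are mapped by `floor((pos - 1)/size)`. Terminal partial windows are
emitted and flagged but excluded from summaries by default: window means
are only comparable when the denominator is a full-length window, and
nothing in the estimators requires the genome length to be a multiple of
the window size. Every per-site quantity is normalised by the number of
*callable* sites in the window — positions at which a variant could have
been detected under the coverage/missingness filters — supplied as a BED
mask. Monomorphic callable sites contribute 0 to numerators and 1 to
denominators; positions outside the mask contribute to neither. Windows
with fewer than 5,000 callable sites carry no statistics, and windows
with fewer than 25 SNPs are additionally excluded from F_ST summaries.

* **F_ST** is the Weir–Cockerham (1984) two-allele estimator from
  variance components *a* (among populations), *b* (among individuals)
  and *c* (within individuals). Windowed values are the weighted
  ratio-of-sums `sum(a)/sum(a+b+c)`. Negative per-site estimates are kept
  (clamping would bias the sums); sites monomorphic across populations
  have a zero denominator and are undefined, never 0.
* **pi** per group is `sum(2*p*q*n/(n-1))/callable` with `p` the
  alt-allele frequency among the group's non-missing alleles and `n`
  their count — the unbiased genotype-based estimator (the data are
  unphased throughout).
* **Tajima's D** uses the total (not per-site) pairwise-difference sum
  and segregating-site count of the window with the standard 1989
  coefficients; the haplotype count for the coefficients is the nominal
  `2 x` group size. Windows with `S = 0` are undefined and excluded from
  means.
* **d_XY** is `sum(p_x(1-p_y) + p_y(1-p_x))/callable` and the net
  divergence is `d_A = d_XY - (pi_x + pi_y)/2`, computed from the same
  callable counts so the identity holds to machine precision.
* **Divergence time** is `t = d_A/(2*mu)` over a configurable range of
  per-year substitution rates. The default range, 1.5625e-9 to 3.333e-9
  substitutions/site/year, spans rates reported for other bird genomes
  and maps `d_A = 0.005` onto roughly 0.75–1.6 Myr. The pipeline feeds it
  the highest per-region *mean* of windowed d_A; a single-window maximum
  overshoots because core-difference counts are Poisson across windows.

The per-group statistics in the pipeline are computed on the "pure"
subsets — samples called homozygous for the same haplotype group in all
divergent regions — not on the sampling populations, which contain
heterozygous carriers.

## Genotyping divergent regions

Within a divergent region, diploids fall into three classes: homozygous
southern (SS), heterozygous (NS), homozygous northern (NN). The package
embeds the samples by classical metric MDS of an allele-sharing distance
(mean absolute dosage difference over loci observed in both samples).
When recombination between haplotype groups is absent, the three classes
form three equally spaced clusters on the first axis; the *equidistance
score* `|d(SS,NS) - d(NS,NN)|/d(SS,NN)` quantifies how well the geometry
matches that expectation (values near 0 are the signature of a
non-recombining block). This replaces the published-but-unexported
`invClust` procedure with an equivalent, fully documented construction.

Classes are then called by a one-dimensional three-component Gaussian
mixture (equal variances) on axis 1, fitted with mclust's deterministic
model-based EM. The middle cluster is NS; the end clusters are polarised
S/N by the majority population-of-origin of their members (for array
samples, the geographic ends of the transect act as anchors), mirroring
how the clusters are named in the field. Samples whose maximum posterior
falls below 0.95 (configurable) are left unassigned rather than forced.
If fewer than three occupied components can be fitted, the call degrades
to 2 or 1 clusters and is flagged.

Genome-wide PCA uses the conventional population-genetic normalisation
(center by `2p`, scale by `sqrt(p(1-p))`, mean-impute missing) and can
exclude loci inside declared regions, to show how much of the observed
structure the haplotype blocks carry.

## Geographic clines

Per sampling site, the northern-haplotype frequency is
`(2*NN + NS)/(2*assigned)`. Sites are projected onto a transect by
orthogonal great-circle projection (haversine geometry, Earth radius
6,371 km); the off-axis (cross-track) distance is reported and flagged
beyond a 300 km tolerance. The transect-projection scheme is this
package's choice — published hybrid-zone studies rarely describe theirs.

The cline model is the tail-free four-parameter sigmoid

p(x) = pMin + (pMax - pMin) / (1 + exp(-4 (x - c) / w)),

with center `c` (km), width `w` (km; the inverse of the maximum relative
slope), and tail frequencies `pMin < pMax`. Fitting maximises the
binomial log-likelihood of per-site northern-allele counts with six
deterministic starts on a center-by-width grid and bounded transforms
(log width; logit tails with the ordering enforced by construction),
via BFGS. Uncertainty comes from a parametric bootstrap (default 200
replicates, seeded): counts are resimulated at the fitted cline and
refitted, and percentile intervals are reported. This replaces MCMC
machinery with a deterministic, testable estimator of the same model;
the simplest (no-tail) cline variant is used because the model variant
behind the published estimates is not stated. Degenerate data are
flagged rather than silently fitted: step-like data drive `w` to the
lower bound, flat frequencies leave `w` unidentifiable
(`width_exceeds_transect`), and all-0/all-n counts are boundary fits.

For context, the expected width of a purely neutral cline after `T`
generations of dispersal `sigma` is `w = 2.51 * sigma * sqrt(T)`
(diffusion approximation); with the conventional post-contact scenario
(50 km, 100 generations) this is 1,255 km — several times wider than
clines maintained by selection at a migratory divide.

## Phenotype association

Associations are computed on sampling-site means of males only (size
traits are sexually dimorphic; unsexed birds are excluded), never on
individuals: the feather nitrogen-isotope ratio (d15N, the migratory
proxy) varies widely among individuals of one population while site
means are stable. Wing, tarsus and bill-head lengths are combined into a
single size axis (first principal component of the standardised traits,
sign fixed so larger birds score positive). The reported statistic is
the Pearson correlation between site haplotype frequency and site trait
mean, optionally within a transect stratum; at least 3 complete sites
are required, zero-variance inputs are flagged undefined, and no
multiple-testing correction is applied (the correlations are
descriptive).

## The synthetic-data generator

The generator produces study-shaped inputs whose statistical
expectations are exact by construction, so estimator recovery can be
tested against analytic truths rather than against another simulator:

* **Background**: Balding–Nichols. Per SNP, an ancestral frequency
  `p ~ Uniform(0.05, 0.95)`, population frequencies
  `Beta(a*p, a*(1-p))` with `a = (1-F)/F`, binomial genotypes. The
  expected weighted Weir–Cockerham estimate equals `F` (default 0.007).
  SNP density defaults to 0.03/bp, matching ~36M biallelic SNPs on a
  ~1.1 Gb genome.
* **Divergent regions**: two clade core haplotypes differing at sites
  drawn with per-site probability `2*mu*T_split`; a haplotype's clade
  label fully determines its core alleles (no recombination between
  clades). Within-clade variation is *shared ancestral polymorphism*:
  `3*theta*L` sites with the same Uniform(0,1) frequency in both clades,
  so `E(pi) = theta` (since `E(2pq) = 1/3`) and — because the shared
  sites cancel exactly between `d_XY` and mean `pi` —
  `E(d_A) = 2*mu*T_split` exactly, the standard relation
  `d_XY = 2*mu*T + theta_anc` with `theta_anc = theta`. Where one clade
  is configured with excess diversity (northern 0.007 vs southern 0.005
  in the chr1/chr5 analogues), the excess is added as clade-private
  sites; each private site adds `E(p^2) = 1/3` to `d_A`, a small
  documented upward bias (~0.002 at the default excess), which is why
  recovery tests use equal-theta regions.
* **Spectra**: a single-group generator offers the Uniform(0,1) spectrum
  above and a neutral-equilibrium spectrum (`P(i) proportional to 1/i`,
  `S = theta*a1*L`) under which both theta estimators are unbiased and
  Tajima's D is centered near zero; the uniform spectrum has an excess
  of intermediate frequencies and yields positive D by design.
* **Transects and phenotypes**: 74 sites on two ~1,500 km transects
  (40 + 34), 15 birds per site with one female; per region the site's
  northern-haplotype frequency follows the configured sigmoid cline
  (east transect: widths 373 and 249 km for the chr1/chr5 analogues;
  Sweden transect: 271 and 310 km, within the few-hundred-km range
  typical of selection-maintained clines at migratory divides) and
  individuals draw two clade labels under Hardy–Weinberg
  within sites — later-generation hybrid combinations emerge rather
  than being imposed. The chr3 analogue follows a logistic
  altitude/latitude model instead of a transect cline (altitude
  Uniform(0, 1000) m, independent of transect position). Site-mean d15N
  is linear in the chr1 frequency plus site and individual noise; size
  traits shift weakly with clade dosage; the color score is a
  discretised 1–9 scale.
* **Resequencing design**: 9 + 9 diploids; 8 southern samples are SS and
  6 northern samples NN at all three regions, the remaining four are
  heterozygous at one region each, so the "pure" subsets recovered by
  region genotyping have sizes 8 and 6.

What the generator does **not** emulate: linkage disequilibrium within
clades (sites are independent), selection dynamics, temporal cline
movement, genotyping error on the array (diagnostic loci are noiseless,
which is why classification accuracy is exactly 100% there), a realistic
site-frequency spectrum in the Balding–Nichols background, and deviation
from Hardy–Weinberg within hybrid-zone sites (an assumption of the
generator, not an empirical claim). Passing recovery tests therefore
demonstrates estimator correctness under the generative model, not
robustness to these real-data features.

## Numerical and validation choices

Problem sizes in the test and acceptance suites were chosen so Monte
Carlo error sits well inside each tolerance: diversity and divergence
recoveries use 1 Mb regions averaged over 5 seeds (MC error well under
1%); F_ST recoveries use 300k SNPs (10 Mb at default density); cline
recoveries use 20 sites x 30 diploids over 20 seeds with 200-replicate
bootstraps; the full end-to-end study uses a 13 Mb genome (three regions
of 2/2/1 Mb plus 8 Mb background), which runs in roughly two minutes.
Assertions on small quantities are written as explicit relative errors.
Where QC thresholds are not printed in the source material they are
configuration parameters with conservative defaults (QUAL >= 20, site
missingness <= 0.2, per-genotype depth within 1/3x–2x of the sample
median — applied per sample by default, with an absolute per-site mode
as the alternative; array MAF >= 0.01 and locus/sample missingness
<= 0.1). Filters apply in a fixed order (quality, repeats, depth,
missingness) and the QC report telescopes, so attrition is auditable and
filtering is idempotent.

## Known limitations

Tajima's D uses the nominal haplotype count even when genotypes are
missing at some sites (adequate at the missingness levels the filters
allow). The MDS distance ignores locus weighting, so regions dominated
by a few high-frequency loci embed less cleanly than the default
synthetic design. Cline width and tails are weakly identified when
sampling does not span both tails — the fit flags, but cannot rescue,
such designs. The polarity of region calls relies on
population-of-origin anchors; in a study without geographic anchors the
SS/NN labels are arbitrary (flagged `polarity_by_axis_orientation`).
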