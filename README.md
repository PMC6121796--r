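# divscan

Population-genomic analysis of weakly differentiated population pairs
that segregate large non-recombining haplotype blocks — the genetic
architecture found across avian migratory divides, where two phenotypes
with different innate migratory directions meet and hybridise. Typical
data: whole-genome resequencing of a handful of birds per phenotype, a
SNP array genotyped in ~1,000 birds from ~74 sites along two hybrid-zone
transects, and routine phenotypes (feather nitrogen isotopes as a
wintering-ground proxy, size measurements, a plumage color score).

## What it computes

* **Windowed scans** over 10 kb windows, normalised by callable-site
  counts: Weir–Cockerham *F*<sub>ST</sub> (variance components *a*, *b*,
  *c*; windowed value Σa/Σ(a+b+c)), nucleotide diversity π per group,
  Tajima's D, absolute divergence *d*<sub>XY</sub> and net divergence
  *d*<sub>A</sub> = *d*<sub>XY</sub> − (π<sub>x</sub>+π<sub>y</sub>)/2,
  plus window/variant ranking (top-1% windows, *F*<sub>ST</sub> ≥ 0.7
  variants), nearest-gene annotation and divergence time
  *t* = *d*<sub>A</sub>/(2μ).
* **Haplotype-block genotyping**: classical MDS of an allele-sharing
  distance within each divergent region and Gaussian-mixture
  classification of samples into SS/NS/NN diploid classes, with an
  equidistance score for the three-cluster geometry; genome-wide PCA
  with optional exclusion of the divergent regions.
* **Geographic clines**: orthogonal great-circle projection of sites
  onto transects and binomial maximum-likelihood fits of the sigmoid
  cline *p*(x) = *p*min + (*p*max − *p*min)/(1 + e^(−4(x−c)/w)), with
  parametric-bootstrap confidence intervals and a neutral-diffusion
  reference width *w* = 2.51·σ·√T.
* **Phenotype association**: male-only site means (δ15N, size PC1,
  color) correlated with per-site northern-haplotype frequencies.
* **A seeded synthetic-study generator** (Balding–Nichols background,
  two-clade divergent regions with exact expectations E[π] = θ,
  E[*d*<sub>A</sub>] = 2μT, sigmoid clinal transects, linked
  phenotypes) and an end-to-end pipeline driver.

## Worked example: fitting a cline

```r
library(divscan)
set.seed(1)
x <- seq(75, 1425, length.out = 20)            # site positions (km)
p <- cline_predict(x, center = 750, width = 373, pmin = 0.02, pmax = 0.98)
k <- rbinom(20, 60, p)                         # northern alleles of 60 per site
fit <- fit_cline(x, n = rep(60, 20), k = k, boot = 200, boot_seed = 1)
fit
#> Sigmoid cline fit (binomial ML)
#>   center = 733.7 km, width = 399.9 km, pmin = 0.014, pmax = 0.967
#>   logLik = -351.01 over 20 sites (1200 alleles)
#>   95% bootstrap CI width: [310.3, 481.2] km
```

The fitted width (400 km, CI 310–481) recovers the generative 373 km
from a single realisation; a cline this narrow is far steeper than the
1,255 km expected from neutral diffusion
(`neutral_diffusion_width(50, 100)$width`) after 100 generations of
50 km dispersal, the signature of selection maintaining the divide.

## Worked example: a full synthetic study

```r
cfg <- pipeline_config(outdir = "study", sim = sim_config(seed = 1),
                       boot = 100)
res <- run_pipeline(cfg)   # simulate -> QC -> stats -> MDS calls ->
res                        # clines -> association (~2 min)
#> divscan pipeline result in study
#>   347106 variants after QC; 1300 windows
#>   pure subsets: 8 southern, 6 northern
#>   6 cline fits; divergence time 1.04-2.22 Myr
res$clines$table[, c("fit", "center", "width")]
#>           fit center   width
#> 1   chr1:east  733.7   382.8
#> 2 chr1:sweden  779.8   242.6
#> 3   chr3:east 1059.6   205.9
#> 4 chr3:sweden 1138.4 22240.8
#> 5   chr5:east  737.0   247.3
#> 6 chr5:sweden  762.4   344.8
```

The MDS genotyping recovers exactly the 8 southern- and 6
northern-homozygous "pure" samples planted in the resequencing design,
the chr1/chr5 clines recover their generative widths (truth: 373/249 km
east, 271/310 km Sweden), and the chr3 analogue — whose clade follows
altitude and latitude, not the divide — fits no meaningful cline on the
Sweden transect (width ≫ transect length, flagged). Site-level
correlations show the same contrast: |r(freq, δ15N)| ≈ 0.97 for
chr1/chr5 versus 0.16 for chr3, while r(chr3, altitude) ≈ 0.89.
`report(res)` writes the figure panels (F_ST track, PCA with/without
regions, MDS clusters, per-region tracks, clines).

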