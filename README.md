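# rppanorm — spatial normalization and QC for reverse-phase protein arrays

Reverse-phase protein arrays (RPPA) quantify one protein across thousands
of lysate samples spotted on a single slide. Uneven exposure of the slide
to detection reagents creates smooth spatial bias: identical samples read
differently depending on where they were printed, inflating replicate
variance and pushing slides past quality cutoffs. `rppanorm` removes this
bias using the positive-control spots already present in the standard
slide design, and quantifies the improvement with replicate-agreement
metrics. It is aimed at RPPA core facilities and analysts working with
MicroVigene-style spot quantification tables, upstream of dose-response
concentration estimation.

## The method

The measured intensity at slide position $(x,y)$ is modelled as the true
intensity scaled by a spatial correction factor:

$$I(x,y) = CF(x,y)\,I'(x,y), \qquad
  CF(x,y) = \frac{PCI^{*}(x,y)}{\langle PCI \rangle}.$$

Positive-control dilution sets are printed at regular intervals across the
slide (96 sets of 5 half-dilutions in the default 132 × 44 layout); all
controls of one dilution are technical replicates, so their variation maps
the bias. Each set contributes one anchor — its median-intensity spot, the
dilution most likely to be in the assay's linear range. Pseudo-positive-
control intensities $PCI^{*}$ are bilinearly interpolated between anchors
at every spot (cubic-spline surface optional), divided by the mean anchor
intensity $\langle PCI \rangle$ to give $CF$, and divided out:
$I' = I / CF$. Spots outside the anchor rectangle take the nearest covered
correction factor. $CF > 1$ marks regions biased high, $CF < 1$ regions
biased low.

Because only one spot per control set is consumed by the fit, the
remaining control dilutions are held-out replicates that honestly measure
bias removal. QC metrics: percent coefficient of variation (`100·σ/μ`,
sample sd) with the conventional 15% slide-acceptance cutoff, Pearson ρ
between duplicate slides, Z′-factor and Welch t for positive/negative
control separation. A synthetic-slide simulator with known multiplicative
bias fields and lognormal noise makes every claim testable without real
data.

## Worked example

Simulate a triplicate study under a ±30% smooth spatial bias with 5%
measurement noise and 10% true biological dispersion, then correct it:

```r
library(rppanorm)

cfg <- simulation_config(seed = 11, bias = bias_field("low_freq_sinusoid", 0.3))
study <- simulate_replicate_study(cfg, n_bio_replicates = 3,
                                  replicate_cv = 0.10)
norm <- normalize_slide(study$slide)
print(norm$surface)
#> RPPA correction surface (bilinear): 96 anchors on a 12 x 8 lattice
#>   reference <PCI> = 2494.11; CF range [0.6883, 1.327]; 0 clamped

compare_before_after(study$slide, norm, study$grouping)
#> Mean replicate %CV: 19.04% -> 10.83%
#> Z'-factor: 0.512 -> 0.797 | Welch t: 61.42 -> 148.52
```

The bias field spreads the correction factors over roughly 0.69–1.33. The
raw slide's mean biological %CV (19%) is dominated by spatial bias — the
simulated biology only carries 10% — and fails the 15% acceptance cutoff;
after correction the slide lands at 10.8%, essentially the simulated
dispersion plus measurement noise, and is rescued for analysis. The
Z′-factor of control separation rises accordingly.

The same pipeline runs from the shell (the launcher script is installed
with the package):

```sh
rppanorm=$(Rscript -e 'cat(system.file("cli", "rppanorm", package = "rppanorm"))')
Rscript $rppanorm simulate  --seed 11 --out-slide slide.tsv --out-grouping groups.tsv
Rscript $rppanorm normalize --input slide.tsv --output corrected.tsv
Rscript $rppanorm qc --input slide.tsv --normalized corrected.tsv \
    --grouping groups.tsv --report report.tsv
```

Corrected tables carry `Corrected` and `CF` columns beside the raw
`Signal` and a `#` provenance header, and remain readable by downstream
dose-response tools.

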