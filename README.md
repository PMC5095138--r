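# fppl — flexible-pattern particle labeling

`fppl` detects small bright particulate objects — typically calcified
microspheres in backscattered-electron SEM images of cardiovascular tissue —
in noisy 8-bit grayscale micrographs, and benchmarks that detector against
the classical alternatives on synthetic images with exact ground truth. It is
aimed at image-analysis practitioners who need to *count* sub-micron bright
particles in cluttered tissue backgrounds where global thresholding and
template matching both break down.

## The method

The detector scans the image with a square pattern built from three zones:
a 3×3 **core** C, an ignored **gap ring** G of width *g* (default 2, giving
an 11×11 pattern), and eight **peripheral blocks** P₁…P₈ tiling the
outermost 2-pixel band. A position is labeled a particle when

```
C̄ > Th₁   and   C̄ − P̄ᵢ > Th₂  for every i = 1…8
```

where C̄ and P̄ᵢ are the zone means. Because the gap pixels never enter the
decision, one pattern tolerates wide variation in particle size and shape;
scanning a small image pyramid (200 %, 100 %, 50 %) extends the covered size
range further, with cross-scale deduplication so each particle is counted
once. The package also implements the standard baselines — global-threshold
particle labeling (BPL), rolling-ball background subtraction (SBP) and Sobel
edge enhancement (FEP) as preprocessors, and multi-template matching (MTM)
with a normalized L1 similarity — plus the usual point-set evaluation:

```
detection rate = 100·Ncyan/(Ncyan+Nred)     (matched)
FN rate        = 100·Nred /(Ncyan+Nred)     (missed references)
FP rate        = 100·Ngreen/(Ncyan+Ngreen)  (spurious detections)
```

## Worked example

Generate an SEM-like test image with known ground truth, run the detector,
and evaluate:

```r
library(fppl)

fx  <- make_sem_like_image(n_particles = 30, seed = 7)
det <- detect_multiscale(fx$image, build_pattern(2), th1 = 100, th2 = 30)
head(det, 3)
#>       x     y scale core_mean min_contrast
#> 1 20.00  62.0     2     109.0        40.30
#> 2 53.75 154.4     2     122.1        71.74
#> 3 59.89 104.8     2     124.7        72.06

evaluate_detections(det, fx$reference, tolerance = 5)
#>   n_cyan n_red n_green detection_rate false_negative_rate false_positive_rate tolerance
#> 1     29     1       0       96.66667            3.333333                   0         5
```

29 of the 30 particles are matched within 5 px (`n_cyan`), one is missed
(`n_red`, a false negative), and nothing is detected that isn't a particle
(`n_green = 0`), giving a 96.7 % detection rate with no false positives.
The `scale` column records the pyramid level that found each particle — the
rows shown were caught in the 200 % image, i.e. particles too small to
resolve at native scale.

Comparing all five detectors over 14 seeded SEM-like images:

```r
fixtures <- lapply(1:14, function(s) make_sem_like_image(n_particles = 25, seed = 100 + s))
bm <- run_benchmark(fixtures)
subset(bm$summary, rate == "detection_rate")
#>     method           rate mean   se  n se_defined
#> 1     fppl detection_rate 94.0 1.37 14       TRUE
#> 4      bpl detection_rate 74.3 2.00 14       TRUE
#> 7  sbp_bpl detection_rate 84.9 2.06 14       TRUE
#> 10 fep_bpl detection_rate 88.3 2.03 14       TRUE
#> 13     mtm detection_rate 45.1 3.76 14       TRUE
```

The flexible-pattern detector leads, edge enhancement helps plain
thresholding, and rigid template matching trails — the ordering this detector
family was designed to demonstrate.

A thin command-line front end wrapping the same functions ships in
`inst/cli/fppl.R` (subcommands `detect`, `evaluate`, `synth`, `benchmark`);
every run writes its resolved configuration and seed next to its outputs so
results can be reproduced bit-exactly.

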