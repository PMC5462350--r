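# leafjdsr

Coarse-to-fine plant species recognition from leaf photographs, using
Jaccard similarity of binary edge-orientation images and a
Jaccard-distance-weighted sparse representation classifier.

## The problem and the method

Identifying a plant species from a photograph of a single leaf is hard at
scale: large databases hold hundreds of species, leaves within one species
vary a lot, and leaves of different species can look nearly identical.
Classifiers that sparsely represent a test image over *all* training
images pay a steep computational price and are degraded by dissimilar
training samples.

`leafjdsr` implements a two-stage remedy.  Every leaf is first reduced to
a 32×16 **binary edge-orientation image**: grayscale conversion
(`Gray = 0.2989·R + 0.5870·G + 0.1140·B`), background segmentation at a
gray threshold of 30, rotation so the blade's geometric long axis is
vertical, bounding-box crop resampled to 32×16 with histogram
equalization, and Canny-style edge extraction (sensitivity threshold
0.12).  Flattened row-major, each leaf becomes a binary vector of length
D = 512.

**Stage 1 — coarse screening.**  For binary vectors the Jaccard
coefficient `J = M11 / (M11 + M01 + M10)` counts only informative
(non-background-matching) pixels.  The test leaf's average coefficient
against each training class ranks the classes; only the top `S = ⌊C/2⌋`
survive, and the rest are excluded outright.

**Stage 2 — fine classification.**  The shortlisted training vectors form
a dictionary `G ∈ R^{D×m}`, and the test vector `y` is represented by
solving the weighted ℓ₂–ℓ₁ problem

```
min_A ‖GA − y‖₂² + μ ‖W′A‖₁ ,   diag(W′) = [d_J(y, x₁), …, d_J(y, x_m)]
```

with `d_J = 1 − J` the Jaccard distance and `μ = 0.001` by default.
Dissimilar atoms carry heavier penalties, so the solution concentrates on
atoms that resemble the test leaf and is typically sparser than the
unweighted representation.  Each class's atoms and coefficients give a
per-class reconstruction `c_i` and residual `e_i = ‖y − c_i‖₂`; the leaf
is assigned to the class with the smallest residual.

The solver is cyclic coordinate descent on the substituted standard-form
LASSO (`B = W′A`); a closed-form ridge baseline and the unweighted (SRC)
solver are included for diagnostics.

Because the published evaluation database cannot be redistributed, the
package ships a parametric synthetic-leaf generator (`make_dataset()`):
radial polar-profile silhouettes with controllable base shape, lobes,
serration and venation, plus rotation/scale/illumination/salt-noise
jitter, rendered on a sub-threshold dark background.  Every stage of the
pipeline is testable offline with it.

## Worked example

```r
library(leafjdsr)

# the exact Jaccard arithmetic on two 10-pixel binary vectors
v1 <- c(1,0,0,1,0,0,1,1,0,0)
v2 <- c(0,0,1,1,0,1,0,1,1,0)
jaccard_counts(v1, v2)       # m11 = 2, m01 = 3, m10 = 2
jaccard_coefficient(v1, v2)  # 0.2857143  (= 2/7)
jaccard_distance(v1, v2)     # 0.7142857  (= 5/7)

# a six-species synthetic benchmark, 10 leaves per species
ds  <- make_dataset(C = 6, per_class = 10, separation = 0.5, seed = 42)
cfg <- pipeline_config(folds = 5, repeats = 1, seed = 7)

# recognize one leaf against the other 59
r <- recognize(ds$images[[11]], ds$images[-11], ds$labels[-11], cfg)
r$shortlist
#> Candidate shortlist: 3 of 6 classes
#> class_02 class_06 class_01
#>   0.6280   0.3841   0.3177
round(r$solution$residuals, 3)
#> class_02 class_06 class_01
#>    4.676   10.241    9.519
r$predicted_class
#> [1] "class_02"

# five-fold cross-validated evaluation
rep <- cross_validate(ds$images, ds$labels, cfg)
rep
#> Cross-validated recognition report
#>   5 folds x 1 repeats (seed 7), 60 predictions
#>   macro recognition rate: 91.67%
#>   fold-level mean +/- sd: 91.67% +/- 10.21%
```

The shortlist scores are the per-class average Jaccard coefficients: the
true species (`class_02`, the leaf's own class) dominates at 0.628, half
the classes are dropped, and the residual of `class_02` (4.68) is well
below the runners-up, so the decision is unambiguous.  The
cross-validated macro rate (mean of per-class recognition rates) on this
medium-separation benchmark is 91.67%.

A thin command-line front end lives at `inst/cli/leafjdsr.R`
(`jaccard`, `classify`, `evaluate`, `synth` subcommands).

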