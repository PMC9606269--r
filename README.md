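# photobleachr

Subunit counting for membrane receptors by single-molecule photobleaching.

Single-molecule TIRF imaging of fluorescently tagged receptors in fixed
cells turns oligomer stoichiometry into a counting problem: each
diffraction-limited spot is one particle, and the number of discrete
downward steps in its bleaching trace counts its labeled subunits. Because
labeling is incomplete (each subunit carries a functional fluorophore only
with probability $P_f \approx 0.8$), the observed step histogram
undercounts true oligomer order and must be corrected. `photobleachr` is
for quantitative microscopists and receptor biologists who want that whole
chain — simulation, detection, tracing, step counting, correction — as
auditable, scriptable R.

## The model

A true $i$-mer shows $m$ bleaching steps with binomial probability
$P_{im} = \binom{i}{m} P_f^m (1-P_f)^{i-m}$; unlabeled particles
($m = 0$) are invisible. With $x$ the true particle fractions over orders
$1..N_{\max}$ (default 5), the expected observed histogram is $R = A w$,
where $w_i \propto (1-(1-P_f)^i)\,x_i$ and
$A_{mi} = P_{im}/(1-(1-P_f)^i)$ is column-stochastic. The corrected
fractions solve $A w = R$ by non-negative least squares, then unweight by
visibility. Subunit-level ("entity") fractions are
$E_i = i x_i / \sum_j j x_j$; density $\times$ cell area gives receptors
per cell. Uncertainty comes from a multinomial bootstrap of the histogram.

The rest of the pipeline: à trous B3-spline wavelet spot detection with 2D
Gaussian sub-pixel refinement and iterative multi-emitter deconvolution;
greedy nearest-neighbor linking (fixed cells); fixed-anchor aperture
photometry with annulus-median background; penalized change-point step
counting with explicit trace QC rules. A synthetic-movie generator with
complete ground truth makes every stage testable.

## Worked example

Simulate a 50/50 monomer/dimer field at low density, run the full
pipeline, and correct the step histogram:

```r
library(photobleachr)

cfg <- pb_config(sim = list(
  true_fractions = c(0.5, 0.5, 0, 0, 0),
  n_particles = 260, particle_density = NULL,
  image_shape = c(256, 256), n_frames = 250,
  mean_bleach_time = 60, shot_noise = FALSE, read_noise_sd = 0))

report <- run_pipeline(cfg, seed = 14)
report
#> Photobleaching pipeline report
#>   particles simulated: 260 (228 visible)
#>   detected density: 0.305 /um^2  (~370 receptors/cell)
#>   tracks: 224; QC-accepted traces: 146; histogram n = 146
#>   observed steps: 1:92  2:53  3:1  4:0  5:0
#>   corrected fractions: 0.496, 0.493, 0.012, 0.000, 0.000
```

Reading the output: 260 particles were simulated, of which 228 carry at
least one fluorophore (the rest are invisible at $P_f = 0.8$). Detection
and tracking yield 224 anchors; QC keeps 146 clean traces. Their step
histogram (92 one-step, 53 two-step) overstates monomers — at 80% labeling
a dimer shows a single step about a third of the time — and inverting the
labeling model recovers 50%/49% monomer/dimer, matching the simulated
50/50 within the sampling noise of ~150 particles. The same objects
compose à la carte: `simulate_movie()`, `detect_spots()`, `link_spots()`,
`extract_traces()`, `count_steps()`, `correct_stoichiometry()` (with
`tidy()`, `glance()`, `autoplot()` methods), `particle_to_entity()`,
`group_fractions()`, `receptors_per_cell()`.

Model-level quantities need no simulation at all:

```r
100 * binomial_label_prob(2, 2, 0.8)   # 64: dimer labeled on both subunits
forward_observe(c(0.435, 0.467, 0.049, 0.049, 0), 0.8)[1]  # ~0.57 one-step
receptors_per_cell(c(0.22, 0.76), 1200)  # 260, 910
```

A command-line wrapper lives at `inst/scripts/pb-pipeline.R`:

```sh
Rscript inst/scripts/pb-pipeline.R --config cfg.json --seed 1 --out run1
```

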