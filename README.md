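# nucleomech

Quantitative image analysis of nuclear-mechanics assays in R.

When cells sense substrate stiffness, the mechanical state of their nucleus
changes on several axes at once: tension across the nuclear envelope,
chromatin compaction, envelope wrinkling, the front–rear distribution of
envelope proteins in polarised cells, cytoskeletal organisation, and
ultimately spreading and motility. Measuring these requires a set of
bespoke image-quantification procedures that usually live in unpublished
microscope-side scripts. nucleomech implements them as one tested,
scriptable package:

| pipeline | readout | core quantity |
|---|---|---|
| `microrheology` | cytoplasmic viscoelasticity from tracer beads | MSD(τ) = ⟨[x(t)−x(t−τ)]² + [y(t)−y(t−τ)]²⟩ₜ; MSD = 4Dτ + b |
| `spectral_fret` | nuclear-envelope tension (Nesprin sensor) | inverted FRET index = I(≈480 nm)/I(≈530 nm), higher = more tension |
| `flim_compaction` | chromatin compaction (H2B FRET pair) | truncated-exponential MLE lifetime τ̂, higher = less compaction |
| `nuclear_morphometry` | envelope wrinkling / invagination | EOP = (outline + internal folds)/convex-hull perimeter ≥ 1 |
| polarity maps | front–rear bias of NE proteins | top-20% occupancy maps; mirror-KS and Cramér–von Mises tests |
| `cell_quant` | YAP localisation, heterochromatin foci, FAs, actin | N/C ratio, dots/µm², FA count, structure-tensor coherency |
| `motility` | 2D migration | mean speed, path persistence = net displacement/path length |

A synthetic-data module generates every input modality — bead movies at
100 fps, 15-channel 460–600 nm emission stacks, TCSPC decay histograms,
nuclei with controlled invaginations, polarised-nucleus image sets,
multichannel cell images, persistent-random-walk trajectories — with known
ground truth, so every stage is verifiable offline by parameter recovery.

## Worked example

Recover a diffusivity from simulated beads in the standard acquisition
regime (500 frames at 100 fps), then estimate a lifetime and an envelope
EOP:

```r
library(nucleomech)

sim <- simulate_brownian_tracks(D = 0.1, n_particles = 100,
                                n_frames = 500, dt = 0.01, seed = 1)
curve <- compute_msd_ensemble(
  data.frame(particle_id = sim$tracks$particle_id,
             x = sim$tracks$x_um, y = sim$tracks$y_um), dt = 0.01)
fit_diffusivity(curve)$D_um2_s
#> [1] 0.1015751

d <- synth_photon_decay(tau_ns = 2.5, n_photons = 1e5,
                        window_ns = 12.5, seed = 2)
fit_lifetime(d$hist)$tau_ns
#> [1] 2.516017

nu <- synth_nucleus(a_um = 8, b_um = 5,
                    invaginations = data.frame(angle = 1, depth_um = 2,
                                               width_um = 0.2),
                    pixel_size_um = 0.1)
compute_eop_skeleton(nu$skeleton, nu$mask)$eop   # truth: 1.0482
#> [1] 1.043989
```

The fitted D is within 2% of the true 0.1 µm²/s, the lifetime within 1% of
the true 2.5 ns, and the skeleton-mode EOP within 0.5% of the generator's
closed-form value — these recoveries, at stated tolerances, are what the
acceptance suite checks.

Every assay is also a CLI subcommand operating on files:

```sh
Rscript -e 'nucleomech::run_cli()' simulate brownian --seed 1 --out beads
Rscript -e 'nucleomech::run_cli()' msd --tracks beads.csv --dt 0.01 --out msd_out
```

Subcommands: `simulate`, `msd`, `fret`, `flim`, `eop`, `polarity`,
`ncratio`, `dots`, `facount`, `coherency`, `spreading`, `motility`. Same
seed and config ⇒ byte-identical CSV output.

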