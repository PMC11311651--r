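---
title: "Quantifying cell invasion on a posts-and-channels microfluidic chip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell invasion on a posts-and-channels microfluidic chip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and its two readouts

`bladderchip` quantifies cancer-cell invasion in an organ-on-a-chip assay
in which cells embedded in Matrigel in a central microfluidic channel
invade toward an adjacent, nutrient-rich channel. The channels are
separated by a row of 16 cylindrical posts (150 µm diameter, 200 µm
edge-to-edge gaps), which creates 17 inter-post thresholds (IPTs) — the
spaces a cell must traverse to change channels. A serum gradient across
the chip (10% FBS above, 1% charcoal-stripped serum below) makes the
invasion directional, toward the upper channel.

Invasiveness is scored per chip and day with two metrics:

1. **IPTs crossed, out of 17.** Window $k$ counts as crossed if any cell
   has any part of its body past the *post outer edge* line (75 µm above
   the post-center line for the default geometry) with x inside window
   $k$. Vertical window boundaries sit at post centers; windows are
   half-open $[x_{lo}, x_{hi})$ so a boundary point belongs to exactly
   one window.
2. **Maximum invasion distance.** The furthest extent of any cell beyond
   the *post-center* line, in µm, clamped at zero.

The two reference lines differ by half a post diameter; the assay defines
crossing at the outer edge but measures distance from the center line,
and the package keeps both in `chip_geometry` rather than conflating
them. Crossing is judged on the full pixel footprint of a detection, not
its centroid, because invading cells extend processes across the
threshold well before their centroid follows.

```{r, eval = FALSE}
library(bladderchip)
geom <- build_geometry()     # 16 posts, 150/200 um, 17 windows
geom$crossing_boundary_y_um  # 75
```

## Coordinate frame and geometry choices

The physical frame puts the origin at the left end of the post row on the
post-center line, +y toward the upper channel, so the crossing boundary
is y = +75 µm and distances are positive. The published channel length
(3 cm) far exceeds the span of 16 posts at 350 µm pitch (5.8 mm); the
posts therefore occupy a 5.8 mm *active window*, and the first and last
IPT windows are closed by the active-window edges. This preserves both
the printed post dimensions and the printed 17-window count; end windows
are 275 µm wide, interior windows 350 µm.

Images are mapped to this frame by an affine `calibration` (µm/px, the
pixel of the physical origin, and the image orientation). The assay
publication reports everything in µm and never states a magnification, so
synthetic data default to 1 µm/px.

## Imaging and segmentation

Cells are detected by thresholding (Otsu by default, or a fixed value)
followed by 4-connected component labeling, with components below
`min_area_um2` (default 50 µm², roughly an 8 µm cell cross-section)
discarded as debris. Brightfield frames — cells dark on a bright, dusty
background — are inverted and median-flattened first so the same
bright-foreground rule applies. Touching cells are deliberately *not*
split: both readouts are insensitive to under-segmentation, since a
merged blob crosses a window or reaches a maximal y exactly where its
constituent cells do.

Labeling positivity (the fraction of brightfield-detected cells that
carry a fluorescent label, which determines whether fluorescence imaging
can stand in for total-cell imaging) is computed by greedy nearest-first
centroid matching within `match_radius_um` (default 15 µm, about one cell
diameter); each fluorescence detection matches at most once. The assay
publication gives no matching rule — this one is the package's choice.

## Statistics

Group comparisons follow the assay's stated procedure: one-way ANOVA
(classical sums-of-squares decomposition) followed by Tukey HSD, with the
Tukey–Kramer statistic
$q = |\bar y_i - \bar y_j| / \sqrt{\tfrac{MS_w}{2}(1/n_i + 1/n_j)}$ and
adjusted p-values from the studentized-range distribution
(`stats::ptukey`, numerically accurate far beyond the 1e-4 needed here).
α = 0.05 throughout. The replicate unit is the chip: each chip
contributes one observation per metric per day, matching "mean ± SD over
independent experiments" reporting. Star annotations follow the
dose-response figure convention (* p<0.01, ** p<0.001, *** p<0.0001);
the assay's earlier figures use only the *** level, so the report labels
its convention explicitly. Dose–response summaries report mean ± SD per
dose plus a monotone-trend flag that is TRUE when per-dose means are
non-increasing (flat included — a flat profile is consistent with
non-increase, and the flag is a direction check, not a test).

## The synthetic-data generator

No microscopy data are deposited for this assay, so the package ships an
agent-based simulator that generates ground-truthed experiments with the
statistical structure the analysis assumes. Each cell is a biased random
walker: per step, $\Delta x \sim N(0, \sigma)$,
$\Delta y \sim N(\mu_{\mathrm{eff}}, \sigma)$, with
$\mu_{\mathrm{eff}} = \mu / (1 + \mathrm{dose}/IC_{50})$, reflecting off
post discs (radially) and channel walls. Day 0 seeds cells uniformly in
the central channel; the non-invasive phenotype is seeded in clusters
(cohesive colonies) and given zero drift — no attractive forces are
simulated, because clustered seeding plus zero drift already reproduces
the scored behavior (no crossings). Cell division is not simulated;
neither metric depends on proliferation over a 2-day window.

**Calibration of defaults.** The publication contains no dynamical
model or migration-rate measurements, only endpoint snapshots, so all
rates here are synthetic calibration: chosen once so the default arms
reproduce the assay's qualitative orderings, then frozen.

| parameter | default | rationale |
|---|---|---|
| drift µ | 7 (T24-like), 8 (J82-like), 0 (RT4-like) µm/step | day-1 maximum distances on the order of 10² µm; J82-like slightly ahead of T24-like, matching the reported ordering |
| diffusion σ | 6 µm/step (invasive), 2 (non-invasive) | spread without overwhelming the drift signal (σ/µ < 1) |
| steps/day | 24 | hourly updates |
| cells/chip | 400 | compute-scaled stand-in for the assay's ~5000 cells/µL seeding; the metrics depend only on the invasion front, which is already dense at 400 agents |
| IC50 | 1 µM | low end of the assayed 0/1/10/100 µM range, so every nonzero dose produces a visible, ordered effect as the assay reports |

What the generator does *not* emulate: proliferation, cell–cell adhesion
during migration, Matrigel mechanics, the actual shape of the serum
gradient (drift direction only), and the small but nonzero invasion
distances of the non-invasive line (simulated RT4-like chips score
exactly 0). A green closed-loop test therefore establishes that the
measurement pipeline recovers what the simulator stated, not that the
simulator is a faithful biophysical model.

## Rendering, ground truth, and numerical conventions

The renderer draws each (labeled) cell as a Gaussian blob
(`psf_sigma_um` default 4 µm ≈ 10 µm cell blurred by the PSF; peak 1000
counts over background 100) on an `acquisition_grid`, adds white noise at
the stated SNR, and quantizes to 8/16-bit. At the nominal half-peak
threshold a blob segments to a disc of radius
$r_\mathrm{eff} = \sigma\sqrt{2\ln 2} \approx 4.7$ µm.

Ground-truth scores are computed from agent positions alone, treating
each agent as a disc of $r_\mathrm{eff}$ *discretized to the pixel
centers of the same acquisition grid*. Discretizing the truth is
deliberate: footprint-based scoring can only see what a pixel center
samples, so a sub-pixel sliver of a disc poking into a window is invisible
to any imaging measurement; a continuous-disc truth would count it and
systematically disagree with a perfect measurement. The truth path still
shares no code with the measurement path (no rendering, no noise, no
labeling, no segmentation). Residual closed-loop disagreement comes from
pixels whose noise-free intensity sits within a few noise SDs of the
threshold and from blob-tail overlap between nearby cells; at high SNR
this affects on the order of 1% of chips, within the 95% agreement the
acceptance criterion demands. Other conventions: distances clamp at 0;
day-over-day folds with a zero day-1 baseline are flagged undefined, not
infinite; downward invasion (into the lower channel, rare in the assay)
is counted as a diagnostic but never scored.

## Design decisions that were genuinely open

- **IPT indexing is 1-based** (1..17), the R convention, everywhere in
  the API and output tables.
- **TIFF I/O is built in.** No TIFF reader exists in the package's
  dependency environment, so a minimal uncompressed grayscale
  baseline-TIFF codec (8/16-bit, multi-page, both byte orders on read) is
  implemented directly and cross-validated against an independent Python
  reader in the test suite. Anything the codec cannot represent raises a
  format error instead of being misread.
- **Run configs are JSON** (the nested key-value format available in the
  dependency environment), with per-image JSON sidecars carrying
  calibration, seed, config digest and package version for provenance.
- **Per-chip seeds** are derived deterministically from the experiment
  seed, so one integer reproduces an entire multi-arm experiment,
  images included.

## Known limitations

- The brightfield segmentation rule (invert + median flatten + Otsu) is a
  stand-in for the manual counting the assay used; positivity rates from
  it are only as good as that rule.
- The closed-loop acceptance check runs at high SNR by design; noise
  robustness is covered separately (recall/precision ≥ 0.95 at SNR 5)
  and degrades below that.
- Simulated non-invasive chips score exactly zero, so fold differences
  against them are undefined in simulation, while the real assay reports
  small nonzero baselines; printed fold values can only be reproduced
  from the published group means, which is what the acceptance report
  does.
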