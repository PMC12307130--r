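---
title: "Quantifying communal roosts from weather-radar reflectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying communal roosts from weather-radar reflectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Swallows and martins roost communally at night and depart together around
sunrise. On a nearby surveillance weather radar this synchronized
departure appears as an expanding doughnut-shaped ring of reflectivity,
visible scan after scan for half an hour or so. Because the radar measures
a physically interpretable quantity — the backscattered power per unit air
volume — the ring is not just a detection: it can be converted into an
absolute number of birds. `roostradar` implements that conversion for a
fixed-strategy S-band radar (1.8° beam, 500 m gates, 294- or 360-azimuth
sweeps, a ~12-minute cadence within a 3-hour morning window), together
with the surrounding bookkeeping a multi-year monitoring analysis needs:
ground-clutter masking, detection-to-track linking, day-level sampling
classification, spatial clustering of roost sites, and cross-region
comparison.

## From reflectivity factor to birds

Radars report the reflectivity factor $Z_e$ in dBZ. The chain to a bird
count runs:

1. **dBZ to linear:** $Z = 10^{\mathrm{dBZ}/10}$ (mm⁶ m⁻³). Gates with no
   detectable echo carry an explicit sentinel (`NA`), distinct from
   0 dBZ, which is a real signal ($Z = 1$).
2. **Linear $Z$ to reflectivity $\eta$:**
   $\eta = 10^3 \, \pi^5 \lambda_{cm}^{-4} \, |K_m|^2 \, Z$
   (cm² km⁻³), the density of scattering cross section per unit air
   volume, with $\lambda = 10$ cm and $|K_m|^2 = 0.93$ for water at
   S band. At these values $\eta \approx 28.46\,Z$.
3. **$\eta$ to density:** dividing by the radar cross section (RCS) of one
   bird gives birds km⁻³. The default RCS is 15.2 cm², the published
   value for a 51 g Purple Martin — the largest Hirundinidae in the
   Americas, so counts are conservative. The mass–RCS power law
   $\log_{10}\mathrm{RCS} = 0.699 \log_{10} m$ is exposed as
   `rcs_from_mass()`; note it yields 15.6 cm² at 51 g. The 15.2 default
   is retained deliberately, for fidelity to the published analysis;
   users preferring internal consistency can set
   `quant_config(sigma = rcs_from_mass(51))`.
4. **Density to birds:** each gate's density multiplies its sampling
   volume (next section); gate contributions are summed over the
   annotated bounding box. Gate membership is by centre-point-in-rectangle
   on the flat-earth ground projection — no partial-gate weighting —
   matching pixel-level extraction from rendered scans.

Pixels with raw dBZ above 30 or below 5 are unlikely to be swallows or
martins (rain and insects, respectively) and are discarded. The filter is
applied to *raw* measured dBZ before clutter subtraction; filtering on
corrected values would make the 5 dBZ floor depend on the mask. The order
is configurable but this default is deliberate.

## Beam geometry and azimuthal oversampling

The sampling volume of one range gate is modelled as a conical frustum of
full beamwidth $\theta = 1.8°$: face radius $r\tan(\theta/2)$ at slant
range $r$ (the $\tan$ form is chosen over the small-angle $\theta/2$; the
difference is below 0.01% here but a contract must pick one).

The radar steps its antenna by $\Delta\varphi = 1°$ (360-azimuth
strategy) or $360/294 \approx 1.22°$ (294-azimuth strategy) — both
*smaller* than the beamwidth, so adjacent beams overlap and a wedge of
air is sampled twice. The intersection volume of two adjacent gate
frustums is estimated by Monte Carlo: points uniform in the first frustum
(ranges $\propto r^2$, directions uniform in the cone), tested against
the second axis. The overlap fraction $f$ is range-independent, so one
draw (default $10^5$ points, seeded, standard error reported) serves
every gate; the degenerate limits $f(0)=1$ and $f(\Delta\varphi \ge
\theta)=0$ are returned analytically. In the small-angle regime $f$ has a
circle-lens closed form, which the test-suite uses as an independent
oracle: $f \approx 0.331$ at $1°$ and $\approx 0.206$ at $1.22°$.

Birds in each intersection are split evenly between the two owning beams:
a gate contributes $N_{left}/2 + N_{core} + N_{right}/2 = d\,V_{full}(1 -
f)$. The suite verifies conservation: summed over a full uniform ring,
the halved contributions equal density × the Monte-Carlo union volume of
all beams, for both strategies.

Counts use only the first sweep (0.9° elevation): higher sweeps either
overlap it (the beam is wide) or overshoot the dispersal. No
earth-curvature, refraction, or range-bias correction is applied — roosts
occur at close range, and range biases are a documented limitation rather
than a modelled effect.

## Ground-clutter masking

Low beams near the radar persistently intercept trees and buildings,
producing a ring of mid-level reflectivity within ~27.5 km. A roost caught
inside it would be overcounted. The mask is the per-gate mean $\eta$ of
the *quietest* scans — those at or below the lower 2% quantile of summed
linear reflectivity within 27.5 km (summation in linear units: dBZ sums
are dominated by gate count; the statistic and sweep are configurable).
Ties break by timestamp and the cutoff count is
$\max(1, \lfloor q \cdot n \rfloor)$, so selection is deterministic. One
mask is built per (elevation, azimuth-strategy) pair.

Subtraction is gate-wise in linear $\eta$ with a floor at zero — negative
scatterer densities are meaningless. The complement,
$\min(\eta, \bar\eta)/\sigma$ integrated over the same corrected volumes,
is reported as `clutter_birds`, so `uncorrected = corrected +
clutter_birds` holds exactly on every box.

## Tracks, days, seasons

Detections are linked scan-to-scan: each box joins the track of the
previous-scan box it overlaps the most (raw intersection area; IoU is a
config alternative), ties resolved by nearest centroid, matching greedy
and one-to-one in descending overlap so losers found new tracks. Tracks
never bridge scan gaps. A track's size estimate is its **peak** count —
the dispersal's fullest visible moment.

A day is **sampled** if it has ≥ 6 in-window scans (a third of the 15
scheduled) and no radar failure, precipitation, or anomalous propagation.
Contaminated days still register **presence** when a roost is visible,
but never contribute to totals; a **true zero** is a sampled day with
full-field visibility and no detection anywhere ("full-field visibility"
is operationalised as the absence of the contamination flags — no finer
visibility rule is available). Daily abundance is the sum of peak counts over
the day's rain-free tracks; clutter-mixed tracks are included by default
(their counts were corrected by the mask) with a switch to drop them.

Roost-site structure across a season comes from flat-kernel mean-shift
clustering of track first-centroids (the package implements the standard
fixed-point iteration directly; modes merge within half a bandwidth). The
bandwidth defaults to 10 km — roughly the footprint of one dispersal —
and is deliberately a visible parameter, since no principled value
exists. Labels `CL0000, CL0001, …` are ordered by member count, ties by
centroid easting, so labelling is deterministic and order-free. A cluster
is **stable** if occupied ≥ 30 distinct days in every observed year
(an artifact convention, recorded in the output), else a satellite.

Region comparison (`compare_regions`) computes per-year means and SDs of
daily totals over sampled days only, their ratio, and the sampled-area
ratio. Fed the published season summaries for Manaus (mean 71,606
birds/day over 90,000 km²) and the Great Lakes (56,956 over 787,229 km²),
it returns the ratios 1.26 and 8.7.

## The synthetic-scene generator

The radar archives behind real analyses are not redistributable, so the
package carries a first-class generator (`simulate_series()`) producing
polar scan series with known ground truth:

- **Roost rings** of specified total bird number $N$: at scan $k$ since
  first appearance, gates in the annulus $[k \cdot \text{expansion},
  k \cdot \text{expansion} + \text{width}]$ receive uniform density
  $d = \text{fraction}_k \cdot N / \sum V_{full}(1-f)$ — the generator
  *inverts the same forward model* quantification applies, so recovery
  tests isolate pipeline bugs rather than model mismatch, and recovery of
  $N$ is exact up to floating point. A `naive_volume` flag generates with
  the uncorrected volume instead, demonstrating the ~$f$ bias the overlap
  halving removes. Rings are placed on the first sweep only, where
  counting happens.
- **Clutter**: a static log-normal-textured annulus (default mean
  $\eta = 300$ cm² km⁻³ ≈ 10 dBZ between 5 and 20 km), seen through
  i.i.d. per-gate mean-one log-normal jitter each scan. Jitter is
  per-gate rather than per-scan so quiet-scan selection ranks scans by
  their clutter content, not by a shared scan-level multiplier, and mask
  error shrinks as $1/\sqrt{k}$ with scans averaged.
- **Precipitation**: circular blobs of fixed dBZ (default 45) that
  overwrite weaker signal on their active dates; matching day flags are
  emitted.

Signals combine additively in linear units, then convert to dBZ; silent
gates carry the sentinel. Everything is reproducible from one integer
seed. Default ring geometry (1.5 km expansion per scan, 3 km width) and
bird numbers (8,000–100,000) are **synthetic conventions** chosen so that
ring pixels land strictly inside the 5–30 dBZ acceptance band at their
sites — no published values for Amazonian ring expansion exist. The
dispersal's airborne-fraction profile (default peaking at 1.0 mid-track)
emulates the ramp-up/dissipation of a real departure.

What the generator does **not** emulate: insect blooms, anomalous
propagation physics (represented only as a day flag), Doppler or
dual-polarization fields, beam refraction, partial beam blockage, or
range-dependent sensitivity loss. Passing recovery tests therefore
demonstrates the pipeline's internal correctness — conversion, geometry,
masking, linking, bookkeeping — not robustness to every contamination a
real archive contains.

## Numerical choices and test scales

- Monte Carlo: $10^5$ points for the overlap fraction (stderr ≈ 0.0015),
  $2 \times 10^5$ for union volumes; seeds fixed via configuration; the
  direction draw uses a spherical cap, exact for a cone about its axis
  and within $O((\theta/2)^2) \approx 2.5\times10^{-4}$ relative of the
  flat-capped frustum at 1.8°.
- Bundled scenes use 360 azimuths × 100 gates (50 km) and about a week of
  15-scan days — small enough that the full suite runs in well under a
  minute while every stage still sees multi-day, multi-roost,
  contaminated, failed, and true-zero days.
- The container format stores dBZ grids as text at 17 significant
  digits, so write/read round-trips are bit-exact.
- Timestamps are UTC throughout; the sampling window is the fixed local
  interval [05:00, 08:00), half-open, rather than a solar-ephemeris
  window: at near-equatorial latitude the sunrise drift is minutes, and a
  clock window keeps the scan count per day exactly reproducible. The
  window and UTC offset are configurable for other radars.

## Worked example

```{r, eval = FALSE}
library(roostradar)

scene <- demo_scene(seed = 1)                 # 8 days, 2 sites, clutter,
                                              # 1 rain day, 1 failure day
masks <- build_masks(scene$series)            # lower-2%-quantile clutter
det   <- quantify_boxes(scene$series, scene$annotations, masks = masks)
tracks <- track_table(track_series(det))
summarize_days(scene$series, tracks)
cluster_roosts(tracks, bandwidth = 10)
```

## Known limitations

- Counts assume a single species-typical RCS; mixed-species roosts with
  very different body masses are counted in Purple-Martin equivalents.
- No range-bias correction: distant roosts are underestimated relative to
  near ones, as in the original analysis this mirrors.
- The clutter mask is a static average; transient clutter (anomalous
  propagation) is excluded only via day flags, never per-gate.
- Mean-shift results depend on the bandwidth; report it alongside any
  cluster count.
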