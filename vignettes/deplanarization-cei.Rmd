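---
title: "Simulating Coulomb-explosion imaging of ultrafast deplanarization in 2-thiouracil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating Coulomb-explosion imaging of ultrafast deplanarization in 2-thiouracil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Planar heterocycles such as the thionated nucleobase 2-thiouracil relax after
UV excitation through internal conversion that formally requires breaking the
planar symmetry: the molecule must move out of its own plane. Time-resolved
Coulomb-explosion imaging (CEI) can watch this happen. An intense X-ray pulse
strips the molecule at a chosen pump-probe delay, the resulting atomic
cations repel each other, and a reaction microscope records all fragment
momenta in coincidence. The peripheral protons turn out to be excellent
messengers: in a suitably chosen molecular frame their emission directions
form four compact features whose loss of compactness reports the loss of
planarity.

`ceisim` implements the computational chain behind this kind of analysis as
a tested, seed-reproducible pipeline:

1. **synthetic geometries and trajectories** that emulate the geometric
   signatures of the excited-state dynamics (module `R/geometry.R`,
   `R/deform.R`, `R/xyz.R`),
2. **an instantaneous point-charge Coulomb-explosion integrator**
   (`R/explode.R`, `src/explode.cpp`),
3. **symmetry-adapted molecular-frame momentum representations**
   (`R/frames.R`, `R/histograms.R`),
4. **pump-probe delay-scan statistics** (`R/scan.R`), and
5. **configuration-driven entry points** (`R/pipeline.R`,
   `inst/cli/ceisim.R`).

## The explosion model

Every atom is replaced in place by a point charge (+1 e by default: singly
charged atomic fragments) and Newton's equations of motion are integrated
for the pure pairwise Coulomb repulsion, from rest, in Hartree atomic units:

$$ m_i \ddot{\mathbf r}_i \;=\; \sum_{j \ne i} q_i q_j
   \frac{\mathbf r_i - \mathbf r_j}{|\mathbf r_i - \mathbf r_j|^3}. $$

The integrator is an adaptive-step velocity Verlet written in C++ with the
step tied to the instantaneous minimum pairwise distance,
`dt = eta * sqrt(m_min * d_min^3 / max(q_i q_j))`, which resolves the stiff
early repulsion and grows quickly afterwards, so an explosion of the
twelve-atom molecule converges in a few thousand steps (about 40 ms). The
integration stops once the residual potential energy falls below
`pe_tolerance` (default `1e-5`) of the total energy; momenta at that point
are reported as asymptotic. With the default step control (`eta = 0.0015`)
total energy is conserved to better than `1e-6` relative, total momentum to
round-off (pairwise force accumulation), and the two-body closed form
$|p| = \sqrt{2\mu\, q_1 q_2 / r_0}$ is matched to `1e-6` relative.

Two model properties matter for interpretation. First, the kinetic energy
release equals the full initial Coulomb energy, a known overestimate of real
explosions (no finite charge-up time, no neutral fragments); this largely
cancels in the *normalized* momentum representations used throughout.
Second, a planar geometry exploded from rest keeps all momenta exactly in
the plane (reflection symmetry of the force field), which is what makes the
molecular-frame proton coordinates symmetry diagnostics.

## Molecular frames

Two frames are built per coincidence event from the S\(^+\) and O\(^+\)
momenta:

* **Recoil frame** (`to_recoil_frame()`): the S momentum defines the z axis,
  the O momentum spans the y-z plane with \(p_{O,y} \ge 0\), x completes a
  right-handed system, and all momenta are divided by \(|p_S|\). Newton
  plots (`newton_plot()`) are projections of these normalized momenta; for
  the planar ground state the four protons give four cleanly separated
  features in the y-z view.

* **Sum/difference frame** (`to_sumdiff_frame()`): z' along
  \(p_S - p_O\), x' along the in-plane component of \(p_S + p_O\), y'
  completing the right-handed frame. Proton emission is reported as
  \((\Phi, \cos\Theta)\) with \(\Phi = \pm180^\circ\) identified. The axis
  assignment was the one genuinely open choice in the frame definition; this
  orientation was validated once against the simulated planar layout (two
  protons at the poles, one at \(\Phi = 0\), one wrapping at
  \(\pm 180^\circ\)) and then frozen.

The scalar `cos_alpha()` — the cosine of the relative S/O emission angle —
is the momentum-space proxy for the C-S/C-O bond-vector angle. For the
packaged planar ground state (bond-vector angle 116°) the twelve-body
explosion yields \(\cos\alpha \approx -0.42\), i.e. a momentum-space angle
of about 115°: the mapping from position to momentum space is remarkably
faithful for this pair, which is what makes the angle a useful observable.

## The synthetic generator and what it emulates

No Cartesian coordinates of 2-thiouracil are hard to come by at this level
of idealization: the packaged planar skeleton was generated once with a
standard molecular-mechanics embedding (RDKit ETKDG + MMFF94 for the thione
tautomer), projected exactly onto its principal plane, and the exocyclic
C-S/C-O bond-vector angle set exactly to 116°, the ground-state value. It
ships both as code (`build_s0()`) and as a versioned fixture
(`inst/extdata/s0_2tu.xyz`, labelled synthetic).

Hydrogen site labels are not dictated by any table; they were assigned once
so that the simulated planar layout reproduces the canonical angular map:
H10 (on N1) and H12 (on C5) at the poles, H9 (on N3) at \(\Phi = 0\), H11
(on C6) wrapping at \(\pm180^\circ\). H9 is deliberately the
*triangle-attached* equator proton, so that the early pyramidalization
mechanism acts on it directly. One cosmetic consequence of the frozen x'
orientation is that the O ion sits near \(\Phi = 0\) rather than at the
wrap; nothing downstream depends on it.

Two deformation operators emulate the excited-state geometries:

* `apply_c2_pyramidalization()` (G2): C2 and the two N-attached protons
  rotate about the N1-N3 axis. The operator moves all three by the stated
  angle; the *generator preset* uses a modest C2 angle (10°) with the
  protons amplified 4.5-fold (`h_factor = 4.5`, i.e. 45° swings). The split
  matters: a decomposition of the simulated response showed that C2's own
  displacement (which perturbs the S and O momenta and hence tilts the
  frames) moves *every* proton feature, while each proton's displacement
  moves only its own feature. A dominant proton flap with a modest ring
  pucker is therefore what produces the cleanly staged observables — and is
  also the physically sensible picture, the floppy N-H bends swinging much
  further than the ring carbon.
* `apply_sulfur_oop()` (G3): the C2-S bond vector rotates out of the ring
  plane (default 40°) and stretches (default +0.1 Å). During trajectory
  synthesis the three-dimensional C-S/C-O angle is additionally steered to
  its late-time value of 104° (`target_co_cs_angle`), blended in with the
  sulfur ramp so the ground state is untouched.

`synth_excited_trajectory()` combines both with smooth logistic onsets.
`tau_pucker` (default 65 fs) and `tau_s` (default 130 fs) mark the times by
which each deformation is essentially (95%) established; the logistic is
centred at `tau - ramp_width/2` with a 5-95% rise width `ramp_width`
(default 30 fs). This convention reflects the step-like time dependence of
the region integrals seen in this class of experiments — the H9 feature is
already depressed at the first measured delay — and makes the onset
detector's contract (`onset = earliest delay departing by > 2 combined
errors`) line up with the nominal onset times. Amplitudes below 5% before
`tau - ramp_width` keep the t = 0 frame at the (thermally sampled) ground
state.

Ensembles (`synth_trajectory_ensemble()`) add three kinds of realism:
independent thermal initial conditions (out-of-plane Gaussian displacements,
default `sigma_oop = 0.05` Å per atom, which reproduces the observed
nonnegligible out-of-plane emission of the unpumped molecule), random
out-of-plane *signs* for both deformations (symmetry breaking has no
preferred side), and lognormal per-trajectory amplitude jitter (sigma 0.25)
emulating the spread of deformation amplitudes across an excited-state
ensemble.

What the generator does **not** emulate: electronic structure of any kind
(no surface hopping, no forces), finite charge-up time, sequential
ionization, charge transfer, in-plane vibrational motion, or detector
acceptance beyond Gaussian momentum smearing. Passing tests therefore show
that the *analysis chain* recovers staged out-of-plane motion from fragment
momenta under the stated model; they do not validate any statement about
real excited-state dynamics beyond that model.

## The delay scan and its statistics

`simulate_delay_scan()` mirrors the experimental protocol: at each delay
(default 65, 130, 260, 1000 fs) the trajectory-ensemble frames at that time
are exploded; each simulated coincidence event draws an excited geometry
with probability `excited_fraction` (default 0.2 — the experiment excites
only part of the population; the exact fraction is not knowable, so it is a
config parameter) and a thermal ground-state geometry otherwise. An
unpumped reference set is always produced. `detector_model()` adds Gaussian
momentum noise (default `sigma_p = 8` a.u. per component, roughly a 7°
angular smear on the protons, chosen so simulated features have widths
comparable to measured ones) and enforces the threefold coincidence: one
S\(^+\), one O\(^+\), and one proton chosen uniformly among the four.

Angular maps are normalized to the integrated number of ions per delay
step; all errors are Poisson on the raw counts, propagated through
normalization, differences (`difference_distribution()`), region integrals
(`integrate_region()`) and scaling (`scale_to_reference()`). Histogram
smoothing (`smooth_hist()`) uses an edge-renormalized Gaussian kernel that
preserves the integral exactly; the kernel and its default width (0.05 in
cos α) are package choices, no particular kernel being canonical.

The three default regions (`default_region_boxes()`) were frozen after
validating them on simulated planar layouts and scans:

* `H9`: \(|\Phi| < 15^\circ\), \(\cos\Theta \in (-0.25, 0.35)\),
* `H11`: within 30° of \(\Phi = 180^\circ\), same \(\cos\Theta\) band,
* `filament`: \(|\Phi| \in (105^\circ, 140^\circ)\),
  \(\cos\Theta \in (-0.1, 0.6)\) — the printed filament band in
  \(\cos\Theta\), restricted in azimuth to the corridor between the
  in-plane features where deplanarized ensembles accumulate their proton
  trails while the planar ensemble leaves it essentially empty (its inner
  edge sits more than 3.5 feature widths from the planar H11 feature, so
  pucker-phase tail broadening does not fire it early).

Tight boxes are essential: with boxes much wider than the features, a
feature can shift without any box count changing, and the onset detector
(`onset_order()`, threshold `k = 2` combined standard errors against the
unpumped baseline) goes blind. All boxes are user-configurable.

With the default study conditions (24 trajectories per ensemble, 20,000
events per delay, 200 ground-state pool geometries) the pipeline recovers
the staged ordering essentially deterministically: H9 drops at 65 fs, H11
at 130 fs, and the filament rises at 130 fs. Swapping the two onset times
destroys the H9-first ordering, but does not strictly invert it: once the
sulfur leaves the plane the frame itself tilts, so *all* features respond —
H9 and H11 then depart together at the first delay. That asymmetry is a
property of the frame construction, not a bug: the early pucker is visible
*only* in H9 precisely because the sulfur is still in plane.

## Numerical choices and degenerate inputs

* Units: coordinates in Å, masses in amu (most abundant isotope), times in
  fs at the interface; atomic units internally
  (1 Å = 1.8897261255 bohr, 1 amu = 1822.888486 m_e).
* Events whose frame is undefined (S and O momenta parallel; degenerate
  sum/difference) are dropped with a warning and counted, never silently.
* \(\Phi\) is wrapped onto \((-180°, 180°]\); ±180° are identified.
* Region membership is decided by bin centres; re-binning that merges bins
  exactly conserves counts.
* Near-empty regions can produce formally infinite z-scores; the onset
  detector treats a zero combined error with zero difference as no
  departure.
* Seeds: every stochastic stage takes an explicit integer seed and is
  bitwise reproducible; scan outputs record the seed and a hash of the full
  configuration.

## Problem sizes used in the tests

The test suite runs the full physics at reduced but honest scales: the
ground-state reference ensemble uses 2000 exploded geometries (about two
minutes), and the onset-recovery property runs 20 independent replicates of
the full scan (24 trajectories, 20,000 events per delay). Unit tests use
ensembles of a few hundred explosions. These sizes were chosen so the
statistical contracts (two-sigma onsets, 95% recovery) are meaningful while
the whole suite stays comfortably runnable on a laptop.

## Known limitations

* The Coulomb explosion is instantaneous and purely Coulombic; absolute
  kinetic energies are overestimates by construction and only normalized
  momentum observables should be compared to measurements.
* The generator imitates geometric signatures with three tunable presets;
  amplitudes (10°/45° pucker split, 40° sulfur bend) are package choices,
  not literature values — only the 116° and 104° bond-vector angles and the
  65/130 fs staging are anchored.
* Carbon and nitrogen fragments are propagated by the integrator but play
  no role in the analysis chain (their measured momenta are known to be
  smeared by charge-up dynamics, which this model does not cover).
* The detector model is Gaussian smearing plus coincidence selection; there
  is no acceptance, dead-time or false-coincidence modelling.
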