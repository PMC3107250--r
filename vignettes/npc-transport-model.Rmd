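---
title: "A coarse-grained Brownian-dynamics model of nuclear pore transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained Brownian-dynamics model of nuclear pore transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

The nuclear pore complex (NPC) gates all traffic across the nuclear
envelope (NE). Cargos larger than ~5 nm cross only when bound to a
karyopherin (kap) transport receptor, whose surface binding spots interact
hydrophobically with the phenylalanine-glycine (FG) repeat domains that
line the pore. `npcbd` implements a coarse-grained bead-spring model of
this machine and simulates single-cargo import with Brownian dynamics.

The model lives in a 2D cross-sectional plane containing two opposing
spokes of the (eightfold-symmetric) pore. Three groups of proteins are
represented:

* **Poms** anchor the structure: each channel-wall bead is tied to a fixed
  point in the rigid NE by a Hookean spring.
* **Structural nups** form the elastic main scaffold — cytoplasmic
  filaments, an hourglass central channel, and the nuclear basket rods
  meeting a distal ring — discretized into beads (~10 nm spacing) joined
  by harmonic bonds, with cosine-bending angles for rigidity.
* **FG-nups** are discrete wormlike chains (WLC) grafted on the scaffold;
  every chain bead is one FG motif. Short chains (50 nm contour) line the
  central channel and are mutually cohesive; long chains (200 nm) occupy
  the cytoplasmic and nuclear peripheries and have no mutual affinity.

The default build places 720 FG motifs. With two of eight spokes in the
plane this scales to 2880 per pore, inside the wild-type range of
2700–3000 — the model's own consistency argument for its FG density.

The cargo-complex (cargo plus kap) is a rigid sphere carrying a
"hydrophobic arc with limited capacity": eight equal-affinity binding
spots spaced over a semicircle of its surface. A cargo with no spots is
*inert* — it keeps its excluded volume but has no attraction — and probes
the selectivity barrier.

## Energies and forces

Five interactions act between beads (energies in kT, lengths in nm):

1. **Harmonic bonds**, `E = k_s (r - r0)^2 / 2`, for scaffold rods and pom
   springs. Spring constants derive from an elastic modulus of 17 kPa (the
   measured NE average, used for the scaffold for want of direct NPC
   measurements) via `k = E A / r0`, with an effective rod cross-section
   of 100 nm².
2. **Cosine bending**, `E = k_theta (1 - cos(theta - theta0))`, with
   `k_theta = 100 kT` for the scaffold (the smallest value that keeps the
   assembly stable) and `k_theta = kT l_p / L_s ≈ 0.043 kT` for FG chains,
   tied to the persistence length `l_p = 0.43 nm` measured for FG domains
   by AFM. Scaffold equilibrium angles are taken from the as-built
   geometry, so the assembled pore is stress-free; chain angles use
   `theta0 = pi` (straight).
3. **Marko–Siggia WLC force** between consecutive chain beads,
   `F = (kT/l_p) [1/(4(1-x/L_s)^2) - 1/4 + x/L_s]`, with segment contour
   `L_s = 10 nm` (≥ 10 persistence lengths, the discrete-WLC validity
   condition). The force diverges as `x -> L_s`; see the rejection scheme
   below.
4. **Hydrophobic attraction**, `E = -eps (exp(-r/xi) - exp(-r_c/xi))` with
   a 10 nm cutoff `r_c`, applied kap–FG (`eps = 2 kT`, `xi = 1.5 nm`,
   between binding spots and every FG bead) and FG–FG (`eps = 1.5 kT`,
   `xi = 1 nm`, between central-channel FG beads only). Only the strength
   and characteristic length are constrained by the colloid-science
   measurements they derive from, not the algebraic form; the
   cutoff-shifted single exponential is the standard long-range
   hydrophobic form in that literature, and it is deliberately kept
   swappable. The kap–FG choice exceeds FG–FG at every distance —
   transport receptors are collectively the more hydrophobic species.
5. **Soft excluded-volume repulsion**,
   `E = eps_rep (exp(-r/sigma) - exp(-r_c/sigma))` with `eps_rep = 100 kT`,
   `sigma = 1 nm`, cutoff 1.35 nm, between all nonbonded pairs. It is
   finite at contact (~74 kT), which is what permits the large diffusive
   time step; against the cargo, `r` is measured bead-center to cargo
   surface so cargo size matters.

There is no other energy source: transport is driven entirely by thermal
noise plus these passive interactions.

## Integration

Everything works in reduced units: energy kT (T = 310 K — the unique
temperature at which the tabulated diffusion coefficients match
`kT/(6 pi eta R)` at `eta = 5 cP`), length nm, time 0.1 ns. Each mobile
bead follows the explicit overdamped Langevin update

```
x <- x + F D dt + N(0, 2 D dt)   per component,
```

with `D = kT / (6 pi eta R)` from free-draining Stokes drag; the
hydrodynamic radius equals the geometric radius implied by the bead's
lumped mass at the average protein density (1.35 g/cm³). FG beads have
R = 0.9 nm (D ≈ 50 µm²/s); a 15 nm cargo has D ≈ 6.1 µm²/s.

Two rejection rules follow each proposed step:

* **Finite extensibility** (Öttinger's scheme): any bead whose move would
  take an adjacent WLC segment to ≥ `f_max L_s` is reverted to its
  previous position; the pass repeats until no violation remains. The
  threshold `f_max = 0.99` operationalizes "near or beyond the contour
  length", which is otherwise unquantified. Rejection is
  per bead, not a whole-timestep redraw — the cheapest scheme consistent
  with the description.
* **Rigid envelope**: the NE is a rigid slab spanning the channel's axial
  extent on both sides of the hourglass wall profile (+2 nm margin). It
  exerts no force; moves into it are rejected. This is needed because a
  bead-discretized wall with a 1.35 nm repulsion cutoff is geometrically
  permeable to 0.9 nm beads. The cargo's finite radius is handled by
  testing eight perimeter points of its circumference.

Randomness comes from one xoshiro256++ stream per run (polar-method
normals), seeded from the run's integer seed, so batches are exactly
reproducible run by run. Nonbonded pairs come from a cell-list-built
neighbor list with a 2 nm skin, rebuilt whenever accumulated displacement
could let an unlisted pair reach a cutoff; an O(N²) brute-force evaluation
is kept as the test oracle.

## The import protocol

`run_transport()` relaxes the FG layer without cargo (default 10⁶ steps =
0.1 ms; the relaxation length is a free choice of this implementation), places the cargo
on the pore axis above the filament tips — outside the kap–FG cutoff of
every FG bead, so the start event is detected dynamically — and
integrates. Events:

* `t_start`: first step at which any binding spot is within the kap–FG
  cutoff of an FG bead belonging to a *cytoplasmic-filament* chain.
* `t_end`: first step at which the whole cargo sphere lies inside the
  basket region (fully past the nuclear-ring plane, above the distal
  ring). RanGTP-mediated release is modeled as instantaneous: the run
  stops there. The first-passage time (FPT) is `t_end - t_start`.

Transport runs bound the open compartments with a reflecting box around
the pore. Like starting the cargo near the entry, this concedes that the
cytoplasmic search for the pore is outside the simulated problem:
unbounded 2D diffusion returns to the pore only after impractically long
excursions. The box is config-exposed and lies far enough out not to
touch the transport pathway.

## Observables

All observables are pure functions of the recorded track/contact data.

* **Radial distribution** (`radial_probability()`): 1 nm histogram of the
  distance from the pore axis over in-channel samples, with a Gaussian
  peak ± SD summary.
* **Binding-spot occupancy** (`occupancy()`): the mean number of spots
  *participating in the hydrophobic interaction* — at least one FG motif
  within the 10 nm kap–FG cutoff — averaged over engaged steps. This
  reading reproduces the model's ≈7.9-of-8 occupancy; counting only
  close contacts (below) yields ≈3 and cannot.
* **Bond lifetimes** (`bond_lifetimes()`): a bond episode is a maximal run
  of consecutive steps during which a given (spot, motif) pair is within
  the *contact radius*, default 3 nm = 2·xi — the width of the interaction
  well. The 10 nm force cutoff is deliberately not used here: it would
  register near-permanent bonds, contradicting the nanosecond-scale mean
  lifetime. This contact radius is the model's largest free parameter for
  lifetime statistics and is config-exposed.
* **Shuttles** (`shuttle_count()`): completed entry → mid-channel → entry
  round trips before final passage, from axial crossing analysis. The
  mid-channel plane is the channel's axial midpoint; the entry plane is
  the cytoplasmic mouth.
* **Channel residence** (`channel_residence_fraction()`): fraction of the
  FPT window spent with the cargo center between the channel planes.

First-passage statistics live in `fit_invgauss()` and friends: the FPT of
drifted Brownian motion to an absorbing wall follows the inverse Gaussian
`f(t) = sqrt(lambda/(2 pi t^3)) exp(-lambda (t-mu)^2 / (2 mu^2 t))`; the
closed-form MLE is `mu-hat = mean(t)`,
`lambda-hat = n / sum(1/t - 1/mu-hat)`. Goodness of fit is reported
descriptively as the maximum empirical-vs-fitted CDF discrepancy, with no
p-value claimed. `drift_estimate()` gives `v = L/mu` over the 160 nm
span; `free_diffusion_fpt()` gives the 1D baseline `L²/2D` for a freely
diffusing particle (0.4 ms for a 3 nm cargo over 160 nm).

## Full-scale and surrogate experiments

The headline numbers of the model — mean FPT 2.6 ± 0.13 ms for a 15 nm
cargo over 150 runs, 53% channel residence, 7%/46% inert-cargo success on
intact/filament-deficient pores — require ~10⁷–10⁸ steps per run times
dozens of runs: cluster work. The package implements that full protocol
(`run_batch()` on the default structure), and its test suite instead
validates the physics on desk-scale systems:

* analytic parameterization and structural counts (desk, exact);
* a physics oracle suite: every force is the negative energy gradient;
  a bead in a harmonic well samples the Boltzmann variance kT/k; free-bead
  MSD reproduces 4Dt; tethered WLC extension never reaches the contour
  length; neighbor-list and brute-force forces agree to 1e-10; the IG MLE
  recovers known parameters; a 1D drift-diffusion simulation matches the
  closed-form inverse Gaussian by CDF comparison;
* transport surrogates on `make_fixture("mini_npc")`, a 90 nm-span pore
  with a 40 nm waist and 312 FG motifs.

The mini pore's design choices matter and are deliberate:

* filament and channel brushes keep the full model's *local* FG density
  (motifs per unit cross-section area), so burial, occupancy and barrier
  physics carry over;
* the peripheral chain contour (90 nm) is set so the chains' random-walk
  extent covers the entrance radius — in the full geometry the 200 nm
  chains do exactly that. Shorter chains leave an open axial corridor and
  no selectivity barrier exists at all;
* the basket brush is thinner than scale because "complete loading into
  the basket" must remain geometrically reachable when the basket is only
  ~2.7 cargo diameters deep (5+ in the full model).

What the surrogates show: active 15 nm cargos complete import with most
binding spots participating; held in the channel, the cargo avoids the
axis (its radial mode sits off-axis and it spends far less time near the
axis than a uniform occupancy would put there — in a corridor only ~1.9
cargo radii wide, a literal near-wall peak cannot appear); an 8-run
ensemble of passive 3 nm passages has a right-skewed FPT sample (a 3–5 run
active sample is too small for a meaningful skewness estimate); and inert
15 nm cargos approach the pore more closely when the cytoplasmic filaments
are deleted, at matched seeds. What they do not show: the quantitative
headline values above, which depend on the full 160 nm span, the full 720
motifs and ≥50-run ensembles.

The generator of the structure itself (`build_npc()`) is deterministic
given its seed; initial FG conformations are self-avoiding random walks at
0.8 of the segment contour, so no segment starts near the extensibility
limit.

## Numerical choices and degenerate inputs

* Time step `dt = 1` (0.1 ns). Lifetime statistics scale with `dt`
  (their floor is one step), and the integrator accepts any positive
  `dt`, e.g. 0.1 for a 0.01 ns production step.
* Bending forces at collinear geometries (sin theta -> 0) are evaluated by
  the smooth limit when `theta0` is 0 or pi, and dropped (measure-zero
  configuration) otherwise; zero-length bonds and overlapping angle beads
  raise errors naming the defect.
* `r0 = 0` harmonic wells are allowed (isotropic tether); the force
  vanishes smoothly at the center.
* The pair-potential exponentials use a range-reduced polynomial `exp`
  kernel (relative error ~1e-12); the neighbor-list-vs-brute-force oracle
  test bounds any resulting force discrepancy at 1e-10.
* Degenerate FPT samples (zero dispersion) make `lambda-hat` diverge; this
  is signalled as an error rather than returning infinity.

## Limitations

* 2D cross-section with two spokes: no azimuthal escape routes, and
  absolute entropic barriers differ from 3D; the per-pore FG scaling
  (×8/2) is a bookkeeping device, not a geometric equivalence.
* Free-draining drag: no hydrodynamic coupling between beads.
* The cargo does not rotate; its binding arc is body-fixed. With the 10 nm
  interaction cutoff this approximates a coherent FG-binding stripe.
* RanGTP biochemistry is reduced to instantaneous release at the basket;
  molecular crowding and competing traffic are absent.
* The exact algebraic forms of the hydrophobic and repulsive potentials
  are modeling choices constrained only by their parameters —
  they are the main model-fidelity risk and are isolated behind
  `hydrophobic_rule()`/`repulsive_rule()`.
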