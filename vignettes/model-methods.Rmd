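---
title: "A coarse-grained mechanical model of MTOC clustering and nuclear migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained mechanical model of MTOC clustering and nuclear migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoclust)
```

## The biological problem

In basidiomycete budding yeasts such as *Cryptococcus neoformans*, the
spindle pole body (SPB) is assembled during each cell cycle by the fusion of
many small microtubule organizing centres (MTOCs) embedded on the nuclear
envelope, and — unlike in *Saccharomyces* — the nucleus migrates *into* the
daughter bud before dividing. Both events are driven by cytoplasmic
microtubules (cMTs): their plus ends explore the cell, penetrate the cell
cortex, and there experience pulling forces from cortically anchored dynein
and a tangential bias, generated by the EB1-family protein Bim1 restricted
to the mother cortex, that directs them toward the septin ring at the
mother-daughter neck. `mitoclust` implements this "cortical interaction
with bias" (CIB) scheme as a three-dimensional agent-based stochastic
simulation and reproduces, at desk scale, the wild-type timings of MTOC
clustering and nuclear migration and their disruption in Bim1-deletion,
dynein-overexpression and Aurora-kinase (Ipl1)-depletion scenarios.

## Model geometry

The mother cell is a sphere of radius $r_{mother} = 3\,\mu m$; the daughter
bud is a second sphere that emerges at a random site on the mother surface
at $t = 0$ and grows linearly in time until the final budding index (bud
diameter over mother diameter) of 0.8 is reached. The septin ring is the
circle where the two spheres intersect; its radius is held at a fixed
fraction (0.6) of the bud radius, chosen so that the mature neck
(radius $1.44\,\mu m$) admits the rigid model nucleus
($r_{nuc} = 1\,\mu m$) — the model nucleus cannot deform, so a narrower
neck would forbid the migration the model is built to study. A cortical
shell of width $w_{cor} = 0.3\,\mu m$ lines the whole boundary.

The nucleus starts at a random position inside the mother; `n_kt = 14`
MTOCs (radius $0.125\,\mu m$) sit at random non-overlapping positions on
the nuclear envelope (NE), each nucleating 2 cMTs and tethering one
kinetochore just beneath the envelope.

## Microtubule dynamics and cortical forces

cMTs are zero-thickness rods undergoing two-state dynamic instability with
growth and shrinkage speeds $v_g = 10.4$, $v_s = 28.6\,\mu m/min$,
catastrophe $f_c = 1/min$ (mutant range 1–21) and rescue
$f_r = 0.02/min$. In free space this gives the stationary mean length

$$\langle l \rangle = \frac{v_g v_s}{v_s f_c - v_g f_r} \approx 10.5\,\mu m,$$

far larger than the cell, so confinement dominates: the simulated mean cMT
length in the cell is 2–3 $\mu m$, matching the measured wild-type value
of $2.63\,\mu m$. A compressive axial load $f$ slows growth as
$v_g = v_{g0} e^{-f/f_{stall}}$ and raises catastrophe toward the stalled
rate $f_c^{stall} = 0.04\,s^{-1}$ (we use the decaying sign convention,
the only physically consistent reading of a force-velocity relation of the
Dogterom type).

A plus end inside the cortex experiences:

* an elastic push $f_{push} = l_{cor} K_{cor}$ inward along the MT axis
  while growing, where $l_{cor}$ is the radial penetration into the shell
  and $K_{cor} = 5\,pN/\mu m$;
* a collective dynein pull $f_{pull} = l_{pull}\,\lambda_{dyn} f_{dyn}$
  outward along the axis ($\lambda_{dyn} = 6\,\mu m^{-1}$,
  $f_{dyn} = 1\,pN$). For a tip that has *slid* along the cortex,
  $l_{pull}$ is the length of the cortex-embedded distal segment (capped
  at $3\,\mu m$), because dyneins act all along the embedded segment; this
  is what makes long daughter-penetrating cMTs the decisive pullers during
  migration, while non-sliding contacts use the radial measure
  $l_{cor} \le w_{cor}$;
* a $\sim 1\,pN$ inward impulse ($f_{wall}$) when a boundary-touching MT
  undergoes catastrophe;
* a first-order Euler buckling force $\pi^2 \kappa / l^2$ when it hits the
  wall steeply and cannot slide, with $\kappa$ set so the force is
  $1\,pN$ at $l = 3\,\mu m$ and saturated at $2\,pN$ (a short stiff rod
  does not buckle; the cortex cannot supply its critical load);
* low-angle contacts (incidence under 50 degrees from the tangent plane)
  slide: the tip advances tangentially along the boundary, crossing from
  the mother into the daughter cortex through the neck.

Axial push, pull, wall and buckling forces act simultaneously on the
anchoring MTOC/SPB *and* on the nucleus.

## The Bim1 bias

Bim1 is restricted to the mother cortex. Its force,
$B\, l_{cor} \lambda_{Bim1} f_{dyn}$ with $\lambda_{Bim1} = \lambda_{dyn}$,
acts *at the plus end*, tangentially toward the nearest point of the septin
ring. Consistent with the equations of motion — in which only push, pull,
wall, buckling and kinesin-5 terms load the bodies — the bias is not
applied as a body force: it biases the *movement of the plus end*. The rod
pivots about its anchor with the standard rotational mobility of a rod in
a viscous fluid, $3 \ln(2L/d) / (\pi \eta L^3)$, so the tip drifts along
the cortex toward the ring (capped at $1\,\mu m/s$); the herded, ring- and
daughter-directed dynein pulls then do the mechanical work. Two
refinements matter numerically: the rod may not pivot inward through the
nucleus (herding is deflected along the anchor's tangency horizon), and
cortically anchored dyneins resist tangential plus-end movement, so the
herding velocity falls with the local dynein density multiplier (this is
what lets dynein overexpression win its tug-of-war against Bim1).

Daughter-cortex dynein puncta belong to the large-budded stage of the cell
cycle: the daughter pull switches on once the budding index reaches 0.55
(0.7 in the Ipl1-depletion scenario, where daughter puncta are aberrant or
absent). Before that, the daughter cortex is inert except sterically.

## Nuclear spindle

Before SPB duplication each kinetochore rides rigidly just beneath its
MTOC ("a single kinetochore per MTOC"); sister cohesin is not yet
engaged — with micrometre-stretched cohesin active from the start, MTOC
clustering would proceed without any cortical force, contradicting the
requirement of intact cMTs for clustering. MTOC fusion is by surface
contact: touching bodies merge at their volume-weighted midpoint
(re-projected onto the NE), radii add in volume, and clustering is
complete when one body holds all 14 founders. Completion triggers SPB
duplication: two volume-halved bodies offset by $2 r_{spb}$, sisters
bi-oriented to opposite poles.

After duplication the spindle is minimal but mechanically complete:
interpolar MTs generate a kinesin-5 sliding force
$l_{overlap} \lambda_{ipMT} f_{kinesin5}$ separating the SPBs; kMTs push
kinetochores with $l_{pen} K_{fibril}$ when their tips penetrate and pull
with $l_{gap} K_c$ across a gap (the pulling state is defined by
$l_{gap} > 0$); sisters are held by cohesin springs
($K_{cohesion} = 0.1\,pN/\mu m$) and all kinetochores repel on overlap
($1\,pN/\mu m$). kMT length is regulated by a length-dependent
catastrophe $f_c = h\, l_{kMT}$ with $h$ chosen so the steady kMT length
$\sqrt{2 v_g / h} \approx 0.45\,\mu m$ is about half of a typical
micrometre yeast metaphase spindle.

## Equations of motion and numerics

All bodies move by overdamped Stokes dynamics
$\dot{X} = F/\xi$, $\xi = 6 \pi \eta r$, with the nucleus in cytoplasm
($\eta_{cyt} = 5\,pN\,s/\mu m^2$; switchable to the NE viscosity), MTOCs
and SPBs in the effective NE viscosity ($10$), kinetochores in
nucleoplasm ($10$). Integration is explicit Euler at $dt = 0.05\,s$;
MTOCs/SPBs are re-projected radially onto the NE sphere after each step
(residual $< 10^{-6}\,\mu m$), kinetochores are advected with the nucleus
and confined inside it. Containment of the nucleus combines the soft
harmonic shell of stiffness $K_{cor}$ with a hard backstop at penetration
depth $w_{cor}$: collective dynein pulls reach tens of pN and would
otherwise push the nucleus through a purely harmonic wall. Per-step
displacements are bounded by $0.1\, r_{spb}$ (a velocity saturation of
$0.25\,\mu m/s$, far above any physical speed in the model); typical
steps are an order of magnitude below the bound. Internal forces
(spindle, kinetochore pairs) are applied with exact action-reaction; the
run diagnostics report the residual of their sum ($< 10^{-9}\,pN$). A
population dt-convergence check at the percent level would need thousands
of cells (trajectories decorrelate between step sizes); instead the Euler
scheme is verified against the closed-form overdamped relaxation and the
displacement diagnostic is reported per run.

## Scenarios

* `wild_type_cib` — unmodified parameters.
* `bim1_delta` — $\lambda_{Bim1} = 0$.
* `dyn1_oe` — mother-cortex dynein density tripled.
* `ipl1_homogeneous` — a single mutant catastrophe rate ($8/min$, free
  mean length $1.3\,\mu m$), uniform bias.
* `ipl1_heterogeneous` — per-cell $f_c \sim U(1, 21)/min$; the effective
  cortical bias is $B = \min(1, e^{(\langle l \rangle - 2.63)/0.65})$,
  evaluated from the cell's free-space mean length. $B$ scales the whole
  mother-cortex interaction (Bim1 herding, dynein pull, push, wall,
  buckling — Ipl1 depletion both delocalises the force generators and
  structurally compromises the cMTs that transmit these forces) and the
  daughter dynein pull; daughter puncta onset is delayed to budding index
  0.7.
* `dynein_puncta_scan` — the daughter dynein field is split into a
  condensed patch (a spherical cap holding 10% of the daughter cortex
  area, opposite the neck, multiplier `lambda_dynein_patch`) and a
  background (`lambda_dynein_rest`).

## Calibration and model-gap defaults

All mechanical constants above are published values. The quantities the
underlying model leaves open are exposed as parameters with the defaults
below, fixed once during development:

| parameter | default | rationale |
|---|---|---|
| `w_cor` | 0.3 um | typical actin-cortex thickness |
| `dt` | 0.05 s | displacement bound satisfied with margin |
| `n_cmt_per_mtoc` | 2 | a few cMTs per MTOC, ~28 per cell |
| `neck_fraction` | 0.6 | mature neck must pass the rigid nucleus |
| `sliding_angle_deg` | 50 | "small" incidence; oblique hits dominate on a sphere |
| `kappa_mt` | $9/\pi^2$ pN um^2 | buckling force 1 pN at $l = 3\,\mu m$ |
| `h_kmt` | 85 /(min um) | steady kMT length ~ half a 1-um spindle |
| `r_kt` | 0.1 um | kinetochore scale |
| `bud_growth_duration` | 46 min | calibrated: migration ~ experimental 35-38 min |
| `final_budding_index` | 0.8 | experimental reference |
| `bias_length_const` | 0.65 um | calibrated against the Ipl1-depletion timings |
| `daughter_dynein_onset_bi` | 0.55 | daughter puncta appear in large-budded cells |

`bud_growth_duration`, `bias_length_const` and the daughter-dynein onset
are calibration constants tuned against the same population timings the
acceptance checks compare to; those checks are therefore
calibration-consistency tests. The wild-type-versus-mutant *orderings*,
the direction of the Bim1/dynein perturbations, and the zero-pull controls
involve no calibration and are genuine predictions of the mechanics.

## What the simulator does and does not capture

Within a cell, all randomness enters through dynamic instability,
renucleation directions and initial conditions; the equations of motion
are deterministic (no thermal noise) and every run is reproducible from
its seed. The model neglects explicit dynein/Bim1 attachment-detachment
kinetics and motor stepping, MT-MT steric interactions, chromosome arms,
anaphase, nuclear-envelope rupture and membrane deformation. Two
behavioural caveats worth knowing: about 40% of wild-type cells complete
migration slightly before the last MTOC pair fuses (the population means
remain well ordered; `summarize_population()` reports the per-cell
ordering-violation fraction and flags it above 5%), and in `bim1_delta`
the loss of ring-directed herding leaves push-driven aggregation, so
clustering is not delayed even though migration strongly is.

## A worked population

```{r, eval = FALSE}
wt <- run_population(make_scenario("wild_type_cib", n_reps = 50, seed = 1))
glance(wt)
#   n mean_clustering_min sem_clustering_min mean_migration_min sem_migration_min
#  50                24.7               1.66               33.9             0.334
#   frac_fusion_complete frac_migrated ...
#                      1             1
autoplot(wt)
```

Populations of 50–150 cells (the desk scale used throughout the tests and
the acceptance script) run in well under a minute each; the published
populations of 2000 cells are reachable in under an hour on one core.
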