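---
title: "Modelling lipid-droplet biogenesis at the seipin cage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lipid-droplet biogenesis at the seipin cage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droplens)
```

## The biological problem

Lipid droplets (LDs) bud from the endoplasmic reticulum (ER) when
triacylglycerol (TG), normally dissolved at low mole fraction in the
bilayer, nucleates an oil lens between the leaflets.  Seipin, an
11-subunit (undecameric) ER membrane protein, marks and catalyses these
events.  Each subunit contributes a lumenal domain, a hydrophobic helix
(HH) that dips into the lumenal leaflet and forms a ring of radius about
2 nm, and two transmembrane (TM) segments whose positively charged
terminal residues anchor at the cytosolic membrane interface.

`droplens` implements the computational workflow for studying this
system across resolutions: reduced-resolution contact analysis of
atomistic simulations, position-dependent lipid diffusion, construction
and desk-scale simulation of a highly coarse-grained (CG) seipin/lipid
model, and morphology metrics for the forming oil lens.  Because the
production trajectories behind such studies are large and external, the
package ships generators that synthesize data with the same statistical
structure, so every analysis stage is testable end-to-end.

## Reduced-resolution mapping

Atomistic frames are first reduced to molecular groups: each POPC
molecule becomes 11 groups (choline head, phosphate, glycerol moiety and
four tail groups per acyl chain), each TG molecule 13 groups (glycerol
moiety plus four tail groups per each of three chains, i.e. 12 tail + 1
glycerol), and each protein residue a backbone and a side-chain group.
Group positions are **mass-weighted** centers; the geometric alternative
was rejected so that the grouped molecule preserves the atomistic center
of mass exactly (a tested invariant).

Chain carbons are divided into four contiguous blocks as evenly as
possible, with extra carbons assigned to the terminal-most blocks, and
ester/carbonyl atoms are assigned to the glycerol moiety so the
hydrophilic unit stays intact.  The shipped atom tables use
CHARMM36-style heavy-atom names; hydrogens are attached to the group of
their nearest heavy atom at mapping time, which makes the same tables
serve united-atom and all-atom inputs.  Unknown heavy-atom names fail
loudly rather than being guessed.

```{r mapping}
schemes <- build_default_schemes()
sapply(schemes, function(s) nrow(s$groups))
```

## Coordination statistic

Per-residue protein-lipid contacts are quantified by summing, over
lipid groups, the rational switching function
$s(r) = [1-(r/r_0)^6]/[1-(r/r_0)^{12}]$ with $r_0 = 0.4$ nm.  The
package evaluates the algebraically equivalent, singularity-free form
$1/(1+(r/r_0)^6)$; the identity holds to machine precision and is
tested.  Distances use the minimum-image convention in the orthorhombic
box.  No cutoff is applied by default (the function decays as $r^{-6}$).
Only side-chain groups probe the lipids; normalizations per molecule
($\|s\|$, dividing by the PL or TG molecule count) and per grouped atom
($\|s_A\|$, dividing by 12 tail or 1 glycerol group per TG) are
provided.  Errors come from three equal-length trajectory blocks:
the reported value is the mean of block means, the error their standard
error.

## Position-dependent diffusion

Lateral diffusion is measured relative to the protein: every frame is
translated so the reference selection's (the lumenal domain's) center of
mass sits at the origin, hence a uniform drift of the whole system
cancels exactly.  Molecules are then classified by their time-averaged
planar (XY) distance from the origin into three zones — within 3.5 nm
(just beyond the HH ring), 3.5–7 nm (the TM zone) and beyond 7 nm
(protein-free) — with boundary ties assigned inward.  The lateral
diffusion coefficient is the slope of the time- and ensemble-averaged
planar MSD over a fit window, divided by $2 \times 2$ dimensions.  Two
undocumented choices were fixed here and exposed as arguments: the MSD
is planar (2D), matching the radial classification of leaflet lipids,
and the default fit window spans lags of 10–50% of the maximum lag.
Block averaging over three sub-trajectories supplies errors.  Confined
molecules (e.g. PLs trapped inside the HH ring) produce an MSD that
levels off; `detect_confinement()` flags curves whose late-lag slope
falls below 20% of the early slope — a labelled heuristic, not a fitted
quantity.

```{r diffusion}
tr <- gen_brownian(200, c(free = 1.0), n_frames = 500, dt_us = 0.01,
                   seed = 1)
fit_diffusion(msd(tr, max_lag = 100))$D  # ground truth: 1 nm^2/us
```

## The coarse-grained seipin model

The CG resolution follows the lipids: linear four-site PL (head,
interfacial, two tail beads) and TG (glycerol, three tail beads)
molecules, and one protein bead per four consecutive residues (the
Arg23–Arg265 construct gives 61 beads per subunit, the final block
holding three residues).  Every bead carries 200 g/mol and no charge.
Bond energies use the convention $k(r-r_0)^2$ — no 1/2 prefactor — with
$k$ quoted in kcal/mol/Å² throughout, and PLs carry a harmonic angle of
0.5 $k_BT$ about 180°.

Protein shape is maintained by an elastic network: either a homogeneous
ENM (spring constant 0.2 or 2 kcal/mol/Å², cutoff 15 Å) or a
heterogeneous network (hENM) obtained by iterative fluctuation matching
against an aligned ensemble, with candidate pairs within 12 Å and weak
0.1 kcal/mol/Å² backfill springs below 11 Å for pairs (notably between
subunits) not covered by the matched network.  The matching acts on
**pairwise distance fluctuations**: spring constants are updated
multiplicatively by the ratio of model to target distance variance
(damping exponent 0.6) until the worst relative mismatch is below 0.1%.
Model-side variances are computed analytically from the network Hessian
(equilibrium covariance $k_BT\,H^+$ with the rigid-body null space
removed), not by simulation.  Two caveats are tested and documented:
a rigid (zero-variance) ensemble drives constants to a cap with a
warning, and recovery of a *known* network is only guaranteed when the
candidate set is identifiable — true spring lengths clearly below the
cutoff and non-spring distances clearly above it.  On ambiguous
geometries the matched variances still converge but individual constants
are not unique.

Twenty-four PL molecules are placed inside the HH ring, oriented like
the lumenal leaflet (heads toward the lumen), flagged as part of the
protein and tied into its elastic network.  Attraction scaling factors
multiply the depth and force of pair attractions linearly: protein beads
in the hydrophobic phase attract PL tails with factor 1 (the lipid-lipid
strength), interfacial protein beads attract PL interfacial beads with
1.5, and the TG-attractive beads — two HH beads plus the four central
beads of each TM segment per subunit — attract TG with 1.5.  The TM
terminal tips attract the membrane interface (PL interfacial and head
beads) with a configurable factor `tip_scaling`, the knob used to mimic
tip-charge mutants; its default 1.5 represents the wild type.

Because the structural model of seipin lives in an external repository,
the package includes an idealized, $C_n$-symmetric cage generator
(`gen_idealized_seipin()`): per subunit a 38-bead lumenal blob, a 5-bead
HH arc at the lumenal leaflet depth and two 9-bead TM segments rising to
a tip ring of default radius 7 nm — a 14 nm neck, inside the
experimentally measured 13–17 nm range.  Its default bead budget (61 per
subunit) matches the 4-residues-per-bead mapping.  All flags
(hydrophobic-phase, interfacial, TG-attractive, tips) are assigned from
depth in the membrane frame and are user-overridable, since the exact
residue windows behind them are structural rather than sequence-derived.

```{r cage}
cage <- gen_idealized_seipin()
model <- add_proteinized_pls(cage)
c(beads_per_subunit = n_beads(cage) / 11,
  proteinized = length(unique(model$mol[model$flags$proteinized_pl])),
  neck_nm = round(neck_diameter(cage), 2))
```

Spherical bilayers (two Fibonacci-lattice leaflets of four-site PLs,
heads outermost/innermost, TG scattered in the tail shell at the
requested mol%) and flat patches are built directly; embedding a protein
removes whole lipid molecules within a 0.5 nm clash cutoff (the
atomistic protocol's 0.9 Å cutoff is not transferable to beads of this
size).  Area per lipid defaults to 0.7 nm².

## The Langevin engine

The paper-scale production runs (10⁸ steps, 40–60 nm vesicles) belong to
LAMMPS, for which `export_lammps()` writes a data file (mass 200, zero
charge, bonds/springs as harmonic bond types, angles), tabulated pair
potentials per class pair and an input-script skeleton encoding the
production integrator settings (50 fs step, Langevin 310 K with 100 ps
coupling, 1.5 nm cutoff).  LAMMPS' `bond_style harmonic` shares the
$K(r-r_0)^2$ convention, so constants pass through unchanged.

For desk-scale experiments the package integrates the same model
internally: velocity-Verlet with BAOAB Langevin splitting, friction
$m/\tau$ and Gaussian noise satisfying fluctuation-dissipation.  Noise
is a counter-based deterministic function of (seed, step, bead, axis),
so trajectories are bit-reproducible and runs resume exactly from a
checkpoint.  The nonbonded form is not printed in the source literature
(it cites prior-work tabulated potentials), so the package ships a
documented parametric family: a Weeks–Chandler–Andersen repulsive core
(σ = 0.68 nm, ε_rep = 0.5 kcal/mol) plus a cosine-squared attractive
well reaching exactly `factor × eps_att` (default 0.7 kcal/mol ≈ 1.1
k_BT at 310 K) and vanishing smoothly at the 1.5 nm cutoff.  This makes
the "scaling factors change force and depth linearly" property exact by
construction.  Externally supplied tables can be used on the LAMMPS
side.  Neighbours come from a cell list over the periodic box; the
all-pairs path is retained and tested to give identical forces.
Nonbonded interactions are excluded within a molecule, across bonded or
spring-connected pairs, and among protein beads (whose internal
energetics are the elastic network's job).  Freshly built systems are
relaxed by displacement-capped steepest descent (`minimize_cg()`) before
dynamics.

Numerical guarantees covered by the tests: analytic forces match central
finite differences to 10⁻⁶ relative on a mixed 50-bead system; with the
thermostat off, total energy drifts by less than 10⁻⁴ relative over 10⁴
steps at a 5 fs step; with it on, a 200-bead fluid holds 310 K within 2%
over 10⁵ steps.

## Oil-lens morphology

TG molecules are clustered by single linkage: two molecules link when
their **minimum inter-bead distance** is below 2 nm (the most inclusive
reading of molecule-molecule distance, and the one that reproduces the
described merging of oil lenses), and clusters are connected components.
The nucleation percentage is the share of TG molecules in the largest
cluster.  Cluster shape is summarized by the relative shape anisotropy
$\kappa^2 = \tfrac{3}{2}\,\frac{\lambda_1^2+\lambda_2^2+\lambda_3^2}
{(\lambda_1+\lambda_2+\lambda_3)^2} - \tfrac12$ from the gyration-tensor
eigenvalues, which attains exactly the quoted limits: 0 for a sphere,
0.25 for a thin plane, 1 for a line.  The ER-LD neck diameter is twice
the mean in-plane radius of the TM tip beads about the complex's
principal (ring symmetry) axis — the circle-fitting procedure is not
otherwise specified, and the principal-axis construction is the
rotationally invariant choice.  Per-frame time series of these metrics
are annotated by a rule-based tagger: a jump in nucleation percentage
above 10 points per frame window marks a coalescence candidate,
sustained sub-threshold growth an Ostwald-ripening candidate.  These
tags are labelled heuristics with their thresholds recorded in the
output.

```{r metrics}
c(ball = anisotropy(gen_tg_cluster("sphere", 5000, seed = 1)),
  disc = anisotropy(gen_tg_cluster("disc", 5000, thickness = 0.005,
                                   seed = 1)))
```

## What the synthetic data does and does not show

The generators emulate the *statistical structure* each analysis
assumes: flat patches with TG either dissolved (all singleton clusters)
or collected in a lens; clusters of controlled shape for the anisotropy
limits; 2D Brownian walkers with known class-wise diffusion constants
and optional harmonic confinement (Ornstein–Uhlenbeck plateau); Gaussian
ensembles drawn exactly from a spring network's normal modes; and the
idealized cage geometry.  Every generator is deterministic per seed and
records its ground truth.  Passing the recovery tests therefore
demonstrates that the estimators are correct and unbiased on data
satisfying their assumptions — it does not demonstrate force-field
realism, nor reproduce the production-scale nucleation phase diagram,
which depends on prior-work tabulated potentials not printed in the
source and on cluster-scale simulation budgets.

Problem sizes used by the checks were chosen as the package's own
desk-scale defaults: 10,000-point clusters for the anisotropy limits;
500 walkers × 1000 frames for diffusion recovery (D̂ within 5%); a
20-bead, 5000-sample round trip for hENM (per-spring constants within
10%, RMSF within 5%); 100-molecule oracle comparisons for clustering;
and a 480-PL patch with 16 dissolved TG and a reduced-footprint cage
(tip radius 4.2 nm, 20,000 steps) for the qualitative demonstration that
the TG-attractive cage raises the nucleation percentage over a cage-free
patch at matched steps.  That last comparison is stochastic and
qualitative by nature; it is run at a fixed seed.

## Known limitations

* The internal engine targets thousands of beads for tens of thousands
  of steps; production-scale runs are delegated to LAMMPS via export.
* No pressure coupling (the vesicle runs are thermostat-only), no
  electrostatics (all beads are neutral by construction), no MARTINI
  model support.
* hENM constants are only identifiable when the candidate-pair topology
  is; see above.
* The idealized cage is a geometric stand-in with the documented ring
  dimensions, not a structural model of seipin.
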