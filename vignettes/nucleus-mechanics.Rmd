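---
title: "A coarse-grained nucleus model for chromatin-based nuclear mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained nucleus model for chromatin-based nuclear mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

nucmech simulates a cell nucleus as chromatin polymers confined in a
polymeric lamina shell, probes it with micromanipulation-style force
spectroscopy, and reads out genome organization (simulated DamID,
contact-frequency curves) before and after deformation. This vignette is the
package's account of the model, its parameters, the numerical choices, and
what the reduced-scale simulations can and cannot show.

## The model

**Chromatin.** Each chromosome is a triblock copolymer of beads of diameter
$\sigma$ (1 bead = 40 kb of chromatin, $\sigma \approx 150$ nm). The two
terminal beads are telomeres (`TEL`); a contiguous block at one end is
constitutive heterochromatin (`CON`); the remaining interior alternates
between facultative heterochromatin (`FAC`, B-type compartment) and
euchromatin (`EUC`, A-type) in blocks. At full scale a chromosome has
$N = 6002$ beads (two telomeres, 1000 CON, 5000 compartment beads), and the
nucleus holds eight chromosomes built as four copies each of two distinct
tracks. The facultative fraction of the compartment region is $f$, with
$f = 45\%$ the control condition.

**Lamina.** The nuclear lamina is a bead–spring spherical shell: lamina
beads placed uniformly at random on a sphere, bonded to near neighbors with
every degree in $[5, 8]$, forming one connected elastic network. At full
scale the shell has 15 000 beads at initial radius $R_i = 42\sigma$, is
shrunk to $R_s = 32\sigma$, and relaxes with the chromatin to
$R_0 \approx 29\sigma$, giving a chromatin volume fraction
$\phi = n_{\mathrm{chr}}\,(\pi/6)\sigma^3 \big/ \tfrac{4}{3}\pi R_0^3
\approx 23\%$.

**Potentials.** Non-bonded beads repel through a WCA core; attractive class
pairs (CON–CON 0.5, FAC–FAC 0.4, CON–FAC 0.3 $k_BT$, and the nonspecific
heterochromatin–lamina affinity $E_{HL} = 0.5\,k_BT$ for CON–LAM and
FAC–LAM) interact through a truncated, energy-shifted 12-6 well cut at
$2.5\sigma$. All pairs involving EUC or TEL are purely repulsive. Chain
bonds are Kremer–Grest FENE springs ($k = 30\,k_BT/\sigma^2$, maximum
extension $1.5\sigma$) with a WCA core, so chains cannot cross. Shell,
tether and crosslink bonds are harmonic springs ($k = 30\,k_BT/\sigma^2$)
with per-bond rest lengths plus a WCA core; they are permanent, and a hard
stability error triggers at $8\sigma$ extension (never approached in
practice — working extensions stay below $\sim 2\sigma$).

Two geometric choices make the shell behave like a thin elastic membrane at
every scale. First, lamina–lamina pairs use a reduced core diameter
($0.8\sigma$): with full-size cores the bead count fixes a jamming radius
*above* the relaxed radius, and the printed $R_i \to R_s \to R_0$ sequence
would be unreachable. Second, chromatin–lamina pairs use an enlarged
effective diameter ($1.2\sigma$): the meshwork presents an excluded
thickness that keeps chromatin from slipping through bond-network gaps
while the shell is still sparse during assembly. Shell bond rest lengths
are the build lengths scaled by a rest factor; the resulting pre-tension
sets where the composite's membrane tension balances the chromatin's
osmotic pressure. The rest factor is calibrated once against the
construction conditions (the target volume fraction and the relaxed-radius
ratio $R_0/R_s \approx 29/32$) and then frozen; it is a property of the
shell construction, not a per-experiment dial.

**Dynamics.** BAOAB Langevin integration at $k_BT = 1$, friction
$1/\mathrm{time}$, time step $0.01$ intrinsic units. The protocol time unit
is $\tau = 500$ integration steps. With friction and temperature zero the
integrator reduces to velocity Verlet, which the energy-conservation test
exploits. All noise comes from a seeded generator: identical seeds give
bitwise-identical trajectories.

## Assembly

Chromosomes start as compact chromatid-like blocks: a serpentine
space-filling walk through a cubic lattice (unit bonds, self-avoiding by
construction), randomized by a cube symmetry and coordinate jitter, placed
in non-overlapping grid slots near the center, with one global random
rotation. Fully random placement of dense lattice blocks interpenetrates
catastrophically at reduced scale, which is why placement is slot-based;
the assembly is still random in orientation and slot assignment.

The shell is built at $R_i$ and shrunk to $R_s$ by staged affine rescaling
of the lamina coordinates (default 10–15 stages) with dynamics between
stages, preceded by a displacement-capped soft start (cap $0.02\sigma$ per
step with a matching velocity clamp, and a bounded repulsive core) that
resolves residual overlaps without bond blow-ups. Free relaxation follows;
$R_0$ is measured as the time-averaged mean lamina radius over the
relaxation tail, and $\phi$ is recomputed from it. Stage durations are
configuration-exposed; the defaults were chosen by watching the radius and
the peripheral segregation of heterochromatin converge at reduced scale.

## Perturbation operators

All constraints are assigned *after* equilibration, from the instantaneous
geometry:

- **Tethers** (chromatin–lamina): every CON or FAC bead within
  $r_L \le 2.5\sigma$ of a lamina bead is tethered, with probability $P_t$
  (control $P_t = 1$), to its *nearest* lamina bead; at most one tether per
  chromatin bead. Constant-tether-number comparisons subsample the
  saturated set uniformly.
- **Crosslinks** (heterochromatin–heterochromatin): heterochromatin beads
  are visited in seeded random order; each is selected with probability
  $P_c$ (control 0.2) and greedily linked to in-contact
  ($r_H \le 2.5\sigma$), same-class partners with spare capacity, to a
  maximum of two crosslinks per bead. Telomeres are excluded; a bead may be
  both tethered and crosslinked.
- **Heterochromatin fraction**: FAC/EUC labels are flipped uniformly at
  random until the compartment FAC fraction equals the target (CON and TEL
  untouched, positions unchanged); constraints are assigned afterwards, so
  tether and crosslink numbers track $f$.

Tether and crosslink rest lengths equal their assignment distances, so
installation is jolt-free; the bonds are permanent.

## Force spectroscopy

Stretching mimics micromanipulation: a fixed group of lamina beads at each
pole (full scale: 80 beads with $|y| \ge 28\sigma$) is restrained through
its center of mass by a harmonic spring ($K = 20\,k_BT/\sigma^2$) to an
anchor moving outward at $v_{\mathrm{pull}} = 0.1\sigma/\tau$. Anchors
start at the pole-group centers so the initial spring extension is zero;
the nominal anchor origin $y_0 = \pm 60\sigma$ is retained as metadata. The
restraint force, the extension $\Delta L$ (change in distance between the
pole-group centers) and the strain $\lambda = \Delta L / R_0$ are recorded;
forces and centers are averaged over each recording interval, which is a
far better estimator than instantaneous samples. The effective spring
constant $k_{\mathrm{nuc}}$ is the least-squares slope of force versus
extension in a strain window (default $0.30 \pm 0.05$; the slope at 30%
strain is the standard readout). Uniaxial compression uses two repulsive
plates approaching along one axis, with the perpendicular directions free.

Reduced-scale protocols keep $K$ and $v_{\mathrm{pull}}$ in intrinsic units
and scale the geometry: pole cut $28/29 \cdot R_0$, pole group
$80 \cdot n_{\mathrm{lam}}/15000$ beads, and total anchor travel
$40/29 \cdot R_0$ per pole — the loading program that produces ~80%
terminal strain at full scale. Because the spring lag $2F/K$ is relatively
smaller at reduced scale, the reduced protocol overshoots the full-scale
terminal strain somewhat; the acceptance script reports the measured value.

## Genomic readouts

Contacts are bead pairs within $r_c \le 2.5\sigma$ (boundary inclusive;
computed by spatial partitioning and verified against brute force). $P(s)$
is the mean contact frequency of intra-chromosome pairs at genomic
separation $s$, restricted to a class filter (both ends in the filter),
averaged over snapshots; log-spaced binning (8 bins per decade) is
available. The simulated DamID contact index is 1 for a chromatin bead
within $r_L \le 2.5\sigma$ of any lamina bead and 0 otherwise, averaged
over frames; a bead counts toward the LAD percentage when its mean index is
at least 0.5 (contact in half the sampled frames). The deformation metric
is $|\Delta_{rel}(s)| = |(P_{\mathrm{after}}(s) -
P_{\mathrm{before}}(s))/P_{\mathrm{before}}(s)|$ with zero-baseline bins
dropped, plus its total summed over separations. Snapshots are sampled
evenly from the windows before and at/after the 30%-strain crossing (full
scale convention: 10 before, 110 after).

Genomic coordinates derive from 40 kb per bead (0.04 Mb); annotation
tracks, DamID profiles, $P(s)$ tables, contact maps and model snapshots all
export as plain text (BED-like, bedGraph-like, TSV, extended-XYZ-style).

## Reduced scales, and what they show

Everything in the package runs at three preset scales:

| preset    | chromosomes | lamina | typical use |
|-----------|-------------|--------|-------------|
| `full`    | 8 × 6002    | 15000  | the headline geometry; hours of compute |
| `reduced` | 2 × 600     | 1500   | acceptance-level physics; ~1–2 min per build, ~1 min per pull |
| `mini`    | 2 × 300     | 600    | unit tests and plumbing; seconds |

Reduced scales preserve the dimensionless state: radii are scaled so the
target $\phi = 0.23$ is reached at a relaxed radius with the full-scale
29:32:42 proportions, and protocols scale geometrically as above. They do
not preserve everything. The shell's membrane tension scales with radius,
so the untethered (pressure-borne) baseline stiffness is relatively larger
at reduced scale than at full scale, and the tethered/untethered stiffness
ratio is somewhat below the full-scale two-fold value at the smallest
scales; pole groups of 8 beads also make small-strain slopes noisy, which
is why stiffness comparisons are made at the 30%-strain point over paired
seeds (the same equilibrated nucleus pulled with and without constraints).
A small number of chromatin beads (a few percent) can pass the sparse
meshwork during assembly at reduced scale; they remain bonded to their
chains and have no visible effect on the readouts.

The synthetic annotation generator emulates compartment-scale block
structure with geometric block lengths (mean 25 beads = 1 Mb, the scale of
the contact-frequency analyses); real compartment tracks have long-range
correlations and chromosome-specific structure that the generator does not
attempt. Passing tests therefore show that the mechanical and contact
machinery behaves correctly for block-compartmentalized chromatin, not that
any particular cell type's compartment geography is reproduced.

## Numerical choices and degenerate inputs

- Neighbor lists: Verlet list with $0.4\sigma$ skin over a cell grid,
  rebuilt when any displacement exceeds half the skin; the production force
  path is tested for exact (1e-10) agreement with an $O(N^2)$ reference.
- Overlapping build coordinates are handled by the soft-start force cap and
  displacement/velocity clamps, never in production dynamics.
- A bond reaching its maximum extension, or any non-finite coordinate,
  aborts the run with the bond index and step (stability errors, not NaN
  propagation).
- Zero-length harmonic bonds guard the $1/r$ singularity.
- Ties in tether partner choice cannot occur for continuous coordinates;
  the nearest-partner rule makes the tether set deterministic given the
  geometry and the Bernoulli draws.
- Contact radii are inclusive ($r \le 2.5\sigma$) everywhere; the
  strict-vs-inclusive distinction is measure-zero for simulated
  coordinates.
- All stage seeds derive deterministically from
  (master seed, stage name, replicate index).

## Known limitations

Bonds never rupture and crosslinkers never exchange, so the model is
elastic by construction and cannot show viscoplastic flow or the softening
that bond turnover would allow. The shell has no bending rigidity beyond
its bond network and no anisotropy; nuclear pores and lamin-type
composition differences are out of scope. Hydrodynamic interactions are
absent. The force response beyond ~60% strain, where lamina bond alignment
dominates in the full-scale system, is not quantitatively meaningful at
reduced scale.
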