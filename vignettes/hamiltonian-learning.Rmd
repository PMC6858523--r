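---
title: "Learning molecular Hamiltonians in a local orbital basis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning molecular Hamiltonians in a local orbital basis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Quantum chemistry represents molecular orbitals in a basis of atom-centered
spherical functions. In that basis the electronic problem is the generalized
symmetric eigenproblem

$$\mathbf{H}\,\mathbf{c}_m = \epsilon_m\,\mathbf{S}\,\mathbf{c}_m,$$

where $\mathbf{H}$ is the effective one-electron (Fock/Kohn–Sham-type)
matrix, $\mathbf{S}$ the overlap metric of the non-orthogonal basis,
$\epsilon_m$ the orbital energies and $\mathbf{c}_m$ the molecular-orbital
coefficients. Orbital energies and coefficients are ill-behaved under
geometric deformation (level crossings, sign/phase freedom), but the matrix
pair $(\mathbf{H}, \mathbf{S})$ varies smoothly with the nuclear positions.
This package therefore regresses $(\mathbf{H}, \mathbf{S})$ — plus the total
energy and its exact position gradient — directly, and derives everything
else (spectra, populations, moments, densities of states, orbital-energy
gradients, dynamics, inverse design) from the predicted pair.

The network has three stages:

1. **Atomic-environment encoder.** Each atom starts from an element
   embedding $\mathbf{x}_i^0 = \mathbf{a}_{Z_i} \in \mathbb{R}^B$ and is
   refined by $T$ continuous-filter convolution interactions: neighbor
   features are modulated elementwise by a learned radial filter
   $W_\mathrm{filter}(r_{ij}) = \mathrm{mlp}(g(r_{ij}))\,f_\mathrm{cut}(r_{ij})$,
   where $g$ expands the distance on a Gaussian grid (spacing
   $\Delta\mu$, width $\gamma$) and the cosine cutoff makes the filter
   exactly zero at and beyond $r_c$. All activations are the shifted
   softplus $\mathrm{ssp}(x) = \ln(\tfrac12 e^x + \tfrac12)$. The resulting
   $\mathbf{x}_i^T$ are invariant under rotation and translation and
   equivariant under atom permutation.

2. **Pair interactions with angular momentum.** For each angular channel
   $\lambda = 0 \dots 2L$ a factorised tensor layer builds a symmetric pair
   representation
   $\mathbf{h}_{ij}^\lambda =
   \mathrm{ssp}(\mathrm{linear}_2[\mathrm{linear}_1(\mathbf{x}_i)\circ
   \mathrm{linear}_1(\mathbf{x}_j)\circ W_\mathrm{filter}(r_{ij})])$,
   which additively refines the atom representations and produces invariant
   pair coefficients
   $\mathbf{p}_{ij}^\lambda = \mathrm{mlp}_\mathrm{pair}(\mathbf{h}_{ij}^\lambda)
   + \sum_{m}\mathrm{mlp}_\mathrm{env}(\mathbf{h}_{mj}^\lambda)
   + \sum_{n}\mathrm{mlp}_\mathrm{env}(\mathbf{h}_{in}^\lambda)$.
   Directional information enters through
   $\boldsymbol{\omega}_{ij}^\lambda = [\mathbf{p}_{ij}^\lambda \otimes
   \hat{\mathbf{r}}_{ij}]\,\mathbf{W}^\lambda$ for $\lambda > 0$ (the
   $\lambda = 0$ factor is direction-degenerate), and products
   $\boldsymbol{\Omega}_{ij}^l = \prod_{\lambda \le l}
   \boldsymbol{\omega}_{ij}^\lambda$ accumulate angular character up to
   $l = 2L$ — a basis with orbitals up to angular momentum $L$ needs pair
   features up to $2L$, hence $2L + 1$ interaction blocks.

3. **Linear heads.** Off-site Hamiltonian blocks are
   $\sum_l \mathrm{linear}^l(\boldsymbol{\Omega}_{ij}^l)$ cropped to the
   atoms' orbital counts; on-site blocks sum the same construction over the
   neighbors of $i$. The heads are linear only, so the angular content of
   the features is conserved. The overlap is predicted analogously, except
   that its on-site blocks are learned per-element constants initialised at
   the identity (the analytic self-overlap of normalised orbitals). The
   full matrix is symmetrised, $\mathbf{H} = \tfrac12(\tilde{\mathbf{H}} +
   \tilde{\mathbf{H}}^\intercal)$. The total energy is a separate sum of
   atom-wise contributions $E = \sum_i \mathrm{mlp}_E(\mathbf{x}_i)$, so
   that forces are available as its exact negative gradient.

The architecture does **not** hard-code rotational covariance of the matrix
blocks; it learns it from data augmentation (below). Invariance of the
energy path and exact symmetry of the matrices *are* structural.

## Exact gradients without autodiff

The package implements reverse-mode differentiation of the whole network by
hand (`R/model-grad.R`): one backward pass yields the gradients of any
linear functional of $(\mathbf{H}, \mathbf{S}, E)$ with respect to every
parameter *and* every atomic coordinate. Forces are therefore analytic, not
finite differences.

The force term of the training loss needs a mixed second derivative,
$\partial_\theta\, [\mathbf{v}\cdot\partial E/\partial \mathbf{r}]$. Every
operation in the forward and backward pass is complex-analytic in the
positions (branches test only real parts), so this directional derivative
is obtained by a complex step: evaluate the parameter gradient of $E$ at
$\mathbf{r} + i\varepsilon\mathbf{v}$ with $\varepsilon = 10^{-20}$ and take
the imaginary part divided by $\varepsilon$. Complex-step differentiation
has no subtractive cancellation, so these derivatives are exact to machine
precision; the test suite nevertheless cross-checks every gradient path
against central finite differences, which are an independent oracle.

Entry-wise derivatives $\partial\mathbf{H}/\partial\mathbf{r}$ and
$\partial\mathbf{S}/\partial\mathbf{r}$ (needed for orbital-energy
gradients $\partial\epsilon_m/\partial\mathbf{r} =
\mathbf{c}_m^\intercal(\partial\mathbf{H}/\partial\mathbf{r} -
\epsilon_m\,\partial\mathbf{S}/\partial\mathbf{r})\mathbf{c}_m$) use the
same complex-step route through either the network or the analytic
integrals.

## The synthetic reference generator

Reference electronic-structure data normally comes from an ab initio code.
To keep the package self-contained the generator produces records
$(\mathbf{H}, \mathbf{S}, E, \mathbf{F})$ from an extended-Hückel-type
model on top of *analytic* Gaussian integrals:

* **Overlap**: contracted spherical Gaussians up to $l = 3$, Obara–Saika
  1-D recursions and a real solid-harmonic transformation (Racah-style,
  $m = -l \dots l$, no Condon–Shortley phase), normalised so
  $\mathrm{diag}(\mathbf{S}) = 1$ exactly. A compiled kernel evaluates the
  same recursion in C++ over complex positions; the pure-R path and a
  Gauss–Hermite quadrature oracle cross-check it in the tests.
* **Hamiltonian**: $H_{\mu\mu} = h_\mu$,
  $H_{\mu\nu} = \tfrac12 K (h_\mu + h_\nu) S_{\mu\nu}$ with
  Wolfsberg–Helmholz constant $K = 1.75$. Because it is linear in
  $\mathbf{S}$ block-wise, it inherits the exact rotational covariance
  $\tilde{\mathbf{M}}_{\mu\nu} = \mathbf{D}^{(l_\mu)}\mathbf{M}_{\mu\nu}
  \mathbf{D}^{(l_\nu)\intercal}$ of the overlap — precisely the property
  the rotation augmentation assumes of the reference theory.
* **Energy and forces**: $E = 2\sum_{m\,\mathrm{occ}}\epsilon_m +
  \sum_{i<j} a\, e^{-d_{ij}/d}$, forces by central finite differences of
  $E$ with step $10^{-4}$ Å (a deliberate, cheap choice for a data
  generator; the model's forces, by contrast, are analytic). Geometries
  whose frontier splitting falls below $10^{-8}$ eV are rejected and
  redrawn so orbital-resolved targets stay well defined.

What the generator emulates: smooth geometry dependence, exact block-wise
covariance, a non-trivial spectrum, consistent energies/forces, thermal-style
geometry sampling (i.i.d. Gaussian distortions of a template). What it does
not emulate: self-consistency (no SCF), electron repulsion, charge transfer,
basis sets beyond the toys, or the error statistics of real DFT/HF data.
Passing tests therefore demonstrate that the learning machinery recovers a
smooth covariant matrix map — not that it reaches any particular accuracy on
ab initio data.

### Toy systems

Three bundled systems (`toy_system()`): `h2` (minimal s basis), `water`
(bent three-atom molecule, s+p on the heavy atom, 8 valence electrons) and
`chain4` (planar four-atom chain, s+p). For `h2` and `water` the pair
repulsion amplitude was fitted once so that the chemistry-like template
geometry is the minimum of the generator surface (least-squares null of the
template force, then relaxation): H–H 0.752 Å; O–H 0.948 Å with a 97°
angle. That makes them sensible starting points for dynamics. `chain4` is
deliberately off-equilibrium, as a distortion template only.

## Rotations

Real Wigner-D blocks up to $l = 3$ come from the Ivanic–Ruedenberg
recursion ($\mathbf{D}^{(1)}$ is the rotation matrix permuted into the
$(y, z, x)$ ordering; higher blocks are built recursively without complex
intermediates). The convention satisfies
$Y_{lm}(R\mathbf{r}) = \sum_{m'} D^{(l)}_{mm'} Y_{lm'}(\mathbf{r})$, which
the tests verify against a least-squares solve on sampled solid harmonics.
The block transform of matrices uses a transpose on the right factor,
$\mathbf{D}^{(l_\mu)}\mathbf{M}\,\mathbf{D}^{(l_\nu)\intercal}$ — the only
convention consistent with the analytic overlap under rotated geometries,
which the generator oracle enforces. Haar-uniform rotors are sampled as
normalised Gaussian quaternions, seeded for reproducibility.

## Training

The loss is
$\lVert\mathbf{H}-\tilde{\mathbf{H}}\rVert_F^2 +
\lVert\mathbf{S}-\tilde{\mathbf{S}}\rVert_F^2 +
\rho\lVert E-\tilde{E}\rVert^2 +
\tfrac{1-\rho}{n}\sum_i\lVert\mathbf{F}_i + \partial\tilde{E}/\partial
\mathbf{r}_i\rVert^2$, optimised with Adam on mini-batches. Each epoch with
augmentation on rotates every training record by a fresh Haar rotor —
positions and forces as vectors, $\mathbf{H}$ and $\mathbf{S}$ block-wise
through the Wigner matrices — so covariance is learned from data. The
learning rate decays by 0.8 after a patience of epochs without validation
improvement (improvement = relative decrease $> 10^{-4}$, guarding against
float noise) and training stops at $\mathrm{lr} \le 5\times10^{-6}$ or the
epoch cap; the lowest-validation-loss parameters are kept.

Defaults that the reference protocol leaves open (batch size 8, patience
15, $\rho = 0.1$, lr$_0 = 10^{-3}$) are package choices, all exposed in
`train_config()`.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `B` | 64 | – | atom/pair feature width (reference scale: 1000; 64 is desk scale) |
| `D` | 4 | – | learned projection directions; $>3$ adds flexibility beyond a frame |
| `T` | 3 | – | environment-encoder interactions |
| `L` | basis max $l$ | – | instantiates $2L+1$ pair channels |
| `r_c` | 6 | Å | filter cutoff; beyond it filters are exactly zero |
| `delta_mu` | 0.1 | Å | radial-grid spacing of $g(r)$ |
| `gamma` | 10 | Å$^{-2}$ | radial-basis width |
| `rho` | 0.1 | – | energy-vs-force trade-off in the loss |
| MD `timestep` | 0.5 | fs | BAOAB integration step |
| MD `friction_time` | 100 | fs | Langevin time constant (friction is its inverse) |
| MD `temperature` | 300 | K | thermostat target |

## Dynamics and inverse design

`langevin_md()` integrates with the BAOAB splitting (chosen for accurate
configurational sampling at the default step; the discretisation is a
package choice). With zero temperature and infinite friction time it
reduces to velocity Verlet, which the tests exploit: energy conservation at
0.1 fs and exact time reversibility. The thermostat applies friction and
noise to all $3n$ degrees of freedom, so equipartition holds with
$\mathrm{dof} = 3n$; center-of-mass motion is removed at initialisation
only. Masses come from a standard atomic-mass table.

`optimize_gap()` performs gradient ascent/descent on
$\epsilon_\mathrm{gap} = \epsilon_\mathrm{LUMO} - \epsilon_\mathrm{HOMO}$
with $\nabla\epsilon_\mathrm{gap}$ from the exact orbital-energy gradients,
accepting a step only if the objective moves the requested way and halving
the step otherwise, so the accepted trace is monotone by construction. Near
frontier degeneracies ($< 10^{-6}$ eV) the gradient is ill-defined and the
optimiser halts with the partial trace.

The "forces exerted by individual orbitals" view is exposed as the plain
unweighted orbital-energy gradient; any occupation weighting or projection
onto a reaction coordinate is left to the user, since no single convention
is canonical.

## Numerical choices and degeneracies

* Generalized eigensolve via $\mathbf{S}^{-1/2}$; overlap eigenvalues below
  $10^{-10}$ raise a conditioning error, and `overlap_matrix()` flags
  near-linear dependence below $10^{-8}$.
* Degenerate eigenvector subspaces are returned with a deterministic
  orientation (QR rotation making the first independent pivot rows
  lower-triangular with positive diagonal), so repeated solves are
  comparable; coefficient comparisons should nevertheless use absolute
  cosine similarity because of the inherent sign/phase freedom.
* The quadrupole is reported as the plain second moment by default
  (`traceless = TRUE` for the traceless form); no single convention is
  standard.
* Populations and moments use the *valence* electron count as the nuclear
  charge, which keeps them internally consistent with the valence-only
  generator; pass full charges for external $(\mathbf{H}, \mathbf{S})$
  input.
* Environment sums exclude self-pairs ($m \ne i, j$ and $n \ne i, j$): a
  pairwise construction has no $\mathbf{h}_{jj}$. The two environment sums
  share one `mlp_env`. The per-channel direction projections
  $\mathbf{W}^\lambda$ are distinct by default (`share_w_dir = FALSE`).
* Pair features and sums run over the cutoff neighbor list; for the bundled
  toys every pair is inside the default cutoff.
* The orbital ordering is atom-major, then basis shell order, then
  $m = -l \dots l$ — self-consistent, though not necessarily the ordering
  of any particular quantum-chemistry code.

## Problem sizes

The test-suite and acceptance-script sizes are chosen for a single CPU: the
learning check trains $B = 64$, $T = 3$, $L = 1$ on 200 water-like records
for up to 50 epochs (about five minutes); the integral oracle covers all
angular-momentum combinations up to d plus f spot checks; the eigensolver
contract uses 100 random dense instances; equivariance uses 50 geometries
times 5 rotations; dynamics runs a 1000-step NVE conservation check, a
100-step reversibility check, and a 20000-step thermostatted run on the
three-atom toy. The production-scale regime ($B = 1000$, basis sets with
over 100 orbitals, multi-day training) is configurable but out of desk
scope.

## Known limitations

* Matrix covariance is learned, not structural: out-of-distribution
  rotations of an unaugmented model are wrong by construction.
* The generator's forces are finite differences of its own energy, so
  generator force components carry $\sim10^{-5}$ eV/Å noise; model forces
  are exact gradients of the *predicted* energy.
* Only closed-shell, neutral systems; no SCF feedback, no electron
  repulsion integrals; basis angular momentum capped at $l = 3$.
* Off-site blocks for atom pairs beyond `r_c` are zero; choose `r_c` larger
  than the molecule for dense matrices.
* Training cost in R is dominated by the per-sample backward pass; the
  desk-scale widths are sized so the bundled protocols finish in minutes.
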