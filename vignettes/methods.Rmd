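---
title: "An agent-based model of immune dynamics in relapsing-remitting multiple sclerosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of immune dynamics in relapsing-remitting multiple sclerosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mssim)
```

## The model

`mssim` simulates the immune system of a relapsing-remitting multiple
sclerosis (MS) patient as a stochastic, discrete-time, bit-string polyclonal
lattice agent-based model.  Two 2D hexagonal lattices (six neighbours per
site, periodic boundaries by default) represent a peripheral lymph node and
a slice of brain white matter populated by oligodendrocytes (ODC).  Immune
cells — B cells, helper (TH), cytotoxic (TC) and regulatory (Treg) T cells,
dendritic cells, macrophages and plasma cells — are tracked individually
with a lattice position, an internal state (resting, active, anergic,
presenting through MHC class I or II, duplicating, antibody-bound) and, for
lymphocytes, a binary-string receptor.  Molecules (interleukins, IFN-gamma,
TGF-beta, myelin basic protein, IgG, chemokines, immunocomplexes) are
per-site integer counts.

### Shape space and binding

Receptors, MHC alleles and peptides are bit strings of common length
$\ell$ (default 16, giving a potential repertoire of $2^{16}$ clonotypes —
small enough to enumerate in tests, large enough for clonal diversity).
Affinity is complementarity measured by the Hamming distance: the number of
mismatching bits *is* the affinity, so a perfect complement has maximal
affinity $\ell$.  A specific interaction succeeds with probability

$$p(a) = \begin{cases} 0 & a < \ell/2 \\ b^{\,\ell-a} & a \ge \ell/2 \end{cases}$$

with base $b = 0.7$: a cutoff-plus-geometric law in the Celada–Seiden
lineage, reaching 1 only at a perfect complement.  Aspecific interactions
(e.g. innate pattern recognition, antigen scavenging) use fixed per-rule
probabilities.  An MHC–peptide complex string is the bitwise XOR of the two
strings: deterministic, length-preserving and symmetric in its arguments;
the model needs only some fixed composition rule, and XOR is the simplest
one with full rank.

### Thymic selection

T-cell candidates are positively selected if their affinity to at least one
MHC string of the relevant class reaches $\ell/2 - m_0$ (default $m_0 = 2$),
then negatively selected (deleted) if their affinity to any MHC–self-peptide
complex reaches $\ell - m_0$.  Central-tolerance impairment raises the
deletion threshold by $\mathrm{round}(2\,m_0\,c)$ bits for impairment
$c \in [0,1]$, releasing more autoreactive clones — one of the model's two
regulatory-failure levers.

### Space, chemotaxis and crowding

Agents move one site per step.  The destination is drawn among the current
site and its six neighbours with probabilities proportional to chemokine
counts ($p_i = C_i/\sum_j C_j$), or uniformly ($1/7$) when no chemokine is
present.  The move is then accepted with the crowding probability
$p = 1 - \min\!\big((\sum E_i / M_\text{cells})\,K,\, 1\big)$, where
$\sum E_i$ counts motile cell agents at the target.  Because $K < 1$
(default 0.5), a nominally full site still admits entry with probability
$1-K$ — immune cells infiltrate crowded inflamed tissue.  The alternative
algebraic reading $1-\min(\sum E_i/(M_\text{cells}K), 1)$ is available as a
configuration switch but is not the default, because it cannot express that
infiltration floor.  Occupancy counts motile cell agents only: resident
oligodendrocytes (hundreds per site) are tissue, not traffic, and counting
them would make the white matter impenetrable at any capacity a lattice
site can plausibly have.

Each molecule unit independently jumps to one of the site and its available
neighbours each step (uniform multinomial), conserving counts exactly.
Soluble species also circulate between compartments: a fraction of
lymph-node IgG enters the white matter each step and a fraction of free
white-matter myelin antigen drains to the lymph node.

### Homeostasis

Bone-marrow output is a mean-reverting Ornstein–Uhlenbeck process per cell
type: $\Delta = (\ln 2/\tau)(\bar x - x)\,\Delta t + \sigma\sqrt{\Delta t}\,z$,
with $\bar x$ the entity-table initial count and $\tau$ the type's
half-life.  New cells enter resting with fresh (thymus-selected, for T
cells) receptors; removals are drawn uniformly from non-memory resting
cells, preserving the antigen-driven shift of the repertoire.  Naive
resting cells are maintained *only* by this process; half-life mortality
applies to activated/effector cells and molecules.  If naive cells also
decayed at their catalogue half-life, the joint fixed point would sit near
$\bar x/2$ rather than $\bar x$, contradicting the homeostasis contract.
Oligodendrocytes regenerate towards baseline by the same mean-reverting
mechanism with a 60-day timescale (a modelling choice: recovery is
documented, but no mechanism is prescribed); they are exempt from
half-life decay, their mortality being spontaneous apoptosis plus
immune-mediated killing.

### The interaction scheme

Interactions are Bernoulli events executed once per step.  The registry is
processed in a fresh random order each step, and within a rule every actor
scans its co-located partners in random order until the first success —
giving exactly $1-(1-q)^n$ for $n$ partners of success probability $q$.
Deleted agents are removed immediately (they cannot act in a later rule of
the same step); created agents are buffered and join the population after
the interaction phase.  No rule reads or writes entities at another lattice
site.  The per-step random rule order is drawn once per step rather than
independently per site; the purpose of the randomisation — removing
systematic ordering bias between rules — is preserved, and all within-rule
actor/partner orderings remain per-site random.

Core rules cover immunocomplex formation, antigen capture and presentation
(specific for B cells through their membrane Ig; aspecific for macrophages
and dendritic cells), T-helper priming with interleukin secretion and
plasma/memory differentiation of helped B cells (with one-bit receptor
hypermutation at differentiation), IL-2-gated cytotoxic priming, clonal
division up to a Hayflick limit (lymphoid tissue only — effectors in the
white matter are terminally differentiated), memory formation, anergy after
unproductive self-engagement, regulatory activation/suppression, and
antibody-dependent (ADCC) killing.

### MS-specific biology

Five autoimmune rules extend the core: dendritic cells cross-present
oligodendrocyte-derived myelin basic protein (MBP) as peptide/MHC-I
*without* B7 costimulation; no-B7 antigen-presenting cells activate
auto-reactive T cells with probability proportional to the
peripheral-tolerance impairment (exactly zero in a healthy subject — the
healthy limit of the model); self-reactive IgG opsonizes oligodendrocytes;
activated macrophages kill opsonized oligodendrocytes; activated cytotoxic
T cells kill oligodendrocytes through the MBP/MHC-I complex.  Both killing
routes release MBP and chemokines in situ, closing the
damage-presentation-priming feedback loop.  Spontaneous ODC apoptosis
(mapped from the patient's baseline lesion load) seeds that loop.

Regulatory T cells are not part of the entity catalogue's literature table
but are required by the tolerance mechanism and by the reported population
read-outs; they are included as a documented modelling addition (44 per
microliter, 3.3-day half-life, longer-lived when active).  Their activation
has a tonic component and an inflammation-recruited component (engaged when
the systemic mean IL-2 tone crosses a threshold); both are damped by the
peripheral-tolerance impairment.  Active Tregs secrete IL-10 and TGF-beta;
the resulting suppressive tone (compartment mean, since these cytokines
act systemically) both scales down autoreactive priming (superlinearly,
exponent 3) and shuts down active effectors.  Suppression of priming is
deliberately sharper than effector shutdown: that asymmetry is what turns
the regulated steady state into an excitable system rather than a fixed
dial.

### Disease dynamics and the relapse read-out

The patient scenario simulates 3 mm^3 of white matter at 50,000 ODC/mm^3;
an MRI-detectable event is an ODC loss of at least 50,000, and a relapse is
the level-crossing interval below baseline minus that threshold (smaller
dips are logged as MRI-silent inflammatory activity).  With both tolerance
impairments at the reference level (0.6) the damage-presentation loop and
the regulatory brake place the system near the detectability threshold:
stochastic excursions of the autoimmune attack produce distinct
MRI-detectable relapses with intervening recovery, on a background of
continuous sub-threshold inflammatory activity.  The healthy control (both
impairments zero) has a structurally closed priming gate: no autoimmune
activation occurs at all, oligodendrocyte counts stay within the
regeneration band, and regulatory activation is tonic and strong.  The
reference impairment level and the loop-gain constants are calibration
choices, fixed once in `inst/extdata/calibration.yaml`; the printed
half-lives and initial counts are literature values and are never touched
by calibration.

### Risk factors and patient mapping

Clinical features map deterministically to parameters:
lesion load at onset to the apoptosis probability
($p_\min + (p_\max-p_\min)\min(L/80, 1)$); oligoclonal bands to a +0.3
bonus on both impairments; onset age to the immune-reactivity multiplier
($\mathrm{clamp}(30/\text{age}, 0.5, 2)$); vitamin D level and smoking to
multiplicative factors on regulatory activation (1/0.8/0.6 and 1/0.8).
EBV exposure injects a viral antigen whose epitope lies within one bit of
the MBP peptide (molecular mimicry) with periodic reactivation episodes;
because viral antigen is presented with full B7 costimulation, it primes
cross-reactive clones even in the face of tolerance, but the accompanying
IL-2 surge also recruits regulatory cells, so its net effect on chronic
disease is modest.  HLA predisposition selects MHC-I strings with elevated
affinity for the MBP peptide and boosts autoantigen capture.  Pregnancy
intervals multiply both impairments by 0.5 while they last.

### Treatments

Five disease-modifying drugs act at effect level on documented axes:
IFN-beta1a (44 mcg, three times weekly) shifts Th1 activation towards Th2,
scales MHC-II presentation down and boosts regulatory activity;
teriflunomide (14 mg daily) scales T/B proliferation by the steady-state
flux ratio of a 29-species, 13-reaction pyrimidine-biosynthesis network
whose DHODH step is inhibited non-competitively
($v = V_\max S/((K_m+S)(1+I/K_i))$, intracellular $I$ proportional to
dose); fingolimod (0.5 mg daily) closes lymph-node egress and suppresses
IL-17 production; natalizumab (300 mg every four weeks) scales white-matter
ingress to 0.1; ocrelizumab (600 mg every six months) routes B cells
through the opsonization/ADCC path.  Overlapping drugs compose
multiplicatively; outside their windows the neutral effect state holds and
the engine's trajectories are identical to a run without the treatment
module.  The network file is a synthetic reconstruction of the canonical
de-novo pyrimidine topology — its species/reaction counts are the modelled
quantity; its kinetic constants are fixture choices.  Every reaction is
nitrogen-balanced, so the closed (unclamped) system conserves total
nitrogen, which the tests verify.

## What the synthetic data does and does not emulate

Virtual cohorts sample risk-factor profiles from severity strata: low
(normal vitamin D, 3-10 lesions, no oligoclonal bands, middle age,
negligible smoking), medium (low vitamin D, 20-40 lesions, bands present,
middle age, not-negligible smoking), high (very low vitamin D, 50-90
lesions, bands present, older age, not-negligible smoking).  The six
bundled patient records carry real anonymized timelines (lesion loads,
pregnancies, treatment switches).  The generator emulates the joint
*direction* of prognostic factors, not their population correlations; a
passing severity-ordering test shows the mapping and the disease engine are
jointly monotone, not that the strata match any epidemiological cohort.
Likewise, passing relapse-statistics tests show the model reproduces the
qualitative relapsing-remitting phenotype under the stated calibration —
individual patients' MRI histories are matched only in the
best-of-replicates sense of the patient protocol.

## Numerical choices

* Time step 8 h (3 per day): resolves the fastest catalogue half-life
  (chemokine, 3 h) within a factor ~2.7 and keeps a 4.5-year course below
  5,000 steps.
* Integer fields throughout; decay by binomial thinning with survival
  $2^{-\Delta t/t_{1/2}}$ (exact in expectation); diffusion by sequential
  binomial splitting (exactly multinomial), conserving counts.
* Priming winners are the first Bernoulli success in a random partner
  order; contention for a consumable partner is resolved first-come in that
  random order.
* Pathway steady state: LSODA to t = 400 with rtol 1e-8; under strong
  inhibition upstream intermediates (dihydroorotate) accumulate — as they
  do pharmacologically — while the downstream demand flux plateaus, and
  the dose multiplier is the plateau flux ratio.
* Replicate seeds derive from the master seed by a Lehmer step plus
  multiplicative mixing, kept below $2^{31}$.
* Degenerate inputs: empty candidate sets, zero-count fields, empty
  treatment windows and single-replicate summaries all return well-defined
  empty/zero results rather than errors.

## Problem sizes used by the test suite

Full-scale runs (1 microliter of immune cells per compartment, L = 16,
150,000 ODC) take a couple of minutes each in plain R.  The packaged
statistical checks therefore run at desk scale, chosen as the package's
standard verification size: quarter-microliter populations, L = 12
lattices, 0.75 mm^3 of white matter with the MRI threshold scaled in
proportion (12,500 of 37,500 ODC), 8 paired seeds over the full 4.5-year
horizon for the healthy-versus-MS contrast, and 7 subjects per stratum
over 1 year for the severity ordering.  The disease phenotype is
scale-consistent: the same relapsing-remitting texture appears at full
scale with the unscaled threshold.

## Known limitations

* Soluble antibody is a single aggregated self-reactive IgG pool; antibody
  fine specificity exists only at the B-cell receptor level.
* The spinal cord is recorded in patient data but not simulated; disability
  scores are out of scope — ODC loss is the sole severity read-out.
* Relapse counts are stochastic with heavy seed-to-seed variation, matching
  the qualitative figures, not per-patient MRI histories.
* No pharmacokinetics: drug effects are rectangular in time at effect
  level, teriflunomide excepted (steady-state dose-response only).
* The 2D hexagonal lattice is a biological, not anatomical, space; no
  blood-brain-barrier geometry is modelled beyond the ingress probability.
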