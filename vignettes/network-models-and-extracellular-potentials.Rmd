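---
title: "Building, simulating and virtually recording neuronal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building, simulating and virtually recording neuronal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lfpnet` models a cortical circuit as three decoupled stages — build,
simulate, record — that talk to each other only through files. This vignette
explains the models behind each stage, the parameters that matter, the
numerical choices, and what the package's synthetic data can and cannot say
about real recordings.

## The type-instance relational network description

A network is a graph whose nodes (cells) and edges (connections) each split
their properties in two: everything shared by a group lives once in a *type*
record, everything per-instance lives in columnar tables that reference the
type by id. Each `add_nodes()` call creates one node type; each `add_edges()`
call creates one edge type and registers a deferred connection rule.
`build_edges()` enumerates the (source, target) cross-product of the rule's
two node queries and asks the rule for an integer synapse count `nsyns` per
pair; pairs with `nsyns >= 1` become edge records.

On disk, instance tables are HDF5 column groups and type tables are plain
CSVs. The practical payoff is the asymmetry of cost: a 10^6-row edge table is
written once, while the knobs a modeler actually turns during refinement
(synaptic weight, delay, kinetics file, placement constraints) are one CSV
row per connection class. The package's validator (`validate_fileset()`)
checks referential integrity and the keys the simulator needs before any
simulation starts.

Node types carry `model_type`: `"biophysical"` (cable cell with an SWC
morphology), `"intfire"` (LIF point neuron), or `"virtual"` (source-only
external population whose spikes are precomputed and loaded from file;
wiring a simulated edge *onto* a virtual population is a setup error, which
enforces the feed-forward contract for external inputs).

## Reproducibility by construction: counter-based random streams

Every stochastic element — connection rules, synapse placement, Poisson
inputs — draws from a hash-based counter RNG (`rng_uniform()`): a
MurmurHash3-style 32-bit avalanche mix of the key `(seed, stream ids,
counter)`, two mixed words giving one 53-bit uniform deviate. A draw is a
pure function of its key, so results cannot depend on iteration order,
chunking, or how many logical ranks the simulation is split over. Connection
draws are keyed `(seed, edge_type_id, source_gid, target_gid)` (source gids
namespaced by a hash of their network's name), placements by
`(seed, target_gid, edge_index, synapse_index)`, Poisson trains by
`(seed, gid, 2i)` / `(seed, gid, 2i + 1)` for the i-th candidate's gap and
thinning draws. The three uses derive separate sub-seeds from the master
seed so they never collide. The generator passes uniformity and
independence checks in the test suite; it is not intended for cryptography.

A corollary worth stating: rebuilding a network after *adding* a rule leaves
all previously built edge types bit-identical, because their draws never
depended on what else was being built.

## Cell models

**LIF point neurons** follow `dV/dt = (-(V - v_rest) + r_m I_syn) / tau_m`,
integrated by exponential Euler with the synaptic current held constant over
the step (exact for constant input). A cell at or above `v_thresh` at a step
end spikes, resets to `v_reset`, and is clamped for `t_ref` ms; equality
counts as a crossing. Parameters (units): `tau_m` ms, `v_rest/v_thresh/
v_reset` mV, `r_m` MOhm, `t_ref` ms.

**Passive cable cells** are built from SWC morphologies. Samples are grouped
into maximal unbranched sections typed somatic/axonal/basal/apical; each
section is split into `ceil(L / max_seg_len)` equal-length line segments
with linearly interpolated endpoints and radii. Equal splitting was chosen
because the extracellular model assumes membrane current is uniform within a
segment — equal segments spread that assumption evenly. The soma is always a
single segment spanning its extent; a one-point soma (common in SWC files)
spans its diameter, which makes its cylinder area equal the sphere area
4 pi r^2. Membrane electrical quantities per segment: area `2 pi r L`,
capacitance `cm x area`, leak `g_pas x area` toward `e_pas`; axial coupling
between a segment and its parent is the series of the two half-segment
resistances `ra (L/2)/(pi r^2)`. Each step solves the backward-Euler system

    (C/dt + G_leak + G_syn + G_axial) V' = (C/dt) V + g_leak e_pas + sum(g_syn e_rev) + I_inj

per cell (dense solve; cells at desk scale have tens of segments). The
returned per-segment transmembrane current `I_n = C dV/dt +
g_leak (V' - e_pas) + g_syn (V' - e_rev)` (outward positive, axial
excluded) satisfies Kirchhoff exactly up to solver roundoff:
`sum_n I_n = I_inj`, measured below 1e-13 nA in the tests. There are no
active conductances; spikes of cable cells are defined as upward crossings
of a somatic detection threshold (`spike_threshold`), a deliberate
simplification discussed under limitations.

**Synapses.** Two kinetics are built in. `conductance_biexp` is a difference
of exponentials `g(t) = w k (e^{-t/tau2} - e^{-t/tau1})`, normalized so the
peak equals the weight `w` (uS) at `t_p = tau1 tau2/(tau2 - tau1)
ln(tau2/tau1)`, driving current `g (e_rev - V)`. `current_exp` is a
single-exponential current pulse with peak `w` (nA). Both are linear in the
weight, and an edge's `nsyns` synapses sum linearly. Activations are
delivered `delay` ms after the presynaptic spike, rounded to the nearest
step with half-step ties rounding up. Per-connection weights are
`syn_weight x weight_function(...)`, with the registry defaulting to the
identity; `gaussian_tuning` ships as an example of tuning-dependent
modulation. On biophysical targets, each of the `nsyns` synapses is placed
independently on a segment drawn with probability proportional to segment
length among those whose section type is in `target_sections` and whose
midpoint path distance from the soma lies in `distance_range`; the midpoint
rule is the single unambiguous eligibility criterion and is applied to the
segment as discretized. Placement constraints on point-neuron targets are
ignored with a warning, since a point has no geometry.

## Partitioning, reports, and the extracellular forward model

Cells are assigned to `M` logical ranks round-robin (`gid mod M`), balancing
load to within one cell. The whole network is advanced in one process; the
partition decides only which rank's temporary file each cell reports to, and
recurrent interactions are computed identically for every `M`. Reports
buffer `N` steps in memory (`buffer_steps`, default 1000) and append to
per-rank HDF5 temp files with an explicit flush, so the flushed prefix is
readable while a long run is still going. At the end of the run, rank files
merge: spike files concatenate and sort by (time, gid); voltage traces
concatenate by gid; extracellular contributions add elementwise. Merged
outputs are byte-identical across `M` in {1, 2, 4} and `N` in {1, 1000} in
the acceptance checks (voltages exactly, potentials to ~1e-18 mV, the
float-summation-order residue).

The extracellular potential at site *m* is `phi_m = sum_n R_mn I_n` over the
segments of every cable cell, in a homogeneous isotropic medium of
conductivity `sigma` (default 0.3 S/m, a standard value for cortical
tissue). `R_mn` is the exact potential of a finite line of uniform current
density, written in the numerically stable asinh form; it is symmetric under
endpoint swap and reduces to the monopole `1/(4 pi sigma d)` in the far
field. Because 1 S/m = 1 uS/um, using um and S/m gives resistances directly
in MOhm, and MOhm x nA = mV. The radial distance is clamped from below to
the segment radius: the line-source log diverges on the axis, and a physical
electrode cannot sit inside the membrane, so the clamp keeps near-field
values finite without affecting any site outside the membrane. Transfer
matrices are computed once per cell at setup (soma position plus rotation
about the depth axis applied to the local geometry), making the per-step
cost one matrix-vector product per cell. Superposition across cells is
exact, which is what lets each rank accumulate its own cells' contributions
independently.

## Synthetic data: what it emulates, what it does not

The fixture generators produce every input the workflow consumes, under a
fixed seed, with no binary assets:

- `ball_and_stick_swc()` — a one-point soma plus a straight dendrite; the
  simplest morphology with a genuine cable and a soma/dendrite distinction.
- `two_pop_network()` / `two_pop_fixture()` — a disc of biophysical
  excitatory cells and LIF inhibitory cells with all four recurrent
  connection classes, wired by a distance-tapered rule
  `p = p0 exp(-d^2 / 2 sigma^2)` on planar somatic distance, driven by
  external Poisson sources. The weights, probabilities and the external
  40 Hz drive were fixed once so that the default 200-ms run produces a
  moderately active network (on the order of a hundred spikes, both
  populations participating); the passive cells use a -45 mV somatic
  detection threshold, reachable by summed synaptic depolarization in the
  absence of spike-generating conductances.
- `layer4_composition_spec()` — the composition of a cortical layer-4-scale
  model: a 400-um-radius, 100-um-high core cylinder of 10,000 biophysical
  cells across five types (three excitatory totaling 85%: 3400/3300/1800,
  two PV inhibitory totaling 15%: 750/750) and a surrounding annulus out to
  845 um of 35,000 LIF cells in two types. The split of the excitatory 85%
  among the three types and the 85/15 split of the periphery are this
  package's own fixed choices; positions are uniform in the respective
  volumes. Optional desk-scale recurrent edges are provided for small
  `scale`.
- `external_population_spikes()` with `rate_profile_on_off()` (alternating
  brain-state-like drive) and `rate_profile_gray_then_stim()` (0.5 s at a
  spontaneous rate, then an elevated rate — the timing skeleton of a visual
  stimulation protocol, with no visual model implied).

Passing tests on these fixtures demonstrates the machinery — relational
round trips, deterministic builds, partition/buffer invariance, oracle-level
integration accuracy, exact superposition — not biological realism. Real
morphologies are branched and tortuous; real cells have active
conductances shaping spikes, resonance and backpropagation; real
connectivity is type- and tuning-specific with structured in-vivo drive.
Dynamical phenomena of full-scale cortical models (orientation tuning,
gamma-band oscillations, realistic LFP depth profiles) are outside what
these fixtures can show.

## Numerical choices and degenerate inputs

- Fixed-step integration only; `dt` defaults to 0.1 ms (use 0.025 ms when
  cable accuracy matters — the RC test holds 0.05% at that step).
  Determinism and partition invariance rule out adaptive stepping.
- Threshold tests happen at step ends; equality counts as crossing. Delays
  round to the nearest step, ties up. Refractory periods round up to whole
  steps.
- Problem sizes in the checks: the invariance grid runs the 25-cell
  two-population fixture for 200 ms at dt = 0.1 across six
  rank-count/buffer combinations; the composition check builds the full
  45,000-node layer-4 network (nodes only); oracle checks use single cells
  and 1000 random line-source geometries.
- Degenerate inputs are errors, not silences: zero-length segments, empty
  synapse-placement candidate sets, negative delays, cyclic or
  forward-referencing SWC files, dangling type ids, unknown config keys
  (typos are the dominant config error), negative or non-integer `nsyns`
  (reported with the offending pair), external populations with incoming
  edges.
- Queries see type- and instance-level properties in one merged namespace;
  a node lacking a referenced property is a non-match, never an error, so
  heterogeneous populations stay queryable. Name collisions between the two
  levels are rejected at `add_nodes()` time.
- Reciprocal or repeated `add_edges()` calls are not deduplicated: each
  registered rule contributes its own edges.

## Known limitations

- No active ion channels, calcium dynamics or gap junctions; cable-cell
  "spikes" are threshold crossings of a passive membrane, so extracellular
  spike waveforms lack the sodium/potassium signature of real units.
- The medium is homogeneous and isotropic; no layered conductivity,
  electrode surface impedance, or MUA/LFP band-splitting (left to analysis
  tools).
- Ranks are a logical contract exercised in-process. A true MPI backend
  could replace it without changing results — everything rank-dependent is
  already keyed by gid — but none ships here.
- One simulated (recurrent) network per run; any number of external source
  populations.
- The HDF5/CSV layout is this package's own faithful expression of the
  type-instance relational design, not byte-compatible with other tools'
  formats.
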