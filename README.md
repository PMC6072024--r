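# lfpnet

Rule-based construction, simulation, and extracellular recording of
heterogeneous neuronal network models, in R.

`lfpnet` is aimed at computational neuroscientists who want to build
large, mixed-resolution network models from high-level rules, run them
reproducibly on a desk machine, and forward-model what a multi-electrode
probe would record from them. It covers the full workflow as three
decoupled stages that communicate only through files:

1. **Build** — populations are added with `add_nodes()` (each call defines a
   *node type* holding every shared property) and connection rules are
   registered with `add_edges()` and instantiated by `build_edges()`. The
   result is stored in a type-instance relational format: per-instance
   columns in HDF5 (`<net>_nodes.h5`, `<net>_edges.h5`), shared type-level
   properties in small editable CSVs (`<net>_node_types.csv`,
   `<net>_edge_types.csv`). Changing a synapse weight for a whole connection
   class means editing one CSV field — the binary edge table is never
   rewritten.
2. **Simulate** — `run_simulation()` loads the file sets and advances the
   network with fixed-step integration: leaky integrate-and-fire point
   neurons (exponential-Euler) and passive multi-compartment cables
   (backward Euler over the discretized SWC morphology), conductance
   (bi-exponential) and current (single-exponential) synapses, delayed spike
   delivery, and precomputed external spike trains as feed-forward drive.
   Cells are assigned to `M` logical ranks round-robin (`gid mod M`); every
   random draw comes from a counter-based stream keyed by gid, so all
   outputs are bit-reproducible and independent of the rank count.
3. **Record** — reports (spikes, somatic voltage, extracellular potential)
   buffer in memory and flush to per-rank HDF5 temp files every `N` steps,
   then merge at the end of the run. The extracellular potential at
   electrode site *m* is the line-source forward model
   `phi_m = sum_n R_mn I_n`, where `I_n` is the transmembrane current of
   segment *n* (capacitive + leak + synaptic; axial excluded) and `R_mn` the
   transfer resistance of a finite line of uniform current density in a
   homogeneous isotropic medium of conductivity sigma:
   `R = 1/(4 pi sigma L) [asinh((L - t)/r) - asinh(-t/r)]`
   with `t`, `r` the site's longitudinal and radial coordinates relative to
   the segment. Units are chosen so MOhm x nA = mV. Per-cell contributions
   superpose exactly.

## Worked example

```r
library(lfpnet)

dir <- tempfile("demo")
config <- two_pop_fixture(dir, n_exc = 20, n_inh = 5, n_ext = 10,
                          tstop = 200, seed = 1)
res <- run_simulation(config)
res$n_spikes
#> [1] 108

library(rhdf5)
spikes <- h5read(file.path(dir, "output", "spikes.h5"), "spikes")
head(cbind(time_ms = spikes$timestamps, gid = spikes$gids), 3)
#>      time_ms gid
#> [1,]    11.3   7
#> [2,]    11.7  19
#> [3,]    11.9  14

lfp <- h5read(file.path(dir, "output", "lfp.h5"), "report/data")
range(lfp)   # mV at 6 electrode sites over 2000 steps
#> [1] -0.004642109  0.002127229
```

The fixture writes a complete model under `dir`: a disc of 20 biophysical
ball-and-stick excitatory cells and 5 LIF inhibitory cells, all four
recurrent connection classes wired with a distance-tapered probability rule,
10 external Poisson sources at 40 Hz driving the network, a 6-site linear
electrode, and the JSON run configuration. Over 200 ms the network fires 108
spikes (mostly excitatory), and the linear probe picks up the summed
extracellular signature of the cable cells at a few microvolts — the numbers
above are what the code prints for seed 1.

The composition of a cortical layer-4-scale model (10,000 biophysical cells
in a 400-um-radius core cylinder across 5 cell types, 85%/15%
excitatory/inhibitory, plus 35,000 LIF cells in the surrounding annulus) is
available as `layer4_composition_spec(scale = 1)`.

There is also a command-line entry point:

```sh
exec/lfpnet run <config.json> [--ranks M] [--seed S] [--output-dir DIR]
exec/lfpnet validate <config.json>
exec/lfpnet build <fixture_spec.json> --output-dir DIR
```

## Scope

Active ion channels, calcium dynamics, gap junctions, NEURON/HOC interop and
real MPI transport are out of scope; ranks are a logical contract exercised
in-process, constructed so that a real MPI backend could be added without
changing any result.
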