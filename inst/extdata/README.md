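# Fixture data

All coupling matrices here are **synthetic reconstructions**, not
redistributed measurements.  They were constructed to reproduce every
published structural property of the two circuits they stand in for:

- `swim_cpg_synthetic_A{1,2,3}.csv`: 6-neuron swim CPG (nodes ordered
  Si1L, Si2L, Si3L, Si1R, Si2R, Si3R).  A1 inhibitory chemical, A2
  excitatory chemical, A3 electrical (symmetric).  The network has three
  equitable clusters, each pairing one left with one contralateral right
  neuron; it is directed with all clusters of size two (class A); the
  transverse sub-block patterns per layer are {1,1,1}, {1,2} and {3}; with
  all layers present the three clusters are intertwined.

- `macaque_synthetic_A{1,2}.csv`, `macaque_synthetic_areas.csv`: 29-area
  cortical network with quantized weights (levels 0, 0.1, 0.5, 1).  A1
  holds short-range (undelayed) connections, A2 long-range (delayed) ones.
  Area V1 is the visually driven node type.  Exactly three non-trivial
  equitable clusters exist: an input-free pair (F7, 8B), the prefrontal
  pair (8l, 9/46v) and the inferotemporal pair (TEO, TEpd); all asymmetric
  links touch trivial clusters (class B); the clusters are pairwise not
  intertwined; four areas (2, F1, 7m, ProM) are fully disconnected.

Orientation: entry (row i, column j) is the weight of the link j -> i
(rows are receiving nodes).  Files are headerless CSV.
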