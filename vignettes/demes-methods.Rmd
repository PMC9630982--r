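---
title: "The Demes data model in demesr: resolution, validation, and conversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Demes data model in demesr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demesr)
```

## The model

A Demes graph describes a set of Wright–Fisher populations (demes) and the
gene flow between them. Each deme has a name, optional ancestry (ancestor
names with admixture proportions summing to one), a `start_time`, and an
ordered list of epochs, oldest first. An epoch carries a time interval, a
`start_size` and `end_size` (census sizes in individuals), a
`size_function`, and `selfing_rate`/`cloning_rate` in `[0, 1]`. Continuous
migrations replace a fraction of a destination deme per generation over a
time interval; pulses replace a stated proportion instantaneously at a
single time.

Two representations carry the same information. The human form is concise:
a `defaults` mechanism assigns values to absent fields of a given entity
type (top level for epochs, migrations, pulses and demes; per deme for
epochs, overriding the top level key by key), sizes are inherited along
the progression of time, and deme start times follow from ancestry. The
machine form is exhaustive: every field explicit, no inference left to the
consumer. `demes_resolve()` maps the former to the latter;
`demes_simplify()` inverts it, and the package maintains
`demes_resolve(demes_simplify(g))` equal to `g` as a tested invariant.

### Time conventions

Times are measured backwards from the present (`0`) in the model's
`time_units`; a root deme's `start_time` may be infinite. A deme or epoch
occupies the half-open interval `(start_time, end_time]`: the boundary
instant belongs to the *older* entity, closed at its (recent) end. This is
the convention that makes "a descendant starts when its ancestor ends"
internally consistent — the ancestor still exists at that instant, the
descendant does not yet. All existence, ancestry-liveness, migration
containment and pulse-endpoint checks use this rule uniformly; it also
fixes the value of `demes_size_at()` at an epoch boundary (the older
epoch's endpoint).

`generation_time` converts model time units to generations. When
`time_units` is `"generations"` it defaults to 1 and any other value is
rejected, preventing accidental double scaling; for any other unit it is
mandatory. `demes_in_generations()` divides every time by it and is
idempotent.

### Size trajectories

Within an epoch, `constant` requires `start_size == end_size`;
`exponential` interpolates
`N(t) = N_start (N_end/N_start)^((t_start - t)/(t_start - t_end))`.
When a `size_function` is not given it is inferred: constant if the two
sizes agree, exponential otherwise. The token `linear` is also accepted
and evaluated by linear interpolation, but nothing in the package emits
it; it exists for interoperability and is rejected by the `ms` converter.
An epoch whose `start_time` is infinite must be constant — an exponential
trajectory from infinitely long ago has no finite size, so this is a
validation error rather than a representable model.

## Resolution and diagnostics

Resolution proceeds in phases: structural checks (unknown fields are
errors everywhere, for typo safety; a top-level `metadata` mapping is the
one extension point and passes through verbatim), defaults application,
an up-front scan of the ancestry name graph (so cycles and forward
references each get one clear diagnostic instead of a cascade), per-deme
time and size resolution, migration desugaring, and finally full semantic
validation. Failures never stop at the first problem: every finding is a
diagnostic — stable code, severity, a path into the document
(`demes[2].epochs[1].start_size`, 1-based), and a message — and an
error-severity finding raises a condition carrying the complete sorted
table. The code catalogue is documented in `R/validator.R`.

Two rules deserve comment. The *ingress budget*: the summed inbound
migration rate into any deme must not exceed 1 on any sub-interval, since
rates are replacement fractions per generation. This is checked by
sweeping the sorted endpoints of all inbound migration intervals and
summing rates on each elementary piece; the test suite holds this sweep
equal to an independent brute-force oracle that evaluates the sum at each
piece's midpoint. Pulse proportions are checked analogously per
`(dest, time)` pair, but pulse mass is *not* counted against concurrent
continuous migration — the two act at different granularities (an instant
versus a rate density), and conflating them would reject models every
simulator accepts. Zero-rate migrations and multiple pulses sharing a
destination and time are warnings, not errors: the former is a dead
stanza, the latter is order-dependent (pulses apply in document order).

### Symmetric migration expansion

A stanza with a `demes` list expands to all `k(k-1)` ordered pairs, outer
loop over sources in document order. Missing times resolve per pair to the
full coexistence interval: `start_time` is the oldest instant both demes
exist, `end_time` the most recent. `demes_simplify()` re-collapses
mirrored pairs with identical rate and interval into one symmetric stanza.
The expansion order itself is an implementation artifact, which is why
graph equality (`demes_graphs_equal()`) compares migration and pulse lists
as multisets.

## Numerical choices

* Proportion sums, size continuity and the ingress budget use relative
  tolerance `1e-9` — tight enough to catch authoring mistakes, loose
  enough for decimal text round trips.
* Serialisation emits numbers at full binary precision (17 significant
  digits in JSON, 22-digit precision in YAML), so `load(dump(x))`
  reproduces values bit-exactly; this is property-tested rather than
  assumed.
* Infinity is `.inf` in YAML. JSON has no infinity literal, so the machine
  form uses the string `"Infinity"`, coerced back to `Inf` only in
  time-typed fields (`start_time`, `end_time`, `time`).
* YAML is restricted to the safe subset: mappings, sequences, scalars.
  Anchors, aliases, tags and multi-document streams are rejected by a
  lexical pre-scan (the underlying libyaml parser would otherwise resolve
  aliases silently); quoted strings and comments are stripped before the
  scan so ordinary description text is unaffected. YAML 1.1 boolean
  spellings (`y`, `n`, `yes`, `no`, ...) are disabled — only `true` and
  `false` parse as booleans — because deme names such as `Y` must remain
  strings. Duplicate mapping keys are errors in both dialects, and NaN is
  rejected everywhere.
* The machine-form JSON uses a fixed, documented key order (graph:
  description, time_units, generation_time, demes, migrations, pulses,
  metadata; analogous orders for nested objects) so byte-level diffs are
  meaningful. The order itself is a package choice; no canonical order is
  mandated by the standard.

## ms conversion

`ms_to_graph()` replays the demographic flag set `-I -n -g -G -m -ma -em
-en -eg -eG -eN -eM -ema -ej -es` backwards in time, carrying per-population
size/growth state and a step-function migration matrix. Scalings: sizes
`x·N0`, times `t·4·N0` generations, rates `M/(4·N0)`. Simultaneous events
apply in command-line order, matching ms. `-en` resets growth to zero, as
in ms. `-ej t i j` ends deme `i` (its `start_time` becomes `t·4N0`, with
ancestor `j`) and zeroes the matrix row and column of `i` for older times;
later events referencing `i` are errors. A growth rate left unbounded
backwards has no finite-size representation, so it is truncated — with a
warning — at twice the oldest event time (at least 10 coalescent units),
after which the size is held constant.

`-es t i p` is modelled as a new deme (`demeK+1`, existing from infinitely
far back until `t·4N0`) plus an admixture *pulse* of proportion `1-p` into
deme `i` at that time. An ancestry-based encoding was considered and
rejected: deme `i` exists on both sides of `t`, and ancestry in Demes is a
property of a deme's start, so expressing the split that way would force
an artificial renaming of `i`'s older part.

`graph_to_ms()` inverts this on the subset ms can express: no pulses,
selfing, cloning or linear epochs; at most one ancestor per deme; root
demes infinite. Because every ms population implicitly exists at all times
up to its join, a deme that ends before the present must be *continued* by
a descendant whose start time equals that end time; the descendant
inherits the ms index and the two size histories concatenate (this is
exactly how isolation-with-migration models are conventionally written for
ms, with the ancestral deme sharing index 1 with one daughter). Such
chain-merged graphs convert faithfully but do not round-trip
deme-for-deme — the merged lineage comes back as one deme — so the
round-trip invariant `ms_to_graph(graph_to_ms(g))` is asserted on graphs
whose demes all reach the present.

## The random-model generator

`demes_random_graph()` exists to drive property tests: round-trip
stability of serialisation, `simplify`/`resolve` inversion, validator
soundness, and the ms round trip. It is valid by construction — demes are
created oldest-first (ancestry acyclic by induction), epoch boundaries
come from stratified interval splitting (strict monotonicity without
rejection sampling), migration rates are drawn log-uniformly from
`[1e-6, 1e-3]` (far below the ingress budget), and sizes log-uniformly
from `[1e2, 1e6]`, the range spanning typical inferred census sizes from
small isolates to large recent expansions. Ancestry windows, admixture
with two ancestors, early-terminating demes, selfing, pulses and
non-generation time units are all exercised with fixed probabilities; an
`ms_subset` switch restricts to the ms-expressible feature set described
above. Randomness comes from a package-local Lehmer multiplicative
congruential generator (multiplier 48271, modulus 2^31-1), exact in
doubles and therefore reproducible across platforms independent of R's
RNG state.

What the generator does **not** emulate: real inferred models with
correlated parameters (e.g. bottleneck-then-expansion shapes), very deep
multi-layer admixture graphs, models at the validity *boundary* (ingress
sums near 1, proportions near 0), or pathological text (the negative side
is covered separately by `demes_perturb_invalid()`, which injects seven
catalogued defects and is tested to trigger exactly the expected
diagnostic codes). Passing the property suite therefore demonstrates
correctness of the resolution algebra on well-formed models, not
robustness to arbitrary hostile input.

Test problem sizes are a package choice balancing coverage against suite
runtime: 500 generated models for the round-trip battery, 200
configurations for the ingress-sweep/oracle comparison, 100 for the ms
round trip.

## Visualization

`demes_layout()` places one tube per deme: half-width proportional to
population size (normalised by the model-wide maximum), time on the
vertical axis, infinite start times capped at 1.5 times the oldest finite
time. Horizontal placement walks the ancestry forest depth-first with
roots and children sorted by name, so the layout is independent of the
order demes are listed; subtree members sit adjacent to their ancestors,
which keeps connector lengths short without a global optimisation (the
greedy placement is a documented simplification). The optional log axis
plots `log10(t + 1)`, offsetting zero by one time unit so the present
remains visible when recent growth compresses the linear view.
`demes_draw_svg()` writes the SVG by hand with fixed-precision coordinate
formatting, making the output byte-deterministic — a testable contract
that off-the-shelf graphics devices do not offer.

## Limitations

* Comments in YAML do not survive rewriting; emission style is canonical,
  not preserved.
* No schema versioning: exactly one model shape is accepted.
* No parameter distributions or confidence intervals; a graph is one
  concrete model.
* The ms converter's supported flag set is exactly the list above;
  anything else errors rather than guessing.
* Selection, genome biology (mutation, recombination, ploidy) and sampling
  specifications are deliberately out of scope of the data model.
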