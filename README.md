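# demesr

Tools for the **Demes** standard for demographic models in population
genetics: read the concise human-written YAML/JSON form, resolve it into
the fully explicit machine form, validate it, simplify it back, convert to
and from the `ms` coalescent simulator's command-line dialect, and draw
models as tube diagrams.

## The problem

A demographic model is a set of populations ("demes") with piecewise size
histories over time intervals, connected by ancestry, continuous
migrations, and instantaneous admixture pulses. Such models are routinely
inferred by one tool and re-simulated by another, and translating between
the many ad-hoc ways of writing them down is tedious and error prone. The
Demes data model fixes one unambiguous representation with two faces:

* the **human form**: concise YAML with hierarchical `defaults`, implicit
  size inheritance ("if an epoch's `start_size` is absent it equals the
  previous epoch's `end_size`"), and start times inferred from ancestry;
* the **machine form**: exhaustive JSON in which every field of every
  deme, epoch, migration and pulse is explicit.

The heavy lifting is the *parser* between the two: it applies defaults,
inherits sizes along the progression of time, infers deme start times from
ancestors, desugars symmetric migration stanzas into asymmetric pairs, and
verifies every semantic rule (identifier hygiene, ancestry liveness and
acyclicity, proportion sums, rate bounds, a unit budget on total inbound
migration), reporting *all* problems as machine-readable diagnostics
rather than stopping at the first.

Conventions: time is measured backwards from the present in the model's
`time_units`; a deme or epoch occupies the half-open interval
`(start_time, end_time]`, so the instant at which an ancestor ends belongs
to the ancestor, which is what lets a descendant's `start_time` equal its
ancestor's `end_time`. Within an epoch the population size is constant or
exponential,

```
N(t) = N_start * (N_end / N_start)^((t_start - t) / (t_start - t_end)) .
```

For `ms` conversion the usual coalescent scalings apply: times in units of
`4*N0` generations, sizes relative to `N0`, matrix entries `4*N0*m`, and
`-m i j M` means migrants *into* subpopulation `i` *from* `j` (backwards
in time), i.e. a Demes migration with `dest = i`, `source = j`.

## Worked example

The bundled model is a three-deme isolation-with-migration history: an
ancestral deme `A` reaching arbitrarily far into the past that ends 100
generations ago, descendants `X` and `Y` (default epoch `start_size`
1000), exponential growth of `Y` to 3000 individuals starting 50
generations ago, and symmetric `X`–`Y` migration.

```r
library(demesr)
g <- demes_resolve(demes_load(demes_example(), file = TRUE))
print(g)
#> Demes graph: 3 deme(s), 2 migration(s), 0 pulse(s)
#>   Isolation-with-migration model with exponential growth in Y.
#>   time units: generations (generation time 1)
#>   deme A            (.inf, 100]  1 epoch(s)
#>   deme X            (100, 0]  1 epoch(s)
#>   deme Y            (100, 0]  2 epoch(s)
```

Resolution filled in everything the author left implicit: `X` and `Y`
start at 100 (the time `A` ends), `Y`'s second epoch starts at size 1000
(inherited across the boundary at 50), and the migration stanza expanded
to the two asymmetric entries `X→Y` and `Y→X` over `(100, 0]`, the full
interval during which both demes exist. The size trajectory of `Y`:

```r
demes_size_at(g$demes[[3]], c(0, 25, 50))
#> [1] 3000.000 1732.051 1000.000     # 1732.05 = 1000 * sqrt(3)
```

The same model as `ms` demography flags with reference size `N0 = 1000`
(deme `X` continues the ancestral lineage under ms population 1; times are
in units of `4*N0` generations, so the split is at 100/4000 = 0.025):

```r
paste(graph_to_ms(g, N0 = 1000), collapse = " ")
#> -I 2 1 1 -n 2 3 -g 2 87.888983... -m 2 1 0.4 -m 1 2 0.4
#>   -en 0.0125 2 1 -en 0.025 1 1 -ej 0.025 2 1
```

`demes_simplify(g)` emits the minimal human form back (one symmetric
migration stanza, all inferable fields dropped), and
`demes_draw_svg(demes_layout(g), "im.svg")` renders the tube diagram.
A command-line wrapper for all of this is installed at
`inst/scripts/demes.R` (`validate`, `resolve`, `simplify`, `ms-to-demes`,
`demes-to-ms`, `generate`, `draw`).

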