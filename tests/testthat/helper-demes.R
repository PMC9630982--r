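# Shared fixtures and independent oracles for the test suite.

im_path <- function() {
  system.file("extdata", "isolation_with_migration.yaml", package = "demesr")
}

im_graph <- function() {
  demes_resolve(demes_load(im_path(), file = TRUE))
}

deme_by_name <- function(graph, nm) {
  for (d in graph$demes) if (d$name == nm) return(d)
  stop("no deme ", nm)
}

# minimal single-deme model text
minimal_yaml <- "
time_units: generations
demes:
  - name: a
    epochs:
      - start_size: 100
"

# Independent ingress-budget oracle: evaluate the summed inbound rate at
# the midpoint of every elementary interval of the endpoint partition.
midpoint_ingress <- function(migrations, dest) {
  ms <- Filter(function(m) m$dest == dest, migrations)
  if (length(ms) == 0L) return(data.frame(mid = numeric(0), rate = numeric(0)))
  cuts <- sort(unique(unlist(lapply(ms, function(m)
    c(m$start_time, m$end_time)))), decreasing = TRUE)
  mids <- vapply(seq_len(length(cuts) - 1L), function(k) {
    hi <- cuts[k]; lo <- cuts[k + 1L]
    if (is.infinite(hi)) lo + 1 else (hi + lo) / 2
  }, numeric(1))
  rate <- vapply(mids, function(t)
    sum(vapply(ms, function(m)
      if (t < m$start_time && t >= m$end_time) m$rate else 0, numeric(1))),
    numeric(1))
  data.frame(mid = mids, rate = rate)
}

# align the deme list of `b` to the name order of `a` (migration/pulse
# comparison is order-free already)
align_demes <- function(a, b) {
  nms <- vapply(a$demes, `[[`, character(1), "name")
  b$demes <- b$demes[match(nms, vapply(b$demes, `[[`, character(1), "name"))]
  b
}
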