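# Defaults application, size/time inheritance, migration desugaring.

test_that("epoch defaults fill absent fields and explicit values win", {
  doc <- demes_load("
time_units: generations
defaults:
  epoch: {start_size: 1000}
demes:
  - name: a
    epochs:
      - end_time: 10
  - name: b
    epochs:
      - start_size: 500
")
  out <- demes_apply_defaults(doc)
  expect_equal(out$demes[[1]]$epochs[[1]]$start_size, 1000)
  expect_equal(out$demes[[2]]$epochs[[1]]$start_size, 500)
  expect_null(out$defaults)
})

test_that("per-deme epoch defaults override top-level key by key", {
  doc <- demes_load("
time_units: generations
defaults:
  epoch: {start_size: 1000, selfing_rate: 0.1}
demes:
  - name: a
    defaults:
      epoch: {start_size: 42}
")
  out <- demes_apply_defaults(doc)
  e <- out$demes[[1]]$epochs[[1]]
  expect_equal(e$start_size, 42)       # deme default wins
  expect_equal(e$selfing_rate, 0.1)    # top-level default still applies
})

test_that("a document without defaults passes through unchanged", {
  doc <- demes_load(minimal_yaml)
  expect_true(demes_doc_equal(doc, demes_apply_defaults(doc)))
})

test_that("unknown keys in defaults stanzas are named in the error", {
  doc <- demes_load("
time_units: generations
defaults:
  epoch: {banana: 1}
demes:
  - name: a
    epochs: [{start_size: 10}]
")
  err <- tryCatch(demes_resolve(doc), demes_error = function(e) e)
  expect_s3_class(err, "demes_error")
  expect_true(any(err$diagnostics$code == "unknown_field" &
                  grepl("banana", err$diagnostics$path)))
})

test_that("missing start_size inherits the previous epoch's end_size", {
  g <- im_graph()
  y <- deme_by_name(g, "Y")
  expect_length(y$epochs, 2L)
  expect_equal(y$epochs[[2]]$start_size, 1000)
  expect_equal(y$epochs[[2]]$end_size, 3000)
  expect_identical(y$epochs[[2]]$size_function, "exponential")
  expect_identical(y$epochs[[1]]$size_function, "constant")
})

test_that("a single size yields a constant epoch; no size at all errors", {
  g <- demes_resolve(minimal_yaml)
  e <- g$demes[[1]]$epochs[[1]]
  expect_equal(e$end_size, 100)
  expect_identical(e$size_function, "constant")
  err <- tryCatch(
    demes_resolve("time_units: generations\ndemes:\n- name: a\n  epochs: [{end_time: 5}, {start_size: 9}]"),
    demes_error = function(e) e)
  expect_true("epoch_missing_size" %in% err$diagnostics$code)
})

test_that("deme start times come from the single ancestor's end time", {
  g <- im_graph()
  expect_equal(deme_by_name(g, "X")$start_time, 100)
  expect_equal(deme_by_name(g, "Y")$start_time, 100)
  expect_equal(deme_end_time(deme_by_name(g, "A")), 100)
})

test_that("an isolated deme spans infinity to the present", {
  g <- demes_resolve(minimal_yaml)
  d <- g$demes[[1]]
  expect_identical(d$start_time, Inf)
  expect_equal(deme_end_time(d), 0)
  expect_identical(d$ancestors, character(0))
})

test_that("epoch intervals chain strictly through listed end times", {
  y <- deme_by_name(im_graph(), "Y")
  expect_equal(y$epochs[[1]]$start_time, 100)
  expect_equal(y$epochs[[1]]$end_time, 50)
  expect_equal(y$epochs[[2]]$start_time, 50)
  expect_equal(y$epochs[[2]]$end_time, 0)
  err <- tryCatch(
    demes_resolve("time_units: generations\ndemes:\n- name: a\n  epochs: [{start_size: 5, end_time: 10}, {end_time: 50}]"),
    demes_error = function(e) e)
  expect_true("times_not_decreasing" %in% err$diagnostics$code)
})

test_that("multiple ancestors require explicit start_time and proportions", {
  base <- "
time_units: generations
demes:
  - name: p
    epochs: [{start_size: 10, end_time: 50}]
  - name: q
    epochs: [{start_size: 10, end_time: 50}]
  - name: c
    ancestors: [p, q]
%s
    epochs: [{start_size: 10}]
"
  err <- tryCatch(demes_resolve(sprintf(base, "    proportions: [0.5, 0.5]")),
                  demes_error = function(e) e)
  expect_true("missing_start_time" %in% err$diagnostics$code)
  g <- demes_resolve(sprintf(base,
    "    proportions: [0.5, 0.5]\n    start_time: 50"))
  expect_equal(deme_by_name(g, "c")$proportions, c(0.5, 0.5))
})

test_that("symmetric migration desugars into all ordered pairs", {
  g <- im_graph()
  expect_length(g$migrations, 2L)
  pairs <- vapply(g$migrations, function(m) paste(m$source, m$dest), "")
  expect_setequal(pairs, c("X Y", "Y X"))
  for (m in g$migrations) {
    expect_equal(m$start_time, 100)
    expect_equal(m$end_time, 0)
    expect_equal(m$rate, 1e-4)
  }
  g3 <- demes_resolve("
time_units: generations
demes:
  - name: a
    epochs: [{start_size: 1}]
  - name: b
    epochs: [{start_size: 1}]
  - name: c
    epochs: [{start_size: 1}]
migrations:
  - demes: [a, b, c]
    rate: 1.0e-5
")
  expect_length(g3$migrations, 6L)
})

test_that("migration times default to the coexistence interval", {
  g <- demes_resolve("
time_units: generations
demes:
  - name: root
    epochs: [{start_size: 10}]
  - name: kid
    ancestors: [root]
    start_time: 100
    epochs: [{start_size: 10}]
migrations:
  - {source: root, dest: kid, rate: 1.0e-4}
")
  expect_equal(g$migrations[[1]]$start_time, 100)
  expect_equal(g$migrations[[1]]$end_time, 0)
})

test_that("a missing time_units field is diagnosed by name", {
  err <- tryCatch(demes_resolve("demes:\n- name: a\n  epochs: [{start_size: 1}]"),
                  demes_error = function(e) e)
  expect_true("missing_time_units" %in% err$diagnostics$code)
  expect_true(any(grepl("time_units", err$diagnostics$path)))
})

test_that("generation_time is required away from generations and fixed at 1 otherwise", {
  err <- tryCatch(demes_resolve("time_units: years\ndemes:\n- name: a\n  epochs: [{start_size: 1}]"),
                  demes_error = function(e) e)
  expect_true("missing_generation_time" %in% err$diagnostics$code)
  err2 <- tryCatch(demes_resolve("time_units: generations\ngeneration_time: 25\ndemes:\n- name: a\n  epochs: [{start_size: 1}]"),
                   demes_error = function(e) e)
  expect_true("generation_time_conflict" %in% err2$diagnostics$code)
})

test_that("all resolution failures are reported together, not just the first", {
  err <- tryCatch(demes_resolve("
demes:
  - name: a
    epochs: [{end_time: 5}]
migrations:
  - {source: a, dest: nowhere, rate: 2.0}
"), demes_error = function(e) e)
  codes <- err$diagnostics$code
  expect_true(all(c("missing_time_units", "epoch_missing_size",
                    "unknown_deme") %in% codes))
})

test_that("the IM example resolves to three demes with no pulses", {
  g <- im_graph()
  expect_length(g$demes, 3L)
  expect_length(g$pulses, 0L)
  expect_identical(vapply(g$demes, `[[`, "", "name"), c("A", "X", "Y"))
})

test_that("resolution is insensitive to stanza ordering", {
  a <- demes_resolve("
time_units: generations
defaults:
  epoch: {start_size: 7}
demes: [{name: a}, {name: b}]
migrations:
  - {source: a, dest: b, rate: 1.0e-5}
  - {source: b, dest: a, rate: 2.0e-5}
")
  b <- demes_resolve("
defaults:
  epoch: {start_size: 7}
time_units: generations
demes: [{name: a}, {name: b}]
migrations:
  - {source: b, dest: a, rate: 2.0e-5}
  - {source: a, dest: b, rate: 1.0e-5}
")
  expect_true(demes_graphs_equal(a, b))
})
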