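# Graph methods: trajectories, unit conversion, JSON, equality, simplify.

test_that("size_at reproduces endpoints and the exponential closed form", {
  y <- deme_by_name(im_graph(), "Y")
  expect_identical(demes_size_at(y, 0), 3000)
  expect_identical(demes_size_at(y, 50), 1000)
  # interior: N(t) = 1000 * 3^((50 - t)/50)
  ts <- c(1, 5, 12.5, 25, 40, 49)
  expect_equal(demes_size_at(y, ts), 1000 * 3^((50 - ts) / 50),
               tolerance = 1e-12)
  expect_identical(demes_size_at(y, 25), 1000 * sqrt(3))
  # older constant epoch, and boundary ownership by the older epoch
  expect_identical(demes_size_at(y, 75), 1000)
  expect_error(demes_size_at(y, 100), "does not exist")
  expect_error(demes_size_at(y, 2000), "does not exist")
})

test_that("constant epochs are flat and linear epochs interpolate", {
  g <- demes_resolve(minimal_yaml)
  expect_identical(demes_size_at(g$demes[[1]], c(0, 3, 1e6)), rep(100, 3))
  gl <- demes_resolve("
time_units: generations
demes:
  - name: a
    start_time: 100
    epochs: [{start_size: 100, end_size: 300, size_function: linear}]
")
  expect_equal(demes_size_at(gl$demes[[1]], 50), 200)
})

test_that("size_at is continuous across epoch boundaries that share a size", {
  for (s in 1:20) {
    g <- demes_random_graph(demes_gen_config(seed = 300 + s, n_demes = c(1, 4)))
    for (d in g$demes) {
      for (j in seq_len(length(d$epochs) - 1L)) {
        b <- d$epochs[[j]]$end_time
        if (d$epochs[[j]]$end_size == d$epochs[[j + 1L]]$start_size) {
          eps <- max(1e-9, b * 1e-9)
          expect_equal(demes_size_at(d, b),
                       demes_size_at(d, max(0, b - eps)),
                       tolerance = 1e-6)
        }
      }
    }
  }
})

test_that("unit conversion divides times, fixes metadata, is idempotent", {
  g <- demes_resolve("
time_units: years
generation_time: 25
demes:
  - name: a
    epochs: [{start_size: 10, end_time: 100}, {end_size: 30}]
")
  gg <- demes_in_generations(g)
  expect_identical(gg$time_units, "generations")
  expect_identical(gg$generation_time, 1)
  expect_equal(gg$demes[[1]]$epochs[[1]]$end_time, 4)
  expect_identical(gg$demes[[1]]$start_time, Inf)
  expect_equal(gg$demes[[1]]$epochs[[1]]$start_size, 10)  # sizes untouched
  expect_true(demes_graphs_equal(gg, demes_in_generations(gg)))
})

test_that("JSON serialisation is exhaustive and invertible", {
  g <- im_graph()
  j <- demes_to_json(g)
  expect_identical(length(gregexpr('"name"', j)[[1]]), 3L)
  expect_true(demes_graphs_equal(g, demes_from_json(j)))
  for (s in 1:30) {
    gr <- demes_random_graph(demes_gen_config(seed = 400 + s, n_demes = c(1, 5)))
    expect_true(demes_graphs_equal(gr, demes_from_json(demes_to_json(gr))),
                label = sprintf("seed %d", 400 + s))
  }
  # a partially resolved document is refused, naming the missing fields
  tree <- jsonlite::parse_json(j)
  tree$demes[[1]]$start_time <- NULL
  broken <- jsonlite::toJSON(tree, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(demes_from_json(broken), "start_time")
})

test_that("graph equality detects change and respects tolerance", {
  g <- im_graph()
  expect_true(demes_graphs_equal(g, g))
  g2 <- g
  g2$demes[[3]]$epochs[[2]]$end_size <- 3300
  expect_false(demes_graphs_equal(g, g2))
  g3 <- g
  g3$demes[[3]]$epochs[[2]]$end_size <- 3000 * (1 + 1e-12)
  expect_true(demes_graphs_equal(g, g3))
  expect_false(demes_graphs_equal(g, g3, tol = 1e-14))
  # migration list order is an implementation artifact
  g4 <- g
  g4$migrations <- rev(g4$migrations)
  expect_true(demes_graphs_equal(g, g4))
})

test_that("simplify collapses mirrored migrations into one symmetric stanza", {
  doc <- demes_simplify(im_graph())
  expect_length(doc$migrations, 1L)
  expect_setequal(unlist(doc$migrations[[1]]$demes), c("X", "Y"))
  expect_null(doc$migrations[[1]]$start_time)
  expect_null(doc$migrations[[1]]$source)
})

test_that("simplify elides every inferable field of a constant deme", {
  doc <- demes_simplify(demes_resolve(minimal_yaml))
  d <- doc$demes[[1]]
  expect_null(d$start_time)
  expect_null(d$ancestors)
  expect_identical(names(d$epochs[[1]]), "start_size")
  expect_null(doc$generation_time)
})

test_that("resolve after simplify is the identity on generated graphs", {
  for (s in 1:60) {
    g <- demes_random_graph(demes_gen_config(
      seed = 500 + s, n_demes = c(1, 6),
      time_units = if (s %% 3 == 0) "years" else "generations"))
    g2 <- demes_resolve(demes_simplify(g))
    expect_true(demes_graphs_equal(g, g2, tol = 1e-9),
                label = sprintf("seed %d", 500 + s))
  }
})

test_that("unit conversion commutes with simplify-then-resolve", {
  for (s in 1:15) {
    g <- demes_random_graph(demes_gen_config(seed = 600 + s,
                                             time_units = "years"))
    a <- demes_in_generations(demes_resolve(demes_simplify(g)))
    b <- demes_resolve(demes_simplify(demes_in_generations(g)))
    expect_true(demes_graphs_equal(a, b, tol = 1e-9),
                label = sprintf("seed %d", 600 + s))
  }
})

test_that("print and summary surface the core structure", {
  g <- im_graph()
  expect_output(print(g), "3 deme\\(s\\), 2 migration\\(s\\)")
  s <- summary(g)
  expect_identical(s$n_demes, 3L)
  expect_equal(s$size_range, c(1000, 3000))
  expect_output(print(s), "oldest finite time: 100")
})
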