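# ms command-line dialect conversion.

test_that("ms flags parse into a structured event list", {
  ev <- ms_parse_args(c("-I", "2", "1", "1", "0.0", "-ej", "0.5", "2", "1"))
  expect_identical(ev$npop, 2L)
  expect_length(ev$events, 1L)
  expect_identical(ev$events[[1]]$kind, "join")
  expect_equal(ev$events[[1]]$t, 0.5)

  ev2 <- ms_parse_args(c("-en", "0.1", "1", "0.5"))
  expect_identical(ev2$events[[1]]$kind, "size")
  expect_equal(ev2$events[[1]]$x, 0.5)

  expect_error(ms_parse_args(c("-ej", "0.5", "2")), "missing argument")
  expect_error(ms_parse_args(c("-Z", "1")), "unknown flag")
  expect_warning(ms_parse_args(c("-t", "10.0")), "non-demographic")
})

test_that("a join becomes ancestry at 4*N0*t with sizes x*N0", {
  g <- ms_to_graph(c("-I", "2", "1", "1", "0.0", "-ej", "0.5", "2", "1"),
                   N0 = 10000)
  expect_length(g$demes, 2L)
  d2 <- deme_by_name(g, "deme2")
  expect_equal(d2$start_time, 20000)
  expect_identical(d2$ancestors, "deme1")
  expect_equal(deme_by_name(g, "deme1")$epochs[[1]]$start_size, 10000)
  expect_equal(d2$epochs[[1]]$start_size, 10000)
  expect_identical(nrow(demes_validate(g)), 0L)
})

test_that("a migration matrix entry becomes a rate M/(4*N0) into deme i", {
  g <- ms_to_graph(c("-I", "2", "1", "1", "-m", "1", "2", "4.0"), N0 = 10000)
  expect_length(g$migrations, 1L)
  m <- g$migrations[[1]]
  expect_identical(m$dest, "deme1")
  expect_identical(m$source, "deme2")
  expect_equal(m$rate, 1e-4)
})

test_that("a size change splits the history into two epochs at 4*N0*t", {
  g <- ms_to_graph(c("-I", "2", "1", "1", "-en", "0.1", "1", "0.5"),
                   N0 = 10000)
  d1 <- deme_by_name(g, "deme1")
  expect_length(d1$epochs, 2L)
  expect_equal(d1$epochs[[1]]$start_size, 5000)  # older than 4000 generations
  expect_equal(d1$epochs[[1]]$end_time, 4000)
  expect_equal(d1$epochs[[2]]$start_size, 10000)
  expect_length(deme_by_name(g, "deme2")$epochs, 1L)
})

test_that("growth flags reconstruct exponential epochs exactly", {
  # size 2*N0 at present, growing at alpha=5 until an -eN bound at t=0.3
  g <- ms_to_graph(c("-n", "1", "2", "-g", "1", "5", "-eN", "0.3", "1"),
                   N0 = 1000)
  d <- g$demes[[1]]
  expect_length(d$epochs, 2L)
  e <- d$epochs[[2]]
  expect_identical(e$size_function, "exponential")
  expect_equal(e$end_size, 2000)
  expect_equal(e$start_size, 2000 * exp(-5 * 0.3), tolerance = 1e-12)
  expect_identical(d$epochs[[1]]$size_function, "constant")
})

test_that("unbounded backwards growth is truncated with a warning", {
  expect_warning(g <- ms_to_graph(c("-n", "1", "2", "-g", "1", "5"), N0 = 1000),
                 "truncating")
  expect_identical(nrow(demes_validate(g)), 0L)
  expect_true(is.infinite(g$demes[[1]]$start_time))
})

test_that("-es creates a new deme and an admixture pulse of 1-p", {
  g <- ms_to_graph(c("-es", "0.1", "1", "0.7"), N0 = 1000)
  expect_length(g$demes, 2L)
  expect_length(g$pulses, 1L)
  p <- g$pulses[[1]]
  expect_identical(p$dest, "deme1")
  expect_identical(p$sources, "deme2")
  expect_equal(p$proportions, 0.3)
  expect_equal(p$time, 400)
  expect_equal(deme_end_time(deme_by_name(g, "deme2")), 400)
})

test_that("events touching a joined-away population are refused", {
  expect_error(
    ms_to_graph(c("-I", "2", "1", "1", "-ej", "0.1", "2", "1",
                  "-en", "0.5", "2", "0.1"), N0 = 1000),
    "joined away")
})

test_that("a single constant deme of size N0 needs no flags", {
  g <- demes_resolve(minimal_yaml)
  expect_length(graph_to_ms(g, N0 = 100), 0L)
})

test_that("features outside ms semantics raise naming errors", {
  g <- demes_resolve("
time_units: generations
demes:
  - name: a
    epochs: [{start_size: 10, selfing_rate: 0.5}]
")
  expect_error(graph_to_ms(g, N0 = 100), "selfing")
  g2 <- demes_resolve(minimal_yaml)
  g2$pulses <- list(list(sources = "a", dest = "a", proportions = 0.1,
                         time = 5))
  expect_error(graph_to_ms(g2, N0 = 100), "pulses")
})

test_that("the IM example maps to one -ej plus symmetric -m entries", {
  tok <- graph_to_ms(im_graph(), N0 = 1000)
  expect_identical(sum(tok == "-ej"), 1L)
  expect_identical(sum(tok == "-m"), 2L)
  back <- ms_to_graph(tok, N0 = 1000, names = attr(tok, "deme_names"))
  expect_identical(nrow(demes_validate(back)), 0L)
  # the merged ancestral lineage keeps Y's two-phase size history
  y <- deme_by_name(back, "Y")
  expect_equal(demes_size_at(y, 0), 3000, tolerance = 1e-9)
  expect_equal(demes_size_at(y, 50), 1000, tolerance = 1e-9)
})

test_that("from_ms inverts to_ms on the ms-expressible subset", {
  for (s in 1:100) {
    g <- demes_random_graph(demes_gen_config(seed = 700 + s,
                                             n_demes = c(1, 5),
                                             ms_subset = TRUE))
    tok <- graph_to_ms(g, N0 = 5000)
    back <- ms_to_graph(tok, N0 = 5000, names = attr(tok, "deme_names"))
    expect_true(
      demes_graphs_equal(demes_in_generations(g),
                         align_demes(demes_in_generations(g), back),
                         tol = 1e-9),
      label = sprintf("seed %d", 700 + s))
  }
})

test_that("conversion covaries with the reference size N0", {
  g <- ms_to_graph(c("-I", "2", "1", "1", "-m", "1", "2", "4.0",
                     "-en", "0.1", "1", "0.5", "-ej", "0.5", "2", "1"),
                   N0 = 1000)
  g2 <- ms_to_graph(c("-I", "2", "1", "1", "-m", "1", "2", "4.0",
                      "-en", "0.1", "1", "0.5", "-ej", "0.5", "2", "1"),
                    N0 = 2000)
  # doubling N0 doubles sizes and times and halves rates
  expect_equal(deme_by_name(g2, "deme1")$epochs[[1]]$start_size,
               2 * deme_by_name(g, "deme1")$epochs[[1]]$start_size)
  expect_equal(deme_by_name(g2, "deme2")$start_time,
               2 * deme_by_name(g, "deme2")$start_time)
  expect_equal(g2$migrations[[1]]$rate, g$migrations[[1]]$rate / 2)
})
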