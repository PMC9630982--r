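# Semantic rules, diagnostic completeness, and the ingress-budget sweep.

valid_two_deme <- function() {
  demes_resolve("
time_units: generations
demes:
  - name: a
    epochs: [{start_size: 10}]
  - name: b
    epochs: [{start_size: 10}]
")
}

test_that("well-formed graphs produce no diagnostics", {
  expect_identical(nrow(demes_validate(im_graph())), 0L)
  expect_identical(nrow(demes_validate(valid_two_deme())), 0L)
})

test_that("duplicate and malformed names and dangling references are caught", {
  g <- valid_two_deme()
  g$demes[[2]]$name <- "a"
  expect_true("duplicate_deme_name" %in% demes_validate_names(g)$code)
  g2 <- valid_two_deme()
  g2$demes[[1]]$name <- "1bad"
  expect_true("invalid_name" %in% demes_validate_names(g2)$code)
  g3 <- valid_two_deme()
  g3$migrations <- list(list(source = "a", dest = "zzz", rate = 1e-4,
                             start_time = Inf, end_time = 0))
  expect_true("unknown_deme" %in% demes_validate_names(g3)$code)
})

test_that("ancestry rules: cycles, self-ancestry, proportion sums, liveness", {
  g <- valid_two_deme()
  g$demes[[1]]$ancestors <- "b"; g$demes[[1]]$proportions <- 1
  g$demes[[2]]$ancestors <- "a"; g$demes[[2]]$proportions <- 1
  expect_true("cyclic_ancestry" %in% demes_validate_ancestry(g)$code)

  g2 <- valid_two_deme()
  g2$demes[[1]]$ancestors <- "a"; g2$demes[[1]]$proportions <- 1
  expect_true("self_ancestor" %in% demes_validate_ancestry(g2)$code)

  g3 <- valid_two_deme()
  g3$demes[[2]]$ancestors <- c("a", "a")
  g3$demes[[2]]$proportions <- c(0.4, 0.7)
  expect_true("proportion_sum" %in% demes_validate_ancestry(g3)$code)

  # ancestor interval is closed at its end: a child starting exactly when
  # the ancestor ends is fine, later is not
  g4 <- demes_resolve("
time_units: generations
demes:
  - name: anc
    epochs: [{start_size: 5, end_time: 100}]
  - name: kid
    ancestors: [anc]
    epochs: [{start_size: 5}]
")
  expect_identical(nrow(demes_validate(g4)), 0L)
  g4$demes[[2]]$start_time <- 90
  g4$demes[[2]]$epochs[[1]]$start_time <- 90
  expect_true("ancestor_not_alive" %in% demes_validate_ancestry(g4)$code)
})

test_that("migration rate bounds and dead stanzas are diagnosed", {
  g <- valid_two_deme()
  g$migrations <- list(list(source = "a", dest = "b", rate = 1.5,
                            start_time = Inf, end_time = 0))
  expect_true("migration_rate_range" %in% demes_validate_rates(g)$code)
  g$migrations[[1]]$rate <- 0
  d <- demes_validate_rates(g)
  expect_true("migration_zero_rate" %in% d$code)
  expect_identical(d$severity[d$code == "migration_zero_rate"], "warning")
  g$migrations[[1]]$rate <- 1e-4
  expect_identical(nrow(demes_validate_rates(g)), 0L)
})

test_that("overlapping inbound migrations busting the unit budget are caught", {
  g <- valid_two_deme()
  g$demes[[3]] <- g$demes[[1]]; g$demes[[3]]$name <- "c"
  g$migrations <- list(
    list(source = "a", dest = "c", rate = 0.6, start_time = 100, end_time = 0),
    list(source = "b", dest = "c", rate = 0.6, start_time = 50, end_time = 10))
  d <- demes_validate_rates(g)
  expect_true("migration_ingress_exceeds_1" %in% d$code)
  # same rates, disjoint intervals: within budget
  g$migrations[[2]]$start_time <- 200
  g$migrations[[2]]$end_time <- 100
  expect_false("migration_ingress_exceeds_1" %in% demes_validate_rates(g)$code)
})

test_that("the ingress sweep agrees with the midpoint brute-force oracle", {
  for (s in 1:200) {
    rng <- new_rng(s)
    k <- rng_int(rng, 1, 6)
    migs <- lapply(seq_len(k), function(i) {
      t1 <- rng_unif(rng, 0, 100); t2 <- rng_unif(rng, 0, 100)
      list(source = paste0("s", i), dest = "d",
           rate = rng_unif(rng, 0, 0.5),
           start_time = max(t1, t2) + 0.5, end_time = min(t1, t2))
    })
    pieces <- ingress_intervals(migs, "d")
    oracle <- midpoint_ingress(migs, "d")
    expect_equal(pieces$rate, oracle$rate, tolerance = 1e-12,
                 label = sprintf("seed %d", s))
    expect_identical(any(pieces$rate > 1 + 1e-9),
                     any(oracle$rate > 1 + 1e-9))
  }
})

test_that("pulse proportions and endpoint liveness are enforced", {
  g <- valid_two_deme()
  g$pulses <- list(list(sources = c("a", "a"), dest = "b",
                        proportions = c(0.5, 0.6), time = 10))
  d <- demes_validate_rates(g)
  expect_true("pulse_proportion_sum" %in% d$code)
  g$pulses <- list(list(sources = "a", dest = "b", proportions = 1.2,
                        time = 10))
  expect_true("pulse_proportion_range" %in% demes_validate_rates(g)$code)
  # two pulses at the same destination and time: order-dependence warning
  g$pulses <- list(
    list(sources = "a", dest = "b", proportions = 0.2, time = 10),
    list(sources = "a", dest = "b", proportions = 0.2, time = 10))
  d2 <- demes_validate_rates(g)
  expect_true("pulse_same_time" %in% d2$code[d2$severity == "warning"])
})

test_that("validation is complete and deterministic, not first-failure", {
  g <- valid_two_deme()
  base <- nrow(demes_validate(g))
  g$migrations <- list(list(source = "a", dest = "zzz", rate = 2,
                            start_time = 10, end_time = 0))
  d1 <- demes_validate(g)
  expect_gte(nrow(d1), base + 2L)  # unknown deme AND bad rate
  g$demes[[2]]$name <- "a"
  d2 <- demes_validate(g)
  expect_gt(nrow(d2), nrow(d1))    # monotone under added defects
  expect_identical(d2, demes_validate(g))  # stable order across runs
})

test_that("every generated graph validates cleanly", {
  for (s in 1:150) {
    g <- demes_random_graph(demes_gen_config(
      seed = 2000 + s, n_demes = c(1, 7),
      time_units = if (s %% 4 == 0) "years" else "generations"))
    d <- demes_validate(g)
    expect_identical(sum(d$severity == "error"), 0L,
                     label = sprintf("seed %d", 2000 + s))
  }
})

test_that("every catalogued defect is caught with its expected code", {
  for (s in c(3, 11)) {
    g <- demes_random_graph(demes_gen_config(seed = s, n_demes = c(2, 5)))
    for (def in names(demes_defect_codes())) {
      doc <- demes_perturb_invalid(g, def, seed = s)
      err <- tryCatch({demes_resolve(doc); NULL}, demes_error = function(e) e)
      expect_false(is.null(err), label = sprintf("%s seed %d", def, s))
      expect_true(demes_defect_codes()[[def]] %in% err$diagnostics$code,
                  label = sprintf("%s seed %d", def, s))
    }
  }
})
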