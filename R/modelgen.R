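# Deterministic pseudo-random generator of valid Demes graphs, used as the
# substrate for round-trip and validator property tests. Graphs are valid
# by construction: demes are created oldest-first so ancestry is acyclic,
# times come from stratified interval splitting so they are strictly
# monotone without rejection sampling, and migration rates are small enough
# that the ingress budget always holds.

#' Configuration for the random model generator
#'
#' @param seed integer seed for the generator's own portable RNG (a Lehmer
#'   multiplicative congruential generator; independent of R's RNG).
#' @param n_demes integer range (length 2) for the number of demes.
#' @param max_epochs maximum epochs per deme.
#' @param p_migration probability that a coexisting deme pair gets a
#'   migration stanza.
#' @param p_pulse probability that a coexisting deme pair gets a pulse.
#' @param time_units time units of the generated model.
#' @param allow_infinite_root whether root demes may extend infinitely far
#'   into the past.
#' @param ms_subset if `TRUE`, restrict to features expressible in ms
#'   flags: every deme extends to the present, single ancestors, infinite
#'   roots, constant/exponential sizes only, no pulses, no selfing/cloning,
#'   at most one migration entry per ordered deme pair.
#' @return A list of class `demes_gen_config`.
#' @export
demes_gen_config <- function(seed = 1, n_demes = c(1, 5), max_epochs = 3,
                             p_migration = 0.5, p_pulse = 0.15,
                             time_units = "generations",
                             allow_infinite_root = TRUE, ms_subset = FALSE) {
  stopifnot(length(n_demes) == 2L, n_demes[1] >= 1, n_demes[2] >= n_demes[1],
            max_epochs >= 1, p_migration >= 0, p_migration <= 1,
            p_pulse >= 0, p_pulse <= 1)
  structure(list(seed = seed, n_demes = n_demes, max_epochs = max_epochs,
                 p_migration = p_migration, p_pulse = p_pulse,
                 time_units = time_units,
                 allow_infinite_root = allow_infinite_root,
                 ms_subset = ms_subset),
            class = "demes_gen_config")
}

# strictly decreasing interior cut points between hi and lo, one per
# stratum, no rejection needed
split_times <- function(rng, lo, hi, k) {
  if (k == 0L) return(numeric(0))
  frac <- vapply(seq_len(k), function(i)
    (i - 0.2 - 0.6 * rng_unif(rng)) / (k + 1), numeric(1))
  sort(lo + (hi - lo) * frac, decreasing = TRUE)
}

GEN_T_MAX <- 1e4   # oldest finite time used for roots and infinity cut-offs
GEN_SIZE_RANGE <- c(1e2, 1e6)

#' Generate a random valid Demes graph
#'
#' Same seed, same graph, on every platform. Every generated graph passes
#' [demes_validate()] with zero errors (the generator stops if not).
#'
#' @param cfg a [demes_gen_config()], or a seed given as a single number.
#' @return A `demes_graph`.
#' @examples
#' g <- demes_random_graph(demes_gen_config(seed = 42, n_demes = c(2, 4)))
#' length(g$demes) >= 2
#' @export
demes_random_graph <- function(cfg = demes_gen_config()) {
  if (is.numeric(cfg)) cfg <- demes_gen_config(seed = cfg)
  stopifnot(inherits(cfg, "demes_gen_config"))
  rng <- new_rng(cfg$seed)
  n <- rng_int(rng, cfg$n_demes[1], cfg$n_demes[2])
  gt <- if (identical(cfg$time_units, "generations")) 1
        else round(rng_unif(rng, 15, 35), 2)

  rand_size <- function() round(rng_logunif(rng, GEN_SIZE_RANGE[1],
                                            GEN_SIZE_RANGE[2]), 3)
  demes <- list()
  for (i in seq_len(n)) {
    nm <- paste0("deme_", letters[((i - 1) %% 26) + 1], (i - 1) %/% 26 + 1)
    root <- i == 1L || rng_bool(rng, 0.25) || length(demes) == 0L
    end_time <- 0
    if (root) {
      start_time <- if (cfg$allow_infinite_root && (cfg$ms_subset || rng_bool(rng, 0.7)))
        Inf else rng_unif(rng, GEN_T_MAX / 2, GEN_T_MAX)
      ancestors <- character(0)
      proportions <- numeric(0)
    } else {
      # candidate ancestors: any earlier deme with a positive-length window
      # (end, start) in which the child could begin and still reach time 0
      cand <- Filter(function(j) {
        d <- demes[[j]]
        min(d$start_time, GEN_T_MAX) > deme_end_time(d)
      }, seq_along(demes))
      if (length(cand) == 0L) {
        start_time <- Inf
        ancestors <- character(0)
        proportions <- numeric(0)
      } else {
        a1 <- demes[[rng_pick(rng, cand)]]
        lo <- deme_end_time(a1)
        hi <- min(a1$start_time, GEN_T_MAX)
        start_time <- rng_unif(rng, lo + 0.05 * (hi - lo), lo + 0.95 * (hi - lo))
        ancestors <- a1$name
        proportions <- 1
        if (!cfg$ms_subset && rng_bool(rng, 0.2)) {
          others <- Filter(function(j) {
            d <- demes[[j]]
            d$name != a1$name && deme_end_time(d) <= start_time &&
              start_time < d$start_time
          }, seq_along(demes))
          if (length(others)) {
            a2 <- demes[[rng_pick(rng, others)]]
            p <- round(rng_unif(rng, 0.05, 0.95), 6)
            ancestors <- c(a1$name, a2$name)
            proportions <- c(p, 1 - p)
          }
        }
      }
    }
    if (!cfg$ms_subset && start_time < Inf && rng_bool(rng, 0.1))
      end_time <- round(rng_unif(rng, 0, start_time / 4), 6)

    k <- rng_int(rng, 1, cfg$max_epochs)
    hi_finite <- min(start_time, GEN_T_MAX)
    cuts <- c(split_times(rng, end_time, hi_finite, k - 1L), end_time)
    epochs <- list()
    prev_size <- rand_size()
    prev_t <- start_time
    for (j in seq_len(k)) {
      infinite_epoch <- is.infinite(prev_t)
      constant <- infinite_epoch || rng_bool(rng, 0.6)
      start_size <- prev_size
      end_size <- if (constant) start_size else {
        s <- rand_size()
        if (abs(s - start_size) <= 1e-6 * start_size) s <- 2 * s
        s
      }
      selfing <- if (!cfg$ms_subset && rng_bool(rng, 0.07))
        round(rng_unif(rng, 0, 0.5), 6) else 0
      epochs[[j]] <- list(
        start_time = prev_t, end_time = cuts[j],
        start_size = start_size, end_size = end_size,
        size_function = if (constant) "constant" else "exponential",
        selfing_rate = selfing, cloning_rate = 0)
      prev_t <- cuts[j]
      # next epoch usually inherits the size across the boundary
      prev_size <- if (rng_bool(rng, 0.7)) end_size else {
        s <- rand_size()
        # avoid a hidden merge of identical adjacent constant epochs
        if (s == end_size) s + 1 else s
      }
    }
    # adjacent constant epochs with equal sizes collapse in several
    # serialisations; nudge them apart
    for (j in seq_len(k - 1L))
      if (epochs[[j]]$size_function == "constant" &&
          epochs[[j + 1L]]$size_function == "constant" &&
          epochs[[j]]$end_size == epochs[[j + 1L]]$start_size) {
        epochs[[j + 1L]]$start_size <- epochs[[j + 1L]]$start_size * 1.1
        epochs[[j + 1L]]$end_size <- epochs[[j + 1L]]$start_size
      }

    demes[[i]] <- list(
      name = nm,
      description = if (rng_bool(rng, 0.2)) paste("random deme", i) else "",
      start_time = start_time, ancestors = ancestors,
      proportions = proportions, epochs = epochs)
  }

  nms <- vapply(demes, `[[`, character(1), "name")
  coexist <- function(a, b) {
    lo <- max(deme_end_time(a), deme_end_time(b))
    hi <- min(a$start_time, b$start_time)
    c(lo, hi)
  }
  migrations <- list()
  pulses <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      win <- coexist(demes[[i]], demes[[j]])
      if (win[2] <= win[1]) next
      if (rng_bool(rng, cfg$p_migration)) {
        rate <- rng_logunif(rng, 1e-6, 1e-3)
        symmetric <- rng_bool(rng, 0.5)
        explicit <- !cfg$ms_subset && rng_bool(rng, 0.4) && is.finite(win[2])
        if (explicit) {
          tt <- split_times(rng, win[1], win[2], 2L)
          iv <- c(tt[1], tt[2])
        } else iv <- c(win[2], win[1])
        add <- function(s, d) migrations[[length(migrations) + 1L]] <<- list(
          source = s, dest = d, rate = rate,
          start_time = iv[1], end_time = iv[2])
        add(nms[i], nms[j])
        if (symmetric) add(nms[j], nms[i])
      }
      if (!cfg$ms_subset && rng_bool(rng, cfg$p_pulse)) {
        hi <- min(win[2], GEN_T_MAX)
        t <- rng_unif(rng, win[1] + 0.05 * (hi - win[1]),
                      win[1] + 0.9 * (hi - win[1]))
        from_i <- rng_bool(rng)
        pulses[[length(pulses) + 1L]] <- list(
          sources = nms[if (from_i) i else j],
          dest = nms[if (from_i) j else i],
          proportions = round(rng_unif(rng, 0.01, 0.5), 6),
          time = t)
      }
    }
  }

  g <- structure(list(
    description = if (rng_bool(rng, 0.3)) "randomly generated model" else "",
    time_units = cfg$time_units,
    generation_time = gt,
    demes = demes, migrations = migrations, pulses = pulses,
    metadata = structure(list(), names = character(0))
  ), class = "demes_graph")
  d <- demes_validate(g)
  if (has_errors(d))
    stop(paste("internal error: generated graph is invalid;",
               paste(d$message[d$severity == "error"], collapse = "; ")))
  g
}

# defect token -> diagnostic code expected from demes_resolve
DEFECT_CODES <- c(
  "bad-rate" = "migration_rate_range",
  "cyclic-ancestry" = "cyclic_ancestry",
  "missing-first-size" = "epoch_missing_size",
  "non-monotone-times" = "times_not_decreasing",
  "dangling-reference" = "unknown_deme",
  "over-budget-ingress" = "migration_ingress_exceeds_1",
  "proportion-sum" = "proportion_sum"
)

#' Defect catalogue for the negative-test factory
#'
#' Names are the defect tokens accepted by [demes_perturb_invalid()];
#' values are the diagnostic codes the damaged document must trigger.
#' @return Named character vector.
#' @export
demes_defect_codes <- function() DEFECT_CODES

#' Damage a valid graph so that it fails validation
#'
#' Emits an unresolved document that fails [demes_resolve()] with (at
#' least) the diagnostic code documented in [demes_defect_codes()] for the
#' requested defect.
#'
#' @param graph a valid `demes_graph`.
#' @param defect a defect token from [demes_defect_codes()].
#' @param seed controls which part of the model is damaged.
#' @return A document tree with the defect injected.
#' @export
demes_perturb_invalid <- function(graph, defect, seed = 1) {
  stopifnot(inherits(graph, "demes_graph"))
  if (!(defect %in% names(DEFECT_CODES)))
    stop(sprintf("unknown defect '%s'; known: %s", defect,
                 paste(names(DEFECT_CODES), collapse = ", ")), call. = FALSE)
  rng <- new_rng(seed)
  doc <- demes_simplify(graph)
  victim <- rng_int(rng, 1, length(doc$demes))
  first_name <- doc$demes[[victim]]$name
  add_root <- function(doc, nm, end_time = 0) {
    ep <- list(start_size = 100)
    if (end_time > 0) ep$end_time <- end_time
    doc$demes[[length(doc$demes) + 1L]] <- list(name = nm, epochs = list(ep))
    doc
  }
  switch(defect,
    "bad-rate" = {
      doc <- add_root(doc, "zz_mig_a")
      doc <- add_root(doc, "zz_mig_b")
      doc$migrations <- c(doc$migrations, list(list(
        demes = list("zz_mig_a", "zz_mig_b"),
        rate = 1 + rng_unif(rng, 0.1, 9))))
    },
    "cyclic-ancestry" = {
      doc$demes <- c(doc$demes, list(
        list(name = "zz_cyc_a", ancestors = list("zz_cyc_b"),
             start_time = 10, epochs = list(list(start_size = 100))),
        list(name = "zz_cyc_b", ancestors = list("zz_cyc_a"),
             start_time = 10, epochs = list(list(start_size = 100)))))
    },
    "missing-first-size" = {
      doc$demes[[victim]]$epochs[[1]]$start_size <- NULL
      doc$demes[[victim]]$epochs[[1]]$end_size <- NULL
    },
    "non-monotone-times" = {
      doc$demes[[victim]]$ancestors <- NULL
      doc$demes[[victim]]$proportions <- NULL
      doc$demes[[victim]]$start_time <- NULL
      doc$demes[[victim]]$epochs <- list(
        list(start_size = 100, end_time = 10),
        list(end_time = 50))
    },
    "dangling-reference" = {
      doc$migrations <- c(doc$migrations, list(list(
        source = first_name, dest = "zz_nowhere", rate = 1e-4)))
    },
    "over-budget-ingress" = {
      for (nm in c("zz_in_a", "zz_in_b", "zz_in_c")) doc <- add_root(doc, nm)
      r <- rng_unif(rng, 0.55, 0.95)
      doc$migrations <- c(doc$migrations, list(
        list(source = "zz_in_a", dest = "zz_in_c", rate = r),
        list(source = "zz_in_b", dest = "zz_in_c", rate = r)))
    },
    "proportion-sum" = {
      doc <- add_root(doc, "zz_pr_a", end_time = 40)
      doc <- add_root(doc, "zz_pr_b", end_time = 40)
      doc$demes <- c(doc$demes, list(list(
        name = "zz_pr_c", ancestors = list("zz_pr_a", "zz_pr_b"),
        proportions = list(0.4, 0.7), start_time = 40,
        epochs = list(list(start_size = 100)))))
    }
  )
  doc
}
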