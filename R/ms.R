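# Conversion between ms-style command-line demography and Demes graphs.
#
# ms conventions: populations are indexed from 1; times are in units of
# 4*N0 generations; sizes are relative to N0; migration matrix entries are
# 4*N0*m. Direction: the matrix entry M[i][j] (flags -m i j M, -em t i j M)
# is the backwards-time fraction of subpopulation i made up of migrants
# from subpopulation j, which maps to a Demes migration with dest = deme i
# and source = deme j. This is the classic source of sign errors; the
# mapping here preserves lineage-movement semantics.

MS_DEMOGRAPHIC_FLAGS <- c("-I", "-n", "-g", "-G", "-m", "-ma", "-em", "-en",
                          "-eg", "-eG", "-eN", "-eM", "-ema", "-ej", "-es")
# non-demographic ms machinery, skipped with a warning: flag -> arity
MS_IGNORED_FLAGS <- c("-t" = 1, "-r" = 2, "-s" = 1, "-T" = 0, "-L" = 0,
                      "-p" = 1, "-seeds" = 3, "-f" = 1, "-c" = 2)

ms_num <- function(tok, what) {
  v <- suppressWarnings(as.numeric(tok))
  if (length(v) != 1L || is.na(v))
    stop(sprintf("ms parse error: expected a number for %s, got '%s'",
                 what, tok), call. = FALSE)
  v
}

ms_int <- function(tok, what) {
  v <- ms_num(tok, what)
  if (v != floor(v) || v < 1)
    stop(sprintf("ms parse error: expected a positive integer for %s, got '%s'",
                 what, tok), call. = FALSE)
  as.integer(v)
}

#' Parse ms demography flags into a structured event list
#'
#' Supports the demographic flag set `-I -n -g -G -m -ma -em -en -eg -eG
#' -eN -eM -ema -ej -es`. Non-demographic ms flags (`-t`, `-r`, sample
#' counts, ...) are skipped with a warning; any other flag is an error.
#'
#' @param tokens character vector of command-line tokens.
#' @return An object of class `ms_events`: number of populations, initial
#'   relative sizes, growth rates and migration matrix, plus a time-ordered
#'   event list in coalescent units.
#' @examples
#' ev <- ms_parse_args(c("-I", "2", "1", "1", "0.0", "-ej", "0.5", "2", "1"))
#' ev$npop
#' @export
ms_parse_args <- function(tokens) {
  tokens <- as.character(tokens)
  i <- 1L
  n <- length(tokens)
  npop <- 1L
  init_sizes <- 1
  init_growth <- 0
  init_M <- matrix(0, 1, 1)
  events <- list()
  take <- function(what) {
    if (i > n) stop(sprintf("ms parse error: missing argument for %s", what),
                    call. = FALSE)
    tok <- tokens[i]
    i <<- i + 1L
    tok
  }
  peek_num <- function() {
    i <= n && !is.na(suppressWarnings(as.numeric(tokens[i])))
  }
  add_event <- function(kind, t, ...) {
    events[[length(events) + 1L]] <<- c(list(kind = kind, t = t), list(...))
  }
  read_matrix <- function(k, flag) {
    m <- matrix(0, k, k)
    for (r in seq_len(k)) for (c in seq_len(k)) {
      tok <- take(flag)
      m[r, c] <- if (r == c) 0 else ms_num(tok, sprintf("%s entry", flag))
    }
    m
  }

  while (i <= n) {
    tok <- take("token")
    if (!startsWith(tok, "-") || !is.na(suppressWarnings(as.numeric(tok)))) {
      warning(sprintf("ignoring non-flag token '%s'", tok), call. = FALSE)
      next
    }
    if (tok %in% names(MS_IGNORED_FLAGS)) {
      for (k in seq_len(MS_IGNORED_FLAGS[[tok]])) take(tok)
      warning(sprintf("ignoring non-demographic flag %s", tok), call. = FALSE)
      next
    }
    if (!(tok %in% MS_DEMOGRAPHIC_FLAGS))
      stop(sprintf("unknown flag '%s'", tok), call. = FALSE)
    switch(tok,
      "-I" = {
        npop <- ms_int(take("-I npop"), "-I npop")
        for (k in seq_len(npop)) take("-I sample size")  # config, not demography
        init_sizes <- rep(1, npop)
        init_growth <- rep(0, npop)
        init_M <- matrix(0, npop, npop)
        if (peek_num()) {
          M <- ms_num(take("-I migration"), "-I migration")
          init_M[] <- M / (npop - 1)
          diag(init_M) <- 0
        }
      },
      "-n" = {
        id <- ms_int(take("-n i"), "-n i")
        init_sizes[id] <- ms_num(take("-n x"), "-n x")
      },
      "-g" = {
        id <- ms_int(take("-g i"), "-g i")
        init_growth[id] <- ms_num(take("-g alpha"), "-g alpha")
      },
      "-G" = init_growth[] <- ms_num(take("-G alpha"), "-G alpha"),
      "-m" = {
        id <- ms_int(take("-m i"), "-m i")
        jd <- ms_int(take("-m j"), "-m j")
        init_M[id, jd] <- ms_num(take("-m M"), "-m M")
      },
      "-ma" = init_M <- read_matrix(npop, "-ma"),
      "-en" = add_event("size", ms_num(take("-en t"), "-en t"),
                        pop = ms_int(take("-en i"), "-en i"),
                        x = ms_num(take("-en x"), "-en x")),
      "-eg" = add_event("growth", ms_num(take("-eg t"), "-eg t"),
                        pop = ms_int(take("-eg i"), "-eg i"),
                        alpha = ms_num(take("-eg alpha"), "-eg alpha")),
      "-eN" = add_event("size_all", ms_num(take("-eN t"), "-eN t"),
                        x = ms_num(take("-eN x"), "-eN x")),
      "-eG" = add_event("growth_all", ms_num(take("-eG t"), "-eG t"),
                        alpha = ms_num(take("-eG alpha"), "-eG alpha")),
      "-em" = add_event("mig", ms_num(take("-em t"), "-em t"),
                        dest = ms_int(take("-em i"), "-em i"),
                        source = ms_int(take("-em j"), "-em j"),
                        M = ms_num(take("-em M"), "-em M")),
      "-eM" = add_event("mig_all", ms_num(take("-eM t"), "-eM t"),
                        M = ms_num(take("-eM M"), "-eM M")),
      "-ema" = {
        t <- ms_num(take("-ema t"), "-ema t")
        k <- ms_int(take("-ema npop"), "-ema npop")
        add_event("mig_matrix", t, M = read_matrix(k, "-ema"))
      },
      "-ej" = add_event("join", ms_num(take("-ej t"), "-ej t"),
                        pop = ms_int(take("-ej i"), "-ej i"),
                        into = ms_int(take("-ej j"), "-ej j")),
      "-es" = add_event("split", ms_num(take("-es t"), "-es t"),
                        pop = ms_int(take("-es i"), "-es i"),
                        p = ms_num(take("-es p"), "-es p"))
    )
  }
  for (e in events)
    if (e$t < 0) stop("ms event times must be non-negative", call. = FALSE)
  # stable time sort preserves command-line order among simultaneous events,
  # matching ms behaviour
  if (length(events))
    events <- events[order(vapply(events, `[[`, numeric(1), "t"))]
  structure(list(npop = npop, sizes = init_sizes, growth = init_growth,
                 M = init_M, events = events), class = "ms_events")
}

#' @export
print.ms_events <- function(x, ...) {
  cat(sprintf("ms demography: %d population(s), %d event(s)\n",
              x$npop, length(x$events)))
  invisible(x)
}

# Horizon (coalescent units) at which unbounded backwards exponential
# growth is truncated: twice the oldest event time, at least 10.
ms_growth_horizon <- function(events) {
  tmax <- if (length(events)) max(vapply(events, `[[`, numeric(1), "t")) else 0
  max(2 * tmax, 10)
}

#' Build a Demes graph from parsed ms demography
#'
#' Replays the event list backwards in time. Sizes become `x * N0`
#' individuals, times `t * 4 * N0` generations, matrix entries `M` become
#' per-generation rates `M / (4 * N0)`. `-ej t i j` makes deme i derive
#' from deme j at `t`; `-es t i p` creates a new deme plus an admixture
#' pulse of proportion `1 - p` into deme i. A growth rate left unbounded
#' backwards is truncated at a documented horizon with a warning.
#'
#' @param events an `ms_events` object (or a character vector of tokens,
#'   parsed first).
#' @param N0 reference effective population size (diploids).
#' @param names optional deme names; default `deme1`, `deme2`, ...
#' @return A `demes_graph` in generations.
#' @export
ms_to_graph <- function(events, N0, names = NULL) {
  if (is.character(events)) events <- ms_parse_args(events)
  stopifnot(inherits(events, "ms_events"), is_finite_number(N0), N0 > 0)
  np <- events$npop
  # per-population replay state, in backwards (coalescent) time
  pop <- lapply(seq_len(np), function(i) list(
    created = 0,          # recent bound of backwards existence
    joined = Inf,         # join time (old bound), Inf if never joined
    into = NA_integer_,
    t_ref = 0, size = events$sizes[i], growth = events$growth[i],
    segments = list()))   # closed (t_recent, t_old, s_recent, s_old, alpha)
  M <- events$M
  snapshots <- list(list(t = 0, M = M))
  pulses <- list()

  size_at_tref <- function(s, t) s$size * exp(-s$growth * (t - s$t_ref))
  close_segment <- function(i, t) {
    s <- pop[[i]]
    if (t > s$t_ref) {
      s$segments[[length(s$segments) + 1L]] <- list(
        t_recent = s$t_ref, t_old = t,
        s_recent = s$size, s_old = size_at_tref(s, t), alpha = s$growth)
      pop[[i]] <<- s
    }
  }
  set_state <- function(i, t, size = NULL, growth = NULL) {
    close_segment(i, t)
    s <- pop[[i]]
    s$size <- if (is.null(size)) size_at_tref(s, t) else size
    if (!is.null(growth)) s$growth <- growth
    s$t_ref <- t
    pop[[i]] <<- s
  }
  check_active <- function(i, t, what) {
    if (i > length(pop) || t < pop[[i]]$created)
      stop(sprintf("%s references population %d before it exists", what, i),
           call. = FALSE)
    if (is.finite(pop[[i]]$joined))
      stop(sprintf("%s references population %d after it was joined away",
                   what, i), call. = FALSE)
  }
  snap <- function(t) {
    snapshots[[length(snapshots) + 1L]] <<- list(t = t, M = M)
  }

  for (e in events$events) {
    t <- e$t
    switch(e$kind,
      size = { check_active(e$pop, t, "-en"); set_state(e$pop, t, size = e$x, growth = 0) },
      growth = { check_active(e$pop, t, "-eg"); set_state(e$pop, t, growth = e$alpha) },
      size_all = for (i in seq_along(pop))
        if (!is.finite(pop[[i]]$joined) && t >= pop[[i]]$created)
          set_state(i, t, size = e$x, growth = 0),
      growth_all = for (i in seq_along(pop))
        if (!is.finite(pop[[i]]$joined) && t >= pop[[i]]$created)
          set_state(i, t, growth = e$alpha),
      mig = {
        check_active(e$dest, t, "-em"); check_active(e$source, t, "-em")
        if (e$dest == e$source)
          stop("-em source and dest must differ", call. = FALSE)
        M[e$dest, e$source] <- e$M
        snap(t)
      },
      mig_all = {
        k <- nrow(M)
        M[] <- e$M / (k - 1)
        diag(M) <- 0
        snap(t)
      },
      mig_matrix = {
        k <- nrow(e$M)
        if (k != nrow(M))
          stop("-ema matrix size does not match the number of populations",
               call. = FALSE)
        M <- e$M
        diag(M) <- 0
        snap(t)
      },
      join = {
        check_active(e$pop, t, "-ej"); check_active(e$into, t, "-ej")
        if (e$pop == e$into) stop("-ej i and j must differ", call. = FALSE)
        close_segment(e$pop, t)
        pop[[e$pop]]$joined <- t
        pop[[e$pop]]$into <- e$into
        M[e$pop, ] <- 0
        M[, e$pop] <- 0
        snap(t)
      },
      split = {
        check_active(e$pop, t, "-es")
        if (e$p < 0 || e$p > 1)
          stop("-es admixture proportion must lie in [0, 1]", call. = FALSE)
        k <- length(pop) + 1L
        pop[[k]] <- list(created = t, joined = Inf, into = NA_integer_,
                         t_ref = t, size = 1, growth = 0, segments = list())
        M2 <- matrix(0, k, k)
        M2[seq_len(k - 1L), seq_len(k - 1L)] <- M
        M <- M2
        snap(t)
        if (e$p < 1)
          pulses[[length(pulses) + 1L]] <- list(dest = e$pop, source = k,
                                                p = 1 - e$p, t = t)
      }
    )
  }

  # close the final (oldest) segment of every surviving population
  horizon <- ms_growth_horizon(events$events)
  for (i in seq_along(pop)) {
    s <- pop[[i]]
    if (is.finite(s$joined)) next
    if (s$growth != 0) {
      warning(sprintf(paste0("population %d has nonzero growth unbounded ",
                             "backwards in time; truncating at %s coalescent ",
                             "units"), i, fmt_num(horizon)), call. = FALSE)
      set_state(i, max(horizon, s$t_ref + 1), growth = 0)
    }
    s <- pop[[i]]
    s$segments[[length(s$segments) + 1L]] <- list(
      t_recent = s$t_ref, t_old = Inf, s_recent = s$size, s_old = s$size,
      alpha = 0)
    pop[[i]] <- s
  }

  K <- length(pop)
  if (is.null(names)) names <- paste0("deme", seq_len(K))
  if (length(names) == events$npop && K > events$npop)
    names <- c(names, paste0("deme", seq(events$npop + 1L, K)))
  if (length(names) != K || anyDuplicated(names))
    stop(sprintf("need %d distinct deme names", K), call. = FALSE)

  scale_t <- function(t) if (is.infinite(t)) Inf else 4 * N0 * t
  demes <- lapply(seq_len(K), function(i) {
    s <- pop[[i]]
    start_time <- scale_t(s$joined)
    segs <- rev(s$segments)  # oldest first
    epochs <- lapply(segs, function(sg) list(
      start_time = scale_t(sg$t_old), end_time = scale_t(sg$t_recent),
      start_size = sg$s_old * N0, end_size = sg$s_recent * N0,
      size_function = if (sg$alpha == 0 || sg$s_old == sg$s_recent)
        "constant" else "exponential",
      selfing_rate = 0, cloning_rate = 0))
    # a constant run split by non-size events stays one epoch per segment;
    # merge adjacent identical-constant segments for a tidier graph
    merged <- list()
    for (e in epochs) {
      m <- length(merged)
      if (m > 0L && merged[[m]]$size_function == "constant" &&
          e$size_function == "constant" &&
          merged[[m]]$end_size == e$start_size &&
          merged[[m]]$end_time == e$start_time) {
        merged[[m]]$end_time <- e$end_time
        merged[[m]]$end_size <- e$end_size
      } else merged[[m + 1L]] <- e
    }
    list(name = names[i], description = "",
         start_time = start_time,
         ancestors = if (is.na(s$into)) character(0) else names[s$into],
         proportions = if (is.na(s$into)) numeric(0) else 1,
         epochs = merged)
  })
  # order demes so ancestors precede descendants (older start first)
  ord <- order(-vapply(demes, `[[`, numeric(1), "start_time"))
  demes <- demes[ord]

  migrations <- ms_matrix_to_migrations(snapshots, pop, names, N0)

  g <- structure(list(
    description = "", time_units = "generations", generation_time = 1,
    demes = demes,
    migrations = migrations,
    pulses = lapply(pulses, function(p) list(
      sources = names[p$source], dest = names[p$dest],
      proportions = p$p, time = scale_t(p$t))),
    metadata = structure(list(), names = character(0))
  ), class = "demes_graph")
  d <- demes_validate(g)
  if (has_errors(d)) demes_stop(d, "graph converted from ms")
  g
}

# Turn the migration-matrix step function into per-pair Demes migrations,
# clipped to the coexistence interval of each deme pair.
ms_matrix_to_migrations <- function(snapshots, pop, names, N0) {
  K <- length(pop)
  times <- vapply(snapshots, `[[`, numeric(1), "t")
  entry <- function(s, i, j) {
    m <- s$M
    if (i <= nrow(m) && j <= nrow(m)) m[i, j] else 0
  }
  out <- list()
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    # runs of constant matrix value over [times[k], times[k+1]) and a final
    # unbounded piece
    lo <- max(pop[[i]]$created, pop[[j]]$created)
    hi <- min(pop[[i]]$joined, pop[[j]]$joined)
    if (hi <= lo) next
    k <- 1L
    while (k <= length(snapshots)) {
      v <- entry(snapshots[[k]], i, j)
      k2 <- k
      while (k2 < length(snapshots) &&
             entry(snapshots[[k2 + 1L]], i, j) == v) k2 <- k2 + 1L
      t_lo <- times[k]
      t_hi <- if (k2 == length(snapshots)) Inf else times[k2 + 1L]
      if (v != 0) {
        a <- max(t_lo, lo)
        b <- min(t_hi, hi)
        if (b > a)
          out[[length(out) + 1L]] <- list(
            source = names[j], dest = names[i], rate = v / (4 * N0),
            start_time = if (is.infinite(b)) Inf else 4 * N0 * b,
            end_time = 4 * N0 * a)
      }
      k <- k2 + 1L
    }
  }
  out
}

#' Express a Demes graph as ms command-line flags
#'
#' The graph is first converted to generations. A deme that ceases to
#' exist before the present must be continued by a descendant whose start
#' time equals the deme's end time; that descendant inherits the ms
#' population index (ms populations exist at all times). Features outside
#' ms semantics (selfing, cloning, pulses, linear size change, multiple
#' ancestors, finite-start root demes) raise an error naming the feature.
#'
#' @param graph a `demes_graph`.
#' @param N0 reference effective population size used for scaling.
#' @return Character vector of ms flag tokens.
#' @export
graph_to_ms <- function(graph, N0) {
  stopifnot(inherits(graph, "demes_graph"), is_finite_number(N0), N0 > 0)
  g <- demes_in_generations(graph)
  if (length(g$pulses))
    stop("cannot express pulses in ms flags", call. = FALSE)
  for (d in g$demes) {
    if (length(d$ancestors) > 1L)
      stop(sprintf("cannot express multiple ancestors (deme '%s') in ms flags",
                   d$name), call. = FALSE)
    if (length(d$ancestors) == 0L && is.finite(d$start_time))
      stop(sprintf("cannot express a root deme with finite start_time ('%s') in ms flags",
                   d$name), call. = FALSE)
    for (e in d$epochs) {
      if (e$selfing_rate != 0 || e$cloning_rate != 0)
        stop(sprintf("cannot express selfing/cloning (deme '%s') in ms flags",
                     d$name), call. = FALSE)
      if (e$size_function == "linear")
        stop(sprintf("cannot express linear size change (deme '%s') in ms flags",
                     d$name), call. = FALSE)
    }
  }

  nms <- vapply(g$demes, `[[`, character(1), "name")
  by_name <- stats::setNames(g$demes, nms)
  # assign ms indices; a deme ending before the present hands its index to
  # the first child whose start time equals the deme's end time
  idx <- stats::setNames(rep(NA_integer_, length(nms)), nms)
  continues <- stats::setNames(rep(NA_character_, length(nms)), nms)  # child -> parent
  for (d in g$demes) {
    et <- deme_end_time(d)
    if (et > 0) {
      kids <- Filter(function(x) length(x$ancestors) == 1L &&
                       x$ancestors == d$name && x$start_time == et, g$demes)
      if (length(kids) == 0L)
        stop(sprintf(paste0("cannot express deme '%s' ending at %s with no ",
                            "descendant continuing it in ms flags"),
                     d$name, fmt_num(et)), call. = FALSE)
      continues[[kids[[1]]$name]] <- d$name
    }
  }
  next_idx <- 1L
  for (d in g$demes) {
    if (!is.na(idx[[d$name]])) next
    if (!is.na(continues[[d$name]])) next  # resolved via parent chain below
    idx[[d$name]] <- next_idx
    next_idx <- next_idx + 1L
  }
  # chains: a continuing child shares its parent's index; walk down
  for (d in g$demes) {
    if (is.na(idx[[d$name]])) {
      chain <- d$name
      while (!is.na(continues[[chain[1]]])) chain <- c(continues[[chain[1]]], chain)
      base <- idx[[chain[1]]]
      if (is.na(base)) { base <- next_idx; next_idx <- next_idx + 1L }
      for (nm in chain) idx[[nm]] <- base
    }
  }
  npop <- max(idx)

  rows <- list()  # t, rank, tokens
  emit <- function(t, rank, ...) {
    rows[[length(rows) + 1L]] <<- list(t = t, rank = rank,
                                       tokens = as.character(c(...)))
  }
  tc <- function(t_gen) t_gen / (4 * N0)

  for (d in g$demes) {
    i <- idx[[d$name]]
    n_ep <- length(d$epochs)
    for (j in rev(seq_len(n_ep))) {
      e <- d$epochs[[j]]
      x <- e$end_size / N0
      alpha <- if (e$size_function == "exponential" && e$end_size != e$start_size)
        log(e$end_size / e$start_size) / (tc(e$start_time) - tc(e$end_time))
      else 0
      t0 <- tc(e$end_time)
      if (e$end_time == 0) {
        if (x != 1) emit(0, 0, "-n", i, fmt_ms(x))
        if (alpha != 0) emit(0, 1, "-g", i, fmt_ms(alpha))
      } else {
        emit(t0, 0, "-en", fmt_ms(t0), i, fmt_ms(x))
        if (alpha != 0) emit(t0, 1, "-eg", fmt_ms(t0), i, fmt_ms(alpha))
      }
    }
    # join: deme derives from its ancestor at start_time, unless it merely
    # continues the ancestor under the same index
    if (length(d$ancestors) == 1L && is.na(continues[[d$name]])) {
      t0 <- tc(d$start_time)
      emit(t0, 3, "-ej", fmt_ms(t0), i, idx[[d$ancestors]])
    }
  }

  for (m in g$migrations) {
    i <- idx[[m$dest]]; j <- idx[[m$source]]
    if (i == j)
      stop(sprintf(paste0("cannot express migration between '%s' and '%s': ",
                          "both map to ms population %d"),
                   m$source, m$dest, i), call. = FALSE)
    M <- 4 * N0 * m$rate
    t_rec <- tc(m$end_time)
    if (t_rec == 0) emit(0, 2, "-m", i, j, fmt_ms(M))
    else emit(t_rec, 2, "-em", fmt_ms(t_rec), i, j, fmt_ms(M))
    if (is.finite(m$start_time)) {
      src <- by_name[[m$source]]; dst <- by_name[[m$dest]]
      bound <- min(src$start_time, dst$start_time)
      if (m$start_time < bound || is.infinite(bound)) {
        t_old <- tc(m$start_time)
        emit(t_old, 2, "-em", fmt_ms(t_old), i, j, "0")
      }
    }
  }

  ord <- order(vapply(rows, `[[`, numeric(1), "t"),
               vapply(rows, `[[`, numeric(1), "rank"))
  tokens <- unlist(lapply(rows[ord], `[[`, "tokens"))
  if (npop > 1L)
    tokens <- c("-I", npop, rep("1", npop), tokens)
  tokens <- as.character(tokens)
  # per-index deme names (for a chain of demes sharing an index, the one
  # reaching closest to the present), so callers can round-trip names
  ends <- vapply(g$demes, deme_end_time, numeric(1))
  by_index <- vapply(seq_len(npop), function(k) {
    members <- which(idx == k)
    nms[members[which.min(ends[members])]]
  }, character(1))
  attr(tokens, "deme_names") <- by_index
  tokens
}

fmt_ms <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
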