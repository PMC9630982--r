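# The fully resolved graph ("machine" form): typed access, size-trajectory
# evaluation, unit conversion, JSON serialisation, structural equality, and
# simplification back to a minimal human-written document.

#' Population size of a deme at a time in the past
#'
#' Evaluates the piecewise size trajectory. Within an epoch, `constant`
#' returns `start_size`; `exponential` returns
#' `start_size * (end_size/start_size)^((t_start - t)/(t_start - t_end))`;
#' `linear` interpolates linearly. A time on an epoch boundary belongs to
#' the older epoch (intervals are half-open, closed at the recent end), so
#' the trajectory endpoints reproduce `start_size`/`end_size` exactly.
#'
#' @param deme a deme element of a `demes_graph` (e.g. `g$demes[[1]]`).
#' @param t time ago, in the graph's time units; may be a vector.
#' @return Numeric vector of population sizes.
#' @export
demes_size_at <- function(deme, t) {
  vapply(t, function(ti) size_at_scalar(deme, ti), numeric(1))
}

size_at_scalar <- function(deme, t) {
  if (!is_time_value(t))
    stop("t must be a non-negative time", call. = FALSE)
  if (t >= deme$start_time || t < deme_end_time(deme))
    stop(sprintf("deme '%s' does not exist at time %s",
                 deme$name, fmt_num(t)), call. = FALSE)
  for (e in deme$epochs) {
    if (t >= e$end_time) {
      if (e$size_function == "constant" || is.infinite(e$start_time))
        return(e$start_size)
      frac <- (e$start_time - t) / (e$start_time - e$end_time)
      return(switch(e$size_function,
        exponential = e$start_size * (e$end_size / e$start_size)^frac,
        linear = e$start_size + (e$end_size - e$start_size) * frac,
        stop(sprintf("unknown size_function '%s'", e$size_function),
             call. = FALSE)))
    }
  }
  stop("time not covered by any epoch", call. = FALSE)  # unreachable
}

#' Convert a graph to units of generations
#'
#' Divides every time by `generation_time`, sets `time_units` to
#' `"generations"` and `generation_time` to 1. Sizes, rates and proportions
#' are unchanged; infinite times remain infinite. Idempotent.
#'
#' @param graph a `demes_graph`.
#' @return A `demes_graph` in generations.
#' @export
demes_in_generations <- function(graph) {
  stopifnot(inherits(graph, "demes_graph"))
  gt <- graph$generation_time
  if (identical(graph$time_units, "generations") && gt == 1) return(graph)
  scale_t <- function(t) if (is.infinite(t)) t else t / gt
  for (i in seq_along(graph$demes)) {
    graph$demes[[i]]$start_time <- scale_t(graph$demes[[i]]$start_time)
    for (j in seq_along(graph$demes[[i]]$epochs)) {
      graph$demes[[i]]$epochs[[j]]$start_time <-
        scale_t(graph$demes[[i]]$epochs[[j]]$start_time)
      graph$demes[[i]]$epochs[[j]]$end_time <-
        scale_t(graph$demes[[i]]$epochs[[j]]$end_time)
    }
  }
  for (i in seq_along(graph$migrations)) {
    graph$migrations[[i]]$start_time <- scale_t(graph$migrations[[i]]$start_time)
    graph$migrations[[i]]$end_time <- scale_t(graph$migrations[[i]]$end_time)
  }
  for (i in seq_along(graph$pulses))
    graph$pulses[[i]]$time <- scale_t(graph$pulses[[i]]$time)
  graph$time_units <- "generations"
  graph$generation_time <- 1
  graph
}

# --- JSON serialisation -----------------------------------------------------

GRAPH_KEYS <- c("description", "time_units", "generation_time", "demes",
                "migrations", "pulses", "metadata")
DEME_KEYS <- c("name", "description", "start_time", "ancestors",
               "proportions", "epochs")
EPOCH_KEYS <- c("start_time", "end_time", "start_size", "end_size",
                "size_function", "selfing_rate", "cloning_rate")
MIG_KEYS <- c("source", "dest", "rate", "start_time", "end_time")
PULSE_KEYS <- c("sources", "dest", "proportions", "time")

#' Serialise a graph to fully explicit JSON
#'
#' Every field is written explicitly, keys in a fixed documented order, and
#' infinity is encoded as the string `"Infinity"`.
#' `demes_from_json(demes_to_json(g))` reproduces `g`.
#'
#' @param graph a `demes_graph`.
#' @return A single JSON string.
#' @export
demes_to_json <- function(graph) {
  stopifnot(inherits(graph, "demes_graph"))
  arr <- function(x) I(as.list(x))
  tree <- list(
    description = graph$description,
    time_units = graph$time_units,
    generation_time = graph$generation_time,
    demes = lapply(graph$demes, function(d) list(
      name = d$name, description = d$description,
      start_time = d$start_time,
      ancestors = arr(d$ancestors), proportions = arr(d$proportions),
      epochs = lapply(d$epochs, `[`, EPOCH_KEYS))),
    migrations = lapply(graph$migrations, `[`, MIG_KEYS),
    pulses = lapply(graph$pulses, function(p) list(
      sources = arr(p$sources), dest = p$dest,
      proportions = arr(p$proportions), time = p$time)),
    metadata = graph$metadata
  )
  as.character(jsonlite::toJSON(infinity_to_string(tree), auto_unbox = TRUE,
                                digits = I(17), null = "null", pretty = TRUE))
}

json_time <- function(x) {
  if (is_string(x) && x == "Infinity") return(Inf)
  if (is_scalar_number(x)) return(as.numeric(x))
  NA_real_
}

#' Reconstruct a graph from its explicit JSON form
#'
#' The machine form is redundant and exhaustive: every field must be
#' present. Missing fields are reported together in a single error.
#'
#' @param text a JSON string as produced by [demes_to_json()].
#' @return A `demes_graph`.
#' @export
demes_from_json <- function(text) {
  tree <- tryCatch(jsonlite::parse_json(text, simplifyVector = FALSE),
                   error = function(e) stop(sprintf("JSON syntax error: %s",
                                                    conditionMessage(e)),
                                            call. = FALSE))
  missing <- character(0)
  need <- function(node, keys, path) {
    for (k in keys)
      if (is.null(node[[k]]))
        missing <<- c(missing, path_str(path, k))
  }
  need(tree, GRAPH_KEYS, "$")
  for (i in seq_along(tree$demes)) {
    need(tree$demes[[i]], DEME_KEYS, path_str("demes", i))
    for (j in seq_along(tree$demes[[i]]$epochs))
      need(tree$demes[[i]]$epochs[[j]], EPOCH_KEYS,
           path_str("demes", i, "epochs", j))
  }
  for (i in seq_along(tree$migrations))
    need(tree$migrations[[i]], MIG_KEYS, path_str("migrations", i))
  for (i in seq_along(tree$pulses))
    need(tree$pulses[[i]], PULSE_KEYS, path_str("pulses", i))
  if (length(missing))
    stop(sprintf("not a fully resolved model; missing fields: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)

  g <- structure(list(
    description = tree$description,
    time_units = tree$time_units,
    generation_time = as.numeric(tree$generation_time),
    demes = lapply(tree$demes, function(d) list(
      name = d$name, description = d$description,
      start_time = json_time(d$start_time),
      ancestors = as_name_vec(d$ancestors),
      proportions = as_num_vec(d$proportions),
      epochs = lapply(d$epochs, function(e) list(
        start_time = json_time(e$start_time),
        end_time = json_time(e$end_time),
        start_size = as.numeric(e$start_size),
        end_size = as.numeric(e$end_size),
        size_function = e$size_function,
        selfing_rate = as.numeric(e$selfing_rate),
        cloning_rate = as.numeric(e$cloning_rate))))),
    migrations = lapply(tree$migrations, function(m) list(
      source = m$source, dest = m$dest, rate = as.numeric(m$rate),
      start_time = json_time(m$start_time),
      end_time = json_time(m$end_time))),
    pulses = lapply(tree$pulses, function(p) list(
      sources = as_name_vec(p$sources), dest = p$dest,
      proportions = as_num_vec(p$proportions),
      time = json_time(p$time))),
    metadata = tree$metadata
  ), class = "demes_graph")
  d <- demes_validate(g)
  if (has_errors(d)) demes_stop(d, "machine-form document")
  g
}

# --- structural equality ----------------------------------------------------

#' Compare two graphs within a numeric tolerance
#'
#' Graphs are equal when they have the same deme names in the same order,
#' every numeric field agrees to relative tolerance `tol`, and the
#' migration and pulse lists are equal as multisets (expansion order is an
#' implementation artifact).
#'
#' @param a,b `demes_graph` objects.
#' @param tol relative tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
demes_graphs_equal <- function(a, b, tol = DEMES_TOL) {
  nums <- function(x, y) num_close(x, y, tol)
  if (!identical(a$time_units, b$time_units)) return(FALSE)
  if (!nums(a$generation_time, b$generation_time)) return(FALSE)
  if (length(a$demes) != length(b$demes)) return(FALSE)
  for (i in seq_along(a$demes)) {
    da <- a$demes[[i]]; db <- b$demes[[i]]
    if (!identical(da$name, db$name)) return(FALSE)
    if (!identical(da$ancestors, db$ancestors)) return(FALSE)
    if (length(da$proportions) != length(db$proportions)) return(FALSE)
    if (!all(mapply(nums, da$proportions, db$proportions))) return(FALSE)
    if (!nums(da$start_time, db$start_time)) return(FALSE)
    if (length(da$epochs) != length(db$epochs)) return(FALSE)
    for (j in seq_along(da$epochs)) {
      ea <- da$epochs[[j]]; eb <- db$epochs[[j]]
      if (!identical(ea$size_function, eb$size_function)) return(FALSE)
      for (f in c("start_time", "end_time", "start_size", "end_size",
                  "selfing_rate", "cloning_rate"))
        if (!nums(ea[[f]], eb[[f]])) return(FALSE)
    }
  }
  match_multiset <- function(xs, ys, same) {
    if (length(xs) != length(ys)) return(FALSE)
    used <- logical(length(ys))
    for (x in xs) {
      hit <- FALSE
      for (j in seq_along(ys)) {
        if (!used[j] && same(x, ys[[j]])) { used[j] <- TRUE; hit <- TRUE; break }
      }
      if (!hit) return(FALSE)
    }
    TRUE
  }
  mig_same <- function(x, y)
    identical(x$source, y$source) && identical(x$dest, y$dest) &&
      nums(x$rate, y$rate) && nums(x$start_time, y$start_time) &&
      nums(x$end_time, y$end_time)
  pulse_same <- function(x, y)
    identical(x$sources, y$sources) && identical(x$dest, y$dest) &&
      length(x$proportions) == length(y$proportions) &&
      all(mapply(nums, x$proportions, y$proportions)) &&
      nums(x$time, y$time)
  if (!match_multiset(a$migrations, b$migrations, mig_same)) return(FALSE)
  if (!match_multiset(a$pulses, b$pulses, pulse_same)) return(FALSE)
  TRUE
}

# --- simplification ---------------------------------------------------------

#' Simplify a resolved graph back to a minimal document
#'
#' Emits the concise human-written form: fields equal to their would-be
#' resolved value are dropped (final end_time 0, inherited start sizes,
#' inferred start times and size functions, zero selfing/cloning), and
#' mirrored asymmetric migration pairs with identical rate and interval
#' collapse into one symmetric stanza. `demes_resolve(demes_simplify(g))`
#' reproduces `g`.
#'
#' @param graph a `demes_graph`.
#' @return A document tree suitable for [demes_dump()].
#' @export
demes_simplify <- function(graph) {
  stopifnot(inherits(graph, "demes_graph"))
  by_name <- stats::setNames(graph$demes,
                             vapply(graph$demes, `[[`, character(1), "name"))
  doc <- list()
  if (nzchar(graph$description)) doc$description <- graph$description
  doc$time_units <- graph$time_units
  if (!identical(graph$time_units, "generations"))
    doc$generation_time <- graph$generation_time

  doc$demes <- lapply(graph$demes, function(d) {
    s <- list(name = d$name)
    if (nzchar(d$description)) s$description <- d$description
    if (length(d$ancestors)) s$ancestors <- as.list(d$ancestors)
    if (length(d$proportions) > 1L) s$proportions <- as.list(d$proportions)
    inferred_start <- if (length(d$ancestors) == 0L) Inf
      else if (length(d$ancestors) == 1L) deme_end_time(by_name[[d$ancestors[[1]]]])
      else NA_real_
    if (is.na(inferred_start) || d$start_time != inferred_start)
      s$start_time <- d$start_time
    n <- length(d$epochs)
    s$epochs <- lapply(seq_len(n), function(j) {
      e <- d$epochs[[j]]
      out <- list()
      if (!(j == n && e$end_time == 0)) out$end_time <- e$end_time
      if (j == 1L) {
        out$start_size <- e$start_size
        if (e$end_size != e$start_size) out$end_size <- e$end_size
      } else {
        prev_end <- d$epochs[[j - 1L]]$end_size
        if (e$start_size != prev_end) out$start_size <- e$start_size
        if (e$end_size != e$start_size) out$end_size <- e$end_size
      }
      inferred_sf <- if (e$start_size == e$end_size) "constant" else "exponential"
      if (!identical(e$size_function, inferred_sf))
        out$size_function <- e$size_function
      if (e$selfing_rate != 0) out$selfing_rate <- e$selfing_rate
      if (e$cloning_rate != 0) out$cloning_rate <- e$cloning_rate
      if (length(out) == 0L) out <- structure(list(), names = character(0))
      out
    })
    s
  })

  migs <- simplify_migrations(graph$migrations, by_name)
  if (length(migs)) doc$migrations <- migs
  if (length(graph$pulses))
    doc$pulses <- lapply(graph$pulses, function(p) list(
      sources = as.list(p$sources), dest = p$dest,
      proportions = as.list(p$proportions), time = p$time))
  if (length(graph$metadata)) doc$metadata <- graph$metadata
  doc
}

simplify_migrations <- function(migrations, by_name) {
  default_interval <- function(s, d) {
    a <- by_name[[s]]; b <- by_name[[d]]
    c(min(a$start_time, b$start_time),
      max(deme_end_time(a), deme_end_time(b)))
  }
  n <- length(migrations)
  used <- logical(n)
  out <- list()
  for (i in seq_len(n)) {
    if (used[i]) next
    m <- migrations[[i]]
    partner <- 0L
    for (j in seq_len(n)) {
      if (j == i || used[j]) next
      w <- migrations[[j]]
      if (identical(w$source, m$dest) && identical(w$dest, m$source) &&
          w$rate == m$rate && w$start_time == m$start_time &&
          w$end_time == m$end_time) { partner <- j; break }
    }
    stanza <- if (partner > 0L) {
      used[partner] <- TRUE
      list(demes = list(m$source, m$dest), rate = m$rate)
    } else {
      list(source = m$source, dest = m$dest, rate = m$rate)
    }
    used[i] <- TRUE
    di <- default_interval(m$source, m$dest)
    if (m$start_time != di[1]) stanza$start_time <- m$start_time
    if (m$end_time != di[2]) stanza$end_time <- m$end_time
    out[[length(out) + 1L]] <- stanza
  }
  out
}

# --- print / summary --------------------------------------------------------

#' @export
print.demes_graph <- function(x, ...) {
  cat(sprintf("Demes graph: %d deme(s), %d migration(s), %d pulse(s)\n",
              length(x$demes), length(x$migrations), length(x$pulses)))
  if (nzchar(x$description)) cat(" ", x$description, "\n")
  cat(sprintf("  time units: %s (generation time %s)\n",
              x$time_units, fmt_num(x$generation_time)))
  for (d in x$demes) {
    cat(sprintf("  deme %-12s (%s, %s]  %d epoch(s)\n", d$name,
                fmt_num(d$start_time), fmt_num(deme_end_time(d)),
                length(d$epochs)))
  }
  invisible(x)
}

#' @export
summary.demes_graph <- function(object, ...) {
  sizes <- unlist(lapply(object$demes, function(d)
    unlist(lapply(d$epochs, function(e) c(e$start_size, e$end_size)))))
  structure(list(
    n_demes = length(object$demes),
    n_migrations = length(object$migrations),
    n_pulses = length(object$pulses),
    time_units = object$time_units,
    oldest_finite_time = max(c(0, unlist(lapply(object$demes, function(d)
      Filter(is.finite, c(d$start_time,
                          vapply(d$epochs, `[[`, numeric(1), "end_time"))))))),
    size_range = range(sizes)
  ), class = "summary.demes_graph")
}

#' @export
print.summary.demes_graph <- function(x, ...) {
  cat(sprintf(paste0("Demes model summary\n",
                     "  demes: %d   migrations: %d   pulses: %d\n",
                     "  time units: %s\n",
                     "  oldest finite time: %s\n",
                     "  population sizes: %s .. %s\n"),
              x$n_demes, x$n_migrations, x$n_pulses, x$time_units,
              fmt_num(x$oldest_finite_time),
              fmt_num(x$size_range[1]), fmt_num(x$size_range[2])))
  invisible(x)
}
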