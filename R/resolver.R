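# Resolution of the concise human-written form into the fully explicit
# graph: hierarchical defaults, size inheritance along time, start-time
# inference from ancestry, desugaring of symmetric migrations.
#
# Every failure is accumulated as a diagnostic; resolution reports the
# complete list rather than stopping at the first problem.

TOP_FIELDS <- c("description", "doi", "time_units", "generation_time",
                "metadata", "defaults", "demes", "migrations", "pulses")
DEME_FIELDS <- c("name", "description", "ancestors", "proportions",
                 "start_time", "epochs", "defaults")
EPOCH_FIELDS <- c("end_time", "start_size", "end_size", "size_function",
                  "selfing_rate", "cloning_rate")
MIGRATION_FIELDS <- c("demes", "source", "dest", "rate", "start_time",
                      "end_time")
PULSE_FIELDS <- c("sources", "dest", "proportions", "time")
DEFAULTS_KINDS <- list(
  epoch = EPOCH_FIELDS,
  migration = MIGRATION_FIELDS,
  pulse = PULSE_FIELDS,
  deme = c("ancestors", "proportions", "start_time")
)
SIZE_FUNCTIONS <- c("constant", "exponential", "linear")

check_unknown <- function(x, allowed, path, col) {
  bad <- setdiff(names(x), allowed)
  for (k in bad)
    collect(col, "unknown_field", path_str(path, k),
            sprintf("unknown field '%s'", k))
  length(bad) == 0L
}

fill_missing <- function(stanza, defaults) {
  for (k in names(defaults))
    if (is.null(stanza[[k]])) stanza[[k]] <- defaults[[k]]
  stanza
}

#' Apply the hierarchical defaults mechanism
#'
#' Fills every field that is absent but has an applicable default, leaving
#' explicit values untouched. Per-deme epoch defaults override top-level
#' epoch defaults key by key. The `defaults` stanzas are removed from the
#' returned document. A deme with no `epochs` entry gains one implicit
#' (empty) epoch before defaults are applied.
#'
#' @param doc an unresolved document tree (see [demes_load()]).
#' @return A new document tree with defaults applied.
#' @export
demes_apply_defaults <- function(doc) {
  col <- new_collector()
  out <- apply_defaults_impl(doc, col)
  if (has_errors(col$d)) demes_stop(col$d, "defaults")
  out
}

apply_defaults_impl <- function(doc, col) {
  top <- doc$defaults
  if (!is.null(top)) {
    check_unknown(top, names(DEFAULTS_KINDS), "defaults", col)
    for (kind in intersect(names(top), names(DEFAULTS_KINDS)))
      check_unknown(top[[kind]], DEFAULTS_KINDS[[kind]],
                    path_str("defaults", kind), col)
  }
  doc$defaults <- NULL
  demes <- doc$demes
  for (i in seq_along(demes)) {
    d <- demes[[i]]
    if (!is.list(d) || is.null(names(d))) next
    local_def <- d$defaults
    if (!is.null(local_def)) {
      check_unknown(local_def, "epoch", path_str("demes", i, "defaults"), col)
      check_unknown(local_def$epoch, EPOCH_FIELDS,
                    path_str("demes", i, "defaults", "epoch"), col)
    }
    d$defaults <- NULL
    d <- fill_missing(d, top$deme)
    epoch_def <- fill_missing(
      local_def$epoch %||% structure(list(), names = character(0)),
      top$epoch)
    if (is.null(d$epochs)) d$epochs <- list(structure(list(), names = character(0)))
    for (j in seq_along(d$epochs)) {
      if (!is.list(d$epochs[[j]])) next
      d$epochs[[j]] <- fill_missing(d$epochs[[j]], epoch_def)
    }
    demes[[i]] <- d
  }
  doc$demes <- demes
  for (i in seq_along(doc$migrations))
    if (is.list(doc$migrations[[i]]))
      doc$migrations[[i]] <- fill_missing(doc$migrations[[i]], top$migration)
  for (i in seq_along(doc$pulses))
    if (is.list(doc$pulses[[i]]))
      doc$pulses[[i]] <- fill_missing(doc$pulses[[i]], top$pulse)
  doc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_name_vec <- function(x) {
  if (is.null(x)) return(character(0))
  vapply(as.list(x), function(v) if (is_string(v)) v else NA_character_,
         character(1))
}

as_num_vec <- function(x) {
  if (is.null(x)) return(numeric(0))
  vapply(as.list(x), function(v) if (is_scalar_number(v)) as.numeric(v) else NA_real_,
         numeric(1))
}

# --- per-deme time and size resolution -------------------------------------

resolve_deme <- function(d, i, resolved_by_name, col) {
  p <- function(...) path_str("demes", i, ...)
  if (!is.list(d) || is.null(names(d))) {
    collect(col, "bad_type", p(), "deme stanza must be a mapping")
    return(NULL)
  }
  check_unknown(d, setdiff(DEME_FIELDS, "defaults"), p(), col)
  name <- d$name
  if (!is_string(name)) {
    collect(col, "bad_type", p("name"), "deme name must be a string")
    return(NULL)
  }
  ancestors <- as_name_vec(d$ancestors)
  if (anyNA(ancestors)) {
    collect(col, "bad_type", p("ancestors"), "ancestors must be deme names")
    return(NULL)
  }
  proportions <- as_num_vec(d$proportions)
  if (is.null(d$proportions) && length(ancestors) == 1L) proportions <- 1.0
  if (is.null(d$proportions) && length(ancestors) > 1L) {
    collect(col, "missing_proportions", p(),
            "a deme with multiple ancestors must list proportions")
    return(NULL)
  }

  # start time: explicit, else infinity for a root, else the single
  # ancestor's end time (the instant the ancestor hands over).
  start_time <- d$start_time
  if (is.null(start_time)) {
    if (length(ancestors) == 0L) {
      start_time <- Inf
    } else if (length(ancestors) == 1L) {
      anc <- resolved_by_name[[ancestors[[1]]]]
      if (is.null(anc)) return(NULL)  # diagnosed elsewhere
      start_time <- anc$epochs[[length(anc$epochs)]]$end_time
    } else {
      collect(col, "missing_start_time", p(),
              "a deme with multiple ancestors must specify start_time")
      return(NULL)
    }
  }
  if (!is_time_value(start_time)) {
    collect(col, "bad_type", p("start_time"),
            "start_time must be a non-negative number or infinity")
    return(NULL)
  }
  start_time <- as.numeric(start_time)

  epochs <- d$epochs
  if (is.null(epochs) || length(epochs) == 0L) {
    collect(col, "no_epochs", p("epochs"), "deme must have at least one epoch")
    return(NULL)
  }
  ok <- TRUE
  res_epochs <- vector("list", length(epochs))
  prev_end_time <- start_time
  prev_end_size <- NULL
  for (j in seq_along(epochs)) {
    e <- epochs[[j]]
    ep <- function(...) p("epochs", j, ...)
    if (!is.list(e)) {
      collect(col, "bad_type", ep(), "epoch stanza must be a mapping")
      ok <- FALSE; next
    }
    check_unknown(e, EPOCH_FIELDS, ep(), col)
    end_time <- e$end_time
    if (is.null(end_time)) {
      if (j == length(epochs)) end_time <- 0
      else {
        collect(col, "missing_end_time", ep(),
                "only the final epoch may omit end_time")
        ok <- FALSE; next
      }
    }
    if (!is_time_value(end_time) || is.infinite(end_time)) {
      collect(col, "bad_type", ep("end_time"),
              "end_time must be a finite non-negative number")
      ok <- FALSE; next
    }
    end_time <- as.numeric(end_time)
    if (!(prev_end_time > end_time)) {
      collect(col, "times_not_decreasing", ep("end_time"),
              sprintf("epoch end_time %s does not precede %s going forwards in time",
                      fmt_num(end_time), fmt_num(prev_end_time)))
      ok <- FALSE
    }

    start_size <- e$start_size
    end_size <- e$end_size
    if (is.null(start_size)) {
      if (j == 1L) start_size <- end_size  # may still be NULL
      else start_size <- prev_end_size
    }
    if (is.null(start_size)) {
      collect(col, "epoch_missing_size", ep(),
              "the first epoch must specify start_size or end_size")
      ok <- FALSE; next
    }
    if (is.null(end_size)) end_size <- start_size
    if (!is_finite_number(start_size) || start_size <= 0) {
      collect(col, "size_nonpositive", ep("start_size"),
              "start_size must be a positive finite number")
      ok <- FALSE; next
    }
    if (!is_finite_number(end_size) || end_size <= 0) {
      collect(col, "size_nonpositive", ep("end_size"),
              "end_size must be a positive finite number")
      ok <- FALSE; next
    }
    start_size <- as.numeric(start_size); end_size <- as.numeric(end_size)

    size_function <- e$size_function
    if (is.null(size_function))
      size_function <- if (num_close(start_size, end_size)) "constant" else "exponential"
    if (!is_string(size_function) || !(size_function %in% SIZE_FUNCTIONS)) {
      collect(col, "bad_type", ep("size_function"),
              sprintf("size_function must be one of: %s",
                      paste(SIZE_FUNCTIONS, collapse = ", ")))
      ok <- FALSE; next
    }
    if (size_function == "constant" && !num_close(start_size, end_size)) {
      collect(col, "size_function_mismatch", ep("size_function"),
              "a constant epoch must have start_size equal to end_size")
      ok <- FALSE
    }
    if (is.infinite(prev_end_time) && !num_close(start_size, end_size)) {
      collect(col, "infinite_epoch_not_constant", ep(),
              "an epoch with infinite start_time must have constant size")
      ok <- FALSE
    }

    selfing_rate <- e$selfing_rate %||% 0
    cloning_rate <- e$cloning_rate %||% 0
    for (nm in c("selfing_rate", "cloning_rate")) {
      v <- get(nm)
      if (!is_finite_number(v) || v < 0 || v > 1) {
        collect(col, "rate_range", ep(nm),
                sprintf("%s must lie in [0, 1]", nm))
        ok <- FALSE
      }
    }

    res_epochs[[j]] <- list(
      start_time = prev_end_time, end_time = end_time,
      start_size = start_size, end_size = end_size,
      size_function = size_function,
      selfing_rate = as.numeric(selfing_rate),
      cloning_rate = as.numeric(cloning_rate))
    prev_end_time <- end_time
    prev_end_size <- end_size
  }
  if (!ok || any(vapply(res_epochs, is.null, logical(1)))) return(NULL)

  list(name = name,
       description = if (is_string(d$description)) d$description else "",
       start_time = start_time,
       ancestors = ancestors,
       proportions = as.numeric(proportions),
       epochs = res_epochs)
}

# existence interval of a resolved deme: (start_time, end_time], i.e. the
# deme exists at instant t iff end_time <= t < start_time, and additionally
# at t == start_time the *ancestor* exists (hand-over convention). For
# checks "closed at the end" means t == end_time counts as existing.
deme_end_time <- function(d) d$epochs[[length(d$epochs)]]$end_time

deme_exists_at <- function(d, t) t >= deme_end_time(d) && t < d$start_time

# --- migrations -------------------------------------------------------------

resolve_migrations <- function(doc, demes_by_name, col) {
  out <- list()
  for (i in seq_along(doc$migrations)) {
    m <- doc$migrations[[i]]
    p <- function(...) path_str("migrations", i, ...)
    if (!is.list(m) || is.null(names(m))) {
      collect(col, "bad_type", p(), "migration stanza must be a mapping")
      next
    }
    check_unknown(m, MIGRATION_FIELDS, p(), col)
    rate <- m$rate
    if (!is_finite_number(rate)) {
      collect(col, "missing_rate", p(), "migration stanza must have a numeric rate")
      next
    }
    sym <- !is.null(m$demes)
    asym <- !is.null(m$source) || !is.null(m$dest)
    if (sym && asym) {
      collect(col, "migration_both_forms", p(),
              "migration may specify either 'demes' or source/dest, not both")
      next
    }
    if (!sym && !asym) {
      collect(col, "migration_missing_endpoints", p(),
              "migration must specify 'demes' or both source and dest")
      next
    }
    pairs <- if (sym) {
      nms <- as_name_vec(m$demes)
      if (anyNA(nms) || length(nms) < 2L) {
        collect(col, "bad_type", p("demes"),
                "'demes' must list at least two deme names")
        next
      }
      # expansion order: outer loop source, inner loop dest, document order
      do.call(rbind, lapply(nms, function(s)
        do.call(rbind, lapply(nms[nms != s], function(d) c(s, d)))))
    } else {
      if (!is_string(m$source) || !is_string(m$dest)) {
        collect(col, "bad_type", p(),
                "asymmetric migration must have string source and dest")
        next
      }
      matrix(c(m$source, m$dest), nrow = 1)
    }
    bad <- FALSE
    for (nm in unique(as.vector(pairs)))
      if (is.null(demes_by_name[[nm]])) {
        collect(col, "unknown_deme", p(), sprintf("unknown deme '%s'", nm))
        bad <- TRUE
      }
    if (bad) next
    for (k in seq_len(nrow(pairs))) {
      s <- demes_by_name[[pairs[k, 1]]]
      d <- demes_by_name[[pairs[k, 2]]]
      if (pairs[k, 1] == pairs[k, 2]) {
        collect(col, "migration_self", p(), "source and dest must differ")
        next
      }
      start_time <- m$start_time %||% min(s$start_time, d$start_time)
      end_time <- m$end_time %||% max(deme_end_time(s), deme_end_time(d))
      if (!is_time_value(start_time) || !is_time_value(end_time) ||
          is.infinite(end_time)) {
        collect(col, "bad_type", p(), "migration times must be valid times")
        next
      }
      if (!(start_time > end_time)) {
        collect(col, "migration_no_overlap", p(),
                sprintf("demes '%s' and '%s' do not coexist over a positive interval",
                        s$name, d$name))
        next
      }
      out[[length(out) + 1L]] <- list(
        source = s$name, dest = d$name, rate = as.numeric(rate),
        start_time = as.numeric(start_time), end_time = as.numeric(end_time))
    }
  }
  out
}

resolve_pulses <- function(doc, demes_by_name, col) {
  out <- list()
  for (i in seq_along(doc$pulses)) {
    pl <- doc$pulses[[i]]
    p <- function(...) path_str("pulses", i, ...)
    if (!is.list(pl) || is.null(names(pl))) {
      collect(col, "bad_type", p(), "pulse stanza must be a mapping")
      next
    }
    check_unknown(pl, PULSE_FIELDS, p(), col)
    sources <- as_name_vec(pl$sources)
    proportions <- as_num_vec(pl$proportions)
    miss <- c(if (length(sources) == 0L || anyNA(sources)) "sources",
              if (!is_string(pl$dest)) "dest",
              if (length(proportions) == 0L || anyNA(proportions)) "proportions",
              if (!is_time_value(pl$time)) "time")
    if (length(miss)) {
      collect(col, "pulse_missing_field", p(),
              sprintf("pulse must have valid fields: %s",
                      paste(miss, collapse = ", ")))
      next
    }
    out[[length(out) + 1L]] <- list(
      sources = sources, dest = pl$dest,
      proportions = proportions, time = as.numeric(pl$time))
  }
  out
}

#' Resolve a Demes document into a fully explicit graph
#'
#' Applies the defaults mechanism, inherits sizes following the progression
#' of time, infers deme start times from ancestry, expands symmetric
#' migrations into asymmetric pairs, validates everything, and returns a
#' `demes_graph` in which every field is explicit.
#'
#' On failure, a condition of class `demes_error` is raised whose
#' `diagnostics` element lists *every* problem found, not just the first.
#'
#' @param doc a document tree (see [demes_load()]), or a single string of
#'   YAML which is loaded first.
#' @return A `demes_graph` object.
#' @examples
#' g <- demes_resolve("
#' time_units: generations
#' demes:
#'  - name: a
#'    epochs:
#'     - start_size: 100
#' ")
#' g$demes[[1]]$start_time   # Inf
#' @export
demes_resolve <- function(doc) {
  if (is_string(doc)) doc <- demes_load(doc)
  col <- new_collector()
  if (!is.list(doc) || is.null(names(doc)))
    demes_stop(demes_diagnostics("root_not_mapping", "error", "$",
                                 "document root must be a mapping"))
  check_unknown(doc, TOP_FIELDS, "$", col)

  time_units <- doc$time_units
  if (!is_string(time_units)) {
    collect(col, "missing_time_units", "time_units",
            "the mandatory time_units field is missing or not a string")
    time_units <- "generations"
  }
  generation_time <- doc$generation_time
  if (identical(time_units, "generations")) {
    if (!is.null(generation_time) && !isTRUE(generation_time == 1))
      collect(col, "generation_time_conflict", "generation_time",
              "generation_time must be 1 (or omitted) when time_units is generations")
    generation_time <- 1
  } else if (is.null(generation_time)) {
    collect(col, "missing_generation_time", "generation_time",
            sprintf("generation_time is required when time_units is '%s'", time_units))
    generation_time <- 1
  } else if (!is_finite_number(generation_time) || generation_time <= 0) {
    collect(col, "bad_type", "generation_time",
            "generation_time must be a positive finite number")
    generation_time <- 1
  }

  doc <- apply_defaults_impl(doc, col)

  demes_raw <- doc$demes
  if (is.null(demes_raw) || length(demes_raw) == 0L)
    collect(col, "no_demes", "demes", "the model must contain at least one deme")

  # ancestry name graph: detect cycles and forward references up front so
  # each gets its own diagnostic rather than a cascade of secondary errors
  names_in_order <- vapply(demes_raw, function(d)
    if (is.list(d) && is_string(d$name)) d$name else NA_character_, character(1))
  anc_lists <- lapply(demes_raw, function(d)
    if (is.list(d)) as_name_vec(d$ancestors) else character(0))
  known <- names_in_order[!is.na(names_in_order)]
  in_cycle <- detect_ancestry_cycles(names_in_order, anc_lists)
  for (i in seq_along(demes_raw)) {
    for (a in anc_lists[[i]]) {
      if (is.na(a)) next
      if (!(a %in% known)) {
        collect(col, "unknown_deme", path_str("demes", i, "ancestors"),
                sprintf("ancestor '%s' is not a deme in this model", a))
      } else if (!is.na(names_in_order[i]) && a == names_in_order[i]) {
        collect(col, "self_ancestor", path_str("demes", i, "ancestors"),
                "a deme may not be its own ancestor")
      } else if (match(a, names_in_order) >= i) {
        code <- if (i %in% in_cycle) "cyclic_ancestry" else "ancestor_not_defined_first"
        collect(col, code, path_str("demes", i, "ancestors"),
                sprintf("ancestor '%s' must be defined before deme '%s'",
                        a, names_in_order[i]))
      }
    }
  }

  resolved <- list()
  by_name <- list()
  for (i in seq_along(demes_raw)) {
    d <- resolve_deme(demes_raw[[i]], i, by_name, col)
    if (!is.null(d)) {
      if (!is.null(by_name[[d$name]]))
        collect(col, "duplicate_deme_name", path_str("demes", i, "name"),
                sprintf("deme name '%s' is used more than once", d$name))
      else by_name[[d$name]] <- d
      resolved[[length(resolved) + 1L]] <- d
    }
  }

  migrations <- resolve_migrations(doc, by_name, col)
  pulses <- resolve_pulses(doc, by_name, col)

  if (has_errors(col$d)) demes_stop(col$d)

  g <- structure(list(
    description = if (is_string(doc$description)) doc$description else "",
    time_units = time_units,
    generation_time = as.numeric(generation_time),
    demes = resolved,
    migrations = migrations,
    pulses = pulses,
    metadata = doc$metadata %||% structure(list(), names = character(0))
  ), class = "demes_graph")

  vd <- demes_validate(g)
  all_d <- diag_bind(col$d, vd)
  if (has_errors(all_d)) demes_stop(all_d)
  g
}

# Return indices of demes participating in an ancestry cycle (on names).
detect_ancestry_cycles <- function(nms, anc_lists) {
  idx_of <- function(a) match(a, nms)
  n <- length(nms)
  color <- integer(n)  # 0 white, 1 grey, 2 black
  cyc <- integer(0)
  visit <- function(i, stack) {
    if (color[i] == 1L) {
      cyc <<- union(cyc, stack)
      return(invisible())
    }
    if (color[i] == 2L) return(invisible())
    color[i] <<- 1L
    for (a in anc_lists[[i]]) {
      j <- idx_of(a)
      if (!is.na(j)) visit(j, c(stack, i))
    }
    color[i] <<- 2L
  }
  for (i in seq_len(n)) if (color[i] == 0L) visit(i, integer(0))
  cyc
}
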