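# Semantic validation of resolved graphs. All rule families return
# diagnostics; demes_validate() concatenates them in a deterministic order.
#
# Diagnostic catalogue (severity error unless noted):
#   duplicate_deme_name        a deme name used more than once
#   invalid_name               name is not an identifier
#   unknown_deme               a reference names a deme that does not exist
#   ancestor_not_defined_first an ancestor is listed after its descendant
#   self_ancestor              a deme lists itself as ancestor
#   cyclic_ancestry            ancestry relation contains a cycle
#   ancestor_not_alive         ancestor does not exist at descendant start
#   proportions_length         proportions length != ancestors length
#   proportion_sum             ancestry proportions do not sum to 1
#   times_not_decreasing       epoch end times not strictly decreasing
#   size_nonpositive           a population size <= 0
#   size_function_mismatch     constant epoch with start_size != end_size
#   infinite_epoch_not_constant  infinite first epoch must be constant
#   rate_range                 selfing/cloning rate outside [0, 1]
#   migration_rate_range       migration rate outside [0, 1]
#   migration_outside_existence  interval not covered by both demes
#   migration_duplicate_overlap  two entries for one (source,dest) overlap
#   migration_ingress_exceeds_1  summed inbound rate > 1 on a sub-interval
#   migration_zero_rate        warning: dead stanza with rate 0
#   pulse_proportion_range     pulse proportion outside (0, 1]
#   pulse_proportion_sum       proportions into (dest, time) sum > 1
#   pulse_endpoint_not_alive   a pulse endpoint does not exist at the time
#   pulse_same_time            warning: several pulses share (dest, time)

NAME_RE <- "^[A-Za-z_][A-Za-z0-9_]*$"

#' Validate deme naming and cross-references
#' @param graph a `demes_graph`.
#' @return A `demes_diagnostics` table.
#' @export
demes_validate_names <- function(graph) {
  col <- new_collector()
  nms <- vapply(graph$demes, `[[`, character(1), "name")
  for (i in seq_along(nms)) {
    if (!grepl(NAME_RE, nms[i]))
      collect(col, "invalid_name", path_str("demes", i, "name"),
              sprintf("'%s' is not a valid identifier", nms[i]))
    if (nms[i] %in% nms[seq_len(i - 1L)])
      collect(col, "duplicate_deme_name", path_str("demes", i, "name"),
              sprintf("deme name '%s' is used more than once", nms[i]))
  }
  check_ref <- function(nm, path) {
    if (!(nm %in% nms))
      collect(col, "unknown_deme", path, sprintf("unknown deme '%s'", nm))
  }
  for (i in seq_along(graph$demes))
    for (a in graph$demes[[i]]$ancestors)
      check_ref(a, path_str("demes", i, "ancestors"))
  for (i in seq_along(graph$migrations)) {
    check_ref(graph$migrations[[i]]$source, path_str("migrations", i, "source"))
    check_ref(graph$migrations[[i]]$dest, path_str("migrations", i, "dest"))
  }
  for (i in seq_along(graph$pulses)) {
    for (s in graph$pulses[[i]]$sources)
      check_ref(s, path_str("pulses", i, "sources"))
    check_ref(graph$pulses[[i]]$dest, path_str("pulses", i, "dest"))
  }
  col$d
}

#' Validate ancestry relationships
#' @inheritParams demes_validate_names
#' @return A `demes_diagnostics` table.
#' @export
demes_validate_ancestry <- function(graph) {
  col <- new_collector()
  nms <- vapply(graph$demes, `[[`, character(1), "name")
  by_name <- stats::setNames(graph$demes, nms)
  anc_lists <- lapply(graph$demes, `[[`, "ancestors")
  in_cycle <- detect_ancestry_cycles(nms, anc_lists)
  for (i in in_cycle)
    collect(col, "cyclic_ancestry", path_str("demes", i, "ancestors"),
            sprintf("deme '%s' participates in an ancestry cycle", nms[i]))
  for (i in seq_along(graph$demes)) {
    d <- graph$demes[[i]]
    if (d$name %in% d$ancestors)
      collect(col, "self_ancestor", path_str("demes", i, "ancestors"),
              "a deme may not be its own ancestor")
    if (length(d$proportions) != length(d$ancestors))
      collect(col, "proportions_length", path_str("demes", i, "proportions"),
              sprintf("%d proportions for %d ancestors",
                      length(d$proportions), length(d$ancestors)))
    else if (length(d$proportions) > 0L &&
             !num_close(sum(d$proportions), 1))
      collect(col, "proportion_sum", path_str("demes", i, "proportions"),
              sprintf("ancestry proportions sum to %s, not 1",
                      fmt_num(sum(d$proportions))))
    for (a in d$ancestors) {
      anc <- by_name[[a]]
      if (is.null(anc) || a == d$name || i %in% in_cycle) next
      if (match(a, nms) > i)
        collect(col, "ancestor_not_defined_first", path_str("demes", i, "ancestors"),
                sprintf("ancestor '%s' must be listed before deme '%s'", a, d$name))
      # ancestor interval (start, end], closed at its end: the ancestor must
      # contain the descendant's start instant
      if (!(d$start_time >= deme_end_time(anc) && d$start_time < anc$start_time))
        collect(col, "ancestor_not_alive", path_str("demes", i, "ancestors"),
                sprintf("ancestor '%s' does not exist at time %s",
                        a, fmt_num(d$start_time)))
    }
  }
  col$d
}

# Brute-force elementary-interval sweep: for each destination deme, cut
# time at every migration endpoint and sum the inbound rates on each piece.
ingress_intervals <- function(migrations, dest) {
  ms <- Filter(function(m) m$dest == dest, migrations)
  if (length(ms) == 0L) return(NULL)
  cuts <- sort(unique(unlist(lapply(ms, function(m) c(m$start_time, m$end_time)))),
               decreasing = TRUE)
  if (length(cuts) < 2L) return(NULL)
  pieces <- data.frame(start = cuts[-length(cuts)], end = cuts[-1])
  pieces$rate <- vapply(seq_len(nrow(pieces)), function(k) {
    mid_hi <- pieces$start[k]; mid_lo <- pieces$end[k]
    sum(vapply(ms, function(m)
      if (m$start_time >= mid_hi && m$end_time <= mid_lo) m$rate else 0,
      numeric(1)))
  }, numeric(1))
  pieces
}

#' Validate migration and pulse rate constraints
#' @inheritParams demes_validate_names
#' @return A `demes_diagnostics` table.
#' @export
demes_validate_rates <- function(graph) {
  col <- new_collector()
  nms <- vapply(graph$demes, `[[`, character(1), "name")
  by_name <- stats::setNames(graph$demes, nms)

  for (i in seq_along(graph$migrations)) {
    m <- graph$migrations[[i]]
    p <- path_str("migrations", i)
    if (!is_finite_number(m$rate) || m$rate < 0 || m$rate > 1)
      collect(col, "migration_rate_range", p,
              sprintf("migration rate %s outside [0, 1]", fmt_num(m$rate)))
    else if (m$rate == 0)
      collect(col, "migration_zero_rate", p,
              "migration with rate 0 has no effect", severity = "warning")
    for (endp in c(m$source, m$dest)) {
      d <- by_name[[endp]]
      if (is.null(d)) next
      if (!(m$start_time <= d$start_time && m$end_time >= deme_end_time(d)))
        collect(col, "migration_outside_existence", p,
                sprintf("deme '%s' does not exist throughout (%s, %s]",
                        endp, fmt_num(m$start_time), fmt_num(m$end_time)))
    }
  }

  # duplicate (source, dest) entries overlapping in time
  keys <- vapply(graph$migrations, function(m)
    paste(m$source, m$dest, sep = "\r"), character(1))
  for (k in unique(keys)) {
    idx <- which(keys == k)
    if (length(idx) < 2L) next
    for (a in idx) for (b in idx) {
      if (a >= b) next
      ma <- graph$migrations[[a]]; mb <- graph$migrations[[b]]
      if (min(ma$start_time, mb$start_time) > max(ma$end_time, mb$end_time))
        collect(col, "migration_duplicate_overlap", path_str("migrations", b),
                sprintf("overlaps an earlier %s->%s migration",
                        mb$source, mb$dest))
    }
  }

  # ingress budget: total inbound rate must never exceed 1
  for (dest in unique(vapply(graph$migrations, `[[`, character(1), "dest"))) {
    pieces <- ingress_intervals(graph$migrations, dest)
    if (is.null(pieces)) next
    bad <- which(pieces$rate > 1 + DEMES_TOL)
    if (length(bad))
      collect(col, "migration_ingress_exceeds_1", path_str("migrations"),
              sprintf("inbound migration into '%s' sums to %s over (%s, %s]",
                      dest, fmt_num(pieces$rate[bad[1]]),
                      fmt_num(pieces$start[bad[1]]), fmt_num(pieces$end[bad[1]])))
  }

  # pulses
  pulse_keys <- character(0)
  for (i in seq_along(graph$pulses)) {
    pl <- graph$pulses[[i]]
    p <- path_str("pulses", i)
    for (pr in pl$proportions)
      if (!is_finite_number(pr) || pr <= 0 || pr > 1)
        collect(col, "pulse_proportion_range", p,
                sprintf("pulse proportion %s outside (0, 1]", fmt_num(pr)))
    if (length(pl$proportions) != length(pl$sources))
      collect(col, "proportions_length", p,
              sprintf("%d proportions for %d sources",
                      length(pl$proportions), length(pl$sources)))
    key <- paste(pl$dest, fmt_num(pl$time), sep = "\r")
    pulse_keys <- c(pulse_keys, key)
    for (endp in c(pl$sources, pl$dest)) {
      d <- by_name[[endp]]
      if (is.null(d)) next
      # endpoints exist at the pulse instant, intervals closed at the end
      if (!(pl$time >= deme_end_time(d) && pl$time < d$start_time))
        collect(col, "pulse_endpoint_not_alive", p,
                sprintf("deme '%s' does not exist at time %s",
                        endp, fmt_num(pl$time)))
    }
  }
  for (k in unique(pulse_keys)) {
    idx <- which(pulse_keys == k)
    tot <- sum(unlist(lapply(graph$pulses[idx], `[[`, "proportions")))
    if (tot > 1 + DEMES_TOL)
      collect(col, "pulse_proportion_sum", path_str("pulses", idx[length(idx)]),
              sprintf("proportions into (%s) sum to %s > 1",
                      gsub("\r", ", ", k), fmt_num(tot)))
    if (length(idx) > 1L)
      collect(col, "pulse_same_time", path_str("pulses", idx[length(idx)]),
              "several pulses share destination and time; they apply in document order",
              severity = "warning")
  }
  col$d
}

# epoch-level structural sanity (sizes, times, size_function coherence)
validate_epochs <- function(graph) {
  col <- new_collector()
  for (i in seq_along(graph$demes)) {
    d <- graph$demes[[i]]
    prev_end <- d$start_time
    for (j in seq_along(d$epochs)) {
      e <- d$epochs[[j]]
      p <- path_str("demes", i, "epochs", j)
      if (!isTRUE(e$start_time > e$end_time))
        collect(col, "times_not_decreasing", p,
                "epoch start_time must exceed end_time")
      if (!num_close(e$start_time, prev_end))
        collect(col, "times_not_decreasing", p, "epochs must be contiguous")
      for (nm in c("start_size", "end_size"))
        if (!is_finite_number(e[[nm]]) || e[[nm]] <= 0)
          collect(col, "size_nonpositive", path_str(p, nm),
                  sprintf("%s must be positive and finite", nm))
      if (identical(e$size_function, "constant") &&
          !num_close(e$start_size, e$end_size))
        collect(col, "size_function_mismatch", p,
                "constant epoch with start_size != end_size")
      if (is.infinite(e$start_time) && !num_close(e$start_size, e$end_size))
        collect(col, "infinite_epoch_not_constant", p,
                "an epoch with infinite start_time must have constant size")
      for (nm in c("selfing_rate", "cloning_rate"))
        if (!is_finite_number(e[[nm]]) || e[[nm]] < 0 || e[[nm]] > 1)
          collect(col, "rate_range", path_str(p, nm),
                  sprintf("%s must lie in [0, 1]", nm))
      prev_end <- e$end_time
    }
  }
  col$d
}

#' Validate a resolved graph
#'
#' Runs every rule family (names, ancestry, epochs, migration and pulse
#' rates) and returns the complete list of diagnostics in a deterministic
#' order (by path, then code). An empty table means the graph is valid.
#'
#' @param graph a `demes_graph`.
#' @return A `demes_diagnostics` table.
#' @export
demes_validate <- function(graph) {
  stopifnot(inherits(graph, "demes_graph"))
  diag_sort(diag_bind(
    demes_validate_names(graph),
    demes_validate_ancestry(graph),
    validate_epochs(graph),
    demes_validate_rates(graph)
  ))
}
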