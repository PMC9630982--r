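# Tube-diagram layout and SVG rendering: time on the vertical axis
# (present at the bottom), one tube per deme whose half-width at time t is
# proportional to the population size at t, ancestry connectors where a
# child's tube meets its ancestor, and arrows for migrations and pulses.

# infinite start times are drawn back to INF_CAP_FACTOR times the oldest
# finite time in the model
INF_CAP_FACTOR <- 1.5
SAMPLES_PER_EPOCH <- 16L

#' Compute a tube-diagram layout for a graph
#'
#' Horizontal placement is deterministic: the ancestry forest is walked
#' depth-first with roots and children ordered by name, so the layout does
#' not depend on the order demes are listed in. Children are placed
#' adjacent to their (first) ancestor's subtree. Tube half-width at time t
#' equals `demes_size_at(deme, t) / max_size` model-wide, so coexisting
#' tubes never overlap.
#'
#' @param graph a `demes_graph`.
#' @param axis `"linear"` or `"log"`; the log axis plots `log10(t + 1)` so
#'   the present remains visible.
#' @return A `demes_layout` object.
#' @export
demes_layout <- function(graph, axis = c("linear", "log")) {
  axis <- match.arg(axis)
  stopifnot(inherits(graph, "demes_graph"))
  finite_times <- unlist(lapply(graph$demes, function(d)
    Filter(function(t) is.finite(t) && t > 0,
           c(d$start_time, unlist(lapply(d$epochs, function(e)
             c(e$start_time, e$end_time)))))))
  t_oldest <- if (length(finite_times)) max(finite_times) else 100
  cap <- INF_CAP_FACTOR * t_oldest
  max_size <- max(unlist(lapply(graph$demes, function(d)
    unlist(lapply(d$epochs, function(e) c(e$start_size, e$end_size))))))

  nms <- vapply(graph$demes, `[[`, character(1), "name")
  by_name <- stats::setNames(graph$demes, nms)
  # depth-first walk of the ancestry forest, name-sorted for determinism
  children <- lapply(nms, function(nm)
    sort(nms[vapply(graph$demes, function(d)
      length(d$ancestors) > 0L && d$ancestors[[1]] == nm, logical(1))]))
  names(children) <- nms
  roots <- sort(nms[vapply(graph$demes, function(d)
    length(d$ancestors) == 0L, logical(1))])
  # demes whose first ancestor forms a cycle-free forest; anything not
  # reached (e.g. all-ancestor ties) is appended name-sorted
  order_out <- character(0)
  walk <- function(nm) {
    order_out <<- c(order_out, nm)
    for (ch in children[[nm]]) walk(ch)
  }
  for (r in roots) walk(r)
  order_out <- c(order_out, sort(setdiff(nms, order_out)))

  gap <- 0.25
  offset <- 0
  tubes <- list()
  for (nm in order_out) {
    d <- by_name[[nm]]
    ts <- numeric(0)
    hw <- numeric(0)
    for (e in d$epochs) {
      s <- min(e$start_time, cap)
      tt <- s - (s - e$end_time) * seq(0, 1, length.out = SAMPLES_PER_EPOCH)
      tt[1] <- s
      tt[length(tt)] <- e$end_time  # pin boundaries exactly
      w <- if (e$size_function == "constant" || is.infinite(e$start_time)) {
        rep(e$start_size, length(tt))
      } else {
        frac <- (e$start_time - tt) / (e$start_time - e$end_time)
        if (e$size_function == "linear")
          e$start_size + (e$end_size - e$start_size) * frac
        else e$start_size * (e$end_size / e$start_size)^frac
      }
      ts <- c(ts, tt)
      hw <- c(hw, w)
    }
    hw <- hw / max_size
    wmax <- max(hw)
    tubes[[nm]] <- list(name = nm, t = ts, halfwidth = hw,
                        center = offset + wmax)
    offset <- offset + 2 * wmax + gap
  }
  tubes <- tubes[nms]  # report in graph order; centers already fixed

  centers <- vapply(tubes, `[[`, numeric(1), "center")
  ancestry <- list()
  for (d in graph$demes)
    for (a in d$ancestors)
      ancestry[[length(ancestry) + 1L]] <- list(
        from = a, to = d$name, time = min(d$start_time, cap),
        x0 = centers[[a]], x1 = centers[[d$name]])
  migration <- lapply(graph$migrations, function(m) {
    tmid <- (min(m$start_time, cap) + m$end_time) / 2
    list(from = m$source, to = m$dest, time = tmid,
         x0 = centers[[m$source]], x1 = centers[[m$dest]])
  })
  pulse <- lapply(graph$pulses, function(p) {
    lapply(p$sources, function(s)
      list(from = s, to = p$dest, time = p$time,
           x0 = centers[[s]], x1 = centers[[p$dest]]))
  })
  pulse <- do.call(c, c(pulse, list(list())))

  structure(list(axis = axis, cap = cap, max_size = max_size,
                 tubes = tubes,
                 connectors = list(ancestry = ancestry,
                                   migration = migration, pulse = pulse)),
            class = "demes_layout")
}

#' @export
print.demes_layout <- function(x, ...) {
  cat(sprintf("Tube-diagram layout: %d tube(s), %s time axis, capped at %s\n",
              length(x$tubes), x$axis, fmt_num(x$cap)))
  invisible(x)
}

svg_y <- function(t, layout) {
  v <- if (layout$axis == "log") log10(t + 1) else t
  vmax <- if (layout$axis == "log") log10(layout$cap + 1) else layout$cap
  v / vmax
}

#' Render a layout as a standalone SVG
#'
#' One filled path per deme tube, lines for ancestry connectors, dashed
#' arrows for continuous migrations and solid arrows for pulses. Output is
#' byte-deterministic for a fixed graph and options.
#'
#' @param layout a `demes_layout` (or a `demes_graph`, laid out with
#'   defaults first).
#' @param out output file path or connection.
#' @param width,height canvas size in pixels.
#' @return Invisibly, the SVG text.
#' @export
demes_draw_svg <- function(layout, out, width = 640, height = 480) {
  if (inherits(layout, "demes_graph")) layout <- demes_layout(layout)
  stopifnot(inherits(layout, "demes_layout"))
  mar <- 40
  xs <- unlist(lapply(layout$tubes, function(tb)
    c(tb$center - max(tb$halfwidth), tb$center + max(tb$halfwidth))))
  xr <- range(xs)
  if (diff(xr) == 0) xr <- xr + c(-1, 1)
  px <- function(x) mar + (x - xr[1]) / diff(xr) * (width - 2 * mar)
  py <- function(t) (height - mar) - svg_y(t, layout) * (height - 2 * mar)
  f <- function(v) sprintf("%.3f", v)

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            width, height, width, height),
    '<rect width="100%" height="100%" fill="white"/>')

  palette <- c("#4878d0", "#ee854a", "#6acc64", "#d65f5f", "#956cb4",
               "#8c613c", "#dc7ec0", "#797979", "#d5bb67", "#82c6e2")
  i <- 0L
  for (tb in layout$tubes) {
    i <- i + 1L
    left <- paste(sprintf("%s,%s", f(px(tb$center - tb$halfwidth)),
                          f(py(tb$t))), collapse = " ")
    right <- paste(rev(sprintf("%s,%s", f(px(tb$center + tb$halfwidth)),
                               f(py(tb$t)))), collapse = " ")
    col <- palette[((i - 1L) %% length(palette)) + 1L]
    lines <- c(lines, sprintf(
      '<path class="deme" id="deme-%s" fill="%s" fill-opacity="0.7" stroke="none" d="M %s L %s Z"/>',
      tb$name, col, left, right))
    lines <- c(lines, sprintf(
      '<text x="%s" y="%s" font-size="11" text-anchor="middle" font-family="sans-serif">%s</text>',
      f(px(tb$center)), f(py(tb$t[length(tb$t)]) + 14), tb$name))
  }
  for (cn in layout$connectors$ancestry)
    lines <- c(lines, sprintf(
      '<line class="ancestry" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#444444" stroke-width="1.5"/>',
      f(px(cn$x0)), f(py(cn$time)), f(px(cn$x1)), f(py(cn$time))))
  for (cn in layout$connectors$migration)
    lines <- c(lines, sprintf(
      '<line class="migration" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#888888" stroke-width="1" stroke-dasharray="4,3"/>',
      f(px(cn$x0)), f(py(cn$time)), f(px(cn$x1)), f(py(cn$time))))
  for (cn in layout$connectors$pulse)
    lines <- c(lines, sprintf(
      '<line class="pulse" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#222222" stroke-width="1.8"/>',
      f(px(cn$x0)), f(py(cn$time)), f(px(cn$x1)), f(py(cn$time))))
  lines <- c(lines, "</svg>")
  text <- paste(lines, collapse = "\n")
  if (is.character(out)) {
    con <- file(out, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(text, "\n")), con)
  } else {
    writeLines(text, out)
  }
  invisible(text)
}
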