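#' @keywords internal
"_PACKAGE"

# Shared numeric tolerance for proportion sums and size-continuity checks.
DEMES_TOL <- 1e-9

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && !is.nan(x)
}

is_finite_number <- function(x) is_scalar_number(x) && is.finite(x)

is_time_value <- function(x) {
  # times are non-negative reals, possibly +Inf
  is_scalar_number(x) && x >= 0
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Relative closeness with absolute fallback near zero; Inf == Inf.
num_close <- function(a, b, tol = DEMES_TOL) {
  if (is.infinite(a) || is.infinite(b)) return(a == b)
  abs(a - b) <= tol * max(1, abs(a), abs(b))
}

# Join a document path for diagnostics, e.g. demes[2].epochs[1].start_size.
# Indices are 1-based, matching R list indexing.
path_str <- function(...) {
  parts <- list(...)
  out <- character(0)
  for (p in parts) {
    if (is.numeric(p)) {
      out[length(out)] <- paste0(out[length(out)], "[", p, "]")
    } else {
      out <- c(out, as.character(p))
    }
  }
  paste(out, collapse = ".")
}

#' Create a diagnostics table
#'
#' Diagnostics are the machine-readable findings produced by validation and
#' resolution: a stable code, a severity, a path into the offending document
#' node, and a human-readable message.
#'
#' @param code character vector of stable diagnostic codes.
#' @param severity "error" or "warning", recycled.
#' @param path character vector of document paths (1-based indices).
#' @param message human-readable explanations.
#' @return A data.frame with class `demes_diagnostics`.
#' @export
demes_diagnostics <- function(code = character(0), severity = character(0),
                              path = character(0), message = character(0)) {
  n <- max(length(code), length(path), length(message))
  d <- data.frame(
    code = rep_len(as.character(code), n),
    severity = if (length(severity)) rep_len(as.character(severity), n) else character(0),
    path = rep_len(as.character(path), n),
    message = rep_len(as.character(message), n),
    stringsAsFactors = FALSE
  )
  class(d) <- c("demes_diagnostics", "data.frame")
  d
}

diag_bind <- function(...) {
  d <- do.call(rbind, Filter(function(x) nrow(x) > 0L, list(...)))
  if (is.null(d)) return(demes_diagnostics())
  class(d) <- c("demes_diagnostics", "data.frame")
  rownames(d) <- NULL
  d
}

diag_sort <- function(d) {
  if (nrow(d) == 0L) return(d)
  d <- d[order(d$path, d$code, method = "radix"), , drop = FALSE]
  rownames(d) <- NULL
  d
}

has_errors <- function(d) any(d$severity == "error")

# Mutable accumulator used by the resolver so every failure is reported,
# not just the first.
new_collector <- function() {
  env <- new.env(parent = emptyenv())
  env$d <- demes_diagnostics()
  env
}

collect <- function(col, code, path, message, severity = "error") {
  col$d <- diag_bind(col$d, demes_diagnostics(code, severity, path, message))
  invisible(NULL)
}

#' Stop with a resolution/validation error carrying diagnostics
#' @noRd
demes_stop <- function(diags, what = "model") {
  diags <- diag_sort(diags)
  lines <- sprintf("[%s] %s: %s (%s)", diags$severity, diags$path,
                   diags$message, diags$code)
  msg <- sprintf("invalid %s: %d problem(s)\n%s", what,
                 sum(diags$severity == "error"),
                 paste(lines, collapse = "\n"))
  cond <- structure(
    class = c("demes_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), diagnostics = diags)
  )
  stop(cond)
}

#' @export
print.demes_diagnostics <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No problems found.\n")
  } else {
    cat(sprintf("%d problem(s): %d error(s), %d warning(s)\n",
                nrow(x), sum(x$severity == "error"),
                sum(x$severity == "warning")))
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  [%s] %s: %s (%s)\n", x$severity[i], x$path[i],
                  x$message[i], x$code[i]))
    }
  }
  invisible(x)
}

# Format a number for deterministic text output (YAML/JSON/SVG).
fmt_num <- function(x) {
  if (is.infinite(x)) return(if (x > 0) ".inf" else "-.inf")
  if (x == floor(x) && abs(x) < 1e15) {
    format(x, scientific = FALSE, trim = TRUE)
  } else {
    format(x, digits = 17, scientific = FALSE, trim = TRUE)
  }
}
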