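#' Path to a bundled example model
#'
#' `"isolation_with_migration"` is the canonical three-deme
#' isolation-with-migration model: an ancestral deme A existing arbitrarily
#' far into the past that ceases to exist 100 generations ago, descendants
#' X and Y with a default epoch start size of 1000 individuals, exponential
#' growth of Y from 1000 to 3000 individuals over the last 50 generations,
#' and symmetric X-Y migration while both exist.
#'
#' @param name example name (currently only `"isolation_with_migration"`).
#' @return File path of the bundled YAML model.
#' @examples
#' g <- demes_resolve(demes_load(demes_example(), file = TRUE))
#' length(g$demes)  # 3
#' @export
demes_example <- function(name = "isolation_with_migration") {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "demesr",
                      mustWork = FALSE)
  if (!nzchar(path))
    stop(sprintf("no bundled example named '%s'", name), call. = FALSE)
  path
}
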