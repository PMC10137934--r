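# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that library code never perturbs the
#' caller's random stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-component substream: one user-facing seed is forked by
# component name so adding a component does not perturb the draws of others.
substream_seed <- function(seed, name) {
  u <- utf8ToInt(name)
  h <- sum(u * seq_along(u)) %% 65537
  as.integer((as.numeric(seed) * 69991 + h * 2003 + 12345) %% 2147483647)
}

# phenotypes are stored as comma-separated label strings on the sample table
has_phenotype <- function(phenotypes, label) {
  vapply(strsplit(phenotypes, ",", fixed = TRUE),
         function(p) label %in% p, logical(1))
}

check_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 0 || x != round(x))
    stop(sprintf("'%s' must be a single nonnegative integer", name), call. = FALSE)
  invisible(as.integer(x))
}
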