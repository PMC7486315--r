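#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

abort <- function(msg, class) {
  stop(structure(class = c(class, "arenosae_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's random state
#' afterwards, so generators never leak global RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# path to a packaged fixture
fixture_path <- function(...) {
  p <- system.file("extdata", ..., package = "arenosae")
  if (identical(p, "")) abort(paste0("fixture not found: ",
                                     paste(c(...), collapse = "/")),
                              "arenosae_io_error")
  p
}
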