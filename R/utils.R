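# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All generators are pure functions of (config, seed): they set the seed
#' locally and put the global RNG state back afterwards.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Derive a deterministic sub-seed (< 2^31) so independent operations draw
# from uncorrelated streams of the same master seed.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629L)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# The eight Collaborative Cross founder strain codes.
FOUNDER_CODES <- c("A", "B", "C", "D", "E", "F", "G", "H")

FOUNDER_NAMES <- c(
  A = "A/J", B = "C57BL/6J", C = "129S1/SvImJ", D = "NOD/ShiLtJ",
  E = "NZO/HlLtJ", F = "CAST/EiJ", G = "PWK/PhJ", H = "WSB/EiJ"
)

# Module label palette, largest module first (grey = unassigned).
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta"
)

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
}

stopifnot_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
}
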