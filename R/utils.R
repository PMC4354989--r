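#' @keywords internal
#' @importFrom jsonlite fromJSON toJSON
#' @importFrom xml2 xml_new_root xml_add_child xml_set_attr
#' @importFrom grDevices col2rgb rgb
#' @importFrom stats runif
"_PACKAGE"

# Classed conditions used across the package.  Every user-facing failure is
# signalled with one of these classes so that callers (and the CLI) can map
# failure kinds to behavior without parsing message strings.
ft_stop <- function(class, message, ...) {
  stop(structure(
    class = c(class, "featuretrack_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

ft_parse_error      <- function(message, ...) ft_stop("ft_parse_error", message, ...)
ft_schema_error     <- function(message, ...) ft_stop("ft_schema_error", message, ...)
ft_validation_error <- function(message, ...) ft_stop("ft_validation_error", message, ...)
ft_format_error     <- function(message, line = NA_integer_, ...) {
  ft_stop("ft_format_error", message, line = line, ...)
}
ft_parameter_error  <- function(message, ...) ft_stop("ft_parameter_error", message, ...)
ft_alignment_error  <- function(message, ...) ft_stop("ft_alignment_error", message, ...)
ft_coordinate_error <- function(message, ...) ft_stop("ft_coordinate_error", message, ...)

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_whole <- function(x) is_scalar_number(x) && abs(x - round(x)) < 1e-9

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards, so generators never perturb ambient randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Format a number for an SVG attribute: fixed notation, trailing zeros
# trimmed, 6 decimal places (far below visual resolution, exact enough
# for sub-micro-pixel alignment checks, and stable across platforms).
fmt_px <- function(x) {
  s <- formatC(round(x, 6), format = "f", digits = 6, drop0trailing = TRUE)
  sub("^-0$", "0", s)
}
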