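#' Round half away from zero at a fixed number of decimal places
#'
#' Display rounding used throughout the package. Unlike [base::round()],
#' which rounds half to even, ties are rounded away from zero (so 46.5
#' prints as 47 and 2.45 prints as 2.5 at one decimal). This is the
#' convention nutrition tables use and the only mode that reproduces the
#' shipped reference tables. It is applied at report time only; all
#' arithmetic stays on unrounded values.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (may be negative).
#' @return numeric vector rounded to `digits` places; idempotent.
#' @examples
#' round_half_up(c(2.44, 2.45, 46.7, -2.45), c(1, 1, 0, 1))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small absolute nudge so decimal literals sitting just under a tie
  # (e.g. 10.45 stored as 10.4499...) still round up
  out <- sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
  out[is.na(x)] <- NA_real_
  out
}

stop_df <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_df <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "dairyflex_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# package-local cache for parsed fixtures
.dairyflex_cache <- new.env(parent = emptyenv())

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "dairyflex")
  if (!nzchar(p)) stop_df("fixture file '%s' not found in installed package", file)
  p
}

read_fixture_csv <- function(file) {
  utils::read.csv(fixture_path(file), stringsAsFactors = FALSE,
                  colClasses = NA, check.names = FALSE)
}
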