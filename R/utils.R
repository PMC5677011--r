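#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Stop with a consistent class so callers can test for mpdlink validation
# failures specifically.
abort_mpd <- function(msg, class = "mpdlink_error") {
  rlang::abort(msg, class = c(class, "mpdlink_error"))
}

assert_square <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m)) {
    abort_mpd(sprintf("`%s` must be a square numeric matrix.", arg))
  }
  invisible(m)
}

assert_scalar_in <- function(x, lo, hi, arg, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    if (open) (x > lo && x < hi) else (x >= lo && x <= hi)
  if (!ok) {
    abort_mpd(sprintf(
      "`%s` must be a single number in %s%g, %g%s.",
      arg, if (open) "(" else "[", lo, hi, if (open) ")" else "]"
    ))
  }
  invisible(x)
}

# Round half away from zero (base round() rounds half to even).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Derive a per-run seed from a master seed
#'
#' Mixes a master seed with a run index through a fixed 32-bit linear
#' congruential step, so that experiment reports are reproducible and
#' portable across platforms. The result is always in `[0, 2^31 - 2]`.
#'
#' @param master Integer master seed.
#' @param i Integer run index (>= 0).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(master, i) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  s <- (as.numeric(master) %% m) * 1103515245 + as.numeric(i) * 12345
  as.integer(s %% m)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
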