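# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; report percentages here follow the
#' conventional half-up rule instead (so 6.85 -> 6.9 at one digit).
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Derive a reproducible sub-seed for a named data product so that adding a
# product to the generator never perturbs the draws of the others. Folds the
# product name into the master seed with a small string hash; result stays
# inside the 32-bit integer range set.seed() accepts.
.sub_seed <- function(seed, product) {
  h <- sum(utf8ToInt(product) * seq_along(utf8ToInt(product)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

.assert_count <- function(x, name, positive = TRUE) {
  .assert_scalar_number(x, name, lower = if (positive) 1 else 0)
  if (x != as.integer(x)) {
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Largest-remainder apportionment of n among proportions p (sums to n exactly;
# deterministic tie-break by vector order).
.largest_remainder <- function(n, p) {
  stopifnot(abs(sum(p) - 1) < 1e-9)
  raw <- n * p
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    frac <- raw - base
    ord <- order(frac, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}
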