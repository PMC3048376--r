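#' Normalized Hill transfer function
#'
#' Maps an input activity in \[0,1\] to an output activity in \[0,1\] through
#' a Hill curve rescaled so that f(0) = 0 and f(1) = 1:
#' \deqn{f(x) = \frac{x^n (1 + k^n)}{x^n + k^n}}
#' where `n` is the Hill coefficient (sharpness of the sigmoid) and `k` is
#' the sensitivity parameter playing the role of the EC50 midpoint.
#'
#' @param x numeric vector of input activities in \[0,1\].
#' @param n Hill coefficient, >= 1.
#' @param k sensitivity (EC50-like midpoint), > 0.
#' @return numeric vector of output activities in \[0,1\].
#' @examples
#' hill_tf(0.5, n = 3, k = 0.5)
#' @export
hill_tf <- function(x, n, k) {
  stopifnot(is.numeric(x), length(n) == 1L, length(k) == 1L)
  if (n < 1) stop("Hill coefficient n must be >= 1", call. = FALSE)
  if (k <= 0) stop("sensitivity parameter k must be > 0", call. = FALSE)
  if (any(x < -1e-9 | x > 1 + 1e-9, na.rm = TRUE)) {
    stop("input x outside [0,1]", call. = FALSE)
  }
  x <- pmin(pmax(x, 0), 1)
  xn <- x^n
  kn <- k^n
  out <- xn * (1 + kn) / (xn + kn)
  out[x == 0] <- 0
  out
}

#' Linear transfer function
#'
#' A zero-intercept linear map `slope * x`, used for edges whose source is a
#' stimulus node: stimuli are applied at saturating (0/1) levels, and a Hill
#' transfer of a 0/1 input is itself 0/1, so graded downstream activity is
#' only reachable through a linear first edge.
#'
#' @param x numeric vector of input activities in \[0,1\].
#' @param slope gain in \[0,1\].
#' @return numeric vector `slope * x`.
#' @export
linear_tf <- function(x, slope) {
  stopifnot(is.numeric(x), length(slope) == 1L)
  if (slope < 0 || slope > 1) stop("slope outside [0,1]", call. = FALSE)
  if (any(x < -1e-9 | x > 1 + 1e-9, na.rm = TRUE)) {
    stop("input x outside [0,1]", call. = FALSE)
  }
  slope * pmin(pmax(x, 0), 1)
}

#' Transfer-function specification
#'
#' Constructors for the two transfer-function families attached to gate
#' inputs. A Hill spec carries (n, k) and counts 2 free parameters; a linear
#' spec carries a slope and counts 1.
#'
#' @param n Hill coefficient (>= 1).
#' @param k sensitivity parameter (> 0).
#' @param slope linear gain in \[0,1\].
#' @return a list of class `cfl_tf` with fields `family` and the family's
#'   parameters.
#' @export
tf_hill <- function(n, k) {
  stopifnot(n >= 1, k > 0)
  structure(list(family = "hill", n = n, k = k), class = "cfl_tf")
}

#' @rdname tf_hill
#' @export
tf_linear <- function(slope) {
  stopifnot(slope >= 0, slope <= 1)
  structure(list(family = "linear", slope = slope), class = "cfl_tf")
}

#' @export
print.cfl_tf <- function(x, ...) {
  if (x$family == "hill") {
    cat(sprintf("Hill transfer function (n = %g, k = %g)\n", x$n, x$k))
  } else {
    cat(sprintf("linear transfer function (slope = %g)\n", x$slope))
  }
  invisible(x)
}

#' Evaluate one edge of a gate
#'
#' Applies the edge's transfer function and, for an inhibitory edge, inverts
#' the result (`1 - t(x)`), so that a fully active inhibitor yields 0 and an
#' inactive inhibitor yields 1.
#'
#' @param x input activity in \[0,1\].
#' @param spec a `cfl_tf` transfer-function specification.
#' @param sign +1 (activating) or -1 (inhibitory).
#' @return transferred (and possibly inverted) activity in \[0,1\].
#' @export
apply_edge_tf <- function(x, spec, sign) {
  if (is.null(spec) || !inherits(spec, "cfl_tf")) {
    stop("absent transfer-function spec: inactive gates must be skipped by the caller",
         call. = FALSE)
  }
  stopifnot(sign %in% c(-1, 1))
  t <- if (spec$family == "hill") hill_tf(x, spec$n, spec$k) else linear_tf(x, spec$slope)
  if (sign > 0) t else 1 - t
}

#' Sensitivity of a transfer function
#'
#' The sensitivity summary reported for gates: `1 - k` for Hill transfer
#' functions and `0.5 * slope` for linear ones. Higher sensitivity means the
#' output responds at lower input activity. Hill specs with k > 1 are floored
#' at 0.
#'
#' @param spec a `cfl_tf` specification.
#' @return sensitivity in \[0,1\].
#' @export
tf_sensitivity <- function(spec) {
  stopifnot(inherits(spec, "cfl_tf"))
  if (spec$family == "hill") max(0, 1 - spec$k) else 0.5 * spec$slope
}

# Discrete transfer-function libraries used by the genetic algorithm.
# Allele 0 is "absent"; alleles 1..7 index the library members below.
# Hill library: one near-linear member (n = 1.01, k = 68.5098) followed by
# sigmoids (n = 3) with EC50 0.2..0.7. Linear library: slopes 0.2..0.8.
# Both slot alphabets therefore have 1 + 7 = 8 states.

#' Discrete transfer-function libraries
#'
#' The per-slot discrete alphabets used during genetic-algorithm training.
#' `tf_library("hill")` returns the 7 Hill members (a near-linear curve plus
#' six sigmoids with ascending EC50), `tf_library("linear")` the 7 linear
#' slopes. Together with the "absent" state each slot has 8 possible values.
#'
#' @param family "hill" or "linear".
#' @return list of `cfl_tf` specs, in fixed allele order (allele i is
#'   element i; allele 0 means absent).
#' @export
tf_library <- function(family = c("hill", "linear")) {
  family <- match.arg(family)
  if (family == "hill") {
    c(list(tf_hill(n = 1.01, k = 68.5098)),
      lapply(seq(0.2, 0.7, by = 0.1), function(k) tf_hill(n = 3, k = k)))
  } else {
    lapply(seq(0.2, 0.8, by = 0.1), function(s) tf_linear(s))
  }
}

# library sizes, shared across the package
.cfl_alphabet_size <- function() 1L + 7L
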