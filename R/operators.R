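# OWA operator family: plain, probabilistic, induced, induced-probabilistic.
# All descending sorts are stable: ties keep their original index order.

#' Validate an OWA or probability weight vector
#'
#' Checks that `w` is numeric, finite, non-negative, of length `n` (when
#' given), and sums to one within `tol`. Printed weight tables often sum to
#' one only after rounding; `renormalize = TRUE` rescales such a vector by
#' its sum instead of failing.
#'
#' @param w Numeric vector of weights.
#' @param n Required length, or `NULL` to accept any length.
#' @param what Label used in error messages ("weights" or "probabilities").
#' @param renormalize Divide by `sum(w)` when the sum is off by more than
#'   `tol` (the vector must still be non-negative with a positive sum).
#' @param tol Tolerance on `abs(sum(w) - 1)`. Default `1e-9`.
#' @return The validated (possibly renormalized) numeric vector.
#' @export
#' @examples
#' validate_weights(c(0.5, 0.3, 0.2))
#' validate_weights(c(2, 1, 1), renormalize = TRUE)
validate_weights <- function(w, n = NULL, what = "weights",
                             renormalize = FALSE, tol = 1e-9) {
  if (!is.numeric(w) || anyNA(w) || any(!is.finite(w)))
    stop(what, " must be finite numeric values", call. = FALSE)
  if (!is.null(n) && length(w) != n)
    stop(what, " must have length ", n, ", got ", length(w), call. = FALSE)
  if (any(w < -tol))
    stop(what, " must be non-negative", call. = FALSE)
  w <- pmax(w, 0)
  s <- sum(w)
  if (abs(s - 1) > tol) {
    if (!renormalize)
      stop(what, " must sum to 1 (got ", format(s), "); ",
           "set renormalize = TRUE to rescale", call. = FALSE)
    if (s <= 0) stop(what, " must have a positive sum", call. = FALSE)
    w <- w / s
  }
  w
}

# Stable descending order: ties resolved by original position.
desc_order <- function(x) order(-x, seq_along(x), method = "radix")

# delta-blend of positional weights with probabilities already reordered to
# follow their arguments under the sort.
blend_weights <- function(w, v_ordered, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta < 0 || delta > 1)
    stop("delta must be a single number in [0, 1]", call. = FALSE)
  delta * w + (1 - delta) * v_ordered
}

#' Ordered weighted averaging (OWA) aggregation
#'
#' Sorts the arguments in descending order and returns the dot product with
#' the positional weight vector. The weight profile spans the minimum
#' (`w = c(0, ..., 1)`), the arithmetic mean (uniform) and the maximum
#' (`w = c(1, 0, ...)`), encoding the decision-maker's optimism.
#'
#' @param a Numeric vector of arguments.
#' @param w Positional weights, same length as `a`, non-negative, summing
#'   to one.
#' @param renormalize Passed to [validate_weights()].
#' @return A single number between `min(a)` and `max(a)`.
#' @seealso [powa()], [iowa()], [ipowa()]
#' @export
#' @examples
#' owa(c(3, 1, 2), c(1, 0, 0))        # max
#' owa(c(3, 1, 2), rep(1 / 3, 3))     # mean
owa <- function(a, w, renormalize = FALSE) {
  if (!is.numeric(a) || length(a) < 1L || anyNA(a))
    stop("arguments must be a non-empty numeric vector", call. = FALSE)
  w <- validate_weights(w, length(a), "weights", renormalize)
  sum(w * a[desc_order(a)])
}

#' Probabilistic OWA (POWA) aggregation
#'
#' Like [owa()], but each argument also carries a probability. The
#' probabilities travel with their arguments under the descending sort and
#' are blended with the positional weights: the weight at rank j is
#' `delta * w[j] + (1 - delta) * v[sigma(j)]`, where `sigma` is the sort
#' permutation. `delta = 1` recovers the OWA; `delta = 0` the
#' probability-weighted mean.
#'
#' @inheritParams owa
#' @param v Probabilities attached to the arguments (same length, sum one).
#' @param delta Blend coefficient in `[0, 1]`: share of the positional (OWA)
#'   component.
#' @return A single number between `min(a)` and `max(a)`.
#' @export
#' @examples
#' powa(c(4, 2), w = c(1, 0), v = c(0.5, 0.5), delta = 0.5)  # 3.5
powa <- function(a, w, v, delta, renormalize = FALSE) {
  if (!is.numeric(a) || length(a) < 1L || anyNA(a))
    stop("arguments must be a non-empty numeric vector", call. = FALSE)
  w <- validate_weights(w, length(a), "weights", renormalize)
  v <- validate_weights(v, length(a), "probabilities", renormalize)
  o <- desc_order(a)
  sum(blend_weights(w, v[o], delta) * a[o])
}

#' Induced OWA (IOWA) aggregation
#'
#' Arguments are reordered by a separate order-inducing variable `u`
#' (descending, stable) instead of by their own magnitude, then combined
#' with the positional weights. When `u == a` this reduces to [owa()].
#'
#' @inheritParams owa
#' @param u Order-inducing values, same length as `a`.
#' @return A single number between `min(a)` and `max(a)`.
#' @export
#' @examples
#' iowa(a = c(5, 6, 7), u = c(1, 2, 3), w = c(1, 0, 0))  # 7
iowa <- function(a, u, w, renormalize = FALSE) {
  if (!is.numeric(a) || length(a) < 1L || anyNA(a))
    stop("arguments must be a non-empty numeric vector", call. = FALSE)
  if (!is.numeric(u) || length(u) != length(a) || anyNA(u))
    stop("induced values must be numeric and match the arguments in length",
         call. = FALSE)
  w <- validate_weights(w, length(a), "weights", renormalize)
  sum(w * a[desc_order(u)])
}

#' Induced probabilistic OWA (IPOWA) aggregation
#'
#' Combines [iowa()] and [powa()]: argument/probability pairs are reordered
#' by the induced variable `u`, and the positional weights are delta-blended
#' with the reordered probabilities. `delta = 1` recovers the IOWA,
#' `delta = 0` the probability-weighted mean.
#'
#' @inheritParams powa
#' @param u Order-inducing values, same length as `a`.
#' @return A single number between `min(a)` and `max(a)`.
#' @export
#' @examples
#' ipowa(a = c(4, 2), u = c(1, 2), w = c(1, 0), v = c(0.5, 0.5),
#'       delta = 0.5)  # 0.75 * 2 + 0.25 * 4 = 2.5
ipowa <- function(a, u, w, v, delta, renormalize = FALSE) {
  if (!is.numeric(a) || length(a) < 1L || anyNA(a))
    stop("arguments must be a non-empty numeric vector", call. = FALSE)
  if (!is.numeric(u) || length(u) != length(a) || anyNA(u))
    stop("induced values must be numeric and match the arguments in length",
         call. = FALSE)
  if (missing(v) || is.null(v))
    stop("ipowa requires a probability vector", call. = FALSE)
  w <- validate_weights(w, length(a), "weights", renormalize)
  v <- validate_weights(v, length(a), "probabilities", renormalize)
  o <- desc_order(u)
  sum(blend_weights(w, v[o], delta) * a[o])
}
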