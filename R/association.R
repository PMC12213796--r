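# OWA-weighted second moments and correlation operators.
#
# Every aggregation here is a positionally weighted sum of reordered terms.
# For the correlation operators a SINGLE sample ordering couples the
# numerator and both denominator sums; with a common coupling the weighted
# Cauchy-Schwarz inequality bounds the ratio by 1 in magnitude, and uniform
# weights collapse every sum to its classical (population) counterpart.
# Magnitude mode orders by the descending cross-product terms; induced mode
# orders by an external inducing variable.

# Positionally weighted sum of terms reordered by order_by (descending,
# stable), optionally delta-blended with probabilities that travel with the
# terms under the reordering.
powa_sum <- function(terms, w, v = NULL, delta = 1, order_by = terms) {
  o <- desc_order(order_by)
  vh <- if (is.null(v)) w else blend_weights(w, v[o], delta)
  sum(vh * terms[o])
}

#' Moment specification for the OWA correlation operators
#'
#' Bundles the options that select how the weighted moments behind
#' [pearson_owa()] and friends are computed.
#'
#' * `mean_mode` — `"plain"` (default) centers every deviation on the
#'   arithmetic mean; `"owa"` activates the OWA aggregate as the center for
#'   the sums flagged by `case`.
#' * `case` — integer 1 to 16 choosing, when `mean_mode = "owa"`, which of
#'   the four centers (numerator a and b, denominator a, denominator b) use
#'   the OWA mean rather than the arithmetic mean. Case 1 = all OWA,
#'   case 16 = all plain.
#' * `ordering` — `"magnitude"` (default) orders dispersion terms by their
#'   own descending size; `"induced"` orders by an external variable.
#'
#' @param mean_mode `"plain"` or `"owa"`.
#' @param ordering `"magnitude"` or `"induced"`.
#' @param case Integer in 1..16.
#' @return An object of class `"moment_spec"`.
#' @export
moment_spec <- function(mean_mode = c("plain", "owa"),
                        ordering = c("magnitude", "induced"),
                        case = 1L) {
  mean_mode <- match.arg(mean_mode)
  ordering <- match.arg(ordering)
  case <- as.integer(case)
  if (length(case) != 1L || is.na(case) || case < 1L || case > 16L)
    stop("case must be an integer in 1..16", call. = FALSE)
  structure(list(mean_mode = mean_mode, ordering = ordering, case = case),
            class = "moment_spec")
}

# Which of the four centers (numerator a, numerator b, denominator a,
# denominator b) use the OWA mean, per variant case. Case 1 is all-OWA,
# case 16 all-plain; the remainder enumerate the mixed combinations.
.pearson_cases <- matrix(c(
  TRUE,  TRUE,  TRUE,  TRUE,   # 1
  FALSE, TRUE,  FALSE, TRUE,   # 2
  TRUE,  FALSE, TRUE,  FALSE,  # 3
  FALSE, FALSE, TRUE,  TRUE,   # 4
  TRUE,  TRUE,  FALSE, FALSE,  # 5
  FALSE, TRUE,  TRUE,  TRUE,   # 6
  TRUE,  FALSE, TRUE,  TRUE,   # 7
  FALSE, TRUE,  FALSE, FALSE,  # 8
  TRUE,  FALSE, FALSE, FALSE,  # 9
  FALSE, FALSE, FALSE, TRUE,   # 10
  FALSE, FALSE, TRUE,  FALSE,  # 11
  FALSE, TRUE,  TRUE,  FALSE,  # 12
  TRUE,  FALSE, FALSE, TRUE,   # 13
  TRUE,  TRUE,  FALSE, TRUE,   # 14
  TRUE,  TRUE,  TRUE,  FALSE,  # 15
  FALSE, FALSE, FALSE, FALSE   # 16
), ncol = 4L, byrow = TRUE,
  dimnames = list(NULL, c("num_a", "num_b", "den_a", "den_b")))

# Center of x for one slot: OWA aggregate when the case flags the slot and
# mean_mode is "owa", arithmetic mean otherwise.
.center <- function(x, w, spec, slot) {
  if (spec$mean_mode == "owa" && .pearson_cases[spec$case, slot])
    powa_sum(x, w) else mean(x)
}

.check_pair <- function(a, b, min_n = 2L) {
  if (!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b))
    stop("paired samples must be numeric without missing values",
         call. = FALSE)
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(a) < min_n)
    stop("paired samples need at least ", min_n, " observations",
         call. = FALSE)
}

#' OWA-weighted variance
#'
#' Squared deviations from the mean, sorted descending (or by the inducing
#' variable `u`) and combined with the positional weights. Uniform weights
#' give the classical population variance.
#'
#' @param a Numeric vector.
#' @param w Positional weights over `length(a)` ranks.
#' @param spec A [moment_spec()]; `mean_mode = "owa"` centers on the OWA
#'   aggregate of `a`.
#' @param u Inducing variable ordering the squared deviations when
#'   `spec$ordering == "induced"`.
#' @param renormalize Passed to [validate_weights()].
#' @return Non-negative scalar.
#' @export
#' @examples
#' var_owa(c(1, 3), c(0.5, 0.5))          # classical population variance 1
#' var_owa(c(0, 1, 5), c(1, 0, 0))        # largest squared deviation 9
var_owa <- function(a, w, spec = moment_spec(), u = NULL,
                    renormalize = FALSE) {
  if (!is.numeric(a) || length(a) < 1L || anyNA(a))
    stop("arguments must be a non-empty numeric vector", call. = FALSE)
  w <- validate_weights(w, length(a), "weights", renormalize)
  mu <- if (spec$mean_mode == "owa") powa_sum(a, w) else mean(a)
  d2 <- (a - mu)^2
  if (spec$ordering == "induced") {
    if (is.null(u)) stop("induced ordering requires u", call. = FALSE)
    powa_sum(d2, w, order_by = u)
  } else {
    powa_sum(d2, w)
  }
}

#' OWA-weighted standard deviation
#'
#' Square root of [var_owa()]. This is the contrast-intensity measure used
#' per criterion by the CRITIC weighting pipeline.
#'
#' @inheritParams var_owa
#' @return Non-negative scalar.
#' @export
sd_owa <- function(a, w, spec = moment_spec(), u = NULL,
                   renormalize = FALSE) {
  sqrt(var_owa(a, w, spec, u, renormalize))
}

#' OWA-weighted covariance
#'
#' Cross-products of deviations sorted descending and combined with the
#' positional weights. Uniform weights give the classical population
#' covariance.
#'
#' @param a,b Numeric vectors of equal length.
#' @inheritParams var_owa
#' @return Scalar.
#' @export
covar_owa <- function(a, b, w, spec = moment_spec(), renormalize = FALSE) {
  .check_pair(a, b, min_n = 1L)
  w <- validate_weights(w, length(a), "weights", renormalize)
  mua <- if (spec$mean_mode == "owa") powa_sum(a, w) else mean(a)
  mub <- if (spec$mean_mode == "owa") powa_sum(b, w) else mean(b)
  powa_sum((a - mua) * (b - mub), w)
}

#' Classical Pearson correlation
#'
#' Textbook product-moment correlation; the uniform-weight reduction of the
#' whole operator family. Errors on zero variance.
#'
#' @param a,b Numeric vectors of equal length, each non-constant.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson_classic <- function(a, b) {
  .check_pair(a, b)
  da <- a - mean(a); db <- b - mean(b)
  qa <- sum(da^2); qb <- sum(db^2)
  if (qa <= 0 || qb <= 0)
    stop("degenerate variance: both samples must be non-constant",
         call. = FALSE)
  sum(da * db) / sqrt(qa * qb)
}

# Shared engine: weighted correlation ratio with one coupling order applied
# to the cross-product and both squared-deviation sums.
.pearson_engine <- function(a, b, w, v, delta, spec, u, zero_variance) {
  .check_pair(a, b)
  d <- (a - .center(a, w, spec, "num_a")) * (b - .center(b, w, spec, "num_b"))
  k <- (a - .center(a, w, spec, "den_a"))^2
  h <- (b - .center(b, w, spec, "den_b"))^2
  order_by <- if (is.null(u)) d else u
  num <- powa_sum(d, w, v, delta, order_by)
  qa <- powa_sum(k, w, v, delta, order_by)
  qb <- powa_sum(h, w, v, delta, order_by)
  if (qa <= 0 || qb <= 0) {
    if (zero_variance == "zero") return(0)
    stop("degenerate weighted variance: correlation undefined",
         call. = FALSE)
  }
  num / sqrt(qa * qb)
}

#' Pearson-OWA correlation
#'
#' Weighted Pearson correlation in which the cross-product and squared
#' deviation sums are reordered (descending by the cross-product terms,
#' stable) and combined with positional weights, so the correlation reflects
#' the decision-maker's attitude rather than equal sample weighting. One
#' common ordering couples all three sums, which keeps the value in
#' `[-1, 1]` whenever numerator and denominators share consistent centers
#' (Cauchy-Schwarz), and makes uniform weights collapse to
#' [pearson_classic()].
#'
#' @param a,b Numeric vectors of equal length.
#' @param w Positional weights over `length(a)` ranks.
#' @param spec A [moment_spec()]; `case` selects which sums center on OWA
#'   means when `mean_mode = "owa"`.
#' @param zero_variance `"error"` (default) fails on a degenerate weighted
#'   variance; `"zero"` maps the correlation to 0, which downstream
#'   pipelines use to treat a constant criterion as conflict-free.
#' @param renormalize Passed to [validate_weights()].
#' @return Scalar correlation.
#' @export
pearson_owa <- function(a, b, w, spec = moment_spec(),
                        zero_variance = c("error", "zero"),
                        renormalize = FALSE) {
  zero_variance <- match.arg(zero_variance)
  w <- validate_weights(w, length(a), "weights", renormalize)
  .pearson_engine(a, b, w, v = NULL, delta = 1, spec = spec, u = NULL,
                  zero_variance = zero_variance)
}

#' Pearson-POWA correlation
#'
#' [pearson_owa()] with probabilities attached to the samples: the
#' positional weights are delta-blended with the probabilities after these
#' travel with their samples under the common reordering. `delta = 1`
#' recovers Pearson-OWA, `delta = 0` the probability-weighted Pearson.
#'
#' @inheritParams pearson_owa
#' @param v Probabilities over the samples (sum one).
#' @param delta Blend coefficient in `[0, 1]`.
#' @return Scalar correlation.
#' @export
pearson_powa <- function(a, b, w, v, delta, spec = moment_spec(),
                         zero_variance = c("error", "zero"),
                         renormalize = FALSE) {
  zero_variance <- match.arg(zero_variance)
  w <- validate_weights(w, length(a), "weights", renormalize)
  v <- validate_weights(v, length(a), "probabilities", renormalize)
  .pearson_engine(a, b, w, v = v, delta = delta, spec = spec, u = NULL,
                  zero_variance = zero_variance)
}

#' Pearson-IPOWA correlation
#'
#' The induced probabilistic Pearson correlation: all three sums
#' (cross-products and both squared deviations) are reordered by the SAME
#' descending inducing variable `u`, probabilities travel with their
#' samples, and positional weights are delta-blended with the reordered
#' probabilities. This is the conflict measure of the IPOWA-CRITIC pipeline,
#' where `u` is each alternative's total normalized score. Symmetric in
#' `(a, b)` and bounded by 1 in magnitude under consistent centers.
#'
#' @inheritParams pearson_powa
#' @param u Order-inducing variable over the samples.
#' @return Scalar correlation.
#' @export
pearson_ipowa <- function(a, b, u, w, v, delta, spec = moment_spec(),
                          zero_variance = c("error", "zero"),
                          renormalize = FALSE) {
  zero_variance <- match.arg(zero_variance)
  if (missing(u) || is.null(u) || !is.numeric(u) || length(u) != length(a))
    stop("pearson_ipowa requires an inducing variable u matching the samples",
         call. = FALSE)
  if (missing(v) || is.null(v))
    stop("pearson_ipowa requires a probability vector", call. = FALSE)
  w <- validate_weights(w, length(a), "weights", renormalize)
  v <- validate_weights(v, length(a), "probabilities", renormalize)
  .pearson_engine(a, b, w, v = v, delta = delta, spec = spec, u = u,
                  zero_variance = zero_variance)
}
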