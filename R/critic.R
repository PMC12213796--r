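# IPOWA-CRITIC pipeline: normalization, OWA dispersion, induced
# probabilistic conflict matrix, criterion weights, and the four
# multicriteria scoring rules with rankings.

#' Construct a decision matrix
#'
#' A decision matrix holds the raw value of every alternative (rows) on
#' every criterion (columns), plus the optimization direction of each
#' criterion: `"benefit"` (larger is better) or `"cost"` (smaller is
#' better).
#'
#' @param values Numeric matrix (or coercible), alternatives x criteria,
#'   no missing values, at least 2 x 2.
#' @param directions Character vector, one `"benefit"`/`"cost"` per
#'   criterion.
#' @param alternatives,criteria Optional labels; default to the dimnames of
#'   `values` or `A1..`, `C1..`.
#' @return An object of class `"decision_matrix"` with elements `values`,
#'   `directions`, `alternatives`, `criteria`.
#' @export
#' @examples
#' dm <- decision_matrix(matrix(c(1, 2, 3, 6, 5, 4), ncol = 2),
#'                       directions = c("benefit", "cost"))
decision_matrix <- function(values, directions,
                            alternatives = NULL, criteria = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values))
    stop("decision matrix must be numeric with no missing values",
         call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("decision matrix needs at least 2 alternatives and 2 criteria",
         call. = FALSE)
  directions <- as.character(directions)
  if (!all(directions %in% c("benefit", "cost")))
    stop("directions must be 'benefit' or 'cost'", call. = FALSE)
  if (length(directions) != ncol(values))
    stop("need one direction per criterion (", ncol(values), "), got ",
         length(directions), call. = FALSE)
  alternatives <- alternatives %||% rownames(values) %||%
    paste0("A", seq_len(nrow(values)))
  criteria <- criteria %||% colnames(values) %||%
    paste0("C", seq_len(ncol(values)))
  if (anyDuplicated(alternatives) || anyDuplicated(criteria))
    stop("alternative and criterion labels must be unique", call. = FALSE)
  dimnames(values) <- list(alternatives, criteria)
  structure(list(values = values, directions = directions,
                 alternatives = as.character(alternatives),
                 criteria = as.character(criteria)),
            class = "decision_matrix")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.decision_matrix <- function(x, ...) {
  cat("Decision matrix:", nrow(x$values), "alternatives x",
      ncol(x$values), "criteria\n")
  cat("Directions:", paste(x$directions, collapse = ", "), "\n")
  print(round(x$values, 3))
  invisible(x)
}

#' Min-max normalize a decision matrix
#'
#' Maps every criterion column onto `[0, 1]` as closeness to its ideal
#' value: for a benefit criterion the column maximum maps to 1 and the
#' minimum to 0; for a cost criterion the minimum maps to 1 and the maximum
#' to 0. Also records the per-criterion arithmetic means and each
#' alternative's total score `u_i` (row sum), the order-inducing variable
#' used downstream.
#'
#' @param dm A [decision_matrix()].
#' @return An object of class `"normalized_matrix"`: `x` (the normalized
#'   matrix), `means` (column means), `u` (row sums), plus the labels and
#'   directions carried over.
#' @export
normalize_matrix <- function(dm) {
  stopifnot(inherits(dm, "decision_matrix"))
  m <- dm$values
  x <- m
  for (j in seq_len(ncol(m))) {
    rng <- range(m[, j])
    if (rng[1] == rng[2])
      stop("degenerate criterion '", dm$criteria[j],
           "': all alternatives share the value ", rng[1], call. = FALSE)
    x[, j] <- if (dm$directions[j] == "benefit")
      (m[, j] - rng[1]) / (rng[2] - rng[1])
    else
      (rng[2] - m[, j]) / (rng[2] - rng[1])
  }
  structure(list(x = x, means = colMeans(x), u = rowSums(x),
                 directions = dm$directions,
                 alternatives = dm$alternatives, criteria = dm$criteria),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("Normalized matrix (closeness to ideal), with row totals u:\n")
  print(round(cbind(x$x, u = x$u), 3))
  invisible(x)
}

as_norm <- function(nm) {
  if (inherits(nm, "normalized_matrix")) return(nm)
  if (is.matrix(nm) && is.numeric(nm))
    return(structure(list(x = nm, means = colMeans(nm), u = rowSums(nm),
                          alternatives = rownames(nm) %||%
                            paste0("A", seq_len(nrow(nm))),
                          criteria = colnames(nm) %||%
                            paste0("C", seq_len(ncol(nm)))),
                     class = "normalized_matrix"))
  stop("expected a normalized_matrix or a numeric matrix", call. = FALSE)
}

#' Positional weights of the greenhouse-tomato study
#'
#' The published rank-position weight vector elicited for twelve
#' alternatives: (0.200, 0.180, 0.170, 0.150, 0.130, 0.100, 0.020, then
#' 0.010 for the last five positions). There is no principled way to
#' interpolate an elicited vector to other sizes, so any other `n` is an
#' error and the user must supply weights.
#'
#' @param n Number of alternatives (ranks).
#' @return Numeric vector of length 12.
#' @export
default_positional_weights <- function(n) {
  if (n != 12L)
    stop("no default positional weights for n = ", n,
         "; the packaged vector is defined for 12 alternatives only - ",
         "supply positional_weights explicitly", call. = FALSE)
  c(0.200, 0.180, 0.170, 0.150, 0.130, 0.100, 0.020,
    0.010, 0.010, 0.010, 0.010, 0.010)
}

#' Aggregation settings for the IPOWA-CRITIC pipeline
#'
#' Bundles everything the pipeline needs beyond the decision matrix:
#'
#' * `delta` — share of the positional (OWA) component in the blended
#'   weights; default 0.6 (60% attitude, 40% probability), the setting of
#'   the packaged case study.
#' * `positional_weights` — OWA weights over alternative ranks; default is
#'   the published 12-alternative vector via
#'   [default_positional_weights()].
#' * `probabilities` / `confidences` — per-alternative probability of
#'   commercial implementation; explicit probabilities take precedence,
#'   otherwise confidences are normalized by their sum.
#' * `moment` — a [moment_spec()] controlling means and ordering inside the
#'   correlation operators.
#' * `sd_ordering` — ordering for the dispersion step: `"magnitude"`
#'   (squared deviations sorted by size, the literal definition) or
#'   `"induced"` (ordered by the row totals `u` and delta-blended with the
#'   probabilities).
#' * `zero_variance` — `"error"` or `"zero"`; see [pearson_owa()].
#' * `renormalize` — accept weight/probability vectors that only sum to one
#'   after rounding.
#'
#' @param delta Blend coefficient in `[0, 1]`.
#' @param positional_weights Numeric vector over ranks, or `NULL` for the
#'   12-alternative default.
#' @param probabilities,confidences Per-alternative vectors (see above).
#' @param moment A [moment_spec()].
#' @param sd_ordering `"magnitude"` or `"induced"`.
#' @param zero_variance `"error"` or `"zero"`.
#' @param renormalize Logical.
#' @return An object of class `"aggregation_spec"`.
#' @export
aggregation_spec <- function(delta = 0.6, positional_weights = NULL,
                             probabilities = NULL, confidences = NULL,
                             moment = moment_spec(),
                             sd_ordering = c("magnitude", "induced"),
                             zero_variance = c("error", "zero"),
                             renormalize = FALSE) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta < 0 || delta > 1)
    stop("delta must be a single number in [0, 1]", call. = FALSE)
  stopifnot(inherits(moment, "moment_spec"))
  structure(list(delta = delta,
                 positional_weights = positional_weights,
                 probabilities = probabilities,
                 confidences = confidences,
                 moment = moment,
                 sd_ordering = match.arg(sd_ordering),
                 zero_variance = match.arg(zero_variance),
                 renormalize = renormalize),
            class = "aggregation_spec")
}

# Resolve the per-alternative probability vector: explicit probabilities
# beat confidence-derived ones (c_i / sum c_i).
resolve_probabilities <- function(spec, n) {
  if (!is.null(spec$probabilities))
    return(validate_weights(spec$probabilities, n, "probabilities",
                            spec$renormalize))
  if (!is.null(spec$confidences)) {
    ci <- spec$confidences
    if (!is.numeric(ci) || length(ci) != n || anyNA(ci) || any(ci < 0) ||
        any(ci > 1) || sum(ci) <= 0)
      stop("confidences must be ", n, " values in [0, 1] with a positive sum",
           call. = FALSE)
    return(ci / sum(ci))
  }
  stop("aggregation_spec carries neither probabilities nor confidences",
       call. = FALSE)
}

resolve_positional <- function(spec, n) {
  w <- spec$positional_weights %||% default_positional_weights(n)
  validate_weights(w, n, "positional weights", spec$renormalize)
}

#' Per-criterion OWA dispersion
#'
#' The OWA standard deviation of every normalized criterion column, the
#' contrast-intensity half of the CRITIC weight. With `"magnitude"`
#' ordering (default) this is [sd_owa()] per column; with `"induced"`
#' ordering the squared deviations are ordered by the row totals `u` and
#' the positional weights are delta-blended with the alternative
#' probabilities.
#'
#' @param nm A [normalize_matrix()] result (or a numeric matrix already in
#'   `[0, 1]`).
#' @param spec An [aggregation_spec()].
#' @return Named numeric vector, one standard deviation per criterion.
#' @export
dispersion_vector <- function(nm, spec = aggregation_spec()) {
  nm <- as_norm(nm)
  n <- nrow(nm$x)
  w <- resolve_positional(spec, n)
  out <- vapply(seq_len(ncol(nm$x)), function(j) {
    col <- nm$x[, j]
    mu <- if (spec$moment$mean_mode == "owa") powa_sum(col, w) else mean(col)
    d2 <- (col - mu)^2
    if (spec$sd_ordering == "induced") {
      v <- resolve_probabilities(spec, n)
      sqrt(powa_sum(d2, w, v, spec$delta, order_by = nm$u))
    } else {
      sqrt(powa_sum(d2, w))
    }
  }, numeric(1))
  names(out) <- nm$criteria
  out
}

#' Induced probabilistic conflict matrix
#'
#' Criterion-by-criterion [pearson_ipowa()] correlations of the normalized
#' columns, induced by the alternatives' row totals `u`, with the
#' per-alternative probabilities blended at `delta`. Low correlation means
#' high conflict and hence more information carried by the criterion pair.
#' The matrix is symmetric with unit diagonal.
#'
#' @inheritParams dispersion_vector
#' @return `|J| x |J|` numeric matrix.
#' @export
conflict_matrix <- function(nm, spec = aggregation_spec()) {
  nm <- as_norm(nm)
  n <- nrow(nm$x); p <- ncol(nm$x)
  w <- resolve_positional(spec, n)
  v <- resolve_probabilities(spec, n)
  r <- diag(1, p)
  dimnames(r) <- list(nm$criteria, nm$criteria)
  for (j in seq_len(p - 1L)) {
    for (k in seq((j + 1L), p)) {
      r[j, k] <- r[k, j] <- pearson_ipowa(
        nm$x[, j], nm$x[, k], u = nm$u, w = w, v = v, delta = spec$delta,
        spec = spec$moment, zero_variance = spec$zero_variance)
    }
  }
  r
}

#' Information content of each criterion
#'
#' The CRITIC information measure: dispersion times total conflict,
#' `C_j = sd_j * sum_k (1 - r_jk)`. More dispersed and less correlated
#' criteria transmit more information and earn larger weights.
#'
#' @param sd Per-criterion dispersion vector.
#' @param conflict Criterion correlation matrix.
#' @return Named numeric vector.
#' @export
information_content <- function(sd, conflict) {
  conflict <- as.matrix(conflict)
  if (length(sd) != nrow(conflict) || nrow(conflict) != ncol(conflict))
    stop("dispersion length and conflict matrix dimensions disagree",
         call. = FALSE)
  out <- sd * rowSums(1 - conflict)
  names(out) <- names(sd) %||% rownames(conflict)
  out
}

#' Criterion weights from information content
#'
#' Normalizes the information-content vector to sum to one.
#'
#' @param info Non-negative vector with a positive sum.
#' @return Weight vector proportional to `info`.
#' @export
criterion_weights <- function(info) {
  if (!is.numeric(info) || anyNA(info) || any(info < 0))
    stop("information content must be non-negative", call. = FALSE)
  s <- sum(info)
  if (s <= 0)
    stop("degenerate weights: total information content is zero",
         call. = FALSE)
  info / s
}

#' Multicriteria scores of the IPOWA-CRITIC family
#'
#' Four scoring rules combine the normalized row of each alternative with
#' the criterion weights:
#'
#' * `score_ipowa_critic()` — plain weighted sum, weights and scores in
#'   criterion order.
#' * `score_s()` — the row scores are sorted descending before meeting the
#'   weights in their original criterion order.
#' * `score_w()` — the weights are sorted descending before meeting the
#'   row scores in their original criterion order.
#' * `score_sw()` — both sorted descending and paired rank-to-rank; by the
#'   rearrangement inequality this is the largest of all pairings, so it
#'   dominates the plain weighted sum row-wise.
#'
#' All four return values in `[0, 1]` for a normalized matrix.
#'
#' @param nm A [normalize_matrix()] result or numeric matrix.
#' @param w Criterion weight vector (non-negative, sum one).
#' @return Named numeric vector of scores, one per alternative.
#' @export
score_ipowa_critic <- function(nm, w) {
  nm <- as_norm(nm)
  w <- validate_weights(w, ncol(nm$x), "criterion weights")
  stats::setNames(as.vector(nm$x %*% w), nm$alternatives)
}

#' @rdname score_ipowa_critic
#' @export
score_s <- function(nm, w) {
  nm <- as_norm(nm)
  w <- validate_weights(w, ncol(nm$x), "criterion weights")
  stats::setNames(apply(nm$x, 1, function(r) sum(w * r[desc_order(r)])),
                  nm$alternatives)
}

#' @rdname score_ipowa_critic
#' @export
score_w <- function(nm, w) {
  nm <- as_norm(nm)
  w <- validate_weights(w, ncol(nm$x), "criterion weights")
  psi <- w[desc_order(w)]
  stats::setNames(as.vector(nm$x %*% psi), nm$alternatives)
}

#' @rdname score_ipowa_critic
#' @export
score_sw <- function(nm, w) {
  nm <- as_norm(nm)
  w <- validate_weights(w, ncol(nm$x), "criterion weights")
  psi <- w[desc_order(w)]
  stats::setNames(apply(nm$x, 1, function(r) sum(psi * r[desc_order(r)])),
                  nm$alternatives)
}

#' Rank alternatives by descending score
#'
#' Rank 1 is the best (highest) score; ties are broken by original
#' alternative order, so every rank vector is a permutation of `1..n`.
#'
#' @param scores Numeric vector.
#' @return Integer vector of ranks.
#' @export
#' @examples
#' rank_alternatives(c(1, 3, 2))  # 3 1 2
rank_alternatives <- function(scores) {
  if (!is.numeric(scores) || length(scores) < 1L || anyNA(scores))
    stop("scores must be a non-empty numeric vector", call. = FALSE)
  o <- desc_order(scores)
  r <- integer(length(scores))
  r[o] <- seq_along(scores)
  names(r) <- names(scores)
  r
}

#' Run the full IPOWA-CRITIC pipeline
#'
#' Executes, in order: min-max normalization, per-criterion OWA dispersion,
#' the induced probabilistic conflict matrix, information content, criterion
#' weights, the four multicriteria scores and their rankings. Supplying
#' `weights` skips the weight derivation and scores with the given vector
#' instead (e.g. to reproduce a published analysis whose weight table is
#' known); the derived dispersion/conflict tables are still reported.
#'
#' @param dm A [decision_matrix()].
#' @param spec An [aggregation_spec()].
#' @param weights Optional criterion weight override.
#' @param methods Which scoring rules to run, a subset of
#'   `c("ipowa_critic", "s", "w", "sw")`.
#' @return An object of class `"critic_report"`: a list with elements
#'   `normalized`, `dispersion`, `conflict`, `information`, `weights`,
#'   `weights_source` (`"derived"` or `"supplied"`), `scores`
#'   (alternatives x methods matrix), `ranks` (same shape, integer), and
#'   `spec`.
#' @export
run_pipeline <- function(dm, spec = aggregation_spec(), weights = NULL,
                         methods = c("ipowa_critic", "s", "w", "sw")) {
  stopifnot(inherits(dm, "decision_matrix"))
  methods <- match.arg(methods, several.ok = TRUE)
  step <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline step '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  nm <- step("normalize", normalize_matrix(dm))
  sd <- step("dispersion", dispersion_vector(nm, spec))
  conf <- step("conflict", conflict_matrix(nm, spec))
  info <- step("information", information_content(sd, conf))
  w_derived <- step("weights", criterion_weights(info))
  if (is.null(weights)) {
    w <- w_derived
    weights_source <- "derived"
  } else {
    w <- stats::setNames(
      validate_weights(weights, ncol(nm$x), "criterion weights",
                       spec$renormalize),
      nm$criteria)
    weights_source <- "supplied"
  }
  scorers <- list(ipowa_critic = score_ipowa_critic, s = score_s,
                  w = score_w, sw = score_sw)
  scores <- step("scores",
                 vapply(methods, function(m) scorers[[m]](nm, w),
                        numeric(nrow(nm$x))))
  if (length(methods) == 1L) scores <- matrix(scores, ncol = 1L)
  dimnames(scores) <- list(nm$alternatives, methods)
  ranks <- apply(scores, 2, rank_alternatives)
  dimnames(ranks) <- dimnames(scores)
  structure(list(normalized = nm, dispersion = sd, conflict = conf,
                 information = info, weights = w,
                 weights_source = weights_source,
                 scores = scores, ranks = ranks, spec = spec),
            class = "critic_report")
}

#' @export
print.critic_report <- function(x, ...) {
  cat("IPOWA-CRITIC report (delta =", x$spec$delta, ")\n\n")
  cat("Criterion weights (", x$weights_source, "):\n", sep = "")
  print(round(x$weights, 3))
  cat("\nScores:\n")
  print(round(x$scores, 3))
  cat("\nRanks (1 = best):\n")
  print(x$ranks)
  invisible(x)
}
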