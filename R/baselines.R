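# Reference MCDM methods and rank-agreement statistics used to benchmark
# the IPOWA-CRITIC family: classic CRITIC weights, SAW, TOPSIS, VIKOR, and
# Spearman rank correlation.

#' Classic CRITIC criterion weights
#'
#' The original objective weighting: `w_j` proportional to
#' `sigma_j * sum_k (1 - r_jk)` with the plain population standard
#' deviation and the plain Pearson correlation of the normalized columns.
#' This is the uniform-weight, delta = 1, plain-mean reduction of the
#' IPOWA pipeline.
#'
#' @param nm A [normalize_matrix()] result or numeric matrix.
#' @return Criterion weight vector summing to one.
#' @export
critic_classic <- function(nm) {
  nm <- as_norm(nm)
  x <- nm$x
  n <- nrow(x)
  sds <- apply(x, 2, function(col) {
    s2 <- sum((col - mean(col))^2) / n
    if (s2 <= 0)
      stop("degenerate criterion: zero variance", call. = FALSE)
    sqrt(s2)
  })
  r <- stats::cor(x)
  criterion_weights(sds * rowSums(1 - r))
}

#' Simple additive weighting (SAW)
#'
#' Weighted sum of each alternative's normalized scores — the same formula
#' as [score_ipowa_critic()] with externally supplied weights.
#'
#' @inheritParams critic_classic
#' @param w Criterion weights.
#' @return Named score vector, higher is better.
#' @export
saw <- function(nm, w) score_ipowa_critic(nm, w)

#' TOPSIS closeness coefficient
#'
#' Euclidean closeness of each weighted normalized row to the ideal point.
#' Because the matrix is already min-max normalized, the ideal and
#' anti-ideal are the weighted all-ones and all-zeros vectors; the
#' closeness is `d- / (d+ + d-)`, in `[0, 1]`, higher is better.
#'
#' @inheritParams saw
#' @return Named closeness vector.
#' @export
topsis <- function(nm, w) {
  nm <- as_norm(nm)
  w <- validate_weights(w, ncol(nm$x), "criterion weights")
  v <- sweep(nm$x, 2, w, "*")
  dplus <- sqrt(rowSums(sweep(v, 2, w, function(a, b) (a - b)^2)))
  dminus <- sqrt(rowSums(v^2))
  if (any(dplus + dminus == 0))
    stop("degenerate alternative equidistant at zero from both ideals",
         call. = FALSE)
  stats::setNames(dminus / (dplus + dminus), nm$alternatives)
}

#' VIKOR compromise index
#'
#' Group utility `S_i = sum_j w_j (1 - x_ij)` (Manhattan distance to the
#' ideal), individual regret `R_i = max_j w_j (1 - x_ij)` (Chebyshev), and
#' the compromise `Q_i = v (S_i - S*) / (S- - S*) +
#' (1 - v)(R_i - R*) / (R- - R*)`, where `*`/`-` mark the best/worst
#' values. Lower `Q` is better; `v` is the weight of the group-utility
#' term (default 0.9, the benchmark setting). If `S` or `R` is constant
#' across alternatives its term is dropped and the other term takes full
#' weight.
#'
#' @inheritParams saw
#' @param v Group-utility coefficient in `[0, 1]`.
#' @return Named `Q` vector (lower is better) with the `S` and `R` vectors
#'   attached as attributes.
#' @export
vikor <- function(nm, w, v = 0.9) {
  nm <- as_norm(nm)
  w <- validate_weights(w, ncol(nm$x), "criterion weights")
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
    stop("v must be a single number in [0, 1]", call. = FALSE)
  g <- sweep(1 - nm$x, 2, w, "*")
  S <- rowSums(g)
  R <- apply(g, 1, max)
  term <- function(z) {
    rng <- range(z)
    if (rng[1] == rng[2]) NULL else (z - rng[1]) / (rng[2] - rng[1])
  }
  tS <- term(S); tR <- term(R)
  Q <- if (is.null(tS) && is.null(tR)) rep(0, length(S))
  else if (is.null(tS)) tR
  else if (is.null(tR)) tS
  else v * tS + (1 - v) * tR
  structure(stats::setNames(Q, nm$alternatives), S = S, R = R)
}

#' Spearman rank correlation of two rankings
#'
#' `r_s = 1 - 6 sum(d^2) / (n (n^2 - 1))` for two permutations of `1..n`
#' (distinct integer ranks, as produced by [rank_alternatives()]).
#'
#' @param r1,r2 Integer rank vectors of equal length.
#' @param strict Require both inputs to be permutations of `1..n`.
#' @return Scalar in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rank(1:4, 4:1)  # -1
spearman_rank <- function(r1, r2, strict = TRUE) {
  if (length(r1) != length(r2))
    stop("rankings must have equal length", call. = FALSE)
  n <- length(r1)
  if (n < 2L) stop("rankings need at least 2 elements", call. = FALSE)
  if (strict &&
      (!setequal(r1, seq_len(n)) || !setequal(r2, seq_len(n))))
    stop("rankings must be permutations of 1..n", call. = FALSE)
  1 - 6 * sum((r1 - r2)^2) / (n * (n^2 - 1))
}

#' Compare MCDM methods on one decision matrix
#'
#' Runs the IPOWA-CRITIC family (via [run_pipeline()]) alongside classic
#' CRITIC, SAW, TOPSIS and VIKOR, and reports every method's scores, ranks,
#' and the pairwise Spearman rank agreement. VIKOR's `Q` is stored as
#' `1 - Q` so that higher-is-better holds across all columns.
#'
#' @param dm A [decision_matrix()].
#' @param spec An [aggregation_spec()].
#' @param weights Weight vector for SAW/TOPSIS/VIKOR (and the IPOWA family
#'   when `inject = TRUE`); default: the classic CRITIC weights.
#' @param vikor_v VIKOR group-utility coefficient.
#' @param inject Use `weights` for the IPOWA scoring rules too instead of
#'   the pipeline-derived weights.
#' @return A list with `scores`, `ranks` (alternatives x methods matrices)
#'   and `spearman` (methods x methods matrix).
#' @export
compare_methods <- function(dm, spec = aggregation_spec(), weights = NULL,
                            vikor_v = 0.9, inject = FALSE) {
  rep_ <- run_pipeline(dm, spec, weights = if (inject) weights else NULL)
  nm <- rep_$normalized
  w_base <- if (is.null(weights)) critic_classic(nm)
  else validate_weights(weights, ncol(nm$x), "criterion weights",
                        spec$renormalize)
  scores <- cbind(
    critic = saw(nm, critic_classic(nm)),
    saw = saw(nm, w_base),
    topsis = topsis(nm, w_base),
    vikor = 1 - as.vector(vikor(nm, w_base, vikor_v)),
    rep_$scores
  )
  ranks <- apply(scores, 2, rank_alternatives)
  dimnames(ranks) <- dimnames(scores)
  p <- ncol(ranks)
  sp <- diag(1, p)
  dimnames(sp) <- list(colnames(ranks), colnames(ranks))
  for (i in seq_len(p - 1L))
    for (j in seq((i + 1L), p))
      sp[i, j] <- sp[j, i] <- spearman_rank(ranks[, i], ranks[, j])
  list(scores = scores, ranks = ranks, spearman = sp)
}
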