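# Independent brute-force oracles. These re-derive every aggregation from
# first principles with explicit sort()/loop mechanics, deliberately not
# sharing code with the package internals they check.

oracle_owa <- function(a, w) sum(w * sort(a, decreasing = TRUE))

oracle_powa <- function(a, w, v, delta) {
  o <- order(a, decreasing = TRUE)
  sum((delta * w + (1 - delta) * v[o]) * a[o])
}

oracle_iowa <- function(a, u, w) sum(w * a[order(u, decreasing = TRUE)])

oracle_ipowa <- function(a, u, w, v, delta) {
  o <- order(u, decreasing = TRUE)
  sum((delta * w + (1 - delta) * v[o]) * a[o])
}

# Literal weighted-correlation ratio with one shared coupling order for the
# cross-product and both squared-deviation sums.
oracle_pearson <- function(a, b, w, v = NULL, delta = 1, u = NULL,
                           owa_means = FALSE) {
  mua <- if (owa_means) oracle_owa(a, w) else mean(a)
  mub <- if (owa_means) oracle_owa(b, w) else mean(b)
  d <- (a - mua) * (b - mub)
  k <- (a - mua)^2
  h <- (b - mub)^2
  o <- order(if (is.null(u)) d else u, decreasing = TRUE)
  vh <- if (is.null(v)) w else delta * w + (1 - delta) * v[o]
  sum(vh * d[o]) / sqrt(sum(vh * k[o]) * sum(vh * h[o]))
}

# Classic CRITIC weights straight from the defining formula (population SD
# times total conflict, normalized).
oracle_critic <- function(x) {
  n <- nrow(x)
  sds <- apply(x, 2, function(col) sqrt(mean((col - mean(col))^2)))
  cj <- sds * rowSums(1 - stats::cor(x))
  cj / sum(cj)
}

# All permutations of 1..n (n small).
perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

rand_weights <- function(n) {
  w <- stats::runif(n)
  w / sum(w)
}

# Random decision problem small enough for exhaustive checking.
rand_problem <- function(n = 6, p = 4) {
  vals <- matrix(stats::runif(n * p, 0, 100), n, p)
  decision_matrix(vals, sample(c("benefit", "cost"), p, replace = TRUE))
}

# Published tables of the greenhouse-tomato case study, used as expected
# values (normalized matrix with row sums and column means; criterion
# weights; multicriteria scores; ranks).
tomato_published <- function() {
  norm <- matrix(c(
    1.000, 1.000, 0.000, 0.000, 1.000, 1.000, 0.605,
    0.867, 0.881, 1.000, 0.025, 0.867, 0.973, 0.471,
    0.644, 0.686, 0.018, 0.032, 0.644, 0.706, 0.276,
    0.605, 0.672, 0.974, 0.044, 0.605, 0.951, 0.302,
    0.118, 0.020, 0.010, 0.198, 0.118, 0.552, 1.000,
    0.133, 0.066, 0.963, 0.179, 0.133, 0.415, 0.644,
    0.202, 0.195, 0.015, 0.139, 0.202, 0.538, 0.460,
    0.000, 0.000, 0.991, 0.174, 0.000, 0.762, 0.197,
    0.305, 0.524, 0.031, 0.942, 0.539, 0.271, 0.732,
    0.138, 0.108, 0.967, 1.000, 0.372, 0.000, 0.596,
    0.403, 0.456, 0.057, 0.897, 0.637, 0.312, 0.473,
    0.275, 0.343, 0.985, 0.926, 0.509, 0.484, 0.000),
    nrow = 12, byrow = TRUE,
    dimnames = list(paste0("A", 1:12), paste0("BI", 1:7)))
  scores <- matrix(c(
    0.442, 0.789, 0.415, 0.796,
    0.632, 0.789, 0.668, 0.828,
    0.294, 0.515, 0.284, 0.534,
    0.546, 0.619, 0.588, 0.724,
    0.261, 0.248, 0.210, 0.455,
    0.429, 0.350, 0.449, 0.515,
    0.208, 0.237, 0.186, 0.334,
    0.389, 0.271, 0.435, 0.495,
    0.501, 0.509, 0.457, 0.608,
    0.627, 0.481, 0.639, 0.638,
    0.478, 0.472, 0.449, 0.572,
    0.635, 0.513, 0.681, 0.659),
    nrow = 12, byrow = TRUE,
    dimnames = list(paste0("A", 1:12),
                    c("ipowa_critic", "s", "w", "sw")))
  ranks <- matrix(c(
    7, 2, 9, 2,
    2, 1, 2, 1,
    10, 4, 10, 8,
    4, 3, 4, 3,
    11, 11, 11, 11,
    8, 9, 6, 9,
    12, 12, 12, 12,
    9, 10, 8, 10,
    5, 6, 5, 6,
    3, 7, 3, 5,
    6, 8, 7, 7,
    1, 5, 1, 4),
    nrow = 12, byrow = TRUE,
    dimnames = dimnames(scores))
  list(
    normalized = norm,
    row_sums = c(4.605, 5.083, 3.007, 4.153, 2.018, 2.532, 1.750, 2.125,
                 3.345, 3.181, 3.236, 3.522),
    col_means = c(0.391, 0.413, 0.501, 0.380, 0.469, 0.580, 0.480),
    weights = c(0.089, 0.090, 0.236, 0.274, 0.079, 0.110, 0.122),
    scores = scores,
    ranks = ranks,
    spearman_pct = c(s = 64, w = 97, sw = 83))
}
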