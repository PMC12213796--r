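# Normalization, conflict weighting, scoring rules, and the full pipeline.

tomato_spec <- function() {
  tom <- tomato_example()
  list(dm = tom$matrix, spec = tom$config$spec,
       wj = tom$raw_config$criterion_weights)
}

test_that("decision_matrix validates its inputs", {
  m <- matrix(1:6, 2, 3)
  expect_error(decision_matrix(m, c("benefit", "up", "cost")), "direction")
  expect_error(decision_matrix(m, c("benefit", "cost")), "one direction")
  expect_error(decision_matrix(matrix(1:2, 2, 1),
                               "benefit"), "at least 2")
  expect_error(decision_matrix(matrix(c(1, NA, 3, 4), 2), c("benefit", "cost")),
               "missing")
})

test_that("normalization maps benefit and cost criteria onto [0, 1]", {
  dm <- decision_matrix(cbind(c(1, 2, 3), c(10, 40, 20)),
                        c("benefit", "cost"))
  nm <- normalize_matrix(dm)
  expect_equal(unname(nm$x[, 1]), c(0, 0.5, 1))
  expect_equal(unname(nm$x[, 2]), c(1, 0, 2 / 3))
  expect_equal(nm$u, rowSums(nm$x))
  expect_equal(nm$means, colMeans(nm$x))
  # every column attains both endpoints
  expect_equal(unname(apply(nm$x, 2, range)), matrix(c(0, 1, 0, 1), 2))
  dm2 <- decision_matrix(cbind(c(1, 1, 1), c(1, 2, 3)),
                         c("benefit", "benefit"),
                         criteria = c("flat", "ok"))
  expect_error(normalize_matrix(dm2), "flat")
})

test_that("case-study normalization reproduces published spot cells", {
  ts <- tomato_spec()
  nm <- normalize_matrix(ts$dm)
  # production of the best photovoltaic full-irrigation strategy
  expect_equal(round(nm$x["A9", "BI1"], 3), 0.305)
  # the lowest water consumer gets the ideal cost score
  expect_equal(nm$x["A2", "BI3"], 1)
  expect_equal(nm$x["A1", "BI3"], 0)
  expect_equal(round(nm$u[["A1"]], 3), 4.605)
})

test_that("dispersion_vector generalizes the per-column SD", {
  x <- matrix(c(0, 1, 5, 2, 2, 8) / 10, nrow = 3)
  sp_unif <- aggregation_spec(positional_weights = rep(1 / 3, 3),
                              probabilities = rep(1 / 3, 3))
  expect_equal(unname(dispersion_vector(x, sp_unif)),
               apply(x, 2, function(col) sqrt(mean((col - mean(col))^2))),
               tolerance = 1e-12)
  sp_max <- aggregation_spec(positional_weights = c(1, 0, 0),
                             probabilities = rep(1 / 3, 3))
  expect_equal(unname(dispersion_vector(x, sp_max)),
               apply(x, 2, function(col) max(abs(col - mean(col)))),
               tolerance = 1e-12)
  # induced ordering blends probabilities and generally differs
  sp_ind <- aggregation_spec(positional_weights = c(1, 0, 0),
                             probabilities = c(0.8, 0.1, 0.1),
                             sd_ordering = "induced", delta = 0.5)
  expect_true(all(dispersion_vector(x, sp_ind) >= 0))
})

test_that("conflict_matrix is a correlation matrix that reduces to cor()", {
  set.seed(21)
  syn <- generate_synthetic(6, 4, seed = 31)
  nm <- normalize_matrix(syn$matrix)
  red <- aggregation_spec(delta = 1, positional_weights = rep(1 / 6, 6),
                          probabilities = rep(1 / 6, 6))
  expect_equal(conflict_matrix(nm, red), stats::cor(nm$x),
               tolerance = 1e-12, ignore_attr = TRUE)
  # general configuration: symmetric, unit diagonal, entries in [-1, 1]
  gen <- aggregation_spec(delta = 0.6,
                          positional_weights = rand_weights(6),
                          confidences = stats::runif(6, 0.1, 1))
  cm <- conflict_matrix(nm, gen)
  expect_equal(cm, t(cm), tolerance = 1e-9)
  expect_equal(unname(diag(cm)), rep(1, 4))
  expect_true(all(abs(cm) <= 1 + 1e-12))
  # duplicated criterion columns are in full agreement
  x2 <- cbind(nm$x, dup = nm$x[, 1])
  cm2 <- conflict_matrix(x2, gen)
  expect_equal(cm2[1, 5], 1, tolerance = 1e-12)
})

test_that("information content and criterion weights follow the
           dispersion-times-conflict rule", {
  conflict <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(unname(information_content(c(0.5, 0), conflict)), c(0.25, 0))
  expect_error(information_content(c(1, 2, 3), conflict), "disagree")
  expect_equal(unname(criterion_weights(c(1, 1))), c(0.5, 0.5))
  expect_equal(unname(criterion_weights(c(2, 1, 1))), c(0.5, 0.25, 0.25))
  expect_error(criterion_weights(c(0, 0)), "degenerate")
  # published case-study magnitudes: sd x total conflict, then normalize
  expect_equal(unname(information_content(
    stats::setNames(0.317, "j"), matrix(1 - 3.846, 1, 1))), 0.317 * 3.846)
  wj <- criterion_weights(c(1.217, 1.226, 3.223, 3.734, 1.082, 1.494, 1.662))
  expect_equal(round(unname(wj), 3),
               c(0.089, 0.090, 0.236, 0.274, 0.079, 0.110, 0.122))
})

test_that("the four scoring rules implement their sorting conventions", {
  x <- matrix(c(0.2, 0.9, 0.8, 0.1, 0.5, 0.7), nrow = 2, byrow = TRUE)
  w <- c(0.5, 0.2, 0.3)
  expect_equal(unname(score_ipowa_critic(x, w)),
               c(0.2 * 0.5 + 0.9 * 0.2 + 0.8 * 0.3,
                 0.1 * 0.5 + 0.5 * 0.2 + 0.7 * 0.3))
  expect_equal(unname(score_s(x, w)),
               c(sum(w * c(0.9, 0.8, 0.2)), sum(w * c(0.7, 0.5, 0.1))))
  expect_equal(unname(score_w(x, w)),
               c(sum(c(0.5, 0.3, 0.2) * c(0.2, 0.9, 0.8)),
                 sum(c(0.5, 0.3, 0.2) * c(0.1, 0.5, 0.7))))
  expect_equal(unname(score_sw(x, w)),
               c(sum(c(0.5, 0.3, 0.2) * c(0.9, 0.8, 0.2)),
                 sum(c(0.5, 0.3, 0.2) * c(0.7, 0.5, 0.1))))
  # idempotency on a constant row; uniform weights give row means
  cst <- matrix(0.4, 1, 3)
  for (f in list(score_ipowa_critic, score_s, score_w, score_sw))
    expect_equal(unname(f(rbind(cst, cst), w)), c(0.4, 0.4))
  expect_equal(unname(score_s(x, rep(1 / 3, 3))), rowMeans(x))
  # equal weights make all four rules coincide with the plain weighted sum
  expect_equal(score_w(x, rep(1 / 3, 3)), score_ipowa_critic(x, rep(1 / 3, 3)))
})

test_that("case-study scores with the published weight vector match the
           published table spots", {
  ts <- tomato_spec()
  nm <- normalize_matrix(ts$dm)
  d <- score_ipowa_critic(nm, ts$wj)
  expect_equal(d[["A1"]], 0.442, tolerance = 0.001)
  expect_equal(d[["A12"]], 0.635, tolerance = 0.001)
  sw <- score_sw(nm, ts$wj)
  expect_equal(sw[["A2"]], 0.828, tolerance = 0.001)
  expect_equal(sw[["A5"]], 0.455, tolerance = 0.001)
  # literal sort-convention values for the S and W rules
  expect_equal(score_s(nm, ts$wj)[["A1"]], 0.737, tolerance = 0.001)
  expect_equal(score_w(nm, ts$wj)[["A1"]], 0.737, tolerance = 0.001)
})

test_that("rank_alternatives ranks descending with stable ties", {
  expect_equal(unname(rank_alternatives(c(1, 3, 2))), c(3, 1, 2))
  expect_equal(unname(rank_alternatives(c(0.5, 0.5))), c(1, 2))
  set.seed(22)
  s <- stats::runif(9)
  expect_true(setequal(rank_alternatives(s), 1:9))
  expect_equal(which(rank_alternatives(s) == 1), which.max(s))
})

test_that("run_pipeline: symmetric criteria get equal weight and all
           invariants hold", {
  dm <- decision_matrix(matrix(c(1, 0, 0, 1), 2),
                        c("benefit", "benefit"))
  sp <- aggregation_spec(positional_weights = c(0.5, 0.5),
                         probabilities = c(0.5, 0.5))
  rep_ <- run_pipeline(dm, sp)
  expect_equal(unname(rep_$weights), c(0.5, 0.5))
  set.seed(23)
  for (i in 1:5) {
    dm <- rand_problem(6, 4)
    sp <- aggregation_spec(delta = 0.6,
                           positional_weights = rand_weights(6),
                           confidences = stats::runif(6, 0.1, 1))
    rep_ <- run_pipeline(dm, sp)
    expect_equal(sum(rep_$weights), 1, tolerance = 1e-12)
    expect_true(all(rep_$scores >= -1e-12 & rep_$scores <= 1 + 1e-12))
    # rearrangement inequality: jointly sorted pairing dominates
    expect_true(all(rep_$scores[, "sw"] >=
                      rep_$scores[, "ipowa_critic"] - 1e-12))
    for (m in colnames(rep_$ranks))
      expect_true(setequal(rep_$ranks[, m], 1:6))
    # scale invariance: positive affine rescaling of a raw column changes
    # nothing downstream
    dm2 <- dm
    dm2$values[, 2] <- dm2$values[, 2] * 3.7 + 11
    rep2 <- run_pipeline(dm2, sp)
    expect_equal(rep2$normalized$x, rep_$normalized$x, tolerance = 1e-9)
    expect_equal(rep2$weights, rep_$weights, tolerance = 1e-9)
    expect_equal(rep2$scores, rep_$scores, tolerance = 1e-9)
    expect_equal(rep2$ranks, rep_$ranks)
  }
})

test_that("pipeline errors name the failing step and weight injection is
           reported", {
  dm <- decision_matrix(cbind(c(1, 1, 1), c(1, 2, 3)),
                        c("benefit", "benefit"))
  sp <- aggregation_spec(positional_weights = rep(1 / 3, 3),
                         probabilities = rep(1 / 3, 3))
  expect_error(run_pipeline(dm, sp), "normalize")
  ts <- tomato_spec()
  rep_ <- run_pipeline(ts$dm, ts$spec, weights = ts$wj)
  expect_identical(rep_$weights_source, "supplied")
  expect_equal(unname(rep_$weights), ts$wj)
})
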