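# File formats, configuration, the packaged case-study fixture, and the
# synthetic decision-matrix generator.
#
# Matrix file layout (CSV or TSV by extension): header row = "alternative"
# then criterion ids; first data row = "direction" then benefit/cost per
# criterion; remaining rows = alternative id then plain numeric values
# (decimal point ".", no thousands separators).

guess_sep <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a decision matrix from CSV/TSV
#'
#' See the layout described above; the direction row is required unless
#' `directions` is supplied. Malformed cells are reported with their
#' row/column coordinates.
#'
#' @param path File path; `.tsv` selects tab separation, anything else
#'   comma.
#' @param directions Optional per-criterion `"benefit"`/`"cost"` vector
#'   overriding (or replacing) the file's direction row.
#' @return A [decision_matrix()].
#' @export
read_matrix <- function(path, directions = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, sep = guess_sep(path), header = TRUE,
                         check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 3L)
    stop("matrix file needs an id column and at least 2 criteria",
         call. = FALSE)
  ids <- raw[[1]]
  body <- raw[, -1, drop = FALSE]
  has_dir_row <- nrow(raw) > 0 &&
    all(tolower(unlist(body[1, ])) %in% c("benefit", "cost"))
  if (has_dir_row) {
    file_dirs <- tolower(unlist(body[1, ]))
    body <- body[-1, , drop = FALSE]
    ids <- ids[-1]
  } else {
    file_dirs <- NULL
  }
  directions <- directions %||% file_dirs
  if (is.null(directions))
    stop("no direction row in ", path,
         " and no directions supplied", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate alternative ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  vals <- matrix(NA_real_, nrow(body), ncol(body))
  for (j in seq_len(ncol(body))) {
    parsed <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(parsed) | !nzchar(trimws(body[[j]])))
    if (length(bad))
      stop("non-numeric or missing cell at row '", ids[bad[1]],
           "', column '", colnames(body)[j], "' in ", path, call. = FALSE)
    vals[, j] <- parsed
  }
  decision_matrix(vals, directions, alternatives = ids,
                  criteria = colnames(body))
}

#' Write a decision matrix to CSV/TSV
#'
#' Inverse of [read_matrix()]: emits the header, the direction row, and the
#' values at full precision so that a round-trip reproduces the matrix
#' exactly.
#'
#' @param dm A [decision_matrix()].
#' @param path Output path; `.tsv` selects tab separation.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "decision_matrix"))
  sep <- guess_sep(path)
  body <- format(dm$values, digits = 17, trim = TRUE, scientific = FALSE)
  tab <- rbind(c("direction", dm$directions),
               cbind(dm$alternatives, body))
  colnames(tab) <- c("alternative", dm$criteria)
  utils::write.table(tab, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' A run configuration is a JSON object with (all optional unless noted):
#' `delta`, `positional_weights`, `probabilities`, `confidences` (at least
#' one of the two latter is required to run the pipeline),
#' `criterion_weights` (override for scoring), `mean_mode`, `sd_ordering`,
#' `case`, `zero_variance`, `renormalize`, `vikor_v`, `methods`, `seed`.
#' Vector lengths are checked against the matrix when one is given.
#'
#' @param path JSON file path.
#' @param dm Optional [decision_matrix()] for length validation.
#' @return A named list with an [aggregation_spec()] under `$spec` and the
#'   remaining fields (`criterion_weights`, `vikor_v`, `methods`, `seed`).
#' @export
read_config <- function(path, dm = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg, dm)
}

#' @rdname read_config
#' @param cfg A configuration list (parsed JSON).
#' @export
validate_config <- function(cfg, dm = NULL) {
  known <- c("delta", "positional_weights", "probabilities", "confidences",
             "criterion_weights", "mean_mode", "sd_ordering", "case",
             "zero_variance", "renormalize", "vikor_v", "methods", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  num_or_null <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (!is.numeric(x)) stop(what, " must be numeric", call. = FALSE)
    as.numeric(x)
  }
  spec <- aggregation_spec(
    delta = if (is.null(cfg$delta)) 0.6 else cfg$delta,
    positional_weights = num_or_null(cfg$positional_weights,
                                     "positional_weights"),
    probabilities = num_or_null(cfg$probabilities, "probabilities"),
    confidences = num_or_null(cfg$confidences, "confidences"),
    moment = moment_spec(
      mean_mode = cfg$mean_mode %||% "plain",
      ordering = "magnitude",
      case = cfg$case %||% 1L),
    sd_ordering = cfg$sd_ordering %||% "magnitude",
    zero_variance = cfg$zero_variance %||% "error",
    renormalize = isTRUE(cfg$renormalize))
  if (!is.null(dm)) {
    n <- nrow(dm$values); p <- ncol(dm$values)
    for (f in c("positional_weights", "probabilities", "confidences"))
      if (!is.null(cfg[[f]]) && length(cfg[[f]]) != n)
        stop("config ", f, " has length ", length(cfg[[f]]),
             " but the matrix has ", n, " alternatives", call. = FALSE)
    if (!is.null(cfg$criterion_weights) &&
        length(cfg$criterion_weights) != p)
      stop("config criterion_weights has length ",
           length(cfg$criterion_weights), " but the matrix has ", p,
           " criteria", call. = FALSE)
  }
  list(spec = spec,
       criterion_weights = num_or_null(cfg$criterion_weights,
                                       "criterion_weights"),
       vikor_v = if (is.null(cfg$vikor_v)) 0.9 else cfg$vikor_v,
       methods = cfg$methods %||% c("ipowa_critic", "s", "w", "sw"),
       seed = cfg$seed)
}

#' Write a pipeline report to disk
#'
#' Emits one CSV per step table (values displayed at 3 decimals, matching
#' the precision of published comparison tables) plus a full-precision JSON
#' twin `report.json` holding every table, keyed by step name
#' (`normalized`, `dispersion`, `conflict`, `information`, `weights`,
#' `scores`, `ranks`).
#'
#' @param report A `"critic_report"` from [run_pipeline()].
#' @param dir Output directory, created if needed.
#' @return The paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "critic_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(tab, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(round(tab, 3), p, row.names = TRUE)
    paths <<- c(paths, p)
  }
  emit(cbind(report$normalized$x, u = report$normalized$u), "normalized")
  emit(report$conflict, "conflict")
  emit(rbind(dispersion = report$dispersion,
             information = report$information,
             weight = report$weights), "weights")
  emit(report$scores, "scores")
  emit(report$ranks, "ranks")
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(normalized = report$normalized$x,
         u = report$normalized$u,
         means = report$normalized$means,
         dispersion = report$dispersion,
         conflict = report$conflict,
         information = report$information,
         weights = report$weights,
         weights_source = report$weights_source,
         scores = report$scores,
         ranks = report$ranks,
         delta = report$spec$delta),
    jp, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(c(paths, jp))
}

#' Generate a synthetic decision problem
#'
#' Draws a random decision matrix with per-criterion uniform value ranges,
#' a benefit/cost direction mix, and a per-alternative confidence vector —
#' the shape of data the pipeline is designed for. Used by the property
#' test-suite; the same seed reproduces the same problem exactly.
#'
#' @param n_alternatives,n_criteria Problem size (each at least 2).
#' @param ranges 2 x n_criteria matrix of (min, max) per criterion, or a
#'   single (min, max) pair recycled; defaults to (0, 100).
#' @param n_cost Number of cost criteria (the last `n_cost` columns).
#' @param confidence_range (min, max) of the uniform confidence draw.
#' @param seed Optional RNG seed for reproducibility.
#' @return A list: `matrix` (a [decision_matrix()]) and `config` (a list
#'   with `delta`, uniform `positional_weights`, `confidences`, and
#'   `renormalize`), ready for [validate_config()]/[run_pipeline()].
#' @export
generate_synthetic <- function(n_alternatives = 12, n_criteria = 7,
                               ranges = c(0, 100), n_cost = 1,
                               confidence_range = c(0.05, 1),
                               seed = NULL) {
  if (n_alternatives < 2 || n_criteria < 2)
    stop("need at least 2 alternatives and 2 criteria", call. = FALSE)
  if (n_cost < 0 || n_cost > n_criteria)
    stop("n_cost must be between 0 and n_criteria", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ranges <- if (is.matrix(ranges)) ranges
  else matrix(ranges, nrow = 2, ncol = n_criteria)
  if (nrow(ranges) != 2 || ncol(ranges) != n_criteria)
    stop("ranges must be a 2 x n_criteria matrix or a (min, max) pair",
         call. = FALSE)
  if (any(ranges[1, ] >= ranges[2, ]))
    stop("degenerate range: every criterion needs min < max", call. = FALSE)
  vals <- sapply(seq_len(n_criteria), function(j)
    stats::runif(n_alternatives, ranges[1, j], ranges[2, j]))
  directions <- c(rep("benefit", n_criteria - n_cost),
                  rep("cost", n_cost))
  conf <- stats::runif(n_alternatives, confidence_range[1],
                       confidence_range[2])
  dm <- decision_matrix(vals, directions)
  cfg <- list(delta = 0.6,
              positional_weights = rep(1 / n_alternatives, n_alternatives),
              confidences = conf,
              renormalize = TRUE)
  list(matrix = dm, config = cfg)
}

#' The greenhouse-tomato sustainability case study
#'
#' Loads the packaged fixture: twelve tomato production strategies
#' (combinations of shading, grafting and irrigation regime) evaluated on
#' seven sustainability criteria (production, profit, water consumption —
#' the one cost criterion —, CO2 fixation, labor, maturity index,
#' nutritional composition), together with the study's aggregation
#' settings: delta = 0.6, the elicited positional weight vector, the expert
#' confidence and probability columns, and the criterion-weight vector
#' reported by the original analysis (usable as an override to reproduce
#' its published score table).
#'
#' @return A list: `matrix` (a [decision_matrix()]), `config` (validated
#'   configuration, see [read_config()]), and `raw_config` (the parsed
#'   JSON, including both `confidences` and `probabilities` and the
#'   published `criterion_weights`).
#' @export
#' @examples
#' tom <- tomato_example()
#' rep <- run_pipeline(tom$matrix, tom$config$spec)
tomato_example <- function() {
  mpath <- system.file("extdata", "tomato_matrix.csv", package = "critowa",
                       mustWork = TRUE)
  cpath <- system.file("extdata", "tomato_config.json", package = "critowa",
                       mustWork = TRUE)
  dm <- read_matrix(mpath)
  raw <- jsonlite::read_json(cpath, simplifyVector = TRUE)
  cfg <- validate_config(raw, dm)
  list(matrix = dm, config = cfg, raw_config = raw)
}
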