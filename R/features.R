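#' MaxEnt-style feature specification
#'
#' Describes how environmental variables are expanded into model features.
#' Variables are first rescaled to [0, 1] by their training-data range;
#' features are then built on the rescaled values:
#' \describe{
#'   \item{linear}{z}
#'   \item{quadratic}{z^2}
#'   \item{product}{z_i * z_j for every unordered pair}
#'   \item{threshold}{step indicators `z >= k` at evenly spaced interior
#'     knots k = t/(K+1), t = 1..K}
#'   \item{hinge}{forward hinges `max(0, (z - k)/(1 - k))` at knots
#'     k = 0, 1/K, ..., (K-1)/K and reverse hinges `max(0, (k - z)/k)` at
#'     knots k = 1/K, ..., 1}
#' }
#'
#' @param classes Character subset of
#'   `c("linear", "quadratic", "product", "threshold", "hinge")`.
#' @param hinge_knots,threshold_knots Number of knots per variable
#'   (default 50; at least 2 when the class is active).
#' @param ranges Two-row matrix (`min`, `max`) with one column per
#'   variable, normally set from training data by [maxent_fit()].
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(classes, hinge_knots = 50, threshold_knots = 50,
                         ranges = NULL) {
  all_classes <- c("linear", "quadratic", "product", "threshold", "hinge")
  classes <- match.arg(classes, all_classes, several.ok = TRUE)
  if (!length(classes)) stop("feature_spec: at least one feature class")
  if ("hinge" %in% classes && hinge_knots < 2)
    stop("feature_spec: hinge_knots must be >= 2")
  if ("threshold" %in% classes && threshold_knots < 2)
    stop("feature_spec: threshold_knots must be >= 2")
  structure(list(classes = classes, hinge_knots = hinge_knots,
                 threshold_knots = threshold_knots, ranges = ranges),
            class = "feature_spec")
}

# abbreviations as used in the SDM tuning literature:
# L, LQ, LQH, LQHP, LQPT, LQHPT
expand_classes <- function(abbrev) {
  map <- c(L = "linear", Q = "quadratic", H = "hinge", P = "product",
           T = "threshold")
  unname(map[strsplit(abbrev, "")[[1]]])
}

#' Set feature ranges from training data
#'
#' @param spec A [feature_spec()].
#' @param env Numeric matrix of training environmental values
#'   (rows = samples, named columns = variables).
#' @return The spec with `ranges` filled; variables constant in training
#'   are recorded in `dropped_vars` and excluded from the expansion, with
#'   a warning.
#' @export
set_feature_ranges <- function(spec, env) {
  rng <- apply(env, 2, range)
  rownames(rng) <- c("min", "max")
  const <- which(rng["max", ] - rng["min", ] == 0)
  if (length(const)) {
    warning("set_feature_ranges: constant variable(s) dropped from ",
            "features: ", paste(colnames(env)[const], collapse = ", "))
    spec$dropped_vars <- colnames(env)[const]
    rng <- rng[, -const, drop = FALSE]
  }
  spec$ranges <- rng
  spec
}

#' Build the feature design matrix
#'
#' Expands raw environmental values into the feature columns described by
#' the spec. Rescaling and (optional) clamping use the spec's training
#' ranges, so projection onto new climates reproduces the training feature
#' space exactly.
#'
#' @param env Numeric matrix (rows = samples, named columns = variables);
#'   must contain every variable in `spec$ranges`.
#' @param spec A [feature_spec()] with ranges set.
#' @param clamp If `TRUE`, raw values are clamped to the training range
#'   before rescaling (so all rescaled values lie in [0, 1]).
#' @return Numeric matrix with one column per feature and attribute
#'   `vars`: a list giving, per column, the variable name(s) the feature
#'   is built from.
#' @export
build_features <- function(env, spec, clamp = FALSE) {
  if (is.null(spec$ranges))
    stop("build_features: feature ranges not set; see set_feature_ranges()")
  vars <- colnames(spec$ranges)
  missing <- setdiff(vars, colnames(env))
  if (length(missing))
    stop("build_features: environment is missing variable(s): ",
         paste(missing, collapse = ", "))
  Z <- sapply(vars, function(v) {
    x <- env[, v]
    lo <- spec$ranges["min", v]; hi <- spec$ranges["max", v]
    if (clamp) x <- pmin(pmax(x, lo), hi)
    (x - lo) / (hi - lo)
  })
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1, dimnames = list(NULL, vars))
  cols <- list(); colvars <- list(); nm <- character(0)
  add <- function(x, name, v) {
    cols[[length(cols) + 1L]] <<- x
    colvars[[length(colvars) + 1L]] <<- v
    nm[length(nm) + 1L] <<- name
  }
  if ("linear" %in% spec$classes)
    for (v in vars) add(Z[, v], paste0("l:", v), v)
  if ("quadratic" %in% spec$classes)
    for (v in vars) add(Z[, v]^2, paste0("q:", v), v)
  if ("product" %in% spec$classes && length(vars) >= 2) {
    pairs <- utils::combn(vars, 2)
    for (k in seq_len(ncol(pairs))) {
      v1 <- pairs[1, k]; v2 <- pairs[2, k]
      add(Z[, v1] * Z[, v2], paste0("p:", v1, "*", v2), c(v1, v2))
    }
  }
  if ("threshold" %in% spec$classes) {
    K <- spec$threshold_knots
    knots <- seq_len(K) / (K + 1)
    for (v in vars) for (k in knots)
      add(as.numeric(Z[, v] >= k), sprintf("t:%s:%.6g", v, k), v)
  }
  if ("hinge" %in% spec$classes) {
    K <- spec$hinge_knots
    for (v in vars) {
      for (k in (seq_len(K) - 1) / K)
        add(pmax(0, (Z[, v] - k) / (1 - k)), sprintf("hf:%s:%.6g", v, k), v)
      for (k in seq_len(K) / K)
        add(pmax(0, (k - Z[, v]) / k), sprintf("hr:%s:%.6g", v, k), v)
    }
  }
  F <- do.call(cbind, cols)
  colnames(F) <- nm
  attr(F, "vars") <- stats::setNames(colvars, nm)
  F
}

# MaxEnt default per-class regularization schedule, linearly interpolated
# in the number of training presences and clamped at the table ends
class_beta <- function(class, m) {
  tab <- switch(class,
    linear    = list(m = c(10, 30, 100),        b = c(1.0, 0.2, 0.05)),
    quadratic = list(m = c(0, 10, 17, 30, 100), b = c(1.3, 0.8, 0.5, 0.25, 0.05)),
    product   = list(m = c(0, 10, 17, 30, 100), b = c(2.6, 1.6, 1.4, 1.0, 0.5)),
    threshold = list(m = c(0, 100),             b = c(2.0, 1.0)),
    hinge     = list(m = c(0, 1),               b = c(0.5, 0.5)))
  stats::approx(tab$m, tab$b, xout = m, rule = 2)$y
}

feature_class_of <- function(names) {
  pre <- sub(":.*$", "", names)
  c(l = "linear", q = "quadratic", p = "product", t = "threshold",
    hf = "hinge", hr = "hinge")[pre]
}

# per-feature L1 penalty: multiplier x class default (interpolated by the
# presence count) x feature sd over presences, scaled by 1/sqrt(m)
feature_penalties <- function(Fp, multiplier, m) {
  cls <- feature_class_of(colnames(Fp))
  bet <- vapply(cls, class_beta, numeric(1), m = m)
  sds <- apply(Fp, 2, stats::sd)
  sds <- pmax(sds, 1e-6)   # floor keeps near-constant features penalized
  multiplier * bet * sds / sqrt(m)
}
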