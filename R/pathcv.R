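# Branduardi-style path collective variables over an ordered milestone set:
# progress s and orthogonal distance z. Milestones may be structures (with a
# metric_spec distance) or abstract points (Euclidean), so 2D toy landscapes
# run through the same interface.

#' Milestone path for path collective variables
#'
#' An ordered set of milestones delineating a conformational transition,
#' together with the metric used for milestone distances and the smoothing
#' parameter `lambda` (units: inverse squared metric units). `path_s()`
#' returns the smooth progress coordinate along the path and `path_z()` the
#' squared-distance-scale orthogonal deviation from it.
#'
#' @param milestones list of [dna_structure()] objects, or a numeric matrix
#'   with one abstract point per row.
#' @param metric a [metric_spec()] (ignored for abstract points, which use
#'   Euclidean distance).
#' @param lambda smoothing parameter; `NULL` selects it via [select_lambda()].
#' @param normalize if `TRUE`, `path_s()` is rescaled so the first milestone
#'   maps to 0 and the last to 1.
#' @return a `milestone_path` object.
#' @export
milestone_path <- function(milestones, metric = metric_spec(), lambda = NULL,
                           normalize = FALSE) {
  if (is.matrix(milestones))
    milestones <- lapply(seq_len(nrow(milestones)), function(i) milestones[i, ])
  if (length(milestones) < 2) abort("need at least 2 milestones")
  p <- structure(list(milestones = milestones, metric = metric,
                      lambda = lambda, normalize = normalize,
                      padded = FALSE), class = "milestone_path")
  dd <- neighbor_distances(p)
  if (any(dd <= 0)) abort("consecutive milestones must be distinct")
  if (is.null(lambda)) p$lambda <- select_lambda(p)
  if (p$lambda <= 0) abort("lambda must be positive")
  p
}

#' @export
print.milestone_path <- function(x, ...) {
  cat("<milestone_path> ", length(x$milestones), " milestones, lambda = ",
      signif(x$lambda, 4), if (x$padded) ", padded", "\n", sep = "")
  invisible(x)
}

milestone_dist <- function(path, X, Xi) {
  if (inherits(Xi, "dna_structure")) metric_distance(X, Xi, path$metric)
  else sqrt(sum((as.numeric(X) - as.numeric(Xi))^2))
}

neighbor_distances <- function(path) {
  m <- path$milestones
  vapply(seq_len(length(m) - 1), function(i)
    milestone_dist(path, m[[i]], m[[i + 1]]), numeric(1))
}

#' Pad a milestone set with extrapolated endpoints
#'
#' Adds one milestone before the first and one after the last by linear
#' coordinate extrapolation of the terminal pairs (`2*X1 - X2` and
#' `2*XN - X(N-1)`), giving uniform sampling weight to the physical endpoints
#' of the path (a 40-milestone path becomes 42). Interior milestones are
#' untouched.
#'
#' @param milestones list of structures, an abstract-point matrix, or a
#'   `milestone_path`.
#' @inheritParams milestone_path
#' @return a padded `milestone_path`.
#' @export
pad_path <- function(milestones, metric = metric_spec(), lambda = NULL,
                     normalize = FALSE) {
  if (inherits(milestones, "milestone_path")) {
    metric <- milestones$metric
    normalize <- milestones$normalize
    milestones <- milestones$milestones
  }
  if (is.matrix(milestones))
    milestones <- lapply(seq_len(nrow(milestones)), function(i) milestones[i, ])
  if (length(milestones) < 2) abort("need at least 2 milestones to pad")
  extrap <- function(a, b) {         # 2a - b, structure- or point-wise
    if (inherits(a, "dna_structure")) {
      out <- a
      out$atoms$x <- 2 * a$atoms$x - b$atoms$x
      out$atoms$y <- 2 * a$atoms$y - b$atoms$y
      out$atoms$z <- 2 * a$atoms$z - b$atoms$z
      out
    } else 2 * as.numeric(a) - as.numeric(b)
  }
  m <- c(list(extrap(milestones[[1]], milestones[[2]])), milestones,
         list(extrap(milestones[[length(milestones)]],
                     milestones[[length(milestones) - 1]])))
  p <- milestone_path(m, metric = metric, lambda = lambda, normalize = normalize)
  p$padded <- TRUE
  p
}

#' Select the pathCV smoothing parameter
#'
#' `lambda = ln(2) / mean(d_i^2)` over consecutive squared milestone
#' distances: a probe halfway between neighbors still feels both, while
#' milestones remain distinguishable.
#'
#' @param path a `milestone_path`.
#' @return positive scalar `lambda`.
#' @export
select_lambda <- function(path) {
  dd <- neighbor_distances(path)
  if (any(dd == 0)) abort("zero consecutive milestone distance")
  log(2) / mean(dd^2)
}

path_dists <- function(X, path) {
  vapply(path$milestones, function(m) milestone_dist(path, X, m), numeric(1))
}

path_weights <- function(X, path) {
  d2 <- path_dists(X, path)^2
  w <- -path$lambda * d2
  mx <- max(w)
  if (!is.finite(mx) || mx < log(.Machine$double.xmin))
    abort("all milestone weights underflow; decrease lambda or move X closer to the path")
  list(logw = w, mx = mx, w = exp(w - mx))
}

#' Path progress collective variable s
#'
#' \eqn{s = \sum_i i e^{-\lambda d_i^2} / \sum_i e^{-\lambda d_i^2}} over
#' milestone indices `i = 1..N`; with `normalize = TRUE` on the path, rescaled
#' so the first milestone maps to 0 and the last to 1. Continuous in `X`.
#'
#' @param X a structure or abstract point.
#' @param path a `milestone_path`.
#' @return progress in index units (or `[0,1]` if normalized).
#' @export
path_s <- function(X, path) {
  raw <- function(Y) {
    pw <- path_weights(Y, path)
    n <- length(path$milestones)
    sum(seq_len(n) * pw$w) / sum(pw$w)
  }
  s <- raw(X)
  if (isTRUE(path$normalize)) {
    # rescale so evaluation at the terminal milestones gives exactly 0 and 1
    s1 <- raw(path$milestones[[1]])
    sN <- raw(path$milestones[[length(path$milestones)]])
    (s - s1) / (sN - s1)
  } else s
}

#' Orthogonal distance collective variable z
#'
#' \eqn{z = -\lambda^{-1} \ln \sum_i e^{-\lambda d_i^2}}: a smooth minimum of
#' the squared milestone distances, tending to `min_i d_i^2` as `lambda` grows.
#' For structural metrics `z` is in A^2, the units of the restraint wall.
#'
#' @inheritParams path_s
#' @return z in squared metric units.
#' @export
path_z <- function(X, path) {
  pw <- path_weights(X, path)
  -(pw$mx + log(sum(pw$w))) / path$lambda
}

#' Tabulate s and z over a 2D grid of abstract points
#'
#' Convenience for toy landscapes: evaluates [path_s()] and [path_z()] on the
#' tensor grid `x` by `y`, returning lookup tables used by the biased-sampling
#' engine.
#'
#' @param path a `milestone_path` over 2D abstract points.
#' @param x,y grid node coordinates.
#' @return list with matrices `s` and `z` of dimension `length(x)` x `length(y)`.
#' @export
pathcv_tables <- function(path, x, y) {
  s <- matrix(0, length(x), length(y)); z <- s
  for (i in seq_along(x)) for (j in seq_along(y)) {
    p <- c(x[i], y[j])
    s[i, j] <- path_s(p, path)
    z[i, j] <- path_z(p, path)
  }
  list(s = s, z = z, x = x, y = y)
}
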