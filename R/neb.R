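# Nudged elastic band over a pluggable energy/force provider, with the
# improved (Henkelman-Jonsson) tangent, spring forces, neighbor RMS fitting
# and a partial moving mask. The optimizer is a deterministic damped descent
# (quick-min velocity projection) rather than the thermostatted MD a
# production engine would use; the stationary points are the same.

#' Energy provider
#'
#' A callable contract `coordinates -> (energy, gradient)` in kcal/mol and
#' kcal/mol/A. If `gradient` is `NULL` a central finite difference of
#' `energy` is used.
#'
#' @param energy function of a numeric coordinate vector returning a scalar.
#' @param gradient function returning the gradient vector, or `NULL`.
#' @param name label used in printing.
#' @return an `energy_provider`.
#' @export
energy_provider <- function(energy, gradient = NULL, name = "custom") {
  if (is.null(gradient))
    gradient <- function(x) num_gradient(energy, x)
  structure(list(energy = energy, gradient = gradient, name = name),
            class = "energy_provider")
}

num_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x; xp[i] <- x[i] + h; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

#' Built-in toy landscapes
#'
#' * `ep_muller_brown()`: the standard 2D Mueller-Brown surface (three minima,
#'   two saddles), the classic NEB benchmark.
#' * `ep_double_well_1d()`: `E = x^4 - x^2`, minima at +-1/sqrt(2), saddle at
#'   the origin with `E = 0`.
#' * `ep_double_well_2d()`: `E = (x^2-1)^2 + c y^2`, two minima joined by a
#'   single saddle at the origin.
#' * `ep_harmonic(k, center)`: isotropic harmonic well `E = k/2 |x-c|^2`.
#' * `ep_two_channel()`: two basins near `x = +-1` connected through an upper
#'   (`y = +1`) and a lower (`y = -1`) channel with different barrier heights
#'   and a tilt between the basins; the reference surface of the end-to-end
#'   two-run free-energy recovery exercise. See [two_channel_params()].
#' @name toy_landscapes
NULL

#' @rdname toy_landscapes
#' @export
ep_muller_brown <- function() {
  A <- c(-200, -100, -170, 15)
  aa <- c(-1, -1, -6.5, 0.7); bb <- c(0, 0, 11, 0.6); cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1); y0 <- c(0, 0.5, 1.5, 1)
  energy <- function(p) {
    dx <- p[1] - x0; dy <- p[2] - y0
    sum(A * exp(aa * dx^2 + bb * dx * dy + cc * dy^2))
  }
  gradient <- function(p) {
    dx <- p[1] - x0; dy <- p[2] - y0
    e <- A * exp(aa * dx^2 + bb * dx * dy + cc * dy^2)
    c(sum(e * (2 * aa * dx + bb * dy)), sum(e * (bb * dx + 2 * cc * dy)))
  }
  energy_provider(energy, gradient, "muller-brown")
}

#' @rdname toy_landscapes
#' @export
ep_double_well_1d <- function() {
  energy_provider(function(x) x[1]^4 - x[1]^2,
                  function(x) c(4 * x[1]^3 - 2 * x[1]),
                  "double-well-1d")
}

#' @rdname toy_landscapes
#' @param confine transverse force constant of the 2D double well.
#' @export
ep_double_well_2d <- function(confine = 2) {
  energy_provider(function(p) (p[1]^2 - 1)^2 + confine * p[2]^2,
                  function(p) c(4 * p[1] * (p[1]^2 - 1), 2 * confine * p[2]),
                  "double-well-2d")
}

#' @rdname toy_landscapes
#' @param k force constant (kcal/mol/A^2).
#' @param center well minimum.
#' @export
ep_harmonic <- function(k = 1, center = 0) {
  energy_provider(function(x) sum(k / 2 * (x - center)^2),
                  function(x) k * (x - center),
                  "harmonic")
}

#' Parameters of the two-channel toy surface
#'
#' `U(x,y) = A (x^2-1)^2 + C (y^2-1)^2 + delta * y * exp(-x^2/w^2) + eps * x`.
#' Defaults: `A = 5` sets the mean channel barrier, `delta = 1` splits the two
#' channel saddles (lower channel at `y = -1` is the easy one), `C = 1` keeps
#' the channels weakly separated mid-transition, `eps = 0.75` tilts the two
#' basins apart. Units kcal/mol.
#'
#' @param A,C,delta,w,eps surface constants.
#' @return named list of constants.
#' @export
two_channel_params <- function(A = 5, C = 1, delta = 1, w = 0.5, eps = 0.75) {
  list(A = A, C = C, delta = delta, w = w, eps = eps)
}

#' @rdname toy_landscapes
#' @param params constants from [two_channel_params()].
#' @export
ep_two_channel <- function(params = two_channel_params()) {
  p <- params
  energy <- function(q) {
    x <- q[1]; y <- q[2]
    p$A * (x^2 - 1)^2 + p$C * (y^2 - 1)^2 +
      p$delta * y * exp(-x^2 / p$w^2) + p$eps * x
  }
  gradient <- function(q) {
    x <- q[1]; y <- q[2]
    g <- exp(-x^2 / p$w^2)
    c(4 * p$A * x * (x^2 - 1) - 2 * x / p$w^2 * p$delta * y * g + p$eps,
      4 * p$C * y * (y^2 - 1) + p$delta * g)
  }
  energy_provider(energy, gradient, "two-channel")
}

# ---- band -------------------------------------------------------------------

#' Nudged-elastic-band image chain
#'
#' Holds `M >= 3` images (numeric coordinate vectors, or [dna_structure()]
#' objects which are flattened over the moving mask), the spring constant
#' (default 5 kcal/mol/A^2), and the moving/fit masks of the partial-NEB
#' scheme: NEB forces act only on moving-mask coordinates, and neighbor RMS
#' fitting (structural bands) uses the fit mask.
#'
#' @param images list of numeric vectors or structures, ordered reactant to
#'   product.
#' @param k_spring spring constant (kcal/mol/A^2).
#' @param moving_mask integer indices of coordinates subject to NEB forces
#'   (`NULL` = all), or an atom-name mask for structural images.
#' @param fit_mask atom selector for neighbor RMS fitting (structural bands).
#' @param fix_endpoints keep the terminal images frozen during optimization.
#' @return a `neb_band`.
#' @export
neb_band <- function(images, k_spring = 5, moving_mask = NULL,
                     fit_mask = "heavy", fix_endpoints = TRUE) {
  if (is.matrix(images))
    images <- lapply(seq_len(nrow(images)), function(i) images[i, ])
  if (length(images) < 3) abort("a band needs at least 3 images")
  if (k_spring <= 0) abort("k_spring must be positive")
  structural <- inherits(images[[1]], "dna_structure")
  structure(list(images = images, k_spring = k_spring,
                 moving_mask = moving_mask, fit_mask = fit_mask,
                 fix_endpoints = fix_endpoints, structural = structural),
            class = "neb_band")
}

#' @export
print.neb_band <- function(x, ...) {
  cat("<neb_band> ", length(x$images), " images, k_spring = ", x$k_spring,
      if (x$structural) " (structural)", "\n", sep = "")
  invisible(x)
}

image_vec <- function(band, i) {
  im <- band$images[[i]]
  if (band$structural) as.numeric(t(coords(im, "all"))) else as.numeric(im)
}

#' Improved (Henkelman-Jonsson) NEB tangent
#'
#' The revised tangent that prevents kinks: forward difference when the image
#' sits on an uphill stretch (`E_{i-1} < E_i < E_{i+1}`), backward on a
#' downhill stretch, and at local extrema an energy-weighted mix of both
#' differences weighted by the larger/smaller neighbor energy gaps.
#'
#' @param band a [neb_band()].
#' @param i interior image index (1-based).
#' @param energies per-image energies (kcal/mol).
#' @return unit tangent vector at image `i`.
#' @export
improved_tangent <- function(band, i, energies) {
  M <- length(band$images)
  if (i <= 1 || i >= M) abort("tangent defined for interior images only")
  x0 <- image_vec(band, i)
  tp <- image_vec(band, i + 1) - x0      # tau+
  tm <- x0 - image_vec(band, i - 1)      # tau-
  if (sqrt(sum(tp^2)) == 0 || sqrt(sum(tm^2)) == 0)
    abort("coincident neighboring images give a zero tangent")
  Em <- energies[i - 1]; E0 <- energies[i]; Ep <- energies[i + 1]
  if (Ep > E0 && E0 > Em) tau <- tp
  else if (Ep < E0 && E0 < Em) tau <- tm
  else {
    dmax <- max(abs(Ep - E0), abs(Em - E0))
    dmin <- min(abs(Ep - E0), abs(Em - E0))
    tau <- if (Ep > Em) tp * dmax + tm * dmin else tp * dmin + tm * dmax
    if (sqrt(sum(tau^2)) == 0) tau <- tp + tm   # flat plateau
  }
  tau / sqrt(sum(tau^2))
}

#' NEB force on an interior image
#'
#' Perpendicular component of the true force plus the parallel spring force
#' `k (|X_{i+1}-X_i| - |X_i-X_{i-1}|) tau`. With `climbing = TRUE` the image
#' instead feels the full true force with its parallel component inverted, so
#' it converges onto the saddle.
#'
#' @inheritParams improved_tangent
#' @param provider an [energy_provider()].
#' @param climbing treat image `i` as the climbing image.
#' @return force vector (moving-mask coordinates only; others zero).
#' @export
neb_force <- function(band, i, provider, energies = NULL, climbing = FALSE) {
  if (is.null(energies))
    energies <- vapply(seq_along(band$images),
                       function(j) provider$energy(image_vec(band, j)), numeric(1))
  x0 <- image_vec(band, i)
  tau <- improved_tangent(band, i, energies)
  Ftrue <- -provider$gradient(x0)
  Fpar <- sum(Ftrue * tau) * tau
  f <- if (climbing) {
    Ftrue - 2 * Fpar
  } else {
    dp <- sqrt(sum((image_vec(band, i + 1) - x0)^2))
    dm <- sqrt(sum((x0 - image_vec(band, i - 1))^2))
    (Ftrue - Fpar) + band$k_spring * (dp - dm) * tau
  }
  if (!is.null(band$moving_mask) && !band$structural) {
    keep <- seq_along(f) %in% band$moving_mask
    f[!keep] <- 0
  }
  f
}

#' Sequentially RMS-fit neighboring images
#'
#' Rigidly superposes each structural image onto its predecessor using the
#' fit-mask atoms (Kabsch), removing overall translation/rotation between
#' neighbors while leaving every image's internal geometry untouched.
#'
#' @param band a structural [neb_band()].
#' @return the aligned band.
#' @export
rms_fit_neighbors <- function(band) {
  if (!band$structural) abort("rms_fit_neighbors needs structural images")
  for (i in seq_along(band$images)[-1]) {
    ref <- band$images[[i - 1]]; mob <- band$images[[i]]
    P <- coords(ref, band$fit_mask); Q <- coords(mob, band$fit_mask)
    if (nrow(P) < 3) abort("fit mask selects fewer than 3 atoms")
    if (qr(sweep(Q, 2, colMeans(Q)))$rank < 2)
      abort("degenerate (collinear) fit mask")
    cp <- colMeans(P); cq <- colMeans(Q)
    s <- svd(crossprod(sweep(P, 2, cp), sweep(Q, 2, cq)))  # H = P0^T Q0
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)               # maps Q frame -> P frame
    allq <- coords(mob, "all")
    new <- sweep(sweep(allq, 2, cq) %*% R, 2, cp, "+")
    mob$atoms$x <- new[, 1]; mob$atoms$y <- new[, 2]; mob$atoms$z <- new[, 3]
    band$images[[i]] <- mob
  }
  band
}

#' Optimize a band to the minimum-energy path
#'
#' Deterministic damped descent on the NEB forces: `step_rule = "quickmin"`
#' (velocity projected on the force, zeroed when opposing it) or `"sd"`
#' (plain steepest descent). Terminates when the largest per-image NEB force
#' norm drops below `tol` or after `steps` iterations. Endpoints stay frozen
#' when the band's `fix_endpoints` flag is set. `climbing = TRUE` lets the
#' highest-energy image climb to the saddle.
#'
#' @param band an abstract-image [neb_band()].
#' @param provider an [energy_provider()].
#' @param steps maximum iterations.
#' @param dt descent step size.
#' @param tol convergence threshold on the max NEB force norm
#'   (kcal/mol/A).
#' @param step_rule `"quickmin"` or `"sd"`.
#' @param climbing enable the climbing image (off by default).
#' @return list with the optimized `band`, per-image `energies`, the final
#'   `max_force`, iterations used, and a `converged` flag.
#' @export
optimize_band <- function(band, provider, steps = 2000, dt = 0.01, tol = 1e-3,
                          step_rule = c("quickmin", "sd"), climbing = FALSE) {
  step_rule <- match.arg(step_rule)
  if (steps < 1) abort("steps must be >= 1")
  M <- length(band$images)
  X <- lapply(seq_len(M), function(i) image_vec(band, i))
  V <- lapply(X, function(x) numeric(length(x)))
  interior <- 2:(M - 1)
  mk_band <- function(X) {
    b <- band; b$images <- X; b$structural <- FALSE; b
  }
  it <- 0; maxf <- Inf
  for (it in seq_len(steps)) {
    E <- vapply(X, provider$energy, numeric(1))
    if (any(!is.finite(E)))
      abort("band optimization diverged (non-finite energy); reduce dt")
    ci <- if (climbing) interior[which.max(E[interior])] else -1L
    b <- mk_band(X)
    Fs <- lapply(interior, function(i)
      neb_force(b, i, provider, energies = E, climbing = (i == ci)))
    maxf <- max(vapply(Fs, function(f) sqrt(sum(f^2)), numeric(1)))
    if (maxf <= tol) break
    for (k in seq_along(interior)) {
      i <- interior[k]; f <- Fs[[k]]
      if (step_rule == "quickmin") {
        v <- V[[i]]
        fn <- sqrt(sum(f^2))
        if (fn > 0) {
          fhat <- f / fn
          vp <- sum(v * fhat)
          v <- if (vp > 0) vp * fhat else numeric(length(f))
        }
        v <- v + f * dt
        V[[i]] <- v
        X[[i]] <- X[[i]] + v * dt
      } else {
        X[[i]] <- X[[i]] + f * dt
      }
    }
    if (!band$fix_endpoints) {
      for (i in c(1L, M)) {
        g <- -provider$gradient(X[[i]])
        X[[i]] <- X[[i]] + g * dt
      }
    }
  }
  E <- vapply(X, provider$energy, numeric(1))
  out <- mk_band(X)
  list(band = out, energies = E, max_force = maxf, iterations = it,
       converged = maxf <= tol)
}

#' @export
tidy.neb_band <- function(x, ...) {
  purrr::imap_dfr(x$images, function(im, i) {
    v <- if (x$structural) as.numeric(t(coords(im, "all"))) else as.numeric(im)
    tibble::tibble(image = i, coord = seq_along(v), value = v)
  })
}

#' Band path length (sum of inter-image distances)
#'
#' @param band a [neb_band()].
#' @return total Euclidean path length over flattened images.
#' @export
band_length <- function(band) {
  M <- length(band$images)
  sum(vapply(seq_len(M - 1), function(i)
    sqrt(sum((image_vec(band, i + 1) - image_vec(band, i))^2)), numeric(1)))
}

#' Linearly interpolated band between two endpoints
#'
#' @param from,to endpoint coordinate vectors.
#' @param n_images total images including endpoints.
#' @param ... passed to [neb_band()].
#' @return a [neb_band()].
#' @export
interpolate_band <- function(from, to, n_images, ...) {
  fr <- as.numeric(from); to <- as.numeric(to)
  imgs <- lapply(seq_len(n_images), function(i) {
    t <- (i - 1) / (n_images - 1)
    (1 - t) * fr + t * to
  })
  neb_band(imgs, ...)
}
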