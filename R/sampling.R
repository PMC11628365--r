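# Desk-scale biased sampling: BAOAB Langevin dynamics, well-tempered
# metadynamics hill deposition, one-sided harmonic walls, dihedral
# flat-bottom restraints, and REST2 ladder utilities.

KT_298 <- 0.5926  # kcal/mol at 298 K

#' Well-tempered metadynamics parameters
#'
#' Defaults follow the production protocol for path-CV metadynamics on
#' G-quadruplex folding: initial hill height 0.956 kcal/mol, Gaussian widths
#' 0.4 (pathCV units) and 0.4 A^2 (z), bias factor `(T + dT)/T = 35`, and a
#' fixed deposition stride with hills accumulated on a grid.
#'
#' @param height initial hill height h0 (kcal/mol).
#' @param sigma_s,sigma_z Gaussian widths along the pathCV and z axes.
#' @param bias_factor well-tempered bias factor `gamma`; `Inf` gives
#'   standard (untempered) metadynamics.
#' @param stride deposition stride in integrator steps (the 50-ps stride of
#'   the production protocol maps onto an abstract step stride at desk
#'   scale).
#' @return a `wt_metad_params` object.
#' @export
wt_metad_params <- function(height = 0.956, sigma_s = 0.4, sigma_z = 0.4,
                            bias_factor = 35, stride = 500L) {
  if (height <= 0 || sigma_s <= 0 || sigma_z <= 0)
    abort("height and widths must be positive")
  if (bias_factor <= 1) abort("bias_factor must exceed 1")
  structure(list(height = height, sigma_s = sigma_s, sigma_z = sigma_z,
                 bias_factor = bias_factor, stride = as.integer(stride)),
            class = "wt_metad_params")
}

#' Hills ledger: deposited Gaussians and the accumulated bias grid
#'
#' @param axes named list of strictly increasing grid node vectors (1 or 2
#'   axes), covering the declared CV ranges.
#' @return a `hills_ledger` with an empty hill table and a zero bias grid.
#' @export
hills_ledger <- function(axes) {
  if (!length(axes) %in% 1:2) abort("hills_ledger supports 1 or 2 CV axes")
  dims <- vapply(axes, length, integer(1))
  structure(list(axes = axes,
                 hills = tibble::tibble(time = double(),
                                        center = list(), sigma = list(),
                                        height = double()),
                 bias = array(0, dim = dims)),
            class = "hills_ledger")
}

ledger_sigmas <- function(ledger, params) {
  c(params$sigma_s, params$sigma_z)[seq_along(ledger$axes)]
}

#' Evaluate the accumulated bias at a point
#'
#' Multilinear interpolation of the ledger's bias grid.
#'
#' @param ledger a [hills_ledger()].
#' @param point CV vector (length = number of axes).
#' @return bias potential (kcal/mol).
#' @export
eval_bias <- function(ledger, point) {
  ax <- ledger$axes
  idx <- purrr::map2(ax, point, function(a, p) {
    if (p < a[1] || p > a[length(a)]) abort("point outside the bias grid")
    i <- findInterval(p, a, all.inside = TRUE)
    t <- (p - a[i]) / (a[i + 1] - a[i])
    list(i = i, t = t)
  })
  if (length(ax) == 1) {
    i <- idx[[1]]$i; t <- idx[[1]]$t
    (1 - t) * ledger$bias[i] + t * ledger$bias[i + 1]
  } else {
    i <- idx[[1]]$i; ti <- idx[[1]]$t
    j <- idx[[2]]$i; tj <- idx[[2]]$t
    b <- ledger$bias
    (1 - ti) * (1 - tj) * b[i, j] + ti * (1 - tj) * b[i + 1, j] +
      (1 - ti) * tj * b[i, j + 1] + ti * tj * b[i + 1, j + 1]
  }
}

#' Deposit a well-tempered hill
#'
#' Appends a Gaussian of height
#' `h = h0 * exp(-V(point) / ((gamma - 1) kT))` -- the well-tempered damping
#' of the initial height by the bias already accumulated at the deposition
#' point -- and adds it to the stored grid. As `gamma -> Inf` the height
#' stays at `h0` (standard metadynamics).
#'
#' @param ledger a [hills_ledger()].
#' @param params a [wt_metad_params()].
#' @param point CV vector inside the grid.
#' @param time deposition time stamp.
#' @param kT thermal energy (kcal/mol).
#' @return the updated ledger.
#' @export
deposit_hill <- function(ledger, params, point, time = NA_real_, kT = KT_298) {
  vb <- eval_bias(ledger, point)
  h <- if (is.finite(params$bias_factor))
    params$height * exp(-vb / ((params$bias_factor - 1) * kT))
  else params$height
  sig <- ledger_sigmas(ledger, params)
  ax <- ledger$axes
  if (length(ax) == 1) {
    g <- h * exp(-0.5 * ((ax[[1]] - point[1]) / sig[1])^2)
    ledger$bias <- ledger$bias + g
  } else {
    gx <- exp(-0.5 * ((ax[[1]] - point[1]) / sig[1])^2)
    gy <- exp(-0.5 * ((ax[[2]] - point[2]) / sig[2])^2)
    ledger$bias <- ledger$bias + h * outer(gx, gy)
  }
  ledger$hills <- dplyr::bind_rows(ledger$hills,
    tibble::tibble(time = time, center = list(point), sigma = list(sig),
                   height = h))
  ledger
}

#' One-sided harmonic wall specification
#'
#' The orthogonal-distance restraint of the path-CV protocol: zero below the
#' onset `z0 = 0.81` A^2, harmonic with force constant `k = 17.2`
#' kcal/mol/A^4 above it, under the half-k convention `E = (k/2)(z - z0)^2`
#' (energy and first derivative continuous at the onset).
#'
#' @param z0 onset (A^2).
#' @param k force constant (kcal/mol/A^4).
#' @return a `wall_spec`.
#' @export
wall_spec <- function(z0 = 0.81, k = 17.2) {
  if (k <= 0) abort("wall force constant must be positive")
  structure(list(z0 = z0, k = k, side = "upper"), class = "wall_spec")
}

#' Wall energy and force
#'
#' @param z orthogonal-distance value(s) (A^2).
#' @param spec a [wall_spec()].
#' @return list with `energy` (kcal/mol) and `force` (`-dE/dz`), vectorized
#'   over `z`.
#' @export
wall_energy <- function(z, spec = wall_spec()) {
  d <- pmax(z - spec$z0, 0)
  list(energy = spec$k / 2 * d^2, force = -spec$k * d)
}

#' Flat-bottom dihedral wall
#'
#' Penalizes the arc between 0 and 180 degrees (the syn-facing glycosidic
#' region) with a harmonic restraint measured from the nearer boundary, in
#' radians, under the half-k convention; angles in the anti region
#' (-180, 0] are free. Periodicity at +-180 degrees is respected.
#'
#' @param angle dihedral angle in degrees, in (-180, 180].
#' @param k force constant (kcal/mol/rad^2).
#' @return restraint energy (kcal/mol), vectorized.
#' @export
dihedral_wall <- function(angle, k = 10) {
  a <- ((angle + 180) %% 360) - 180   # wrap into (-180, 180]
  inside <- a > 0 & a < 180
  d <- pmin(a, 180 - a) * pi / 180    # distance to nearer boundary (rad)
  ifelse(inside, k / 2 * d^2, 0)
}

#' REST2 scaling factor
#'
#' `lambda = T_ref / T_eff`: the Hamiltonian scaling that makes a replica at
#' the reference temperature sample as if the solute were at the effective
#' temperature. For the 298-491 K ladder the hottest rung scales by 0.607.
#'
#' @param T_ref reference temperature (K).
#' @param T_eff effective temperature (K), `>= T_ref`.
#' @return scaling factor in (0, 1].
#' @export
rest2_lambda <- function(T_ref, T_eff) {
  if (T_ref <= 0 || T_eff <= 0) abort("temperatures must be positive")
  if (T_eff < T_ref) abort("T_eff must be >= T_ref")
  T_ref / T_eff
}

#' Geometric effective-temperature ladder
#'
#' Builds an `n_replicas`-rung geometric ladder from `T_ref` to `T_max` with
#' the corresponding strictly decreasing REST2 scaling factors.
#'
#' @param T_ref,T_max first and last effective temperatures (K).
#' @param n_replicas number of rungs, `>= 2`.
#' @return tibble with columns `replica`, `T_eff`, `lambda`.
#' @export
build_ladder <- function(T_ref, T_max, n_replicas) {
  if (n_replicas < 2) abort("need at least 2 replicas")
  if (T_max <= T_ref) abort("T_max must exceed T_ref")
  r <- (T_max / T_ref)^(1 / (n_replicas - 1))
  T_eff <- T_ref * r^(seq_len(n_replicas) - 1)
  tibble::tibble(replica = seq_len(n_replicas), T_eff = T_eff,
                 lambda = vapply(T_eff, function(t) rest2_lambda(T_ref, t),
                                 numeric(1)))
}

#' Metropolis replica-exchange acceptance
#'
#' Accepts a swap between replicas m and n with probability
#' `min(1, exp(-Delta))`,
#' `Delta = [(E_m_at_n + E_n_at_m) - (E_m_at_m + E_n_at_n)] / kT`, where
#' `E_a_at_b` is configuration a evaluated under Hamiltonian b.
#'
#' @param E_m_at_m,E_m_at_n,E_n_at_m,E_n_at_n cross-evaluated energies
#'   (kcal/mol).
#' @param kT thermal energy (kcal/mol).
#' @param draw uniform(0,1) random number; drawn internally if `NULL`.
#' @return logical: accept the exchange.
#' @export
exchange_accept <- function(E_m_at_m, E_m_at_n, E_n_at_m, E_n_at_n,
                            kT = KT_298, draw = NULL) {
  stopifnot(is.finite(c(E_m_at_m, E_m_at_n, E_n_at_m, E_n_at_n)))
  delta <- ((E_m_at_n + E_n_at_m) - (E_m_at_m + E_n_at_n)) / kT
  if (delta <= 0) return(TRUE)
  if (is.null(draw)) draw <- runif(1)
  draw < exp(-delta)
}

#' Single BAOAB Langevin step (reference implementation)
#'
#' One step of the BAOAB splitting at unit mass: half kick, half drift,
#' Ornstein-Uhlenbeck velocity refresh, half drift, half kick. With zero
#' friction the O step is the identity and the scheme reduces to velocity
#' Verlet. Uses R's RNG, so `set.seed()` makes trajectories reproducible.
#' The compiled driver [run_biased_sampling()] integrates the same scheme for
#' long runs.
#'
#' @param state list with numeric `x` and `v`.
#' @param provider an [energy_provider()].
#' @param dt time step.
#' @param friction friction coefficient (1/time), `>= 0`.
#' @param kT thermal energy (kcal/mol).
#' @return updated state list.
#' @export
langevin_step <- function(state, provider, dt, friction = 1, kT = KT_298) {
  if (dt <= 0 || friction < 0 || kT <= 0) abort("need dt > 0, friction >= 0, kT > 0")
  x <- state$x; v <- state$v
  if (any(!is.finite(x)) || any(!is.finite(v))) abort("non-finite state")
  v <- v - dt / 2 * provider$gradient(x)
  x <- x + dt / 2 * v
  if (friction > 0) {
    c1 <- exp(-friction * dt)
    v <- c1 * v + sqrt(kT * (1 - c1^2)) * rnorm(length(v))
  }
  x <- x + dt / 2 * v
  v <- v - dt / 2 * provider$gradient(x)
  list(x = x, v = v)
}

POTENTIAL_IDS <- c("harmonic" = 0L, "double-well-1d" = 1L,
                   "two-channel" = 2L, "muller-brown" = 3L)

#' Run biased Langevin sampling on a toy landscape
#'
#' Long-run driver (compiled): BAOAB Langevin dynamics on a built-in
#' landscape, optionally biased by 1D well-tempered metadynamics on a
#' collective variable and restrained by a one-sided wall on the orthogonal
#' distance z. The CV is either the first coordinate (`cv = "x"`) or a
#' tabulated pathCV (`cv = ` the result of [pathcv_tables()]), in which case
#' z comes from the same tables. Deterministic per seed.
#'
#' @param potential one of `"harmonic"`, `"double-well-1d"`, `"two-channel"`,
#'   `"muller-brown"`.
#' @param potential_params numeric parameter vector (see the corresponding
#'   `ep_*` constructors; harmonic: `c(k, center)`, double-well:
#'   `c(A, eps)`, two-channel: `unlist(two_channel_params())`).
#' @param x0 initial coordinates.
#' @param n_steps number of integrator steps.
#' @param dt,friction,kT integrator settings.
#' @param seed integer seed.
#' @param cv `"x"` or a [pathcv_tables()] list.
#' @param metad `NULL` or a [wt_metad_params()].
#' @param cv_range length-2 range of the biased CV (grid extent for the
#'   stored bias).
#' @param cv_bins bias grid nodes along the CV.
#' @param wall `NULL` or a [wall_spec()] applied to z (table mode only).
#' @param record_stride store every `record_stride`-th frame.
#' @return list with `colvar` (tibble: time, coordinates, `s`, `z`, `bias`),
#'   `hills` (tibble: time, center, height), and `bias_grid` (tibble: `s`,
#'   `bias` -- the final accumulated bias).
#' @export
run_biased_sampling <- function(potential, potential_params = NULL, x0,
                                n_steps, dt = 0.005, friction = 5,
                                kT = KT_298, seed = 1L, cv = "x",
                                metad = NULL, cv_range = c(-2, 2),
                                cv_bins = 201L, wall = NULL,
                                record_stride = 10L) {
  pid <- POTENTIAL_IDS[[match.arg(potential, names(POTENTIAL_IDS))]]
  if (is.null(potential_params))
    potential_params <- switch(as.character(pid),
      "0" = c(1, 0), "1" = c(1, 0), "2" = unlist(two_channel_params()),
      "3" = numeric(0))
  table_mode <- is.list(cv)
  if (table_mode) {
    tg <- c(cv$x[1], cv$x[2] - cv$x[1], length(cv$x),
            cv$y[1], cv$y[2] - cv$y[1], length(cv$y))
    s_tab <- as.numeric(cv$s); z_tab <- as.numeric(cv$z)
  } else {
    tg <- numeric(6); s_tab <- 0; z_tab <- 0
  }
  use_metad <- !is.null(metad)
  ns <- if (use_metad) as.integer(cv_bins) else 0L
  smin <- cv_range[1]
  dsg <- if (ns > 1) (cv_range[2] - cv_range[1]) / (ns - 1) else 1
  res <- withr::with_seed(as.integer(seed),
    .run_engine(pid, as.numeric(potential_params), as.numeric(x0),
                as.integer(n_steps), dt, friction, kT,
                as.integer(table_mode), s_tab, z_tab, tg,
                use_metad,
                if (use_metad) metad$height else 0,
                if (use_metad) metad$sigma_s else 1,
                if (use_metad) metad$bias_factor else Inf,
                if (use_metad) metad$stride else 0L,
                smin, dsg, ns,
                !is.null(wall),
                if (!is.null(wall)) wall$z0 else 0,
                if (!is.null(wall)) wall$k else 0,
                as.integer(record_stride)))
  dim_x <- length(x0)
  tr <- res$traj[seq_len(res$n_recorded), , drop = FALSE]
  cn <- c("time", paste0("x", seq_len(dim_x)), "s", "bias")
  colvar <- tibble::as_tibble(setNames(as.data.frame(tr), cn))
  colvar$z <- res$z
  hills <- tibble::tibble(time = res$hills[, 1], center = res$hills[, 2],
                          height = res$hills[, 3])
  bias_grid <- tibble::tibble(s = smin + dsg * (seq_len(max(ns, 1)) - 1),
                              bias = as.numeric(res$bias_grid))
  list(colvar = colvar, hills = hills, bias_grid = bias_grid,
       kT = kT, metad = metad)
}

#' Reconstruct a bias profile from a hill table
#'
#' Sums the recorded Gaussians on a grid, optionally restricted to a window
#' of deposition times -- used for time-averaged well-tempered free-energy
#' estimates.
#'
#' @param hills tibble with `center` and `height` columns (and `time`).
#' @param grid CV grid nodes.
#' @param sigma Gaussian width.
#' @param time_range optional length-2 inclusive window on `time`.
#' @return numeric bias values on `grid`.
#' @export
bias_from_hills <- function(hills, grid, sigma, time_range = NULL) {
  if (!is.null(time_range))
    hills <- hills[hills$time >= time_range[1] & hills$time <= time_range[2], ]
  b <- numeric(length(grid))
  for (i in seq_len(nrow(hills)))
    b <- b + hills$height[i] * exp(-0.5 * ((grid - hills$center[i]) / sigma)^2)
  b
}

#' Well-tempered free-energy estimate from deposited hills
#'
#' `F(s) = -(gamma/(gamma-1)) * V_bias(s) + const`, where `V_bias` is
#' averaged over bias snapshots in the final fraction of the deposition
#' history (time averaging washes out the hill-by-hill ripple of the
#' converged well-tempered bias). Min-shifted to zero.
#'
#' @param run result of [run_biased_sampling()] with metadynamics enabled.
#' @param average_over fraction of late deposition history to average
#'   (default final half); 0 uses only the final bias.
#' @param n_snapshots number of snapshots in the average.
#' @return tibble with `s` and `fes` (kcal/mol).
#' @export
metad_fes_estimate <- function(run, average_over = 0.5, n_snapshots = 20) {
  stopifnot(!is.null(run$metad))
  g <- run$metad$bias_factor
  pref <- if (is.finite(g)) g / (g - 1) else 1
  grid <- run$bias_grid$s
  hl <- run$hills
  t_end <- max(hl$time)
  if (average_over <= 0) {
    vb <- bias_from_hills(hl, grid, run$metad$sigma_s)
  } else {
    t0 <- t_end * (1 - average_over)
    ts <- seq(t0, t_end, length.out = n_snapshots)
    vb <- rowMeans(vapply(ts, function(tt)
      bias_from_hills(hl, grid, run$metad$sigma_s, c(0, tt)),
      numeric(length(grid))))
  }
  f <- -pref * vb
  tibble::tibble(s = grid, fes = f - min(f))
}
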