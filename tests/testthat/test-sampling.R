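test_that("langevin_step is seeded, reduces to velocity Verlet, conserves energy", {
  ep <- ep_harmonic(1, 0)
  s0 <- list(x = 1, v = 0)
  r1 <- withr::with_seed(4, {
    s <- s0; for (k in 1:100) s <- langevin_step(s, ep, 0.01, 1, KT298); s
  })
  r2 <- withr::with_seed(4, {
    s <- s0; for (k in 1:100) s <- langevin_step(s, ep, 0.01, 1, KT298); s
  })
  expect_identical(r1, r2)
  # zero friction: symplectic, energy conserved to 1e-4 over 1e4 steps
  s <- list(x = 1, v = 0)
  E0 <- ep$energy(s$x) + 0.5 * s$v^2
  for (k in 1:10000) s <- langevin_step(s, ep, 0.001, 0, KT298)
  expect_lt(abs(ep$energy(s$x) + 0.5 * s$v^2 - E0), 1e-4)
  expect_error(langevin_step(list(x = NaN, v = 0), ep, 0.01), "non-finite")
  expect_error(langevin_step(s, ep, -0.01), "dt > 0")
})

test_that("compiled driver agrees with the R reference in the deterministic limit", {
  ep <- ep_harmonic(2, 0.5)
  r <- run_biased_sampling("harmonic", c(2, 0.5), x0 = 1.3, n_steps = 200,
                           dt = 0.01, friction = 0, seed = 1, record_stride = 1)
  s <- list(x = 1.3, v = 0)
  xs <- numeric(201); xs[1] <- s$x
  for (k in 1:200) { s <- langevin_step(s, ep, 0.01, 0, KT298); xs[k + 1] <- s$x }
  expect_equal(r$colvar$x1, xs, tolerance = 1e-10)
})

test_that("long harmonic run satisfies equipartition", {
  r <- run_biased_sampling("harmonic", c(1, 0), x0 = 0, n_steps = 1e6,
                           dt = 0.01, friction = 2, kT = KT298, seed = 4,
                           record_stride = 10)
  expect_equal(var(r$colvar$x1), KT298 / 1, tolerance = 0.05)
  r2 <- run_biased_sampling("harmonic", c(1, 0), x0 = 0, n_steps = 1000,
                            dt = 0.01, friction = 2, seed = 4)
  r3 <- run_biased_sampling("harmonic", c(1, 0), x0 = 0, n_steps = 1000,
                            dt = 0.01, friction = 2, seed = 4)
  expect_identical(r2$colvar, r3$colvar)       # seed determinism
})

test_that("deposit_hill applies the well-tempered damping", {
  led <- hills_ledger(list(s = seq(-2, 2, by = 0.02)))
  p <- wt_metad_params()                        # h0 = 0.956, gamma = 35
  kT <- 0.5926
  led <- deposit_hill(led, p, 0, time = 1, kT = kT)
  expect_equal(led$hills$height[1], 0.956)
  led <- deposit_hill(led, p, 0, time = 2, kT = kT)
  expect_equal(led$hills$height[2], 0.956 * exp(-0.956 / (34 * kT)),
               tolerance = 1e-12)
  # standard-metadynamics limit: undamped heights
  led2 <- hills_ledger(list(s = seq(-2, 2, by = 0.02)))
  pinf <- wt_metad_params(bias_factor = Inf)
  for (k in 1:5) led2 <- deposit_hill(led2, pinf, 0.3, time = k, kT = kT)
  expect_true(all(led2$hills$height == 0.956))
  expect_error(deposit_hill(led, p, 5, kT = kT), "outside")
})

test_that("hill heights at a revisited point are non-increasing in time", {
  led <- hills_ledger(list(s = seq(0, 4, by = 0.05), z = seq(0, 2, by = 0.05)))
  p <- wt_metad_params(height = 0.5, sigma_s = 0.3, sigma_z = 0.2,
                       bias_factor = 10)
  withr::local_seed(8)
  pts <- cbind(runif(30, 1.4, 1.6), runif(30, 0.9, 1.1))
  for (k in 1:30) led <- deposit_hill(led, p, pts[k, ], time = k)
  # revisit one fixed point repeatedly
  for (k in 31:40) led <- deposit_hill(led, p, c(1.5, 1.0), time = k)
  h <- led$hills$height[31:40]
  expect_true(all(diff(h) < 0))
  expect_true(all(led$hills$height > 0))
})

test_that("wall energy is one-sided, C1 at the onset, and uses half-k", {
  ws <- wall_spec()                             # z0 = 0.81, k = 17.2
  expect_equal(wall_energy(0.5, ws)$energy, 0)
  expect_equal(wall_energy(0.81, ws)$energy, 0)
  expect_equal(wall_energy(0.81, ws)$force, 0)
  expect_equal(wall_energy(1.81, ws)$energy, 17.2 / 2)
  # C1 continuity by central finite difference across the onset
  h <- 1e-6
  num_dE <- (wall_energy(0.81 + h, ws)$energy -
               wall_energy(0.81 - h, ws)$energy) / (2 * h)
  expect_lt(abs(num_dE), 1e-5)
  zs <- seq(0.7, 1.0, by = 1e-4)
  dE <- diff(wall_energy(zs, ws)$energy) / 1e-4
  expect_lt(max(abs(diff(dE))), 0.01)           # derivative continuous
})

test_that("dihedral wall penalizes only the syn-facing arc", {
  expect_equal(dihedral_wall(-90), 0)
  expect_equal(dihedral_wall(90, k = 10), 10 / 2 * (pi / 2)^2)
  expect_equal(dihedral_wall(0), 0)
  expect_equal(dihedral_wall(180), 0)
  # zero slope at the boundary
  expect_lt(dihedral_wall(1e-4), 1e-10)
  # periodic wrap: 350 deg is -10 deg, allowed
  expect_equal(dihedral_wall(350), 0)
  ang <- seq(1, 179, by = 1)
  w <- dihedral_wall(ang)
  expect_equal(w, dihedral_wall(rev(ang)))      # symmetric about 90
})

test_that("REST2 lambda and ladder reproduce the printed scaling factors", {
  expect_equal(rest2_lambda(298, 298), 1.0)
  expect_equal(round(rest2_lambda(298, 491), 3), 0.607)
  expect_equal(rest2_lambda(150, 300), 0.5)
  expect_error(rest2_lambda(298, 200), ">=")
  lad <- build_ladder(298, 491, 10)
  expect_equal(nrow(lad), 10)
  expect_equal(lad$T_eff[1], 298)
  expect_equal(lad$T_eff[10], 491)
  ratios <- lad$T_eff[-1] / lad$T_eff[-10]
  expect_lt(max(ratios) - min(ratios), 1e-10)   # geometric
  expect_equal(lad$lambda, 298 / lad$T_eff)
  expect_true(all(diff(lad$lambda) < 0))
  expect_equal(round(lad$lambda[10], 3), 0.607)
  lad2 <- build_ladder(298, 491, 2)
  expect_equal(lad2$T_eff, c(298, 491))
  expect_error(build_ladder(298, 200, 4), "exceed")
})

test_that("exchange acceptance is Metropolis-correct", {
  expect_true(exchange_accept(1, 0.5, 2, 3, draw = 0.999))   # downhill
  expect_true(exchange_accept(1, 1, 2, 2, draw = 0.999))     # identical H
  # two-state toy: enumerate the exact expected acceptance and compare with
  # the empirical rate
  kT <- 1
  Em <- c(0, 1); En <- c(0, 2)                 # state energies under each H
  pm <- exp(-Em / kT); pm <- pm / sum(pm)
  pn <- exp(-En / kT); pn <- pn / sum(pn)
  exact <- 0
  for (i in 1:2) for (j in 1:2) {
    delta <- ((Em[j] + En[i]) - (Em[i] + En[j])) / kT
    exact <- exact + pm[i] * pn[j] * min(1, exp(-delta))
  }
  withr::local_seed(12)
  N <- 20000
  i <- sample(1:2, N, TRUE, pm); j <- sample(1:2, N, TRUE, pn)
  acc <- mapply(function(ii, jj)
    exchange_accept(Em[ii], Em[jj], En[ii], En[jj], kT = kT), i, j)
  se <- sqrt(exact * (1 - exact) / N)
  expect_lt(abs(mean(acc) - exact), 2 * se + 1e-3)
})

test_that("WT-MetaD recovers the double-well free energy within 0.3 kcal/mol", {
  A <- 1.2; eps <- 0.25; kT <- KT298
  mp <- wt_metad_params(height = 0.1, sigma_s = 0.15, sigma_z = 0.4,
                        bias_factor = 8, stride = 200)
  r <- run_biased_sampling("double-well-1d", c(A, eps), x0 = -1,
                           n_steps = 1e6, dt = 0.005, friction = 5, kT = kT,
                           seed = 7, metad = mp, cv_range = c(-1.8, 1.8),
                           cv_bins = 181L, record_stride = 20)
  est <- metad_fes_estimate(r)
  U <- function(x) A * (x^2 - 1)^2 + eps * x
  keep <- est$s > -1.45 & est$s < 1.45
  ref <- U(est$s[keep]); ref <- ref - min(ref)
  err <- (est$fes[keep] - min(est$fes[keep])) - ref
  err <- err - mean(err)                       # profiles defined up to a constant
  expect_lt(max(abs(err)), 0.3)
  # reweighted well populations against the Boltzmann ratio
  rw <- metad_reweight(r$colvar, kT = kT, bias_grid = r$bias_grid)
  pL <- sum(rw$weight[rw$s < 0]); pR <- sum(rw$weight[rw$s > 0])
  f <- function(x) exp(-U(x) / kT)
  ana <- integrate(f, -3, 0)$value / integrate(f, 0, 3)$value
  expect_lt(abs(pL / pR - ana) / ana, 0.10)
})
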