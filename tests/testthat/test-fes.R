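test_that("metad_reweight handles the unbiased limit and closed forms", {
  kT <- KT298
  cv <- tibble::tibble(time = 1:10, s = seq(0, 1, length.out = 10), bias = 0)
  w <- metad_reweight(cv, kT = kT)
  expect_equal(w$weight, rep(0.1, 10))
  expect_equal(sum(w$weight), 1, tolerance = 1e-10)
  two <- tibble::tibble(time = 1:2, s = c(0, 1), bias = c(0, kT * log(2)))
  w2 <- metad_reweight(two, kT = kT)
  expect_equal(w2$weight, c(1 / 3, 2 / 3), tolerance = 1e-12)
  expect_error(metad_reweight(tibble::tibble(s = 1)), "bias column")
})

test_that("binless_wham degenerate and invariance cases", {
  frames <- tibble::tibble(x = rnorm(50), run = "a")
  w <- binless_wham(frames, matrix(0, 50, 1))
  expect_equal(w$weight, rep(1 / 50, 50))
  # K = 1 with bias reduces exactly to metad_reweight
  b <- runif(50)
  w1 <- binless_wham(frames, matrix(b, 50, 1), kT = KT298)
  rw <- metad_reweight(tibble::tibble(s = frames$x, bias = b), kT = KT298)
  expect_equal(w1$weight, rw$weight, tolerance = 1e-10)
  # duplicating a run leaves the pooled estimate unchanged
  withr::local_seed(2)
  f2 <- tibble::tibble(x = c(rnorm(40, -1), rnorm(40, 1)),
                       run = rep(c("a", "b"), each = 40))
  B <- cbind((f2$x + 1)^2, (f2$x - 1)^2)
  base <- binless_wham(f2, B, kT = 1)
  dup <- binless_wham(
    dplyr::mutate(dplyr::bind_rows(f2, f2),
                  run = rep(c("a", "b", "a2", "b2"), each = 40)),
    rbind(B, B)[, c(1, 2, 1, 2)], kT = 1)
  expect_equal(dup$weight[1:80] / sum(dup$weight[1:80]), base$weight,
               tolerance = 1e-8)
  # run-order invariance
  perm <- c(41:80, 1:40)
  sw <- binless_wham(f2[perm, ], B[perm, c(2, 1)], kT = 1)
  expect_equal(sw$weight, base$weight[perm], tolerance = 1e-8)
})

test_that("binless_wham recovers the Gaussian umbrella closed form", {
  kT <- KT298; kh <- 1; ku <- 2; c1 <- -0.5; c2 <- 0.8
  kb <- kh + ku
  dana <- ku * kh * (c2^2 - c1^2) / (2 * kb)    # analytic f2 - f1
  reps <- withr::with_seed(31, {
    vapply(1:8, function(r) {
      n <- 2000
      x1 <- rnorm(n, ku * c1 / kb, sqrt(kT / kb))
      x2 <- rnorm(n, ku * c2 / kb, sqrt(kT / kb))
      fr <- tibble::tibble(x = c(x1, x2), run = rep(c("w1", "w2"), each = n))
      B <- cbind(ku / 2 * (fr$x - c1)^2, ku / 2 * (fr$x - c2)^2)
      fk <- attr(binless_wham(fr, B, kT = kT), "f_k")
      fk[2] - fk[1]
    }, numeric(1))
  })
  sigma <- sd(reps)
  expect_lt(abs(mean(reps) - dana), 3 * sigma / sqrt(8) + 1e-6)
})

test_that("binless_wham reports non-convergence and missing overlap", {
  fr <- tibble::tibble(x = c(-5, -5.1, 5, 5.1), run = c("a", "a", "b", "b"))
  B <- cbind(1e4 * (fr$x + 5)^2, 1e4 * (fr$x - 5)^2)
  w <- testthat::capture_warnings(binless_wham(fr, B, kT = 0.1))
  expect_true(any(grepl("overlap", w)))
  expect_error(binless_wham(fr[1:2, ], matrix(0, 3, 1)), "rows")
})

test_that("build_fes closed forms, masking, and Gaussian curvature", {
  kT <- KT298
  s <- weighted_samples(tibble::tibble(s = c(0.25, 0.75)),
                        weight = c(0.5, 0.5), kT = kT)
  fg <- build_fes(s, list(s = c(0, 0.5, 1)), n_blocks = 2)
  expect_equal(fg$F[1], fg$F[2])
  s2 <- weighted_samples(tibble::tibble(s = c(0.25, 0.75)),
                         weight = c(2, 1), kT = kT)
  fg2 <- build_fes(s2, list(s = c(0, 0.5, 1)), n_blocks = 2)
  expect_equal(fg2$F[2] - fg2$F[1], kT * log(2), tolerance = 1e-10)
  # unsampled bins masked, never zero-filled
  fg3 <- build_fes(s2, list(s = c(0, 0.3, 0.6, 0.9, 1.2)), n_blocks = 2)
  expect_true(is.na(fg3$F[2]))
  expect_false(fg3$sampled[2])
  expect_equal(min(fg3$F, na.rm = TRUE), 0)
  # Gaussian samples give a quadratic FES with matching curvature
  withr::local_seed(21)
  sg <- weighted_samples(tibble::tibble(s = rnorm(2e5, 0, 0.5)), kT = kT)
  fgg <- build_fes(sg, list(s = list(range = c(-1, 1), bins = 25)))
  td <- tidy(fgg)
  td <- td[td$sampled, ]
  fit <- lm(fes ~ I(s^2), data = td, weights = exp(-td$fes / kT))
  expect_equal(unname(coef(fit)[2]), kT / (2 * 0.5^2), tolerance = 0.1)
  expect_error(build_fes(s[0, ], list(s = c(0, 1))), "no samples")
})

test_that("fep_along_path is the 1D specialization with SEM", {
  withr::local_seed(4)
  s <- weighted_samples(tibble::tibble(s = runif(5000)), kT = KT298)
  fep <- fep_along_path(s, bins = 10, range = c(0, 1))
  expect_equal(nrow(fep), 10)
  expect_true(all(fep$sampled))
  expect_lt(max(fep$fes), 0.2)                 # uniform density -> flat
  expect_true(all(fep$sem >= 0))
})

test_that("block_sem matches closed forms", {
  expect_equal(block_sem(rep(3.7, 100), n_blocks = 5), 0)
  withr::local_seed(6)
  x <- rnorm(10000)
  est <- block_sem(x, n_blocks = 10)
  target <- 1 / sqrt(10000)
  # the SEM estimator from B blocks has relative sd ~ 1/sqrt(2(B-1))
  expect_lt(abs(est - target), 3 * target / sqrt(2 * 9))
  expect_error(block_sem(1:10, n_blocks = 1), "2 blocks")
  expect_error(block_sem(1:3, n_blocks = 5), "shorter")
})

test_that("property-map projection hits the endpoints and midpoints", {
  line <- function(dim3_axis) {
    m <- matrix(0, 5, 3)
    m[, dim3_axis] <- 0:4
    m
  }
  spec <- property_map_spec(list(milestone_path(line(1)),
                                 milestone_path(line(2)),
                                 milestone_path(line(3))))
  frames <- list(c(0, 0, 0), c(4, 0, 0), c(0, 2, 0))
  pm <- project_property_map(frames, spec)
  expect_equal(unname(unlist(pm[1, ])), c(0, 0, 0), tolerance = 0.02)
  expect_equal(pm$pm1[2], 1, tolerance = 0.02)
  expect_equal(pm$pm2[3], 0.5, tolerance = 1e-6)   # symmetry of the middle milestone
  expect_equal(pm$pm3[3], 0, tolerance = 0.02)
})

test_that("restraint correction: inactive wall, quadrature oracle", {
  ws <- wall_spec(z0 = 0.81, k = 17.2)
  kT <- KT298
  inside <- weighted_samples(tibble::tibble(z = runif(100, 0, 0.7)), kT = kT)
  r0 <- restraint_correction(inside, ws)
  expect_equal(as.numeric(r0), 0)
  expect_equal(attr(r0, "note"), "wall never active")
  stiff <- restraint_correction(inside, wall_spec(z0 = 0.81, k = 34.4))
  expect_equal(as.numeric(stiff), 0)
  # analytic exponential z-distribution, restrained by the wall:
  # quadrature oracle for -kT ln(Z_unrestrained / Z_restrained)
  tau <- 0.5
  wallE <- function(z) ifelse(z > ws$z0, ws$k / 2 * (z - ws$z0)^2, 0)
  zg <- seq(0, 4, length.out = 20001)
  pu <- exp(-zg / tau)
  pr <- pu * exp(-wallE(zg) / kT)
  oracle <- -kT * log(sum(pu) / sum(pr))
  samp <- weighted_samples(tibble::tibble(z = zg), weight = pr, kT = kT)
  est <- restraint_correction(samp, ws)
  expect_equal(est, oracle, tolerance = 0.01)
  expect_lt(est, 0)                            # relaxation can only lower F
})

test_that("gHBfix bookkeeping is linear and matches the worked number", {
  expect_equal(ghbfix_shift(-9, 24, 0.5), 3)
  expect_equal(ghbfix_shift(-4.2, 0, 0.5), -4.2)
  expect_equal(ghbfix_shift(-9, 24, 0), -9)
  # linearity in n and per_bond
  expect_equal(ghbfix_shift(0, 7, 0.3) + ghbfix_shift(0, 5, 0.3),
               ghbfix_shift(0, 12, 0.3))
  expect_equal(ghbfix_shift(0, 6, 0.4), 2 * ghbfix_shift(0, 6, 0.2))
  expect_error(ghbfix_shift(0, -1), ">= 0")
})

test_that("weight normalization holds after every estimator", {
  withr::local_seed(14)
  cv <- tibble::tibble(s = rnorm(200), bias = runif(200, 0, 3))
  expect_equal(sum(metad_reweight(cv, kT = 1)$weight), 1, tolerance = 1e-10)
  fr <- tibble::tibble(x = rnorm(100), run = rep(c("a", "b"), each = 50))
  B <- cbind(fr$x^2, (fr$x - 0.5)^2)
  expect_equal(sum(binless_wham(fr, B, kT = 1)$weight), 1, tolerance = 1e-10)
})
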