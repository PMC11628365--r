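test_that("cube combinatorics match the folding-state counts", {
  expect_equal(cube_counts(3), list(vertices = 8, edges = 12, monotone_paths = 6))
  expect_equal(cube_counts(2), list(vertices = 4, edges = 4, monotone_paths = 2))
  expect_equal(cube_counts(1), list(vertices = 2, edges = 1, monotone_paths = 1))
  expect_error(cube_counts(0), ">= 1")
  cb <- folding_cube(3)
  expect_equal(nrow(cb$vertices), 8)
  expect_equal(nrow(cb$edges), 12)
  expect_true(all(vapply(seq_len(nrow(cb$edges)), function(k)
    sum(cb$vertices[cb$edges$from[k], ] != cb$vertices[cb$edges$to[k], ]),
    integer(1)) == 1))
})

test_that("monotone pathway enumeration is complete, sorted and duplicate-free", {
  cb3 <- folding_cube(3)
  p3 <- enumerate_monotone_paths(cb3)
  expect_length(p3, 6)
  keys <- vapply(p3, function(p) paste(p$labels, collapse = ">"), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  for (p in p3) {
    expect_equal(nrow(p$states), 4)
    expect_equal(unname(p$states[1, ]), c(0L, 0L, 0L))
    expect_equal(unname(p$states[4, ]), c(1L, 1L, 1L))
    expect_true(all(rowSums(p$states) == 0:3))
  }
  # two-hairpin case reproduces the two triplex channels
  cb2 <- folding_cube(2)
  p2 <- enumerate_monotone_paths(cb2)
  expect_length(p2, 2)
  expect_equal(p2[[1]]$labels, c("ss", "Cs", "CC"))
  expect_equal(p2[[2]]$labels, c("ss", "sC", "CC"))
  expect_length(enumerate_monotone_paths(folding_cube(1)), 1)
})

test_that("dijkstra_mep on a flat surface takes a shortest path with zero barrier", {
  fg <- fes_grid(list(x = 1:4, y = 1:4), matrix(1, 4, 4))
  r <- dijkstra_mep(fg, c(1, 1), c(4, 4))
  expect_equal(nrow(r$nodes), 7)               # Manhattan-shortest
  expect_equal(r$barrier, 0)
  r2 <- dijkstra_mep(fg, c(1, 1), c(4, 4))
  expect_identical(r$nodes, r2$nodes)          # deterministic tie-break
})

test_that("dijkstra_mep crosses the saddle of a two-basin surface", {
  x <- seq(-1.5, 1.5, length.out = 21)
  U <- outer(x, x, function(a, b) 3 * (a^2 - 1)^2 + 3 * b^2)
  fg <- fes_grid(list(x = x, y = x), U)
  st <- c(which.min(abs(x + 1)), 11); en <- c(which.min(abs(x - 1)), 11)
  r <- dijkstra_mep(fg, st, en)
  # path must pass through the saddle node at (0, 0)
  expect_true(any(r$nodes[, 1] == 11 & r$nodes[, 2] == 11))
  expect_equal(r$barrier, U[st[1], 11] * -1 + 3, tolerance = 1e-10)
  orc <- minimax_threshold_oracle(fg$F, st, en)
  expect_equal(max(r$profile), orc)
})

test_that("both MEP modes equal exhaustive enumeration on small random grids", {
  withr::local_seed(33)
  for (rep in 1:4) {
    Fv <- matrix(runif(16, 0, 5), 4, 4)
    fg <- fes_grid(list(x = 1:4, y = 1:4), Fv)
    st <- c(1, 1); en <- c(4, 4)
    paths <- enumerate_lattice_paths(c(4, 4), st, en, array(TRUE, c(4, 4)))
    for (mode in c("minimax", "integrated")) {
      costs <- t(vapply(paths, function(p) path_cost(fg$F, p, mode),
                        numeric(2)))
      best <- min(costs[, 1])
      r <- dijkstra_mep(fg, st, en, mode = mode)
      got <- if (mode == "minimax") max(r$profile) else sum(r$profile)
      expect_equal(got, best, tolerance = 1e-12)
      if (mode == "minimax") {
        # among max-optimal paths, the sum tie-break is also optimal
        best_sum <- min(costs[costs[, 1] <= best + 1e-12, 2])
        expect_equal(sum(r$profile), best_sum, tolerance = 1e-12)
      }
    }
  }
})

test_that("minimax optimum on 5x5x5 grids matches the threshold oracle", {
  withr::local_seed(44)
  for (rep in 1:3) {
    Fv <- array(runif(125, 0, 8), c(5, 5, 5))
    fg <- fes_grid(list(x = 1:5, y = 1:5, z = 1:5), Fv)
    st <- c(1, 1, 1); en <- c(5, 5, 5)
    r <- dijkstra_mep(fg, st, en, mode = "minimax")
    orc <- minimax_threshold_oracle(fg$F, st, en)
    expect_equal(max(r$profile), orc, tolerance = 1e-12)
    # spot-check dominance over random alternative monotone-ish paths
    for (k in 1:100) {
      moves <- sample(rep(1:3, each = 4))
      node <- st; mx <- fg$F[matrix(st, 1)]
      for (d in moves) {
        node[d] <- node[d] + 1
        mx <- max(mx, fg$F[matrix(node, 1)])
      }
      expect_lte(max(r$profile), mx + 1e-12)
    }
  }
})

test_that("integrated mode agrees with an independent igraph shortest path", {
  skip_if_not_installed("igraph")
  withr::local_seed(55)
  fg <- fes_grid(list(x = 1:6, y = 1:6), matrix(runif(36, 0, 4), 6, 6))
  Fv <- fg$F                                    # min-shifted node energies
  r <- dijkstra_mep(fg, c(1, 1), c(6, 6), mode = "integrated")
  # node-weighted shortest path via edge weights (F_u + F_v)/2
  id <- function(i, j) (j - 1) * 6 + i
  ed <- c(); wts <- c()
  for (i in 1:6) for (j in 1:6) {
    if (i < 6) { ed <- c(ed, id(i, j), id(i + 1, j))
                 wts <- c(wts, (Fv[i, j] + Fv[i + 1, j]) / 2) }
    if (j < 6) { ed <- c(ed, id(i, j), id(i, j + 1))
                 wts <- c(wts, (Fv[i, j] + Fv[i, j + 1]) / 2) }
  }
  g <- igraph::make_graph(ed, directed = FALSE)
  dist <- igraph::distances(g, v = id(1, 1), to = id(6, 6), weights = wts)
  expect_equal(sum(r$profile),
               as.numeric(dist) + (Fv[1, 1] + Fv[6, 6]) / 2,
               tolerance = 1e-10)
})

test_that("reversing endpoints shifts the minimax barrier by F(start) - F(end)", {
  withr::local_seed(66)
  Fv <- matrix(runif(25, 0, 5), 5, 5)
  fg <- fes_grid(list(x = 1:5, y = 1:5), Fv)
  f <- dijkstra_mep(fg, c(1, 1), c(5, 5))
  b <- dijkstra_mep(fg, c(5, 5), c(1, 1))
  expect_equal(f$barrier - b$barrier,
               fg$F[5, 5] - fg$F[1, 1], tolerance = 1e-12)
})

test_that("path_barrier closed forms", {
  expect_equal(path_barrier(c(5, 4, 3, 1)), 0)
  expect_equal(path_barrier(c(0, 5, 2)), 5)
  expect_equal(path_barrier(0), 0)
  expect_error(path_barrier(numeric(0)), "empty")
})

test_that("masked/unsampled nodes block the search unless capped", {
  Fv <- matrix(0, 3, 3)
  Fv[2, ] <- NA                                 # impassable wall
  fg <- fes_grid(list(x = 1:3, y = 1:3), Fv)
  expect_error(dijkstra_mep(fg, c(1, 1), c(3, 1)), "unreachable")
  r <- dijkstra_mep(fg, c(1, 1), c(3, 1), cap = 10)
  expect_equal(max(r$profile), 10)
})

test_that("sector MEPs traverse a symmetric corner-basin cube correctly", {
  # separable 3D surface: double well along each axis, basins at every corner
  x <- seq(0, 1, length.out = 7)
  B <- function(t) 16 * 2 * (t * (1 - t))^2    # 0 at ends, max 2 at center
  Fv <- array(0, c(7, 7, 7))
  for (i in 1:7) for (j in 1:7) for (k in 1:7)
    Fv[i, j, k] <- B(x[i]) + B(x[j]) + B(x[k])
  fg <- fes_grid(list(c1 = x, c2 = x, c3 = x), Fv)
  cb <- folding_cube(3, folded_labels = c("C", "H", "C"))
  pws <- enumerate_monotone_paths(cb)
  meps <- lapply(pws, function(p) sector_mep(fg, cb, p))
  sigs <- vapply(meps, function(m) paste(m$nodes, collapse = ","), character(1))
  expect_equal(anyDuplicated(sigs), 0L)        # six mutually distinct MEPs
  for (q in seq_along(meps)) {
    m <- meps[[q]]; p <- pws[[q]]
    # projection visits the pathway's anchors in order
    corner_steps <- apply(p$states, 1, function(st)
      which(apply(m$nodes, 1, function(nd)
        all(nd == ifelse(st == 1L, 7L, 1L))))[1])
    expect_true(all(diff(corner_steps) > 0))
    expect_equal(attr(m, "anchors"), p$labels)
  }
  barriers <- vapply(meps, function(m) m$barrier, numeric(1))
  expect_lt(max(barriers) - min(barriers), 1e-10)   # symmetric surface
  # block the middle edge unique to the c1 -> c2 -> c3 pathway
  Fv2 <- Fv
  Fv2[4:7, 4, 1:4] <- NA
  fg2 <- fes_grid(list(c1 = x, c2 = x, c3 = x), Fv2)
  ok <- 0; failed <- 0
  for (p in pws) {
    res <- tryCatch(sector_mep(fg2, cb, p), error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1 else ok <- ok + 1
  }
  expect_equal(failed, 1)
  expect_equal(ok, 5)
})
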