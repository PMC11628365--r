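# Independent oracles: plain scalar transcriptions of the defining formulas,
# written separately from the package implementations they check.

KT298 <- 0.5926

# --- eRMSD oracle: direct nested-loop evaluation of the G-vector metric ----
oracle_base_frame <- function(structure, rid, purine) {
  a <- structure$atoms
  g <- function(nm) as.numeric(a[a$res_id == rid & a$atom == nm, c("x", "y", "z")][1, ])
  c2 <- g("C2"); c4 <- g("C4"); c6 <- g("C6")
  o <- (c2 + c4 + c6) / 3
  if (purine) { p1 <- c2; p2 <- c4 } else { p1 <- c4; p2 <- c2 }
  x <- (p1 - o); x <- x / sqrt(sum(x * x))
  y <- (p2 - o); y <- y - sum(y * x) * x; y <- y / sqrt(sum(y * y))
  z <- c(x[2] * y[3] - x[3] * y[2], x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  list(o = o, R = rbind(x, y, z))
}

oracle_ermsd <- function(A, B, cutoff = 2.4, sp = 5, sn = 3) {
  bs <- A$bases[A$bases$is_base, ]
  n <- nrow(bs)
  gvec <- function(structure, i, j) {
    fi <- oracle_base_frame(structure, bs$res_id[i], bs$purine[i])
    fj <- oracle_base_frame(structure, bs$res_id[j], bs$purine[j])
    r <- as.numeric(fi$R %*% (fj$o - fi$o)) / c(sp, sp, sn)
    rr <- sqrt(sum(r * r))
    if (rr >= cutoff) return(c(0, 0, 0, 0))
    gam <- pi / cutoff
    c(sin(gam * rr) * r / rr, 1 + cos(gam * rr))
  }
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- gvec(A, i, j) - gvec(B, i, j)
    acc <- acc + sum(d * d)
  }
  sqrt(acc / n)
}

# --- pathCV oracle: literal evaluation of the defining sums ---------------
oracle_path_sz <- function(d, lambda) {
  num <- 0; den <- 0
  for (i in seq_along(d)) {
    e <- exp(-lambda * d[i]^2)
    num <- num + i * e
    den <- den + e
  }
  list(s = num / den, z = -log(den) / lambda)
}

# --- improved-tangent weighted mix at a local extremum --------------------
oracle_tangent_extremum <- function(xm, x0, xp, Em, E0, Ep) {
  tp <- xp - x0; tm <- x0 - xm
  dmax <- max(abs(Ep - E0), abs(Em - E0))
  dmin <- min(abs(Ep - E0), abs(Em - E0))
  tau <- if (Ep > Em) tp * dmax + tm * dmin else tp * dmin + tm * dmax
  tau / sqrt(sum(tau^2))
}

# --- Mueller-Brown stationary points by multi-start gradient-norm descent --
mb_energy <- function(p) {
  A <- c(-200, -100, -170, 15)
  aa <- c(-1, -1, -6.5, 0.7); bb <- c(0, 0, 11, 0.6); cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1); y0 <- c(0, 0.5, 1.5, 1)
  dx <- p[1] - x0; dy <- p[2] - y0
  sum(A * exp(aa * dx^2 + bb * dx * dy + cc * dy^2))
}

mb_saddle_oracle <- function() {
  gn2 <- function(p) {
    h <- 1e-6
    gx <- (mb_energy(p + c(h, 0)) - mb_energy(p - c(h, 0))) / (2 * h)
    gy <- (mb_energy(p + c(0, h)) - mb_energy(p - c(0, h))) / (2 * h)
    gx^2 + gy^2
  }
  starts <- expand.grid(x = seq(-1.5, 1.2, by = 0.1),
                        y = seq(-0.3, 2.0, by = 0.1))
  pts <- list()
  for (k in seq_len(nrow(starts))) {
    o <- suppressWarnings(stats::optim(as.numeric(starts[k, ]), gn2,
                                       method = "BFGS",
                                       control = list(maxit = 1000,
                                                      reltol = 1e-16)))
    if (o$value < 1e-6) pts[[length(pts) + 1]] <- o$par
  }
  pts <- unique(lapply(pts, function(p) round(p, 4)))
  hess_signature <- function(p) {
    h <- 1e-4
    H <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2) {
      ei <- ej <- c(0, 0); ei[i] <- h; ej[j] <- h
      H[i, j] <- (mb_energy(p + ei + ej) - mb_energy(p + ei - ej) -
                  mb_energy(p - ei + ej) + mb_energy(p - ei - ej)) / (4 * h^2)
    }
    sum(eigen(H, symmetric = TRUE)$values < 0)
  }
  saddles <- Filter(function(p) hess_signature(p) == 1, pts)
  sort(vapply(saddles, mb_energy, numeric(1)))
}

# --- exhaustive simple-path enumeration on small 2D lattices --------------
enumerate_lattice_paths <- function(dims, start, end, ok) {
  paths <- list()
  visit <- function(node, seen, trail) {
    if (all(node == end)) {
      paths[[length(paths) + 1]] <<- trail
      return(invisible())
    }
    for (d in seq_along(dims)) for (s in c(-1L, 1L)) {
      nb <- node; nb[d] <- nb[d] + s
      if (any(nb < 1) || any(nb > dims)) next
      key <- paste(nb, collapse = ",")
      if (key %in% seen || !ok[matrix(nb, 1)]) next
      visit(nb, c(seen, key), c(trail, list(nb)))
    }
  }
  visit(start, paste(start, collapse = ","), list(start))
  paths
}

path_cost <- function(Fv, path, mode) {
  f <- vapply(path, function(idx) Fv[matrix(idx, 1)], numeric(1))
  if (mode == "minimax") c(max(f), sum(f)) else c(sum(f), sum(f))
}

# minimax optimum by threshold connectivity: the smallest F-level at which
# start and end join through nodes of F <= level (exact, independent of
# Dijkstra)
minimax_threshold_oracle <- function(Farr, start, end, ok = NULL) {
  dims <- dim(Farr)
  if (is.null(ok)) ok <- array(TRUE, dims)
  ok <- ok & is.finite(Farr)
  levels <- sort(unique(Farr[ok]))
  connected_at <- function(level) {
    pass <- ok & (Farr <= level)
    if (!pass[matrix(start, 1)] || !pass[matrix(end, 1)]) return(FALSE)
    # flood fill
    frontier <- list(start)
    seen <- array(FALSE, dims)
    seen[matrix(start, 1)] <- TRUE
    while (length(frontier)) {
      nxt <- list()
      for (node in frontier) {
        for (d in seq_along(dims)) for (s in c(-1L, 1L)) {
          nb <- node; nb[d] <- nb[d] + s
          if (any(nb < 1) || any(nb > dims)) next
          if (seen[matrix(nb, 1)] || !pass[matrix(nb, 1)]) next
          seen[matrix(nb, 1)] <- TRUE
          nxt[[length(nxt) + 1]] <- nb
        }
      }
      frontier <- nxt
    }
    seen[matrix(end, 1)]
  }
  for (lv in levels) if (connected_at(lv)) return(lv)
  Inf
}

# --- fixtures --------------------------------------------------------------
# Synthetic G-quartet-like arrangement: four guanine residues rotated by 90
# degrees about z, each with its O6 at distance r_o6 from the origin, plus
# optional channel ions. Purely geometric fixture for the ion-coordination
# observable.
make_quartet <- function(r_o6 = 2.8, n_stack = 1, ions = NULL) {
  one <- generate_strand("G", "extended", seed = 1)
  rows <- list()
  rid <- 0
  for (lev in seq_len(n_stack)) {
    for (k in 0:3) {
      rid <- rid + 1
      g <- one
      o6 <- as.numeric(g$atoms[g$atoms$atom == "O6", c("x", "y", "z")])
      g$atoms$x <- g$atoms$x - o6[1] + r_o6
      g$atoms$y <- g$atoms$y - o6[2]
      g$atoms$z <- g$atoms$z - o6[3]
      g <- transform_rigid(g, angles = c(0, 0, k * pi / 2))
      g$atoms$z <- g$atoms$z + (lev - 1) * 3.4
      g$atoms$res_id <- rid
      rows[[rid]] <- g$atoms
    }
  }
  atoms <- dplyr::bind_rows(rows)
  dna_structure(atoms, ions = ions)
}
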