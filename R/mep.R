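# Folding-state cube combinatorics and minimum-energy-path extraction from
# free-energy grids by Dijkstra search (minimax and integrated modes).

#' Construct a free-energy grid directly from values
#'
#' Constructor for synthetic surfaces (tests, toy workflows): node-centered
#' axes plus a free-energy array. Values are min-shifted to zero over
#' sampled (finite) nodes; non-finite entries become masked nodes.
#'
#' @param axes named list of node-center coordinate vectors.
#' @param values array of free energies (kcal/mol), dim matching `axes`.
#' @param sem optional array of per-node SEM.
#' @param kT thermal energy label.
#' @return a `fes_grid`.
#' @export
fes_grid <- function(axes, values, sem = NULL, kT = KT_298) {
  values <- array(values, dim = vapply(axes, length, integer(1)))
  sampled <- is.finite(values)
  if (!any(sampled)) abort("all nodes masked")
  values[!sampled] <- NA_real_
  values <- values - min(values, na.rm = TRUE)
  if (is.null(sem)) sem <- array(0, dim = dim(values))
  structure(list(axes = axes, breaks = NULL, F = values, sem = sem,
                 sampled = sampled, kT = kT), class = "fes_grid")
}

#' Folding-state cube
#'
#' The n-dimensional hypercube whose vertices are the binary folded/unfolded
#' combinations of n hairpin coordinates and whose edges are single-
#' coordinate folding steps. Display labels render unfolded coordinates as
#' `"s"` and folded ones by a per-coordinate character (default `"C"`),
#' supplied via `folded_labels` since folded coordinates may carry cross or
#' Hoogsteen-hairpin character.
#'
#' @param n number of hairpin coordinates.
#' @param folded_labels character vector of length n for folded coordinates.
#' @return a `folding_cube` with `vertices` (2^n x n 0/1 matrix), `labels`,
#'   and `edges` (tibble `from`/`to` of vertex row indices).
#' @export
folding_cube <- function(n, folded_labels = rep("C", n)) {
  if (n < 1) abort("cube dimension must be >= 1")
  v <- as.matrix(do.call(expand.grid, rep(list(0:1), n)))
  colnames(v) <- paste0("c", seq_len(n))
  lab <- apply(v, 1, function(row)
    paste(ifelse(row == 1, folded_labels, "s"), collapse = ""))
  e <- list()
  for (i in seq_len(nrow(v))) for (j in seq_len(nrow(v)))
    if (i < j && sum(v[i, ] != v[j, ]) == 1)
      e[[length(e) + 1]] <- c(i, j)
  edges <- tibble::tibble(from = vapply(e, `[`, integer(1), 1),
                          to = vapply(e, `[`, integer(1), 2))
  structure(list(n = n, vertices = v, labels = lab, edges = edges,
                 folded_labels = folded_labels), class = "folding_cube")
}

#' Cube combinatorics
#'
#' Vertices, edges and monotone (all-unfolded to all-folded) paths of the
#' n-dimensional folding cube: `(2^n, n 2^(n-1), n!)`. For the three-hairpin
#' quadruplex this is 8 folding states, 12 folding steps and 6 unique
#' sequential pathways; for the two-hairpin triplex, 4/4/2.
#'
#' @param n cube dimension, `>= 1`.
#' @return named list `vertices`, `edges`, `monotone_paths`.
#' @export
cube_counts <- function(n) {
  if (n < 1) abort("cube dimension must be >= 1")
  list(vertices = 2^n, edges = n * 2^(n - 1), monotone_paths = factorial(n))
}

#' Enumerate monotone folding pathways
#'
#' All `n!` orderings in which the n coordinates can fold one at a time,
#' each a sequence of `n + 1` vertices from all-unfolded to all-folded,
#' sorted lexicographically by flip order, without duplicates.
#'
#' @param cube a [folding_cube()].
#' @return list of pathways; each is a list with `states` (an `(n+1) x n`
#'   0/1 matrix) and `labels`.
#' @export
enumerate_monotone_paths <- function(cube) {
  n <- cube$n
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  ords <- perms(seq_len(n))
  key <- vapply(ords, function(o) paste(o, collapse = "."), character(1))
  ords <- ords[order(key)]
  lapply(ords, function(o) {
    states <- matrix(0L, n + 1, n)
    for (k in seq_len(n)) {
      states[k + 1, ] <- states[k, ]
      states[k + 1, o[k]] <- 1L
    }
    labels <- apply(states, 1, function(row)
      paste(ifelse(row == 1, cube$folded_labels, "s"), collapse = ""))
    list(order = o, states = states, labels = labels)
  })
}

# ---- Dijkstra MEP -----------------------------------------------------------

neighbors_of <- function(idx, dims) {
  n <- length(dims)
  out <- list()
  for (d in seq_len(n)) for (s in c(-1L, 1L)) {
    j <- idx
    j[d] <- j[d] + s
    if (j[d] >= 1 && j[d] <= dims[d]) out[[length(out) + 1]] <- j
  }
  out
}

lin_index <- function(idx, dims) {
  k <- idx[1]
  mult <- 1L
  for (d in seq_along(dims)[-1]) {
    mult <- mult * dims[d - 1]
    k <- k + (idx[d] - 1L) * mult
  }
  k
}

unlin_index <- function(k, dims) {
  idx <- integer(length(dims))
  k <- k - 1L
  for (d in seq_along(dims)) {
    idx[d] <- k %% dims[d] + 1L
    k <- k %/% dims[d]
  }
  idx
}

#' Minimum-energy path on a free-energy grid by Dijkstra search
#'
#' Lattice search between two sampled nodes over face neighbors (no
#' diagonals). `mode = "minimax"` minimizes the highest free energy touched
#' along the path -- the physically meaningful "lowest highest point"
#' criterion -- breaking ties by the smaller sum of node free energies, then
#' by node order. `mode = "integrated"` minimizes the plain sum of node free
#' energies. Unsampled nodes are impassable unless `cap` assigns them a
#' finite penalty energy.
#'
#' @param fes a `fes_grid`.
#' @param start,end per-axis node index vectors (1-based).
#' @param mode `"minimax"` or `"integrated"`.
#' @param cap optional energy (kcal/mol) assigned to unsampled nodes to make
#'   them passable; `NULL` leaves them blocked.
#' @param mask optional logical array of admissible nodes (sector search).
#' @return a `mep_result`: node index matrix, per-node free energies,
#'   barrier (max F minus start F), and the mode used.
#' @export
dijkstra_mep <- function(fes, start, end, mode = c("minimax", "integrated"),
                         cap = NULL, mask = NULL) {
  mode <- match.arg(mode)
  dims <- dim(fes$F)
  if (is.null(dims)) dims <- length(fes$F)
  Fv <- as.numeric(fes$F)
  ok <- as.logical(fes$sampled)
  if (!is.null(cap)) {
    Fv[!ok] <- cap
    ok[!ok] <- TRUE
  }
  if (!is.null(mask)) ok <- ok & as.logical(mask)
  s <- lin_index(as.integer(start), dims)
  e <- lin_index(as.integer(end), dims)
  if (!ok[s] || !ok[e]) abort("start/end must be sampled (and unmasked) nodes")
  nV <- prod(dims)
  INF <- Inf
  cost1 <- rep(INF, nV)    # minimax: running max; integrated: running sum
  cost2 <- rep(INF, nV)    # minimax tie-break: running sum
  prev <- rep(NA_integer_, nV)
  done <- rep(FALSE, nV)
  cost1[s] <- Fv[s]
  cost2[s] <- Fv[s]
  # precompute neighbor offsets once
  repeat {
    u <- which.min(ifelse(done | !is.finite(cost1), NA, cost1))
    if (!length(u) || is.na(u)) break
    cand <- which(!done & cost1 == cost1[u])
    if (length(cand) > 1) {               # tie-break by sum, then node order
      u <- cand[order(cost2[cand], cand)][1]
    }
    if (u == e) break
    done[u] <- TRUE
    ui <- unlin_index(u, dims)
    for (vi in neighbors_of(ui, dims)) {
      v <- lin_index(vi, dims)
      if (done[v] || !ok[v]) next
      if (mode == "minimax") {
        nc1 <- max(cost1[u], Fv[v])
        nc2 <- cost2[u] + Fv[v]
      } else {
        nc1 <- cost1[u] + Fv[v]
        nc2 <- nc1
      }
      if (nc1 < cost1[v] || (nc1 == cost1[v] && nc2 < cost2[v]) ||
          (nc1 == cost1[v] && nc2 == cost2[v] && (is.na(prev[v]) || u < prev[v]))) {
        cost1[v] <- nc1
        cost2[v] <- nc2
        prev[v] <- u
      }
    }
  }
  if (!is.finite(cost1[e])) {
    abort(sprintf("end node unreachable from start: %d of %d nodes are blocked",
                  sum(!ok), nV))
  }
  node <- e
  path <- integer(0)
  while (!is.na(node)) {
    path <- c(node, path)
    if (node == s) break
    node <- prev[node]
  }
  idx <- t(vapply(path, unlin_index, integer(length(dims)), dims = dims))
  colnames(idx) <- names(fes$axes)
  profile <- Fv[path]
  structure(list(nodes = idx, profile = profile,
                 coords = tibble::as_tibble(
                   purrr::imap_dfc(fes$axes, function(a, nm)
                     tibble::tibble(!!nm := a[idx[, nm]]))),
                 barrier = path_barrier(profile), mode = mode),
            class = "mep_result")
}

#' Barrier of a free-energy profile
#'
#' `max(F) - F[1]`: the highest point relative to the start.
#'
#' @param profile numeric per-node free energies along a path.
#' @return barrier (kcal/mol).
#' @export
path_barrier <- function(profile) {
  if (!length(profile)) abort("empty profile")
  max(profile) - profile[1]
}

#' @export
print.mep_result <- function(x, ...) {
  cat("<mep_result> ", nrow(x$nodes), " nodes, mode = ", x$mode,
      ", barrier = ", signif(x$barrier, 4), " kcal/mol\n", sep = "")
  invisible(x)
}

#' @export
tidy.mep_result <- function(x, ...) {
  out <- x$coords
  out$step <- seq_len(nrow(out))
  out$fes <- x$profile
  dplyr::relocate(out, "step")
}

#' @export
glance.mep_result <- function(x, ...) {
  tibble::tibble(nodes = nrow(x$nodes), barrier = x$barrier, mode = x$mode,
                 f_start = x$profile[1], f_end = x$profile[length(x$profile)])
}

#' Sector-constrained MEP along a folding pathway
#'
#' Follows one monotone pathway of the folding cube across an n-dimensional
#' FES: each cube vertex is anchored to the grid corner matching its
#' folded/unfolded tuple, and each folding step is searched with
#' [dijkstra_mep()] restricted to the sector it spans -- the flipping
#' coordinate ranges freely while every other coordinate is confined to the
#' grid half matching its state at that step. Returns the concatenated MEP,
#' whose projection visits the pathway's vertices in order.
#'
#' @param fes an n-dimensional `fes_grid`.
#' @param cube a [folding_cube()] with `n` matching the grid dimension.
#' @param pathway one element of [enumerate_monotone_paths()].
#' @param mode,cap passed to [dijkstra_mep()].
#' @return a `mep_result` with an `anchors` attribute (vertex labels).
#' @export
sector_mep <- function(fes, cube, pathway, mode = "minimax", cap = NULL) {
  dims <- dim(fes$F)
  n <- cube$n
  if (length(dims) != n) abort("grid dimension must match cube dimension")
  corner <- function(state)
    ifelse(state == 1L, dims, 1L)
  half <- function(d, state) {
    if (state == 1L) seq(floor(dims[d] / 2) + 1L, dims[d])
    else seq(1L, ceiling(dims[d] / 2))
  }
  all_nodes <- matrix(FALSE, 0, 0)
  nodes <- NULL; profile <- NULL
  for (k in seq_len(nrow(pathway$states) - 1)) {
    v <- pathway$states[k, ]; w <- pathway$states[k + 1, ]
    flip <- which(v != w)
    mask <- array(TRUE, dim = dims)
    for (d in seq_len(n)) {
      if (d == flip) next
      keep <- half(d, v[d])
      slc <- rep(list(quote(expr = )), n)
      idxs <- lapply(seq_len(n), function(dd)
        if (dd == d) setdiff(seq_len(dims[dd]), keep) else seq_len(dims[dd]))
      mask[as.matrix(do.call(expand.grid, idxs))] <- FALSE
    }
    st <- corner(v); en <- corner(w)
    if (!fes$sampled[matrix(st, 1)] || !fes$sampled[matrix(en, 1)])
      abort(sprintf("anchor region for step %s -> %s is unsampled",
                    pathway$labels[k], pathway$labels[k + 1]))
    seg <- dijkstra_mep(fes, st, en, mode = mode, cap = cap, mask = mask)
    if (is.null(nodes)) {
      nodes <- seg$nodes; profile <- seg$profile
    } else {
      nodes <- rbind(nodes, seg$nodes[-1, , drop = FALSE])
      profile <- c(profile, seg$profile[-1])
    }
  }
  out <- structure(list(nodes = nodes, profile = profile,
                        coords = tibble::as_tibble(
                          purrr::imap_dfc(fes$axes, function(a, nm)
                            tibble::tibble(!!nm := a[nodes[, nm]]))),
                        barrier = path_barrier(profile), mode = mode),
                   class = "mep_result")
  attr(out, "anchors") <- pathway$labels
  out
}
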