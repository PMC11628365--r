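# Free-energy estimation: metadynamics reweighting, binless WHAM across
# biased runs, property-map projection, FES grids with block standard
# errors, restraint-bias corrections and gHBfix bookkeeping.

#' Weighted sample set
#'
#' A tibble of per-frame CV values carrying normalized statistical weights
#' (column `weight`), a source-run label (column `run`) and the sampling
#' temperature as `kT` attribute. The common currency between reweighting,
#' WHAM and FES construction.
#'
#' @param data data.frame of per-frame CV values.
#' @param weight per-frame weights (any scale; normalized to sum 1).
#' @param run source-run label(s).
#' @param kT thermal energy (kcal/mol).
#' @return a `weighted_samples` tibble.
#' @export
weighted_samples <- function(data, weight = NULL, run = "run1", kT = KT_298) {
  out <- tibble::as_tibble(data)
  if (is.null(weight)) weight <- rep(1, nrow(out))
  if (any(weight < 0) || !all(is.finite(weight))) abort("weights must be finite and >= 0")
  sw <- sum(weight)
  if (sw <= 0) abort("weights sum to zero")
  out$weight <- weight / sw
  if (!"run" %in% names(out)) out$run <- run
  attr(out, "kT") <- kT
  class(out) <- c("weighted_samples", class(out))
  out
}

samples_kT <- function(samples, kT = NULL) {
  if (!is.null(kT)) kT else attr(samples, "kT") %||% KT_298
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reweight a metadynamics time series
#'
#' Assigns each retained frame the weight `exp(+V_bias/kT)` (normalized),
#' where `V_bias` is the bias at the frame's CV location. By default the
#' frame's recorded bias column is used; supplying `bias_grid` (a tibble
#' `s`/`bias`, e.g. the final accumulated grid of a run) switches to the
#' final-bias convention: every frame is weighted by the *final* bias at its
#' CV value, which absorbs the time-dependent well-tempered offset c(t) into
#' the normalization. An initial transient is discarded.
#'
#' @param colvar tibble with CV columns and a `bias` column (kcal/mol).
#' @param kT thermal energy (kcal/mol).
#' @param bias_grid optional tibble (`s`, `bias`) for final-bias weighting;
#'   requires an `s` column in `colvar`.
#' @param discard_fraction fraction of initial frames dropped as transient
#'   (default 0.25 when a bias grid is given, else 0).
#' @return a [weighted_samples()] tibble.
#' @export
metad_reweight <- function(colvar, kT = KT_298, bias_grid = NULL,
                           discard_fraction = if (is.null(bias_grid)) 0 else 0.25) {
  colvar <- tibble::as_tibble(colvar)
  n0 <- floor(nrow(colvar) * discard_fraction)
  if (n0 > 0) colvar <- colvar[-seq_len(n0), ]
  if (!is.null(bias_grid)) {
    if (!"s" %in% names(colvar)) abort("final-bias reweighting needs an s column")
    vb <- stats::approx(bias_grid$s, bias_grid$bias, xout = colvar$s,
                        rule = 2)$y
  } else {
    if (!"bias" %in% names(colvar)) abort("colvar lacks a bias column")
    vb <- colvar$bias
  }
  if (any(!is.finite(vb))) abort("non-finite bias values")
  w <- exp((vb - max(vb)) / kT)
  weighted_samples(colvar[setdiff(names(colvar), "weight")], weight = w, kT = kT)
}

#' Binless WHAM over multiple biased runs
#'
#' Self-consistent multistate reweighting without histogramming: given K
#' biased runs pooled into one frame set and the bias energy of every run's
#' Hamiltonian evaluated at every pooled frame, iterates the run free
#' energies
#' \deqn{e^{-f_k/kT} = \sum_i w_i e^{-b_k(x_i)/kT}, \quad
#'       w_i \propto 1 / \sum_k N_k e^{(f_k - b_k(x_i))/kT}}
#' until the largest free-energy update falls below `tol`. With a single run
#' this reduces exactly to [metad_reweight()]'s `exp(+b/kT)` weights.
#'
#' @param frames pooled tibble of frames with a `run` column (factor/char).
#' @param bias_matrix N x K matrix: `bias_matrix[i, k]` is the bias energy of
#'   run k's Hamiltonian at frame i (kcal/mol).
#' @param kT thermal energy (kcal/mol).
#' @param tol convergence threshold on run free energies (kcal/mol).
#' @param max_iter iteration cap.
#' @return a [weighted_samples()] tibble with attributes `f_k` (converged
#'   run free energies, first run = 0) and `iterations`.
#' @export
binless_wham <- function(frames, bias_matrix, kT = KT_298, tol = 1e-7,
                         max_iter = 1e5) {
  frames <- tibble::as_tibble(frames)
  B <- as.matrix(bias_matrix)
  K <- ncol(B); N <- nrow(B)
  if (N != nrow(frames)) abort("bias_matrix rows must match frames")
  if (!"run" %in% names(frames)) frames$run <- "run1"
  runs <- unique(frames$run)
  if (length(runs) != K) abort("number of runs must match bias_matrix columns")
  Nk <- as.numeric(table(factor(frames$run, levels = runs)))
  f <- numeric(K)
  expB <- exp(-B / kT)               # N x K
  orphan <- rowSums(expB) == 0     # zero density under every run's Hamiltonian
  if (any(orphan)) {
    warn(sprintf(paste("%d of %d pooled frames have zero density under every",
                       "run and were dropped; runs lack overlap there"),
                 sum(orphan), N))
  }
  it <- 0
  repeat {
    it <- it + 1
    denom <- as.numeric(expB %*% (Nk * exp(f / kT)))   # sum_k N_k e^{(f_k - b_k)/kT}
    w <- ifelse(denom > 0, 1 / denom, 0)
    zk <- as.numeric(crossprod(expB, w))               # sum_i w_i e^{-b_k/kT}
    fnew <- -kT * log(zk)
    fnew <- fnew - fnew[1]
    if (any(!is.finite(fnew)))
      abort("a run's normalization vanished during iteration; runs have no usable overlap")
    res <- max(abs(fnew - f))
    f <- fnew
    if (res < tol) break
    if (it >= max_iter)
      abort(sprintf("binless WHAM did not converge: residual %.3g after %d iterations",
                    res, it))
  }
  # overlap diagnostic: a run whose frames carry (almost) no density under
  # every other run cannot be tied into the common free-energy scale
  if (K > 1) {
    for (k in seq_len(K)) {
      own <- frames$run == runs[k]
      other <- expB[own, -k, drop = FALSE]
      if (all(rowSums(other) < 1e-300))
        warn(sprintf("run '%s' has no overlap with any other run; its free-energy offset is unconstrained", runs[k]))
    }
  }
  out <- weighted_samples(frames[setdiff(names(frames), "weight")],
                          weight = w, kT = kT)
  attr(out, "f_k") <- setNames(f, runs)
  attr(out, "iterations") <- it
  out
}

#' Property-map specification
#'
#' One milestone path per folding coordinate (three for the full
#' three-hairpin quadruplex case); each component of the property map is the
#' normalized pathCV progress of a frame along its path.
#'
#' @param paths list of `milestone_path` objects.
#' @return a `property_map_spec`.
#' @export
property_map_spec <- function(paths) {
  if (!length(paths)) abort("need at least one component path")
  paths <- lapply(paths, function(p) { p$normalize <- TRUE; p })
  structure(list(paths = paths), class = "property_map_spec")
}

#' Project frames onto a property-map CV
#'
#' @param frames list of structures/points, or (for abstract 2D components)
#'   a tibble whose rows are points.
#' @param spec a [property_map_spec()].
#' @return tibble with one normalized progress column per component
#'   (`pm1`, `pm2`, ...), values in `[0, 1]` for frames between the path
#'   endpoints.
#' @export
project_property_map <- function(frames, spec) {
  if (is.data.frame(frames))
    frames <- lapply(seq_len(nrow(frames)), function(i) as.numeric(frames[i, ]))
  vals <- purrr::map(frames, function(fr)
    vapply(spec$paths, function(p) path_s(fr, p), numeric(1)))
  m <- do.call(rbind, vals)
  colnames(m) <- paste0("pm", seq_along(spec$paths))
  tibble::as_tibble(m)
}

# ---- FES grids --------------------------------------------------------------

#' Build an N-dimensional free-energy grid from weighted samples
#'
#' Bins the samples on the requested axes and sets
#' `F(node) = -kT ln(sum of weights in node)`, min-shifted so the lowest
#' sampled node is zero. Unsampled nodes are masked (`NA` free energy), never
#' zero-filled. Per-node SEM comes from block analysis: the node weight is
#' re-estimated on `n_blocks` contiguous frame blocks and the SEM of
#' `-kT ln w` is propagated as `kT * sem(w) / w`.
#'
#' @param samples a [weighted_samples()] tibble.
#' @param axes named list: for each CV column, either a vector of bin-edge
#'   breaks or `list(range = c(lo, hi), bins = n)`.
#' @param kT thermal energy; defaults to the samples' attribute.
#' @param n_blocks blocks for the per-node SEM (default 5).
#' @return a `fes_grid` object.
#' @export
build_fes <- function(samples, axes, kT = NULL, n_blocks = 5) {
  kT <- samples_kT(samples, kT)
  if (!nrow(samples)) abort("no samples")
  breaks <- purrr::map(axes, function(a) {
    if (is.list(a)) seq(a$range[1], a$range[2], length.out = a$bins + 1)
    else a
  })
  nms <- names(axes)
  if (!all(nms %in% names(samples))) abort("axis names must match sample columns")
  nbin <- vapply(breaks, function(b) length(b) - 1L, integer(1))
  idx <- purrr::imap(breaks, function(b, nm) {
    i <- findInterval(samples[[nm]], b, rightmost.closed = TRUE)
    i[i < 1 | i > length(b) - 1] <- NA_integer_
    i
  })
  keep <- Reduce(`&`, lapply(idx, function(i) !is.na(i)))
  flat <- rep(1L, nrow(samples))
  mult <- 1L
  for (d in seq_along(nbin)) {
    flat <- flat + (idx[[d]] - 1L) * mult
    mult <- mult * nbin[d]
  }
  w <- samples$weight
  tot <- numeric(prod(nbin))
  tw <- tapply(w[keep], flat[keep], sum)
  tot[as.integer(names(tw))] <- tw
  Farr <- array(ifelse(tot > 0, -kT * log(tot), NA_real_), dim = nbin)
  Farr <- Farr - min(Farr, na.rm = TRUE)
  # block SEM on node weights
  blocks <- cut(seq_len(nrow(samples)), n_blocks, labels = FALSE)
  bw <- matrix(0, prod(nbin), n_blocks)
  for (b in seq_len(n_blocks)) {
    sel <- keep & blocks == b
    if (any(sel)) {
      tb <- tapply(w[sel], flat[sel], sum)
      bw[as.integer(names(tb)), b] <- tb
    }
  }
  bw <- sweep(bw, 2, colSums(bw) + .Machine$double.xmin, "/")
  semw <- apply(bw, 1, sd) / sqrt(n_blocks)
  sem <- array(ifelse(tot > 0, kT * semw / (tot / sum(tot[tot > 0])), NA_real_),
               dim = nbin)
  centers <- purrr::map(breaks, function(b) (head(b, -1) + tail(b, -1)) / 2)
  names(centers) <- nms
  structure(list(axes = centers, breaks = breaks, F = Farr, sem = sem,
                 sampled = !is.na(Farr), kT = kT), class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat("<fes_grid> ", paste(vapply(x$axes, length, integer(1)), collapse = " x "),
      " nodes (", sum(x$sampled), " sampled), F in [0, ",
      signif(max(x$F, na.rm = TRUE), 4), "] kcal/mol\n", sep = "")
  invisible(x)
}

#' @export
tidy.fes_grid <- function(x, ...) {
  g <- do.call(expand.grid, c(x$axes, KEEP.OUT.ATTRS = FALSE))
  out <- tibble::as_tibble(g)
  out$fes <- as.numeric(x$F)
  out$sem <- as.numeric(x$sem)
  out$sampled <- as.numeric(x$sampled) > 0
  out
}

#' @export
glance.fes_grid <- function(x, ...) {
  tibble::tibble(dims = length(x$axes),
                 nodes = prod(vapply(x$axes, length, integer(1))),
                 sampled = sum(x$sampled),
                 f_max = max(x$F, na.rm = TRUE),
                 sem_median = stats::median(x$sem[x$sampled]),
                 kT = x$kT)
}

#' 1D free-energy profile along the path CV
#'
#' Binned `-kT ln` density along the progress coordinate with per-bin block
#' SEM; empty bins are masked. The 1D specialization of [build_fes()].
#'
#' @param samples a [weighted_samples()] tibble with an `s` column.
#' @param bins number of bins or a break vector.
#' @param range CV range when `bins` is a count.
#' @inheritParams build_fes
#' @return tibble with `s`, `fes`, `sem`, `sampled`.
#' @export
fep_along_path <- function(samples, bins = 50, range = NULL, kT = NULL,
                           n_blocks = 5) {
  if (!"s" %in% names(samples)) abort("samples lack an s column")
  ax <- if (length(bins) > 1) list(s = bins)
        else list(s = list(range = range %||% base::range(samples$s), bins = bins))
  fg <- build_fes(samples, ax, kT = kT, n_blocks = n_blocks)
  tidy(fg)
}

#' Block standard error of a (weighted) series mean
#'
#' Splits the series into `n_blocks` contiguous, equal blocks, takes the
#' weighted mean within each block, and returns
#' `sd(block means) / sqrt(n_blocks)`.
#'
#' @param x numeric series.
#' @param weights optional per-element weights.
#' @param n_blocks number of blocks, `>= 2` (default 5).
#' @return SEM estimate.
#' @export
block_sem <- function(x, weights = NULL, n_blocks = 5) {
  if (n_blocks < 2) abort("need at least 2 blocks")
  if (length(x) < n_blocks) abort("series shorter than the number of blocks")
  if (is.null(weights)) weights <- rep(1, length(x))
  b <- cut(seq_along(x), n_blocks, labels = FALSE)
  means <- vapply(seq_len(n_blocks), function(k)
    weighted.mean(x[b == k], weights[b == k]), numeric(1))
  sd(means) / sqrt(n_blocks)
}

#' Restraint-relaxation free-energy correction
#'
#' Correction for the bias introduced by the one-sided wall on the
#' orthogonal-distance coordinate: from samples of z drawn in the
#' *restrained* ensemble,
#' \deqn{\Delta\Delta G = -kT \ln \langle e^{+U_{wall}(z)/kT}\rangle_{restr}}
#' the free-energy change of relaxing the wall, to be added to the
#' restrained minimum's free energy (it is `<= 0`: releasing the restraint
#' can only open configuration space). Returns 0 with a note when no sample
#' lies beyond the wall onset.
#'
#' @param z_samples a [weighted_samples()] tibble with a `z` column.
#' @param spec a [wall_spec()].
#' @param kT thermal energy.
#' @return correction (kcal/mol) with attribute `note` when the wall never
#'   engaged.
#' @export
restraint_correction <- function(z_samples, spec = wall_spec(), kT = NULL) {
  kT <- samples_kT(z_samples, kT)
  if (!"z" %in% names(z_samples)) abort("samples lack a z column")
  z <- z_samples$z; w <- z_samples$weight
  if (!any(z > spec$z0)) {
    out <- 0
    attr(out, "note") <- "wall never active"
    return(out)
  }
  u <- wall_energy(z, spec)$energy / kT
  -kT * (log(sum(w * exp(u - max(u)))) + max(u) - log(sum(w)))
}

#' Remove the per-bond H-bond stabilization from a folding free energy
#'
#' The gHBfix potential stabilizes each native hydrogen bond by a fixed
#' increment; a folded state supported by `n` native H-bonds absent in the
#' unfolded state is stabilized by `n * per_bond` in total. This helper
#' reports what the folding free energy would be without that support:
#' `dG_without = dG_with + n * per_bond` (removing the stabilization raises
#' the folded state). With dG = -9 kcal/mol, 24 bonds and 0.5 kcal/mol per
#' bond the unfixed estimate is +3 kcal/mol.
#'
#' @param dG_with_fix folding free energy with the H-bond support (kcal/mol).
#' @param n_native_hbonds native H-bonds unique to the folded state.
#' @param per_bond per-bond stabilization (kcal/mol, default 0.5).
#' @return folding free energy without the support (kcal/mol).
#' @export
ghbfix_shift <- function(dG_with_fix, n_native_hbonds, per_bond = 0.5) {
  if (n_native_hbonds < 0) abort("n_native_hbonds must be >= 0")
  dG_with_fix + n_native_hbonds * per_bond
}
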