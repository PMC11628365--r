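# COLVAR/HILLS-style TSV adapters, FES serialization, run configuration and
# the toy workflow driver binding the modules into a runnable pipeline.

#' Read a COLVAR-style time series
#'
#' Whitespace-delimited numeric table with a `#! FIELDS ...` header naming
#' the columns (the convention of common biasing engines). Unknown columns
#' are preserved verbatim. Rows whose column count disagrees with the header
#' and non-finite bias values are reported with their line number.
#'
#' @param path file path.
#' @return tibble with the named columns.
#' @export
read_colvar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^#! FIELDS", lines[1]))
    abort(paste(path, "lacks a '#! FIELDS' header"))
  fields <- strsplit(sub("^#! FIELDS\\s+", "", lines[1]), "\\s+")[[1]]
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  rows <- strsplit(trimws(lines[body]), "\\s+")
  nbad <- which(lengths(rows) != length(fields))
  if (length(nbad))
    abort(sprintf("line %d of %s has %d columns, header names %d",
                  body[nbad[1]], path, lengths(rows)[nbad[1]], length(fields)))
  m <- matrix(as.numeric(unlist(rows)), ncol = length(fields), byrow = TRUE)
  colnames(m) <- fields
  out <- tibble::as_tibble(m)
  if ("bias" %in% fields && any(!is.finite(out$bias))) {
    bad <- which(!is.finite(out$bias))[1]
    abort(sprintf("non-finite bias value at data row %d (line %d) of %s",
                  bad, body[bad], path))
  }
  out
}

#' Write a COLVAR-style time series
#'
#' @param df tibble/data.frame of numeric columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_colvar <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(df), collapse = " ")), con)
  utils::write.table(format(as.data.frame(df), digits = 17, trim = TRUE,
                            scientific = NA),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_colvar
#' @export
read_hills <- function(path) read_colvar(path)

#' @rdname write_colvar
#' @param hills tibble with `time`, center column(s), sigma column(s),
#'   `height`.
#' @export
write_hills <- function(hills, path) write_colvar(hills, path)

#' Serialize / read a free-energy grid as a dense TSV table
#'
#' Axis headers (`#! AXIS name n`) followed by one row per node: axis
#' coordinates, free energy, SEM and the sampled flag. Masked nodes are
#' written with `nan` free energy.
#'
#' @param fes a `fes_grid`.
#' @param path output path.
#' @return `path` invisibly (`write_fes`) or the reconstructed `fes_grid`
#'   (`read_fes`).
#' @export
write_fes <- function(fes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(fes$axes))
    writeLines(sprintf("#! AXIS %s %d", nm, length(fes$axes[[nm]])), con)
  td <- tidy(fes)
  writeLines(paste("#! FIELDS", paste(names(td), collapse = " ")), con)
  utils::write.table(format(as.data.frame(td), digits = 17, trim = TRUE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ax <- grep("^#! AXIS", lines, value = TRUE)
  meta <- do.call(rbind, strsplit(sub("^#! AXIS ", "", ax), " "))
  fl <- grep("^#! FIELDS", lines, value = TRUE)[1]
  fields <- strsplit(sub("^#! FIELDS\\s+", "", fl), "\\s+")[[1]]
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rows <- strsplit(trimws(body), "\\s+")
  m <- suppressWarnings(matrix(as.numeric(unlist(rows)), ncol = length(fields),
                               byrow = TRUE))
  colnames(m) <- fields
  df <- tibble::as_tibble(m)
  axes <- lapply(seq_len(nrow(meta)), function(i) sort(unique(df[[meta[i, 1]]])))
  names(axes) <- meta[, 1]
  dims <- as.integer(meta[, 2])
  Farr <- array(NA_real_, dims)
  sarr <- array(NA_real_, dims)
  idx <- sapply(seq_along(axes), function(d)
    match(df[[names(axes)[d]]], axes[[d]]))
  Farr[idx] <- df$fes
  sarr[idx] <- df$sem
  fes_grid(axes, Farr, sem = sarr)
}

# ---- run configuration & workflow ------------------------------------------

#' Default configuration of the bundled two-channel toy workflow
#'
#' End-to-end pipeline on the [ep_two_channel()] surface: locate the basin
#' minima, NEB-optimize one band per channel, build padded pathCVs from the
#' optimized images, run one walled well-tempered metadynamics simulation
#' per channel, WHAM-merge the two runs, rebuild the 2D FES and extract both
#' channel MEPs.
#'
#' @param seed base integer seed (each stochastic stage derives its own
#'   stream as `seed + stage offset`).
#' @param n_steps integrator steps per metadynamics run.
#' @return a named configuration list.
#' @export
toy_2d_config <- function(seed = 1L, n_steps = 400000L) {
  list(
    workflow = "toy-2d",
    seed = as.integer(seed),
    surface = two_channel_params(),
    neb = list(n_images = 21, k_spring = 5, steps = 4000, dt = 0.01, tol = 1e-3),
    pathcv = list(grid_x = seq(-1.8, 1.8, length.out = 61),
                  grid_y = seq(-1.8, 1.8, length.out = 61)),
    metad = list(height = 0.15, sigma_s = 0.6, sigma_z = 0.4, bias_factor = 8,
                 stride = 250L),
    wall = list(z0 = 0.81, k = 17.2),
    sampling = list(n_steps = as.integer(n_steps), dt = 0.005, friction = 5,
                    kT = KT_298, record_stride = 10L),
    fes = list(bins = 42L, range_x = c(-1.6, 1.6), range_y = c(-1.6, 1.6)),
    milestone_files = character()
  )
}

validate_config <- function(config) {
  req <- c("workflow", "seed", "surface", "neb", "pathcv", "metad", "wall",
           "sampling", "fes")
  miss <- setdiff(req, names(config))
  if (length(miss))
    abort(paste("config lacks fields:", paste(miss, collapse = ", ")))
  for (f in config$milestone_files %||% character())
    if (!file.exists(f)) abort(paste("milestone file not found:", f))
  invisible(config)
}

stage_manifest <- function(dir, stage, inputs, outputs, seed = NA) {
  mf <- list(stage = stage, inputs = inputs, seed = seed,
             package_version = as.character(utils::packageVersion("quadfold")),
             outputs = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(mf, file.path(dir, paste0("manifest-", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run a configured workflow end to end
#'
#' Executes the stage chain of the toy two-channel pipeline (minima ->
#' NEB -> pathCV -> walled WT-MetaD per channel -> binless WHAM -> FES ->
#' MEPs), writing every intermediate (COLVAR/HILLS TSV, FES TSV, MEP TSV +
#' JSON summary) with a per-stage JSON manifest carrying seeds and
#' checksums. Re-running with the same config reproduces every artifact
#' bit-exactly.
#'
#' @param config list from [toy_2d_config()], or a path to a YAML/JSON file
#'   with the same fields.
#' @param out_dir artifact directory (created).
#' @return (invisibly) a list with the pooled samples, the `fes_grid`, both
#'   `mep_result`s and the artifact directory.
#' @export
run_workflow <- function(config = toy_2d_config(), out_dir = tempfile("quadfold-run-")) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- config$surface
  provider <- ep_two_channel(sp)
  # stage 1: basin minima
  mins <- lapply(list(c(-1, -1), c(1, -1)), function(p0)
    stats::optim(p0, provider$energy, provider$gradient, method = "BFGS")$par)
  # stage 2: NEB per channel (upper channel via an elevated initial band)
  nb <- config$neb
  bands <- lapply(c(lower = -1, upper = 1), function(yc) {
    b <- interpolate_band(mins[[1]], mins[[2]], nb$n_images,
                          k_spring = nb$k_spring)
    # bow the initial band through the requested channel
    for (i in seq_along(b$images)) {
      t <- (i - 1) / (nb$n_images - 1)
      b$images[[i]][2] <- b$images[[i]][2] + (yc - b$images[[i]][2]) *
        sin(pi * t)^2
    }
    optimize_band(b, provider, steps = nb$steps, dt = nb$dt, tol = nb$tol)
  })
  # stage 3: padded pathCVs + lookup tables
  gx <- config$pathcv$grid_x; gy <- config$pathcv$grid_y
  paths <- lapply(bands, function(ob) {
    m <- do.call(rbind, ob$band$images)
    pad_path(m)
  })
  tables <- lapply(paths, function(p) pathcv_tables(p, gx, gy))
  # stage 4: walled WT-MetaD per channel
  mp <- wt_metad_params(height = config$metad$height,
                        sigma_s = config$metad$sigma_s,
                        sigma_z = config$metad$sigma_z,
                        bias_factor = config$metad$bias_factor,
                        stride = config$metad$stride)
  ws <- wall_spec(config$wall$z0, config$wall$k)
  sm <- config$sampling
  n_mil <- length(paths[[1]]$milestones)
  runs <- purrr::imap(tables, function(tb, nm) {
    off <- if (nm == "lower") 11L else 12L
    run_biased_sampling("two-channel", unlist(sp),
                        x0 = mins[[1]], n_steps = sm$n_steps, dt = sm$dt,
                        friction = sm$friction, kT = sm$kT,
                        seed = config$seed + off, cv = tb, metad = mp,
                        cv_range = c(1, n_mil), cv_bins = 2L * n_mil + 1L,
                        wall = ws, record_stride = sm$record_stride)
  })
  for (nm in names(runs)) {
    write_colvar(runs[[nm]]$colvar[, c("time", "x1", "x2", "s", "z", "bias")],
                 file.path(out_dir, paste0("colvar-", nm, ".tsv")))
    write_hills(runs[[nm]]$hills, file.path(out_dir, paste0("hills-", nm, ".tsv")))
  }
  stage_manifest(out_dir, "sampling", list(workflow = config$workflow),
                 file.path(out_dir, c(paste0("colvar-", names(runs), ".tsv"),
                                      paste0("hills-", names(runs), ".tsv"))),
                 seed = config$seed)
  # stage 5: binless WHAM over both runs
  pooled <- wham_pool(runs, tables, ws, kT = sm$kT)
  # stage 6: 2D FES
  fg <- build_fes(pooled, axes = list(
    x1 = list(range = config$fes$range_x, bins = config$fes$bins),
    x2 = list(range = config$fes$range_y, bins = config$fes$bins)))
  write_fes(fg, file.path(out_dir, "fes.tsv"))
  # stage 7: MEPs through each channel
  nearest_sampled <- function(target, mask) {
    idx <- which(fg$sampled & mask, arr.ind = TRUE)
    d2 <- (fg$axes$x1[idx[, 1]] - target[1])^2 +
      (fg$axes$x2[idx[, 2]] - target[2])^2
    as.integer(idx[which.min(d2), ])
  }
  meps <- lapply(c(lower = -1, upper = 1), function(side) {
    mask <- array(TRUE, dim(fg$F))
    ys <- fg$axes$x2
    if (side < 0) mask[, ys > 0.4] <- FALSE else mask[, ys < -0.4] <- FALSE
    st <- nearest_sampled(c(mins[[1]][1], side), mask)
    en <- nearest_sampled(c(mins[[2]][1], side), mask)
    dijkstra_mep(fg, st, en, mode = "minimax", mask = mask)
  })
  for (nm in names(meps)) {
    utils::write.table(tidy(meps[[nm]]),
                       file.path(out_dir, paste0("mep-", nm, ".tsv")),
                       quote = FALSE, row.names = FALSE, sep = "\t")
    jsonlite::write_json(glance(meps[[nm]]),
                         file.path(out_dir, paste0("mep-", nm, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage_manifest(out_dir, "analysis", list(workflow = config$workflow),
                 file.path(out_dir, c("fes.tsv", paste0("mep-", names(meps), ".tsv"))),
                 seed = config$seed)
  invisible(list(runs = runs, pooled = pooled, fes = fg, meps = meps,
                 bands = bands, paths = paths, tables = tables,
                 minima = mins, out_dir = out_dir))
}

#' Pool walled metadynamics runs with binless WHAM
#'
#' Builds the pooled frame set and the run-by-frame bias matrix (each run's
#' final metadynamics bias evaluated at the frame's progress under that
#' run's pathCV, plus that run's wall energy at the frame's orthogonal
#' distance) and calls [binless_wham()].
#'
#' @param runs named list of [run_biased_sampling()] results (table mode).
#' @param tables the matching [pathcv_tables()] list.
#' @param wall the shared [wall_spec()].
#' @param kT thermal energy.
#' @param discard_fraction initial transient dropped from each run.
#' @return pooled [weighted_samples()].
#' @export
wham_pool <- function(runs, tables, wall, kT = KT_298, discard_fraction = 0.25) {
  frames <- purrr::imap_dfr(runs, function(r, nm) {
    cv <- r$colvar
    cv <- cv[-seq_len(floor(nrow(cv) * discard_fraction)), ]
    cv$run <- nm
    cv
  })
  interp2 <- function(tb, what, x, y) {
    # bilinear interpolation matching the engine's lookup
    fx <- findInterval(x, tb$x, all.inside = TRUE)
    fy <- findInterval(y, tb$y, all.inside = TRUE)
    tx <- pmin(pmax((x - tb$x[fx]) / diff(tb$x)[fx], 0), 1)
    ty <- pmin(pmax((y - tb$y[fy]) / diff(tb$y)[fy], 0), 1)
    M <- tb[[what]]
    M[cbind(fx, fy)] * (1 - tx) * (1 - ty) +
      M[cbind(fx + 1, fy)] * tx * (1 - ty) +
      M[cbind(fx, fy + 1)] * (1 - tx) * ty +
      M[cbind(fx + 1, fy + 1)] * tx * ty
  }
  B <- vapply(names(runs), function(nm) {
    tb <- tables[[nm]]
    sk <- interp2(tb, "s", frames$x1, frames$x2)
    zk <- interp2(tb, "z", frames$x1, frames$x2)
    bg <- runs[[nm]]$bias_grid
    stats::approx(bg$s, bg$bias, xout = sk, rule = 2)$y +
      wall_energy(zk, wall)$energy
  }, numeric(nrow(frames)))
  binless_wham(frames, B, kT = kT)
}

#' Read a YAML or JSON run configuration
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste("config not found:", path))
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
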