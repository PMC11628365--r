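#' @useDynLib quadfold, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data abort warn
#' @importFrom generics tidy glance
#' @importFrom stats rnorm runif sd setNames var weighted.mean
#' @importFrom utils head tail
NULL

#' @export
generics::tidy

#' @export
generics::glance

# ---- base geometry templates ------------------------------------------------
# Idealized planar nucleobases in a local frame: six-membered ring as a regular
# hexagon (bond length 1.39 A) in the xy plane, exocyclic atoms placed at
# chemically sensible in-plane positions, plus C1'/O4' sugar stubs carrying the
# glycosidic attachment. Good enough for metric and observable testing; these
# are not force-field geometries.
hexagon_xy <- function() {
  ang <- (seq_len(6) - 1) * pi / 3
  r <- 1.39
  cbind(r * cos(ang), r * sin(ang), 0)
}

base_template <- function(base) {
  hx <- hexagon_xy()
  # six-membered ring order: N1 C2 N3 C4 C5 C6 (purines and pyrimidines share
  # this naming for the pyrimidine-like ring)
  ring6 <- c("N1", "C2", "N3", "C4", "C5", "C6")
  atoms <- data.frame(atom = ring6, x = hx[, 1], y = hx[, 2], z = 0,
                      stringsAsFactors = FALSE)
  dir_out <- function(nm) {   # unit vector from ring center through atom nm
    p <- atoms[atoms$atom == nm, c("x", "y", "z")]
    v <- as.numeric(p); v / sqrt(sum(v^2))
  }
  add <- function(nm, anchor, dist, perp = 0) {
    v <- dir_out(anchor)
    p <- as.numeric(atoms[atoms$atom == anchor, c("x", "y", "z")]) + dist * v
    atoms <<- rbind(atoms, data.frame(atom = nm, x = p[1], y = p[2] + perp, z = 0))
  }
  purine <- base %in% c("G", "A")
  if (purine) {
    # fused five-membered ring atoms placed off C4-C5 edge
    c4 <- as.numeric(atoms[atoms$atom == "C4", c("x", "y", "z")])
    c5 <- as.numeric(atoms[atoms$atom == "C5", c("x", "y", "z")])
    mid <- (c4 + c5) / 2
    out <- mid / sqrt(sum(mid^2))
    n7 <- c5 + 1.35 * out; n9 <- c4 + 1.35 * out
    c8 <- mid + 2.2 * out
    atoms <- rbind(atoms,
      data.frame(atom = c("N7", "C8", "N9"),
                 x = c(n7[1], c8[1], n9[1]),
                 y = c(n7[2], c8[2], n9[2]), z = 0))
    if (base == "G") { add("O6", "C6", 1.23); add("N2", "C2", 1.34) }
    if (base == "A") add("N6", "C6", 1.34)
    glyc_n <- "N9"
  } else {
    if (base == "C") { add("O2", "C2", 1.23); add("N4", "C4", 1.34) }
    if (base == "T") { add("O2", "C2", 1.23); add("O4", "C4", 1.23)
                       add("C7", "C5", 1.50) }
    glyc_n <- "N1"
  }
  # sugar stubs: C1' bonded to the glycosidic nitrogen, slightly out of plane
  gp <- as.numeric(atoms[atoms$atom == glyc_n, c("x", "y", "z")])
  v <- gp / sqrt(sum(gp^2))
  c1 <- gp + 1.47 * v + c(0, 0, 0.45)
  o4 <- c1 + c(0.8, -0.9, 0.6)
  atoms <- rbind(atoms,
    data.frame(atom = c("C1'", "O4'"), x = c(c1[1], o4[1]),
               y = c(c1[2], o4[2]), z = c(c1[3], o4[3])))
  list(atoms = atoms, purine = purine, glyc_n = glyc_n,
       ring_atoms = if (purine) c(ring6, "N7", "C8", "N9") else ring6,
       chi_atoms = if (purine) c("O4'", "C1'", "N9", "C4")
                   else c("O4'", "C1'", "N1", "C2"))
}

res_name_for <- function(base) paste0("D", base)

# ---- dna_structure class ----------------------------------------------------

#' Construct a molecular structure object
#'
#' A `dna_structure` bundles a tibble of atom records, per-residue base
#' annotations (purine flag, ring-atom names, glycosidic chi quadruple) and an
#' optional tibble of monovalent-ion records. All coordinates are in Angstrom
#' and residue numbering is 1-based, following PDB convention.
#'
#' @param atoms tibble/data.frame with columns `atom`, `element`, `res_id`,
#'   `res_name`, `chain`, `x`, `y`, `z`.
#' @param bases tibble with columns `res_id`, `res_name`, `is_base`, `purine`,
#'   `ring_atoms` (list), `chi_atoms` (list). Derived from `atoms` if `NULL`.
#' @param ions tibble with columns `element`, `x`, `y`, `z` (may be empty).
#' @return An object of class `dna_structure`.
#' @export
dna_structure <- function(atoms, bases = NULL, ions = NULL) {
  atoms <- tibble::as_tibble(atoms)
  req <- c("atom", "element", "res_id", "res_name", "chain", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    abort(paste("atoms must have columns:", paste(req, collapse = ", ")))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    abort("all atom positions must be finite")
  for (ch in unique(atoms$chain)) {
    ri <- atoms$res_id[atoms$chain == ch]
    if (is.unsorted(ri)) abort("residue indices must be non-decreasing within a chain")
  }
  if (is.null(bases)) bases <- annotate_bases(atoms)
  if (is.null(ions))
    ions <- tibble::tibble(element = character(), x = double(),
                           y = double(), z = double())
  structure(list(atoms = atoms, bases = tibble::as_tibble(bases),
                 ions = tibble::as_tibble(ions)),
            class = "dna_structure")
}

annotate_bases <- function(atoms) {
  ring6 <- c("N1", "C2", "N3", "C4", "C5", "C6")
  res <- dplyr::distinct(atoms[atoms$res_id > 0, ], .data$res_id, .data$res_name)
  rows <- purrr::pmap(res, function(res_id, res_name) {
    nm <- atoms$atom[atoms$res_id == res_id]
    purine <- any(c("N9", "N7") %in% nm)
    ring <- if (purine) c(ring6, "N7", "C8", "N9") else ring6
    is_base <- all(ring6 %in% nm) && length(intersect(ring, nm)) >= 6
    chi <- if (purine) c("O4'", "C1'", "N9", "C4") else c("O4'", "C1'", "N1", "C2")
    tibble::tibble(res_id = res_id, res_name = res_name, is_base = is_base,
                   purine = purine,
                   ring_atoms = list(intersect(ring, nm)),
                   chi_atoms = list(if (all(chi %in% nm)) chi else character()))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.dna_structure <- function(x, ...) {
  cat("<dna_structure> ", nrow(x$atoms), " atoms, ",
      nrow(x$bases), " residues (", sum(x$bases$is_base), " nucleobases), ",
      nrow(x$ions), " ions\n", sep = "")
  invisible(x)
}

#' Coordinate matrix of selected atoms
#'
#' @param structure a [dna_structure()].
#' @param mask atom selector: `"all"`, `"heavy"` (non-hydrogen; the default
#'   solute mask), `"ring"` (base ring atoms), or a character vector of atom
#'   names.
#' @return numeric matrix with one row per selected atom (Angstrom), ordered
#'   as in the atom table.
#' @export
coords <- function(structure, mask = "heavy") {
  a <- structure$atoms
  keep <- select_mask(a, mask)
  as.matrix(a[keep, c("x", "y", "z")])
}

select_mask <- function(atoms, mask) {
  if (length(mask) == 1 && mask %in% c("all", "heavy", "ring")) {
    switch(mask,
      all = rep(TRUE, nrow(atoms)),
      heavy = atoms$element != "H",
      ring = atoms$atom %in% c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"))
  } else atoms$atom %in% mask
}

element_of <- function(atom_name) {
  e <- substr(gsub("[^A-Za-z].*$", "", atom_name), 1, 1)
  toupper(e)
}

# ---- PDB I/O ----------------------------------------------------------------

ION_ELEMENTS <- c("NA", "K", "MG", "CL", "SR", "LI", "RB", "CS")

#' Read a PDB file into a structure object
#'
#' Parses PDB v3.3 fixed-width ATOM/HETATM records (through bio3d). HETATM
#' records whose element is a recognized monovalent/divalent cation (NA, K,
#' MG, ...) become ion records. Residues lacking a complete six-membered ring
#' are annotated as non-base rather than raising an error.
#'
#' @param path path to a PDB file.
#' @return a [dna_structure()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (!any(rec)) abort(paste("no ATOM/HETATM records in", path))
  bad <- which(rec & nchar(lines) < 54)
  if (length(bad))
    abort(paste0("malformed ATOM/HETATM record at line ", bad[1], " of ", path))
  for (i in which(rec)) {
    xyz <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
             substr(lines[i], 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(xyz)))))
      abort(paste0("malformed coordinates at line ", i, " of ", path))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elem <- ifelse(!is.na(at$elesy) & nzchar(trimws(at$elesy)),
                 toupper(trimws(at$elesy)), element_of(at$elety))
  is_ion <- at$type == "HETATM" & elem %in% ION_ELEMENTS
  atoms <- tibble::tibble(
    atom = trimws(at$elety[!is_ion]), element = elem[!is_ion],
    res_id = at$resno[!is_ion], res_name = trimws(at$resid[!is_ion]),
    chain = ifelse(is.na(at$chain[!is_ion]), "A", at$chain[!is_ion]),
    x = at$x[!is_ion], y = at$y[!is_ion], z = at$z[!is_ion])
  ions <- tibble::tibble(element = elem[is_ion], x = at$x[is_ion],
                         y = at$y[is_ion], z = at$z[is_ion])
  dna_structure(atoms, ions = ions)
}

#' Write a structure (or list of structures) to a PDB file
#'
#' Single structures are written as plain PDB v3.3; a list is written as a
#' multi-model PDB (MODEL/ENDMDL), the on-disk format used for milestone sets.
#'
#' @param structure a [dna_structure()] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  if (inherits(structure, "dna_structure")) structure <- list(structure)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(structure) > 1
  for (m in seq_along(structure)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    s <- structure[[m]]
    i <- 0
    fmt <- "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
    pad_name <- function(nm) if (nchar(nm) < 4) paste0(" ", nm) else nm
    for (k in seq_len(nrow(s$atoms))) {
      i <- i + 1
      a <- s$atoms[k, ]
      writeLines(sprintf(fmt, "ATOM", i, pad_name(a$atom), "", a$res_name,
                         a$chain, a$res_id, "", a$x, a$y, a$z, 1, 0,
                         a$element), con)
    }
    if (nrow(s$ions)) for (k in seq_len(nrow(s$ions))) {
      i <- i + 1
      io <- s$ions[k, ]
      writeLines(sprintf(fmt, "HETATM", i, pad_name(io$element), "",
                         io$element, "I", 9000 + k, "", io$x, io$y, io$z,
                         1, 0, io$element), con)
    }
    if (multi) writeLines("ENDMDL", con) else writeLines("END", con)
  }
  invisible(path)
}

#' Read a multi-model PDB as a list of structures
#'
#' @param path multi-model PDB path.
#' @return list of [dna_structure()] objects, one per MODEL (a single-model
#'   file yields a length-1 list).
#' @export
read_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (!length(starts)) return(list(read_pdb(path)))
  ends <- grep("^ENDMDL", lines)
  purrr::map2(starts, ends, function(s, e) {
    tf <- tempfile(fileext = ".pdb")
    writeLines(c(lines[(s + 1):(e - 1)], "END"), tf)
    on.exit(unlink(tf))
    read_pdb(tf)
  })
}

# ---- synthetic strand generator --------------------------------------------

#' Generate a synthetic single-stranded DNA structure
#'
#' Builds an idealized single strand from planar base templates, either as a
#' B-form-like stacked helix (3.4 A rise, 30 deg twist per step) or as an
#' extended chain with monotone rise along the helix axis. This synthetic
#' generator stands in for experimental structures when exercising the
#' metrics, pathCV and observable machinery; it makes no claim to force-field
#' realism. A small seeded jitter (0.02 A) breaks exact degeneracies while
#' keeping the output bit-reproducible per `(sequence, conformation, seed)`.
#'
#' @param sequence string over the alphabet G/A/C/T.
#' @param conformation `"stacked-helix"` or `"extended"`.
#' @param seed integer seed for the jitter.
#' @param rise,twist stacked-helix rise (A) and twist (degrees) per step.
#' @return a [dna_structure()] with full base annotations.
#' @export
generate_strand <- function(sequence, conformation = c("stacked-helix", "extended"),
                            seed = 1L, rise = 3.4, twist = 30) {
  conformation <- match.arg(conformation)
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (!length(bases)) abort("sequence must be non-empty")
  if (!all(bases %in% c("G", "A", "C", "T")))
    abort(paste("unknown base letter:",
                paste(setdiff(bases, c("G", "A", "C", "T")), collapse = ",")))
  rows <- withr::with_seed(as.integer(seed), {
    purrr::imap(bases, function(b, i) {
      tpl <- base_template(b)
      xyz <- as.matrix(tpl$atoms[, c("x", "y", "z")])
      if (conformation == "stacked-helix") {
        th <- (i - 1) * twist * pi / 180
        R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                    3, 3, byrow = TRUE)
        xyz <- xyz %*% t(R)
        xyz[, 3] <- xyz[, 3] + (i - 1) * rise
      } else {
        # flip alternate bases so the chain extends without clashes
        th <- (i - 1) * pi
        R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                    3, 3, byrow = TRUE)
        xyz <- xyz %*% t(R)
        xyz[, 1] <- xyz[, 1] + (i - 1) * 6.5
      }
      xyz <- xyz + matrix(rnorm(length(xyz), sd = 0.02), ncol = 3)
      tibble::tibble(atom = tpl$atoms$atom,
                     element = element_of(tpl$atoms$atom),
                     res_id = i, res_name = res_name_for(b), chain = "A",
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    })
  })
  dna_structure(dplyr::bind_rows(rows))
}

#' Randomly perturb atomic coordinates
#'
#' Adds i.i.d. Gaussian displacements of standard deviation `amplitude` to
#' every atom (and ion). Deterministic per seed; `amplitude = 0` returns the
#' input unchanged.
#'
#' @param structure a [dna_structure()].
#' @param amplitude displacement standard deviation (A), `>= 0`.
#' @param seed integer seed.
#' @return perturbed [dna_structure()].
#' @export
perturb <- function(structure, amplitude, seed = 1L) {
  if (amplitude < 0) abort("amplitude must be >= 0")
  if (amplitude == 0) return(structure)
  withr::with_seed(as.integer(seed), {
    n <- nrow(structure$atoms)
    d <- matrix(rnorm(3 * n, sd = amplitude), ncol = 3)
    structure$atoms$x <- structure$atoms$x + d[, 1]
    structure$atoms$y <- structure$atoms$y + d[, 2]
    structure$atoms$z <- structure$atoms$z + d[, 3]
    if (nrow(structure$ions)) {
      di <- matrix(rnorm(3 * nrow(structure$ions), sd = amplitude), ncol = 3)
      structure$ions$x <- structure$ions$x + di[, 1]
      structure$ions$y <- structure$ions$y + di[, 2]
      structure$ions$z <- structure$ions$z + di[, 3]
    }
  })
  structure
}

# ---- observables ------------------------------------------------------------

#' Hydrogen-bond specification
#'
#' Geometric H-bond criterion plus the list of native donor-acceptor pairs to
#' monitor. Defaults: donor-acceptor distance <= 3.5 A and donor-H...acceptor
#' angle >= 135 deg, the standard geometric definition. Pairs reference atoms
#' as `"res_id:atom"` strings; the hydrogen may be `NA`, in which case only
#' the distance criterion applies (synthetic fixtures carry no hydrogens).
#'
#' @param pairs data.frame/tibble with columns `donor`, `hydrogen`, `acceptor`.
#' @param dist_cutoff donor-acceptor distance cutoff (A).
#' @param angle_cutoff donor-H...acceptor angle cutoff (degrees).
#' @return an `hbond_spec` object.
#' @export
hbond_spec <- function(pairs, dist_cutoff = 3.5, angle_cutoff = 135) {
  if (dist_cutoff <= 0 || angle_cutoff <= 0) abort("cutoffs must be positive")
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("donor", "acceptor") %in% names(pairs)))
    abort("pairs must have donor and acceptor columns")
  if (!"hydrogen" %in% names(pairs)) pairs$hydrogen <- NA_character_
  key <- paste(pairs$donor, pairs$acceptor)
  if (anyDuplicated(key)) abort("duplicate donor-acceptor pairs")
  structure(list(pairs = pairs, dist_cutoff = dist_cutoff,
                 angle_cutoff = angle_cutoff), class = "hbond_spec")
}

atom_xyz <- function(structure, selector) {
  parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
  a <- structure$atoms
  hit <- a$res_id == as.integer(parts[1]) & a$atom == parts[2]
  if (!any(hit)) abort(paste("atom not found:", selector))
  as.numeric(a[which(hit)[1], c("x", "y", "z")])
}

#' Count native hydrogen bonds
#'
#' Counts the native donor-acceptor pairs of `spec` that satisfy the distance
#' cutoff and (when the pair names a hydrogen) the donor-H...acceptor angle
#' cutoff. This is the per-frame native H-bond observable tracked along a
#' folding pathway.
#'
#' @param structure a [dna_structure()].
#' @param spec an [hbond_spec()].
#' @return integer count in `[0, nrow(spec$pairs)]`.
#' @export
count_native_hbonds <- function(structure, spec) {
  p <- spec$pairs
  if (!nrow(p)) return(0L)
  ok <- purrr::pmap_lgl(p, function(donor, hydrogen, acceptor) {
    d <- atom_xyz(structure, donor)
    ac <- atom_xyz(structure, acceptor)
    if (sqrt(sum((d - ac)^2)) > spec$dist_cutoff) return(FALSE)
    if (is.na(hydrogen)) return(TRUE)
    h <- atom_xyz(structure, hydrogen)
    v1 <- d - h; v2 <- ac - h
    ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    ang >= spec$angle_cutoff
  })
  sum(ok)
}

#' Count channel-coordinated cations
#'
#' Counts ions coordinated to at least `min_coordination` guanine O6/N7 atoms
#' within `cutoff` Angstrom -- the "at least tetracoordinated" cation
#' observable for G-quadruplex channel occupancy. Structures without ion
#' records yield 0.
#'
#' @param structure a [dna_structure()].
#' @param min_coordination minimum number of coordinating guanine O6/N7 atoms.
#' @param cutoff coordination distance cutoff (A); default 3.0 A, a typical
#'   Na+-O coordination distance.
#' @return integer ion count.
#' @export
count_coordinated_ions <- function(structure, min_coordination = 4, cutoff = 3.0) {
  if (min_coordination < 1) abort("min_coordination must be >= 1")
  if (!nrow(structure$ions)) return(0L)
  a <- structure$atoms
  gua <- a[grepl("G", a$res_name) & a$atom %in% c("O6", "N7"), c("x", "y", "z")]
  if (!nrow(gua)) return(0L)
  gm <- as.matrix(gua)
  n <- 0L
  for (k in seq_len(nrow(structure$ions))) {
    ion <- as.numeric(structure$ions[k, c("x", "y", "z")])
    dd <- sqrt(rowSums((gm - matrix(ion, nrow(gm), 3, byrow = TRUE))^2))
    if (sum(dd <= cutoff) >= min_coordination) n <- n + 1L
  }
  n
}
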