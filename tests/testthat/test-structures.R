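test_that("PDB round-trip preserves atoms, names, numbering and coordinates", {
  s <- generate_strand("GGGAGGG", "stacked-helix", seed = 2)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, tf)
  s2 <- read_pdb(tf)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$atom, s$atoms$atom)
  expect_equal(s2$atoms$res_id, s$atoms$res_id)
  expect_lt(max(abs(coords(s, "all") - coords(s2, "all"))), 1e-3)
  expect_equal(sum(s2$bases$purine), 7)
})

test_that("multi-model PDB stores and restores a milestone set", {
  ms <- lapply(1:3, function(k) perturb(generate_strand("GG", "extended", 1),
                                        0.3, seed = k))
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ms, tf)
  back <- read_pdb_models(tf)
  expect_length(back, 3)
  for (k in 1:3)
    expect_lt(max(abs(coords(ms[[k]], "all") - coords(back[[k]], "all"))), 1e-3)
})

test_that("malformed and degenerate PDB input is reported usefully", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  C2  DG  A   1       bad coords here"), tf)
  expect_error(read_pdb(tf), "line 1")
  writeLines(character(), tf)
  expect_error(read_pdb(tf), "no ATOM")
  # residue lacking ring atoms is annotated non-base, not an error
  s <- generate_strand("GGG", "stacked-helix", 1)
  s$atoms <- s$atoms[!(s$atoms$res_id == 3 &
                         s$atoms$atom %in% c("N1", "N3", "C5", "C6")), ]
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(dna_structure(s$atoms), tf2)
  s3 <- read_pdb(tf2)
  expect_false(s3$bases$is_base[s3$bases$res_id == 3])
  expect_equal(sum(s3$bases$is_base), 2)
})

test_that("generate_strand is reproducible, validated, and geometrically sane", {
  a <- generate_strand("GGGAGGG", "stacked-helix", seed = 1)
  b <- generate_strand("GGGAGGG", "stacked-helix", seed = 1)
  expect_identical(a, b)
  expect_error(generate_strand("GGX", "extended", 1), "unknown base")
  expect_error(generate_strand("", "extended", 1), "non-empty")
  one <- generate_strand("G", "extended", seed = 0)
  expect_true(one$bases$is_base[1])
  # stacked helix: consecutive ring-center distances within stacking range
  s <- generate_strand("GGGAGGGAGGGAGGG", "stacked-helix", seed = 7)
  expect_equal(nrow(s$bases), 15)
  ctr <- t(vapply(seq_len(15), function(r) {
    m <- s$atoms[s$atoms$res_id == r &
                   s$atoms$atom %in% c("N1", "C2", "N3", "C4", "C5", "C6"), ]
    c(mean(m$x), mean(m$y), mean(m$z))
  }, numeric(3)))
  dd <- sqrt(rowSums((ctr[-1, ] - ctr[-15, ])^2))
  expect_true(all(dd > 3.2 & dd < 7.0))
  expect_equal(ermsd(s, s), 0)
  # extended: monotone rise along the chain axis
  e <- generate_strand("GGGG", "extended", seed = 3)
  cx <- vapply(1:4, function(r) mean(e$atoms$x[e$atoms$res_id == r]), numeric(1))
  expect_true(all(diff(cx) > 0))
})

test_that("perturb is seeded, validated, and a no-op at zero amplitude", {
  s <- generate_strand("GGG", "stacked-helix", 1)
  expect_identical(perturb(s, 0, 5), s)
  expect_identical(perturb(s, 0.5, 3), perturb(s, 0.5, 3))
  expect_gt(kabsch_rmsd(s, perturb(s, 0.5, 3), "all"), 0)
  expect_error(perturb(s, -0.1, 1), ">= 0")
})

test_that("native H-bond counting follows the geometric criterion", {
  # hand-built: donor N1 (res 1), hydrogen on the N1-acceptor axis, acceptor
  # O6 (res 2) at 2.9 A -> angle 180 deg
  atoms <- tibble::tibble(
    atom = c("N1", "H1", "O6"), element = c("N", "H", "O"),
    res_id = c(1L, 1L, 2L), res_name = "DG", chain = "A",
    x = c(0, 1, 2.9), y = 0, z = 0)
  s <- dna_structure(atoms)
  spec <- hbond_spec(tibble::tibble(donor = "1:N1", hydrogen = "1:H1",
                                    acceptor = "2:O6"))
  expect_equal(count_native_hbonds(s, spec), 1L)
  empty <- hbond_spec(tibble::tibble(donor = character(),
                                     hydrogen = character(),
                                     acceptor = character()))
  expect_equal(count_native_hbonds(s, empty), 0L)
  # acceptor beyond cutoff
  s2 <- s; s2$atoms$x[3] <- 3.6
  expect_equal(count_native_hbonds(s2, spec), 0L)
  # bad angle: hydrogen perpendicular to the donor-acceptor axis
  s3 <- s; s3$atoms$x[2] <- 0; s3$atoms$y[2] <- 1
  expect_equal(count_native_hbonds(s3, spec), 0L)
  # invariant under rigid motion
  sr <- transform_rigid(s, angles = c(0.7, -0.2, 1.9), shift = c(10, -4, 2))
  expect_equal(count_native_hbonds(sr, spec), 1L)
  # missing atom is named
  bad <- hbond_spec(tibble::tibble(donor = "1:N9", hydrogen = NA,
                                   acceptor = "2:O6"))
  expect_error(count_native_hbonds(s, bad), "1:N9")
  expect_error(hbond_spec(tibble::tibble(donor = c("1:N1", "1:N1"),
                                         hydrogen = NA,
                                         acceptor = c("2:O6", "2:O6"))),
               "duplicate")
})

test_that("ion coordination counting matches constructed quartet geometry", {
  ion_ctr <- tibble::tibble(element = "NA", x = 0, y = 0, z = 0)
  q <- make_quartet(r_o6 = 2.8, ions = ion_ctr)
  expect_equal(count_coordinated_ions(q, 4, 3.0), 1L)
  far <- make_quartet(r_o6 = 2.8,
                      ions = dplyr::mutate(ion_ctr, x = 10))
  expect_equal(count_coordinated_ions(far, 4, 3.0), 0L)
  two <- make_quartet(r_o6 = 2.8, n_stack = 2,
                      ions = tibble::tibble(element = c("NA", "NA"),
                                            x = 0, y = 0, z = c(0, 3.4)))
  expect_equal(count_coordinated_ions(two, 4, 3.0), 2L)
  none <- make_quartet()
  expect_equal(count_coordinated_ions(none, 4, 3.0), 0L)
  # monotone non-decreasing in cutoff
  counts <- vapply(seq(1, 6, by = 0.5),
                   function(cc) count_coordinated_ions(two, 4, cc), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(count_coordinated_ions(q, 0), ">= 1")
})
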