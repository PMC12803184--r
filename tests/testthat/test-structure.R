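test_that("PDB ATOM records round-trip through writer and parser", {
  atoms <- acetylatlas:::helix_atoms("MKAV", c(91.2, 85.5, 70.25, 60))
  f <- tempfile(fileext = ".pdb")
  write_pdb(atoms, f)
  got <- parse_pdb(f)
  expect_equal(nrow(got), nrow(atoms))
  expect_equal(got$x, atoms$x, tolerance = 1e-3)
  expect_equal(got$y, atoms$y, tolerance = 1e-3)
  expect_equal(got$z, atoms$z, tolerance = 1e-3)
  expect_equal(got$b_factor[1], 91.2)
  expect_equal(got$residue_index, atoms$residue_index)
  expect_equal(got$element, atoms$element)
  unlink(f)
})

test_that("parser agrees with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  atoms <- acetylatlas:::helix_atoms("MKAVLE", runif(6, 50, 99))
  f <- tempfile(fileext = ".pdb")
  write_pdb(atoms, f)
  ref <- bio3d::read.pdb(f)
  got <- parse_pdb(f)
  expect_equal(got$x, ref$atom$x, tolerance = 1e-6)
  expect_equal(got$b_factor, ref$atom$b, tolerance = 1e-6)
  expect_equal(got$residue_index, ref$atom$resno)
  unlink(f)
})

test_that("parser reports malformed lines, HETATM-only files and multi-model files", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1   CA LYS A   1      1.0001.000   1.000  1.00 90.00           C",
    "END"), f)
  # mangled x/y fields: non-numeric after fixed-column slicing
  expect_error(parse_pdb(f), "line 1")
  writeLines(c(
    "HETATM    1   O  HOH A   1       1.000   1.000   1.000  1.00  0.00          O",
    "END"), f)
  expect_warning(got <- parse_pdb(f), "HETATM")
  expect_equal(nrow(got), 0)
  atoms <- acetylatlas:::helix_atoms("MK", c(80, 80))
  f2 <- tempfile(fileext = ".pdb")
  write_pdb(atoms, f2)
  lines <- readLines(f2)
  body <- lines[-length(lines)]
  writeLines(c("MODEL     1", body, "ENDMDL",
               "MODEL     2", body, "ENDMDL", "END"), f2)
  expect_warning(got2 <- parse_pdb(f2), "first model")
  expect_equal(nrow(got2), nrow(atoms))
  unlink(c(f, f2))
})

test_that("per-residue pLDDT collapses atom B-factors, averaging disagreement", {
  atoms <- data.frame(serial = 1:4, name = c("N", "CA", "N", "CA"),
                      resname = "LYS", chain = "A",
                      residue_index = c(1, 1, 2, 2),
                      x = 0, y = 0, z = 0,
                      b_factor = c(91.2, 91.2, 90, 92),
                      element = c("N", "C", "N", "C"), hetatm = FALSE,
                      vdw_radius = 1.7)
  expect_warning(pl <- plddt_per_residue(atoms), "disagree")
  expect_equal(unname(pl["1"]), 91.2)
  expect_equal(unname(pl["2"]), 91)
  expect_equal(length(plddt_per_residue(atoms[0, ])), 0)
})

single_atom <- function(x = 0, y = 0, z = 0, r = 1.7, el = "C") {
  data.frame(serial = 1, name = "CA", resname = "LYS", chain = "A",
             residue_index = 1, x = x, y = y, z = z, b_factor = 90,
             element = el, hetatm = FALSE, vdw_radius = r)
}

test_that("SASA of an isolated atom equals the analytic sphere area", {
  a <- single_atom()
  got <- as.numeric(shrake_rupley(a, probe = 1.4, n_points = 100))
  expect_equal(got, 4 * pi * 3.1^2, tolerance = 1e-3)  # every point accessible
  # two atoms far apart: no occlusion
  two <- rbind(a, single_atom(x = 100) |> transform(serial = 2,
                                                    residue_index = 2))
  got2 <- as.numeric(shrake_rupley(two, probe = 1.4, n_points = 100))
  expect_equal(got2, rep(4 * pi * 3.1^2, 2), tolerance = 1e-3)
})

test_that("a small atom inside a much larger sphere has zero SASA", {
  small <- single_atom(r = 1.2, el = "H")
  big <- single_atom(r = 10) |> transform(serial = 2, residue_index = 2)
  got <- as.numeric(shrake_rupley(rbind(small, big), probe = 1.4,
                                  n_points = 100))
  expect_equal(got[1], 0)
})

test_that("two intersecting equal spheres match the closed-form cap area", {
  r <- 1.7; probe <- 1.4; R <- r + probe
  for (d in c(2.0, 3.0, 4.0)) {
    a <- single_atom()
    b <- single_atom(x = d) |> transform(serial = 2, residue_index = 2)
    got <- as.numeric(shrake_rupley(rbind(a, b), probe = probe,
                                    n_points = 960))
    expected <- 2 * pi * R * (R + d / 2)   # sphere minus spherical cap
    expect_equal(got, rep(expected, 2), tolerance = 0.02)
  }
})

test_that("SASA is stable under point doubling and monotone in crowding", {
  a <- single_atom()
  s1 <- as.numeric(shrake_rupley(a, n_points = 100))
  s2 <- as.numeric(shrake_rupley(a, n_points = 200))
  expect_equal(s1, s2, tolerance = 1e-3)
  # adding neighbors can only reduce an atom's SASA
  base <- single_atom()
  nb1 <- single_atom(x = 3) |> transform(serial = 2, residue_index = 2)
  nb2 <- single_atom(y = 3) |> transform(serial = 3, residue_index = 3)
  s_alone <- as.numeric(shrake_rupley(base))[1]
  s_one <- as.numeric(shrake_rupley(rbind(base, nb1)))[1]
  s_two <- as.numeric(shrake_rupley(rbind(base, nb1, nb2)))[1]
  expect_gte(s_alone, s_one)
  expect_gte(s_one, s_two)
  expect_true(all(c(s_alone, s_one, s_two) >= 0))
})

test_that("residue SASA sums member atoms and conserves the total", {
  atoms <- acetylatlas:::helix_atoms("GKG", c(80, 80, 80))
  sa <- shrake_rupley(atoms)
  res <- residue_sasa(sa)
  expect_equal(sum(res), sum(sa), tolerance = 1e-9)
  expect_equal(unname(res["2"]),
               sum(as.numeric(sa)[atoms$residue_index == 2]))
})

test_that("site-structure join flags non-lysine residues and drops missing proteins", {
  d <- tiny_design(tissues = "liver", sexes = "female", replicates = 2)
  x <- make_sites(d, c("P1_K2", "P1_K3", "P2_K2"),
                  protein_id = c("P1", "P1", "P2"),
                  position = c(2L, 3L, 2L))
  st <- list(P1 = data.frame(residue_index = 1:3, aa = c("M", "K", "A"),
                             plddt = c(70, 91.2, 80), sasa = c(10, 55, 20)))
  got <- join_site_structure(x, st)
  expect_equal(nrow(got), 2)                     # P2 dropped (no structure)
  expect_equal(attr(got, "n_unmapped"), 1)
  k2 <- got[got$position == 2, ]
  expect_false(k2$mismatch)
  expect_equal(k2$plddt, 91.2)
  expect_equal(k2$sasa, 55)
  expect_true(got$mismatch[got$position == 3])   # ALA at position 3
})

test_that("planted buried lysines are less exposed than planted exposed ones", {
  fx <- atlas_fixture()
  pairs <- fx$sim$truth$structure_pairs
  res <- fx$res$structure$residues
  for (i in seq_len(nrow(pairs))) {
    rt <- res[[pairs$protein_id[i]]]
    expect_lt(rt$sasa[rt$residue_index == pairs$buried[i]],
              rt$sasa[rt$residue_index == pairs$exposed[i]])
  }
})

test_that("sites planted at buried residues shift the SASA distribution left", {
  # rank-sum comparison of buried-site SASA vs all lysines in the decoys
  fx <- atlas_fixture()
  pairs <- fx$sim$truth$structure_pairs
  res <- fx$res$structure$residues
  buried <- mapply(function(p, b) {
    rt <- res[[p]]; rt$sasa[rt$residue_index == b]
  }, pairs$protein_id, pairs$buried)
  all_lys <- unlist(lapply(res, function(rt) rt$sasa[rt$aa == "K"]))
  w <- suppressWarnings(wilcox.test(buried, all_lys, alternative = "less"))
  expect_lt(w$p.value, 0.01)
})
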