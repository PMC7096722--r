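test_that("ideal polypeptides hit the requested torsions and dictionary geometry", {
  s <- make_ideal_polypeptide(20)
  for (i in 2:19) {
    om <- dihedral_angle(atom_pos(s, "A", i, "CA"), atom_pos(s, "A", i, "C"),
                         atom_pos(s, "A", i + 1, "N"),
                         atom_pos(s, "A", i + 1, "CA"))
    expect_lt(abs(abs(om) - 180), 0.1)
    pp <- phi_psi(s, "A", i)
    expect_equal(unname(pp), c(-57, -47), tolerance = 0.1)
  }
  st <- make_ideal_polypeptide(6, conformation = "strand")
  expect_equal(unname(phi_psi(st, "A", 3)), c(-120, 120), tolerance = 0.1)
  # geometry energy under the dictionary is numerically zero
  ts <- total_score(s, build_standard_restraints(s), NULL,
                    refinement_config(map_weight = 0))
  expect_lt(ts$breakdown[["total"]], 1e-6)
  expect_error(make_ideal_polypeptide("AXB"), "invalid")
})

test_that("map synthesis: peak amplitude, Gaussian integral, blur consistency", {
  one <- make_ideal_polypeptide(1)
  one$atoms <- one$atoms[one$atoms$atom == "CA", , drop = FALSE]
  # put the atom exactly on a grid node so the peak is sampled
  ap <- c(one$atoms$x, one$atoms$y, one$atoms$z)
  m <- synthesize_map(one, spacing = 0.5, origin = ap - 8)
  expect_equal(max(m$grid), 6, tolerance = 1e-6)   # occ * Z for carbon
  sigma2 <- 40 / (8 * pi^2)
  integral <- sum(m$grid) * prod(m$spacing)
  expect_equal(integral, 6 * (2 * pi * sigma2)^1.5, tolerance = 0.01)
  # synthesizing at a larger B equals blurring the sharper map, up to the
  # amplitude factor ((B+dB)/B)^(3/2) of amplitude-normalised Gaussians
  s <- make_ideal_polypeptide(5)
  m40 <- synthesize_map(s, spacing = 0.5, atom_b = 40, padding = 8)
  m80 <- synthesize_map(s, spacing = 0.5, atom_b = 80, padding = 8,
                        origin = m40$origin, dims = dim(m40$grid))
  blurred <- sharpen_blur(m40, 40)
  scale <- (80 / 40)^1.5
  expect_rms_close(blurred$grid * scale, m80$grid, 0.02)
  expect_error(synthesize_map(rs_structure()), "empty")
})

test_that("perturbation is exact for pure transforms and seed-reproducible", {
  s <- make_ideal_polypeptide(5)
  expect_identical(coords(perturb_structure(s)), coords(s))
  t <- c(1.5, -2, 0.25)
  moved <- perturb_structure(s, translation = t)
  expect_equal(coords(moved), sweep(coords(s), 2, t, `+`))
  n1 <- perturb_structure(s, noise_A = 0.3, seed = 7)
  n2 <- perturb_structure(s, noise_A = 0.3, seed = 7)
  expect_identical(coords(n1), coords(n2))
  n3 <- perturb_structure(s, noise_A = 0.3, seed = 8)
  expect_false(identical(coords(n1), coords(n3)))
  # rotation preserves internal distances
  rot <- perturb_structure(s, rotation_axis = c(1, 1, 0), rotation_deg = 35)
  expect_lt(max(abs(dist(coords(rot)) - dist(coords(s)))), 1e-9)
})

test_that("the residue templates are chiral L-amino acids with correct chis", {
  for (rt in names(ROTAMER_LIB)) {
    tpl <- build_residue_template(rt)
    p <- function(nm) unlist(tpl[tpl$atom == nm, c("x", "y", "z")],
                             use.names = FALSE)
    v <- rsfit:::chiral_volume(p("CA"), p("N"), p("C"), p("CB"))
    expect_gt(v, 2)   # L configuration
    chis <- ROTAMER_LIB[[rt]][[which.max(
      vapply(ROTAMER_LIB[[rt]], function(r) r[[2]], numeric(1)))]][[3]]
    defs <- rsfit:::CHI_ATOMS[[rt]]
    for (k in seq_along(defs)) {
      q <- defs[[k]]
      got <- dihedral_angle(p(q[1]), p(q[2]), p(q[3]), p(q[4]))
      expect_lt(abs(wrap180(got - chis[k])), 0.1, label = paste(rt, k))
    }
  }
})

test_that("external dictionary round trip and template error handling", {
  d <- default_dictionary()
  sub <- d[c("LEU", "TOY")]; class(sub) <- "monomer_dictionary"
  tf <- withr::local_tempfile(fileext = ".cif")
  write_restraint_dictionary(sub, tf)
  d2 <- read_restraint_dictionary(tf)
  expect_setequal(names(d2), c("LEU", "TOY"))
  expect_equal(d2$LEU$bonds$target, d$LEU$bonds$target, tolerance = 1e-9)
  expect_identical(d2$LEU$torsions$period, d$LEU$torsions$period)
  expect_equal(length(d2$TOY$planes), length(d$TOY$planes))
  # the shipped TOY dictionary file parses to the in-code entry
  shipped <- read_restraint_dictionary(
    system.file("extdata", "toy_ligand.cif", package = "rsfit"))
  expect_equal(shipped$TOY$bonds$target, d$TOY$bonds$target,
               tolerance = 1e-9)
  expect_error(build_residue_template("ZZZ"), "unsupported")
  expect_error(read_restraint_dictionary(tempfile()), "no such")
})

test_that("the shipped rotamer TSV reproduces the built-in library", {
  lib <- read_rotamer_library(
    system.file("extdata", "rotamer_library.tsv", package = "rsfit"))
  expect_setequal(names(lib), unique(rotamer_library()$res_type))
  for (rt in c("LEU", "ARG", "SER")) {
    expect_equal(length(lib[[rt]]), length(rsfit:::ROTAMER_LIB[[rt]]))
    expect_equal(lib[[rt]][[1]][[3]], rsfit:::ROTAMER_LIB[[rt]][[1]][[3]])
  }
})
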