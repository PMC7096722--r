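test_that("phi/psi measurement round-trips the generator and matches a brute-force dihedral", {
  s <- make_ideal_polypeptide(6)
  pp <- phi_psi(s, "A", 3)
  expect_equal(unname(pp), c(-57, -47), tolerance = 0.1)
  expect_null(phi_psi(s, "A", 1))
  expect_null(phi_psi(s, "A", 6))
  # sign convention against an independently written vector formula
  set.seed(8)
  for (k in 1:5) {
    p <- matrix(rnorm(12), 4, 3) * 2
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 brute_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("Ramachandran report: helix preferred, classes, markers, outliers", {
  rep <- rama_report(helix20)
  expect_equal(rep$summary$n, 18)   # termini undefined
  expect_true(all(rep$points$category == "preferred"))
  expect_true(all(rep$points$class == "general"))
  expect_equal(unname(rep$summary$counts["preferred"] +
                        rep$summary$counts["allowed"] +
                        rep$summary$counts["outlier"]), rep$summary$n)
  # pre-Pro precedence over Ile/Val; Gly/Pro markers
  s2 <- make_ideal_polypeptide("AIPGA")
  rep2 <- rama_report(s2)
  expect_identical(rep2$points$class,
                   c("pre_pro", "pro", "gly"))
  expect_identical(rep2$points$marker, c("circle", "square", "triangle"))
  # a forbidden-region conformation is flagged
  bad <- make_ideal_polypeptide(6, phi = 75, psi = -60)
  rep3 <- rama_report(bad)
  expect_true(all(rep3$points$category == "outlier"))
  only <- rama_report(bad, outliers_only = TRUE)
  expect_equal(nrow(only$points), rep3$summary$n)
  # selection restriction
  rep4 <- rama_report(helix20, sel = "//A/5-10")
  expect_equal(rep4$summary$n, 6)
})

test_that("Kleywegt comparison: identity, ranking, wrap, symmetry, top-n", {
  two <- merge_molecules(helix20, helix20)
  kc <- kleywegt_compare(two, "A", two, "B")
  expect_true(all(kc$torus_distance == 0))
  # rotate one residue's psi by 30 degrees in chain B: that pair ranks first
  twisted <- two
  b_atoms <- twisted$atoms$chain == "B"
  # rotate everything after residue 10's CA about the CA-C bond of B/10
  ca <- atom_pos(twisted, "B", 10, "CA"); cc <- atom_pos(twisted, "B", 10, "C")
  after <- which(b_atoms & (twisted$atoms$seqnum > 10 |
                              (twisted$atoms$seqnum == 10 &
                                 twisted$atoms$atom == "O")))
  xyz <- coords(twisted)
  xyz[after, ] <- rotate_about_axis(xyz[after, , drop = FALSE], ca, cc - ca,
                                    30)
  coords(twisted) <- xyz
  kc2 <- kleywegt_compare(twisted, "A", twisted, "B")
  expect_equal(kc2$seqnum_a[1], 10)
  expect_equal(kc2$torus_distance[1], 30, tolerance = 0.2)
  # symmetry: distances identical under argument swap
  kc2r <- kleywegt_compare(twisted, "B", twisted, "A")
  expect_equal(sort(kc2$torus_distance), sort(kc2r$torus_distance))
  # wrap-around on the torus
  expect_equal(abs(wrap180(350)), 10)
  # triangle inequality on sampled torus triples
  set.seed(11)
  for (k in 1:20) {
    a <- runif(2, -180, 180); b <- runif(2, -180, 180); c <- runif(2, -180, 180)
    td <- function(u, v) sqrt(sum(wrap180(u - v)^2))
    expect_lte(td(a, c), td(a, b) + td(b, c) + 1e-9)
  }
  # default plot data for two 100-residue NCS chains is 50 pairs
  big <- make_ideal_polypeptide(100)
  two_big <- merge_molecules(big, perturb_structure(big, noise_A = 0.05,
                                                    seed = 2))
  kc3 <- kleywegt_compare(two_big, "A", two_big, "B")
  expect_equal(nrow(kc3), 50)
  expect_true(all(diff(kc3$torus_distance) <= 0))
})

test_that("rotamer analysis names the nearest rotamer and skips GLY/ALA", {
  s <- place_rotamer_side_chain(make_ideal_polypeptide("ALA"), "A", 2,
                                c(-177, 65))
  ra <- rotamer_analysis(s)
  expect_equal(nrow(ra), 1)            # ALA residues skipped
  expect_identical(ra$rotamer, "tp")
  expect_lt(ra$chi_distance, 1e-9)
  expect_equal(ra$probability, 0.29)
  sg <- make_ideal_polypeptide("GGG")
  expect_equal(nrow(rotamer_analysis(sg)), 0)
})

test_that("B-factor statistics: robustness of the median", {
  s <- make_ideal_polypeptide(20)
  s$atoms$b <- 20
  bs <- b_factor_stats(s)
  expect_equal(bs$mean, 20); expect_equal(bs$median, 20)
  # 99 atoms at 20 plus one hot water: median unmoved, mean = 21.8
  s2 <- s; s2$atoms <- s2$atoms[1:99, ]
  w <- s2$atoms[1, ]
  w$b <- 200; w$seqnum <- 999L; w$resname <- "HOH"; w$atom <- "O"
  w$element <- "O"
  s2$atoms <- rbind(s2$atoms, w)
  bs2 <- b_factor_stats(s2)
  expect_equal(bs2$median, 20)
  expect_equal(bs2$mean, 21.8)
  # median invariant under monotone inflation of values above it
  s3 <- s2; s3$atoms$b[s3$atoms$b > 20.0001] <- 5000
  expect_equal(b_factor_stats(s3)$median, bs2$median)
  # per-residue means are consistent with the global mean
  pr <- bs2$per_residue
  sizes <- table(rsfit:::res_key(s2$atoms$chain, s2$atoms$seqnum,
                                 s2$atoms$inscode))
  key <- rsfit:::res_key(pr$chain, pr$seqnum, "")
  expect_equal(sum(pr$mean_b * as.numeric(sizes[key])) / sum(sizes),
               bs2$mean)
  expect_error(b_factor_stats(s, sel = "//Q"), "empty")
})

test_that("density-fit graph is local to the modified residue", {
  s <- make_ideal_polypeptide("AVLIV")
  map <- synthesize_map(s)
  base <- density_fit_graph(s, map)
  expect_true(all(base$fit > 0))
  # erase residue 3's side chain from the map
  no_side <- s
  drop <- no_side$atoms$seqnum == 3 &
    !no_side$atoms$atom %in% c("N", "CA", "C", "O")
  no_side$atoms <- no_side$atoms[!drop, ]
  map2 <- synthesize_map(no_side, origin = map$origin, dims = dim(map$grid))
  after <- density_fit_graph(s, map2)
  delta <- base$fit - after$fit
  expect_gt(delta[3], 0.5)
  expect_lt(max(delta[c(1, 5)]), delta[3] / 4)
  # residue far outside the map scores zero
  off <- perturb_structure(s, translation = c(500, 0, 0))
  expect_true(all(density_fit_graph(off, map)$fit == 0))
})

test_that("ligand distortion: zeros at ideal geometry, z per restraint, rigid invariance", {
  tl <- make_toy_ligand()
  ld <- ligand_distortion(tl, "X", 1)
  expect_true(all(abs(ld$bonds$z) < 1e-9))
  expect_true(all(abs(ld$angles$z) < 1e-9))
  expect_equal(unname(ld$rms_z["bond"]), 0)
  # stretch C8-C9 by exactly 2 sigma
  p8 <- atom_pos(tl, "X", 1, "C8"); p9 <- atom_pos(tl, "X", 1, "C9")
  entry <- default_dictionary()$TOY
  sig <- entry$bonds$sigma[entry$bonds$atom1 == "C8" &
                             entry$bonds$atom2 == "C9"]
  tl2 <- tl
  i <- which(tl2$atoms$atom == "C9")
  tl2$atoms[i, c("x", "y", "z")] <-
    as.list(p9 + 2 * sig * (p9 - p8) / vnorm_test(p9 - p8))
  ld2 <- ligand_distortion(tl2, "X", 1)
  expect_equal(ld2$bonds$z[ld2$bonds$atom1 == "C8"], 2, tolerance = 1e-6)
  # torsion periodicity: observed at target + 360 has z = 0
  expect_equal(ld$torsions$z, c(0, 0), tolerance = 1e-9)
  # rigid motion leaves all z-scores unchanged
  moved <- perturb_structure(tl2, rotation_axis = c(1, 2, 3),
                             rotation_deg = 77, translation = c(5, -3, 2))
  ld3 <- ligand_distortion(moved, "X", 1)
  expect_equal(ld3$rms_z, ld2$rms_z, tolerance = 1e-9)
  expect_error(ligand_distortion(tl, "X", 99), "no residue")
})
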