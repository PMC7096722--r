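test_that("Geman-McClure residual: harmonic limit, bound, gradient", {
  z <- seq(-3, 3, by = 0.1)
  d <- 2 + 0.1 * z
  harm <- gm_residual(d, 2, 0.1, alpha = 0)
  expect_lt(max(abs(harm$energy - z^2)), 1e-8)
  expect_equal(gm_residual(2, 2, 0.1)$energy, 0)
  expect_equal(gm_residual(2, 2, 0.1)$gradient, 0)
  # saturation at 1/alpha
  far <- gm_residual(2 + 1e4, 2, 0.1, alpha = 0.01)
  expect_lt(abs(far$energy - 100), 0.01)
  # robust loss never exceeds the harmonic one
  rob <- gm_residual(d, 2, 0.1, alpha = 0.05)
  expect_true(all(rob$energy <= z^2 + 1e-12))
  # analytic gradient vs central differences over a (z, alpha) grid
  h <- 1e-7
  for (al in c(0, 0.01, 0.1, 1)) for (zz in c(-2.5, -0.5, 0.3, 2)) {
    dd <- 2 + 0.1 * zz
    fd <- (gm_residual(dd + h, 2, 0.1, al)$energy -
             gm_residual(dd - h, 2, 0.1, al)$energy) / (2 * h)
    an <- gm_residual(dd, 2, 0.1, al)$gradient
    expect_lt(abs(fd - an) / max(1, abs(an)), 1e-6)
  }
  expect_error(gm_residual(2, 2, 0), "sigma")
})

test_that("self-restraint generation matches brute-force enumeration on random atoms", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 500
    atoms <- data.frame(
      chain = "A", seqnum = seq_len(n), inscode = "", resname = "DUM",
      atom = "X", altloc = "", element = "C",
      x = runif(n, 0, 25), y = runif(n, 0, 25), z = runif(n, 0, 25),
      occ = 1, b = 20, stringsAsFactors = FALSE)
    s <- rs_structure(atoms)
    for (limit in c(4.2, 6, 7)) {
      gm <- generate_self_gm_restraints(s, limit = limit)
      # brute force O(n^2): single-atom residues have no bonds, so every
      # in-range pair counts
      xyz <- coords(s)
      cnt <- 0L; targets <- numeric(0)
      for (i in 1:(n - 1)) {
        dd <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
        hit <- dd <= limit
        cnt <- cnt + sum(hit)
        targets <- c(targets, dd[hit])
      }
      expect_equal(nrow(gm), cnt)
      expect_equal(sort(gm$target), sort(targets), tolerance = 1e-12)
    }
  }
})

test_that("self-restraints exclude 1-2/1-3 pairs and grow with the limit", {
  s <- make_ideal_polypeptide(10)
  gm42 <- generate_self_gm_restraints(s, limit = 4.2)
  gm6 <- generate_self_gm_restraints(s, limit = 6)
  expect_true(all(paste(gm42$i, gm42$j) %in% paste(gm6$i, gm6$j)))
  cp <- rsfit:::covalent_pairs(s)
  bonded_keys <- paste(pmin(cp[, 1], cp[, 2]), pmax(cp[, 1], cp[, 2]))
  expect_false(any(paste(gm42$i, gm42$j) %in% bonded_keys))
  expect_true(all(gm42$target > 0 & gm42$target <= 4.2))
  expect_error(generate_self_gm_restraints(s, sel = "//Q"), "empty|Q")
})

test_that("standard restraints: dictionary terms, peptide link, unknown types", {
  s <- make_ideal_polypeptide("AA")
  rs <- build_standard_restraints(s)
  pep <- rs$bonds[abs(rs$bonds$target - 1.329) < 1e-9, ]
  expect_equal(nrow(pep), 1)
  expect_gt(nrow(rs$angles), 8)
  expect_equal(length(rs$planes), 1)       # one peptide plane
  expect_equal(nrow(rs$chirals), 2)        # two CA centres
  sG <- make_ideal_polypeptide("G")
  expect_equal(nrow(build_standard_restraints(sG)$torsions), 0)
  bad <- s; bad$atoms$resname <- "XYZ"
  expect_error(build_standard_restraints(bad), "XYZ")
})

test_that("metal LINK records become bond restraints and suppress nonbonded", {
  s <- make_ideal_polypeptide("AHA")
  ne2 <- atom_pos(s, "A", 2, "NE2")
  zn <- data.frame(chain = "A", seqnum = 10L, inscode = "", resname = "ZN",
                   atom = "ZN", altloc = "", element = "ZN",
                   x = ne2[1] + 2.05, y = ne2[2], z = ne2[3], occ = 1, b = 20,
                   stringsAsFactors = FALSE)
  s$atoms <- rbind(s$atoms, zn)
  s$links <- data.frame(chain1 = "A", seqnum1 = 10L, inscode1 = "",
                        atom1 = "ZN", chain2 = "A", seqnum2 = 2L,
                        inscode2 = "", atom2 = "NE2", link_type = "metalc",
                        dist = 2.05, stringsAsFactors = FALSE)
  ml <- metal_link_restraints(s)
  expect_equal(nrow(ml$bonds), 1)
  expect_equal(ml$bonds$target, 2.05)      # Zn-N from the built-in table
  full <- build_standard_restraints(s)
  nb_keys <- paste(pmin(full$nonbonded$i, full$nonbonded$j),
                   pmax(full$nonbonded$i, full$nonbonded$j))
  supp_key <- paste(pmin(ml$suppressed$i, ml$suppressed$j),
                    pmax(ml$suppressed$i, ml$suppressed$j))
  expect_false(supp_key %in% nb_keys)
  # carbon-ligand LINK ignored
  s2 <- s; s2$links$atom2 <- "CB"
  expect_equal(nrow(metal_link_restraints(s2)$bonds), 0)
  # dangling LINK warns and is skipped
  s3 <- s; s3$links$seqnum2 <- 99L
  expect_warning(ml3 <- metal_link_restraints(s3), "dangling")
  expect_equal(nrow(ml3$bonds), 0)
  # table override
  ml4 <- metal_link_restraints(s, table = c("ZN:N" = 2.20))
  expect_equal(ml4$bonds$target, 2.2)
})

test_that("torsion flip deltas follow the periodicity", {
  expect_equal(torsion_flip_deltas(3), c(120, -120))
  expect_equal(torsion_flip_deltas(2), 180)
  expect_equal(torsion_flip_deltas(1), 180)
  expect_equal(sort(torsion_flip_deltas(4)), c(-90, 90, 180))
  # closed under negation for period > 2
  for (p in 3:6) {
    d <- torsion_flip_deltas(p)
    dn <- d[abs(d) < 180 - 1e-9]
    expect_setequal(round(dn, 6), round(-dn, 6))
  }
  expect_error(torsion_flip_deltas(0), "period")
  # accepts a torsion restraint row
  entry <- default_dictionary()$TOY
  expect_equal(torsion_flip_deltas(entry$torsions[1, ]), c(120, -120))
})

test_that("JED flip rotates one rigid half and inverts cleanly", {
  tl <- make_toy_ligand()
  d0 <- as.matrix(dist(coords(tl)))
  # default moves the smaller half (the tail); reverse moves the ring + Cl
  fl <- apply_jed_flip(tl, "X", 1, c("C1", "C2"), 180, reverse = TRUE)
  d1 <- as.matrix(dist(coords(fl)))
  ring <- which(tl$atoms$atom %in% c("C2", "C3", "C4", "C5", "C6", "C7",
                                     "CL1"))
  tail <- which(tl$atoms$atom %in% c("C8", "C9"))
  expect_lt(max(abs(d0[ring, ring] - d1[ring, ring])), 1e-9)
  expect_identical(coords(fl)[tail, ], coords(tl)[tail, ])
  # the meta-chlorine swaps sides
  expect_gt(vnorm_test(coords(fl)[tl$atoms$atom == "CL1", ] -
                         coords(tl)[tl$atoms$atom == "CL1", ]), 2)
  # flip then opposite flip restores the input
  back <- apply_jed_flip(fl, "X", 1, c("C1", "C2"), -180, reverse = TRUE)
  expect_lt(max(abs(coords(back) - coords(tl))), 1e-9)
  # 360 degrees is the identity
  full <- apply_jed_flip(tl, "X", 1, c("C1", "C2"), 360)
  expect_lt(max(abs(coords(full) - coords(tl))), 1e-9)
  expect_error(apply_jed_flip(tl, "X", 1, c("C3", "C4"), 120), "ring")
})
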