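test_that("total_score: ideal geometry is zero, harmonic terms behave", {
  rs <- build_standard_restraints(helix20)
  ts <- total_score(helix20, rs, NULL, refinement_config(map_weight = 0))
  expect_lt(ts$breakdown[["total"]], 1e-6)
  # stretching one bond by +0.1 A at sigma 0.02 raises the bond term by 25
  s2 <- make_ideal_polypeptide("AA")
  rs2 <- build_standard_restraints(s2)
  rs2$bonds <- rs2$bonds[1, ]
  rs2$angles <- rs2$angles[0, ]; rs2$torsions <- rs2$torsions[0, ]
  rs2$planes <- list(); rs2$chirals <- rs2$chirals[0, ]
  rs2$nonbonded <- rs2$nonbonded[0, ]
  rs2$bonds$sigma <- 0.02
  xyz <- coords(s2)
  dirv <- xyz[rs2$bonds$i, ] - xyz[rs2$bonds$j, ]
  xyz[rs2$bonds$i, ] <- xyz[rs2$bonds$i, ] + 0.1 * dirv / vnorm_test(dirv)
  coords(s2) <- xyz
  ts2 <- total_score(s2, rs2, NULL, refinement_config(map_weight = 0))
  expect_equal(ts2$breakdown[["bond"]], 25, tolerance = 1e-9)
  # total equals the sum of the parts
  expect_equal(ts2$breakdown[["total"]],
               sum(unclass(ts2$breakdown)[-1]))
})

test_that("total_score gradients match finite differences", {
  s <- perturb_structure(make_ideal_polypeptide("NFT"), noise_A = 0.15,
                         seed = 3)
  rs <- build_standard_restraints(s)
  rs$gm <- generate_self_gm_restraints(make_ideal_polypeptide("NFT"),
                                       limit = 4.2)
  map <- synthesize_map(make_ideal_polypeptide("NFT"))
  cfg <- refinement_config(map_weight = 0.3)
  ts <- total_score(s, rs, map, cfg)
  xyz <- coords(s); h <- 1e-6
  set.seed(17)
  for (trial in 1:30) {
    i <- sample(nrow(xyz), 1); k <- sample(3, 1)
    sp <- s; sm <- s
    cp <- xyz; cp[i, k] <- cp[i, k] + h; coords(sp) <- cp
    cm <- xyz; cm[i, k] <- cm[i, k] - h; coords(sm) <- cm
    fd <- (total_score(sp, rs, map, cfg)$breakdown[["total"]] -
             total_score(sm, rs, map, cfg)$breakdown[["total"]]) / (2 * h)
    expect_lt(abs(fd - ts$gradient[i, k]) / max(1, abs(fd)), 1e-5)
  }
  # dangling restraint reference is caught
  rs$bonds$i[1] <- 9999L
  expect_error(total_score(s, rs, NULL, cfg), "missing atom")
})

test_that("density term falls monotonically when translated off its own map", {
  shifts <- seq(0, 5, by = 1)
  scores <- vapply(shifts, function(dx)
    density_fit_score(helix20_map,
                      perturb_structure(helix20, translation = c(dx, 0, 0))),
    numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("refine_zone: monotone trace, fixed outside atoms, stationary optimum", {
  noisy <- perturb_structure(helix20, noise_A = 0.1, seed = 4)
  rs <- build_standard_restraints(noisy)
  cfg <- refinement_config(max_iter = 200)
  rr <- refine_zone(noisy, "//A/5-10", rs, helix20_map, cfg)
  expect_true(all(diff(rr$trace) <= 1e-9))
  outside <- !rsfit:::selection_mask(noisy, "//A/5-10")
  expect_identical(coords(rr$structure)[outside, ], coords(noisy)[outside, ])
  expect_lte(rr$breakdown[["total"]], rr$trace[1])
  # re-refining an already-converged model barely moves it
  rs2 <- build_standard_restraints(rr$structure)
  again <- refine_zone(rr$structure, "//A/5-10", rs2, helix20_map, cfg)
  expect_lt(structure_rmsd(again$structure, rr$structure), 0.02)
  expect_error(refine_zone(noisy, "//Z/1-2", rs, NULL, cfg), "empty")
})

test_that("with harmonic restraints only, refinement restores ideal geometry", {
  noisy <- perturb_structure(make_ideal_polypeptide(8), noise_A = 0.05,
                             seed = 6)
  rs <- build_standard_restraints(noisy)
  rr <- refine_zone(noisy, NULL, rs, NULL,
                    refinement_config(map_weight = 0, max_iter = 800,
                                      convergence_tol = 1e-10))
  expect_lt(rr$breakdown[["total"]], 1e-4)
})

test_that("rigid-body refinement recovers a displaced fragment rigidly", {
  disp <- perturb_structure(helix20, translation = c(0.7, 0.5, -0.4))
  rb <- rigid_body_refine(disp, rep(TRUE, n_atoms(disp)), helix20_map)
  expect_lt(structure_rmsd(rb$structure, helix20), 0.2)
  expect_lt(max(abs(dist(coords(disp)) - dist(coords(rb$structure)))), 1e-9)
  # applying the returned transform to the input reproduces the output
  tf <- rb$transform
  applied <- sweep(sweep(coords(disp), 2, tf$pivot) %*% t(tf$rotation), 2,
                   tf$pivot + tf$translation, `+`)
  expect_lt(max(abs(applied - coords(rb$structure))), 1e-9)
  # starting at the optimum returns (near-)identity
  rb2 <- rigid_body_refine(rb$structure, rep(TRUE, n_atoms(disp)),
                           helix20_map)
  expect_lt(max(abs(rb2$transform$rotation - diag(3))), 0.01)
  expect_lt(vnorm_test(rb2$transform$translation), 0.05)
  # degenerate fragment
  line <- helix20
  line$atoms <- line$atoms[line$atoms$atom == "CA", ][1:3, ]
  line$atoms$x <- 1:3; line$atoms$y <- 0; line$atoms$z <- 0
  expect_error(rigid_body_refine(line, rep(TRUE, 3), helix20_map),
               "degenerate|collinear")
})

test_that("jiggle fit recovers a displaced helix and is deterministic", {
  mapb <- sharpen_blur(synthesize_map(helix20, padding = 8), 200)
  pert <- perturb_structure(helix20, rotation_axis = c(0.3, 1, 0.2),
                            rotation_deg = 20,
                            translation = c(2.3, -2.6, 1.8))
  expect_gt(structure_rmsd(pert, helix20), 3)
  jf <- jiggle_fit(pert, rep(TRUE, n_atoms(pert)), mapb, n_trials = 400,
                   cfg = refinement_config(rng_seed = 1))
  expect_true(jf$accepted)
  expect_lt(structure_rmsd(jf$structure, helix20), 1.0)
  expect_gte(jf$score, jf$start_score)
  jf2 <- jiggle_fit(pert, rep(TRUE, n_atoms(pert)), mapb, n_trials = 400,
                    cfg = refinement_config(rng_seed = 1))
  expect_identical(coords(jf$structure), coords(jf2$structure))
  # starting at the truth pose, no hypothesis wins
  jf3 <- jiggle_fit(helix20, rep(TRUE, n_atoms(helix20)), mapb,
                    n_trials = 50, cfg = refinement_config(rng_seed = 2))
  expect_false(jf3$accepted)
  expect_identical(coords(jf3$structure), coords(helix20))
})

test_that("register nudge re-threads the zone and inverts on the interior", {
  s <- make_ideal_polypeptide("AVLIFSTY", conformation = "strand")
  t0 <- residue_table(s)$resname
  hyp <- nudge_register(s, "//A/1-8", 1, refine = FALSE)
  t1 <- residue_table(hyp)$resname
  expect_identical(t1[2:8], t0[1:7])
  back <- nudge_register(hyp, "//A/1-8", -1, refine = FALSE)
  t2 <- residue_table(back)$resname
  expect_identical(t2[1:7], t0[1:7])   # terminus keeps a stub
  expect_error(nudge_register(s, "//A/1-8", 0), "not a register")
  expect_error(nudge_register(s, "//A/1-3", 4), "too small")
  # input model untouched, refined hypothesis is valid
  map <- synthesize_map(s)
  hyp2 <- nudge_register(s, "//A/2-7", 1, map,
                         refinement_config(max_iter = 100))
  expect_identical(residue_table(s)$resname, t0)
  expect_true(all(is.finite(coords(hyp2))))
})
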