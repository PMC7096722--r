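test_that("backrub axis joins the flanking Calphas; termini refuse", {
  s <- make_ideal_polypeptide("AAA")
  ax <- backrub_axis(s, "A", 2)
  expect_equal(vnorm_test(ax$dir), 1)
  ca1 <- atom_pos(s, "A", 1, "CA"); ca3 <- atom_pos(s, "A", 3, "CA")
  expect_equal(ax$point, ca1)
  expect_lt(vnorm_test(ca3 - (ax$point + vnorm_test(ca3 - ca1) * ax$dir)),
            1e-9)
  expect_error(backrub_axis(s, "A", 1), "terminus")
  expect_error(backrub_axis(s, "A", 3), "terminus")
})

test_that("the moving set is residue i plus C,O(i-1) and N(i+1)", {
  s <- make_ideal_polypeptide("AAA")
  mv <- rsfit:::backrub_moving_set(s, "A", 2)
  got <- paste(s$atoms$seqnum[mv$all], s$atoms$atom[mv$all])
  own <- paste(2, c("N", "CA", "C", "O", "CB"))
  expect_setequal(got, c(own, "1 C", "1 O", "3 N"))
})

test_that("backrub hypotheses are rigid, keep central tau, bound flanking tau", {
  s <- make_ideal_polypeptide("AAA")
  tau <- function(st, i) bond_angle(atom_pos(st, "A", i, "N"),
                                    atom_pos(st, "A", i, "CA"),
                                    atom_pos(st, "A", i, "C"))
  tau0 <- vapply(1:3, function(i) tau(s, i), numeric(1))
  hyps <- generate_backrub_hypotheses(s, "A", 2)
  expect_length(hyps, 21)
  expect_true(any(vapply(hyps, function(h) h$angle == 0, logical(1))))
  dts <- c()
  for (h in hyps) {
    st <- s; nx <- coords(st); nx[h$idx, ] <- h$xyz; coords(st) <- nx
    # central residue tau exactly invariant (N, CA, C move rigidly)
    expect_lt(abs(tau(st, 2) - tau0[2]), 1e-9)
    dts <- c(dts, abs(tau(st, 1) - tau0[1]), abs(tau(st, 3) - tau0[3]))
  }
  expect_lt(median(dts), 2)
  # without the peptide back-rotations the set is a single rigid body
  raw <- generate_backrub_hypotheses(s, "A", 2, back_rotate = FALSE)
  for (h in raw[c(1, 11, 21)]) {
    expect_lt(max(abs(dist(coords(s)[h$idx, ]) - dist(h$xyz))), 1e-9)
  }
})

test_that("rotamer side chains rebuild at the requested chi angles", {
  # parameterised over every multi-chi residue type
  for (rt in c("LEU", "MET", "LYS", "ARG", "TRP", "GLU")) {
    one <- AA_ONE[[rt]]
    s <- make_ideal_polypeptide(paste0("A", one, "A"))
    for (r in ROTAMER_LIB[[rt]]) {
      s2 <- place_rotamer_side_chain(s, "A", 2, r[[3]])
      got <- measure_chis(s2, "A", 2)
      expect_lt(max(abs(wrap180(got - r[[3]]))), 0.1,
                label = paste(rt, r[[1]]))
    }
  }
  sG <- make_ideal_polypeptide("AGA")
  expect_error(place_rotamer_side_chain(sG, "A", 2, numeric(0)), "glycine")
})

test_that("clash penalty follows the overlap formula and decays with distance", {
  cand <- data.frame(element = "C", x = 0, y = 0, z = 0)
  env1 <- data.frame(element = "C", x = 1, y = 0, z = 0)
  expect_equal(clash_score(cand, env1), (2 * 1.70 - 1)^2)
  expect_equal(clash_score(cand, env1[0, ]), 0)
  seps <- seq(0.5, 4, by = 0.5)
  pens <- vapply(seps, function(d)
    clash_score(cand, data.frame(element = "C", x = d, y = 0, z = 0)),
    numeric(1))
  expect_true(all(diff(pens) <= 0))
  expect_equal(pens[length(pens)], 0)  # beyond contact distance
})

test_that("backrub fit recovers the generating rotamer and respects no-op", {
  base <- make_ideal_polypeptide("ALA")   # LEU at position 2
  truth <- place_rotamer_side_chain(base, "A", 2, c(-177, 65))  # tp rotamer
  map <- synthesize_map(truth, spacing = 0.5)
  start <- base                            # starts at top rotamer mt
  fit <- backrub_rotamer_fit(start, "A", 2, map)
  expect_true(fit$accepted)
  got <- measure_chis(fit$structure, "A", 2)
  expect_lt(abs(wrap180(got[1] - (-177))), 30)
  # map synthesized from the current pose: strict improvement fails
  own <- synthesize_map(start, spacing = 0.5)
  fit2 <- backrub_rotamer_fit(start, "A", 2, own)
  expect_false(fit2$accepted)
  expect_identical(coords(fit2$structure), coords(start))
  # peptide bonds after an accepted fit stay within 3 sigma of target
  for (i in 1:2) {
    d <- vnorm_test(atom_pos(fit$structure, "A", i, "C") -
                      atom_pos(fit$structure, "A", i + 1, "N"))
    expect_lt(abs(d - 1.329), 3 * 0.014)
  }
})

test_that("acceptance never lowers the combined score", {
  base <- make_ideal_polypeptide("ASA")
  truth <- place_rotamer_side_chain(base, "A", 2, c(-65))
  map <- synthesize_map(truth, spacing = 0.5)
  fit <- backrub_rotamer_fit(base, "A", 2, map)
  if (fit$accepted) expect_gt(fit$best$score, fit$best$current)
})
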