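test_that("selection parsing handles ranges, atoms, and round-trips", {
  sel <- parse_selection("//A/50-100")
  expect_equal(sel$chain, "A")
  expect_equal(c(sel$start, sel$end), c(50L, 100L))
  expect_identical(format_selection(sel), "//A/50-100")
  expect_identical(format_selection(parse_selection("//B")), "//B")
  expect_equal(parse_selection("//A/12")$end, 12L)
  expect_equal(parse_selection("//A/1-5/CA,CB")$atom_names, c("CA", "CB"))
  # en-dash (as printed in interactive selections) is accepted
  expect_equal(parse_selection("//A/50–100")$end, 100L)
  expect_error(parse_selection("A/1-5"), "unparseable")
  expect_error(parse_selection("//A/5-1"), "unparseable|before")
})

test_that("select_fragment extracts an inclusive range as a deep copy", {
  s <- make_ideal_polypeptide(paste(rep("A", 200), collapse = ""))
  fr <- select_fragment(s, "//A/50-100")
  expect_equal(nrow(residue_table(fr)), 51)
  before <- coords(s)
  fr$atoms$x <- fr$atoms$x + 99
  expect_identical(coords(s), before)   # master untouched
  expect_warning(empty <- select_fragment(s, "//B/1-5"), "empty")
  expect_equal(n_atoms(empty), 0)
  expect_equal(nrow(residue_table(select_fragment(s, "//A"))), 200)
})

test_that("replace_fragment writes back only the fragment atoms", {
  s <- make_ideal_polypeptide(paste(rep("A", 120), collapse = ""))
  fr <- select_fragment(s, "//A/50-100")
  fr2 <- perturb_structure(fr, translation = c(1, 0, 0))
  s2 <- replace_fragment(s, fr2)
  moved <- rowSums(abs(coords(s2) - coords(s))) > 0
  expect_setequal(unique(s$atoms$seqnum[moved]), 50:100)
  expect_equal(n_atoms(s2), n_atoms(s))
  # identity replace is the identity
  expect_identical(coords(replace_fragment(s, fr)), coords(s))
  # select then replace unchanged fragment round-trips exactly
  expect_identical(coords(replace_fragment(s, select_fragment(s, "//A/10-20"))),
                   coords(s))
  bad <- fr; bad$atoms$seqnum[1:5] <- 999L
  expect_error(replace_fragment(s, bad), "999")
})

test_that("merge_molecules remaps colliding chains to fresh ids", {
  s <- make_ideal_polypeptide(10)
  m1 <- merge_molecules(s, make_ideal_polypeptide(5))
  expect_setequal(unique(m1$atoms$chain), c("A", "B"))
  expect_equal(n_atoms(m1), n_atoms(s) + 25)
  m2 <- merge_molecules(m1, make_ideal_polypeptide(5))
  expect_setequal(unique(m2$atoms$chain), c("A", "B", "C"))
  # existing atoms never move
  expect_identical(coords(m2)[seq_len(n_atoms(m1)), ], coords(m1))
  expect_identical(coords(merge_molecules(s, rs_structure())), coords(s))
})

test_that("merge_ligand picks the closest chain and numbers above its max", {
  s <- merge_molecules(make_ideal_polypeptide(10),
                       perturb_structure(make_ideal_polypeptide(10),
                                         translation = c(40, 0, 0)))
  lig <- perturb_structure(make_toy_ligand(), translation = c(3, 10, 3))
  out <- merge_ligand(s, lig)
  la <- out$atoms[out$atoms$resname == "TOY", ]
  expect_equal(unique(la$chain), "A")   # 3 A from chain A, ~40 from B
  expect_equal(unique(la$seqnum), 11L)
  out2 <- merge_ligand(s, lig, gap = 5)
  expect_equal(unique(out2$atoms$seqnum[out2$atoms$resname == "TOY"]), 15L)
  # numbering strictly above every extant seqnum of the receiving chain
  expect_gt(min(la$seqnum), max(s$atoms$seqnum[s$atoms$chain == "A"]))
  expect_error(merge_ligand(rs_structure(), lig), "empty")
})

test_that("merge_ligand breaks exact ties toward the lower chain id", {
  a <- make_ideal_polypeptide(3, chain_id = "A")
  b <- a; b$atoms$chain <- "B"
  s <- rs_structure(rbind(a$atoms, b$atoms))   # chains coincide exactly
  out <- merge_ligand(s, make_toy_ligand())
  expect_equal(unique(out$atoms$chain[out$atoms$resname == "TOY"]), "A")
})
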