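# Derivation of modified structures: substitution eligibility, round-robin
# fairness, tailoring edits, and the zero-modification control.

sub_spec <- function(n = 1L, ...) modification_spec(n, aa_set, ...)

test_that("one substitution changes exactly one position", {
  sc <- peptide(c("gly", "ala", "ser", "val"))
  set.seed(1)
  p2 <- substitute_monomers(sc, sub_spec(1L))
  ids0 <- vapply(sc$polymer$residues, `[[`, "", "id")
  ids1 <- vapply(p2$residues, `[[`, "", "id")
  expect_equal(sum(ids0 != ids1), 1L)
  # replacement differs from the incumbent
  expect_false(any(ids1[ids0 != ids1] == ids0[ids0 != ids1]))
})

test_that("tailored residues are never substituted", {
  sc <- peptide(c("gly", "ser", "thr", "ser"))
  # glycosylate every original side-chain hydroxyl: residues 2-4 blocked
  for (a in detect_sites(sc, "glycosylation")$atom)
    sc <- execute_reaction(sc, "glycosylation", a,
                           payload = "s_hex_ohohoh", sugars = sugar_lib)
  expect_setequal(npenum:::.blocked_positions(sc), c(2L, 3L, 4L))
  set.seed(2)
  for (i in 1:10) {
    p2 <- substitute_monomers(sc, sub_spec(1L))
    ids <- unname(vapply(p2$residues, `[[`, "", "id"))
    expect_equal(ids[-1], c("ser", "thr", "ser"))
    expect_false(ids[1] == "gly")
  }
  expect_error(substitute_monomers(sc, sub_spec(2L)), "substitutable")
})

test_that("round-robin fairness: every position used once before reuse", {
  sc <- peptide(c("gly", "ala", "ser", "val", "leu"))
  state <- new_substitution_state()
  set.seed(3)
  used <- integer()
  for (i in 1:5) {
    p2 <- substitute_monomers(sc, sub_spec(1L), state, "s1")
    ids0 <- vapply(sc$polymer$residues, `[[`, "", "id")
    used <- c(used, which(ids0 != vapply(p2$residues, `[[`, "", "id")))
  }
  expect_setequal(used, 1:5)            # a full pass uses each position once
  counts <- state[["s1"]]
  expect_true(max(counts) - min(counts) <= 1L)
  # a sixth call starts the second round
  substitute_monomers(sc, sub_spec(1L), state, "s1")
  expect_equal(sum(state[["s1"]]), 6L)
  expect_true(max(state[["s1"]]) - min(state[["s1"]]) <= 1L)
})

test_that("starter units are substituted only at position 1", {
  swap <- npenum:::new_monomer_set("swap", c(aa_set$members,
                                             starter_set$members))
  sc <- condense(new_polymer(list(starter_set$members$bza, aa$ala,
                                  aa$gly)))
  spec <- modification_spec(1L, swap)
  set.seed(4)
  for (i in 1:100) {
    p2 <- substitute_monomers(sc, spec)
    classes <- vapply(p2$residues, `[[`, "", "monomer_class")
    expect_false(any(classes[-1] == "starter"))
  }
})

test_that("modified scaffolds rebuild deterministically and sanitize", {
  set.seed(5)
  cfg <- generation_config(list(aa_set, pk_set))
  plan <- reaction_plan(halogenation = 0.5, glycosylation = 0.5,
                        azole = 0.5, n_methylation = 0.5)
  for (i in 1:25) {
    sc <- apply_plan(condense(sample_polymer(cfg)), plan,
                     sugars = sugar_lib)
    mod <- derive_modified(sc, sub_spec(1L), sugars = sugar_lib)
    expect_length(check_valence(mod$mol), 0)
    expect_equal(length(mod$tailorings), length(sc$tailorings))
  }
})

test_that("zero modification reproduces the original exactly", {
  set.seed(6)
  cfg <- generation_config(aa_set)
  plan <- reaction_plan(glycosylation = 1, n_methylation = 1,
                        cyclization = 0.5)
  spec0 <- modification_spec(0L, aa_set)
  for (i in 1:10) {
    sc <- apply_plan(condense(sample_polymer(cfg)), plan,
                     sugars = sugar_lib)
    m0 <- derive_modified(sc, spec0, sugars = sugar_lib)
    expect_identical(canonical_smiles(write_smiles(m0$mol)),
                     canonical_smiles(write_smiles(sc$mol)))
  }
})

test_that("removal edits chemically revert the tailoring", {
  sc <- peptide(c("gly", "ala", "val", "gly"))
  site <- detect_sites(sc, "n_methylation")$atom[1]
  sc1 <- execute_reaction(sc, "n_methylation", site)
  spec <- modification_spec(0L, aa_set,
                            reactions_remove = c(n_methylation = 1))
  set.seed(7)
  back <- edit_tailorings(sc1, spec)
  expect_identical(inchi(write_smiles(back$mol)),
                   inchi(write_smiles(sc$mol)))
  expect_equal(formula_vec(sc1$mol)["C"] - formula_vec(back$mol)["C"],
               c(C = 1L))
  # removal of a kind with no record is a logged no-op
  spec2 <- modification_spec(0L, aa_set,
                             reactions_remove = c(glycosylation = 1))
  nop <- edit_tailorings(sc1, spec2)
  expect_match(attr(nop, "noops"), "remove:glycosylation")
})

test_that("site moves relocate the reaction or no-op without alternatives", {
  # three amide nitrogens: a move must land somewhere new
  sc <- peptide(c("gly", "ala", "val", "gly"))
  site <- detect_sites(sc, "n_methylation")$atom[1]
  sc1 <- execute_reaction(sc, "n_methylation", site)
  spec <- modification_spec(0L, aa_set,
                            reactions_move = c(n_methylation = 1))
  set.seed(8)
  mv <- edit_tailorings(sc1, spec)
  expect_equal(formula_vec(mv$mol), formula_vec(sc1$mol))
  expect_false(identical(inchi(write_smiles(mv$mol)),
                         inchi(write_smiles(sc1$mol))))
  # single glycosylatable hydroxyl: moving it is a no-op
  g4 <- peptide(c("gly", "gly", "ser", "gly"))
  g4 <- execute_reaction(g4, "glycosylation",
                         detect_sites(g4, "glycosylation")$atom[1],
                         payload = "s_hex_ohohoh", sugars = sugar_lib)
  spec2 <- modification_spec(0L, aa_set,
                             reactions_move = c(glycosylation = 1))
  mv2 <- edit_tailorings(g4, spec2, sugars = sugar_lib)
  expect_match(attr(mv2, "noops"), "no-alternative")
  expect_identical(canonical_smiles(write_smiles(mv2$mol)),
                   canonical_smiles(write_smiles(g4$mol)))
})
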