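# Polymer sampling and condensation: length bounds, starter placement,
# junction chemistry, formula conservation, determinism.

test_that("sampled polymer lengths stay within the configured range", {
  cfg <- generation_config(aa_set, length_range = c(4L, 15L))
  set.seed(1)
  lens <- replicate(500, sample_polymer(cfg)$length)
  expect_true(all(lens >= 4L & lens <= 15L))
  expect_gt(length(unique(lens)), 8L)   # spread across the range
  cfg1 <- generation_config(npenum:::new_monomer_set("g", list(aa$gly)),
                            length_range = c(1L, 1L))
  p1 <- sample_polymer(cfg1)
  expect_equal(p1$length, 1L)
  expect_equal(p1$residues[[1]]$id, "gly")
  expect_error(generation_config(aa_set, length_range = c(5L, 4L)))
})

test_that("starter units occur at position 1 only", {
  cfg <- generation_config(list(aa_set, pk_set), length_range = c(2L, 6L),
                           starter_set = starter_set, starter_prob = 1)
  set.seed(2)
  for (i in 1:200) {
    p <- sample_polymer(cfg)
    classes <- unname(vapply(p$residues, `[[`, "", "monomer_class"))
    expect_equal(classes[1], "starter")
    expect_false(any(classes[-1] == "starter"))
  }
  expect_error(new_polymer(list(aa$gly, starter_set$members[[1]])),
               "position 1")
})

test_that("condensation reproduces hand-drawn peptides (InChI oracle)", {
  expect_identical(inchi(write_smiles(condense(
    new_polymer(list(aa$gly)))$mol)), inchi("NCC(=O)O"))
  expect_identical(inchi(write_smiles(peptide(c("gly", "gly"))$mol)),
                   inchi("NCC(=O)NCC(=O)O"))
  expect_identical(inchi(write_smiles(peptide(c("gly", "ala"))$mol)),
                   inchi("NCC(=O)NC(C)C(=O)O"))
})

test_that("a tetrapeptide has exactly 3 backbone amides and free termini", {
  sc <- peptide(c("gly", "ala", "ser", "gly"))
  expect_equal(count_amides(sc$mol), 3L)
  # free N-terminal amine
  expect_equal(sc$mol$atoms$elem[sc$n_term], "N")
  expect_equal(sc$mol$atoms$nH[sc$n_term], 2L)
  # free C-terminal carboxylic acid
  adj <- npenum:::neighbor_list(sc$mol)
  os <- adj[[sc$c_term]][sc$mol$atoms$elem[adj[[sc$c_term]]] == "O"]
  expect_length(os, 2L)
})

test_that("residue map partitions all atoms and backbone is annotated", {
  set.seed(3)
  cfg <- generation_config(list(aa_set, pk_set))
  for (i in 1:10) {
    sc <- condense(sample_polymer(cfg))
    atoms <- sort(unlist(sc$residue_atoms))
    expect_identical(atoms, seq_len(n_atoms(sc$mol)))
    expect_true(all(sc$backbone %in% atoms))
  }
})

test_that("formula conservation: one H2O lost per junction", {
  set.seed(4)
  cfg <- generation_config(list(aa_set, pk_set,
                                load_monomer_set("nonproteinogenic")))
  for (i in 1:25) {
    p <- sample_polymer(cfg)
    sc <- condense(p)
    expected <- Reduce(`+`, lapply(p$residues, function(m)
      formula_vec(m$mol)))
    expected["H"] <- expected["H"] - 2L * (p$length - 1L)
    expected["O"] <- expected["O"] - (p$length - 1L)
    expect_equal(formula_vec(sc$mol), expected)
  }
})

test_that("condensation is deterministic", {
  set.seed(5)
  p <- sample_polymer(generation_config(aa_set))
  expect_identical(canonical_smiles(write_smiles(condense(p)$mol)),
                   canonical_smiles(write_smiles(condense(p)$mol)))
})

test_that("sampled scaffolds sanitize in bulk", {
  set.seed(6)
  cfg <- generation_config(list(aa_set, pk_set), starter_set = starter_set,
                           starter_prob = 0.5)
  scs <- replicate(300, condense(sample_polymer(cfg)), simplify = FALSE)
  expect_true(all(vapply(scs, function(s)
    length(check_valence(s$mol)) == 0L, NA)))
  # batched OpenBabel parse of every structure
  expect_length(canonical_smiles(vapply(scs, function(s)
    write_smiles(s$mol), "")), 300L)
})

test_that("scaffold SMILES export writes one indexed line per structure", {
  set.seed(7)
  scs <- replicate(4, condense(sample_polymer(generation_config(aa_set))),
                   simplify = FALSE)
  tf <- tempfile()
  write_scaffold_smiles(scs, tf)
  lines <- readLines(tf)
  expect_length(lines, 4L)
  expect_match(lines[4], "\t4$")
})
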