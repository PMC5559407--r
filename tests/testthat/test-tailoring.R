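# Tailoring chemistry: site detection rules, formula deltas, probabilistic
# plans, and the random-bond stress test.

test_that("site detection matches hand-enumerated examples", {
  gg <- peptide(c("gly", "gly"))
  expect_equal(nrow(detect_sites(gg, "n_methylation")), 1L)
  expect_equal(nrow(detect_sites(gg, "halogenation")), 0L)
  g4 <- peptide(c("gly", "gly", "ser", "gly"))
  expect_equal(nrow(detect_sites(g4, "cyclization")), 2L)
  # no cysteine -> no thiazole; serine at position 3 -> one azole site
  expect_equal(detect_sites(g4, "azole")$residue, 3L)
  expect_equal(nrow(detect_sites(peptide(c("gly", "ala", "val", "gly")),
                                 "azole")), 0L)
  # glycine side chains offer no halogenation carbon; leucine does
  la <- peptide(c("leu", "ala"))
  expect_gt(nrow(detect_sites(la, "halogenation")), 0L)
  expect_error(detect_sites(gg, "transglycosylation"), "unknown")
})

test_that("azole formation is never proposed at position 1", {
  cs <- peptide(c("cys", "ser", "cys"))
  expect_setequal(detect_sites(cs, "azole")$residue, c(2L, 3L))
  c1 <- peptide(c("cys", "gly"))
  expect_equal(nrow(detect_sites(c1, "azole")), 0L)
})

test_that("macrolactamization loses H2O and consumes the C-terminal acid", {
  g4 <- peptide(c("gly", "ala", "ser", "gly"))
  f0 <- formula_vec(g4$mol)
  cyc <- execute_reaction(g4, "cyclization", g4$n_term)
  f1 <- formula_vec(cyc$mol)
  expect_equal(f0 - f1, c(C = 0L, H = 2L, N = 0L, O = 1L, S = 0L))
  expect_true(cyc$cyclized)
  expect_equal(nrow(detect_sites(cyc, "cyclization")), 0L)
  # cycle rank (bonds - atoms + 1) increased by one
  expect_equal(nrow(cyc$mol$bonds) - n_atoms(cyc$mol),
               nrow(g4$mol$bonds) - n_atoms(g4$mol) + 1L)
})

test_that("macrolactonization uses a side-chain sp3 hydroxyl", {
  g4 <- peptide(c("gly", "ala", "ser", "gly"))
  sites <- detect_sites(g4, "cyclization")$atom
  oh <- setdiff(sites, g4$n_term)
  expect_length(oh, 1L)
  expect_equal(g4$mol$atoms$elem[oh], "O")
  lac <- execute_reaction(g4, "cyclization", oh)
  expect_length(check_valence(lac$mol), 0)
  expect_equal(sum(formula_vec(g4$mol) - formula_vec(lac$mol)), 3L) # H2O
})

test_that("halogenation adds Cl or Br with equal probability", {
  la <- peptide(c("leu", "ala"))
  site <- detect_sites(la, "halogenation")$atom[1]
  h <- execute_reaction(la, "halogenation", site, payload = "Cl")
  d <- formula_vec(h$mol, c("C", "H", "Cl")) -
    formula_vec(la$mol, c("C", "H", "Cl"))
  expect_equal(d, c(C = 0L, H = -1L, Cl = 1L))
  set.seed(42)
  draws <- replicate(2000, {
    hx <- execute_reaction(la, "halogenation", site)
    hx$tailorings[[1]]$payload
  })
  p_cl <- mean(draws == "Cl")
  expect_lt(abs(p_cl - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("glycosylation grafts a sugar with loss of water", {
  g4 <- peptide(c("gly", "gly", "ser", "gly"))
  site <- detect_sites(g4, "glycosylation")$atom
  expect_length(site, 1L)     # serine hydroxyl only (acids excluded)
  gs <- execute_reaction(g4, "glycosylation", site,
                         payload = "s_hex_ohohoh", sugars = sugar_lib)
  d <- formula_vec(gs$mol) - formula_vec(g4$mol)
  expect_equal(d, c(C = 6L, H = 10L, N = 0L, O = 5L, S = 0L))
  # consumed hydroxyl no longer listed; sugar hydroxyls now are
  sites2 <- detect_sites(gs, "glycosylation")$atom
  expect_false(site %in% sites2)
  expect_gt(length(sites2), 0L)
  # tyrosine phenol is an sp2-bound glycosylation site but not a
  # cyclization site
  ty <- peptide(c("gly", "tyr"))
  expect_equal(nrow(detect_sites(ty, "glycosylation")), 1L)
  expect_equal(detect_sites(ty, "cyclization")$atom, ty$n_term)
})

test_that("azole formation applies the cyclodehydration/oxidation arithmetic", {
  gc <- peptide(c("gly", "cys", "gly"))
  f0 <- formula_vec(gc$mol)
  az <- execute_reaction(gc, "azole", 2L)
  expect_equal(f0 - formula_vec(az$mol),
               c(C = 0L, H = 4L, N = 0L, O = 1L, S = 0L))  # -H2O -H2
  expect_length(check_valence(az$mol), 0)
  # the new ring is aromatic and contains the sulfur
  ar <- perceive_aromatic(az$mol)
  expect_equal(sum(ar$atom), 5L)
  expect_true(any(az$mol$atoms$elem[ar$atom] == "S"))
  # serine gives the oxazole analogue
  gs <- peptide(c("gly", "ser", "gly"))
  oz <- execute_reaction(gs, "azole", 2L)
  expect_equal(formula_vec(gs$mol) - formula_vec(oz$mol),
               c(C = 0L, H = 4L, N = 0L, O = 1L, S = 0L))
  # consumed residue is no longer a site; its amide N is gone too
  expect_false(2L %in% detect_sites(az, "azole")$residue)
  expect_false(az$tails[2] %in% detect_sites(az, "n_methylation")$atom)
})

test_that("N-methylation adds CH2 to a backbone amide nitrogen", {
  gg <- peptide(c("gly", "gly"))
  site <- detect_sites(gg, "n_methylation")$atom
  nm <- execute_reaction(gg, "n_methylation", site)
  expect_equal(formula_vec(nm$mol) - formula_vec(gg$mol),
               c(C = 1L, H = 2L, N = 0L, O = 0L, S = 0L))
  # methylated nitrogen is consumed
  expect_equal(nrow(detect_sites(nm, "n_methylation")), 0L)
  # the N-terminal amine is never a methylation site
  expect_false(gg$n_term %in% site)
})

test_that("reaction plans honor probabilistic and counted weights", {
  expect_error(reaction_plan(oxidation = 1), "unknown reaction kind")
  expect_error(reaction_plan(halogenation = -1), "non-negative")
  la <- peptide(c("leu", "leu", "leu"))
  # weight 0: never executed
  p0 <- apply_plan(la, reaction_plan(glycosylation = 0))
  expect_length(p0$tailorings, 0L)
  # integer weight 2: exactly two halogens when sites suffice
  set.seed(8)
  h2 <- apply_plan(la, reaction_plan(halogenation = 2))
  expect_equal(sum(h2$mol$atoms$elem %in% c("Cl", "Br")), 2L)
  # probabilistic weight ~0.5 across scaffolds
  set.seed(9)
  hits <- replicate(600, {
    length(apply_plan(la, reaction_plan(halogenation = 0.5))$tailorings)
  })
  expect_lt(abs(mean(hits) - 0.5), 3 * sqrt(0.25 / 600))
  # attempts without sites are logged no-ops
  gg <- peptide(c("gly", "gly"))
  res <- apply_plan(gg, reaction_plan(halogenation = 1))
  expect_length(res$tailorings, 0L)
  expect_equal(attr(res, "skipped"), "halogenation")
})

test_that("random bonds add rings and shed hydrogens", {
  hexa <- peptide(c("leu", "ala", "phe", "gly", "ser", "val"))
  expect_identical(write_smiles(add_random_bond(hexa, 0L)$mol),
                   write_smiles(hexa$mol))
  set.seed(10)
  rb <- add_random_bond(hexa, 1L)
  expect_equal(formula_vec(hexa$mol)["H"] - formula_vec(rb$mol)["H"],
               c(H = 2L))
  expect_equal(nrow(rb$mol$bonds), nrow(hexa$mol$bonds) + 1L)
  expect_length(check_valence(rb$mol), 0)
  # a 3-atom toy molecule cannot absorb 8 bonds
  toy <- condense(new_polymer(list(aa$gly)))
  expect_error(add_random_bond(toy, 8L), "achieved")
})

test_that("tailored structures sanitize over many random draws", {
  set.seed(11)
  cfg <- generation_config(list(aa_set, pk_set))
  plan <- reaction_plan(cyclization = 0.3, halogenation = 0.5,
                        glycosylation = 0.5, azole = 0.5,
                        n_methylation = 0.5)
  scs <- replicate(150, apply_plan(condense(sample_polymer(cfg)), plan,
                                   sugars = sugar_lib),
                   simplify = FALSE)
  expect_true(all(vapply(scs, function(s)
    length(check_valence(s$mol)) == 0L, NA)))
  expect_length(canonical_smiles(vapply(scs, function(s)
    write_smiles(s$mol), "")), 150L)
})
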