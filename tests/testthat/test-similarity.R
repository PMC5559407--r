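# Fingerprints and Tanimoto: determinism, family-specific discrimination
# properties, the LINGO q-gram rules, and similarity-matrix consistency.

test_that("all 17 built-in methods are registered", {
  reg <- list_similarity_methods()
  expect_equal(nrow(reg), 17L)
  expect_equal(sum(reg$family == "circular"), 8L)
  expect_equal(sum(reg$family == "substructure_keys"), 4L)
  expect_equal(sum(reg$family == "topological"), 4L)
  expect_equal(sum(reg$family == "lexicographic"), 1L)
  expect_error(get_similarity_method("GRAPE"), "unregistered")
})

test_that("fingerprints are deterministic for a fixed structure", {
  sc <- peptide(c("ala", "ser", "trp", "gly"))
  for (m in c("ECFP4", "FCFP4", "CDK-default", "EState", "LINGO",
              "KlekotaRoth")) {
    f1 <- compute_fingerprint(sc, m)
    f2 <- compute_fingerprint(sc, m)
    expect_equal(tanimoto(f1, f2), 1, label = m)
  }
})

test_that("radius-0 circular fingerprints distinguish methane from ethane", {
  f_me <- compute_fingerprint(parse_smiles("C"), "ECFP0")
  f_et <- compute_fingerprint(parse_smiles("CC"), "ECFP0")
  expect_lt(tanimoto(f_me, f_et), 1)
})

test_that("circular environments at radius 0 ignore distant changes", {
  # butane vs pentane: every atom class present in one is present in the
  # other only where first shells coincide; interior CH2 classes match
  f1 <- compute_fingerprint(parse_smiles("CCCC"), "ECFP0")
  f2 <- compute_fingerprint(parse_smiles("CCCCC"), "ECFP0")
  expect_equal(tanimoto(f1, f2), 1)
  # at radius 2 the chains differ
  g1 <- compute_fingerprint(parse_smiles("CCCC"), "ECFP4")
  g2 <- compute_fingerprint(parse_smiles("CCCCC"), "ECFP4")
  expect_lt(tanimoto(g1, g2), 1)
})

test_that("graph-only topological paths ignore bond orders", {
  bz <- parse_smiles("C1=CC=CC=C1")
  ch <- parse_smiles("C1CCCCC1")
  expect_equal(tanimoto(compute_fingerprint(bz, "CDK-graph"),
                        compute_fingerprint(ch, "CDK-graph")), 1)
  expect_lt(tanimoto(compute_fingerprint(bz, "CDK-default"),
                     compute_fingerprint(ch, "CDK-default")), 1)
  # hybridization variant separates them too (sp2 vs sp3 atoms)
  expect_lt(tanimoto(compute_fingerprint(bz, "CDK-hybridization"),
                     compute_fingerprint(ch, "CDK-hybridization")), 1)
})

test_that("LINGO follows the q-gram rules", {
  # benzene: 8-character canonical SMILES -> 5 grams after digit
  # normalization, one duplicated
  lf <- lingo_fingerprint("c1ccccc1")
  expect_equal(sum(lf), 5L)        # 8 - 4 + 1 grams in total
  expect_length(lf, 4L)            # "cccc" occurs twice
  expect_equal(unname(lf[["cccc"]]), 2L)
  expect_setequal(names(lf), c("c0cc", "0ccc", "cccc", "ccc0"))
  # short strings yield the whole-string gram
  expect_equal(lingo_fingerprint("CCO"), c(CCO = 1L))
  expect_error(lingo_fingerprint(""), "empty")
  # identical SMILES pair -> similarity 1
  sc <- peptide(c("ala", "gly"))
  f <- compute_fingerprint(sc, "LINGO")
  expect_equal(tanimoto(f, f), 1)
})

test_that("tanimoto obeys the stated examples and conventions", {
  mk <- function(ids) structure(list(method = "x", type = "bits",
                                     ids = ids), class = "np_fingerprint")
  expect_equal(tanimoto(mk(c(1L, 2L, 3L)), mk(c(2L, 3L, 4L))), 0.5)
  expect_equal(tanimoto(mk(1:3), mk(4:6)), 0)
  expect_equal(tanimoto(mk(integer()), mk(integer())), 1)
  expect_error(tanimoto(mk(1L),
                        structure(list(method = "y", type = "bits",
                                       ids = 1L),
                                  class = "np_fingerprint")),
               "different methods")
})

test_that("tanimoto is symmetric and in [0, 1] over random scaffolds", {
  set.seed(20)
  cfg <- generation_config(aa_set, length_range = c(3L, 8L))
  scs <- replicate(8, condense(sample_polymer(cfg)), simplify = FALSE)
  for (m in c("ECFP6", "EState", "LINGO")) {
    fps <- compute_fingerprints(scs, m)
    M <- tanimoto_matrix(fps, fps)
    expect_true(all(M >= 0 & M <= 1), label = m)
    expect_equal(M, t(M), label = m)
    expect_equal(unname(diag(M)), rep(1, 8), label = m)
    # matrix agrees with pairwise computation
    expect_equal(M[1, 2], tanimoto(npenum:::fp_at(fps, 1),
                                   npenum:::fp_at(fps, 2)), label = m)
  }
})

test_that("native circular similarities track an independent implementation", {
  # OpenBabel's ECFP4 is an independent implementation of the same circular
  # idea; both must agree that a one-residue variant is closer to its parent
  # than an unrelated peptide
  parent <- peptide(c("ala", "ser", "trp", "gly", "leu"))
  near <- peptide(c("ala", "ser", "trp", "gly", "val"))
  far <- peptide(c("his", "pro", "met", "cys", "arg", "glu", "lys"))
  f <- lapply(list(parent, near, far), compute_fingerprint,
              method_id = "ECFP4")
  expect_gt(tanimoto(f[[1]], f[[2]]), tanimoto(f[[1]], f[[3]]))
  smis <- vapply(list(parent, near, far), function(s)
    write_smiles(s$mol), "")
  mols <- ChemmineOB::forEachMol("SMILES",
                                 paste0(paste(smis, collapse = "\n"), "\n"),
                                 identity, reduce = c)
  fpm <- ChemmineOB::fingerprint_OB(mols, "ECFP4")
  obt <- function(i, j) {
    ni <- sum(fpm[i, ] & fpm[j, ]); nu <- sum(fpm[i, ] | fpm[j, ])
    ni / nu
  }
  expect_gt(obt(1, 2), obt(1, 3))
})

test_that("external methods plug into the registry", {
  register_similarity_method(
    "toy-external", "external",
    pair_fn = function(a, b)
      as.numeric(identical(canonical_smiles(write_smiles(a$mol)),
                           canonical_smiles(write_smiles(b$mol)))))
  m <- get_similarity_method("toy-external")
  sc <- peptide(c("gly", "ala"))
  expect_equal(m$pair_fn(sc, sc), 1)
  expect_error(compute_fingerprints(list(sc), "toy-external"), "external")
  rm("toy-external", envir = npenum:::.fp_registry)
})
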