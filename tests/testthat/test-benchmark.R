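# Experiment orchestration: strict-tie rank semantics, accuracy
# aggregation, comparison bookkeeping, determinism, and the
# zero-modification control.

test_that("rank_parent applies the strict-inequality rule", {
  r1 <- rank_parent(c(0.9, 0.5, 0.4), 1L)
  expect_equal(r1$rank, 1L)
  expect_true(r1$correct)
  r2 <- rank_parent(c(0.9, 0.9, 0.1), 1L)
  expect_equal(r2$rank, 2L)
  expect_equal(r2$n_tied, 1L)
  expect_false(r2$correct)
  r3 <- rank_parent(c(rep(0.9, 9), 0.2), 10L)
  expect_equal(r3$rank, 10L)
  expect_error(rank_parent(c(0.1, 0.2), 5L), "out of range")
})

test_that("accuracy_summary aggregates strict and tie-adjusted fractions", {
  rec <- data.frame(repeat_ = 1L, structure = 1:3, method = "M",
                    rank = c(1L, 1L, 2L), ties = c(0L, 0L, 0L),
                    correct = c(TRUE, TRUE, FALSE))
  out <- accuracy_summary(rec)
  expect_equal(out$per_repeat$fraction, 2 / 3)
  # rank 1 but tied with one competitor counts incorrect strictly,
  # half under uniform tie resolution
  rec2 <- data.frame(repeat_ = 1L, structure = 1L, method = "M",
                     rank = 2L, ties = 1L, correct = FALSE)
  out2 <- accuracy_summary(rec2)
  expect_equal(out2$per_repeat$fraction, 0)
  expect_equal(out2$per_repeat$fraction_tie_adjusted, 0.5)
  # all ranks 1
  rec3 <- rec; rec3$rank <- 1L; rec3$correct <- TRUE
  expect_equal(accuracy_summary(rec3)$summary$mean, 1)
})

test_that("a single-structure library is always matched", {
  cfg <- preset_config("proteinogenic", seed = 5, repeats = 1,
                       library_size = 1, methods = "ECFP4")
  res <- run_experiment(cfg)
  expect_equal(res$summary$mean, 1)
})

test_that("comparison bookkeeping equals repeats x library_size^2 per method", {
  cfg <- preset_config("proteinogenic", seed = 6, repeats = 3,
                       library_size = 12,
                       methods = c("ECFP0", "LINGO", "EState"))
  res <- run_experiment(cfg)
  expect_equal(unname(res$comparisons), rep(3 * 12^2, 3))
  expect_equal(nrow(res$records), 3L * 12L * 3L)
  expect_true(all(res$records$rank >= 1L & res$records$rank <= 12L))
})

test_that("zero-modification control gives parent similarity 1 everywhere", {
  set.seed(7)
  cfg <- generation_config(aa_set, length_range = c(4L, 8L))
  sc <- apply_plan(condense(sample_polymer(cfg)),
                   reaction_plan(glycosylation = 1, n_methylation = 1),
                   sugars = sugar_lib)
  spec0 <- modification_spec(0L, aa_set)
  m0 <- derive_modified(sc, spec0, sugars = sugar_lib)
  for (m in list_similarity_methods(enabled_only = TRUE)$id) {
    expect_equal(tanimoto(compute_fingerprint(sc, m),
                          compute_fingerprint(m0, m)), 1, label = m)
  }
})

test_that("experiments are deterministic for a fixed seed", {
  cfg <- preset_config("proteinogenic", seed = 8, repeats = 2,
                       library_size = 10,
                       methods = c("ECFP4", "LINGO", "KlekotaRoth"))
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$records, r2$records)
  d1 <- tempfile(); d2 <- tempfile()
  write_outputs(r1, d1); write_outputs(r2, d2)
  for (f in c("rank_distribution.tsv", "accuracy_per_repeat.tsv",
              "accuracy_summary.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # a different seed changes the rank file
  cfg$seed <- 9L
  r3 <- run_experiment(cfg)
  expect_false(identical(r1$records$rank, r3$records$rank))
})

test_that("accuracy does not increase with more substitutions", {
  accs <- vapply(c(1L, 3L), function(k) {
    cfg <- preset_config("proteinogenic", seed = 10, repeats = 2,
                         library_size = 25, n_substitutions = k,
                         methods = "ECFP4")
    run_experiment(cfg)$summary$mean
  }, 1)
  expect_gte(accs[1] + 0.02, accs[2])
})

test_that("run manifests inventory every output file with checksums", {
  cfg <- preset_config("proteinogenic", seed = 11, repeats = 1,
                       library_size = 5, methods = "ECFP2")
  res <- run_experiment(cfg)
  d <- tempfile()
  man <- write_outputs(res, d)
  expect_setequal(names(man$files),
                  c("ranks", "accuracy", "summary", "config"))
  for (f in man$files) {
    expect_true(file.exists(f$path))
    expect_identical(unname(tools::md5sum(f$path)), f$md5)
  }
  cfgy <- yaml::read_yaml(file.path(d, "config.yaml"))
  expect_equal(cfgy$library_size, 5L)
  expect_equal(cfgy$seed, 11L)
})
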