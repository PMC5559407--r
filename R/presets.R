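# Experiment presets encoding the benchmark conditions: proteinogenic
# proof-of-concept, NRP / PK / hybrid monomer alphabets, starter units,
# fixed sizes, macrocyclization, glycosylation, the complex tailored-hybrid
# experiment, and the random-bond stress test.
#
# The nonproteinogenic alphabet used by the NRP/hybrid presets is the
# 32-member core subset (the full packaged set has 45 members; see
# load_monomer_set).

.preset_sets <- function(which) {
  aa <- load_monomer_set("proteinogenic")
  switch(which,
         proteinogenic = list(aa),
         nrp = list(aa, load_monomer_set("nonproteinogenic", core32 = TRUE)),
         pk = list(expand_polyketide_monomers()),
         hybrid = list(aa,
                       load_monomer_set("nonproteinogenic", core32 = TRUE),
                       expand_polyketide_monomers()))
}

.union_set <- function(sets, name = "union") {
  new_monomer_set(name, unlist(lapply(sets, `[[`, "members"),
                               recursive = FALSE))
}

#' Names of the available experiment presets
#' @return character vector
#' @export
preset_names <- function() {
  c("proteinogenic", "nrp", "pk", "hybrid", "starter", "fixed_size",
    "cyclic", "glycosylation", "complex", "random_bond")
}

#' Build an experiment configuration from a named preset
#'
#' Presets: `proteinogenic` (linear peptides of the 20 amino acids),
#' `nrp` / `pk` / `hybrid` (linear nonribosomal peptides, polyketides, and
#' hybrids), `starter` (hybrids with a starter unit at position 1),
#' `fixed_size` (hybrids of exactly `size` monomers), `cyclic` (macrocyclized
#' hybrids), `glycosylation` (hybrids carrying `n_sugars` glycosylations),
#' `complex` (half-cyclic hybrids, two substitutions, four tailoring kinds at
#' 50% incidence with 25% remove / 25% move edits), and `random_bond`
#' (linear hybrids with `n_bonds` random bonds).
#'
#' @param preset preset name (see [preset_names()])
#' @param seed master seed
#' @param repeats,library_size experiment scale (defaults 100 x 100)
#' @param n_substitutions monomers substituted per structure (preset default
#'   otherwise)
#' @param methods similarity methods (default: all enabled registered
#'   methods)
#' @param size fixed polymer length for `fixed_size`
#' @param n_sugars glycosylations per scaffold for `glycosylation`
#' @param n_bonds random bonds for `random_bond`
#' @param length_range residue-count range (default 4-15)
#' @return an [experiment_config()]
#' @export
preset_config <- function(preset, seed = 1L, repeats = 100L,
                          library_size = 100L, n_substitutions = NULL,
                          methods = NULL, size = 8L, n_sugars = 1L,
                          n_bonds = 1L, length_range = c(4L, 15L)) {
  preset <- match.arg(preset, preset_names())
  if (is.null(methods))
    methods <- list_similarity_methods(enabled_only = TRUE)$id
  base_sets <- switch(preset,
                      proteinogenic = .preset_sets("proteinogenic"),
                      nrp = .preset_sets("nrp"),
                      pk = .preset_sets("pk"),
                      .preset_sets("hybrid"))
  starter_set <- if (preset == "starter") load_monomer_set("starters")
  else NULL
  gen <- generation_config(base_sets,
                           length_range = if (preset == "fixed_size")
                             c(size, size) else length_range,
                           starter_set = starter_set)
  swap <- .union_set(c(base_sets,
                       if (!is.null(starter_set)) list(starter_set)),
                     "substitution")
  nsub <- if (!is.null(n_substitutions)) n_substitutions
  else if (preset == "complex") 2L else 1L
  initial_plan <- switch(preset,
    cyclic = reaction_plan(cyclization = 1),
    glycosylation = reaction_plan(glycosylation = n_sugars),
    complex = reaction_plan(cyclization = 0.5, glycosylation = 0.5,
                            n_methylation = 0.5, halogenation = 0.5,
                            azole = 0.5),
    NULL)
  mod <- if (preset == "complex") {
    kinds <- c(glycosylation = 0.25, n_methylation = 0.25,
               halogenation = 0.25, azole = 0.25)
    modification_spec(nsub, swap, reactions_remove = kinds,
                      reactions_move = kinds)
  } else {
    modification_spec(nsub, swap)
  }
  experiment_config(generation = gen, mod_spec = mod, methods = methods,
                    library_size = library_size, repeats = repeats,
                    initial_plan = initial_plan,
                    random_bonds = if (preset == "random_bond") n_bonds
                    else 0L,
                    seed = seed)
}
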