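# Synthetic privileged-fragment key sets.
#
# The published Klekota-Roth (4860 substructures enriched for biological
# activity) and PubChem (881 structural keys) collections are not
# redistributable here, so the package constructs *synthetic* stand-in key
# sets of the same dimensionality and spirit: linear fragments mined from a
# deterministic corpus of natural-product building blocks (all packaged
# monomer sets, the sugar library, and the proteinogenic/ketide dipeptides
# they form).  Fragments that recur across the corpus -- present in at least
# two corpus molecules but not in nearly all of them -- are kept, ranked by
# corpus frequency, and capped at the published key counts (4860 / 881).
# Key membership of a query molecule is decided by enumerating its own
# fragments, which is equivalent to (and much faster than) SMARTS matching
# for linear patterns.

.keyset_cache <- new.env(parent = emptyenv())

# Key counts are capped at the published dimensionalities (4860 / 881).
# For the Klekota-Roth stand-in the fragment length (8 bonds) is the
# smallest bound whose mined vocabulary reaches the published key count, so
# the cap binds; the coarser PubChem stand-in saturates below its cap and
# keeps every recurring fragment (realized sizes are reported by
# fragment_key_universe()).
.KEYSET_PARAMS <- list(
  klekota_roth_synthetic = list(max_bonds = 8L, n_keys = 4860L,
                                typing = "rich"),
  pubchem_synthetic = list(max_bonds = 5L, n_keys = 881L,
                           typing = "plain")
)

.fragment_labels <- function(ctx, typing) {
  mol <- ctx$mol
  if (typing == "rich") {
    # substructure-key collections specify hydrogen counts, aromaticity and
    # ring membership; the rich typing mirrors that
    al <- paste0(ifelse(ctx$arom$atom, tolower(mol$atoms$elem),
                        mol$atoms$elem),
                 ifelse(ctx$ring_atom, "R", ""),
                 ifelse(mol$atoms$nH > 0L, paste0("H", mol$atoms$nH), ""))
    bl <- ifelse(ctx$arom$bond, ":", c("-", "=", "#")[mol$bonds$order])
  } else {
    al <- mol$atoms$elem
    bl <- c("-", "=", "#")[mol$bonds$order]
  }
  list(atom = al, bond = bl)
}

.mol_fragments <- function(ctx, params) {
  lb <- .fragment_labels(ctx, params$typing)
  cpp_path_strings(n_atoms(ctx$mol),
                   as.matrix(ctx$mol$bonds[, c("a1", "a2")]),
                   lb$atom, lb$bond, params$max_bonds)
}

# deterministic fragment corpus: every packaged building block plus the
# dipeptides/diketides they form (junction chemistry contributes fragments
# that single monomers cannot).
.keyset_corpus <- function() {
  if (!is.null(.keyset_cache$corpus)) return(.keyset_cache$corpus)
  aa <- load_monomer_set("proteinogenic")
  npa <- load_monomer_set("nonproteinogenic")
  pk <- expand_polyketide_monomers()
  st <- load_monomer_set("starters")
  sugars <- load_sugar_library()
  mols <- c(lapply(aa$members, `[[`, "mol"),
            lapply(npa$members, `[[`, "mol"),
            lapply(pk$members, `[[`, "mol"),
            lapply(st$members, `[[`, "mol"),
            lapply(sugars, `[[`, "mol"))
  # proteinogenic dipeptides (400)
  for (i in names(aa$members)) {
    for (j in names(aa$members)) {
      mols[[length(mols) + 1L]] <-
        condense(new_polymer(aa$members[c(i, j)]))$mol
    }
  }
  # ketide-ketide and amino-acid/ketide junctions (representative partners)
  for (i in names(pk$members)) {
    mols[[length(mols) + 1L]] <-
      condense(new_polymer(list(pk$members[[i]],
                                pk$members$mal_ket)))$mol
    mols[[length(mols) + 1L]] <-
      condense(new_polymer(list(pk$members$mal_ket,
                                pk$members[[i]])))$mol
    mols[[length(mols) + 1L]] <-
      condense(new_polymer(list(aa$members$gly, pk$members[[i]])))$mol
    mols[[length(mols) + 1L]] <-
      condense(new_polymer(list(pk$members[[i]], aa$members$ser)))$mol
  }
  .keyset_cache$corpus <- mols
  mols
}

#' Fragment key universe for a synthetic key set
#'
#' Built once per session from the packaged building-block corpus; fully
#' deterministic (no random input).
#'
#' @param keyset `"klekota_roth_synthetic"` or `"pubchem_synthetic"`
#' @return character vector of fragment keys (the key universe, in rank
#'   order)
#' @export
fragment_key_universe <- function(keyset) {
  params <- .KEYSET_PARAMS[[keyset]]
  if (is.null(params)) stop("unknown key set '", keyset, "'")
  if (!is.null(.keyset_cache[[keyset]])) return(.keyset_cache[[keyset]])
  corpus <- .keyset_corpus()
  frag_lists <- lapply(corpus, function(m)
    .mol_fragments(fp_context(m), params))
  df <- table(unlist(frag_lists))
  n_docs <- length(corpus)
  keep <- df >= 2L & df <= 0.9 * n_docs
  keys <- names(df)[keep]
  freq <- as.integer(df[keep])
  ord <- order(-freq, keys)
  keys <- keys[ord]
  if (length(keys) > params$n_keys) keys <- keys[seq_len(params$n_keys)]
  .keyset_cache[[keyset]] <- keys
  keys
}

# key-set fingerprint: indices of the universe keys present in the molecule
fragment_key_bits <- function(ctx, keyset) {
  universe <- fragment_key_universe(keyset)
  params <- .KEYSET_PARAMS[[keyset]]
  frags <- .mol_fragments(ctx, params)
  sort(match(intersect(frags, universe), universe))
}
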