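# Shared fixtures: monomer sets are loaded once per test run; peptides are
# built in code from the packaged alphabet.

aa_set <- load_monomer_set("proteinogenic")
aa <- aa_set$members
pk_set <- expand_polyketide_monomers()
starter_set <- load_monomer_set("starters")
sugar_lib <- load_sugar_library()

# condense a peptide given amino-acid ids
peptide <- function(ids) condense(new_polymer(aa[ids]))

# count amide bonds by direct graph inspection (independent of the
# package's backbone bookkeeping): C-N single bonds where the carbon also
# carries a double-bonded oxygen
count_amides <- function(mol) {
  adj <- npenum:::neighbor_list(mol)
  n_amide <- 0L
  for (b in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[b] != 1L) next
    a <- mol$bonds$a1[b]; z <- mol$bonds$a2[b]
    ec <- mol$atoms$elem[c(a, z)]
    if (!setequal(ec, c("C", "N"))) next
    c0 <- if (ec[1] == "C") a else z
    os <- adj[[c0]][mol$atoms$elem[adj[[c0]]] == "O"]
    has_dbl <- any(vapply(os, function(o) {
      bo <- mol$bonds[npenum:::bonds_at(mol, o), , drop = FALSE]
      any(bo$order == 2L & (bo$a1 == c0 | bo$a2 == c0))
    }, NA))
    if (isTRUE(has_dbl)) n_amide <- n_amide + 1L
  }
  n_amide
}

# formula as a complete named vector over given elements
formula_vec <- function(mol, elements = c("C", "H", "N", "O", "S")) {
  f <- mol_formula(mol)
  out <- stats::setNames(integer(length(elements)), elements)
  common <- intersect(names(f), elements)
  out[common] <- f[common]
  out
}
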