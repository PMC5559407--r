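# Polymer sampling and condensation into linear molecular scaffolds.
#
# Chain convention: residue i's head (acyl carbon) bonds residue i+1's tail
# (amine N for amino acids, alpha carbon for ketide units, hydroxyl O for
# alpha-hydroxy acids).  Residue 1 keeps a free tail (the N-terminus for
# peptides); residue n keeps a free head (the C-terminal acid).  Starter
# units expose only a head and therefore occupy only position 1.  Each
# junction loses H2O: the head's leaving hydroxyl plus one tail hydrogen.

#' Generation parameters for polymer sampling
#'
#' @param monomer_sets list of `np_monomer_set` objects to draw residues from
#'   (their union, uniformly, with replacement across positions)
#' @param length_range integer vector `c(min, max)`; the residue count is
#'   drawn uniformly from this range
#' @param starter_set optional `np_monomer_set` of starter units for
#'   position 1
#' @param starter_prob probability that position 1 is a starter unit when
#'   `starter_set` is given
#' @return a `np_generation_config`
#' @export
generation_config <- function(monomer_sets, length_range = c(4L, 15L),
                              starter_set = NULL, starter_prob = 1) {
  if (inherits(monomer_sets, "np_monomer_set"))
    monomer_sets <- list(monomer_sets)
  stopifnot(length(length_range) == 2L,
            length_range[1] >= 1L, length_range[1] <= length_range[2])
  pool <- unlist(lapply(monomer_sets, `[[`, "members"), recursive = FALSE)
  if (length(pool) == 0L) stop("empty monomer union")
  if (any(vapply(pool, `[[`, "", "monomer_class") == "starter"))
    stop("starter units belong in starter_set, not monomer_sets")
  structure(list(pool = pool, length_range = as.integer(length_range),
                 starter_set = starter_set, starter_prob = starter_prob),
            class = "np_generation_config")
}

#' Sample a random polymer (ordered monomer sequence)
#'
#' Uses R's global random number generator; seed with [set.seed()] for
#' reproducibility.
#'
#' @param config a [generation_config()]
#' @return an `np_polymer`
#' @export
sample_polymer <- function(config) {
  rng <- config$length_range
  len <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
  idx <- sample.int(length(config$pool), len, replace = TRUE)
  residues <- config$pool[idx]
  if (!is.null(config$starter_set) &&
      stats::runif(1) < config$starter_prob) {
    s <- config$starter_set$members[[
      sample.int(length(config$starter_set$members), 1L)]]
    residues[[1L]] <- s
  }
  new_polymer(residues)
}

new_polymer <- function(residues) {
  stopifnot(length(residues) >= 1L)
  classes <- vapply(residues, `[[`, "", "monomer_class")
  if (any(classes[-1L] == "starter"))
    stop("starter units may occupy only position 1")
  names(residues) <- vapply(residues, `[[`, "", "id")
  structure(list(residues = residues, length = length(residues)),
            class = "np_polymer")
}

#' @export
print.np_polymer <- function(x, ...) {
  cat(sprintf("<polymer of %d residues: %s>\n", x$length,
              paste(vapply(x$residues, `[[`, "", "id"), collapse = "-")))
  invisible(x)
}

# Leaving hydroxyl on a head carbon: a singly-bonded terminal O with >= 1 H.
# For gem-diol heads either hydroxyl may leave; the lowest index is taken.
find_leaving_oh <- function(mol, head_atom) {
  nb <- neighbor_list(mol)[[head_atom]]
  cand <- nb[mol$atoms$elem[nb] == "O" & mol$atoms$nH[nb] >= 1L]
  cand <- cand[vapply(cand, function(o) length(bonds_at(mol, o)) == 1L, NA)]
  if (length(cand) == 0L) return(NA_integer_)
  min(cand)
}

# Shortest path between two atoms restricted to a set of atoms (BFS).
shortest_path_within <- function(mol, from, to, within) {
  ok <- rep(FALSE, n_atoms(mol)); ok[within] <- TRUE
  prev <- rep(NA_integer_, n_atoms(mol))
  adj <- neighbor_list(mol)
  queue <- from; seen <- rep(FALSE, n_atoms(mol)); seen[from] <- TRUE
  while (length(queue) > 0L) {
    a <- queue[1L]; queue <- queue[-1L]
    if (a == to) {
      path <- a
      while (!is.na(prev[a])) { a <- prev[a]; path <- c(a, path) }
      return(path)
    }
    for (v in adj[[a]]) {
      if (ok[v] && !seen[v]) {
        seen[v] <- TRUE; prev[v] <- a; queue <- c(queue, v)
      }
    }
  }
  integer()
}

#' Condense a polymer into a molecular scaffold
#'
#' Forms one single bond per adjacent residue pair, from residue i's head
#' carbon to residue i+1's tail atom, deleting the head's leaving hydroxyl
#' and one tail hydrogen (net loss of one H2O per junction).  Amino-acid
#' junctions are amides; ketide junctions are carbon-carbon bonds;
#' alpha-hydroxy-acid junctions are esters.
#'
#' @param polymer an `np_polymer`
#' @return an `np_scaffold` with residue map, backbone flags, and terminal
#'   markers
#' @export
condense <- function(polymer) {
  res <- polymer$residues
  n <- length(res)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (is.na(res[[i + 1L]]$tail_atom))
        stop("residue ", i + 1L, " (", res[[i + 1L]]$id,
             ") has no tail atom and cannot be extended")
    }
  }
  # concatenate atom/bond tables (column-wise, avoiding data.frame rbind)
  offsets <- cumsum(c(0L, vapply(res, function(m) n_atoms(m$mol), 1L)))
  atoms <- data.frame(
    elem = unlist(lapply(res, function(m) m$mol$atoms$elem)),
    nH = unlist(lapply(res, function(m) m$mol$atoms$nH)),
    charge = unlist(lapply(res, function(m) m$mol$atoms$charge)),
    map = unlist(lapply(res, function(m) m$mol$atoms$map)),
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(
    a1 = unlist(lapply(seq_len(n), function(i)
      res[[i]]$mol$bonds$a1 + offsets[i])),
    a2 = unlist(lapply(seq_len(n), function(i)
      res[[i]]$mol$bonds$a2 + offsets[i])),
    order = unlist(lapply(res, function(m) m$mol$bonds$order))
  )
  mol <- new_mol(atoms, bonds)
  residue_atoms <- lapply(seq_len(n), function(i)
    seq.int(offsets[i] + 1L, offsets[i + 1L]))
  heads <- vapply(seq_len(n), function(i) res[[i]]$head_atom + offsets[i], 1L)
  tails <- vapply(seq_len(n), function(i) {
    if (is.na(res[[i]]$tail_atom)) NA_integer_
    else res[[i]]$tail_atom + offsets[i]
  }, 1L)
  # junctions
  to_delete <- integer()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      oh <- find_leaving_oh(mol, heads[i])
      if (is.na(oh))
        stop("residue ", i, " (", res[[i]]$id, ") has no leaving hydroxyl")
      tl <- tails[i + 1L]
      if (mol$atoms$nH[tl] < 1L)
        stop("residue ", i + 1L, " (", res[[i + 1L]]$id,
             ") tail has no hydrogen available for condensation")
      mol <- adjust_h(mol, tl, -1L)
      mol <- add_bond(mol, heads[i], tl, 1L)
      to_delete <- c(to_delete, oh)
    }
  }
  del <- delete_atoms(mol, to_delete)
  mol <- del$mol
  imap <- del$index_map
  residue_atoms <- lapply(residue_atoms, function(v) imap[v][!is.na(imap[v])])
  heads <- imap[heads]
  tails <- ifelse(is.na(tails), NA_integer_, imap[tails])
  # backbone: tail->head path within each residue, plus head oxygens
  adj <- neighbor_list(mol)
  backbone <- integer()
  for (i in seq_len(n)) {
    ra <- residue_atoms[[i]]
    bb <- if (is.na(tails[i])) heads[i]
    else shortest_path_within(mol, tails[i], heads[i], ra)
    head_o <- intersect(adj[[heads[i]]], ra)
    head_o <- head_o[mol$atoms$elem[head_o] == "O"]
    backbone <- c(backbone, bb, head_o)
  }
  info <- data.frame(
    position = seq_len(n),
    monomer_id = vapply(res, `[[`, "", "id"),
    class = vapply(res, `[[`, "", "monomer_class"),
    stringsAsFactors = FALSE
  )
  origin <- data.frame(res = rep(seq_len(n),
                                 vapply(residue_atoms, length, 1L)),
                       rec = NA_integer_)
  origin <- origin[order(unlist(residue_atoms)), , drop = FALSE]
  rownames(origin) <- NULL
  sc <- structure(list(
    mol = mol,
    residue_atoms = residue_atoms,
    backbone = sort(unique(backbone)),
    residue_info = info,
    heads = heads,
    tails = tails,
    n_term = tails[1L],
    c_term = heads[n],
    cyclized = FALSE,
    tailorings = list(),
    atom_origin = origin,
    polymer = polymer
  ), class = "np_scaffold")
  probs <- check_valence(sc$mol)
  if (length(probs) > 0L)
    stop("condensation produced an invalid structure: ",
         paste(probs, collapse = "; "))
  sc
}

#' @export
print.np_scaffold <- function(x, ...) {
  cat(sprintf(
    "<scaffold: %d residues (%s), %d atoms, %d tailoring(s)%s>\n",
    nrow(x$residue_info),
    paste(x$residue_info$monomer_id, collapse = "-"),
    n_atoms(x$mol), length(x$tailorings),
    if (x$cyclized) ", cyclized" else ""))
  invisible(x)
}

# Stable provenance of an atom: either (res, ord) -- within-residue ordinal,
# stable across rebuilds because per-residue atom lists are deterministic --
# or (rec, ord) for atoms added by the tailoring record with stable key
# `rec`.
atom_provenance <- function(scaffold, atom) {
  r <- scaffold$atom_origin$res[atom]
  if (!is.na(r))
    return(list(res = r, rec = NA_integer_,
                ord = match(atom, scaffold$residue_atoms[[r]])))
  key <- scaffold$atom_origin$rec[atom]
  list(res = NA_integer_, rec = key,
       ord = match(atom, .record_by_key(scaffold, key)$added_atoms))
}

# Resolve a provenance triple back to a current atom index.
resolve_provenance <- function(scaffold, prov) {
  if (!is.na(prov$res)) return(scaffold$residue_atoms[[prov$res]][prov$ord])
  .record_by_key(scaffold, prov$rec)$added_atoms[prov$ord]
}

#' SMILES export of scaffolds
#' @param scaffolds list of `np_scaffold`
#' @param path output file (one SMILES + library index per line)
#' @return `path`, invisibly
#' @export
write_scaffold_smiles <- function(scaffolds, path) {
  smi <- canonical_smiles(vapply(scaffolds,
                                 function(s) write_smiles(s$mol), ""))
  writeLines(paste0(smi, "\t", seq_along(scaffolds)), path)
  invisible(path)
}
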