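# Minimal editable molecular graph used throughout the package.
#
# A molecule ("np_mol") is a list with two data frames:
#   atoms: elem (symbol), nH (explicit hydrogen count), charge, map
#   bonds: a1, a2 (1-based atom indices), order (1, 2, 3)
#
# Structures are kept in Kekule form internally; aromaticity is perceived on
# demand.  OpenBabel (via ChemmineOB) is used for canonical SMILES and InChI,
# so equality checks and the LINGO fingerprint do not depend on the internal
# atom ordering.

.VALENCE <- list(C = 4L, N = 3L, O = 2L, S = c(2L, 4L, 6L), P = c(3L, 5L),
                 F = 1L, Cl = 1L, Br = 1L, I = 1L, B = 3L)

.allowed_valence <- function(elem, charge) {
  v <- .VALENCE[[elem]]
  if (is.null(v)) return(NA_integer_)
  if (charge != 0 && elem %in% c("N", "O", "S", "P", "C", "B")) {
    v <- v + ifelse(elem %in% c("N", "O", "S", "P"), charge, -abs(charge))
  }
  v[v >= 0]
}

new_mol <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "np_mol")
}

empty_bonds <- function() {
  data.frame(a1 = integer(), a2 = integer(), order = integer())
}

#' Number of atoms in a molecule
#' @param mol an `np_mol` molecular graph
#' @return integer atom count (heavy atoms; hydrogens are implicit)
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

# ---------------------------------------------------------------------------
# SMILES parsing (Kekule subset: uppercase organic + bracket atoms, branches,
# ring closures, bond orders -, =, #; atom maps).  Aromatic lowercase input is
# rejected: packaged tables store kekulized structures.
# ---------------------------------------------------------------------------

#' Parse a Kekule SMILES string into a molecular graph
#'
#' Supports the organic subset (C, N, O, S, P, F, Cl, Br, I, B), bracket
#' atoms with explicit hydrogen counts, charges and atom maps, branches,
#' ring-closure digits, and bond orders `-`, `=`, `#`.  Aromatic (lowercase)
#' SMILES are rejected: all packaged structures are kekulized, and aromaticity
#' is perceived from the Kekule graph when needed.
#'
#' @param smiles a single SMILES string
#' @return an `np_mol` object
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  elem <- character(); nH <- integer(); charge <- integer(); map <- integer()
  bracket <- logical()
  b_a1 <- integer(); b_a2 <- integer(); b_ord <- integer()
  prev <- NA_integer_
  stack <- integer()
  pending <- 0L                        # 0 = default single
  ring <- list()                       # digit -> c(atom, order)
  i <- 1L
  add_atom <- function(e, h, ch, mp, br) {
    elem[length(elem) + 1L] <<- e
    nH[length(nH) + 1L] <<- h
    charge[length(charge) + 1L] <<- ch
    map[length(map) + 1L] <<- mp
    bracket[length(bracket) + 1L] <<- br
    idx <- length(elem)
    if (!is.na(prev)) {
      b_a1[length(b_a1) + 1L] <<- prev
      b_a2[length(b_a2) + 1L] <<- idx
      b_ord[length(b_ord) + 1L] <<- if (pending == 0L) 1L else pending
    }
    pending <<- 0L
    prev <<- idx
    idx
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("c", "n", "o", "s", "p")) {
      stop("aromatic (lowercase) SMILES atoms are not supported; ",
           "supply a kekulized SMILES: ", smiles)
    } else if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket atom in SMILES: ", smiles)
      tok <- substr(smiles, i + 1L, j - 1L)
      m <- regmatches(tok, regexec(
        "^([A-Z][a-z]?)(H[0-9]*)?(\\+{1,2}|-{1,2}|\\+[0-9]|-[0-9])?(:[0-9]+)?$",
        tok))[[1]]
      if (length(m) == 0L) stop("cannot parse bracket atom [", tok, "]")
      if (!(m[2] %in% names(.VALENCE)))
        stop("cannot parse bracket atom [", tok, "]: unknown element ",
             m[2])
      hh <- m[3]
      h <- if (hh == "") 0L else if (hh == "H") 1L else
        as.integer(substr(hh, 2L, nchar(hh)))
      cc <- m[4]
      chg <- if (cc == "") 0L
      else if (cc == "+") 1L else if (cc == "++") 2L
      else if (cc == "-") -1L else if (cc == "--") -2L
      else if (substr(cc, 1L, 1L) == "+") as.integer(substr(cc, 2L, 3L))
      else -as.integer(substr(cc, 2L, 3L))
      mp <- if (m[5] == "") NA_integer_ else
        as.integer(substr(m[5], 2L, nchar(m[5])))
      add_atom(m[2], h, chg, mp, TRUE)
      i <- j + 1L
    } else if (ch %in% c("C", "N", "O", "S", "P", "F", "B", "I")) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, NA_integer_, 0L, NA_integer_, FALSE)
        i <- i + 2L
      } else {
        add_atom(ch, NA_integer_, 0L, NA_integer_, FALSE)
        i <- i + 1L
      }
    } else if (ch == "=") { pending <- 2L; i <- i + 1L
    } else if (ch == "#") { pending <- 3L; i <- i + 1L
    } else if (ch == "-") { pending <- 1L; i <- i + 1L
    } else if (ch == "(") { stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced parentheses in SMILES")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == "%" || grepl("[0-9]", ch)) {
      if (ch == "%") {
        if (i + 2L > n) stop("truncated %nn ring closure in SMILES")
        key <- substr(smiles, i + 1L, i + 2L)
        i <- i + 2L
      } else {
        key <- ch
      }
      if (is.null(ring[[key]])) {
        ring[[key]] <- c(prev, if (pending == 0L) 1L else pending)
        pending <- 0L
      } else {
        opened <- ring[[key]]
        ord <- max(opened[2], if (pending == 0L) 1L else pending)
        b_a1[length(b_a1) + 1L] <- opened[1]
        b_a2[length(b_a2) + 1L] <- prev
        b_ord[length(b_ord) + 1L] <- ord
        ring[[key]] <- NULL
        pending <- 0L
      }
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in SMILES: ", smiles)
    }
  }
  if (length(ring) > 0L) stop("unclosed ring bond in SMILES: ", smiles)
  if (length(stack) > 0L) stop("unbalanced parentheses in SMILES: ", smiles)
  atoms <- data.frame(elem = elem, nH = nH, charge = charge, map = map,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = b_a1, a2 = b_a2, order = b_ord)
  mol <- new_mol(atoms, bonds)
  # implicit hydrogens for non-bracket atoms: smallest allowed valence
  bs <- bond_order_sums(mol)
  for (a in seq_len(nrow(atoms))) {
    if (is.na(atoms$nH[a])) {
      v <- .allowed_valence(atoms$elem[a], atoms$charge[a])
      fit <- v[v >= bs[a]]
      mol$atoms$nH[a] <- if (length(fit) == 0L) 0L else min(fit) - bs[a]
    }
  }
  mol
}

bond_order_sums <- function(mol) {
  bs <- integer(n_atoms(mol))
  if (nrow(mol$bonds) > 0L) {
    tab <- rowsum(c(mol$bonds$order, mol$bonds$order),
                  c(mol$bonds$a1, mol$bonds$a2))
    bs[as.integer(rownames(tab))] <- tab[, 1L]
  }
  bs
}

#' Validate atom valences of a molecular graph
#'
#' @param mol an `np_mol`
#' @return character vector of problems; length zero when the molecule is
#'   valence-valid
#' @export
check_valence <- function(mol) {
  probs <- character()
  if (nrow(mol$bonds) > 0L) {
    key <- paste(pmin(mol$bonds$a1, mol$bonds$a2),
                 pmax(mol$bonds$a1, mol$bonds$a2))
    if (anyDuplicated(key)) probs <- c(probs, "duplicate bond")
    if (any(mol$bonds$a1 == mol$bonds$a2)) probs <- c(probs, "self bond")
    if (any(c(mol$bonds$a1, mol$bonds$a2) > n_atoms(mol)) ||
        any(c(mol$bonds$a1, mol$bonds$a2) < 1L))
      probs <- c(probs, "bond endpoint out of range")
  }
  bs <- bond_order_sums(mol)
  for (a in seq_len(n_atoms(mol))) {
    v <- .allowed_valence(mol$atoms$elem[a], mol$atoms$charge[a])
    tot <- bs[a] + mol$atoms$nH[a]
    if (anyNA(v)) {
      probs <- c(probs, paste0("unknown element ", mol$atoms$elem[a]))
    } else if (!(tot %in% v) || mol$atoms$nH[a] < 0L) {
      probs <- c(probs, sprintf("atom %d (%s) has valence %d (allowed: %s)",
                                a, mol$atoms$elem[a], tot,
                                paste(v, collapse = "/")))
    }
  }
  probs
}

#' Molecular formula of a molecular graph
#' @param mol an `np_mol`
#' @return named integer vector of element counts, including implicit H
#' @export
mol_formula <- function(mol) {
  counts <- table(mol$atoms$elem)
  out <- stats::setNames(as.integer(counts), names(counts))
  h <- sum(mol$atoms$nH)
  out["H"] <- (if ("H" %in% names(out)) out[["H"]] else 0L) + h
  out[order(names(out))]
}

#' Render a molecular formula as a Hill-order string
#' @param counts named integer vector as from [mol_formula()]
#' @return character formula string, e.g. `"C2H5NO2"`
#' @export
formula_string <- function(counts) {
  counts <- counts[counts > 0L]
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, ""), collapse = "")
}

# ---------------------------------------------------------------------------
# Graph edits.  All edits keep the atom table consistent; deletions remap
# bond indices and return the index map so callers can update annotations.
# ---------------------------------------------------------------------------

add_bond <- function(mol, a1, a2, order = 1L) {
  mol$bonds <- rbind(mol$bonds, data.frame(a1 = a1, a2 = a2, order = order))
  mol
}

add_atom <- function(mol, elem, nH = 0L, charge = 0L) {
  mol$atoms <- rbind(mol$atoms,
                     data.frame(elem = elem, nH = as.integer(nH),
                                charge = as.integer(charge),
                                map = NA_integer_, stringsAsFactors = FALSE))
  mol
}

# Remove atoms; returns list(mol, index_map) where index_map[old] = new or NA.
delete_atoms <- function(mol, idx) {
  keep <- setdiff(seq_len(n_atoms(mol)), idx)
  index_map <- rep(NA_integer_, n_atoms(mol))
  index_map[keep] <- seq_along(keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds[!(mol$bonds$a1 %in% idx | mol$bonds$a2 %in% idx), ,
                     drop = FALSE]
  bonds$a1 <- index_map[bonds$a1]
  bonds$a2 <- index_map[bonds$a2]
  rownames(bonds) <- NULL
  list(mol = new_mol(atoms, bonds), index_map = index_map)
}

set_bond_order <- function(mol, a1, a2, order) {
  hit <- (mol$bonds$a1 == a1 & mol$bonds$a2 == a2) |
    (mol$bonds$a1 == a2 & mol$bonds$a2 == a1)
  if (!any(hit)) stop("no bond between atoms ", a1, " and ", a2)
  mol$bonds$order[hit] <- order
  mol
}

adjust_h <- function(mol, atom, delta) {
  mol$atoms$nH[atom] <- mol$atoms$nH[atom] + as.integer(delta)
  if (any(mol$atoms$nH[atom] < 0L)) stop("negative hydrogen count on atom")
  mol
}

neighbor_list <- function(mol) {
  n <- n_atoms(mol)
  ends <- c(mol$bonds$a1, mol$bonds$a2)
  other <- c(mol$bonds$a2, mol$bonds$a1)
  adj <- rep(list(integer()), n)
  if (length(ends) > 0L) {
    grp <- split(other, factor(ends, levels = seq_len(n)))
    adj <- unname(grp)
  }
  adj
}

bonds_at <- function(mol, atom) {
  which(mol$bonds$a1 == atom | mol$bonds$a2 == atom)
}

are_bonded <- function(mol, a1, a2) {
  any((mol$bonds$a1 == a1 & mol$bonds$a2 == a2) |
        (mol$bonds$a1 == a2 & mol$bonds$a2 == a1))
}

# ---------------------------------------------------------------------------
# Ring perception (bridge detection) and aromaticity.
# ---------------------------------------------------------------------------

# Bonds that lie on a cycle (i.e. are not bridges), via iterative DFS
# low-link computation.
ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(logical(0))
  n <- n_atoms(mol)
  adj <- rep(list(NULL), n)
  for (b in seq_len(nb)) {
    a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
    adj[[a1]] <- rbind(adj[[a1]], c(a2, b))
    adj[[a2]] <- rbind(adj[[a2]], c(a1, b))
  }
  disc <- rep(0L, n); low <- rep(0L, n)
  is_bridge <- rep(FALSE, nb)
  timer <- 0L
  for (root in seq_len(n)) {
    if (disc[root] > 0L) next
    stack <- list(list(a = root, pe = 0L, i = 1L))
    timer <- timer + 1L
    disc[root] <- low[root] <- timer
    while (length(stack) > 0L) {
      fr <- stack[[length(stack)]]
      nbrs <- adj[[fr$a]]
      if (!is.null(nbrs) && fr$i <= nrow(nbrs)) {
        stack[[length(stack)]]$i <- fr$i + 1L
        v <- nbrs[fr$i, 1L]; be <- nbrs[fr$i, 2L]
        if (be == fr$pe) next
        if (disc[v] == 0L) {
          timer <- timer + 1L
          disc[v] <- low[v] <- timer
          stack[[length(stack) + 1L]] <- list(a = v, pe = be, i = 1L)
        } else {
          low[fr$a] <- min(low[fr$a], disc[v])
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack) > 0L) {
          par <- stack[[length(stack)]]$a
          low[par] <- min(low[par], low[fr$a])
          if (low[fr$a] > disc[par]) is_bridge[fr$pe] <- TRUE
        }
      }
    }
  }
  !is_bridge
}

#' Perceive aromatic atoms and bonds on a Kekule molecular graph
#'
#' Ring systems (connected components of cyclic bonds) are tested with a
#' Hueckel-style rule: every ring atom must be sp2-capable (carbon with one
#' double bond into the system; nitrogen with an in-system double bond or a
#' lone pair; divalent O/S) and the total pi-electron count over the fused
#' system must equal 4n + 2.
#'
#' @param mol an `np_mol`
#' @return list with logical vectors `atom` and `bond`
#' @export
perceive_aromatic <- function(mol) {
  n <- n_atoms(mol)
  arom_atom <- rep(FALSE, n)
  arom_bond <- rep(FALSE, nrow(mol$bonds))
  rb <- ring_bonds(mol)
  if (!any(rb)) return(list(atom = arom_atom, bond = arom_bond))
  ring_b <- which(rb)
  # connected components over ring bonds
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (b in ring_b) {
    r1 <- find(mol$bonds$a1[b]); r2 <- find(mol$bonds$a2[b])
    if (r1 != r2) parent[r1] <- r2
  }
  roots <- vapply(seq_len(n), find, 1L)
  sys_ids <- unique(roots[mol$bonds$a1[ring_b]])
  deg_dbl <- integer(n)       # number of double bonds at each atom
  for (b in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[b] == 2L) {
      deg_dbl[mol$bonds$a1[b]] <- deg_dbl[mol$bonds$a1[b]] + 1L
      deg_dbl[mol$bonds$a2[b]] <- deg_dbl[mol$bonds$a2[b]] + 1L
    }
  }
  for (s in sys_ids) {
    atoms_s <- which(roots == s)
    atoms_s <- atoms_s[atoms_s %in% c(mol$bonds$a1[ring_b],
                                      mol$bonds$a2[ring_b])]
    if (length(atoms_s) < 5L) next
    in_sys <- rep(FALSE, n); in_sys[atoms_s] <- TRUE
    ok <- TRUE; n_pi_dbl <- 0L; n_lone <- 0L
    # in-system double bonds
    for (b in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$order[b] == 2L && in_sys[mol$bonds$a1[b]] &&
          in_sys[mol$bonds$a2[b]] && rb[b])
        n_pi_dbl <- n_pi_dbl + 1L
    }
    for (a in atoms_s) {
      e <- mol$atoms$elem[a]
      if (mol$atoms$charge[a] != 0L) { ok <- FALSE; break }
      bidx <- bonds_at(mol, a)
      dbl_in <- any(mol$bonds$order[bidx] == 2L & rb[bidx] &
                      in_sys[mol$bonds$a1[bidx]] & in_sys[mol$bonds$a2[bidx]])
      if (e == "C") {
        if (!(deg_dbl[a] == 1L && dbl_in)) { ok <- FALSE; break }
      } else if (e == "N") {
        if (dbl_in) {
          # pyridine-type: contributes no lone pair
        } else if (deg_dbl[a] == 0L) {
          n_lone <- n_lone + 1L   # pyrrole-type
        } else { ok <- FALSE; break }
      } else if (e %in% c("O", "S")) {
        if (deg_dbl[a] != 0L) { ok <- FALSE; break }
        n_lone <- n_lone + 1L
      } else { ok <- FALSE; break }
    }
    if (!ok) next
    n_pi <- 2L * n_pi_dbl + 2L * n_lone
    if (n_pi %% 4L != 2L) next
    arom_atom[atoms_s] <- TRUE
    hit <- rb & in_sys[mol$bonds$a1] & in_sys[mol$bonds$a2]
    arom_bond[hit] <- TRUE
  }
  list(atom = arom_atom, bond = arom_bond)
}

# Hybridization codes: 1 = sp, 2 = sp2, 3 = sp3 (from Kekule bond orders).
hybridization <- function(mol, arom = NULL) {
  n <- n_atoms(mol)
  n_dbl <- integer(n); n_trp <- integer(n)
  for (b in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[b] == 2L) {
      n_dbl[mol$bonds$a1[b]] <- n_dbl[mol$bonds$a1[b]] + 1L
      n_dbl[mol$bonds$a2[b]] <- n_dbl[mol$bonds$a2[b]] + 1L
    } else if (mol$bonds$order[b] == 3L) {
      n_trp[mol$bonds$a1[b]] <- n_trp[mol$bonds$a1[b]] + 1L
      n_trp[mol$bonds$a2[b]] <- n_trp[mol$bonds$a2[b]] + 1L
    }
  }
  hyb <- rep(3L, n)
  hyb[n_dbl >= 1L] <- 2L
  if (!is.null(arom)) hyb[arom$atom] <- 2L
  hyb[n_trp >= 1L | n_dbl >= 2L] <- 1L
  hyb
}

# ---------------------------------------------------------------------------
# SMILES writing.  Always-bracket form: every atom is written with explicit
# hydrogen count and charge, which round-trips exactly through the parser and
# through OpenBabel.  Output is kekulized (internal representation).
# ---------------------------------------------------------------------------

#' Write a molecular graph as a (non-canonical) Kekule SMILES string
#'
#' Atoms are emitted in bracket form with explicit hydrogen counts so the
#' string is dialect-free.  Use [canonical_smiles()] for canonical output.
#'
#' @param mol an `np_mol`
#' @return SMILES string
#' @export
write_smiles <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return("")
  adj <- rep(list(NULL), n)
  for (b in seq_len(nrow(mol$bonds))) {
    a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
    adj[[a1]] <- rbind(adj[[a1]], c(a2, mol$bonds$order[b]))
    adj[[a2]] <- rbind(adj[[a2]], c(a1, mol$bonds$order[b]))
  }
  visited <- rep(FALSE, n)
  atom_token <- function(a) {
    at <- mol$atoms[a, ]
    h <- if (at$nH == 0L) "" else if (at$nH == 1L) "H" else paste0("H", at$nH)
    ch <- if (at$charge == 0L) ""
    else if (at$charge == 1L) "+" else if (at$charge == -1L) "-"
    else if (at$charge > 1L) paste0("+", at$charge)
    else paste0("-", -at$charge)
    paste0("[", at$elem, h, ch, "]")
  }
  bond_token <- function(ord) c("", "=", "#")[ord]
  out <- character()
  for (root in seq_len(n)) {
    if (visited[root]) next
    if (length(out) > 0L) out <- c(out, ".")
    pieces <- emit_tokens_dfs(mol, adj, root, visited, atom_token, bond_token)
    visited <- pieces$visited
    out <- c(out, pieces$tokens)
  }
  paste0(out, collapse = "")
}

# DFS SMILES emitter for one connected component (recursive; molecules are
# small).  Returns tokens and updated visited vector.
emit_tokens_dfs <- function(mol, adj, root, visited, atom_token, bond_token) {
  n <- n_atoms(mol)
  closures <- rep(list(character()), n)   # digit strings per atom
  digit_next <- 0L
  tree_children <- rep(list(NULL), n)     # rows (child, order)
  back_seen <- character()
  visited_local <- visited
  # first DFS: build spanning tree + back edges
  stack <- list(list(a = root, i = 1L, pe_key = ""))
  visited_local[root] <- TRUE
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]
    nbrs <- adj[[fr$a]]
    if (!is.null(nbrs) && fr$i <= nrow(nbrs)) {
      stack[[length(stack)]]$i <- fr$i + 1L
      v <- nbrs[fr$i, 1L]; ord <- nbrs[fr$i, 2L]
      key <- paste(min(fr$a, v), max(fr$a, v))
      if (key == fr$pe_key) {
        # skip the tree edge back to parent (once)
        stack[[length(stack)]]$pe_key <- ""
        next
      }
      if (!visited_local[v]) {
        visited_local[v] <- TRUE
        tree_children[[fr$a]] <- rbind(tree_children[[fr$a]], c(v, ord))
        stack[[length(stack) + 1L]] <- list(a = v, i = 1L, pe_key = key)
      } else if (!(key %in% back_seen)) {
        back_seen <- c(back_seen, key)
        digit_next <- digit_next + 1L
        if (digit_next > 99L) stop("more than 99 ring closures")
        dg <- if (digit_next <= 9L) as.character(digit_next) else
          sprintf("%%%02d", digit_next)
        btok <- bond_token(ord)
        closures[[fr$a]] <- c(closures[[fr$a]], paste0(btok, dg))
        closures[[v]] <- c(closures[[v]], dg)
      }
    } else {
      stack[[length(stack)]] <- NULL
    }
  }
  # second DFS over the spanning tree, emitting tokens
  tokens <- character()
  emit <- function(a, bond_ord) {
    tks <- character()
    if (!is.na(bond_ord)) tks <- c(tks, bond_token(bond_ord))
    tks <- c(tks, paste0(atom_token(a), paste(closures[[a]], collapse = "")))
    ch <- tree_children[[a]]
    if (!is.null(ch)) {
      nc <- nrow(ch)
      for (k in seq_len(nc)) {
        sub <- emit(ch[k, 1L], ch[k, 2L])
        if (k < nc) {
          tks <- c(tks, "(", sub, ")")
        } else {
          tks <- c(tks, sub)
        }
      }
    }
    tks
  }
  tokens <- emit(root, NA_integer_)
  list(tokens = tokens, visited = visited_local)
}

# ---------------------------------------------------------------------------
# OpenBabel bridge: canonicalization, InChI, and round-trip sanitization.
# ---------------------------------------------------------------------------

# Batch conversion through the openbabel command-line tool, which handles
# large batches far faster than per-molecule library calls.  Titles keep the
# input/output alignment explicit, so parse failures are detectable.
.ob_convert <- function(smiles, to) {
  ob <- Sys.which("obabel")
  if (!nzchar(ob)) stop("the 'obabel' executable is required but not found")
  inp <- tempfile(fileext = ".smi")
  outp <- tempfile(fileext = ".txt")
  on.exit(unlink(c(inp, outp)), add = TRUE)
  writeLines(paste0(smiles, " m", seq_along(smiles)), inp)
  fmt <- c(CAN = "-ocan", INCHI = "-oinchi")[[to]]
  status <- suppressWarnings(system2(
    ob, c(inp, fmt, "-O", shQuote(outp)),
    stdout = FALSE, stderr = FALSE))
  if (status != 0L || !file.exists(outp))
    stop("obabel conversion to ", to, " failed")
  lines <- readLines(outp, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (to == "INCHI") {
    # the InChI writer drops titles; alignment is positional
    if (length(lines) != length(smiles))
      stop("OpenBabel failed to convert ",
           length(smiles) - length(lines), " structure(s)")
    return(lines)
  }
  parts <- regmatches(lines, regexpr("[ \t]m[0-9]+$", lines))
  idx <- as.integer(sub("^[ \t]m", "", parts))
  vals <- sub("[ \t]m[0-9]+$", "", lines)
  vals <- sub("[ \t]+$", "", vals)
  out <- rep(NA_character_, length(smiles))
  out[idx] <- vals
  if (anyNA(out))
    stop("OpenBabel failed to convert ", sum(is.na(out)), " structure(s)")
  out
}

#' Canonical SMILES via OpenBabel
#'
#' One canonicalizer is used everywhere in the package (structure equality
#' checks, LINGO q-grams, deterministic output files).
#'
#' @param smiles character vector of SMILES strings (or an `np_mol`)
#' @return character vector of canonical SMILES
#' @export
canonical_smiles <- function(smiles) {
  if (inherits(smiles, "np_mol")) smiles <- write_smiles(smiles)
  out <- .ob_convert(smiles, "CAN")
  if (length(out) != length(smiles))
    stop("OpenBabel failed to canonicalize ",
         length(smiles) - length(out), " structure(s)")
  out
}

#' InChI via OpenBabel
#' @param smiles character vector of SMILES (or an `np_mol`)
#' @return character vector of InChI strings
#' @export
inchi <- function(smiles) {
  if (inherits(smiles, "np_mol")) smiles <- write_smiles(smiles)
  out <- .ob_convert(smiles, "INCHI")
  if (length(out) != length(smiles))
    stop("OpenBabel failed to generate InChI for ",
         length(smiles) - length(out), " structure(s)")
  out
}

#' Sanitize a molecular graph
#'
#' Combines the package's strict valence model with an OpenBabel parse
#' round-trip.  Errors (or returns problems) when the structure is invalid.
#'
#' @param mol an `np_mol`
#' @param strict error on failure (default) instead of returning problems
#' @return invisibly, a character vector of problems (empty when valid)
#' @export
sanitize <- function(mol, strict = TRUE) {
  probs <- check_valence(mol)
  if (length(probs) == 0L) {
    smi <- write_smiles(mol)
    ok <- tryCatch(length(.ob_convert(smi, "CAN")) == 1L,
                   error = function(e) FALSE)
    if (!ok) probs <- "OpenBabel could not parse the generated SMILES"
  }
  if (strict && length(probs) > 0L)
    stop("structure failed sanitization: ", paste(probs, collapse = "; "))
  invisible(probs)
}
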