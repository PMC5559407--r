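# Tailoring reactions: site detection, execution, probabilistic plans, and
# the random-bond stress test.
#
# Reactions are recorded as replayable records (kind, provenance of the site
# atom, payload such as the chosen halogen or sugar).  Because tailored
# residues are never substituted, records re-resolve deterministically on a
# rebuilt scaffold (see rebuild_scaffold), which is how modified structures
# "of the same assembly line" are derived.

.REACTION_KINDS <- c("cyclization", "halogenation", "glycosylation",
                     "azole", "n_methylation", "random_bond")

#' Build a tailoring reaction plan
#'
#' Each entry pairs a reaction kind with a weight: a weight below 1 is the
#' per-scaffold probability of attempting the reaction once; an integer
#' weight k attempts k executions.  An attempt with no available site is a
#' logged no-op.
#'
#' @param ... reaction weights by name, e.g.
#'   `reaction_plan(halogenation = 0.5, glycosylation = 1)`
#' @return an `np_reaction_plan`
#' @export
reaction_plan <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1]]) &&
      is.null(names(entries)))
    entries <- entries[[1]]
  kinds <- names(entries)
  if (length(entries) > 0L && (is.null(kinds) || any(!nzchar(kinds))))
    stop("reaction plan entries must be named by reaction kind")
  bad <- setdiff(kinds, .REACTION_KINDS)
  if (length(bad) > 0L)
    stop("unknown reaction kind(s): ", paste(bad, collapse = ", "))
  w <- vapply(entries, as.numeric, 1)
  if (any(w < 0)) stop("reaction weights must be non-negative")
  structure(list(kinds = kinds, weights = unname(w)),
            class = "np_reaction_plan")
}

# hydroxyl oxygens: terminal O with at least one H, bonded to a carbon
.hydroxyl_oxygens <- function(mol, adj) {
  which(vapply(seq_len(n_atoms(mol)), function(a) {
    mol$atoms$elem[a] == "O" && mol$atoms$nH[a] >= 1L &&
      length(adj[[a]]) == 1L && mol$atoms$elem[adj[[a]]] == "C"
  }, NA))
}

.n_double_bonds <- function(mol) {
  n <- n_atoms(mol)
  nd <- integer(n)
  dbl <- mol$bonds[mol$bonds$order == 2L, , drop = FALSE]
  for (i in seq_len(nrow(dbl))) {
    nd[dbl$a1[i]] <- nd[dbl$a1[i]] + 1L
    nd[dbl$a2[i]] <- nd[dbl$a2[i]] + 1L
  }
  nd
}

# Does the C-terminal head still carry a free carboxylic acid?
.has_free_carboxyl <- function(scaffold, adj = neighbor_list(scaffold$mol)) {
  if (scaffold$cyclized) return(FALSE)
  mol <- scaffold$mol
  ct <- scaffold$c_term
  os <- adj[[ct]][mol$atoms$elem[adj[[ct]]] == "O"]
  has_dbl <- any(vapply(os, function(o)
    any(mol$bonds$order[bonds_at(mol, o)] == 2L), NA))
  has_oh <- any(mol$atoms$nH[os] >= 1L &
                  vapply(os, function(o) length(adj[[o]]) == 1L, NA))
  isTRUE(has_dbl) && isTRUE(has_oh)
}

# Serine/cysteine-like side chains: X (O/S, terminal, with H) on a CH2 beta
# carbon attached to the backbone alpha carbon.  Returns rows
# (residue, calpha, cbeta, x) for residues at position >= 2 whose preceding
# junction is an intact amide.
.azole_candidates <- function(scaffold, adj) {
  mol <- scaffold$mol
  n <- nrow(scaffold$residue_info)
  out <- NULL
  nd <- .n_double_bonds(mol)
  for (r in seq_len(n)[-1L]) {
    tl <- scaffold$tails[r]
    if (is.na(tl) || mol$atoms$elem[tl] != "N") next
    if (mol$atoms$nH[tl] < 1L) next      # consumed (azole ring or methylated+?)
    prev_head <- scaffold$heads[r - 1L]
    # preceding carbonyl must be intact
    os <- adj[[prev_head]][mol$atoms$elem[adj[[prev_head]]] == "O"]
    if (!any(vapply(os, function(o)
      any(mol$bonds$order[bonds_at(mol, o)] == 2L), NA)))
      next
    ra <- scaffold$residue_atoms[[r]]
    path <- shortest_path_within(mol, tl, scaffold$heads[r], ra)
    if (length(path) != 3L) next        # alpha-amino acids only
    ca <- path[2L]
    if (nd[ca] > 0L || mol$atoms$nH[ca] < 1L) next
    for (cb in setdiff(adj[[ca]], path)) {
      if (!(cb %in% ra) || mol$atoms$elem[cb] != "C") next
      if (mol$atoms$nH[cb] != 2L || length(adj[[cb]]) != 2L) next
      x <- setdiff(adj[[cb]], ca)
      if (length(x) != 1L) next
      if (!(mol$atoms$elem[x] %in% c("O", "S"))) next
      if (mol$atoms$nH[x] < 1L || length(adj[[x]]) != 1L) next
      out <- rbind(out, data.frame(residue = r, calpha = ca, cbeta = cb,
                                   x = x))
    }
  }
  if (is.null(out)) data.frame(residue = integer(), calpha = integer(),
                               cbeta = integer(), x = integer())
  else out
}

#' Detect candidate sites for a tailoring reaction
#'
#' Site rules: cyclization pairs the N-terminal free amine and every
#' sp3-carbon-bound hydroxyl with the C-terminal carboxyl (empty once
#' cyclized); halogenation lists every non-backbone carbon with an available
#' hydrogen; O-glycosylation lists every sp2- or sp3-carbon-bound hydroxyl
#' (carboxylic-acid hydroxyls excluded); azole formation lists every
#' serine/cysteine-type residue at position >= 2 whose preceding amide
#' carbonyl is intact; N-methylation lists every backbone amide nitrogen
#' still carrying a hydrogen.
#'
#' @param scaffold an `np_scaffold`
#' @param kind one of `"cyclization"`, `"halogenation"`, `"glycosylation"`,
#'   `"azole"`, `"n_methylation"`
#' @return data frame of candidate sites with column `atom` (or `residue`
#'   for azole formation)
#' @export
detect_sites <- function(scaffold, kind) {
  mol <- scaffold$mol
  adj <- neighbor_list(mol)
  nd <- .n_double_bonds(mol)
  if (kind == "cyclization") {
    if (!.has_free_carboxyl(scaffold, adj))
      return(data.frame(atom = integer()))
    sites <- integer()
    nt <- scaffold$n_term
    if (!is.na(nt) && mol$atoms$elem[nt] == "N" && mol$atoms$nH[nt] >= 1L)
      sites <- nt
    oh <- .hydroxyl_oxygens(mol, adj)
    carbons <- vapply(oh, function(o) adj[[o]], 1L)
    sp3 <- nd[carbons] == 0L
    not_cterm <- carbons != scaffold$c_term
    sites <- c(sites, oh[sp3 & not_cterm])
    data.frame(atom = sites)
  } else if (kind == "halogenation") {
    cand <- setdiff(which(mol$atoms$elem == "C" & mol$atoms$nH >= 1L),
                    scaffold$backbone)
    data.frame(atom = cand)
  } else if (kind == "glycosylation") {
    oh <- .hydroxyl_oxygens(mol, adj)
    carbons <- vapply(oh, function(o) adj[[o]], 1L)
    # exclude acid hydroxyls: carbon also bears a double-bonded oxygen
    acid <- vapply(carbons, function(c0) {
      os <- adj[[c0]][mol$atoms$elem[adj[[c0]]] == "O"]
      any(vapply(os, function(o)
        any(mol$bonds$order[bonds_at(mol, o)] == 2L), NA))
    }, NA)
    data.frame(atom = oh[!acid])
  } else if (kind == "azole") {
    .azole_candidates(scaffold, adj)[, "residue", drop = FALSE]
  } else if (kind == "n_methylation") {
    n <- nrow(scaffold$residue_info)
    sites <- integer()
    for (r in seq_len(n)[-1L]) {
      tl <- scaffold$tails[r]
      if (is.na(tl) || mol$atoms$elem[tl] != "N") next
      if (!grepl("_aa$", scaffold$residue_info$class[r])) next
      if (mol$atoms$nH[tl] < 1L) next
      prev_head <- scaffold$heads[r - 1L]
      os <- adj[[prev_head]][mol$atoms$elem[adj[[prev_head]]] == "O"]
      if (!any(vapply(os, function(o)
        any(mol$bonds$order[bonds_at(mol, o)] == 2L), NA)))
        next                             # not an amide nitrogen
      sites <- c(sites, tl)
    }
    data.frame(atom = sites)
  } else {
    stop("unknown reaction kind '", kind, "'")
  }
}

# next unique record key for a scaffold (keys are stable across rebuilds,
# unlike list positions, so records can reference the records whose atoms
# they modified)
.next_record_key <- function(scaffold) {
  keys <- vapply(scaffold$tailorings, function(tr)
    if (is.null(tr$key)) 0L else tr$key, 1L)
  if (length(keys) == 0L) 1L else max(keys) + 1L
}

# find a tailoring record by its stable key
.record_by_key <- function(scaffold, key) {
  for (tr in scaffold$tailorings) if (identical(tr$key, key)) return(tr)
  stop("no tailoring record with key ", key)
}

# Record provenance for a site atom and the residues it blocks from
# substitution.
.site_record <- function(scaffold, kind, atom = NA_integer_,
                         residue = NA_integer_, payload = NULL) {
  prov <- if (!is.na(atom)) atom_provenance(scaffold, atom) else
    list(res = residue, rec = NA_integer_, ord = NA_integer_)
  involved <- integer()
  if (!is.na(prov$res)) involved <- prov$res
  if (kind == "cyclization")
    involved <- c(involved, nrow(scaffold$residue_info))
  if (kind == "azole" && !is.na(residue))
    involved <- c(residue - 1L, residue)
  if (kind == "n_methylation" && !is.na(prov$res))
    involved <- c(prov$res - 1L, prov$res)   # the amide spans both residues
  list(kind = kind, prov = prov, payload = payload,
       involved = unique(involved), added_atoms = integer(),
       key = NA_integer_)
}

#' Execute one tailoring reaction at a chosen site
#'
#' @param scaffold an `np_scaffold`
#' @param kind reaction kind (see [detect_sites()])
#' @param site one row of the corresponding [detect_sites()] result (atom
#'   index, or residue position for azole formation)
#' @param payload optional fixed payload: halogen element (`"Cl"`/`"Br"`) or
#'   sugar id; drawn at random when `NULL`
#' @param sugars sugar library for glycosylation (defaults to the packaged
#'   library)
#' @param .record_key internal: stable record key to reuse when replaying a
#'   recorded reaction on a rebuilt scaffold
#' @return the modified `np_scaffold`, with a tailoring record appended
#' @export
execute_reaction <- function(scaffold, kind, site, payload = NULL,
                             sugars = NULL, .record_key = NULL) {
  mol <- scaffold$mol
  rec_idx <- length(scaffold$tailorings) + 1L
  key <- if (is.null(.record_key)) .next_record_key(scaffold)
  else .record_key
  if (kind == "cyclization") {
    nu <- site
    valid <- detect_sites(scaffold, "cyclization")$atom
    if (!(nu %in% valid)) stop("invalid cyclization site")
    rec <- .site_record(scaffold, kind, atom = nu)
    adj <- neighbor_list(mol)
    ct <- scaffold$c_term
    oh <- find_leaving_oh(mol, ct)
    mol <- adjust_h(mol, nu, -1L)
    mol <- add_bond(mol, nu, ct, 1L)
    scaffold <- .apply_deletion(scaffold, mol, oh)
    scaffold$cyclized <- TRUE
  } else if (kind == "halogenation") {
    at <- site
    if (!(at %in% detect_sites(scaffold, "halogenation")$atom))
      stop("invalid halogenation site")
    if (is.null(payload))
      payload <- if (stats::runif(1) < 0.5) "Cl" else "Br"
    rec <- .site_record(scaffold, kind, atom = at, payload = payload)
    mol <- adjust_h(mol, at, -1L)
    mol <- add_atom(mol, payload, nH = 0L)
    newa <- n_atoms(mol)
    mol <- add_bond(mol, at, newa, 1L)
    scaffold <- .apply_addition(scaffold, mol, newa, key)
    rec$added_atoms <- newa
  } else if (kind == "glycosylation") {
    at <- site
    if (!(at %in% detect_sites(scaffold, "glycosylation")$atom))
      stop("invalid glycosylation site")
    if (is.null(sugars)) sugars <- .default_sugars()
    if (is.null(payload))
      payload <- names(sugars)[sample.int(length(sugars), 1L)]
    sugar <- sugars[[payload]]
    if (is.null(sugar)) stop("unknown sugar '", payload, "'")
    rec <- .site_record(scaffold, kind, atom = at, payload = payload)
    # strip the anomeric hydroxyl from the sugar, then graft
    sdel <- delete_atoms(sugar$mol, sugar$anomeric_oh)
    smol <- sdel$mol
    anom <- sdel$index_map[sugar$anomeric_atom]
    offset <- n_atoms(mol)
    smol$atoms$map <- NA_integer_
    mol$atoms <- rbind(mol$atoms, smol$atoms)
    sb <- smol$bonds
    sb$a1 <- sb$a1 + offset; sb$a2 <- sb$a2 + offset
    mol$bonds <- rbind(mol$bonds, sb)
    mol <- adjust_h(mol, at, -1L)
    mol <- add_bond(mol, at, anom + offset, 1L)
    newa <- seq.int(offset + 1L, n_atoms(mol))
    scaffold <- .apply_addition(scaffold, mol, newa, key)
    rec$added_atoms <- newa
  } else if (kind == "azole") {
    r <- site
    adj <- neighbor_list(mol)
    cand <- .azole_candidates(scaffold, adj)
    row <- cand[cand$residue == r, , drop = FALSE]
    if (nrow(row) == 0L) stop("invalid azole site (residue ", r, ")")
    row <- row[1L, ]
    rec <- .site_record(scaffold, kind, residue = r,
                        payload = mol$atoms$elem[row$x])
    prev_head <- scaffold$heads[r - 1L]
    os <- adj[[prev_head]][mol$atoms$elem[adj[[prev_head]]] == "O"]
    dbl_o <- os[vapply(os, function(o)
      any(mol$bonds$order[bonds_at(mol, o)] == 2L), NA)][1L]
    tl <- scaffold$tails[r]
    mol <- adjust_h(mol, c(tl, row$calpha, row$cbeta, row$x), -1L)
    mol <- add_bond(mol, row$x, prev_head, 1L)
    mol <- set_bond_order(mol, prev_head, tl, 2L)
    mol <- set_bond_order(mol, row$calpha, row$cbeta, 2L)
    scaffold <- .apply_deletion(scaffold, mol, dbl_o)
  } else if (kind == "n_methylation") {
    at <- site
    if (!(at %in% detect_sites(scaffold, "n_methylation")$atom))
      stop("invalid N-methylation site")
    rec <- .site_record(scaffold, kind, atom = at)
    mol <- adjust_h(mol, at, -1L)
    mol <- add_atom(mol, "C", nH = 3L)
    newa <- n_atoms(mol)
    mol <- add_bond(mol, at, newa, 1L)
    scaffold <- .apply_addition(scaffold, mol, newa, key)
    rec$added_atoms <- newa
  } else {
    stop("unknown reaction kind '", kind, "'")
  }
  probs <- check_valence(scaffold$mol)
  if (length(probs) > 0L)
    stop(kind, " produced an invalid structure: ",
         paste(probs, collapse = "; "))
  rec$key <- key
  scaffold$tailorings[[rec_idx]] <- rec
  scaffold
}

# update scaffold bookkeeping after adding atoms (provenance: record key)
.apply_addition <- function(scaffold, mol, new_atoms, rec_key) {
  scaffold$mol <- mol
  scaffold$atom_origin <- rbind(
    scaffold$atom_origin,
    data.frame(res = NA_integer_, rec = rep(rec_key, length(new_atoms))))
  scaffold
}

# update scaffold bookkeeping after deleting atoms (remaps all indices)
.apply_deletion <- function(scaffold, mol, del_atoms) {
  del <- delete_atoms(mol, del_atoms)
  imap <- del$index_map
  scaffold$mol <- del$mol
  scaffold$residue_atoms <- lapply(scaffold$residue_atoms, function(v) {
    v <- imap[v]; v[!is.na(v)]
  })
  scaffold$backbone <- sort(imap[scaffold$backbone])
  scaffold$heads <- imap[scaffold$heads]
  scaffold$tails <- ifelse(is.na(scaffold$tails), NA_integer_,
                           imap[scaffold$tails])
  scaffold$n_term <- if (is.na(scaffold$n_term)) NA_integer_
  else imap[scaffold$n_term]
  scaffold$c_term <- imap[scaffold$c_term]
  scaffold$atom_origin <- scaffold$atom_origin[!is.na(imap), , drop = FALSE]
  rownames(scaffold$atom_origin) <- NULL
  scaffold$tailorings <- lapply(scaffold$tailorings, function(tr) {
    tr$added_atoms <- imap[tr$added_atoms]
    tr
  })
  scaffold
}

.sugar_cache <- new.env(parent = emptyenv())
.default_sugars <- function() {
  if (is.null(.sugar_cache$sugars))
    .sugar_cache$sugars <- load_sugar_library()
  .sugar_cache$sugars
}

#' Apply a probabilistic tailoring plan to a scaffold
#'
#' For each plan entry, a weight below 1 attempts the reaction once with
#' that probability; an integer weight k attempts k executions.  Each
#' attempt picks a site uniformly among the currently detected sites; an
#' attempt with no available site is recorded as a skipped no-op.
#'
#' @param scaffold an `np_scaffold`
#' @param plan an [reaction_plan()]
#' @param sugars optional sugar library for glycosylation
#' @return the tailored `np_scaffold`; skipped attempts are available in
#'   `attr(, "skipped")`
#' @export
apply_plan <- function(scaffold, plan, sugars = NULL) {
  skipped <- character()
  for (i in seq_along(plan$kinds)) {
    kind <- plan$kinds[i]
    w <- plan$weights[i]
    n_att <- if (w < 1) (if (stats::runif(1) < w) 1L else 0L) else
      as.integer(round(w))
    for (k in seq_len(n_att)) {
      sites <- detect_sites(scaffold, kind)
      if (nrow(sites) == 0L) {
        skipped <- c(skipped, kind)
        next
      }
      pick <- sites[sample.int(nrow(sites), 1L), 1L]
      scaffold <- execute_reaction(scaffold, kind, pick, sugars = sugars)
    }
  }
  attr(scaffold, "skipped") <- skipped
  scaffold
}

#' Add random bonds to a scaffold
#'
#' Stress test simulating tailoring chemistry that violates retrobiosynthetic
#' logic: k single bonds are added, each between two uniformly chosen,
#' currently non-bonded atoms that each surrender one hydrogen.
#'
#' @param scaffold an `np_scaffold`
#' @param k number of bonds to add
#' @return the modified `np_scaffold`
#' @export
add_random_bond <- function(scaffold, k) {
  stopifnot(k >= 0L)
  for (i in seq_len(k)) {
    mol <- scaffold$mol
    hs <- which(mol$atoms$nH >= 1L)
    pairs <- NULL
    if (length(hs) >= 2L) {
      cmb <- utils::combn(hs, 2L)
      ok <- !vapply(seq_len(ncol(cmb)), function(j)
        are_bonded(mol, cmb[1L, j], cmb[2L, j]), NA)
      pairs <- cmb[, ok, drop = FALSE]
    }
    if (is.null(pairs) || ncol(pairs) == 0L)
      stop("no valid atom pair for random bond ", i, " of ", k,
           " (achieved ", i - 1L, ")")
    j <- sample.int(ncol(pairs), 1L)
    p1 <- atom_provenance(scaffold, pairs[1L, j])
    p2 <- atom_provenance(scaffold, pairs[2L, j])
    mol <- adjust_h(mol, pairs[, j], -1L)
    mol <- add_bond(mol, pairs[1L, j], pairs[2L, j], 1L)
    scaffold$mol <- mol
    rec <- list(kind = "random_bond",
                prov = p1, prov2 = p2, payload = NULL,
                involved = unique(c(p1$res, p2$res)[!is.na(c(p1$res,
                                                             p2$res))]),
                added_atoms = integer(),
                key = .next_record_key(scaffold))
    scaffold$tailorings[[length(scaffold$tailorings) + 1L]] <- rec
  }
  scaffold
}
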