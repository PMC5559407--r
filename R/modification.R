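# Derivation of modified structures from the same in silico assembly line:
# monomer substitution (round-robin over positions) and tailoring edits
# (add / remove / move), all realized by replaying tailoring records onto a
# rebuilt scaffold.

#' Specification of how modified structures are derived
#'
#' @param n_substitutions number of monomer positions to substitute (>= 0)
#' @param substitution_set `np_monomer_set` to draw replacements from; may
#'   differ from the generation set.  Starter-class members are substituted
#'   only at position 1.
#' @param reactions_add optional [reaction_plan()] of tailorings to add to
#'   the modified structure
#' @param reactions_remove named numeric vector: per-kind probability (or
#'   count) of removing an existing tailoring of that kind
#' @param reactions_move named numeric vector: per-kind probability (or
#'   count) of moving an existing tailoring of that kind to a different site
#' @return an `np_modification_spec`
#' @export
modification_spec <- function(n_substitutions = 1L, substitution_set,
                              reactions_add = NULL,
                              reactions_remove = NULL,
                              reactions_move = NULL) {
  stopifnot(n_substitutions >= 0L)
  structure(list(n_substitutions = as.integer(n_substitutions),
                 substitution_set = substitution_set,
                 reactions_add = reactions_add,
                 reactions_remove = reactions_remove,
                 reactions_move = reactions_move),
            class = "np_modification_spec")
}

#' Round-robin substitution state
#'
#' Tracks how many times each position of each scaffold has been substituted,
#' so that every substitutable position is used once before any position is
#' used twice ("round-robin" fairness).
#'
#' @return an environment to pass to [substitute_monomers()]
#' @export
new_substitution_state <- function() new.env(parent = emptyenv())

# positions blocked by tailoring records
.blocked_positions <- function(scaffold) {
  sort(unique(unlist(lapply(scaffold$tailorings, `[[`, "involved"))))
}

#' Substitute monomers within a polymer
#'
#' Picks `n_substitutions` distinct eligible positions (residues that are not
#' sites of tailoring reactions), respecting round-robin fairness across
#' repeated calls for the same scaffold, and replaces each with a different
#' monomer drawn uniformly from the substitution set.  Starter-class
#' replacements are used only at position 1.
#'
#' @param scaffold the original `np_scaffold` (supplies the polymer and the
#'   tailoring-blocked positions)
#' @param spec an [modification_spec()]
#' @param state a [new_substitution_state()] (optional); pass the same state
#'   across a library pass to enforce fairness
#' @param scaffold_id key identifying the scaffold within `state`
#' @return the substituted `np_polymer`
#' @export
substitute_monomers <- function(scaffold, spec, state = NULL,
                                scaffold_id = "scaffold") {
  polymer <- scaffold$polymer
  n <- polymer$length
  k <- spec$n_substitutions
  if (k == 0L) return(polymer)
  eligible <- setdiff(seq_len(n), .blocked_positions(scaffold))
  members <- spec$substitution_set$members
  classes <- vapply(members, `[[`, "", "monomer_class")
  # a position is substitutable only if some replacement differs from the
  # incumbent and respects the position rules
  pool_for <- function(pos) {
    ok <- if (pos == 1L) rep(TRUE, length(members)) else classes != "starter"
    if (pos > 1L && pos < n)
      ok <- ok & !vapply(members, function(m) is.na(m$tail_atom), NA)
    ok <- ok & vapply(members, `[[`, "", "id") !=
      polymer$residues[[pos]]$id
    which(ok)
  }
  pools <- lapply(seq_len(n), function(p)
    if (p %in% eligible) pool_for(p) else integer())
  eligible <- eligible[vapply(eligible, function(p)
    length(pools[[p]]) > 0L, NA)]
  if (length(eligible) < k)
    stop("only ", length(eligible), " substitutable position(s) for ",
         k, " requested substitution(s)")
  counts <- if (!is.null(state) && !is.null(state[[scaffold_id]]))
    state[[scaffold_id]] else rep(0L, n)
  chosen <- integer()
  remaining <- eligible
  for (i in seq_len(k)) {
    mn <- min(counts[remaining])
    cand <- remaining[counts[remaining] == mn]
    pick <- if (length(cand) == 1L) cand else
      cand[sample.int(length(cand), 1L)]
    chosen <- c(chosen, pick)
    counts[pick] <- counts[pick] + 1L
    remaining <- setdiff(remaining, pick)
  }
  if (!is.null(state)) state[[scaffold_id]] <- counts
  residues <- polymer$residues
  for (pos in chosen) {
    pl <- pools[[pos]]
    residues[[pos]] <- members[[
      if (length(pl) == 1L) pl else pl[sample.int(length(pl), 1L)]]]
  }
  new_polymer(residues)
}

#' Rebuild a scaffold from a polymer and tailoring records
#'
#' Condenses the polymer and replays each record at its recorded site
#' (re-resolved through residue/record provenance).  Because tailored
#' residues are never substituted, replay is deterministic.
#'
#' @param polymer an `np_polymer`
#' @param records list of tailoring records (from an existing scaffold)
#' @param sugars optional sugar library
#' @return an `np_scaffold`
#' @export
rebuild_scaffold <- function(polymer, records, sugars = NULL) {
  sc <- condense(polymer)
  for (rec in records) {
    if (rec$kind == "random_bond") {
      a1 <- resolve_provenance(sc, rec$prov)
      a2 <- resolve_provenance(sc, rec$prov2)
      mol <- adjust_h(sc$mol, c(a1, a2), -1L)
      mol <- add_bond(mol, a1, a2, 1L)
      sc$mol <- mol
      sc$tailorings[[length(sc$tailorings) + 1L]] <-
        list(kind = "random_bond", prov = rec$prov, prov2 = rec$prov2,
             payload = NULL, involved = rec$involved,
             added_atoms = integer(), key = rec$key)
    } else if (rec$kind == "azole") {
      sc <- execute_reaction(sc, "azole", rec$prov$res,
                             payload = rec$payload, sugars = sugars,
                             .record_key = rec$key)
    } else {
      site <- resolve_provenance(sc, rec$prov)
      sc <- execute_reaction(sc, rec$kind, site, payload = rec$payload,
                             sugars = sugars, .record_key = rec$key)
    }
  }
  sc
}

# Records that (directly or transitively) depend on any of the given record
# keys: a record depends on another when its site or either random-bond
# endpoint lies on atoms that record added.
.dependent_records <- function(records, keys) {
  repeat {
    dep <- vapply(records, function(r) {
      refs <- c(r$prov$rec,
                if (!is.null(r$prov2)) r$prov2$rec else NA_integer_)
      any(refs %in% keys) && !(r$key %in% keys)
    }, NA)
    if (!any(dep)) break
    keys <- c(keys, vapply(records[dep], `[[`, 1L, "key"))
  }
  keys
}

#' Edit the tailoring decorations of a scaffold
#'
#' Removals delete a uniformly chosen existing record of the named kind and
#' chemically revert it (by rebuilding without it); moves revert a record and
#' re-execute the reaction at a different, uniformly chosen valid site (a
#' logged no-op when no alternative site exists); additions apply a
#' [reaction_plan()] on top.
#'
#' @param scaffold an `np_scaffold`
#' @param spec an [modification_spec()]
#' @param sugars optional sugar library
#' @return the edited `np_scaffold`; no-ops are listed in `attr(, "noops")`
#' @export
edit_tailorings <- function(scaffold, spec, sugars = NULL) {
  noops <- character()
  records <- scaffold$tailorings
  weight_events <- function(w) {
    if (is.null(w)) return(character())
    out <- character()
    for (kind in names(w)) {
      n_att <- if (w[[kind]] < 1)
        (if (stats::runif(1) < w[[kind]]) 1L else 0L)
      else as.integer(round(w[[kind]]))
      out <- c(out, rep(kind, n_att))
    }
    out
  }
  changed <- FALSE
  for (kind in weight_events(spec$reactions_remove)) {
    idx <- which(vapply(records, `[[`, "", "kind") == kind)
    if (length(idx) == 0L) { noops <- c(noops, paste0("remove:", kind)); next }
    drop <- if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
    # reverting a tailoring also reverts anything chemically built on the
    # atoms it introduced (e.g. a halogen on a removed sugar)
    gone <- .dependent_records(records, records[[drop]]$key)
    records <- records[!vapply(records, function(r) r$key %in% gone, NA)]
    changed <- TRUE
  }
  if (changed) scaffold <- rebuild_scaffold(scaffold$polymer, records, sugars)
  for (kind in weight_events(spec$reactions_move)) {
    records <- scaffold$tailorings
    idx <- which(vapply(records, `[[`, "", "kind") == kind)
    if (length(idx) == 0L) { noops <- c(noops, paste0("move:", kind)); next }
    mv <- if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
    moved <- records[[mv]]
    gone <- .dependent_records(records, moved$key)
    kept <- records[!vapply(records, function(r) r$key %in% gone, NA)]
    base <- rebuild_scaffold(scaffold$polymer, kept, sugars)
    sites <- detect_sites(base, kind)
    old_site <- if (kind == "azole") moved$prov$res else
      tryCatch(resolve_provenance(base, moved$prov), error = function(e)
        NA_integer_)
    alt <- sites[!(sites[, 1L] %in% old_site), 1L]
    if (length(alt) == 0L) {
      noops <- c(noops, paste0("move:", kind, ":no-alternative"))
      next
    }
    pick <- if (length(alt) == 1L) alt else alt[sample.int(length(alt), 1L)]
    scaffold <- execute_reaction(base, kind, pick, payload = moved$payload,
                                 sugars = sugars)
  }
  if (!is.null(spec$reactions_add))
    scaffold <- apply_plan(scaffold, spec$reactions_add, sugars = sugars)
  attr(scaffold, "noops") <- noops
  scaffold
}

#' Derive a modified structure from an original scaffold
#'
#' Applies monomer substitutions, replays the original tailoring records on
#' the substituted polymer, then applies any tailoring edits.
#'
#' @inheritParams substitute_monomers
#' @param sugars optional sugar library
#' @return the modified `np_scaffold`
#' @export
derive_modified <- function(scaffold, spec, state = NULL,
                            scaffold_id = "scaffold", sugars = NULL) {
  polymer <- substitute_monomers(scaffold, spec, state, scaffold_id)
  sc <- rebuild_scaffold(polymer, scaffold$tailorings, sugars)
  if (!is.null(spec$reactions_add) || !is.null(spec$reactions_remove) ||
      !is.null(spec$reactions_move))
    sc <- edit_tailorings(sc, spec, sugars)
  sc
}
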