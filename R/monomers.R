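# Monomer alphabets: loading, validation, and polyketide expansion.
#
# Monomer tables are TSV files with columns id, name, class, smiles (plus
# set-specific extras).  Attachment atoms are annotated with atom-map numbers
# inside the SMILES: map 1 = head (the acyl carbon condensed onto the next
# residue's tail), map 2 = tail (the nucleophilic extension atom; absent for
# starter units, which occupy only position 1).  For sugars, map 1 marks the
# anomeric carbon.
#
# The proteinogenic set is the standard 20 amino-acid alphabet.  The
# nonproteinogenic, starter, and sugar sets are reconstructions assembled
# from the published category descriptions and counts (45 nonproteinogenic
# with a 32-entry core subset; 23 starters = 4 fatty + 13 aromatic +
# 3 alicyclic + 3 small; 69 deoxy/hexose sugars); their exact member
# identities are this package's own, hence the `_synthetic` file names.

new_monomer <- function(id, name, monomer_class, smiles, extras = list()) {
  mol <- parse_smiles(smiles)
  head_atom <- which(!is.na(mol$atoms$map) & mol$atoms$map == 1L)
  tail_atom <- which(!is.na(mol$atoms$map) & mol$atoms$map == 2L)
  if (length(head_atom) != 1L)
    stop("monomer '", id, "': expected exactly one head atom (map :1)")
  if (length(tail_atom) > 1L)
    stop("monomer '", id, "': more than one tail atom (map :2)")
  structure(c(list(id = id, name = name, monomer_class = monomer_class,
                   smiles = smiles, mol = mol, head_atom = head_atom,
                   tail_atom = if (length(tail_atom)) tail_atom
                   else NA_integer_),
              extras),
            class = "np_monomer")
}

#' @export
print.np_monomer <- function(x, ...) {
  cat(sprintf("<monomer %s (%s), class %s, %d atoms>\n", x$id, x$name,
              x$monomer_class, n_atoms(x$mol)))
  invisible(x)
}

new_monomer_set <- function(name, members) {
  ids <- vapply(members, `[[`, "", "id")
  names(members) <- ids
  structure(list(name = name, members = members), class = "np_monomer_set")
}

#' @export
print.np_monomer_set <- function(x, ...) {
  cat(sprintf("<monomer set '%s': %d members>\n", x$name, length(x$members)))
  invisible(x)
}

#' @export
length.np_monomer_set <- function(x) length(x$members)

.builtin_table <- function(file) {
  system.file("extdata", file, package = "npenum", mustWork = TRUE)
}

read_monomer_table <- function(path, set_name = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("id", "name", "class", "smiles")
  if (!all(req %in% names(df)))
    stop("monomer table ", path, " lacks columns: ",
         paste(setdiff(req, names(df)), collapse = ", "))
  extras_cols <- setdiff(names(df), req)
  members <- lapply(seq_len(nrow(df)), function(i) {
    new_monomer(df$id[i], df$name[i], df$class[i], df$smiles[i],
                extras = as.list(df[i, extras_cols, drop = FALSE]))
  })
  new_monomer_set(set_name, members)
}

#' Load a packaged (or file-based) monomer set
#'
#' Registered set names: `"proteinogenic"` (20 amino acids),
#' `"nonproteinogenic"` (45 modified amino acids; `core32 = TRUE` restricts
#' to the 32-entry core subset), `"starters"` (23 starter units),
#' `"polyketide"` (26 ketide monomers, generated by
#' [expand_polyketide_monomers()]).  Any other value is treated as a path to
#' a monomer table TSV.
#'
#' @param name registered set name or path to a TSV monomer table
#' @param core32 for the nonproteinogenic set, restrict to the 32-member core
#' @return an `np_monomer_set`
#' @export
load_monomer_set <- function(name, core32 = FALSE) {
  if (name == "proteinogenic") {
    read_monomer_table(.builtin_table("proteinogenic.tsv"), "proteinogenic")
  } else if (name == "nonproteinogenic") {
    set <- read_monomer_table(.builtin_table("nonproteinogenic_synthetic.tsv"),
                              "nonproteinogenic")
    if (core32) {
      keep <- vapply(set$members, function(m) isTRUE(m$core32), NA)
      set$members <- set$members[keep]
      set$name <- "nonproteinogenic32"
    }
    set
  } else if (name == "starters") {
    read_monomer_table(.builtin_table("starters_synthetic.tsv"), "starters")
  } else if (name == "polyketide") {
    expand_polyketide_monomers()
  } else if (file.exists(name)) {
    read_monomer_table(name)
  } else {
    stop("unknown monomer set '", name, "' (and no such file exists)")
  }
}

#' The seven default polyketide extender units
#'
#' Each unit is described by its alpha-carbon substituents (SMILES branch
#' fragments).  Note that decarboxylative incorporation makes some units
#' (e.g. methylmalonate and propionate) coincide as two-dimensional
#' structures; both are kept as distinct monomers.
#'
#' @return data frame with columns `id`, `name`, `substituents` (list column)
#' @export
pk_extender_units <- function() {
  data.frame(
    id = c("mal", "mmal", "emal", "omal", "prop", "ibut", "mbut"),
    name = c("malonate", "methylmalonate", "ethylmalonate",
             "methoxymalonate", "propionate", "isobutyrate",
             "2-methylbutyrate"),
    substituents = I(list(character(), "C", "CC", "OC", "C",
                          c("C", "C"), c("C", "CC"))),
    stringsAsFactors = FALSE
  )
}

.PK_STATES <- c("ketone", "hydroxyl", "enoyl", "reduced")

# Free-monomer SMILES for one extender unit at one beta-oxidation state.
# The unit contributes two chain carbons: the alpha carbon (tail, map 2,
# carrying the unit's substituents) and the acyl-derived carbon (head,
# map 1, carrying the oxidation state plus the hydroxyl lost on
# condensation).  Returns NA when the state is chemically impossible for
# the substitution pattern (enoyl needs a free alpha hydrogen).
pk_monomer_smiles <- function(substituents, state) {
  ns <- length(substituents)
  if (ns > 2L) stop("at most two alpha substituents supported")
  branch <- paste0(vapply(substituents, function(s) paste0("(", s, ")"), ""),
                   collapse = "")
  if (state == "enoyl") {
    if (ns > 1L) return(NA_character_)   # no alpha H left for the double bond
    alpha <- if (ns == 0L) "[CH2:2]" else paste0("[CH:2]", branch)
    return(paste0(alpha, "=[CH:1]O"))
  }
  alpha <- paste0(c("[CH3:2]", "[CH2:2]", "[CH:2]")[ns + 1L], branch)
  head <- switch(state,
                 ketone = "[C:1](=O)O",
                 hydroxyl = "[CH:1](O)O",
                 reduced = "[CH2:1]O",
                 stop("unknown oxidation state ", state))
  paste0(alpha, head)
}

#' Expand polyketide extender units over their beta-oxidation states
#'
#' Each extender unit is emitted at every chemically valid beta-position
#' oxidation state (ketone, hydroxyl, enoyl, fully reduced).  The enoyl
#' (alpha,beta-dehydro) state requires a hydrogen at the alpha carbon, so it
#' is pruned for doubly alpha-substituted units (isobutyrate and
#' 2-methylbutyrate); the seven default units therefore expand to exactly 26
#' monomers.
#'
#' @param extenders data frame as from [pk_extender_units()]
#' @return an `np_monomer_set` of class-`polyketide` monomers
#' @export
expand_polyketide_monomers <- function(extenders = pk_extender_units()) {
  if (nrow(extenders) == 0L) return(new_monomer_set("polyketide", list()))
  known <- pk_extender_units()
  members <- list()
  for (i in seq_len(nrow(extenders))) {
    id <- extenders$id[i]
    if (!"substituents" %in% names(extenders)) {
      j <- match(id, known$id)
      if (is.na(j)) stop("unknown polyketide extender unit '", id, "'")
      subs <- known$substituents[[j]]
      nm <- known$name[j]
    } else {
      subs <- extenders$substituents[[i]]
      nm <- extenders$name[i]
    }
    for (state in .PK_STATES) {
      smi <- pk_monomer_smiles(subs, state)
      if (is.na(smi)) next
      mono <- new_monomer(paste0(id, "_", substr(state, 1L, 3L)),
                          paste0(nm, " (", state, ")"),
                          "polyketide", smi,
                          extras = list(extender = id, state = state))
      if (length(check_valence(mono$mol)) > 0L) next
      members[[length(members) + 1L]] <- mono
    }
  }
  new_monomer_set("polyketide", members)
}

# ---------------------------------------------------------------------------
# Sugars
# ---------------------------------------------------------------------------

new_sugar <- function(id, name, smiles, deoxy) {
  mol <- parse_smiles(smiles)
  anomeric <- which(!is.na(mol$atoms$map) & mol$atoms$map == 1L)
  if (length(anomeric) != 1L)
    stop("sugar '", id, "': expected exactly one anomeric atom (map :1)")
  # the anomeric carbon must carry exactly one hydroxyl in the free sugar
  nb <- neighbor_list(mol)[[anomeric]]
  ohs <- nb[mol$atoms$elem[nb] == "O" & mol$atoms$nH[nb] >= 1L]
  if (length(ohs) != 1L)
    stop("sugar '", id, "': anomeric carbon must carry exactly one hydroxyl")
  structure(list(id = id, name = name, smiles = smiles, mol = mol,
                 anomeric_atom = anomeric, anomeric_oh = ohs,
                 deoxy_flag = deoxy),
            class = "np_sugar")
}

#' Load the packaged deoxy/hexose sugar library
#'
#' 69 distinct two-dimensional pyranose structures (hexoses and deoxy sugars
#' with amino, N-methylamino and O-methyl decorations), used by the
#' O-glycosylation tailoring reaction.  Stereochemistry is not modelled.
#'
#' @param path optional path to a custom sugar table TSV
#' @return list of `np_sugar` objects
#' @export
load_sugar_library <- function(path = NULL) {
  if (is.null(path)) path <- .builtin_table("sugars_synthetic.tsv")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sugars <- lapply(seq_len(nrow(df)), function(i) {
    new_sugar(df$id[i], df$name[i], df$smiles[i], as.logical(df$deoxy[i]))
  })
  names(sugars) <- df$id
  sugars
}

# ---------------------------------------------------------------------------
# Validation and round-trip export
# ---------------------------------------------------------------------------

#' Validate monomer sets (and sugar libraries)
#'
#' @param sets list of `np_monomer_set` objects and/or sugar libraries
#'   (lists of `np_sugar`)
#' @param strict error on any failure instead of just reporting
#' @return data frame with one row per set: name, size, duplicate ids,
#'   sanitization failures
#' @export
validate_library <- function(sets, strict = FALSE) {
  if (length(sets) == 0L)
    return(data.frame(set = character(), size = integer(),
                      duplicate_ids = character(),
                      invalid_ids = character()))
  rows <- lapply(sets, function(s) {
    if (inherits(s, "np_monomer_set")) {
      nm <- s$name
      ids <- vapply(s$members, `[[`, "", "id")
      mols <- lapply(s$members, `[[`, "mol")
    } else {
      nm <- "sugars"
      ids <- vapply(s, `[[`, "", "id")
      mols <- lapply(s, `[[`, "mol")
    }
    dup <- unique(ids[duplicated(ids)])
    bad <- ids[vapply(mols, function(m) length(check_valence(m)) > 0L, NA)]
    data.frame(set = nm, size = length(ids),
               duplicate_ids = paste(dup, collapse = ","),
               invalid_ids = paste(bad, collapse = ","),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(report))
    report <- data.frame(set = character(), size = integer(),
                         duplicate_ids = character(),
                         invalid_ids = character())
  if (strict) {
    if (any(nzchar(report$duplicate_ids)))
      stop("duplicate monomer ids: ",
           paste(report$duplicate_ids[nzchar(report$duplicate_ids)],
                 collapse = "; "))
    if (any(nzchar(report$invalid_ids)))
      stop("invalid monomer structures: ",
           paste(report$invalid_ids[nzchar(report$invalid_ids)],
                 collapse = "; "))
  }
  report
}

#' Write a monomer set to its TSV table format
#'
#' The written table reloads to an identical set via [load_monomer_set()].
#'
#' @param set an `np_monomer_set`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_monomer_table <- function(set, path) {
  df <- data.frame(
    id = vapply(set$members, `[[`, "", "id"),
    name = vapply(set$members, `[[`, "", "name"),
    class = vapply(set$members, `[[`, "", "monomer_class"),
    smiles = vapply(set$members, `[[`, "", "smiles"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
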