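# Two-dimensional fingerprints and the similarity-method registry.
#
# Four families are provided: circular fingerprints (extended-connectivity
# ECFP and pharmacophoric FCFP at diameters 0/2/4/6, hashed to 1024 bits),
# substructure-key fingerprints (MACCS via OpenBabel; E-state atom types;
# two corpus-derived privileged-fragment key sets standing in for the
# Klekota-Roth and PubChem key collections, see key-sets.R), Daylight-like
# topological path fingerprints in four atom/bond-typing variants, and the
# lexicographic LINGO fingerprint over canonical SMILES q-grams.

.ATOMIC_NUMBER <- c(B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, P = 15L,
                    S = 16L, Cl = 17L, Br = 35L, I = 53L)

# Per-molecule context shared by several fingerprints.
fp_context <- function(mol) {
  arom <- perceive_aromatic(mol)
  rb <- ring_bonds(mol)
  ring_atom <- rep(FALSE, n_atoms(mol))
  if (any(rb))
    ring_atom[unique(c(mol$bonds$a1[rb], mol$bonds$a2[rb]))] <- TRUE
  deg <- integer(n_atoms(mol))
  if (nrow(mol$bonds) > 0L) {
    t1 <- table(factor(c(mol$bonds$a1, mol$bonds$a2),
                       levels = seq_len(n_atoms(mol))))
    deg <- as.integer(t1)
  }
  list(mol = mol, arom = arom, ring_atom = ring_atom, degree = deg,
       bond_sum = bond_order_sums(mol), hyb = hybridization(mol, arom))
}

# bond type codes for circular fingerprints: 1/2/3 = order, 4 = aromatic
.bond_types <- function(mol, arom) {
  bt <- mol$bonds$order
  bt[arom$bond] <- 4L
  bt
}

# Pharmacophoric atom features (FCFP initial invariants): H-bond donor,
# H-bond acceptor, positively/negatively ionizable, aromatic, halogen.
atom_features <- function(ctx) {
  mol <- ctx$mol
  n <- n_atoms(mol)
  elem <- mol$atoms$elem
  adj <- neighbor_list(mol)
  is_NO <- elem %in% c("N", "O")
  donor <- is_NO & mol$atoms$nH >= 1L
  acceptor <- is_NO & mol$atoms$charge <= 0L
  # carbonyl carbons (for amide/acid recognition)
  carbonyl_c <- rep(FALSE, n)
  dbl <- mol$bonds[mol$bonds$order == 2L, , drop = FALSE]
  for (i in seq_len(nrow(dbl))) {
    a1 <- dbl$a1[i]; a2 <- dbl$a2[i]
    if (elem[a1] == "C" && elem[a2] == "O") carbonyl_c[a1] <- TRUE
    if (elem[a2] == "C" && elem[a1] == "O") carbonyl_c[a2] <- TRUE
  }
  pos <- mol$atoms$charge > 0L
  neg <- mol$atoms$charge < 0L
  for (a in seq_len(n)) {
    if (elem[a] == "N" && mol$atoms$nH[a] >= 1L && !ctx$arom$atom[a] &&
        ctx$hyb[a] == 3L && !any(carbonyl_c[adj[[a]]]))
      pos[a] <- TRUE                       # basic amine
    if (elem[a] == "O" && mol$atoms$nH[a] >= 1L &&
        any(carbonyl_c[adj[[a]]]))
      neg[a] <- TRUE                       # carboxylic acid
  }
  cbind(donor, acceptor, pos, neg,
        aromatic = ctx$arom$atom,
        halogen = elem %in% c("F", "Cl", "Br", "I")) * 1L
}

# Morgan environment identifiers for all radii up to max_radius.
morgan_ids <- function(ctx, family = c("ecfp", "fcfp"), max_radius = 3L) {
  family <- match.arg(family)
  mol <- ctx$mol
  init_mat <- if (family == "ecfp") {
    cbind(.ATOMIC_NUMBER[mol$atoms$elem], ctx$degree, mol$atoms$nH,
          mol$atoms$charge, ctx$ring_atom * 1L, ctx$bond_sum)
  } else {
    atom_features(ctx)
  }
  storage.mode(init_mat) <- "integer"
  init <- cpp_hash_int_rows(init_mat)
  cpp_morgan_ids(n_atoms(mol), init,
                 as.matrix(mol$bonds[, c("a1", "a2")]),
                 .bond_types(mol, ctx$arom), max_radius)
}

# fold uint32 identifiers (doubles) into 1..nbits
.fold_bits <- function(ids, nbits = 1024L) {
  sort(unique(as.integer(ids %% nbits) + 1L))
}

circular_bits <- function(ctx, family, radius, nbits = 1024L) {
  ids <- morgan_ids(ctx, family, max_radius = radius)
  .fold_bits(ids[, seq_len(radius + 1L), drop = FALSE], nbits)
}

# ---------------------------------------------------------------------------
# Topological (path-based) fingerprints: four CDK-style variants differing
# in atom/bond typing; paths up to 7 bonds, hashed to 1024 bits.
# ---------------------------------------------------------------------------

.topo_labels <- function(ctx, variant) {
  mol <- ctx$mol
  elem <- mol$atoms$elem
  al <- switch(variant,
    default = ifelse(ctx$arom$atom, tolower(elem), elem),
    extended = paste0(ifelse(ctx$arom$atom, tolower(elem), elem),
                      ifelse(ctx$ring_atom, "R", "")),
    hybridization = paste0(elem, ctx$hyb),
    graph = elem)
  bsym <- c("-", "=", "#")[mol$bonds$order]
  bl <- switch(variant,
    default = ifelse(ctx$arom$bond, ":", bsym),
    extended = ifelse(ctx$arom$bond, ":", bsym),
    hybridization = bsym,
    graph = rep("-", nrow(mol$bonds)))
  list(atom = al, bond = bl)
}

topological_bits <- function(ctx, variant, max_bonds = 7L, nbits = 1024L) {
  lb <- .topo_labels(ctx, variant)
  paths <- cpp_path_strings(n_atoms(ctx$mol),
                            as.matrix(ctx$mol$bonds[, c("a1", "a2")]),
                            lb$atom, lb$bond, max_bonds)
  .fold_bits(cpp_hash_strings(paths), nbits)
}

# ---------------------------------------------------------------------------
# E-state atom types (Hall-Kier): per-atom type strings built from the
# element, hydrogen count, and bond-type pattern (s/d/t/a), used as a
# presence key fingerprint.
# ---------------------------------------------------------------------------

estate_types <- function(ctx) {
  mol <- ctx$mol
  n <- n_atoms(mol)
  ns <- integer(n); nd <- integer(n); nt <- integer(n); na_ <- integer(n)
  for (b in seq_len(nrow(mol$bonds))) {
    a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
    if (ctx$arom$bond[b]) {
      na_[a1] <- na_[a1] + 1L; na_[a2] <- na_[a2] + 1L
    } else if (mol$bonds$order[b] == 1L) {
      ns[a1] <- ns[a1] + 1L; ns[a2] <- ns[a2] + 1L
    } else if (mol$bonds$order[b] == 2L) {
      nd[a1] <- nd[a1] + 1L; nd[a2] <- nd[a2] + 1L
    } else {
      nt[a1] <- nt[a1] + 1L; nt[a2] <- nt[a2] + 1L
    }
  }
  # aromatic atoms: in-ring double bonds are subsumed by the aromatic count
  adj_d <- nd
  paste0(strrep("t", nt), strrep("d", adj_d), strrep("a", na_),
         strrep("s", ns), mol$atoms$elem,
         ifelse(mol$atoms$nH > 0L, paste0("H", mol$atoms$nH), ""),
         ifelse(mol$atoms$charge != 0L,
                sprintf("%+d", mol$atoms$charge), ""))
}

estate_bits <- function(ctx) {
  sort(unique(as.integer(cpp_hash_strings(unique(estate_types(ctx))) %%
                           2147483647)))
}

# ---------------------------------------------------------------------------
# LINGO: multiset of length-4 substrings of the canonical SMILES with all
# ring-closure digits normalized to '0'.  Strings shorter than q yield the
# single whole-string gram.
# ---------------------------------------------------------------------------

#' LINGO q-gram multiset of a canonical SMILES string
#'
#' @param smiles canonical SMILES (from the package's canonicalizer,
#'   [canonical_smiles()])
#' @param q gram length (default 4)
#' @return named integer vector of q-gram counts
#' @export
lingo_fingerprint <- function(smiles, q = 4L) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("empty SMILES string")
  s <- gsub("[0-9]", "0", smiles)
  n <- nchar(s)
  grams <- if (n < q) s else
    substring(s, seq_len(n - q + 1L), seq_len(n - q + 1L) + q - 1L)
  tab <- table(grams)
  stats::setNames(as.integer(tab), names(tab))
}

# ---------------------------------------------------------------------------
# MACCS structural keys via OpenBabel (ChemmineOB).
# ---------------------------------------------------------------------------

maccs_bits_batch <- function(smiles) {
  inp <- paste0(paste(smiles, collapse = "\n"), "\n")
  mols <- ChemmineOB::forEachMol("SMILES", inp, identity, reduce = c)
  if (!is.list(mols)) mols <- list(mols)
  fpm <- ChemmineOB::fingerprint_OB(mols, "MACCS")
  if (is.null(dim(fpm))) fpm <- matrix(fpm, nrow = 1L)
  if (nrow(fpm) != length(smiles))
    stop("MACCS fingerprinting failed for ",
         length(smiles) - nrow(fpm), " structure(s)")
  lapply(seq_len(nrow(fpm)), function(i) which(fpm[i, ] != 0))
}

# ---------------------------------------------------------------------------
# Method registry
# ---------------------------------------------------------------------------

.fp_registry <- new.env(parent = emptyenv())

#' Register a similarity method
#'
#' Built-in methods are fingerprint generators; external methods (the
#' plug-in seam for retrobiosynthetic scorers and the like) supply a
#' `pair_fn(scaffold_a, scaffold_b)` returning a similarity in `[0, 1]`.
#'
#' @param id method identifier
#' @param family one of `"circular"`, `"substructure_keys"`,
#'   `"topological"`, `"lexicographic"`, `"external"`
#' @param fp_fn batch fingerprint generator
#'   `function(ctxs, canonical) -> np_fp_set`, or `NULL` for external methods
#' @param pair_fn pairwise similarity callable for external methods
#' @param enabled logical; disabled methods are skipped by experiments
#' @param meta list of method metadata (e.g. `radius`)
#' @return the method id, invisibly
#' @export
register_similarity_method <- function(id, family, fp_fn = NULL,
                                       pair_fn = NULL, enabled = TRUE,
                                       meta = list()) {
  .fp_registry[[id]] <- list(id = id, family = family, fp_fn = fp_fn,
                             pair_fn = pair_fn, enabled = enabled,
                             meta = meta)
  invisible(id)
}

#' Look up a registered similarity method
#' @param id method identifier
#' @return the registry entry
#' @export
get_similarity_method <- function(id) {
  m <- .fp_registry[[id]]
  if (is.null(m)) stop("unregistered similarity method '", id, "'")
  m
}

#' List registered similarity methods
#' @param enabled_only drop disabled methods
#' @return data frame with columns id, family, enabled
#' @export
list_similarity_methods <- function(enabled_only = FALSE) {
  ids <- sort(ls(.fp_registry))
  df <- data.frame(
    id = ids,
    family = vapply(ids, function(i) .fp_registry[[i]]$family, ""),
    enabled = vapply(ids, function(i) .fp_registry[[i]]$enabled, NA),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (enabled_only) df[df$enabled, , drop = FALSE] else df
}

.mk_bits_set <- function(method, idlists) {
  structure(list(method = method, type = "bits", ids = idlists),
            class = "np_fp_set")
}

.register_builtins <- function() {
  for (r in c(0L, 1L, 2L, 3L)) {
    for (fam in c("ecfp", "fcfp")) {
      id <- paste0(toupper(fam), 2L * r)
      local({
        fam0 <- fam; r0 <- r; id0 <- id
        register_similarity_method(
          id0, "circular",
          fp_fn = function(ctxs, canonical)
            .mk_bits_set(id0, lapply(ctxs, circular_bits, family = fam0,
                                     radius = r0)),
          meta = list(radius = r0, diameter = 2L * r0))
      })
    }
  }
  for (v in c("default", "extended", "hybridization", "graph")) {
    id <- paste0("CDK-", v)
    local({
      v0 <- v; id0 <- id
      register_similarity_method(
        id0, "topological",
        fp_fn = function(ctxs, canonical)
          .mk_bits_set(id0, lapply(ctxs, topological_bits, variant = v0)))
    })
  }
  register_similarity_method(
    "EState", "substructure_keys",
    fp_fn = function(ctxs, canonical)
      .mk_bits_set("EState", lapply(ctxs, estate_bits)))
  register_similarity_method(
    "MACCS", "substructure_keys",
    fp_fn = function(ctxs, canonical)
      .mk_bits_set("MACCS", maccs_bits_batch(
        vapply(ctxs, function(cc) write_smiles(cc$mol), ""))))
  register_similarity_method(
    "KlekotaRoth", "substructure_keys",
    fp_fn = function(ctxs, canonical)
      .mk_bits_set("KlekotaRoth", lapply(ctxs, fragment_key_bits,
                                         keyset = "klekota_roth_synthetic")))
  register_similarity_method(
    "PubChem", "substructure_keys",
    fp_fn = function(ctxs, canonical)
      .mk_bits_set("PubChem", lapply(ctxs, fragment_key_bits,
                                     keyset = "pubchem_synthetic")))
  register_similarity_method(
    "LINGO", "lexicographic",
    fp_fn = function(ctxs, canonical) {
      grams <- lapply(canonical, lingo_fingerprint)
      structure(list(method = "LINGO", type = "multiset", grams = grams),
                class = "np_fp_set")
    })
  invisible(NULL)
}

#' Compute fingerprints for a batch of scaffolds
#'
#' @param scaffolds list of `np_scaffold` (or `np_mol`) objects
#' @param method_id a registered method id
#' @param canonical optional pre-computed canonical SMILES (computed when
#'   needed otherwise)
#' @return an `np_fp_set`
#' @export
compute_fingerprints <- function(scaffolds, method_id, canonical = NULL) {
  m <- get_similarity_method(method_id)
  if (is.null(m$fp_fn))
    stop("method '", method_id, "' is external; it has no fingerprint form")
  if (!m$enabled) stop("method '", method_id, "' is disabled")
  mols <- lapply(scaffolds, function(s)
    if (inherits(s, "np_scaffold")) s$mol else s)
  ctxs <- lapply(mols, fp_context)
  if (is.null(canonical) && m$family == "lexicographic")
    canonical <- canonical_smiles(vapply(mols, write_smiles, ""))
  m$fp_fn(ctxs, canonical)
}

#' Compute a single fingerprint
#'
#' @param scaffold an `np_scaffold` or `np_mol`
#' @param method_id a registered method id
#' @return an `np_fingerprint`
#' @export
compute_fingerprint <- function(scaffold, method_id) {
  set <- compute_fingerprints(list(scaffold), method_id)
  fp_at(set, 1L)
}

# extract element i of a fingerprint set as a single np_fingerprint
fp_at <- function(set, i) {
  structure(list(method = set$method, type = set$type,
                 ids = if (set$type == "bits") set$ids[[i]] else NULL,
                 grams = if (set$type == "multiset") set$grams[[i]]
                 else NULL),
            class = "np_fingerprint")
}

#' @export
print.np_fingerprint <- function(x, ...) {
  n <- if (x$type == "bits") length(x$ids) else length(x$grams)
  cat(sprintf("<%s fingerprint (%s): %d features>\n", x$method, x$type, n))
  invisible(x)
}

#' Tanimoto coefficient between two fingerprints
#'
#' Bit fingerprints: |intersection| / |union|.  Multisets: sum of minimum
#' counts over sum of maximum counts.  Two empty fingerprints have
#' similarity 1 by convention.
#'
#' @param a,b `np_fingerprint` objects from the same method
#' @return similarity in `[0, 1]`
#' @export
tanimoto <- function(a, b) {
  if (!identical(a$method, b$method))
    stop("fingerprints come from different methods (", a$method, " vs ",
         b$method, ")")
  if (a$type == "bits") {
    ni <- length(intersect(a$ids, b$ids))
    nu <- length(a$ids) + length(b$ids) - ni
    if (nu == 0L) return(1)
    ni / nu
  } else {
    keys <- union(names(a$grams), names(b$grams))
    if (length(keys) == 0L) return(1)
    ca <- cb <- stats::setNames(integer(length(keys)), keys)
    ca[names(a$grams)] <- a$grams
    cb[names(b$grams)] <- b$grams
    sum(pmin(ca, cb)) / sum(pmax(ca, cb))
  }
}

#' Tanimoto similarity matrix between two fingerprint sets
#'
#' @param A,B `np_fp_set` objects from the same method
#' @return numeric matrix of dimension `length(A) x length(B)`
#' @export
tanimoto_matrix <- function(A, B) {
  if (!identical(A$method, B$method)) stop("method mismatch")
  if (A$type == "bits") {
    universe <- sort(unique(c(unlist(A$ids), unlist(B$ids))))
    mkmat <- function(ids) {
      m <- matrix(0L, nrow = length(ids), ncol = length(universe))
      for (i in seq_along(ids))
        m[i, match(ids[[i]], universe)] <- 1L
      m
    }
    ma <- mkmat(A$ids); mb <- mkmat(B$ids)
    inter <- ma %*% t(mb)
    uni <- outer(rowSums(ma), rowSums(mb), "+") - inter
    out <- ifelse(uni == 0, 1, inter / uni)
    out
  } else {
    keys <- sort(unique(c(unlist(lapply(A$grams, names)),
                          unlist(lapply(B$grams, names)))))
    mk <- function(gr) {
      m <- matrix(0L, nrow = length(gr), ncol = length(keys))
      for (i in seq_along(gr)) m[i, match(names(gr[[i]]), keys)] <- gr[[i]]
      m
    }
    ma <- mk(A$grams); mb <- mk(B$grams)
    sa <- rowSums(ma); sb <- rowSums(mb)
    out <- matrix(0, nrow(ma), nrow(mb))
    for (j in seq_len(nrow(mb))) {
      # sum(min) = (sa + sb - sum|a-b|) / 2
      sad <- colSums(abs(t(ma) - mb[j, ]))
      smin <- (sa + sb[j] - sad) / 2
      smax <- sa + sb[j] - smin
      out[, j] <- ifelse(smax == 0, 1, smin / smax)
    }
    out
  }
}
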