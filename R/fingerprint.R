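# Circular substructure (ECFP-style) enumeration and fingerprint folding.
#
# Identifiers are produced by iterated neighbourhood hashing in the spirit of
# the Morgan/ECFP algorithm: every atom starts from a hash of its local
# invariants, then at each radius rehashes its own identifier together with
# the (bond class, neighbour identifier) pairs in sorted order. Environments
# covering a bond set already covered by an earlier environment are dropped
# (radius-0 environments, whose bond set is empty, are always kept), which
# reproduces the conventional unique-environment counts (benzene 3,
# phenol 11 at the ECFP4 radius of 2).
#
# Ring bonds are hashed under one common bond class and atom invariants use
# ring membership, making the identifier set independent of the arbitrary
# kekulization that SMILES round-trips through openbabel produce.

HASH_PRIME <- 2147483647   # 2^31 - 1; identifiers stay below this
HASH_MULT <- 1000003

hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * HASH_MULT + x) %% HASH_PRIME
  h
}

#' Enumerate the unique circular substructures of a molecule
#'
#' Generates the set of hashed circular atom-environment identifiers of a
#' molecule up to `max_radius` bonds, deduplicating environments that cover
#' an identical bond set. The identifier set is the operand of the
#' structure-inclusive similarity [sis_weight()].
#'
#' @param smiles a single SMILES string.
#' @param max_radius maximum environment radius in bonds (default 2, the
#'   ECFP4 convention).
#' @param id molecule identifier carried in the result and in error messages.
#' @return an object of class `substructure_set`: a list with
#'   `molecule_id`, `identifiers` (sorted numeric vector of non-negative
#'   integers), `max_radius` and `n_atoms`.
#' @examples
#' length(enumerate_substructures("c1ccccc1")$identifiers)   # benzene: 3
#' length(enumerate_substructures("Oc1ccccc1")$identifiers)  # phenol: 11
#' @export
enumerate_substructures <- function(smiles, max_radius = 2, id = smiles) {
  if (!is.numeric(max_radius) || length(max_radius) != 1 ||
      is.na(max_radius) || max_radius < 0 || max_radius != floor(max_radius)) {
    config_error("max_radius must be a single integer >= 0, got %s", max_radius)
  }
  mol <- parse_molecule(smiles, id)
  n <- mol$n_atoms
  n_bonds <- nrow(mol$bonds)

  # bond class: all ring bonds share one class so identifiers do not depend
  # on which kekule structure openbabel happened to write
  bond_class <- ifelse(mol$ring_bond, 5L, pmin(mol$orders, 3L))

  neighbours <- vector("list", n)  # per atom: matrix of (bond index, other atom)
  for (b in seq_len(n_bonds)) {
    u <- mol$bonds[b, 1]; v <- mol$bonds[b, 2]
    neighbours[[u]] <- rbind(neighbours[[u]], c(b, v))
    neighbours[[v]] <- rbind(neighbours[[v]], c(b, u))
  }

  # initial invariants: element, heavy degree, H count, charge, ring flag
  ids <- vapply(seq_len(n), function(a) {
    z <- ATOMIC_NUMBERS[[mol$elements[a]]] %||% 0
    hash_ints(c(
      1, z, length(neighbours[[a]]) %/% 1, mol$hydrogens[a],
      mol$charges[a] + 10, as.integer(mol$ring_atom[a])
    ))
  }, numeric(1))

  identifiers <- ids
  if (max_radius >= 1 && n_bonds > 0) {
    # hop distances between all atoms (molecules are small; BFS per atom)
    dist <- matrix(Inf, n, n)
    for (a in seq_len(n)) {
      dist[a, a] <- 0
      frontier <- a
      d <- 0
      while (length(frontier) > 0) {
        d <- d + 1
        nxt <- unique(unlist(lapply(frontier, function(u) neighbours[[u]][, 2])))
        nxt <- nxt[dist[a, nxt] == Inf]
        dist[a, nxt] <- d
        frontier <- nxt
      }
    }
    env_bonds <- function(a, r) {
      which(pmin(dist[a, mol$bonds[, 1]], dist[a, mol$bonds[, 2]]) <= r - 1)
    }

    seen <- new.env(parent = emptyenv())
    for (r in seq_len(max_radius)) {
      new_ids <- vapply(seq_len(n), function(a) {
        nb <- neighbours[[a]]
        if (is.null(nb)) return(ids[a])
        pairs <- cbind(bond_class[nb[, 1]], ids[nb[, 2]])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        hash_ints(c(2, ids[a], as.vector(t(pairs))))
      }, numeric(1))
      for (a in seq_len(n)) {
        eb <- env_bonds(a, r)
        if (length(eb) == 0) next
        key <- paste(eb, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          identifiers <- c(identifiers, new_ids[a])
        }
      }
      ids <- new_ids
    }
  }

  as_substructure_set(sort(unique(identifiers)), id = id,
                      max_radius = max_radius, n_atoms = n)
}

#' Construct a substructure set from raw identifiers
#'
#' Wraps an arbitrary set of non-negative integer identifiers as a
#' `substructure_set`, e.g. for abstract synthetic molecules that have no
#' chemical structure.
#'
#' @param identifiers numeric vector of non-negative integers (deduplicated).
#' @param id molecule identifier.
#' @param max_radius radius annotation (informational).
#' @param n_atoms atom-count annotation (informational).
#' @return a `substructure_set`.
#' @export
as_substructure_set <- function(identifiers, id = "molecule", max_radius = NA,
                                n_atoms = NA) {
  identifiers <- as.numeric(identifiers)
  if (any(is.na(identifiers)) || any(identifiers < 0) ||
      any(identifiers != floor(identifiers))) {
    input_error("molecule '%s': identifiers must be non-negative integers", id)
  }
  structure(
    list(molecule_id = id, identifiers = sort(unique(identifiers)),
         max_radius = max_radius, n_atoms = n_atoms),
    class = "substructure_set"
  )
}

#' @export
print.substructure_set <- function(x, ...) {
  cat(sprintf("substructure_set '%s': %d identifiers (max radius %s)\n",
              x$molecule_id, length(x$identifiers), x$max_radius))
  invisible(x)
}

#' Enumerate substructure sets for a vector of molecules
#'
#' @param smiles named character vector of SMILES strings (names are ids).
#' @param max_radius maximum environment radius, see
#'   [enumerate_substructures()].
#' @return named list of `substructure_set` objects.
#' @export
substructure_sets <- function(smiles, max_radius = 2) {
  ids <- names(smiles) %||% as.character(smiles)
  if (anyDuplicated(ids)) input_error("duplicate molecule ids in SMILES map")
  out <- lapply(seq_along(smiles), function(i) {
    enumerate_substructures(smiles[[i]], max_radius = max_radius, id = ids[i])
  })
  names(out) <- ids
  out
}

#' Fold a substructure set to a fixed-length fingerprint bit vector
#'
#' Each identifier is mapped to bit position `identifier mod length`; the
#' popcount therefore never exceeds the identifier count.
#'
#' @param s a `substructure_set`.
#' @param length fingerprint length in bits (default 1024).
#' @return integer 0/1 vector of the requested length.
#' @export
fold_fingerprint <- function(s, length = 1024) {
  if (!is.numeric(length) || length(length) != 1 || is.na(length) || length < 1) {
    config_error("fingerprint length must be >= 1")
  }
  stopifnot(inherits(s, "substructure_set"))
  bits <- integer(length)
  if (base::length(s$identifiers) > 0) {
    bits[(s$identifiers %% length) + 1] <- 1L
  }
  bits
}

#' Fingerprint matrix for a list of substructure sets
#'
#' @param sets named list of `substructure_set` objects.
#' @param length fingerprint length in bits.
#' @param propagate whether the resulting view is propagated through the
#'   relationship graph before fusion (default TRUE, the structural view).
#' @return a [feature_view()] of dimension (molecules x length).
#' @export
fingerprint_matrix <- function(sets, length = 1024, propagate = TRUE) {
  ids <- names(sets) %||% vapply(sets, function(s) s$molecule_id, character(1))
  m <- t(vapply(sets, fold_fingerprint, integer(length), length = length))
  rownames(m) <- ids
  feature_view("fingerprint", ids, m, propagate = propagate)
}
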