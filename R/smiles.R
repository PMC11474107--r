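# SMILES -> molecular graph, via openbabel (ChemmineOB/ChemmineR).
# openbabel emits kekulized V2000 molfiles, so aromatic flags are not
# available downstream; ring perception is done here instead (see
# enumerate_substructures for how ring bonds enter the atom invariants).

ATOMIC_NUMBERS <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, As = 33, Se = 34, Br = 35, I = 53
)

# allowed valences used to derive implicit hydrogen counts from a
# kekulized bond-order sum; charge shifts the target valence
ALLOWED_VALENCES <- list(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5),
  S = c(2, 4, 6), Cl = 1, As = c(3, 5), Se = c(2, 4, 6), Br = 1, I = 1
)

implicit_hydrogens <- function(element, charge, bond_order_sum) {
  v <- ALLOWED_VALENCES[[element]]
  if (is.null(v)) return(0L)
  # cations/anions of C-group elements lose a bond either way; for the
  # others the charge adds to (N+, O+) or subtracts from (N-, O-) valence
  v <- if (element %in% c("C", "Si")) v - abs(charge) else v + charge
  v <- v[v >= bond_order_sum]
  if (length(v) == 0) return(0L)
  as.integer(min(v) - bond_order_sum)
}

# charges live in "M  CHG" property lines, which ChemmineR does not expose
read_chg_lines <- function(lines, n_atoms) {
  charges <- integer(n_atoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    n <- f[1]
    for (i in seq_len(n)) {
      charges[f[2 * i]] <- f[2 * i + 1]
    }
  }
  charges
}

#' Parse a SMILES string into an internal molecular graph
#'
#' Uses openbabel (via ChemmineOB) to interpret the SMILES and returns the
#' heavy-atom graph: elements, formal charges, implicit hydrogen counts,
#' bonds with kekulized orders, and ring membership of atoms and bonds
#' (a bond is in a ring iff it is not a bridge of the molecular graph).
#'
#' @param smiles a single SMILES string.
#' @param id identifier used in error messages.
#' @return a list with elements `elements`, `charges`, `hydrogens`,
#'   `bonds` (two-column atom-index matrix), `orders`, `ring_bond`,
#'   `ring_atom`, `n_atoms`.
#' @keywords internal
parse_molecule <- function(smiles, id = smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    input_error("molecule '%s': SMILES must be a non-empty string", id)
  }
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(trimws(smiles), "\n")),
    error = function(e) ""
  )
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4 || !grepl("V2000", lines[4])) {
    input_error("molecule '%s': SMILES '%s' could not be parsed", id, smiles)
  }
  n_atoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(n_atoms) || n_atoms < 1) {
    input_error("molecule '%s': empty molecule", id)
  }

  if (n_atoms == 1) {
    # ChemmineR rejects 1-atom/0-bond molfiles, so read the single atom line
    fields <- strsplit(trimws(lines[5]), "\\s+")[[1]]
    elements <- fields[4]
    bonds <- matrix(integer(0), ncol = 2)
    orders <- integer(0)
  } else {
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(lines))
    if (length(sdfset) < 1 || !ChemmineR::validSDF(sdfset)[1]) {
      input_error("molecule '%s': SMILES '%s' could not be parsed", id, smiles)
    }
    sdf <- sdfset[[1]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
    orders <- as.integer(bb[, 3])
  }
  charges <- read_chg_lines(lines, n_atoms)

  n_bonds <- nrow(bonds)
  ring_bond <- logical(n_bonds)
  if (n_bonds > 0) {
    g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
    ring_bond <- rep(TRUE, n_bonds)
    ring_bond[as.integer(igraph::bridges(g))] <- FALSE
  }
  ring_atom <- logical(n_atoms)
  if (any(ring_bond)) {
    ring_atom[unique(as.vector(bonds[ring_bond, , drop = FALSE]))] <- TRUE
  }

  # aromatic order 4 (query molfiles) counts 1.5; openbabel kekulizes, so
  # this is a safety net only
  order_sum <- numeric(n_atoms)
  for (b in seq_len(n_bonds)) {
    o <- if (orders[b] == 4) 1.5 else orders[b]
    order_sum[bonds[b, 1]] <- order_sum[bonds[b, 1]] + o
    order_sum[bonds[b, 2]] <- order_sum[bonds[b, 2]] + o
  }
  hydrogens <- vapply(
    seq_len(n_atoms),
    function(a) implicit_hydrogens(elements[a], charges[a], ceiling(order_sum[a])),
    integer(1)
  )

  list(
    elements = elements, charges = charges, hydrogens = hydrogens,
    bonds = bonds, orders = orders, ring_bond = ring_bond,
    ring_atom = ring_atom, n_atoms = n_atoms
  )
}
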