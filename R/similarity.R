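# Pairwise similarity kernels and entity x entity similarity matrices.
#
# The central kernel is the structure-inclusive similarity (SIS)
#   SIS_{i,j} = |r_i intersect r_j| / |r_j|,
# the fraction of molecule j's substructures contained in molecule i — the
# weight with which i (the collector) gathers information from j (the
# source). It is asymmetric: a superset molecule collects everything from a
# subset molecule (weight 1) while the reverse direction is damped.

#' Structure-inclusive similarity between two substructure sets
#'
#' Computes `|collector ∩ source| / |source|`, the weight with which the
#' collector molecule gathers information from the source molecule. Equals 1
#' iff the source set is contained in the collector set.
#'
#' @param collector,source `substructure_set` objects (see
#'   [enumerate_substructures()], [as_substructure_set()]).
#' @return a weight in `[0, 1]`.
#' @examples
#' benzene <- enumerate_substructures("c1ccccc1")
#' phenol <- enumerate_substructures("Oc1ccccc1")
#' sis_weight(phenol, benzene)  # 1.0: phenol contains all of benzene
#' sis_weight(benzene, phenol)  # 3/11 = 0.27
#' @export
sis_weight <- function(collector, source) {
  stopifnot(inherits(collector, "substructure_set"),
            inherits(source, "substructure_set"))
  if (length(source$identifiers) == 0) {
    domain_error("sis_weight: source molecule '%s' has an empty substructure set",
                 source$molecule_id)
  }
  length(intersect(collector$identifiers, source$identifiers)) /
    length(source$identifiers)
}

#' Jaccard (Tanimoto) similarity of two substructure sets or bit vectors
#'
#' `|a ∩ b| / |a ∪ b|`; symmetric. Tanimoto similarity is the same formula
#' evaluated on fingerprint bit vectors.
#'
#' @param a,b `substructure_set` objects, or 0/1 bit vectors of equal length.
#' @return a value in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  if (inherits(a, "substructure_set") && inherits(b, "substructure_set")) {
    ia <- a$identifiers; ib <- b$identifiers
  } else {
    a <- as.numeric(a); b <- as.numeric(b)
    if (length(a) != length(b)) input_error("jaccard: length mismatch")
    ia <- which(a != 0); ib <- which(b != 0)
  }
  u <- length(union(ia, ib))
  if (u == 0) domain_error("jaccard: both sets are empty")
  length(intersect(ia, ib)) / u
}

#' @rdname jaccard_similarity
#' @export
tanimoto_similarity <- jaccard_similarity

#' Euclidean similarity of two numeric vectors
#'
#' Maps the Euclidean distance d to a bounded similarity. The default kernel
#' is `1 / (1 + d)`; a Gaussian kernel `exp(-d^2 / sigma^2)` is available as
#' an alternative. Both are 1 iff the vectors are equal and decrease
#' monotonically in d.
#'
#' @param a,b numeric vectors of equal length.
#' @param kernel `"inverse"` (default) or `"gaussian"`.
#' @param sigma bandwidth of the Gaussian kernel.
#' @return a value in `(0, 1]`.
#' @export
euclidean_similarity <- function(a, b, kernel = c("inverse", "gaussian"),
                                 sigma = 1) {
  kernel <- match.arg(kernel)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    input_error("euclidean_similarity: lengths %d and %d differ",
                length(a), length(b))
  }
  d <- sqrt(sum((a - b)^2))
  if (kernel == "inverse") 1 / (1 + d) else exp(-d^2 / sigma^2)
}

#' Normalized Smith-Waterman similarity of two protein sequences
#'
#' Computes `SW(a, b) / sqrt(SW(a, a) * SW(b, b))` where SW is the optimal
#' local-alignment score (negative optima are clamped at 0, the score of the
#' empty alignment). Symmetric; 1 for identical sequences.
#'
#' @param seq_a,seq_b amino-acid sequences over the 20-letter alphabet
#'   plus X.
#' @param substitution substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend gap penalties (defaults 10 and 1).
#' @return a value in `[0, 1]`.
#' @export
smith_waterman_normalized <- function(seq_a, seq_b, substitution = "BLOSUM62",
                                      gap_open = 10, gap_extend = 1) {
  check_protein(seq_a, "seq_a")
  check_protein(seq_b, "seq_b")
  sub <- get_substitution_matrix(substitution)
  sw <- function(x, y) {
    s <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(x), Biostrings::AAString(y), type = "local",
      substitutionMatrix = sub, gapOpening = gap_open, gapExtension = gap_extend,
      scoreOnly = TRUE
    )
    max(0, s)
  }
  saa <- sw(seq_a, seq_a); sbb <- sw(seq_b, seq_b)
  if (saa <= 0 || sbb <= 0) {
    domain_error("smith_waterman_normalized: non-positive self-alignment score")
  }
  sw(seq_a, seq_b) / sqrt(saa * sbb)
}

check_protein <- function(seq, what) {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq) || nchar(seq) == 0) {
    input_error("%s: protein sequence must be a non-empty string", what)
  }
  ok <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% ok)
  if (length(bad) > 0) {
    input_error("%s: illegal residue '%s' at position %d", what,
                chars[bad[1]], bad[1])
  }
}

get_substitution_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Construct a similarity_matrix object
#'
#' @param entity_ids ordered entity ids.
#' @param values square numeric matrix in `[0, 1]` with unit diagonal.
#' @param kind one of `"sis"`, `"tanimoto"`, `"jaccard"`, `"euclidean"`,
#'   `"smith_waterman"`, `"precomputed"`.
#' @return an object of class `similarity_matrix` with fields `entity_ids`,
#'   `values`, `symmetric` (TRUE iff the matrix equals its transpose) and
#'   `kind`.
#' @export
new_similarity_matrix <- function(entity_ids, values, kind) {
  values <- as.matrix(values)
  n <- length(entity_ids)
  if (nrow(values) != n || ncol(values) != n) {
    input_error("similarity matrix must be %d x %d", n, n)
  }
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
    input_error("similarity values must lie in [0, 1]")
  }
  if (any(abs(diag(values) - 1) > 1e-12)) {
    input_error("similarity matrix must have a unit diagonal")
  }
  dimnames(values) <- list(entity_ids, entity_ids)
  structure(
    list(entity_ids = as.character(entity_ids), values = values,
         symmetric = max(abs(values - t(values))) < 1e-12, kind = kind),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix (%s): %d entities, %s\n", x$kind,
              length(x$entity_ids),
              if (x$symmetric) "symmetric" else "asymmetric"))
  invisible(x)
}

#' Structure-inclusive similarity matrix
#'
#' Entry (i, j) is [sis_weight()] with molecule i as collector and molecule j
#' as source; the diagonal is 1 and the matrix is in general asymmetric.
#'
#' @param sets named list of `substructure_set` objects, all non-empty.
#' @return a `similarity_matrix` of kind `"sis"`.
#' @export
sis_matrix <- function(sets) {
  ids <- names(sets) %||% vapply(sets, function(s) s$molecule_id, character(1))
  sizes <- vapply(sets, function(s) length(s$identifiers), numeric(1))
  if (any(sizes == 0)) {
    domain_error("sis_matrix: empty substructure set for molecule '%s'",
                 ids[which(sizes == 0)[1]])
  }
  n <- length(sets)
  v <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) v[i, j] <- sis_weight(sets[[i]], sets[[j]])
    }
  }
  new_similarity_matrix(ids, v, "sis")
}

#' Entity similarity matrix of a chosen kind
#'
#' Dispatches to the per-pair kernels: `"sis"`, `"jaccard"`/`"tanimoto"` on
#' substructure sets; `"euclidean"` on the rows of a numeric feature matrix;
#' `"smith_waterman"` on a named character vector of protein sequences;
#' `"precomputed"` validates a user-supplied square matrix (values in
#' `[0, 1]`, unit diagonal).
#'
#' @param x input matching the kind (see Details).
#' @param kind similarity kind.
#' @param ... passed to the kernel ([euclidean_similarity()] /
#'   [smith_waterman_normalized()]).
#' @return a `similarity_matrix`.
#' @export
similarity_matrix <- function(x, kind = c("sis", "tanimoto", "jaccard",
                                          "euclidean", "smith_waterman",
                                          "precomputed"), ...) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) config_error("unknown similarity kind '%s'",
                                                    kind[1]))
  if (kind == "sis") return(sis_matrix(x))
  if (kind %in% c("tanimoto", "jaccard")) {
    ids <- names(x) %||% vapply(x, function(s) s$molecule_id, character(1))
    n <- length(x)
    v <- matrix(1, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j) v[i, j] <- v[j, i] <- jaccard_similarity(x[[i]], x[[j]])
    }
    return(new_similarity_matrix(ids, v, kind))
  }
  if (kind == "euclidean") {
    m <- if (inherits(x, "feature_view")) x$matrix else as.matrix(x)
    ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
    n <- nrow(m)
    v <- matrix(1, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j) v[i, j] <- v[j, i] <- euclidean_similarity(m[i, ], m[j, ], ...)
    }
    return(new_similarity_matrix(ids, v, kind))
  }
  if (kind == "smith_waterman") {
    ids <- names(x) %||% as.character(seq_along(x))
    n <- length(x)
    v <- matrix(1, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j) v[i, j] <- v[j, i] <- smith_waterman_normalized(x[[i]], x[[j]], ...)
    }
    return(new_similarity_matrix(ids, v, kind))
  }
  # precomputed
  m <- as.matrix(x)
  ids <- rownames(m) %||% colnames(m) %||% as.character(seq_len(nrow(m)))
  new_similarity_matrix(ids, m, "precomputed")
}

#' Write / read a similarity matrix as square CSV
#'
#' The CSV has a header row of entity ids and an id first column; values are
#' written at full precision so matrices round-trip exactly.
#'
#' @param s a `similarity_matrix`.
#' @param path file path.
#' @export
write_similarity <- function(s, path) {
  stopifnot(inherits(s, "similarity_matrix"))
  df <- data.frame(id = s$entity_ids,
                   formatC(s$values, format = "g", digits = 17),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", s$entity_ids)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @param kind kind label attached to the matrix read back.
#' @export
read_similarity <- function(path, kind = "precomputed") {
  df <- read_table_auto(path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  s <- new_similarity_matrix(ids, m, kind)
  s
}
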