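# Feature views: named (entities x dims) matrices with a flag saying whether
# the view is propagated through the relationship graph before fusion.

#' Create a feature view
#'
#' A feature view is a named numeric matrix over an ordered set of entities,
#' together with a flag stating whether it is passed through the graph
#' convolution before fusion (structural views) or concatenated raw
#' (sequence-embedding views).
#'
#' @param name view name.
#' @param entity_ids ordered character vector of entity ids (matrix rows).
#' @param matrix numeric matrix, one row per entity; all entries finite.
#' @param propagate logical flag.
#' @return an object of class `feature_view`.
#' @export
feature_view <- function(name, entity_ids, matrix, propagate = FALSE) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (nrow(matrix) != length(entity_ids)) {
    input_error("view '%s': %d rows for %d entities", name, nrow(matrix),
                length(entity_ids))
  }
  if (length(matrix) > 0 && !all(is.finite(matrix))) {
    input_error("view '%s': non-finite entries", name)
  }
  rownames(matrix) <- entity_ids
  structure(
    list(name = name, entity_ids = as.character(entity_ids), matrix = matrix,
         propagate = isTRUE(propagate)),
    class = "feature_view"
  )
}

#' @export
print.feature_view <- function(x, ...) {
  cat(sprintf("feature_view '%s': %d x %d (%s)\n", x$name, nrow(x$matrix),
              ncol(x$matrix), if (x$propagate) "propagated" else "raw"))
  invisible(x)
}

#' Binary gene-ontology annotation matrix
#'
#' Builds the proteins x GO-terms binary indicator matrix: columns are the
#' sorted union of all terms observed in the dataset, and entry (i, t) is 1
#' iff protein i carries term t.
#'
#' @param go named list mapping protein id to a character vector of GO terms.
#' @param propagate whether the view is propagated through the protein graph
#'   (default TRUE).
#' @return a [feature_view()] named `"go"`.
#' @export
build_go_matrix <- function(go, propagate = TRUE) {
  if (length(go) < 1) input_error("build_go_matrix: at least one protein required")
  ids <- names(go)
  if (is.null(ids) || anyDuplicated(ids)) {
    input_error("build_go_matrix: proteins must have unique ids")
  }
  vocab <- sort(unique(unlist(go, use.names = FALSE)))
  m <- matrix(0, nrow = length(go), ncol = length(vocab),
              dimnames = list(ids, vocab))
  for (i in seq_along(go)) {
    terms <- unique(go[[i]])
    if (length(terms) == 0) {
      warning(sprintf("protein '%s' has no GO terms (all-zero row)", ids[i]))
    } else {
      m[i, terms] <- 1
    }
  }
  feature_view("go", ids, m, propagate = propagate)
}

#' Recover term sets from a GO feature view
#'
#' Inverse of [build_go_matrix()]: maps rows back through the column
#' vocabulary.
#'
#' @param view a GO [feature_view()].
#' @return named list of character term vectors.
#' @export
go_terms_from_matrix <- function(view) {
  stopifnot(inherits(view, "feature_view"))
  vocab <- colnames(view$matrix)
  out <- lapply(seq_len(nrow(view$matrix)), function(i) {
    vocab[view$matrix[i, ] != 0]
  })
  names(out) <- view$entity_ids
  out
}

#' Load a precomputed embedding table as a feature view
#'
#' Reads a delimited numeric table keyed by an id column (first column, or a
#' column named `id`), reorders rows to `entity_ids` and optionally checks
#' the embedding width.
#'
#' @param path TSV/CSV file path.
#' @param entity_ids ordered entity ids the rows must cover.
#' @param expected_dims required number of embedding dimensions, or NULL.
#' @param name view name (default the file base name).
#' @param propagate propagate flag (default FALSE: embedding views are fused
#'   raw).
#' @return a [feature_view()].
#' @export
load_embedding_view <- function(path, entity_ids, expected_dims = NULL,
                                name = sub("\\.[^.]+$", "", basename(path)),
                                propagate = FALSE) {
  df <- read_table_auto(path)
  idcol <- if ("id" %in% names(df)) "id" else names(df)[1]
  ids <- as.character(df[[idcol]])
  missing <- setdiff(entity_ids, ids)
  if (length(missing) > 0) {
    input_error("embedding table '%s' is missing ids: %s", path,
                paste(missing, collapse = ", "))
  }
  m <- as.matrix(df[match(entity_ids, ids), setdiff(names(df), idcol), drop = FALSE])
  storage.mode(m) <- "double"
  if (!is.null(expected_dims) && ncol(m) != expected_dims) {
    input_error("embedding table '%s': width %d, expected %d", path, ncol(m),
                expected_dims)
  }
  feature_view(name, entity_ids, m, propagate = propagate)
}

#' Seeded random-projection embedding view
#'
#' Deterministic stand-in for precomputed sequence embeddings (e.g. when no
#' Mol2Vec/ProtTrans table is available): a simple content feature per entity
#' (folded fingerprint bits for substructure sets, residue composition and
#' length for sequences) multiplied by a seeded Gaussian projection.
#'
#' @param x a named list of `substructure_set` objects, or a named character
#'   vector of amino-acid sequences.
#' @param dims output dimensionality.
#' @param seed integer seed; the same `x`, `dims` and `seed` give a bitwise
#'   identical matrix.
#' @param name view name.
#' @param propagate propagate flag (default FALSE).
#' @return a [feature_view()].
#' @export
random_projection_view <- function(x, dims, seed, name = "random_projection",
                                   propagate = FALSE) {
  if (!is.numeric(dims) || dims < 1) config_error("dims must be >= 1")
  dims <- as.integer(dims)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "substructure_set"))) {
    base <- t(vapply(x, fold_fingerprint, integer(128), length = 128))
    ids <- names(x) %||% vapply(x, function(s) s$molecule_id, character(1))
  } else if (is.character(x)) {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
    base <- t(vapply(x, function(s) {
      counts <- table(factor(strsplit(s, "")[[1]], levels = aa))
      c(as.numeric(counts) / max(1, nchar(s)), nchar(s) / 1000)
    }, numeric(length(aa) + 1)))
    ids <- names(x) %||% as.character(seq_along(x))
  } else {
    input_error("random_projection_view: x must be substructure sets or sequences")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  proj <- matrix(rnorm(ncol(base) * dims), ncol(base), dims)
  feature_view(name, ids, base %*% proj, propagate = propagate)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
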