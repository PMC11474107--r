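# The drug x protein affinity dataset container.

#' Construct a drug-target affinity dataset
#'
#' Bundles the affinity matrix (drugs x proteins, `NA` = unmeasured cell)
#' with the raw entity inputs. Fold assignments index the *labeled* pairs:
#' the cells `which(!is.na(affinity))` enumerated in R's column-major order
#' (see [labeled_pairs()]).
#'
#' @param affinity numeric matrix with drug rownames and protein colnames
#'   (or supplied via `drug_ids` / `protein_ids`); `NA` marks missing cells.
#' @param drug_ids,protein_ids entity orderings (default: dimnames).
#' @param folds list with `train` (list of integer vectors) and `test`
#'   (integer vector), indexing rows of [labeled_pairs()]; disjoint. NULL
#'   means all labeled pairs are training pairs.
#' @param smiles named character vector of drug SMILES (optional).
#' @param substructures named list of identifier vectors for abstract
#'   molecules (optional alternative to `smiles`).
#' @param sequences named character vector of protein sequences (optional).
#' @param go named list of GO term sets per protein (optional).
#' @param drug_embedding,protein_embedding numeric matrices of precomputed
#'   per-entity embeddings, rows ordered like the ids (optional).
#' @param protein_similarity precomputed protein similarity matrix
#'   (optional; used instead of Smith-Waterman when present).
#' @return an object of class `dta_dataset`.
#' @export
dta_dataset <- function(affinity, drug_ids = rownames(affinity),
                        protein_ids = colnames(affinity), folds = NULL,
                        smiles = NULL, substructures = NULL, sequences = NULL,
                        go = NULL, drug_embedding = NULL,
                        protein_embedding = NULL, protein_similarity = NULL) {
  affinity <- as.matrix(affinity)
  if (is.null(drug_ids) || is.null(protein_ids)) {
    input_error("dta_dataset: affinity matrix needs drug and protein ids")
  }
  if (anyDuplicated(drug_ids) || anyDuplicated(protein_ids)) {
    input_error("dta_dataset: entity ids must be unique")
  }
  if (nrow(affinity) != length(drug_ids) ||
      ncol(affinity) != length(protein_ids)) {
    input_error("dta_dataset: affinity is %d x %d but there are %d drugs and %d proteins",
                nrow(affinity), ncol(affinity), length(drug_ids),
                length(protein_ids))
  }
  dimnames(affinity) <- list(drug_ids, protein_ids)
  n_labeled <- sum(!is.na(affinity))
  if (n_labeled == 0) input_error("dta_dataset: no labeled pairs (all cells missing)")
  check_cover <- function(x, what) {
    if (is.null(x)) return(invisible())
    nm <- if (is.matrix(x)) rownames(x) else names(x)
    ids <- if (what == "drug") drug_ids else protein_ids
    miss <- setdiff(ids, nm)
    if (length(miss) > 0) {
      input_error("dta_dataset: %s input missing ids: %s", what,
                  paste(miss, collapse = ", "))
    }
  }
  check_cover(smiles, "drug"); check_cover(substructures, "drug")
  check_cover(drug_embedding, "drug")
  check_cover(sequences, "protein"); check_cover(go, "protein")
  check_cover(protein_embedding, "protein")

  d <- structure(
    list(drug_ids = as.character(drug_ids),
         protein_ids = as.character(protein_ids), affinity = affinity,
         folds = folds, smiles = smiles, substructures = substructures,
         sequences = sequences, go = go, drug_embedding = drug_embedding,
         protein_embedding = protein_embedding,
         protein_similarity = protein_similarity),
    class = "dta_dataset"
  )
  validate_folds(d)
  d
}

validate_folds <- function(d) {
  if (is.null(d$folds)) return(invisible())
  n <- nrow(labeled_pairs(d))
  groups <- c(d$folds$train, list(d$folds$test))
  idx <- unlist(groups)
  if (length(idx) == 0) return(invisible())
  if (any(idx < 1 | idx > n | idx != floor(idx))) {
    input_error("fold indices must address labeled pairs (1..%d)", n)
  }
  if (anyDuplicated(idx)) input_error("folds must be disjoint")
  invisible()
}

#' Enumerate the labeled drug-protein pairs of a dataset
#'
#' Lists the non-missing affinity cells in column-major order; fold indices
#' address rows of this table.
#'
#' @param d a `dta_dataset`.
#' @return data.frame with columns `drug` and `protein` (integer indices),
#'   `drug_id`, `protein_id`, `y`.
#' @export
labeled_pairs <- function(d) {
  stopifnot(inherits(d, "dta_dataset"))
  cells <- which(!is.na(d$affinity))
  di <- ((cells - 1) %% nrow(d$affinity)) + 1
  pi_ <- ((cells - 1) %/% nrow(d$affinity)) + 1
  data.frame(drug = di, protein = pi_, drug_id = d$drug_ids[di],
             protein_id = d$protein_ids[pi_], y = d$affinity[cells],
             stringsAsFactors = FALSE)
}

#' Indices of training / test pairs of a dataset
#'
#' @param d a `dta_dataset`.
#' @return list with integer vectors `train` and `test` (rows of
#'   [labeled_pairs()]). With no fold information all labeled pairs are
#'   training pairs.
#' @export
dataset_split <- function(d) {
  n <- nrow(labeled_pairs(d))
  if (is.null(d$folds)) return(list(train = seq_len(n), test = integer(0)))
  list(train = sort(unlist(d$folds$train)), test = sort(d$folds$test))
}

#' @export
print.dta_dataset <- function(x, ...) {
  lp <- labeled_pairs(x)
  cat(sprintf("dta_dataset: %d drugs x %d proteins, %d labeled pairs (%.1f%% missing)\n",
              length(x$drug_ids), length(x$protein_ids), nrow(lp),
              100 * mean(is.na(x$affinity))))
  if (!is.null(x$folds)) {
    cat(sprintf("  folds: %d train folds (%d pairs), %d test pairs\n",
                length(x$folds$train), length(unlist(x$folds$train)),
                length(x$folds$test)))
  }
  invisible(x)
}
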