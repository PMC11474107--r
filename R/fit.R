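# The main model: sisdta() fits the SIS-graph GCN affinity regressor and
# returns a classed object with the usual modelling methods.

#' Fit the SIS-graph affinity regression model
#'
#' Builds the drug and protein relationship graphs from the chosen
#' similarities, propagates the structural feature views through two-layer
#' weighted graph convolutions, fuses them with the raw embedding views per
#' drug-protein pair, and trains the autoencoder + regression head under the
#' joint prediction/reconstruction objective with full-batch Adam.
#'
#' Drugs use the structure similarity named by `similarity` (default the
#' asymmetric SIS, giving a directed graph); proteins use a precomputed
#' similarity matrix when the dataset carries one, otherwise normalized
#' Smith-Waterman on the sequences, and always an undirected graph.
#'
#' @param data a [dta_dataset()].
#' @param similarity drug similarity kind: `"sis"` (directed graph) or one of
#'   the symmetric kernels `"tanimoto"`, `"jaccard"`, `"euclidean"`.
#' @param delta drug similarity threshold (default 0.6; 0.7 suits
#'   KIBA-scaled data).
#' @param delta_protein protein similarity threshold (default `delta`).
#' @param k backfill floor: minimum number of information sources per node.
#' @param radius circular-substructure radius for ECFP enumeration.
#' @param fp_length fingerprint length in bits.
#' @param sis_on operands of the SIS computation: `"sets"` (unfolded
#'   identifier sets, default) or `"bits"` (folded fingerprint positions).
#' @param gcn_dims widths of the two graph-convolution layers.
#' @param latent_dim autoencoder code width.
#' @param hidden_dim regression-head hidden width.
#' @param epochs training epochs (full-batch).
#' @param learning_rate Adam learning rate.
#' @param lambda weight of the reconstruction loss term (default 1, the
#'   printed objective).
#' @param ae_activation autoencoder activation (`"relu"` or `"identity"`).
#' @param seed integer seed controlling parameter initialisation.
#' @param verbose print the loss every 50 epochs.
#' @return an object of class `sisdta`; see [predict.sisdta()],
#'   [evaluate_fit()], [plot.sisdta()].
#' @examples
#' \donttest{
#' d <- generate_dataset(synthetic_spec(m_drugs = 12, n_proteins = 6, seed = 7))
#' fit <- sisdta(d, epochs = 50, seed = 7)
#' print(fit)
#' head(predict(fit))
#' }
#' @export
sisdta <- function(data,
                   similarity = c("sis", "tanimoto", "jaccard", "euclidean"),
                   delta = 0.6, delta_protein = delta, k = 5,
                   radius = 2, fp_length = 1024,
                   sis_on = c("sets", "bits"),
                   gcn_dims = c(64, 32), latent_dim = 64, hidden_dim = 32,
                   epochs = 200, learning_rate = 1e-3, lambda = 1,
                   ae_activation = "relu", seed = 1, verbose = FALSE) {
  stopifnot(inherits(data, "dta_dataset"))
  similarity <- match.arg(similarity)
  sis_on <- match.arg(sis_on)
  if (length(gcn_dims) != 2) config_error("gcn_dims must give two layer widths")

  # --- substructure sets -------------------------------------------------
  sets <- drug_substructure_sets(data, radius)

  # --- feature views -----------------------------------------------------
  fp_view <- fingerprint_matrix(sets, length = fp_length, propagate = TRUE)
  drug_views <- list(fp_view)
  if (!is.null(data$drug_embedding)) {
    drug_views <- c(drug_views, list(feature_view(
      "drug_embedding", data$drug_ids,
      data$drug_embedding[data$drug_ids, , drop = FALSE], propagate = FALSE)))
  }
  protein_views <- list()
  if (!is.null(data$go)) {
    protein_views <- c(protein_views,
                       list(build_go_matrix(data$go[data$protein_ids])))
  }
  if (!is.null(data$protein_embedding)) {
    protein_views <- c(protein_views, list(feature_view(
      "protein_embedding", data$protein_ids,
      data$protein_embedding[data$protein_ids, , drop = FALSE],
      propagate = FALSE)))
  }
  if (length(protein_views) == 0) {
    input_error("no protein feature view available (need GO terms or embeddings)")
  }

  # --- similarities and graphs ------------------------------------------
  sis_sets <- sets
  if (sis_on == "bits") {
    sis_sets <- lapply(sets, function(s) {
      as_substructure_set(which(fold_fingerprint(s, fp_length) == 1) - 1,
                          id = s$molecule_id)
    })
  }
  S_drug <- switch(similarity,
    sis = sis_matrix(sis_sets),
    tanimoto = similarity_matrix(sis_sets, "tanimoto"),
    jaccard = similarity_matrix(sis_sets, "jaccard"),
    euclidean = similarity_matrix(fp_view$matrix, "euclidean")
  )
  drug_graph <- build_relationship_graph(S_drug, delta = delta, k = k,
                                         symmetric = S_drug$symmetric)
  S_protein <- protein_similarity_matrix(data)
  protein_graph <- build_relationship_graph(S_protein, delta = delta_protein,
                                            k = k, symmetric = TRUE)

  # --- training ----------------------------------------------------------
  pairs <- labeled_pairs(data)
  split <- dataset_split(data)
  if (length(split$train) == 0) input_error("no training pairs")
  model <- model_init(drug_views, protein_views, gcn_dims, latent_dim,
                      hidden_dim, ae_activation, seed)
  state <- list(drug_views = drug_views, protein_views = protein_views,
                A_drug = drug_graph$normalized,
                A_protein = protein_graph$normalized)
  di <- pairs$drug[split$train]
  pi_ <- pairs$protein[split$train]
  y <- pairs$y[split$train]

  st <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        mse = numeric(0), reconstruction = numeric(0))
  if (epochs > 0) {
    for (e in seq_len(epochs)) {
      fw <- model_forward(model, state, di, pi_, keep = TRUE)
      l_mse <- mean((y - fw$y_hat)^2)
      l_rec <- mean((fw$H_I - fw$H_D)^2)
      l <- l_mse + lambda * l_rec
      if (!is.finite(l)) {
        stop(sprintf("training diverged: non-finite loss at epoch %d", e))
      }
      history[e, ] <- list(e, l, l_mse, l_rec)
      grads <- model_gradients(model, state, di, pi_, y, lambda, fw)
      upd <- adam_step(model$params, grads, st, learning_rate)
      model$params <- upd$params
      st <- upd$state
      if (verbose && (e %% 50 == 0 || e == 1)) {
        message(sprintf("epoch %4d  loss %.5f (mse %.5f, recon %.5f)",
                        e, l, l_mse, l_rec))
      }
    }
  }

  fit <- structure(list(
    call = match.call(),
    config = list(similarity = similarity, delta = delta,
                  delta_protein = delta_protein, k = k, radius = radius,
                  fp_length = fp_length, sis_on = sis_on,
                  gcn_dims = gcn_dims, latent_dim = latent_dim,
                  hidden_dim = hidden_dim, epochs = epochs,
                  learning_rate = learning_rate, lambda = lambda,
                  ae_activation = ae_activation, seed = seed),
    drug_ids = data$drug_ids, protein_ids = data$protein_ids,
    substructure_sets = sets,
    drug_similarity = S_drug, protein_similarity = S_protein,
    drug_graph = drug_graph, protein_graph = protein_graph,
    model = model, state = state, history = history,
    pairs = pairs, train_index = split$train, test_index = split$test,
    seed = seed
  ), class = "sisdta")
  fw <- model_forward(model, state, di, pi_)
  fit$fitted.values <- fw$y_hat
  fit$residuals <- y - fw$y_hat
  fit
}

drug_substructure_sets <- function(data, radius) {
  if (!is.null(data$substructures)) {
    sets <- lapply(data$drug_ids, function(id) {
      x <- data$substructures[[id]]
      if (inherits(x, "substructure_set")) x else as_substructure_set(x, id = id)
    })
    names(sets) <- data$drug_ids
    sets
  } else if (!is.null(data$smiles)) {
    substructure_sets(data$smiles[data$drug_ids], max_radius = radius)
  } else {
    input_error("dataset has neither SMILES nor substructure sets for drugs")
  }
}

protein_similarity_matrix <- function(data) {
  if (!is.null(data$protein_similarity)) {
    m <- data$protein_similarity[data$protein_ids, data$protein_ids]
    similarity_matrix(m, "precomputed")
  } else if (!is.null(data$sequences)) {
    similarity_matrix(data$sequences[data$protein_ids], "smith_waterman")
  } else {
    input_error("dataset has neither protein similarities nor sequences")
  }
}

#' Predict binding affinities from a fitted model
#'
#' @param object a fitted `sisdta` model.
#' @param pairs a data.frame with columns `drug_id` and `protein_id` (or
#'   `drug` / `protein` integer indices). The default predicts the model's
#'   held-out test pairs, or all labeled pairs when no test split exists.
#' @param ... unused.
#' @return numeric vector of predicted affinities, in input order.
#' @export
predict.sisdta <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) {
    idx <- if (length(object$test_index) > 0) object$test_index
           else seq_len(nrow(object$pairs))
    pairs <- object$pairs[idx, ]
  }
  if (!is.null(pairs$drug_id)) {
    unknown <- setdiff(unique(as.character(pairs$drug_id)), object$drug_ids)
    if (length(unknown) > 0) {
      input_error("unknown drug ids: %s", paste(unknown, collapse = ", "))
    }
    di <- match(as.character(pairs$drug_id), object$drug_ids)
  } else {
    di <- as.integer(pairs$drug)
  }
  if (!is.null(pairs$protein_id)) {
    unknown <- setdiff(unique(as.character(pairs$protein_id)), object$protein_ids)
    if (length(unknown) > 0) {
      input_error("unknown protein ids: %s", paste(unknown, collapse = ", "))
    }
    pi_ <- match(as.character(pairs$protein_id), object$protein_ids)
  } else {
    pi_ <- as.integer(pairs$protein)
  }
  if (any(is.na(di)) || any(is.na(pi_)) ||
      any(di < 1 | di > length(object$drug_ids)) ||
      any(pi_ < 1 | pi_ > length(object$protein_ids))) {
    input_error("pair indices out of range")
  }
  model_forward(object$model, object$state, di, pi_)$y_hat
}

#' @export
print.sisdta <- function(x, ...) {
  cat("SIS-graph affinity regression model\n")
  cat(sprintf("  %d drugs, %d proteins; %d training pairs, %d test pairs\n",
              length(x$drug_ids), length(x$protein_ids),
              length(x$train_index), length(x$test_index)))
  cat(sprintf("  drug similarity: %s (%s graph, delta = %g, k = %d)\n",
              x$config$similarity,
              if (x$drug_similarity$symmetric) "undirected" else "directed",
              x$config$delta, x$config$k))
  if (nrow(x$history) > 0) {
    cat(sprintf("  final training loss %.5f after %d epochs\n",
                tail(x$history$loss, 1), nrow(x$history)))
  }
  invisible(x)
}

#' @export
summary.sisdta <- function(object, ...) {
  out <- list(config = object$config, history = object$history,
              train = evaluate_fit(object, split = "train"),
              test = if (length(object$test_index) > 0)
                evaluate_fit(object, split = "test") else NULL)
  class(out) <- "summary.sisdta"
  out
}

#' @export
print.summary.sisdta <- function(x, ...) {
  cat("SIS-graph affinity regression model\n\n")
  cat("Training metrics:\n"); print(x$train)
  if (!is.null(x$test)) { cat("\nHeld-out test metrics:\n"); print(x$test) }
  invisible(x)
}

#' @export
coef.sisdta <- function(object, ...) object$model$params

#' @export
fitted.sisdta <- function(object, ...) object$fitted.values

#' @export
residuals.sisdta <- function(object, ...) object$residuals

#' Plot the training history of a fitted model
#'
#' Draws the joint loss and its prediction / reconstruction components per
#' epoch.
#'
#' @param x a fitted `sisdta` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sisdta <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) {
    warning("model was fitted with 0 epochs; nothing to plot")
    return(invisible(x))
  }
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "sisdta training history", ...)
  lines(h$epoch, h$mse, lty = 2)
  lines(h$epoch, h$reconstruction, lty = 3)
  legend("topright", legend = c("joint", "prediction MSE", "reconstruction"),
         lty = 1:3, bty = "n")
  invisible(x)
}

#' Save / load a fitted model
#'
#' Checkpoints carry the configuration, all parameter tensors and the cached
#' entity state; a reloaded model produces bitwise-identical predictions.
#'
#' @param object a fitted `sisdta` model.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "sisdta"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "sisdta")) input_error("'%s' is not a sisdta checkpoint", path)
  object
}
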