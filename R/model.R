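# Network primitives: weighted graph convolution, multi-view entity
# encoding, the pair autoencoder and the joint loss, plus the full-batch
# Adam training engine used by sisdta(). Everything is dense base-R linear
# algebra; gradients are hand-derived and locked by numerical-gradient tests.

relu <- function(x) pmax(x, 0)

apply_activation <- function(x, activation) {
  switch(activation,
         relu = relu(x),
         identity = x,
         config_error("unknown activation '%s'", activation))
}

#' Weighted graph convolution layer
#'
#' Computes `activation(A_norm %*% X %*% theta)`: node features are averaged
#' over each node's information sources under the symmetric degree
#' normalization and linearly transformed.
#'
#' @param X node-feature matrix (nodes x d).
#' @param A_norm a `normalized_adjacency` (see [normalize_adjacency()]) or a
#'   plain square matrix.
#' @param theta parameter matrix (d x k).
#' @param activation `"relu"` or `"identity"`.
#' @return the propagated (nodes x k) matrix.
#' @export
gcn_layer <- function(X, A_norm, theta, activation = "identity") {
  a <- if (inherits(A_norm, "normalized_adjacency")) A_norm$values else A_norm
  X <- as.matrix(X); theta <- as.matrix(theta)
  if (nrow(X) != nrow(a)) {
    input_error("gcn_layer: %d feature rows for a %d-node graph",
                nrow(X), nrow(a))
  }
  if (ncol(X) != nrow(theta)) {
    input_error("gcn_layer: feature width %d does not match theta rows %d",
                ncol(X), nrow(theta))
  }
  apply_activation(a %*% X %*% theta, activation)
}

#' Encode an entity type from its feature views
#'
#' Views flagged `propagate` pass through a two-layer graph convolution
#' stack (`relu` after the first layer, linear output); raw views pass
#' through unchanged. The resulting view outputs are concatenated
#' column-wise in the declared view order.
#'
#' @param views list of [feature_view()] objects sharing entity order with
#'   the graph.
#' @param A_norm the entity graph's `normalized_adjacency`.
#' @param params named list: for each propagated view name, a list of
#'   parameter matrices `theta1`, `theta2`.
#' @return the (entities x total width) embedding matrix.
#' @export
encode_entity <- function(views, A_norm, params) {
  a <- if (inherits(A_norm, "normalized_adjacency")) A_norm$values else A_norm
  pieces <- lapply(views, function(v) {
    if (!v$propagate) return(v$matrix)
    if (!identical(v$entity_ids, rownames(a) %||% v$entity_ids)) {
      input_error("view '%s': entity order does not match the graph", v$name)
    }
    p <- params[[v$name]]
    if (is.null(p)) input_error("no GCN parameters for view '%s'", v$name)
    z1 <- gcn_layer(v$matrix, a, p$theta1, activation = "relu")
    gcn_layer(z1, a, p$theta2, activation = "identity")
  })
  do.call(cbind, pieces)
}

#' Concatenate a drug and a protein vector into a pair feature
#'
#' @param drug_vec,protein_vec numeric vectors.
#' @return the concatenated vector, drug first.
#' @export
pair_feature <- function(drug_vec, protein_vec) {
  c(as.numeric(drug_vec), as.numeric(protein_vec))
}

#' Autoencoder parameter initialisation
#'
#' @param input_dim width of the pair feature.
#' @param latent_dim width of the code layer; must be < `input_dim`.
#' @param activation encoder activation (`"relu"` or `"identity"`).
#' @param seed integer seed for the Gaussian initialisation.
#' @return a parameter list (`W_enc`, `b_enc`, `W_dec`, `b_dec`,
#'   `activation`).
#' @export
autoencoder_params <- function(input_dim, latent_dim, activation = "relu",
                               seed = 1) {
  if (latent_dim >= input_dim) {
    config_error("latent width (%d) must be smaller than the input width (%d)",
                 latent_dim, input_dim)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  list(
    W_enc = he_init(input_dim, latent_dim),
    b_enc = numeric(latent_dim),
    W_dec = he_init(latent_dim, input_dim),
    b_dec = numeric(input_dim),
    activation = activation
  )
}

#' Encode and reconstruct pair features
#'
#' @param H pair-feature matrix (pairs x input width) or a single vector.
#' @param params autoencoder parameters (see [autoencoder_params()]); an
#'   identity-initialized linear autoencoder reproduces its input exactly.
#' @return list with `latent` and `reconstruction`.
#' @export
autoencode <- function(H, params) {
  H <- if (is.matrix(H)) H else matrix(H, nrow = 1)
  if (ncol(H) != nrow(params$W_enc)) {
    input_error("autoencode: input width %d does not match encoder width %d",
                ncol(H), nrow(params$W_enc))
  }
  latent <- apply_activation(
    sweep(H %*% params$W_enc, 2, params$b_enc, "+"),
    params$activation %||% "relu"
  )
  recon <- sweep(latent %*% params$W_dec, 2, params$b_dec, "+")
  list(latent = latent, reconstruction = recon)
}

#' Joint prediction + reconstruction loss
#'
#' Mean squared prediction error plus the mean squared reconstruction error
#' of the pair features, equally weighted; the reconstruction residual of a
#' vector feature is reduced by the mean over its components so the two
#' terms share scale.
#'
#' @param y,y_hat true and predicted affinities (length q).
#' @param H_I,H_D original and decoded pair features (q x D matrices, or
#'   vectors for q = 1).
#' @param lambda weight of the reconstruction term (default 1, the printed
#'   form of the objective).
#' @return scalar loss.
#' @export
joint_loss <- function(y, y_hat, H_I, H_D, lambda = 1) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  H_I <- if (is.matrix(H_I)) H_I else matrix(H_I, nrow = 1)
  H_D <- if (is.matrix(H_D)) H_D else matrix(H_D, nrow = 1)
  q <- length(y)
  if (q < 1) input_error("joint_loss: q must be >= 1")
  if (length(y_hat) != q || nrow(H_I) != q || nrow(H_D) != q ||
      ncol(H_I) != ncol(H_D)) {
    input_error("joint_loss: length mismatch (q = %d, |y_hat| = %d, H rows %d/%d)",
                q, length(y_hat), nrow(H_I), nrow(H_D))
  }
  mean((y - y_hat)^2) + lambda * mean((H_I - H_D)^2)
}

he_init <- function(d_in, d_out) {
  matrix(rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out)
}

# ---- internal training engine -------------------------------------------

# parameters are a flat named list of matrices/vectors; `spec` records which
# views are propagated and the layer widths
model_init <- function(drug_views, protein_views, gcn_dims, latent_dim,
                       hidden_dim, ae_activation, seed) {
  set.seed(seed)
  params <- list()
  spec <- list(drug = list(), protein = list())
  width <- function(views, entity) {
    total <- 0
    for (v in views) {
      if (v$propagate) {
        d <- ncol(v$matrix)
        params[[paste0(entity, ".", v$name, ".theta1")]] <<-
          he_init(d, gcn_dims[1])
        params[[paste0(entity, ".", v$name, ".theta2")]] <<-
          he_init(gcn_dims[1], gcn_dims[2])
        total <- total + gcn_dims[2]
      } else {
        total <- total + ncol(v$matrix)
      }
    }
    total
  }
  d_drug <- width(drug_views, "drug")
  d_protein <- width(protein_views, "protein")
  input_dim <- d_drug + d_protein
  if (latent_dim >= input_dim) {
    config_error("latent width (%d) must be smaller than the pair width (%d)",
                 latent_dim, input_dim)
  }
  params$W_enc <- he_init(input_dim, latent_dim)
  params$b_enc <- numeric(latent_dim)
  params$W_dec <- he_init(latent_dim, input_dim)
  params$b_dec <- numeric(input_dim)
  params$W_h <- he_init(latent_dim, hidden_dim)
  params$b_h <- numeric(hidden_dim)
  params$w_out <- he_init(hidden_dim, 1)
  params$b_out <- 0
  list(params = params, d_drug = d_drug, d_protein = d_protein,
       ae_activation = ae_activation)
}

encode_with_params <- function(views, a_norm, params, entity) {
  p <- list()
  for (v in views) {
    if (v$propagate) {
      p[[v$name]] <- list(
        theta1 = params[[paste0(entity, ".", v$name, ".theta1")]],
        theta2 = params[[paste0(entity, ".", v$name, ".theta2")]]
      )
    }
  }
  encode_entity(views, a_norm, p)
}

# forward pass over a set of pairs; returns intermediates for the backward
# pass when keep = TRUE
model_forward <- function(model, state, di, pi, keep = FALSE) {
  params <- model$params
  E_d <- encode_with_params(state$drug_views, state$A_drug, params, "drug")
  E_p <- encode_with_params(state$protein_views, state$A_protein, params,
                            "protein")
  H_I <- cbind(E_d[di, , drop = FALSE], E_p[pi, , drop = FALSE])
  S_lat <- sweep(H_I %*% params$W_enc, 2, params$b_enc, "+")
  Lat <- apply_activation(S_lat, model$ae_activation)
  H_D <- sweep(Lat %*% params$W_dec, 2, params$b_dec, "+")
  S_h <- sweep(Lat %*% params$W_h, 2, params$b_h, "+")
  M <- relu(S_h)
  y_hat <- as.numeric(M %*% params$w_out + params$b_out)
  out <- list(y_hat = y_hat, H_I = H_I, H_D = H_D)
  if (keep) {
    out <- c(out, list(E_d = E_d, E_p = E_p, S_lat = S_lat, Lat = Lat,
                       S_h = S_h, M = M))
  }
  out
}

# hand-derived gradients of joint_loss w.r.t. every parameter
model_gradients <- function(model, state, di, pi, y, lambda, fw) {
  params <- model$params
  q <- length(y)
  D <- ncol(fw$H_I)
  g <- list()

  g_yhat <- 2 * (fw$y_hat - y) / q
  g$w_out <- crossprod(fw$M, g_yhat)
  g$b_out <- sum(g_yhat)
  g_M <- tcrossprod(g_yhat, params$w_out[, 1])
  g_Sh <- g_M * (fw$S_h > 0)
  g$W_h <- crossprod(fw$Lat, g_Sh)
  g$b_h <- colSums(g_Sh)

  g_HD <- 2 * lambda * (fw$H_D - fw$H_I) / (q * D)
  g$W_dec <- crossprod(fw$Lat, g_HD)
  g$b_dec <- colSums(g_HD)

  g_Lat <- g_Sh %*% t(params$W_h) + g_HD %*% t(params$W_dec)
  g_Slat <- if (model$ae_activation == "relu") g_Lat * (fw$S_lat > 0) else g_Lat
  g$W_enc <- crossprod(fw$H_I, g_Slat)
  g$b_enc <- colSums(g_Slat)

  g_HI <- g_Slat %*% t(params$W_enc) - g_HD
  dd <- ncol(fw$E_d)
  accum <- function(gpart, idx, n) {
    out <- matrix(0, n, ncol(gpart))
    agg <- rowsum(gpart, group = idx)
    out[as.integer(rownames(agg)), ] <- agg
    out
  }
  g_Ed <- accum(g_HI[, seq_len(dd), drop = FALSE], di, nrow(fw$E_d))
  g_Ep <- accum(g_HI[, dd + seq_len(ncol(fw$E_p)), drop = FALSE], pi,
                nrow(fw$E_p))

  # propagate through the GCN stacks of each entity type
  for (entity in c("drug", "protein")) {
    views <- if (entity == "drug") state$drug_views else state$protein_views
    a <- (if (entity == "drug") state$A_drug else state$A_protein)$values
    g_E <- if (entity == "drug") g_Ed else g_Ep
    col <- 0
    for (v in views) {
      if (v$propagate) {
        k1 <- paste0(entity, ".", v$name, ".theta1")
        k2 <- paste0(entity, ".", v$name, ".theta2")
        th1 <- params[[k1]]; th2 <- params[[k2]]
        wv <- ncol(th2)
        g_out <- g_E[, col + seq_len(wv), drop = FALSE]
        AX <- a %*% v$matrix
        S1 <- AX %*% th1
        Z1 <- relu(S1)
        AZ1 <- a %*% Z1
        g[[k2]] <- crossprod(AZ1, g_out)
        g_Z1 <- (t(a) %*% g_out) %*% t(th2)
        g_S1 <- g_Z1 * (S1 > 0)
        g[[k1]] <- crossprod(AX, g_S1)
        col <- col + wv
      } else {
        col <- col + ncol(v$matrix)
      }
    }
  }
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  for (k in names(grads)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * grads[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- st$m[[k]] / (1 - beta1^st$t)
    vhat <- st$v[[k]] / (1 - beta2^st$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

#' Fit an autoencoder to a feature matrix
#'
#' Trains the pair autoencoder in isolation (full-batch Adam on the mean
#' squared reconstruction error). Mainly useful for studying the capacity of
#' the code layer.
#'
#' @param H numeric matrix (samples x width).
#' @param latent_dim code width (< width of `H`).
#' @param epochs,learning_rate optimisation settings.
#' @param activation encoder activation.
#' @param seed initialisation seed.
#' @return list with `params`, `history` (per-epoch reconstruction MSE) and
#'   `mse` (final reconstruction MSE).
#' @export
fit_autoencoder <- function(H, latent_dim, epochs = 300, learning_rate = 1e-2,
                            activation = "relu", seed = 1) {
  H <- as.matrix(H)
  params <- autoencoder_params(ncol(H), latent_dim, activation, seed)
  act <- params$activation
  p <- params[c("W_enc", "b_enc", "W_dec", "b_dec")]
  st <- adam_init(p)
  q <- nrow(H); D <- ncol(H)
  history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    S <- sweep(H %*% p$W_enc, 2, p$b_enc, "+")
    L <- apply_activation(S, act)
    R <- sweep(L %*% p$W_dec, 2, p$b_dec, "+")
    history[e] <- mean((H - R)^2)
    g_R <- 2 * (R - H) / (q * D)
    g <- list(W_dec = crossprod(L, g_R), b_dec = colSums(g_R))
    g_L <- g_R %*% t(p$W_dec)
    g_S <- if (act == "relu") g_L * (S > 0) else g_L
    g$W_enc <- crossprod(H, g_S)
    g$b_enc <- colSums(g_S)
    upd <- adam_step(p, g, st, learning_rate)
    p <- upd$params; st <- upd$state
  }
  S <- sweep(H %*% p$W_enc, 2, p$b_enc, "+")
  L <- apply_activation(S, act)
  R <- sweep(L %*% p$W_dec, 2, p$b_dec, "+")
  list(params = c(p, list(activation = act)), history = history,
       mse = mean((H - R)^2))
}
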