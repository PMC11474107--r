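# Independent oracles used to lock the package implementations.

# Smith-Waterman local alignment with affine gaps (Gotoh), quadratic space.
# Gap of length L costs open + L * extend, matching the package convention.
sw_oracle <- function(a, b, sub, open = 10, extend = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (horizontal)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - (open + extend), E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - (open + extend), F[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[a[i - 1], b[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

sw_normalized_oracle <- function(a, b, sub, open = 10, extend = 1) {
  sw_oracle(a, b, sub, open, extend) /
    sqrt(sw_oracle(a, a, sub, open, extend) * sw_oracle(b, b, sub, open, extend))
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# concordance index by explicit pair enumeration
ci_oracle <- function(y, yhat) {
  num <- 0; den <- 0
  n <- length(y)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (y[i] > y[j]) {
        den <- den + 1
        if (yhat[i] > yhat[j]) num <- num + 1
        else if (yhat[i] == yhat[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# rm2 via explicit least-squares sums (no cor())
rm2_oracle <- function(y, yhat) {
  n <- length(y)
  sxy <- sum((y - mean(y)) * (yhat - mean(yhat)))
  r2 <- sxy^2 / (sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2))
  k <- sum(y * yhat) / sum(yhat^2)
  r02 <- 1 - sum((y - k * yhat)^2) / sum((y - mean(y))^2)
  r2 * (1 - sqrt(abs(r2 - r02)))
}

# spearman via explicit average ranks + pearson formula
spearman_oracle <- function(y, yhat) {
  r1 <- rank(y); r2 <- rank(yhat)
  sum((r1 - mean(r1)) * (r2 - mean(r2))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
}

# small random substructure sets
random_sets <- function(n, seed, universe = 1:40, min_size = 2, max_size = 10) {
  set.seed(seed)
  sets <- lapply(seq_len(n), function(i) {
    as_substructure_set(sample(universe, sample(min_size:max_size, 1)),
                        id = sprintf("m%02d", i))
  })
  names(sets) <- sprintf("m%02d", seq_len(n))
  sets
}

# central finite differences of f at x
numerical_gradient <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# a small fast synthetic dataset for structural tests
tiny_dataset <- function(seed = 1, m = 10, n = 5) {
  generate_dataset(synthetic_spec(
    m_drugs = m, n_proteins = n, latent_dim = 2, noise_sd = 0.1,
    missing_fraction = 0.1, seed = seed,
    drug_embedding_dim = 16, protein_embedding_dim = 16, go_vocab = 8
  ))
}

tiny_fit <- function(d, epochs = 20, seed = 1, ...) {
  sisdta(d, epochs = epochs, seed = seed, gcn_dims = c(8, 4), latent_dim = 8,
         hidden_dim = 8, fp_length = 64, ...)
}
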