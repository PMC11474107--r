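# Seeded generators for every input the pipeline consumes, so the full
# system can be exercised without downloading any dataset.
#
# Affinities follow a bilinear latent model y_ij = u_i . v_j + noise: similar
# entities (nearby latent factors) then share affinity profiles, which is
# exactly the guilt-by-association structure the graph model assumes.
# Synthetic drug "substructure sets" are abstract integer sets with planted
# strict-containment pairs (to exercise the SIS asymmetry); chemically real
# molecules live in the frozen fixture returned by make_fixture().

#' Specification of a synthetic affinity dataset
#'
#' @param m_drugs,n_proteins entity counts (>= 2 each).
#' @param latent_dim width of the latent factors behind the affinities.
#' @param noise_sd standard deviation of the affinity noise.
#' @param missing_fraction fraction of affinity cells masked as unmeasured.
#' @param seed integer seed; everything is reproducible from it.
#' @param drug_embedding_dim,protein_embedding_dim widths of the generated
#'   embedding views (defaults 300 and 1024, the usual Mol2Vec / ProtTrans
#'   widths).
#' @param go_vocab number of distinct GO terms.
#' @param test_fraction fraction of labeled pairs held out as the test set.
#' @param n_folds number of training folds.
#' @return a validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m_drugs = 20, n_proteins = 10, latent_dim = 3,
                           noise_sd = 0.1, missing_fraction = 0.1, seed = 1,
                           drug_embedding_dim = 300,
                           protein_embedding_dim = 1024, go_vocab = 30,
                           test_fraction = 1 / 6, n_folds = 5) {
  if (m_drugs < 2 || n_proteins < 2) {
    config_error("need at least 2 drugs and 2 proteins")
  }
  if (noise_sd < 0) config_error("noise_sd must be >= 0")
  if (missing_fraction < 0 || missing_fraction >= 1) {
    config_error("missing_fraction must lie in [0, 1)")
  }
  if (latent_dim < 1 || go_vocab < 1) config_error("latent_dim and go_vocab must be >= 1")
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a complete synthetic affinity dataset
#'
#' Draws latent factors `u_i`, `v_j`, sets `y_ij = u_i . v_j + eps` with
#' Gaussian noise, masks a fraction of cells, and produces every raw input
#' of the pipeline: abstract substructure sets with planted containment
#' pairs, random protein sequences, GO term sets, and drug/protein embedding
#' views that are noisy linear images of the latent factors (so the model
#' can learn). Fold assignments follow the usual held-out-test convention
#' (1/6 test, remaining pairs split into training folds).
#'
#' @param spec a [synthetic_spec()].
#' @return a [dta_dataset()]; the latent factors are attached as
#'   `attr(, "truth")`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  m <- spec$m_drugs; n <- spec$n_proteins; L <- spec$latent_dim
  drug_ids <- sprintf("D%02d", seq_len(m))
  protein_ids <- sprintf("P%02d", seq_len(n))

  # abstract substructure sets; every even-indexed drug is a strict subset
  # of its predecessor, planting SIS weights of exactly 1 in one direction
  universe <- 1:400
  sets <- vector("list", m)
  for (i in seq_len(m)) {
    if (i %% 2 == 0) {
      parent <- sets[[i - 1]]
      size <- max(1, length(parent) %/% 2)
      sets[[i]] <- sort(sample(parent, size))
    } else {
      sets[[i]] <- sort(sample(universe, sample(8:16, 1)))
    }
  }
  names(sets) <- drug_ids

  U <- matrix(rnorm(m * L), m, L)
  V <- matrix(rnorm(n * L), n, L)
  Y <- U %*% t(V) + matrix(rnorm(m * n, sd = spec$noise_sd), m, n)
  dimnames(Y) <- list(drug_ids, protein_ids)
  if (spec$missing_fraction > 0) {
    n_miss <- floor(m * n * spec$missing_fraction)
    Y[sample(m * n, n_miss)] <- NA
  }

  view_noise <- 0.1  # measurement noise of the embedding views
  drug_embedding <- U %*% matrix(rnorm(L * spec$drug_embedding_dim), L) +
    matrix(rnorm(m * spec$drug_embedding_dim, sd = view_noise), m)
  rownames(drug_embedding) <- drug_ids
  protein_embedding <- V %*% matrix(rnorm(L * spec$protein_embedding_dim), L) +
    matrix(rnorm(n * spec$protein_embedding_dim, sd = view_noise), n)
  rownames(protein_embedding) <- protein_ids

  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sequences <- vapply(protein_ids, function(id) {
    paste(sample(aa, sample(40:80, 1), replace = TRUE), collapse = "")
  }, character(1))
  go <- go_sample(protein_ids, spec$go_vocab)

  n_labeled <- sum(!is.na(Y))
  if (n_labeled < 4) input_error("too few labeled pairs; lower missing_fraction")
  perm <- sample(n_labeled)
  n_test <- max(1, round(n_labeled * spec$test_fraction))
  test <- sort(perm[seq_len(n_test)])
  rest <- perm[-seq_len(n_test)]
  fold_of <- rep(seq_len(spec$n_folds), length.out = length(rest))
  train <- lapply(seq_len(spec$n_folds), function(f) sort(rest[fold_of == f]))

  d <- dta_dataset(
    affinity = Y, folds = list(train = train, test = test),
    substructures = sets, sequences = sequences, go = go,
    drug_embedding = drug_embedding, protein_embedding = protein_embedding
  )
  attr(d, "truth") <- list(U = U, V = V, spec = spec)
  d
}

go_sample <- function(ids, vocab_size) {
  vocab <- sprintf("GO:%07d", seq_len(vocab_size))
  out <- lapply(ids, function(id) {
    sort(sample(vocab, sample(seq_len(min(8, vocab_size)), 1)))
  })
  names(out) <- ids
  out
}

#' Random GO annotations for a set of proteins
#'
#' Every protein receives at least one term from a vocabulary of
#' `vocab_size` terms; reproducible from `seed`.
#'
#' @param n_proteins number of proteins (ids `prot01`, `prot02`, ...), or a
#'   character vector of ids.
#' @param vocab_size number of distinct terms (>= 1).
#' @param seed integer seed.
#' @return named list mapping protein id to a character vector of terms.
#' @export
generate_go_annotations <- function(n_proteins, vocab_size = 30, seed = 1) {
  if (vocab_size < 1) config_error("vocab_size must be >= 1")
  ids <- if (is.character(n_proteins)) n_proteins
         else sprintf("prot%02d", seq_len(n_proteins))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  go_sample(ids, vocab_size)
}

#' Frozen molecule / protein fixture
#'
#' A fixed set of small drug-like molecules — including benzene
#' (`c1ccccc1`, 3 circular substructures) and phenol (`Oc1ccccc1`, 11) —
#' plus two short protein sequences with GO term sets. The fixture is a
#' constant: two calls return identical content.
#'
#' @return list with `smiles` (named character), `sequences` (named
#'   character) and `go` (named list).
#' @export
make_fixture <- function() {
  list(
    smiles = c(
      benzene      = "c1ccccc1",
      phenol       = "Oc1ccccc1",
      toluene      = "Cc1ccccc1",
      aniline      = "Nc1ccccc1",
      catechol     = "Oc1ccccc1O",
      benzoic_acid = "OC(=O)c1ccccc1",
      paracetamol  = "CC(=O)Nc1ccc(O)cc1",
      aspirin      = "CC(=O)Oc1ccccc1C(=O)O",
      ibuprofen    = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
      caffeine     = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
      pyridine     = "c1ccncc1",
      nicotinamide = "NC(=O)c1cccnc1",
      naphthalene  = "c1ccc2ccccc2c1",
      ethanol      = "CCO"
    ),
    sequences = c(
      kin1 = "MGSNKSKPKDASQRRRSLEPAENVHGAGGGAFPASQTPSKPASADGHRGPSAAFAPAAAE",
      kin2 = "MELKNGEVVQCLAAALEYLHSQDIIHRDLKPENILVDQNLNIKLTDFGFAKRVKGRTWTL"
    ),
    go = list(
      kin1 = c("GO:0004672", "GO:0005524", "GO:0006468"),
      kin2 = c("GO:0004672", "GO:0005524", "GO:0016301", "GO:0005737")
    )
  )
}
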