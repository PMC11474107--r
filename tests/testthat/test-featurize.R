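# Substructure enumeration, fingerprint folding, GO matrices and embedding
# views.

test_that("circular substructure counts match the known small-molecule values", {
  expect_length(enumerate_substructures("c1ccccc1")$identifiers, 3)   # benzene
  expect_length(enumerate_substructures("Oc1ccccc1")$identifiers, 11) # phenol
  expect_length(enumerate_substructures("C")$identifiers, 1)          # methane
})

test_that("enumeration is invariant to SMILES rewriting of the same molecule", {
  variants <- list(
    benzene = c("c1ccccc1", "C1=CC=CC=C1"),
    phenol = c("Oc1ccccc1", "c1ccccc1O", "OC1=CC=CC=C1", "C1=CC=C(C=C1)O"),
    ethanol = c("CCO", "OCC", "C(O)C")
  )
  for (v in variants) {
    sets <- lapply(v, function(s) enumerate_substructures(s)$identifiers)
    for (i in seq_along(sets)[-1]) expect_identical(sets[[i]], sets[[1]])
  }
})

test_that("radius is a knob: larger radius yields a superset of identifiers", {
  s1 <- enumerate_substructures("CC(=O)Oc1ccccc1C(=O)O", max_radius = 1)
  s2 <- enumerate_substructures("CC(=O)Oc1ccccc1C(=O)O", max_radius = 2)
  s3 <- enumerate_substructures("CC(=O)Oc1ccccc1C(=O)O", max_radius = 3)
  expect_true(all(s1$identifiers %in% s2$identifiers))
  expect_true(all(s2$identifiers %in% s3$identifiers))
  expect_gt(length(s2$identifiers), length(s1$identifiers))
})

test_that("unparseable or empty SMILES raise input errors naming the molecule", {
  expect_error(enumerate_substructures("xyz123", id = "drugA"),
               "drugA", class = "sisdta_input_error")
  expect_error(enumerate_substructures("", id = "drugB"),
               "drugB", class = "sisdta_input_error")
  expect_error(enumerate_substructures("c1ccccc1", max_radius = -1),
               class = "sisdta_config_error")
})

test_that("intersection sizes obey set algebra on real molecules", {
  fx <- make_fixture()
  sets <- substructure_sets(fx$smiles)
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      inter <- length(intersect(sets[[i]]$identifiers, sets[[j]]$identifiers))
      expect_lte(inter, min(length(sets[[i]]$identifiers),
                            length(sets[[j]]$identifiers)))
    }
  }
})

test_that("folding maps identifiers to bits without increasing popcount", {
  benzene <- enumerate_substructures("c1ccccc1")
  fp <- fold_fingerprint(benzene, 1024)
  expect_length(fp, 1024)
  expect_equal(sum(fp), 3)  # 3 identifiers, no collision at this density
  expect_identical(which(fp == 1) - 1, benzene$identifiers %% 1024)

  empty <- as_substructure_set(numeric(0), id = "void")
  expect_equal(sum(fold_fingerprint(empty, 64)), 0)

  aspirin <- enumerate_substructures("CC(=O)Oc1ccccc1C(=O)O")
  for (len in c(1, 8, 64, 4096)) {
    expect_lte(sum(fold_fingerprint(aspirin, len)), length(aspirin$identifiers))
  }
  expect_equal(sum(fold_fingerprint(aspirin, 2^20)), length(aspirin$identifiers))
  expect_error(fold_fingerprint(aspirin, 0), class = "sisdta_config_error")
})

test_that("GO matrix construction and reconstruction are exact inverses", {
  go <- list(p1 = c("A", "B"), p2 = "B")
  v <- build_go_matrix(go)
  expect_identical(colnames(v$matrix), c("A", "B"))
  expect_equal(unname(v$matrix), rbind(c(1, 1), c(0, 1)))
  expect_true(v$propagate)

  shared <- list(p1 = c("X", "Y"), p2 = c("Y", "X"), p3 = c("X", "Y"))
  vs <- build_go_matrix(shared)
  expect_equal(unname(vs$matrix[1, ]), unname(vs$matrix[2, ]))
  expect_equal(unname(vs$matrix[1, ]), unname(vs$matrix[3, ]))

  expect_warning(v0 <- build_go_matrix(list(p1 = character(0), p2 = "A")),
                 "no GO terms")
  expect_equal(sum(v0$matrix[1, ]), 0)

  anns <- generate_go_annotations(12, vocab_size = 9, seed = 5)
  round_trip <- go_terms_from_matrix(build_go_matrix(anns))
  expect_identical(lapply(round_trip, sort), lapply(anns, sort))
  expect_equal(rowSums(build_go_matrix(anns)$matrix),
               vapply(anns, length, numeric(1)))
})

test_that("embedding tables load in entity order and validate shape", {
  tmp <- tempfile(fileext = ".tsv")
  m <- matrix(round(rnorm(12), 6), 4, 3)
  df <- data.frame(id = c("d3", "d1", "d4", "d2"), m)
  write.table(df, tmp, sep = "\t", row.names = FALSE, quote = FALSE)

  v <- load_embedding_view(tmp, c("d1", "d2", "d3", "d4"), expected_dims = 3)
  expect_equal(unname(v$matrix[1, ]), unname(m[2, ]))  # d1 was row 2
  expect_equal(unname(v$matrix[3, ]), unname(m[1, ]))
  expect_false(v$propagate)

  expect_error(load_embedding_view(tmp, c("d1", "d9")), "d9",
               class = "sisdta_input_error")
  expect_error(load_embedding_view(tmp, c("d1", "d2"), expected_dims = 300),
               "expected 300", class = "sisdta_input_error")
  unlink(tmp)
})

test_that("random projection views are deterministic in the seed", {
  sets <- random_sets(6, seed = 11)
  a <- random_projection_view(sets, dims = 10, seed = 42)
  b <- random_projection_view(sets, dims = 10, seed = 42)
  c <- random_projection_view(sets, dims = 10, seed = 43)
  expect_identical(a$matrix, b$matrix)
  expect_false(isTRUE(all.equal(a$matrix, c$matrix)))
  expect_equal(dim(a$matrix), c(6, 10))

  seqs <- c(s1 = "MKT", s2 = "GAVLL")
  p <- random_projection_view(seqs, dims = 300, seed = 1)
  expect_equal(dim(p$matrix), c(2, 300))
  expect_identical(p$matrix, random_projection_view(seqs, 300, 1)$matrix)
})

test_that("feature views validate row counts and finiteness", {
  expect_error(feature_view("v", c("a", "b"), matrix(0, 3, 2)),
               class = "sisdta_input_error")
  expect_error(feature_view("v", "a", matrix(NA_real_, 1, 1)),
               class = "sisdta_input_error")
})
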