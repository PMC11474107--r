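# Readers and writers for the standard dataset layout: JSON id maps, FASTA
# sequences, delimited embedding tables, CSV affinity matrices with NA
# markers, and JSON fold indices. All text readers tolerate CRLF line
# endings and a UTF-8 byte-order mark.

read_lines_clean <- function(path) {
  if (!file.exists(path)) input_error("file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) > 0) lines[1] <- sub("^\\uFEFF", "", lines[1])
  sub("\r$", "", lines)
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.delim(text = paste(read_lines_clean(path), collapse = "\n"),
                    sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

read_json_clean <- function(path) {
  jsonlite::fromJSON(paste(read_lines_clean(path), collapse = "\n"),
                     simplifyVector = TRUE)
}

#' Read a drug SMILES map
#'
#' Accepts a JSON object `{id: smiles}` or a headerless two-column TSV.
#'
#' @param path file path.
#' @return named character vector.
#' @export
read_smiles_map <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- read_json_clean(path)
    return(vapply(x, as.character, character(1)))
  }
  lines <- read_lines_clean(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    input_error("SMILES TSV '%s' must have two tab-separated columns", path)
  }
  stats::setNames(vapply(parts, `[`, character(1), 2),
                  vapply(parts, `[`, character(1), 1))
}

#' Read protein sequences
#'
#' Accepts FASTA (via Biostrings) or a JSON object `{id: sequence}`.
#'
#' @param path file path.
#' @return named character vector.
#' @export
read_sequences <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- read_json_clean(path)
    return(vapply(x, as.character, character(1)))
  }
  aas <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aas), sub("\\s.*$", "", names(aas)))
}

#' Read GO annotations
#'
#' JSON object mapping protein id to an array of term strings.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_go_annotations <- function(path) {
  x <- read_json_clean(path)
  lapply(x, as.character)
}

#' Read / write an affinity matrix
#'
#' Square-ish CSV with an `id` first column (drug ids) and protein ids as the
#' header; empty cells or `NA` mark unmeasured affinities.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_affinity <- function(path) {
  df <- read_table_auto(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_affinity
#' @param m numeric matrix with drug rownames and protein colnames.
#' @export
write_affinity <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a dataset directory
#'
#' Writes every component of a [dta_dataset()] in the plain-text formats the
#' readers consume: `affinity.csv`, `folds.json`, `smiles.json` /
#' `substructures.json`, `sequences.json`, `go.json`,
#' `drug_embeddings.tsv`, `protein_embeddings.tsv`,
#' `protein_similarity.csv`.
#'
#' @param d a `dta_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(d, dir) {
  stopifnot(inherits(d, "dta_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_affinity(d$affinity, file.path(dir, "affinity.csv"))
  if (!is.null(d$folds)) {
    jsonlite::write_json(d$folds, file.path(dir, "folds.json"), digits = NA)
  }
  if (!is.null(d$smiles)) {
    jsonlite::write_json(as.list(d$smiles), file.path(dir, "smiles.json"),
                         auto_unbox = TRUE)
  }
  if (!is.null(d$substructures)) {
    sets <- lapply(d$substructures, function(s) {
      if (inherits(s, "substructure_set")) s$identifiers else as.numeric(s)
    })
    jsonlite::write_json(sets, file.path(dir, "substructures.json"), digits = NA)
  }
  if (!is.null(d$sequences)) {
    jsonlite::write_json(as.list(d$sequences), file.path(dir, "sequences.json"),
                         auto_unbox = TRUE)
  }
  if (!is.null(d$go)) {
    jsonlite::write_json(d$go, file.path(dir, "go.json"))
  }
  write_embedding <- function(m, file) {
    df <- data.frame(id = rownames(m),
                     formatC(m, format = "g", digits = 17),
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("id", sprintf("e%d", seq_len(ncol(m))))
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(d$drug_embedding)) {
    write_embedding(d$drug_embedding, "drug_embeddings.tsv")
  }
  if (!is.null(d$protein_embedding)) {
    write_embedding(d$protein_embedding, "protein_embeddings.tsv")
  }
  if (!is.null(d$protein_similarity)) {
    write_similarity(similarity_matrix(d$protein_similarity, "precomputed"),
                     file.path(dir, "protein_similarity.csv"))
  }
  invisible(dir)
}

#' Read a dataset directory
#'
#' Counterpart of [write_dataset()]: assembles a [dta_dataset()] from the
#' files present in `dir`. The number of missing affinity cells is reported
#' as a message.
#'
#' @param dir dataset directory.
#' @return a `dta_dataset`.
#' @export
read_dataset <- function(dir) {
  path <- function(f) file.path(dir, f)
  have <- function(f) file.exists(path(f))
  if (!have("affinity.csv")) input_error("no affinity.csv in '%s'", dir)
  affinity <- read_affinity(path("affinity.csv"))

  smiles <- if (have("smiles.json")) read_smiles_map(path("smiles.json"))
  substructures <- if (have("substructures.json")) {
    lapply(read_json_clean(path("substructures.json")), as.numeric)
  }
  sequences <- if (have("sequences.json")) read_sequences(path("sequences.json"))
    else if (have("sequences.fasta")) read_sequences(path("sequences.fasta"))
  go <- if (have("go.json")) read_go_annotations(path("go.json"))
  folds <- if (have("folds.json")) {
    x <- read_json_clean(path("folds.json"))
    list(train = lapply(x$train, as.integer), test = as.integer(x$test))
  }
  emb <- function(f, ids) {
    if (!have(f)) return(NULL)
    v <- load_embedding_view(path(f), ids)
    v$matrix
  }
  drug_embedding <- emb("drug_embeddings.tsv", rownames(affinity))
  protein_embedding <- emb("protein_embeddings.tsv", colnames(affinity))
  protein_similarity <- if (have("protein_similarity.csv")) {
    read_similarity(path("protein_similarity.csv"))$values
  }

  if (!is.null(smiles) && length(smiles) != nrow(affinity)) {
    input_error("SMILES map has %d drugs but the affinity matrix has %d rows",
                length(smiles), nrow(affinity))
  }
  d <- dta_dataset(affinity, folds = folds, smiles = smiles,
                   substructures = substructures, sequences = sequences,
                   go = go, drug_embedding = drug_embedding,
                   protein_embedding = protein_embedding,
                   protein_similarity = protein_similarity)
  message(sprintf("read_dataset: %d labeled pairs, %d missing cells",
                  sum(!is.na(affinity)), sum(is.na(affinity))))
  d
}

#' Write a run manifest
#'
#' Records the configuration, seed, package version and md5 checksums of the
#' input files next to a command's outputs, so artifact directories are
#' reproducible bit-for-bit given config + seed.
#'
#' @param path output JSON path.
#' @param command command name.
#' @param config named list of settings (serialized verbatim).
#' @param seed integer seed.
#' @param inputs character vector of input file paths to checksum.
#' @export
write_manifest <- function(path, command, config = list(), seed = NA,
                           inputs = character(0)) {
  sums <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  jsonlite::write_json(
    list(command = command, config = config, seed = seed,
         input_checksums = sums,
         package = list(name = "sisdta",
                        version = as.character(utils::packageVersion("sisdta")))),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
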