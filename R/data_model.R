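#' @importFrom stats setNames runif rbinom
#' @importFrom utils read.delim write.table head
NULL

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

KNOWN_SOURCES <- c("chemical", "protein", "side_effect")

#' Binary drug-by-feature incidence matrix
#'
#' Constructs and validates the core container of the package: a binary
#' matrix whose rows are drugs and whose columns are the features of one
#' data source (chemical substructures, protein targets, side-effects, or
#' a custom source). Row presence is meaningful: a drug absent from a
#' source is simply not a row, which is distinct from an all-zero row.
#'
#' @param values numeric or integer matrix with values in \{0, 1\}.
#' @param source_name label for the data source; one of
#'   \code{"chemical"}, \code{"protein"}, \code{"side_effect"} or any
#'   custom label.
#' @param drug_ids,feature_ids optional character vectors overriding
#'   \code{dimnames(values)}.
#' @return an integer matrix of class \code{"feature_matrix"} with a
#'   \code{source_name} attribute.
#' @examples
#' m <- feature_matrix(rbind(d1 = c(f1 = 1, f2 = 0), d2 = c(1, 1)),
#'                     source_name = "chemical")
#' sparsity(m)
#' @export
feature_matrix <- function(values, source_name = "custom",
                           drug_ids = NULL, feature_ids = NULL) {
  values <- as.matrix(values)
  if (!is.null(drug_ids)) rownames(values) <- drug_ids
  if (!is.null(feature_ids)) colnames(values) <- feature_ids
  check_binary_matrix(values, what = sprintf("feature matrix '%s'", source_name))
  storage.mode(values) <- "integer"
  structure(values, source_name = source_name,
            class = c("feature_matrix", class(values)))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d drugs x %d features, sparsity %.4f\n",
              attr(x, "source_name"), nrow(x), ncol(x), sparsity(x)))
  invisible(x)
}

#' Binary drug-by-disease ground-truth matrix
#'
#' The "golden" matrix of known drug-disease treatment associations used
#' both for disease scoring (the neighbours' votes) and as ground truth in
#' leave-one-out evaluation.
#'
#' @param values binary matrix, rows = drugs, columns = diseases.
#' @param drug_ids,disease_ids optional dimname overrides.
#' @return an integer matrix of class \code{"golden_associations"}.
#' @export
golden_associations <- function(values, drug_ids = NULL, disease_ids = NULL) {
  values <- as.matrix(values)
  if (!is.null(drug_ids)) rownames(values) <- drug_ids
  if (!is.null(disease_ids)) colnames(values) <- disease_ids
  check_binary_matrix(values, what = "golden associations")
  storage.mode(values) <- "integer"
  structure(values, class = c("golden_associations", class(values)))
}

#' @export
print.golden_associations <- function(x, ...) {
  cat(sprintf("golden_associations: %d drugs x %d diseases, %d positives (sparsity %.4f)\n",
              nrow(x), ncol(x), sum(x), sparsity(x)))
  invisible(x)
}

check_binary_matrix <- function(values, what = "matrix") {
  if (length(values) == 0L)
    stop(what, " is empty", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop(what, " must have row and column names", call. = FALSE)
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    stop(sprintf("%s has non-binary cell at row '%s', column '%s' (value '%s')",
                 what, rownames(values)[i[1L]], colnames(values)[i[2L]],
                 format(values[bad[1L]])), call. = FALSE)
  }
  if (anyDuplicated(rownames(values)))
    stop(what, ": duplicate drug id '",
         rownames(values)[duplicated(rownames(values))][1L], "'", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop(what, ": duplicate feature/disease id '",
         colnames(values)[duplicated(colnames(values))][1L], "'", call. = FALSE)
  invisible(values)
}

#' Read a binary incidence matrix from delimited text
#'
#' Expects a header row of feature (or disease) names and a first column
#' of drug names; all cells must be 0 or 1. Row and column order are
#' preserved.
#'
#' @param path path to a delimited text file.
#' @param source_name source label stored on the result.
#' @param delim field delimiter, tab by default.
#' @return a \code{\link{feature_matrix}}.
#' @export
load_feature_matrix <- function(path, source_name = "custom", delim = "\t") {
  feature_matrix(read_incidence(path), source_name = source_name)
}

#' @rdname load_feature_matrix
#' @export
load_golden_associations <- function(path, delim = "\t") {
  golden_associations(read_incidence(path, delim))
}

read_incidence <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = delim, header = TRUE, row.names = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Write a binary incidence matrix as delimited text
#'
#' Inverse of \code{\link{load_feature_matrix}}; a load of the written
#' file reproduces the matrix exactly.
#'
#' @param m a \code{feature_matrix} or \code{golden_associations}.
#' @param path output path.
#' @param delim field delimiter.
#' @export
write_incidence_matrix <- function(m, path, delim = "\t") {
  df <- data.frame(drug = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug-name synonym table
#'
#' Two-column delimited text (alias, canonical). The returned map is made
#' idempotent: chains alias -> b -> canonical are collapsed so one
#' application suffices.
#'
#' @param path path to the two-column file (no header required; a header
#'   line "alias<TAB>canonical" is tolerated).
#' @return named character vector: names are aliases, values canonical.
#' @export
load_synonym_map <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("synonym file must have two columns", call. = FALSE)
  if (identical(tolower(df[1L, 1L]), "alias")) df <- df[-1L, , drop = FALSE]
  synonym_map(setNames(as.character(df[[2L]]), as.character(df[[1L]])))
}

#' @rdname load_synonym_map
#' @param map named character vector (alias -> canonical).
#' @export
synonym_map <- function(map) {
  if (is.null(names(map))) stop("synonym map must be named", call. = FALSE)
  map <- vapply(map, as.character, character(1L))
  resolve <- function(x) {  # collapse chains so one application suffices
    seen <- character()
    while (x %in% names(map) && !identical(unname(map[[x]]), x)) {
      if (x %in% seen)
        stop("synonym map contains a cycle at '", x, "'", call. = FALSE)
      seen <- c(seen, x)
      x <- unname(map[[x]])
    }
    x
  }
  out <- vapply(names(map), function(a) resolve(unname(map[[a]])), character(1L))
  structure(setNames(out, names(map)), class = "synonym_map")
}

canonical_name <- function(ids, synonyms) {
  if (is.null(synonyms)) return(ids)
  hit <- ids %in% names(synonyms)
  ids[hit] <- unclass(synonyms)[ids[hit]]
  ids
}

#' Assemble a repositioning dataset
#'
#' Bundles one or more feature matrices, the golden drug-disease matrix
#' and (optionally) per-drug protein sequences. Drugs need not appear in
#' every source; \code{\link{harmonize_names}} reconciles naming and
#' drops golden drugs with no feature information at all.
#'
#' @param features named list of \code{\link{feature_matrix}} objects; if
#'   unnamed, each matrix's \code{source_name} attribute is used.
#' @param golden a \code{\link{golden_associations}} matrix.
#' @param sequences optional named list: drug -> character vector of
#'   residue sequences (see \code{\link{load_sequence_features}}).
#' @return a list of class \code{"repo_dataset"}.
#' @export
repo_dataset <- function(features, golden, sequences = NULL) {
  if (inherits(features, "feature_matrix")) features <- list(features)
  if (is.null(names(features)) || any(!nzchar(names(features))))
    names(features) <- vapply(features, attr, "", "source_name")
  stopifnot(all(vapply(features, inherits, TRUE, "feature_matrix")))
  if (!inherits(golden, "golden_associations"))
    golden <- golden_associations(golden)
  structure(list(features = features, golden = golden, sequences = sequences),
            class = "repo_dataset")
}

#' @export
print.repo_dataset <- function(x, ...) {
  cat(sprintf("repo_dataset: %d feature source(s), golden %d drugs x %d diseases\n",
              length(x$features), nrow(x$golden), ncol(x$golden)))
  for (nm in names(x$features)) {
    m <- x$features[[nm]]
    cat(sprintf("  %-12s %4d drugs x %4d features, sparsity %.4f\n",
                nm, nrow(m), ncol(m), sparsity(m)))
  }
  if (!is.null(x$sequences))
    cat(sprintf("  sequences for %d drugs\n", length(x$sequences)))
  invisible(x)
}

#' All drug ids known to any feature source of a dataset
#' @param dataset a \code{repo_dataset}.
#' @export
feature_drugs <- function(dataset) {
  unique(unlist(lapply(dataset$features, rownames), use.names = FALSE))
}

#' Harmonize drug names across data sources
#'
#' Applies the synonym map to every drug id in every feature source, the
#' golden matrix and the sequence map; merges rows that collapse to the
#' same canonical name by elementwise OR; and drops golden drugs that
#' appear in no feature source (no prior information means no basis for
#' prediction). Idempotent: a second application is a no-op.
#'
#' @param dataset a \code{\link{repo_dataset}}.
#' @param synonyms a \code{\link{synonym_map}} or NULL.
#' @param quiet suppress the merge/drop log message.
#' @return the harmonized \code{repo_dataset}, with a
#'   \code{harmonize_log} attribute recording counts of merged and
#'   dropped drugs.
#' @export
harmonize_names <- function(dataset, synonyms = NULL, quiet = FALSE) {
  n_merged <- 0L
  dataset$features <- lapply(dataset$features, function(m) {
    src <- attr(m, "source_name")
    ids <- canonical_name(rownames(m), synonyms)
    if (anyDuplicated(ids)) {
      n_merged <<- n_merged + sum(duplicated(ids))
      m <- rowsum(unclass(m), ids, reorder = FALSE)
      m[m > 1L] <- 1L  # elementwise OR of merged records
    } else {
      rownames(m) <- ids
      m <- unclass(m)
    }
    feature_matrix(m, source_name = src)
  })
  gids <- canonical_name(rownames(dataset$golden), synonyms)
  g <- rowsum(unclass(dataset$golden), gids, reorder = FALSE)
  g[g > 1L] <- 1L
  known <- feature_drugs(dataset)
  keep <- rownames(g) %in% known
  n_dropped <- sum(!keep)
  dataset$golden <- golden_associations(g[keep, , drop = FALSE])
  if (!is.null(dataset$sequences)) {
    alpha <- attr(dataset$sequences, "alphabet")
    sids <- canonical_name(names(dataset$sequences), synonyms)
    merged <- lapply(split(unclass(dataset$sequences), sids),
                     function(x) unique(unlist(x, use.names = FALSE)))
    dataset$sequences <- structure(merged, alphabet = alpha)
  }
  log <- list(merged = n_merged, dropped = n_dropped,
              golden_drugs = nrow(dataset$golden),
              golden_positives = sum(dataset$golden))
  if (!quiet)
    message(sprintf("harmonize_names: merged %d synonym row(s), dropped %d golden drug(s); golden now %d drugs, %d positives",
                    log$merged, log$dropped, log$golden_drugs, log$golden_positives))
  attr(dataset, "harmonize_log") <- log
  dataset
}

#' Fraction of zero cells of a binary incidence matrix
#'
#' @param m a \code{feature_matrix}, \code{golden_associations} or plain
#'   binary matrix.
#' @return \code{1 - sum(m) / length(m)}, in [0, 1].
#' @export
sparsity <- function(m) {
  if (length(m) == 0L) stop("cannot compute sparsity of an empty matrix")
  1 - sum(m) / length(m)
}

#' Read per-drug protein sequences from FASTA
#'
#' Headers are expected as \code{drug|protein}; all sequences sharing the
#' drug part are collected into that drug's sequence set.
#'
#' @param path FASTA file path.
#' @param alphabet allowed residue letters; defaults to the 20 amino
#'   acids.
#' @return named list drug -> character vector of sequences, with an
#'   \code{alphabet} attribute.
#' @export
load_sequence_features <- function(path, alphabet = AA_ALPHABET) {
  seqs <- Biostrings::readAAStringSet(path)
  drug <- sub("\\|.*$", "", names(seqs))
  out <- split(as.character(seqs), drug)
  sequence_features(out, alphabet = alphabet)
}

#' @rdname load_sequence_features
#' @param sequences named list drug -> character vector.
#' @export
sequence_features <- function(sequences, alphabet = AA_ALPHABET) {
  if (is.null(names(sequences))) stop("sequence list must be named by drug")
  for (d in names(sequences)) {
    for (s in sequences[[d]]) {
      if (!nzchar(s)) stop("empty sequence for drug '", d, "'", call. = FALSE)
      check_alphabet(s, alphabet)
    }
  }
  structure(sequences, alphabet = alphabet)
}

check_alphabet <- function(s, alphabet) {
  letters <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!(letters %in% alphabet))
  if (length(bad))
    stop(sprintf("residue '%s' at position %d is outside the declared alphabet",
                 letters[bad[1L]], bad[1L]), call. = FALSE)
  invisible(TRUE)
}
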