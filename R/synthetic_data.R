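#' Specification for the planted-cluster synthetic data generator
#'
#' Describes a generative model with the structure the repositioning
#' method assumes: drugs fall into latent clusters; each cluster owns a
#' signature set of features per source (disjoint across clusters) and a
#' signature set of disease indications; a drug's row is its cluster
#' signature thinned by the within-cluster sharing probability, plus
#' background noise; some drugs are missing from some sources; protein
#' sequences are mutated copies of per-cluster ancestor sequences.
#'
#' Defaults mirror a real three-source drug-feature compendium at 1/5
#' scale: 200 drugs, 150 diseases, feature counts 176/155/277, and
#' signature/noise rates chosen in closed form so the expected
#' sparsities are about 0.8625 (chemical), 0.9960 (protein) and 0.9503
#' (side-effect), with roughly 4 indications per drug.
#'
#' @param n_drugs,n_diseases,n_clusters counts; clusters must not exceed
#'   drugs.
#' @param features named integer vector: features per source.
#' @param signature_features named integer vector: per-cluster signature
#'   size per source; \code{n_clusters * signature_features <= features}
#'   (signatures are disjoint).
#' @param within_prob per-source probability that a drug carries each of
#'   its cluster's signature features.
#' @param background_prob per-source background one-probability (noise).
#' @param indications_per_cluster,indication_within_prob,indication_background_prob
#'   same three roles for the golden disease matrix.
#' @param missingness per-source probability that a drug is entirely
#'   absent from that source; a drug missing everywhere is re-added to
#'   the first source so every golden drug keeps some prior information.
#' @param seq_length_range ancestor sequence length range (residues).
#' @param seqs_per_drug range of sequence counts per drug.
#' @param mutation_rate per-residue substitution probability applied to
#'   the cluster ancestor when emitting a drug's sequence.
#' @param alphabet residue alphabet.
#' @param seed integer seed; the whole dataset is a deterministic
#'   function of the spec.
#' @return list of class \code{"generator_spec"}.
#' @export
generator_spec <- function(n_drugs = 200L, n_diseases = 150L, n_clusters = 10L,
                           features = c(chemical = 176L, protein = 155L,
                                        side_effect = 277L),
                           signature_features = c(chemical = 16L, protein = 1L,
                                                  side_effect = 13L),
                           within_prob = c(chemical = 0.9, protein = 0.62,
                                           side_effect = 0.9),
                           background_prob = c(chemical = 0.0607, protein = 0,
                                               side_effect = 0.0078),
                           indications_per_cluster = 4L,
                           indication_within_prob = 0.9,
                           indication_background_prob = 0.002,
                           missingness = c(chemical = 0.18, protein = 0.18,
                                           side_effect = 0.27),
                           seq_length_range = c(20L, 40L),
                           seqs_per_drug = c(1L, 3L),
                           mutation_rate = 0.05,
                           alphabet = AA_ALPHABET,
                           seed = 1L) {
  # accept YAML-style named lists as well as named vectors
  features <- unlist(features); signature_features <- unlist(signature_features)
  within_prob <- unlist(within_prob); background_prob <- unlist(background_prob)
  missingness <- unlist(missingness)
  seq_length_range <- unlist(seq_length_range)
  seqs_per_drug <- unlist(seqs_per_drug)
  alphabet <- unlist(alphabet)
  spec <- list(n_drugs = as.integer(n_drugs), n_diseases = as.integer(n_diseases),
               n_clusters = as.integer(n_clusters), features = features,
               signature_features = signature_features,
               within_prob = within_prob, background_prob = background_prob,
               indications_per_cluster = as.integer(indications_per_cluster),
               indication_within_prob = indication_within_prob,
               indication_background_prob = indication_background_prob,
               missingness = missingness, seq_length_range = seq_length_range,
               seqs_per_drug = seqs_per_drug, mutation_rate = mutation_rate,
               alphabet = alphabet, seed = as.integer(seed))
  validate_generator_spec(spec)
  structure(spec, class = "generator_spec")
}

validate_generator_spec <- function(spec) {
  with(spec, {
    if (n_clusters > n_drugs)
      stop("infeasible spec: more clusters (", n_clusters, ") than drugs (",
           n_drugs, ")", call. = FALSE)
    if (n_drugs < 1L || n_diseases < 1L || n_clusters < 1L)
      stop("counts must be positive", call. = FALSE)
    stopifnot(identical(sort(names(features)), sort(names(signature_features))))
    probs <- c(within_prob, background_prob, indication_within_prob,
               indication_background_prob, missingness, mutation_rate)
    if (any(probs < 0 | probs > 1))
      stop("all probabilities must lie in [0, 1]", call. = FALSE)
    bad <- names(features)[n_clusters * signature_features[names(features)] >
                             features]
    if (length(bad))
      stop("infeasible spec: disjoint cluster signatures need n_clusters * ",
           "signature_features <= features for source(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (n_clusters * indications_per_cluster > n_diseases)
      stop("infeasible spec: disjoint disease signatures exceed n_diseases",
           call. = FALSE)
  })
  invisible(spec)
}

#' Expected sparsity under the generative model
#'
#' Closed form: a cell of a source with F features, signature size s,
#' within-probability w and background probability b is one with
#' probability \code{(s/F) * (1 - (1-w)(1-b)) + (1 - s/F) * b}; the
#' expected sparsity is one minus that. The golden matrix follows the
#' same form with the indication parameters. Missingness removes whole
#' rows and leaves the sparsity of the retained rows unchanged.
#'
#' @param spec a \code{\link{generator_spec}}.
#' @return named numeric vector: expected zero-fraction per source plus
#'   \code{"golden"}.
#' @export
expected_sparsity <- function(spec) {
  srcs <- names(spec$features)
  dens <- vapply(srcs, function(src) {
    f <- spec$features[[src]]; s <- spec$signature_features[[src]]
    w <- spec$within_prob[[src]]; b <- spec$background_prob[[src]]
    (s / f) * (1 - (1 - w) * (1 - b)) + (1 - s / f) * b
  }, numeric(1L))
  gd <- (spec$indications_per_cluster / spec$n_diseases) *
    (1 - (1 - spec$indication_within_prob) *
       (1 - spec$indication_background_prob)) +
    (1 - spec$indications_per_cluster / spec$n_diseases) *
    spec$indication_background_prob
  c(setNames(1 - dens, srcs), golden = 1 - gd)
}

# sample() treats a length-1 numeric as 1:x; draw by index instead
resample <- function(x, n) x[sample.int(length(x), n)]

random_sequence <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

mutate_sequence <- function(s, rate, alphabet) {
  letters <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- runif(length(letters)) < rate
  if (any(hit))
    letters[hit] <- sample(alphabet, sum(hit), replace = TRUE)
  paste(letters, collapse = "")
}

planted_binary_matrix <- function(n_rows, n_cols, cluster_of, sig_cols,
                                  within, background, row_names, col_names) {
  M <- matrix(rbinom(n_rows * n_cols, 1L, background), n_rows, n_cols,
              dimnames = list(row_names, col_names))
  for (i in seq_len(n_rows)) {
    sig <- sig_cols[[cluster_of[i]]]
    M[i, sig[runif(length(sig)) < within]] <- 1L
  }
  storage.mode(M) <- "integer"
  M
}

#' Generate a planted-cluster synthetic repositioning dataset
#'
#' Fully reproducible from the spec's seed. Cluster feature signatures
#' and disease signatures are disjoint across clusters, so with
#' \code{within_prob = 1}, zero background noise and zero missingness,
#' within-cluster rows are identical and cross-cluster similarity is
#' exactly 0 -- the regime where leave-one-out recovery must be perfect.
#'
#' @param spec a \code{\link{generator_spec}}.
#' @return list of class \code{"synthetic_repositioning_data"}:
#'   \code{$dataset} (a \code{\link{repo_dataset}} with sequences when a
#'   protein source is present), \code{$clusters} (named integer vector,
#'   drug -> cluster), \code{$feature_signatures},
#'   \code{$disease_signatures}.
#' @export
generate_dataset <- function(spec) {
  validate_generator_spec(spec)
  set.seed(spec$seed)
  drugs <- sprintf("drug_%03d", seq_len(spec$n_drugs))
  diseases <- sprintf("disease_%03d", seq_len(spec$n_diseases))
  cl <- sort(rep_len(seq_len(spec$n_clusters), spec$n_drugs))
  names(cl) <- drugs

  srcs <- names(spec$features)
  feat_sigs <- list()
  mats <- list()
  for (src in srcs) {
    f <- spec$features[[src]]; s <- spec$signature_features[[src]]
    cols <- sprintf("%s_%04d", src, seq_len(f))
    pool <- sample.int(f, spec$n_clusters * s)
    feat_sigs[[src]] <- split(pool, rep(seq_len(spec$n_clusters), each = s))
    mats[[src]] <- planted_binary_matrix(
      spec$n_drugs, f, cl, feat_sigs[[src]],
      spec$within_prob[[src]], spec$background_prob[[src]], drugs, cols)
  }

  dis_pool <- sample.int(spec$n_diseases,
                         spec$n_clusters * spec$indications_per_cluster)
  dis_sigs <- split(dis_pool, rep(seq_len(spec$n_clusters),
                                  each = spec$indications_per_cluster))
  golden <- planted_binary_matrix(
    spec$n_drugs, spec$n_diseases, cl, dis_sigs,
    spec$indication_within_prob, spec$indication_background_prob,
    drugs, diseases)

  # per-source missingness; a drug absent everywhere is restored to the
  # first source so it keeps at least one defined feature row
  present <- vapply(srcs, function(src)
    runif(spec$n_drugs) >= spec$missingness[[src]], logical(spec$n_drugs))
  if (is.null(dim(present))) present <- matrix(present, nrow = spec$n_drugs)
  orphan <- rowSums(present) == 0L
  present[orphan, 1L] <- TRUE
  features <- lapply(seq_along(srcs), function(j)
    feature_matrix(mats[[srcs[j]]][present[, j], , drop = FALSE],
                   source_name = srcs[j]))
  names(features) <- srcs

  sequences <- NULL
  if ("protein" %in% srcs) {
    prot_drugs <- rownames(features[["protein"]])
    n_anc <- max(spec$seqs_per_drug)
    ancestors <- lapply(seq_len(spec$n_clusters), function(cc)
      vapply(seq_len(n_anc), function(a)
        random_sequence(resample(seq(spec$seq_length_range[1L],
                                     spec$seq_length_range[2L]), 1L),
                        spec$alphabet), character(1L)))
    sequences <- lapply(prot_drugs, function(d) {
      ns <- resample(seq(spec$seqs_per_drug[1L], spec$seqs_per_drug[2L]), 1L)
      vapply(seq_len(ns), function(a)
        mutate_sequence(ancestors[[cl[[d]]]][a], spec$mutation_rate,
                        spec$alphabet), character(1L))
    })
    names(sequences) <- prot_drugs
    sequences <- sequence_features(sequences, alphabet = spec$alphabet)
  }

  ds <- repo_dataset(features, golden_associations(golden), sequences)
  structure(list(dataset = ds, clusters = cl,
                 feature_signatures = feat_sigs,
                 disease_signatures = dis_sigs, spec = spec),
            class = "synthetic_repositioning_data")
}

#' @export
print.synthetic_repositioning_data <- function(x, ...) {
  cat(sprintf("synthetic planted-cluster dataset: %d drugs in %d clusters, seed %d\n",
              x$spec$n_drugs, x$spec$n_clusters, x$spec$seed))
  print(x$dataset)
  invisible(x)
}
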