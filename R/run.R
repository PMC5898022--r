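#' Load a full repositioning dataset from delimited text files
#'
#' Reads the per-source incidence matrices, the golden matrix, optional
#' per-drug FASTA sequences and an optional synonym table, then
#' harmonizes names (see \code{\link{harmonize_names}}).
#'
#' @param paths named list/vector with entries \code{golden} (required),
#'   any of \code{chemical}, \code{protein}, \code{side_effect} (at
#'   least one required), and optionally \code{sequences} (FASTA) and
#'   \code{synonyms} (two-column TSV).
#' @param quiet passed to \code{\link{harmonize_names}}.
#' @return a harmonized \code{\link{repo_dataset}}.
#' @export
load_dataset <- function(paths, quiet = FALSE) {
  paths <- as.list(paths)
  if (is.null(paths$golden)) stop("paths$golden is required", call. = FALSE)
  srcs <- intersect(KNOWN_SOURCES, names(paths))
  if (length(srcs) == 0L)
    stop("at least one feature source path (chemical/protein/side_effect) ",
         "is required", call. = FALSE)
  features <- lapply(srcs, function(s) load_feature_matrix(paths[[s]], s))
  names(features) <- srcs
  golden <- load_golden_associations(paths$golden)
  sequences <- if (!is.null(paths$sequences))
    load_sequence_features(paths$sequences)
  synonyms <- if (!is.null(paths$synonyms)) load_synonym_map(paths$synonyms)
  harmonize_names(repo_dataset(features, golden, sequences), synonyms,
                  quiet = quiet)
}

#' Write a dataset (or generated synthetic data) as delimited text
#'
#' Emits one TSV per feature source, \code{golden.tsv}, a FASTA of
#' sequences when present, and for synthetic data a
#' \code{ground_truth.json} with the cluster assignment and signatures.
#'
#' @param x a \code{\link{repo_dataset}} or the result of
#'   \code{\link{generate_dataset}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_dataset <- function(x, dir) {
  truth <- NULL
  if (inherits(x, "synthetic_repositioning_data")) {
    truth <- list(clusters = as.list(x$clusters),
                  disease_signatures = x$disease_signatures,
                  feature_signatures = x$feature_signatures,
                  seed = x$spec$seed)
    x <- x$dataset
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  for (src in names(x$features)) {
    p <- file.path(dir, paste0(src, ".tsv"))
    write_incidence_matrix(x$features[[src]], p)
    files[src] <- p
  }
  files["golden"] <- file.path(dir, "golden.tsv")
  write_incidence_matrix(x$golden, files["golden"])
  if (!is.null(x$sequences)) {
    files["sequences"] <- file.path(dir, "sequences.fasta")
    lines <- unlist(lapply(names(x$sequences), function(d)
      as.vector(rbind(sprintf(">%s|seq%d", d, seq_along(x$sequences[[d]])),
                      x$sequences[[d]]))))
    writeLines(lines, files["sequences"])
  }
  if (!is.null(truth)) {
    files["ground_truth"] <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(truth, files["ground_truth"], auto_unbox = TRUE)
  }
  invisible(files)
}

normalize_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- list(sim = "CCC", mot = "ND", ist = "WSUM", n = 4L, k = 4L,
                   collapse = "mean", normalize = TRUE, seed = 1L,
                   out_dir = NULL, targets = NULL, quiet = TRUE)
  config <- utils::modifyList(defaults, config)
  stopifnot(config$n >= 1L, config$k >= 1L)
  config
}

run_manifest <- function(config, extra = list()) {
  cfg <- config[!vapply(config, is.null, TRUE)]
  c(list(package = "paretodr",
         version = as.character(utils::packageVersion("paretodr")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         config = cfg,
         config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = "")))),
    extra)
}

#' Run the repositioning pipeline over every eligible target
#'
#' Loads (or accepts) a dataset, predicts up to \code{k} diseases per
#' target drug, and optionally writes \code{predictions.tsv} plus a
#' \code{manifest.json} sufficient to reproduce the run bit-identically.
#'
#' @param config a YAML file path or a list with entries: either
#'   \code{paths} (see \code{\link{load_dataset}}) or \code{dataset} (a
#'   \code{repo_dataset}); \code{sim} (shorthand or named measure map);
#'   \code{mot}, \code{ist}, \code{n}, \code{k}; optional
#'   \code{collapse}, \code{normalize}, \code{targets}, \code{seed},
#'   \code{out_dir}.
#' @return invisibly, a list with \code{$predictions} (data.frame:
#'   target, disease, score, rank), \code{$manifest} and \code{$files}.
#' @export
run_repurpose <- function(config) {
  config <- normalize_run_config(config)
  dataset <- config$dataset %||% load_dataset(config$paths, quiet = config$quiet)
  simcfg <- similarity_config(config$sim, normalize = config$normalize,
                              collapse = config$collapse)
  simmats <- similarity_matrices(dataset, simcfg)
  targets <- config$targets %||% rownames(dataset$golden)
  preds <- lapply(targets, function(t) {
    pl <- withCallingHandlers(
      predict_indications(dataset, t, simcfg, mot = config$mot, n = config$n,
                          ist = config$ist, k = config$k, simmats = simmats),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(pl) == 0L) return(NULL)
    cbind(target = t, as.data.frame(pl), stringsAsFactors = FALSE)
  })
  predictions <- do.call(rbind, c(preds, list(make.row.names = FALSE)))
  if (is.null(predictions))
    predictions <- data.frame(target = character(), disease = character(),
                              score = numeric(), rank = integer())
  manifest <- run_manifest(
    config[c("sim", "mot", "ist", "n", "k", "collapse", "normalize", "seed")],
    extra = list(n_targets = length(targets),
                 n_predictions = nrow(predictions)))
  files <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(predictions = file.path(config$out_dir, "predictions.tsv"),
               manifest = file.path(config$out_dir, "manifest.json"))
    write.table(predictions, files[["predictions"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(list(predictions = predictions, manifest = manifest,
                 files = files))
}

#' Leave-one-out evaluation over a settings grid
#'
#' Convenience wrapper running \code{\link{leave_one_out}} for every
#' combination of the supplied neighbour counts and list sizes.
#'
#' @inheritParams run_repurpose
#' @param n_grid,k_grid integer vectors of neighbour counts and list
#'   sizes to sweep.
#' @return invisibly, a list with \code{$grid} (one row per setting with
#'   the mean metrics) and \code{$files} when \code{out_dir} is set.
#' @export
run_evaluate <- function(config, n_grid = c(1, 4, 8, 12, 16, 20),
                         k_grid = c(1, 4, 8, 12, 16, 20)) {
  config <- normalize_run_config(config)
  dataset <- config$dataset %||% load_dataset(config$paths, quiet = config$quiet)
  simcfg <- similarity_config(config$sim, normalize = config$normalize,
                              collapse = config$collapse)
  simmats <- similarity_matrices(dataset, simcfg)
  grid <- expand.grid(n = n_grid, k = k_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rep <- leave_one_out(dataset, simcfg, mot = config$mot, n = grid$n[i],
                         ist = config$ist, k = grid$k[i],
                         targets = config$targets, simmats = simmats)
    data.frame(sim = paste(simcfg$measures, collapse = ","),
               mot = config$mot, ist = config$ist,
               n = grid$n[i], k = grid$k[i], t(rep$summary),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  files <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(report = file.path(config$out_dir, "evaluation.tsv"),
               json = file.path(config$out_dir, "evaluation.json"))
    write.table(out, files[["report"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(
      list(manifest = run_manifest(config[c("sim", "mot", "ist", "seed")]),
           grid = out),
      files[["json"]], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(grid = out, files = files))
}
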