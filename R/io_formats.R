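# Plain-text serialization of the pipeline objects: fingerprint matrices
# (dense TSV and a compact sparse form), pathway profiles (TSV + JSON
# header), null models (JSON), predictions (TSV) and evaluation reports
# (JSON + TSV tables).

#' Write a fingerprint matrix as TSV
#'
#' Dense layout: header row of fragment labels, first column `compound_id`.
#'
#' @param matrix A `fingerprint_matrix`.
#' @param path Output file.
#' @export
write_fingerprint_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "fingerprint_matrix"))
  df <- data.frame(compound_id = rownames(matrix$values),
                   matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fingerprint matrix written by [write_fingerprint_matrix()]
#'
#' @param path TSV file.
#' @return A `fingerprint_matrix`.
#' @export
read_fingerprint_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  V <- as.matrix(df[, -1, drop = FALSE])
  rownames(V) <- df[[1]]
  storage.mode(V) <- "integer"
  fingerprint_matrix(V)
}

#' Write a fingerprint matrix in sparse form
#'
#' Line format: `compound_id <TAB> space-separated 1-based column indices`.
#' A first comment line `#vocab <TAB> label...` stores the vocabulary.
#'
#' @inheritParams write_fingerprint_matrix
#' @export
write_sparse_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "fingerprint_matrix"))
  V <- matrix$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#vocab\t", paste(colnames(V), collapse = "\t")), con)
  for (r in seq_len(nrow(V))) {
    writeLines(paste0(rownames(V)[r], "\t",
                      paste(which(V[r, ] == 1L), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a sparse fingerprint matrix written by [write_sparse_matrix()]
#'
#' @param path Sparse matrix file.
#' @return A `fingerprint_matrix`.
#' @export
read_sparse_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stopifnot(startsWith(lines[1], "#vocab\t"))
  vocab <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  body <- lines[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  V <- matrix(0L, nrow = length(ids), ncol = length(vocab),
              dimnames = list(ids, vocab))
  for (r in seq_along(parts)) {
    if (length(parts[[r]]) >= 2L && nzchar(parts[[r]][2])) {
      V[r, as.integer(strsplit(parts[[r]][2], " ", fixed = TRUE)[[1]])] <- 1L
    }
  }
  fingerprint_matrix(V)
}

#' Write a pathway map as two-column TSV
#'
#' @param map A [pathway_map()].
#' @param path Output file.
#' @export
write_pathway_map <- function(map, path) {
  stopifnot(inherits(map, "pathway_map"))
  df <- data.frame(
    pathway_id = rep(names(map$pathways), lengths(map$pathways)),
    compound_id = unlist(map$pathways, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pathway profile (TSV table + JSON header)
#'
#' The TSV holds one row per fragment (label, K, x, pv); the JSON sidecar
#' (`<path>.json`) holds pathway_id, M, N and the applied p-value floor.
#'
#' @param profile A `pathway_profile`.
#' @param path Output TSV file.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "pathway_profile"))
  utils::write.table(
    data.frame(fragment = names(profile$pv), K = unname(profile$K),
               x = unname(profile$x), pv = unname(profile$pv),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(pathway_id = profile$pathway_id, M = profile$M, N = profile$N,
         p_floor = profile$p_floor),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a pathway profile written by [write_profile()]
#'
#' @param path TSV file (expects `<path>.json` next to it).
#' @return A `pathway_profile`.
#' @export
read_profile <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(pathway_id = hdr$pathway_id,
                 pv = stats::setNames(tab$pv, tab$fragment),
                 M = as.integer(hdr$M), N = as.integer(hdr$N),
                 K = stats::setNames(as.integer(tab$K), tab$fragment),
                 x = stats::setNames(as.integer(tab$x), tab$fragment),
                 p_floor = if (is.null(hdr$p_floor)) NA_real_ else hdr$p_floor),
            class = "pathway_profile")
}

#' Write a null model as JSON
#'
#' @param model A `null_model`.
#' @param path Output JSON file.
#' @export
write_null_model <- function(model, path) {
  stopifnot(inherits(model, "null_model"))
  jsonlite::write_json(unclass(model)[c("pathway_id", "mean_sr", "sd_sr",
                                        "evd_location", "evd_scale",
                                        "n_random", "n_scores", "seed")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a null model written by [write_null_model()]
#'
#' @param path JSON file.
#' @return A `null_model`.
#' @export
read_null_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(pathway_id = x$pathway_id, mean_sr = x$mean_sr,
                 sd_sr = x$sd_sr, evd_location = x$evd_location,
                 evd_scale = x$evd_scale, n_random = as.integer(x$n_random),
                 n_scores = as.integer(x$n_scores),
                 seed = as.integer(x$seed)),
            class = "null_model")
}

#' Write prediction results as TSV
#'
#' One row per (compound, pathway): compound_id, rank, pathway_id, sc, z,
#' p, unscorable.
#'
#' @param results List of `prediction_result` objects.
#' @param path Output file.
#' @export
write_predictions <- function(results, path) {
  rows <- lapply(results, function(r) {
    data.frame(compound_id = r$compound_id, rank = r$table$rank,
               pathway_id = r$table$pathway_id, sc = r$table$sc,
               z = r$table$z, p = r$table$p, unscorable = r$unscorable,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an evaluation report (JSON summary + TSV tables)
#'
#' Writes `<stem>.json` with the global AUC, seed, method and fold
#' assignment, and TSV tables `<stem>_per_pathway.tsv`, `<stem>_by_size.tsv`
#' and `<stem>_single_multi.tsv`.
#'
#' @param report An `evaluation_report`.
#' @param stem Output path stem.
#' @export
write_report <- function(report, stem) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(
    list(method = report$method, seed = report$seed,
         global_auc = report$global_auc,
         n_compounds = length(report$predictions),
         n_random = report$n_random, k = report$k,
         folds = as.list(report$folds), skipped = report$skipped),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  for (part in c("per_pathway", "by_size", "single_multi")) {
    if (!is.null(report[[part]])) {
      utils::write.table(report[[part]], paste0(stem, "_", part, ".tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(stem)
}
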