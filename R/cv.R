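# Tenfold cross-validation harness. The fold assignment is a pure function
# of (seed, compound ids), so the profile method and the k-NN baseline can
# be evaluated on exactly the same partition.

#' Seeded fold assignment
#'
#' @param ids Compound ids to partition.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return Named integer vector: id -> fold in 1..n_folds.
#' @export
assign_folds <- function(ids, n_folds = 10L, seed = 1L) {
  stopifnot(length(ids) >= n_folds)
  folds <- withr::with_seed(as.integer(seed),
                            sample(rep(seq_len(n_folds), length.out = length(ids))))
  stats::setNames(as.integer(folds), ids)
}

#' Cross-validated evaluation of the profile method or the k-NN baseline
#'
#' Compounds are partitioned into folds by a seeded shuffle; for each fold,
#' profiles and null models (or the neighbour set) are rebuilt from the
#' other folds only, and the held-out compounds are ranked against them.
#' Pathways left with fewer than 2 training compounds in some fold are
#' skipped for that fold with a warning; held-out compounds with no true
#' pathway among that fold's predictable set are excluded from the pooled
#' statistics. The report aggregates the pooled AUC, per-pathway AUCs,
#' AUC by compound size (equal-frequency bins of fingerprint fragment
#' counts), the single- versus multi-pathway split, and optional
#' user-supplied pathway groupings.
#'
#' The matrix should be deduplicated ([merge_redundant()]) and the map
#' filtered ([filter_pathways()]) beforehand; duplicate rows trigger a
#' warning because they can sit on both sides of a split.
#'
#' @param matrix A `fingerprint_matrix`.
#' @param map A [pathway_map()].
#' @param method `"profile"` or `"knn"`.
#' @param seed Integer seed controlling folds and (for the profile method)
#'   the null randomizations.
#' @param n_folds Number of folds (default 10).
#' @param n_random Randomizations per fold for the null models
#'   (default 200; raise for publication-grade p-values).
#' @param k Neighbours for the k-NN baseline (default 3).
#' @param knn_rule Ranking rule passed to [knn_predict()].
#' @param size_bins Number of equal-frequency compound-size bins
#'   (default 8).
#' @param groups Optional named list: group label -> pathway ids, for
#'   group-wise AUC.
#' @return Object of class `evaluation_report`: `global_auc`, `per_pathway`
#'   (data.frame), `by_size` (data.frame), `single_multi` (data.frame),
#'   `by_group` (data.frame or NULL), `folds`, `seed`, `method`,
#'   `predictions` (list of `prediction_result`), `skipped` log.
#' @export
tenfold_cv <- function(matrix, map, method = c("profile", "knn"),
                       seed = 1L, n_folds = 10L, n_random = 200L, k = 3L,
                       knn_rule = "max_similarity", size_bins = 8L,
                       groups = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "fingerprint_matrix"),
            inherits(map, "pathway_map"))
  V <- matrix$values
  if (anyDuplicated(apply(V, 1L, paste, collapse = ""))) {
    warning("matrix contains identical fingerprints; run merge_redundant() ",
            "first to keep duplicates out of train/test splits")
  }
  eval_ids <- intersect(rownames(V), names(map$compounds))
  if (length(eval_ids) < n_folds) stop("not enough annotated compounds")
  folds <- assign_folds(eval_ids, n_folds, seed)
  results <- list()
  skipped <- character(0)
  for (f in seq_len(n_folds)) {
    test_ids <- eval_ids[folds == f]
    train_ids <- setdiff(rownames(V), test_ids)
    train <- fingerprint_matrix(V[train_ids, , drop = FALSE], matrix$config)
    members <- lapply(map$pathways, intersect, y = train_ids)
    ok <- lengths(members) >= 2L
    if (any(!ok)) {
      bad <- names(members)[!ok]
      skipped <- c(skipped, paste0("fold ", f, ": ", bad))
      warning("fold ", f, ": skipping pathway(s) with <2 training compounds: ",
              paste(bad, collapse = ", "), call. = FALSE)
    }
    pw_ok <- names(members)[ok]
    if (length(pw_ok) == 0L) next
    if (method == "profile") {
      profiles <- lapply(pw_ok, function(p)
        build_profile(train, members[[p]], pathway_id = p))
      names(profiles) <- pw_ok
      nulls <- suppressWarnings(
        build_nulls(train, profiles, n_random = n_random,
                    seed = as.integer(seed) + f))
      fold_res <- lapply(test_ids, function(id)
        predict_pathways(V[id, ], profiles, nulls, compound_id = id))
    } else {
      fold_map <- pathway_map(stats::setNames(members[pw_ok], pw_ok))
      fold_res <- lapply(test_ids, function(id)
        knn_predict(V[id, ], train, fold_map, k = k, rule = knn_rule,
                    compound_id = id))
    }
    # keep compounds with at least one true predictable pathway
    keep <- vapply(fold_res, function(r) {
      !r$unscorable && length(intersect(map$compounds[[r$compound_id]],
                                        r$table$pathway_id)) > 0L
    }, logical(1))
    results <- c(results, fold_res[keep])
  }
  if (length(results) == 0L) stop("no evaluable predictions in any fold")
  global <- roc_auc(results, map)
  res_ids <- vapply(results, function(r) r$compound_id, character(1))

  per_pathway <- do.call(rbind, lapply(names(map$pathways), function(p) {
    out <- tryCatch(roc_auc(results, map, pathways = p), error = function(e) NULL)
    if (is.null(out) || out$n_true == 0L) return(NULL)
    data.frame(pathway_id = p, auc = out$auc, n_compounds = out$n_true,
               stringsAsFactors = FALSE)
  }))

  sizes <- rowSums(V)[res_ids]
  nb <- min(size_bins, length(unique(sizes)))
  brk <- unique(stats::quantile(sizes, probs = seq(0, 1, length.out = nb + 1L)))
  bin <- cut(sizes, breaks = brk, include.lowest = TRUE)
  by_size <- do.call(rbind, lapply(levels(bin), function(b) {
    ids <- res_ids[bin == b]
    out <- tryCatch(roc_auc(results, map, compounds = ids),
                    error = function(e) NULL)
    if (is.null(out)) return(NULL)
    data.frame(size_bin = b, auc = out$auc, n_compounds = out$n_compounds,
               stringsAsFactors = FALSE)
  }))

  multi <- lengths(map$compounds[res_ids]) > 1L
  single_multi <- do.call(rbind, lapply(c(FALSE, TRUE), function(m) {
    ids <- res_ids[multi == m]
    if (length(ids) == 0L) return(NULL)
    out <- tryCatch(roc_auc(results, map, compounds = ids),
                    error = function(e) NULL)
    if (is.null(out)) return(NULL)
    data.frame(class = if (m) "multi" else "single", auc = out$auc,
               n_compounds = out$n_compounds, stringsAsFactors = FALSE)
  }))

  by_group <- NULL
  if (!is.null(groups)) {
    by_group <- do.call(rbind, lapply(names(groups), function(g) {
      out <- tryCatch(roc_auc(results, map, pathways = groups[[g]]),
                      error = function(e) NULL)
      if (is.null(out) || out$n_true == 0L) return(NULL)
      data.frame(group = g, auc = out$auc, n_true = out$n_true,
                 stringsAsFactors = FALSE)
    }))
  }

  structure(list(global_auc = global$auc, roc = global$curve,
                 per_pathway = per_pathway, by_size = by_size,
                 single_multi = single_multi, by_group = by_group,
                 folds = folds, seed = as.integer(seed), method = method,
                 n_random = if (method == "profile") as.integer(n_random) else NA_integer_,
                 k = if (method == "knn") as.integer(k) else NA_integer_,
                 predictions = results, skipped = skipped),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> method=", x$method, ", seed=", x$seed,
      ", compounds=", length(x$predictions), "\n", sep = "")
  cat("  global AUC: ", round(x$global_auc, 4), "\n", sep = "")
  if (!is.null(x$single_multi)) {
    for (i in seq_len(nrow(x$single_multi))) {
      cat("  ", x$single_multi$class[i], "-pathway AUC: ",
          round(x$single_multi$auc[i], 4), " (n=",
          x$single_multi$n_compounds[i], ")\n", sep = "")
    }
  }
  if (!is.null(x$per_pathway)) {
    cat("  per-pathway AUC: median ", round(stats::median(x$per_pathway$auc), 4),
        " [", round(min(x$per_pathway$auc), 4), ", ",
        round(max(x$per_pathway$auc), 4), "] over ",
        nrow(x$per_pathway), " pathways\n", sep = "")
  }
  invisible(x)
}
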