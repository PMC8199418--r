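# Pathway ranking for query compounds, enriched-fragment reporting, the
# Tanimoto k-NN baseline, and ROC/AUC evaluation via the top-n predictor
# family: taking the n best-ranked pathways per compound as predictions
# and sweeping n from 1 to the number of pathways traces the ROC curve.

#' Rank all pathways for one compound
#'
#' Scores the compound against every profile, converts to z-scores and
#' extreme-value p-values with the matching null models, and ranks by
#' increasing p-value (ties: decreasing z, then pathway id).
#'
#' @param x_vec Binary vector aligned to the shared vocabulary.
#' @param profiles Named list of `pathway_profile` objects.
#' @param nulls Named list of `null_model` objects aligned to `profiles`.
#' @param compound_id Identifier stored in the result.
#' @return Object of class `prediction_result`: `compound_id`, `table`
#'   (data.frame pathway_id, sc, z, p, rank) and `unscorable` flag. For an
#'   empty fingerprint the table carries NA ranks.
#' @export
predict_pathways <- function(x_vec, profiles, nulls,
                             compound_id = "query") {
  stopifnot(length(profiles) >= 1L,
            identical(names(profiles), names(nulls)))
  if (sum(x_vec != 0) == 0L) {
    tab <- data.frame(pathway_id = names(profiles), sc = 0,
                      z = NA_real_, p = NA_real_, rank = NA_integer_,
                      stringsAsFactors = FALSE)
    return(structure(list(compound_id = compound_id, table = tab,
                          unscorable = TRUE), class = "prediction_result"))
  }
  sc <- vapply(profiles, function(pr) score_compound(x_vec, pr), numeric(1))
  z <- mapply(z_score, sc, nulls)
  p <- mapply(p_from_z, z, nulls)
  ord <- order(p, -z, names(profiles), method = "radix")
  tab <- data.frame(pathway_id = names(profiles)[ord], sc = sc[ord],
                    z = z[ord], p = p[ord],
                    rank = seq_along(profiles), stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(list(compound_id = compound_id, table = tab, unscorable = FALSE),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, n = 5L, ...) {
  cat("<prediction_result> ", x$compound_id,
      if (x$unscorable) " (unscorable)", "\n", sep = "")
  print(utils::head(x$table, n))
  invisible(x)
}

#' Top-n predicted pathways
#'
#' @param result A `prediction_result`.
#' @param n Number of top-ranked pathways to return.
#' @return Character vector of the first `n` ranked pathway ids.
#' @export
top_n_pathways <- function(result, n) {
  stopifnot(inherits(result, "prediction_result"),
            n >= 1L, n <= nrow(result$table))
  if (result$unscorable) return(character(0))
  result$table$pathway_id[seq_len(n)]
}

#' Most enriched fragments of a pathway profile
#'
#' Fragments sorted by increasing enrichment p-value (ties broken by
#' label). Optionally restricted to the fragments a query compound
#' contains, with the atom positions at which each fragment occurs.
#'
#' @param profile A `pathway_profile`.
#' @param k Return exactly the `k` most enriched fragments.
#' @param p_threshold Alternatively, return all fragments with `pv <=`
#'   this value.
#' @param compound Optional query: a [molecule()] (enables atom-index hits)
#'   or a binary vector aligned to the vocabulary.
#' @param config [fragment_config()] used when `compound` is a molecule.
#' @return data.frame (fragment, pv, K, x); with a molecule query, a list
#'   column `atom_hits` of per-occurrence atom-index vectors.
#' @export
enriched_fragments <- function(profile, k = NULL, p_threshold = NULL,
                               compound = NULL, config = fragment_config()) {
  stopifnot(inherits(profile, "pathway_profile"))
  lab <- names(profile$pv)
  tab <- data.frame(fragment = lab, pv = unname(profile$pv),
                    K = unname(profile$K), x = unname(profile$x),
                    stringsAsFactors = FALSE)
  if (!is.null(compound)) {
    if (inherits(compound, "fragpath_mol")) {
      present <- molecule_fragments(compound, config)
      tab <- tab[tab$fragment %in% present, , drop = FALSE]
    } else {
      stopifnot(length(compound) == length(lab))
      tab <- tab[compound != 0, , drop = FALSE]
    }
  }
  ord <- order(tab$pv, tab$fragment, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  if (!is.null(p_threshold)) tab <- tab[tab$pv <= p_threshold, , drop = FALSE]
  if (!is.null(k)) tab <- utils::head(tab, k)
  rownames(tab) <- NULL
  if (!is.null(compound) && inherits(compound, "fragpath_mol")) {
    tab$atom_hits <- unname(fragment_atom_hits(compound, tab$fragment, config))
  }
  tab
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|a AND b| / |a OR b|`; defined as 0 when both vectors are all zero.
#'
#' @param a,b Binary vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a != 0 & b != 0)
  uni <- sum(a != 0 | b != 0)
  if (uni == 0L) 0 else inter / uni
}

# Tanimoto of one query against every row of a binary matrix
.tanimoto_rows <- function(V, x) {
  inter <- as.numeric(V %*% x)
  uni <- rowSums(V) + sum(x) - inter
  s <- ifelse(uni == 0, 0, inter / uni)
  names(s) <- rownames(V)
  s
}

#' k-nearest-neighbour pathway prediction (Tanimoto baseline)
#'
#' Ranks first the pathways annotated to any of the query's top-k most
#' similar database compounds, by the best similarity of such a neighbour
#' (optionally by neighbour vote count); pathways not covered by the top-k
#' follow, ordered by the best similarity of any of their member compounds
#' in the whole database, so that the ranking is complete and the top-n
#' sweep is well defined.
#'
#' @param x_vec Binary query fingerprint (the query itself must not be a
#'   row of the matrix).
#' @param matrix Training `fingerprint_matrix`.
#' @param map A [pathway_map()].
#' @param k Number of neighbours (default 3).
#' @param rule `"max_similarity"` (default) or `"vote"` (neighbour count,
#'   ties by similarity).
#' @param compound_id Identifier stored in the result.
#' @return A `prediction_result`; `sc` holds the similarity used for the
#'   rank, `z` and `p` are NA.
#' @export
knn_predict <- function(x_vec, matrix, map, k = 3L,
                        rule = c("max_similarity", "vote"),
                        compound_id = "query") {
  stopifnot(inherits(matrix, "fingerprint_matrix"),
            inherits(map, "pathway_map"), k >= 1L)
  rule <- match.arg(rule)
  V <- matrix$values
  stopifnot(length(x_vec) == ncol(V))
  pw_ids <- names(map$pathways)
  if (sum(x_vec != 0) == 0L) {
    tab <- data.frame(pathway_id = pw_ids, sc = 0, z = NA_real_,
                      p = NA_real_, rank = NA_integer_,
                      stringsAsFactors = FALSE)
    return(structure(list(compound_id = compound_id, table = tab,
                          unscorable = TRUE), class = "prediction_result"))
  }
  sims <- .tanimoto_rows(V, x_vec)
  ord <- order(-sims, rownames(V), method = "radix")
  topk <- rownames(V)[utils::head(ord, k)]
  # best similarity of any annotated member, per pathway, over (a) top-k
  # neighbours and (b) the full database
  best_top <- rep(NA_real_, length(pw_ids)); names(best_top) <- pw_ids
  votes <- rep(0L, length(pw_ids)); names(votes) <- pw_ids
  best_all <- rep(-1, length(pw_ids)); names(best_all) <- pw_ids
  for (p in pw_ids) {
    mem <- intersect(map$pathways[[p]], rownames(V))
    if (length(mem)) best_all[p] <- max(sims[mem])
    hit <- intersect(map$pathways[[p]], topk)
    if (length(hit)) {
      best_top[p] <- max(sims[hit])
      votes[p] <- length(hit)
    }
  }
  covered <- !is.na(best_top)
  key1 <- ifelse(covered, 0L, 1L)  # covered pathways first
  if (rule == "vote") {
    ordp <- order(key1, -votes, -ifelse(covered, best_top, best_all),
                  pw_ids, method = "radix")
  } else {
    ordp <- order(key1, -ifelse(covered, best_top, best_all), pw_ids,
                  method = "radix")
  }
  tab <- data.frame(
    pathway_id = pw_ids[ordp],
    sc = ifelse(covered, best_top, best_all)[ordp],
    z = NA_real_, p = NA_real_,
    rank = seq_along(pw_ids), stringsAsFactors = FALSE, row.names = NULL)
  structure(list(compound_id = compound_id, table = tab, unscorable = FALSE),
            class = "prediction_result")
}

#' Pooled top-n-sweep ROC and AUC of a set of ranked predictions
#'
#' Every (compound, pathway) pair is one instance, positive when the
#' compound is annotated to the pathway. At cutoff n, pairs inside the
#' top-n ranks count as predicted. TPR and FPR against the totals of true
#' and false pairs trace the ROC as n sweeps from 1 to the number of
#' pathways; the AUC is the trapezoidal integral. Restrict `pathways` or
#' `compounds` to obtain per-pathway or subgroup curves.
#'
#' @param results List of `prediction_result` objects (unscorable ones are
#'   dropped with a warning).
#' @param map A [pathway_map()] giving the true annotations.
#' @param pathways Optional pathway ids: only pairs involving these
#'   pathways are counted.
#' @param compounds Optional compound ids: only these compounds' pairs.
#' @return List with `auc`, `curve` (data.frame n, tp, fp, tpr, fpr),
#'   `n_true`, `n_false`, `n_compounds`.
#' @export
roc_auc <- function(results, map, pathways = NULL, compounds = NULL) {
  stopifnot(inherits(map, "pathway_map"))
  drop <- vapply(results, function(r) r$unscorable, logical(1))
  if (any(drop)) {
    warning("dropping ", sum(drop), " unscorable compound(s) from ROC")
    results <- results[!drop]
  }
  if (!is.null(compounds)) {
    results <- results[vapply(results, function(r)
      r$compound_id %in% compounds, logical(1))]
  }
  if (length(results) == 0L) stop("no scorable predictions to evaluate")
  maxn <- max(vapply(results, function(r) nrow(r$table), integer(1)))
  # a (compound, pathway) pair enters the prediction set at cutoff
  # n = rank(pathway); accumulate entries per rank, then cumulate
  tp_inc <- fp_inc <- numeric(maxn)
  n_true <- n_false <- 0L
  used <- 0L
  for (r in results) {
    truth <- map$compounds[[r$compound_id]]
    tab <- r$table
    if (!is.null(pathways)) tab <- tab[tab$pathway_id %in% pathways, , drop = FALSE]
    if (nrow(tab) == 0L) next
    pos <- tab$pathway_id %in% truth
    if (!any(pos) && is.null(pathways)) next  # no true pathway predictable
    used <- used + 1L
    n_true <- n_true + sum(pos)
    n_false <- n_false + sum(!pos)
    tp_inc <- tp_inc + tabulate(tab$rank[pos], maxn)
    fp_inc <- fp_inc + tabulate(tab$rank[!pos], maxn)
  }
  tp <- cumsum(tp_inc)
  fp <- cumsum(fp_inc)
  if (n_true == 0L) stop("no true (compound, pathway) pairs to evaluate")
  tpr <- tp / n_true
  fpr <- if (n_false > 0L) fp / n_false else rep(1, maxn)
  xs <- c(0, fpr); ys <- c(0, tpr)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  list(auc = auc,
       curve = data.frame(n = seq_len(maxn), tp = tp, fp = fp,
                          tpr = tpr, fpr = fpr),
       n_true = n_true, n_false = n_false, n_compounds = used)
}

#' Filter ranked predictions by p-value and rank
#'
#' Generic filter over a `prediction_result` table: keep rows with rank at
#' most `top_n` and (when p-values exist) p-value below `p_max`. Filtering
#' top-1 predictions at p < 0.05 trades sensitivity for precision.
#'
#' @param result A `prediction_result`.
#' @param top_n Maximum rank kept (default all).
#' @param p_max Keep rows with `p < p_max` (default 1, i.e. no filter).
#' @return The filtered prediction table (data.frame).
#' @export
filter_predictions <- function(result, top_n = Inf, p_max = 1) {
  stopifnot(inherits(result, "prediction_result"))
  tab <- result$table
  if (result$unscorable) return(tab[0, , drop = FALSE])
  tab <- tab[tab$rank <= top_n, , drop = FALSE]
  if (!all(is.na(tab$p))) tab <- tab[tab$p < p_max, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
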