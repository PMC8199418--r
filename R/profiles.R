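# Per-pathway enrichment profiles and the compound-vs-pathway score.
#
# For each fragment i, the profile holds the probability of seeing, by
# chance, at least the observed number of pathway compounds carrying the
# fragment, given its frequency in the whole database (cumulative
# hypergeometric upper tail). A compound is scored against a pathway as
# the mean of -log(pv) over the fragments the compound contains.

#' Upper tail of the hypergeometric distribution
#'
#' Probability of drawing at least `x` marked items when `N` items are
#' drawn without replacement from a population of `M` items of which `K`
#' are marked: `P(X >= x) = sum_{i=x..N} C(K,i) C(M-K,N-i) / C(M,N)`.
#' Computed via [stats::phyper()], which works in log space and is stable
#' for large `M`.
#'
#' @param M Population size (compounds in the database).
#' @param K Marked items (compounds carrying the fragment).
#' @param N Draws (compounds in the pathway).
#' @param x Observed marked draws (pathway compounds with the fragment).
#' @return `P(X >= x)`, vectorized over the arguments.
#' @export
hypergeom_upper_tail <- function(M, K, N, x) {
  if (any(M < 0) || any(K < 0) || any(K > M) || any(N < 0) || any(N > M) ||
      any(x < 0) || any(x > N)) {
    stop("require 0 <= x <= N <= M and 0 <= K <= M")
  }
  stats::phyper(x - 1, K, M - K, N, lower.tail = FALSE)
}

#' Build the enrichment profile of one pathway
#'
#' For every vocabulary fragment, computes the upper-tail hypergeometric
#' p-value of its in-pathway count against the whole-database background
#' (all rows of the matrix). Fragments with a p-value of exactly zero
#' (possible only through floating-point underflow) are floored at the
#' smallest nonzero p-value of the profile divided by 50, so that
#' `-log(pv)` stays finite.
#'
#' @param matrix A `fingerprint_matrix` (the database).
#' @param pathway_ids Character vector of member compound ids (must be rows
#'   of the matrix; at least 2).
#' @param pathway_id Label stored in the profile.
#' @param p_floor Optional explicit floor overriding the per-profile
#'   `min(nonzero pv)/50` rule (e.g. a globally computed floor).
#' @return Object of class `pathway_profile`: `pathway_id`, `pv` (named
#'   vector over the vocabulary), `M`, `N`, `K`, `x`, `p_floor`.
#' @export
build_profile <- function(matrix, pathway_ids, pathway_id = "pathway",
                          p_floor = NULL) {
  stopifnot(inherits(matrix, "fingerprint_matrix"))
  V <- matrix$values
  pathway_ids <- unique(pathway_ids)
  if (length(pathway_ids) < 2L) stop("pathway must have at least 2 compounds")
  missing <- setdiff(pathway_ids, rownames(V))
  if (length(missing)) {
    stop("pathway compounds not in matrix: ", paste(missing, collapse = ", "))
  }
  M <- nrow(V)
  N <- length(pathway_ids)
  K <- colSums(V)
  x <- colSums(V[pathway_ids, , drop = FALSE])
  pv <- hypergeom_upper_tail(M, K, N, x)
  floor_used <- NA_real_
  if (any(pv == 0)) {
    floor_used <- if (!is.null(p_floor)) p_floor else min(pv[pv > 0]) / 50
    pv[pv == 0] <- floor_used
  }
  structure(list(pathway_id = pathway_id, pv = pv, M = M, N = N,
                 K = K, x = x, p_floor = floor_used),
            class = "pathway_profile")
}

#' @export
print.pathway_profile <- function(x, ...) {
  cat("<pathway_profile> ", x$pathway_id, ": N=", x$N, " of M=", x$M,
      " compounds, ", length(x$pv), " fragments, min pv ",
      signif(min(x$pv), 3), "\n", sep = "")
  invisible(x)
}

#' Score a compound against a pathway profile
#'
#' `Sc = -sum_i log(pv_i) x_i / sum_i x_i` (natural log): the mean negative
#' log enrichment p-value over the fragments present in the compound.
#' Fragments absent from the compound do not contribute. A compound with no
#' vocabulary fragments gets `Sc = 0` and an `unscorable` attribute rather
#' than an error, so batch prediction never aborts.
#'
#' @param x_vec Binary vector aligned to the profile's vocabulary.
#' @param profile A [build_profile()] result.
#' @return The score (single number); attribute `unscorable` is `TRUE` for
#'   empty fingerprints.
#' @export
score_compound <- function(x_vec, profile) {
  stopifnot(inherits(profile, "pathway_profile"),
            length(x_vec) == length(profile$pv))
  idx <- which(x_vec != 0)
  if (length(idx) == 0L) {
    return(structure(0, unscorable = TRUE))
  }
  mean(-log(profile$pv[idx]))
}

# scores of all rows of a binary matrix against one pv vector (vectorized)
.score_rows <- function(V, pv) {
  w <- -log(pv)
  supp <- rowSums(V)
  s <- as.numeric(V %*% w) / pmax(supp, 1L)
  s[supp == 0L] <- 0
  s
}

#' Build profiles for every pathway of a map
#'
#' @param matrix A `fingerprint_matrix`.
#' @param map A [pathway_map()]; only compounds present in the matrix count
#'   as members. Pathways with fewer than 2 such members are skipped with a
#'   warning.
#' @param p_floor_scope `"profile"` (default: each profile floors its own
#'   zero p-values at its min nonzero pv / 50) or `"global"` (one floor from
#'   the min nonzero pv across all profiles).
#' @return Named list of `pathway_profile` objects.
#' @export
build_profiles <- function(matrix, map,
                           p_floor_scope = c("profile", "global")) {
  p_floor_scope <- match.arg(p_floor_scope)
  ids <- rownames(matrix$values)
  members <- lapply(map$pathways, intersect, y = ids)
  ok <- lengths(members) >= 2L
  if (any(!ok)) {
    warning("skipping ", sum(!ok),
            " pathway(s) with fewer than 2 compounds in the matrix")
  }
  profiles <- lapply(names(members)[ok], function(p) {
    build_profile(matrix, members[[p]], pathway_id = p)
  })
  names(profiles) <- names(members)[ok]
  if (p_floor_scope == "global" && length(profiles)) {
    gmin <- min(vapply(profiles, function(pr) min(pr$pv[pr$pv > 0]),
                       numeric(1)))
    for (p in names(profiles)) {
      pr <- profiles[[p]]
      raw <- hypergeom_upper_tail(pr$M, pr$K, pr$N, pr$x)
      if (any(raw == 0)) {
        pr$p_floor <- gmin / 50
        pr$pv <- raw
        pr$pv[raw == 0] <- pr$p_floor
        profiles[[p]] <- pr
      }
    }
  }
  profiles
}
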