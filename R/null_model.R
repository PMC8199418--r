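# Null-model calibration: raw scores Sc are not comparable across pathways
# (profiles differ in how informative their fragments are), so each pathway
# gets a null distribution of scores (Sr) obtained by scoring randomized
# fingerprints, a z-transform from the Sr moments, and a maximum-Gumbel
# extreme-value fit on the z scale from which analytic p-values are read.

#' Randomize a fingerprint matrix by within-column permutation
#'
#' Each fragment column is permuted independently across compounds. This
#' preserves every fragment's database frequency K exactly - the quantity
#' the enrichment test conditions on - while destroying all compound-level
#' structure. Row sums are preserved in expectation only.
#'
#' @param matrix A `fingerprint_matrix`.
#' @param seed Integer seed; the result is a pure function of
#'   (matrix, seed).
#' @param scheme `"column"` (default, per-column permutation) or
#'   `"matrix"` (single whole-matrix shuffle of all entries).
#' @return A `fingerprint_matrix` of the same shape and dimnames.
#' @export
randomize_matrix <- function(matrix, seed, scheme = c("column", "matrix")) {
  stopifnot(inherits(matrix, "fingerprint_matrix"))
  scheme <- match.arg(scheme)
  V <- matrix$values
  R <- withr::with_seed(as.integer(seed), .permute_values(V, scheme))
  fingerprint_matrix(R, matrix$config)
}

.permute_values <- function(V, scheme = "column") {
  if (scheme == "column") {
    R <- apply(V, 2L, sample)
  } else {
    R <- V
    R[] <- sample(as.vector(V))
  }
  dimnames(R) <- dimnames(V)
  storage.mode(R) <- "integer"
  R
}

#' Fit a maximum-Gumbel distribution by maximum likelihood
#'
#' CDF `F(z) = exp(-exp(-(z - location)/scale))`. The scale solves the
#' standard profile-likelihood fixed-point equation
#' `b = mean(z) - sum(z e^{-z/b}) / sum(e^{-z/b})` (found by bracketed root
#' search to tolerance 1e-10) and the location follows in closed form.
#'
#' @param z Numeric sample (at least 10 values, non-degenerate).
#' @return List with `location` and `scale`.
#' @export
fit_gumbel <- function(z) {
  z <- z[is.finite(z)]
  n <- length(z)
  if (n < 10L) stop("need at least 10 finite values to fit")
  if (stats::sd(z) == 0) stop("degenerate sample: all values identical")
  zbar <- mean(z)
  g <- function(b) {
    # softmax-weighted mean of z with weights exp(-z/b), computed shifted
    w <- exp(-(z - min(z)) / b)
    b - zbar + sum(z * w) / sum(w)
  }
  b0 <- stats::sd(z) * sqrt(6) / pi  # moment estimate
  lo <- b0; hi <- b0
  while (g(lo) > 0 && lo > b0 * 1e-8) lo <- lo / 2
  while (g(hi) < 0 && hi < b0 * 1e8) hi <- hi * 2
  b <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  mu <- -b * (log(mean(exp(-(z - min(z)) / b))) - min(z) / b)
  list(location = mu, scale = b)
}

#' Build the null score model of one pathway
#'
#' Runs `n_random` randomizations of the matrix, scores every randomized
#' fingerprint against the profile, and pools all resulting scores into the
#' null sample Sr (randomized rows that end up with no fragments are
#' skipped: their conventional score of 0 is not a draw from the score
#' distribution). Stores the Sr moments and a maximum-Gumbel fit on the
#' z-scored sample.
#'
#' @param matrix A `fingerprint_matrix` (the training database).
#' @param profile A [build_profile()] result.
#' @param n_random Number of matrix randomizations (default 10000; values
#'   below 1000 trigger a warning as the tail fit becomes unreliable;
#'   100000 reproduces the full-fidelity setting).
#' @param seed Integer seed making the construction reproducible.
#' @param keep_sample Keep the pooled Sr sample in the result (for
#'   diagnostics; default `FALSE`).
#' @return Object of class `null_model`: `pathway_id`, `mean_sr`, `sd_sr`,
#'   `evd_location`, `evd_scale` (on the z scale), `n_random`, `n_scores`,
#'   `seed`.
#' @export
build_null <- function(matrix, profile, n_random = 10000L, seed = 1L,
                       keep_sample = FALSE) {
  res <- build_nulls(matrix, list(profile), n_random = n_random, seed = seed,
                     keep_sample = keep_sample)
  res[[1]]
}

#' Build null models for several pathways sharing the same randomizations
#'
#' All profiles are scored against the same sequence of randomized
#' matrices, which is both cheaper and exactly what a shared null means.
#'
#' @inheritParams build_null
#' @param profiles List of `pathway_profile` objects (same vocabulary).
#' @return Named list of `null_model` objects.
#' @export
build_nulls <- function(matrix, profiles, n_random = 10000L, seed = 1L,
                        keep_sample = FALSE) {
  stopifnot(inherits(matrix, "fingerprint_matrix"), length(profiles) >= 1L,
            n_random >= 1L)
  if (n_random < 1000L) {
    warning("n_random = ", n_random,
            " is low; null tail estimates may be unstable", call. = FALSE)
  }
  V <- matrix$values
  W <- vapply(profiles, function(p) {
    stopifnot(length(p$pv) == ncol(V))
    -log(p$pv)
  }, numeric(ncol(V)))
  samples <- withr::with_seed(as.integer(seed), {
    acc <- vector("list", n_random)
    for (r in seq_len(n_random)) {
      R <- .permute_values(V, "column")
      supp <- rowSums(R)
      S <- (R %*% W) / pmax(supp, 1L)
      acc[[r]] <- S[supp > 0L, , drop = FALSE]
    }
    do.call(rbind, acc)
  })
  out <- vector("list", length(profiles))
  for (p in seq_along(profiles)) {
    sr <- samples[, p]
    m <- mean(sr); s <- stats::sd(sr)
    if (!is.finite(s) || s == 0) {
      stop("degenerate null: all random scores identical for pathway '",
           profiles[[p]]$pathway_id, "'")
    }
    z <- (sr - m) / s
    fit <- fit_gumbel(z)
    nm <- structure(list(pathway_id = profiles[[p]]$pathway_id,
                         mean_sr = m, sd_sr = s,
                         evd_location = fit$location, evd_scale = fit$scale,
                         n_random = as.integer(n_random),
                         n_scores = length(sr), seed = as.integer(seed)),
                    class = "null_model")
    if (keep_sample) nm$sr <- sr
    out[[p]] <- nm
  }
  names(out) <- vapply(profiles, function(p) p$pathway_id, character(1))
  out
}

#' @export
print.null_model <- function(x, ...) {
  cat("<null_model> ", x$pathway_id, ": Sr mean ", signif(x$mean_sr, 4),
      ", sd ", signif(x$sd_sr, 4), "; Gumbel(loc ",
      signif(x$evd_location, 4), ", scale ", signif(x$evd_scale, 4),
      ") from ", x$n_scores, " scores (", x$n_random,
      " randomizations, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' z-score of a raw score under a null model
#'
#' @param sc Raw score(s) Sc.
#' @param model A `null_model`.
#' @return `(sc - mean_sr) / sd_sr`.
#' @export
z_score <- function(sc, model) {
  stopifnot(inherits(model, "null_model"))
  (sc - model$mean_sr) / model$sd_sr
}

#' Analytic p-value of a z-score under the fitted extreme-value null
#'
#' Maximum-Gumbel survival function
#' `p = 1 - exp(-exp(-(z - location)/scale))`, monotone decreasing in z and
#' clamped to (0, 1].
#'
#' @param z z-score(s).
#' @param model A `null_model`.
#' @return p-value(s) in (0, 1].
#' @export
p_from_z <- function(z, model) {
  stopifnot(inherits(model, "null_model"))
  t <- (z - model$evd_location) / model$evd_scale
  p <- -expm1(-exp(-t))
  pmin(pmax(p, .Machine$double.xmin), 1)
}
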