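# Pathway ranking, the k-NN baseline, and the top-n-sweep ROC machinery.

# small planted world shared by the ranking tests
planted_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sim <- generate_planted_matrix(small_design(seed = 31))
    profiles <- build_profiles(sim$matrix, sim$map)
    nulls <- suppressWarnings(build_nulls(sim$matrix, profiles,
                                          n_random = 50, seed = 32))
    cache <<- list(sim = sim, profiles = profiles, nulls = nulls)
    cache
  }
})

test_that("a compound carrying one pathway's fragments ranks it first", {
  w <- planted_world()
  vocab <- colnames(w$sim$matrix$values)
  for (p in c("P01", "P04")) {
    x <- as.integer(vocab %in% w$sim$truth[[p]])
    res <- predict_pathways(x, w$profiles, w$nulls, compound_id = "probe")
    expect_identical(res$table$pathway_id[1], p)
    expect_false(res$unscorable)
    expect_identical(res$table$rank, seq_along(w$profiles))
    expect_true(all(diff(res$table$p) >= 0))
  }
})

test_that("ties break deterministically and empty queries are flagged", {
  w <- planted_world()
  # two pathways with identical profiles -> identical p, tie by id
  profs <- w$profiles[c("P02", "P02")]
  names(profs) <- c("Pb", "Pa")
  nulls <- w$nulls[c("P02", "P02")]
  names(nulls) <- c("Pb", "Pa")
  x <- w$sim$matrix$values[1, ]
  res <- predict_pathways(x, profs[c("Pa", "Pb")], nulls[c("Pa", "Pb")])
  expect_identical(res$table$p[1], res$table$p[2])
  expect_identical(res$table$pathway_id, c("Pa", "Pb"))

  empty <- predict_pathways(integer(ncol(w$sim$matrix$values)),
                            w$profiles, w$nulls)
  expect_true(empty$unscorable)
  expect_true(all(is.na(empty$table$rank)))
  expect_identical(nrow(filter_predictions(empty)), 0L)
})

test_that("top-n predictions nest and truncate correctly", {
  w <- planted_world()
  res <- predict_pathways(w$sim$matrix$values[3, ], w$profiles, w$nulls)
  np <- length(w$profiles)
  expect_identical(top_n_pathways(res, np), res$table$pathway_id)
  expect_identical(top_n_pathways(res, 1), res$table$pathway_id[1])
  for (k in 1:(np - 1)) {
    expect_true(all(top_n_pathways(res, k) %in% top_n_pathways(res, k + 1)))
  }
})

test_that("enriched fragments surface the planted signal", {
  w <- planted_world()
  for (p in names(w$profiles)) {
    top <- enriched_fragments(w$profiles[[p]], k = length(w$sim$truth[[p]]))
    expect_setequal(top$fragment, w$sim$truth[[p]])
  }
  full <- enriched_fragments(w$profiles$P01, p_threshold = 1)
  expect_identical(nrow(full), ncol(w$sim$matrix$values))
  expect_true(all(diff(full$pv) >= 0))
  # a fragment absent from the pathway (x = 0) has pv 1 and ranks last
  absent <- full[full$x == 0, ]
  expect_true(all(absent$pv == 1))
})

test_that("enriched fragments can be matched onto a query molecule", {
  # tiny chemical world: the alcohol pathway is enriched in C-O bonds
  mols <- list(a = parse_smiles("CCO", "a"), b = parse_smiles("CCCO", "b"),
               c = parse_smiles("CCCCO", "c"), d = parse_smiles("CCC", "d"),
               e = parse_smiles("CCCC", "e"), f = parse_smiles("CC", "f"))
  mat <- build_matrix(mols)
  prof <- build_profile(mat, c("a", "b", "c"), "alcohols")
  hits <- enriched_fragments(prof, k = 3, compound = mols$a)
  expect_true(all(c("pv", "atom_hits") %in% names(hits)))
  expect_true(all(vapply(hits$atom_hits, length, integer(1)) >= 1L))
  expect_true(any(grepl("O", hits$fragment)))
})

test_that("shared backbone fragments pull in related pathways", {
  # histidine-like scenario: the query carries an imidazole side chain
  # (specific to one pathway) plus the amino-acid backbone shared with a
  # second pathway; both should outrank an unrelated pathway
  mols <- list(
    ala = parse_smiles("CC(N)C(=O)O", "ala"),
    gly = parse_smiles("NCC(=O)O", "gly"),
    ser = parse_smiles("OCC(N)C(=O)O", "ser"),
    val = parse_smiles("CC(C)C(N)C(=O)O", "val"),
    hsm = parse_smiles("NCCc1cnc[nH]1", "hsm"),
    iaa = parse_smiles("OC(=O)Cc1cnc[nH]1", "iaa"),
    mim = parse_smiles("Cc1cnc[nH]1", "mim"),
    hex = parse_smiles("CCCCCC", "hex"),
    hep = parse_smiles("CCCCCCC", "hep"),
    oct = parse_smiles("CCCCCCCC", "oct"))
  map <- pathway_map(data.frame(
    pathway_id = c(rep("aa_backbone", 4), rep("imidazole", 3), rep("alkane", 3)),
    compound_id = names(mols)))
  mat <- build_matrix(mols)
  profiles <- build_profiles(mat, map)
  nulls <- suppressWarnings(build_nulls(mat, profiles, n_random = 500,
                                        seed = 61))
  his <- parse_smiles("NC(Cc1cnc[nH]1)C(=O)O", "histidine")
  res <- predict_pathways(fingerprint(his, colnames(mat$values)),
                          profiles, nulls, compound_id = "histidine")
  expect_setequal(res$table$pathway_id[1:2], c("imidazole", "aa_backbone"))
  expect_identical(res$table$pathway_id[3], "alkane")
})

test_that("tanimoto similarity follows the set formula", {
  expect_identical(tanimoto(c(1, 1, 0), c(0, 1, 1)), 1 / 3)
  expect_identical(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_identical(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_identical(tanimoto(c(0, 0, 0), c(0, 0, 0)), 0)
})

test_that("k-NN recovers the labels of an identical neighbour", {
  w <- planted_world()
  V <- w$sim$matrix$values
  id <- rownames(V)[5]
  truth <- w$sim$map$compounds[[id]]
  res <- knn_predict(V[id, ], w$sim$matrix, w$sim$map, k = 1,
                     compound_id = "copy")
  expect_identical(sort(res$table$pathway_id[seq_along(truth)]), sort(truth))
  expect_equal(res$table$sc[1], 1)

  # k = database size: ranking by per-pathway best similarity
  resall <- knn_predict(V[id, ], w$sim$matrix, w$sim$map,
                        k = nrow(V), compound_id = "copy")
  best <- vapply(w$sim$map$pathways, function(mem)
    max(apply(V[mem, , drop = FALSE], 1, tanimoto, b = V[id, ])), numeric(1))
  expect_identical(resall$table$pathway_id,
                   names(best)[order(-best, names(best), method = "radix")])
})

test_that("the top-n sweep AUC hits its analytic anchors", {
  np <- 20L
  pw <- sprintf("P%02d", 1:np)
  mk_result <- function(id, ranked) {
    structure(list(compound_id = id,
                   table = data.frame(pathway_id = ranked,
                                      sc = rev(seq_along(ranked)),
                                      z = NA_real_, p = NA_real_,
                                      rank = seq_along(ranked),
                                      stringsAsFactors = FALSE),
                   unscorable = FALSE), class = "prediction_result")
  }
  ids <- sprintf("c%03d", 1:200)
  truth <- withr::with_seed(71, lapply(ids, function(i) sample(pw, 2)))
  map <- pathway_map(data.frame(
    pathway_id = unlist(truth),
    compound_id = rep(ids, lengths(truth))))

  perfect <- lapply(ids, function(i)
    mk_result(i, c(map$compounds[[i]], setdiff(pw, map$compounds[[i]]))))
  expect_identical(roc_auc(perfect, map)$auc, 1)

  reversed <- lapply(ids, function(i)
    mk_result(i, c(setdiff(pw, map$compounds[[i]]), map$compounds[[i]])))
  expect_identical(roc_auc(reversed, map)$auc, 0)

  random <- withr::with_seed(72, lapply(ids, function(i)
    mk_result(i, sample(pw))))
  expect_equal(roc_auc(random, map)$auc, 0.5, tolerance = 0.03)

  # restricting to one pathway gives the per-pathway view
  one <- roc_auc(perfect, map, pathways = pw[1])
  expect_identical(one$auc, 1)
})

test_that("cross-validation partitions, reuses folds and is deterministic", {
  sim <- generate_planted_matrix(small_design(seed = 41))
  repp <- suppressWarnings(tenfold_cv(sim$matrix, sim$map, "profile",
                                      seed = 42, n_random = 30))
  repk <- suppressWarnings(tenfold_cv(sim$matrix, sim$map, "knn",
                                      seed = 42, k = 3))
  ids <- intersect(rownames(sim$matrix$values), names(sim$map$compounds))
  expect_setequal(names(repp$folds), ids)
  expect_identical(sort(unique(repp$folds)), 1:10)
  expect_identical(repp$folds, repk$folds)  # same partition for both methods

  repp2 <- suppressWarnings(tenfold_cv(sim$matrix, sim$map, "profile",
                                       seed = 42, n_random = 30))
  expect_identical(repp2$global_auc, repp$global_auc)
  expect_identical(repp2$folds, repp$folds)

  expect_true(repp$global_auc >= 0 && repp$global_auc <= 1)
  expect_true(all(repp$per_pathway$auc >= 0 & repp$per_pathway$auc <= 1))
  expect_true(!is.null(repp$by_size) && nrow(repp$by_size) >= 1L)
})

test_that("p-value filtering prunes prediction tables", {
  w <- planted_world()
  res <- predict_pathways(w$sim$matrix$values[2, ], w$profiles, w$nulls)
  f1 <- filter_predictions(res, top_n = 1)
  expect_identical(nrow(f1), 1L)
  f2 <- filter_predictions(res, p_max = 0.05)
  expect_true(all(f2$p < 0.05))
})
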