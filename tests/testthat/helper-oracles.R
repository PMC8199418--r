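# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately re-derive labels and probabilities by
# exhaustive enumeration, sharing only the label grammar (the public
# contract) with the package.

# atom label: element + formal charge suffix (shared grammar)
oracle_atom_label <- function(el, ch) {
  suff <- if (ch == 1L) "+" else if (ch == -1L) "-" else if (ch != 0L)
    sprintf("%+d", ch) else ""
  paste0(el, suff)
}

oracle_bond_mark <- function(o) c("-", "=", "#", ":")[o]

# symmetric bond-order lookup matrix
oracle_bond_matrix <- function(mol) {
  n <- nrow(mol$atoms)
  B <- matrix(0L, n, n)
  for (k in seq_len(nrow(mol$bonds))) {
    B[mol$bonds$i[k], mol$bonds$j[k]] <- mol$bonds$order[k]
    B[mol$bonds$j[k], mol$bonds$i[k]] <- mol$bonds$order[k]
  }
  B
}

.all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in .all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# exhaustive linear-fragment enumeration: every ordered arrangement of
# every atom subset, kept when consecutive atoms are bonded
oracle_linear <- function(mol, min_atoms = 2L, max_atoms = 7L) {
  B <- oracle_bond_matrix(mol)
  n <- nrow(mol$atoms)
  lab <- mapply(oracle_atom_label, mol$atoms$element, mol$atoms$charge)
  out <- character(0)
  if (min_atoms <= 1L) out <- lab
  for (k in max(2L, min_atoms):max_atoms) {
    if (k > n) break
    subs <- utils::combn(n, k)
    for (ci in seq_len(ncol(subs))) {
      for (perm in .all_perms(subs[, ci])) {
        ok <- all(B[cbind(perm[-k], perm[-1])] > 0L)
        if (!ok) next
        pieces <- lab[perm[1]]
        for (q in 2:k) {
          pieces <- paste0(pieces, oracle_bond_mark(B[perm[q - 1], perm[q]]),
                           lab[perm[q]])
        }
        rpieces <- lab[perm[k]]
        for (q in (k - 1):1) {
          rpieces <- paste0(rpieces, oracle_bond_mark(B[perm[q + 1], perm[q]]),
                            lab[perm[q]])
        }
        out <- c(out, min(pieces, rpieces))
      }
    }
  }
  sort(unique(out), method = "radix")
}

# exhaustive atom-centered enumeration via neighbour-subset bitmasks
oracle_centered <- function(mol, min_atoms = 2L, max_atoms = 4L) {
  B <- oracle_bond_matrix(mol)
  lab <- mapply(oracle_atom_label, mol$atoms$element, mol$atoms$charge)
  out <- character(0)
  for (a in seq_len(nrow(mol$atoms))) {
    nb <- which(B[a, ] > 0L)
    if (length(nb) == 0L) next
    for (mask in seq_len(2L^length(nb) - 1L)) {
      sel <- nb[bitwAnd(mask, 2L^(seq_along(nb) - 1L)) > 0L]
      if (length(sel) + 1L < min_atoms || length(sel) + 1L > max_atoms) next
      parts <- sort(paste0("(", oracle_bond_mark(B[a, sel]), lab[sel], ")"),
                    method = "radix")
      out <- c(out, paste0(lab[a], paste(parts, collapse = "")))
    }
  }
  sort(unique(out), method = "radix")
}

# P(X >= x) by exhaustive enumeration of all C(M, N) draws
oracle_hyper <- function(M, K, N, x) {
  if (N == 0L) return(as.numeric(x <= 0L))
  subs <- utils::combn(M, N)
  marked <- colSums(matrix(subs <= K, nrow = N))
  mean(marked >= x)
}

# max-Gumbel sampler
rgumbel_max <- function(n, location, scale) {
  location - scale * log(-log(stats::runif(n)))
}

# relabel a molecule's atoms by a permutation (perm[new] = old index)
permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  b <- mol$bonds
  b$i <- inv[b$i]
  b$j <- inv[b$j]
  molecule(mol$id, mol$atoms[perm, , drop = FALSE], b)
}

# molecules used by round-trip and oracle tests (all <= 8 heavy atoms)
oracle_panel_smiles <- c(
  ethanol = "CCO", benzene = "c1ccccc1", neopentane = "CC(C)(C)C",
  acetate = "CC(=O)[O-]", glycerol = "OCC(O)CO",
  ethylbenzene = "CCc1ccccc1", pyridine = "c1ccncc1",
  cyclohexane = "C1CCCCC1", alanine = "CC(N)C(=O)O",
  chloroethanol = "ClCCO", acetone = "CC(=O)C", propyne = "CC#C"
)

# small planted design used by several test files (fast to generate)
small_design <- function(seed = 1L, ...) {
  planted_design(n_pathways = 5L, compounds_per_pathway = 12L,
                 vocab_size = 80L, n_enriched = 4L, p_in = 0.9,
                 p_bg = 0.05, seed = seed, ...)
}

# parse the toy SMILES library into molecules once per test run
toy_library_molecules <- local({
  cache <- NULL
  function(seed = 1L) {
    if (!is.null(cache)) return(cache)
    lib <- generate_toy_smiles_library(seed)
    mols <- lapply(seq_len(nrow(lib$smiles)), function(i)
      parse_smiles(lib$smiles$smiles[i], lib$smiles$id[i]))
    names(mols) <- lib$smiles$id
    cache <<- list(lib = lib, mols = mols)
    cache
  }
})
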