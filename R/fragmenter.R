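# Fragment enumeration and binary fingerprint encoding.
#
# Two fragment families are enumerated: linear fragments (simple atom/bond
# paths, default 2-7 atoms) and atom-centered fragments (an atom plus a
# subset of its direct neighbours, default 2-4 atoms). Labels are canonical
# strings - a path and its reverse share one label, and atom-centered
# neighbour lists are sorted - so the fragment set of a molecule does not
# depend on atom numbering. Bond marks: "-" single, "=" double, "#" triple,
# ":" aromatic.

# enumerate simple paths; returns list(label=<chr>, atoms=<list of int>)
.linear_occurrences <- function(mol, min_atoms, max_atoms, charges = TRUE) {
  lab <- atom_labels(mol, charges)
  n <- nrow(mol$atoms)
  labels <- character(0)
  atoms <- list()
  if (min_atoms <= 1L) {
    labels <- lab
    atoms <- as.list(seq_len(n))
  }
  if (max_atoms >= 2L && nrow(mol$bonds) > 0L) {
    adj <- adjacency(mol)
    marks <- BOND_MARKS
    path <- integer(max_atoms)
    onpath <- logical(n)
    fwd <- character(max_atoms)  # forward label pieces
    emit <- function(depth) {
      seg_lab <- fwd[seq_len(depth)]
      forward <- paste(seg_lab, collapse = "")
      # reverse label: atoms reversed, bond marks between them reversed
      idx <- path[seq_len(depth)]
      rev_pieces <- character(depth)
      rev_pieces[1] <- lab[idx[depth]]
      if (depth > 1L) {
        for (q in 2:depth) {
          # bond mark between idx[depth-q+2] and idx[depth-q+1] is the one
          # stored in fwd[depth-q+2] (its first char)
          rev_pieces[q] <- paste0(substr(fwd[depth - q + 2L], 1L, 1L),
                                  lab[idx[depth - q + 1L]])
        }
      }
      backward <- paste(rev_pieces, collapse = "")
      labels[[length(labels) + 1L]] <<- if (forward <= backward) forward else backward
      atoms[[length(atoms) + 1L]] <<- idx
    }
    recurse <- function(depth) {
      cur <- path[depth]
      for (t in seq_along(adj$nb[[cur]])) {
        nxt <- adj$nb[[cur]][t]
        if (onpath[nxt]) next
        path[depth + 1L] <<- nxt
        fwd[depth + 1L] <<- paste0(marks[[adj$ord[[cur]][t]]], lab[nxt])
        onpath[nxt] <<- TRUE
        if (depth + 1L >= min_atoms) emit(depth + 1L)
        if (depth + 1L < max_atoms) recurse(depth + 1L)
        onpath[nxt] <<- FALSE
      }
    }
    for (s in seq_len(n)) {
      path[1L] <- s
      fwd[1L] <- lab[s]
      onpath[s] <- TRUE
      recurse(1L)
      onpath[s] <- FALSE
    }
  }
  list(label = unlist(labels, use.names = FALSE) %||% character(0),
       atoms = atoms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# atom-centered occurrences: center + neighbour subset
.centered_occurrences <- function(mol, min_atoms, max_atoms, charges = TRUE) {
  lab <- atom_labels(mol, charges)
  adj <- adjacency(mol)
  marks <- BOND_MARKS
  labels <- character(0)
  atoms <- list()
  for (c0 in seq_len(nrow(mol$atoms))) {
    deg <- length(adj$nb[[c0]])
    if (deg == 0L) next
    parts <- paste0("(", marks[adj$ord[[c0]]], lab[adj$nb[[c0]]], ")")
    for (s in seq.int(min_atoms - 1L, max_atoms - 1L)) {
      if (s < 1L || s > deg) next
      combos <- utils::combn(deg, s)
      for (ci in seq_len(ncol(combos))) {
        sel <- combos[, ci]
        labels[[length(labels) + 1L]] <-
          paste0(lab[c0], paste(sort(parts[sel], method = "radix"),
                                collapse = ""))
        atoms[[length(atoms) + 1L]] <- c(c0, adj$nb[[c0]][sel])
      }
    }
  }
  list(label = unlist(labels, use.names = FALSE) %||% character(0),
       atoms = atoms)
}

#' Enumerate linear fragments of a molecule
#'
#' A linear fragment is a simple path (no repeated atoms) through the
#' heavy-atom graph, labeled by the alternating sequence of atom labels and
#' bond marks. A path and its reverse map to the same canonical label.
#'
#' @param mol A [molecule()].
#' @param min_atoms,max_atoms Path length bounds in atoms (defaults 2 and 7).
#' @param charges Append formal charges to atom labels (default `TRUE`).
#' @return Sorted character vector of unique fragment labels.
#' @export
enumerate_linear_fragments <- function(mol, min_atoms = 2L, max_atoms = 7L,
                                       charges = TRUE) {
  stopifnot(inherits(mol, "fragpath_mol"),
            min_atoms >= 1L, min_atoms <= max_atoms)
  occ <- .linear_occurrences(mol, min_atoms, max_atoms, charges)
  sort(unique(occ$label), method = "radix")
}

#' Enumerate atom-centered fragments of a molecule
#'
#' An atom-centered fragment is an atom together with a non-empty subset of
#' its direct neighbours, with total atom count (center plus neighbours)
#' within the bounds. The label is the center's atom label followed by the
#' sorted list of (bond mark, neighbour label) pairs.
#'
#' @inheritParams enumerate_linear_fragments
#' @param min_atoms,max_atoms Total atom count bounds (defaults 2 and 4).
#' @return Sorted character vector of unique fragment labels.
#' @export
enumerate_atom_centered_fragments <- function(mol, min_atoms = 2L,
                                              max_atoms = 4L, charges = TRUE) {
  stopifnot(inherits(mol, "fragpath_mol"),
            min_atoms >= 2L, min_atoms <= max_atoms)
  occ <- .centered_occurrences(mol, min_atoms, max_atoms, charges)
  sort(unique(occ$label), method = "radix")
}

#' Full fragment set of a molecule under a fragmentation configuration
#'
#' @inheritParams enumerate_linear_fragments
#' @param config List with elements `linear_min`, `linear_max`,
#'   `centered_min`, `centered_max`, `charges`; see
#'   [fragment_config()].
#' @return Sorted character vector of unique fragment labels (both kinds).
#' @export
molecule_fragments <- function(mol, config = fragment_config()) {
  sort(unique(c(
    enumerate_linear_fragments(mol, config$linear_min, config$linear_max,
                               config$charges),
    enumerate_atom_centered_fragments(mol, config$centered_min,
                                      config$centered_max, config$charges)
  )), method = "radix")
}

#' Fragmentation configuration
#'
#' Defaults follow the standard setup for this descriptor family: linear
#' paths of 2-7 atoms and atom-centered neighbourhoods of 2-4 atoms, with
#' formal charges kept in atom labels. `linear_min` may be lowered to 1 to
#' include single-atom fragments.
#'
#' @param linear_min,linear_max Linear path bounds in atoms.
#' @param centered_min,centered_max Atom-centered total atom count bounds.
#' @param charges Append formal charges to atom labels.
#' @return A named list used by the fragmenter functions.
#' @export
fragment_config <- function(linear_min = 2L, linear_max = 7L,
                            centered_min = 2L, centered_max = 4L,
                            charges = TRUE) {
  stopifnot(linear_min >= 1L, linear_min <= linear_max,
            centered_min >= 2L, centered_min <= centered_max)
  list(linear_min = as.integer(linear_min), linear_max = as.integer(linear_max),
       centered_min = as.integer(centered_min),
       centered_max = as.integer(centered_max), charges = isTRUE(charges))
}

#' Atom-index hits of fragments in a molecule
#'
#' Re-enumerates the molecule's fragments and returns, for each requested
#' label, the list of atom-index vectors at which it occurs. Used to map
#' enriched fragments back onto query structures.
#'
#' @inheritParams molecule_fragments
#' @param labels Fragment labels to locate.
#' @return Named list: label -> list of integer atom-index vectors
#'   (empty list for labels absent from the molecule).
#' @export
fragment_atom_hits <- function(mol, labels, config = fragment_config()) {
  lin <- .linear_occurrences(mol, config$linear_min, config$linear_max,
                             config$charges)
  cen <- .centered_occurrences(mol, config$centered_min, config$centered_max,
                               config$charges)
  all_lab <- c(lin$label, cen$label)
  all_atoms <- c(lin$atoms, cen$atoms)
  out <- stats::setNames(vector("list", length(labels)), labels)
  for (k in seq_along(labels)) {
    hit <- which(all_lab == labels[k])
    out[[k]] <- unique(lapply(all_atoms[hit], function(a) sort(a)))
  }
  out
}

#' Encode a molecule as a binary fingerprint over a fixed vocabulary
#'
#' @inheritParams molecule_fragments
#' @param vocabulary Ordered character vector of fragment labels.
#' @return Named integer 0/1 vector aligned to `vocabulary`; attribute
#'   `n_outside` counts the molecule's fragments not in the vocabulary.
#' @export
fingerprint <- function(mol, vocabulary, config = fragment_config()) {
  stopifnot(length(vocabulary) > 0L)
  frs <- molecule_fragments(mol, config)
  v <- as.integer(vocabulary %in% frs)
  names(v) <- vocabulary
  attr(v, "n_outside") <- sum(!(frs %in% vocabulary))
  v
}

#' Build the compounds x fragments fingerprint matrix of a corpus
#'
#' The vocabulary is the union of all fragments observed in the corpus,
#' sorted lexicographically (byte order) for a stable column order.
#'
#' @param mols Named list of molecules (names are compound ids).
#' @param config A [fragment_config()].
#' @return An object of class `fingerprint_matrix`: list with `values`
#'   (binary integer matrix, rownames = compound ids, colnames =
#'   vocabulary) and `config`.
#' @export
build_matrix <- function(mols, config = fragment_config()) {
  stopifnot(length(mols) >= 1L)
  ids <- names(mols)
  if (is.null(ids)) ids <- vapply(mols, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate compound ids in corpus")
  sets <- lapply(mols, molecule_fragments, config = config)
  vocab <- sort(unique(unlist(sets, use.names = FALSE)), method = "radix")
  if (length(vocab) == 0L) stop("no fragments found in corpus")
  values <- matrix(0L, nrow = length(mols), ncol = length(vocab),
                   dimnames = list(ids, vocab))
  for (r in seq_along(sets)) {
    values[r, match(sets[[r]], vocab)] <- 1L
  }
  fingerprint_matrix(values, config)
}

#' Construct a fingerprint matrix object from a binary matrix
#'
#' @param values Binary integer matrix with compound ids as rownames and
#'   fragment labels as colnames.
#' @param config Optional [fragment_config()] provenance.
#' @return An object of class `fingerprint_matrix`.
#' @export
fingerprint_matrix <- function(values, config = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  storage.mode(values) <- "integer"
  if (!all(values %in% c(0L, 1L))) stop("fingerprint matrix must be binary")
  structure(list(values = values, config = config),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat("<fingerprint_matrix> ", nrow(x$values), " compounds x ",
      ncol(x$values), " fragments; density ",
      signif(mean(x$values), 3), "\n", sep = "")
  invisible(x)
}

#' Merge compounds with identical fingerprints
#'
#' Compounds whose binary vectors are identical are collapsed into a single
#' row (the first id in input order becomes the representative) and the
#' representative inherits the union of the merged compounds' pathway
#' annotations. This keeps indistinguishable compounds from landing on both
#' sides of a cross-validation split.
#'
#' @param matrix A `fingerprint_matrix`.
#' @param map A [pathway_map()].
#' @return List with `matrix` (deduplicated), `map` (updated) and
#'   `merge_log` (named list: representative -> merged ids, only groups of
#'   size > 1).
#' @export
merge_redundant <- function(matrix, map) {
  stopifnot(inherits(matrix, "fingerprint_matrix"),
            inherits(map, "pathway_map"))
  V <- matrix$values
  key <- apply(V, 1L, paste, collapse = "")
  first <- !duplicated(key)
  groups <- split(rownames(V), key)[unique(key)]  # input order of first hit
  log <- groups[lengths(groups) > 1L]
  reps <- unname(vapply(groups, `[`, character(1), 1L))
  V2 <- V[first, , drop = FALSE]
  rownames(V2) <- reps
  # union pathway annotations over each merge group
  assign <- list()
  for (g in seq_along(groups)) {
    pws <- unique(unlist(map$compounds[groups[[g]]], use.names = FALSE))
    if (length(pws)) {
      assign[[length(assign) + 1L]] <-
        data.frame(pathway_id = pws, compound_id = unname(reps[g]),
                   stringsAsFactors = FALSE)
    }
  }
  # keep annotations of compounds absent from the matrix untouched
  extra <- setdiff(names(map$compounds), rownames(V))
  for (id in extra) {
    assign[[length(assign) + 1L]] <-
      data.frame(pathway_id = map$compounds[[id]], compound_id = id,
                 stringsAsFactors = FALSE)
  }
  new_map <- pathway_map(do.call(rbind, assign))
  list(matrix = fingerprint_matrix(V2, matrix$config),
       map = new_map,
       merge_log = stats::setNames(log, reps[lengths(groups) > 1L]))
}
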