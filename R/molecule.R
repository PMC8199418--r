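# Internal heavy-atom graph model shared by the SDF and SMILES readers.
# Bond orders are stored as integers 1, 2, 3 with 4 meaning aromatic,
# matching the MDL V2000 convention.

BOND_MARKS <- c(`1` = "-", `2` = "=", `3` = "#", `4` = ":")

#' Construct a molecule from atom and bond tables
#'
#' A molecule is a heavy-atom graph: hydrogens are implicit and never take
#' part in fragment enumeration. Atoms carry an element symbol, a formal
#' charge and an aromatic flag; bonds carry the two atom indices and an
#' integer order (1, 2, 3, or 4 for aromatic).
#'
#' @param id Compound identifier (single string).
#' @param atoms `data.frame` with columns `element` (character), `charge`
#'   (integer) and `aromatic` (logical). One row per heavy atom.
#' @param bonds `data.frame` with columns `i`, `j` (1-based atom indices)
#'   and `order` (integer in 1:4). May have zero rows.
#' @return An object of class `fragpath_mol`.
#' @export
molecule <- function(id, atoms, bonds) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  atoms <- data.frame(
    element = as.character(atoms$element),
    charge = as.integer(atoms$charge),
    aromatic = as.logical(atoms$aromatic),
    stringsAsFactors = FALSE
  )
  if (nrow(atoms) < 1L) {
    stop("molecule '", id, "' has no atoms")
  }
  if (nrow(bonds) > 0L) {
    bonds <- data.frame(
      i = as.integer(bonds$i), j = as.integer(bonds$j),
      order = as.integer(bonds$order), stringsAsFactors = FALSE
    )
    if (any(bonds$i < 1L | bonds$i > nrow(atoms)) ||
        any(bonds$j < 1L | bonds$j > nrow(atoms))) {
      stop("molecule '", id, "': bond atom index out of range")
    }
    if (any(bonds$i == bonds$j)) {
      stop("molecule '", id, "': self-bond")
    }
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) {
      stop("molecule '", id, "': duplicate bond between an atom pair")
    }
    if (!all(bonds$order %in% 1:4)) {
      stop("molecule '", id, "': bond order must be 1, 2, 3 or 4 (aromatic)")
    }
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  structure(list(id = id, atoms = atoms, bonds = bonds),
            class = "fragpath_mol")
}

#' @export
print.fragpath_mol <- function(x, ...) {
  cat("<fragpath_mol> ", x$id, ": ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

# adjacency list: for each atom, data of neighbour index and bond order
adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  ord <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]; o <- mol$bonds$order[k]
    nb[[i]] <- c(nb[[i]], j); ord[[i]] <- c(ord[[i]], o)
    nb[[j]] <- c(nb[[j]], i); ord[[j]] <- c(ord[[j]], o)
  }
  list(nb = nb, ord = ord)
}

# Remove explicit hydrogens (and their bonds), remapping bond indices.
strip_hydrogens <- function(mol) {
  keep <- mol$atoms$element != "H"
  if (all(keep)) return(mol)
  if (!any(keep)) stop("molecule '", mol$id, "' has no heavy atoms")
  remap <- cumsum(keep)
  b <- mol$bonds
  b <- b[keep[b$i] & keep[b$j], , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  molecule(mol$id, mol$atoms[keep, , drop = FALSE], b)
}

# Normalise aromatic rings so kekulized and aromatic encodings of the same
# ring system give identical fragment sets. A 5- or 6-ring is marked
# aromatic when every ring atom is C/N/O/S and is either already involved
# in a double or aromatic bond (sp2) or is a heteroatom contributing a lone
# pair (pyrrole-type N/O/S). This is a deliberately simple perception
# model; it covers benzenoid and common five-membered heteroaromatic rings
# and leaves saturated or partially saturated rings alone.
perceive_aromaticity <- function(mol) {
  n <- nrow(mol$atoms)
  if (n < 5L || nrow(mol$bonds) < 5L) return(.flag_order4(mol))
  adj <- adjacency(mol)
  has_multi <- logical(n)  # atom touches a double/triple/aromatic bond
  for (k in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[k] >= 2L) {
      has_multi[mol$bonds$i[k]] <- TRUE
      has_multi[mol$bonds$j[k]] <- TRUE
    }
  }
  el <- mol$atoms$element
  eligible <- el %in% c("C", "N", "O", "S") &
    (has_multi | el %in% c("N", "O", "S"))
  cycles <- .find_cycles(adj$nb, sizes = c(5L, 6L))
  bkey <- paste(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
  for (cyc in cycles) {
    if (all(eligible[cyc])) {
      m <- length(cyc)
      pairs <- paste(pmin(cyc, cyc[c(2:m, 1L)]), pmax(cyc, cyc[c(2:m, 1L)]))
      mol$bonds$order[match(pairs, bkey)] <- 4L
      mol$atoms$aromatic[cyc] <- TRUE
    }
  }
  .flag_order4(mol)
}

# ensure atoms on order-4 bonds (e.g. from SDF input) carry the flag
.flag_order4 <- function(mol) {
  arom <- mol$bonds$order == 4L
  if (any(arom)) {
    mol$atoms$aromatic[unique(c(mol$bonds$i[arom], mol$bonds$j[arom]))] <- TRUE
  }
  mol
}

# All simple cycles of the requested sizes, each reported once with its
# smallest atom index first and direction fixed by the second atom.
.find_cycles <- function(nb, sizes) {
  maxlen <- max(sizes)
  out <- list()
  n <- length(nb)
  for (start in seq_len(n)) {
    path <- integer(maxlen)
    path[1L] <- start
    onpath <- logical(n); onpath[start] <- TRUE
    recurse <- function(depth) {
      cur <- path[depth]
      for (nxt in nb[[cur]]) {
        if (nxt == start && depth >= 3L && depth %in% sizes) {
          if (path[2L] < path[depth]) {  # one direction only
            out[[length(out) + 1L]] <<- path[seq_len(depth)]
          }
        }
        if (nxt > start && !onpath[nxt] && depth < maxlen) {
          path[depth + 1L] <<- nxt
          onpath[nxt] <<- TRUE
          recurse(depth + 1L)
          onpath[nxt] <<- FALSE
        }
      }
    }
    recurse(1L)
  }
  out
}

# Label for one atom: element symbol with the formal charge appended
# ("O-", "N+", "Fe+2"). Charges are chemically informative for these
# fragment types, so they are kept by default.
atom_labels <- function(mol, charges = TRUE) {
  el <- mol$atoms$element
  if (!charges) return(el)
  ch <- mol$atoms$charge
  suff <- character(length(ch))
  suff[ch == 1L] <- "+"
  suff[ch == -1L] <- "-"
  big <- abs(ch) > 1L
  suff[big] <- sprintf("%+d", ch[big])
  paste0(el, suff)
}
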