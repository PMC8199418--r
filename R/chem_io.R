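# Readers for the external formats the pipeline consumes: MDL V2000 SDF,
# SMILES lists and the two-column pathway membership TSV. Structure parsing
# is delegated to ChemmineR (with OpenBabel behind smiles2sdf); records are
# then converted into the package's heavy-atom graph and normalised
# (explicit hydrogens stripped, aromatic rings perceived) so that the same
# molecule yields the same fragments regardless of input format.

# MDL old-style charge codes used in atom-block column 6
.MDL_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

# Parse one raw MDL V2000 record into a fragpath_mol. The atom and bond
# blocks are read from the record text directly (fixed-width columns with
# a whitespace-token fallback): this keeps zero-bond molecules and
# "M  CHG" property lines working, which the higher-level SDF containers
# in ChemmineR do not round-trip.
.parse_v2000 <- function(lines, id) {
  if (length(lines) < 4L) stop("truncated record")
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || natoms < 1L || is.na(nbonds) || nbonds < 0L) {
    stop("bad counts line")
  }
  if (length(lines) < 4L + natoms + nbonds) stop("truncated record")
  at <- lines[4L + seq_len(natoms)]
  el <- trimws(substr(at, 32L, 34L))
  chgcode <- suppressWarnings(as.integer(trimws(substr(at, 37L, 39L))))
  fix <- !nzchar(el)
  if (any(fix)) {  # whitespace-tokenized atom lines
    tok <- strsplit(trimws(at[fix]), "\\s+")
    el[fix] <- vapply(tok, function(t) t[4] %||% "", character(1))
    chgcode[fix] <- suppressWarnings(
      as.integer(vapply(tok, function(t) t[5] %||% NA_character_,
                        character(1))))
  }
  if (!all(grepl("^[A-Z][a-z]?$", el))) stop("bad element symbol")
  charge <- .MDL_CHARGE[as.character(chgcode)]
  charge[is.na(charge)] <- 0L
  if (nbonds > 0L) {
    bl <- lines[4L + natoms + seq_len(nbonds)]
    bi <- suppressWarnings(as.integer(substr(bl, 1L, 3L)))
    bj <- suppressWarnings(as.integer(substr(bl, 4L, 6L)))
    bo <- suppressWarnings(as.integer(substr(bl, 7L, 9L)))
    fix <- is.na(bi) | is.na(bj) | is.na(bo)
    if (any(fix)) {
      tok <- lapply(strsplit(trimws(bl[fix]), "\\s+"), as.integer)
      bi[fix] <- vapply(tok, `[`, integer(1), 1L)
      bj[fix] <- vapply(tok, `[`, integer(1), 2L)
      bo[fix] <- vapply(tok, `[`, integer(1), 3L)
    }
    if (anyNA(c(bi, bj, bo))) stop("bad bond line")
    bonds <- data.frame(i = bi, j = bj, order = bo)
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  # M CHG property lines supersede the atom-block charge column
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge[] <- 0L
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
      k <- f[1]
      charge[f[seq(2, by = 2, length.out = k)]] <-
        f[seq(3, by = 2, length.out = k)]
    }
  }
  atoms <- data.frame(element = el, charge = as.integer(charge),
                      aromatic = FALSE, stringsAsFactors = FALSE)
  mol <- molecule(id, atoms, bonds)
  perceive_aromaticity(strip_hydrogens(mol))
}

#' Read compound structures from an MDL V2000 SDF file
#'
#' Each record becomes one molecule; the record name (first header line)
#' becomes the compound id, falling back to `record_<n>` when blank.
#' Unparseable records are skipped with a warning, mirroring the dirt found
#' in real structure dumps; the skip count is attached to the result.
#' Explicit hydrogens are stripped and aromatic rings are perceived after
#' parsing, so kekulized and aromatic encodings of the same ring match.
#'
#' @param path Path to a multi-record MDL V2000 SDF file.
#' @return A named list of [molecule()] objects, with attribute `skipped`
#'   giving the number of records that could not be parsed.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!any(nzchar(trimws(readLines(path, warn = FALSE))))) {
    stop("empty SDF file: ", path)
  }
  recs <- methods::as(ChemmineR::read.SDFstr(path), "list")
  if (length(recs) == 0L) stop("empty SDF file: ", path)
  mols <- list()
  skipped <- 0L
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    mol <- tryCatch({
      id <- trimws(rec[1])
      if (!nzchar(id)) id <- paste0("record_", i)
      .parse_v2000(rec, id)
    }, error = function(e) NULL)
    if (is.null(mol)) {
      skipped <- skipped + 1L
      warning("skipping unparseable SDF record ", i, " in ", path,
              call. = FALSE)
    } else {
      mols[[length(mols) + 1L]] <- mol
    }
  }
  if (length(mols) == 0L) stop("no parseable records in ", path)
  ids <- vapply(mols, function(m) m$id, character(1))
  if (anyDuplicated(ids)) {
    for (id in unique(ids[duplicated(ids)])) {
      grp <- mols[ids == id]
      same <- vapply(grp[-1], function(m) identical(m$atoms, grp[[1]]$atoms) &&
                       identical(m$bonds, grp[[1]]$bonds), logical(1))
      if (!all(same)) {
        stop("compound id '", id, "' used for different structures in ", path)
      }
    }
    message("dropping ", sum(duplicated(ids)),
            " duplicate record id(s) with identical structures")
    mols <- mols[!duplicated(ids)]
    ids <- ids[!duplicated(ids)]
  }
  names(mols) <- ids
  attr(mols, "skipped") <- skipped
  mols
}

#' Parse a single SMILES string into a molecule
#'
#' Aromaticity is perceived with the same normalisation as [read_sdf()], so
#' the same molecule gives the same fragment set regardless of the input
#' format or kekulization.
#'
#' @param smiles A SMILES string.
#' @param id Compound identifier to assign.
#' @return A [molecule()] object.
#' @export
parse_smiles <- function(smiles, id = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!.smiles_syntax_ok(smiles)) stop("invalid SMILES: '", smiles, "'")
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
    error = function(e) NULL)
  mol <- NULL
  if (!is.null(txt) && nzchar(txt)) {
    mol <- tryCatch(.parse_v2000(strsplit(txt, "\n", fixed = TRUE)[[1]], id),
                    error = function(e) NULL)
  }
  if (is.null(mol)) stop("invalid SMILES: '", smiles, "'")
  mol
}

# Cheap syntax screen applied before handing a SMILES to OpenBabel, which
# silently drops unbalanced trailing tokens instead of erroring.
.smiles_syntax_ok <- function(s) {
  if (!nzchar(trimws(s))) return(FALSE)
  ch <- strsplit(s, "", fixed = FALSE)[[1]]
  if (sum(ch == "(") != sum(ch == ")")) return(FALSE)
  if (sum(ch == "[") != sum(ch == "]")) return(FALSE)
  if (grepl("[-=#(\\[]$", s)) return(FALSE)
  # ring-closure digits must pair up (two-digit %nn closures included)
  stripped <- gsub("\\[[^]]*\\]", "", s)  # bracket atoms may contain digits
  ring <- c(regmatches(stripped, gregexpr("%[0-9]{2}", stripped))[[1]],
            strsplit(gsub("%[0-9]{2}", "", stripped), "")[[1]])
  ring <- ring[grepl("^%|^[0-9]$", ring)]
  all(table(ring) %% 2L == 0L)
}

#' Read a SMILES list file
#'
#' One SMILES per line, optionally followed by a tab and an identifier.
#' Lines that fail to parse are skipped with a warning.
#'
#' @param path Path to the SMILES file.
#' @return Named list of molecules with attribute `skipped`.
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty SMILES file: ", path)
  mols <- list()
  skipped <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    id <- if (length(f) >= 2L && nzchar(trimws(f[2]))) trimws(f[2]) else trimws(f[1])
    mol <- tryCatch(parse_smiles(trimws(f[1]), id), error = function(e) NULL)
    if (is.null(mol)) {
      skipped <- skipped + 1L
      warning("skipping unparseable SMILES on line ", i, call. = FALSE)
    } else {
      mols[[length(mols) + 1L]] <- mol
    }
  }
  if (length(mols) == 0L) stop("no parseable SMILES in ", path)
  ids <- vapply(mols, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate compound ids in ", path)
  names(mols) <- ids
  attr(mols, "skipped") <- skipped
  mols
}

#' Construct a pathway membership map
#'
#' Stores the pathway -> compounds map and the derived reverse map
#' (compound -> pathways). Compounds may belong to several pathways
#' (multi-label).
#'
#' @param assignments Two-column `data.frame` (pathway_id, compound_id) or a
#'   named list of character vectors (pathway -> compound ids).
#' @return An object of class `pathway_map` with elements `pathways` (named
#'   list pathway -> sorted compound ids) and `compounds` (named list
#'   compound -> sorted pathway ids).
#' @export
pathway_map <- function(assignments) {
  if (is.data.frame(assignments)) {
    stopifnot(ncol(assignments) >= 2L)
    pw <- as.character(assignments[[1]])
    cp <- as.character(assignments[[2]])
  } else if (is.list(assignments)) {
    pw <- rep(names(assignments), lengths(assignments))
    cp <- as.character(unlist(assignments, use.names = FALSE))
  } else {
    stop("assignments must be a data.frame or a named list")
  }
  keep <- nzchar(pw) & nzchar(cp)
  pw <- pw[keep]; cp <- cp[keep]
  if (length(pw) == 0L) stop("empty pathway map")
  fwd <- lapply(split(cp, pw), function(x) sort(unique(x), method = "radix"))
  rev <- lapply(split(pw, cp), function(x) sort(unique(x), method = "radix"))
  fwd <- fwd[sort(names(fwd), method = "radix")]
  rev <- rev[sort(names(rev), method = "radix")]
  structure(list(pathways = fwd, compounds = rev), class = "pathway_map")
}

#' @export
print.pathway_map <- function(x, ...) {
  cat("<pathway_map> ", length(x$pathways), " pathways, ",
      length(x$compounds), " compounds (",
      sum(lengths(x$compounds) > 1L), " multi-pathway)\n", sep = "")
  invisible(x)
}

#' Read a pathway membership table
#'
#' Expects a two-column TSV (`pathway_id <TAB> compound_id`); a header line
#' is detected and dropped. Duplicate rows collapse under set semantics.
#'
#' @param path Path to the TSV file.
#' @return A [pathway_map()] object.
#' @export
read_pathway_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty pathway map file: ", path)
  first <- tolower(strsplit(lines[1], "\t", fixed = TRUE)[[1]][1])
  if (grepl("pathway", first)) lines <- lines[-1]
  if (length(lines) == 0L) stop("pathway map file has a header but no rows: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("pathway map rows must have two tab-separated columns")
  }
  pathway_map(data.frame(
    pathway_id = trimws(vapply(parts, `[`, character(1), 1L)),
    compound_id = trimws(vapply(parts, `[`, character(1), 2L)),
    stringsAsFactors = FALSE
  ))
}

#' Drop pathways with too few compounds
#'
#' Pathways with fewer than `min_compounds` distinct member compounds are
#' removed; compounds left with no pathway disappear from the reverse map.
#' The default of 10 reflects the minimum set size at which per-fragment
#' enrichment statistics are considered reliable.
#'
#' @param map A [pathway_map()].
#' @param min_compounds Minimum number of distinct compounds (default 10).
#' @return A filtered [pathway_map()].
#' @export
filter_pathways <- function(map, min_compounds = 10L) {
  stopifnot(inherits(map, "pathway_map"), min_compounds >= 1L)
  keep <- lengths(map$pathways) >= min_compounds
  fwd <- map$pathways[keep]
  if (length(fwd) == 0L) {
    return(structure(list(pathways = fwd, compounds = list()),
                     class = "pathway_map"))
  }
  pathway_map(fwd)
}

#' Flag compounds present in the map but missing structures (or vice versa)
#'
#' @param map A [pathway_map()].
#' @param compound_ids Character vector of ids with known structures.
#' @return List with `missing_structure` (in map, no structure) and
#'   `unmapped` (structure, not in map).
#' @export
validate_compounds <- function(map, compound_ids) {
  stopifnot(inherits(map, "pathway_map"))
  list(
    missing_structure = setdiff(names(map$compounds), compound_ids),
    unmapped = setdiff(compound_ids, names(map$compounds))
  )
}
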