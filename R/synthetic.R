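# Seeded synthetic inputs with known ground truth. Two fixture levels:
# an abstract planted-enrichment fingerprint matrix (tests the statistical
# machinery directly) and a small SMILES library built from scaffold
# grammars (tests the chemistry pipeline end to end).

#' Design of a planted-enrichment fingerprint matrix
#'
#' Each pathway owns `n_enriched` dedicated fragment columns that its
#' member compounds carry with probability `p_in` while everyone else
#' carries them with the background probability `p_bg`; all remaining
#' columns are background everywhere. Setting `p_in = p_bg` gives a null
#' design with no recoverable signal. Optional structural families
#' (crosscutting the pathways) add strong family-specific columns that
#' make pathways structurally heterogeneous: nearest-neighbour similarity
#' then follows the family, not the pathway.
#'
#' @param n_pathways Number of pathways.
#' @param compounds_per_pathway Compounds primarily assigned to each
#'   pathway.
#' @param vocab_size Total number of fragment columns.
#' @param n_enriched Enriched columns owned by each pathway.
#' @param p_in In-pathway presence probability of an enriched column.
#' @param p_bg Background presence probability.
#' @param frac_multi Fraction of compounds also assigned to a second,
#'   random pathway (multi-label compounds sample both pathways' enriched
#'   columns at `p_in`).
#' @param n_families Number of crosscutting structural families (0 = none).
#' @param n_family_frags Family-specific columns per family.
#' @param p_family Presence probability of a family column for members.
#' @param seed Integer seed; generation is a pure function of the design.
#' @return A list of class `planted_design`.
#' @export
planted_design <- function(n_pathways = 20L, compounds_per_pathway = 30L,
                           vocab_size = 400L, n_enriched = 5L,
                           p_in = 0.9, p_bg = 0.05, frac_multi = 0,
                           n_families = 0L, n_family_frags = 10L,
                           p_family = 0.9, seed = 1L) {
  stopifnot(n_pathways >= 1L, compounds_per_pathway >= 2L,
            n_enriched >= 1L, p_bg >= 0, p_bg <= p_in, p_in <= 1,
            frac_multi >= 0, frac_multi < 1,
            vocab_size >= n_pathways * n_enriched +
              (n_families > 0L) * n_families * n_family_frags)
  structure(list(n_pathways = as.integer(n_pathways),
                 compounds_per_pathway = as.integer(compounds_per_pathway),
                 vocab_size = as.integer(vocab_size),
                 n_enriched = as.integer(n_enriched),
                 p_in = p_in, p_bg = p_bg, frac_multi = frac_multi,
                 n_families = as.integer(n_families),
                 n_family_frags = as.integer(n_family_frags),
                 p_family = p_family, seed = as.integer(seed)),
            class = "planted_design")
}

#' Generate a planted-enrichment fingerprint matrix
#'
#' @param design A [planted_design()].
#' @return List with `matrix` (a `fingerprint_matrix`), `map` (a
#'   [pathway_map()]), `truth` (named list: pathway -> its enriched column
#'   labels) and `families` (named integer vector, present when
#'   `n_families > 0`).
#' @export
generate_planted_matrix <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  d <- design
  n_comp <- d$n_pathways * d$compounds_per_pathway
  comp_ids <- sprintf("C%04d", seq_len(n_comp))
  pw_ids <- sprintf("P%02d", seq_len(d$n_pathways))
  frag_ids <- sprintf("F%04d", seq_len(d$vocab_size))
  primary <- rep(seq_len(d$n_pathways), each = d$compounds_per_pathway)
  enr_cols <- lapply(seq_len(d$n_pathways), function(p)
    (p - 1L) * d$n_enriched + seq_len(d$n_enriched))
  fam_offset <- d$n_pathways * d$n_enriched
  fam_cols <- if (d$n_families > 0L) {
    lapply(seq_len(d$n_families), function(fm)
      fam_offset + (fm - 1L) * d$n_family_frags + seq_len(d$n_family_frags))
  } else list()

  out <- withr::with_seed(d$seed, {
    secondary <- rep(NA_integer_, n_comp)
    if (d$frac_multi > 0) {
      n_multi <- round(d$frac_multi * n_comp)
      pick <- sample(n_comp, n_multi)
      secondary[pick] <- vapply(primary[pick], function(p)
        sample(setdiff(seq_len(d$n_pathways), p), 1L), integer(1))
    }
    family <- if (d$n_families > 0L) {
      # families crosscut pathways: within each pathway, members cycle
      # through the families
      as.integer((seq_len(n_comp) - 1L) %% d$n_families + 1L)
    } else NULL
    prob <- matrix(d$p_bg, nrow = n_comp, ncol = d$vocab_size)
    for (c0 in seq_len(n_comp)) {
      own <- enr_cols[[primary[c0]]]
      if (!is.na(secondary[c0])) own <- c(own, enr_cols[[secondary[c0]]])
      prob[c0, own] <- d$p_in
      if (!is.null(family)) prob[c0, fam_cols[[family[c0]]]] <- d$p_family
    }
    V <- matrix(as.integer(stats::runif(length(prob)) < prob),
                nrow = n_comp, dimnames = list(comp_ids, frag_ids))
    list(V = V, secondary = secondary, family = family)
  })
  assign <- data.frame(pathway_id = pw_ids[primary], compound_id = comp_ids,
                       stringsAsFactors = FALSE)
  if (any(!is.na(out$secondary))) {
    sec <- !is.na(out$secondary)
    assign <- rbind(assign, data.frame(
      pathway_id = pw_ids[out$secondary[sec]], compound_id = comp_ids[sec],
      stringsAsFactors = FALSE))
  }
  truth <- stats::setNames(lapply(enr_cols, function(ix) frag_ids[ix]), pw_ids)
  res <- list(matrix = fingerprint_matrix(out$V),
              map = pathway_map(assign), truth = truth)
  if (!is.null(out$family)) {
    res$families <- stats::setNames(out$family, comp_ids)
  }
  res
}

# scaffold + substituent grammars for three chemically coherent families
.TOY_FAMILIES <- list(
  alcohol_acid = list(
    scaffold = c("CCO", "CCCO", "CCCCO", "CCCCCO", "CC(=O)O", "CCC(=O)O",
                 "CCCC(=O)O", "OCCO", "OCCCO", "CC(O)CO"),
    subst = c("", "C", "CC", "O")
  ),
  benzenoid = list(
    scaffold = c("c1ccccc1", "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
                 "c1ccc(cc1)C(=O)O", "CCc1ccccc1", "Clc1ccccc1",
                 "c1ccc(cc1)C=O", "Cc1ccc(C)cc1", "Oc1ccc(O)cc1"),
    subst = c("", "C", "O")
  ),
  phospho_sugar = list(
    scaffold = c("OCC(O)COP(=O)(O)O", "OCC(O)C(O)COP(=O)(O)O",
                 "OCC(O)C(O)C(O)COP(=O)(O)O", "CC(O)COP(=O)(O)O",
                 "OCC(=O)COP(=O)(O)O", "CC(O)C(O)COP(=O)(O)O",
                 "OCC(O)C(O)C(O)C(O)COP(=O)(O)O", "OP(=O)(O)OCC1OC(O)C(O)C1O",
                 "OCC1OC(O)C(O)C1OP(=O)(O)O", "CC(=O)C(O)COP(=O)(O)O"),
    subst = c("", "C", "O")
  )
)

#' Generate a toy SMILES library with pathway annotations
#'
#' Builds three chemically coherent families (linear alcohols/acids,
#' benzene derivatives, phospho-sugars) of at least 12 molecules each from
#' scaffold + substituent grammars; each family doubles as one pathway.
#' The library deliberately contains one molecule annotated to two
#' families (benzyl alcohol: benzenoid and alcohol) and one structure
#' present under two different ids in two different families, so that
#' downstream deduplication ([merge_redundant()]) has real work to do.
#'
#' @param seed Integer seed (selects substituent combinations).
#' @return List with `smiles` (data.frame id, smiles), `map`
#'   (a [pathway_map()]).
#' @export
generate_toy_smiles_library <- function(seed = 1L) {
  rows <- withr::with_seed(as.integer(seed), {
    out <- list()
    for (fam in names(.TOY_FAMILIES)) {
      g <- .TOY_FAMILIES[[fam]]
      sm <- g$scaffold
      # extend scaffolds with sampled substituents until >= 12 members
      k <- 0L
      while (length(sm) < 12L) {
        k <- k + 1L
        base <- sample(g$scaffold, 1L)
        sub <- sample(g$subst[nzchar(g$subst)], 1L)
        cand <- paste0(sub, base)
        if (!(cand %in% sm)) sm <- c(sm, cand)
        if (k > 100L) break
      }
      out[[fam]] <- data.frame(
        id = sprintf("%s_%02d", fam, seq_along(sm)), smiles = sm,
        pathway = fam, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  # shared molecule: benzyl alcohol belongs to both families
  shared <- data.frame(id = "shared_benzyl_alcohol", smiles = "OCc1ccccc1",
                       pathway = c("benzenoid", "alcohol_acid"),
                       stringsAsFactors = FALSE)
  # duplicate structure under a second id, in a different pathway
  dup <- data.frame(id = "dup_phenol", smiles = "Oc1ccccc1",
                    pathway = "alcohol_acid", stringsAsFactors = FALSE)
  rows <- rbind(rows, shared, dup)
  rownames(rows) <- NULL
  smiles <- unique(rows[, c("id", "smiles")])
  map <- pathway_map(rows[, c("pathway", "id")])
  list(smiles = smiles, map = map)
}
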