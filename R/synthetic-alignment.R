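#' @title Toy alignments with planted conservation patterns
#' @description
#' Generates gapped toy alignments whose per-column conservation labels and
#' per-domain identities are known by construction, so the lineage
#' classifier and identity computations can be tested without the curated
#' alignment. Residues are drawn from disjoint chemical families so that a
#' "mixed" group can never accidentally reach support on any residue-type
#' set.
#' @name synthetic-alignment
NULL

# Disjoint residue families used for planting; each maps onto one of the
# default residue-type sets (or singletons).
PLANT_FAMILIES <- list(acidic = c("D", "E"), basic = c("K", "R"),
                       aromatic = c("F", "Y", "W"),
                       aliphatic = c("I", "L", "V", "M"),
                       hydroxyl = c("S", "T"))

#' Generate a toy alignment with planted lineage-conservation labels
#'
#' Sequences fall into the canonical groups `a_I`, `a_II`, `b_I`, `b_II`
#' (plus `outgroup` when requested). For every column a scenario is drawn:
#' conserved in all groups (ancestral), in one lineage, in one class
#' lineage, in all MHC groups but not the outgroup (MHC-characteristic), or
#' in no group. Conserved groups share one residue family; unconserved
#' groups cycle through three other families so no type set reaches 50%
#' support.
#'
#' @param n_per_group sequences per group (default 4).
#' @param n_columns alignment length (default 30).
#' @param with_outgroup include a non-MHC IgSF-like outgroup.
#' @param labels optional character vector of planted labels per column
#'   (sampled otherwise).
#' @return a `pmhc_alignment` with `attr(, "ground_truth")` = planted label
#'   per column; groups and a single `all` block are attached.
#' @export
make_toy_alignment <- function(n_per_group = 4, n_columns = 30,
                               with_outgroup = FALSE, labels = NULL) {
  groups <- c("a_I", "a_II", "b_I", "b_II", if (with_outgroup) "outgroup")
  seq_names <- unlist(lapply(groups, function(g)
    paste0(g, "_", seq_len(n_per_group))))
  group_cfg <- lapply(groups, function(g)
    seq_names[startsWith(seq_names, paste0(g, "_"))])
  names(group_cfg) <- groups

  scenarios <- c("ancestral", "a-lineage", "b-lineage", "I-a-specific",
                 "IIalpha-specific", "I-b-specific", "IIbeta-specific",
                 "none", if (with_outgroup) "MHC-characteristic")
  if (is.null(labels)) labels <- sample(scenarios, n_columns, replace = TRUE)
  stopifnot(length(labels) == n_columns, all(labels %in% scenarios))

  required_groups <- function(lab) switch(
    lab,
    "ancestral" = c("a_I", "a_II", "b_I", "b_II",
                    if (with_outgroup) "outgroup"),
    "MHC-characteristic" = c("a_I", "a_II", "b_I", "b_II"),
    "a-lineage" = c("a_I", "a_II"), "b-lineage" = c("b_I", "b_II"),
    "I-a-specific" = "a_I", "IIalpha-specific" = "a_II",
    "I-b-specific" = "b_I", "IIbeta-specific" = "b_II",
    "none" = character())

  m <- matrix("", nrow = length(seq_names), ncol = n_columns,
              dimnames = list(seq_names, NULL))
  fam_names <- names(PLANT_FAMILIES)
  for (cc in seq_len(n_columns)) {
    req <- required_groups(labels[cc])
    fam_cons <- sample(fam_names, 1)
    fam_rest <- setdiff(fam_names, fam_cons)
    for (g in groups) {
      members <- group_cfg[[g]]
      if (g %in% req) {
        m[members, cc] <- sample(PLANT_FAMILIES[[fam_cons]],
                                 length(members), replace = TRUE)
      } else {
        fams <- rep_len(sample(fam_rest, 4), length(members))
        m[members, cc] <- vapply(fams, function(f)
          sample(PLANT_FAMILIES[[f]], 1), character(1))
      }
    }
  }
  aln <- structure(list(
    seqs = m,
    blocks = list(all = list(cols = c(1, n_columns),
                             positions = as.character(seq_len(n_columns)))),
    groups = group_cfg, ncol = n_columns),
    class = "pmhc_alignment")
  attr(aln, "ground_truth") <- labels
  aln
}

#' Write an alignment as gapped FASTA text
#'
#' @param aln a `pmhc_alignment`.
#' @param path optional file path; lines are returned invisibly.
#' @return character vector of FASTA lines.
#' @export
write_alignment_fasta <- function(aln, path = NULL) {
  lines <- unlist(lapply(rownames(aln$seqs), function(nm)
    c(paste0(">", nm), paste(aln$seqs[nm, ], collapse = ""))))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
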