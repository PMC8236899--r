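#' @title Residue conservation and lineage classification
#' @description
#' Consumes a curated gapped alignment of MHC domain sequences (the
#' evolutionary correspondence is hand-curated, never recomputed here),
#' computes per-domain pairwise identity, and classifies per-column
#' conservation by evolutionary lineage: a column may be conserved across
#' all lineages (inherited from the presumed MHC homodimer ancestor),
#' specific to the "a" lineage (I-alpha1 + beta-2-m / II-alpha) or the "b"
#' lineage (I-alpha2 + I-alpha3 / II-beta), specific to a single class
#' lineage, or characteristic of MHC relative to non-MHC IgSF outgroup
#' sequences. Conservation is evaluated over configurable residue-type sets
#' (e.g. acidic \{D,E\}, aromatic \{F,Y,W\}), since the field shades
#' positions by residue type, not strict identity.
#' @name conservation
NULL

AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Default residue-type sets
#'
#' Each standard amino acid as a singleton plus the common property groups
#' used when shading MHC alignments.
#' @return named list of character vectors.
#' @export
default_type_sets <- function() {
  sets <- as.list(AA_CODES)
  names(sets) <- AA_CODES
  c(sets, list(
    acidic = c("D", "E"),
    amide_acidic = c("D", "E", "N", "Q"),
    aromatic = c("F", "Y", "W"),
    aliphatic = c("I", "L", "V", "M"),
    hydroxyl = c("S", "T"),
    basic = c("K", "R"),
    small = c("G", "A", "S")))
}

#' Read a gapped FASTA alignment with a block configuration
#'
#' @param path FASTA file (gaps `-` or `.`); or a character vector of lines
#'   via `text`.
#' @param block_config named list: per domain class, a list with `cols =
#'   c(first, last)` (1-based alignment columns) and optionally `positions`
#'   (character vector of canonical labels per column, e.g. `"62b"`).
#' @param groups optional named list mapping group names to sequence-name
#'   vectors.
#' @param text alternative to `path`.
#' @return a `pmhc_alignment` list: `seqs` (named character matrix, one row
#'   per sequence), `blocks`, `groups`, `ncol`.
#' @export
read_alignment <- function(path = NULL, block_config = NULL, groups = NULL,
                           text = NULL) {
  if (is.null(path) && is.null(text)) stop("need path or text")
  if (is.null(path)) {
    path <- tempfile(fileext = ".fasta")
    writeLines(text, path)
    on.exit(unlink(path))
  }
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                           set.attributes = FALSE)
  if (!length(fa)) stop("empty alignment")
  lens <- lengths(fa)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: sequence lengths ",
         paste(unique(lens), collapse = ", "))
  m <- toupper(do.call(rbind, fa))
  m[m == "."] <- "-"
  allowed <- c(AA_CODES, "-", "X")
  bad <- setdiff(unique(as.vector(m)), allowed)
  if (length(bad))
    stop("unknown alignment symbol(s): ", paste(bad, collapse = ", "))
  rownames(m) <- names(fa)
  blocks <- block_config
  if (!is.null(blocks)) {
    for (b in names(blocks)) {
      cc <- blocks[[b]]$cols
      if (cc[1] < 1 || cc[2] > ncol(m) || cc[2] < cc[1])
        stop("block ", b, " columns out of range")
      if (is.null(blocks[[b]]$positions))
        blocks[[b]]$positions <- as.character(seq_len(cc[2] - cc[1] + 1))
    }
  }
  structure(list(seqs = m, blocks = blocks, groups = groups, ncol = ncol(m)),
            class = "pmhc_alignment")
}

#' @export
print.pmhc_alignment <- function(x, ...) {
  cat("pmhc_alignment:", nrow(x$seqs), "sequences x", x$ncol, "columns; ",
      length(x$blocks), "domain block(s)\n")
  invisible(x)
}

#' Pairwise per-domain percent identity
#'
#' Identity = 100 * matching columns / columns where both sequences are
#' non-gap, restricted to the domain block. `X` counts as a non-match.
#'
#' @param aln a `pmhc_alignment`.
#' @param seq_a,seq_b sequence names.
#' @param domain_class block name (e.g. `"pa"`); `NULL` = all columns.
#' @return percent identity (numeric, unrounded).
#' @export
pairwise_domain_identity <- function(aln, seq_a, seq_b, domain_class = NULL) {
  for (s in c(seq_a, seq_b))
    if (!s %in% rownames(aln$seqs)) stop("no such sequence: ", s)
  cols <- seq_len(aln$ncol)
  if (!is.null(domain_class)) {
    if (is.null(aln$blocks[[domain_class]]))
      stop("no block for domain ", domain_class)
    cc <- aln$blocks[[domain_class]]$cols
    cols <- cc[1]:cc[2]
  }
  a <- aln$seqs[seq_a, cols]
  b <- aln$seqs[seq_b, cols]
  shared <- a != "-" & b != "-"
  if (!any(shared))
    stop("no shared non-gap columns between ", seq_a, " and ", seq_b)
  match_ <- shared & a == b & a != "X"
  100 * sum(match_) / sum(shared)
}

#' Per-domain identity matrix
#'
#' @inheritParams pairwise_domain_identity
#' @param seqs sequence names (default all).
#' @return symmetric percent-identity matrix with 100 on the diagonal.
#' @export
identity_matrix <- function(aln, domain_class = NULL, seqs = NULL) {
  if (is.null(seqs)) seqs <- rownames(aln$seqs)
  n <- length(seqs)
  m <- diag(100, n)
  dimnames(m) <- list(seqs, seqs)
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      m[i, j] <- m[j, i] <-
        pairwise_domain_identity(aln, seqs[i], seqs[j], domain_class)
  m
}

#' Default lineage classification rules
#'
#' Rules are evaluated in order; the first applicable label wins. With the
#' canonical group names (`a_I` = I-alpha1 + beta-2-m blocks, `a_II` =
#' II-alpha, `b_I` = I-alpha2 + I-alpha3, `b_II` = II-beta, optional
#' `outgroup` = non-MHC IgSF sequences) the precedence is: MHC-characteristic
#' (conserved in all MHC groups but not the outgroup) > ancestral (all MHC
#' groups) > a/b lineage > class-specific.
#'
#' @param group_names names of the groups present.
#' @return list of rules (`label`, `required`, `excluded`).
#' @export
default_conservation_rules <- function(group_names) {
  mhc <- setdiff(group_names, "outgroup")
  a_groups <- intersect(c("a_I", "a_II"), group_names)
  b_groups <- intersect(c("b_I", "b_II"), group_names)
  rules <- list()
  if ("outgroup" %in% group_names)
    rules <- c(rules, list(list(label = "MHC-characteristic",
                                required = mhc, excluded = "outgroup")))
  rules <- c(rules, list(list(label = "ancestral", required = mhc,
                              excluded = character())))
  if (length(a_groups) > 1)
    rules <- c(rules, list(list(label = "a-lineage", required = a_groups,
                                excluded = b_groups)))
  if (length(b_groups) > 1)
    rules <- c(rules, list(list(label = "b-lineage", required = b_groups,
                                excluded = a_groups)))
  cls <- c(a_I = "I-a-specific", a_II = "IIalpha-specific",
           b_I = "I-b-specific", b_II = "IIbeta-specific")
  for (g in intersect(names(cls), group_names))
    rules <- c(rules, list(list(label = unname(cls[g]), required = g,
                                excluded = setdiff(mhc, g))))
  rules
}

group_support <- function(residues, type_set) {
  if (!length(residues)) return(0)
  mean(residues %in% type_set)
}

#' Classify conservation of one alignment column
#'
#' A label applies when some residue-type set reaches support >= threshold
#' in every required group and stays below threshold in every excluded
#' group. Columns that only reach a relaxed support of 0.5 are reported with
#' `uncertain = TRUE` (the low-confidence tier used for small-font shading).
#'
#' @param aln a `pmhc_alignment` with `groups`.
#' @param column alignment column index.
#' @param type_sets named list of residue-type sets
#'   (default [default_type_sets()]).
#' @param rules classification rules
#'   (default [default_conservation_rules()]).
#' @param support_threshold minimum within-group fraction (default 0.8).
#' @return list: `column`, `label` (`"none"` if no rule fires), `type_set`,
#'   `support` (minimum support over required groups), `uncertain`.
#' @export
classify_column_conservation <- function(aln, column,
                                         type_sets = default_type_sets(),
                                         rules = NULL,
                                         support_threshold = 0.8) {
  if (column < 1 || column > aln$ncol) stop("column out of range")
  if (is.null(aln$groups)) stop("alignment has no group configuration")
  if (is.null(rules)) rules <- default_conservation_rules(names(aln$groups))
  col_res <- lapply(aln$groups, function(members) {
    mem <- intersect(members, rownames(aln$seqs))
    r <- aln$seqs[mem, column]
    r[r != "-"]
  })
  eval_at <- function(thr) {
    for (rule in rules) {
      best <- NULL
      for (ts in names(type_sets)) {
        sup_req <- vapply(rule$required, function(g)
          group_support(col_res[[g]], type_sets[[ts]]), numeric(1))
        if (any(sup_req < thr)) next
        sup_exc <- vapply(rule$excluded, function(g)
          group_support(col_res[[g]], type_sets[[ts]]), numeric(1))
        if (length(sup_exc) && any(sup_exc >= thr)) next
        cand <- list(type_set = ts, support = min(sup_req))
        if (is.null(best) || cand$support > best$support) best <- cand
      }
      if (!is.null(best))
        return(list(label = rule$label, type_set = best$type_set,
                    support = best$support))
    }
    NULL
  }
  hit <- eval_at(support_threshold)
  uncertain <- FALSE
  if (is.null(hit) && support_threshold > 0.5) {
    hit <- eval_at(0.5)
    uncertain <- !is.null(hit)
  }
  if (is.null(hit))
    return(list(column = column, label = "none", type_set = NA_character_,
                support = NA_real_, uncertain = FALSE))
  list(column = column, label = hit$label, type_set = hit$type_set,
       support = hit$support, uncertain = uncertain)
}

#' Classify every column of an alignment
#'
#' @inheritParams classify_column_conservation
#' @return data frame with one row per column: `column`, `label`,
#'   `type_set`, `support`, `uncertain`.
#' @export
classify_alignment_conservation <- function(aln,
                                            type_sets = default_type_sets(),
                                            rules = NULL,
                                            support_threshold = 0.8) {
  rows <- lapply(seq_len(aln$ncol), function(cc)
    classify_column_conservation(aln, cc, type_sets, rules,
                                 support_threshold))
  do.call(rbind, lapply(rows, as.data.frame))
}
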