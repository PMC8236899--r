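#' @title Beta-sheet topology, beta-bulges and the S2-S3 cleft
#' @description
#' Strand runs are labelled S1, S2, ... within each domain in canonical
#' sequence order (IgSF domains additionally get the conventional A-G
#' aliases). Ladders carry the main-chain paired positions; a beta-bulge is a
#' pairing irregularity where two consecutive residues on one strand sit
#' opposite a single residue on the partner strand, flanked by regular pairs
#' -- in MHC peptide-binding domains this occurs, conserved, at positions
#' p33/p34 of strand S3. The S2-S3 cleft is the truncation of main-chain
#' pairing between strands S2 and S3: pairing that stops at the p24-p36 pair
#' (instead of extending to p22-p38) marks the cleft, which distinguishes the
#' pb domain of pMHC-I and the pa domain of pMHC-II from their partners.
#' @name beta-topology
NULL

IGSF_ALIAS <- c(S1 = "A", S2 = "B", S3 = "C", S4 = "D", S5 = "E", S6 = "F",
                S7 = "G")

#' Build beta-sheet topology
#'
#' @param hbonds result of [compute_backbone_hbonds()].
#' @param ss result of [assign_secondary_structure()] for the same bonds.
#' @param map optional `pmhc_numbering`; enables canonical labels and
#'   per-domain strand naming.
#' @return a `pmhc_beta_topology` list: `ladders` (each with `sense` and a
#'   `rungs` data frame of paired residue keys/canonical ids) and `strands`
#'   (one row per strand run: domain, label, first/last residue). Strand
#'   counts other than 4 per p-domain / 7 per IgSF domain are labelled
#'   best-effort with a warning.
#' @export
build_beta_topology <- function(hbonds, ss, map = NULL) {
  fr <- attr(ss, "frame")
  ladders <- attr(ss, "ladders")
  ladders <- Filter(function(l) nrow(l$rungs) >= 2, ladders)
  lad_out <- lapply(ladders, function(l) {
    rungs <- data.frame(
      res_a = fr$reskey[l$rungs$i], res_b = fr$reskey[l$rungs$j],
      idx_a = l$rungs$i, idx_b = l$rungs$j, stringsAsFactors = FALSE)
    if (!is.null(map)) {
      rungs$canon_a <- map$canon[match(rungs$res_a, map$reskey)]
      rungs$canon_b <- map$canon[match(rungs$res_b, map$reskey)]
    }
    list(sense = l$sense, rungs = rungs)
  })

  e_idx <- which(ss$state == "E")
  strands <- data.frame(first = integer(), last = integer(),
                        first_key = character(), last_key = character(),
                        domain = character(), label = character(),
                        stringsAsFactors = FALSE)
  if (length(e_idx)) {
    brk <- c(TRUE, diff(e_idx) != 1)
    grp <- cumsum(brk)
    strands <- do.call(rbind, lapply(split(e_idx, grp), function(ix)
      data.frame(first = min(ix), last = max(ix))))
    strands$first_key <- fr$reskey[strands$first]
    strands$last_key <- fr$reskey[strands$last]
    strands$domain <- NA_character_
    strands$label <- NA_character_
  }
  if (!is.null(map) && nrow(strands)) {
    strands$domain <- map$domain[match(strands$first_key, map$reskey)]
    strands$canon_first <- map$canon_pos[match(strands$first_key, map$reskey)]
    for (d in unique(stats::na.omit(strands$domain))) {
      ix <- which(strands$domain == d)
      ix <- ix[order(strands$canon_first[ix])]
      expected <- if (d %in% c("pa", "pb")) 4L else 7L
      if (length(ix) != expected)
        warning("domain ", d, ": found ", length(ix), " strands, expected ",
                expected, "; labelling best-effort")
      strands$label[ix] <- paste0("S", seq_along(ix))
      if (d %in% c("ia", "ib"))
        strands$alias[ix] <- unname(IGSF_ALIAS[strands$label[ix]])
    }
  } else if (nrow(strands)) {
    strands$label <- paste0("S", seq_len(nrow(strands)))
  }
  rownames(strands) <- NULL
  structure(list(ladders = lad_out, strands = strands, ss = ss, map = map,
                 hbonds = hbonds),
            class = "pmhc_beta_topology")
}

#' @export
print.pmhc_beta_topology <- function(x, ...) {
  cat("pmhc_beta_topology:", length(x$ladders), "ladder(s),",
      nrow(x$strands), "strand(s)\n")
  if (nrow(x$strands))
    print(x$strands[, intersect(c("domain", "label", "first_key", "last_key"),
                                names(x$strands))])
  invisible(x)
}

#' Detect beta-bulges
#'
#' Scans ladder rungs for the classic bulge signature: consecutive rungs
#' whose residue step is one larger on one strand than on the other (one
#' extra residue squeezed in), i.e. two consecutive residues opposite one
#' partner residue, flanked by regular pairs.
#'
#' @param topology a `pmhc_beta_topology`.
#' @param st the structure (for sidechain direction); optional.
#' @param reference_point optional 3-vector defining "up" (e.g. the mean
#'   helix CA centroid of the same pab domain); when `NULL` and the
#'   structure's own helices cannot orient the sheet normal, the direction is
#'   reported as `NA`.
#' @return data frame, one row per bulge: `res_1`, `res_2` (the bulge pair),
#'   `opposite` (partner-strand residue), canonical ids when a map is
#'   attached, and `sidechain_direction` (`"up"`, `"down"`, `"lateral"` or
#'   `NA`).
#' @export
detect_beta_bulges <- function(topology, st = NULL, reference_point = NULL) {
  fr <- attr(topology$ss, "frame")
  out <- list()
  for (ld in topology$ladders) {
    r <- ld$rungs
    if (nrow(r) < 2) next
    anti <- ld$sense == "antiparallel"
    for (q in seq_len(nrow(r) - 1)) {
      gi <- r$idx_a[q + 1] - r$idx_a[q] - 1
      gj <- if (anti) r$idx_b[q] - r$idx_b[q + 1] - 1 else
        r$idx_b[q + 1] - r$idx_b[q] - 1
      pair <- opp <- NULL
      if (gi == gj + 1 && gi %in% c(1, 2, 3)) {       # extra residue on a
        # for the widest disruption (3 skipped) the bulge pair is the two
        # residues adjacent to the resuming rung
        sh <- if (gi == 3) 2 else 1
        pair <- c(r$idx_a[q] + sh, r$idx_a[q] + sh + 1)
        opp <- if (anti) r$idx_b[q] - sh else r$idx_b[q] + sh
      } else if (gj == gi + 1 && gj %in% c(1, 2, 3)) { # extra residue on b
        sh <- if (gj == 3) 2 else 1
        # on the descending strand the bulge pair is always the two skipped
        # residues highest in sequence, next to the preceding rung
        pair <- if (anti) c(r$idx_b[q] - 2, r$idx_b[q] - 1) else
          c(r$idx_b[q] + sh, r$idx_b[q] + sh + 1)
        opp <- r$idx_a[q] + sh
      }
      if (!is.null(pair)) {
        out[[length(out) + 1]] <- data.frame(
          res_1 = fr$reskey[pair[1]], res_2 = fr$reskey[pair[2]],
          opposite = fr$reskey[opp], sense = ld$sense,
          stringsAsFactors = FALSE)
      }
    }
  }
  bulges <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(res_1 = character(), res_2 = character(),
               opposite = character(), sense = character(),
               stringsAsFactors = FALSE)
  rownames(bulges) <- NULL
  map <- topology$map
  if (!is.null(map) && nrow(bulges)) {
    bulges$canon_1 <- map$canon[match(bulges$res_1, map$reskey)]
    bulges$canon_2 <- map$canon[match(bulges$res_2, map$reskey)]
  }
  if (!is.null(st) && nrow(bulges)) {
    bulges$sidechain_direction <- vapply(seq_len(nrow(bulges)), function(b) {
      sidechain_direction(st, topology, c(bulges$res_1[b], bulges$res_2[b]),
                          reference_point)
    }, character(1))
  }
  bulges
}

# Direction of the mean CB vector of `reskeys` relative to the local sheet
# plane, "up" oriented toward reference_point (or the structure's helix CA
# centroid). Lateral dead-band: |cos| < 0.3.
sidechain_direction <- function(st, topology, reskeys, reference_point) {
  strand_keys <- unique(c(topology$ladders[[1]]$rungs$res_a,
                          unlist(lapply(topology$ladders, function(l)
                            c(l$rungs$res_a, l$rungs$res_b)))))
  ca_sheet <- atom_coords(st, strand_keys, "CA")
  ca_sheet <- ca_sheet[stats::complete.cases(ca_sheet), , drop = FALSE]
  if (nrow(ca_sheet) < 3) return(NA_character_)
  pl <- fit_plane(ca_sheet)
  nrm <- pl$normal
  if (is.null(reference_point)) {
    ssdf <- topology$ss
    helix_keys <- ssdf$reskey[ssdf$state %in% c("H", "G", "I")]
    if (!length(helix_keys)) return(NA_character_)
    hca <- atom_coords(st, helix_keys, "CA")
    reference_point <- colMeans(hca[stats::complete.cases(hca), , drop = FALSE])
  }
  if (sum((reference_point - pl$center) * nrm) < 0) nrm <- -nrm
  ca <- atom_coords(st, reskeys, "CA")
  cb <- atom_coords(st, reskeys, "CB")
  ok <- stats::complete.cases(ca) & stats::complete.cases(cb)
  if (!any(ok)) return(NA_character_)
  v <- colMeans(cb[ok, , drop = FALSE] - ca[ok, , drop = FALSE])
  cosang <- sum(vunit(v) * nrm)
  if (abs(cosang) < 0.3) "lateral" else if (cosang > 0) "up" else "down"
}

#' Detect the S2-S3 cleft of a peptide-binding domain
#'
#' Identifies strands S2 and S3 of the requested p-domain as the strands
#' containing canonical positions 24 and 36, collects the main-chain N-O
#' hydrogen-bonded pairs between them, and reports the outermost pair. The
#' cleft is present exactly when pairing stops at p24-p36; pairing extending
#' to p22-p38 (or beyond p24) means no cleft.
#'
#' @param topology a `pmhc_beta_topology` built with a numbering map.
#' @param domain_class `"pa"` or `"pb"`.
#' @return list with `domain_class`, `last_pair` (canonical positions,
#'   S2 then S3), `cleft_present` (logical; `NA` when S2/S3 cannot be
#'   identified) and `pairs` (all paired positions found).
#' @export
detect_s2s3_cleft <- function(topology, domain_class = c("pb", "pa")) {
  domain_class <- match.arg(domain_class)
  map <- topology$map
  if (is.null(map)) stop("topology was built without a numbering map")
  undetermined <- list(domain_class = domain_class,
                       last_pair = c(NA_integer_, NA_integer_),
                       cleft_present = NA, pairs = NULL)
  str <- topology$strands
  str <- str[!is.na(str$domain) & str$domain == domain_class, , drop = FALSE]
  if (!nrow(str)) return(undetermined)
  fr <- attr(topology$ss, "frame")
  strand_positions <- function(row) {
    keys <- fr$reskey[row$first:row$last]
    map$canon_pos[match(keys, map$reskey)]
  }
  s2 <- s3 <- NULL
  for (k in seq_len(nrow(str))) {
    pos <- strand_positions(str[k, ])
    if (24 %in% pos) s2 <- str[k, ]
    if (36 %in% pos) s3 <- str[k, ]
  }
  if (is.null(s2) || is.null(s3)) return(undetermined)
  keys2 <- fr$reskey[s2$first:s2$last]
  keys3 <- fr$reskey[s3$first:s3$last]
  # facing (bridge) pairs between the two strands, from the ladders
  k2 <- k3 <- character()
  for (ld in topology$ladders) {
    r <- ld$rungs
    in23 <- r$res_a %in% keys2 & r$res_b %in% keys3
    in32 <- r$res_a %in% keys3 & r$res_b %in% keys2
    k2 <- c(k2, r$res_a[in23], r$res_b[in32])
    k3 <- c(k3, r$res_b[in23], r$res_a[in32])
  }
  if (!length(k2)) return(undetermined)
  pairs <- unique(data.frame(
    s2_pos = map$canon_pos[match(k2, map$reskey)],
    s3_pos = map$canon_pos[match(k3, map$reskey)]))
  pairs <- pairs[order(pairs$s2_pos), , drop = FALSE]
  rownames(pairs) <- NULL
  outer <- pairs[pairs$s2_pos == min(pairs$s2_pos), , drop = FALSE]
  last_pair <- c(outer$s2_pos[1], max(outer$s3_pos))
  list(domain_class = domain_class, last_pair = last_pair,
       cleft_present = identical(as.integer(last_pair), c(24L, 36L)),
       pairs = pairs)
}
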