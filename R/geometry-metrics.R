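#' @title Peptide-register geometry and knob-insertion metrics
#' @description
#' Distance and dihedral measurements addressed by canonical residue ids,
#' plus the two composite metrics that discriminate the MHC classes: the
#' peptide-register geometry report (P1-P9 / P2-P9 / P1-P-omega CA spans,
#' bulge height above the end-to-end axis, per-register sidechain
#' orientation relative to the groove floor) and the fractional burial of
#' the beta-2-microglobulin hydrophobic knob (ia56 + ia60 sidechains)
#' against the peptide-binding superdomain. In pMHC-I the 9-mer peptide
#' bulges and its P1 sidechain points up out of the groove while the knob is
#' buried in the pa9 pleat; in pMHC-II the peptide lies extended, P1 points
#' down, and no knob insertion occurs.
#' @name geometry-metrics
NULL

#' Measure a distance between two canonically addressed atoms
#'
#' @param st a [pmhc_structure].
#' @param map its `pmhc_numbering`.
#' @param id_a,id_b canonical ids (`"pa45"`, `"pb90b"`) or peptide registers
#'   (`"P1"`, `"P9"`, `"P-2"`).
#' @param atom atom name (default `"CA"`).
#' @return a list with `id_a`, `id_b`, `atom` and `value` (Angstrom).
#' @export
measure_distance <- function(st, map, id_a, id_b, atom = "CA") {
  ka <- canon_to_reskey(map, id_a)
  kb <- canon_to_reskey(map, id_b)
  xa <- atom_coords(st, ka, atom)[1, ]
  xb <- atom_coords(st, kb, atom)[1, ]
  if (anyNA(xa)) stop("atom ", atom, " missing in residue ", id_a)
  if (anyNA(xb)) stop("atom ", atom, " missing in residue ", id_b)
  list(id_a = id_a, id_b = id_b, atom = atom,
       value = vnorm(xa - xb))
}

#' Measure a dihedral over four atoms
#'
#' Thin wrapper over [dihedral_angle()] taking four coordinate vectors or a
#' 4 x 3 matrix; IUPAC sign convention.
#' @param coords 4 x 3 matrix of atom coordinates.
#' @return angle in degrees, (-180, 180].
#' @export
measure_dihedral <- function(coords) {
  coords <- as.matrix(coords)
  if (!all(dim(coords) == c(4, 3))) stop("need a 4 x 3 coordinate matrix")
  if (anyDuplicated(coords)) stop("dihedral atoms must be distinct")
  dihedral_angle(coords[1, ], coords[2, ], coords[3, ], coords[4, ])
}

#' Backbone phi/psi of one residue
#'
#' @param st a [pmhc_structure].
#' @param reskey residue key (`"A:12"`).
#' @return list with `phi` and `psi` in degrees (`NA` at chain termini).
#' @export
phi_psi <- function(st, reskey) {
  fr <- backbone_frame(st)
  i <- match(reskey, fr$reskey)
  if (is.na(i)) stop("no backbone-complete residue ", reskey)
  N <- attr(fr, "N"); CA <- attr(fr, "CA"); C <- attr(fr, "C")
  phi <- if (i > 1 && fr$continuous[i])
    dihedral_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ]) else NA_real_
  psi <- if (i < nrow(fr) && fr$continuous[i + 1])
    dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ]) else NA_real_
  list(phi = phi, psi = psi)
}

# Groove frame: least-squares plane of the pab strand CAs with the normal
# oriented toward the pab helix CAs (fallback: toward the peptide CAs).
groove_frame <- function(st, map, ss = NULL) {
  doms <- assign_domains(st, map)
  if (is.null(ss)) {
    hb <- suppressWarnings(compute_backbone_hbonds(st))
    ss <- assign_secondary_structure(hb)
  }
  pab <- ss[ss$reskey %in% doms$pab, , drop = FALSE]
  strand_keys <- pab$reskey[pab$state == "E"]
  helix_keys <- pab$reskey[pab$state %in% c("H", "G", "I")]
  if (length(strand_keys) < 3) strand_keys <- doms$pab
  ca <- atom_coords(st, strand_keys, "CA")
  ca <- ca[stats::complete.cases(ca), , drop = FALSE]
  pl <- fit_plane(ca)
  up_ref <- NULL
  if (length(helix_keys) >= 3) {
    hca <- atom_coords(st, helix_keys, "CA")
    up_ref <- colMeans(hca[stats::complete.cases(hca), , drop = FALSE])
  } else if (length(doms$peptide)) {
    pca <- atom_coords(st, doms$peptide, "CA")
    up_ref <- colMeans(pca[stats::complete.cases(pca), , drop = FALSE])
  }
  nrm <- pl$normal
  if (!is.null(up_ref) && sum((up_ref - pl$center) * nrm) < 0) nrm <- -nrm
  list(center = pl$center, up = nrm)
}

#' Peptide-register geometry report
#'
#' @param st a [pmhc_structure].
#' @param map its `pmhc_numbering` with a configured peptide register.
#' @param ss optional precomputed [assign_secondary_structure()] result.
#' @param sasa logical; also report P1/P-omega exposed areas.
#' @return a `pmhc_peptide_geometry` list: `register_distances` (named list,
#'   P1-P9 / P2-P9 / P1-POmega CA spans where measurable), `bulge_height`
#'   (max CA deviation from the P1->P-omega axis, Angstrom), `orientation`
#'   (per register: `"up"`, `"down"`, `"lateral"`; `NA` without CB) and
#'   `terminal_exposure` (A^2, when `sasa = TRUE`).
#' @export
peptide_geometry_report <- function(st, map, ss = NULL, sasa = FALSE) {
  pep <- map[map$domain == "peptide", , drop = FALSE]
  if (nrow(pep) < 2) stop("need at least 2 registered peptide residues")
  pep <- pep[order(pep$register), , drop = FALSE]
  omega <- attr(map, "omega")
  if (is.na(omega)) omega <- max(pep$register)
  reg_id <- function(r) paste0("P", r)
  dist_or_na <- function(a, b) {
    if (all(c(a, b) %in% pep$register))
      measure_distance(st, map, reg_id(a), reg_id(b))$value else NA_real_
  }
  register_distances <- list(
    "P1-P9" = dist_or_na(1, 9),
    "P2-P9" = dist_or_na(2, 9),
    "P1-POmega" = dist_or_na(1, omega))

  core <- pep[pep$register >= 1 & pep$register <= omega, , drop = FALSE]
  ca <- atom_coords(st, core$reskey, "CA")
  ok <- stats::complete.cases(ca)
  bulge_height <- NA_real_
  if (sum(ok) >= 3 && all(c(1, omega) %in% core$register[ok])) {
    p1 <- ca[core$register == 1, ]
    pw <- ca[core$register == omega, ]
    axis <- pw - p1
    if (vnorm(axis) > 1e-6) {
      u <- vunit(axis)
      mid <- core$register > 1 & core$register < omega & ok
      if (any(mid)) {
        devs <- apply(ca[mid, , drop = FALSE], 1, function(p) {
          v <- p - p1
          vnorm(v - sum(v * u) * u)
        })
        bulge_height <- max(devs)
      } else bulge_height <- 0
    }
  }

  gf <- tryCatch(groove_frame(st, map, ss), error = function(e) {
    warning("groove frame unavailable (", conditionMessage(e),
            "); orientations not reported")
    NULL
  })
  cb <- atom_coords(st, pep$reskey, "CB")
  ca_all <- atom_coords(st, pep$reskey, "CA")
  orientation <- rep(NA_character_, nrow(pep))
  if (!is.null(gf)) {
    for (i in seq_len(nrow(pep))) {
      if (anyNA(cb[i, ]) || anyNA(ca_all[i, ])) next
      cosang <- sum(vunit(cb[i, ] - ca_all[i, ]) * gf$up)
      orientation[i] <- if (abs(cosang) < 0.3) "lateral" else
        if (cosang > 0) "up" else "down"
    }
  }
  names(orientation) <- reg_id(pep$register)

  terminal_exposure <- NULL
  if (sasa) {
    all_keys <- unique(st$atoms$reskey[!st$atoms$water])
    s_all <- compute_sasa(st, select = all_keys)
    getexp <- function(r) {
      k <- pep$reskey[pep$register == r]
      if (!length(k)) return(NA_real_)
      sum(s_all$residue$area[s_all$residue$reskey %in% k])
    }
    terminal_exposure <- c(P1 = getexp(1), POmega = getexp(omega))
  }
  structure(list(register_distances = register_distances,
                 bulge_height = bulge_height, orientation = orientation,
                 terminal_exposure = terminal_exposure, omega = omega),
            class = "pmhc_peptide_geometry")
}

#' @export
print.pmhc_peptide_geometry <- function(x, ...) {
  d <- x$register_distances
  cat("peptide geometry: ",
      paste(sprintf("%s = %.1f A", names(d)[!is.na(unlist(d))],
                    unlist(d)[!is.na(unlist(d))]), collapse = ", "),
      "; bulge height ", sprintf("%.2f", x$bulge_height), " A\n", sep = "")
  cat("orientations:", paste(names(x$orientation), x$orientation,
                             sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Knob-insertion score for the ia-domain hydrophobic knob
#'
#' Fractional burial of the knob sidechains (default ia56 + ia60, the
#' beta-2-microglobulin F56/W60 pair in MHC-I) against a target domain
#' selection: 1 - SASA(sidechains, knob residues + target) /
#' SASA(sidechains, knob residues alone). The `inserted` flag compares the
#' score with the threshold; the continuous score is always reported.
#'
#' @param st a [pmhc_structure].
#' @param map its `pmhc_numbering`.
#' @param knob canonical ids of the knob residues.
#' @param target domain selector (default `"pab"`) or residue keys.
#' @param threshold fractional-burial threshold for `inserted` (default 0.6).
#' @param ... passed to [compute_sasa()].
#' @return a `pmhc_knob` list: `fractional_burial`, `inserted`,
#'   `per_residue` (burial per knob residue; `NA` for glycine), `knob`,
#'   `threshold`.
#' @export
knob_insertion <- function(st, map, knob = c("ia56", "ia60"),
                           target = "pab", threshold = 0.6, ...) {
  doms <- assign_domains(st, map)
  target_keys <- if (length(target) == 1 && target %in% names(doms))
    doms[[target]] else target
  knob_keys <- canon_to_reskey(map, knob)
  rtab <- residue_table(st)
  sidechain_sel <- function(at)
    at[!(at$elety %in% c("N", "CA", "C", "O", "OXT")), , drop = FALSE]
  per_res <- numeric(0)
  tot_alone <- tot_complex <- 0
  un <- atoms_of(st, unique(c(knob_keys, target_keys)))
  un <- un[un$element != "H", , drop = FALSE]
  fr <- molecular_frame(as.matrix(un[, c("x", "y", "z")]))
  s_alone <- compute_sasa(st, select = knob_keys, frame = fr, ...)
  s_cplx <- compute_sasa(st, select = unique(c(knob_keys, target_keys)),
                         frame = fr, ...)
  for (i in seq_along(knob_keys)) {
    k <- knob_keys[i]
    resname <- rtab$resname[match(k, rtab$reskey)]
    if (identical(resname, "GLY")) {
      per_res[knob[i]] <- NA_real_
      next
    }
    sc <- sidechain_sel(atoms_of(st, k))$elety
    a_alone <- sum(s_alone$atom$area[s_alone$atom$reskey == k &
                                       s_alone$atom$elety %in% sc])
    a_cplx <- sum(s_cplx$atom$area[s_cplx$atom$reskey == k &
                                     s_cplx$atom$elety %in% sc])
    per_res[knob[i]] <- if (a_alone > 0) 1 - a_cplx / a_alone else NA_real_
    tot_alone <- tot_alone + a_alone
    tot_complex <- tot_complex + a_cplx
  }
  frac <- if (tot_alone > 0) 1 - tot_complex / tot_alone else NA_real_
  structure(list(knob = knob, fractional_burial = frac,
                 inserted = !is.na(frac) && frac >= threshold,
                 per_residue = per_res, threshold = threshold),
            class = "pmhc_knob")
}

#' @export
print.pmhc_knob <- function(x, ...) {
  cat("knob ", paste(x$knob, collapse = "+"), ": fractional burial ",
      sprintf("%.2f", x$fractional_burial), " -> ",
      if (isTRUE(x$inserted)) "inserted" else "not inserted", "\n", sep = "")
  invisible(x)
}
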