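#' @title Contacts, polar contacts, disulfides and solvent accessibility
#' @description
#' Contact residues follow the convention used throughout comparative pMHC
#' work: two residues are in contact when any heavy-atom pair lies within
#' 4.0 Angstrom. Polar contacts are N/O/S heavy-atom pairs within 3.5 A
#' (optionally bridged by waters). Solvent-accessible surface area uses the
#' Shrake-Rupley numerical method (deterministic golden-spiral sphere points,
#' probe 1.4 A) with a Bondi-type element radii table; interface summaries
#' report any-burial interface residues (delta-SASA threshold) and the
#' symmetric buried area 0.5 * (A_alone + B_alone - AB_complex).
#' @name contacts-sasa
NULL

#' Van der Waals radii table (Angstrom, element-keyed, Bondi-type values)
#' @export
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               FE = 1.40, ZN = 1.39, MG = 1.73, CA = 1.74, "NA" = 2.27,
               K = 2.75, MN = 1.40, CU = 1.40)
DEFAULT_RADIUS <- 1.70

atom_radii <- function(elements, radii = VDW_RADII) {
  r <- unname(radii[toupper(elements)])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(elements[unknown]),
                                         collapse = ", "),
            ": default radius ", DEFAULT_RADIUS, " A used")
    r[unknown] <- DEFAULT_RADIUS
  }
  r
}

# squared-distance matrix between two coordinate matrices
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
}

heavy_atoms <- function(at) at[at$element != "H", , drop = FALSE]

#' Residue-residue contacts between two groups at a distance cutoff
#'
#' @param st a [pmhc_structure].
#' @param group_a,group_b disjoint residue-key vectors.
#' @param cutoff heavy-atom distance cutoff, Angstrom (default 4.0).
#' @param map optional numbering map for canonical labels.
#' @return data frame of contact records: `res_a`, `res_b`,
#'   `min_atom_distance`, `n_atom_pairs` (pairs within the cutoff).
#' @export
contact_residues <- function(st, group_a, group_b, cutoff = 4.0, map = NULL) {
  if (length(intersect(group_a, group_b)))
    stop("contact groups overlap: ",
         paste(utils::head(intersect(group_a, group_b), 3), collapse = ", "))
  at_a <- heavy_atoms(atoms_of(st, group_a))
  at_b <- heavy_atoms(atoms_of(st, group_b))
  empty <- data.frame(res_a = character(), res_b = character(),
                      min_atom_distance = numeric(), n_atom_pairs = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(at_a) || !nrow(at_b) || cutoff <= 0) return(empty)
  d2 <- cross_dist2(as.matrix(at_a[, c("x", "y", "z")]),
                    as.matrix(at_b[, c("x", "y", "z")]))
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  key <- paste(at_a$reskey[hit[, 1]], at_b$reskey[hit[, 2]], sep = "\r")
  dmin <- tapply(sqrt(pmax(d2[hit], 0)), key, min)
  npair <- tapply(rep(1L, nrow(hit)), key, length)
  parts <- strsplit(names(dmin), "\r", fixed = TRUE)
  out <- data.frame(res_a = vapply(parts, `[`, "", 1),
                    res_b = vapply(parts, `[`, "", 2),
                    min_atom_distance = as.numeric(dmin),
                    n_atom_pairs = as.integer(npair),
                    stringsAsFactors = FALSE)
  out <- out[order(out$res_a, out$res_b), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(map)) {
    out$canon_a <- map$canon[match(out$res_a, map$reskey)]
    out$canon_b <- map$canon[match(out$res_b, map$reskey)]
  }
  out
}

POLAR_ELEMENTS <- c("N", "O", "S")

#' Polar contacts between two groups
#'
#' N/O/S heavy-atom pairs within the polar cutoff; with
#' `include_waters = TRUE`, water oxygens within the cutoff of both groups
#' are reported as bridging contacts.
#'
#' @inheritParams contact_residues
#' @param cutoff polar-contact distance cutoff, Angstrom (default 3.5).
#' @param include_waters report water-mediated bridges.
#' @return data frame with one row per polar atom pair (`water` column marks
#'   bridge rows; bridging waters appear once per bridged group pair).
#' @export
polar_contacts <- function(st, group_a, group_b, cutoff = 3.5,
                           include_waters = FALSE, map = NULL) {
  pol <- function(keys) {
    at <- atoms_of(st, keys)
    at[at$element %in% POLAR_ELEMENTS, , drop = FALSE]
  }
  at_a <- pol(group_a); at_b <- pol(group_b)
  out <- data.frame(res_a = character(), atom_a = character(),
                    res_b = character(), atom_b = character(),
                    distance = numeric(), water = character(),
                    stringsAsFactors = FALSE)
  if (nrow(at_a) && nrow(at_b)) {
    d2 <- cross_dist2(as.matrix(at_a[, c("x", "y", "z")]),
                      as.matrix(at_b[, c("x", "y", "z")]))
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit))
      out <- data.frame(res_a = at_a$reskey[hit[, 1]],
                        atom_a = at_a$elety[hit[, 1]],
                        res_b = at_b$reskey[hit[, 2]],
                        atom_b = at_b$elety[hit[, 2]],
                        distance = sqrt(pmax(d2[hit], 0)),
                        water = NA_character_, stringsAsFactors = FALSE)
  }
  if (include_waters) {
    wat <- st$atoms[st$atoms$water & st$atoms$elety == "O", , drop = FALSE]
    if (nrow(wat)) {
      dw_a <- cross_dist2(as.matrix(wat[, c("x", "y", "z")]),
                          as.matrix(at_a[, c("x", "y", "z")]))
      dw_b <- cross_dist2(as.matrix(wat[, c("x", "y", "z")]),
                          as.matrix(at_b[, c("x", "y", "z")]))
      bridging <- which(apply(dw_a <= cutoff^2, 1, any) &
                          apply(dw_b <= cutoff^2, 1, any))
      for (w in bridging) {
        ia <- which.min(dw_a[w, ]); ib <- which.min(dw_b[w, ])
        out <- rbind(out, data.frame(
          res_a = at_a$reskey[ia], atom_a = at_a$elety[ia],
          res_b = at_b$reskey[ib], atom_b = at_b$elety[ib],
          distance = NA_real_, water = wat$reskey[w],
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Detect disulfide bridges
#'
#' Cysteine SG-SG pairs within 2.5 Angstrom.
#'
#' @param st a [pmhc_structure].
#' @param map optional numbering map for canonical labels.
#' @return data frame with `res_1`, `res_2`, `distance` (and canonical ids
#'   when a map is given).
#' @export
detect_disulfides <- function(st, map = NULL) {
  sg <- st$atoms[st$atoms$resname == "CYS" & st$atoms$elety == "SG", ,
                 drop = FALSE]
  out <- data.frame(res_1 = character(), res_2 = character(),
                    distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(sg) >= 2) {
    d2 <- cross_dist2(as.matrix(sg[, c("x", "y", "z")]),
                      as.matrix(sg[, c("x", "y", "z")]))
    hit <- which(d2 <= 2.5^2 & upper.tri(d2), arr.ind = TRUE)
    if (nrow(hit))
      out <- data.frame(res_1 = sg$reskey[hit[, 1]],
                        res_2 = sg$reskey[hit[, 2]],
                        distance = sqrt(pmax(d2[hit], 0)),
                        stringsAsFactors = FALSE)
  }
  if (!is.null(map) && nrow(out)) {
    out$canon_1 <- map$canon[match(out$res_1, map$reskey)]
    out$canon_2 <- map$canon[match(out$res_2, map$reskey)]
  }
  out
}

# Molecule-anchored orthonormal frame: principal axes of the coordinate
# cloud with signs fixed by the third moment along each axis (falling back
# to a fixed world rule when the skew vanishes). Sphere test points are
# expressed in this frame so that numerical SASA is exactly invariant under
# rigid transformation of the input.
molecular_frame <- function(xyz) {
  if (nrow(xyz) < 3) return(diag(3))
  cc <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors
  for (k in 1:2) {
    s <- sum((cc %*% ev[, k])^3)
    if (abs(s) > 1e-6) {
      if (s < 0) ev[, k] <- -ev[, k]
    } else {
      big <- which.max(abs(ev[, k]))
      if (ev[big, k] < 0) ev[, k] <- -ev[, k]
    }
  }
  ev[, 3] <- c(ev[2, 1] * ev[3, 2] - ev[3, 1] * ev[2, 2],
               ev[3, 1] * ev[1, 2] - ev[1, 1] * ev[3, 2],
               ev[1, 1] * ev[2, 2] - ev[2, 1] * ev[1, 2])
  ev
}

# Deterministic near-uniform unit-sphere point set (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom accessible area = unoccluded fraction of test points on the
#' solvent-exposed sphere of radius r_vdw + probe, times the sphere area.
#' Waters and hydrogens are excluded from both the evaluated set and the
#' occluders unless requested.
#'
#' @param st a [pmhc_structure].
#' @param select optional residue keys: areas are computed for these atoms
#'   with only these atoms as occluders (i.e. the selection "alone").
#' @param probe probe radius, Angstrom (default 1.4).
#' @param n_points sphere test points per atom (default 960).
#' @param radii element-keyed radii table.
#' @param include_waters include water oxygens as occluders and targets.
#' @param frame optional 3 x 3 orientation for the sphere-point set. By
#'   default the points are expressed in the molecule's own principal-axis
#'   frame so that areas are invariant under rigid transformation; pass a
#'   common frame (see [interface_summary()]) when several selections of the
#'   same structure must cancel exactly.
#' @return a `pmhc_sasa` list: `atom` data frame (reskey, elety, area),
#'   `residue` data frame (reskey, area), `total`, plus the parameters.
#' @export
compute_sasa <- function(st, select = NULL, probe = 1.4, n_points = 960,
                         radii = VDW_RADII, include_waters = FALSE,
                         frame = NULL) {
  at <- st$atoms
  if (!include_waters) at <- at[!at$water, , drop = FALSE]
  at <- heavy_atoms(at)
  if (!is.null(select)) at <- at[at$reskey %in% select, , drop = FALSE]
  if (!nrow(at)) stop("no atoms selected for SASA")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- atom_radii(at$element, radii) + probe
  if (is.null(frame)) frame <- molecular_frame(xyz)
  pts <- sphere_points(n_points) %*% t(frame)
  n <- nrow(at)
  area <- numeric(n)
  d2 <- cross_dist2(xyz, xyz)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * rad[i]^2
      next
    }
    sp <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
    occ <- cross_dist2(sp, xyz[nb, , drop = FALSE])
    occ <- occ < matrix(rad[nb]^2, n_points, length(nb), byrow = TRUE)
    area[i] <- 4 * pi * rad[i]^2 * sum(rowSums(occ) == 0) / n_points
  }
  atom_df <- data.frame(reskey = at$reskey, elety = at$elety, area = area,
                        stringsAsFactors = FALSE)
  res_area <- tapply(area, at$reskey, sum)
  res_df <- data.frame(reskey = names(res_area), area = as.numeric(res_area),
                       stringsAsFactors = FALSE)
  structure(list(atom = atom_df, residue = res_df, total = sum(area),
                 probe = probe, n_points = n_points),
            class = "pmhc_sasa")
}

#' Interface summary between two parts of a structure
#'
#' Computes per-residue delta-SASA (part alone vs in the two-part complex),
#' the symmetric buried area, and the 4.0-A contact records.
#'
#' @param st a [pmhc_structure].
#' @param part_a,part_b disjoint residue-key vectors.
#' @param dsasa_threshold burial threshold for calling a residue an
#'   interface residue, Angstrom^2 (default 0.1: any burial).
#' @param contact_cutoff contact distance, Angstrom.
#' @param map optional numbering map for labels.
#' @param ... passed to [compute_sasa()].
#' @return a `pmhc_interface` list: `buried_area`, `interface_residues_a/b`,
#'   `dsasa_a/b` (per-residue data frames), `contacts`.
#' @export
interface_summary <- function(st, part_a, part_b, dsasa_threshold = 0.1,
                              contact_cutoff = 4.0, map = NULL, ...) {
  if (!length(part_a) || !length(part_b)) stop("empty interface part")
  if (length(intersect(part_a, part_b))) stop("interface parts overlap")
  # one sphere-point frame from the union, so that the three areas cancel
  # exactly when the parts do not touch
  un <- heavy_atoms(atoms_of(st, c(part_a, part_b)))
  fr <- molecular_frame(as.matrix(un[, c("x", "y", "z")]))
  s_a <- compute_sasa(st, select = part_a, frame = fr, ...)
  s_b <- compute_sasa(st, select = part_b, frame = fr, ...)
  s_ab <- compute_sasa(st, select = c(part_a, part_b), frame = fr, ...)
  buried <- 0.5 * (s_a$total + s_b$total - s_ab$total)
  dsasa <- function(alone, part) {
    cx <- s_ab$residue[s_ab$residue$reskey %in% part, , drop = FALSE]
    d <- alone$residue
    d$dsasa <- d$area - cx$area[match(d$reskey, cx$reskey)]
    d
  }
  da <- dsasa(s_a, part_a); db <- dsasa(s_b, part_b)
  if (!is.null(map)) {
    da$canon <- map$canon[match(da$reskey, map$reskey)]
    db$canon <- map$canon[match(db$reskey, map$reskey)]
  }
  contacts <- contact_residues(st, part_a, part_b, cutoff = contact_cutoff,
                               map = map)
  structure(list(
    buried_area = max(buried, 0),
    interface_residues_a = da$reskey[da$dsasa > dsasa_threshold],
    interface_residues_b = db$reskey[db$dsasa > dsasa_threshold],
    dsasa_a = da, dsasa_b = db, contacts = contacts,
    dsasa_threshold = dsasa_threshold),
    class = "pmhc_interface")
}

#' @export
print.pmhc_interface <- function(x, ...) {
  cat("pmhc_interface: buried area ", sprintf("%.1f", x$buried_area),
      " A^2, interface residues ", length(x$interface_residues_a), " + ",
      length(x$interface_residues_b), ", contacts ", nrow(x$contacts),
      "\n", sep = "")
  invisible(x)
}

#' Exposed surface of the peptide ligand within the complex
#'
#' The peptide's accessible surface inside the assembled complex, i.e. its
#' isolated accessible area minus the part buried by the receptor.
#'
#' @param st a [pmhc_structure].
#' @param peptide peptide residue keys.
#' @param ... passed to [compute_sasa()].
#' @return list with `exposed` (A^2), `isolated` (A^2) and `buried`
#'   (isolated - exposed).
#' @export
peptide_exposed_surface <- function(st, peptide, ...) {
  if (!length(peptide)) stop("empty peptide selection")
  all_keys <- unique(st$atoms$reskey[!st$atoms$water])
  un <- heavy_atoms(atoms_of(st, all_keys))
  fr <- molecular_frame(as.matrix(un[, c("x", "y", "z")]))
  s_all <- compute_sasa(st, select = all_keys, frame = fr, ...)
  pep_rows <- s_all$residue$reskey %in% peptide
  exposed <- sum(s_all$residue$area[pep_rows])
  isolated <- compute_sasa(st, select = peptide, frame = fr, ...)$total
  list(exposed = exposed, isolated = isolated, buried = isolated - exposed)
}
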