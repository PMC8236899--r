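#' @title Synthetic structure generators
#' @description
#' Deterministic generators for idealised poly-alanine fixtures with known
#' ground truth: single helices of alpha/3-10/pi geometry, antiparallel
#' beta-sheets with optional engineered two-residue bulges, and toy
#' groove-plus-peptide complexes that caricature the pMHC architecture (a
#' curved strand floor topped by two antiparallel wall helices, with IgSF
#' stand-in domains underneath). The toys are geometric caricatures, not
#' homology models; they exist to give every detector a constructed answer.
#' Bond lengths and angles are standard ideal values.
#' @name synthetic-structures
NULL

# Ideal backbone internal coordinates (Angstrom / degrees).
BB <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
           b_ca_cb = 1.530, a_n_ca_c = 111.2, a_ca_c_n = 116.2,
           a_c_n_ca = 121.7, a_ca_c_o = 120.8, a_c_ca_cb = 109.5,
           t_n_c_ca_cb = -120.0, omega = 180)

HELIX_PHIPSI <- list(alpha = c(-57, -47), g310 = c(-49, -26), pi = c(-57, -70))
HELIX_MINLEN <- c(alpha = 4, g310 = 3, pi = 5)

# Build an n-residue poly-ALA backbone (N, CA, C, O, CB) from phi/psi vectors
# (length n; phi[1] and psi[n] only affect O/CB placement conventions).
# Returns a list of per-residue 5 x 3 coordinate matrices.
build_backbone <- function(n, phi, psi, omega = BB$omega) {
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  res <- vector("list", n)
  # seed first residue in a canonical frame
  N <- c(0, 0, 0)
  CA <- c(BB$b_n_ca, 0, 0)
  C <- place_atom(c(-1, 1, 0), N, CA, BB$b_ca_c, BB$a_n_ca_c, phi[1])
  for (i in seq_len(n)) {
    O <- place_atom(N, CA, C, BB$b_c_o, BB$a_ca_c_o, psi[i] + 180)
    CB <- place_atom(N, C, CA, BB$b_ca_cb, BB$a_c_ca_cb, BB$t_n_c_ca_cb)
    res[[i]] <- rbind(N = N, CA = CA, C = C, O = O, CB = CB)
    if (i < n) {
      N2 <- place_atom(N, CA, C, BB$b_c_n, BB$a_ca_c_n, psi[i])
      CA2 <- place_atom(CA, C, N2, BB$b_n_ca, BB$a_c_n_ca, omega)
      C2 <- place_atom(C, N2, CA2, BB$b_ca_c, BB$a_n_ca_c, phi[i + 1])
      N <- N2; CA <- CA2; C <- C2
    }
  }
  res
}

# Assemble per-residue coordinate blocks into a pmhc_structure atom table.
residues_to_structure <- function(reslist, id, chain = "A", start_resno = 1,
                                  resname = "ALA") {
  rows <- lapply(seq_along(reslist), function(i) {
    m <- reslist[[i]]
    data.frame(chain = chain, resno = start_resno + i - 1, icode = "",
               resname = resname, elety = rownames(m),
               element = substr(rownames(m), 1, 1),
               x = m[, 1], y = m[, 2], z = m[, 3], o = 1,
               het = FALSE, alt = "", stringsAsFactors = FALSE)
  })
  new_structure(id, do.call(rbind, rows))
}

#' Generate an ideal helix fixture
#'
#' Poly-alanine backbone with exact phi/psi for the requested helix kind
#' (alpha -57/-47, 3-10 -49/-26, pi -57/-70) and omega = 180.
#'
#' @param n_residues helix length; must reach the kind's minimum (alpha 4,
#'   3-10 3, pi 5).
#' @param kind `"alpha"`, `"g310"` or `"pi"`.
#' @param phi,psi optional explicit backbone dihedrals (degrees) overriding
#'   the kind defaults.
#' @param chain chain identifier.
#' @return a [pmhc_structure] with attribute `ground_truth` recording the
#'   construction parameters.
#' @export
make_ideal_helix <- function(n_residues, kind = c("alpha", "g310", "pi"),
                             phi = NULL, psi = NULL, chain = "A") {
  kind <- match.arg(kind)
  if (n_residues < HELIX_MINLEN[[kind]])
    stop("helix of kind ", kind, " needs at least ", HELIX_MINLEN[[kind]],
         " residues")
  pp <- HELIX_PHIPSI[[kind]]
  if (is.null(phi)) phi <- pp[1]
  if (is.null(psi)) psi <- pp[2]
  st <- residues_to_structure(build_backbone(n_residues, phi, psi),
                              id = paste0("ideal_", kind, "_helix"),
                              chain = chain)
  attr(st, "ground_truth") <- list(kind = kind, phi = phi, psi = psi,
                                   n = n_residues)
  st
}

# --- beta-sheet machinery -------------------------------------------------

# Ideal antiparallel-strand dihedrals and placement offsets for partner
# strands. The offsets (axial shift, inter-strand spacing, bulge lift) were
# fixed once by minimising the Kabsch-Sander energy of the resulting ladder
# on a reference fixture; they are construction constants, not tunables.
SHEET <- list(phi = -150.3186, psi = 148.3977, dx = 2.498, dy = 4.397,
              lift = 1.5)
BULGE_SHIFT <- c(1.05, 0, 0.7)    # post-bulge segment displacement

# Build a strand template of length L in a canonical frame: strand axis along
# +x, least-squares backbone plane normal along +z, CA centroid at origin.
strand_template <- function(L, phi = SHEET$phi, psi = SHEET$psi) {
  res <- build_backbone(L, phi, psi)
  bb <- do.call(rbind, lapply(res, function(m) m[c("N", "CA", "C"), ]))
  ca <- do.call(rbind, lapply(res, function(m) m["CA", , drop = FALSE]))
  # parity-independent on-axis centre (equals the CA centroid for even L):
  # midpoint of the first two CAs advanced by (L-2)/2 per-residue steps
  ctr <- (ca[1, ] + ca[2, ]) / 2 + (L - 2) / 2 * (ca[3, ] - ca[1, ]) / 2
  xax <- vunit(ca[3, ] - ca[1, ])   # exact 2-residue repeat direction
  # the thin direction of the N/CA/C point cloud is the hydrogen-bond
  # direction within the sheet plane; the pleat is perpendicular to both
  pl <- fit_plane(bb)
  yax <- pl$normal - sum(pl$normal * xax) * xax
  yax <- vunit(yax)
  zax <- vcross(xax, yax)
  Rt <- rbind(xax, yax, zax)        # world -> canonical
  lapply(res, function(m) t(Rt %*% (t(m) - ctr)))
}

rot_z180 <- function(m) {
  m[, 1] <- -m[, 1]; m[, 2] <- -m[, 2]
  m
}

shift_block <- function(m, v) sweep(m, 2, v, `+`)

#' Generate an antiparallel beta-sheet fixture
#'
#' Strands are exact translates/rotates of a flat-strand template whose
#' phi/psi were solved so that the two-residue screw repeat is a pure
#' translation and the NH/CO vectors lie in the sheet plane; neighbouring
#' strands are related by a two-fold rotation about the sheet normal, giving
#' clean Kabsch-Sander ladders. With `bulge_at = c(strand, pos)`, residue
#' `pos` of that strand is lifted out of the sheet plane between two template
#' slots and the downstream residues shift back by one slot, creating a
#' classic beta-bulge: residues `pos` and `pos + 1` sit opposite a single
#' partner-strand residue, flanked by regular pairs.
#'
#' @param n_strands number of strands (>= 1).
#' @param strand_length residues per strand (>= 3; >= 5 when bulged).
#' @param bulge_at `NULL` or `c(strand_index, position)` with position in
#'   `5..strand_length - 3` (both flanking regular pairs must be detectable
#'   rungs, which excludes near-terminal positions).
#' @param chain chain id; strands share the chain, with author numbering
#'   gaps of 100 between strands (strand k starts at residue (k-1)*100 + 1).
#' @return a [pmhc_structure]; `attr(, "ground_truth")` records strand
#'   residue ranges and the planted bulge pair, if any.
#' @export
make_beta_sheet <- function(n_strands = 2, strand_length = 6,
                            bulge_at = NULL, chain = "A") {
  L <- strand_length
  if (L < 3) stop("strand_length must be at least 3")
  if (n_strands < 1) stop("need at least one strand")
  if (!is.null(bulge_at)) {
    if (length(bulge_at) != 2) stop("bulge_at must be c(strand, position)")
    if (bulge_at[1] < 1 || bulge_at[1] > n_strands)
      stop("bulge_at strand index out of range")
    if (L < 8 || bulge_at[2] < 5 || bulge_at[2] > L - 3)
      stop("bulge position must lie in the strand interior (5..L-3, L >= 8):",
           " the flanking regular pairs must themselves be detectable")
  }
  tmpl <- strand_template(L)
  # antiparallel registration: narrow pairs need residue-index sums of even
  # parity, so odd-length strands take an extra half-repeat axial shift
  xstep <- vnorm(tmpl[[3]]["CA", ] - tmpl[[1]]["CA", ]) / 2
  dx_eff <- SHEET$dx + if (L %% 2 == 1) xstep else 0
  blocks <- list()
  resnos <- integer()
  for (k in seq_len(n_strands)) {
    orient <- if (k %% 2 == 1) identity else rot_z180
    off <- c(if (k %% 2 == 1) 0 else dx_eff, (k - 1) * SHEET$dy, 0)
    bulge_here <- !is.null(bulge_at) && bulge_at[1] == k
    if (!bulge_here) {
      sl <- lapply(tmpl, function(m) shift_block(orient(m), off))
    } else {
      pos <- bulge_at[2]
      sl <- vector("list", L)
      for (r in seq_len(L)) {
        slot <- if (r < pos) r else if (r == pos) NA else r - 1
        if (is.na(slot)) {
          mid <- (tmpl[[pos - 1]] + tmpl[[pos]]) / 2
          sl[[r]] <- shift_block(orient(shift_block(mid, c(0, 0, SHEET$lift))),
                                 off)
        } else {
          # residues past the bulge slide along the strand axis (so the
          # chain does not collapse onto the vacated peptide bond) and lift
          # slightly out of plane (clearing the partner-strand sidechains)
          sh <- if (r > pos) BULGE_SHIFT else c(0, 0, 0)
          sl[[r]] <- shift_block(orient(shift_block(tmpl[[slot]], sh)), off)
        }
      }
    }
    blocks <- c(blocks, sl)
    resnos <- c(resnos, (k - 1) * 100 + seq_len(L))
  }
  st <- residues_to_structure(blocks, "beta_sheet", chain = chain)
  st$atoms$resno <- as.integer(resnos[match(st$atoms$resno,
                                            seq_along(blocks))])
  st$atoms$reskey <- residue_key(st$atoms$chain, st$atoms$resno,
                                 st$atoms$icode)
  gt <- list(n_strands = n_strands, strand_length = L,
             strand_ranges = lapply(seq_len(n_strands), function(k)
               c((k - 1) * 100 + 1, (k - 1) * 100 + L)))
  if (!is.null(bulge_at)) {
    b_res <- (bulge_at[1] - 1) * 100 + bulge_at[2]
    gt$bulge <- list(strand = bulge_at[1],
                     pair_resno = c(b_res, b_res + 1),
                     pair_key = residue_key(chain, c(b_res, b_res + 1),
                                            c("", "")))
  }
  attr(st, "ground_truth") <- gt
  st
}

# --- toy pMHC complex -----------------------------------------------------

# Rodrigues rotation taking unit vector u onto unit vector v.
rotation_between <- function(u, v) {
  u <- vunit(u); v <- vunit(v)
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees about any axis perpendicular to u
    a <- vunit(vcross(u, if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    return(2 * outer(a, a) - diag(3))
  }
  k <- vcross(u, v)
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3,
              byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

# Build a helix block of n residues with its axis along `axis`, CA centroid
# at `center`.
helix_block <- function(n, axis, center, kind = "alpha") {
  res <- build_backbone(n, HELIX_PHIPSI[[kind]][1], HELIX_PHIPSI[[kind]][2])
  ca <- t(sapply(res, function(m) m["CA", ]))
  u <- ca[n, ] - ca[1, ]
  R <- rotation_between(u, axis)
  ctr <- colMeans(ca)
  lapply(res, function(m)
    sweep((m - matrix(ctr, nrow(m), 3, byrow = TRUE)) %*% t(R), 2, center,
          `+`))
}

# Independent brute-force residue contact scan used to freeze ground truth
# at build time (plain nested loop over residue pairs).
brute_contact_scan <- function(atoms, keys_a, keys_b, cutoff = 4.0) {
  heavy <- atoms[atoms$element != "H", , drop = FALSE]
  res <- list()
  for (ka in unique(keys_a)) {
    xa <- as.matrix(heavy[heavy$reskey == ka, c("x", "y", "z")])
    if (!nrow(xa)) next
    for (kb in unique(keys_b)) {
      xb <- as.matrix(heavy[heavy$reskey == kb, c("x", "y", "z")])
      if (!nrow(xb)) next
      dmin <- Inf
      for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
        d <- sqrt(sum((xa[i, ] - xb[j, ])^2))
        if (d < dmin) dmin <- d
      }
      if (dmin <= cutoff)
        res[[length(res) + 1]] <- data.frame(res_a = ka, res_b = kb,
                                             min_atom_distance = dmin,
                                             stringsAsFactors = FALSE)
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(res_a = character(), res_b = character(),
               min_atom_distance = numeric(), stringsAsFactors = FALSE)
}

#' Generate a toy peptide-MHC-like complex with known ground truth
#'
#' A geometric caricature of the pMHC architecture: an 8-strand antiparallel
#' floor (two 4-strand halves = pa and pb), two alpha-helical walls above the
#' floor (one per half), a peptide lying in the groove between the walls,
#' and two small helical stand-ins for the IgSF (ia, ib) domains underneath.
#' The class II variant uses shorter walls and a 13-mer peptide whose ends
#' (P-2/P-1 and P10/P11) extend beyond the walls, with all core sidechains
#' alternating and P1/P9 pointing down; the class I variant uses longer
#' walls enclosing a 9-mer whose midsection is lifted (bulge) and whose P1
#' residue is rotated so its sidechain points up. The `ib_hinge_angle`
#' rotates the ib stand-in about the wall axis through its attachment point;
#' the programmed centroid displacement is stored as ground truth.
#'
#' @param class_type `"I"` or `"II"`.
#' @param peptide_length default 9 (class I) or 13 (class II).
#' @param ib_hinge_angle degrees; default 0.
#' @param bulge_height class I peptide lift in Angstrom (default 2).
#' @return list with `structure` ([pmhc_structure]), `map`
#'   (`pmhc_numbering`), `config` (the numbering config used) and
#'   `ground_truth` (peptide-pab contact list from an independent
#'   brute-force scan, wall/floor layout, hinge data).
#' @export
make_toy_pmhc <- function(class_type = c("II", "I"), peptide_length = NULL,
                          ib_hinge_angle = 0, bulge_height = 2.0) {
  class_type <- match.arg(class_type)
  L <- 10                                  # floor strand length
  wall_n <- if (class_type == "I") 22 else 18
  if (is.null(peptide_length))
    peptide_length <- if (class_type == "I") 9 else 13
  tmpl <- strand_template(L)
  blocks <- list(); meta <- list()
  add <- function(bl, chain, resno, domain, canon) {
    for (i in seq_along(bl)) {
      blocks[[length(blocks) + 1]] <<- bl[[i]]
      meta[[length(meta) + 1]] <<- data.frame(
        chain = chain, resno = resno[i], domain = domain,
        canon = canon[i], stringsAsFactors = FALSE)
    }
  }
  chains <- if (class_type == "I")
    list(pa = "A", pb = "A", ia = "B", ib = "A", pep = "C") else
    list(pa = "A", pb = "B", ia = "A", ib = "B", pep = "C")

  # floor: strands 1..4 = pa (canon 1..40), 5..8 = pb (canon 1..40)
  for (k in 1:8) {
    orient <- if (k %% 2 == 1) identity else rot_z180
    off <- c(if (k %% 2 == 1) 0 else SHEET$dx, (k - 1) * SHEET$dy, 0)
    sl <- lapply(tmpl, function(m) shift_block(orient(m), off))
    dom <- if (k <= 4) "pa" else "pb"
    k_in <- if (k <= 4) k else k - 4
    base <- if (dom == "pa") 0 else 100
    add(sl, chains[[dom]], base + (k_in - 1) * 10 + seq_len(L), dom,
        (k_in - 1) * 10 + seq_len(L))
  }
  y_pa <- mean(c(0, 3 * SHEET$dy))          # centre of the pa half
  y_pb <- mean(c(4, 7) * SHEET$dy)
  y_mid <- mean(c(y_pa, y_pb))

  # walls: one helix per half, axis along x, above the floor
  wall_z <- 9; wall_dy <- 6.6
  add(helix_block(wall_n, c(1, 0, 0), c(0, y_mid - wall_dy, wall_z)),
      chains$pa, 45 + seq_len(wall_n), "pa", 45 + seq_len(wall_n))
  add(helix_block(wall_n, c(-1, 0, 0), c(0, y_mid + wall_dy, wall_z)),
      chains$pb, 100 + 45 + seq_len(wall_n), "pb", 45 + seq_len(wall_n))

  # peptide: extended strand in the groove, sidechains vertical
  pep <- build_backbone(peptide_length, SHEET$phi, SHEET$psi)
  ca <- t(sapply(pep, function(m) m["CA", ]))
  Rax <- rotation_between(ca[min(3, peptide_length), ] - ca[1, ], c(1, 0, 0))
  ctr <- colMeans(ca)
  pep <- lapply(pep, function(m)
    (m - matrix(ctr, nrow(m), 3, byrow = TRUE)) %*% t(Rax))
  # rotate about x so CB vectors lie along +-z; choose the sign that points
  # odd-register sidechains down
  cb1 <- pep[[1]]["CB", ] - pep[[1]]["CA", ]
  th <- atan2(cb1[2], cb1[3])   # current angle of CB in the (z, y) plane
  Rx <- matrix(c(1, 0, 0,
                 0, cos(th), -sin(th),
                 0, sin(th), cos(th)), 3, byrow = TRUE)
  pep <- lapply(pep, function(m) m %*% Rx)
  if ((pep[[1]]["CB", 3] - pep[[1]]["CA", 3]) > 0)
    pep <- lapply(pep, function(m) m %*% diag(c(1, -1, -1)))
  p1_index <- if (class_type == "I") 1 else 3
  if (class_type == "I") {
    # lift the midsection (bulge) and flip P1 so its sidechain points up
    n <- peptide_length
    for (i in seq_len(n)) {
      lift <- bulge_height * sin(pi * (i - 1) / (n - 1))^2
      pep[[i]][, 3] <- pep[[i]][, 3] + lift
    }
    caP1 <- pep[[1]]["CA", ]
    flip <- diag(c(1, -1, -1))               # 180 about x through CA(P1)
    pep[[1]] <- sweep(sweep(pep[[1]], 2, caP1) %*% flip, 2, caP1, `+`)
  }
  pep_z <- 6.0
  pep <- lapply(pep, function(m) shift_block(m, c(0, y_mid, pep_z)))
  add(pep, chains$pep, seq_len(peptide_length), "peptide",
      paste0("P", seq_len(peptide_length) - p1_index + 1))

  # IgSF stand-ins: helices under each half; ib hinged about the x axis
  ia_c <- c(0, y_pa, -8)
  add(helix_block(12, c(1, 0, 0), ia_c), chains$ia, 200 + seq_len(12),
      "ia", seq_len(12))
  hinge_pt <- c(0, y_pb, -2)
  th2 <- deg2rad(ib_hinge_angle)
  Rh <- matrix(c(1, 0, 0,
                 0, cos(th2), -sin(th2),
                 0, sin(th2), cos(th2)), 3, byrow = TRUE)
  ib_c0 <- c(0, y_pb, -8)
  ib_bl <- helix_block(12, c(1, 0, 0), ib_c0)
  ib_bl <- lapply(ib_bl, function(m)
    sweep(sweep(m, 2, hinge_pt) %*% t(Rh), 2, hinge_pt, `+`))
  add(ib_bl, chains$ib, 300 + seq_len(12), "ib", seq_len(12))

  meta <- do.call(rbind, meta)
  rows <- lapply(seq_along(blocks), function(i) {
    m <- blocks[[i]]
    data.frame(chain = meta$chain[i], resno = meta$resno[i], icode = "",
               resname = "ALA", elety = rownames(m),
               element = substr(rownames(m), 1, 1),
               x = m[, 1], y = m[, 2], z = m[, 3], o = 1, het = FALSE,
               alt = "", stringsAsFactors = FALSE)
  })
  st <- new_structure(paste0("toy_pmhc_", class_type), do.call(rbind, rows))

  config <- list(
    accession = st$id,
    class_label = paste0("MHC-", class_type),
    domains = list(
      pa = list(chain = chains$pa, ranges = list(
        list(start = 1, end = 40, canon_start = 1),
        list(start = 46, end = 45 + wall_n, canon_start = 46))),
      pb = list(chain = chains$pb, ranges = list(
        list(start = 101, end = 140, canon_start = 1),
        list(start = 146, end = 145 + wall_n, canon_start = 46))),
      ia = list(chain = chains$ia, start = 201, end = 212, canon_start = 1),
      ib = list(chain = chains$ib, start = 301, end = 312, canon_start = 1)),
    peptide = list(chain = chains$pep, p1 = p1_index,
                   omega = p1_index + 8))
  map <- suppressMessages(build_numbering_map(st, config))

  pep_keys <- residue_key(chains$pep, seq_len(peptide_length), "")
  pab_keys <- map$reskey[map$domain %in% c("pa", "pb")]
  gt_contacts <- brute_contact_scan(st$atoms, pep_keys, pab_keys)
  # programmed hinge displacement of the ib centroid
  disp <- vnorm(as.vector((Rh - diag(3)) %*% (ib_c0 - hinge_pt)))
  list(structure = st, map = map, config = config,
       ground_truth = list(
         peptide_pab_contacts = gt_contacts,
         p1_index = p1_index, wall_half_span = wall_n * 1.5 / 2,
         hinge = list(angle = ib_hinge_angle, point = hinge_pt,
                      centroid0 = ib_c0, displacement = disp)))
}
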