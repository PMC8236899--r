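test_that("distance measurement: self-distance zero, symmetric, triangle
           inequality over canonical ids", {
  toy <- make_toy_pmhc("II")
  st <- toy$structure; map <- toy$map
  expect_equal(measure_distance(st, map, "pa1", "pa1")$value, 0)
  d_ab <- measure_distance(st, map, "pa1", "pb5")$value
  expect_equal(measure_distance(st, map, "pb5", "pa1")$value, d_ab)
  d_bc <- measure_distance(st, map, "pb5", "P1")$value
  d_ac <- measure_distance(st, map, "pa1", "P1")$value
  expect_lte(d_ac, d_ab + d_bc + 1e-9)
})

test_that("toy peptide P1-P9 span equals the generator's analytic value", {
  toy <- make_toy_pmhc("II")
  st <- toy$structure; map <- toy$map
  # the extended peptide is a rigidly placed flat-strand template: its
  # P1-P9 CA span equals the span of the template CA coordinates
  tmpl <- pmhcstruct:::strand_template(13)
  ca <- t(sapply(tmpl, function(m) m["CA", ]))
  expected <- sqrt(sum((ca[11, ] - ca[3, ])^2))   # registers P1=res3, P9=res11
  got <- measure_distance(st, map, "P1", "P9")$value
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("dihedrals: planar cases, generator recovery and a dual-formula
           oracle agree", {
  # planar cis = 0, trans = 180
  expect_equal(measure_dihedral(rbind(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0),
                                      c(3, 1, 0))), 0)
  expect_equal(abs(measure_dihedral(rbind(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0),
                                          c(3, -1, 0)))), 180)
  # interior phi/psi of the ideal helix recover the construction parameters
  h <- make_ideal_helix(10, "alpha")
  pp <- phi_psi(h, "A:5")
  expect_equal(pp$phi, -57, tolerance = 1e-3)
  expect_equal(pp$psi, -47, tolerance = 1e-3)
  # independent formula: acos magnitude + sign from the triple product
  dihedral_oracle <- function(a, b, c, d) {
    n1 <- pmhcstruct:::vcross(b - a, c - b)
    n2 <- pmhcstruct:::vcross(c - b, d - c)
    ang <- acos(max(-1, min(1, sum(n1 * n2) /
                              sqrt(sum(n1^2) * sum(n2^2))))) * 180 / pi
    s <- -sign(sum(pmhcstruct:::vcross(n1, n2) * (c - b)))
    if (s == 0) s <- 1
    ang * s
  }
  set.seed(40)
  for (k in 1:50) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    mine <- tryCatch(measure_dihedral(p), error = function(e) NA)
    if (is.na(mine)) next
    expect_equal(mine, dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-8)
  }
  expect_error(measure_dihedral(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                      c(3, 1, 0))), "collinear")
})

test_that("bulge height: zero for collinear CAs, exact for one displaced CA", {
  # straight synthetic peptide: CAs on a line
  ca <- cbind(seq(0, 30, length.out = 9), 0, 0)
  mk_pep <- function(ca) {
    at <- do.call(rbind, lapply(seq_len(nrow(ca)), function(i)
      data.frame(chain = "C", resno = i, icode = "", resname = "GLY",
                 elety = "CA", element = "C", x = ca[i, 1], y = ca[i, 2],
                 z = ca[i, 3], o = 1, het = FALSE, alt = "",
                 stringsAsFactors = FALSE)))
    st <- pmhcstruct:::new_structure("pep", at)
    cfg <- list(domains = list(pa = list(chain = "Z", start = 1, end = 1)),
                peptide = list(chain = "C", p1 = 1, omega = 9))
    map <- suppressMessages(build_numbering_map(st, cfg))
    list(st = st, map = map)
  }
  straight <- mk_pep(ca)
  # no pab residues -> groove frame unavailable; orientation NA but the
  # distances and bulge height still computed
  rep1 <- suppressWarnings(peptide_geometry_report(straight$st, straight$map))
  expect_equal(rep1$bulge_height, 0, tolerance = 1e-9)
  ca2 <- ca; ca2[5, 3] <- 2.0
  rep2 <- suppressWarnings(peptide_geometry_report(mk_pep(ca2)$st,
                                                   mk_pep(ca2)$map))
  expect_equal(rep2$bulge_height, 2.0, tolerance = 1e-9)
})

test_that("class-specific peptide geometry: class I bulges with P1 up / P9
           down, class II lies extended with P1 and P9 down", {
  tI <- make_toy_pmhc("I")
  tII <- make_toy_pmhc("II")
  gI <- peptide_geometry_report(tI$structure, tI$map)
  gII <- peptide_geometry_report(tII$structure, tII$map)
  expect_identical(unname(gI$orientation["P1"]), "up")
  expect_identical(unname(gI$orientation["P9"]), "down")
  expect_identical(unname(gII$orientation["P1"]), "down")
  expect_identical(unname(gII$orientation["P9"]), "down")
  expect_gt(gI$bulge_height, gII$bulge_height + 1.0)
  # class II registers extend beyond the wall span on both sides
  wall <- tII$ground_truth$wall_half_span
  pep_x <- pmhcstruct:::atom_coords(
    tII$structure, pmhcstruct:::canon_to_reskey(tII$map, c("P-2", "P11")),
    "CA")[, 1]
  expect_true(all(abs(pep_x) > wall))
})

test_that("geometry metrics are invariant under rigid transforms", {
  toy <- make_toy_pmhc("I")
  base <- peptide_geometry_report(toy$structure, toy$map)
  set.seed(41)
  for (k in 1:3) {
    moved <- random_transform_structure(toy$structure)
    g <- peptide_geometry_report(moved, toy$map)
    expect_equal(g$register_distances$`P1-P9`,
                 base$register_distances$`P1-P9`, tolerance = 1e-9)
    expect_equal(g$bulge_height, base$bulge_height, tolerance = 1e-9)
    expect_identical(g$orientation, base$orientation)
  }
})

# A compact knob fixture: two large synthetic sidechains over a sheet
# cavity; the "sidechain" is a short arm of pseudo-atoms on poly-ALA.
make_knob_fixture <- function(gap = 0) {
  sheet <- make_beta_sheet(4, 8)
  at <- sheet$atoms
  at$chain <- "A"
  at$reskey <- pmhcstruct:::residue_key(at$chain, at$resno, at$icode)
  # knob residues: two residues whose CB arms point down into the sheet
  arm <- function(resno, x0, y0) {
    z <- c(6, 4.7, 3.4) + gap
    data.frame(chain = "B", resno = resno, icode = "", resname = "PHE",
               elety = c("N", "CA", "C", "O", "CB", "CG", "CD1"),
               element = c("N", "C", "C", "O", "C", "C", "C"),
               x = x0, y = y0,
               z = c(8 + gap, 7.5 + gap, 8 + gap, 9 + gap, z),
               o = 1, het = FALSE, alt = "", stringsAsFactors = FALSE)
  }
  arms <- rbind(arm(56, 0, 4.4), arm(60, 3.5, 8.8))
  at2 <- rbind(at[, names(arms)], arms)
  st <- pmhcstruct:::new_structure("knob_fixture", at2)
  cfg <- list(domains = list(
    pa = list(chain = "A", ranges = list(
      list(start = 1, end = 8, canon_start = 1),
      list(start = 101, end = 108, canon_start = 11),
      list(start = 201, end = 208, canon_start = 21),
      list(start = 301, end = 308, canon_start = 31))),
    ia = list(chain = "B", start = 56, end = 60, canon_start = 56)))
  map <- suppressMessages(build_numbering_map(st, cfg))
  list(st = st, map = map)
}

test_that("knob burial equals a direct isolated-vs-complex SASA ratio and
           the inserted flag follows the threshold", {
  kf <- make_knob_fixture()
  res <- knob_insertion(kf$st, kf$map, knob = c("ia56", "ia60"),
                        target = "pa", n_points = 480)
  # direct recomputation
  keys <- pmhcstruct:::canon_to_reskey(kf$map, c("ia56", "ia60"))
  target <- kf$map$reskey[kf$map$domain == "pa"]
  sc <- c("CB", "CG", "CD1")
  un <- pmhcstruct:::atoms_of(kf$st, c(keys, target))
  fr <- pmhcstruct:::molecular_frame(as.matrix(un[, c("x", "y", "z")]))
  alone <- compute_sasa(kf$st, select = keys, n_points = 480, frame = fr)
  cplx <- compute_sasa(kf$st, select = c(keys, target), n_points = 480,
                       frame = fr)
  a0 <- sum(alone$atom$area[alone$atom$reskey %in% keys &
                              alone$atom$elety %in% sc])
  a1 <- sum(cplx$atom$area[cplx$atom$reskey %in% keys &
                             cplx$atom$elety %in% sc])
  expect_equal(res$fractional_burial, 1 - a1 / a0, tolerance = 1e-9)
  expect_gt(res$fractional_burial, 0)
})

test_that("knob burial is zero when the ia domain is far away and decreases
           monotonically along a retraction sweep", {
  far <- make_knob_fixture(gap = 50)
  res_far <- knob_insertion(far$st, far$map, knob = c("ia56", "ia60"),
                            target = "pa", n_points = 480)
  expect_equal(res_far$fractional_burial, 0, tolerance = 1e-6)
  expect_false(res_far$inserted)
  burials <- vapply(c(0, 2, 5, 10, 25), function(g) {
    kf <- make_knob_fixture(gap = g)
    knob_insertion(kf$st, kf$map, knob = c("ia56", "ia60"),
                   target = "pa", n_points = 480)$fractional_burial
  }, numeric(1))
  expect_true(all(diff(burials) <= 1e-9))
})

test_that("glycine knob positions are reported as undefined", {
  kf <- make_knob_fixture()
  at <- kf$st$atoms
  at$resname[at$chain == "B" & at$resno == 56] <- "GLY"
  st <- pmhcstruct:::new_structure("glyknob", at)
  res <- knob_insertion(st, kf$map, knob = c("ia56", "ia60"),
                        target = "pa", n_points = 480)
  expect_true(is.na(res$per_residue[["ia56"]]))
  expect_false(is.na(res$per_residue[["ia60"]]))
})
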