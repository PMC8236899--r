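test_that("the 4.0-A cutoff is sharp", {
  xyz <- matrix(c(0, 0, 0, 3.9, 0, 0), 2, 3, byrow = TRUE)
  st <- point_structure(xyz)
  expect_equal(nrow(contact_residues(st, "A:1", "A:2")), 1)
  xyz[2, 1] <- 4.1
  st2 <- point_structure(xyz)
  expect_equal(nrow(contact_residues(st2, "A:1", "A:2")), 0)
  expect_equal(nrow(contact_residues(st, "A:1", "A:2", cutoff = 0)), 0)
  expect_error(contact_residues(st, "A:1", "A:1"), "overlap")
})

test_that("contacts equal a brute-force atom-pair scan on random fixtures", {
  set.seed(20)
  for (k in 1:12) {
    n_a <- sample(3:6, 1); n_b <- sample(3:6, 1)
    xyz <- matrix(rnorm((n_a + n_b) * 3, sd = 4), ncol = 3)
    st <- point_structure(xyz)
    keys <- pmhcstruct:::residue_table(st)$reskey
    ka <- keys[1:n_a]; kb <- keys[(n_a + 1):(n_a + n_b)]
    fast <- contact_residues(st, ka, kb)
    slow <- pmhcstruct:::brute_contact_scan(st$atoms, ka, kb)
    key_f <- paste(fast$res_a, fast$res_b)
    key_s <- paste(slow$res_a, slow$res_b)
    expect_setequal(key_f, key_s)
    expect_equal(fast$min_atom_distance[order(key_f)],
                 slow$min_atom_distance[order(key_s)], tolerance = 1e-9)
  }
})

test_that("contact sets grow monotonically with the cutoff", {
  toy <- make_toy_pmhc("II")
  doms <- assign_domains(toy$structure, toy$map)
  prev <- character()
  for (cutoff in seq(3.0, 5.0, by = 0.5)) {
    cc <- contact_residues(toy$structure, doms$peptide, doms$pab, cutoff)
    cur <- paste(cc$res_a, cc$res_b)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("polar contacts require polar elements and respect the cutoff", {
  xyz <- matrix(c(0, 0, 0, 2.9, 0, 0), 2, 3, byrow = TRUE)
  polar <- point_structure(xyz, elem = c("O", "N"), elety = c("O", "N"))
  expect_equal(nrow(polar_contacts(polar, "A:1", "A:2")), 1)
  apolar <- point_structure(xyz, elem = "C", elety = "CB")
  expect_equal(nrow(polar_contacts(apolar, "A:1", "A:2")), 0)
})

test_that("a placed water bridges two groups", {
  at <- data.frame(
    chain = c("A", "B", "W"), resno = c(1, 1, 1), icode = "",
    resname = c("SER", "THR", "HOH"), elety = c("OG", "OG1", "O"),
    element = "O",
    x = c(0, 5.2, 2.6), y = 0, z = 0, o = 1,
    het = c(FALSE, FALSE, TRUE), alt = "", stringsAsFactors = FALSE)
  st <- pmhcstruct:::new_structure("wb", at)
  dry <- polar_contacts(st, "A:1", "B:1", include_waters = FALSE)
  expect_equal(nrow(dry), 0)
  wet <- polar_contacts(st, "A:1", "B:1", include_waters = TRUE)
  expect_equal(nrow(wet), 1)
  expect_equal(wet$water, "W:1")
})

test_that("polar contacts are a subset of 4.0-A contacts on fixtures", {
  # inter-strand backbone N...O pairs of a sheet sit well within 3.5 A
  st <- make_beta_sheet(2, 8)
  keys <- pmhcstruct:::residue_table(st)$reskey
  pc <- polar_contacts(st, keys[1:8], keys[9:16])
  cc <- contact_residues(st, keys[1:8], keys[9:16])
  expect_gt(nrow(pc), 0)
  expect_true(all(paste(pc$res_a, pc$res_b) %in%
                    paste(cc$res_a, cc$res_b)))
})

test_that("disulfides are called at canonical S-S distance only", {
  mk_cys <- function(d) {
    at <- data.frame(chain = "A", resno = c(1, 2), icode = "",
                     resname = "CYS", elety = "SG", element = "S",
                     x = c(0, d), y = 0, z = 0, o = 1, het = FALSE,
                     alt = "", stringsAsFactors = FALSE)
    pmhcstruct:::new_structure("ss", at)
  }
  expect_equal(nrow(detect_disulfides(mk_cys(2.05))), 1)
  expect_equal(nrow(detect_disulfides(mk_cys(4.0))), 0)
})

test_that("isolated-atom SASA equals the closed-form sphere area", {
  st <- point_structure(matrix(0, 1, 3))
  s <- compute_sasa(st)
  exact <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(s$total, exact, tolerance = 0.005)
  # and exactly, since no point is occluded
  expect_equal(s$total, exact, tolerance = 1e-12)
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  d <- 3.0; r <- 1.7 + 1.4
  st <- point_structure(matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE))
  s <- compute_sasa(st, n_points = 960)
  h <- r - d / 2
  exact <- 2 * (4 * pi * r^2 - 2 * pi * r * h)
  expect_equal(s$total, exact, tolerance = 0.01)
})

test_that("a fully caged atom has zero accessible area", {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  cage <- g / sqrt(rowSums(g^2)) * 2.0
  st <- point_structure(rbind(c(0, 0, 0), cage))
  s <- compute_sasa(st)
  expect_equal(s$atom$area[s$atom$reskey == "A:1"], 0)
})

test_that("SASA converges between 960 and 4000 sphere points", {
  st <- make_beta_sheet(2, 6)
  a1 <- compute_sasa(st, n_points = 960)$total
  a2 <- compute_sasa(st, n_points = 4000)$total
  expect_lt(abs(a1 - a2) / a2, 0.02)
})

test_that("per-residue areas sum the per-atom areas; unknown elements warn", {
  st <- make_beta_sheet(2, 6)
  s <- compute_sasa(st)
  agg <- tapply(s$atom$area, s$atom$reskey, sum)
  expect_equal(as.numeric(agg[s$residue$reskey]), s$residue$area)
  odd <- point_structure(matrix(0, 1, 3), elem = "XX", elety = "XX")
  expect_warning(compute_sasa(odd), "unknown element")
})

test_that("interface summary: separated parts bury nothing; interface
           residues equal a brute-force per-residue delta-SASA scan", {
  sheet <- make_beta_sheet(2, 6)
  keys <- pmhcstruct:::residue_table(sheet)$reskey
  part_a <- keys[1:6]; part_b <- keys[7:12]
  # far-apart control
  at <- sheet$atoms
  at[at$reskey %in% part_b, c("x", "y", "z")] <-
    at[at$reskey %in% part_b, c("x", "y", "z")] + 100
  far <- pmhcstruct:::new_structure("far", at)
  isep <- interface_summary(far, part_a, part_b, n_points = 480)
  expect_equal(isep$buried_area, 0, tolerance = 1e-9)
  expect_length(isep$interface_residues_a, 0)
  # assembled sheet: compare against per-residue isolated-vs-complex scan
  ifc <- interface_summary(sheet, part_a, part_b, n_points = 480)
  expect_gt(ifc$buried_area, 10)
  both <- c(part_a, part_b)
  s_cplx <- compute_sasa(sheet, select = both, n_points = 480)
  brute_a <- vapply(part_a, function(k) {
    alone <- compute_sasa(sheet, select = part_a, n_points = 480)
    alone$residue$area[alone$residue$reskey == k] -
      s_cplx$residue$area[s_cplx$residue$reskey == k]
  }, numeric(1))
  expect_setequal(ifc$interface_residues_a, part_a[brute_a > 0.1])
})

test_that("buried area is invariant under rigid transformation", {
  sheet <- make_beta_sheet(2, 10, bulge_at = c(1, 6))
  keys <- pmhcstruct:::residue_table(sheet)$reskey
  part_a <- keys[1:10]; part_b <- keys[11:20]
  base <- interface_summary(sheet, part_a, part_b,
                            n_points = 480)$buried_area
  set.seed(30)
  for (k in 1:5) {
    m <- random_transform_structure(sheet)
    b2 <- interface_summary(m, part_a, part_b,
                            n_points = 480)$buried_area
    expect_lt(abs(b2 - base) / base, 0.005)
  }
})

test_that("peptide exposed surface: isolated when alone, near zero when
           enclosed, and consistent with the interface buried area", {
  toy <- make_toy_pmhc("I")
  st <- toy$structure
  doms <- assign_domains(st, toy$map)
  pep <- doms$peptide
  res <- peptide_exposed_surface(st, pep, n_points = 480)
  # peptide alone: exposed equals isolated
  pep_only <- pmhcstruct:::new_structure(
    "pep", st$atoms[st$atoms$reskey %in% pep, ])
  alone <- peptide_exposed_surface(pep_only, pep, n_points = 480)
  expect_equal(alone$exposed, alone$isolated, tolerance = 1e-9)
  expect_equal(alone$buried, 0, tolerance = 1e-9)
  # within the complex part of the peptide is buried
  expect_lt(res$exposed, res$isolated)
  # consistency: buried part of peptide + buried part of receptor
  # = 2 x symmetric buried area of the peptide/receptor interface
  rest <- setdiff(unique(st$atoms$reskey[!st$atoms$water]), pep)
  ifc <- interface_summary(st, pep, rest, n_points = 480)
  expect_equal(res$buried, sum(ifc$dsasa_a$dsasa), tolerance = 0.005)
  lhs <- res$buried + sum(ifc$dsasa_b$dsasa)
  expect_equal(lhs, 2 * ifc$buried_area, tolerance = 0.005)
})

test_that("a synthetic shell encloses the peptide almost completely", {
  # a tight cage around every heavy atom (a loose shell would not occlude
  # the atom spheres: the accessibility test is local, not topological)
  pep <- make_ideal_helix(6, "alpha")
  at <- pep$atoms
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  dirs <- g / sqrt(rowSums(g^2)) * 2.0
  shell <- do.call(rbind, lapply(seq_len(nrow(at)), function(i)
    sweep(dirs, 2, as.numeric(at[i, c("x", "y", "z")]), `+`)))
  shell_at <- data.frame(chain = "S", resno = seq_len(nrow(shell)),
                         icode = "", resname = "UNK", elety = "C",
                         element = "C", x = shell[, 1], y = shell[, 2],
                         z = shell[, 3], o = 1, het = FALSE, alt = "",
                         stringsAsFactors = FALSE)
  st <- pmhcstruct:::new_structure("caged",
                                   rbind(at[, names(shell_at)], shell_at))
  res <- peptide_exposed_surface(st, unique(at$reskey), n_points = 480)
  expect_lt(res$exposed / res$isolated, 0.02)
})
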