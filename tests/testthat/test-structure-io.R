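test_that("a single well-formed ATOM record parses to one atom", {
  st <- parse_structure(ONE_ATOM_PDB, "pdb")
  expect_s3_class(st, "pmhc_structure")
  expect_equal(nrow(st$atoms), 1)
  expect_equal(st$atoms$chain, "A")
  expect_equal(st$atoms$resname, "ALA")
  expect_equal(st$atoms$elety, "CA")
  expect_equal(st$atoms$element, "C")
  expect_equal(unlist(st$atoms[, c("x", "y", "z")]),
               c(x = 11.104, y = 6.134, z = -6.504))
})

test_that("writer/parser round trip preserves atoms and coordinates", {
  for (st in list(make_ideal_helix(12, "alpha"), make_beta_sheet(2, 8))) {
    txt <- write_structure_pdb(st)
    st2 <- parse_structure(txt, "pdb")
    expect_equal(nrow(st2$atoms), nrow(st$atoms))
    expect_identical(st2$atoms$elety, st$atoms$elety)
    expect_identical(st2$atoms$resno, st$atoms$resno)
    expect_lt(max(abs(as.matrix(st2$atoms[, c("x", "y", "z")]) -
                        as.matrix(st$atoms[, c("x", "y", "z")]))), 1e-3)
  }
})

test_that("malformed and empty input raise informative errors", {
  bad <- c("ATOM      1  CA  ALA A   1      bad_coordinates_here")
  expect_error(parse_structure(bad, "pdb"), "line 1")
  expect_error(parse_structure("   ", "pdb"), "empty")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       1.458   1.000   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.000   1.000  1.00  0.00           C")
  st <- parse_structure(lines, "pdb")
  ca <- st$atoms[st$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)           # one conformer kept
  expect_equal(ca$alt, "B")           # the 0.60-occupancy one
  expect_equal(ca$y, 1.0)
  # tie broken by altloc letter order
  lines2 <- sub("  0.40", "  0.60", lines)
  ca2 <- parse_structure(lines2, "pdb")
  ca2 <- ca2$atoms[ca2$atoms$elety == "CA", ]
  expect_equal(ca2$alt, "A")
  # atom count equals a direct count of expected kept records
  expect_equal(nrow(st$atoms), 3)
})

test_that("waters are flagged and separated from the polymer", {
  lines <- c(ONE_ATOM_PDB,
    "HETATM    2  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O")
  st <- parse_structure(lines, "pdb")
  expect_equal(sum(st$atoms$water), 1)
  expect_equal(nrow(pmhcstruct:::residue_table(st)), 1)
})

test_that("numbering map is bijective and errors on bad configs", {
  sm <- sheet_with_map(6)
  map <- sm$map
  # forward then inverse is the identity over every mapped residue
  expect_false(anyDuplicated(map$reskey) > 0)
  expect_false(anyDuplicated(map$canon) > 0)
  idx <- match(map$canon, map$canon)
  expect_identical(map$reskey[idx], map$reskey)
  # direct lookup
  expect_equal(unname(pmhcstruct:::canon_to_reskey(map, "pb21")), "A:1")
  # overlapping author ranges
  bad1 <- list(domains = list(
    pa = list(chain = "A", start = 1, end = 6),
    pb = list(chain = "A", start = 5, end = 10)))
  expect_error(build_numbering_map(sm$structure, bad1), "overlapping")
  # duplicate canonical position
  bad2 <- list(domains = list(
    pb = list(chain = "A", ranges = list(
      list(start = 1, end = 3, canon_start = 1),
      list(start = 101, end = 103, canon_start = 1)))))
  expect_error(build_numbering_map(sm$structure, bad2), "twice")
})

test_that("unmapped polymer residues are reported, never dropped silently", {
  st <- make_beta_sheet(2, 6)
  cfg <- list(domains = list(pb = list(chain = "A", start = 1, end = 6)))
  expect_message(map <- build_numbering_map(st, cfg), "not covered")
  expect_length(attr(map, "unmapped"), 6)
})

test_that("domain assignment matches the chain architecture of each class", {
  for (ct in c("I", "II")) {
    toy <- make_toy_pmhc(ct)
    doms <- assign_domains(toy$structure, toy$map)
    chain_of <- function(keys) unique(sub(":.*", "", keys))
    if (ct == "I") {
      # heavy chain carries pa+pb+ib; the ia stand-in is a separate chain
      expect_identical(chain_of(c(doms$pa, doms$pb, doms$ib)), "A")
      expect_identical(chain_of(doms$ia), "B")
    } else {
      expect_identical(chain_of(c(doms$pa, doms$ia)), "A")
      expect_identical(chain_of(c(doms$pb, doms$ib)), "B")
    }
    # five sets pairwise disjoint, union = mapped residues, pab = pa+pb
    sets <- doms[c("pa", "pb", "ia", "ib", "peptide")]
    expect_equal(sum(lengths(sets)), length(unique(unlist(sets))))
    expect_setequal(unlist(sets), toy$map$reskey)
    expect_setequal(doms$pab, c(doms$pa, doms$pb))
  }
})

test_that("empty peptide selection is a valid empty set, not an error", {
  st <- make_beta_sheet(2, 6)
  cfg <- list(domains = list(pb = list(chain = "A", ranges = list(
    list(start = 1, end = 6, canon_start = 1),
    list(start = 101, end = 106, canon_start = 11)))),
    peptide = list(chain = "Z", p1 = 1, omega = 9))
  map <- suppressMessages(build_numbering_map(st, cfg))
  doms <- assign_domains(st, map)
  expect_length(doms$peptide, 0)
})

test_that("canonical id strings parse, including insertion codes", {
  expect_equal(canonical_id("pa45"), list(domain = "pa", pos = 45L,
                                          icode = ""))
  expect_equal(canonical_id("pb90b")$icode, "b")
  expect_equal(canonical_id("P-2"), list(domain = "peptide", pos = -2L,
                                         icode = ""))
  expect_error(canonical_id("zz9"), "not a canonical")
})
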