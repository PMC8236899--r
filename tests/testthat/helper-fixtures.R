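# Shared fixture helpers. All fixtures are generated in code; nothing is
# read from disk.

# Minimal structure from a coordinate matrix (one atom per residue).
point_structure <- function(xyz, elem = "C", elety = elem, resname = "UNK",
                            chain = "A") {
  n <- nrow(xyz)
  pmhcstruct:::new_structure("points", data.frame(
    chain = chain, resno = seq_len(n), icode = "", resname = resname,
    elety = rep_len(elety, n), element = rep_len(elem, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, het = FALSE, alt = "",
    stringsAsFactors = FALSE))
}

# A well-formed single-ATOM PDB line fixture.
ONE_ATOM_PDB <- paste0(
  "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00 20.00",
  "           C")

# Apply a random rigid transform to a structure (uses the package internals).
random_transform_structure <- function(st) {
  tr <- pmhcstruct:::random_rigid_transform()
  pmhcstruct:::transform_structure(st, tr$R, tr$t)
}

# Two-strand sheet with a gap-free reskey layout plus a numbering map that
# assigns canonical p-domain positions to the two strands.
sheet_with_map <- function(L, domain = "pb", canon_start_1 = 21,
                           canon_start_2 = 31) {
  st <- make_beta_sheet(2, L)
  cfg <- list(
    class_label = "MHC-I",
    domains = setNames(list(list(chain = "A", ranges = list(
      list(start = 1, end = L, canon_start = canon_start_1),
      list(start = 101, end = 100 + L, canon_start = canon_start_2)))),
      domain))
  map <- suppressMessages(build_numbering_map(st, cfg))
  list(structure = st, map = map)
}

expect_states <- function(st, expected) {
  hb <- suppressWarnings(compute_backbone_hbonds(st))
  ss <- assign_secondary_structure(hb)
  expect_identical(paste(ss$state, collapse = ""), expected)
}
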