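test_that("a two-strand sheet gives one antiparallel ladder whose rungs are
           supported by the exhaustive hydrogen-bond scan", {
  st <- make_beta_sheet(2, 8)
  hb <- compute_backbone_hbonds(st, prefilter = Inf)
  ss <- assign_secondary_structure(hb)
  topo <- build_beta_topology(hb, ss)
  expect_length(topo$ladders, 1)
  expect_equal(topo$ladders[[1]]$sense, "antiparallel")
  # every narrow rung is backed by at least one accepted bond each way
  r <- topo$ladders[[1]]$rungs
  for (q in seq_len(nrow(r))) {
    sup <- sum(hb$donor_idx == r$idx_a[q] & hb$acceptor_idx == r$idx_b[q]) +
      sum(hb$donor_idx == r$idx_b[q] & hb$acceptor_idx == r$idx_a[q])
    wide <- sum(hb$donor_idx == r$idx_a[q] - 1 &
                  hb$acceptor_idx == r$idx_b[q] + 1) +
      sum(hb$donor_idx == r$idx_b[q] - 1 & hb$acceptor_idx == r$idx_a[q] + 1)
    expect_gte(sup + wide, 1)
  }
})

test_that("a helix-only structure yields no ladders", {
  st <- make_ideal_helix(14, "alpha")
  hb <- compute_backbone_hbonds(st)
  topo <- build_beta_topology(hb, assign_secondary_structure(hb))
  expect_length(topo$ladders, 0)
  expect_equal(nrow(topo$strands), 0)
})

test_that("the toy complex floor carries 4 strands per p-domain, labelled in
           canonical order", {
  toy <- make_toy_pmhc("II")
  hb <- suppressWarnings(compute_backbone_hbonds(toy$structure))
  ss <- assign_secondary_structure(hb)
  topo <- suppressWarnings(build_beta_topology(hb, ss, toy$map))
  pstr <- topo$strands[topo$strands$domain %in% c("pa", "pb"), ]
  expect_equal(sum(pstr$domain == "pa"), 4)
  expect_equal(sum(pstr$domain == "pb"), 4)
  for (d in c("pa", "pb")) {
    lab <- pstr$label[pstr$domain == d][order(
      pstr$canon_first[pstr$domain == d])]
    expect_identical(lab, paste0("S", 1:4))
  }
})

test_that("regular sheets contain no bulges; engineered bulges are found
           exactly at the planted pair", {
  reg <- make_beta_sheet(2, 10)
  hb <- compute_backbone_hbonds(reg)
  expect_equal(nrow(detect_beta_bulges(
    build_beta_topology(hb, assign_secondary_structure(hb)))), 0)
  for (case in list(c(1, 5), c(1, 7), c(2, 6))) {
    st <- make_beta_sheet(2, 10, bulge_at = case)
    hb <- compute_backbone_hbonds(st)
    topo <- build_beta_topology(hb, assign_secondary_structure(hb))
    b <- detect_beta_bulges(topo)
    gt <- attr(st, "ground_truth")$bulge
    expect_equal(nrow(b), 1)
    expect_identical(c(b$res_1, b$res_2), gt$pair_key)
  }
})

test_that("bulge sidechain direction is reported relative to a reference", {
  st <- make_beta_sheet(2, 10, bulge_at = c(1, 5))
  hb <- compute_backbone_hbonds(st)
  topo <- build_beta_topology(hb, assign_secondary_structure(hb))
  up <- detect_beta_bulges(topo, st, reference_point = c(0, 0, 100))
  dn <- detect_beta_bulges(topo, st, reference_point = c(0, 0, -100))
  expect_true(up$sidechain_direction %in% c("up", "down", "lateral"))
  flip <- c(up = "down", down = "up", lateral = "lateral")
  expect_identical(unname(flip[up$sidechain_direction]),
                   dn$sidechain_direction)
})

test_that("S2-S3 cleft present iff pairing stops at the p24-p36 pair", {
  # choose canonical offsets so that the outermost narrow pair of a 2x8
  # ladder lands exactly on (24, 36): rungs of the fixture pair residue 3
  # with residue 107 and extend inward
  st <- make_beta_sheet(2, 8)
  hb <- compute_backbone_hbonds(st)
  ss <- assign_secondary_structure(hb)
  topo0 <- build_beta_topology(hb, ss)
  r <- topo0$ladders[[1]]$rungs
  outer_a <- min(r$idx_a)               # residue index on strand 1
  outer_b <- r$idx_b[which.min(r$idx_a)] - 8  # residue index within strand 2
  # truncated case: outermost pair mapped to exactly (24, 36)
  cfg_true <- list(class_label = "MHC-I", domains = list(
    pb = list(chain = "A", ranges = list(
      list(start = 1, end = 8, canon_start = 24 - outer_a + 1),
      list(start = 101, end = 108, canon_start = 36 - outer_b + 1)))))
  map_true <- suppressMessages(build_numbering_map(st, cfg_true))
  topo <- suppressWarnings(build_beta_topology(hb, ss, map_true))
  res <- detect_s2s3_cleft(topo, "pb")
  expect_equal(res$last_pair, c(24, 36))
  expect_true(res$cleft_present)
  # extended case: same sheet, canonical offsets shifted so pairing reaches
  # beyond p24-p36 (outermost pair at p22-p38)
  cfg_false <- list(class_label = "MHC-I", domains = list(
    pb = list(chain = "A", ranges = list(
      list(start = 1, end = 8, canon_start = 22 - outer_a + 1),
      list(start = 101, end = 108, canon_start = 38 - outer_b + 1)))))
  map_false <- suppressMessages(build_numbering_map(st, cfg_false))
  topo2 <- suppressWarnings(build_beta_topology(hb, ss, map_false))
  res2 <- detect_s2s3_cleft(topo2, "pb")
  expect_equal(res2$last_pair, c(22, 38))
  expect_false(res2$cleft_present)
})

test_that("cleft status is undetermined, not false, when S2/S3 are absent", {
  st <- make_ideal_helix(12, "alpha")
  cfg <- list(domains = list(pb = list(chain = "A", start = 1, end = 12)))
  map <- build_numbering_map(st, cfg)
  hb <- compute_backbone_hbonds(st)
  topo <- build_beta_topology(hb, assign_secondary_structure(hb), map)
  res <- detect_s2s3_cleft(topo, "pb")
  expect_true(is.na(res$cleft_present))
})
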