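FENTANYL_SMILES <- "CCC(=O)N(c1ccccc1)C1CCN(CCc2ccccc2)CC1"

test_that("parse_smiles builds the expected molecular graphs", {
  fent <- parse_smiles(FENTANYL_SMILES)
  # C22H28N2O: 25 heavy atoms; 3 rings -> bonds = atoms - 1 + 3
  expect_equal(nrow(fent$atoms), 25L)
  expect_equal(nrow(fent$bonds), 27L)
  expect_equal(sum(fent$atoms$element == "N"), 2L)
  expect_equal(sum(fent$atoms$element == "O"), 1L)
  expect_equal(sum(fent$atoms$aromatic), 12L)  # two phenyl rings

  eth <- parse_smiles("CC")
  expect_equal(nrow(eth$atoms), 2L)
  expect_equal(nrow(eth$bonds), 1L)
  # charges in bracket atoms
  chg <- parse_smiles("CC[N+]1CCCCC1")
  expect_equal(sum(chg$atoms$charge), 1L)
  expect_error(parse_smiles("C?C"), "unsupported")
  expect_error(parse_smiles("C1CC"), "unclosed")
})

test_that("find_tertiary_amine picks the piperidine N, not the amide N", {
  fent <- parse_smiles(FENTANYL_SMILES)
  cand <- find_tertiary_amine(fent)
  expect_length(cand, 1L)
  # the hit is a ring nitrogen with three carbon neighbours
  expect_equal(fent$atoms$element[cand], "N")
  in_ring <- oracle_bond_in_ring(fent$bonds, nrow(fent$atoms))
  ring_atoms <- unique(c(fent$bonds$i[in_ring], fent$bonds$j[in_ring]))
  expect_true(cand %in% ring_atoms)
  expect_false(fent$atoms$aromatic[cand])

  # trimethylamine: its single N
  tma <- parse_smiles("CN(C)C")
  expect_equal(find_tertiary_amine(tma), 2L)

  # N-methylacetamide: amide N excluded by the carbonyl rule
  nma <- parse_smiles("CC(=O)NC")
  expect_error(find_tertiary_amine(nma), "no_amine")
})

test_that("rotatable_bond_count applies the full rule set", {
  expect_equal(rotatable_bond_count(parse_smiles("CC")), 0L)      # ethane
  expect_equal(rotatable_bond_count(parse_smiles("CCCC")), 1L)    # n-butane
  expect_equal(rotatable_bond_count(parse_smiles(FENTANYL_SMILES)), 6L)
  # amide C-N exclusion: N-methylacetamide has no rotatable bond besides
  # the (excluded) amide; C-C to the carbonyl is terminal-methyl
  expect_equal(rotatable_bond_count(parse_smiles("CC(=O)NC")), 0L)
  # ring bonds never count
  expect_equal(rotatable_bond_count(parse_smiles("C1CCCCC1")), 0L)
  # biphenyl: the inter-ring single bond rotates
  expect_equal(rotatable_bond_count(parse_smiles("c1ccccc1c1ccccc1")), 1L)

  # 20 random toy graphs vs the rule-by-rule oracle
  set.seed(29)
  for (rep in 1:20) {
    cf <- random_toy_graph(sample(4:14, 1), n_extra = sample(0:2, 1))
    expect_equal(rotatable_bond_count(cf), oracle_rotatable(cf),
                 info = paste("rep", rep))
  }
})

test_that("ring perception agrees with the BFS cycle oracle", {
  set.seed(37)
  for (rep in 1:15) {
    cf <- random_toy_graph(sample(5:30, 1), n_extra = sample(0:4, 1))
    acyc <- ssmenrich:::acyclic_bonds(cf)
    expect_equal(acyc, !oracle_bond_in_ring(cf$bonds, nrow(cf$atoms)),
                 info = paste("rep", rep))
  }
})

test_that("amine water sits at the fourth tetrahedral vertex", {
  cf <- toy_tetra_amine()
  hs <- place_amine_water(cf, 1)
  n <- c(0, 0, 0)
  expect_equal(sqrt(sum((hs$water_O - n)^2)), 3.0, tolerance = 1e-9)
  expect_equal(hs$angles, rep(acos(-1 / 3) * 180 / pi, 3), tolerance = 1e-6)
  expect_equal(hs$mean_angle, 109.4712, tolerance = 1e-3)

  # perturbed amine (0.05 A coordinate jitter): within 2 degrees of the
  # spherical grid-search oracle minimizing sum((angle - 109)^2)
  set.seed(41)
  cf2 <- cf
  cf2$atoms[2:4, c("x", "y", "z")] <-
    cf2$atoms[2:4, c("x", "y", "z")] + matrix(runif(9, -0.05, 0.05), 3)
  hs2 <- place_amine_water(cf2, 1)
  expect_equal(sqrt(sum(hs2$water_O^2)), 3.0, tolerance = 1e-9)
  worc <- oracle_amine_water_grid(cf2, 1, target = 109)
  ang_between <- acos(sum(hs2$water_O * worc) /
                        (sqrt(sum(hs2$water_O^2)) * sqrt(sum(worc^2)))) * 180 / pi
  expect_lt(ang_between, 2)

  # degenerate (exactly planar) nitrogen errors out
  cfp <- conformer(
    data.frame(element = c("N", "C", "C", "C"),
               x = 1.4 * c(0, cos(0), cos(2 * pi / 3), cos(4 * pi / 3)),
               y = 1.4 * c(0, sin(0), sin(2 * pi / 3), sin(4 * pi / 3)),
               z = c(0, 0, 0, 0)),
    data.frame(i = c(1, 1, 1), j = c(2, 3, 4), order = 1L))
  expect_error(place_amine_water(cfp, 1), "degenerate")
})

test_that("carbonyl water is in-plane at 3.0 A and 120 degrees", {
  cf <- toy_carbonyl()
  hs <- place_carbonyl_water(cf, 1, 2)
  o <- c(1.23, 0, 0)
  expect_equal(sqrt(sum((hs$water_O - o)^2)), 3.0, tolerance = 1e-9)
  expect_equal(hs$angle, 120, tolerance = 1e-9)
  expect_lt(abs(hs$water_O[3]), 1e-6)  # coplanar with the sp2 plane
  expect_false(hs$flagged)
  expect_error(place_carbonyl_water(cf, 1, 3), "double bond")

  # clearance rule: both in-plane candidates enumerated, the clear one wins
  for (ysign in c(1, -1)) {
    at <- rbind(cf$atoms,
                data.frame(element = "C", x = 2.6, y = ysign * 2.6, z = 0,
                           charge = 0L, aromatic = FALSE))
    cf2 <- conformer(at, cf$bonds)
    hs2 <- place_carbonyl_water(cf2, 1, 2)
    # brute force over the two candidates
    th <- 120 * pi / 180
    a <- (c(0, 0, 0) - o) / 1.23
    b <- c(0, 1, 0)
    cands <- list(o + 3 * (cos(th) * a + sin(th) * b),
                  o + 3 * (cos(th) * a - sin(th) * b))
    clearance <- vapply(cands, function(w)
      min(apply(cf2$atoms[3:5, c("x", "y", "z")], 1,
                function(p) sqrt(sum((w - p)^2)))), 0)
    expect_equal(unname(hs2$water_O),
                 unname(cands[[which.max(clearance)]]), tolerance = 1e-9)
  }
})

test_that("hydration is equivariant under rigid motions", {
  set.seed(43)
  fentless <- toy_tetra_amine()
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- c(4, -2, 7)
  moved <- fentless
  xyz <- as.matrix(fentless$atoms[, c("x", "y", "z")])
  moved$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, shift, `+`)
  h0 <- place_amine_water(fentless, 1)
  h1 <- place_amine_water(moved, 1)
  expect_equal(h1$water_O, as.numeric(R %*% h0$water_O + shift),
               tolerance = 1e-9)

  cb <- toy_carbonyl()
  movedc <- cb
  xyzc <- as.matrix(cb$atoms[, c("x", "y", "z")])
  movedc$atoms[, c("x", "y", "z")] <- sweep(xyzc %*% t(R), 2, shift, `+`)
  g0 <- place_carbonyl_water(cb, 1, 2)
  g1 <- place_carbonyl_water(movedc, 1, 2)
  expect_equal(g1$water_O, as.numeric(R %*% g0$water_O + shift),
               tolerance = 1e-9)
})

test_that("hydrate_ligand + SDF output round-trips", {
  # toy molecule with both site kinds: a tertiary amine and a ketone
  at <- rbind(
    toy_tetra_amine()$atoms,
    data.frame(element = c("C", "O", "C"),
               x = c(5, 6.23, 5.2), y = c(0, 0, 1.4), z = c(0, 0, 0),
               charge = 0L, aromatic = FALSE))
  bd <- rbind(toy_tetra_amine()$bonds,
              data.frame(i = c(2, 5, 5), j = c(5, 6, 7),
                         order = c(1L, 2L, 1L)))
  cf <- conformer(at, bd)
  hc <- hydrate_ligand(cf)
  kinds <- vapply(hc$sites, `[[`, "", "site_kind")
  expect_setequal(kinds, c("amine", "carbonyl"))
  for (s in hc$sites) {
    anchor <- as.numeric(cf$atoms[s$anchor_atom, c("x", "y", "z")])
    expect_equal(sqrt(sum((s$water_O - anchor)^2)), s$target_distance,
                 tolerance = 1e-6)
  }
  td <- withr::local_tempdir()
  paths <- write_hydrated_sdf(hc, file.path(td, "lig.sdf"))
  back <- read_sdf(file.path(td, "lig.sdf"))
  expect_equal(nrow(back$atoms), nrow(cf$atoms) + length(hc$sites))
  expect_equal(nrow(back$bonds), nrow(cf$bonds))
  expect_equal(back$atoms$x[seq_len(nrow(cf$atoms))], cf$atoms$x,
               tolerance = 1e-4)
  meta <- jsonlite::read_json(paths[2])
  expect_length(meta, length(hc$sites))
})
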