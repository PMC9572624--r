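test_that("residue centroid is the unweighted heavy-atom mean", {
  one <- data.frame(name = "CA", resname = "GLY", chain = "A", resno = 1,
                    insert = "", x = 1, y = 2, z = 3, occ = 1,
                    element = "C", is_h = FALSE)
  expect_equal(residue_centroid(one), c(1, 2, 3))
  two <- rbind(one, transform(one, name = "C", x = 3, y = 2, z = 3))
  expect_equal(residue_centroid(two), c(2, 2, 3))
  # hydrogens are excluded
  three <- rbind(two, transform(one, name = "H", x = 100, element = "H",
                                is_h = TRUE))
  expect_equal(residue_centroid(three), c(2, 2, 3))
  expect_error(residue_centroid(three[three$is_h, ]), "degenerate")
  # template residue: centroid equals independent coordinate averaging
  arg <- residue_template("ARG", hydrogens = FALSE)
  m <- build_model(list(arg), "A", 1, "ARG")$atoms
  expect_equal(residue_centroid(m),
               unname(colMeans(as.matrix(m[, c("x", "y", "z")]))))
})

test_that("hydrogen-bond criteria accept and reject as specified", {
  # planted bond inside every threshold
  p <- make_pair_complex("hydrogen", key_distance = 2.9, key_angle = 160,
                         seed = 11)
  b <- detect_quiet(p$model)
  expect_equal(nrow(b$hydrogen), 1L)
  expect_equal(b$hydrogen$distance, 2.9, tolerance = 2e-3)
  expect_equal(b$hydrogen$dha_angle, 160, tolerance = 0.5)
  expect_gt(b$hydrogen$dha_angle, 90)
  # donor-acceptor beyond 3.9 A: nothing (decoy with same chemistry)
  d <- make_pair_complex("none", violated_criterion = "ha_distance",
                         seed = 11)
  expect_equal(nrow(detect_quiet(d$model)$hydrogen), 0L)
  # same interface group: nothing
  aa_spec <- interface_spec("A", "B")
  m <- p$model
  m$atoms$chain <- "A"  # collapse onto one side
  m$atoms$chain[1] <- "A"
  expect_error(detect_all(m, aa_spec))  # chain B gone -> config error
})

test_that("hydrogen bonds via rotatable hydroxyl donors are found", {
  # SER OG donor toward a GLN OE1 acceptor placed on the hydroxyl-H
  # cone (109.5 degrees off the CB-OG axis) 2.8 A from OG, so some
  # sampled O-H dihedral points straight at the acceptor
  ser <- interbond:::.pose(residue_template("SER", hydrogens = FALSE),
                           "OG", "CB", c(0, 0, 0), c(-1, 0, 0))
  cone <- cos(70.5 * pi / 180) * c(1, 0, 0) +
    sin(70.5 * pi / 180) * c(0, 0, 1)
  gln <- interbond:::.pose(residue_template("GLN", hydrogens = FALSE),
                           "OE1", "CD", 2.8 * cone, cone)
  m <- build_model(list(ser, gln), c("A", "B"), c(1, 1), c("SER", "GLN"))
  b <- detect_quiet(m)
  hb <- b$hydrogen
  expect_true(any(hb$atom1 == "OG" & hb$atom2 == "OE1"))
})

test_that("ionic bonds need opposite charge, centroid and atom distance", {
  # in range at both criteria
  p <- make_pair_complex("ionic", key_distance = 4.5, seed = 12)
  b <- detect_quiet(p$model)
  expect_equal(nrow(b$ionic), 1L)
  expect_equal(b$ionic$distance, 4.5, tolerance = 2e-3)
  expect_lt(b$ionic$centroid_distance, 5)
  expect_equal(nrow(b$salt_bridge), 0L)  # 4.5 > 4
  # like charges never bond
  lk <- make_pair_complex("none", violated_criterion = "charge", seed = 3)
  expect_equal(sum(bond_counts(detect_quiet(lk$model))), 0L)
  # ARG/ASP pairing works through the generic builder too
  q <- make_pair_complex("ionic", key_distance = 3.5,
                         residues = c("ASP", "HIS"), seed = 4)
  expect_equal(detect_quiet(q$model)$ionic$distance, 3.5, tolerance = 2e-3)
})

test_that("far centroids suppress ionic bonds at 5 A but not 7.5/10 A", {
  d <- make_pair_complex("none", violated_criterion = "distance",
                         key_distance = 6.5, seed = 13)
  expect_equal(nrow(detect_quiet(d$model)$ionic), 0L)
  p75 <- detection_params(ionic_centroid_cutoff = 7.5)
  b75 <- detect_quiet(d$model, params = p75)
  expect_equal(nrow(b75$ionic), 1L)
  p10 <- detection_params(ionic_centroid_cutoff = 10)
  expect_equal(nrow(detect_quiet(d$model, params = p10)$ionic), 1L)
})

test_that("ionic bond sets are monotone in the cutoff", {
  key <- function(b) paste(b$resnum1, b$resnum2)
  ic <- make_interface_complex(9, seed = 21)
  sets <- lapply(c(5, 7.5, 10), function(co) {
    key(detect_quiet(ic$model,
                     params = detection_params(
                       ionic_centroid_cutoff = co))$ionic)
  })
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("salt bridges require side-chain charged N...O within 4 A", {
  p <- make_pair_complex("salt_bridge", key_distance = 3.2, seed = 14)
  b <- detect_quiet(p$model)
  expect_equal(nrow(b$salt_bridge), 1L)
  expect_equal(b$salt_bridge$distance, 3.2, tolerance = 1e-3)
  # beyond 4 A: nothing of any type
  d <- make_pair_complex("none", violated_criterion = "distance",
                         key_distance = 4.5, seed = 14)
  expect_equal(sum(bond_counts(detect_quiet(d$model))), 0L)
})

test_that("the synthetic barnase-barstar example shows Arg59-Glu76", {
  bb <- make_synthetic_barnase_barstar()
  b <- suppressWarnings(detect_all(bb$model, interface_spec("A", "D")))
  sb <- b$salt_bridge
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$resname1, "ARG")
  expect_equal(sb$resnum1, "59")
  expect_equal(sb$resname2, "GLU")
  expect_equal(sb$resnum2, "76")
  expect_lte(sb$distance, 4)
})

test_that("detect_all is the stateless union of the three detectors", {
  ic <- make_interface_complex(3, seed = 31)
  all1 <- detect_quiet(ic$model)
  expect_equal(all1$hydrogen,
               suppressWarnings(find_hydrogen_bonds(ic$model, ab_spec)))
  expect_equal(all1$ionic,
               suppressWarnings(find_ionic_bonds(ic$model, ab_spec)))
  expect_equal(all1$salt_bridge,
               suppressWarnings(find_salt_bridges(ic$model, ab_spec)))
  # rerun is identical
  expect_equal(all1, detect_quiet(ic$model))
  # counts match the one-of-each construction
  expect_equal(unname(bond_counts(all1)), c(1L, 1L, 1L))
})

test_that("interfaces farther than every cutoff yield no bonds", {
  p <- make_pair_complex("salt_bridge", seed = 41)
  m <- p$model
  shift <- m$atoms$chain == "B"
  m$atoms$x[shift] <- m$atoms$x[shift] + 50
  expect_equal(sum(bond_counts(detect_quiet(m))), 0L)
})

test_that("swapping the interface groups transposes every record", {
  ic <- make_interface_complex(6, seed = 51)
  fwd <- detect_quiet(ic$model, interface_spec("A", "B"))
  rev <- detect_quiet(ic$model, interface_spec("B", "A"))
  for (ty in names(fwd)) {
    expect_equal(nrow(fwd[[ty]]), nrow(rev[[ty]]))
    k_f <- sort(paste(fwd[[ty]]$chain1, fwd[[ty]]$resnum1,
                      fwd[[ty]]$chain2, fwd[[ty]]$resnum2))
    k_r <- sort(paste(rev[[ty]]$chain2, rev[[ty]]$resnum2,
                      rev[[ty]]$chain1, rev[[ty]]$resnum1))
    expect_equal(k_f, k_r)
    expect_equal(sort(fwd[[ty]]$distance), sort(rev[[ty]]$distance))
  }
})

test_that("rigid motions leave bond sets and measurements unchanged", {
  ic <- make_interface_complex(6, seed = 61)
  b0 <- detect_quiet(ic$model)
  R <- interbond:::.with_seed(7, interbond:::.random_rotation())
  m <- ic$model
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
  m$atoms$x <- xyz[, 1] + 12.3
  m$atoms$y <- xyz[, 2] - 4.56
  m$atoms$z <- xyz[, 3] + 0.789
  b1 <- detect_quiet(m)
  for (ty in names(b0)) {
    expect_equal(b0[[ty]]$atom1, b1[[ty]]$atom1)
    expect_equal(b0[[ty]]$atom2, b1[[ty]]$atom2)
    expect_equal(b0[[ty]]$distance, b1[[ty]]$distance, tolerance = 1e-6)
    if (ty == "hydrogen") {
      expect_equal(b0[[ty]]$dha_angle, b1[[ty]]$dha_angle,
                   tolerance = 1e-4)
    }
  }
})

test_that("residues with missing charged side-chain atoms are skipped", {
  p <- make_pair_complex("salt_bridge", seed = 71)
  m <- p$model
  m$atoms <- m$atoms[m$atoms$name != "NZ", ]  # disordered lysine tip
  expect_warning(find_salt_bridges(m, ab_spec), "missing side-chain")
  expect_equal(nrow(suppressWarnings(find_salt_bridges(m, ab_spec))), 0L)
})
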