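test_that("free energy from Kd follows RT ln K", {
  expect_equal(delta_g(1), 0)
  expect_equal(delta_g(1, 310), 0)
  expect_equal(delta_g(1e-9, 298.15), -12.28, tolerance = 1e-3)
  # linear in temperature
  expect_equal(delta_g(1e-6, 298.15) / delta_g(1e-6, 310), 298.15 / 310)
  expect_error(delta_g(0), "positive")
  expect_error(delta_g(-1), "positive")
})

test_that("ddG is the Keq ratio on the free-energy scale", {
  r <- data.frame(keq_wt = 1e-9, keq_mut = 1e-6)
  expect_equal(compute_ddg(r)$ddg, 4.093, tolerance = 1e-3)
  # antisymmetry under swapping wild type and mutant
  r2 <- data.frame(keq_wt = 1e-6, keq_mut = 1e-9)
  expect_equal(compute_ddg(r2)$ddg, -compute_ddg(r)$ddg)
  # identical constants give zero
  expect_equal(compute_ddg(data.frame(keq_wt = 2e-8, keq_mut = 2e-8))$ddg,
               0)
  # invariance under common rescaling: only the ratio matters
  for (f in c(1e-3, 0.5, 7, 1e4)) {
    rs <- data.frame(keq_wt = 1e-9 * f, keq_mut = 1e-6 * f)
    expect_equal(compute_ddg(rs)$ddg, compute_ddg(r)$ddg,
                 tolerance = 1e-12)
  }
})

test_that("per-complex min-max normalization lands in [0, 1]", {
  r <- data.frame(complex_id = c("X", "X", "X", "Y", "Y", "Z"),
                  ddg = c(1, 2, 3, 10, 30, 5))
  n <- normalize_ddg(r)
  expect_equal(n$ddg_normalized[1:3], c(0, 0.5, 1))
  expect_equal(n$ddg_normalized[4:5], c(0, 1))   # per-complex scaling
  expect_equal(n$ddg_normalized[6], 0.5)         # degenerate singleton
  expect_true(all(n$ddg_normalized >= 0 & n$ddg_normalized <= 1))
})

test_that("normalized ddG attains 0 and 1 in complexes with spread", {
  mt <- make_mutation_table(120, "broken_high_ddg", seed = 5)
  n <- normalize_ddg(compute_ddg(mt$table))
  for (cx in unique(n$complex_id)) {
    v <- n$ddg_normalized[n$complex_id == cx]
    expect_equal(min(v), 0)
    expect_equal(max(v), 1)
  }
})

test_that("compact mutation codes parse and reject garbage", {
  expect_warning(p <- parse_mutation_string(c("RA59A", "EI76K", "bogus",
                                               "XA1Z")),
                 "unparseable")
  expect_equal(p$wt_residue[1], "ARG")
  expect_equal(p$chain[1], "A")
  expect_equal(p$position[1], "59")
  expect_equal(p$mut_residue[1], "ALA")
  expect_equal(p$mut_residue[2], "LYS")
  expect_true(is.na(p$chain[3]))
  expect_true(is.na(p$chain[4]))  # X and Z are not amino acids
  expect_warning(parse_mutation_string("???"), "unparseable")
})

test_that("mutation tables read through the column mapping", {
  tab <- data.frame(
    "#Pdb" = c("1XYZ_A_B", "1XYZ_A_B", "1XYZ_A_B", "2ABC_C_D"),
    "Mutation(s)_cleaned" = c("RA59A", "EB12K", "RA59A,EB12K", "KC3D"),
    "Affinity_wt_parsed" = c(1e-9, 2e-9, 1e-9, 5e-8),
    "Affinity_mut_parsed" = c(1e-7, 2e-9, 1e-7, 5e-9),
    "Temperature" = c("298", "298(assumed)", "298", "310"),
    check.names = FALSE)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(recs <- read_mutation_table(f), "multi-point")
  expect_equal(nrow(recs), 3L)  # multi-point row dropped
  expect_equal(recs$complex_id, c("1XYZ", "1XYZ", "2ABC"))
  expect_equal(recs$temperature, c(298, 298, 310))
  expect_equal(recs$wt_residue[1], "ARG")
  unlink(f)
})

test_that("bond-change classes follow mutant chemistry", {
  p <- make_pair_complex("salt_bridge", seed = 3)  # LYS(A:1)-GLU(B:1)
  wt <- detect_quiet(p$model)
  classify <- function(mut_res, chain = "A", pos = "1", wt_res = "LYS") {
    classify_bond_change(wt, data.frame(chain = chain, position = pos,
                                        wt_residue = wt_res,
                                        mut_residue = mut_res),
                         p$model, ab_spec)
  }
  # charged -> uncharged: broken
  cA <- classify("ALA")
  expect_equal(cA$classification[cA$bond_type == "salt_bridge"], "broken")
  # charged -> similarly charged: intact
  cR <- classify("ARG")
  expect_equal(cR$classification[cR$bond_type == "salt_bridge"], "intact")
  # charged -> oppositely charged: broken
  cE <- classify("GLU")
  expect_equal(cE$classification[cE$bond_type == "salt_bridge"], "broken")
  # mutation to the identical residue gives only intact/none
  cK <- classify("LYS")
  expect_true(all(cK$classification %in% c("intact", "none")))
  # the partner side classifies symmetrically
  cP <- classify("ALA", chain = "B", wt_res = "GLU")
  expect_equal(cP$classification[cP$bond_type == "salt_bridge"], "broken")
  # unknown site errors
  expect_error(classify("ALA", pos = "99"), "not found")
})

test_that("uncharged-to-charged mutations near a partner form bonds", {
  # ALA on chain A with a GLU carboxylate ~6 A from CB: within the
  # salt cutoff + ARG reach, so A -> R can form an ionic/salt bond
  ala <- interbond:::.pose(residue_template("ALA", hydrogens = FALSE),
                           "CB", "CA", c(0, 0, 0), c(-1, 0, 0))
  glu <- interbond:::.pose(residue_template("GLU", hydrogens = FALSE),
                           "OE1", "CD", c(6, 0, 0), c(1, 0, 0))
  m <- build_model(list(ala, glu), c("A", "B"), c(1, 1), c("ALA", "GLU"))
  wt <- detect_quiet(m)
  expect_equal(sum(bond_counts(wt)), 0L)
  ch <- classify_bond_change(wt, data.frame(chain = "A", position = "1",
                                            wt_residue = "ALA",
                                            mut_residue = "ARG"),
                             m, ab_spec)
  expect_equal(ch$classification[ch$bond_type == "salt_bridge"], "formed")
  expect_equal(ch$classification[ch$bond_type == "ionic"], "formed")
  # a mutation that does not add charge cannot form a charged bond
  ch2 <- classify_bond_change(wt, data.frame(chain = "A", position = "1",
                                             wt_residue = "ALA",
                                             mut_residue = "LEU"),
                              m, ab_spec)
  expect_true(all(ch2$classification %in% "none"))
})

test_that("backbone-mediated hydrogen bonds survive side-chain mutation", {
  # donor TRP NE1 is side-chain; acceptor GLN OE1 is side-chain; check a
  # backbone acceptor case instead: build TRP donor vs GLY backbone O
  trp <- interbond:::.pose(residue_template("TRP"), "NE1", "HE1",
                           c(0, 0, 0), c(1, 0, 0))
  gly <- interbond:::.pose(residue_template("GLY", hydrogens = FALSE),
                           "O", "C", c(2.9, 0, 0), c(1, 0, 0))
  m <- build_model(list(trp, gly), c("A", "B"), c(1, 1), c("TRP", "GLY"))
  wt <- detect_quiet(m)
  expect_equal(nrow(wt$hydrogen), 1L)
  expect_equal(wt$hydrogen$atom2, "O")
  # mutating the backbone-acceptor residue leaves the bond intact
  ch <- classify_bond_change(wt, data.frame(chain = "B", position = "1",
                                            wt_residue = "GLY",
                                            mut_residue = "PRO"),
                             m, ab_spec)
  expect_equal(ch$classification[ch$bond_type == "hydrogen"], "intact")
  # mutating the side-chain donor to a donor-less residue breaks it
  ch2 <- classify_bond_change(wt, data.frame(chain = "A", position = "1",
                                             wt_residue = "TRP",
                                             mut_residue = "LEU"),
                              m, ab_spec)
  expect_equal(ch2$classification[ch2$bond_type == "hydrogen"], "broken")
})

test_that("group summaries report t intervals, CV and empty groups", {
  g <- group_summary(c(0.5, 0.5, 0.5), factor(rep("a", 3),
                                              levels = c("a", "b")))
  a <- g[g$group == "a", ]
  expect_equal(a$mean, 0.5)
  expect_equal(a$cv, 0)
  expect_equal(a$ci_lo, a$ci_hi)
  b <- g[g$group == "b", ]
  expect_true(b$empty)
  expect_true(is.na(b$mean))
  # single observation: mean but no interval
  s <- group_summary(0.7, "only")
  expect_equal(s$mean, 0.7)
  expect_true(is.na(s$ci_lo) && is.na(s$ci_hi))
  # t interval matches t.test
  v <- c(0.2, 0.4, 0.9, 0.5, 0.3)
  gs <- group_summary(v, rep("g", 5))
  tt <- t.test(v)
  expect_equal(c(gs$ci_lo, gs$ci_hi), as.numeric(tt$conf.int),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(gs$cv, sd(v) / mean(v))
})
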