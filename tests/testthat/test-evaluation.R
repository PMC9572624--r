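ref_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(chain1 = r[[1]], resnum1 = r[[2]], resname1 = r[[3]],
               chain2 = r[[4]], resnum2 = r[[5]], resname2 = r[[6]],
               bond_type = r[[7]], source = "test",
               stringsAsFactors = FALSE)
  }))
}

test_that("hydrogen + ionic reference entries imply a salt bridge", {
  ref <- ref_df(list("A", "59", "ARG", "D", "76", "GLU", "hydrogen"),
                list("A", "59", "ARG", "D", "76", "GLU", "ionic"),
                list("A", "10", "LYS", "D", "20", "ASP", "hydrogen"))
  aug <- infer_reference_salt_bridges(ref)
  expect_equal(sum(aug$bond_type == "salt_bridge"), 1L)
  expect_equal(aug$resnum1[aug$bond_type == "salt_bridge"], "59")
  # hydrogen-only pair unchanged
  expect_equal(sum(aug$resnum1 == "10"), 1L)
  # idempotent
  expect_equal(infer_reference_salt_bridges(aug), aug)
})

test_that("confusion counting matches unordered residue pairs by type", {
  pred <- data.frame(bond_type = "ionic", chain1 = "A", resname1 = "ARG",
                     resnum1 = "59", chain2 = "D", resname2 = "GLU",
                     resnum2 = "76", atom1 = "NH1", atom2 = "OE1",
                     role1 = NA, distance = 3.1, dha_angle = NA,
                     centroid_distance = 4.4, stringsAsFactors = FALSE)
  ref <- ref_df(list("A", "59", "ARG", "D", "76", "GLU", "ionic"))
  cc <- score_predictions(pred, ref, "ionic")
  expect_equal(cc$tp, 1L)
  expect_equal(cc$fp, 0L)
  expect_equal(cc$fn, 0L)
  # residue order within the reference pair does not matter
  ref_swapped <- ref_df(list("D", "76", "GLU", "A", "59", "ARG", "ionic"))
  cc2 <- score_predictions(pred, ref_swapped, "ionic")
  expect_equal(cc2$tp, 1L)
  # a reference entry of another type is not a match
  ref_h <- ref_df(list("A", "59", "ARG", "D", "76", "GLU", "hydrogen"))
  cc3 <- score_predictions(pred, ref_h, "ionic")
  expect_equal(cc3$tp, 0L)
  expect_equal(cc3$fp, 1L)
  # empty predictions: all reference bonds are misses
  cc4 <- score_predictions(pred[0, ],
                           ref_df(list("A", "1", "LYS", "B", "2", "GLU",
                                       "ionic"),
                                  list("A", "3", "LYS", "B", "4", "GLU",
                                       "ionic")),
                           "ionic")
  expect_equal(c(cc4$tp, cc4$fp, cc4$fn), c(0L, 0L, 2L))
  # duplicate reference entries collapse with a warning
  expect_warning(score_predictions(pred, rbind(ref, ref), "ionic"),
                 "duplicated")
})

test_that("count identities hold: tp+fp = predictions, tp+fn = knowns", {
  ic <- make_interface_complex(5, seed = 77)
  pred <- bind_bonds(detect_quiet(ic$model))
  # build a reference from a subset of truth plus an extra unknown bond
  tr <- ic$truth
  ref <- data.frame(chain1 = tr$chain1, resnum1 = tr$resnum1,
                    resname1 = tr$resname1, chain2 = tr$chain2,
                    resnum2 = tr$resnum2, resname2 = tr$resname2,
                    bond_type = tr$bond_type, source = "planted",
                    stringsAsFactors = FALSE)
  ref <- ref[-1, ]
  ref <- rbind(ref, ref_df(list("A", "999", "LYS", "B", "999", "GLU",
                                ref$bond_type[1])))
  for (ty in unique(pred$bond_type)) {
    cc <- score_predictions(pred, ref, ty)
    n_pred <- length(unique(paste(pred$resnum1, pred$resnum2)[
      pred$bond_type == ty]))
    n_ref <- sum(ref$bond_type == ty)
    expect_equal(cc$tp + cc$fp, n_pred)
    expect_equal(cc$tp + cc$fn, n_ref)
  }
})

test_that("scoring predictions against themselves is perfect", {
  ic <- make_interface_complex(4, seed = 78)
  pred <- bind_bonds(detect_quiet(ic$model))
  ref <- data.frame(chain1 = pred$chain1, resnum1 = pred$resnum1,
                    resname1 = pred$resname1, chain2 = pred$chain2,
                    resnum2 = pred$resnum2, resname2 = pred$resname2,
                    bond_type = pred$bond_type, source = "self",
                    stringsAsFactors = FALSE)
  for (ty in unique(pred$bond_type)) {
    cc <- score_predictions(pred, ref, ty)
    expect_equal(cc$fp, 0L)
    expect_equal(cc$fn, 0L)
    pr <- precision_recall(cc)
    expect_equal(pr$precision, 1)
    expect_equal(pr$recall, 1)
  }
})

test_that("precision and recall use the count arithmetic", {
  pr <- precision_recall(confusion_counts(14, 2, 3))
  expect_equal(pr$precision, 0.875, tolerance = 1e-3)
  expect_equal(pr$recall, 0.824, tolerance = 1e-3)
  pr2 <- precision_recall(confusion_counts(6, 1, 6))
  expect_equal(pr2$precision, 0.857, tolerance = 1e-3)
  expect_equal(pr2$recall, 0.5)
  # zero denominators are undefined, not zero
  pr3 <- precision_recall(confusion_counts(0, 0, 5))
  expect_true(is.na(pr3$precision))
  expect_equal(pr3$recall, 0)
  pr4 <- precision_recall(confusion_counts(0, 0, 0))
  expect_true(is.na(pr4$precision))
  expect_true(is.na(pr4$recall))
})

test_that("the evaluation report prints Unknown TN and totals", {
  ic <- make_interface_complex(3, seed = 79)
  pred <- bind_bonds(detect_quiet(ic$model))
  ref <- data.frame(chain1 = pred$chain1, resnum1 = pred$resnum1,
                    resname1 = pred$resname1, chain2 = pred$chain2,
                    resnum2 = pred$resnum2, resname2 = pred$resname2,
                    bond_type = pred$bond_type, source = "self",
                    stringsAsFactors = FALSE)
  rep_ <- evaluation_report(pred, ref)
  expect_equal(rep_[rep_$metric == "True Negative", "ionic"], "Unknown")
  expect_equal(rep_[rep_$metric == "Precision", "salt_bridge"], "100.0%")
  expect_equal(rep_[rep_$metric == "Recall", "hydrogen"], "100.0%")
})
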