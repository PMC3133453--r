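test_that("wheat germ class totals match the reported values within rounding", {
  comp <- wheat_germ_composition()
  hydro <- class_fraction(comp, "hydrophobic")
  arom <- class_fraction(comp, "aromatic")
  expect_equal(hydro, 42.84, tolerance = 0.02 / 42.84)
  expect_equal(arom, 8.89, tolerance = 0.02 / 8.89)
  expect_equal(class_fraction(comp, c("Z")), 0)   # empty intersection
})

test_that("combined Asx/Glx entries are excluded from partial classes", {
  comp <- wheat_germ_composition()
  ## D is in the class but its combined partner N is not -> ambiguous
  expect_message(v <- class_fraction(comp, c("D", "G")), "partially")
  expect_equal(v, 6.19)  # only Gly counts
  ## fully covered combined entry counts as a whole
  expect_equal(class_fraction(comp, c("D", "N")), 8.40)
})

test_that("class fractions add over disjoint residue classes", {
  comp <- wheat_germ_composition()
  a <- class_fraction(comp, c("A", "V", "L"))
  b <- class_fraction(comp, c("F", "Y", "W"))
  both <- class_fraction(comp, c("A", "V", "L", "F", "Y", "W"))
  expect_equal(a + b, both)
})

test_that("sequence-derived compositions are mass fractions summing to 100", {
  pa <- composition_from_sequence("AAAAA")
  expect_equal(pa$codes, "A")
  expect_equal(pa$g_per_100g, 100)

  av <- composition_from_sequence("AV")
  m <- aceqsar:::AA_RESIDUE_MASS
  expect_equal(av$g_per_100g[av$codes == "A"],
               100 * m["A"] / (m["A"] + m["V"]), ignore_attr = TRUE)
  expect_equal(sum(av$g_per_100g), 100, tolerance = 1e-9)

  set.seed(2)
  seq <- paste(sample(aceqsar:::AA_CODES, 200, replace = TRUE), collapse = "")
  expect_equal(sum(composition_from_sequence(seq)$g_per_100g), 100,
               tolerance = 1e-9)
  expect_error(composition_from_sequence("AXZ1"), "unknown residue")
})

test_that("built-in protease specificities carry the documented preference sets", {
  specs <- builtin_protease_specs()
  expect_length(specs, 4)
  expect_true("L" %in% specs[["Alcalase"]]$preference)
  expect_length(specs[["Neutrase"]]$preference, 3)
  expect_setequal(specs[["Neutrase"]]$preference, c("Y", "W", "F"))
  for (s in specs) {
    expect_true(all(s$preference %in% aceqsar:::AA_CODES))
    expect_gt(length(s$preference), 0)
  }
})

test_that("candidate dipeptides are adjacent pairs ending in preferred residues", {
  specs <- builtin_protease_specs()
  expect_equal(candidate_dipeptides("GAVW", specs[["Neutrase"]])$dipeptide, "VW")
  expect_equal(candidate_dipeptides("GAVW", specs[["Alcalase"]])$dipeptide,
               c("AV", "VW"))
  expect_equal(nrow(candidate_dipeptides("GGGG", specs[["Neutrase"]])), 0)

  set.seed(5)
  seq <- paste(sample(aceqsar:::AA_CODES, 60, replace = TRUE), collapse = "")
  for (s in specs) {
    cand <- candidate_dipeptides(seq, s)
    expect_lte(nrow(cand), nchar(seq) - 1)
    for (i in seq_len(nrow(cand))) {
      expect_equal(substr(seq, cand$position[i], cand$position[i] + 1),
                   cand$dipeptide[i])
      expect_true(substr(cand$dipeptide[i], 2, 2) %in% s$preference)
    }
  }
})

test_that("protease ranking is stable, order-invariant, and handles empty sets", {
  m <- quick_model()
  seq <- "GAVWLWPWAWKWGY"
  specs <- builtin_protease_specs()
  rk1 <- rank_proteases(seq, specs, net = m$network, scaler = m$scaler)
  rk2 <- rank_proteases(seq, rev(specs), net = m$network, scaler = m$scaler)
  expect_equal(rk1$summary[order(rk1$summary$protease), ],
               rk2$summary[order(rk2$summary$protease), ],
               ignore_attr = TRUE)

  two <- list(a = specs[["Neutrase"]], b = specs[["Neutrase"]])
  two$b$name <- "Neutrase-copy"
  rk3 <- rank_proteases(seq, two, net = m$network, scaler = m$scaler)
  expect_equal(rk3$summary$mean_activity[1], rk3$summary$mean_activity[2])

  ## a protease that never matches is excluded but reported
  none <- structure(list(name = "NoCut", preference = "C", note = ""),
                    class = "protease_spec")
  rk4 <- rank_proteases(seq, list(none), net = m$network, scaler = m$scaler)
  expect_null(rk4$summary)
  expect_equal(rk4$excluded, "NoCut")
})

test_that("a Trp-exposing protease outranks a Gly-exposing one on Trp-rich protein", {
  ## C-terminal Trp is the strongest activity signal in the training data
  m <- quick_model()
  seq <- "AWIWGWRWVWGAGAGGAG"
  wspec <- structure(list(name = "Wcut", preference = "W", note = ""),
                     class = "protease_spec")
  gspec <- structure(list(name = "Gcut", preference = "G", note = ""),
                     class = "protease_spec")
  rk <- rank_proteases(seq, list(wspec, gspec), net = m$network,
                       scaler = m$scaler)
  expect_equal(rk$summary$protease[1], "Wcut")
  expect_gt(rk$summary$mean_activity[1], rk$summary$mean_activity[2])
})

test_that("activity prediction validates model compatibility and input", {
  m <- quick_model()
  preds <- predict_activity(m$network, m$scaler, c("IW", "GG"))
  expect_length(preds, 2)
  expect_named(preds, c("IW", "GG"))
  expect_error(predict_activity(m$network, m$scaler, "IWG"), "dipeptide")
  small <- bp_network(3, 2, seed = 1)
  expect_error(predict_activity(small, m$scaler, "IW"), "mismatch")
})
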