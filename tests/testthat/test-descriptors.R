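test_that("Z-scale table holds the full 20-residue descriptor set", {
  z <- zscales()
  expect_equal(nrow(z), 20)
  expect_setequal(rownames(z), aceqsar:::AA_CODES)
  expect_equal(unname(z["W", ]), c(-4.75, 3.65, 0.85))
  expect_equal(unname(z["G", ]), c(2.23, -5.36, 0.30))
  expect_equal(unname(z["I", ]), c(-4.44, -1.68, -1.03))  # "Lie" typo = Ile
  expect_equal(unname(z["Q", ]), c(2.18, 0.53, -1.14))    # "GIn" typo = Gln
})

test_that("peptide encoding concatenates per-residue triples, N-terminal first", {
  expect_equal(unname(encode_peptide("IW")),
               c(-4.44, -1.68, -1.03, -4.75, 3.65, 0.85))
  gg <- encode_peptide("GG")
  expect_equal(unname(gg), c(2.23, -5.36, 0.3, 2.23, -5.36, 0.3))
  aa <- encode_peptide("AA")
  expect_equal(unname(aa[1:3]), unname(aa[4:6]))
  expect_equal(names(encode_peptide("IW")),
               c("z11", "z12", "z13", "z21", "z22", "z23"))
  ## longer peptides encode too: 3 x length
  expect_length(encode_peptide("IWGH"), 12)
})

test_that("unknown residues are rejected naming the offender and position", {
  expect_error(encode_peptide("IX"), "'X' at position 2")
  expect_error(encode_peptide("BW"), "'B' at position 1")
})

test_that("encoding equals direct table lookup for all 400 dipeptides", {
  z <- zscales()
  for (a in rownames(z)) {
    for (b in rownames(z)) {
      expect_identical(unname(encode_peptide(paste0(a, b), table = z)),
                       c(z[a, ], z[b, ], use.names = FALSE))
    }
  }
})

test_that("the packaged dataset loads 58 records in both modes", {
  d <- ace_dipeptides("as-printed")
  dc <- ace_dipeptides("canonical")
  expect_equal(nrow(d), 58)
  expect_equal(nrow(dc), 58)
  ## modes agree record-for-record on sequences and activities
  expect_identical(d$sequence, dc$sequence)
  expect_identical(d$activity, dc$activity)
  iw <- d[d$sequence == "IW", ]
  expect_equal(iw$activity, 5.7)
  gw <- dc[dc$sequence == "GW", ]
  expect_equal(unlist(gw[1, aceqsar:::DESCRIPTOR_NAMES], use.names = FALSE),
               unname(encode_peptide("GW")))
})

test_that("the data audit exposes the printed table's internal inconsistencies", {
  v <- validate_dataset(ace_dipeptides("as-printed"))
  expect_true("AY" %in% v$mismatches$sequence)
  expect_true("RP" %in% v$mismatches$sequence)
  expect_true("RP" %in% v$duplicates$sequence)
  expect_equal(v$duplicates$n[v$duplicates$sequence == "RP"], 2L)
  ## re-derived descriptors are self-consistent by construction
  vc <- validate_dataset(ace_dipeptides("canonical"))
  expect_equal(nrow(vc$mismatches), 0)
})

test_that("min-max normalization maps min to 0, max to 1, midpoint to 0.5", {
  d <- ace_dipeptides()
  sc <- fit_normalizer(d)
  n <- apply_normalizer(sc, d)
  x <- as.matrix(n[, aceqsar:::DESCRIPTOR_NAMES])
  expect_equal(unname(apply(x, 2, min)), rep(0, 6))
  expect_equal(unname(apply(x, 2, max)), rep(1, 6))
  expect_true(all(x >= 0 & x <= 1))
  mid <- (sc$feature_min + sc$feature_max) / 2
  expect_equal(unname(apply_normalizer(sc, mid)), rep(0.5, 6))
  expect_equal(unname(apply_normalizer(sc, sc$feature_min)), rep(0, 6))
})

test_that("normalization round-trips exactly and rejects constant features", {
  d <- ace_dipeptides()
  sc <- fit_normalizer(d)
  x <- as.matrix(as.data.frame(d)[, aceqsar:::DESCRIPTOR_NAMES])
  back <- aceqsar:::denormalize_features(sc, apply_normalizer(sc, x))
  expect_lt(max(abs(back - x)), 1e-12)
  y <- d$activity
  expect_lt(max(abs(denormalize_activity(
    sc, apply_normalizer(sc, d)$activity) - y)), 1e-12)

  dflat <- as.data.frame(d)
  dflat$z13 <- 1
  expect_error(fit_normalizer(aceqsar:::new_qsar_dataset(dflat, "user")), "z13")
})

test_that("out-of-range values pass through unclamped with a flag", {
  sc <- fit_normalizer(ace_dipeptides())
  beyond <- sc$feature_max + 1
  expect_message(out <- apply_normalizer(sc, beyond), "outside")
  expect_true(all(out > 1))
})

test_that("dataset CSV export/import round-trips and rejects non-dipeptides", {
  d <- ace_dipeptides()
  tf <- tempfile(fileext = ".csv")
  write_dataset_csv(d, tf)
  d2 <- read_dataset_csv(tf)
  expect_equal(as.data.frame(d2), as.data.frame(d), ignore_attr = TRUE)
  expect_equal(attr(d2, "provenance"), "user")

  ## sequence+activity only: descriptors re-derived canonically
  tf2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(sequence = c("IW", "GG"), activity = c(5.7, 2.14)),
                   tf2, row.names = FALSE)
  d3 <- read_dataset_csv(tf2)
  expect_equal(unlist(d3[1, aceqsar:::DESCRIPTOR_NAMES], use.names = FALSE),
               unname(encode_peptide("IW")))

  tf3 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(sequence = "IWG", activity = 1), tf3,
                   row.names = FALSE)
  expect_error(read_dataset_csv(tf3), "dipeptide")
})
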