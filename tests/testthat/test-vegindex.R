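test_that("hand-computed single-index values are reproduced", {
  b <- bands1
  # difference indices
  b2 <- b; b2[["nir840"]] <- 0.52; b2[["r660"]] <- 0.08
  expect_equal(compute_index("DVI", b2), 0.44)
  # NDVI symmetry: NIR = R gives 0
  b3 <- b; b3[["nir840"]] <- b3[["r660"]]
  expect_equal(compute_index("NDVI", b3), 0)
  # OSAVI with NIR = 0.5, R = 0.1 -> 0.4 / 0.76
  b4 <- b; b4[["nir840"]] <- 0.5; b4[["r660"]] <- 0.1
  expect_equal(compute_index("OSAVI", b4), 0.4 / 0.76, tolerance = 1e-12)
  # literature forms, evaluated by hand at bands1
  B <- b[["b450"]]; G <- b[["g550"]]; R <- b[["r660"]]
  RE <- b[["re750"]]; NIR <- b[["nir840"]]
  expect_equal(compute_index("TCARI", b),
               3 * ((RE - R) - 0.2 * (RE - G) * (RE / R)))
  expect_equal(compute_index("MSR", b), (NIR / R - 1) / (sqrt(NIR / R) + 1))
  expect_equal(compute_index("CIrededge", b), NIR / RE - 1)
  expect_equal(compute_index("ARVI", b),
               (NIR - (2 * R - B)) / (NIR + (2 * R - B)))
})

test_that("as-printed mode evaluates the parseable literal variants", {
  b <- bands1
  R <- b[["r660"]]; RE <- b[["re750"]]; NIR <- b[["nir840"]]
  expect_equal(compute_index("CIrededge", b, formulas = "as-printed"),
               NIR / (RE - 1))
  expect_equal(compute_index("MNVI", b, formulas = "as-printed"),
               1.5 * (NIR^2 - 2) / (NIR^2 + R + 0.5))
  expect_equal(compute_index("MSR", b, formulas = "as-printed"),
               (NIR / R - 1) / (NIR / R) + 1)
  # no literal variant exists for MTVI: falls back to the corrected form
  expect_equal(compute_index("MTVI", b, formulas = "as-printed"),
               compute_index("MTVI", b))
})

test_that("the registry exposes provenance for every index", {
  reg <- index_registry()
  expect_equal(nrow(reg), 12)
  expect_setequal(reg$provenance, c("as-printed", "literature-corrected"))
  expect_true(all(reg$name[reg$has_printed_variant] %in%
                  c("MSR", "CIrededge", "MNVI")))
})

test_that("NDVI is monotone increasing in NIR and decreasing in R", {
  base <- bands1
  nirs <- seq(0.2, 0.9, length.out = 20)
  vals <- sapply(nirs, function(v) { b <- base; b[["nir840"]] <- v
                                     compute_index("NDVI", b) })
  expect_true(all(diff(vals) > 0))
  rs <- seq(0.02, 0.5, length.out = 20)
  vals <- sapply(rs, function(v) { b <- base; b[["r660"]] <- v
                                   compute_index("NDVI", b) })
  expect_true(all(diff(vals) < 0))
})

test_that("batch computation is total, bounded and deterministic", {
  p <- default_plots(seed = 4)
  tab <- compute_all_indices(p)
  expect_equal(dim(tab), c(66, 13))
  expect_false(anyNA(tab))
  expect_true(all(abs(tab$NDVI) <= 1) && all(abs(tab$GNDVI) <= 1))
  expect_true(all(abs(tab$DVI) < 1))
  expect_identical(tab, compute_all_indices(p))

  # all bands equal: every difference index vanishes
  one <- data.frame(plot_id = "p1", b450 = 0.3, g550 = 0.3, r660 = 0.3,
                    re750 = 0.3, nir840 = 0.3)
  t1 <- compute_all_indices(one)
  expect_equal(t1$NDVI, 0); expect_equal(t1$GNDVI, 0); expect_equal(t1$DVI, 0)
})

test_that("bad inputs are rejected with context", {
  expect_error(compute_index("NOPE", bands1), "NDVI")   # error lists valid names
  expect_error(compute_index("NDVI", c(b450 = 0.1)), "bands")
  bad <- bands1; bad[["nir840"]] <- -0.2
  expect_error(compute_index("NDVI", bad), "finite and > 0")
  p <- default_plots(seed = 5)
  p$r660[7] <- -1
  expect_error(compute_all_indices(p), "plot_07")
})
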