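test_that("pearson_with_p matches hand computation and handles exact fits", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  ct <- pearson_with_p(x, y)
  expect_equal(ct$r, 9 / (2 * sqrt(21)), tolerance = 1e-12)
  expect_equal(pearson_with_p(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_with_p(x, -x)$r, -1)
  expect_error(pearson_with_p(x, c(5, 5, 5)), "constant")
  expect_error(pearson_with_p(x, c(1, 2)), "equal length")
  expect_error(pearson_with_p(c(1, 2), c(3, 4)), "at least 3")
})

test_that("correlation report has the contracted shape and symmetry", {
  p <- default_plots(seed = 8)
  idx <- compute_all_indices(p)
  cg <- build_cgmi(p)
  targ <- cbind(p[c("spad", "ph", "lai", "agb")], cg$table[c("CGMI1", "CGMI2")])
  rep <- correlation_report(idx, targ)
  expect_equal(dim(rep$r), c(12, 6))
  expect_true(all(abs(rep$r) <= 1))
  expect_equal(diag(rep$index_r), rep(1, 12), ignore_attr = TRUE)
  expect_equal(rep$index_r, t(rep$index_r))
  long <- correlation_long(rep)
  expect_equal(nrow(long), 72)
  expect_equal(long$r[long$index == "TCARI" & long$target == "CGMI2"],
               rep$r["TCARI", "CGMI2"])
})

test_that("selection filters by significance then ranks by |r|", {
  p <- default_plots(seed = 9)
  idx <- compute_all_indices(p)
  cg <- build_cgmi(p)
  targ <- cbind(p[c("spad", "ph", "lai", "agb")], cg$table[c("CGMI1", "CGMI2")])
  rep <- correlation_report(idx, targ)
  sel <- select_indices(rep, k = 5, alpha = 0.01)
  expect_length(sel, 5)
  rs <- abs(rep$r[sel, "CGMI2"])
  expect_true(all(diff(rs) <= 1e-12))           # ordered by decreasing |r|
  expect_true(all(rep$p[sel, "CGMI2"] < 0.01))
  # alpha = 1, k = 12: no filtering
  expect_length(select_indices(rep, k = 12, alpha = 1), 12)
  expect_error(select_indices(rep, k = 0), "k")
  expect_error(select_indices(rep, target = "XX"), "unknown target")
})

test_that("selection is invariant to affine rescaling of an index column", {
  p <- default_plots(seed = 10)
  idx <- compute_all_indices(p)
  cg <- build_cgmi(p)
  targ <- cg$table[c("CGMI1", "CGMI2")]
  s1 <- select_indices(correlation_report(idx, targ))
  idx$TCARI <- 100 * idx$TCARI + 3
  idx$DVI <- -2 * idx$DVI
  s2 <- select_indices(correlation_report(idx, targ))
  expect_identical(s1, s2)
})

test_that("fewer significant indices than requested yields all, with warning", {
  set.seed(1)
  idx <- data.frame(A = rnorm(20), B = rnorm(20), C = rnorm(20))
  y <- idx$A + rnorm(20, sd = 0.1)                 # only A is related
  rep <- correlation_report(idx, data.frame(CGMI2 = y))
  expect_warning(sel <- select_indices(rep, k = 5, alpha = 1e-6), "significant")
  expect_true("A" %in% sel && length(sel) < 5)
})

test_that("TCARI is selected for the composite index in most generator draws", {
  hits <- sapply(1:20, function(s) {
    p <- default_plots(seed = s)
    idx <- compute_all_indices(p)
    cg <- build_cgmi(p)
    targ <- cbind(p[c("spad", "ph", "lai", "agb")],
                  cg$table[c("CGMI1", "CGMI2")])
    "TCARI" %in% select_indices(correlation_report(idx, targ))
  })
  expect_gte(mean(hits), 0.8)
})

test_that("noise-free generator makes all red/NIR difference indices significant", {
  p <- generate_plots(noisefree_config())
  idx <- compute_all_indices(p)
  cg <- build_cgmi(p)
  rep <- correlation_report(idx, cg$table["CGMI2"])
  for (nm in c("NDVI", "DVI", "OSAVI", "MSR", "MNVI", "ARVI"))
    expect_lt(rep$p[nm, "CGMI2"], 0.01)
})
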