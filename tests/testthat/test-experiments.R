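# In-silico experiment drivers.

test_that("titration scan has a reference row and responds per the control structure", {
  m <- ref_as30d()
  ss <- ss_as30d()
  sc <- titration_scan(m, c("ENO", "PYK"), factors = c(1, 0.6, 0.25))
  expect_s3_class(sc, "glyco_scan")
  ref <- sc[sc$factor == 1, ]
  expect_equal(ref$flux, ss$pathway_flux, tolerance = 1e-8)
  expect_equal(ref$FBP, unname(ss$concentrations[["FBP"]]),
               tolerance = 1e-8)
  expect_true(all(sc$converged))
  # scan variable strictly monotone within the scan
  expect_true(all(diff(sc$factor) < 0))
  # weakly controlling LDH: titration to 20% barely moves FBP and DHAP
  scl <- titration_scan(m, "LDH", factors = c(1, 0.2))
  rise <- scl[scl$factor == 0.2, c("FBP", "DHAP")] /
    scl[scl$factor == 1, c("FBP", "DHAP")]
  expect_lt(max(unlist(rise)), 1.25)
  expect_gt(min(unlist(rise)), 1)   # still an increase, just marginal
})

test_that("lowering ENO+PYK activity monotonically accumulates Fru1,6BP and DHAP", {
  sc <- titration_scan(ref_as30d(), c("ENO", "PYK"),
                       factors = seq(1, 0.2, by = -0.2))
  expect_true(all(sc$converged))
  # factors are descending, so concentrations must be increasing down rows
  expect_true(all(diff(sc$FBP) > 0))
  expect_true(all(diff(sc$DHAP) > 0))
  # severalfold accumulation at 20% activity
  expect_gt(sc$FBP[nrow(sc)] / sc$FBP[1], 2)
  expect_gt(sc$DHAP[nrow(sc)] / sc$DHAP[1], 2)
})

test_that("factor validation rejects out-of-range titrations", {
  expect_error(titration_scan(ref_as30d(), "ENO", factors = c(1, -0.1)))
  expect_error(titration_scan(ref_as30d(), "ENO", factors = c(2)))
})

test_that("feedback scenarios separate metabolite accumulation from flux inhibition", {
  m <- ref_as30d()
  sc <- scenario_experiment(m, scenarios = c("a", "b", "c", "d", "e"),
                            factors = c(1, 0.25))
  expect_true(all(sc$converged))
  get <- function(s, f, col) sc[sc$scenario == s & sc$factor == f, col]
  for (s in c("a", "b", "c", "d", "e")) {
    # metabolites accumulate in every scenario
    expect_gt(get(s, 0.25, "FBP"), get(s, 1, "FBP"))
    expect_gt(get(s, 0.25, "DHAP"), get(s, 1, "DHAP"))
  }
  # without any feedback the flux and ATP are untouched by the titration
  expect_lt(abs(get("a", 0.25, "flux") / get("a", 1, "flux") - 1), 0.02)
  expect_lt(abs(get("a", 0.25, "ATP") / get("a", 1, "ATP") - 1), 0.02)
  # with feedback on the controlling steps both fall
  for (s in c("d", "e")) {
    expect_lt(get(s, 0.25, "flux"), get(s, 1, "flux"))
    expect_lt(get(s, 0.25, "ATP"), get(s, 1, "ATP"))
  }
  # flux suppression ordering at 25% activity: both-enzymes feedback is at
  # least as inhibitory as either single-enzyme scenario
  supp <- function(s) 1 - get(s, 0.25, "flux") / get(s, 1, "flux")
  expect_gte(supp("d") + 1e-3, supp("b"))
  expect_gte(supp("d") + 1e-3, supp("c"))
})

test_that("Ki scans separate the inhibition mechanisms in the expected order", {
  m <- ref_hela_hypo()
  grid <- c(0.1, 1, 3, 10, 1000)
  scans <- lapply(c("competitive", "uncompetitive", "mixed"), function(me)
    ki_scan(m, me, ki_scale = grid))
  names(scans) <- c("competitive", "uncompetitive", "mixed")
  for (sc in scans) {
    expect_true(all(sc$converged))
    # stronger inhibition (smaller Ki) raises the HPI flux control
    expect_true(all(diff(sc$CJ_HPI) <= 1e-6))
    # and suppresses flux while Glc6P accumulates
    expect_true(all(diff(sc$flux) >= -1e-9))
    expect_true(all(diff(sc$Glc6P) <= 1e-9))
  }
  # at equal Ki: competitive flux >= mixed >= uncompetitive
  for (i in seq_along(grid)) {
    expect_gte(scans$competitive$flux[i] + 1e-9, scans$mixed$flux[i])
    expect_gte(scans$mixed$flux[i] + 1e-9, scans$uncompetitive$flux[i])
  }
  # mechanisms converge to the uninhibited model at very large Ki
  f_inf <- vapply(scans, function(sc) sc$flux[length(grid)], numeric(1))
  expect_lt(max(f_inf) - min(f_inf), 1e-3 * max(f_inf))
})

test_that("observation comparison computes z-scores, fold changes and Welch tests", {
  obs <- observation_table(
    metabolite = rep(c("FBP", "DHAP", "ATP"), 2),
    treatment = rep(c("control", "iodoacetate_2"), each = 3),
    mean = c(2.4, 1.8, 6, 7, 33, 1.4),
    sd = c(1.7, 0.4, 2, 1, 9, 0.5),
    n = c(3, 5, 3, 3, 3, 3))
  pred <- c(FBP = 7, DHAP = 20, ATP = 2)
  cmp <- compare_observations(pred, obs, treatment = "iodoacetate_2")
  # prediction equal to the observed mean has z = 0
  expect_equal(cmp$z[cmp$metabolite == "FBP"], 0)
  expect_equal(cmp$z[cmp$metabolite == "DHAP"], (20 - 33) / 9)
  # the reported DHAP accumulation is significant under a Welch test
  expect_lt(cmp$p_value_vs_control[cmp$metabolite == "DHAP"], 0.05)
  # fold changes against the control means
  expect_equal(cmp$fold_change_vs_control[cmp$metabolite == "FBP"],
               7 / 2.4)
  # unmatched observed metabolites are listed, not fatal
  obs2 <- rbind(obs, observation_table("Mgo", "iodoacetate_2", 2.2, 0.6, 3))
  cmp2 <- compare_observations(pred, obs2, treatment = "iodoacetate_2")
  expect_equal(attr(cmp2, "unmatched"), "Mgo")
})

test_that("fold change of printed magnitude arises from a strong joint titration", {
  # oxamate-style inhibition emulated as a ~75% ENO+PYK activity decrease
  # yields a severalfold rise of Fru1,6BP over its own control value
  sc <- titration_scan(ref_as30d(), c("ENO", "PYK"), factors = c(1, 0.25))
  fold <- sc$FBP[sc$factor == 0.25] / sc$FBP[sc$factor == 1]
  expect_gt(fold, 2)
})

test_that("scan tables round-trip losslessly through the results writer", {
  sc <- titration_scan(ref_as30d(), "ENO", factors = c(1, 0.5))
  dir <- withr::local_tempdir()
  write_results(list(titration = as.data.frame(sc)), dir, format = "csv",
                meta = list(model = "AS30D", seed = 1))
  back <- read_results_table(file.path(dir, "titration.csv"))
  for (col in c("factor", "flux", "FBP", "DHAP", "ATP"))
    expect_identical(back[[col]], sc[[col]])
  expect_true(any(grepl("seed", attr(back, "meta"))))
})
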