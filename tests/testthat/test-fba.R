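# FBA, flux-variability readouts, anti-Warburg ratio, pHi sweep.

test_that("biomass optima match the hand-derived LP solutions", {
  m <- make_toy_model()
  fba <- optimize_biomass(m)
  # carrier saturates at 5: B = (2*10 + 15*5) / 10
  expect_equal(fba$biomass, 9.5, tolerance = 1e-9)
  expect_equal(fba$fluxes[["PYRt"]], 5, tolerance = 1e-9)
  m2 <- make_toy_model(toy_spec(include_oxphos = FALSE))
  fba2 <- optimize_biomass(m2)
  expect_equal(fba2$biomass, 2, tolerance = 1e-9)
  expect_equal(fba2$fluxes[["EX_lac"]], 18, tolerance = 1e-9)
})

test_that("FBA agrees with the vertex-enumeration oracle on all fixtures", {
  fixtures <- list(
    load_model(system.file("extdata", "toy_model_sbml.xml",
                           package = "phifba")),
    make_toy_model(toy_spec(include_oxphos = FALSE)),
    make_toy_model(toy_spec(n_glycolysis_steps = 1L,
                            paralog_pairs = list())))
  for (m in fixtures) {
    expect_equal(optimize_biomass(m)$biomass,
                 oracle_fba(m)$objective, tolerance = 1e-6)
    # also under pH constraints
    db <- make_profiles(m, "cancer_like", seed = 3)
    for (ph in c(6.6, 7.1, 7.9)) {
      st <- constrain_model(m, db, ph)
      expect_equal(optimize_biomass(m, st)$biomass,
                   max(oracle_fba(m, st)$objective, 0),
                   tolerance = 1e-6)
    }
  }
})

test_that("starved or cut models report zero biomass, not errors", {
  m <- make_toy_model()
  closed <- m
  ex <- closed$reactions$id %in% c("EX_glc", "EX_o2")
  closed$reactions$lb[ex] <- 0
  closed$reactions$ub[ex] <- 0
  expect_equal(optimize_biomass(closed)$biomass, 0)
  # knocking out the sole glucose entry is a lethal cut
  st <- constrain_model(m, list(), 7.0,
                        gene_weight_override = c(g_glut1 = 0))
  expect_equal(optimize_biomass(m, st)$biomass, 0)
})

test_that("reported fluxes below 1e-7 are exact zeros", {
  m <- make_toy_model(toy_spec(include_oxphos = FALSE))
  rd <- fva_readouts(m)
  expect_identical(rd$rates[["oxygen"]], 0)  # no sink: exactly zero
  fb <- optimize_biomass(m)
  expect_true(all(fb$fluxes == 0 | abs(fb$fluxes) >= 1e-7))
})

test_that("degenerate FVA at fraction 1 returns the unique optimum", {
  m <- make_toy_model()
  rd <- fva_readouts(m, biomass_fraction = 1)
  fb <- optimize_biomass(m)
  expect_equal(rd$biomass, fb$biomass)
  expect_equal(rd$rates[["oxygen"]], fb$fluxes[["EX_o2"]],
               tolerance = 1e-6)
  expect_equal(rd$rates[["lactate"]], fb$fluxes[["EX_lac"]],
               tolerance = 1e-6)
  expect_equal(rd$rates[["glucose"]], -10, tolerance = 1e-6)
})

test_that("with oxygen closed the cell ferments: lactate out, no OCR", {
  m <- make_toy_model()
  m$reactions$lb[m$reactions$id == "EX_o2"] <- 0
  rd <- fva_readouts(m)
  expect_identical(rd$rates[["oxygen"]], 0)
  expect_gt(rd$rates[["lactate"]], 0)
  expect_equal(rd$biomass, 2, tolerance = 1e-9)
})

test_that("readouts are robust across the 70-90% biomass floor", {
  m <- make_toy_model()
  db <- make_profiles(m, "cancer_like", seed = 1)
  st <- constrain_model(m, db, 7.4)
  r8 <- fva_readouts(m, st, biomass_fraction = 0.8)
  r9 <- fva_readouts(m, st, biomass_fraction = 0.9)
  for (role in c("oxygen", "glucose", "lactate")) {
    expect_lt(abs(r9$rates[[role]] - r8$rates[[role]]) /
                max(abs(r8$rates[[role]]), 1e-9), 0.3)
  }
  expect_error(fva_readouts(m, st, biomass_fraction = 1.5), "biomass")
})

test_that("anti-Warburg ratio handles oxidative and undefined limits", {
  mk <- function(o2, lac) {
    structure(list(rates = c(oxygen = o2, lactate = lac)),
              class = "flux_readout")
  }
  expect_equal(anti_warburg_ratio(mk(-2, 4)), 0.5)
  expect_identical(anti_warburg_ratio(mk(-3, 0)), Inf)
  expect_true(is.nan(anti_warburg_ratio(mk(0, 0))))
})

test_that("uptake rates are negative, secretion positive, biomass >= 0", {
  m <- make_toy_model()
  db <- make_profiles(m, "cancer_like", seed = 2)
  sw <- ph_sweep(m, db, ph_grid = seq(6.6, 8.2, by = 0.4))
  expect_true(all(sw$biomass >= 0))
  expect_true(all(sw$o2 <= 0, na.rm = TRUE))
  expect_true(all(sw$glc <= 0, na.rm = TRUE))
  expect_true(all(sw$lac >= 0, na.rm = TRUE))
})

test_that("pH sweep normalizes by the sweep maximum and flags failures", {
  m <- make_toy_model()
  flat <- flat_profiles(m)
  sw <- ph_sweep(m, flat, ph_grid = seq(6.7, 7.7, by = 0.5),
                 readouts = FALSE)
  expect_equal(sw$norm_biomass, rep(1, nrow(sw)))
  expect_equal(sw$biomass, rep(9.5, nrow(sw)), tolerance = 1e-9)
  # acidic extremes legitimately shut the model down: biomass 0, no error
  db <- make_profiles(m, "cancer_like", seed = 1, jitter_sd = 0)
  sw2 <- ph_sweep(m, db, ph_grid = c(5.5, 7.3), readouts = FALSE)
  expect_equal(sw2$biomass[1], 0)
  expect_equal(sw2$norm_biomass[2], 1)
})

test_that("cancer-like and normal-like toys reproduce the divergent
           pH response", {
  m <- make_toy_model()
  swc <- ph_sweep(m, make_profiles(m, "cancer_like", seed = 1),
                  readouts = FALSE)
  expect_gte(swc$ph[which.max(swc$biomass)], 7.3)
  expect_lt(swc$biomass[swc$ph == 6.7] / max(swc$biomass), 0.5)
  swn <- ph_sweep(m, make_profiles(m, "normal_like", seed = 2),
                  readouts = FALSE)
  win <- swn[swn$ph >= 6.7 & swn$ph <= 7.8, ]
  expect_lt(max(win$biomass) / min(win$biomass), 1.25)
  expect_lt(abs(swn$biomass[swn$ph == 6.7] -
                  swn$biomass[swn$ph == 7.3]) / max(swn$biomass), 0.1)
})

test_that("the cancer-like toy is Warburg-like at alkaline pHi", {
  m <- make_toy_model()
  db <- make_profiles(m, "cancer_like", seed = 1)
  low <- fva_readouts(m, constrain_model(m, db, 6.7))
  phys <- fva_readouts(m, constrain_model(m, db, 7.4))
  # higher glucose uptake and lower |OCR|-to-lactate at alkaline pHi
  expect_lt(phys$rates[["glucose"]], low$rates[["glucose"]])
  expect_gt(low$anti_warburg, phys$anti_warburg)
})
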