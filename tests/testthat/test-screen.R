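# Knockout screen: scores, recurrence, quadrants, panel behavior.

test_that("gene knockouts respect GPR logic: lethal cuts and isozyme
           rescue", {
  m <- make_toy_model()
  db <- flat_profiles(m)
  b_wt <- optimize_biomass(m, constrain_model(m, db, 7.0))$biomass
  # sole transporter: lethal
  expect_equal(knockout_gene(m, db, "g_glut1", 7.0), 0)
  # one isozyme of the OR junction: fully rescued by its paralog
  expect_equal(knockout_gene(m, db, "g_gapdh", 7.0), b_wt)
  expect_equal(knockout_gene(m, db, "g_gapdhs", 7.0), b_wt)
  # the shared reaction: not rescued (the step every isozyme feeds)
  b_rxn <- knockout_reaction(m, db, "GLY1", 7.0)
  expect_lt(b_rxn, b_wt)
  expect_equal(b_rxn, 1.2, tolerance = 1e-9)  # pentose-shunt bypass
  expect_error(knockout_gene(m, db, "nope", 7.0), "unknown gene")
  expect_error(knockout_reaction(m, db, "nope", 7.0), "unknown reaction")
})

test_that("a gene absent from every rule is a knockout no-op", {
  m <- load_model(system.file("extdata", "toy_model_sbml.xml",
                              package = "phifba"))
  db <- flat_profiles(m)
  b_wt <- optimize_biomass(m, constrain_model(m, db, 7.0))$biomass
  expect_equal(knockout_gene(m, db, "g0", 7.0), b_wt)
})

test_that("reaction knockouts: zero-flux reactions are no-ops, biomass
           knockout is fatal", {
  m <- make_toy_model()
  db <- flat_profiles(m)
  b_wt <- optimize_biomass(m, constrain_model(m, db, 7.0))$biomass
  expect_equal(knockout_reaction(m, db, "PPP", 7.0), b_wt)  # unused shunt
  expect_equal(knockout_reaction(m, db, "BIOMASS", 7.0), 0)
})

test_that("gene KO equals reaction KO when the rule is that single leaf", {
  m <- make_toy_model()
  db <- make_profiles(m, "cancer_like", seed = 5)
  for (ph in c(6.7, 7.3)) {
    expect_identical(knockout_gene(m, db, "g_glut1", ph),
                     knockout_reaction(m, db, "GLCt", ph))
    expect_identical(knockout_gene(m, db, "g_mpc1", ph),
                     knockout_reaction(m, db, "PYRt", ph))
  }
})

test_that("normalized biomass handles the zero-growth conventions", {
  expect_equal(normalized_biomass(0.4, 0.8), 0.5)
  expect_equal(normalized_biomass(0, 0.8), 0)
  expect_equal(normalized_biomass(0.8, 0.8), 1)
  expect_equal(normalized_biomass(0, 0), 1)       # nothing changed
  expect_true(is.na(normalized_biomass(0.5, 0)))  # growth from nothing
  expect_error(normalized_biomass(1, -1))
})

test_that("SEL and PHS are simple differences, antisymmetric in their
           arguments", {
  expect_equal(sel_score(0.9, 0.4), 0.5)
  expect_equal(phs_score(0.9, 0.6), 0.3)
  expect_equal(phs_score(1.0, 0.2), 0.8)
  set.seed(3)
  a <- runif(10); b <- runif(10)
  expect_equal(sel_score(a, b), -sel_score(b, a))
  expect_equal(phs_score(a, b), -phs_score(b, a))
})

test_that("recurrence filter: 12 of 96 pairs, 1 of 8 cells", {
  r96 <- recurrence_filter(c(rep(0.2, 12), rep(0, 84)))
  expect_equal(r96$min_count, 12)
  expect_true(r96$pass)
  expect_equal(r96$frequency, 0.125)
  expect_false(recurrence_filter(c(rep(0.2, 11), rep(0, 85)))$pass)
  r8 <- recurrence_filter(c(0.3, rep(0, 7)))
  expect_equal(r8$min_count, 1)
  expect_true(r8$pass)
  rz <- recurrence_filter(rep(0, 20))
  expect_false(rz$pass)
  expect_equal(rz$frequency, 0)
  expect_error(recurrence_filter(numeric()), "empty")
})

test_that("quadrant classification combines score sign and recurrence", {
  expect_identical(classify_target(0.2, TRUE, 0.1, TRUE),
                   "selective_and_ph_specific")
  expect_identical(classify_target(0.2, TRUE, 0, TRUE), "selective_only")
  expect_identical(classify_target(0, TRUE, 0.1, TRUE),
                   "ph_specific_only")
  expect_identical(classify_target(0, TRUE, 0, TRUE), "neither")
  # positive mean without recurrence does not count
  expect_identical(classify_target(0.2, FALSE, 0.1, FALSE), "neither")
})

test_that("the fixture screen finds the respiratory bottleneck as
           selective and pH-specific", {
  panel <- make_test_panel()
  sc <- run_screen(panel, "gene")
  row <- sc[sc$target == "g_mpc1", ]
  expect_identical(row$quadrant, "selective_and_ph_specific")
  expect_gt(row$SEL, 0)
  expect_gt(row$PHS, 0)
  expect_equal(row$sel_recurrence, 1)
  # sorted by PHS then SEL descending
  expect_true(!is.unsorted(rev(sc$PHS)))
  # normalized biomass never exceeds 1 (knockouts only shrink the cone)
  expect_true(all(attr(sc, "nB") <= 1 + 1e-6, na.rm = TRUE))
})

test_that("flat profiles silence every score", {
  m <- make_toy_model()
  flat <- flat_profiles(m)
  panel <- panel_config(
    cancer_cells = list(screen_cell("c1", m, flat)),
    normal_cells = list(screen_cell("n1", m, flat),
                        screen_cell("n2", m, flat)))
  sc <- run_screen(panel, "gene")
  expect_true(all(abs(sc$SEL) < 1e-9))
  expect_true(all(abs(sc$PHS) < 1e-9))
  expect_true(all(sc$quadrant == "neither"))
})

test_that("rankings are stable under partial gene inhibition", {
  # a residual weight leaves the knockout a fraction of the bottleneck
  # flux; at toy scale a 10% residual of the single respiratory carrier
  # already rewrites the energy budget, so stability is asserted over
  # the range the five-reaction energy core can resolve (see the
  # methods vignette on granularity)
  sc0 <- run_screen(make_test_panel(inhibition = 0), "gene")
  sc1 <- run_screen(make_test_panel(inhibition = 0.02), "gene")
  expect_identical(sc0$target[1], sc1$target[1])
  expect_identical(stats::setNames(sc1$quadrant, sc1$target)[sc0$target],
                   stats::setNames(sc0$quadrant, sc0$target))
  expect_setequal(sc0$target[sc0$PHS > 1e-9], sc1$target[sc1$PHS > 1e-9])
  expect_setequal(sc0$target[sc0$SEL > 1e-9], sc1$target[sc1$SEL > 1e-9])
  # the full inhibition range still runs and keeps scores bounded
  sc2 <- run_screen(make_test_panel(inhibition = 0.1), "gene")
  expect_true(all(abs(sc2$SEL) <= 1 + 1e-6))
  expect_true(all(abs(sc2$PHS) <= 1 + 1e-6))
})

test_that("equal low and physiological pH nullifies pH-specificity", {
  panel <- make_test_panel(ph_low = 7.3 - 1e-9, ph_phys = 7.3)
  sc <- run_screen(panel, "gene")
  expect_true(all(abs(sc$PHS) < 1e-6))
})

test_that("screen output is invariant to panel cell ordering", {
  m <- make_toy_model()
  cc <- lapply(1:2, function(i) screen_cell(
    paste0("cancer", i), m, make_profiles(m, "cancer_like", 10L + i)))
  nn <- lapply(1:3, function(i) screen_cell(
    paste0("normal", i), m, make_profiles(m, "normal_like", 20L + i)))
  s1 <- run_screen(panel_config(cc, nn), "gene")
  s2 <- run_screen(panel_config(rev(cc), rev(nn)), "gene")
  expect_identical(s1$target, s2$target)
  expect_equal(s1$SEL, s2$SEL)
  expect_equal(s1$PHS, s2$PHS)
})

test_that("reaction-level screening reveals the isozyme-masked junction", {
  panel <- make_test_panel()
  scg <- run_screen(panel, "gene",
                    targets = c("g_gapdh", "g_gapdhs"))
  scr <- run_screen(panel, "reaction", targets = "GLY1")
  # each isozyme alone is silent, the shared reaction is not
  expect_true(all(abs(scg$SEL) < 1e-9))
  expect_false(abs(scr$SEL) < 1e-9)
})

test_that("readout columns quantify the knockout's anti-Warburg shift", {
  panel <- make_test_panel()
  sc <- run_screen(panel, "gene", targets = c("g_mpc1", "g_ldha"),
                   readouts = TRUE)
  expect_true(all(c("dOCR", "dGlc", "dLac", "dATP", "dNADPH", "dROS",
                    "anti_warburg_low", "anti_warburg_phys")
                  %in% names(sc)))
  mpc <- sc[sc$target == "g_mpc1", ]
  expect_gt(mpc$dOCR, 0)   # oxygen uptake collapses (rate moves toward 0)
  expect_lt(mpc$dATP, 0)   # respiration lost
})
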