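# Homolog transfer, per-point regression, imputation, cross-validation.

make_hom_table <- function(query, hits) {
  data.frame(query_id = query, hit_id = hits,
             rank = seq_along(hits), score = rev(seq_along(hits)),
             stringsAsFactors = FALSE)
}

test_that("homolog transfer fills missing points with the hit median", {
  db <- list(
    h1 = ph_profile("h1", c(A50 = 6.2)),
    h2 = ph_profile("h2", c(A50 = 6.4)),
    h3 = ph_profile("h3", c(A50 = 6.9)))
  q <- ph_profile("q", c(A100 = 7.0, B100 = 7.4))
  tbl <- make_hom_table("q", c("h1", "h2", "h3"))
  out <- transfer_from_homologs(q, tbl, db, k = 5)
  expect_equal(out$points[["A50"]], 6.4)
  expect_identical(out$source[["A50"]], "homolog")
  # points no hit carries stay missing
  expect_true(is.na(out$points[["B0"]]))
  # only the k closest informative hits are used
  db$h4 <- ph_profile("h4", c(A50 = 9.9))
  out2 <- transfer_from_homologs(q, make_hom_table("q", paste0("h", 1:4)),
                                 db, k = 3)
  expect_equal(out2$points[["A50"]], 6.4)
})

test_that("complete profiles and empty tables pass through unchanged", {
  full <- linear_profile_db(1, seed = 5)[[1]]
  tbl <- make_hom_table(full$enzyme_id, "h1")
  expect_identical(transfer_from_homologs(full, tbl, list()), full)
  q <- ph_profile("q", c(A100 = 7.0))
  expect_identical(
    transfer_from_homologs(q, make_hom_table("other", "h1"), list()), q)
})

test_that("homology table validation enforces unique ranks from 1", {
  bad <- data.frame(query_id = "q", hit_id = c("a", "b"),
                    rank = c(2L, 3L), score = c(1, 2))
  expect_error(validate_homology(bad), "start at 1")
  bad2 <- data.frame(query_id = "q", hit_id = c("a", "b"),
                     rank = c(1L, 1L), score = c(1, 2))
  expect_error(validate_homology(bad2), "unique")
})

test_that("point regressors recover exact and noisy linear relations", {
  # exact affine rule: zero residual, exact prediction (the design is
  # perfectly collinear, which the fitter flags)
  db <- linear_profile_db(30, seed = 2)
  reg <- suppressWarnings(fit_point_regressors(db))
  p <- db[[1]]$points
  pred <- predict_point(reg, "A50", p[setdiff(PH_POINTS, "A50")])
  expect_equal(pred, unname(p[["A50"]]), tolerance = 1e-8)

  # A0 = A100 - 1 + noise(sd 0.05): the acidic-limit predictor refit on
  # the {A100} availability pattern recovers slope 1 on held-out input
  set.seed(7)
  db2 <- list()
  for (i in 1:200) {
    a100 <- runif(1, 6.8, 7.4)
    pts <- c(A0 = a100 - 1 + rnorm(1, 0, 0.05),
             A50 = a100 - runif(1, 0.3, 0.6),
             A100 = a100,
             B100 = a100 + runif(1, 0.2, 0.6),
             B50 = a100 + runif(1, 0.8, 1.2),
             B0 = a100 + runif(1, 1.4, 1.8))
    id <- sprintf("n%03d", i)
    db2[[id]] <- ph_profile(id, pts)
  }
  reg2 <- fit_point_regressors(db2)
  slope <- (predict_point(reg2, "A0", c(A100 = 7.4)) -
              predict_point(reg2, "A0", c(A100 = 6.8))) / 0.6
  expect_equal(slope, 1, tolerance = 0.05)
})

test_that("degenerate training sets are signalled", {
  expect_error(fit_point_regressors(linear_profile_db(5)),
               "at least 10")
  const <- lapply(sprintf("c%02d", 1:12), function(id)
    ph_profile(id, c(A0 = 6, A50 = 6.3, A100 = 6.6, B100 = 7.4,
                     B50 = 7.8, B0 = 8.2)))
  names(const) <- vapply(const, `[[`, "", "enzyme_id")
  w <- capture_warnings(reg <- fit_point_regressors(const))
  expect_true(any(grepl("degenerate", w)))  # flagged once per point
  # intercept-only fallback predicts the constant
  expect_equal(predict_point(reg, "A50", c(A100 = 7.0)), 6.3,
               tolerance = 1e-8)
})

test_that("imputation order is homologs first, then regression", {
  db <- linear_profile_db(30, seed = 4)
  reg <- suppressWarnings(fit_point_regressors(db))
  q <- ph_profile("q", c(A0 = 6.0, A100 = 7.0, B100 = 7.6, B50 = 8.0))
  hom_db <- list(h1 = ph_profile("h1", c(A50 = 6.5)))
  tbl <- make_hom_table("q", "h1")
  out <- impute_profile(q, tbl, hom_db, reg)
  expect_true(profile_is_complete(out))
  expect_identical(out$source[["A50"]], "homolog")
  expect_identical(out$source[["B0"]], "regressed")
  expect_identical(out$source[["A0"]], "experimental")
})

test_that("imputation is idempotent on complete profiles and rejects
           unusable or disordered results", {
  db <- linear_profile_db(30, seed = 4)
  reg <- suppressWarnings(fit_point_regressors(db))
  full <- db[[1]]
  expect_identical(impute_profile(full, regressors = reg), full)
  expect_error(impute_profile(ph_profile("void")), "unusable")
  # a homolog fill that lands inside the plateau breaks the ordering
  q <- ph_profile("q", c(A0 = 6.0, A50 = 6.5, A100 = 7.0, B100 = 7.6,
                         B50 = 8.0))
  hom_db <- list(h1 = ph_profile("h1", c(B0 = 7.1)))
  expect_warning(out <- impute_profile(q, make_hom_table("q", "h1"),
                                       hom_db),
                 "invalid")
  expect_true(isTRUE(attr(out, "invalid")))
  # impute_db drops it and reports
  dropped <- impute_db(list(q = q), table = make_hom_table("q", "h1"))
  expect_identical(attr(dropped, "dropped"), "q")
})

test_that("cross-validation is exact on a noise-free linear database", {
  db <- linear_profile_db(60, seed = 0)
  for (proto in c("kfold", "leave_species_out", "leave_ec_out")) {
    cv <- cross_validate(db, folds = 10, protocol = proto, seed = 0)
    expect_equal(cv$r, rep(1, 6), tolerance = 1e-6)
    expect_equal(cv$rmse, rep(0, 6), tolerance = 1e-6)
  }
})

test_that("cross-validation RMSE tracks the generating noise", {
  db <- linear_profile_db(200, seed = 0, noise_sd = 0.1)
  # sorting the six noisy points can only tighten them; drop profiles
  # whose draw violated the generating offsets' order to keep the rule
  cv <- cross_validate(db, folds = 10, protocol = "kfold", seed = 0)
  expect_true(all(cv$rmse >= 0.05 & cv$rmse <= 0.2))
  expect_true(all(cv$r > 0.9))
  # constant database: zero RMSE
  const <- lapply(sprintf("c%02d", 1:15), function(id)
    ph_profile(id, c(A0 = 6, A50 = 6.3, A100 = 6.6, B100 = 7.4,
                     B50 = 7.8, B0 = 8.2), taxon = "human",
    ec = "1.1.1.1"))
  names(const) <- vapply(const, `[[`, "", "enzyme_id")
  cvc <- suppressWarnings(cross_validate(const, folds = 5, seed = 0))
  expect_equal(cvc$rmse, rep(0, 6), tolerance = 1e-8)
  expect_error(cross_validate(linear_profile_db(8), folds = 10),
               "at least 10")
})
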