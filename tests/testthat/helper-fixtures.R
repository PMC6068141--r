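# Shared fixture builders.

# The standing five-cell panel: two cancer-like, three normal-like
# toy cells sharing the default topology, individualized by seeded
# profile jitter.
make_test_panel <- function(model = make_toy_model(), ...) {
  panel_config(
    cancer_cells = lapply(1:2, function(i) screen_cell(
      paste0("cancer", i), model,
      make_profiles(model, "cancer_like", seed = 10L + i))),
    normal_cells = lapply(1:3, function(i) screen_cell(
      paste0("normal", i), model,
      make_profiles(model, "normal_like", seed = 20L + i))),
    ...)
}

# Flat profile database: full activity everywhere in (6.0, 8.4).
flat_profiles <- function(model) {
  tpl <- c(A0 = 6.0, A50 = 6.3, A100 = 6.6, B100 = 7.8,
           B50 = 8.1, B0 = 8.4)
  stats::setNames(lapply(model$genes, ph_profile, points = tpl),
                  model$genes)
}

# Synthetic profile database following an exact linear rule: every
# critical point is an affine function of a per-enzyme anchor, so a
# linear regressor predicts each point from the others perfectly.
linear_profile_db <- function(n, seed = 0L, noise_sd = 0,
                              taxa = c("human", "mouse", "yeast"),
                              ecs = c("1.1.1.1", "2.7.1.1", "5.3.1.9")) {
  set.seed(seed)
  anchors <- runif(n, 6.2, 7.4)
  offsets <- c(A0 = -1.0, A50 = -0.5, A100 = 0, B100 = 0.6,
               B50 = 1.0, B0 = 1.6)
  out <- list()
  for (i in seq_len(n)) {
    pts <- anchors[i] + offsets + stats::rnorm(6L, 0, noise_sd)
    pts <- stats::setNames(sort(pts), names(offsets))
    id <- sprintf("enz%03d", i)
    out[[id]] <- ph_profile(id, pts,
                            taxon = taxa[(i %% length(taxa)) + 1L],
                            ec = ecs[(i %% length(ecs)) + 1L])
  }
  out
}

# The worked six-record example enzyme: one record per critical point.
example_records <- function(enzyme_id = "enzA") {
  data.frame(
    enzyme_id = enzyme_id, ec = "1.1.1.1", taxon = "human",
    ph = c(6.0, 6.5, 7.0, 7.6, 8.0, 8.6),
    activity_pct = c(10, 60, 100, 100, 60, 10),
    record_kind = c("range", "range", "optimum", "optimum", "range",
                    "range"),
    stringsAsFactors = FALSE)
}
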