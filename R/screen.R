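# In-silico knockout screen: gene- and reaction-level knockouts, SEL and
# PHS scores, recurrence filtering, quadrant classification, the
# divide-and-conquer modulator search, and robustness analyses.

#' Bundle a cell (model + its pH-activity profiles) for screening
#' @param id cell identifier.
#' @param model a \code{metabolic_model}.
#' @param profiles named list of complete \code{ph_profile}.
#' @export
screen_cell <- function(id, model, profiles) {
  list(id = id, model = model, profiles = profiles)
}

#' Panel configuration for the knockout screen
#'
#' @param cancer_cells,normal_cells lists of [screen_cell()] objects.
#' @param ph_low "low" intracellular pH (default 6.7).
#' @param ph_phys "physiological" intracellular pH (default 7.3).
#' @param inhibition residual gene weight used for knockouts, in
#'   \[0, 0.1\] (default 0 = full knockout; rankings are robust over the
#'   whole range).
#' @param zero_tol flux/score zeroing threshold (default 1e-7).
#' @param recurrence_min minimal recurrence frequency for a score to
#'   count (default 0.125, i.e. 12/96 pairs or 1/8 cancer cells on the
#'   full panel).
#' @param biomass_fraction FVA biomass floor (default 0.8).
#' @export
panel_config <- function(cancer_cells, normal_cells, ph_low = 6.7,
                         ph_phys = 7.3, inhibition = 0, zero_tol = 1e-7,
                         recurrence_min = 0.125, biomass_fraction = 0.8) {
  stopifnot(ph_low < ph_phys, inhibition >= 0, inhibition <= 0.1)
  structure(list(cancer = cancer_cells, normal = normal_cells,
                 ph_low = ph_low, ph_phys = ph_phys,
                 inhibition = inhibition, zero_tol = zero_tol,
                 recurrence_min = recurrence_min,
                 biomass_fraction = biomass_fraction),
            class = "panel_config")
}

#' Biomass after a simulated gene knockout
#'
#' The knockout of gene G is simulated by overriding its weight to
#' \code{w_ko} (0 = complete inhibition, up to 0.1 = 90% inhibition)
#' before constraining and optimizing.
#'
#' @param model a \code{metabolic_model}.
#' @param profiles named list of complete \code{ph_profile}.
#' @param gene gene id present in the model.
#' @param ph intracellular pH.
#' @param w_ko residual weight in \[0, 0.1\].
#' @param cytosol_only see [constrain_model()].
#' @return the knockout biomass flux.
#' @export
knockout_gene <- function(model, profiles, gene, ph, w_ko = 0,
                          cytosol_only = TRUE) {
  stopifnot(w_ko >= 0, w_ko <= 0.1)
  if (!gene %in% model$genes) stop("unknown gene '", gene, "'")
  st <- constrain_model(model, profiles, ph, cytosol_only,
                        gene_weight_override = stats::setNames(w_ko, gene))
  optimize_biomass(model, st)$biomass
}

#' Biomass after a reaction knockout
#'
#' The reaction's bounds are forced to (0, 0) on top of the pH
#' constraints, bypassing any gene-level redundancy (isozymes mask
#' gene-level knockouts of shared steps; the reaction-level knockout
#' reveals them).
#'
#' @inheritParams knockout_gene
#' @param reaction reaction id present in the model.
#' @export
knockout_reaction <- function(model, profiles, reaction, ph,
                              cytosol_only = TRUE) {
  j <- match(reaction, model$reactions$id)
  if (is.na(j)) stop("unknown reaction '", reaction, "'")
  st <- constrain_model(model, profiles, ph, cytosol_only)
  st$LB[j] <- 0; st$UB[j] <- 0
  optimize_biomass(model, st)$biomass
}

#' Normalized post-knockout biomass nB = B_KO / B_WT
#'
#' When the wild type itself cannot grow (B_WT below \code{zero_tol})
#' the ratio is defined as 1 when the knockout cannot grow either (the
#' knockout changed nothing) and flagged undefined (`NA`) otherwise.
#'
#' @param b_ko knockout biomass.
#' @param b_wt wild-type biomass (>= 0).
#' @param zero_tol zeroing threshold.
#' @export
normalized_biomass <- function(b_ko, b_wt, zero_tol = 1e-7) {
  stopifnot(b_wt >= 0)
  if (b_wt < zero_tol) {
    if (b_ko < zero_tol) return(1)
    return(NA_real_)
  }
  b_ko / b_wt
}

#' Selectivity score SEL = nB(normal) - nB(cancer)
#'
#' Evaluated at low pH over every cancer-normal pair; positive values
#' mean the knockout impairs the cancer cell more than the normal cell.
#' Vectorized over pairs; `NA` (undefined nB) propagates.
#' @param nb_normal,nb_cancer normalized biomasses at the same pH.
#' @export
sel_score <- function(nb_normal, nb_cancer) nb_normal - nb_cancer

#' pH-specificity score PHS = nB(pH phys) - nB(pH low)
#'
#' For a given cancer cell; positive values mean the knockout bites
#' harder at low pH than at physiological pH.
#' @param nb_at_phys,nb_at_low normalized biomasses of the same cell.
#' @export
phs_score <- function(nb_at_phys, nb_at_low) nb_at_phys - nb_at_low

#' Recurrence filter over per-pair (or per-cell) scores
#'
#' The recurrence frequency is the fraction of scores strictly above the
#' zeroing threshold; a target passes when it reaches
#' \code{min_freq}.  The minimal passing count is
#' \code{ceiling(min_freq * n)} — 12 of 96 pairs, 1 of 8 cells at the
#' default 12.5%.
#'
#' @param scores numeric vector of pair scores (`NA` entries dropped).
#' @param min_freq minimal recurrence frequency (default 0.125).
#' @param zero_tol zeroing threshold.
#' @return list with \code{pass}, \code{frequency}, \code{min_count},
#'   \code{n}.
#' @export
recurrence_filter <- function(scores, min_freq = 0.125, zero_tol = 1e-7) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("scores list is empty")
  n <- length(scores)
  freq <- sum(scores > zero_tol) / n
  list(pass = freq >= min_freq, frequency = freq,
       min_count = ceiling(min_freq * n), n = n)
}

#' Classify a target into the selectivity / pH-specificity quadrants
#'
#' Selective: mean SEL above the zeroing threshold and passing
#' recurrence; pH-specific: likewise for PHS.
#'
#' @param sel_mean,phs_mean mean scores.
#' @param sel_pass,phs_pass recurrence-filter pass flags.
#' @param zero_tol zeroing threshold.
#' @return one of \code{"selective_and_ph_specific"},
#'   \code{"selective_only"}, \code{"ph_specific_only"},
#'   \code{"neither"}.
#' @export
classify_target <- function(sel_mean, sel_pass, phs_mean, phs_pass,
                            zero_tol = 1e-7) {
  selective <- !is.na(sel_mean) && sel_mean > zero_tol && sel_pass
  ph_specific <- !is.na(phs_mean) && phs_mean > zero_tol && phs_pass
  if (selective && ph_specific) "selective_and_ph_specific"
  else if (selective) "selective_only"
  else if (ph_specific) "ph_specific_only"
  else "neither"
}

#' Run the knockout screen over a cancer/normal panel
#'
#' For every target the wild-type and knockout biomasses are computed in
#' every cell at the low and physiological pH, normalized, and scored:
#' SEL over all cancer-normal pairs at low pH, PHS over cancer cells,
#' both with recurrence frequencies and a quadrant label.  With
#' \code{readouts = TRUE} each target additionally carries the knockout's
#' anti-Warburg ratio at both pH and the change of the exchange readouts
#' versus wild type at low pH (means over cancer cells).
#'
#' @param panel a [panel_config()].
#' @param level \code{"gene"} or \code{"reaction"}.
#' @param targets optional subset of targets (default: all genes or all
#'   GPR-carrying reactions shared across the panel's models).
#' @param readouts also compute exchange/anti-Warburg readouts per target
#'   (slower; default FALSE).
#' @param cytosol_only see [constrain_model()].
#' @return data.frame sorted by PHS then SEL (descending) with columns
#'   \code{target}, \code{level}, \code{SEL}, \code{PHS},
#'   \code{sel_recurrence}, \code{phs_recurrence}, \code{quadrant} and,
#'   with readouts, \code{dOCR dGlc dLac dATP dNADPH dROS
#'   anti_warburg_low anti_warburg_phys}.  The attribute \code{nB} keeps
#'   the full (cell x pH x target) normalized-biomass bookkeeping.
#' @export
run_screen <- function(panel, level = c("gene", "reaction"),
                       targets = NULL, readouts = FALSE,
                       cytosol_only = TRUE) {
  level <- match.arg(level)
  cells <- c(panel$cancer, panel$normal)
  kind <- rep(c("cancer", "normal"),
              c(length(panel$cancer), length(panel$normal)))
  names(kind) <- vapply(cells, `[[`, character(1), "id")
  phs <- c(low = panel$ph_low, phys = panel$ph_phys)
  if (is.null(targets)) {
    pool <- lapply(cells, function(ce)
      if (level == "gene") ce$model$genes
      else ce$model$reactions$id[nzchar(ce$model$reactions$gpr)])
    targets <- sort(Reduce(union, pool))
  }
  # wild-type states and biomasses per cell x pH
  wt <- list()
  for (ce in cells) {
    wt[[ce$id]] <- lapply(phs, function(p) {
      st <- constrain_model(ce$model, ce$profiles, p, cytosol_only)
      list(state = st,
           B = optimize_biomass(ce$model, st, panel$zero_tol)$biomass,
           readout = if (readouts)
             fva_readouts(ce$model, st, panel$biomass_fraction,
                          panel$zero_tol) else NULL)
    })
  }
  nB <- array(NA_real_, dim = c(length(cells), 2L, length(targets)),
              dimnames = list(names(kind), names(phs), targets))
  rows <- list()
  for (tg in targets) {
    ko_read <- list(low = list(), phys = list())
    for (ce in cells) {
      ok <- if (level == "gene") tg %in% ce$model$genes
            else tg %in% ce$model$reactions$id
      if (!ok) next
      for (pn in names(phs)) {
        b_ko <- tryCatch({
          if (level == "gene")
            knockout_gene(ce$model, ce$profiles, tg, phs[[pn]],
                          w_ko = panel$inhibition,
                          cytosol_only = cytosol_only)
          else
            knockout_reaction(ce$model, ce$profiles, tg, phs[[pn]],
                              cytosol_only = cytosol_only)
        }, error = function(e) NA_real_)
        if (is.na(b_ko)) next
        nB[ce$id, pn, tg] <-
          normalized_biomass(b_ko, wt[[ce$id]][[pn]]$B, panel$zero_tol)
        if (readouts && kind[[ce$id]] == "cancer") {
          st <- constrain_model(
            ce$model, ce$profiles, phs[[pn]], cytosol_only,
            gene_weight_override = if (level == "gene")
              stats::setNames(panel$inhibition, tg) else NULL)
          if (level == "reaction") {
            j <- match(tg, ce$model$reactions$id)
            st$LB[j] <- 0; st$UB[j] <- 0
          }
          ko_read[[pn]][[ce$id]] <- tryCatch(
            fva_readouts(ce$model, st, panel$biomass_fraction,
                         panel$zero_tol),
            error = function(e) NULL)
        }
      }
    }
    is_cancer <- kind[dimnames(nB)[[1]]] == "cancer"
    sel_pairs <- as.numeric(outer(nB[!is_cancer, "low", tg],
                                  nB[is_cancer, "low", tg], sel_score))
    phs_vals <- phs_score(nB[is_cancer, "phys", tg],
                          nB[is_cancer, "low", tg])
    sel_rec <- recurrence_filter(sel_pairs, panel$recurrence_min,
                                 panel$zero_tol)
    phs_rec <- recurrence_filter(phs_vals, panel$recurrence_min,
                                 panel$zero_tol)
    sel_mean <- mean(sel_pairs, na.rm = TRUE)
    phs_mean <- mean(phs_vals, na.rm = TRUE)
    row <- data.frame(
      target = tg, level = level, SEL = sel_mean, PHS = phs_mean,
      sel_recurrence = sel_rec$frequency,
      phs_recurrence = phs_rec$frequency,
      quadrant = classify_target(sel_mean, sel_rec$pass, phs_mean,
                                 phs_rec$pass, panel$zero_tol),
      stringsAsFactors = FALSE)
    if (readouts) {
      delta <- function(role) {
        ids <- names(kind)[is_cancer]
        d <- vapply(ids, function(id) {
          kr <- ko_read$low[[id]]
          if (is.null(kr)) return(NA_real_)
          kr$rates[[role]] - wt[[id]]$low$readout$rates[[role]]
        }, numeric(1))
        mean(d, na.rm = TRUE)
      }
      aw <- function(pn) {
        v <- vapply(names(kind)[is_cancer], function(id) {
          kr <- ko_read[[pn]][[id]]
          if (is.null(kr)) NA_real_ else kr$anti_warburg
        }, numeric(1))
        mean(v[is.finite(v)], na.rm = TRUE)
      }
      row$dOCR <- delta("oxygen"); row$dGlc <- delta("glucose")
      row$dLac <- delta("lactate"); row$dATP <- delta("atp_total")
      row$dNADPH <- delta("nadph_total"); row$dROS <- delta("ros")
      row$anti_warburg_low <- aw("low")
      row$anti_warburg_phys <- aw("phys")
    }
    rows[[tg]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(-out$PHS, -out$SEL, out$target), , drop = FALSE]
  attr(out, "nB") <- nB
  out
}

#' Divide-and-conquer search for minimal pH-effect modulator sets
#'
#' The pH-activity profiles are applied to increasingly smaller subsets
#' of the profiled genes; a half of the current set is kept when it
#' preserves at least \code{theta} of the full-set phenotype difference.
#' Recursion stops at singletons, or returns the current set when
#' neither half preserves the effect (e.g. two redundant isozymes split
#' across the halves).  Bisection follows model gene order, making the
#' search deterministic.
#'
#' @param model a \code{metabolic_model}.
#' @param profiles named list of complete \code{ph_profile}.
#' @param ph pH at which the effect is measured (default 6.7).
#' @param criterion function(model, profile_subset) returning the scalar
#'   phenotype difference; the default is the biomass gap between the
#'   unconstrained and the subset-constrained model at \code{ph}.
#' @param theta effect-preservation threshold (default 0.8).
#' @param zero_tol below this full-set effect the search returns empty.
#' @param cytosol_only see [constrain_model()].
#' @return character vector of gene ids (empty, with attribute
#'   \code{no_effect = TRUE}, when the full profile set has no effect).
#' @export
divide_and_conquer <- function(model, profiles, ph = 6.7,
                               criterion = NULL, theta = 0.8,
                               zero_tol = 1e-7, cytosol_only = TRUE) {
  if (is.null(criterion)) {
    b0 <- optimize_biomass(model)$biomass
    criterion <- function(m, prof_sub) {
      st <- constrain_model(m, prof_sub, ph, cytosol_only)
      b0 - optimize_biomass(m, st)$biomass
    }
  }
  profiled <- intersect(model$genes, names(profiles))
  effect <- function(genes) criterion(model, profiles[genes])
  full <- effect(profiled)
  if (!length(profiled) || full <= zero_tol) {
    out <- character()
    attr(out, "no_effect") <- TRUE
    return(out)
  }
  recurse <- function(genes) {
    if (length(genes) <= 1L) return(genes)
    h <- split(genes, rep(1:2, c(ceiling(length(genes) / 2),
                                 floor(length(genes) / 2))))
    keep <- Filter(function(hh) effect(hh) >= theta * full, h)
    if (!length(keep)) return(genes)
    sort(unique(unlist(lapply(keep, recurse))))
  }
  res <- recurse(profiled)
  # minimality pass: bisection boundaries can trap bystanders (a redundant
  # pair straddling a split drags its half along); greedily drop genes
  # whose removal keeps the effect
  for (g in res) {
    cand <- setdiff(res, g)
    if (length(cand) && effect(cand) >= theta * full) res <- cand
  }
  res
}

# Gaussian perturbation of a profile's critical points; points are
# re-sorted when noise breaks the ordering (count returned as attribute)
# so Monte-Carlo runs stay alive.
perturb_profile <- function(profile, sigma) {
  p <- profile$points + stats::rnorm(6L, 0, sigma)
  p <- pmin(pmax(p, 0.1), 13.9)
  resorted <- is.unsorted(p)
  profile$points <- stats::setNames(sort(p), PH_POINTS)
  attr(profile, "resorted") <- resorted
  profile
}

# Mean cancer-minus-normal gap of the pH response: per cell, the
# difference of constrained biomass at the alkaline vs. acidic pH,
# normalized by the cell's unconstrained optimum.
panel_ph_gap <- function(cells, kind, ph_alk, ph_acid,
                         profile_sets = NULL, cytosol_only = TRUE) {
  d <- vapply(seq_along(cells), function(i) {
    ce <- cells[[i]]
    prof <- if (is.null(profile_sets)) ce$profiles else profile_sets[[i]]
    b0 <- optimize_biomass(ce$model)$biomass
    if (b0 <= 0) return(NA_real_)
    b_at <- function(p) {
      st <- constrain_model(ce$model, prof, p, cytosol_only)
      optimize_biomass(ce$model, st)$biomass
    }
    (b_at(ph_alk) - b_at(ph_acid)) / b0
  }, numeric(1))
  mean(d[kind == "cancer"], na.rm = TRUE) -
    mean(d[kind == "normal"], na.rm = TRUE)
}

#' Robustness of the screen to profile perturbation or misassignment
#'
#' Two modes. \code{perturb}: Gaussian shifts (sd \code{sigma} pH units)
#' are added to every critical point of every profile (ordering restored
#' by re-sorting, logged), the screen is re-run and compared with the
#' baseline by Spearman rank correlation of the SEL and PHS score
#' vectors and by the identity of the top-ranked target.
#' \code{randomize}: the profile-to-gene assignment of each cell is
#' permuted \code{n_perm} times and the cancer-minus-normal gap of the
#' pH response (alkaline minus acidic biomass, each normalized by the
#' cell's unconstrained optimum) is recomputed; a real pH architecture
#' collapses under wrong assignment, so the report carries the ratio of
#' the mean permuted gap to the engineered baseline gap.
#'
#' @param panel a [panel_config()].
#' @param mode \code{"perturb"} or \code{"randomize"}.
#' @param sigma perturbation sd in pH units (perturb mode).
#' @param n_perm number of permutations (randomize mode).
#' @param seed RNG seed (default 0).
#' @param gap_ph,acid_ph alkaline / acidic pH of the gap readout
#'   (defaults 7.8 and 6.7).
#' @param cytosol_only see [constrain_model()].
#' @return a list report; see Details of each mode above.
#' @export
robustness_suite <- function(panel, mode = c("perturb", "randomize"),
                             sigma = 0.1, n_perm = 100L, seed = 0L,
                             gap_ph = 7.8, acid_ph = 6.7,
                             cytosol_only = TRUE) {
  mode <- match.arg(mode)
  set.seed(seed)
  cells <- c(panel$cancer, panel$normal)
  kind <- rep(c("cancer", "normal"),
              c(length(panel$cancer), length(panel$normal)))
  if (mode == "perturb") {
    base <- run_screen(panel, "gene", cytosol_only = cytosol_only)
    n_resorted <- 0L
    pert_cells <- lapply(cells, function(ce) {
      ce$profiles <- lapply(ce$profiles, function(p) {
        pp <- perturb_profile(p, sigma)
        if (isTRUE(attr(pp, "resorted"))) n_resorted <<- n_resorted + 1L
        pp
      })
      ce
    })
    ppanel <- panel
    ppanel$cancer <- pert_cells[kind == "cancer"]
    ppanel$normal <- pert_cells[kind == "normal"]
    pert <- run_screen(ppanel, "gene", cytosol_only = cytosol_only)
    m <- match(base$target, pert$target)
    rank_cor <- function(col) {
      if (stats::sd(base[[col]]) == 0 || stats::sd(pert[[col]][m]) == 0)
        return(NA_real_)
      stats::cor(base[[col]], pert[[col]][m], method = "spearman")
    }
    # co-essential targets (e.g. a transporter and the enzyme behind it)
    # tie exactly at the top; preservation is judged against the tied set
    top_set <- base$target[base$PHS >= max(base$PHS) - 1e-9]
    list(mode = "perturb", sigma = sigma, seed = seed,
         n_resorted = n_resorted,
         rank_cor_sel = rank_cor("SEL"), rank_cor_phs = rank_cor("PHS"),
         top_baseline = top_set, top_perturbed = pert$target[1],
         top_preserved = pert$target[1] %in% top_set)
  } else {
    baseline <- panel_ph_gap(cells, kind, gap_ph, acid_ph,
                             cytosol_only = cytosol_only)
    gaps <- vapply(seq_len(n_perm), function(i) {
      sets <- lapply(cells, function(ce) {
        ids <- names(ce$profiles)
        stats::setNames(ce$profiles[sample(length(ids))], ids)
      })
      panel_ph_gap(cells, kind, gap_ph, acid_ph, profile_sets = sets,
                   cytosol_only = cytosol_only)
    }, numeric(1))
    list(mode = "randomize", seed = seed, n_perm = n_perm,
         baseline_gap = baseline, perm_gaps = gaps,
         mean_perm_gap = mean(gaps),
         collapse_ratio = if (abs(baseline) > 0)
           abs(mean(gaps)) / abs(baseline) else NA_real_)
  }
}
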