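# Flux balance analysis on (constrained) models: LP core, biomass
# optimization, flux-variability readouts, anti-Warburg ratio, pHi sweep.

# Two-phase primal simplex with Bland's anti-cycling rule.  Solves
#   min cost'z  s.t.  A z = b (b >= 0), z >= 0
# on a dense tableau.  Deterministic (smallest-index pivoting), which
# keeps every downstream readout byte-reproducible.  Internal tolerance
# 1e-9; problems here are toy-scale (tens of variables), where a dense
# tableau is both fast and simple to reason about.
simplex_core <- function(A, b, cost, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  # phase 1: artificial basis
  tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  run_phase <- function(tab, basis, costv, ncols) {
    zrow <- c(costv, 0)
    for (i in seq_len(nrow(tab)))
      if (costv[basis[i]] != 0) zrow <- zrow - costv[basis[i]] * tab[i, ]
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > 10000L) stop("simplex iteration limit")
      enter <- which(zrow[seq_len(ncols)] < -tol)[1]
      if (is.na(enter)) break
      ratios <- ifelse(tab[, enter] > tol,
                       tab[, ncol(tab)] / tab[, enter], Inf)
      if (all(is.infinite(ratios))) stop("LP unbounded")
      cand <- which(ratios <= min(ratios) + tol)
      leave <- cand[which.min(basis[cand])]  # Bland tie-break
      piv <- tab[leave, enter]
      tab[leave, ] <- tab[leave, ] / piv
      for (r in seq_len(nrow(tab)))
        if (r != leave && abs(tab[r, enter]) > 0)
          tab[r, ] <- tab[r, ] - tab[r, enter] * tab[leave, ]
      zrow <- zrow - zrow[enter] * tab[leave, ]
      basis[leave] <- enter
    }
    list(tab = tab, basis = basis, zrow = zrow)
  }
  ph1_cost <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(tab, basis, ph1_cost, n + m)
  resid <- sum(ph1$tab[ph1$basis > n, ncol(ph1$tab)])
  if (resid > 1e-7) return(list(status = "infeasible"))
  tab <- ph1$tab; basis <- ph1$basis
  # pivot lingering zero-level artificials out of the basis
  for (i in which(basis > n)) {
    col <- which(abs(tab[i, seq_len(n)]) > tol)[1]
    if (is.na(col)) next  # redundant row
    piv <- tab[i, col]
    tab[i, ] <- tab[i, ] / piv
    for (r in seq_len(nrow(tab)))
      if (r != i && abs(tab[r, col]) > 0)
        tab[r, ] <- tab[r, ] - tab[r, col] * tab[i, ]
    basis[i] <- col
  }
  keep <- basis <= n
  tab <- tab[keep, c(seq_len(n), ncol(tab)), drop = FALSE]
  basis <- basis[keep]
  ph2 <- run_phase(tab, basis, cost, n)
  z <- numeric(n)
  z[ph2$basis] <- ph2$tab[, ncol(ph2$tab)]
  list(status = "optimal", z = z)
}

# Solve  max/min  obj'v  s.t.  S v = 0,  lb <= v <= ub.
# Variables are shifted (x = v - lb >= 0) and upper bounds folded in as
# equality rows x + s = ub - lb; all model bounds are finite (readers
# cap infinities), so the LP is never unbounded.
solve_lp <- function(obj, S, lb, ub, maximize = TRUE) {
  n <- length(lb)
  stopifnot(length(ub) == n, length(obj) == n, ncol(S) == n)
  if (any(lb > ub)) return(list(status = "infeasible", objective = NA_real_,
                                fluxes = NULL))
  b0 <- as.numeric(-S %*% lb)
  keep <- rowSums(abs(S)) > 0 | abs(b0) > 0
  Sk <- S[keep, , drop = FALSE]; b0 <- b0[keep]
  neg <- b0 < 0
  Sk[neg, ] <- -Sk[neg, , drop = FALSE]; b0 <- abs(b0)
  m <- nrow(Sk)
  u <- ub - lb
  A <- rbind(cbind(Sk, matrix(0, m, n)),
             cbind(diag(n), diag(n)))
  b <- c(b0, u)
  cost <- c(if (maximize) -obj else obj, rep(0, n))
  res <- simplex_core(A, b, cost)
  if (res$status != "optimal")
    return(list(status = "infeasible", objective = NA_real_, fluxes = NULL))
  v <- res$z[seq_len(n)] + lb
  names(v) <- colnames(S)
  list(status = "optimal",
       objective = sum(obj * v),
       fluxes = v)
}

# Bounds of a model after applying an optional constrained state.
effective_bounds <- function(model, state = NULL) {
  lb <- model$reactions$lb; ub <- model$reactions$ub
  if (!is.null(state)) {
    idx <- match(state$reaction_id, model$reactions$id)
    lb[idx] <- state$LB; ub[idx] <- state$UB
  }
  list(lb = lb, ub = ub)
}

zero_small <- function(x, zero_tol = 1e-7) {
  x[abs(x) < zero_tol] <- 0
  x
}

#' Maximize biomass flux (FBA)
#'
#' Cell proliferation is estimated as the maximal flux through the
#' biomass reaction under steady state and the (possibly pH-scaled)
#' bounds.  An infeasible model reports biomass 0 with a flag rather
#' than erroring — acidic extremes legitimately shut a model down.
#' Fluxes below the reporting threshold \code{|zero_tol|} are returned
#' as exact zeros.
#'
#' @param model a \code{metabolic_model}.
#' @param state optional \code{constrained_state} from [constrain_model()].
#' @param zero_tol reporting threshold (default 1e-7).
#' @return list with \code{biomass}, \code{fluxes} (named vector, `NULL`
#'   when infeasible) and \code{status}.
#' @export
optimize_biomass <- function(model, state = NULL, zero_tol = 1e-7) {
  b <- effective_bounds(model, state)
  obj <- as.numeric(model$reactions$id == model$biomass_id)
  res <- solve_lp(obj, model$S, b$lb, b$ub, maximize = TRUE)
  if (res$status != "optimal")
    return(list(biomass = 0, fluxes = NULL, status = res$status))
  list(biomass = zero_small(max(res$objective, 0), zero_tol),
       fluxes = zero_small(res$fluxes, zero_tol),
       status = "optimal")
}

# Production flux-sum of all metabolites whose id matches `pattern`:
# sum over positive stoichiometry x flux terms (consumption excluded).
production_flux_sum <- function(model, fluxes, pattern) {
  rows <- grep(pattern, model$mets$id, ignore.case = TRUE)
  if (!length(rows) || is.null(fluxes)) return(NA_real_)
  tot <- 0
  for (i in rows) {
    terms <- model$S[i, ] * fluxes
    tot <- tot + sum(terms[terms > 0])
  }
  tot
}

#' Exchange-rate readout under a biomass floor (FVA)
#'
#' With biomass constrained to at least \code{biomass_fraction} of its
#' maximum, each exchange role's extreme flux is computed by flux
#' variability: uptake roles (oxygen, glucose) report the minimum (most
#' negative — maximal uptake) and secretion roles (lactate, ros) the
#' maximum, the maximal flux serving as a proxy for catalytic activity.
#' Total ATP and NADPH are production flux-sums over all matching
#' metabolites at the deterministic biomass-re-maximizing solution.
#' Signs follow the convention uptake < 0, secretion > 0.
#'
#' @param model a \code{metabolic_model}.
#' @param state optional \code{constrained_state}.
#' @param biomass_fraction floor as a fraction of maximal biomass
#'   (default 0.8; the screen is robust over 0.7–0.9).
#' @param zero_tol reporting threshold.
#' @param total_patterns regexes selecting the ATP / NADPH metabolite
#'   rows for the flux-sum readouts.
#' @return object of class \code{flux_readout}: list with \code{biomass},
#'   \code{rates} (oxygen, glucose, lactate, atp_total, nadph_total, ros),
#'   \code{anti_warburg}, \code{status}.
#' @export
fva_readouts <- function(model, state = NULL, biomass_fraction = 0.8,
                         zero_tol = 1e-7,
                         total_patterns = c(atp = "^atp", nadph = "^nadph")) {
  stopifnot(biomass_fraction >= 0, biomass_fraction <= 1)
  fba <- optimize_biomass(model, state, zero_tol)
  rates <- c(oxygen = NA_real_, glucose = NA_real_, lactate = NA_real_,
             atp_total = NA_real_, nadph_total = NA_real_, ros = NA_real_)
  if (fba$status != "optimal" || fba$biomass <= 0) {
    out <- list(biomass = 0, rates = zero_small(rates, zero_tol),
                anti_warburg = NA_real_, status = "infeasible")
    class(out) <- "flux_readout"
    return(out)
  }
  b <- effective_bounds(model, state)
  bio_j <- match(model$biomass_id, model$reactions$id)
  # floor slightly relaxed to absorb simplex round-off
  b$lb[bio_j] <- max(b$lb[bio_j], biomass_fraction * fba$biomass - 1e-9)
  if (b$lb[bio_j] > b$ub[bio_j])
    stop("infeasible after fixing biomass >= ", biomass_fraction,
         " x maximum on reaction '", model$biomass_id, "'")
  fva_extreme <- function(rid, maximize) {
    j <- match(rid, model$reactions$id)
    obj <- numeric(nrow(model$reactions)); obj[j] <- 1
    res <- solve_lp(obj, model$S, b$lb, b$ub, maximize = maximize)
    if (res$status != "optimal")
      stop("FVA infeasible for reaction '", rid, "'")
    res$objective
  }
  role_dir <- c(oxygen = FALSE, glucose = FALSE, lactate = TRUE, ros = TRUE)
  for (role in names(role_dir)) {
    rid <- model$exchanges[[role]]
    if (!is.null(rid))
      rates[[role]] <- fva_extreme(rid, role_dir[[role]])
  }
  # flux-sum totals at the biomass-re-maximizing solution under the floor
  obj <- as.numeric(model$reactions$id == model$biomass_id)
  sol <- solve_lp(obj, model$S, b$lb, b$ub, maximize = TRUE)
  rates[["atp_total"]] <- production_flux_sum(model, sol$fluxes,
                                              total_patterns[["atp"]])
  rates[["nadph_total"]] <- production_flux_sum(model, sol$fluxes,
                                                total_patterns[["nadph"]])
  rates <- zero_small(rates, zero_tol)
  out <- list(biomass = fba$biomass, rates = rates,
              anti_warburg = NA_real_, status = "optimal")
  out$anti_warburg <- anti_warburg_ratio(out, zero_tol)
  class(out) <- "flux_readout"
  out
}

#' Anti-Warburg ratio OCR / ECAR of a readout
#'
#' Oxygen consumption rate over lactate production rate (the proxy for
#' extracellular acidification).  A fully oxidative state (no lactate,
#' positive OCR) returns \code{Inf}; with both rates at zero the ratio is
#' undefined (\code{NaN}).
#'
#' @param readout a \code{flux_readout} (or any list with a \code{rates}
#'   element holding \code{oxygen} and \code{lactate}).
#' @param zero_tol threshold below which a rate counts as zero.
#' @export
anti_warburg_ratio <- function(readout, zero_tol = 1e-7) {
  ocr <- abs(readout$rates[["oxygen"]])
  lac <- readout$rates[["lactate"]]
  if (is.na(ocr) || is.na(lac)) return(NA_real_)
  if (lac < zero_tol) {
    if (ocr < zero_tol) return(NaN)  # both zero: undefined
    return(Inf)                      # fully oxidative
  }
  ocr / lac
}

#' @export
print.flux_readout <- function(x, ...) {
  cat("<flux_readout> biomass", signif(x$biomass, 6),
      "anti-Warburg", signif(x$anti_warburg, 4), "\n")
  print(signif(x$rates, 6))
  invisible(x)
}

#' Simulate a model across an intracellular-pH sweep
#'
#' At each grid pH the model is constrained by the profiles, biomass is
#' maximized, and (optionally) the exchange readouts are computed under
#' the biomass floor.  Biomass is also reported normalized by its maximum
#' across the sweep.  Failures at individual grid points are recorded as
#' biomass 0 with a flag and the sweep continues.
#'
#' @param model a \code{metabolic_model}.
#' @param profiles named list of complete \code{ph_profile}.
#' @param ph_grid ordered numeric grid (default 6.5 to 8.5, step 0.1).
#' @param biomass_fraction FVA biomass floor (default 0.8).
#' @param cytosol_only see [constrain_model()].
#' @param readouts compute FVA exchange readouts per point (default TRUE;
#'   FALSE computes biomass only, which is what the knockout screen needs).
#' @param zero_tol reporting threshold.
#' @return data.frame of class \code{sweep_curve} with columns \code{ph},
#'   \code{biomass}, \code{norm_biomass}, \code{o2}, \code{glc},
#'   \code{lac}, \code{atp}, \code{nadph}, \code{ros},
#'   \code{anti_warburg}, \code{status}.
#' @export
ph_sweep <- function(model, profiles, ph_grid = seq(6.5, 8.5, by = 0.1),
                     biomass_fraction = 0.8, cytosol_only = TRUE,
                     readouts = TRUE, zero_tol = 1e-7) {
  if (is.unsorted(ph_grid)) stop("ph_grid must be ordered")
  rows <- lapply(ph_grid, function(ph) {
    row <- data.frame(ph = ph, biomass = 0, norm_biomass = NA_real_,
                      o2 = NA_real_, glc = NA_real_, lac = NA_real_,
                      atp = NA_real_, nadph = NA_real_, ros = NA_real_,
                      anti_warburg = NA_real_, status = "failed",
                      stringsAsFactors = FALSE)
    tryCatch({
      st <- constrain_model(model, profiles, ph, cytosol_only)
      if (readouts) {
        rd <- fva_readouts(model, st, biomass_fraction, zero_tol)
        row$biomass <- rd$biomass
        row[c("o2", "glc", "lac", "atp", "nadph", "ros")] <-
          as.list(unname(rd$rates[c("oxygen", "glucose", "lactate",
                                    "atp_total", "nadph_total", "ros")]))
        row$anti_warburg <- rd$anti_warburg
        row$status <- rd$status
      } else {
        fba <- optimize_biomass(model, st, zero_tol)
        row$biomass <- fba$biomass
        row$status <- fba$status
      }
      row
    }, error = function(e) { row$status <- "failed"; row })
  })
  out <- do.call(rbind, rows)
  mx <- max(out$biomass, na.rm = TRUE)
  out$norm_biomass <- if (mx > 0) out$biomass / mx else NA_real_
  class(out) <- c("sweep_curve", "data.frame")
  out
}
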