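# Synthetic fixtures: a lumped toy cell (glycolysis / oxidative
# phosphorylation / lactate secretion / biomass), cancer-like and
# normal-like profile databases, activity-record generation (the inverse
# of curation), and the SNARF-1 ratiometric pH calibration.

#' Specification of a synthetic toy cell model
#'
#' @param n_glycolysis_steps number of lumped glycolytic steps (>= 1,
#'   default 1), one gene each.
#' @param include_oxphos include the mitochondrial pyruvate route
#'   (carrier + lumped oxidative phosphorylation).
#' @param include_lactate_exchange include lactate dehydrogenase, the
#'   lactate transporter and the lactate exchange.
#' @param paralog_pairs list of character(2) gene pairs; the first pair
#'   replaces the gene of the last glycolytic step with an OR rule (the
#'   classic isozyme junction).  Default one pair,
#'   \code{c("g_gapdh", "g_gapdhs")}.
#' @param seed integer seed (kept for provenance; the builder itself is
#'   deterministic).
#' @export
toy_spec <- function(n_glycolysis_steps = 1L, include_oxphos = TRUE,
                     include_lactate_exchange = TRUE,
                     paralog_pairs = list(c("g_gapdh", "g_gapdhs")),
                     seed = 0L) {
  stopifnot(n_glycolysis_steps >= 1L)
  if (!include_oxphos && !include_lactate_exchange)
    stop("contradictory spec: pyruvate needs at least one downstream route")
  structure(list(n_glycolysis_steps = as.integer(n_glycolysis_steps),
                 include_oxphos = include_oxphos,
                 include_lactate_exchange = include_lactate_exchange,
                 paralog_pairs = paralog_pairs, seed = as.integer(seed)),
            class = "toy_spec")
}

#' Build the synthetic toy cell model
#'
#' A lumped network with hand-verifiable linear-programming optima:
#' glucose uptake (bound 10) feeds a glycolytic chain yielding
#' 2 pyruvate + 2 ATP per glucose; pyruvate is either reduced to lactate
#' and secreted, or carried into the mitochondrion (carrier bound 5 —
#' the deliberate respiratory bottleneck producing Warburg-like overflow)
#' and oxidized at 3 O2 per pyruvate for 15 ATP; a small
#' pentose-phosphate shunt yields 2 NADPH + 1 pyruvate per glucose
#' (bound 2); biomass consumes 10 ATP + 1 pyruvate.  With the default
#' spec the unconstrained biomass optimum is 9.5 (carrier saturated at
#' 5) and the fermentation-only optimum is 2 (with 18 lactate secreted).
#'
#' @param spec a [toy_spec()].
#' @return a \code{metabolic_model}.
#' @export
make_toy_model <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  n <- spec$n_glycolysis_steps
  mets <- list(
    list(id = "glc_e", compartment = "e"),
    list(id = "o2_e", compartment = "e"),
    list(id = "glc_c", compartment = "c"),
    list(id = "pyr_c", compartment = "c"),
    list(id = "atp_c", compartment = "c"),
    list(id = "nadph_c", compartment = "c"))
  if (n > 1L) for (i in seq_len(n - 1L))
    mets <- c(mets, list(list(id = paste0("gint", i, "_c"),
                              compartment = "c")))
  junction_gpr <- if (length(spec$paralog_pairs))
    paste(spec$paralog_pairs[[1]], collapse = " or ") else
      paste0("g_gly", n)
  rxns <- list(
    list(id = "EX_glc", mets = list(glc_e = -1), lb = -10, ub = 0,
         gpr = ""),
    list(id = "EX_o2", mets = list(o2_e = -1), lb = -20, ub = 0,
         gpr = ""),
    list(id = "GLCt", mets = list(glc_e = -1, glc_c = 1), lb = 0, ub = 10,
         gpr = "g_glut1"))
  chain_in <- "glc_c"
  if (n > 1L) for (i in seq_len(n - 1L)) {
    out <- paste0("gint", i, "_c")
    step <- list(id = paste0("GLY", i),
                 mets = stats::setNames(list(-1, 1), c(chain_in, out)),
                 lb = 0, ub = 40, gpr = paste0("g_gly", i))
    rxns <- c(rxns, list(step)); chain_in <- out
  }
  rxns <- c(rxns, list(
    list(id = paste0("GLY", n),
         mets = stats::setNames(list(-1, 2, 2),
                                c(chain_in, "pyr_c", "atp_c")),
         lb = 0, ub = 40, gpr = junction_gpr),
    list(id = "PPP", mets = list(glc_c = -1, nadph_c = 2, pyr_c = 1),
         lb = 0, ub = 2, gpr = "g_g6pd"),
    list(id = "NADPHd", mets = list(nadph_c = -1), lb = 0, ub = 1000,
         gpr = ""),
    list(id = "BIOMASS", mets = list(atp_c = -10, pyr_c = -1),
         lb = 0, ub = 1000, gpr = "")))
  if (spec$include_lactate_exchange) {
    mets <- c(mets, list(list(id = "lac_c", compartment = "c"),
                         list(id = "lac_e", compartment = "e")))
    rxns <- c(rxns, list(
      list(id = "LDH", mets = list(pyr_c = -1, lac_c = 1), lb = 0,
           ub = 30, gpr = "g_ldha"),
      list(id = "LACt", mets = list(lac_c = -1, lac_e = 1), lb = 0,
           ub = 30, gpr = "g_mct1"),
      list(id = "EX_lac", mets = list(lac_e = -1), lb = 0, ub = 1000,
           gpr = "")))
  }
  if (spec$include_oxphos) {
    mets <- c(mets, list(list(id = "pyr_m", compartment = "m"),
                         list(id = "o2_m", compartment = "m"),
                         list(id = "atp_m", compartment = "m"),
                         list(id = "ros_m", compartment = "m")))
    rxns <- c(rxns, list(
      list(id = "PYRt", mets = list(pyr_c = -1, pyr_m = 1), lb = 0,
           ub = 5, gpr = "g_mpc1"),
      list(id = "O2t", mets = list(o2_e = -1, o2_m = 1), lb = 0,
           ub = 1000, gpr = ""),
      list(id = "OXPHOS",
           mets = list(pyr_m = -1, o2_m = -3, atp_m = 15, ros_m = 0.05),
           lb = 0, ub = 6, gpr = "g_oxphos"),
      list(id = "ATPt", mets = list(atp_m = -1, atp_c = 1), lb = 0,
           ub = 1000, gpr = ""),
      list(id = "ROSd", mets = list(ros_m = -1), lb = 0, ub = 1000,
           gpr = "")))
  }
  model_from_list(list(
    metabolites = mets, reactions = rxns, biomass = "BIOMASS",
    exchanges = Filter(Negate(is.null), list(
      oxygen = "EX_o2", glucose = "EX_glc",
      lactate = if (spec$include_lactate_exchange) "EX_lac",
      atp_drain = NULL, nadph_drain = "NADPHd",
      ros = if (spec$include_oxphos) "ROSd"))))
}

# Profile templates: six critical points per phenotype class.  The
# acid-shifted template mirrors lactate-export machinery that operates
# under acidosis; having both acid- and alkaline-optimum enzymes in the
# cancer-like database mirrors the spread of real pH optima across
# compartments and is what makes a randomized profile-to-gene
# assignment wash the engineered pH architecture out.
toy_profile_templates <- function() {
  list(
    alkaline = c(A0 = 6.4, A50 = 6.9, A100 = 7.3, B100 = 7.9,
                 B50 = 8.3, B0 = 8.6),
    neutral = c(A0 = 6.2, A50 = 6.6, A100 = 7.0, B100 = 7.4,
                B50 = 7.8, B0 = 8.2),
    acid = c(A0 = 5.2, A50 = 5.6, A100 = 6.0, B100 = 6.8,
             B50 = 7.6, B0 = 8.4),
    flat = c(A0 = 6.0, A50 = 6.3, A100 = 6.6, B100 = 7.8,
             B50 = 8.1, B0 = 8.4))
}

#' Generate a synthetic profile database for a toy model
#'
#' Cancer-like cells mirror the alkaline-shifted machinery of tumor
#' cytosol: glycolytic genes (glucose transporter, chain, isozyme
#' junction) receive alkaline-shifted plateaus (A100 ~ 7.3), the
#' pyruvate carrier and oxidative genes a narrower neutral plateau
#' (7.0–7.4), and the lactate-export machinery (LDH, MCT), which
#' operates under acidosis, an acid-shifted plateau.  Normal-like cells
#' receive broad flat plateaus (6.6–7.8) for every gene, making biomass
#' pH-insensitive over the physiological range.  A per-gene rigid shift (sd
#' \code{jitter_sd}) individualizes profiles without ever breaking the
#' ordering invariant.
#'
#' @param model a toy \code{metabolic_model}.
#' @param phenotype \code{"cancer_like"} or \code{"normal_like"}.
#' @param seed RNG seed for the jitter.
#' @param jitter_sd sd of the rigid per-profile shift (pH units,
#'   default 0.03).
#' @return named list of complete \code{ph_profile}.
#' @export
make_profiles <- function(model, phenotype = c("cancer_like",
                                               "normal_like"),
                          seed = 0L, jitter_sd = 0.03) {
  phenotype <- match.arg(phenotype)
  tpl <- toy_profile_templates()
  set.seed(seed)
  out <- list()
  for (g in model$genes) {
    base <- if (phenotype == "normal_like") tpl$flat
    else if (grepl("glut|gly|gapdh", g)) tpl$alkaline
    else if (grepl("mpc|oxphos", g)) tpl$neutral
    else if (grepl("ldh|mct|g6pd", g)) tpl$acid
    else tpl$flat
    shift <- stats::rnorm(1L, 0, jitter_sd)
    out[[g]] <- ph_profile(g, base + shift)
  }
  out
}

#' Emit synthetic activity records around a profile database
#'
#' The inverse of curation, for testing the curation pipeline: for every
#' enzyme and critical point, \code{records_per_point} records are
#' emitted with Gaussian pH noise; 100%-level points yield
#' \code{"optimum"} records (activity 100), the 0% and 50% points yield
#' \code{"range"} records (activities 10 and 60, which discretize back
#' to levels 0 and 50).  [build_profiles()] applied to the output
#' recovers each critical point within about \eqn{2\sigma/\sqrt{n}} on
#' average.
#'
#' @param db named list of complete \code{ph_profile}.
#' @param records_per_point records per critical point (default 1).
#' @param noise_sd pH noise sd (default 0).
#' @param seed RNG seed.
#' @return activity-record data.frame (see [validate_records()]).
#' @export
make_activity_records <- function(db, records_per_point = 1L,
                                  noise_sd = 0, seed = 0L) {
  set.seed(seed)
  act <- c(A0 = 10, A50 = 60, A100 = 100, B100 = 100, B50 = 60, B0 = 10)
  kind <- c(A0 = "range", A50 = "range", A100 = "optimum",
            B100 = "optimum", B50 = "range", B0 = "range")
  rows <- list()
  for (p in db) {
    validate_profile(p, require_complete = TRUE)
    for (pt in PH_POINTS) {
      ph <- p$points[[pt]] + stats::rnorm(records_per_point, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        enzyme_id = p$enzyme_id,
        ec = if (is.na(p$ec)) "0.0.0.0" else p$ec,
        taxon = if (is.na(p$taxon)) "synthetic" else p$taxon,
        ph = pmin(pmax(ph, 0.1), 13.9),
        activity_pct = act[[pt]], record_kind = kind[[pt]],
        stringsAsFactors = FALSE)
    }
  }
  validate_records(do.call(rbind, rows))
}

#' SNARF calibration constants
#'
#' @param pKa probe pKa (pH units).
#' @param R_min,R_max asymptotic 580/640 fluorescence ratios at the
#'   acidic and basic ends of the calibration; must differ.
#' @export
calibration_constants <- function(pKa, R_min, R_max) {
  if (R_min == R_max) stop("R_min and R_max must differ")
  structure(list(pKa = pKa, R_min = R_min, R_max = R_max),
            class = "calibration_constants")
}

#' In-situ SNARF-1 calibration constants for MCF7 cells
#'
#' The published in-situ calibration for MCF7 breast cancer cells:
#' pKa 7.30, R_min 2.54, R_max 0.56.
#' @export
mcf7_calibration <- function() calibration_constants(7.30, 2.54, 0.56)

#' Intracellular pH from a SNARF-1 fluorescence ratio
#'
#' Ratiometric calibration
#' \deqn{pH = pK_a - \log_{10}\frac{R - R_{max}}{R_{min} - R}}
#' with the base-10 logarithm of the Henderson-Hasselbalch convention.
#' \code{R} must lie strictly between the two asymptotic ratios; at the
#' arithmetic midpoint the log term vanishes and the pKa is returned.
#'
#' @param R measured 580/640 fluorescence ratio (vectorized).
#' @param constants a [calibration_constants()].
#' @return pH values.
#' @export
snarf_ph <- function(R, constants = mcf7_calibration()) {
  lo <- min(constants$R_min, constants$R_max)
  hi <- max(constants$R_min, constants$R_max)
  if (any(R <= lo | R >= hi))
    stop("R must lie strictly between R_max and R_min (",
         lo, ", ", hi, ")")
  constants$pKa - log10((R - constants$R_max) / (constants$R_min - R))
}
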