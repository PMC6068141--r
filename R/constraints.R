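# Injection of pH-activity profiles into a metabolic model: per-gene
# weights W_G, GPR-evaluated reaction weights W_R, direction-aware bound
# scaling, cytosol-only application.

#' pH-specific gene weights
#'
#' At a given intracellular pH every profiled gene carries the fractional
#' activity \eqn{W_G = activity/100 \in [0,1]} from its profile; genes
#' without a profile are conservatively assigned constant full activity
#' (\eqn{W_G = 1}).
#'
#' @param profiles named list of complete \code{ph_profile}.
#' @param genes character vector of model gene ids.
#' @param ph intracellular pH, in (0, 14).
#' @return named numeric vector of weights in \[0, 1\].
#' @export
gene_weights <- function(profiles, genes, ph) {
  stopifnot(length(ph) == 1L, ph > 0, ph < 14)
  w <- stats::setNames(rep(1, length(genes)), genes)
  for (g in intersect(genes, names(profiles)))
    w[[g]] <- activity_at(profiles[[g]], ph) / 100
  w
}

#' Scale flux bounds by a reaction weight, direction-aware
#'
#' Bidirectional reactions (\eqn{v_{min} \le 0 \le v_{max}}) have both
#' bounds scaled: \eqn{LB = W_R v_{min}}, \eqn{UB = W_R v_{max}}.  For a
#' forward reaction (\eqn{v_{min} \ge 0}) only the upper bound is scaled,
#' guarded so that \eqn{UB \ge v_{min}}; symmetrically for a reverse
#' reaction (\eqn{v_{max} \le 0}) only the lower bound is scaled with
#' \eqn{LB \le v_{max}}.  The guards guarantee LB <= UB for every weight.
#'
#' @param v_min,v_max base bounds, \code{v_min <= v_max}.
#' @param w_r reaction weight in \[0, 1\].
#' @return numeric c(LB, UB).
#' @export
scale_bounds <- function(v_min, v_max, w_r) {
  if (is.na(w_r) || w_r < 0 || w_r > 1) stop("W_R must lie in [0, 1]")
  if (v_min > v_max) stop("v_min must not exceed v_max")
  if (v_min <= 0 && v_max >= 0) c(w_r * v_min, w_r * v_max)
  else if (v_min >= 0) c(v_min, max(w_r * v_max, v_min))
  else c(min(w_r * v_min, v_max), v_max)
}

#' Constrain a model's flux bounds at a given intracellular pH
#'
#' Computes gene weights from the profiles, evaluates each reaction's GPR
#' (AND = min, OR = max) to a reaction weight \eqn{W_R}, and scales the
#' reaction's bounds by [scale_bounds()].  Organelles are assumed well
#' buffered, so by default only reactions whose enzymes act in the
#' cytosol are touched: a gene counts as cytosolic when any reaction it
#' catalyzes involves a cytosolic metabolite, and a reaction is gated by
#' whether any gene of its rule is cytosolic (the rule's non-cytosolic
#' genes still enter the W_R evaluation — gating is at the enzyme level,
#' not per leaf).  With \code{cytosol_only = FALSE} every compartment is
#' constrained (robustness mode).
#'
#' @param model a \code{metabolic_model}.
#' @param profiles named list of complete \code{ph_profile}.
#' @param ph intracellular pH.
#' @param cytosol_only apply constraints to cytosolic enzymes only
#'   (default TRUE).
#' @param cytosol_code compartment code of the cytosol (default "c").
#' @param gene_weight_override named numeric vector replacing the
#'   profile-derived weight of specific genes (used for knockouts).
#'   Overrides model a perturbation of the gene itself, not a buffering
#'   question, so they apply in every compartment: a non-cytosolic
#'   reaction whose rule contains an overridden gene is evaluated with
#'   all profile-derived weights at 1 and only the overrides active.
#' @return a \code{constrained_state}: data.frame with columns
#'   \code{reaction_id}, \code{W_R}, \code{LB}, \code{UB}, \code{flag}
#'   (one of \code{scaled}, \code{untouched-noncytosolic},
#'   \code{untouched-noprofile}); attribute \code{ph}.
#' @export
constrain_model <- function(model, profiles, ph, cytosol_only = TRUE,
                            cytosol_code = "c",
                            gene_weight_override = NULL) {
  w_g <- gene_weights(profiles, model$genes, ph)
  w_ko <- stats::setNames(rep(1, length(model$genes)), model$genes)
  if (!is.null(gene_weight_override)) {
    unknown <- setdiff(names(gene_weight_override), model$genes)
    if (length(unknown)) stop("unknown gene(s): ",
                              paste(unknown, collapse = ", "))
    w_g[names(gene_weight_override)] <- gene_weight_override
    w_ko[names(gene_weight_override)] <- gene_weight_override
  }
  gc <- gene_compartments(model)
  cytosolic <- vapply(gc, function(cc) cytosol_code %in% cc, logical(1))
  n <- nrow(model$reactions)
  W_R <- rep(1, n); LB <- model$reactions$lb; UB <- model$reactions$ub
  flag <- rep("untouched-noprofile", n)
  for (j in seq_len(n)) {
    tree <- model$gprs[[j]]
    g <- gpr_genes(tree)
    if (!length(g)) next
    gated_out <- cytosol_only && !any(cytosolic[g])
    if (gated_out && !any(g %in% names(gene_weight_override))) {
      flag[j] <- "untouched-noncytosolic"
      next
    }
    w <- reaction_weight(tree, if (gated_out) w_ko else w_g)
    W_R[j] <- w
    b <- scale_bounds(model$reactions$lb[j], model$reactions$ub[j], w)
    LB[j] <- b[1]; UB[j] <- b[2]
    flag[j] <- "scaled"
  }
  st <- data.frame(reaction_id = model$reactions$id, W_R = W_R,
                   LB = LB, UB = UB, flag = flag,
                   stringsAsFactors = FALSE)
  attr(st, "ph") <- ph
  class(st) <- c("constrained_state", "data.frame")
  st
}

#' Write a constrained state to TSV
#' @param state a \code{constrained_state}.
#' @param path output file.
#' @export
write_state <- function(state, path) {
  utils::write.table(state, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
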