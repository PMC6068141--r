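# Metabolic model container and readers: JSON dialect, SBML Level-3 + fbc,
# screen-result TSV round-trip.

#' Default id patterns used to resolve exchange roles
#'
#' Roles are matched (case-insensitively) against reaction ids since model
#' collections never agree on exchange naming; override per model source.
#' @export
default_exchange_patterns <- function() {
  list(oxygen = "o2", glucose = "glc", lactate = "lac",
       atp_drain = "atp", nadph_drain = "nadph", ros = "ros")
}

new_metabolic_model <- function(mets, rxns, S, biomass_id, exchanges,
                                genes) {
  structure(list(mets = mets, reactions = rxns, S = S,
                 biomass_id = biomass_id, exchanges = exchanges,
                 genes = genes),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", nrow(x$mets), "metabolites,",
      nrow(x$reactions), "reactions,", length(x$genes), "genes\n")
  cat("  biomass:", x$biomass_id, "\n")
  ex <- unlist(x$exchanges)
  if (length(ex)) cat("  exchanges:",
                      paste(names(ex), ex, sep = "=", collapse = " "), "\n")
  invisible(x)
}

validate_model <- function(m) {
  if (ncol(m$S) != nrow(m$reactions))
    stop("stoichiometric matrix has ", ncol(m$S),
         " columns for ", nrow(m$reactions), " reactions")
  if (!m$biomass_id %in% m$reactions$id)
    stop("biomass reaction '", m$biomass_id, "' not found in model")
  if (any(m$reactions$lb > m$reactions$ub))
    stop("reaction(s) with lower bound above upper bound: ",
         paste(m$reactions$id[m$reactions$lb > m$reactions$ub],
               collapse = ", "))
  for (i in seq_len(nrow(m$reactions))) {
    g <- gpr_genes(m$gprs[[i]])
    unknown <- setdiff(g, m$genes)
    if (length(unknown))
      stop("reaction '", m$reactions$id[i],
           "' references undeclared gene(s): ",
           paste(unknown, collapse = ", "))
  }
  m
}

# Assemble a model from the plain-list form of the JSON dialect.
model_from_list <- function(x, bound_cap = 1000,
                            exchange_patterns = default_exchange_patterns()) {
  mets <- data.frame(
    id = vapply(x$metabolites, `[[`, character(1), "id"),
    compartment = vapply(x$metabolites, `[[`, character(1), "compartment"),
    stringsAsFactors = FALSE)
  rids <- vapply(x$reactions, `[[`, character(1), "id")
  S <- matrix(0, nrow(mets), length(rids),
              dimnames = list(mets$id, rids))
  lb <- ub <- numeric(length(rids))
  gpr_str <- character(length(rids))
  for (j in seq_along(x$reactions)) {
    r <- x$reactions[[j]]
    for (mid in names(r$mets)) {
      if (!mid %in% mets$id) stop("reaction '", r$id,
                                  "' uses undeclared metabolite '", mid, "'")
      S[mid, j] <- as.numeric(r$mets[[mid]])
    }
    lb[j] <- max(as.numeric(r$lb), -bound_cap)
    ub[j] <- min(as.numeric(r$ub), bound_cap)
    gpr_str[j] <- if (is.null(r$gpr)) "" else as.character(r$gpr)
  }
  rxns <- data.frame(id = rids, lb = lb, ub = ub, gpr = gpr_str,
                     stringsAsFactors = FALSE)
  gprs <- lapply(gpr_str, parse_gpr)
  genes <- sort(unique(unlist(lapply(gprs, gpr_genes))))
  exch <- if (!is.null(x$exchanges)) lapply(x$exchanges, as.character)
          else resolve_exchanges(rids, S, exchange_patterns)
  m <- new_metabolic_model(mets, rxns, S, as.character(x$biomass), exch,
                           genes)
  m$gprs <- gprs
  validate_model(m)
}

# Exchange reactions move a single metabolite across the system boundary;
# roles are matched by id pattern among them.
resolve_exchanges <- function(rids, S, patterns) {
  n_mets <- colSums(S != 0)
  ex_ids <- rids[n_mets == 1L]
  out <- list()
  for (role in names(patterns)) {
    hit <- grep(patterns[[role]], ex_ids, ignore.case = TRUE, value = TRUE)
    if (length(hit)) out[[role]] <- hit[1]
  }
  out
}

#' Load a metabolic model
#'
#' Two on-disk formats are supported: SBML Level-3 with the \code{fbc}
#' flux-bounds and gene-association package, and a minimal JSON dialect
#' (\code{\{reactions:[\{id, mets:\{met:coef\}, lb, ub, gpr\}],
#' metabolites:[\{id, compartment\}], biomass, exchanges:\{role:id\}\}}).
#' Reaction and gene orderings follow the file and are stable across
#' repeated loads.
#'
#' @param path model file.
#' @param format \code{"json"} or \code{"sbml"}; inferred from the file
#'   extension when omitted.
#' @param bound_cap finite cap replacing infinite bounds (default 1000,
#'   the usual convention in constraint-based models).
#' @param exchange_patterns named list of regexes resolving the roles
#'   oxygen/glucose/lactate/atp_drain/nadph_drain/ros to reaction ids when
#'   the file does not name them (see [default_exchange_patterns()]).
#' @return a \code{metabolic_model}.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml"),
                       bound_cap = 1000,
                       exchange_patterns = default_exchange_patterns()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "json") {
    x <- jsonlite::read_json(path)
    model_from_list(x, bound_cap, exchange_patterns)
  } else {
    load_sbml(path, bound_cap, exchange_patterns)
  }
}

# SBML L3 + fbc subset reader: species/compartments, stoichiometry,
# flux-bound parameters, geneProductAssociation with and/or nesting.
load_sbml <- function(path, bound_cap = 1000,
                      exchange_patterns = default_exchange_patterns()) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  att <- function(node, a) xml2::xml_attr(node, a)
  # global flux-bound parameters
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(att(pars, "value")), att(pars, "id"))
  # gene products
  gps <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct",
                            ns)
  gp_ids <- xml2::xml_attr(gps, "id")
  gp_labels <- xml2::xml_attr(gps, "label")
  gene_of <- stats::setNames(ifelse(is.na(gp_labels), gp_ids, gp_labels),
                             gp_ids)
  # species
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  boundary <- att(sp, "boundaryCondition") %in% "true"
  mets <- data.frame(id = att(sp, "id")[!boundary],
                     compartment = att(sp, "compartment")[!boundary],
                     stringsAsFactors = FALSE)
  gpa_tree <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      if (!ref %in% names(gene_of))
        stop("gene association references undeclared gene product '",
             ref, "'")
      return(gpr_gene(unname(gene_of[ref])))
    }
    kids <- lapply(xml2::xml_children(node), gpa_tree)
    gpr_node(if (nm == "and") "and" else "or", kids)
  }
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rids <- att(rx, "id")
  S <- matrix(0, nrow(mets), length(rids), dimnames = list(mets$id, rids))
  lb <- ub <- numeric(length(rids))
  gpr_str <- character(length(rids))
  gprs <- vector("list", length(rids))
  for (j in seq_along(rids)) {
    r <- rx[[j]]
    for (sr in xml2::xml_find_all(
      r, "./s:listOfReactants/s:speciesReference", ns)) {
      mid <- xml2::xml_attr(sr, "species")
      if (mid %in% mets$id)
        S[mid, j] <- S[mid, j] - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(
      r, "./s:listOfProducts/s:speciesReference", ns)) {
      mid <- xml2::xml_attr(sr, "species")
      if (mid %in% mets$id)
        S[mid, j] <- S[mid, j] + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    lb_ref <- xml2::xml_attr(r, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(r, "upperFluxBound")
    if (is.na(lb_ref) || is.na(ub_ref))
      stop("reaction '", rids[j], "' lacks fbc flux-bound attributes")
    if (!lb_ref %in% names(parval) || !ub_ref %in% names(parval))
      stop("reaction '", rids[j], "' references undefined bound parameter")
    lb[j] <- max(parval[[lb_ref]], -bound_cap)
    ub[j] <- min(parval[[ub_ref]], bound_cap)
    gpa <- xml2::xml_find_first(r, "./fbc:geneProductAssociation", ns)
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) {
        tree <- gpa_tree(kids[[1]])
        unknown <- setdiff(gpr_genes(tree), unname(gene_of))
        if (length(unknown) || anyNA(gpr_genes(tree)))
          stop("reaction '", rids[j],
               "' gene association references undeclared gene(s): ",
               paste(unknown, collapse = ", "))
        gprs[[j]] <- tree
        gpr_str[j] <- serialize_gpr(tree)
      }
    }
  }
  rxns <- data.frame(id = rids, lb = lb, ub = ub, gpr = gpr_str,
                     stringsAsFactors = FALSE)
  biomass <- grep("biomass", rids, ignore.case = TRUE, value = TRUE)
  if (!length(biomass)) stop("no biomass reaction found in SBML model")
  m <- new_metabolic_model(mets, rxns, S, biomass[1],
                           resolve_exchanges(rids, S, exchange_patterns),
                           sort(unique(unname(gene_of))))
  m$gprs <- gprs
  validate_model(m)
}

#' Write a model to the JSON dialect (inverse of the JSON reader)
#' @param model a \code{metabolic_model}.
#' @param path output file.
#' @export
write_model_json <- function(model, path) {
  rxns <- lapply(seq_len(nrow(model$reactions)), function(j) {
    col <- model$S[, j]
    nz <- col[col != 0]
    list(id = model$reactions$id[j],
         mets = as.list(nz),
         lb = model$reactions$lb[j], ub = model$reactions$ub[j],
         gpr = model$reactions$gpr[j])
  })
  mets <- lapply(seq_len(nrow(model$mets)), function(i)
    list(id = model$mets$id[i], compartment = model$mets$compartment[i]))
  jsonlite::write_json(
    list(reactions = rxns, metabolites = mets,
         biomass = model$biomass_id, exchanges = model$exchanges),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Compartments each gene acts in
#'
#' A gene's compartments are the union of the compartments of the
#' metabolites of every reaction whose gene association references it.
#' @param model a \code{metabolic_model}.
#' @return named list: gene id -> character vector of compartment codes.
#' @export
gene_compartments <- function(model) {
  comp_of <- stats::setNames(model$mets$compartment, model$mets$id)
  out <- stats::setNames(vector("list", length(model$genes)), model$genes)
  for (g in model$genes) out[[g]] <- character()
  for (j in seq_len(nrow(model$reactions))) {
    g <- gpr_genes(model$gprs[[j]])
    if (!length(g)) next
    comps <- unique(unname(comp_of[names(which(model$S[, j] != 0))]))
    for (gg in g) out[[gg]] <- union(out[[gg]], comps)
  }
  out
}

#' Write knockout-screen scores to TSV
#'
#' Rows are sorted by pH-specificity then selectivity (both descending),
#' ties broken by target id, so repeated runs are byte-identical.
#' @param scores data.frame as returned by [run_screen()].
#' @param path output file.
#' @export
write_results <- function(scores, path) {
  cols <- c("target", "level", "SEL", "PHS", "sel_recurrence",
            "phs_recurrence", "quadrant")
  extra <- setdiff(names(scores), cols)
  scores <- scores[, c(cols, extra), drop = FALSE]
  if (nrow(scores))
    scores <- scores[order(-scores$PHS, -scores$SEL, scores$target), ,
                     drop = FALSE]
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read knockout-screen scores from TSV (inverse of [write_results()])
#' @param path TSV file.
#' @export
read_results <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}
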