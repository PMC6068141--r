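# Completion of partial pH-activity profiles: homolog transfer first, then
# per-point linear regression; grouped cross-validation of the predictors.

#' Read a precomputed homology table from TSV
#'
#' The table is the tabular output of an externally run profile-HMM search:
#' per query, hits ranked from closest (rank 1) upward.
#' @param path TSV with header \code{query_id hit_id rank score}.
#' @export
read_homology <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_homology(df)
}

#' Validate a homology table
#' @param table data.frame with columns \code{query_id}, \code{hit_id},
#'   \code{rank}, \code{score}; per query, ranks must be unique and start
#'   at 1.
#' @export
validate_homology <- function(table) {
  need <- c("query_id", "hit_id", "rank", "score")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("homology table missing column(s): ",
                         paste(miss, collapse = ", "))
  for (q in unique(table$query_id)) {
    r <- sort(table$rank[table$query_id == q])
    if (anyDuplicated(r) || r[1] != 1L)
      stop("ranks for query '", q, "' must be unique and start at 1")
  }
  table
}

#' Fill missing critical points from close homologs
#'
#' Each missing point is set to the median of that point over the \code{k}
#' closest homologs (by rank) whose profiles carry it; points no homolog
#' carries stay missing.  Provenance of filled points is \code{"homolog"}.
#'
#' @param profile a \code{ph_profile} (possibly incomplete).
#' @param table homology table (see [validate_homology()]).
#' @param db named list of \code{ph_profile} providing the hit profiles.
#' @param k number of closest informative hits to aggregate (default 5).
#' @return the profile with homolog-filled points.
#' @export
transfer_from_homologs <- function(profile, table, db, k = 5L) {
  if (profile_is_complete(profile) || is.null(table) || !nrow(table))
    return(profile)
  hits <- table[table$query_id == profile$enzyme_id, , drop = FALSE]
  if (!nrow(hits)) return(profile)
  hits <- hits[order(hits$rank), , drop = FALSE]
  for (pt in PH_POINTS[is.na(profile$points)]) {
    vals <- numeric()
    for (h in hits$hit_id) {
      hp <- db[[h]]
      if (!is.null(hp) && !is.na(hp$points[[pt]]))
        vals <- c(vals, hp$points[[pt]])
      if (length(vals) >= k) break
    }
    if (length(vals)) {
      profile$points[[pt]] <- aggregate_point(vals)
      profile$source[[pt]] <- "homolog"
    }
  }
  profile
}

#' Fit per-point linear regressors from complete training profiles
#'
#' For each critical point an ordinary-least-squares predictor from the
#' other five points is fitted.  The training matrix is retained so that,
#' at prediction time, the model can be refitted on exactly the predictor
#' subset a partial profile makes available (listwise availability
#' patterns).  The regressor interface is deliberately pluggable: anything
#' with a \code{predict_point(reg, target, available)} contract can stand
#' in.
#'
#' @param training list of complete \code{ph_profile} (at least 10).
#' @return object of class \code{ph_regressors}; element
#'   \code{coefficients} exposes the full-pattern coefficients per point.
#' @export
fit_point_regressors <- function(training) {
  training <- Filter(profile_is_complete, training)
  if (length(training) < 10L)
    stop("need at least 10 complete training profiles, got ",
         length(training))
  mat <- t(vapply(training, function(p) p$points[PH_POINTS], numeric(6)))
  colnames(mat) <- PH_POINTS
  coefs <- list()
  for (pt in PH_POINTS) {
    others <- setdiff(PH_POINTS, pt)
    d <- as.data.frame(mat)
    fml <- stats::reformulate(others, response = pt)
    fit <- stats::lm(fml, data = d)
    if (fit$rank < length(others) + 1L)
      warning("degenerate training set: rank-deficient design for point ",
              pt, " (collinear or constant predictors)")
    coefs[[pt]] <- stats::coef(fit)
  }
  structure(list(training = mat, coefficients = coefs),
            class = "ph_regressors")
}

#' Predict one critical point from the available others
#'
#' Refits the OLS model on the training matrix using only the predictors
#' present in \code{available}; with no usable predictor the training mean
#' of the target point is returned (intercept-only model).
#'
#' @param reg a \code{ph_regressors}.
#' @param target one of the six point names.
#' @param available named numeric vector of the profile's known points.
#' @export
predict_point <- function(reg, target, available) {
  stopifnot(inherits(reg, "ph_regressors"), target %in% PH_POINTS)
  preds <- intersect(setdiff(PH_POINTS, target),
                     names(available)[!is.na(available)])
  d <- as.data.frame(reg$training)
  if (!length(preds)) return(mean(d[[target]]))
  fit <- stats::lm(stats::reformulate(preds, response = target), data = d)
  newdata <- as.data.frame(as.list(available[preds]))
  as.vector(suppressWarnings(stats::predict(fit, newdata = newdata)))
}

#' Complete a partial profile: homologs first, then regression
#'
#' Missing points are first transferred from close homologs, then any
#' still-missing point is predicted by the per-point regressors from the
#' points available after transfer.  A completed profile that violates the
#' ordering invariant is returned flagged (attribute \code{invalid} with a
#' diagnostic) rather than clamped; callers are expected to drop and
#' report such profiles.
#'
#' @param profile a \code{ph_profile} with at least one assigned point.
#' @param table optional homology table.
#' @param db profile database backing the homology table.
#' @param regressors optional \code{ph_regressors}.
#' @return a complete \code{ph_profile} (possibly flagged invalid).
#' @export
impute_profile <- function(profile, table = NULL, db = NULL,
                           regressors = NULL, k = 5L) {
  if (all(is.na(profile$points)))
    stop("profile '", profile$enzyme_id,
         "' has no assigned point: unusable enzyme")
  if (profile_is_complete(profile)) return(profile)
  if (!is.null(table)) profile <- transfer_from_homologs(profile, table, db, k)
  if (!profile_is_complete(profile) && !is.null(regressors)) {
    avail <- profile$points[!is.na(profile$points)]
    for (pt in PH_POINTS[is.na(profile$points)]) {
      profile$points[[pt]] <- predict_point(regressors, pt, avail)
      profile$source[[pt]] <- "regressed"
    }
  }
  if (!profile_is_ordered(profile)) {
    msg <- paste0("imputed profile '", profile$enzyme_id,
                  "' violates point ordering; flagged invalid")
    warning(msg)
    attr(profile, "invalid") <- TRUE
    attr(profile, "diagnostic") <- msg
  }
  profile
}

#' Impute every incomplete profile of a database
#'
#' Applies [impute_profile()] across the database, dropping profiles that
#' remain incomplete or end up violating the ordering invariant.
#'
#' @inheritParams impute_profile
#' @param db named list of \code{ph_profile}.
#' @return named list of complete, valid profiles; attribute
#'   \code{dropped} lists the enzyme ids that were rejected.
#' @export
impute_db <- function(db, table = NULL, regressors = NULL, k = 5L) {
  out <- list(); dropped <- character()
  for (eid in names(db)) {
    p <- tryCatch(
      suppressWarnings(impute_profile(db[[eid]], table, db, regressors, k)),
      error = function(e) NULL)
    if (is.null(p) || !profile_is_complete(p) || isTRUE(attr(p, "invalid")))
      dropped <- c(dropped, eid)
    else out[[eid]] <- p
  }
  attr(out, "dropped") <- dropped
  out
}

#' Cross-validate the point predictors on a profile database
#'
#' Three train/test split protocols of increasing stringency are
#' available: plain k-fold over profiles, leave-species-out (all profiles
#' of a taxon held out together) and leave-EC-out (all profiles of an EC
#' class held out together).  For each held-out profile every critical
#' point is hidden in turn and predicted from the remaining five; Pearson
#' correlation and RMSE between predictions and truth are reported per
#' point.
#'
#' @param db named list of complete \code{ph_profile}.
#' @param folds number of folds (k-fold protocol only).
#' @param protocol one of \code{"kfold"}, \code{"leave_species_out"},
#'   \code{"leave_ec_out"}.
#' @param seed integer seed for the fold shuffle (default 0).
#' @return data.frame with columns \code{point}, \code{r}, \code{rmse},
#'   \code{n}.
#' @export
cross_validate <- function(db, folds = 10L,
                           protocol = c("kfold", "leave_species_out",
                                        "leave_ec_out"),
                           seed = 0L) {
  protocol <- match.arg(protocol)
  db <- Filter(profile_is_complete, db)
  n <- length(db)
  if (protocol == "kfold" && n < folds)
    stop("need at least ", folds, " complete profiles, got ", n)
  if (n < 12L) stop("too few complete profiles for cross-validation: ", n)
  ids <- names(db)
  grp <- switch(protocol,
    kfold = {
      set.seed(seed)
      stats::setNames(sample(rep_len(seq_len(folds), n)), ids)
    },
    leave_species_out = {
      tx <- vapply(db, function(p) as.character(p$taxon), character(1))
      stats::setNames(match(tx, unique(tx)), ids)
    },
    leave_ec_out = {
      ec <- vapply(db, function(p) as.character(p$ec), character(1))
      stats::setNames(match(ec, unique(ec)), ids)
    })
  if (length(unique(grp)) < 2L)
    stop("protocol '", protocol, "' produces fewer than 2 groups")
  preds <- stats::setNames(vector("list", 6L), PH_POINTS)
  truth <- stats::setNames(vector("list", 6L), PH_POINTS)
  for (g in unique(grp)) {
    train <- db[ids[grp != g]]
    if (length(train) < 10L) next
    reg <- suppressWarnings(fit_point_regressors(train))
    for (eid in ids[grp == g]) {
      p <- db[[eid]]
      for (pt in PH_POINTS) {
        avail <- p$points[setdiff(PH_POINTS, pt)]
        preds[[pt]] <- c(preds[[pt]], predict_point(reg, pt, avail))
        truth[[pt]] <- c(truth[[pt]], p$points[[pt]])
      }
    }
  }
  res <- lapply(PH_POINTS, function(pt) {
    pr <- preds[[pt]]; tr <- truth[[pt]]
    r <- if (length(pr) > 2L && stats::sd(tr) > 0 && stats::sd(pr) > 0)
      stats::cor(pr, tr) else NA_real_
    data.frame(point = pt, r = r,
               rmse = sqrt(mean((pr - tr)^2)), n = length(pr))
  })
  do.call(rbind, res)
}
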