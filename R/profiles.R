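# Six-point pH-activity profiles: construction from activity records,
# interpolation, and TSV serialization.

#' Names of the six critical pH points, in required order
#'
#' A complete profile must satisfy A0 <= A50 <= A100 <= B100 <= B50 <= B0:
#' the pH at which the enzyme reaches 0%, 50% and 100% of maximal activity
#' on the acidic (A) flank, and loses it again on the basic (B) flank.
#' @export
PH_POINTS <- c("A0", "A50", "A100", "B100", "B50", "B0")

#' Activity levels at the six critical points (percent of maximum)
#' @keywords internal
PH_LEVELS <- c(A0 = 0, A50 = 50, A100 = 100, B100 = 100, B50 = 50, B0 = 0)

#' Construct a pH-activity profile
#'
#' @param enzyme_id character scalar, gene symbol or EC number.
#' @param points named numeric vector; any subset of
#'   \code{A0, A50, A100, B100, B50, B0} (pH units). Missing points are `NA`.
#' @param source named character vector giving per-point provenance, one of
#'   \code{"experimental"}, \code{"homolog"}, \code{"regressed"},
#'   \code{"default"}; `NA` for absent points.
#' @param taxon,ec optional metadata carried from the contributing records
#'   (used by the grouped cross-validation protocols).
#' @return an object of class \code{ph_profile}.
#' @export
ph_profile <- function(enzyme_id, points = numeric(), source = NULL,
                       taxon = NA_character_, ec = NA_character_) {
  stopifnot(is.character(enzyme_id), length(enzyme_id) == 1L)
  full <- stats::setNames(rep(NA_real_, 6L), PH_POINTS)
  if (length(points)) {
    bad <- setdiff(names(points), PH_POINTS)
    if (length(bad)) stop("unknown critical point name(s): ",
                          paste(bad, collapse = ", "))
    full[names(points)] <- as.numeric(points)
  }
  if (any(!is.na(full) & (full <= 0 | full >= 14)))
    stop("critical pH points must lie in (0, 14)")
  src <- stats::setNames(rep(NA_character_, 6L), PH_POINTS)
  src[!is.na(full)] <- "experimental"
  if (!is.null(source)) src[names(source)] <- source
  src[is.na(full)] <- NA_character_
  structure(list(enzyme_id = enzyme_id, points = full, source = src,
                 taxon = taxon, ec = ec),
            class = "ph_profile")
}

#' @export
print.ph_profile <- function(x, ...) {
  cat("<ph_profile>", x$enzyme_id,
      if (profile_is_complete(x)) "(complete)" else "(incomplete)", "\n")
  print(round(x$points, 3))
  invisible(x)
}

#' Is every critical point of the profile assigned?
#' @param profile a \code{ph_profile}.
#' @export
profile_is_complete <- function(profile) !any(is.na(profile$points))

#' Does the profile respect the point ordering A0 <= ... <= B0?
#'
#' Only the points that are present are compared; an incomplete profile is
#' ordered when its assigned points, taken in canonical order, are
#' non-decreasing.
#' @param profile a \code{ph_profile}.
#' @export
profile_is_ordered <- function(profile) {
  p <- profile$points[!is.na(profile$points)]
  !is.unsorted(p)
}

#' Validate a profile for downstream use
#'
#' @param profile a \code{ph_profile}.
#' @param require_complete error also on missing points.
#' @return the profile, invisibly; ordering violations raise an error
#'   (violations are rejected, never silently reordered).
#' @export
validate_profile <- function(profile, require_complete = FALSE) {
  if (!profile_is_ordered(profile))
    stop("profile '", profile$enzyme_id,
         "' violates the ordering A0 <= A50 <= A100 <= B100 <= B50 <= B0")
  if (require_complete && !profile_is_complete(profile))
    stop("profile '", profile$enzyme_id, "' is incomplete: missing ",
         paste(PH_POINTS[is.na(profile$points)], collapse = ", "))
  invisible(profile)
}

#' Discretize a relative-activity percentage into the 0/50/100 levels
#'
#' Activity records are binned before curation: activities up to 25% count
#' as 0% points, activities in (25, 75] as 50% points, and activities above
#' 75% as 100% points.
#'
#' @param activity_pct numeric vector in \[0, 100\].
#' @return integer vector with values in \{0, 50, 100\}.
#' @examples
#' discretize_activity(c(10, 60, 100))  # 0, 50, 100
#' @export
discretize_activity <- function(activity_pct) {
  if (any(is.na(activity_pct)) || any(activity_pct < 0 | activity_pct > 100))
    stop("activity_pct must lie in [0, 100]")
  ifelse(activity_pct <= 25, 0L, ifelse(activity_pct <= 75, 50L, 100L))
}

#' Aggregate the pH values contributing to one critical point
#'
#' When several records report the same critical point the median pH is
#' used (for even counts, the mean of the two central values).
#'
#' @param values numeric vector of pH values, non-empty.
#' @export
aggregate_point <- function(values) {
  if (length(values) == 0L) stop("no data for this critical point")
  stats::median(values)
}

#' Validate a table of activity records
#'
#' @param records data.frame with columns \code{enzyme_id}, \code{ec},
#'   \code{taxon}, \code{ph}, \code{activity_pct}, \code{record_kind}
#'   (\code{"optimum"} or \code{"range"}).
#' @return the validated data.frame (invisibly usable).
#' @export
validate_records <- function(records) {
  need <- c("enzyme_id", "ec", "taxon", "ph", "activity_pct", "record_kind")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(records$ph <= 0 | records$ph >= 14))
    stop("record pH values must lie in (0, 14)")
  if (any(records$activity_pct < 0 | records$activity_pct > 100))
    stop("record activity_pct values must lie in [0, 100]")
  if (!all(records$record_kind %in% c("optimum", "range")))
    stop("record_kind must be 'optimum' or 'range'")
  records
}

#' Build six-point profiles from binned activity records
#'
#' Per enzyme, each record's activity is discretized to the 0/50/100 level.
#' The 100%-level records define the optimum plateau: they are split into
#' an acidic (lowest) and a basic (highest) side at the midpoint of their
#' span, and the per-side median populates A100 and B100 (a side left
#' empty takes the other side's value, so a single optimum record gives
#' the degenerate plateau A100 = B100).  0%- and 50%-level records are
#' assigned to the acidic or basic flank by their position relative to
#' the plateau midpoint (falling back to the median record pH when the
#' enzyme has no 100% record), and the per-flank median populates
#' A0/A50/B50/B0.
#'
#' Profiles whose assigned points violate the canonical ordering are kept
#' but flagged through the \code{violations} attribute of the returned
#' list, never silently reordered.
#'
#' @param records validated activity-record data.frame
#'   (see [validate_records()]).
#' @return named list of \code{ph_profile}, one per enzyme, with attribute
#'   \code{violations}: character vector of enzyme ids whose raw points are
#'   out of order.
#' @export
build_profiles <- function(records) {
  records <- validate_records(records)
  out <- list()
  violations <- character()
  for (eid in unique(records$enzyme_id)) {
    rec <- records[records$enzyme_id == eid, , drop = FALSE]
    lev <- discretize_activity(rec$activity_pct)
    pts <- c()
    opt_ph <- rec$ph[lev == 100L]
    if (length(opt_ph)) {
      mid <- (min(opt_ph) + max(opt_ph)) / 2
      acid <- opt_ph[opt_ph < mid]
      basic <- opt_ph[opt_ph >= mid]
      a100 <- if (length(acid)) aggregate_point(acid) else NA_real_
      b100 <- if (length(basic)) aggregate_point(basic) else NA_real_
      if (is.na(a100)) a100 <- b100
      if (is.na(b100)) b100 <- a100
      pts["A100"] <- a100
      pts["B100"] <- b100
    } else {
      mid <- stats::median(rec$ph)
    }
    for (l in c(0L, 50L)) {
      ph_l <- rec$ph[lev == l]
      acid <- ph_l[ph_l < mid]
      basic <- ph_l[ph_l >= mid]
      a_name <- if (l == 0L) "A0" else "A50"
      b_name <- if (l == 0L) "B0" else "B50"
      if (length(acid)) pts[a_name] <- aggregate_point(acid)
      if (length(basic)) pts[b_name] <- aggregate_point(basic)
    }
    prof <- ph_profile(eid, pts,
                       taxon = names(sort(table(rec$taxon),
                                          decreasing = TRUE))[1],
                       ec = rec$ec[1])
    if (!profile_is_ordered(prof)) violations <- c(violations, eid)
    out[[eid]] <- prof
  }
  attr(out, "violations") <- violations
  out
}

#' Relative enzyme activity at a given pH
#'
#' Piecewise-linear interpolation through the six critical points
#' \code{(A0, 0), (A50, 50), (A100, 100), (B100, 100), (B50, 50), (B0, 0)};
#' 0 outside \[A0, B0\], 100 on the optimum plateau \[A100, B100\],
#' continuous everywhere.  Coincident neighbouring points (a degenerate
#' segment) take the larger of the two node activities.
#'
#' @param profile a complete, ordered \code{ph_profile}.
#' @param ph numeric vector of pH values.
#' @return numeric vector of activities in \[0, 100\].
#' @export
activity_at <- function(profile, ph) {
  validate_profile(profile, require_complete = TRUE)
  x <- profile$points[PH_POINTS]
  y <- unname(PH_LEVELS)
  vapply(ph, function(p) {
    if (p < x[1] || p > x[6]) return(0)
    best <- 0
    for (i in 1:5) {
      if (p >= x[i] && p <= x[i + 1]) {
        v <- if (x[i + 1] == x[i]) max(y[i], y[i + 1]) else
          y[i] + (y[i + 1] - y[i]) * (p - x[i]) / (x[i + 1] - x[i])
        best <- max(best, v)
      }
    }
    best
  }, numeric(1))
}

#' pH optimum of a profile
#'
#' Defined as the midpoint of the optimum plateau, (A100 + B100) / 2.
#' @param profile a \code{ph_profile} with both plateau points assigned.
#' @export
ph_optimum <- function(profile) {
  a <- profile$points[["A100"]]; b <- profile$points[["B100"]]
  if (is.na(a) || is.na(b))
    stop("profile '", profile$enzyme_id, "' lacks plateau points A100/B100")
  (a + b) / 2
}

# ---- TSV serialization -----------------------------------------------------

#' Write a profile database to TSV
#'
#' Columns: \code{enzyme_id}, the six points, \code{src_*} provenance
#' columns, \code{taxon}, \code{ec}.  Missing points are written as `NA`.
#' Rows are sorted by enzyme id for byte-stable output.
#'
#' @param db named list of \code{ph_profile}.
#' @param path output file.
#' @export
write_profiles <- function(db, path) {
  rows <- lapply(db[order(names(db))], function(p) {
    v <- as.list(c(stats::setNames(as.list(p$points), PH_POINTS),
                   stats::setNames(as.list(p$source),
                                   paste0("src_", PH_POINTS))))
    c(list(enzyme_id = p$enzyme_id), v,
      list(taxon = p$taxon, ec = p$ec))
  })
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a profile database from TSV (inverse of [write_profiles()])
#' @param path TSV file written by [write_profiles()].
#' @return named list of \code{ph_profile}.
#' @export
read_profiles <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  out <- list()
  for (i in seq_len(nrow(df))) {
    pts <- unlist(df[i, PH_POINTS])
    src <- unlist(df[i, paste0("src_", PH_POINTS)])
    names(src) <- PH_POINTS
    keep <- !is.na(pts)
    out[[df$enzyme_id[i]]] <- ph_profile(
      df$enzyme_id[i], pts[keep], source = src[keep],
      taxon = if ("taxon" %in% names(df)) df$taxon[i] else NA_character_,
      ec = if ("ec" %in% names(df)) df$ec[i] else NA_character_)
  }
  out
}

#' Read activity records from TSV
#' @param path TSV with header
#'   \code{enzyme_id ec taxon ph activity_pct record_kind}.
#' @export
read_records <- function(path) {
  validate_records(utils::read.table(path, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE))
}

#' Write activity records to TSV
#' @param records validated record data.frame.
#' @param path output file.
#' @export
write_records <- function(records, path) {
  utils::write.table(validate_records(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
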