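#' Length-frequency table
#'
#' Binned length-frequency counts by sampling month: a matrix of
#' non-negative integer counts with one row per length bin and one column
#' per sampling date. Bins are uniform, left-closed right-open
#' `[lower, lower + width)` and labelled by their lower edge.
#'
#' @param counts Numeric matrix, bins x dates, non-negative.
#' @param bin_lower Strictly increasing, uniformly spaced lower bin edges (cm).
#' @param dates `Date` vector (month resolution) of the sampling occasions,
#'   one per column of `counts`. Days other than the 1st are truncated to the
#'   month with a warning.
#' @return An object of class `"lfq"`.
#' @export
lfq <- function(counts, bin_lower, dates) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts), is.numeric(bin_lower))
  dates <- as.Date(dates)
  if (length(bin_lower) != nrow(counts))
    stop("length(bin_lower) must equal nrow(counts)")
  if (length(dates) != ncol(counts))
    stop("length(dates) must equal ncol(counts)")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be finite and non-negative")
  if (length(bin_lower) < 2L)
    stop("at least two length bins are required")
  w <- diff(bin_lower)
  if (any(w <= 0) || max(abs(w - w[1])) > 1e-8)
    stop("bin edges must be strictly increasing with uniform spacing")
  if (is.unsorted(dates)) {
    o <- order(dates)
    dates <- dates[o]
    counts <- counts[, o, drop = FALSE]
  }
  if (any(as.integer(format(dates, "%d")) != 1L)) {
    warning("dates truncated to month resolution")
    dates <- as.Date(format(dates, "%Y-%m-01"))
  }
  dimnames(counts) <- list(format(bin_lower), format(dates, "%Y-%m"))
  structure(list(counts = counts, bin_lower = as.numeric(bin_lower),
                 bin_width = w[1], dates = dates),
            class = "lfq")
}

#' @export
print.lfq <- function(x, ...) {
  cat(sprintf("Length-frequency table: %d bins of %g cm (%g-%g cm), %d dates (%s to %s), %g individuals\n",
              nrow(x$counts), x$bin_width, min(x$bin_lower),
              max(x$bin_lower) + x$bin_width, ncol(x$counts),
              format(min(x$dates), "%Y-%m"), format(max(x$dates), "%Y-%m"),
              sum(x$counts)))
  invisible(x)
}

#' @export
summary.lfq <- function(object, ...) {
  print(object)
  cat("Counts per date:\n")
  print(colSums(object$counts))
  invisible(object)
}

#' @param x An `lfq` object.
#' @param ... Passed to [graphics::image()].
#' @rdname lfq
#' @export
plot.lfq <- function(x, ...) {
  graphics::image(x = as.numeric(x$dates), y = x$bin_lower + x$bin_width / 2,
                  z = t(x$counts), xlab = "Date", ylab = "Fork length (cm)",
                  ...)
  invisible(x)
}

# decimal calendar year at month resolution (month start)
decimal_date <- function(dates) {
  dates <- as.Date(dates)
  as.integer(format(dates, "%Y")) + (as.integer(format(dates, "%m")) - 1L) / 12
}

#' Read a length-frequency CSV
#'
#' Reads the long-format dialect `date,length_lower,count` (dates as ISO
#' months `YYYY-MM` or full dates truncated to month), validates it, fills
#' missing bins and months with zero counts, and returns an [lfq()] object.
#'
#' @param path CSV file path.
#' @param bin_width Expected bin width in cm; inferred from the data when
#'   `NULL`. Default 5 cm.
#' @param date_range Optional length-2 vector declaring the month range to
#'   gap-fill; defaults to the observed range.
#' @return An `lfq` object.
#' @seealso [write_lfq()]
#' @export
read_lfq <- function(path, bin_width = 5, date_range = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "length_lower", "count")
  if (!all(need %in% names(d)))
    stop("LFQ CSV must have columns: ", paste(need, collapse = ", "))
  dt <- as.Date(paste0(substr(as.character(d$date), 1, 7), "-01"),
                format = "%Y-%m-%d")
  bad <- which(is.na(dt))
  if (length(bad))
    stop("unparseable date(s) at row(s): ", paste(bad, collapse = ", "))
  bad <- which(!is.finite(d$count) | d$count < 0)
  if (length(bad))
    stop("negative or non-finite count(s) at row(s): ", paste(bad, collapse = ", "))
  lowers <- sort(unique(d$length_lower))
  if (is.null(bin_width)) {
    if (length(lowers) < 2L) stop("cannot infer bin width from a single bin")
    bin_width <- min(diff(lowers))
  }
  off <- (d$length_lower - lowers[1]) / bin_width
  bad <- which(abs(off - round(off)) > 1e-8)
  if (length(bad))
    stop("length_lower not on a uniform ", bin_width,
         " cm grid at row(s): ", paste(bad, collapse = ", "))
  edges <- seq(lowers[1], max(lowers), by = bin_width)
  if (is.null(date_range)) date_range <- range(dt)
  date_range <- as.Date(paste0(substr(as.character(date_range), 1, 7), "-01"))
  months <- seq(date_range[1], date_range[2], by = "month")
  counts <- matrix(0, length(edges), length(months))
  i <- match(round((d$length_lower - edges[1]) / bin_width) + 1, seq_along(edges))
  j <- match(format(dt, "%Y-%m"), format(months, "%Y-%m"))
  keep <- !is.na(i) & !is.na(j)
  for (r in which(keep)) counts[i[r], j[r]] <- counts[i[r], j[r]] + d$count[r]
  lfq(counts, edges, months)
}

#' Write a length-frequency table as CSV
#'
#' Long format `date,length_lower,count`, the dialect read by [read_lfq()].
#' Zero-count cells are written too, so the table round-trips exactly.
#'
#' @param x An `lfq` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lfq <- function(x, path) {
  stopifnot(inherits(x, "lfq"))
  d <- data.frame(
    date = rep(format(x$dates, "%Y-%m"), each = nrow(x$counts)),
    length_lower = rep(x$bin_lower, ncol(x$counts)),
    count = as.vector(x$counts))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pool a length-frequency table over dates
#'
#' @param x An `lfq` object.
#' @return Named numeric vector of counts per bin (names = lower edges).
#' @export
pool_lfq <- function(x) {
  stopifnot(inherits(x, "lfq"))
  stats::setNames(rowSums(x$counts), format(x$bin_lower))
}
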