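#' Read a counts file
#'
#' The default dialect is a delimited text file with a header row and two
#' columns: \code{timestamp} (ISO-8601, minute resolution) and \code{counts}
#' (nonnegative number), one row per minute, strictly increasing with no
#' gaps. A gap, duplicate or out-of-order timestamp is a hard error naming
#' the offending row. A headerless single-column file of counts is accepted
#' with \code{header = FALSE} plus an explicit \code{start_time}.
#'
#' @param path file path
#' @param sep field separator (default ",")
#' @param header file has a timestamp,counts header row (default TRUE)
#' @param start_time required when \code{header = FALSE}: timestamp of the
#'   first sample
#' @param dt_sec sampling interval for the headerless dialect (default 60)
#' @param warn_nonwear forwarded to \code{\link{validate_count_series}}
#' @return a validated \code{count_series}
#' @export
read_counts <- function(path, sep = ",", header = TRUE, start_time = NULL,
                        dt_sec = 60, warn_nonwear = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!header) {
    if (is.null(start_time))
      stop("headerless input needs an explicit start_time")
    v <- utils::read.table(path, sep = sep, header = FALSE)[[1L]]
    if (!is.numeric(v)) stop("headerless input must hold one numeric column")
    return(validate_count_series(
      count_series(v, start_time = start_time, dt_sec = dt_sec),
      warn_nonwear = warn_nonwear))
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = c("character", "numeric"))
  if (ncol(df) < 2L) stop("expected columns: timestamp, counts")
  ts <- as.POSIXct(df[[1L]], tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                                  "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"))
  if (anyNA(ts))
    stop("unparseable timestamp at data row ", which(is.na(ts))[1L])
  d <- as.numeric(difftime(ts[-1L], ts[-length(ts)], units = "secs"))
  if (any(d <= 0))
    stop("duplicate or out-of-order timestamp at data row ",
         which(d <= 0)[1L] + 1L)
  dt0 <- d[1L]
  gap <- which(abs(d - dt0) > 1e-6)
  if (length(gap))
    stop(sprintf("gap in timestamps at data row %d (%g s instead of %g s)",
                 gap[1L] + 1L, d[gap[1L]], dt0))
  validate_count_series(
    count_series(df[[2L]], start_time = ts[1L], dt_sec = dt0),
    warn_nonwear = warn_nonwear)
}

#' Write a counts file
#'
#' Writes the timestamp,counts dialect read back by \code{\link{read_counts}}
#' (round-trip identity).
#'
#' @param series a \code{count_series}
#' @param path output path
#' @param sep field separator
#' @return \code{path}, invisibly
#' @export
write_counts <- function(series, path, sep = ",") {
  stopifnot(inherits(series, "count_series"))
  df <- as.data.frame(series)
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a complexity track as delimited text
#'
#' Columns: \code{timestamp, eval_scale_minutes, slope_b, fractal_dimension,
#' n_levels_used, status}.
#'
#' @param track a \code{\link{run_taaa}} result
#' @param path output path
#' @param sep field separator
#' @return \code{path}, invisibly
#' @export
write_track <- function(track, path, sep = ",") {
  stopifnot(inherits(track, "complexity_track"))
  out <- data.frame(
    timestamp = format(track$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    eval_scale_minutes = track$timescale_min,
    slope_b = track$slope_b,
    fractal_dimension = track$D,
    n_levels_used = track$n_levels,
    status = track$status)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a weekly functioning ranking table
#'
#' Delimited text with header \code{patient_id, week, rank} where rank is a
#' number (1 = worst ... 3 = best) or a label among worst/average/best.
#' Partial rankings are allowed; ties are resolved to average ranks by
#' \code{\link{functioning_ranks}} at use time.
#'
#' @param path file path
#' @param sep field separator
#' @return data.frame with columns \code{patient_id, week, rank} (rank kept
#'   as given, character)
#' @export
read_ranking <- function(path, sep = ",") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character")
  names(df) <- tolower(names(df))
  need <- c("patient_id", "week", "rank")
  if (!all(need %in% names(df)))
    stop("ranking file needs columns: ", paste(need, collapse = ", "))
  df$week <- as.integer(df$week)
  df[need]
}
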