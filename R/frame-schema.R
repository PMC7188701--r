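#' Frame timing schema for a dynamic PET acquisition
#'
#' A frame schema is the ordered list of frame start/end times (seconds) of a
#' dynamic acquisition. Frames must be contiguous, non-overlapping and
#' strictly increasing, with the first frame starting at 0 s.
#'
#' @param start_s numeric vector of frame start times, seconds.
#' @param end_s numeric vector of frame end times, seconds.
#' @return An object of class \code{frame_schema}: a data frame with columns
#'   \code{frame_index}, \code{start_s}, \code{end_s}.
#' @examples
#' sch <- frame_schema(c(0, 60), c(60, 120))
#' frame_mid_min(default_frame_schema())
#' @export
frame_schema <- function(start_s, end_s) {
  if (length(start_s) != length(end_s) || length(start_s) < 1L)
    stop("start_s and end_s must be non-empty vectors of equal length")
  start_s <- as.numeric(start_s); end_s <- as.numeric(end_s)
  if (anyNA(start_s) || anyNA(end_s))
    stop("frame times must be finite")
  if (start_s[1L] != 0)
    stop("first frame must start at 0 s, got ", start_s[1L])
  if (any(end_s <= start_s))
    stop("all frame durations must be positive")
  if (length(start_s) > 1L && any(start_s[-1L] != end_s[-length(end_s)]))
    stop("frames must be contiguous: each start must equal the previous end")
  out <- data.frame(frame_index = seq_along(start_s),
                    start_s = start_s, end_s = end_s)
  class(out) <- c("frame_schema", "data.frame")
  out
}

#' Default 16-frame dynamic acquisition schema
#'
#' The standard 0-50 min dynamic FET protocol: five 1-min frames, five 3-min
#' frames and six 5-min frames, ending at 3000 s.
#'
#' @return A \code{\link{frame_schema}} with 16 frames.
#' @export
default_frame_schema <- function() {
  dur <- c(rep(60, 5), rep(180, 5), rep(300, 6))
  end <- cumsum(dur)
  frame_schema(c(0, end[-length(end)]), end)
}

#' @rdname frame_schema
#' @param schema a \code{frame_schema}.
#' @return \code{frame_mid_min}/\code{frame_end_min}: frame mid/end times in
#'   minutes.
#' @export
frame_mid_min <- function(schema) (schema$start_s + schema$end_s) / 2 / 60

#' @rdname frame_schema
#' @export
frame_end_min <- function(schema) schema$end_s / 60

#' Read or write a frame schema as CSV
#'
#' The CSV has columns \code{frame_index}, \code{start_s}, \code{end_s}. A
#' copy of the default 16-frame schema ships with the package at
#' \code{system.file("extdata", "frame_schema_16.csv", package = "dynfet")}.
#'
#' @param path CSV file path.
#' @return \code{read_frame_table}: a \code{\link{frame_schema}}.
#' @export
read_frame_table <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("start_s", "end_s")
  if (!all(need %in% names(tab)))
    stop("frame table must have columns start_s and end_s: ", path)
  if (!is.null(tab$frame_index)) tab <- tab[order(tab$frame_index), ]
  frame_schema(tab$start_s, tab$end_s)
}

#' @rdname read_frame_table
#' @param schema a \code{frame_schema} to write.
#' @export
write_frame_table <- function(schema, path) {
  utils::write.csv(as.data.frame(schema), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.frame_schema <- function(x, ...) {
  cat(sprintf("Dynamic frame schema: %d frames, 0-%g min\n",
              nrow(x), max(x$end_s) / 60))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
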