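#' Whole-cell current trace
#'
#' A uniformly sampled current recording with metadata and an optional
#' link to the [application_protocol()] that produced it. Current is
#' signed: inward current at -60 mV is negative; analysis functions work
#' on magnitudes.
#'
#' @param time sample times, s, on a uniform grid.
#' @param current current, pA.
#' @param sampling_rate sampling rate, Hz.
#' @param protocol optional [application_protocol()].
#' @param cell_id,genotype labels.
#' @return An object of class `trace`.
#' @export
new_trace <- function(time, current, sampling_rate, protocol = NULL,
                      cell_id = NA_character_, genotype = NA_character_) {
  if (length(time) != length(current))
    stop("time and current must have the same length", call. = FALSE)
  if (length(time) < 2L)
    stop("a trace needs at least two samples", call. = FALSE)
  if (any(!is.finite(time)) || any(!is.finite(current)))
    stop("trace contains non-finite samples", call. = FALSE)
  dt <- diff(time)
  if (max(abs(dt - 1 / sampling_rate)) > 1e-9)
    stop("time grid is not uniform at the stated sampling rate ",
         "(max jitter exceeds 1e-9 s)", call. = FALSE)
  structure(list(time = as.numeric(time), current = as.numeric(current),
                 sampling_rate = sampling_rate, protocol = protocol,
                 cell_id = cell_id, genotype = genotype),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("Trace: %d samples at %g Hz (%.3f-%.3f s)",
              length(x$time), x$sampling_rate, min(x$time), max(x$time)))
  if (!is.na(x$genotype)) cat(", genotype", x$genotype)
  if (!is.na(x$cell_id)) cat(", cell", x$cell_id)
  cat(sprintf("\n  peak |I| = %.1f pA\n", max(abs(x$current))))
  invisible(x)
}

#' Write / read a trace as delimited text
#'
#' Two tab-separated columns with a required header (`time_s`,
#' `current_pA`). When the trace carries a protocol it is written to a
#' YAML sidecar `<path>.protocol.yaml` and restored on read.
#'
#' @param trace a [new_trace()] object.
#' @param path file path.
#' @param sampling_rate sampling rate for `read_trace`; inferred from the
#'   time column when `NULL`.
#' @return `write_trace` returns `path` invisibly; `read_trace` a trace.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_s = sprintf("%.17g", trace$time),
                   current_pA = sprintf("%.17g", trace$current))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(trace$protocol))
    write_protocol(trace$protocol, paste0(path, ".protocol.yaml"))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, sampling_rate = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_s", "current_pA") %in% names(df)))
    stop("trace file must have header columns time_s and current_pA",
         call. = FALSE)
  if (is.null(sampling_rate))
    sampling_rate <- 1 / stats::median(diff(df$time_s))
  proto_path <- paste0(path, ".protocol.yaml")
  protocol <- if (file.exists(proto_path)) read_protocol(proto_path) else NULL
  new_trace(df$time_s, df$current_pA, sampling_rate, protocol = protocol)
}
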