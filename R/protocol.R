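#' Solution-application protocol
#'
#' Describes which solutions were present around the cell in which time
#' windows. Segments are rows of a data frame with columns `t_start`,
#' `t_end` (s), `glutamate`, `glycine`, `mk801`, `steroid_conc` (uM) and
#' `steroid_id` (label, `NA` when none). A multibarrel fast perfusion
#' system does not exchange solutions instantaneously; `exchange_tau`
#' carries its exponential time constant (default 10 ms).
#'
#' @param segments data frame of application segments. Missing
#'   concentration columns default to 0; missing `steroid_id` to `NA`.
#' @param exchange_tau solution-exchange time constant, s.
#' @return An object of class `application_protocol`.
#' @examples
#' application_protocol(data.frame(
#'   t_start = c(0, 0.1), t_end = c(0.1, 5.1),
#'   glutamate = c(0, 1000), glycine = 30))
#' @export
application_protocol <- function(segments, exchange_tau = 0.010) {
  if (!is.data.frame(segments) || nrow(segments) == 0L)
    stop("segments must be a non-empty data frame", call. = FALSE)
  need <- c("t_start", "t_end")
  if (!all(need %in% names(segments)))
    stop("segments must have columns t_start and t_end", call. = FALSE)
  for (col in c("glutamate", "glycine", "mk801", "steroid_conc"))
    if (is.null(segments[[col]])) segments[[col]] <- 0
  if (is.null(segments$steroid_id)) segments$steroid_id <- NA_character_
  segments <- segments[order(segments$t_start),
                       c("t_start", "t_end", "glutamate", "glycine",
                         "mk801", "steroid_id", "steroid_conc")]
  if (any(segments$t_end <= segments$t_start))
    stop("every segment needs t_end > t_start", call. = FALSE)
  if (nrow(segments) > 1L &&
      any(segments$t_start[-1L] < segments$t_end[-nrow(segments)] - 1e-12))
    stop("segments must not overlap", call. = FALSE)
  conc <- as.matrix(segments[, c("glutamate", "glycine", "mk801", "steroid_conc")])
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  if (!is.numeric(exchange_tau) || length(exchange_tau) != 1L ||
      !is.finite(exchange_tau) || exchange_tau < 0)
    stop("exchange_tau must be a single finite number >= 0", call. = FALSE)
  rownames(segments) <- NULL
  structure(list(segments = segments, exchange_tau = exchange_tau),
            class = "application_protocol")
}

#' @export
print.application_protocol <- function(x, ...) {
  cat(sprintf("Application protocol: %d segment(s), exchange tau = %g s\n",
              nrow(x$segments), x$exchange_tau))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Convenience protocol: glutamate step with optional MK-801 co-application
#'
#' A baseline segment followed by a step of glutamate (in the continuous
#' presence of glycine), optionally with MK-801 co-applied from glutamate
#' onset — the default geometry of the open-probability recordings.
#'
#' @param t_pre baseline duration before agonist onset, s.
#' @param t_app agonist application duration, s.
#' @param glutamate,glycine,mk801 concentrations during the step, uM.
#' @param exchange_tau solution-exchange time constant, s.
#' @return An [application_protocol()].
#' @export
glu_step_protocol <- function(t_pre = 0.1, t_app = 5, glutamate = 1000,
                              glycine = 30, mk801 = 0, exchange_tau = 0.010) {
  application_protocol(data.frame(
    t_start = c(0, t_pre), t_end = c(t_pre, t_pre + t_app),
    glutamate = c(0, glutamate), glycine = glycine,
    mk801 = c(0, mk801)), exchange_tau = exchange_tau)
}

protocol_t_range <- function(protocol) {
  c(min(protocol$segments$t_start), max(protocol$segments$t_end))
}

# index of the segment covering time t (last segment wins at boundaries)
protocol_segment_at <- function(protocol, t) {
  s <- protocol$segments
  i <- findInterval(t, s$t_start)
  i[i < 1L] <- 1L
  i
}

# first time at which glutamate is present; NA when never
glutamate_onset <- function(protocol) {
  s <- protocol$segments
  i <- which(s$glutamate > 0)
  if (length(i) == 0L) NA_real_ else s$t_start[min(i)]
}

#' Write / read an application protocol (YAML, bit-exact round trip)
#'
#' Numeric fields are serialized as full-precision decimal strings
#' (`%.17g`) so that write followed by read reproduces the protocol
#' bit-exactly.
#'
#' @param protocol an [application_protocol()].
#' @param path file path.
#' @return `write_protocol` returns `path` invisibly; `read_protocol`
#'   returns the protocol.
#' @export
write_protocol <- function(protocol, path) {
  s <- protocol$segments
  num <- function(v) sprintf("%.17g", v)
  segs <- lapply(seq_len(nrow(s)), function(i) list(
    t_start = num(s$t_start[i]), t_end = num(s$t_end[i]),
    glutamate = num(s$glutamate[i]), glycine = num(s$glycine[i]),
    mk801 = num(s$mk801[i]),
    steroid_id = if (is.na(s$steroid_id[i])) NULL else s$steroid_id[i],
    steroid_conc = num(s$steroid_conc[i])))
  yaml::write_yaml(list(exchange_tau = num(protocol$exchange_tau),
                        segments = segs), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  segs <- do.call(rbind, lapply(y$segments, function(g) data.frame(
    t_start = as.numeric(g$t_start), t_end = as.numeric(g$t_end),
    glutamate = as.numeric(g$glutamate), glycine = as.numeric(g$glycine),
    mk801 = as.numeric(g$mk801),
    steroid_id = if (is.null(g$steroid_id)) NA_character_ else g$steroid_id,
    steroid_conc = as.numeric(g$steroid_conc))))
  application_protocol(segs, exchange_tau = as.numeric(y$exchange_tau))
}
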