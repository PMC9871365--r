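#' Trial protocol definition
#'
#' A trial is a fixed sequence of contiguous epochs on a common clock that
#' starts at 0 s. The default protocol is a 195-s trial: a 40-s pre-immersion
#' baseline, a 25-s preparation period during which the feet are positioned
#' over the water, a 90-s immersion, and a 40-s recovery after the feet are
#' withdrawn.
#'
#' Epoch intervals are half-open `[start, end)` so that epochs tile the trial
#' without overlap. The analysis grid is one point per second, at integer
#' times `0, 1, ..., total_duration - 1`.
#'
#' @param durations named numeric vector of epoch durations in seconds, in
#'   trial order.
#' @return an object of class `protocol_definition`: a list with `epochs`
#'   (named list of `c(start, end)` intervals) and `total_duration`.
#' @export
protocol_definition <- function(durations = c(baseline = 40, prep = 25,
                                              immersion = 90, recovery = 40)) {
  if (is.null(names(durations)) || any(!nzchar(names(durations))))
    stop("epoch durations must be named")
  if (any(durations <= 0)) stop("epoch durations must be positive")
  ends <- cumsum(as.numeric(durations))
  starts <- c(0, ends[-length(ends)])
  epochs <- Map(function(s, e) c(start = s, end = e), starts, ends)
  names(epochs) <- names(durations)
  structure(list(epochs = epochs, total_duration = ends[length(ends)]),
            class = "protocol_definition")
}

#' Default four-epoch 195-s trial protocol
#'
#' @return a `protocol_definition` with baseline `[0,40)`, prep `[40,65)`,
#'   immersion `[65,155)` and recovery `[155,195)`.
#' @export
make_default_protocol <- function() {
  protocol_definition()
}

#' @export
print.protocol_definition <- function(x, ...) {
  cat("Trial protocol,", x$total_duration, "s total\n")
  for (nm in names(x$epochs)) {
    iv <- x$epochs[[nm]]
    cat(sprintf("  %-10s [%g, %g)\n", nm, iv["start"], iv["end"]))
  }
  invisible(x)
}

#' Epoch interval lookup
#'
#' @param protocol a `protocol_definition`.
#' @param name epoch name.
#' @return numeric `c(start, end)` in seconds (half-open).
#' @export
epoch_interval <- function(protocol, name) {
  iv <- protocol$epochs[[name]]
  if (is.null(iv)) stop("unknown epoch: ", name)
  iv
}

#' Integer-second grid times covered by an epoch
#'
#' Grid times are `0:(total_duration - 1)`; an epoch `[a, b)` covers grid
#' times `a, ..., b - 1`.
#'
#' @inheritParams epoch_interval
#' @return integer vector of grid times (seconds).
#' @export
epoch_grid_times <- function(protocol, name) {
  iv <- epoch_interval(protocol, name)
  seq.int(ceiling(iv["start"]), ceiling(iv["end"]) - 1L)
}

#' Full analysis grid of a protocol (integer seconds)
#' @inheritParams epoch_interval
#' @return integer vector `0:(total_duration-1)`.
#' @export
time_grid <- function(protocol) {
  seq.int(0L, protocol$total_duration - 1L)
}

n_grid <- function(protocol) as.integer(protocol$total_duration)

#' Epoch membership of arbitrary times
#' @inheritParams epoch_interval
#' @param t numeric times in seconds.
#' @return character vector of epoch names (NA outside the trial).
#' @export
epoch_of <- function(protocol, t) {
  out <- rep(NA_character_, length(t))
  for (nm in names(protocol$epochs)) {
    iv <- protocol$epochs[[nm]]
    out[t >= iv["start"] & t < iv["end"]] <- nm
  }
  out
}
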