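#' Derive a child seed from a base seed
#'
#' Deterministic fan-out of one global seed into per-stage / per-point child
#' seeds, so individual stages of an experiment can be rerun independently.
#' Kept below 2^31 to stay a valid R integer.
#'
#' @param seed base integer seed
#' @param index stage or point index (>= 1)
#' @return integer child seed
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

# degrees <-> radians
.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi

#' Wrap angles in degrees to [0, 360)
#' @param a angle(s) in degrees
#' @return wrapped angle(s)
#' @export
wrap_angle <- function(a) ((a %% 360) + 360) %% 360

#' Unwrap a circular angle series
#'
#' Maps a sequence of angles on the circle to a real-valued series by
#' choosing a single cut point c and representing every angle inside
#' \[c, c + 360): a monotone circular mapping (which shows one sharp
#' 360-degree jump when plotted on \[0, 360)) becomes a monotone real
#' sequence. The cut is chosen to minimize the total variation of the
#' resulting series, which makes the choice robust to response noise —
#' unlike cumulative difference unwrapping, it cannot accumulate spurious
#' full turns.
#'
#' @param a angles in degrees
#' @return real-valued angle series suitable for rank correlation
#' @export
unwrap_angles <- function(a) {
  if (length(a) <= 2) return(a)
  cuts <- sort(unique(wrap_angle(a)))
  cuts <- (cuts + c(diff(cuts), 360 - cuts[length(cuts)] + cuts[1]) / 2)
  best <- a
  best_tv <- Inf
  for (cc in cuts) {
    s <- wrap_angle(a - cc) + cc
    tv <- sum(abs(diff(s)))
    if (tv < best_tv) { best_tv <- tv; best <- s }
  }
  best
}
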