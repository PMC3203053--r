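#' Define a gate as the shortest distance between two atom groups
#'
#' A gate follows the shortest heavy-atom distance between two charged or
#' polar groups (e.g. the carboxylate oxygens of a glutamate vs the
#' guanidinium nitrogens of an arginine).  The formed/broken cutoffs feed
#' the hysteresis state machine of \code{\link{detect_state_change}}.
#'
#' @param name gate name.
#' @param groupA,groupB selection strings or lists.
#' @param formed_cutoff distance (Angstrom) below which the gate counts as
#'   formed; default 4.
#' @param broken_cutoff distance above which it counts as broken; default 6.
#'   Must exceed \code{formed_cutoff}.
#' @export
gate_definition <- function(name, groupA, groupB,
                            formed_cutoff = 4.0, broken_cutoff = 6.0) {
  if (!(broken_cutoff > formed_cutoff && formed_cutoff > 0))
    stop("need broken_cutoff > formed_cutoff > 0")
  structure(list(name = name, groupA = groupA, groupB = groupB,
                 formed_cutoff = formed_cutoff,
                 broken_cutoff = broken_cutoff),
            class = "gate_definition")
}

#' Minimum cross-pair Euclidean distance between two point sets
#'
#' @param coordsA,coordsB non-empty \code{n x 3} matrices.
#' @return minimum distance in Angstrom.
#' @export
min_pairwise_distance <- function(coordsA, coordsB) {
  A <- rbind(as.matrix(coordsA)); B <- rbind(as.matrix(coordsB))
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("empty input: both point sets must be non-empty")
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(max(min(d2), 0))
}

#' Per-frame gate distance trace
#'
#' @param traj a \code{trajectory}.
#' @param gate a \code{\link{gate_definition}}.
#' @return a \code{metric_series} (Angstrom) named after the gate.
#' @export
gate_distance_series <- function(traj, gate) {
  top <- traj$topology
  ia <- resolve_selection(top, gate$groupA)
  ib <- resolve_selection(top, gate$groupB)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    fr <- frame_coords(traj, k)
    min_pairwise_distance(fr[ia, , drop = FALSE], fr[ib, , drop = FALSE])
  }, numeric(1))
  metric_series(gate$name, "Angstrom", traj$times, vals)
}

#' Detect gate break/reform events with hysteresis
#'
#' The gate state becomes \code{break} when the distance exceeds
#' \code{broken_cutoff} for at least \code{min_dwell} consecutive frames and
#' \code{reform} when it drops below \code{formed_cutoff} for at least
#' \code{min_dwell} frames.  Events are reported at the first frame of each
#' qualifying run (1-based), and alternate strictly.
#'
#' @param series a \code{metric_series} of gate distances.
#' @param gate the \code{\link{gate_definition}} providing the cutoffs.
#' @param min_dwell minimum run length in frames (>= 1); default 5.
#' @return data.frame with columns \code{event} ("break"/"reform") and
#'   \code{frame}; zero rows when nothing happens.
#' @export
detect_state_change <- function(series, gate, min_dwell = 5L) {
  stopifnot(min_dwell >= 1L)
  v <- series$values
  n <- length(v)
  events <- list()
  state <- "formed"   # gates start formed; first reportable event is a break
  run_start <- NA_integer_; run_len <- 0L
  target <- "broken"
  for (k in seq_len(n)) {
    qual <- if (target == "broken") v[k] > gate$broken_cutoff
            else v[k] < gate$formed_cutoff
    if (isTRUE(qual)) {
      if (run_len == 0L) run_start <- k
      run_len <- run_len + 1L
      if (run_len >= min_dwell) {
        events[[length(events) + 1L]] <- list(
          event = if (target == "broken") "break" else "reform",
          frame = run_start)
        state <- target
        target <- if (target == "broken") "formed" else "broken"
        # frames of the completed run may already qualify for the next
        # transition only after leaving this run; reset and continue
        run_len <- 0L; run_start <- NA_integer_
      }
    } else {
      run_len <- 0L; run_start <- NA_integer_
    }
  }
  if (length(events) == 0L)
    return(data.frame(event = character(), frame = integer()))
  data.frame(event = vapply(events, `[[`, "", "event"),
             frame = vapply(events, `[[`, 0L, "frame"))
}
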