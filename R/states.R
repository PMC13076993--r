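#' Classify frames into bound states I and II
#'
#' Dual-threshold classification of the inter-domain-angle series with
#' hysteresis: a frame above `midpoint + hysteresis` is state II, below
#' `midpoint - hysteresis` state I, and frames inside the dead band inherit
#' the previous frame's label (leading dead-band frames stay unassigned).
#' The hysteresis band suppresses spurious state flips from frame noise
#' while leaving genuine transitions sharp.
#'
#' @param angle numeric vector of per-frame angles, degrees.
#' @param low_center,high_center nominal state centres in degrees (defaults
#'   87 and 157, the compact and extended states of the PD-1/PD-L1
#'   complex; use 135 for the extended state of PD-1/PD-L2).
#' @param hysteresis half-width of the dead band around the midpoint,
#'   degrees.
#' @param valid optional logical vector marking frames to classify;
#'   dissociated (post-rupture) frames should be `FALSE` and come out as
#'   `"unassigned"`.
#' @return data.frame of class `state_series` with columns `frame`,
#'   `label` (`"I"`, `"II"`, `"unassigned"`); attribute `thresholds_used`
#'   records the two switching thresholds in degrees.
#' @export
classify_frames <- function(angle, low_center = 87, high_center = 157,
                            hysteresis = 10, valid = NULL) {
  if (length(angle) == 0L) stop("empty angle series")
  if (low_center >= high_center) stop("low_center must be below high_center")
  mid <- (low_center + high_center) / 2
  up <- mid + hysteresis
  dn <- mid - hysteresis
  if (is.null(valid)) valid <- rep(TRUE, length(angle))
  labels <- rep("unassigned", length(angle))
  prev <- "unassigned"
  for (i in seq_along(angle)) {
    if (!valid[i] || is.na(angle[i])) {
      labels[i] <- "unassigned"
      # a masked frame breaks inheritance: the bond state after rupture is
      # undefined, so classification restarts
      prev <- "unassigned"
      next
    }
    lab <- if (angle[i] > up) "II" else if (angle[i] < dn) "I" else prev
    labels[i] <- lab
    prev <- lab
  }
  if (all(labels == "unassigned")) {
    warning("all frames inside the dead band; no state assigned")
  }
  out <- data.frame(frame = seq_along(angle), label = labels,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds_used") <- c(lower = dn, upper = up)
  class(out) <- c("state_series", "data.frame")
  out
}

#' Cross-trajectory per-state statistics
#'
#' For each trajectory, the mean inter-domain angle and mean CT-CT distance
#' are computed separately over state-I and state-II frames; a state is
#' reported for a trajectory only when it holds at least `min_frames`
#' frames (guarding against single-frame "states").  Across trajectories
#' the per-trajectory means are summarised as mean and SD with n equal to
#' the number of contributing trajectories, matching the convention of
#' reporting per-trajectory averages as points with mean +/- SD.
#'
#' @param series_list list of observable series ([extract_observables()] or
#'   [generate_state_trajectory()] output).
#' @param state_list list of matching state series ([classify_frames()]).
#' @param min_frames minimum frames per state per trajectory (default 10).
#' @return list with `per_trajectory` (data.frame: trajectory, state,
#'   n_frames, mean_angle_deg, mean_ctct_A) and `summary` (data.frame:
#'   state, mean_angle_deg, sd_angle_deg, mean_ctct_A, sd_ctct_A, n);
#'   states observed in no trajectory are absent from both tables.
#' @export
state_statistics <- function(series_list, state_list, min_frames = 10L) {
  if (length(series_list) != length(state_list)) {
    stop("series_list and state_list lengths differ")
  }
  if (length(series_list) == 0L) stop("need at least one trajectory")
  per <- NULL
  for (k in seq_along(series_list)) {
    obs <- series_list[[k]]; st <- state_list[[k]]
    if (nrow(obs) != nrow(st)) {
      stop("trajectory ", k, ": observable and state series lengths differ")
    }
    for (state in c("I", "II")) {
      idx <- which(st$label == state)
      if (length(idx) >= min_frames) {
        per <- rbind(per, data.frame(
          trajectory = k, state = state, n_frames = length(idx),
          mean_angle_deg = mean(obs$angle_deg[idx]),
          mean_ctct_A = if ("ctct_A" %in% names(obs))
            mean(obs$ctct_A[idx]) else NA_real_))
      }
    }
  }
  if (is.null(per)) stop("no state reaches min_frames in any trajectory")
  summ <- NULL
  for (state in c("I", "II")) {
    rows <- per[per$state == state, , drop = FALSE]
    if (nrow(rows) == 0L) next
    summ <- rbind(summ, data.frame(
      state = state,
      mean_angle_deg = mean(rows$mean_angle_deg),
      sd_angle_deg = if (nrow(rows) > 1L) sd(rows$mean_angle_deg) else NA_real_,
      mean_ctct_A = mean(rows$mean_ctct_A),
      sd_ctct_A = if (nrow(rows) > 1L) sd(rows$mean_ctct_A) else NA_real_,
      n = nrow(rows)))
  }
  list(per_trajectory = per, summary = summ)
}
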