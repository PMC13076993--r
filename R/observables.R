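#' Per-frame observables of a trajectory
#'
#' Applies the single-structure geometry operations to every frame:
#' inter-domain angle, CT-CT distance, optional per-pair salt-bridge
#' presence and optional buried contact area.  The result is the
#' `observable_series` consumed by the state-assignment layer.
#'
#' @param traj a `trajectory`.
#' @param def_a,def_b [vector_definition()]s for the two molecules.
#' @param criteria an [interaction_criteria()].
#' @param pairs optional salt-bridge pair table (see
#'   [detect_salt_bridges()]); each pair becomes a logical column
#'   `sb_<chain1><resno1>_<chain2><resno2>`.
#' @param ct_res_a,ct_res_b optional terminal residue numbers for the CT-CT
#'   distance (default: last residue with a CA in each chain).
#' @param contact_a,contact_b optional residue selections for a per-frame
#'   [buried_contact_area()] (`contact_area_A2` column; this is the slow
#'   observable, off by default).
#' @return data.frame with columns `frame`, `angle_deg`, `ctct_A`, any
#'   salt-bridge columns and optional `contact_area_A2`; attribute
#'   `frame_interval` carries the trajectory's frame spacing.
#' @export
extract_observables <- function(traj, def_a, def_b,
                                criteria = interaction_criteria(),
                                pairs = NULL,
                                ct_res_a = NULL, ct_res_b = NULL,
                                contact_a = NULL, contact_b = NULL) {
  nf <- n_frames(traj)
  out <- data.frame(frame = seq_len(nf),
                    angle_deg = NA_real_, ctct_A = NA_real_)
  sb_cols <- character(0)
  if (!is.null(pairs)) {
    sb_cols <- sprintf("sb_%s%d_%s%d", pairs$chain1, pairs$resno1,
                       pairs$chain2, pairs$resno2)
    for (cn in sb_cols) out[[cn]] <- NA
  }
  do_contact <- !is.null(contact_a) && !is.null(contact_b)
  if (do_contact) out$contact_area_A2 <- NA_real_
  for (i in seq_len(nf)) {
    frame <- get_frame(traj, i)
    res <- tryCatch({
      row <- list(angle = interdomain_angle(frame, def_a, def_b),
                  ctct = ctct_distance(frame, ct_res_a, ct_res_b))
      if (!is.null(pairs)) {
        sb <- detect_salt_bridges(frame, criteria, pairs)
        row$sb <- sb$bridged
      }
      if (do_contact) {
        row$area <- buried_contact_area(frame, contact_a, contact_b, criteria)
      }
      row
    }, error = function(e) {
      stop("frame ", i, ": ", conditionMessage(e), call. = FALSE)
    })
    out$angle_deg[i] <- res$angle
    out$ctct_A[i] <- res$ctct
    if (!is.null(pairs)) out[i, sb_cols] <- res$sb
    if (do_contact) out$contact_area_A2[i] <- res$area
  }
  attr(out, "frame_interval") <- traj$frame_interval
  class(out) <- c("observable_series", "data.frame")
  out
}

#' Salt-bridge formation probability across trajectories
#'
#' Per-trajectory fraction of frames in which a given bridge is present,
#' plus the cross-trajectory mean and SD (n = number of trajectories, the
#' convention used for per-trajectory state statistics).
#'
#' @param series_list list of observable series (from
#'   [extract_observables()]), each containing the pair's salt-bridge
#'   column.
#' @param pair the salt-bridge column name (e.g. `"sb_A136_B113"`), or a
#'   one-row pair table as in [detect_salt_bridges()].
#' @return list with `per_trajectory` (numeric vector of per-trajectory
#'   probabilities), `mean`, `sd`, `n`.
#' @export
salt_bridge_probability <- function(series_list, pair) {
  if (is.data.frame(pair)) {
    pair <- sprintf("sb_%s%d_%s%d", pair$chain1[1L], pair$resno1[1L],
                    pair$chain2[1L], pair$resno2[1L])
  }
  if (length(series_list) == 0L) stop("need at least one trajectory")
  p <- vapply(series_list, function(s) {
    if (!pair %in% names(s)) stop("pair column not tracked: ", pair)
    mean(s[[pair]], na.rm = TRUE)
  }, 0)
  list(per_trajectory = unname(p), mean = mean(p),
       sd = if (length(p) > 1L) sd(p) else NA_real_, n = length(p))
}

#' Write / read an observable series as CSV
#'
#' @param series an observable series data.frame.
#' @param file path.
#' @return `file` (write) or the series (read).
#' @export
write_observables <- function(series, file) {
  write.csv(as.data.frame(series), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_observables
#' @export
read_observables <- function(file) {
  out <- read.csv(file, stringsAsFactors = FALSE)
  class(out) <- c("observable_series", "data.frame")
  out
}
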