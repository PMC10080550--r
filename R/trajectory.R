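# Per-cross-peak titration trajectories and direction-change detection.
#
# In the fast-exchange regime a single binding mode moves a cross-peak along
# a straight line toward the bound-state position as the site saturates. A
# change of direction along the titration indicates a second binding mode
# with a different effect on the chemical shifts. The detector formalizes
# the visual criterion as a turning-angle threshold between successive
# displacement vectors, computed in the same alpha-weighted plane the CSP
# metric uses.

#' Extract a cross-peak trajectory from a titration series
#'
#' Collects the (ratio, F1, F2) coordinates of one assignment across the
#' series, skipping titration points where the cross-peak is absent (their
#' ratios are reported as gaps). For HSQC series the carbon (F1) axis is
#' weighted by `sqrt(alpha)` before any geometry, so distances and angles
#' live in the same metric as the heteronuclear CSP.
#'
#' @param series A [titration_series()].
#' @param residue_index Peptide-local residue index of the assignment.
#' @param atom_f1,atom_f2 Atom names of the assignment.
#' @param alpha Carbon scaling coefficient used for the axis weight
#'   (HSQC only), default 0.3.
#' @return Object of class `trajectory`: list with `assignment`, `points`
#'   (data.frame ratio/f1_ppm/f2_ppm), `gap_ratios`, `axis_weights`.
#' @export
extract_trajectory <- function(series, residue_index, atom_f1, atom_f2,
                               alpha = 0.3) {
  stopifnot(inherits(series, "titration_series"))
  rows <- lapply(series$points, function(pl) {
    p <- pl$peaks
    i <- which(p$residue_index == residue_index &
                 p$atom_f1 == atom_f1 & p$atom_f2 == atom_f2)
    if (length(i) == 0L) return(NULL)
    data.frame(ratio = pl$ratio, f1_ppm = p$f1_ppm[i], f2_ppm = p$f2_ppm[i],
               present = p$present[i])
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    stop(sprintf("assignment %d:%s/%s not found in series",
                 residue_index, atom_f1, atom_f2))
  }
  pts <- rows[rows$present, c("ratio", "f1_ppm", "f2_ppm"), drop = FALSE]
  if (nrow(pts) < 3L) {
    stop(sprintf(
      "insufficient points for %d:%s/%s: %d present (need >= 3)",
      residue_index, atom_f1, atom_f2, nrow(pts)))
  }
  w1 <- if (series$spectrum_type == "HSQC_CH") sqrt(alpha) else 1
  rownames(pts) <- NULL
  structure(
    list(
      assignment = list(residue_index = residue_index,
                        atom_f1 = atom_f1, atom_f2 = atom_f2),
      spectrum_type = series$spectrum_type,
      points = pts,
      gap_ratios = rows$ratio[!rows$present],
      axis_weights = c(f1 = w1, f2 = 1)
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d:%s/%s (%s), %d points%s\n",
    x$assignment$residue_index, x$assignment$atom_f1, x$assignment$atom_f2,
    x$spectrum_type, nrow(x$points),
    if (length(x$gap_ratios) > 0)
      paste0(", gaps at ", paste(x$gap_ratios, collapse = ", ")) else ""
  ))
  invisible(x)
}

#' Detect a direction change along a titration trajectory
#'
#' Successive displacement vectors (in the axis-weighted plane) are
#' compared; steps shorter than `min_step_ppm` are merged with the
#' following step so that digitisation noise cannot fake a turn. The
#' trajectory has a break if any turning angle between successive merged
#' steps reaches `turn_threshold_deg`. The reported `break_ratio` is the
#' ratio of the vertex point of the first qualifying turn, i.e. the last
#' titration point before the new direction is taken.
#'
#' @param trajectory A [extract_trajectory()] result.
#' @param turn_threshold_deg Turning angle (degrees) that declares a break;
#'   default 30.
#' @param min_step_ppm Minimum step length (ppm, in the weighted plane)
#'   below which steps are merged; default 0.005.
#' @return List of class `breakpoint_result`: `has_break`, `break_ratio`
#'   (NA when none), `max_turn_deg`, `turns` (data.frame vertex_ratio /
#'   angle_deg), `zero_motion`.
#' @export
detect_direction_change <- function(trajectory, turn_threshold_deg = 30,
                                    min_step_ppm = 0.005) {
  stopifnot(inherits(trajectory, "trajectory"),
            turn_threshold_deg > 0, min_step_ppm > 0)
  pts <- trajectory$points
  w <- trajectory$axis_weights
  xy <- cbind(pts$f1_ppm * w[["f1"]], pts$f2_ppm * w[["f2"]])
  n <- nrow(xy)
  # merge sub-threshold steps forward into the following step
  steps <- list()
  acc <- c(0, 0)
  for (i in seq_len(n - 1L)) {
    acc <- acc + (xy[i + 1L, ] - xy[i, ])
    if (sqrt(sum(acc^2)) >= min_step_ppm) {
      steps[[length(steps) + 1L]] <- list(v = acc, end = i + 1L)
      acc <- c(0, 0)
    }
  }
  if (sqrt(sum(acc^2)) > 0 && length(steps) > 0L) {
    # trailing sub-threshold motion folds into the last step
    last <- steps[[length(steps)]]
    steps[[length(steps)]] <- list(v = last$v + acc, end = n)
  }
  empty <- list(has_break = FALSE, break_ratio = NA_real_,
                max_turn_deg = 0,
                turns = data.frame(vertex_ratio = numeric(0),
                                   angle_deg = numeric(0)),
                zero_motion = length(steps) == 0L)
  if (length(steps) < 2L) {
    return(structure(empty, class = "breakpoint_result"))
  }
  angles <- numeric(length(steps) - 1L)
  vertex <- numeric(length(steps) - 1L)
  for (k in seq_len(length(steps) - 1L)) {
    a <- steps[[k]]$v
    b <- steps[[k + 1L]]$v
    cosang <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
    angles[k] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    vertex[k] <- pts$ratio[steps[[k]]$end]
  }
  hit <- which(angles >= turn_threshold_deg)
  structure(
    list(
      has_break = length(hit) > 0L,
      break_ratio = if (length(hit) > 0L) vertex[hit[1]] else NA_real_,
      max_turn_deg = max(angles),
      turns = data.frame(vertex_ratio = vertex, angle_deg = angles),
      zero_motion = FALSE
    ),
    class = "breakpoint_result"
  )
}

#' @export
print.breakpoint_result <- function(x, ...) {
  if (x$zero_motion) {
    cat("<breakpoint_result> no measurable motion\n")
  } else if (x$has_break) {
    cat(sprintf(
      "<breakpoint_result> direction change after ratio %.3g (max turn %.1f deg)\n",
      x$break_ratio, x$max_turn_deg))
  } else {
    cat(sprintf("<breakpoint_result> straight path (max turn %.1f deg)\n",
                x$max_turn_deg))
  }
  invisible(x)
}
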