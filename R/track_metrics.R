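#' @importFrom rlang .data
NULL

validate_track <- function(track) {
  if (nrow(track) < 2L) stop("track must have at least 2 points")
  dt <- diff(track$t_s)
  if (any(dt <= 0)) stop("track times must be strictly increasing")
  invisible(track)
}

#' Net track displacement
#'
#' Euclidean distance between the first and last positions of a track: the
#' measure of directed, processive movement (as opposed to random walks).
#'
#' @param track A tibble of ordered track points with columns `t_s`, `x_um`,
#'   `y_um`.
#' @return Displacement in um.
#' @examples
#' tr <- tibble::tibble(t_s = 0:2, x_um = c(0, 3, 3), y_um = c(0, 0, 4))
#' track_displacement(tr) # 5
#' @export
track_displacement <- function(track) {
  validate_track(track)
  n <- nrow(track)
  sqrt((track$x_um[n] - track$x_um[1])^2 + (track$y_um[n] - track$y_um[1])^2)
}

path_length <- function(track) {
  sum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2))
}

#' Mean track speed
#'
#' Total path length divided by total elapsed time.
#'
#' @inheritParams track_displacement
#' @return Speed in um/s.
#' @export
mean_speed <- function(track) {
  validate_track(track)
  elapsed <- track$t_s[nrow(track)] - track$t_s[1]
  if (elapsed <= 0) stop("track has zero elapsed time")
  path_length(track) / elapsed
}

#' Per-track and per-batch master parameters
#'
#' Computes the nine per-track master parameters (net displacement, total
#' path length, duration, mean/max/min speed, speed SD, straightness, mean
#' diameter) and, per batch (movie surrogate), the two post-processing
#' parameters (anterograde/retrograde track ratio and percentage of moving
#' tracks). Instantaneous speeds are step distance over step time; mean
#' speed is path length over elapsed time; straightness is net displacement
#' over path length (1 for collinear monotone tracks).
#'
#' @param ts A non-empty `trackset`.
#' @param moving_threshold_um Net-displacement cut for "moving" tracks (um).
#' @return An object of class `master_parameter_table`: list with tibbles
#'   `per_track` (one row per track) and `per_batch` (one row per batch),
#'   plus the track set `metadata`.
#' @export
compute_master_parameters <- function(ts, moving_threshold_um = 1.2) {
  stopifnot(inherits(ts, "trackset"))
  if (nrow(ts$tracks) == 0L) stop("cannot compute parameters of an empty trackset")
  tr <- ts$tracks
  if (!"batch" %in% names(tr)) tr$batch <- 1L
  if (!"diameter_um" %in% names(tr)) tr$diameter_um <- NA_real_

  tr <- dplyr::arrange(tr, .data$track_id, .data$t_s)
  same <- c(FALSE, tr$track_id[-1] == tr$track_id[-nrow(tr)])
  dt <- c(NA_real_, diff(tr$t_s))
  if (any(same & dt <= 0)) {
    stop("track times must be strictly increasing (duplicate or ",
         "non-monotone timestamps)")
  }
  step <- c(NA_real_, sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2))
  tr$step_um <- ifelse(same, step, NA_real_)
  tr$inst_speed <- ifelse(same, step / dt, NA_real_)

  per_track <- tr |>
    dplyr::group_by(.data$track_id, .data$batch) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      net_displacement_um = sqrt((dplyr::last(.data$x_um) -
                                  dplyr::first(.data$x_um))^2 +
                                 (dplyr::last(.data$y_um) -
                                  dplyr::first(.data$y_um))^2),
      path_length_um = sum(.data$step_um, na.rm = TRUE),
      duration_s = dplyr::last(.data$t_s) - dplyr::first(.data$t_s),
      max_speed_um_s = max(.data$inst_speed, na.rm = TRUE),
      min_speed_um_s = min(.data$inst_speed, na.rm = TRUE),
      speed_sd_um_s = ifelse(dplyr::n() > 2L,
                             stats::sd(.data$inst_speed, na.rm = TRUE), 0),
      diameter_um = mean(.data$diameter_um),
      net_dx_um = dplyr::last(.data$x_um) - dplyr::first(.data$x_um),
      .groups = "drop")
  if (any(per_track$n_points < 2L)) {
    stop("every track must have at least 2 points")
  }
  per_track <- per_track |>
    dplyr::mutate(
      mean_speed_um_s = .data$path_length_um / .data$duration_s,
      straightness = ifelse(.data$path_length_um > 0,
                            .data$net_displacement_um / .data$path_length_um,
                            1)) |>
    dplyr::select("track_id", "batch",
                  dplyr::all_of(per_track_parameters()), "net_dx_um")

  per_batch <- per_track |>
    dplyr::group_by(.data$batch) |>
    dplyr::summarise(
      antero_retro_ratio = directional_ratio(.data$net_dx_um),
      percent_moving = 100 *
        mean(.data$net_displacement_um >= moving_threshold_um),
      n_tracks = dplyr::n()) |>
    dplyr::ungroup()

  structure(list(per_track = dplyr::select(per_track, -"net_dx_um"),
                 per_batch = per_batch,
                 metadata = ts$metadata),
            class = "master_parameter_table")
}

#' The nine per-track master parameter names
#' @return Character vector in canonical order.
#' @export
per_track_parameters <- function() {
  c("net_displacement_um", "path_length_um", "duration_s", "mean_speed_um_s",
    "max_speed_um_s", "min_speed_um_s", "speed_sd_um_s", "straightness",
    "diameter_um")
}

#' The two per-batch post-processing parameter names
#' @return Character vector.
#' @export
per_batch_parameters <- function() {
  c("antero_retro_ratio", "percent_moving")
}

directional_ratio <- function(net_dx) {
  antero <- sum(net_dx > 0)
  retro <- sum(net_dx < 0)
  if (retro == 0L) return(NA_real_)  # undefined sentinel, not an error
  antero / retro
}

#' Percentage of moving tracks
#'
#' Fraction (as a percentage) of tracks whose net displacement is at least
#' `threshold_um` (inclusive at the threshold); the conventional cut between
#' moving and stationary organelles is 1.2 um.
#'
#' @param ts A non-empty `trackset`.
#' @param threshold_um Displacement threshold in um.
#' @return Percentage in `[0, 100]`.
#' @export
percent_moving <- function(ts, threshold_um = 1.2) {
  stopifnot(inherits(ts, "trackset"))
  if (nrow(ts$tracks) == 0L) stop("empty trackset")
  disp <- track_summaries(ts)$net_displacement_um
  100 * mean(disp >= threshold_um)
}

#' Anterograde/retrograde track ratio
#'
#' Ratio of tracks with positive net displacement along the channel axis
#' (anterograde, soma-to-distal) to tracks with negative net displacement
#' (retrograde). Tracks with exactly zero net axial displacement are
#' excluded. When no retrograde track exists the ratio is undefined and
#' `NA` is returned (a sentinel, not an error).
#'
#' @param ts A non-empty `trackset`.
#' @return Dimensionless ratio, or `NA` when undefined.
#' @export
antero_retro_ratio <- function(ts) {
  stopifnot(inherits(ts, "trackset"))
  if (nrow(ts$tracks) == 0L) stop("empty trackset")
  directional_ratio(track_summaries(ts)$net_dx_um)
}

track_summaries <- function(ts) {
  ts$tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      net_displacement_um = sqrt((dplyr::last(.data$x_um) -
                                  dplyr::first(.data$x_um))^2 +
                                 (dplyr::last(.data$y_um) -
                                  dplyr::first(.data$y_um))^2),
      net_dx_um = dplyr::last(.data$x_um) - dplyr::first(.data$x_um)) |>
    dplyr::ungroup()
}

#' @export
print.master_parameter_table <- function(x, ...) {
  cat("<master_parameter_table> ", nrow(x$per_track), " track(s), ",
      nrow(x$per_batch), " batch(es)\n", sep = "")
  invisible(x)
}
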