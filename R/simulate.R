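#' Construct a track set
#'
#' A track set holds the trajectories of many organelles imaged (or
#' simulated) under one experimental condition, plus the condition metadata.
#'
#' @param tracks A tibble with columns `track_id`, `frame` (0-based),
#'   `t_s`, `x_um`, `y_um`, `intensity`, and optionally `diameter_um`,
#'   `batch`, `state`.
#' @param metadata Named list: `genotype`, `day`, `compartment`, `organelle`,
#'   `batch`, `seed`, and anything else worth carrying.
#' @return An object of class `trackset`.
#' @export
trackset <- function(tracks, metadata = list()) {
  stopifnot(is.data.frame(tracks))
  needed <- c("track_id", "frame", "t_s", "x_um", "y_um")
  missing <- setdiff(needed, names(tracks))
  if (length(missing)) {
    stop("tracks is missing columns: ", paste(missing, collapse = ", "))
  }
  structure(list(tracks = tibble::as_tibble(tracks), metadata = metadata),
            class = "trackset")
}

#' @export
print.trackset <- function(x, ...) {
  n <- n_tracks(x)
  md <- x$metadata
  cat("<trackset> ", n, " track(s), ", nrow(x$tracks), " points",
      if (!is.null(md$organelle)) paste0("; organelle=", md$organelle),
      if (!is.null(md$compartment)) paste0(", compartment=", md$compartment),
      if (!is.null(md$day)) paste0(", day=", md$day),
      if (!is.null(md$genotype)) paste0(", genotype=", md$genotype),
      "\n", sep = "")
  invisible(x)
}

#' Number of tracks in a track set
#' @param x A `trackset`.
#' @return Integer count.
#' @export
n_tracks <- function(x) {
  stopifnot(inherits(x, "trackset"))
  length(unique(x$tracks$track_id))
}

resolve_state <- function(state, organelle) {
  if (inherits(state, "motility_state")) return(state)
  if (is.character(state) && length(state) == 1L) {
    return(motility_preset(state, organelle))
  }
  stop("state must be a motility_state, a preset name, or a motility_schedule")
}

#' Simulate organelle trajectories under a two-state run-and-pause model
#'
#' Each track performs a persistent run-and-pause walk along the channel
#' axis (x): at every time step the organelle either pauses (probability
#' `pause_fraction`) or runs at a speed drawn from the state's truncated
#' normal speed law, in a direction that reverses with probability
#' `reversal_prob_per_step`; small isotropic jitter is added to both axes.
#' Track start positions are uniform in the viewing field and start
#' directions are balanced. To emulate detection-limited track lifetimes,
#' each track is observed over a contiguous window covering 50-100% of the
#' movie, placed uniformly at random.
#'
#' When `state_or_schedule` is a `motility_schedule`, each track's state is
#' an independent Bernoulli draw: mobile with probability
#' `mobile_fraction_at(schedule, compartment, day)`, immobile otherwise.
#'
#' @param state_or_schedule A `motility_state`, a preset name (`"mobile"` /
#'   `"immobile"`), or a `motility_schedule`.
#' @param organelle `"mito"` or `"lyso"`; selects the preset pair when a
#'   name or schedule is given.
#' @param compartment `"distal"` or `"proximal"` (metadata; selects the
#'   schedule column when a schedule is given).
#' @param day Day in culture (used with a schedule).
#' @param n_tracks Number of tracks to simulate (may be 0).
#' @param seed Integer seed; identical arguments and seed give identical
#'   track sets.
#' @param duration_s Movie duration (s).
#' @param dt_s Time step = frame interval (s).
#' @param geometry An `acquisition_geometry` (start-position bounds).
#' @param batch Batch (movie surrogate) identifier, recycled over tracks;
#'   give a vector of length `n_tracks` to split one call into several
#'   batches.
#'
#' @return A `trackset`; `tracks$state` records each track's ground-truth
#'   state draw.
#' @examples
#' ts <- simulate_tracks("mobile", "mito", n_tracks = 5, seed = 1)
#' n_tracks(ts)
#' @export
simulate_tracks <- function(state_or_schedule,
                            organelle = c("mito", "lyso"),
                            compartment = c("distal", "proximal"),
                            day = NA_integer_,
                            n_tracks = 100L,
                            seed = 1L,
                            duration_s = 120,
                            dt_s = 0.3,
                            geometry = acquisition_geometry(),
                            batch = 1L) {
  organelle <- match.arg(organelle)
  compartment <- match.arg(compartment)
  if (n_tracks < 0) stop("n_tracks must be >= 0")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (dt_s <= 0) stop("dt_s must be > 0")

  is_schedule <- inherits(state_or_schedule, "motility_schedule")
  genotype <- if (is_schedule) state_or_schedule$genotype else NA_character_

  md <- list(genotype = genotype, day = day, compartment = compartment,
             organelle = organelle, seed = seed, duration_s = duration_s,
             dt_s = dt_s)

  empty <- tibble::tibble(track_id = integer(), frame = integer(),
                          t_s = numeric(), x_um = numeric(), y_um = numeric(),
                          intensity = numeric(), diameter_um = numeric(),
                          batch = integer(), state = character())
  if (n_tracks == 0L) return(trackset(empty, md))

  m <- max(2L, as.integer(round(duration_s / dt_s)))  # frames per movie
  n <- as.integer(n_tracks)
  batch <- rep_len(as.integer(batch), n)

  mobile <- motility_preset("mobile", organelle)
  immobile <- motility_preset("immobile", organelle)

  withr::with_seed(seed, {
    if (is_schedule) {
      p_mobile <- mobile_fraction_at(state_or_schedule, compartment, day)
      is_mobile <- stats::runif(n) < p_mobile
    } else {
      st <- resolve_state(state_or_schedule, organelle)
      is_mobile <- rep(st$name == "mobile", n)
      mobile <- immobile <- st
    }
    pick <- function(field) {
      ifelse(is_mobile, mobile[[field]], immobile[[field]])
    }
    vm <- pick("run_speed_mean"); vs <- pick("run_speed_sd")
    pf <- pick("pause_fraction"); rp <- pick("reversal_prob_per_step")
    js <- pick("jitter_sd")

    ns <- m - 1L  # steps
    rep_p <- function(v) rep(v, times = ns)
    paused <- matrix(stats::rbinom(n * ns, 1L, rep_p(pf)), nrow = n)
    flip <- matrix(stats::rbinom(n * ns, 1L, rep_p(rp)), nrow = n)
    speed <- matrix(pmax(0, stats::rnorm(n * ns, rep_p(vm), rep_p(vs))),
                    nrow = n)
    jx <- matrix(stats::rnorm(n * ns, 0, rep_p(js)), nrow = n)
    jy <- matrix(stats::rnorm(n * ns, 0, rep_p(js)), nrow = n)

    dir <- matrix(0L, n, ns)
    dir[, 1L] <- sample(c(-1L, 1L), n, replace = TRUE)
    sgn <- 1L - 2L * flip
    dir[, 1L] <- dir[, 1L] * sgn[, 1L]
    for (j in seq_len(ns)[-1L]) dir[, j] <- dir[, j - 1L] * sgn[, j]

    dx <- dir * speed * dt_s * (1 - paused) + jx
    x0 <- stats::runif(n, 0, geometry$field_length_um)
    y0 <- stats::runif(n, 0, geometry$field_height_um)
    x <- cbind(x0, x0 + t(apply(dx, 1L, cumsum)))
    y <- cbind(y0, y0 + t(apply(jy, 1L, cumsum)))

    # observation windows: 50-100% of the movie, uniform start
    len <- pmax(2L, as.integer(round(stats::runif(n, 0.5, 1) * m)))
    start <- floor(stats::runif(n, 0, m - len + 1))  # 0-based first frame

    base_int <- stats::runif(n, 0.8, 1.2)
    diam <- stats::rlnorm(n, pick("diameter_meanlog"), pick("diameter_sdlog"))

    row_idx <- rep.int(seq_len(n), len)
    fr <- sequence(len, from = as.integer(start))
    tracks <- tibble::tibble(
      track_id = row_idx,
      frame = as.integer(fr),
      t_s = fr * dt_s,
      x_um = x[cbind(row_idx, fr + 1L)],
      y_um = y[cbind(row_idx, fr + 1L)],
      intensity = base_int[row_idx] * stats::runif(length(fr), 0.9, 1.1),
      diameter_um = diam[row_idx],
      batch = batch[row_idx],
      state = ifelse(is_mobile[row_idx], "mobile", "immobile"))
    trackset(tracks, md)
  })
}
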