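#' Sampled time course of the in-silico ageing study
#'
#' Days in culture at which readouts are taken.
#' @export
STUDY_DAYS <- c(14L, 21L, 28L, 40L, 50L, 60L, 80L)

#' Supported genotype labels
#' @export
GENOTYPES <- c("Ctrl", "C9", "C9-GC", "C9-KO", "WT-KO",
               "FUS-like", "TDP43-like")

# Canonical onset table. Onsets are closed on the left: at the onset day the
# compartment is already in the declining regime. NA = no decline at that site.
schedule_table <- function() {
  tibble::tribble(
    ~genotype,     ~distal_onset_day, ~proximal_onset_day, ~f_onset, ~f_after,
    "Ctrl",        40L,               NA_integer_,         0.35,     0.10,
    "C9",          40L,               40L,                 0.35,     0.10,
    "C9-GC",       40L,               NA_integer_,         0.35,     0.10,
    "C9-KO",       21L,               21L,                 0.35,     0.10,
    "WT-KO",       21L,               50L,                 0.35,     0.10,
    "FUS-like",    14L,               NA_integer_,         0.35,     0.10,
    "TDP43-like",  14L,               NA_integer_,         0.65,     0.50
  )
}

#' Genotype-specific schedule of trafficking decline
#'
#' Encodes, for one genotype, the day at which each axonal compartment
#' (distal readout at the channel exits, proximal readout at the soma side)
#' switches from fully mobile trafficking into a progressive decline, and how
#' deep that decline runs. Before the onset day every track is drawn from the
#' mobile state; from the onset day onwards the mobile fraction ramps
#' linearly from `mobile_fraction_onset` down to `mobile_fraction_after` at
#' the final sampled day (D80), emulating phenotypes that deteriorate with
#' ageing rather than switching once.
#'
#' The canonical table: Ctrl declines distally from D40 with the proximal
#' site spared; C9 declines at both sites from D40; C9-GC (repeat-excised)
#' restores the proximal site, keeping only the distal D40 decline; C9-KO
#' (repeat kept, coding knockout) declines globally already at D21; WT-KO
#' declines distally at D21 with a delayed proximal decline from D50;
#' FUS-like shows an early (D14) purely distal decline and TDP43-like a
#' milder early distal decline.
#'
#' @param genotype One of `"Ctrl"`, `"C9"`, `"C9-GC"`, `"C9-KO"`, `"WT-KO"`,
#'   `"FUS-like"`, `"TDP43-like"`.
#' @return An object of class `motility_schedule` with fields `genotype`,
#'   `distal_onset_day`, `proximal_onset_day` (integer or `NA`),
#'   `mobile_fraction_before`, `mobile_fraction_onset`,
#'   `mobile_fraction_after`.
#' @examples
#' make_schedule("C9-KO")$distal_onset_day # 21
#' mobile_fraction_at(make_schedule("C9-GC"), "proximal", 80) # 1: spared
#' @export
make_schedule <- function(genotype) {
  tab <- schedule_table()
  row <- tab[tab$genotype == genotype, ]
  if (nrow(row) != 1L) {
    stop("unknown genotype label: '", genotype, "' (supported: ",
         paste(GENOTYPES, collapse = ", "), ")")
  }
  structure(
    list(genotype = genotype,
         distal_onset_day = row$distal_onset_day,
         proximal_onset_day = row$proximal_onset_day,
         mobile_fraction_before = 1.0,
         mobile_fraction_onset = row$f_onset,
         mobile_fraction_after = row$f_after),
    class = "motility_schedule")
}

#' Mobile fraction of a schedule at a given compartment and day
#'
#' @param schedule A `motility_schedule`.
#' @param compartment `"distal"` or `"proximal"`.
#' @param day Day in culture (integer).
#' @return Probability in `[0, 1]` that a track at this (compartment, day) is
#'   drawn from the mobile state.
#' @export
mobile_fraction_at <- function(schedule, compartment = c("distal", "proximal"),
                               day) {
  stopifnot(inherits(schedule, "motility_schedule"))
  compartment <- match.arg(compartment)
  onset <- if (compartment == "distal") schedule$distal_onset_day
           else schedule$proximal_onset_day
  if (is.na(onset) || day < onset) {
    return(schedule$mobile_fraction_before)
  }
  d_max <- max(STUDY_DAYS)
  if (onset >= d_max) {
    return(schedule$mobile_fraction_after)
  }
  frac <- (min(day, d_max) - onset) / (d_max - onset)
  schedule$mobile_fraction_onset +
    frac * (schedule$mobile_fraction_after - schedule$mobile_fraction_onset)
}

#' @export
print.motility_schedule <- function(x, ...) {
  fmt <- function(d) if (is.na(d)) "none" else paste0("D", d)
  cat("<motility_schedule> ", x$genotype, ": distal onset ",
      fmt(x$distal_onset_day), ", proximal onset ",
      fmt(x$proximal_onset_day), "; mobile fraction ",
      x$mobile_fraction_before, " -> ", x$mobile_fraction_onset,
      " (onset) -> ", x$mobile_fraction_after, " (D", max(STUDY_DAYS),
      ")\n", sep = "")
  invisible(x)
}
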