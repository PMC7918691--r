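#' Configuration of an in-silico trafficking study
#'
#' @param genotypes Genotype labels to simulate (subset of [GENOTYPES]).
#' @param days Sampled days (subset of [STUDY_DAYS]); must include 21, the
#'   baseline day.
#' @param n_tracks Tracks per (genotype, day, compartment, channel).
#' @param n_batches Batches (movie surrogates) the tracks are split into;
#'   the replicate unit for the two per-batch parameters.
#' @param seed Base seed; every condition derives its own sub-seed from it.
#' @param duration_s,dt_s Movie duration and frame interval (s).
#' @param geometry An `acquisition_geometry`.
#' @param preset_file Optional alternative motility preset YAML.
#' @param out_dir Optional output directory; when set, [run_study()] writes
#'   signatures (CSV/JSON), strength curves (CSV), dendrograms (Newick) and
#'   the onset report (JSON) there.
#' @return A `study_config` object.
#' @export
study_config <- function(genotypes = GENOTYPES,
                         days = STUDY_DAYS,
                         n_tracks = 300L,
                         n_batches = 10L,
                         seed = 1L,
                         duration_s = 120,
                         dt_s = 0.3,
                         geometry = acquisition_geometry(),
                         preset_file = NULL,
                         out_dir = NULL) {
  bad <- setdiff(genotypes, GENOTYPES)
  if (length(bad)) stop("unknown genotype(s): ", paste(bad, collapse = ", "))
  if (!21 %in% days) {
    stop("days must include 21 (the pooled-control baseline day)")
  }
  if (n_tracks < 1) stop("n_tracks must be >= 1")
  if (n_batches < 2) stop("n_batches must be >= 2 (per-batch Z-scores need spread)")
  structure(list(genotypes = genotypes, days = sort(unique(as.integer(days))),
                 n_tracks = as.integer(n_tracks),
                 n_batches = as.integer(n_batches), seed = as.integer(seed),
                 duration_s = duration_s, dt_s = dt_s, geometry = geometry,
                 preset_file = preset_file, out_dir = out_dir),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Recognized keys mirror the [study_config()] arguments (geometry given as
#' a mapping of [acquisition_geometry()] arguments).
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
study_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(study_config)), "geometry")
  bad <- setdiff(names(y), c(known, "geometry"))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- y[intersect(names(y), known)]
  if (!is.null(y$geometry)) {
    args$geometry <- do.call(acquisition_geometry, y$geometry)
  }
  do.call(study_config, args)
}

condition_seed <- function(base, index) {
  as.integer((as.double(base) * 1009 + 7919 * index) %% 2147483629 + 1)
}

#' Run the in-silico ageing study end-to-end
#'
#' For every (genotype, day, compartment, channel) the study simulates
#' tracks under the genotype's decline schedule, computes the master
#' parameter tables, assembles 44-parameter Z-score signatures against the
#' pooled-control D21 proximal baseline, derives phenotypic-strength time
#' courses, clusters signatures at each day (full/distal/proximal), and
#' detects onset days (first sampled day with any Z <= -5 at a site; the
#' onset rule is closed at -5, whereas [significant_parameters()] is
#' strict, matching the two conventions' wording).
#'
#' @param config A `study_config`.
#' @return An object of class `study_report`: list with `config`,
#'   `signatures` (list keyed `genotype_Dday`), `strengths` (tibble),
#'   `onsets` (tibble `genotype`, `site`, `onset_day`),
#'   `significant` (tibble of flagged parameters), `dendrograms`
#'   (per-day list of full/distal/proximal `hclust` objects).
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  channels <- c("mito", "lyso")
  sites <- c("distal", "proximal")
  batch_of <- rep(seq_len(config$n_batches), length.out = config$n_tracks)

  tables <- list()
  idx <- 0L
  for (gt in config$genotypes) {
    sched <- make_schedule(gt)
    for (day in config$days) {
      for (site in sites) {
        for (ch in channels) {
          idx <- idx + 1L
          ts <- simulate_tracks(sched, organelle = ch, compartment = site,
                                day = day, n_tracks = config$n_tracks,
                                seed = condition_seed(config$seed, idx),
                                duration_s = config$duration_s,
                                dt_s = config$dt_s,
                                geometry = config$geometry,
                                batch = batch_of)
          tables[[gt]][[as.character(day)]][[paste(ch, site, sep = "_")]] <-
            compute_master_parameters(ts)
        }
      }
    }
  }

  if (!"Ctrl" %in% config$genotypes) {
    stop("config must include the Ctrl genotype (baseline)")
  }
  baseline <- list(
    mito = tables[["Ctrl"]][["21"]][["mito_proximal"]],
    lyso = tables[["Ctrl"]][["21"]][["lyso_proximal"]])

  signatures <- list()
  for (gt in config$genotypes) {
    for (day in config$days) {
      key <- paste0(gt, "_D", day)
      signatures[[key]] <- assemble_signature(
        tables[[gt]][[as.character(day)]], baseline, line = gt, day = day)
    }
  }

  strengths <- dplyr::bind_rows(lapply(config$genotypes, function(gt) {
    strength_curve(signatures[paste0(gt, "_D", config$days)])
  }))

  onsets <- dplyr::bind_rows(lapply(config$genotypes, function(gt) {
    dplyr::bind_rows(lapply(sites, function(site) {
      onset <- NA_integer_
      for (day in config$days) {
        s <- signatures[[paste0(gt, "_D", day)]]
        z <- s$values[s$labels$site == site]
        if (any(z <= -5)) { onset <- day; break }
      }
      tibble::tibble(genotype = gt, site = site, onset_day = onset)
    }))
  }))

  significant <- dplyr::bind_rows(lapply(names(signatures), function(key) {
    s <- signatures[[key]]
    sig <- significant_parameters(s)
    if (!length(sig)) return(NULL)
    tibble::tibble(line = s$line, day = s$day, label = names(sig), z = sig)
  }))

  dendrograms <- list()
  if (length(config$genotypes) >= 2L) {
    for (day in config$days) {
      sigs <- signatures[paste0(config$genotypes, "_D", day)]
      dendrograms[[as.character(day)]] <- list(
        full = cluster_signatures(sigs, "full"),
        distal = cluster_signatures(sigs, "distal"),
        proximal = cluster_signatures(sigs, "proximal"))
    }
  }

  report <- structure(list(config = config, signatures = signatures,
                           strengths = strengths, onsets = onsets,
                           significant = significant,
                           dendrograms = dendrograms),
                      class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", length(x$config$genotypes), " genotype(s) x ",
      length(x$config$days), " day(s), ", x$config$n_tracks,
      " tracks/condition (seed ", x$config$seed, ")\n", sep = "")
  on <- x$onsets
  for (i in seq_len(nrow(on))) {
    cat("  ", format(on$genotype[i], width = 10), " ",
        format(on$site[i], width = 8), " onset: ",
        ifelse(is.na(on$onset_day[i]), "none",
               paste0("D", on$onset_day[i])), "\n", sep = "")
  }
  invisible(x)
}

write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(report$signatures)) {
    write_signature(report$signatures[[key]],
                    file.path(out_dir, paste0("signature_", key)))
  }
  utils::write.csv(report$strengths,
                   file.path(out_dir, "strength_curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(onsets = report$onsets, significant = report$significant),
    file.path(out_dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  for (day in names(report$dendrograms)) {
    for (sub in names(report$dendrograms[[day]])) {
      signature_dendrogram_newick(
        report$dendrograms[[day]][[sub]],
        file.path(out_dir, paste0("dendrogram_D", day, "_", sub, ".nwk")))
    }
  }
  invisible(out_dir)
}
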