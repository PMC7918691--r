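#' Z-score of a condition against a pooled-control baseline
#'
#' Deviation of the condition's mean from the baseline mean in units of the
#' baseline's sample standard deviation (divisor n - 1). This estimator is
#' isolated here so a robust (median/MAD) variant can be swapped in via
#' `robust = TRUE`.
#'
#' @param condition_values Numeric samples of one parameter under the
#'   condition.
#' @param baseline_values Numeric samples of the same parameter from pooled
#'   controls; at least 2, with non-zero spread.
#' @param parameter Parameter name used in error messages.
#' @param robust If `TRUE`, use median and MAD instead of mean and SD.
#' @return A single dimensionless Z value.
#' @examples
#' zscore(6, c(0, 1, 2)) # 5
#' @export
zscore <- function(condition_values, baseline_values, parameter = "parameter",
                   robust = FALSE) {
  condition_values <- condition_values[is.finite(condition_values)]
  baseline_values <- baseline_values[is.finite(baseline_values)]
  if (length(baseline_values) < 2L) {
    stop("baseline for '", parameter, "' needs at least 2 samples")
  }
  if (length(condition_values) < 1L) {
    stop("no finite condition values for '", parameter, "'")
  }
  centre <- if (robust) stats::median else mean
  spread <- if (robust) stats::mad else stats::sd
  s <- spread(baseline_values)
  if (s == 0) {
    stop("baseline for '", parameter, "' has zero spread")
  }
  (centre(condition_values) - centre(baseline_values)) / s
}

signature_blocks <- function() {
  expand.grid(site = c("distal", "proximal"),
              channel = c("mito", "lyso"),
              stringsAsFactors = FALSE)[c(1, 2, 3, 4),
                                        c("channel", "site")]
}

#' Assemble a 44-parameter phenotypic signature
#'
#' Scores every master parameter of one condition (cell line x day) against
#' the pooled-control baseline (control lines at D21, proximal readout) and
#' assembles the Z-scores into one ordered signature: 11 parameters x
#' (mito/lyso) x (distal/proximal) = 44 values, block order mito-distal,
#' mito-proximal, lyso-distal, lyso-proximal. The nine per-track parameters
#' are scored against the baseline's per-track distribution, the two
#' per-batch parameters against the baseline's per-batch distribution.
#'
#' @param tables Named list of `master_parameter_table`s with entries
#'   `mito_distal`, `mito_proximal`, `lyso_distal`, `lyso_proximal`.
#' @param baseline_tables Named list (`mito`, `lyso`) of pooled-control
#'   `master_parameter_table`s at D21 proximal.
#' @param line Cell line / genotype label.
#' @param day Day in culture.
#' @param baseline_id Identifier of the baseline (bookkeeping).
#' @param robust Passed to [zscore()].
#' @return An object of class `phenotypic_signature`: list with `values`
#'   (named numeric, length 44), `labels` (tibble `channel`, `site`,
#'   `parameter`), `line`, `day`, `baseline_id`.
#' @export
assemble_signature <- function(tables, baseline_tables, line = NA_character_,
                               day = NA_integer_,
                               baseline_id = "pooled-Ctrl-D21-proximal",
                               robust = FALSE) {
  blocks <- signature_blocks()
  need <- paste(blocks$channel, blocks$site, sep = "_")
  missing <- setdiff(need, names(tables))
  if (length(missing)) {
    stop("missing condition table(s): ", paste(missing, collapse = ", "))
  }
  for (ch in unique(blocks$channel)) {
    if (!ch %in% names(baseline_tables)) {
      stop("missing baseline table for channel '", ch, "'")
    }
  }
  values <- numeric(0)
  labels <- list()
  for (b in seq_len(nrow(blocks))) {
    ch <- blocks$channel[b]; site <- blocks$site[b]
    tab <- tables[[paste(ch, site, sep = "_")]]
    base <- baseline_tables[[ch]]
    stopifnot(inherits(tab, "master_parameter_table"),
              inherits(base, "master_parameter_table"))
    for (p in per_track_parameters()) {
      z <- zscore(tab$per_track[[p]], base$per_track[[p]],
                  parameter = paste(ch, site, p, sep = "."), robust = robust)
      values <- c(values, z)
    }
    for (p in per_batch_parameters()) {
      z <- zscore(tab$per_batch[[p]], base$per_batch[[p]],
                  parameter = paste(ch, site, p, sep = "."), robust = robust)
      values <- c(values, z)
    }
    labels[[b]] <- tibble::tibble(
      channel = ch, site = site,
      parameter = c(per_track_parameters(), per_batch_parameters()))
  }
  labels <- dplyr::bind_rows(labels)
  names(values) <- paste(labels$channel, labels$site, labels$parameter,
                         sep = ".")
  structure(list(values = values, labels = labels, line = line, day = day,
                 baseline_id = baseline_id),
            class = "phenotypic_signature")
}

#' @export
print.phenotypic_signature <- function(x, ...) {
  cat("<phenotypic_signature> ", x$line, " D", x$day, ": ",
      length(x$values), " Z-scores vs ", x$baseline_id, "; |Z| range ",
      round(min(abs(x$values)), 2), "-", round(max(abs(x$values)), 2),
      "\n", sep = "")
  invisible(x)
}

#' Significantly deviating parameters of a signature
#'
#' By the established convention, only Z-scores strictly below `-threshold`
#' or strictly above `+threshold` count as significant deviations
#' (default threshold 5; values exactly at the boundary are not flagged).
#'
#' @param signature A `phenotypic_signature`.
#' @param threshold Positive significance threshold.
#' @return Named numeric vector of the significant Z-scores.
#' @export
significant_parameters <- function(signature, threshold = 5) {
  stopifnot(inherits(signature, "phenotypic_signature"))
  if (threshold <= 0) stop("threshold must be > 0")
  v <- signature$values
  v[v < -threshold | v > threshold]
}

subset_labels <- function(signature, subset) {
  switch(subset,
         total = ,
         full = rep(TRUE, length(signature$values)),
         distal = signature$labels$site == "distal",
         proximal = signature$labels$site == "proximal",
         stop("unknown subset '", subset,
              "' (use total/full, distal, or proximal)"))
}

#' Phenotypic strength of a signature
#'
#' Sum of the absolute Z-scores over the whole signature or over its distal
#' or proximal half: a scalar severity measure whose time course exposes
#' the onset and progression of trafficking decline. By construction
#' `total = distal + proximal`.
#'
#' @param signature A `phenotypic_signature`.
#' @param subset `"total"`, `"distal"`, or `"proximal"`.
#' @return Non-negative scalar.
#' @export
phenotypic_strength <- function(signature,
                                subset = c("total", "distal", "proximal")) {
  stopifnot(inherits(signature, "phenotypic_signature"))
  subset <- match.arg(subset)
  sum(abs(signature$values[subset_labels(signature, subset)]))
}

#' Hierarchically cluster phenotypic signatures
#'
#' Agglomerative clustering of signatures (full, or restricted to the
#' distal or proximal half) with Ward linkage on Euclidean distances by
#' default. The result is a standard `hclust` object (leaf labels
#' `line_Dday`), so `stats::cutree()` and plotting work directly; use
#' [signature_dendrogram_newick()] to serialize.
#'
#' @param signatures List of `phenotypic_signature`s with identical label
#'   sets (>= 2).
#' @param subset `"full"`, `"distal"`, or `"proximal"`.
#' @param linkage `"ward"` (Ward on Euclidean distances, `ward.D2`),
#'   `"complete"`, `"average"`, or `"single"`.
#' @param metric Distance metric for `stats::dist()`.
#' @return An `hclust` object.
#' @export
cluster_signatures <- function(signatures,
                               subset = c("full", "distal", "proximal"),
                               linkage = "ward", metric = "euclidean") {
  subset <- match.arg(subset)
  if (length(signatures) < 2L) stop("need at least 2 signatures")
  lab0 <- names(signatures[[1]]$values)
  for (s in signatures) {
    stopifnot(inherits(s, "phenotypic_signature"))
    if (!identical(names(s$values), lab0)) {
      stop("signatures have inconsistent label sets")
    }
  }
  sel <- subset_labels(signatures[[1]], subset)
  m <- do.call(rbind, lapply(signatures, function(s) s$values[sel]))
  rownames(m) <- vapply(signatures,
                        function(s) paste0(s$line, "_D", s$day),
                        character(1))
  method <- switch(linkage, ward = "ward.D2", linkage)
  stats::hclust(stats::dist(m, method = metric), method = method)
}

#' Export a signature dendrogram as a Newick string
#'
#' Branch lengths derive from the merge heights of the clustering.
#'
#' @param hc An `hclust` object from [cluster_signatures()].
#' @param file Optional path; when given the tree is written there.
#' @return The Newick string, invisibly when writing to a file.
#' @export
signature_dendrogram_newick <- function(hc, file = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(file)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(ape::write.tree(phy))
  }
}

#' Phenotypic-strength time course of one cell line
#'
#' @param signatures List of `phenotypic_signature`s of a single line at
#'   several days.
#' @return A tibble `day`, `total`, `distal`, `proximal` sorted by day.
#' @export
strength_curve <- function(signatures) {
  rows <- lapply(signatures, function(s) {
    tibble::tibble(line = s$line, day = s$day,
                   total = phenotypic_strength(s, "total"),
                   distal = phenotypic_strength(s, "distal"),
                   proximal = phenotypic_strength(s, "proximal"))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$day)
}
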