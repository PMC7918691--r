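# Shared fixture builders (all synthetic, generated at test time).

# Master parameter tables for one condition: chosen motility state per site,
# both channels, split into batches.
condition_tables <- function(distal_state, proximal_state, seed0 = 100,
                             n = 80, batches = 4) {
  batch <- rep(seq_len(batches), length.out = n)
  tabs <- list()
  i <- 0
  for (ch in c("mito", "lyso")) {
    for (site in c("distal", "proximal")) {
      i <- i + 1
      st <- if (site == "distal") distal_state else proximal_state
      ts <- simulate_tracks(st, ch, site, n_tracks = n, seed = seed0 + i,
                            batch = batch)
      tabs[[paste(ch, site, sep = "_")]] <- compute_master_parameters(ts)
    }
  }
  tabs
}

# A signature object with prescribed Z values (labels filled in canonical
# order, truncated to the requested length).
fake_signature <- function(values) {
  labels <- dplyr::bind_rows(lapply(c("mito", "lyso"), function(ch) {
    dplyr::bind_rows(lapply(c("distal", "proximal"), function(site) {
      tibble::tibble(channel = ch, site = site,
                     parameter = c(per_track_parameters(),
                                   per_batch_parameters()))
    }))
  }))
  labels <- labels[seq_along(values), ]
  names(values) <- paste(labels$channel, labels$site, labels$parameter,
                         sep = ".")
  structure(list(values = values, labels = labels, line = "test", day = 21,
                 baseline_id = "test"), class = "phenotypic_signature")
}
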