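test_that("zscore matches hand arithmetic and rejects bad baselines", {
  expect_equal(zscore(6, c(0, 1, 2)), 5)          # baseline mean 1, sd 1
  expect_equal(zscore(c(1, 1), c(0, 1, 2)), 0)    # equal means
  expect_error(zscore(1, 5), "2 samples")
  expect_error(zscore(1, c(3, 3, 3), parameter = "straightness"),
               "straightness")
  # scale coherence: common positive rescaling leaves Z unchanged
  base <- c(1.2, 3.4, 2.2, 5.1)
  cond <- c(4.4, 6.1)
  for (k in c(0.01, 3, 250)) {
    expect_equal(zscore(k * cond, k * base), zscore(cond, base))
  }
})

test_that("an assembled signature has 44 labelled finite Z-scores", {
  tabs <- condition_tables("mobile", "mobile")
  baseline <- list(mito = tabs$mito_proximal, lyso = tabs$lyso_proximal)
  sig <- assemble_signature(tabs, baseline, line = "Ctrl", day = 21)
  expect_length(sig$values, 44L)
  expect_true(all(is.finite(sig$values)))
  expect_false(any(duplicated(names(sig$values))))
  # block order: mito-distal, mito-proximal, lyso-distal, lyso-proximal
  expect_equal(unique(paste(sig$labels$channel, sig$labels$site)),
               c("mito distal", "mito proximal",
                 "lyso distal", "lyso proximal"))
  # self-comparison: proximal blocks scored against themselves are 0
  prox <- sig$values[sig$labels$site == "proximal"]
  expect_equal(unname(prox), rep(0, 22), tolerance = 1e-12)
  # missing block is a named error
  expect_error(assemble_signature(tabs[-3], baseline), "lyso_distal")
})

test_that("declined conditions score strongly negative against baseline", {
  ctrl <- condition_tables("mobile", "mobile", seed0 = 100)
  sick <- condition_tables("immobile", "immobile", seed0 = 200)
  baseline <- list(mito = ctrl$mito_proximal, lyso = ctrl$lyso_proximal)
  sig <- assemble_signature(sick, baseline, line = "sick", day = 80)
  z_speed <- sig$values["mito.distal.mean_speed_um_s"]
  expect_lt(z_speed, -5)
})

test_that("significance flagging is strictly exclusive at the threshold", {
  sig <- fake_signature(c(4.9, 5.0, 5.1, -4.9, -5.0, -6.0))
  flagged <- significant_parameters(sig)
  expect_equal(unname(flagged), c(5.1, -6.0))
  expect_length(significant_parameters(fake_signature(rep(0, 6))), 0L)
  expect_error(significant_parameters(sig, threshold = 0), "threshold")
})

test_that("phenotypic strength sums |Z| and partitions by site", {
  sig <- fake_signature(rep(0, 44))
  expect_equal(phenotypic_strength(sig, "total"), 0)
  tabs <- condition_tables("immobile", "mobile", seed0 = 300)
  ctrl <- condition_tables("mobile", "mobile", seed0 = 400)
  baseline <- list(mito = ctrl$mito_proximal, lyso = ctrl$lyso_proximal)
  s <- assemble_signature(tabs, baseline)
  expect_equal(phenotypic_strength(s, "total"), sum(abs(s$values)))
  expect_equal(phenotypic_strength(s, "total"),
               phenotypic_strength(s, "distal") +
               phenotypic_strength(s, "proximal"))
  # hand case: {1, -2, 3} -> 6
  s3 <- fake_signature(c(1, -2, 3))
  expect_equal(phenotypic_strength(s3, "total"), 6)
})

test_that("clustering reproduces a brute-force Ward oracle", {
  # three signatures with pairwise distances (1, 1, sqrt(2)) scaled:
  # the close pair merges first
  sigs <- list(fake_signature(c(0, 0, 0, 0)),
               fake_signature(c(0.5, 0, 0, 0)),
               fake_signature(c(10, 0, 0, 0)))
  sigs[[1]]$line <- "a"; sigs[[2]]$line <- "b"; sigs[[3]]$line <- "c"
  hc <- cluster_signatures(sigs, "full")
  expect_equal(stats::cutree(hc, 2)[["a_D21"]], stats::cutree(hc, 2)[["b_D21"]])
  # heights match the Lance-Williams oracle exactly, up to 5 signatures
  withr::with_seed(8, {
    vals <- lapply(1:5, function(i) rnorm(44))
  })
  sigs5 <- lapply(seq_along(vals), function(i) {
    s <- fake_signature(vals[[i]]); s$line <- letters[i]; s
  })
  hc5 <- cluster_signatures(sigs5, "full")
  m <- do.call(rbind, vals)
  expect_equal(hc5$height, ward_oracle_heights(m))
  # identical signatures merge at height zero
  twin <- list(sigs5[[1]], sigs5[[1]])
  expect_equal(cluster_signatures(twin, "full")$height[1], 0)
  # inconsistent label sets are rejected
  short <- fake_signature(c(1, 2, 3))
  expect_error(cluster_signatures(list(sigs5[[1]], short)), "label sets")
  expect_error(cluster_signatures(sigs5[1]), "at least 2")
})

test_that("dendrograms export as Newick with all leaves", {
  withr::with_seed(9, vals <- lapply(1:4, function(i) rnorm(44)))
  sigs <- lapply(seq_along(vals), function(i) {
    s <- fake_signature(vals[[i]]); s$line <- paste0("L", i); s
  })
  nwk <- signature_dendrogram_newick(cluster_signatures(sigs, "full"))
  expect_match(nwk, "^\\(.*\\);$")
  for (i in 1:4) expect_match(nwk, paste0("L", i, "_D21"))
  tree <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(tree), 4L)
})
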