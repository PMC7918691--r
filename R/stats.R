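#' One-way ANOVA with Bonferroni post hoc comparisons
#'
#' Standard between/within variance decomposition across k groups, followed
#' by all pairwise two-sample t-tests using the pooled within-group variance,
#' with raw p-values multiplied by the number of comparisons
#' `k * (k - 1) / 2` and capped at 1 (Bonferroni over all pairs, not only
#' versus control).
#'
#' @param groups Named list of numeric vectors (k >= 2 groups, each with at
#'   least 2 values).
#' @return An object of class `anova_bonferroni`: list with `F`, `p`,
#'   `df` (c(between, within)), and `pairwise` (tibble `group1`, `group2`,
#'   `p_raw`, `p_adj`).
#' @examples
#' res <- one_way_anova_bonferroni(list(a = c(1, 2, 3), b = c(2, 3, 4),
#'                                      c = c(3, 4, 5)))
#' res$F
#' @export
one_way_anova_bonferroni <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  if (stats::var(values) == 0) stop("all values identical: no variance")
  g <- factor(rep(names(groups), sizes), levels = names(groups))

  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  F_stat <- tab[["F value"]][1]
  p_global <- tab[["Pr(>F)"]][1]
  df <- c(between = tab[["Df"]][1], within = tab[["Df"]][2])

  raw <- stats::pairwise.t.test(values, g, p.adjust.method = "none",
                                pool.sd = TRUE)$p.value
  adj <- stats::pairwise.t.test(values, g, p.adjust.method = "bonferroni",
                                pool.sd = TRUE)$p.value
  pairs <- which(!is.na(raw), arr.ind = TRUE)
  pairwise <- tibble::tibble(
    group1 = colnames(raw)[pairs[, 2]],
    group2 = rownames(raw)[pairs[, 1]],
    p_raw = raw[pairs],
    p_adj = adj[pairs])

  structure(list(F = F_stat, p = p_global, df = df, pairwise = pairwise),
            class = "anova_bonferroni")
}

#' @export
print.anova_bonferroni <- function(x, ...) {
  cat("<anova_bonferroni> F(", x$df[1], ", ", x$df[2], ") = ",
      signif(x$F, 5), ", p = ", signif(x$p, 4), "; ",
      nrow(x$pairwise), " pairwise comparison(s)\n", sep = "")
  invisible(x)
}

#' Overlap arithmetic of two gene (or any id) sets
#'
#' Exact set intersection and the percentage of each set that is shared,
#' as displayed in a two-set Venn diagram. Percentages are reported both
#' unrounded and rounded to the nearest integer.
#'
#' @param set_a,set_b Character (or coercible) vectors of ids; duplicates
#'   are ignored.
#' @return List with `size_a`, `size_b`, `size_intersection`, `pct_of_a`,
#'   `pct_of_b` (unrounded), `pct_of_a_rounded`, `pct_of_b_rounded`.
#' @examples
#' deg_overlap(letters[1:4], letters[3:6])$size_intersection # 2
#' @export
deg_overlap <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  inter <- length(intersect(a, b))
  pct_a <- if (length(a)) 100 * inter / length(a) else 0
  pct_b <- if (length(b)) 100 * inter / length(b) else 0
  list(size_a = length(a), size_b = length(b), size_intersection = inter,
       pct_of_a = pct_a, pct_of_b = pct_b,
       pct_of_a_rounded = round(pct_a), pct_of_b_rounded = round(pct_b))
}

#' Read a plain-text id list (one id per line)
#'
#' @param path File path; blank lines are dropped.
#' @return Character vector of ids.
#' @export
read_id_list <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids[nzchar(trimws(ids))]
}
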