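#' Triangle threshold of an intensity image
#'
#' Classic geometric triangle method for background subtraction: the
#' intensity histogram (256 uniform bins over the observed range) is
#' normalized, a line is drawn from the histogram peak to the far end of the
#' longer tail, and the threshold is placed at the bin whose histogram value
#' lies at maximal perpendicular distance below that line. Works well for
#' strongly unimodal backgrounds with a sparse bright tail, the typical
#' situation for fluorescent foci on a dark background.
#'
#' @param image Numeric matrix (or vector) of intensities with at least two
#'   distinct values.
#' @param n_bins Number of histogram bins.
#' @return The threshold intensity (centre of the selected bin).
#' @export
triangle_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) stop("constant image: triangle threshold undefined")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2

  peak <- which.max(counts)
  nz <- which(counts > 0)
  lo <- min(nz); hi <- max(nz)
  # orient toward the longer tail
  far <- if ((hi - peak) >= (peak - lo)) hi else lo
  if (far == peak) stop("degenerate histogram: peak at the only occupied bin")
  idx <- if (far > peak) peak:far else far:peak

  h <- counts / max(counts)
  x1 <- peak; y1 <- h[peak]
  x2 <- far; y2 <- h[far]
  nx <- y2 - y1; ny <- -(x2 - x1)  # normal to the peak-tail line
  nrm <- sqrt(nx^2 + ny^2)
  d <- ((idx - x1) * nx + (h[idx] - y1) * ny) / nrm
  best <- idx[which.max(abs(d))]
  mids[best]
}

label_components_8 <- function(binary) {
  # 8-connected component labelling via the pixel adjacency graph
  h <- nrow(binary); w <- ncol(binary)
  fg <- which(binary)
  lab <- matrix(0L, h, w)
  if (!length(fg)) return(lab)
  idx <- matrix(0L, h, w)
  idx[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% h) + 1L
  c <- ((fg - 1L) %/% h) + 1L
  edges <- list()
  k <- 0L
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + sh[1]; c2 <- c + sh[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- idx[cbind(r2[ok], c2[ok])]
    has <- nb > 0L
    if (any(has)) {
      k <- k + 1L
      edges[[k]] <- rbind(idx[fg][ok][has], nb[has])
    }
  }
  g <- igraph::make_graph(edges = if (k) as.vector(do.call(cbind, edges))
                          else integer(0),
                          n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[fg] <- comp
  lab
}

#' Count foci per nucleus
#'
#' Binarizes the channel image above `threshold`, labels 8-connected
#' components, discards components smaller than `min_size_px` pixels, and
#' assigns each remaining focus to the nucleus containing its centroid.
#' Foci whose centroid falls outside every nucleus (perinuclear foci) are
#' assigned to the nearest nucleus if its boundary lies within
#' `assign_radius_um`, otherwise they are left unassigned.
#'
#' @param channel_image Numeric intensity matrix.
#' @param nucleus_mask Labelled integer matrix of the same shape
#'   (0 = background, k = nucleus k).
#' @param threshold Intensity threshold (e.g. from [triangle_threshold()]).
#' @param min_size_px Minimum component area in pixels.
#' @param assign_radius_um Maximal centroid-to-nucleus distance for
#'   perinuclear assignment (um).
#' @param pixel_size_um Pixel size (um).
#' @return A tibble `nucleus`, `count` with one row per labelled nucleus
#'   (nuclei without foci get 0); attribute `unassigned` holds the number
#'   of foci not attributable to any nucleus.
#' @export
count_foci <- function(channel_image, nucleus_mask, threshold,
                       min_size_px = 4L, assign_radius_um = 5,
                       pixel_size_um = 0.22955) {
  if (!identical(dim(channel_image), dim(nucleus_mask))) {
    stop("channel_image and nucleus_mask must have the same shape")
  }
  n_nuclei <- max(nucleus_mask)
  counts <- integer(n_nuclei)
  unassigned <- 0L
  lab <- label_components_8(channel_image > threshold)
  n_comp <- max(lab)
  if (n_comp > 0) {
    h <- nrow(lab)
    px <- which(lab > 0)
    comp <- lab[px]
    area <- tabulate(comp, nbins = n_comp)
    rr <- ((px - 1L) %% h) + 1L
    cc <- ((px - 1L) %/% h) + 1L
    cen_r <- vapply(split(rr, comp), mean, numeric(1))
    cen_c <- vapply(split(cc, comp), mean, numeric(1))
    mask_px <- which(nucleus_mask > 0)
    mask_r <- ((mask_px - 1L) %% h) + 1L
    mask_c <- ((mask_px - 1L) %/% h) + 1L
    mask_lab <- nucleus_mask[mask_px]
    for (k in which(area >= min_size_px)) {
      r0 <- round(cen_r[as.character(k)]); c0 <- round(cen_c[as.character(k)])
      nuc <- nucleus_mask[r0, c0]
      if (nuc == 0L && n_nuclei > 0L && length(mask_px)) {
        d2 <- (mask_r - cen_r[as.character(k)])^2 +
              (mask_c - cen_c[as.character(k)])^2
        j <- which.min(d2)
        if (sqrt(d2[j]) * pixel_size_um <= assign_radius_um) {
          nuc <- mask_lab[j]
        }
      }
      if (nuc > 0L) counts[nuc] <- counts[nuc] + 1L else
        unassigned <- unassigned + 1L
    }
  }
  structure(tibble::tibble(nucleus = seq_len(n_nuclei), count = counts),
            unassigned = unassigned)
}

#' Classify nuclei by focus co-occurrence
#'
#' Two-channel co-occurrence rule for perinuclear aggregate foci (e.g.
#' dipeptide-repeat inclusions, "GA") versus nuclear DNA double-strand
#' break foci ("DSB"): category `A` is at least one GA focus with no DSB
#' focus in the same cell; category `B` is at least one GA focus together
#' with at least `dsb_min_b` (default 3) DSB foci. Everything else —
#' including cells without GA foci, and GA-positive cells with 1-2 DSB
#' foci — is `unclassified`. Set `dsb_free_max` to relax what counts as
#' "DSB-free" for category A.
#'
#' @param ga_count,dsb_count Non-negative integer vectors (recycled).
#' @param dsb_free_max Maximum DSB count still treated as DSB-free (A).
#' @param dsb_min_b Minimum DSB count for category B.
#' @return Factor with levels `A`, `B`, `unclassified`.
#' @examples
#' classify_ga_dsb(c(2, 1, 0, 1), c(0, 3, 5, 2))
#' @export
classify_ga_dsb <- function(ga_count, dsb_count, dsb_free_max = 0L,
                            dsb_min_b = 3L) {
  n <- max(length(ga_count), length(dsb_count))
  ga <- rep_len(ga_count, n); dsb <- rep_len(dsb_count, n)
  if (any(ga < 0) || any(dsb < 0)) stop("counts must be non-negative")
  out <- rep("unclassified", n)
  out[ga >= 1 & dsb <= dsb_free_max] <- "A"
  out[ga >= 1 & dsb >= dsb_min_b] <- "B"
  factor(out, levels = c("A", "B", "unclassified"))
}

#' Pearson pixel-intensity colocalization
#'
#' Pearson correlation coefficient of the pixel intensities of two channels
#' over a mask: r = 0 means no colocalization, r = 1 complete
#' colocalization. Equals the signed square root of the R-squared of the
#' linear regression of one channel on the other, and is invariant under
#' positive affine rescaling of either channel.
#'
#' @param channel1,channel2 Numeric matrices of the same shape.
#' @param mask Logical or 0/1 matrix selecting pixels (default: all).
#' @return r in `[-1, 1]`.
#' @export
pearson_colocalization <- function(channel1, channel2, mask = NULL) {
  if (!identical(dim(channel1), dim(channel2))) {
    stop("channels must have the same shape")
  }
  if (is.null(mask)) mask <- rep(TRUE, length(channel1))
  sel <- as.logical(mask)
  a <- as.numeric(channel1)[sel]
  b <- as.numeric(channel2)[sel]
  if (length(a) < 2L) stop("need at least 2 masked pixels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in a channel: correlation undefined")
  }
  stats::cor(a, b)
}

#' Foci count normalized to 100 cells
#'
#' @param total_foci Total number of foci counted (>= 0).
#' @param n_cells Number of cells examined (>= 1).
#' @return `100 * total_foci / n_cells`.
#' @examples
#' foci_per_100_cells(30, 60) # 50
#' @export
foci_per_100_cells <- function(total_foci, n_cells) {
  if (any(n_cells < 1)) stop("n_cells must be >= 1")
  if (any(total_foci < 0)) stop("total_foci must be >= 0")
  100 * total_foci / n_cells
}
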