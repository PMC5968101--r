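# Stained-area and object-count contracts on (synthetic) grayscale images.
# Background is removed by a morphological top-hat (image minus its opening),
# the residual is binarized at an intensity quantile, and connected
# components (8-connectivity) below a minimum size are discarded.

# 8-connected component labeling of a logical mask; returns component sizes
# and the component id per foreground pixel.
label_components <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(list(sizes = integer(0), membership = integer(0),
                                index = idx))
  nr <- nrow(mask)
  nc <- ncol(mask)
  lookup <- integer(nr * nc)
  lookup[idx] <- seq_along(idx)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rr + off[1]
    c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- lookup[nb] > 0L
    if (any(hit)) {
      edges <- rbind(edges, cbind(lookup[idx[ok]][hit], lookup[nb][hit]))
    }
  }
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(0L, 0, 2) else edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  list(sizes = as.integer(comp$csize), membership = comp$membership,
       index = idx)
}

# shared preprocessing: top-hat background subtraction + quantile threshold
stain_mask <- function(image, quantile_threshold, background_radius) {
  image <- as.matrix(image)
  if (!is.numeric(image) || !length(image)) {
    stop_irritmap("`image` must be a non-empty numeric matrix.",
                  "irritmap_config_error")
  }
  if (quantile_threshold <= 0 || quantile_threshold >= 1) {
    stop_irritmap("`quantile_threshold` must be in (0, 1).",
                  "irritmap_config_error")
  }
  if (max(image) == min(image)) {
    warn("Constant image: no stained area detected.")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  if (background_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(background_radius) + 1L,
                                shape = "disc")
    bg <- EBImage::imageData(EBImage::opening(EBImage::Image(image), brush))
    resid <- image - bg
  } else {
    resid <- image
  }
  thr <- quantile(resid, quantile_threshold)
  resid > thr
}

#' Stained-area fraction of an image
#'
#' Fraction of pixels covered by stain after background subtraction
#' (morphological top-hat), quantile binarization and removal of connected
#' components (8-connectivity) smaller than `min_object_px`.
#'
#' @param image numeric matrix of intensities (grayscale).
#' @param quantile_threshold binarization quantile of the
#'   background-subtracted intensities (default 0.95).
#' @param min_object_px components smaller than this are treated as noise.
#' @param background_radius disc radius (px) of the opening used for
#'   background subtraction; 0 disables it.
#' @return The retained-pixel fraction in \[0, 1\].
#' @export
stained_area_fraction <- function(image, quantile_threshold = 0.95,
                                  min_object_px = 5, background_radius = 15) {
  mask <- stain_mask(image, quantile_threshold, background_radius)
  if (!any(mask)) return(0)
  lab <- label_components(mask)
  keep <- lab$sizes[lab$membership] >= min_object_px
  sum(keep) / length(mask)
}

#' Count stained objects in an image
#'
#' Number of connected components (8-connectivity) of the binarized,
#' background-subtracted image that reach `min_object_px` pixels. Two blobs
#' joined by even a single-pixel diagonal bridge count as one object.
#'
#' @inheritParams stained_area_fraction
#' @return Integer object count.
#' @export
count_objects <- function(image, quantile_threshold = 0.95,
                          min_object_px = 5, background_radius = 15) {
  mask <- stain_mask(image, quantile_threshold, background_radius)
  if (!any(mask)) return(0L)
  lab <- label_components(mask)
  sum(lab$sizes >= min_object_px)
}

#' Synthetic stained-tissue image
#'
#' Draws disc-shaped stained objects on a dark background with optional
#' Gaussian noise; returns the image together with its ground-truth mask so
#' area and count contracts can be checked exactly.
#'
#' @param width,height image size, px.
#' @param centers matrix (n x 2) of blob centers (row, col); random when
#'   `NULL`.
#' @param radii blob radii, px (recycled).
#' @param n_blobs number of random blobs when `centers` is `NULL`.
#' @param intensity stain intensity of the blobs.
#' @param noise_sd Gaussian background noise SD.
#' @param seed integer seed.
#' @return A list with `image`, `mask` (logical truth) and `centers`.
#' @export
synthetic_stain_image <- function(width = 600, height = 600, centers = NULL,
                                  radii = 8, n_blobs = 5, intensity = 1,
                                  noise_sd = 0, seed = 1L) {
  img <- matrix(0, height, width)
  centers <- if (is.null(centers)) {
    with_seed(seed, cbind(runif(n_blobs, 30, height - 30),
                          runif(n_blobs, 30, width - 30)))
  } else as.matrix(centers)
  radii <- rep_len(radii, nrow(centers))
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  mask <- matrix(FALSE, height, width)
  for (i in seq_len(nrow(centers))) {
    mask <- mask | ((rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <=
                      radii[i]^2)
  }
  img[mask] <- intensity
  if (noise_sd > 0) {
    img <- img + with_seed(derive_seed(seed, 99L),
                           matrix(rnorm(length(img), 0, noise_sd), height,
                                  width))
  }
  list(image = img, mask = mask, centers = centers)
}
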