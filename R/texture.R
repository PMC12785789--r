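#' Quantize a grayscale image to 256 levels
#'
#' 8-bit input (values already in 0-255) passes through unchanged; deeper
#' input is mapped linearly from `[0, max_level]` onto `[0, 255]` with
#' round-half-even rounding. Images are plain numeric matrices (rows x
#' columns of gray values).
#'
#' @param image A single-channel numeric matrix.
#' @param max_level Full-scale value of the input (255 for 8-bit, 65535
#'   for 16-bit). `NULL` infers 255 when all values fit, 65535 otherwise.
#' @return An integer-valued matrix with levels 0-255.
#' @export
quantize <- function(image, max_level = NULL) {
  if (is.array(image) && length(dim(image)) > 2L) {
    stop("multi-channel image: convert to grayscale first", call. = FALSE)
  }
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  if (any(image < 0)) stop("gray values must be non-negative", call. = FALSE)
  if (is.null(max_level)) {
    max_level <- if (max(image) <= 255) 255 else 65535
  }
  if (max_level <= 0) stop("`max_level` must be positive", call. = FALSE)
  if (max_level == 255) {
    out <- round(image)  # pass 8-bit through (tolerating non-integer noise)
  } else {
    out <- round(image / max_level * 255)
  }
  storage.mode(out) <- "integer"
  out
}

# displacement (row, col) for the four standard GLCM directions;
# 0 deg = horizontal neighbour to the right, angles grow counter-clockwise
glcm_displacement <- function(angle) {
  switch(as.character(angle),
         "0" = c(0L, 1L),
         "45" = c(-1L, 1L),
         "90" = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("`angle` must be one of 0, 45, 90, 135 degrees",
              call. = FALSE))
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring gray-level pairs at a fixed pixel displacement and
#' normalizes them to probabilities. The four standard directions at
#' 1-pixel offset are supported; symmetrization (adding the transpose
#' before normalizing) makes the matrix direction-invariant under pair
#' exchange.
#'
#' @param image Quantized integer matrix with levels 0-255 (see
#'   [quantize()]).
#' @param angle Direction in degrees: 0, 45, 90 or 135.
#' @param offset Displacement length in pixels (default 1).
#' @param symmetric Add the transpose before normalizing (default TRUE).
#' @param levels Number of gray levels (default 256).
#' @return An object of class `"glcm"`: list with the `probabilities`
#'   matrix (levels x levels, summing to 1) and the parameters used.
#' @export
compute_glcm <- function(image, angle = 0, offset = 1L, symmetric = TRUE,
                         levels = 256L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  if (any(image != round(image)) || any(image < 0) ||
      any(image >= levels)) {
    stop("`image` must be quantized to integer levels 0..levels-1",
         call. = FALSE)
  }
  d <- glcm_displacement(angle) * as.integer(offset)
  nr <- nrow(image)
  nc <- ncol(image)
  if (nr <= abs(d[1]) || nc <= abs(d[2])) {
    stop("image too small for the requested offset", call. = FALSE)
  }
  rs <- seq.int(max(1L, 1L - d[1]), min(nr, nr - d[1]))
  cs <- seq.int(max(1L, 1L - d[2]), min(nc, nc - d[2]))
  i <- image[rs, cs, drop = FALSE]
  j <- image[rs + d[1], cs + d[2], drop = FALSE]
  counts <- tabulate(as.vector(i) * levels + as.vector(j) + 1L,
                     nbins = levels * levels)
  G <- matrix(counts, levels, levels, byrow = TRUE)
  if (symmetric) G <- G + t(G)
  structure(
    list(probabilities = G / sum(G), angle = angle, offset = offset,
         symmetric = symmetric, levels = levels),
    class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("GLCM: %d levels, angle %g deg, offset %d px, %s\n",
              x$levels, x$angle, x$offset,
              if (x$symmetric) "symmetrized" else "raw"))
  invisible(x)
}

#' Texture metrics from a co-occurrence matrix
#'
#' Scalar texture descriptors of the normalized GLCM `P(i, j)` over gray
#' levels `i, j`:
#' entropy `-sum P log2 P` (bits, with `0 log 0 = 0`),
#' homogeneity `sum P / (1 + |i - j|)`,
#' energy `sum P^2`,
#' correlation `sum (i - mu_i)(j - mu_j) P / (sigma_i sigma_j)`,
#' and contrast `sum (i - j)^2 P`.
#' For a constant image the marginal standard deviations vanish and the
#' correlation is undefined: it is reported as `NA` with a warning rather
#' than as 0 or 1, so that averages over directions are not silently
#' biased.
#'
#' @param g A [compute_glcm()] result (or a bare normalized probability
#'   matrix).
#' @return An object of class `"texture_metrics"`: named list with
#'   `contrast`, `entropy`, `homogeneity`, `energy`, `correlation`.
#' @export
texture_metrics <- function(g) {
  P <- if (inherits(g, "glcm")) g$probabilities else g
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stop("`g` must be a square GLCM", call. = FALSE)
  }
  if (abs(sum(P) - 1) > 1e-9) {
    stop("GLCM must be normalized (probabilities summing to 1)",
         call. = FALSE)
  }
  lv <- seq_len(nrow(P)) - 1  # gray levels 0..L-1
  diffs <- outer(lv, lv, "-")
  nz <- P > 0
  entropy <- -sum(P[nz] * log2(P[nz]))
  homogeneity <- sum(P / (1 + abs(diffs)))
  energy <- sum(P^2)
  contrast <- sum(diffs^2 * P)
  pi_ <- rowSums(P)
  pj_ <- colSums(P)
  mu_i <- sum(lv * pi_)
  mu_j <- sum(lv * pj_)
  sd_i <- sqrt(sum((lv - mu_i)^2 * pi_))
  sd_j <- sqrt(sum((lv - mu_j)^2 * pj_))
  if (sd_i * sd_j == 0) {
    warning("constant image: GLCM correlation undefined", call. = FALSE)
    correlation <- NA_real_
  } else {
    correlation <- sum(outer(lv - mu_i, lv - mu_j) * P) / (sd_i * sd_j)
  }
  structure(
    list(contrast = contrast, entropy = entropy, homogeneity = homogeneity,
         energy = energy, correlation = correlation),
    class = "texture_metrics")
}

#' @export
print.texture_metrics <- function(x, ...) {
  cat(sprintf(
    "texture: contrast %.4g, entropy %.4g bits, homogeneity %.4g, energy %.4g, correlation %s\n",
    x$contrast, x$entropy, x$homogeneity, x$energy,
    if (is.na(x$correlation)) "undefined" else sprintf("%.4g",
                                                       x$correlation)))
  invisible(x)
}

#' Average texture metrics over the four GLCM directions
#'
#' Arithmetic mean of each metric over the 0/45/90/135-degree results; an
#' undefined correlation in any direction leaves the averaged correlation
#' undefined.
#'
#' @param metrics List of exactly four [texture_metrics()] objects.
#' @return A [texture_metrics()] object.
#' @export
direction_average <- function(metrics) {
  if (length(metrics) != 4L ||
      !all(vapply(metrics, inherits, logical(1), "texture_metrics"))) {
    stop("need texture metrics for all four directions", call. = FALSE)
  }
  avg <- lapply(c("contrast", "entropy", "homogeneity", "energy",
                  "correlation"),
                function(nm) mean(vapply(metrics, `[[`, numeric(1), nm)))
  names(avg) <- c("contrast", "entropy", "homogeneity", "energy",
                  "correlation")
  structure(avg, class = "texture_metrics")
}

#' Direction-averaged GLCM texture metrics of an image
#'
#' Convenience wrapper implementing the full protocol: quantized image,
#' GLCMs at 0, 45, 90 and 135 degrees with 1-pixel offset, symmetrized,
#' metrics per direction, then the four-direction average.
#'
#' @param image Quantized integer matrix (see [quantize()]).
#' @param offset Displacement in pixels.
#' @param symmetric Symmetrize each GLCM.
#' @return List with `per_angle` (named list of [texture_metrics()]) and
#'   `average` (the four-direction mean).
#' @export
glcm_features <- function(image, offset = 1L, symmetric = TRUE) {
  angles <- c(0, 45, 90, 135)
  per <- lapply(angles, function(a) {
    texture_metrics(compute_glcm(image, a, offset, symmetric))
  })
  names(per) <- paste0("deg", angles)
  list(per_angle = per, average = direction_average(per))
}

#' Local standard-deviation heterogeneity map
#'
#' Per-pixel sample standard deviation of gray values over a square
#' neighborhood, with mirror (reflect) padding at the borders. High values
#' mark heterogeneous regions: cracks, char blotches and grain boundaries
#' on toasted stave surfaces.
#'
#' @param image Numeric matrix of gray values.
#' @param window Odd neighborhood side length in pixels (default 15).
#' @return A numeric matrix of the same size as `image` (values >= 0).
#' @export
heterogeneity_map <- function(image, window = 15L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  if (window > min(dim(image))) {
    stop("`window` exceeds the image size", call. = FALSE)
  }
  h <- (window - 1L) %/% 2L
  nr <- nrow(image)
  nc <- ncol(image)
  ridx <- c(rev(seq_len(h)), seq_len(nr), seq.int(nr, by = -1L,
                                                  length.out = h))
  cidx <- c(rev(seq_len(h)), seq_len(nc), seq.int(nc, by = -1L,
                                                  length.out = h))
  pad <- image[ridx, cidx, drop = FALSE]
  # summed-area tables of values and squares, with a zero border
  sat <- function(M) {
    S <- apply(M, 2, cumsum)
    S <- t(apply(S, 1, cumsum))
    rbind(0, cbind(0, S))
  }
  S1 <- sat(pad)
  S2 <- sat(pad^2)
  box <- function(S) {
    r0 <- seq_len(nr)
    c0 <- seq_len(nc)
    S[r0 + window, c0 + window] - S[r0, c0 + window] -
      S[r0 + window, c0] + S[r0, c0]
  }
  nwin <- window^2
  s1 <- box(S1)
  s2 <- box(S2)
  sqrt(pmax((s2 - s1^2 / nwin) / (nwin - 1), 0))
}

#' Read and write 8-bit grayscale PNG images
#'
#' Images are numeric matrices with gray levels 0-255. Multi-channel PNGs
#' are refused on read.
#'
#' @param image Integer-valued matrix with levels 0-255.
#' @param path File path.
#' @return `write_gray_png()` returns `path` invisibly; `read_gray_png()`
#'   returns an integer matrix 0-255.
#' @export
write_gray_png <- function(image, path) {
  if (any(image < 0 | image > 255)) {
    stop("gray levels must lie in [0, 255]", call. = FALSE)
  }
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
read_gray_png <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) > 2L) {
    stop("multi-channel PNG: convert to grayscale first", call. = FALSE)
  }
  quantize(img * 255)
}
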