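#' Geometric mean
#'
#' `exp(mean(log(x)))` of a strictly positive vector — the standard
#' location summary for flow-cytometry fluorescence, which is
#' approximately log-normal. Errors on non-positive values rather than
#' silently dropping events.
#'
#' @param values numeric vector, all > 0.
#' @export
geometric_mean <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("geometric mean requires strictly positive finite values", call. = FALSE)
  }
  exp(mean(log(values)))
}

#' Net normalized fluorescence intensity (NNFI)
#'
#' The flow-cytometry readout used for ligand-binding assays on receptor
#' transfectants: the geometric mean fluorescence intensity of the sample
#' after subtracting a nonspecific-binding background, divided by the
#' relative surface receptor expression (a dimensionless fraction, e.g.
#' 0.8 for a line expressing 80 percent of the reference level). The
#' background well is an explicit input (excess unlabeled antibody and
#' EDTA wells are both in use; the caller chooses). Negative NNFI (sample
#' below background) is permitted and flagged, not an error.
#'
#' @param gmfi_sample geometric mean fluorescence of the sample, a.u. (> 0).
#' @param gmfi_background geometric mean fluorescence of the background
#'   well, a.u. (> 0).
#' @param expression_ratio relative receptor expression, fraction > 0.
#' @return list of class `NNFIResult`: `nnfi`, `negative` flag, and the
#'   echoed inputs.
#' @export
nnfi <- function(gmfi_sample, gmfi_background, expression_ratio) {
  stopifnot(is.numeric(gmfi_sample), is.numeric(gmfi_background),
            is.numeric(expression_ratio))
  if (any(gmfi_sample <= 0) || any(gmfi_background <= 0)) {
    stop("GMFI values must be positive", call. = FALSE)
  }
  if (any(expression_ratio <= 0)) {
    stop("expression_ratio must be positive", call. = FALSE)
  }
  value <- (gmfi_sample - gmfi_background) / expression_ratio
  structure(list(nnfi = value, negative = value < 0,
                 gmfi_sample = gmfi_sample, gmfi_background = gmfi_background,
                 expression_ratio = expression_ratio),
            class = "NNFIResult")
}

#' @export
print.NNFIResult <- function(x, ...) {
  cat("NNFI:", format(x$nnfi), "\n")
  if (any(x$negative)) cat("  (negative: sample below background)\n")
  invisible(x)
}

#' Percent inhibition
#'
#' `(1 - treated/control) * 100`: the fractional loss of signal under a
#' treatment (e.g. adhesion in the presence of an antagonist) relative to
#' an untreated control, expressed in percent.
#'
#' @param signal_control untreated signal (> 0).
#' @param signal_treated treated signal.
#' @export
percent_inhibition <- function(signal_control, signal_treated) {
  stopifnot(is.numeric(signal_control), is.numeric(signal_treated))
  if (any(signal_control <= 0)) stop("control signal must be positive", call. = FALSE)
  (1 - signal_treated / signal_control) * 100
}

# 8-connected component labelling by flood fill; returns largest component mask
largest_component <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask & lab == 0L)
  best <- NULL; best_n <- 0L; n_comp <- 0L
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L; n_comp <- n_comp + 1L
    stack <- s
    members <- integer()
    lab[s] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, p)
      r0 <- (p - 1L) %% nr + 1L
      c0 <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r1 <- r0 + dr; c1 <- c0 + dc
        if (r1 >= 1L && r1 <= nr && c1 >= 1L && c1 <= nc) {
          q <- (c1 - 1L) * nr + r1
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            stack <- c(stack, q)
          }
        }
      }
    }
    if (length(members) > best_n) {
      best_n <- length(members)
      best <- members
    }
  }
  list(indices = best, n_components = n_comp)
}

#' Fit an ellipse to a binary cell mask
#'
#' Moments-based ellipse fit (the regionprops convention): the foreground
#' pixel set's second central moments define a covariance matrix whose
#' eigenvalues give the axis lengths (`4 * sqrt(eigenvalue)` = full axis,
#' exact for an ideal filled ellipse) and whose eigenvectors give the
#' orientation. When the mask holds several connected components the
#' largest (8-connected) one is used and a warning is issued; segmentation
#' of multi-cell images is upstream of this function.
#'
#' @param mask logical or 0/1 numeric matrix; nonzero = foreground.
#' @param min_pixels minimum foreground pixel count (default 16).
#' @return list of class `EllipseFit`: `centroid` (row, col),
#'   `major_axis_length`, `minor_axis_length` (px), `orientation`
#'   (radians in (-pi/2, pi/2], angle of the major axis against the row
#'   axis), `form_factor` (major/minor), `area_px`.
#' @export
fit_ellipse <- function(mask, min_pixels = 16) {
  stopifnot(is.matrix(mask))
  m <- mask != 0 & !is.na(mask)
  if (!any(m)) stop("empty mask", call. = FALSE)
  comp <- largest_component(m)
  if (comp$n_components > 1L) {
    warning(sprintf("mask has %d connected components; using the largest",
                    comp$n_components))
  }
  idx <- comp$indices
  if (length(idx) < min_pixels) {
    stop(sprintf("largest component has %d pixels (< %d)", length(idx), min_pixels),
         call. = FALSE)
  }
  nr <- nrow(m)
  r <- (idx - 1L) %% nr + 1L
  c0 <- (idx - 1L) %/% nr + 1L
  mu_r <- mean(r); mu_c <- mean(c0)
  # second central moments of the pixel set
  m20 <- mean((r - mu_r)^2)
  m02 <- mean((c0 - mu_c)^2)
  m11 <- mean((r - mu_r) * (c0 - mu_c))
  cov <- matrix(c(m20, m11, m11, m02), 2, 2)
  ev <- eigen(cov, symmetric = TRUE)
  lam <- ev$values
  if (lam[2] <= .Machine$double.eps * max(1, lam[1])) {
    stop("degenerate mask: foreground pixels are collinear", call. = FALSE)
  }
  v <- ev$vectors[, 1]
  ang <- atan2(v[2], v[1])
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  structure(list(
    centroid = c(row = mu_r, col = mu_c),
    major_axis_length = 4 * sqrt(lam[1]),
    minor_axis_length = 4 * sqrt(lam[2]),
    orientation = ang,
    form_factor = sqrt(lam[1] / lam[2]),
    area_px = length(idx)
  ), class = "EllipseFit")
}

#' Elliptical form factor
#'
#' The ratio of the major to the minor axis of a fitted ellipse; 1 for a
#' circle, larger for more eccentric cell spreading.
#'
#' @param fit an `EllipseFit` from [fit_ellipse()].
#' @export
elliptical_form_factor <- function(fit) {
  stopifnot(inherits(fit, "EllipseFit"))
  fit$major_axis_length / fit$minor_axis_length
}

#' @export
print.EllipseFit <- function(x, ...) {
  cat(sprintf("EllipseFit: %d px, axes %.1f x %.1f px, orientation %.1f deg, form factor %.2f\n",
              x$area_px, x$major_axis_length, x$minor_axis_length,
              x$orientation * 180 / pi, x$form_factor))
  invisible(x)
}
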