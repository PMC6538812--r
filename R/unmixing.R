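## Image conventions: images are numeric matrices indexed [row, column]; the
## reported pixel coordinates in masks/labels are 0-based row-major indices.

#' Disc-shaped median filter
#'
#' Replaces each pixel with the median of the values inside a disc of the
#' given radius (truncated at the image border). Used to suppress compact
#' bright objects (cells) so that only the slowly varying background
#' remains.
#'
#' @param img Numeric matrix.
#' @param radius Disc radius in pixels.
#' @return Filtered matrix of the same shape.
#' @export
median_disc <- function(img, radius) {
  stopifnot(is.matrix(img), radius >= 0)
  if (radius == 0) return(img)
  r <- as.integer(ceiling(radius))
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  nr <- nrow(img); nc <- ncol(img)
  n_off <- nrow(off)
  stacked <- matrix(NA_real_, nr * nc, n_off)
  for (k in seq_len(n_off)) {
    dr <- off$dr[k]; dc <- off$dc[k]
    shifted <- matrix(NA_real_, nr, nc)
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    shifted[rs, cs] <- img[rs + dr, cs + dc]
    stacked[, k] <- shifted
  }
  matrix(apply(stacked, 1, stats::median, na.rm = TRUE), nr, nc)
}

#' Estimate the illumination field of a time-lapse series
#'
#' Fluorescence images follow the forward model `I = L (C + b)`: a smooth
#' multiplicative vignetting field `L` times cell signal `C` plus a flat
#' background `b`. The field is recovered by (1) median-disc filtering each
#' frame to suppress cell signal, (2) averaging the background-only frames
#' over all timepoints, (3) fitting a low-order smooth surface (2-D
#' polynomial, default degree 2) to the average, and (4) normalizing the
#' surface to a maximum of 1.
#'
#' @param images A list of numeric matrices (one per timepoint) or a single
#'   matrix.
#' @param radius Median-disc radius in pixels. Default 50 (full-frame
#'   microscopy scale; use a radius larger than the cell diameter).
#' @param degree Polynomial surface degree. Default 2.
#' @return An `illumination_field`: matrix with values in `(0, 1]`,
#'   `max == 1`.
#' @export
estimate_illumination <- function(images, radius = 50, degree = 2) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1L, all(vapply(images, is.matrix, logical(1))))
  dims <- dim(images[[1]])
  if (!all(vapply(images, function(x) identical(dim(x), dims), logical(1))))
    stop("all images must share one shape", call. = FALSE)
  if (all(vapply(images, function(x) all(x == 0), logical(1))))
    stop("all-zero images", call. = FALSE)

  bg <- Reduce(`+`, lapply(images, median_disc, radius = radius)) /
    length(images)

  nr <- dims[1]; nc <- dims[2]
  px <- expand.grid(row = seq_len(nr) - 1, col = seq_len(nc) - 1)
  ## raw 2-D polynomial design, scaled coordinates for conditioning
  x <- px$col / max(nc - 1, 1); y <- px$row / max(nr - 1, 1)
  X <- do.call(cbind, lapply(0:degree, function(i)
    vapply(0:(degree - i), function(j) x^i * y^j, numeric(length(x)))))
  fit <- stats::lm.fit(X, as.vector(bg))
  surf <- matrix(X %*% ifelse(is.na(fit$coefficients), 0,
                              fit$coefficients), nr, nc)
  mx <- max(surf)
  if (mx <= 0) stop("degenerate illumination surface", call. = FALSE)
  L <- surf / mx
  if (any(L <= 0)) {
    warning("fitted surface non-positive in places; clamped")
    L[L <= 0] <- min(L[L > 0])
  }
  structure(L, class = c("illumination_field", "matrix", "array"))
}

#' Correct an image for uneven illumination
#'
#' Elementwise division by the illumination field: inverts the forward model
#' `I = L (C + b)` to recover `C + b`.
#'
#' @param image Numeric matrix.
#' @param L Illumination field (same shape, strictly positive).
#' @return Corrected matrix.
#' @export
correct_illumination <- function(image, L) {
  if (!identical(dim(image), dim(L)))
    stop("image and illumination field shapes differ", call. = FALSE)
  if (any(L <= 0)) stop("illumination field has non-positive entries",
                        call. = FALSE)
  unclass(image / L)
}

#' Build the spectral mixing matrix from control images
#'
#' Each control sample contains a single fluorophore imaged under all
#' filter settings. The row of the mixing matrix `T` for that fluorophore is
#' its mean intensity per channel, normalized so that the brightest channel
#' (the "true image") equals 1. Rows are assembled in the order of the
#' `controls` list; the standard set is H2B (nuclear label), MDR (GFP-tagged
#' efflux pump), Dox (doxorubicin autofluorescence) and background (medium).
#'
#' @param controls Named list, one entry per fluorophore; each entry is
#'   either a numeric vector of per-channel mean intensities or a list of
#'   per-channel images (means are taken).
#' @return A `mixing_matrix`: rows = fluorophores, columns = channels,
#'   entries in `[0, 1]`, one 1 per row. Rank deficiency (spectrally
#'   indistinguishable fluorophores) is reported with a warning and a
#'   `rank_deficient` attribute.
#' @export
build_mixing_matrix <- function(controls) {
  stopifnot(is.list(controls), length(controls) >= 1L)
  rows <- lapply(controls, function(ctl) {
    v <- if (is.list(ctl)) vapply(ctl, function(im) mean(as.numeric(im)),
                                  numeric(1))
         else as.numeric(ctl)
    if (all(v == 0)) stop("control with all-zero signal", call. = FALSE)
    v / max(v)
  })
  nch <- unique(vapply(rows, length, integer(1)))
  if (length(nch) != 1L)
    stop("controls disagree on the number of channels", call. = FALSE)
  Tm <- do.call(rbind, rows)
  rownames(Tm) <- names(controls)
  colnames(Tm) <- paste0("I", seq_len(ncol(Tm)))
  rk <- qr(Tm)$rank
  deficient <- rk < nrow(Tm)
  if (deficient)
    warning("mixing matrix is rank deficient (rank ", rk, " < ", nrow(Tm),
            "): fluorophore spectra are not distinguishable")
  structure(Tm, class = c("mixing_matrix", "matrix", "array"),
            rank_deficient = deficient)
}

#' Linear spectral unmixing of channel means
#'
#' Solves the overdetermined linear system `S %*% T = I` for the fluorophore
#' signals `S` by QR least squares, one solve per region (row of `I`). With
#' 4 fluorophores and 5 channels the residual norm is a consistency
#' diagnostic: it is zero (to solver precision) exactly when the data lie in
#' the row space of `T`.
#'
#' @param region_means Numeric vector of per-channel means for one region,
#'   or a matrix with one region per row (e.g. intracellular and
#'   extracellular compartments). Per-pixel unmixing is the same call with
#'   one row per pixel: reshape each channel image to a column and bind
#'   them into an `n_pixels x n_channels` matrix.
#' @param T_mix A `mixing_matrix` (or plain fluorophore x channel matrix).
#' @return Matrix of unmixed signals, one region per row, one column per
#'   fluorophore, with attribute `"residual_norm"` per region.
#' @export
unmix_signals <- function(region_means, T_mix) {
  if (is.null(dim(region_means)))
    region_means <- matrix(region_means, nrow = 1)
  if (ncol(region_means) != ncol(T_mix))
    stop("channel count mismatch between data and mixing matrix",
         call. = FALSE)
  if (any(!is.finite(region_means)))
    stop("region means must be finite", call. = FALSE)
  if (qr(T_mix)$rank < nrow(T_mix))
    stop("rank-deficient mixing matrix; cannot unmix", call. = FALSE)
  A <- t(unclass(T_mix))                     # channels x fluorophores
  dec <- qr(A)
  S <- t(qr.coef(dec, t(region_means)))
  fitted <- S %*% unclass(T_mix)
  rn <- sqrt(rowSums((region_means - fitted)^2))
  colnames(S) <- rownames(T_mix)
  attr(S, "residual_norm") <- rn
  S
}

#' Doxorubicin signal calibration
#'
#' The unmixed doxorubicin signal is linear in concentration:
#' `S_Dox = a * [Dox] + b`. `calibrate_signal` fits the line to standards of
#' known concentration; `signal_to_concentration` inverts it, clipping
#' negative concentrations to zero (with a `clipped` attribute flagging
#' which entries were clipped).
#'
#' @param conc_nM Known standard concentrations, nM (at least 2 distinct).
#' @param signal Measured doxorubicin signals at the standards.
#' @return `calibrate_signal`: a `calibration_line` with slope `a`
#'   (signal per nM, positive) and intercept `b`.
#' @export
calibrate_signal <- function(conc_nM, signal) {
  if (length(unique(conc_nM)) < 2L)
    stop("need at least 2 distinct standard concentrations", call. = FALSE)
  fit <- stats::lm(signal ~ conc_nM)
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  if (!is.finite(a) || a <= 0)
    stop("calibration slope must be positive", call. = FALSE)
  structure(list(a = a, b = b), class = "calibration_line")
}

#' @rdname calibrate_signal
#' @param S_Dox Unmixed doxorubicin signal(s).
#' @param cal A `calibration_line`.
#' @return `signal_to_concentration`: concentration(s) in nM, `>= 0`.
#' @export
signal_to_concentration <- function(S_Dox, cal) {
  stopifnot(inherits(cal, "calibration_line"))
  conc <- (S_Dox - cal$b) / cal$a
  clipped <- conc < 0
  conc[clipped] <- 0
  attr(conc, "clipped") <- clipped
  conc
}

#' Threshold segmentation with 8-connected component counting
#'
#' Thresholds an (illumination-corrected) image and labels connected
#' components of the binary mask with 8-connectivity (diagonal neighbors
#' join).
#'
#' @param image Numeric matrix; corrected for illumination first when `L` is
#'   supplied.
#' @param threshold Intensity threshold (`> threshold` is foreground).
#' @param L Optional illumination field applied via
#'   [correct_illumination()].
#' @return List with `mask` (logical matrix), `labels` (integer matrix, 0 =
#'   background) and `count` (number of objects).
#' @export
segment_cells <- function(image, threshold, L = NULL) {
  stopifnot(is.matrix(image), threshold >= 0)
  if (!is.null(L)) image <- correct_illumination(image, L)
  mask <- image > threshold
  labels <- label_components(mask)
  list(mask = mask, labels = labels, count = max(labels))
}

## 8-connected component labeling by iterative flood fill
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  nxt <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cur - 1L) %% nr) + 1L
      cl <- ((cur - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        j <- (cc - 1L) * nr + rr
        if (mask[j] && labels[j] == 0L) {
          labels[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

#' Unmix a spectral stack into compartment doxorubicin concentrations
#'
#' Convenience wrapper over the full region-mean pipeline for one timepoint:
#' correct each channel for illumination, average channel intensities over
#' the intracellular mask and the extracellular complement (minus a guard
#' band around cells to avoid edge bleed), unmix both 5-vectors, and convert
#' the doxorubicin signals to concentration.
#'
#' @param stack List of channel images (one per filter setting).
#' @param T_mix A `mixing_matrix`.
#' @param L Illumination field (use a matrix of ones to skip correction).
#' @param mask Logical intracellular mask (e.g. from [segment_cells()]).
#' @param cal A `calibration_line`.
#' @param guard_px Guard band width in pixels excluded from the
#'   extracellular region around the mask. Default 2.
#' @return List with `conc` (named: intracellular, extracellular nM),
#'   `signals` (unmixed signal matrix) and `residual_norm`.
#' @export
unmix_stack <- function(stack, T_mix, L, mask, cal, guard_px = 2L) {
  stopifnot(is.list(stack), length(stack) == ncol(T_mix))
  corrected <- lapply(stack, correct_illumination, L = L)
  dil <- dilate_mask(mask, guard_px)
  extra <- !dil
  if (!any(mask) || !any(extra))
    stop("segmentation leaves an empty compartment", call. = FALSE)
  means <- rbind(
    intracellular = vapply(corrected, function(im) mean(im[mask]), numeric(1)),
    extracellular = vapply(corrected, function(im) mean(im[extra]), numeric(1)))
  S <- unmix_signals(means, T_mix)
  dox <- S[, "Dox"]
  conc <- signal_to_concentration(dox, cal)
  list(conc = stats::setNames(as.numeric(conc), rownames(means)),
       signals = S, residual_norm = attr(S, "residual_norm"))
}

## binary dilation with a (2k+1)-square structuring element
dilate_mask <- function(mask, k) {
  k <- as.integer(k)
  if (k <= 0) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (dr in -k:k) for (dc in -k:k) {
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    out[rs, cs] <- out[rs, cs] | mask[rs + dr, cs + dc]
  }
  out
}
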