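#' Render a synthetic two-channel microscopy field
#'
#' Draws each nucleus record as a disk (DAPI channel: nuclear stain; GFP
#' channel: disk pixels set to the record's median intensity, so the median
#' over the true mask reproduces `median_gfp` exactly) on a flat background,
#' placed by dart throwing without overlap. This module exists to exercise
#' the table-level pipeline from pixels; it makes no attempt at realistic
#' microscopy artifacts.
#'
#' Intensities are clipped to the 16-bit range `[0, 65535]` with a warning on
#' saturation.
#'
#' @param records tibble with columns `median_gfp` and `area_px` (e.g. from
#'   [simulate_well()]); zero rows give a background-only field.
#' @param image_shape `c(height, width)` in pixels.
#' @param seed optional integer seed for placement and noise.
#' @param bg_dapi,bg_gfp background levels of the two channels.
#' @param dapi_level in-nucleus DAPI intensity.
#' @param noise_sd SD of additive Gaussian background noise (0 = noiseless).
#' @param max_tries dart-throwing attempts per nucleus before giving up.
#' @return an object of class `synthetic_field`: list with integer matrices
#'   `dapi`, `gfp`, label matrix `truth_mask` (0 = background, k = nucleus
#'   k), and `placement` (tibble of centers and radii).
#' @export
render_field <- function(records, image_shape = c(512, 512), seed = NULL,
                         bg_dapi = 200, bg_gfp = 100, dapi_level = 20000,
                         noise_sd = 0, max_tries = 500) {
  stopifnot(is.data.frame(records), length(image_shape) == 2)
  if (nrow(records) > 0) {
    stopifnot(all(c("median_gfp", "area_px") %in% names(records)))
  }
  if (!is.null(seed)) set.seed(seed)
  h <- image_shape[1]; w <- image_shape[2]
  dapi <- matrix(bg_dapi, h, w)
  gfp <- matrix(bg_gfp, h, w)
  mask <- matrix(0L, h, w)
  n <- nrow(records)
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  for (k in seq_len(n)) {
    r <- max(2, round(sqrt(records$area_px[k] / pi)))
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cy <- stats::runif(1, r + 1, h - r)
      cx <- stats::runif(1, r + 1, w - r)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >
              radii + r + 2)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf("could not place all nuclei: placed %d of %d at shape %dx%d",
                   k - 1L, n, h, w), call. = FALSE)
    }
    centers <- rbind(centers, c(cy, cx))
    radii <- c(radii, r)
    yy <- pmax(1, floor(cy - r)):pmin(h, ceiling(cy + r))
    xx <- pmax(1, floor(cx - r)):pmin(w, ceiling(cx + r))
    for (y in yy) {
      xs <- xx[(xx - cx)^2 + (y - cy)^2 <= r^2]
      if (length(xs) > 0) {
        dapi[y, xs] <- dapi_level
        gfp[y, xs] <- records$median_gfp[k]
        mask[y, xs] <- k
      }
    }
  }
  if (noise_sd > 0) {
    dapi <- dapi + stats::rnorm(length(dapi), 0, noise_sd)
    gfp <- gfp + stats::rnorm(length(gfp), 0, noise_sd)
  }
  if (any(dapi > 65535) || any(gfp > 65535)) {
    warning("intensities clipped at the 16-bit ceiling (65535)")
  }
  dapi <- matrix(as.integer(pmin(pmax(round(dapi), 0), 65535)), h, w)
  gfp <- matrix(as.integer(pmin(pmax(round(gfp), 0), 65535)), h, w)
  placement <- tibble::tibble(
    nucleus = seq_len(n),
    center_y = if (n > 0) centers[, 1] else numeric(0),
    center_x = if (n > 0) centers[, 2] else numeric(0),
    radius_px = radii)
  structure(list(dapi = dapi, gfp = gfp, truth_mask = mask,
                 placement = placement),
            class = "synthetic_field")
}

#' Segment nuclei and measure per-nucleus intensities
#'
#' A deliberately simple segmentation stand-in: global Otsu threshold on the
#' DAPI channel, connected-component labelling, and a minimum-area filter;
#' each component is measured by its median GFP intensity and pixel area.
#' Fidelity is only intended for well-separated nuclei on clean backgrounds.
#'
#' @param field a `synthetic_field`, or any list with `dapi` and `gfp`
#'   matrices (the truth mask, if present, is ignored).
#' @param min_area minimum component area in pixels (default 20).
#' @return tibble with `nucleus_id`, `median_gfp`, `area_px`, one row per
#'   retained component; the label matrix is attached as attribute `"mask"`.
#'   A blank DAPI channel yields zero rows with a warning.
#' @export
segment_and_measure <- function(field, min_area = 20) {
  stopifnot(is.list(field), !is.null(field$dapi), !is.null(field$gfp))
  dapi <- field$dapi; gfp <- field$gfp
  stopifnot(all(dim(dapi) == dim(gfp)))
  if (max(dapi) == min(dapi)) {
    warning("blank DAPI channel: no nuclei segmented")
    out <- tibble::tibble(nucleus_id = integer(), median_gfp = numeric(),
                          area_px = numeric())
    attr(out, "mask") <- matrix(0L, nrow(dapi), ncol(dapi))
    return(out)
  }
  img <- EBImage::Image(dapi / 65535)
  thr <- EBImage::otsu(img, range = c(0, 1))
  labels <- EBImage::bwlabel(img > thr)
  lab <- EBImage::imageData(labels)
  keep <- which(tabulate(lab[lab > 0]) >= min_area)
  vals <- split(gfp[lab > 0], lab[lab > 0])
  areas <- vapply(vals, length, integer(1))
  meds <- vapply(vals, stats::median, numeric(1))
  sel <- as.integer(names(vals)) %in% keep
  out <- tibble::tibble(
    nucleus_id = seq_len(sum(sel)),
    median_gfp = unname(meds[sel]),
    area_px = as.numeric(unname(areas[sel])))
  relab <- matrix(0L, nrow(lab), ncol(lab))
  old <- as.integer(names(vals))[sel]
  for (i in seq_along(old)) relab[lab == old[i]] <- i
  attr(out, "mask") <- relab
  out
}

#' Write / read a synthetic field as multi-page TIFF
#'
#' The two channels are stored as one 16-bit multi-page TIFF (page 1 DAPI,
#' page 2 GFP); the truth mask, when present, goes to a sibling
#' `*_mask.tiff` as 16-bit labels.
#'
#' @param field a `synthetic_field`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "synthetic_field"))
  tiff::writeTIFF(list(field$dapi / 65535, field$gfp / 65535), path,
                  bits.per.sample = 16)
  if (!is.null(field$truth_mask)) {
    tiff::writeTIFF(field$truth_mask / 65535,
                    sub("\\.tiff?$", "_mask.tif", path),
                    bits.per.sample = 16)
  }
  invisible(path)
}

#' @rdname write_field_tiff
#' @param with_mask also read the sibling mask file if it exists.
#' @export
read_field_tiff <- function(path, with_mask = TRUE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) >= 2)
  to_int <- function(m) matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  mask_path <- sub("\\.tiff?$", "_mask.tif", path)
  mask <- NULL
  if (with_mask && file.exists(mask_path)) {
    mask <- to_int(tiff::readTIFF(mask_path))
  }
  structure(list(dapi = to_int(pages[[1]]), gfp = to_int(pages[[2]]),
                 truth_mask = mask, placement = NULL),
            class = "synthetic_field")
}
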