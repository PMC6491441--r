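#' Render a molecule list into a localization image
#'
#' Re-builds a super-resolution localization image from a molecule list,
#' the first step of the outlining technique: membrane/periplasm-marker
#' localizations are rendered on a fine grid (default 32 nm pixels, i.e.
#' a 40960 nm field becomes a 1280 x 1280 image), then binarized and
#' segmented.
#'
#' In `"counts"` mode each molecule adds 1 to the pixel containing it
#' (half-open pixel intervals `[k*px, (k+1)*px)`), so the grid total
#' equals the number of in-field molecules. In `"gaussian"` mode each
#' molecule adds a unit-integral isotropic Gaussian kernel sampled on the
#' grid; this is a display mode only and is never used for
#' quantification. Molecules outside the field extent are dropped with a
#' warning.
#'
#' @param mols Molecule tibble with `x_nm`, `y_nm`.
#' @param pixel_nm Rendering pixel size in nm (> 0), default 32.
#' @param mode `"counts"` (default) or `"gaussian"`.
#' @param sigma_nm Kernel sigma for gaussian mode, default 20 nm
#'   (a typical PALM localization precision).
#' @param extent_nm Field extent (width, height) in nm; defaults to the
#'   molecule list's `extent_nm` attribute, else 40960 x 40960.
#' @return An object of class `loc_image`: list with `counts` (matrix
#'   indexed `[ix, iy]`, x = first index), `pixel_nm`, `origin_nm`,
#'   `extent_nm`, `n_rendered`.
#' @export
render_localization_image <- function(mols, pixel_nm = 32,
                                      mode = c("counts", "gaussian"),
                                      sigma_nm = 20, extent_nm = NULL) {
  mode <- match.arg(mode)
  stopifnot(pixel_nm > 0)
  if (mode == "gaussian") stopifnot(sigma_nm > 0)
  extent_nm <- ml_extent(mols, extent_nm)
  nx <- as.integer(ceiling(extent_nm[1] / pixel_nm))
  ny <- as.integer(ceiling(extent_nm[2] / pixel_nm))
  counts <- matrix(0, nx, ny)

  x <- mols$x_nm; y <- mols$y_nm
  infield <- x >= 0 & x < extent_nm[1] & y >= 0 & y < extent_nm[2]
  if (any(!infield)) {
    warn(paste0("render_localization_image: dropping ", sum(!infield),
                " molecules outside the field extent"))
  }
  x <- x[infield]; y <- y[infield]

  if (length(x)) {
    ix <- pmin(floor(x / pixel_nm) + 1L, nx)
    iy <- pmin(floor(y / pixel_nm) + 1L, ny)
    if (mode == "counts") {
      idx <- (iy - 1L) * nx + ix
      tab <- tabulate(idx, nbins = nx * ny)
      counts <- matrix(tab, nx, ny)
    } else {
      r <- max(1L, ceiling(4 * sigma_nm / pixel_nm))
      off <- seq(-r, r)
      for (k in seq_along(x)) {
        gx <- ix[k] + off; gy <- iy[k] + off
        okx <- gx >= 1 & gx <= nx; oky <- gy >= 1 & gy <= ny
        cx <- (gx[okx] - 0.5) * pixel_nm
        cy <- (gy[oky] - 0.5) * pixel_nm
        kx <- exp(-(cx - x[k])^2 / (2 * sigma_nm^2))
        ky <- exp(-(cy - y[k])^2 / (2 * sigma_nm^2))
        kern <- outer(kx, ky)
        s <- sum(kern)
        if (s > 0) {
          counts[gx[okx], gy[oky]] <- counts[gx[okx], gy[oky]] + kern / s
        }
      }
    }
  }

  structure(list(counts = counts, pixel_nm = pixel_nm,
                 origin_nm = c(0, 0), extent_nm = extent_nm,
                 n_rendered = length(x)),
            class = "loc_image")
}

#' @export
print.loc_image <- function(x, ...) {
  cat("<loc_image> ", nrow(x$counts), " x ", ncol(x$counts),
      " px @ ", x$pixel_nm, " nm, total signal ", signif(sum(x$counts), 6),
      "\n", sep = "")
  invisible(x)
}

#' Binarize a localization image
#'
#' Thresholds a localization image into a binary cell mask. The default
#' `method = "count"` keeps every pixel onto which at least `min_count`
#' molecules were rendered: a localization-count image is a Poisson
#' sample of the underlying structure, so any rendered localization is
#' evidence of signal, and spurious isolated pixels are removed later by
#' the morphology and component-area filters. `method = "otsu"` computes
#' the threshold by Otsu's method on the log1p-transformed nonzero pixel
#' values (localization images are sparse with heavy-tailed counts, so
#' Otsu on the raw histogram would be dominated by the empty
#' background); it suits data with appreciable nonspecific background
#' but can over-threshold clean membrane rings into open curves.
#' Pixels with raw count below `min_count` are forced off before
#' morphological closing (disk of radius `closing_radius_nm`), which
#' bridges small gaps in the rendered membrane ring.
#'
#' @param img A `loc_image` from [render_localization_image()].
#' @param method `"count"` (default), `"otsu"` or `"fixed"`.
#' @param threshold Threshold for `method = "fixed"`; pixels strictly
#'   above it become foreground.
#' @param closing_radius_nm Radius of the closing disk in nm (default 64;
#'   0 disables closing).
#' @param min_count Minimum raw pixel count to be eligible as foreground
#'   (default 1).
#' @return Object of class `loc_mask`: list with logical `mask` (same
#'   shape as the image), `pixel_nm`, `origin_nm`, `threshold`.
#' @export
binarize <- function(img, method = c("count", "otsu", "fixed"),
                     threshold = NULL, closing_radius_nm = 64,
                     min_count = 1) {
  method <- match.arg(method)
  counts <- img$counts
  if (all(counts <= 0)) {
    warn("binarize: all-zero image, returning all-false mask")
    return(structure(list(mask = matrix(FALSE, nrow(counts), ncol(counts)),
                          pixel_nm = img$pixel_nm, origin_nm = img$origin_nm,
                          threshold = Inf),
                     class = "loc_mask"))
  }
  if (method == "count") {
    threshold <- 0
  } else if (method == "otsu") {
    nz <- counts[counts > 0]
    lg <- log1p(nz)
    mx <- max(lg)
    th_log <- if (length(unique(lg)) < 2L) {
      mx / 2
    } else {
      EBImage::otsu(EBImage::Image(matrix(lg / mx, ncol = 1)), range = c(0, 1)) * mx
    }
    threshold <- expm1(th_log)
  } else if (is.null(threshold)) {
    abort("binarize: method 'fixed' needs a threshold")
  }
  mask <- counts > threshold
  mask[counts < min_count] <- FALSE
  if (closing_radius_nm > 0) {
    r_px <- floor(closing_radius_nm / img$pixel_nm)
    if (r_px >= 1) {
      brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
      mask <- EBImage::closing(EBImage::Image(mask * 1), brush) > 0.5
    }
  }
  structure(list(mask = matrix(as.logical(mask), nrow(counts), ncol(counts)),
                 pixel_nm = img$pixel_nm, origin_nm = img$origin_nm,
                 threshold = threshold),
            class = "loc_mask")
}

#' @export
print.loc_mask <- function(x, ...) {
  cat("<loc_mask> ", nrow(x$mask), " x ", ncol(x$mask), " px @ ",
      x$pixel_nm, " nm, ", sum(x$mask), " foreground px (threshold ",
      signif(x$threshold, 4), ")\n", sep = "")
  invisible(x)
}
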