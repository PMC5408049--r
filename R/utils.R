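#' Round half away from zero
#'
#' Displayed percentages and doses follow commercial-rounding convention
#' (half away from zero), not the IEC banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(76.5)   # 77
#' round_half_up(-0.5)   # -1
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Bilinear interpolation on a pixel grid.
# `img` is an (nx, ny) matrix; pixel (i, j) has physical centre
# ((i - 0.5) * pixel_mm, (j - 0.5) * pixel_mm).  NA neighbours are dropped
# and the remaining weights renormalised, so samples adjacent to a masked
# border stay finite; a sample whose four neighbours are all NA returns NA.
bilinear_interp <- function(img, x_mm, y_mm, pixel_mm) {
  nx <- nrow(img); ny <- ncol(img)
  fx <- x_mm / pixel_mm + 0.5
  fy <- y_mm / pixel_mm + 0.5
  i0 <- pmin(pmax(floor(fx), 1), nx - 1L)
  j0 <- pmin(pmax(floor(fy), 1), ny - 1L)
  wx <- pmin(pmax(fx - i0, 0), 1)
  wy <- pmin(pmax(fy - j0, 0), 1)
  v00 <- img[cbind(i0, j0)]
  v10 <- img[cbind(i0 + 1L, j0)]
  v01 <- img[cbind(i0, j0 + 1L)]
  v11 <- img[cbind(i0 + 1L, j0 + 1L)]
  w00 <- (1 - wx) * (1 - wy); w10 <- wx * (1 - wy)
  w01 <- (1 - wx) * wy;       w11 <- wx * wy
  vals <- cbind(v00, v10, v01, v11)
  wts <- cbind(w00, w10, w01, w11)
  wts[is.na(vals)] <- 0
  vals[is.na(vals)] <- 0
  tot <- rowSums(wts)
  out <- rowSums(vals * wts) / tot
  out[tot == 0] <- NA_real_
  out
}

# Physical centre coordinates (mm) of all pixels of an (nx, ny) grid.
pixel_centres <- function(nx, ny, pixel_mm) {
  list(
    x = (seq_len(nx) - 0.5) * pixel_mm,
    y = (seq_len(ny) - 0.5) * pixel_mm
  )
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
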