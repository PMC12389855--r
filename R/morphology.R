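# Refined-mask generation: threshold then morphological opening.
#
# The opening (3 erosions then 3 dilations with a solid 5x5 square) removes
# every foreground component that cannot contain a 13x13 square — in
# particular all small spurious blobs — while large contact areas survive
# essentially intact. Pixels beyond the frame border count as background.

#' Mask-refinement parameters
#'
#' @param threshold absolute pressure threshold (same unit as the frame,
#'   typically kPa), or `"otsu"` to pick the threshold from the histogram of
#'   the frame's nonzero pixels.
#' @param n_erosions,n_dilations numbers of successive erosions / dilations.
#' @param kernel odd side length (>= 3) of the solid square structuring element.
#' @return an object of class `mask_params`.
#' @export
mask_params <- function(threshold = "otsu", n_erosions = 3, n_dilations = 3,
                        kernel = 5) {
  if (!identical(threshold, "otsu") &&
      !(is.numeric(threshold) && length(threshold) == 1 && is.finite(threshold))) {
    stop_("threshold must be a finite number or \"otsu\"")
  }
  if (kernel < 3 || kernel %% 2 != 1) stop_("kernel must be odd and >= 3")
  if (n_erosions < 0 || n_dilations < 0) stop_("erosion/dilation counts must be >= 0")
  structure(list(threshold = threshold, n_erosions = as.integer(n_erosions),
                 n_dilations = as.integer(n_dilations), kernel = as.integer(kernel)),
            class = "mask_params")
}

#' Otsu threshold on the nonzero pixels of a frame
#'
#' Maximises between-class variance over a 256-bin histogram of the nonzero
#' values. Returns `Inf` for an all-zero frame so the resulting mask is empty.
#'
#' @param frame numeric matrix.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(frame) {
  v <- frame[frame > 0]
  if (length(v) == 0) return(Inf)
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  nb <- 256L
  br <- seq(r[1], r[2], length.out = nb + 1)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = nb)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(nb + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Binarize a pressure frame
#'
#' A pixel is foreground (1) iff its value is `>=` the threshold.
#'
#' @param frame numeric matrix, finite.
#' @param params a [mask_params()] object.
#' @return 0/1 matrix of the same shape.
#' @export
binarize <- function(frame, params = mask_params()) {
  stopifnot(all(is.finite(frame)))
  thr <- if (identical(params$threshold, "otsu")) otsu_threshold(frame)
         else params$threshold
  out <- (frame >= thr) * 1
  dim(out) <- dim(frame)
  out
}

# min/max filter along rows then columns: a solid-square structuring element
# is separable, so a kxk erosion is a k-long running min over rows composed
# with one over columns (and dually for dilation). pad = value outside frame.
filter_sep <- function(m, k, fun, pad) {
  r <- (k - 1L) %/% 2L
  run1 <- function(x) { # along rows (dim 1)
    acc <- x
    n <- nrow(x)
    for (o in seq_len(r)) {
      if (o >= n) {
        acc <- fun(acc, matrix(pad, n, ncol(x)))
        next
      }
      up <- rbind(x[-seq_len(o), , drop = FALSE], matrix(pad, o, ncol(x)))
      dn <- rbind(matrix(pad, o, ncol(x)), x[seq_len(n - o), , drop = FALSE])
      acc <- fun(acc, fun(up, dn))
    }
    acc
  }
  t(run1(t(run1(m))))
}

#' Morphological opening of a binary mask
#'
#' Applies `n_erosions` binary erosions followed by `n_dilations` binary
#' dilations with a solid `kernel` x `kernel` square. Outside-frame pixels are
#' background (0), so erosion shrinks the foreground at the border.
#'
#' @param mask 0/1 matrix.
#' @param params a [mask_params()] object.
#' @return 0/1 matrix.
#' @export
open_mask <- function(mask, params = mask_params()) {
  if (!is_binary(mask)) stop_("open_mask expects a binary (0/1) mask")
  m <- mask
  for (i in seq_len(params$n_erosions)) m <- filter_sep(m, params$kernel, pmin, 0)
  for (i in seq_len(params$n_dilations)) m <- filter_sep(m, params$kernel, pmax, 0)
  m
}

#' Refined foreground mask of a pressure frame
#'
#' Composition [binarize()] then [open_mask()]: thresholds the frame and
#' removes small noise blobs by opening, leaving the genuine contact areas.
#'
#' @inheritParams binarize
#' @return 0/1 matrix.
#' @export
refine <- function(frame, params = mask_params()) {
  open_mask(binarize(frame, params), params)
}

#' Label 4-connected components of a binary mask
#'
#' Two-pass flood fill used by tests and the synthetic-scene checks.
#'
#' @param mask 0/1 matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  stopifnot(is_binary(mask))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (mask[i, j] == 1 && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- matrix(c(i, j), 1)
      lab[i, j] <- cur
      while (nrow(queue) > 0) {
        p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          ni <- p[1] + d[1]; nj <- p[2] + d[2]
          if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
              mask[ni, nj] == 1 && lab[ni, nj] == 0L) {
            lab[ni, nj] <- cur
            queue <- rbind(queue, c(ni, nj))
          }
        }
      }
    }
  }
  lab
}

n_components <- function(mask) max(label_components(mask))
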