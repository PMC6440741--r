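#' Z-score a numeric vector
#'
#' Centres and scales to unit standard deviation (denominator `n - 1`).
#' Errors on zero-variance input naming the offending regressor, because a
#' constant modulator carries no information and would silently produce
#' `NaN` columns in a design matrix.
#'
#' @param x Numeric vector.
#' @param label Name used in the degenerate-regressor error message.
#' @return Numeric vector with mean 0 and sd 1.
#' @export
zscore <- function(x, label = deparse(substitute(x))) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("degenerate regressor '", label, "': zero variance, cannot z-score",
         call. = FALSE)
  }
  (x - mean(x)) / s
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Label connected components of a 3-D logical mask
#'
#' Flood-fill labelling used for cluster-extent thresholding of exceedance
#' probability maps. Connectivity is 26-neighbour by default (all voxels
#' sharing a face, edge or corner), 6-neighbour (faces only) optionally.
#'
#' @param mask Logical 3-D array.
#' @param connectivity 26 (default) or 6.
#' @return Integer array of the same dimension; 0 outside the mask,
#'   components labelled 1, 2, ... in discovery order (lowest linear index
#'   first).
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L,
            connectivity %in% c(6L, 26L))
  dm <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6L) {
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1L, ]
  }
  labels <- array(0L, dm)
  lab <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] > 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      co <- arrayInd(v, dm)
      nx <- co[1L] + offs$dx; ny <- co[2L] + offs$dy; nz <- co[3L] + offs$dz
      ok <- nx >= 1L & nx <= dm[1L] & ny >= 1L & ny <= dm[2L] & nz >= 1L & nz <= dm[3L]
      ni <- (nz[ok] - 1L) * dm[1L] * dm[2L] + (ny[ok] - 1L) * dm[1L] + nx[ok]
      ni <- ni[mask[ni] & labels[ni] == 0L]
      if (length(ni)) {
        labels[ni] <- lab
        queue <- c(queue, ni)
      }
    }
  }
  labels
}
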