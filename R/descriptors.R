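#' Geometric descriptors of a four-residue fragment
#'
#' Each overlapping four-residue window of a C-alpha trace is summarised
#' by four rigid-motion-invariant descriptors: the three "skipping"
#' distances d13, d14 and d24 (Angstrom), and the signed volume of the
#' tetrahedron built on the four C-alpha atoms (Angstrom^3).  The sign
#' of the volume comes from the scalar triple product, so mirror-image
#' fragments have identical distances but opposite volume — chirality is
#' retained.
#'
#' @param four_ca numeric `4 x 3` matrix of consecutive C-alpha
#'   coordinates in Angstrom.
#' @return named numeric vector `c(d13, d14, d24, v)`.
#' @export
#' @examples
#' helix <- make_motif("helix", 4, noise_sd = 0, seed = 1)
#' fragment_descriptors(trace_coords(helix))
fragment_descriptors <- function(four_ca) {
  four_ca <- as.matrix(four_ca)
  if (nrow(four_ca) != 4L || ncol(four_ca) != 3L) {
    abort("`four_ca` must be a 4 x 3 coordinate matrix.")
  }
  if (any(!is.finite(four_ca))) abort("coordinates must be finite.")
  a <- four_ca[2, ] - four_ca[1, ]
  b <- four_ca[3, ] - four_ca[1, ]
  d <- four_ca[4, ] - four_ca[1, ]
  v <- det(rbind(a, b, d)) / 6
  c(
    d13 = sqrt(sum(b^2)),
    d14 = sqrt(sum(d^2)),
    d24 = sqrt(sum((four_ca[4, ] - four_ca[2, ])^2)),
    v = v
  )
}

#' Descriptor matrix of a whole trace
#'
#' Applies [fragment_descriptors()] to every overlapping four-residue
#' window.  Windows spanning a chain break are returned as `NA` rows;
#' such positions are never encoded and never matched.
#'
#' @param trace a [ca_trace()] with at least four residues.
#' @return numeric `(n - 3) x 4` matrix with columns
#'   `d13`, `d14`, `d24`, `v`.
#' @export
trace_descriptors <- function(trace) {
  xyz <- trace_coords(trace)
  n <- nrow(xyz)
  if (n < 4L) abort("trace must contain at least 4 residues.")
  ok <- window_valid(trace)
  out <- matrix(NA_real_, n - 3L, 4L,
                dimnames = list(NULL, c("d13", "d14", "d24", "v")))
  for (i in which(ok)) {
    out[i, ] <- fragment_descriptors(xyz[i:(i + 3L), , drop = FALSE])
  }
  out
}
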