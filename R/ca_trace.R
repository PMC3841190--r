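#' Build a C-alpha trace
#'
#' A `ca_trace` is the minimal structural carrier used throughout the
#' package: one row per residue with its C-alpha coordinates in
#' Angstrom.  Consecutive C-alpha distances outside \[2.0, 4.5\] A are
#' treated as chain breaks; no four-residue encoding window and no
#' fragment ever spans a break.
#'
#' @param coords numeric matrix, one row per residue, three columns
#'   (x, y, z) in Angstrom.
#' @param residue_ids integer or character residue identifiers in chain
#'   order (author numbering is preserved); defaults to `1:n`.
#' @param chain_id single chain identifier.
#'
#' @return A tibble of class `ca_trace` with columns `chain`, `resid`,
#'   `x`, `y`, `z`.
#' @export
#' @examples
#' tr <- ca_trace(cbind(3.8 * (0:5), 0, 0))
#' chain_breaks(tr)
ca_trace <- function(coords, residue_ids = NULL, chain_id = "A") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || !is.numeric(coords)) {
    abort("`coords` must be a numeric matrix with 3 columns (x, y, z).")
  }
  if (anyNA(coords) || any(!is.finite(coords))) {
    abort("`coords` contains non-finite values.")
  }
  n <- nrow(coords)
  if (is.null(residue_ids)) residue_ids <- seq_len(n)
  if (length(residue_ids) != n) {
    abort("`residue_ids` must have one entry per coordinate row.")
  }
  out <- tibble(
    chain = as.character(chain_id),
    resid = residue_ids,
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  class(out) <- c("ca_trace", class(out))
  out
}

#' @export
print.ca_trace <- function(x, ...) {
  nb <- sum(chain_breaks(x))
  cat(sprintf(
    "<ca_trace> chain %s, %d residues, %d chain break%s\n",
    x$chain[1] %||% "?", nrow(x), nb, if (nb == 1) "" else "s"
  ))
  NextMethod()
}

#' Coordinate matrix of a trace
#'
#' @param trace a [ca_trace()].
#' @return numeric `n x 3` matrix of C-alpha coordinates (Angstrom).
#' @export
trace_coords <- function(trace) {
  unname(cbind(trace$x, trace$y, trace$z))
}

#' Chain-break flags
#'
#' Flags the gap after each residue whose distance to the next C-alpha
#' falls outside \[2.0, 4.5\] Angstrom.
#'
#' @param trace a [ca_trace()].
#' @return logical vector of length `n - 1`; element `i` is `TRUE` when
#'   the bond between residues `i` and `i + 1` is a break.
#' @export
chain_breaks <- function(trace) {
  xyz <- trace_coords(trace)
  n <- nrow(xyz)
  if (n < 2L) return(logical(0))
  d <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  d < 2.0 | d > 4.5
}

# TRUE for each 4-residue window (N - 3 of them) that does not span a break
window_valid <- function(trace) {
  n <- nrow(trace)
  if (n < 4L) return(logical(0))
  br <- chain_breaks(trace)
  vapply(seq_len(n - 3L), function(i) !any(br[i:(i + 2L)]), logical(1))
}

# contiguous break-free segments as (start, end) residue indices
trace_segments <- function(trace) {
  n <- nrow(trace)
  br <- chain_breaks(trace)
  bounds <- c(0L, which(br), n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  keep <- ends - starts + 1L >= 1L
  tibble(start = starts[keep], end = ends[keep])
}

#' Read a C-alpha trace from a PDB or mmCIF file
#'
#' Keeps the first model of multi-model files and, when alternate
#' locations are present, the highest-occupancy alternate of each
#' residue.  Requires the bio3d package.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param chain chain identifier to extract; defaults to the first
#'   chain found.
#' @return a [ca_trace()].
#' @export
read_ca_trace <- function(path, chain = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("read_ca_trace() requires the 'bio3d' package.")
  }
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    bio3d::read.cif(path, multi = FALSE, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  }
  at <- pdb$atom
  at <- at[at$elety == "CA" & !is.na(at$x), , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) abort(sprintf("no C-alpha atoms for chain '%s'.", chain))
  # resolve altlocs by occupancy, then keep chain order
  at$o[is.na(at$o)] <- 1
  at <- at[order(at$resno, -at$o), , drop = FALSE]
  at <- at[!duplicated(at$resno), , drop = FALSE]
  at <- at[order(at$resno), , drop = FALSE]
  ca_trace(cbind(at$x, at$y, at$z), residue_ids = at$resno, chain_id = chain)
}
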