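#' Optimal-superposition C-alpha RMSD (Kabsch)
#'
#' Minimal root-mean-square deviation between two equal-size point
#' sets over proper rotations and translations.  The optimal rotation
#' comes from the SVD of the cross-covariance with the usual
#' determinant correction, so reflections are never used: a chiral
#' fragment keeps a strictly positive cRMSD to its mirror image.
#'
#' @param x,y numeric `n x 3` coordinate matrices (Angstrom), `n >= 3`.
#' @return nonnegative scalar (Angstrom); symmetric in its arguments.
#' @export
#' @examples
#' h <- trace_coords(make_motif("helix", 9, noise_sd = 0, seed = 1))
#' kabsch_crmsd(h, h + 5)  # rigid translation: 0
kabsch_crmsd <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) abort("`x` and `y` must have identical dimensions.")
  n <- nrow(x)
  if (n < 3L) abort("at least 3 points are required.")
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$v %*% t(s$u)))
  # rotate and measure residuals (numerically exact at 0, unlike the
  # singular-value identity which loses ~1e-7 to cancellation)
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((xc %*% R - yc)^2)))
}

#' Size-dependent true-positive rule
#'
#' A hit of `n` residues is a true positive when its cRMSD to the
#' query fragment is below `max(mu_n - k * sigma_n, floor)`, where
#' `mu_n` and `sigma_n` describe the background cRMSD distribution of
#' random same-size fragment pairs ([background_stats()]).  The floor
#' keeps the rule meaningful when the background is very tight.
#'
#' @param stats tibble with columns `size`, `mu`, `sigma` (Angstrom).
#' @param k background multiplier.
#' @param floor minimal cutoff (Angstrom).
#' @return tibble of class `tp_rule` with an added `cutoff` column.
#' @export
tp_rule <- function(stats, k = 2, floor = 0.5) {
  if (!all(c("size", "mu", "sigma") %in% names(stats))) {
    abort("`stats` needs columns size, mu, sigma.")
  }
  if (any(stats$mu <= 0) || any(stats$sigma < 0)) {
    abort("background mean must be positive and sd nonnegative.")
  }
  out <- as_tibble(stats)
  out$cutoff <- pmax(out$mu - k * out$sigma, floor)
  class(out) <- c("tp_rule", class(out))
  out
}

tp_cutoff <- function(rule, size) {
  i <- match(size, rule$size)
  if (anyNA(i)) abort(sprintf("no TP cutoff for fragment size %d.",
                              size[which(is.na(i))[1]]))
  rule$cutoff[i]
}

# residue-fragment starts of a given aa length that avoid chain breaks
valid_fragment_starts <- function(trace, size) {
  n <- nrow(trace)
  if (n < size) return(integer(0))
  br <- chain_breaks(trace)
  ok <- vapply(seq_len(n - size + 1L),
               function(i) !any(br[i:(i + size - 2L)]), logical(1))
  which(ok)
}

#' Background cRMSD statistics of random fragment pairs
#'
#' Draws `n_samples` uniform pairs of same-size fragments from the
#' bank per fragment size and records the mean and standard deviation
#' of their cRMSD.  These are the `mu_n`, `sigma_n` inputs of
#' [tp_rule()].
#'
#' @param bank an [sa_bank()].
#' @param sizes fragment sizes (amino acids).
#' @param n_samples pairs drawn per size.
#' @param seed integer seed.
#' @return tibble with columns `size`, `mu`, `sigma`, `n_pairs`.
#' @export
background_stats <- function(bank, sizes = 6:27, n_samples = 200L, seed = 1L) {
  frags <- purrr::map(sizes, function(sz) {
    purrr::imap_dfr(bank$trace, function(tr, i) {
      tibble(entry = i, start = valid_fragment_starts(tr, sz))
    })
  })
  names(frags) <- as.character(sizes)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_along(sizes), function(si) {
      sz <- sizes[si]
      fr <- frags[[si]]
      if (nrow(fr) < 2L) {
        abort(sprintf("bank holds fewer than 2 fragments of size %d.", sz))
      }
      i1 <- sample.int(nrow(fr), n_samples, replace = TRUE)
      i2 <- sample.int(nrow(fr), n_samples, replace = TRUE)
      vals <- vapply(seq_len(n_samples), function(j) {
        a <- fr[i1[j], ]; b <- fr[i2[j], ]
        xa <- trace_coords(bank$trace[[a$entry]])[a$start:(a$start + sz - 1L), ]
        xb <- trace_coords(bank$trace[[b$entry]])[b$start:(b$start + sz - 1L), ]
        kabsch_crmsd(xa, xb)
      }, numeric(1))
      tibble(size = sz, mu = mean(vals), sigma = sd(vals),
             n_pairs = n_samples)
    })
  })
}

#' Evaluate kept hits against the known query structure
#'
#' Labels every hit as true or false positive by superposing its bank
#' fragment onto the corresponding query fragment ([kabsch_crmsd()]
#' against the [tp_rule()] cutoff for its size), then summarises
#' precision and residue coverage.
#'
#' @param hits hit tibble (as returned by the search stages) with
#'   columns `query_start`, `size_aa` and the `coords` list-column.
#' @param query_trace the query [ca_trace()].
#' @param rule a [tp_rule()].
#' @return object of class `fragment_eval`: list with the per-hit
#'   tibble (`hits`, with `crmsd` and `tp` columns) and the scalar
#'   summaries `coverage`, `tp_coverage` (percent of query residues)
#'   and `precision` (percent of hits; `NA` when there are no hits).
#' @export
evaluate <- function(hits, query_trace, rule) {
  nq <- nrow(query_trace)
  qxyz <- trace_coords(query_trace)
  hits <- as_tibble(hits)
  if (nrow(hits)) {
    if (any(hits$query_start < 1L |
            hits$query_start + hits$size_aa - 1L > nq)) {
      abort("a hit span falls outside the query.")
    }
    hits$crmsd <- vapply(seq_len(nrow(hits)), function(i) {
      span <- hits$query_start[i]:(hits$query_start[i] + hits$size_aa[i] - 1L)
      kabsch_crmsd(hits$coords[[i]], qxyz[span, , drop = FALSE])
    }, numeric(1))
    hits$tp <- hits$crmsd < tp_cutoff(rule, hits$size_aa)
  } else {
    hits$crmsd <- numeric(0)
    hits$tp <- logical(0)
  }
  covered <- rep(FALSE, nq)
  tp_covered <- rep(FALSE, nq)
  for (i in seq_len(nrow(hits))) {
    span <- hits$query_start[i]:(hits$query_start[i] + hits$size_aa[i] - 1L)
    covered[span] <- TRUE
    if (hits$tp[i]) tp_covered[span] <- TRUE
  }
  structure(
    list(
      hits = hits,
      n_hits = nrow(hits),
      coverage = 100 * mean(covered),
      tp_coverage = 100 * mean(tp_covered),
      precision = if (nrow(hits)) 100 * mean(hits$tp) else NA_real_
    ),
    class = "fragment_eval"
  )
}

#' @export
print.fragment_eval <- function(x, ...) {
  cat(sprintf(
    "<fragment_eval> %d hits | Cov %.1f%% | TPCov %.1f%% | Prec %s\n",
    x$n_hits, x$coverage, x$tp_coverage,
    if (is.na(x$precision)) "NA" else sprintf("%.1f%%", x$precision)
  ))
  invisible(x)
}

#' @describeIn evaluate per-hit tibble with cRMSD and TP labels.
#' @param x a `fragment_eval`.
#' @param ... unused.
#' @export
tidy.fragment_eval <- function(x, ...) {
  dplyr::select(x$hits, -dplyr::any_of("coords"))
}

#' @describeIn evaluate one-row summary (Cov / TPCov / Prec, percent).
#' @export
glance.fragment_eval <- function(x, ...) {
  tibble(
    n_hits = x$n_hits,
    coverage = x$coverage,
    tp_coverage = x$tp_coverage,
    precision = x$precision
  )
}
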