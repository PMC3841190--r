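#' Expected-precision filtering configuration
#'
#' Two-threshold rule on the calibrated expected precision: candidates
#' at or above `upper` are always kept, candidates below `lower` are
#' always discarded, and the mid-band is kept greedily only where it
#' adds query coverage.  The `"strict"` preset (0.99 / 0.82) suits
#' compact low-redundancy banks; `"broad"` (0.995 / 0.65) trades
#' precision for coverage on larger, more redundant banks.
#'
#' @param preset `"strict"` or `"broad"`.
#' @param upper,lower override the preset thresholds (0 < lower <
#'   upper <= 1).
#' @param min_grid_support minimal number of calibration clusters for
#'   a precision-grid cell to be considered defined.
#' @param fallback expected precision assigned to candidates falling
#'   in undefined grid cells; the default `lower - 1e-6` treats them
#'   as unreliable (discarded).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(preset = c("strict", "broad"),
                          upper = NULL, lower = NULL,
                          min_grid_support = 10L, fallback = NULL) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    strict = c(upper = 0.99, lower = 0.82),
    broad = c(upper = 0.995, lower = 0.65)
  )
  upper <- upper %||% defaults[["upper"]]
  lower <- lower %||% defaults[["lower"]]
  if (!(0 < lower && lower < upper && upper <= 1)) {
    abort("need 0 < lower < upper <= 1.")
  }
  structure(
    list(upper = upper, lower = lower,
         min_grid_support = as.integer(min_grid_support),
         fallback = fallback %||% (lower - 1e-6)),
    class = "filter_config"
  )
}

#' Calibrate per-size MJS acceptance thresholds
#'
#' For each fragment size, sweeps candidate thresholds on a 0.001 MJS
#' grid and returns the largest threshold `t` such that the precision
#' among scored pairs with `mjs <= t` stays at or above
#' `precision_target` (default 0.95).  Pairs are labeled true/false
#' positive with the [tp_rule()].  Sizes with too few pairs, or where
#' no threshold reaches the target, fall back to linear interpolation
#' between neighbouring sizes.
#'
#' @param scored_pairs tibble with columns `size`, `mjs`, `crmsd` —
#'   e.g. from [calibration_pairs()].
#' @param rule a [tp_rule()].
#' @param precision_target precision the threshold must guarantee.
#' @param sizes fragment sizes the threshold map must cover; defaults
#'   to the sizes present in `scored_pairs`.  Sizes without pairs are
#'   interpolated like under-supported ones.
#' @param bin MJS grid step.
#' @param min_pairs minimal pairs per size for a direct estimate.
#' @return tibble with columns `size`, `threshold`, `n_pairs`,
#'   `precision_at_threshold`, `interpolated`.
#' @export
calibrate_mjs_thresholds <- function(scored_pairs, rule,
                                     precision_target = 0.95,
                                     sizes = NULL,
                                     bin = 0.001, min_pairs = 50L) {
  sizes <- sort(unique(c(sizes, scored_pairs$size)))
  res <- purrr::map_dfr(sizes, function(sz) {
    pr <- scored_pairs[scored_pairs$size == sz, , drop = FALSE]
    tp <- pr$crmsd < tp_cutoff(rule, sz)
    if (nrow(pr) < min_pairs || !any(tp)) {
      return(tibble(size = sz, threshold = NA_real_, n_pairs = nrow(pr),
                    precision_at_threshold = NA_real_))
    }
    # index j corresponds to threshold t = j * bin, covering bins 0..j-1
    b <- pmin(floor(pr$mjs / bin), round(1 / bin))
    nb <- max(b) + 1L
    ntot <- cumsum(tabulate(b + 1L, nbins = nb))
    ntp <- cumsum(tabulate(b[tp] + 1L, nbins = nb))
    prec <- ifelse(ntot > 0, ntp / ntot, NA_real_)
    ok <- which(!is.na(prec) & prec >= precision_target)
    if (!length(ok)) {
      return(tibble(size = sz, threshold = NA_real_, n_pairs = nrow(pr),
                    precision_at_threshold = NA_real_))
    }
    g <- max(ok)                       # grid index, threshold = g * bin
    tibble(size = sz, threshold = g * bin, n_pairs = nrow(pr),
           precision_at_threshold = prec[g])
  })
  res$interpolated <- is.na(res$threshold)
  if (any(res$interpolated)) {
    if (all(is.na(res$threshold))) {
      abort("no fragment size has enough labeled pairs to calibrate.")
    }
    known <- which(!res$interpolated)
    filled <- if (length(known) == 1L) {
      rep(res$threshold[known], nrow(res))
    } else {
      stats::approx(res$size[known], res$threshold[known],
                    xout = res$size, rule = 2)$y
    }
    res$threshold[res$interpolated] <- filled[res$interpolated]
  }
  res
}

#' Calibrate the (MJS, W) expected-precision grid
#'
#' For each fragment size, bins the calibration clusters by the MJS of
#' their representative (steps of `bin`) and by their weight (steps of
#' 1), and stores in every cell `(x, y)` the cumulative observed
#' precision over all clusters with `mjs <= x` and `weight >= y`.
#' Cells supported by fewer than `min_support` clusters are
#' undefined.  The value served by [expected_precision()] is the
#' isotonic envelope of the raw cumulative precision (never increasing
#' with MJS, never decreasing with W); [tidy()] exposes both.
#'
#' @param clusters tibble with columns `size`, `mjs`, `weight`,
#'   `is_tp` — e.g. from [calibration_clusters()].
#' @param min_support minimal clusters per defined cell.
#' @param bin MJS grid step.
#' @return object of class `precision_grid`.
#' @export
calibrate_precision_grid <- function(clusters, min_support = 10L,
                                     bin = 0.001) {
  per_size <- split(as_tibble(clusters), clusters$size)
  grids <- purrr::map(per_size, function(cl) {
    b <- pmin(floor(cl$mjs / bin), round(1 / bin))
    bmax <- max(b)
    wmax <- max(cl$weight)
    N <- matrix(0L, bmax + 1L, wmax)
    Ntp <- matrix(0L, bmax + 1L, wmax)
    for (i in seq_len(nrow(cl))) {
      w <- min(cl$weight[i], wmax)
      N[b[i] + 1L, w] <- N[b[i] + 1L, w] + 1L
      if (cl$is_tp[i]) Ntp[b[i] + 1L, w] <- Ntp[b[i] + 1L, w] + 1L
    }
    # cumulative: mjs bins downward, weights from the top (dimension-safe
    # for single-bin and single-weight sizes)
    if (bmax >= 1L) {
      for (x in 2:(bmax + 1L)) {
        N[x, ] <- N[x, ] + N[x - 1L, ]
        Ntp[x, ] <- Ntp[x, ] + Ntp[x - 1L, ]
      }
    }
    if (wmax > 1L) {
      for (y in (wmax - 1L):1L) {
        N[, y] <- N[, y] + N[, y + 1L]
        Ntp[, y] <- Ntp[, y] + Ntp[, y + 1L]
      }
    }
    raw <- matrix(ifelse(N >= min_support, Ntp / N, NA_real_),
                  bmax + 1L, wmax)
    # isotonic envelope: the reported expected precision never increases
    # with MJS and never decreases with W (see the methods vignette)
    prec <- raw
    for (x in seq_len(bmax + 1L)[-1]) {
      prec[x, ] <- pmin(prec[x, ], prec[x - 1L, ], na.rm = FALSE)
      nafix <- is.na(prec[x, ]) & !is.na(raw[x, ])
      prec[x, nafix] <- raw[x, nafix]
    }
    if (wmax > 1L) {
      for (y in 2:wmax) {
        both <- !is.na(prec[, y]) & !is.na(prec[, y - 1L])
        prec[both, y] <- pmax(prec[both, y], prec[both, y - 1L])
      }
    }
    prec[is.na(raw)] <- NA_real_
    list(prec = prec, raw = raw, support = N, max_bin = bmax, max_w = wmax)
  })
  structure(list(sizes = grids, bin = bin,
                 min_support = as.integer(min_support)),
            class = "precision_grid")
}

#' @export
print.precision_grid <- function(x, ...) {
  cat(sprintf("<precision_grid> sizes %s | MJS step %g | min support %d\n",
              paste(range(as.integer(names(x$sizes))), collapse = "-"),
              x$bin, x$min_support))
  invisible(x)
}

#' Look up the expected precision of a cluster
#'
#' Returns the cumulative-precision cell containing `(mjs, w)`; the
#' MJS axis uses half-open bins `[x, x + bin)`.  Undefined cells (too
#' little calibration support, unseen size, or weight above anything
#' calibrated) return `fallback`.
#'
#' @param grid a [calibrate_precision_grid()] result.
#' @param size fragment size (amino acids).
#' @param mjs representative MJS in \[0, 1\].
#' @param w cluster weight (>= 1).
#' @param fallback value for undefined cells.
#' @return precision in \[0, 1\], or `fallback`.
#' @export
expected_precision <- function(grid, size, mjs, w, fallback = NA_real_) {
  if (any(mjs < 0 | mjs > 1)) abort("`mjs` must lie in [0, 1].")
  n <- max(length(size), length(mjs), length(w))
  size <- rep_len(size, n); mjs <- rep_len(mjs, n); w <- rep_len(w, n)
  vapply(seq_len(n), function(i) {
    g <- grid$sizes[[as.character(size[i])]]
    if (is.null(g)) return(fallback)
    if (w[i] < 1 || w[i] > g$max_w) return(fallback)
    b <- min(floor(mjs[i] / grid$bin), g$max_bin)
    v <- g$prec[b + 1L, w[i]]
    if (is.na(v)) fallback else v
  }, numeric(1))
}

#' @describeIn calibrate_precision_grid long-format view of the grid
#'   (one row per defined cell).
#' @param x a `precision_grid`.
#' @param ... unused.
#' @export
tidy.precision_grid <- function(x, ...) {
  purrr::imap_dfr(x$sizes, function(g, sz) {
    cells <- which(!is.na(g$prec), arr.ind = TRUE)
    if (!nrow(cells)) return(tibble())
    tibble(
      size = as.integer(sz),
      mjs_bin = (cells[, 1] - 1L) * x$bin,
      w_bin = as.integer(cells[, 2]),
      precision = g$prec[cells],
      raw_precision = g$raw[cells],
      support = g$support[cells]
    )
  })
}

#' @describeIn calibrate_precision_grid heat map of one size's grid.
#' @param object a `precision_grid`.
#' @param size fragment size to plot.
#' @export
autoplot.precision_grid <- function(object, size = NULL, ...) {
  df <- tidy(object)
  if (!is.null(size)) df <- df[df$size == size, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mjs_bin, y = .data$w_bin,
                                   fill = .data$precision)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~size) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "MJS of representative", y = "cluster weight W",
                  fill = "expected\nprecision") +
    ggplot2::theme_minimal()
}

#' Attach expected precisions to candidates
#'
#' @param candidates candidate tibble from [search_all()].
#' @param grid a [calibrate_precision_grid()] result.
#' @param cfg a [filter_config()] (supplies the fallback).
#' @return `candidates` with an `expected_precision` column.
#' @export
add_expected_precision <- function(candidates, grid, cfg = filter_config()) {
  candidates$expected_precision <- if (nrow(candidates)) {
    expected_precision(grid, candidates$size_aa, candidates$mjs,
                       candidates$weight, fallback = cfg$fallback)
  } else {
    numeric(0)
  }
  candidates
}

span_contained <- function(s1, e1, s2, e2) s1 >= s2 & e1 <= e2

#' Final redundancy elimination
#'
#' Applies the two-threshold expected-precision rule: candidates with
#' expected precision at or above the upper threshold are kept,
#' candidates below the lower threshold are discarded, and mid-band
#' candidates (sorted by descending expected precision, then ascending
#' MJS, then longer size, then span order) are kept greedily only when
#' they cover at least one query residue not yet covered.  Finally a
#' kept candidate whose query span and bank span both lie inside those
#' of another kept candidate from the same bank protein is dropped.
#'
#' @param candidates candidate tibble carrying `expected_precision`
#'   (see [add_expected_precision()]).
#' @param query_len query length in residues.
#' @param cfg a [filter_config()].
#' @return the kept subset of `candidates`.
#' @export
redundancy_eliminate <- function(candidates, query_len,
                                 cfg = filter_config()) {
  cand <- as_tibble(candidates)
  if (!"expected_precision" %in% names(cand)) {
    abort("candidates must carry `expected_precision`; see add_expected_precision().")
  }
  if (!nrow(cand)) return(cand)
  ep <- cand$expected_precision
  keep <- which(ep >= cfg$upper)
  mid <- which(ep >= cfg$lower & ep < cfg$upper)
  covered <- rep(FALSE, query_len)
  for (i in keep) covered[cand$query_start[i]:cand$query_end[i]] <- TRUE
  mid <- mid[order(-ep[mid], cand$mjs[mid], -cand$size_aa[mid],
                   cand$query_start[mid], cand$bank_id[mid],
                   cand$bank_start[mid])]
  for (i in mid) {
    span <- cand$query_start[i]:cand$query_end[i]
    if (!all(covered[span])) {
      keep <- c(keep, i)
      covered[span] <- TRUE
    }
  }
  kept <- cand[sort(keep), , drop = FALSE]
  # nested-hit removal: same bank protein, both spans contained
  if (nrow(kept) > 1L) {
    drop <- rep(FALSE, nrow(kept))
    for (a in seq_len(nrow(kept))) {
      for (b in seq_len(nrow(kept))) {
        if (a == b || drop[a]) next
        if (kept$bank_id[a] == kept$bank_id[b] &&
            kept$size_aa[a] < kept$size_aa[b] &&
            span_contained(kept$query_start[a], kept$query_end[a],
                           kept$query_start[b], kept$query_end[b]) &&
            span_contained(kept$bank_start[a], kept$bank_end[a],
                           kept$bank_start[b], kept$bank_end[b])) {
          drop[a] <- TRUE
        }
      }
    }
    kept <- kept[!drop, , drop = FALSE]
  }
  kept
}
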