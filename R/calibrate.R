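# Collectors that turn a bank plus a set of structure-known queries
# into the raw material of the two calibrations: (mjs, crmsd) scored
# pairs for the per-size thresholds, and labeled clusters for the
# expected-precision grid.

precompute_js <- function(query_profiles, bank) {
  purrr::map(query_profiles, function(qp) {
    Q <- profile_matrix(qp)
    purrr::map(bank$profile, ~ js_cross(Q, profile_matrix(.x)))
  })
}

#' Scored (MJS, cRMSD) fragment pairs for threshold calibration
#'
#' Pairs every window of every calibration query with every
#' same-length bank window, records the MJS, and measures the cRMSD of
#' a (seeded) subsample of at most `max_per_size` pairs per fragment
#' size among those with MJS at or below `mjs_cap`.  The cap discards
#' only pairs far above any plausible acceptance threshold; the
#' subsample keeps the superposition cost bounded.
#'
#' @param query_traces list of [ca_trace()] calibration queries.
#' @param query_profiles matching list of [sa_profile()]s (typically
#'   [pseudo_predict()]-degraded posteriors).
#' @param bank an [sa_bank()].
#' @param sizes fragment sizes to calibrate.
#' @param max_per_size cRMSD-labeled pairs kept per size.
#' @param mjs_cap ignore pairs scoring above this MJS.
#' @param seed integer seed for the subsample.
#' @return tibble with columns `size`, `mjs`, `crmsd`.
#' @export
calibration_pairs <- function(query_traces, query_profiles, bank,
                              sizes = 6:27, max_per_size = 2000L,
                              mjs_cap = 0.9, seed = 1L) {
  Ds <- precompute_js(query_profiles, bank)
  qxyz <- purrr::map(query_traces, trace_coords)
  bxyz <- purrr::map(bank$trace, trace_coords)
  withr::with_seed(seed, {
    purrr::map_dfr(sizes, function(size) {
      l <- size - 3L
      pool <- purrr::map_dfr(seq_along(Ds), function(q) {
        purrr::map_dfr(seq_along(Ds[[q]]), function(e) {
          S <- window_score_matrix(Ds[[q]][[e]], l)
          if (!length(S)) return(tibble())
          idx <- which(!is.na(S) & S <= mjs_cap, arr.ind = TRUE)
          if (!nrow(idx)) return(tibble())
          tibble(q = q, e = e, i = idx[, 1], j = idx[, 2], mjs = S[idx])
        })
      })
      if (!nrow(pool)) return(tibble())
      if (nrow(pool) > max_per_size) {
        pool <- pool[sample.int(nrow(pool), max_per_size), , drop = FALSE]
      }
      pool$crmsd <- vapply(seq_len(nrow(pool)), function(r) {
        kabsch_crmsd(
          qxyz[[pool$q[r]]][pool$i[r]:(pool$i[r] + size - 1L), , drop = FALSE],
          bxyz[[pool$e[r]]][pool$j[r]:(pool$j[r] + size - 1L), , drop = FALSE]
        )
      }, numeric(1))
      tibble(size = size, mjs = pool$mjs, crmsd = pool$crmsd)
    })
  })
}

#' Labeled clusters for expected-precision calibration
#'
#' Runs the hit-collection and clustering stages of the search on
#' every (position, size) cell of every calibration query, and labels
#' each resulting cluster true/false positive by superposing its
#' representative onto the known query fragment (cRMSD below the
#' [tp_rule()] cutoff for its size).
#'
#' @inheritParams calibration_pairs
#' @param cfg a [search_config()] holding the calibrated MJS
#'   thresholds.
#' @param rule a [tp_rule()].
#' @return tibble with columns `size`, `mjs`, `weight`, `is_tp`, one
#'   row per cluster.
#' @export
calibration_clusters <- function(query_traces, query_profiles, bank,
                                 cfg, rule) {
  purrr::map_dfr(seq_along(query_profiles), function(q) {
    qp <- query_profiles[[q]]
    qxyz <- trace_coords(query_traces[[q]])
    nq_res <- nrow(qp) + 3L
    Q <- profile_matrix(qp)
    banks <- purrr::map(seq_len(nrow(bank)), function(e) {
      list(D = js_cross(Q, profile_matrix(bank$profile[[e]])),
           xyz = trace_coords(bank$trace[[e]]), id = bank$id[e])
    })
    res <- list()
    for (size in cfg$min_len:min(cfg$max_len, nq_res)) {
      l <- size - 3L
      thr <- cfg$mjs_thresholds[[as.character(size)]]
      crth <- cfg$crmsd_thresholds[[as.character(size)]]
      cut <- tp_cutoff(rule, size)
      Ss <- purrr::map(banks, ~ window_score_matrix(.x$D, l))
      for (i in seq_len(nq_res - size + 1L)) {
        hits <- purrr::map_dfr(seq_along(banks), function(e) {
          S <- Ss[[e]]
          if (!ncol(S) || i > nrow(S)) return(empty_hits())
          j <- which(!is.na(S[i, ]) & S[i, ] <= thr)
          if (!length(j)) return(empty_hits())
          tibble(
            query_start = i, query_end = i + size - 1L, size_aa = size,
            bank_id = banks[[e]]$id, bank_start = j,
            bank_end = j + size - 1L, mjs = S[i, j],
            coords = purrr::map(j, ~ banks[[e]]$xyz[.x:(.x + size - 1L), ,
                                                    drop = FALSE])
          )
        })
        if (!nrow(hits)) next
        hits <- head(sort_hits(hits), cfg$top_n)
        cl <- cluster_hits(hits, crth)
        span <- i:(i + size - 1L)
        res[[length(res) + 1L]] <- tibble(
          size = size, mjs = cl$mjs, weight = cl$weight,
          is_tp = vapply(cl$coords, function(xy) {
            kabsch_crmsd(xy, qxyz[span, , drop = FALSE]) < cut
          }, logical(1))
        )
      }
    }
    bind_rows(res)
  })
}

#' Write / read candidates as TSV
#'
#' Tab-separated candidate table: `query_start`, `query_end`,
#' `size_aa`, `bank_id`, `bank_start`, `bank_end`, `mjs` (4 decimals),
#' `weight`, `expected_precision` (3 decimals or `NA`) and
#' `kept_flag`.  Coordinates are not serialized.
#'
#' @param candidates candidate tibble; a logical `kept` vector (or
#'   column `kept_flag`) marks the survivors of
#'   [redundancy_eliminate()].
#' @param path file path.
#' @param kept optional logical vector overriding `kept_flag`.
#' @return `write_candidates()` returns `path` invisibly;
#'   `read_candidates()` returns a tibble.
#' @export
write_candidates <- function(candidates, path, kept = NULL) {
  df <- as_tibble(candidates)
  col_or <- function(nm, default) {
    if (nm %in% names(df)) df[[nm]] else rep(default, nrow(df))
  }
  flag <- kept %||% col_or("kept_flag", TRUE)
  ep <- col_or("expected_precision", NA_real_)
  w <- col_or("weight", NA_integer_)
  out <- data.frame(
    query_start = df$query_start, query_end = df$query_end,
    size_aa = df$size_aa, bank_id = df$bank_id,
    bank_start = df$bank_start, bank_end = df$bank_end,
    mjs = sprintf("%.4f", df$mjs),
    weight = w,
    expected_precision = ifelse(is.na(ep), "NA", sprintf("%.3f", ep)),
    kept_flag = as.integer(flag)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$expected_precision <- suppressWarnings(as.numeric(df$expected_precision))
  df$kept_flag <- df$kept_flag == 1L
  as_tibble(df)
}
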