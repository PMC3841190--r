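#' Search configuration
#'
#' Bundles the tunables of the fragment search: the fragment size
#' range, the per-size MJS acceptance thresholds, the cap on the
#' number of hits kept per elementary search, and the per-size cRMSD
#' thresholds of the incremental clustering.
#'
#' @param min_len,max_len fragment size range in amino acids.
#' @param mjs_thresholds named numeric vector (names = fragment sizes)
#'   of MJS acceptance thresholds in (0, 1\]; the default loads the
#'   thresholds calibrated on the shipped synthetic set
#'   ([toy_mjs_thresholds()]).
#' @param top_n keep at most this many best hits per elementary search
#'   (the protocol's default is 500).
#' @param crmsd_threshold either a function of the fragment size
#'   returning a clustering cutoff in Angstrom, or a named numeric
#'   vector; the default is `0.5 + 0.04 * (n - 6)` capped at 1.5 A.
#' @return list of class `search_config`.
#' @export
search_config <- function(min_len = 6L, max_len = 27L,
                          mjs_thresholds = toy_mjs_thresholds(),
                          top_n = 500L,
                          crmsd_threshold = NULL) {
  if (min_len < 4L || max_len < min_len) abort("invalid fragment size range.")
  if (top_n < 1L) abort("`top_n` must be at least 1.")
  sizes <- min_len:max_len
  th <- mjs_thresholds
  if (is.null(names(th))) {
    if (length(th) == 1L) th <- setNames(rep(th, length(sizes)), sizes)
    else abort("`mjs_thresholds` must be named by fragment size.")
  }
  missing <- setdiff(as.character(sizes), names(th))
  if (length(missing)) {
    abort(sprintf("no MJS threshold for size(s) %s.",
                  paste(missing, collapse = ", ")))
  }
  if (any(th <= 0 | th > 1)) abort("MJS thresholds must lie in (0, 1].")
  if (is.null(crmsd_threshold)) {
    crmsd_threshold <- function(n) pmin(0.5 + 0.04 * (n - 6), 1.5)
  }
  cr <- if (is.function(crmsd_threshold)) {
    setNames(crmsd_threshold(sizes), sizes)
  } else {
    crmsd_threshold
  }
  if (any(is.na(cr[as.character(sizes)]))) {
    abort("`crmsd_threshold` must cover every fragment size.")
  }
  structure(
    list(min_len = as.integer(min_len), max_len = as.integer(max_len),
         mjs_thresholds = th, top_n = as.integer(top_n),
         crmsd_thresholds = cr),
    class = "search_config"
  )
}

#' MJS thresholds calibrated on the shipped synthetic set
#'
#' Per-size thresholds produced by [calibrate_mjs_thresholds()] on the
#' package's synthetic calibration bank (see the methods vignette).
#' They describe the synthetic study conditions only; recalibrate for
#' any real bank.
#'
#' @return named numeric vector, one threshold per size 6..27.
#' @export
toy_mjs_thresholds <- function() {
  j <- jsonlite::fromJSON(system.file("extdata", "mjs_thresholds_toy.json",
                                      package = "sapick", mustWork = TRUE))
  setNames(as.numeric(j$threshold), as.character(j$size))
}

empty_hits <- function() {
  tibble(
    query_start = integer(0), query_end = integer(0), size_aa = integer(0),
    bank_id = character(0), bank_start = integer(0), bank_end = integer(0),
    mjs = numeric(0), coords = list()
  )
}

# sliding max over the diagonals of a column-pair score matrix:
# S[i, j] = max_k D[i + k, j + k], k = 0 .. l - 1
window_score_matrix <- function(D, l) {
  nq <- nrow(D); nb <- ncol(D)
  if (nq < l || nb < l) return(matrix(numeric(0), max(nq - l + 1L, 0L), 0L))
  S <- D[seq_len(nq - l + 1L), seq_len(nb - l + 1L), drop = FALSE]
  if (l > 1L) {
    for (k in seq_len(l - 1L)) {
      S <- pmax(S, D[k + seq_len(nq - l + 1L), k + seq_len(nb - l + 1L),
                     drop = FALSE])
    }
  }
  S
}

sort_hits <- function(hits) {
  hits[order(hits$mjs, hits$bank_id, hits$bank_start), , drop = FALSE]
}

#' Scan a bank for one query fragment
#'
#' Slides the query window over every same-length window of every bank
#' protein (ungapped), scores each pair with [mjs()], keeps the
#' windows at or below `threshold`, sorts them by ascending MJS (ties
#' by bank id then bank start) and truncates to the `top_n` best.
#'
#' @param query_window a [fragment_window()] on the query profile.
#' @param bank an [sa_bank()].
#' @param threshold MJS acceptance threshold.
#' @param top_n cap on the number of hits returned.
#' @return hit tibble: `query_start`, `query_end`, `size_aa`,
#'   `bank_id`, `bank_start`, `bank_end`, `mjs` and the bank
#'   fragment's C-alpha coordinates in the `coords` list-column.
#' @export
scan_fragment <- function(query_window, bank, threshold, top_n = 500L) {
  l <- query_window$n_cols
  size <- l + 3L
  Q <- window_matrix(query_window)
  if (anyNA(Q)) return(empty_hits())
  out <- purrr::map_dfr(seq_len(nrow(bank)), function(e) {
    B <- profile_matrix(bank$profile[[e]])
    if (nrow(B) < l) return(empty_hits())
    D <- js_cross(Q, B)
    S <- window_score_matrix(D, l)[1, ]
    j <- which(!is.na(S) & S <= threshold)
    if (!length(j)) return(empty_hits())
    xyz <- trace_coords(bank$trace[[e]])
    tibble(
      query_start = query_window$start,
      query_end = query_window$start + size - 1L,
      size_aa = size,
      bank_id = bank$id[e],
      bank_start = j,
      bank_end = j + size - 1L,
      mjs = S[j],
      coords = purrr::map(j, ~ xyz[.x:(.x + size - 1L), , drop = FALSE])
    )
  })
  head(sort_hits(out), top_n)
}

#' Incremental cRMSD clustering of hits
#'
#' Processes hits in ascending MJS order; each hit joins the first
#' existing cluster whose representative superposes on it within
#' `crmsd_threshold` ([kabsch_crmsd()]), otherwise it founds a new
#' cluster.  Representatives are therefore the lowest-MJS member of
#' their cluster, and the cluster weights sum to the number of hits.
#'
#' @param hits hit tibble from [scan_fragment()] (sorted ascending by
#'   MJS; re-sorted if not).
#' @param crmsd_threshold clustering cutoff (Angstrom).
#' @return cluster tibble: `cluster`, `weight`, the representative's
#'   hit fields, and the member row indices in `members`.
#' @export
cluster_hits <- function(hits, crmsd_threshold) {
  hits <- sort_hits(as_tibble(hits))
  n <- nrow(hits)
  if (!n) {
    return(mutate(empty_hits(), cluster = integer(0), weight = integer(0),
                  members = list()))
  }
  rep_idx <- integer(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (ci in seq_along(rep_idx)) {
      if (kabsch_crmsd(hits$coords[[i]],
                       hits$coords[[rep_idx[ci]]]) <= crmsd_threshold) {
        assign[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      assign[i] <- length(rep_idx)
    }
  }
  out <- hits[rep_idx, , drop = FALSE]
  out$cluster <- seq_along(rep_idx)
  out$weight <- as.integer(tabulate(assign, nbins = length(rep_idx)))
  out$members <- purrr::map(seq_along(rep_idx), ~ which(assign == .x))
  out
}

#' Pick the consensus cluster
#'
#' Keeps the cluster with the largest weight; weight ties go to the
#' lowest representative MJS, remaining ties to the representative's
#' (bank id, bank start).
#'
#' @param clusters cluster tibble from [cluster_hits()].
#' @return one-row cluster tibble, or `NULL` on empty input.
#' @export
select_cluster <- function(clusters) {
  if (is.null(clusters) || nrow(clusters) == 0L) return(NULL)
  ord <- order(-clusters$weight, clusters$mjs, clusters$bank_id,
               clusters$bank_start)
  clusters[ord[1], , drop = FALSE]
}

#' Full position-by-size fragment search
#'
#' For every fragment size in the configured range and every
#' admissible query position, scans the bank ([scan_fragment()]),
#' clusters the hits ([cluster_hits()]) and keeps the consensus
#' cluster representative ([select_cluster()]): at most one candidate
#' per (position, size) cell.
#'
#' @param query_profile the query [sa_profile()].
#' @param bank an [sa_bank()].
#' @param cfg a [search_config()].
#' @return candidate tibble: one row per surviving cell with the
#'   representative hit fields plus `weight` (cluster size) and
#'   `n_hits` (hits entering the clustering).
#' @export
search_all <- function(query_profile, bank, cfg = search_config()) {
  search_stages(query_profile, bank, cfg, keep_stages = FALSE)$best
}

#' Staged fragment search
#'
#' Like [search_all()], but also returns the two intermediate stages
#' of the protocol — the thresholded-and-capped hits of every cell and
#' the full set of cluster representatives — so the effect of each
#' filter can be inspected.
#'
#' @inheritParams search_all
#' @param keep_stages set `FALSE` to skip accumulating the `raw` and
#'   `clustered` stages.
#' @return list with tibbles `raw` (all hits entering the clustering),
#'   `clustered` (every cluster representative, with `weight`) and
#'   `best` (the per-cell consensus candidates, as [search_all()]).
#' @export
search_stages <- function(query_profile, bank, cfg = search_config(),
                          keep_stages = TRUE) {
  nq_res <- nrow(query_profile) + 3L
  if (nq_res < cfg$min_len) {
    abort(sprintf("query has %d residues; at least %d are required.",
                  nq_res, cfg$min_len))
  }
  Q <- profile_matrix(query_profile)
  banks <- purrr::map(seq_len(nrow(bank)), function(e) {
    list(D = js_cross(Q, profile_matrix(bank$profile[[e]])),
         xyz = trace_coords(bank$trace[[e]]),
         id = bank$id[e])
  })
  raw <- list(); reps <- list(); res <- list()
  for (size in cfg$min_len:min(cfg$max_len, nq_res)) {
    l <- size - 3L
    thr <- cfg$mjs_thresholds[[as.character(size)]]
    crth <- cfg$crmsd_thresholds[[as.character(size)]]
    Ss <- purrr::map(banks, ~ window_score_matrix(.x$D, l))
    for (i in seq_len(nq_res - size + 1L)) {
      hits <- purrr::map_dfr(seq_along(banks), function(e) {
        S <- Ss[[e]]
        if (!ncol(S) || i > nrow(S)) return(empty_hits())
        j <- which(!is.na(S[i, ]) & S[i, ] <= thr)
        if (!length(j)) return(empty_hits())
        tibble(
          query_start = i, query_end = i + size - 1L, size_aa = size,
          bank_id = banks[[e]]$id, bank_start = j, bank_end = j + size - 1L,
          mjs = S[i, j],
          coords = purrr::map(j, ~ banks[[e]]$xyz[.x:(.x + size - 1L), ,
                                                  drop = FALSE])
        )
      })
      if (!nrow(hits)) next
      hits <- head(sort_hits(hits), cfg$top_n)
      clusters <- cluster_hits(hits, crth)
      best <- select_cluster(clusters)
      best$n_hits <- nrow(hits)
      res[[length(res) + 1L]] <- select(best, -"members", -"cluster")
      if (keep_stages) {
        raw[[length(raw) + 1L]] <- hits
        reps[[length(reps) + 1L]] <- select(clusters, -"members", -"cluster")
      }
    }
  }
  empty_cand <- function() {
    mutate(empty_hits(), weight = integer(0), n_hits = integer(0))
  }
  list(
    raw = if (length(raw)) bind_rows(raw) else empty_hits(),
    clustered = if (length(reps)) bind_rows(reps) else
      mutate(empty_hits(), weight = integer(0)),
    best = if (length(res)) bind_rows(res) else empty_cand()
  )
}
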