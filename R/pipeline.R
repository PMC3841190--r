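#' Run the complete fragment-picking protocol
#'
#' Convenience wrapper chaining the three stages: position-by-size
#' search ([search_all()]), expected-precision annotation
#' ([add_expected_precision()]) and redundancy elimination
#' ([redundancy_eliminate()]).
#'
#' @param query_profile the query [sa_profile()].
#' @param bank an [sa_bank()].
#' @param grid a calibrated [calibrate_precision_grid()].
#' @param cfg a [search_config()].
#' @param fcfg a [filter_config()].
#' @return candidate tibble with `expected_precision` and a logical
#'   `kept_flag` marking the candidates surviving the final filter.
#' @export
pick_fragments <- function(query_profile, bank, grid,
                           cfg = search_config(), fcfg = filter_config()) {
  cand <- search_all(query_profile, bank, cfg)
  cand <- add_expected_precision(cand, grid, fcfg)
  kept <- redundancy_eliminate(cand, query_len = nrow(query_profile) + 3L,
                               cfg = fcfg)
  key <- paste(cand$query_start, cand$size_aa, cand$bank_id, cand$bank_start)
  cand$kept_flag <- key %in% paste(kept$query_start, kept$size_aa,
                                   kept$bank_id, kept$bank_start)
  cand
}

#' Coverage map of candidate fragments
#'
#' One segment per candidate, positioned at its query span and
#' fragment size; kept candidates are opaque, discarded ones faded.
#'
#' @param candidates tibble from [pick_fragments()] (or any candidate
#'   tibble; a missing `kept_flag` shows everything as kept).
#' @return a ggplot object.
#' @export
plot_candidate_map <- function(candidates) {
  df <- as_tibble(candidates)
  if (!"kept_flag" %in% names(df)) df$kept_flag <- TRUE
  ggplot2::ggplot(df, ggplot2::aes(x = .data$query_start,
                                   xend = .data$query_end,
                                   y = .data$size_aa,
                                   yend = .data$size_aa,
                                   colour = .data$mjs,
                                   alpha = .data$kept_flag)) +
    ggplot2::geom_segment(linewidth = 1.2) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                guide = "none") +
    ggplot2::scale_colour_viridis_c(direction = -1) +
    ggplot2::labs(x = "query residue", y = "fragment size (aa)",
                  colour = "MJS") +
    ggplot2::theme_minimal()
}
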