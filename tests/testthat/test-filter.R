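rule1 <- tp_rule(tibble::tibble(size = 9L, mu = 4, sigma = 1.5),
                 k = 2, floor = 0.5)  # cutoff 1.0

test_that("threshold calibration sweeps the 0.001 grid to 0.95 precision", {
  # all pairs TP: threshold is the max observed MJS rounded up to grid
  all_tp <- tibble::tibble(size = 9L, mjs = runif(100, 0, 0.4234),
                           crmsd = 0.2)
  all_tp$mjs[1] <- 0.4234
  th <- calibrate_mjs_thresholds(all_tp, rule1, min_pairs = 10L)
  expect_equal(th$threshold, 0.424)
  expect_equal(th$precision_at_threshold, 1)

  # precision >= 0.95 only below 0.15: threshold lands on 0.150
  withr::with_seed(101, {
    good <- tibble::tibble(size = 9L, mjs = runif(200, 0, 0.1495),
                           crmsd = 0.1)
    bad <- tibble::tibble(size = 9L, mjs = runif(200, 0.1502, 0.16),
                          crmsd = 5)
  })
  th2 <- calibrate_mjs_thresholds(dplyr::bind_rows(good, bad), rule1,
                                  min_pairs = 10L)
  expect_equal(th2$threshold, 0.150)

  # sizes without support inherit from neighbours
  mixed <- dplyr::bind_rows(
    good,
    tibble::tibble(size = 11L, mjs = 0.2, crmsd = 0.1)  # 1 pair only
  )
  rule2 <- tp_rule(tibble::tibble(size = c(9L, 11L), mu = c(4, 4),
                                  sigma = c(1.5, 1.5)))
  th3 <- calibrate_mjs_thresholds(mixed, rule2, min_pairs = 10L,
                                  sizes = c(9L, 11L))
  expect_true(th3$interpolated[th3$size == 11L])
  expect_equal(th3$threshold[th3$size == 11L],
               th3$threshold[th3$size == 9L])

  # a size whose pairs are all FP cannot be calibrated directly
  fp_only <- tibble::tibble(size = 9L, mjs = runif(60), crmsd = 5)
  expect_error(calibrate_mjs_thresholds(fp_only, rule1, min_pairs = 10L),
               "no fragment size")
})

test_that("self-consistency: re-evaluated precision at the threshold >= 0.95", {
  withr::with_seed(103, {
    pairs <- tibble::tibble(
      size = 9L,
      mjs = runif(3000),
      crmsd = NA_real_
    )
    # make TP probability decay with mjs so a meaningful threshold exists
    p_tp <- 1 - 0.9 * pairs$mjs^0.35
    pairs$crmsd <- ifelse(runif(3000) < p_tp, 0.3, 3)
  })
  th <- calibrate_mjs_thresholds(pairs, rule1)
  sel <- pairs$mjs < th$threshold
  tp <- pairs$crmsd < 1.0
  expect_gte(sum(tp[sel]) / sum(sel), 0.95)
})

grid_fixture <- function(n = 400L, seed = 107L) {
  withr::with_seed(seed, tibble::tibble(
    size = 9L,
    mjs = runif(n, 0, 0.5),
    weight = sample(1:20, n, replace = TRUE),
    is_tp = runif(n) < 0.9 - runif(n, 0, 0.5)
  ))
}

test_that("the precision grid is cumulative and its envelope is monotone", {
  cl <- grid_fixture()
  grid <- calibrate_precision_grid(cl, min_support = 10L)
  df <- tidy(grid)
  expect_true(all(df$support >= 10L))

  # brute-force recomputation of every stored cell's raw value
  withr::with_seed(3, rows <- sample(seq_len(nrow(df)), 60))
  for (r in rows) {
    sel <- cl$mjs < df$mjs_bin[r] + 0.001 & cl$weight >= df$w_bin[r]
    expect_equal(df$raw_precision[r], mean(cl$is_tp[sel]))
    expect_equal(df$support[r], sum(sel))
  }

  # served values: non-increasing in MJS, non-decreasing in W
  g <- grid$sizes[["9"]]
  for (w in seq_len(g$max_w)) {
    col <- g$prec[!is.na(g$prec[, w]), w]
    expect_false(is.unsorted(rev(col)))
    expect_false(is.unsorted(g$support[, w]))   # support is cumulative
  }
  for (b in seq_len(g$max_bin + 1L)) {
    row <- g$prec[b, !is.na(g$prec[b, ])]
    expect_false(is.unsorted(row))
    expect_false(is.unsorted(rev(g$support[b, ])))
  }

  # the envelope stays a probability and agrees with raw wherever raw
  # is already locally monotone at the grid origin
  expect_true(all(df$precision >= 0 & df$precision <= 1))
  first <- which.min(df$mjs_bin + df$w_bin)
  expect_equal(df$precision[first], df$raw_precision[first])
})

test_that("expected precision lookup honours bins, fallback and errors", {
  cl <- tibble::tibble(size = 9L, mjs = c(0.10, 0.10), weight = c(5L, 5L),
                       is_tp = TRUE)
  grid <- calibrate_precision_grid(cl, min_support = 1L)
  # cumulative cell: defined for x >= 0.10, y <= 5
  expect_equal(expected_precision(grid, 9L, 0.10, 5L), 1)
  expect_equal(expected_precision(grid, 9L, 0.25, 3L), 1)
  # half-open bin convention: just below the bin edge is undefined
  expect_equal(expected_precision(grid, 9L, 0.0999, 5L, fallback = -1), -1)
  expect_equal(expected_precision(grid, 9L, 0.10, 6L, fallback = -1), -1)
  expect_equal(expected_precision(grid, 12L, 0.10, 5L, fallback = -1), -1)
  expect_error(expected_precision(grid, 9L, 1.2, 1L), "0, 1")

  # all-TP grids are 1 everywhere defined
  all_tp <- grid_fixture()
  all_tp$is_tp <- TRUE
  g2 <- calibrate_precision_grid(all_tp, min_support = 10L)
  expect_true(all(tidy(g2)$precision == 1))
})

mk_cand <- function(qs, size, bank_id, bs, mjs, ep) tibble::tibble(
  query_start = qs, query_end = qs + size - 1L, size_aa = size,
  bank_id = bank_id, bank_start = bs, bank_end = bs + size - 1L,
  mjs = mjs, weight = 3L, expected_precision = ep
)

test_that("redundancy elimination applies the two-threshold greedy rule", {
  cfg <- filter_config()  # 0.99 / 0.82

  # everything confidently precise and non-nested: untouched
  top <- dplyr::bind_rows(mk_cand(1L, 8L, "a", 1L, 0.1, 0.995),
                          mk_cand(20L, 8L, "b", 4L, 0.2, 0.999))
  expect_equal(nrow(redundancy_eliminate(top, 40L, cfg)), 2L)

  # everything unreliable: dropped
  low <- mk_cand(c(1L, 5L), 8L, c("a", "b"), 1L, 0.1, 0.5)
  expect_equal(nrow(redundancy_eliminate(low, 40L, cfg)), 0L)

  # identical mid-band spans: only the higher expected precision kept
  mid <- dplyr::bind_rows(mk_cand(3L, 8L, "a", 1L, 0.1, 0.90),
                          mk_cand(3L, 8L, "b", 9L, 0.1, 0.85))
  kept <- redundancy_eliminate(mid, 40L, cfg)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$expected_precision, 0.90)

  # mid-band only contributes where residues are uncovered
  mix <- dplyr::bind_rows(
    mk_cand(1L, 10L, "a", 1L, 0.1, 0.995),   # kept outright, covers 1-10
    mk_cand(2L, 8L, "b", 1L, 0.1, 0.90),     # nested in coverage: dropped
    mk_cand(9L, 8L, "c", 1L, 0.1, 0.88)      # extends to 16: kept
  )
  kept2 <- redundancy_eliminate(mix, 40L, cfg)
  expect_equal(sort(kept2$bank_id), c("a", "c"))

  # nested same-protein spans: the shorter one is removed
  nest <- dplyr::bind_rows(
    mk_cand(1L, 12L, "a", 5L, 0.1, 0.995),
    mk_cand(2L, 8L, "a", 6L, 0.1, 0.995)
  )
  kept3 <- redundancy_eliminate(nest, 40L, cfg)
  expect_equal(kept3$size_aa, 12L)
  # same spans from different proteins survive
  nest$bank_id <- c("a", "b")
  expect_equal(nrow(redundancy_eliminate(nest, 40L, cfg)), 2L)

  # output is a subset and never keeps sub-lower candidates
  withr::with_seed(109, {
    rnd <- purrr::map_dfr(1:30, function(i) {
      mk_cand(sample(1:30, 1), sample(6:12, 1),
              sample(letters[1:4], 1), sample(1:20, 1),
              runif(1), runif(1))
    })
  })
  keptr <- redundancy_eliminate(rnd, 45L, cfg)
  expect_true(all(keptr$expected_precision >= cfg$lower))
  expect_lte(nrow(keptr), nrow(rnd))

  expect_error(redundancy_eliminate(dplyr::select(rnd, -expected_precision),
                                    45L, cfg), "expected_precision")
})

test_that("filter presets and fallback behave as configured", {
  strict <- filter_config("strict")
  expect_equal(c(strict$upper, strict$lower), c(0.99, 0.82))
  broad <- filter_config("broad")
  expect_equal(c(broad$upper, broad$lower), c(0.995, 0.65))
  expect_lt(strict$fallback, strict$lower)
  expect_error(filter_config(upper = 0.5, lower = 0.8), "lower < upper")
})

test_that("candidate TSV round-trips with formatting rules", {
  cand <- mk_cand(c(1L, 4L), 8L, c("a", "b"), c(2L, 9L),
                  c(0.12345, 0.5), c(0.995, NA))
  cand$kept_flag <- c(TRUE, FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(cand, path)
  back <- read_candidates(path)
  expect_equal(back$mjs, c(0.1235, 0.5))
  expect_equal(back$expected_precision, c(0.995, NA))
  expect_equal(back$kept_flag, c(TRUE, FALSE))
  expect_equal(back$bank_start, cand$bank_start)
})
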