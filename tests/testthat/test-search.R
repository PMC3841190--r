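test_that("scan_fragment finds a planted identical window at MJS zero", {
  model <- toy_sa_model()
  bank <- tiny_bank(model)
  qp <- bank$profile[[2]]               # identical profile generator
  w <- fragment_window(qp, 5, 6)        # a 9-residue fragment
  hits <- scan_fragment(w, bank, threshold = 0.3)
  self <- hits[hits$bank_id == bank$id[2] & hits$bank_start == 5, ]
  expect_equal(nrow(self), 1L)
  expect_equal(self$mjs, 0)
  expect_equal(self$size_aa, 9L)
  expect_equal(self$query_end, 13L)

  # threshold 0 with no identical window elsewhere: only the exact copy
  hits0 <- scan_fragment(w, bank, threshold = 0)
  expect_true(all(hits0$mjs == 0))
  expect_true(all(hits0$bank_id == bank$id[2]))
})

test_that("scan_fragment equals the exhaustive oracle and caps at top_n", {
  model <- toy_sa_model()
  bank <- tiny_bank(model, n = 5L, len = 26L, seed = 31L)
  qtr <- make_motif("helix", 20, noise_sd = 0.12, seed = 77)
  qp <- posterior_profile(qtr, model, source_id = "q")
  for (l in c(3L, 7L, 12L)) {
    w <- fragment_window(qp, 6, l)
    got <- scan_fragment(w, bank, threshold = 0.9, top_n = 500L)
    want <- scan_oracle(w, bank, threshold = 0.9)
    expect_gt(nrow(want), 0L)
    expect_equal(got$bank_id, want$bank_id)
    expect_equal(got$bank_start, want$bank_start)
    expect_lt(max(abs(got$mjs - want$mjs), 0), 1e-12)
  }
  # cap contract: more sub-threshold windows than top_n
  w <- fragment_window(qp, 2, 3)
  all_hits <- scan_fragment(w, bank, threshold = 1, top_n = 10000L)
  expect_gt(nrow(all_hits), 20L)
  capped <- scan_fragment(w, bank, threshold = 1, top_n = 20L)
  expect_equal(nrow(capped), 20L)
  expect_equal(capped$mjs, sort(all_hits$mjs)[1:20], tolerance = 1e-12)
})

test_that("incremental clustering partitions hits under the lowest-MJS rep", {
  # two near-identical fragments and one remote: two clusters
  xyz <- trace_coords(make_motif("helix", 9, 0, 1))
  hits <- tibble::tibble(
    query_start = 1L, query_end = 9L, size_aa = 9L,
    bank_id = c("a", "b", "c"), bank_start = c(1L, 1L, 1L),
    bank_end = 9L, mjs = c(0.05, 0.10, 0.20),
    coords = list(xyz, xyz + 0.05, trace_coords(make_motif("strand", 9, 0, 2)))
  )
  cl <- cluster_hits(hits, crmsd_threshold = 1.0)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$weight, c(2L, 1L))
  expect_equal(cl$mjs[1], 0.05)           # representative = lowest MJS
  expect_equal(sum(cl$weight), nrow(hits))

  # single hit: trivial cluster
  one <- cluster_hits(hits[1, ], 1.0)
  expect_equal(one$weight, 1L)
  expect_equal(one$mjs, 0.05)

  # randomized hit sets always partition
  withr::with_seed(51, {
    for (rep in 1:5) {
      n <- sample(5:25, 1)
      hs <- tibble::tibble(
        query_start = 1L, query_end = 9L, size_aa = 9L,
        bank_id = sprintf("p%02d", seq_len(n)), bank_start = 1L,
        bank_end = 9L, mjs = sort(runif(n)),
        coords = lapply(seq_len(n), function(i) {
          trace_coords(make_motif(sample(c("helix", "strand", "coil"), 1),
                                  9, noise_sd = 0.4,
                                  seed = sample.int(1e6, 1)))
        })
      )
      cl <- cluster_hits(hs, crmsd_threshold = 0.8)
      expect_equal(sum(cl$weight), n)
      members <- sort(unlist(cl$members))
      expect_equal(members, seq_len(n))   # every hit in exactly one cluster
      for (ci in seq_len(nrow(cl))) {
        expect_equal(cl$mjs[ci], min(hs$mjs[cl$members[[ci]]]))
      }
    }
  })
})

test_that("select_cluster keeps the heaviest cluster with stated tie-breaks", {
  base <- cluster_hits(tibble::tibble(
    query_start = 1L, query_end = 9L, size_aa = 9L,
    bank_id = c("a", "b"), bank_start = 1L, bank_end = 9L,
    mjs = c(0.08, 0.12),
    coords = list(trace_coords(make_motif("helix", 9, 0, 1)),
                  trace_coords(make_motif("strand", 9, 0, 1)))
  ), crmsd_threshold = 0.5)
  # weights 5 vs 3
  two <- base
  two$weight <- c(5L, 3L)
  expect_equal(select_cluster(two)$bank_id, "a")
  two$weight <- c(3L, 5L)
  expect_equal(select_cluster(two)$bank_id, "b")
  # tie on W: lowest representative MJS wins
  two$weight <- c(4L, 4L)
  expect_equal(select_cluster(two)$mjs, 0.08)
  expect_null(select_cluster(base[0, ]))
})

test_that("search_all emits at most one candidate per cell within bounds", {
  model <- toy_sa_model()
  bank <- tiny_bank(model, n = 4L, len = 28L, seed = 61L)
  qtr <- make_motif("helix", 14, noise_sd = 0.1, seed = 71)
  qp <- posterior_profile(qtr, model, source_id = "q")
  cfg <- search_config(min_len = 6L, max_len = 12L,
                       mjs_thresholds = toy_mjs_thresholds())
  cand <- search_all(qp, bank, cfg)
  expect_lte(max(table(paste(cand$query_start, cand$size_aa))), 1L)
  expect_true(all(cand$query_end <= 14L))
  expect_true(all(cand$query_start >= 1L))
  expect_true(all(cand$bank_start >= 1L))
  for (i in seq_len(nrow(cand))) {
    expect_lte(cand$bank_end[i],
               nrow(bank$trace[[match(cand$bank_id[i], bank$id)]]))
  }
  expect_true(all(cand$weight >= 1L))
  # determinism
  cand2 <- search_all(qp, bank, cfg)
  expect_identical(dplyr::select(cand, -coords), dplyr::select(cand2, -coords))

  # a 6-residue query exposes exactly one searchable cell
  q6 <- sa_profile(profile_matrix(qp)[1:3, ], source_id = "q6")
  cand6 <- search_all(q6, bank, search_config(
    min_len = 6L, max_len = 27L, mjs_thresholds = toy_mjs_thresholds()))
  expect_true(all(cand6$size_aa == 6L & cand6$query_start == 1L))
  expect_lte(nrow(cand6), 1L)

  expect_error(search_all(sa_profile(profile_matrix(qp)[1:2, ]), bank, cfg),
               "at least")
})
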