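test_that("fragment descriptors reproduce closed-form geometry", {
  # collinear points: distances add up, tetrahedron volume vanishes
  line <- cbind(3.8 * (0:3), 0, 0)
  d <- fragment_descriptors(line)
  expect_equal(unname(d), c(7.6, 11.4, 7.6, 0))

  # mirror image: same distances, opposite volume sign
  withr::with_seed(4, {
    for (i in 1:20) {
      x <- matrix(rnorm(12, sd = 3), 4, 3)
      dx <- fragment_descriptors(x)
      xm <- x %*% diag(c(1, 1, -1))
      dm <- fragment_descriptors(xm)
      expect_equal(dx[c("d13", "d14", "d24")], dm[c("d13", "d14", "d24")])
      expect_equal(dx[["v"]], -dm[["v"]])
    }
  })

  # ideal alpha-helix: d14 around 5 A
  h <- trace_coords(make_motif("helix", 4, noise_sd = 0, seed = 1))
  expect_gt(fragment_descriptors(h)[["d14"]], 5.0)
  expect_lt(fragment_descriptors(h)[["d14"]], 5.2)

  expect_error(fragment_descriptors(matrix(c(Inf, rep(0, 11)), 4, 3)),
               "finite")
})

test_that("descriptors are rigid-motion invariant", {
  withr::with_seed(9, {
    for (i in 1:10) {
      x <- matrix(rnorm(12, sd = 3), 4, 3)
      R <- random_rotation()
      y <- x %*% R + matrix(rnorm(3), 4, 3, byrow = TRUE)
      expect_equal(fragment_descriptors(x), fragment_descriptors(y),
                   tolerance = 1e-10)
    }
  })
})

test_that("model constructor enforces its invariants", {
  m <- toy_hmm(3)
  expect_s3_class(m, "sa_model")
  badA <- m$transitions
  badA[1, 1] <- badA[1, 1] + 1e-6
  expect_error(sa_model(m$means, m$covariances, badA, m$initial,
                        labels = m$labels), "row-stochastic")
  expect_error(sa_model(m$means, m$covariances, m$transitions,
                        c(0.5, 0.5, 0.1), labels = m$labels), "initial")
  badS <- m$covariances
  badS[[1]] <- matrix(0, 4, 4)
  expect_error(sa_model(m$means, badS, m$transitions, m$initial,
                        labels = m$labels), "positive-definite")
  expect_error(sa_model(m$means, m$covariances, m$transitions, m$initial,
                        labels = c("A", "A", "B")), "unique")
})

test_that("model JSON round-trips", {
  m <- toy_hmm(3)
  path <- withr::local_tempfile(fileext = ".json")
  write_sa_model(m, path, digits = 10)
  m2 <- read_sa_model(path)
  expect_equal(m2$means, m$means, tolerance = 1e-8)
  expect_equal(m2$transitions, m$transitions, tolerance = 1e-6)
  expect_equal(m2$labels, m$labels)
})

test_that("Viterbi matches exhaustive path enumeration on short traces", {
  m <- toy_hmm(3, sep = 2)       # overlapping emissions: non-trivial paths
  logA <- log(m$transitions)
  logpi <- log(m$initial)
  withr::with_seed(11, {
    for (rep in 1:8) {
      tt <- sample(2:6, 1)
      logB <- matrix(rnorm(tt * 3), tt, 3)
      got <- sapick:::viterbi_path(logB, logA, logpi)
      want <- viterbi_oracle(logB, logA, logpi)
      expect_equal(got$path, want$path)
      expect_equal(got$logprob, want$logprob, tolerance = 1e-10)
    }
  })
})

test_that("encode_viterbi recovers well-separated simulated paths", {
  m <- toy_hmm(2, sep = 50)
  sim <- simulate_hmm(m, 40, seed = 3)
  # build a trace whose descriptors equal the simulated emissions is not
  # possible directly; decode at the descriptor level instead
  logB <- matrix(NA_real_, 40, 2)
  for (j in 1:2) {
    logB[, j] <- sapick:::mvn_logdens(sim$X, m$means[j, ], m$covariances[[j]])
  }
  vit <- sapick:::viterbi_path(logB, log(m$transitions), log(m$initial))
  expect_gte(mean(vit$path == sim$states), 0.95)

  # trace-level contract: N residues give N - 3 letters
  tr <- make_motif("helix", 4, noise_sd = 0, seed = 2)
  expect_equal(nchar(encode_viterbi(tr, toy_sa_model())), 1L)
  expect_error(trace_descriptors(ca_trace(cbind(0:2 * 3.8, 0, 0))),
               "at least 4")
})

test_that("posterior profiles are normalized and consistent with Viterbi", {
  m <- toy_sa_model()
  tr <- make_motif("hairpin", 20, noise_sd = 0.1, seed = 6)
  p <- posterior_profile(tr, m)
  pm <- profile_matrix(p)
  expect_equal(nrow(pm), nrow(tr) - 3L)
  expect_true(all(abs(rowSums(pm) - 1) < 1e-9))
  expect_true(all(pm >= 0))

  # argmax letter equals the Viterbi letter for well-separated emissions
  m2 <- toy_hmm(2, sep = 50)
  tr2 <- make_motif("helix", 15, noise_sd = 0, seed = 2)
  # helix descriptors sit close to state 1 of the toy model by construction
  p2 <- posterior_profile(tr2, m2)
  v2 <- strsplit(encode_viterbi(tr2, m2), "")[[1]]
  argmax <- m2$labels[max.col(profile_matrix(p2))]
  expect_equal(argmax, v2)
})

test_that("degenerate one-state model yields point-mass posteriors", {
  m1 <- toy_hmm(1)
  tr <- make_motif("coil", 12, noise_sd = 0.2, seed = 8)
  p <- profile_matrix(posterior_profile(tr, m1))
  expect_true(all(p == 1))
})

test_that("posterior decoding respects chain breaks", {
  xyz <- rbind(trace_coords(make_motif("helix", 8, 0, 1)),
               trace_coords(make_motif("helix", 8, 0, 1)) +
                 matrix(c(50, 0, 0), 8, 3, byrow = TRUE))
  tr <- ca_trace(xyz)
  expect_equal(sum(chain_breaks(tr)), 1L)
  p <- profile_matrix(posterior_profile(tr, toy_sa_model()))
  bad <- which(!complete.cases(p))
  expect_equal(bad, 6:8)           # windows spanning the break
  s <- encode_viterbi(tr, toy_sa_model())
  expect_equal(gsub("[^-]", "x", s), "xxxxx---xxxxx")
})

test_that("Baum-Welch log-likelihood is monotone and seeded fits repeat", {
  traces <- lapply(1:4, function(i) {
    make_motif(c("helix", "strand")[(i %% 2) + 1], 25,
               noise_sd = 0.15, seed = i)
  })
  f1 <- fit_baum_welch(traces, 2, seed = 3, max_iter = 10)
  f2 <- fit_baum_welch(traces, 2, seed = 3, max_iter = 10)
  ll <- attr(f1, "fit")$loglik
  expect_false(is.unsorted(ll))
  expect_identical(f1$means, f2$means)
  expect_identical(f1$transitions, f2$transitions)
  expect_error(fit_baum_welch(traces, 0), "at least 1")
})
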