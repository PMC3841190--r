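# Independent oracles and small generators shared across the suite.
# Every oracle is written from the mathematical definition, not from
# the package internals it cross-checks.

# random probability row over k letters
random_prob_row <- function(k = 27L, peaked = FALSE) {
  g <- rgamma(k, shape = if (peaked) 0.15 else 1)
  g / sum(g)
}

random_profile <- function(n_rows, k = 27L, id = "rnd") {
  m <- t(vapply(seq_len(n_rows), function(i) random_prob_row(k), numeric(k)))
  sa_profile(m, letters = sa_letters(k), source_id = id)
}

# Jensen-Shannon by direct 2k-term summation (log base 2)
js_oracle <- function(p, q) {
  m <- (p + q) / 2
  term <- function(a, b) {
    # terms below 1e-300 contribute < 1e-297 bits but can hit denormal
    # underflow in a/b; drop them
    i <- a > 1e-300
    sum(a[i] * log2(a[i] / b[i]))
  }
  0.5 * term(p, m) + 0.5 * term(q, m)
}

# brute-force max over paired columns
mjs_oracle <- function(A, B) {
  max(vapply(seq_len(nrow(A)), function(i) js_oracle(A[i, ], B[i, ]),
             numeric(1)))
}

# exhaustive joint-likelihood maximization over all state paths
viterbi_oracle <- function(logB, logA, logpi) {
  k <- ncol(logB); tt <- nrow(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), tt)))
  score <- apply(paths, 1, function(p) {
    s <- logpi[p[1]] + logB[1, p[1]]
    if (tt > 1) for (t in 2:tt) s <- s + logA[p[t - 1], p[t]] + logB[t, p[t]]
    s
  })
  list(path = unname(paths[which.max(score), ]), logprob = max(score))
}

# quaternion (Horn) closed-form optimal superposition RMSD
quaternion_crmsd <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  S <- crossprod(xc, yc)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(xc^2) + sum(yc^2) - 2 * lam) / nrow(x)
  sqrt(max(msd, 0))
}

random_rotation <- function() {
  q <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(q)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# brute-force scan oracle: score every window via per-column JS,
# filter, sort, cap
scan_oracle <- function(query_window, bank, threshold, top_n = 500L) {
  l <- query_window$n_cols
  Q <- sapick:::window_matrix(query_window)
  rows <- list()
  for (e in seq_len(nrow(bank))) {
    B <- profile_matrix(bank$profile[[e]])
    if (nrow(B) < l) next
    for (j in seq_len(nrow(B) - l + 1L)) {
      W <- B[j:(j + l - 1L), , drop = FALSE]
      if (anyNA(W) || anyNA(Q)) next
      s <- mjs_oracle(Q, W)
      if (s <= threshold) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          bank_id = bank$id[e], bank_start = j, mjs = s
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(bank_id = character(0), bank_start = integer(0),
                          mjs = numeric(0)))
  }
  head(out[order(out$mjs, out$bank_id, out$bank_start), ], top_n)
}

# well-separated toy Gaussian HMM over the 4 descriptors
toy_hmm <- function(k = 2L, sep = 40) {
  means <- matrix(0, k, 4)
  for (j in seq_len(k)) means[j, ] <- c(5, 8, 5, 2) + (j - 1) * sep
  covs <- replicate(k, diag(0.25, 4), simplify = FALSE)
  A <- matrix(0.1 / (k - 1 + (k == 1)), k, k)
  diag(A) <- if (k == 1) 1 else 0.9
  sa_model(means, covs, A / rowSums(A), rep(1 / k, k),
           labels = sa_letters(k))
}

# sample a state path and descriptor emissions from a toy model
simulate_hmm <- function(model, tt, seed = 1L) {
  withr::with_seed(seed, {
    k <- model$n_states
    states <- integer(tt)
    states[1] <- sample.int(k, 1, prob = model$initial)
    if (tt > 1) {
      for (t in 2:tt) {
        states[t] <- sample.int(k, 1, prob = model$transitions[states[t - 1], ])
      }
    }
    X <- t(vapply(states, function(s) {
      ch <- chol(model$covariances[[s]])
      model$means[s, ] + as.numeric(t(ch) %*% rnorm(4))
    }, numeric(4)))
    list(states = states, X = X)
  })
}

# tiny deterministic bank of noiseless motifs with exact posteriors
tiny_bank <- function(model, n = 4L, len = 30L, seed = 5L) {
  kinds <- rep(c("helix", "strand", "hairpin", "coil"), length.out = n)
  traces <- lapply(seq_len(n), function(i) {
    tr <- make_motif(kinds[i], len, noise_sd = 0.1, seed = seed + i)
    ca_trace(trace_coords(tr), chain_id = sprintf("b%02d", i))
  })
  profiles <- lapply(traces, function(tr) {
    posterior_profile(tr, model, source_id = tr$chain[1])
  })
  sa_bank(vapply(traces, function(tr) tr$chain[1], character(1)),
          traces, profiles)
}
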