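# Gaussian-emission HMM machinery behind the structural alphabet.
# All recursions are scaled (forward-backward) or run in natural-log
# space (Viterbi); per-column log-density offsets keep the scaled
# recursions finite for chains up to at least 1e4 fragments.

# log N(x | mean, cov) for every row of X; cov factored once
mvn_logdens <- function(X, mean, cov) {
  ch <- chol(cov)
  z <- forwardsolve(t(ch), t(X) - mean)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * ncol(X) * log(2 * pi)
}

# T x K matrix of per-state emission log-densities (rows with NA stay NA)
emission_loglik <- function(desc, model) {
  k <- model$n_states
  out <- matrix(NA_real_, nrow(desc), k)
  ok <- stats::complete.cases(desc)
  if (any(ok)) {
    Xok <- desc[ok, , drop = FALSE]
    for (j in seq_len(k)) {
      out[ok, j] <- mvn_logdens(Xok, model$means[j, ], model$covariances[[j]])
    }
  }
  out
}

# Viterbi path for one break-free stretch of emission log-densities
viterbi_path <- function(logB, logA, logpi) {
  tt <- nrow(logB); k <- ncol(logB)
  delta <- logpi + logB[1, ]
  psi <- matrix(0L, tt, k)
  if (tt > 1) {
    for (t in 2:tt) {
      cand <- delta + logA                    # k x k: prev state x next state
      psi[t, ] <- max.col(t(cand), ties.method = "first")
      delta <- cand[cbind(psi[t, ], seq_len(k))] + logB[t, ]
    }
  }
  path <- integer(tt)
  path[tt] <- which.max(delta)
  if (tt > 1) for (t in (tt - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  list(path = path, logprob = max(delta))
}

# scaled forward-backward; returns gamma, xi sums and the log-likelihood
forward_backward_core <- function(logB, A, pi0) {
  tt <- nrow(logB); k <- ncol(logB)
  off <- apply(logB, 1, max)
  B <- exp(logB - off)
  alpha <- matrix(0, tt, k)
  cvec <- numeric(tt)
  a <- pi0 * B[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  if (tt > 1) {
    for (t in 2:tt) {
      a <- (alpha[t - 1, ] %*% A) * B[t, ]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
  }
  beta <- matrix(0, tt, k)
  beta[tt, ] <- 1
  if (tt > 1) {
    for (t in (tt - 1):1) {
      beta[t, ] <- (A %*% (B[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, k, k)
  if (tt > 1) {
    for (t in 1:(tt - 1)) {
      m <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * A / cvec[t + 1]
      xi <- xi + m
    }
  }
  list(gamma = gamma, xi = xi, loglik = sum(log(cvec)) + sum(off))
}

# runs of consecutive encodable windows (maximal break-free stretches)
valid_runs <- function(ok) {
  if (!length(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  purrr::map2(starts[r$values], ends[r$values], ~ .x:.y)
}

#' Encode a trace as its optimal letter string
#'
#' Runs the Viterbi algorithm on the descriptor sequence of every
#' break-free stretch of the trace and returns the jointly most
#' probable letter series.  Windows spanning a chain break are marked
#' `-` and the Markov chain restarts after each break.
#'
#' @param trace a [ca_trace()] with at least four residues.
#' @param model an [sa_model()].
#' @return single string of length `n - 3` over the model's labels
#'   plus `-` for break-spanning windows.
#' @export
#' @examples
#' m <- toy_sa_model()
#' encode_viterbi(make_motif("helix", 12, noise_sd = 0, seed = 1), m)
encode_viterbi <- function(trace, model) {
  desc <- trace_descriptors(trace)
  logB <- emission_loglik(desc, model)
  out <- rep("-", nrow(desc))
  logA <- log(model$transitions)
  logpi <- log(model$initial)
  for (run in valid_runs(stats::complete.cases(desc))) {
    vit <- viterbi_path(logB[run, , drop = FALSE], logA, logpi)
    out[run] <- model$labels[vit$path]
  }
  paste(out, collapse = "")
}

#' Posterior letter probabilities along a trace
#'
#' Runs the forward-backward algorithm on every break-free stretch of
#' the trace and returns, for each four-residue window, the posterior
#' probability that each structural alphabet letter generated it.
#'
#' @inheritParams encode_viterbi
#' @param source_id identifier stored with the profile.
#' @return an [sa_profile()] with `n - 3` rows; rows at break-spanning
#'   windows are `NA`.
#' @export
posterior_profile <- function(trace, model, source_id = trace$chain[1]) {
  desc <- trace_descriptors(trace)
  logB <- emission_loglik(desc, model)
  prob <- matrix(NA_real_, nrow(desc), model$n_states)
  for (run in valid_runs(stats::complete.cases(desc))) {
    fb <- forward_backward_core(logB[run, , drop = FALSE],
                                model$transitions, model$initial)
    prob[run, ] <- fb$gamma
  }
  sa_profile(prob, letters = model$labels, source_id = source_id)
}

#' Fit a structural alphabet model by Baum-Welch EM
#'
#' Fits a Gaussian-emission hidden Markov model to the four-residue
#' descriptor sequences of a set of traces.  Initialisation is by
#' k-means on the pooled descriptors (seeded, hence deterministic);
#' covariances carry a ridge of `ridge` on the diagonal so that
#' near-degenerate clusters stay positive-definite.  The log-likelihood
#' is non-decreasing across iterations; fitting stops when its gain
#' drops below `tol` or after `max_iter` iterations.
#'
#' @param traces list of [ca_trace()] objects, or list of plain
#'   numeric matrices of four-column descriptor sequences (one row per
#'   four-residue window).
#' @param n_states number of letters to fit.
#' @param seed integer seed controlling initialisation.
#' @param max_iter,tol EM stopping rule.
#' @param ridge diagonal regularization added to every covariance
#'   (Angstrom^2).
#' @return an [sa_model()]; attribute `"fit"` holds the log-likelihood
#'   trace, iteration count, convergence flag and any notes about
#'   degenerate states.
#' @export
fit_baum_welch <- function(traces, n_states, seed = 1L,
                           max_iter = 100L, tol = 1e-4, ridge = 1e-6) {
  if (n_states < 1L) abort("`n_states` must be at least 1.")
  seqs <- purrr::map(traces, function(tr) {
    d <- if (is.matrix(tr)) tr else trace_descriptors(tr)
    if (ncol(d) != 4L) abort("descriptor sequences must have 4 columns.")
    d[stats::complete.cases(d), , drop = FALSE]
  })
  seqs <- purrr::keep(seqs, ~ nrow(.x) >= 1L)
  X <- do.call(rbind, seqs)
  if (nrow(X) < 2L * n_states) {
    abort("not enough descriptor windows to fit the requested model.")
  }
  k <- n_states
  notes <- character(0)

  init <- withr::with_seed(seed, {
    km <- if (k == 1L) list(centers = matrix(colMeans(X), 1L),
                            cluster = rep(1L, nrow(X)))
          else kmeans(X, centers = k, nstart = 5L, iter.max = 50L)
    A0 <- matrix(runif(k * k, 0.5, 1.5), k, k)
    list(km = km, A0 = A0 / rowSums(A0))
  })
  means <- unname(as.matrix(init$km$centers))
  covs <- lapply(seq_len(k), function(j) {
    Xi <- X[init$km$cluster == j, , drop = FALSE]
    s <- if (nrow(Xi) > 4L) cov(Xi) else cov(X)
    (s + t(s)) / 2 + diag(ridge, 4L)
  })
  A <- init$A0
  pi0 <- rep(1 / k, k)

  model <- sa_model(means, covs, A, pi0, labels = sa_letters(k))
  llks <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    gsum <- matrix(0, 1, k)          # sum of gamma over all t
    g1 <- rep(0, k)                  # gamma at t = 1
    xi <- matrix(0, k, k)
    mom1 <- matrix(0, k, 4L)
    mom2 <- vector("list", k)
    for (j in seq_len(k)) mom2[[j]] <- matrix(0, 4L, 4L)
    ll <- 0
    for (Xs in seqs) {
      logB <- matrix(0, nrow(Xs), k)
      for (j in seq_len(k)) {
        logB[, j] <- mvn_logdens(Xs, model$means[j, ], model$covariances[[j]])
      }
      fb <- forward_backward_core(logB, model$transitions, model$initial)
      ll <- ll + fb$loglik
      g1 <- g1 + fb$gamma[1, ]
      xi <- xi + fb$xi
      gsum <- gsum + colSums(fb$gamma)
      mom1 <- mom1 + t(fb$gamma) %*% Xs
      for (j in seq_len(k)) {
        Xw <- Xs * sqrt(fb$gamma[, j])
        mom2[[j]] <- mom2[[j]] + t(Xw) %*% Xw
      }
    }
    llks <- c(llks, ll)
    if (iter > 1 && abs(ll - llks[iter - 1]) < tol) { converged <- TRUE; break }

    w <- as.numeric(gsum)
    means_new <- model$means
    covs_new <- model$covariances
    for (j in seq_len(k)) {
      if (w[j] < 1e-8) {
        notes <- c(notes, sprintf(
          "state %d received ~zero responsibility at iteration %d; kept.",
          j, iter))
        next
      }
      mu <- mom1[j, ] / w[j]
      s <- mom2[[j]] / w[j] - tcrossprod(mu)
      s <- (s + t(s)) / 2 + diag(ridge, 4L)
      if (min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
        notes <- c(notes, sprintf(
          "covariance of state %d regularized at iteration %d.", j, iter))
        s <- s + diag(max(ridge, 1e-4), 4L)
      }
      means_new[j, ] <- mu
      covs_new[[j]] <- s
    }
    A_new <- xi + 1e-12
    A_new <- A_new / rowSums(A_new)
    pi_new <- g1 / sum(g1)
    model <- sa_model(means_new, covs_new, A_new, pi_new,
                      labels = sa_letters(k))
  }
  attr(model, "fit") <- list(
    loglik = llks, iterations = length(llks),
    converged = converged, notes = notes
  )
  model
}
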