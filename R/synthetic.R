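# Synthetic structures: idealized helices, strands, beta hairpins and
# smooth coil, assembled into toy banks so the entire search protocol
# can be exercised and calibrated without external structure sets.

rotation_from_seed <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

helix_coords <- function(n) {
  i <- seq_len(n) - 1
  th <- i * 100 * pi / 180
  cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
}

strand_coords <- function(n) {
  i <- seq_len(n) - 1
  cbind(3.46 * i, 0.787 * (-1)^i, 0)
}

hairpin_coords <- function(n) {
  n1 <- ceiling((n - 4L) / 2)
  n2 <- n - 4L - n1
  D <- 5.0
  xe <- 3.8 * (n1 - 1)
  # circle through the two strand ends whose major arc holds the
  # 4 turn residues at ~3.8 A spacing
  gap_eq <- function(R) {
    5 * 2 * asin(pmin(1.9 / R, 1)) + 2 * asin(pmin(D / 2 / R, 1)) - 2 * pi
  }
  R <- stats::uniroot(gap_eq, c(2.6, 30))$root
  h <- sqrt(R^2 - (D / 2)^2)
  ctr <- c(xe + h, D / 2)
  a1 <- asin(D / 2 / R)
  phi0 <- -pi + a1
  dphi <- 2 * asin(1.9 / R)
  turn <- t(vapply(1:4, function(k) {
    ph <- phi0 + k * dphi
    c(ctr[1] + R * cos(ph), ctr[2] + R * sin(ph), 0.3 * sin(k * pi / 5))
  }, numeric(3)))
  s1 <- cbind(3.8 * (seq_len(n1) - 1), 0, 0)
  s2 <- cbind(xe - 3.8 * (seq_len(n2) - 1), D, 0)
  rbind(s1, turn, s2)
}

coil_coords <- function(n) {
  p <- matrix(0, n, 3)
  u <- c(1, 0, 0)
  for (i in 2:n) {
    u <- u + 0.6 * rnorm(3)
    u <- u / sqrt(sum(u^2))
    p[i, ] <- p[i - 1, ] + 3.8 * u
  }
  p
}

#' Generate an idealized structural motif
#'
#' Ideal C-alpha geometry for one of four motif kinds, with optional
#' isotropic Gaussian coordinate noise: `helix` (radius 2.3 A, rise
#' 1.5 A/residue, 100 degrees/residue), `strand` (3.46 A rise
#' zig-zag), `hairpin` (two antiparallel strands joined by a
#' four-residue turn, strand separation 5 A) and `coil` (smooth random
#' walk with 3.8 A steps).  At zero noise all consecutive C-alpha
#' distances fall in \[3.6, 4.0\] A.
#'
#' @param kind one of `"helix"`, `"strand"`, `"hairpin"`, `"coil"`.
#' @param n_res number of residues (>= 4; hairpins need >= 10).
#' @param noise_sd isotropic Gaussian noise SD (Angstrom) added to
#'   every coordinate.
#' @param seed integer seed; same arguments, same coordinates.
#' @return a [ca_trace()].
#' @export
#' @examples
#' h <- make_motif("helix", 12, noise_sd = 0, seed = 1)
make_motif <- function(kind = c("helix", "strand", "hairpin", "coil"),
                       n_res, noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (n_res < 4L) abort("`n_res` must be at least 4.")
  if (kind == "hairpin" && n_res < 10L) {
    abort("hairpins need at least 10 residues (two strands + 4-residue turn).")
  }
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  xyz <- withr::with_seed(seed, {
    p <- switch(kind,
      helix = helix_coords(n_res),
      strand = strand_coords(n_res),
      hairpin = hairpin_coords(n_res),
      coil = coil_coords(n_res)
    )
    p + matrix(rnorm(3 * n_res, sd = noise_sd), n_res, 3)
  })
  ca_trace(xyz, chain_id = kind)
}

#' Specification of a synthetic profile bank
#'
#' @param n_proteins number of chains to generate.
#' @param len_range inclusive chain-length range (residues).
#' @param weights sampling weights for the motif kinds
#'   (helix / strand / hairpin / coil); normalized to sum to 1.
#' @param noise_sd coordinate noise SD (Angstrom) applied to every
#'   motif.
#' @param seed integer seed.
#' @return list of class `bank_spec`.
#' @export
bank_spec <- function(n_proteins = 10L, len_range = c(40L, 70L),
                      weights = c(helix = 0.35, strand = 0.25,
                                  hairpin = 0.2, coil = 0.2),
                      noise_sd = 0.15, seed = 1L) {
  if (any(len_range < 6L)) abort("chain lengths must be at least 6.")
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  if (any(weights < 0) || sum(weights) <= 0) {
    abort("`weights` must be nonnegative and not all zero.")
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      len_range = as.integer(len_range),
      weights = weights / sum(weights),
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "bank_spec"
  )
}

#' Profile banks
#'
#' A bank pairs, for every entry, a structure ([ca_trace()]) with its
#' structural alphabet profile (one probability row per four-residue
#' window).
#'
#' @param ids character entry identifiers (unique).
#' @param traces list of [ca_trace()]s.
#' @param profiles list of matching [sa_profile()]s
#'   (`nrow(profile) == nrow(trace) - 3`).
#' @return tibble of class `sa_bank` with columns `id`, `trace`,
#'   `profile`.
#' @export
sa_bank <- function(ids, traces, profiles) {
  if (anyDuplicated(ids)) abort("bank ids must be unique.")
  if (length(traces) != length(ids) || length(profiles) != length(ids)) {
    abort("`ids`, `traces` and `profiles` must have equal length.")
  }
  for (i in seq_along(ids)) {
    if (nrow(profiles[[i]]) != nrow(traces[[i]]) - 3L) {
      abort(sprintf("entry '%s': profile has %d rows, expected %d.",
                    ids[i], nrow(profiles[[i]]), nrow(traces[[i]]) - 3L))
    }
  }
  out <- tibble(id = as.character(ids), trace = traces, profile = profiles)
  class(out) <- c("sa_bank", class(out))
  out
}

# assemble sampled motifs into one chain (3.8 A junctions, no breaks)
assemble_chain <- function(target_len, weights, noise_sd, chain_id) {
  kinds <- names(weights)
  coords <- NULL
  total <- 0L
  while (total < target_len) {
    kind <- sample(kinds, 1L, prob = weights)
    len <- sample(8:16, 1L)
    if (kind == "hairpin") len <- max(len, 12L)
    len <- min(len, max(target_len - total, 4L))
    if (kind == "hairpin" && len < 10L) kind <- "coil"
    motif <- make_motif(kind, len, noise_sd = noise_sd,
                        seed = sample.int(.Machine$integer.max, 1L))
    m <- trace_coords(motif)
    m <- m %*% rotation_from_seed()
    if (is.null(coords)) {
      coords <- m
    } else {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      anchor <- coords[nrow(coords), ] + 3.8 * u
      m <- sweep(m, 2, m[1, ] - anchor)
      coords <- rbind(coords, m)
    }
    total <- nrow(coords)
  }
  ca_trace(coords[seq_len(target_len), , drop = FALSE], chain_id = chain_id)
}

#' Build a synthetic profile bank
#'
#' Samples motifs according to the spec's composition weights,
#' concatenates them into chains, encodes every chain with
#' [posterior_profile()], and (optionally) degrades the profiles with
#' [pseudo_predict()] to emulate sequence-based prediction.
#'
#' @param spec a [bank_spec()].
#' @param model an [sa_model()].
#' @param concentration if non-`NULL`, Dirichlet concentration passed
#'   to [pseudo_predict()] for every profile.
#' @return an [sa_bank()]; deterministic given `spec$seed`.
#' @export
build_bank <- function(spec, model, concentration = NULL) {
  stopifnot(inherits(spec, "bank_spec"))
  traces <- withr::with_seed(spec$seed, {
    rng <- seq(spec$len_range[1], spec$len_range[2])
    lens <- rng[sample.int(length(rng), spec$n_proteins, replace = TRUE)]
    purrr::map(seq_len(spec$n_proteins), function(i) {
      assemble_chain(lens[i], spec$weights, spec$noise_sd,
                     chain_id = sprintf("syn%03d", i))
    })
  })
  ids <- vapply(traces, function(tr) tr$chain[1], character(1))
  profiles <- purrr::map2(traces, ids, function(tr, id) {
    posterior_profile(tr, model, source_id = id)
  })
  if (!is.null(concentration)) {
    profiles <- purrr::imap(profiles, function(p, i) {
      pseudo_predict(p, concentration = concentration,
                     seed = (spec$seed + 7919L * i) %% .Machine$integer.max)
    })
  }
  sa_bank(ids, traces, profiles)
}

# rigid transform of x least-squares posed onto y (proper rotation)
pose_onto <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx)
  s <- svd(crossprod(xc, sweep(y, 2, cy)))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    s$u[, 3] <- -s$u[, 3]
    R <- s$u %*% t(s$v)
  }
  sweep(xc %*% R, 2, cy, `+`)
}

#' Plant a fragment inside a bank
#'
#' Replaces a span of one bank entry by the given fragment, rigidly
#' posed onto the replaced segment (least-squares superposition, so
#' the planted geometry is exactly the fragment's), and re-encodes the
#' entry's profile.  The posed fragment is re-anchored on the upstream
#' junction bond and the downstream part of the chain is rigidly
#' shifted to preserve the downstream bond, so planting never
#' introduces a chain break.  Used to set up recall experiments with a
#' known answer.
#'
#' @param bank an [sa_bank()].
#' @param fragment a [ca_trace()] holding the fragment to plant.
#' @param entry bank entry index (or id) to modify.
#' @param position 1-based residue index where the fragment starts.
#' @param model the [sa_model()] used to re-encode the profile.
#' @param concentration,seed if `concentration` is non-`NULL`, the
#'   re-encoded profile is degraded with [pseudo_predict()].
#' @return a modified copy of the bank.
#' @export
plant_fragment <- function(bank, fragment, entry, position, model,
                           concentration = NULL, seed = 1L) {
  if (is.character(entry)) entry <- match(entry, bank$id)
  if (is.na(entry) || entry < 1L || entry > nrow(bank)) {
    abort("`entry` does not identify a bank entry.")
  }
  tr <- bank$trace[[entry]]
  nf <- nrow(fragment)
  if (position < 1L || position + nf - 1L > nrow(tr)) {
    abort("planted span exceeds the target protein.")
  }
  span <- position:(position + nf - 1L)
  xyz <- trace_coords(tr)
  posed <- pose_onto(trace_coords(fragment), xyz[span, , drop = FALSE])
  if (position > 1L) {
    # keep the upstream junction bond exactly as it was
    posed <- sweep(posed, 2, xyz[position, ] - posed[1, ], `+`)
  }
  last <- position + nf - 1L
  if (last < nrow(tr)) {
    # carry the rest of the chain along so the downstream bond survives
    delta <- posed[nf, ] - xyz[last, ]
    down <- (last + 1L):nrow(tr)
    xyz[down, ] <- sweep(xyz[down, , drop = FALSE], 2, delta, `+`)
  }
  xyz[span, ] <- posed
  new_tr <- ca_trace(xyz, residue_ids = tr$resid, chain_id = tr$chain[1])
  prof <- posterior_profile(new_tr, model, source_id = bank$id[entry])
  if (!is.null(concentration)) {
    prof <- pseudo_predict(prof, concentration = concentration, seed = seed)
  }
  bank$trace[[entry]] <- new_tr
  bank$profile[[entry]] <- prof
  bank
}
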