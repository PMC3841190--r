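#' Structural alphabet letters
#'
#' Default labels for a 27-letter alphabet: `A`..`Z` then `a`.
#'
#' @param n number of letters.
#' @return character vector of `n` distinct single characters.
#' @export
sa_letters <- function(n = 27L) {
  pool <- c(LETTERS, letters)
  if (n > length(pool)) abort("at most 52 state labels are available.")
  pool[seq_len(n)]
}

#' Construct a structural alphabet model
#'
#' The model is a hidden Markov chain over `n_states` local
#' conformations ("letters").  Each letter emits the four-dimensional
#' geometric descriptor of a four-residue fragment
#' ([fragment_descriptors()]) from a multivariate Gaussian; successive
#' fragments (overlapping by three residues) follow the transition
#' matrix.
#'
#' @param means numeric `n_states x 4` matrix of emission means
#'   (d13, d14, d24 in Angstrom; v in Angstrom^3).
#' @param covariances list of `n_states` symmetric positive-definite
#'   `4 x 4` matrices, or a `4 x 4 x n_states` array.
#' @param transitions `n_states x n_states` row-stochastic matrix.
#' @param initial initial state distribution (sums to 1).
#' @param labels distinct single-character state labels;
#'   default [sa_letters()].
#' @return an object of class `sa_model`.
#' @export
sa_model <- function(means, covariances, transitions, initial,
                     labels = sa_letters(nrow(as.matrix(means)))) {
  means <- as.matrix(means)
  k <- nrow(means)
  if (is.array(covariances) && length(dim(covariances)) == 3L) {
    covariances <- lapply(seq_len(dim(covariances)[3]),
                          function(i) covariances[, , i])
  }
  transitions <- as.matrix(transitions)
  m <- structure(
    list(
      n_states = k,
      labels = as.character(labels),
      means = unname(means),
      covariances = lapply(covariances, unname),
      transitions = unname(transitions),
      initial = unname(as.numeric(initial))
    ),
    class = "sa_model"
  )
  validate_sa_model(m)
  m
}

validate_sa_model <- function(m, tol = 1e-9) {
  k <- m$n_states
  if (length(m$labels) != k || anyDuplicated(m$labels)) {
    abort("state labels must be unique, one per state.")
  }
  if (any(nchar(m$labels) != 1L)) abort("state labels must be single characters.")
  if (nrow(m$means) != k || ncol(m$means) != 4L) {
    abort("`means` must be n_states x 4.")
  }
  if (length(m$covariances) != k) abort("one covariance per state is required.")
  for (i in seq_len(k)) {
    s <- m$covariances[[i]]
    if (!isTRUE(all.equal(s, t(s), tolerance = 1e-8))) {
      abort(sprintf("covariance of state %d is not symmetric.", i))
    }
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      abort(sprintf("covariance of state %d is not positive-definite.", i))
    }
  }
  if (any(dim(m$transitions) != k) || any(m$transitions < 0) ||
      any(abs(rowSums(m$transitions) - 1) > tol)) {
    abort("`transitions` must be row-stochastic (rows sum to 1 within 1e-9).")
  }
  if (length(m$initial) != k || any(m$initial < 0) ||
      abs(sum(m$initial) - 1) > tol) {
    abort("`initial` must be a probability vector summing to 1 within 1e-9.")
  }
  invisible(m)
}

#' @export
print.sa_model <- function(x, ...) {
  cat(sprintf(
    "<sa_model> %d letters (%s), Gaussian emissions over (d13, d14, d24, v)\n",
    x$n_states, paste(head(x$labels, 6), collapse = "")
  ))
  invisible(x)
}

#' Read / write a structural alphabet model as JSON
#'
#' The on-disk schema is a single JSON object with fields `labels`,
#' `descriptors`, `means`, `covariances`, `transitions` and `initial`.
#'
#' @param path file path.
#' @return `read_sa_model()` returns an `sa_model`;
#'   `write_sa_model()` returns `path` invisibly.
#' @export
read_sa_model <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  covs <- j$covariances
  if (is.array(covs) && length(dim(covs)) == 3L) {
    # stored as [state][row][col]
    covs <- lapply(seq_len(dim(covs)[1]), function(i) covs[i, , ])
  } else if (is.list(covs)) {
    covs <- lapply(covs, function(s) matrix(unlist(s), 4L, 4L, byrow = TRUE))
  }
  # printed precision can leave row sums a hair off 1; renormalize
  A <- as.matrix(j$transitions)
  if (any(abs(rowSums(A) - 1) > 1e-6)) {
    abort("transition rows in the model file do not sum to 1.")
  }
  A <- A / rowSums(A)
  p0 <- as.numeric(j$initial)
  if (abs(sum(p0) - 1) > 1e-6) {
    abort("initial probabilities in the model file do not sum to 1.")
  }
  sa_model(
    means = j$means, covariances = covs, transitions = A,
    initial = p0 / sum(p0), labels = j$labels
  )
}

#' @rdname read_sa_model
#' @param model an `sa_model`.
#' @param digits significant digits kept on disk.
#' @export
write_sa_model <- function(model, path, digits = 8) {
  validate_sa_model(model)
  obj <- list(
    labels = model$labels,
    descriptors = c("d13", "d14", "d24", "v"),
    means = signif(model$means, digits),
    covariances = lapply(model$covariances, signif, digits = digits),
    transitions = signif(model$transitions, digits),
    initial = signif(model$initial, digits)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' The toy 27-letter model shipped with the package
#'
#' A 27-state model fitted with [fit_baum_welch()] on a synthetic bank
#' of idealized helices, strands, hairpins and coil ([build_bank()]).
#' It is a stand-in for alphabets trained on real structure
#' collections: adequate to encode the package's synthetic structures
#' and to exercise the full search protocol, not a description of the
#' true local-conformation landscape of proteins.
#'
#' @return an `sa_model` with 27 states.
#' @export
toy_sa_model <- function() {
  read_sa_model(system.file("extdata", "sa_model_toy27.json",
                            package = "sapick", mustWork = TRUE))
}
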