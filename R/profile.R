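#' Structural alphabet probability profiles
#'
#' An `sa_profile` holds, for an `N`-residue chain, the `N - 3` rows of
#' per-letter probabilities (one row per overlapping four-residue
#' window, one column per letter).  Rows are probability vectors
#' summing to 1; rows at windows spanning a chain break are `NA`.
#'
#' @param prob numeric matrix (or data frame) of probabilities, one
#'   column per letter.
#' @param letters letter labels, one per column.
#' @param source_id identifier of the chain the profile describes.
#' @return a tibble of class `sa_profile` with column `pos` (1-based
#'   window index) followed by one probability column per letter;
#'   attributes `source_id` and `letters`.
#' @export
sa_profile <- function(prob, letters = sa_letters(ncol(as.matrix(prob))),
                       source_id = "query") {
  prob <- as.matrix(prob)
  if (length(letters) != ncol(prob)) {
    abort("`letters` must name every probability column.")
  }
  # absorb print/round-off drift; anything larger needs normalize_profile()
  if (nrow(prob)) {
    ok <- stats::complete.cases(prob)
    s <- rowSums(prob)
    if (any(abs(s[ok] - 1) > 1e-4)) {
      abort(sprintf("profile row %d does not sum to 1 (use normalize_profile()).",
                    which(ok & abs(s - 1) > 1e-4)[1]))
    }
    prob[ok, ] <- prob[ok, , drop = FALSE] / s[ok]
  }
  colnames(prob) <- letters
  out <- tibble(pos = seq_len(nrow(prob)))
  out <- dplyr::bind_cols(out, as_tibble(prob))
  attr(out, "source_id") <- as.character(source_id)
  attr(out, "letters") <- as.character(letters)
  class(out) <- c("sa_profile", class(out))
  validate_sa_profile(out)
  out
}

profile_letters <- function(profile) {
  attr(profile, "letters") %||% setdiff(colnames(profile), "pos")
}

#' Probability matrix of a profile
#'
#' @param profile an [sa_profile()].
#' @return numeric matrix, one row per window, one column per letter.
#' @export
profile_matrix <- function(profile) {
  as.matrix(profile[, profile_letters(profile), drop = FALSE])
}

validate_sa_profile <- function(profile, tol = 1e-6) {
  p <- profile_matrix(profile)
  ok <- stats::complete.cases(p)
  if (any(p[ok, ] < -tol) || any(p[ok, ] > 1 + tol)) {
    abort("profile entries must lie in [0, 1].")
  }
  bad <- which(ok & abs(rowSums(p) - 1) > tol)
  if (length(bad)) {
    abort(sprintf("profile row %d does not sum to 1.", bad[1]))
  }
  invisible(profile)
}

#' @export
print.sa_profile <- function(x, ...) {
  cat(sprintf("<sa_profile> %s: %d positions x %d letters\n",
              attr(x, "source_id") %||% "?", nrow(x),
              length(profile_letters(x))))
  NextMethod()
}

#' Normalize nonnegative rows into a probability profile
#'
#' Divides every row by its sum.  Idempotent on valid profiles.
#'
#' @param raw matrix, data frame or [sa_profile()] of nonnegative
#'   values, one column per letter (a leading `pos` column is
#'   ignored).
#' @inheritParams sa_profile
#' @return an [sa_profile()].
#' @export
#' @examples
#' normalize_profile(matrix(c(2, 2, rep(0, 25)), 1), source_id = "x")
normalize_profile <- function(raw, letters = NULL, source_id = NULL) {
  if (inherits(raw, "sa_profile") || (is.data.frame(raw) && "pos" %in% names(raw))) {
    letters <- letters %||% profile_letters(raw)
    source_id <- source_id %||% attr(raw, "source_id") %||% "query"
    m <- as.matrix(raw[, setdiff(colnames(raw), "pos"), drop = FALSE])
  } else {
    m <- as.matrix(raw)
    letters <- letters %||% colnames(m) %||% sa_letters(ncol(m))
    source_id <- source_id %||% "query"
  }
  ok <- stats::complete.cases(m)
  if (any(m[ok, ] < 0)) {
    abort(sprintf("negative entry in row %d.",
                  which(ok & apply(m < 0, 1, any))[1]))
  }
  s <- rowSums(m)
  zero <- which(ok & s <= 0)
  if (length(zero)) {
    abort(sprintf("row %d is all zero and cannot be normalized.", zero[1]))
  }
  sa_profile(m / s, letters = letters, source_id = source_id)
}

#' Read / write profiles in the package's TSV dialect
#'
#' The dialect is: line 1 `#SA-PROFILE 1 <source_id>`; line 2 the
#' tab-separated letter labels; then one line per window holding the
#' 1-based position index and the per-letter probabilities printed
#' with six decimals.  Rows at chain breaks are written as `NA`.
#'
#' @param path file path.
#' @return `read_profile()` returns an [sa_profile()];
#'   `write_profile()` returns `path` invisibly.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1], "#SA-PROFILE 1")) {
    abort("not a v1 profile file (missing '#SA-PROFILE 1' header).")
  }
  source_id <- sub("^#SA-PROFILE 1\\s*", "", lines[1])
  letters <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(letters)) abort("duplicated letter labels in header.")
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(sa_profile(matrix(numeric(0), 0, length(letters)),
                      letters = letters, source_id = source_id))
  }
  rows <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(rows)
  bad <- which(nfield != length(letters) + 1L)
  if (length(bad)) {
    abort(sprintf("line %d: expected %d fields, found %d.",
                  bad[1] + 2L, length(letters) + 1L, nfield[bad[1]]))
  }
  m <- matrix(NA_real_, length(rows), length(letters))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]][-1]))
    if (any(is.na(v) & rows[[i]][-1] != "NA")) {
      abort(sprintf("line %d: non-numeric probability field.", i + 2L))
    }
    m[i, ] <- v
  }
  sa_profile(m, letters = letters, source_id = source_id)
}

#' @rdname read_profile
#' @param profile an [sa_profile()].
#' @export
write_profile <- function(profile, path) {
  validate_sa_profile(profile)
  letters <- profile_letters(profile)
  m <- profile_matrix(profile)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#SA-PROFILE 1 %s", attr(profile, "source_id") %||% "query"),
             con)
  writeLines(paste(letters, collapse = "\t"), con)
  if (nrow(m)) {
    txt <- apply(m, 1, function(r) {
      paste(ifelse(is.na(r), "NA", sprintf("%.6f", r)), collapse = "\t")
    })
    writeLines(paste(seq_len(nrow(m)), txt, sep = "\t"), con)
  }
  invisible(path)
}

#' Emulate a sequence-based profile predictor
#'
#' Real profiles predicted from sequence are smoother and noisier than
#' posteriors decoded from the structure itself.  This generator
#' emulates that: each row is replaced by a Dirichlet draw centred on
#' it, with parameter `concentration * row + 0.01` (the 0.01 floor
#' keeps all letters represented).  As `concentration` grows the draw
#' concentrates on the input row.
#'
#' @param profile an [sa_profile()] of exact posteriors.
#' @param concentration Dirichlet concentration (> 0); the default 50
#'   gives realistic predictor-grade smearing.
#' @param seed integer seed; same seed, same output.
#' @return an [sa_profile()] of the same shape.
#' @export
pseudo_predict <- function(profile, concentration = 50, seed = 1L) {
  if (!is.numeric(concentration) || concentration <= 0) {
    abort("`concentration` must be a positive number.")
  }
  m <- profile_matrix(profile)
  ok <- stats::complete.cases(m)
  out <- m
  withr::with_seed(seed, {
    for (i in which(ok)) {
      g <- rgamma(ncol(m), shape = concentration * m[i, ] + 0.01)
      out[i, ] <- g / sum(g)
    }
  })
  sa_profile(out, letters = profile_letters(profile),
             source_id = attr(profile, "source_id") %||% "query")
}

#' @describeIn sa_profile stacked-probability view of a profile.
#' @param object an `sa_profile`.
#' @param ... unused.
#' @export
autoplot.sa_profile <- function(object, ...) {
  letters <- profile_letters(object)
  long <- tidyr::pivot_longer(as_tibble(object), cols = dplyr::all_of(letters),
                              names_to = "letter", values_to = "prob")
  long$letter <- factor(long$letter, levels = letters)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$prob,
                                     fill = .data$letter)) +
    ggplot2::geom_col(width = 1, show.legend = FALSE) +
    ggplot2::labs(x = "window position", y = "letter probability",
                  title = attr(object, "source_id")) +
    ggplot2::theme_minimal()
}
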