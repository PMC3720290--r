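#' Lower-triangular Toeplitz abundance matrix
#'
#' Builds the convolution matrix whose columns are shifted copies of a
#' generator vector (zero-padded): `A[i, j] = g[i - j + 1]` whenever
#' `0 <= i - j < length(g)` and 0 elsewhere. Multiplying this matrix by an
#' isotopomer-group vector performs the forward convolution of the generator
#' with that vector; solving the system in the least-squares sense undoes it.
#'
#' The generator is normally a natural-abundance distribution, so that each
#' column j holds the isotope envelope of the isotopomer group carrying j - 1
#' heavy atoms, aligned at mass offset j - 1.
#'
#' @param generator Non-empty numeric vector (e.g. [natural_abundance()]).
#' @param n_rows Number of rows = number of observed mass offsets.
#' @param n_cols Number of columns = number of isotopomer groups; must not
#'   exceed `n_rows`.
#' @return An `n_rows` x `n_cols` numeric matrix of class `abundance_matrix`
#'   with the generator kept in attribute `generator`.
#' @examples
#' abundance_matrix(c(0.9, 0.08, 0.02), n_rows = 4, n_cols = 2)
#' @export
abundance_matrix <- function(generator, n_rows, n_cols) {
  generator <- as.numeric(generator)
  if (length(generator) == 0L || anyNA(generator))
    stop("`generator` must be a non-empty numeric vector without NA",
         call. = FALSE)
  if (n_rows < n_cols || n_cols < 1L)
    stop(sprintf("need n_rows >= n_cols >= 1 (got %d x %d)", n_rows, n_cols),
         call. = FALSE)
  a <- matrix(0, nrow = n_rows, ncol = n_cols)
  for (j in seq_len(n_cols)) {
    k <- min(length(generator), n_rows - j + 1L)
    if (k > 0L) a[j:(j + k - 1L), j] <- generator[seq_len(k)]
  }
  structure(a, generator = generator, class = c("abundance_matrix", "matrix"))
}

#' Least-squares deconvolution via the Moore-Penrose pseudoinverse
#'
#' Solves \eqn{\min_x \|A x - P\|_2} for the isotopomer-group abundances `x`
#' given the abundance matrix `A` and the observed relative intensities `P`.
#' The solution is computed through the singular value decomposition; singular
#' values below `sv_tol` times the largest are treated as zero (and, by
#' default, trigger a conditioning error rather than a silently truncated
#' solution).
#'
#' Fitted abundances can come out slightly negative when noise pushes a group
#' that is truly absent below zero; these are clamped to zero in the `clamped`
#' field (the `raw` solution is always retained for diagnostics).
#'
#' @param a Abundance matrix from [abundance_matrix()] (or any numeric matrix
#'   with at least as many rows as columns).
#' @param p Numeric vector of observed relative intensities, one per row of
#'   `a`.
#' @param sv_tol Relative singular-value cutoff (default `1e-12`).
#' @param clamp If `TRUE` (default) negatives in the solution are set to zero
#'   before the model reconstruction is formed.
#' @return An object of class `fitted_abundances`: a list with fields
#'   `raw` (the unconstrained least-squares solution), `clamped`
#'   (`pmax(raw, 0)` if `clamp`, else `raw`), `reconstruction` (`a %*%
#'   clamped`, the model-predicted intensities), `residual` (`p -
#'   a %*% raw`), and `condition` (ratio of extreme singular values).
#' @examples
#' na <- natural_abundance(3)
#' a <- abundance_matrix(na, n_rows = 7, n_cols = 4)
#' p <- forward_convolve(c(0.5, 0.1, 0.1, 0.3), na)
#' least_squares_solve(a, p)$raw
#' @export
least_squares_solve <- function(a, p, sv_tol = 1e-12, clamp = TRUE) {
  a <- unclass(a)
  attr(a, "generator") <- NULL
  p <- as.numeric(p)
  if (!is.matrix(a)) stop("`a` must be a matrix", call. = FALSE)
  if (length(p) != nrow(a))
    stop(sprintf("length(p) = %d must equal nrow(a) = %d",
                 length(p), nrow(a)), call. = FALSE)
  if (nrow(a) < ncol(a))
    stop("system is underdetermined: fewer observations than groups",
         call. = FALSE)
  sv <- svd(a)
  d <- sv$d
  if (d[1] <= 0)
    stop("abundance matrix is identically zero", call. = FALSE)
  condition <- d[1] / d[length(d)]
  keep <- d > sv_tol * d[1]
  if (!all(keep))
    stop(sprintf(
      "abundance matrix is rank-deficient beyond tolerance (condition estimate %.3g)",
      condition), call. = FALSE)
  raw <- as.numeric(sv$v %*% ((crossprod(sv$u, p)) / d))
  clamped <- if (clamp) pmax(raw, 0) else raw
  structure(list(
    raw = raw,
    clamped = clamped,
    reconstruction = as.numeric(a %*% clamped),
    residual = as.numeric(p - a %*% raw),
    condition = condition
  ), class = "fitted_abundances")
}

#' @export
print.fitted_abundances <- function(x, ...) {
  cat("<fitted_abundances>\n")
  cat("  raw:     ", paste(format(x$raw, digits = 6), collapse = "  "), "\n")
  cat("  clamped: ", paste(format(x$clamped, digits = 6), collapse = "  "), "\n")
  cat(sprintf("  condition estimate: %.4g\n", x$condition))
  invisible(x)
}

#' Clamp negative entries of a vector to zero
#'
#' Small negative fitted abundances are numerical artifacts of the
#' unconstrained least-squares fit; reports print them as exactly 0.
#'
#' @param x Numeric vector.
#' @return `pmax(x, 0)`, same length and order.
#' @examples
#' clamp_negatives(c(1.02, -0.003, -0.001, 0.44))
#' @export
clamp_negatives <- function(x) pmax(as.numeric(x), 0)

#' Natural-abundance correction of an observed fragment spectrum
#'
#' The core pipeline step: from a validated [metabolite_record()], build the
#' natural-abundance generator for the fragment, place it into a Toeplitz
#' abundance matrix with one row per observed mass offset and one column per
#' isotopomer group (fragment carbons + 1), and solve the least-squares
#' system for the group abundances of the labelled sample.
#'
#' When the fragment carries carbons from a derivatization agent whose
#' natural-abundance signal should be modelled but which cannot themselves be
#' labelled, pass their count as `extra_atoms`: the generator is then computed
#' for `n_carbons_fragment + extra_atoms` positions while the number of
#' isotopomer groups stays at `n_carbons_fragment + 1`.
#'
#' @param record A [metabolite_record()].
#' @param isotopes An [isotope_pair()] (default natural \eqn{^{13}C}).
#' @param extra_atoms Additional (unlabelable) atoms contributing natural
#'   abundance, default 0.
#' @param window Optional [mass_window()]; computed from the record via
#'   [estimate_mass_window()] when missing.
#' @param two_stage If `TRUE`, after the standard fit the abundance matrix is
#'   rebuilt from the stage-one model-reconstructed intensities and the system
#'   is solved a second time against the observed intensities. This mirrors a
#'   historically described (but mathematically circular) second regression
#'   stage; it is off by default and intended for diagnostics only.
#' @param clamp,sv_tol Passed to [least_squares_solve()].
#' @param verbose If `TRUE`, log excluded peaks, the condition estimate and
#'   clamped groups to `message()`.
#' @return A `fitted_abundances` object (see [least_squares_solve()]) with two
#'   extra fields: `offsets` (the integer mass offsets used) and `observed`
#'   (the intensities entering the fit).
#' @examples
#' rec <- metabolite_record("Gly", c(100.1, 101.1, 102.1), c(9, 0.5, 3),
#'                          n_carbons_metabolite = 2, n_carbons_fragment = 2)
#' correct_spectrum(rec)
#' @export
correct_spectrum <- function(record, isotopes = isotope_pair(),
                             extra_atoms = 0L, window = NULL,
                             two_stage = FALSE, clamp = TRUE,
                             sv_tol = 1e-12, verbose = FALSE) {
  stopifnot(inherits(record, "metabolite_record"))
  if (all(record$intensities == 0))
    stop("all observed intensities are zero", call. = FALSE)
  if (is.null(window)) window <- estimate_mass_window(record)
  spec <- map_offsets(record, window, verbose = verbose)
  n_groups <- record$n_carbons_fragment + 1L
  if (length(spec$intensities) < n_groups)
    stop(sprintf(
      "only %d usable peaks for %d isotopomer groups; system is underdetermined",
      length(spec$intensities), n_groups), call. = FALSE)
  gen <- natural_abundance(record$n_carbons_fragment + extra_atoms, isotopes)
  n_rows <- max(spec$offsets) + 1L
  p <- numeric(n_rows)
  p[spec$offsets + 1L] <- spec$intensities
  a <- abundance_matrix(gen, n_rows = n_rows, n_cols = n_groups)
  fit <- least_squares_solve(a, p, sv_tol = sv_tol, clamp = clamp)
  if (two_stage) {
    gen2 <- fit$reconstruction
    if (all(gen2 == 0)) stop("stage-one reconstruction is zero", call. = FALSE)
    a2 <- abundance_matrix(gen2 / sum(gen2), n_rows = n_rows, n_cols = n_groups)
    fit <- least_squares_solve(a2, p, sv_tol = sv_tol, clamp = clamp)
  }
  if (verbose) {
    message(sprintf("condition estimate: %.4g", fit$condition))
    neg <- which(fit$raw < 0)
    if (clamp && length(neg))
      message("clamped negative group(s): ",
              paste(neg - 1L, collapse = ", "))
  }
  fit$offsets <- spec$offsets
  fit$observed <- spec$intensities
  fit
}
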