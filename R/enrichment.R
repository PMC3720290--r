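#' Normalize non-negative abundances to molar percentages
#'
#' @param abundances Non-negative numeric vector with at least one positive
#'   entry.
#' @return Numeric vector `100 * abundances / sum(abundances)`; sums to 100.
#' @examples
#' normalize_to_percent(c(1.01811623727288, 0, 0, 0.436317933953475))
#' @export
normalize_to_percent <- function(abundances) {
  x <- as.numeric(abundances)
  if (length(x) == 0L || anyNA(x) || any(x < 0))
    stop("`abundances` must be non-negative and NA-free", call. = FALSE)
  s <- sum(x)
  if (s <= 0) stop("all abundances are zero; nothing to normalize",
                   call. = FALSE)
  100 * x / s
}

#' Absolute isotope enrichment of a fragment
#'
#' The mean fraction of labelled positions per molecule: with normalized
#' isotopomer-group fractions \eqn{f_0 \dots f_n} over a fragment of `a`
#' labelable atoms,
#' \deqn{\mathrm{Abs} = \frac{\sum_{i=0}^{n} f_i \, i}{a} \in [0, 1].}
#' For a binomial distribution with per-atom heavy probability \eqn{p_1} this
#' equals \eqn{p_1} exactly (the binomial mean is \eqn{n p_1}).
#'
#' @param fractions Numeric vector of group fractions summing to 1, length
#'   `n_fragment_atoms + 1`.
#' @param n_fragment_atoms Number of labelable atoms in the fragment.
#' @param normalized If `TRUE` (default) `fractions` must already sum to 1
#'   within `1e-6`; set `FALSE` to normalize internally.
#' @return A single fraction in \[0, 1\].
#' @examples
#' absolute_enrichment(c(0.7, 0, 0, 0.3), 3)   # 0.3
#' absolute_enrichment(natural_abundance(3), 3)  # 0.0111
#' @export
absolute_enrichment <- function(fractions, n_fragment_atoms,
                                normalized = TRUE) {
  f <- as.numeric(fractions)
  if (length(f) != n_fragment_atoms + 1L)
    stop(sprintf("length(fractions) = %d must equal n_fragment_atoms + 1 = %d",
                 length(f), n_fragment_atoms + 1L), call. = FALSE)
  if (normalized) {
    if (abs(sum(f) - 1) > 1e-6)
      stop("`fractions` do not sum to 1; pass normalized = FALSE to rescale",
           call. = FALSE)
  } else {
    f <- f / sum(f)
  }
  sum(f * (seq_along(f) - 1L)) / n_fragment_atoms
}

#' Notation labels for isotopomer groups
#'
#' Group 0 (no heavy atoms) is written as all zeros, group n (fully labelled)
#' as all ones; intermediate groups, whose label positions the mass
#' spectrometer cannot resolve, are written with `X` placeholders followed by
#' the number of labels, e.g. `"[XXX] 2"`.
#'
#' @param n_atoms Number of labelable atoms (positive integer).
#' @return Character vector of `n_atoms + 1` labels.
#' @examples
#' isotopomer_labels(3)  # "[000]" "[XXX] 1" "[XXX] 2" "[111]"
#' @export
isotopomer_labels <- function(n_atoms) {
  if (!is.numeric(n_atoms) || length(n_atoms) != 1L || n_atoms < 1 ||
      n_atoms != round(n_atoms))
    stop("`n_atoms` must be a single positive integer", call. = FALSE)
  n <- as.integer(n_atoms)
  labs <- character(n + 1L)
  labs[1L] <- paste0("[", strrep("0", n), "]")
  labs[n + 1L] <- paste0("[", strrep("1", n), "]")
  if (n > 1L)
    for (k in seq_len(n - 1L))
      labs[k + 1L] <- paste0("[", strrep("X", n), "] ", k)
  labs
}

#' Assemble an isotopomer analysis result
#'
#' Combines the natural-abundance model and the fitted labelled-sample
#' abundances of one fragment into the quantities a report prints: molar
#' percentages for both, group labels, and absolute enrichments. The
#' enrichment of the labelled sample is computed from the *normalized*
#' fraction vector; the unnormalized weighted sum is kept in
#' `abs_enrichment_unnormalized` as a diagnostic.
#'
#' @param na [natural_abundance()] distribution of the fragment.
#' @param fitted Non-negative fitted group abundances of the labelled sample
#'   (e.g. the `clamped` field of [correct_spectrum()]).
#' @param n_atoms Number of labelable atoms; defaults to `length(na) - 1`.
#' @return An object of class `isotopomer_result` with fields `labels`,
#'   `natural_percent`, `labelled_percent`, `abs_enrichment_natural`,
#'   `abs_enrichment_labelled`, `abs_enrichment_unnormalized`.
#' @examples
#' isotopomer_result(natural_abundance(3),
#'                   c(1.01811623727288, 0, 0, 0.436317933953475))
#' @export
isotopomer_result <- function(na, fitted, n_atoms = length(na) - 1L) {
  na <- as.numeric(na)
  fitted <- as.numeric(fitted)
  if (length(na) != n_atoms + 1L || length(fitted) != n_atoms + 1L)
    stop("`na` and `fitted` must both have length n_atoms + 1", call. = FALSE)
  if (any(fitted < 0))
    stop("`fitted` must be non-negative (clamp first)", call. = FALSE)
  np <- normalize_to_percent(na)
  lp <- normalize_to_percent(fitted)
  structure(list(
    labels = isotopomer_labels(n_atoms),
    natural_percent = np,
    labelled_percent = lp,
    abs_enrichment_natural = absolute_enrichment(np / 100, n_atoms),
    abs_enrichment_labelled = absolute_enrichment(lp / 100, n_atoms),
    abs_enrichment_unnormalized =
      sum(fitted * (seq_along(fitted) - 1L)) / n_atoms
  ), class = "isotopomer_result")
}

#' @export
print.isotopomer_result <- function(x, digits = 10, ...) {
  cat("<isotopomer_result>\n")
  df <- data.frame(
    group = x$labels,
    `natural %` = formatC(x$natural_percent, digits = digits, format = "g"),
    `labelled %` = formatC(x$labelled_percent, digits = digits, format = "g"),
    check.names = FALSE
  )
  print(df, row.names = FALSE)
  cat(sprintf("absolute enrichment: natural %.6g, labelled %.6g\n",
              x$abs_enrichment_natural, x$abs_enrichment_labelled))
  invisible(x)
}

#' @export
as.data.frame.isotopomer_result <- function(x, ...) {
  data.frame(
    label = x$labels,
    natural_percent = x$natural_percent,
    labelled_percent = x$labelled_percent,
    abs_enrichment_natural = x$abs_enrichment_natural,
    abs_enrichment_labelled = x$abs_enrichment_labelled,
    stringsAsFactors = FALSE
  )
}
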