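#' Two-isotope abundance pair
#'
#' Describes a chemical element with exactly two stable isotopes by the
#' fractional abundance of its light (`p0`) and heavy (`p1`) form, e.g.
#' \eqn{^{12}C}/\eqn{^{13}C} or \eqn{^{14}N}/\eqn{^{15}N}. The two fractions
#' must sum to one; only `p1` needs to be supplied.
#'
#' The default `p1 = 0.0111` is the natural \eqn{^{13}C} abundance used
#' throughout the worked examples (1.11\% heavy carbon per position). For
#' \eqn{^{15}N} a typical value is `0.00364`. Elements with more than two
#' stable isotopes (Si, S) are outside the scope of the binomial model.
#'
#' @param p1 Fractional abundance of the heavy isotope, in \[0, 1\].
#' @param p0 Fractional abundance of the light isotope; defaults to `1 - p1`.
#' @return An object of class `isotope_pair` with fields `p0` and `p1`.
#' @examples
#' isotope_pair()            # natural 13C
#' isotope_pair(p1 = 0.00364)  # natural 15N
#' @export
isotope_pair <- function(p1 = 0.0111, p0 = 1 - p1) {
  if (!is.numeric(p1) || length(p1) != 1L || is.na(p1) || p1 < 0 || p1 > 1)
    stop("`p1` must be a single number in [0, 1]", call. = FALSE)
  if (!is.numeric(p0) || length(p0) != 1L || is.na(p0) || p0 < 0 || p0 > 1)
    stop("`p0` must be a single number in [0, 1]", call. = FALSE)
  if (abs(p0 + p1 - 1) > 1e-12)
    stop("`p0` + `p1` must equal 1 (got ", format(p0 + p1, digits = 17), ")",
         call. = FALSE)
  structure(list(p0 = p0, p1 = p1), class = "isotope_pair")
}

#' @export
print.isotope_pair <- function(x, ...) {
  cat(sprintf("<isotope_pair> light p0 = %.6g, heavy p1 = %.6g\n", x$p0, x$p1))
  invisible(x)
}

#' Binomial natural-abundance distribution of isotopomer groups
#'
#' Probability that a fragment with `n_atoms` labelable positions carries
#' exactly i heavy atoms purely by natural isotope abundance:
#' \deqn{A_i = \binom{n}{i} p_0^{\,n-i} p_1^{\,i}, \qquad i = 0 \dots n.}
#' This is the isotope envelope an unlabelled compound shows in the mass
#' spectrum, and the generator vector from which the correction matrix is
#' built.
#'
#' Binomial coefficients are evaluated on the log scale (`lchoose`) so that
#' large fragments (derivatized amino acids can exceed 20 carbons) do not
#' overflow.
#'
#' @param n_atoms Number of labelable atoms in the fragment (positive integer).
#' @param isotopes An [isotope_pair()]; defaults to natural \eqn{^{13}C}.
#' @return An object of class `na_distribution`: a numeric vector of length
#'   `n_atoms + 1` summing to 1, with attributes `n_atoms` and `p1`.
#' @examples
#' natural_abundance(3)                 # 3-carbon fragment, natural 13C
#' natural_abundance(2, isotope_pair(0.5))  # 1:2:1
#' @export
natural_abundance <- function(n_atoms, isotopes = isotope_pair()) {
  if (!is.numeric(n_atoms) || length(n_atoms) != 1L || is.na(n_atoms) ||
      n_atoms < 1 || n_atoms != round(n_atoms))
    stop("`n_atoms` must be a single positive integer", call. = FALSE)
  if (!inherits(isotopes, "isotope_pair"))
    isotopes <- isotope_pair(p1 = isotopes)
  n <- as.integer(n_atoms)
  i <- 0:n
  p0 <- isotopes$p0
  p1 <- isotopes$p1
  # log-scale product; the p1 = 0 / p1 = 1 edges need 0*log(0) := 0
  lp1 <- ifelse(i == 0L, 0, i * log(p1))
  lp0 <- ifelse(i == n, 0, (n - i) * log(p0))
  a <- exp(lchoose(n, i) + lp0 + lp1)
  a <- a / sum(a)
  structure(a, n_atoms = n, p1 = p1, class = "na_distribution")
}

#' @export
print.na_distribution <- function(x, ...) {
  n <- attr(x, "n_atoms")
  cat(sprintf("<na_distribution> n = %d atoms, p1 = %.6g\n", n, attr(x, "p1")))
  v <- as.numeric(x)
  names(v) <- paste0("M+", 0:n)
  print(v, ...)
  invisible(x)
}

#' Forward convolution of an isotopomer distribution with natural abundance
#'
#' Predicts the relative mass pattern observed for a labelled compound: the
#' molar isotopomer-group fractions (index = number of heavy atoms introduced
#' by labelling) are convolved with the natural-abundance envelope of the
#' remaining positions,
#' \deqn{U_k = \sum_j d_j \, a_{k-j}.}
#' This is the generative model inverted by [least_squares_solve()]; the
#' synthetic-spectrum generator uses it to produce spectra with known truth.
#'
#' @param dist Numeric vector of isotopomer-group fractions (index 0 first).
#' @param na Numeric vector of natural-abundance probabilities (index 0 first),
#'   typically from [natural_abundance()].
#' @return Numeric vector of length `length(dist) + length(na) - 1` of
#'   predicted relative intensities; its sum is `sum(dist) * sum(na)`.
#' @examples
#' na <- natural_abundance(3)
#' forward_convolve(c(0.7, 0, 0, 0.3), na)
#' @export
forward_convolve <- function(dist, na) {
  dist <- as.numeric(dist)
  na <- as.numeric(na)
  if (length(dist) == 0L || length(na) == 0L)
    stop("`dist` and `na` must be non-empty", call. = FALSE)
  if (anyNA(dist) || anyNA(na))
    stop("`dist` and `na` must not contain NA", call. = FALSE)
  out <- numeric(length(dist) + length(na) - 1L)
  for (j in seq_along(dist)) {
    idx <- j:(j + length(na) - 1L)
    out[idx] <- out[idx] + dist[j] * na
  }
  out
}
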