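#' One fragment's raw mass-spectrometric observation
#'
#' A metabolite record couples the m/e readings of one fragment with their
#' integrated relative intensities and the carbon counts needed to size the
#' natural-abundance model. Peak integration itself is delegated to the
#' instrument vendor's software; this package starts from the integrated
#' intensities.
#'
#' @param name Metabolite (and fragment) name; non-empty.
#' @param mz_values Strictly increasing numeric m/e readings (Th).
#' @param intensities Matched non-negative relative intensities.
#' @param n_carbons_metabolite Carbons in the intact metabolite.
#' @param n_carbons_fragment Labelable carbons in this fragment (sets the
#'   number of isotopomer groups to `n_carbons_fragment + 1`).
#' @return An object of class `metabolite_record`.
#' @examples
#' metabolite_record("Alanine (Ala)",
#'   c(259.15, 260.1, 261.1, 262.1, 263.1, 264.1, 265.1),
#'   c(0.07, 8.53, 2.3, 2.39, 44.59, 8.79, 3.88), 3, 3)
#' @export
metabolite_record <- function(name, mz_values, intensities,
                              n_carbons_metabolite, n_carbons_fragment) {
  name <- as.character(name)
  if (length(name) != 1L || is.na(name) || !nzchar(trimws(name)))
    stop("record name must be a non-empty string", call. = FALSE)
  mz_values <- as.numeric(mz_values)
  intensities <- as.numeric(intensities)
  if (length(mz_values) != length(intensities) || length(mz_values) < 1L)
    stop(sprintf(
      "m/e and intensity lists must be matched and non-empty (got %d m/e vs %d intensities)",
      length(mz_values), length(intensities)), call. = FALSE)
  if (anyNA(mz_values) || anyNA(intensities))
    stop("m/e values and intensities must not contain NA", call. = FALSE)
  if (is.unsorted(mz_values, strictly = TRUE))
    stop("m/e values must be strictly increasing", call. = FALSE)
  if (any(intensities < 0))
    stop("intensities must be non-negative", call. = FALSE)
  for (nm in c("n_carbons_metabolite", "n_carbons_fragment")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != round(v))
      stop(sprintf("`%s` must be a single positive integer", nm),
           call. = FALSE)
  }
  structure(list(
    name = name,
    mz_values = mz_values,
    intensities = intensities,
    n_carbons_metabolite = as.integer(n_carbons_metabolite),
    n_carbons_fragment = as.integer(n_carbons_fragment)
  ), class = "metabolite_record")
}

#' @export
print.metabolite_record <- function(x, ...) {
  cat(sprintf("<metabolite_record> %s  (%d carbons, fragment %d)\n",
              x$name, x$n_carbons_metabolite, x$n_carbons_fragment))
  print(data.frame(mz = x$mz_values, intensity = x$intensities),
        row.names = FALSE)
  invisible(x)
}

# -- '.ls' dialect -----------------------------------------------------------
# One record per line, five TAB-separated fields in the order
#   name <TAB> m/e list <TAB> intensity list <TAB> C metabolite <TAB> C fragment
# Numeric lists are '#'-separated; a trailing '#' is tolerated. Decimal mark
# is '.' or (per locale) ','. Blank lines and lines starting with ';' are
# skipped on read.

split_hash <- function(s) {
  toks <- strsplit(s, "#", fixed = TRUE)[[1]]
  toks <- trimws(toks)
  while (length(toks) && !nzchar(toks[length(toks)]))
    toks <- toks[-length(toks)]
  toks
}

parse_numeric_tokens <- function(tokens, locale, what) {
  vapply(seq_along(tokens), function(i) {
    tok <- tokens[i]
    t2 <- switch(locale,
      dot = tok,
      comma = gsub(",", ".", tok, fixed = TRUE),
      auto = if (grepl(",", tok, fixed = TRUE) &&
                 !grepl(".", tok, fixed = TRUE))
               gsub(",", ".", tok, fixed = TRUE) else tok
    )
    v <- suppressWarnings(as.numeric(t2))
    if (is.na(v))
      stop(sprintf("unparseable %s token '%s' at position %d", what, tok, i),
           call. = FALSE)
    v
  }, numeric(1))
}

#' Parse one '.ls' metabolite record
#'
#' Reads a single tab-separated record line of the '.ls' dialect (see
#' [read_ls()]). Numeric lists are split on `'#'` with empty trailing tokens
#' dropped. The decimal mark is locale-dependent: `"dot"` uses `'.'`,
#' `"comma"` uses `','` (the convention of German-locale exports), and
#' `"auto"` (default) treats a `','` in a token as the decimal mark whenever
#' the token contains no `'.'`.
#'
#' @param text One record line.
#' @param locale `"auto"`, `"dot"` or `"comma"`.
#' @return A [metabolite_record()].
#' @examples
#' parse_ls_record(paste("Alanine (Ala)",
#'   "259.15#260.1#261.1#262.1#263.1#264.1#265.1#",
#'   "0.07#8.53#2.3#2.39#44.59#8.79#3.88#", "3", "3", sep = "\t"))
#' @export
parse_ls_record <- function(text, locale = c("auto", "dot", "comma")) {
  locale <- match.arg(locale)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("record text must be a single non-empty string", call. = FALSE)
  fields <- strsplit(text, "\t", fixed = TRUE)[[1]]
  fields <- trimws(fields)
  if (length(fields) < 5L)
    stop(sprintf("expected 5 tab-separated fields, got %d", length(fields)),
         call. = FALSE)
  mz_tok <- split_hash(fields[2])
  ri_tok <- split_hash(fields[3])
  if (length(mz_tok) != length(ri_tok))
    stop(sprintf("m/e list has %d values but intensity list has %d",
                 length(mz_tok), length(ri_tok)), call. = FALSE)
  mz <- parse_numeric_tokens(mz_tok, locale, "m/e")
  ri <- parse_numeric_tokens(ri_tok, locale, "intensity")
  nm <- parse_numeric_tokens(fields[4], locale, "metabolite carbon count")
  nf <- parse_numeric_tokens(fields[5], locale, "fragment carbon count")
  metabolite_record(fields[1], mz, ri, nm, nf)
}

# shortest decimal representation that survives a parse round trip
format_exact <- function(x) {
  vapply(x, function(v) {
    for (d in 15:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

#' Serialize a metabolite record to one '.ls' line
#'
#' Values are written with enough digits that [parse_ls_record()] recovers
#' them bit-exactly, in either locale.
#'
#' @param record A [metabolite_record()].
#' @param locale `"dot"` (default) or `"comma"` decimal mark.
#' @return A single record line (no trailing newline).
#' @export
write_ls_record <- function(record, locale = c("dot", "comma")) {
  locale <- match.arg(locale)
  stopifnot(inherits(record, "metabolite_record"))
  fmt <- function(x) {
    s <- format_exact(x)
    if (locale == "comma") s <- gsub(".", ",", s, fixed = TRUE)
    paste0(paste(s, collapse = "#"), "#")
  }
  paste(record$name, fmt(record$mz_values), fmt(record$intensities),
        record$n_carbons_metabolite, record$n_carbons_fragment, sep = "\t")
}

#' Read / write '.ls' record files
#'
#' A '.ls' file holds one record per line in the dialect described under
#' [parse_ls_record()]. Blank lines and lines whose first non-blank character
#' is `';'` are ignored on read.
#'
#' @param path File path.
#' @param locale Decimal-mark convention, see [parse_ls_record()].
#' @return `read_ls()`: a list of [metabolite_record()] objects.
#' @export
read_ls <- function(path, locale = c("auto", "dot", "comma")) {
  locale <- match.arg(locale)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), ";")
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop(sprintf("no records found in '%s'", path), call. = FALSE)
  lapply(seq_along(lines), function(i) {
    tryCatch(parse_ls_record(lines[i], locale), error = function(e)
      stop(sprintf("%s: record %d: %s", path, i, conditionMessage(e)),
           call. = FALSE))
  })
}

#' @rdname read_ls
#' @param records List of [metabolite_record()] objects.
#' @return `write_ls()`: `path`, invisibly.
#' @export
write_ls <- function(records, path, locale = c("dot", "comma")) {
  locale <- match.arg(locale)
  if (inherits(records, "metabolite_record")) records <- list(records)
  writeLines(vapply(records, write_ls_record, character(1), locale = locale),
             path, useBytes = TRUE)
  invisible(path)
}

#' Merge record collections
#'
#' Concatenates record collections in order. Records sharing both name and
#' m/e list are duplicates: the later occurrence wins. Records sharing name
#' and m/e list but disagreeing on carbon counts are a conflict and raise an
#' error naming the records involved.
#'
#' @param ... Record collections (lists of [metabolite_record()]), or single
#'   records.
#' @return A list of records with duplicates collapsed; the number of
#'   collapsed duplicates is attached as attribute `n_collapsed`.
#' @export
merge_records <- function(...) {
  colls <- list(...)
  records <- list()
  for (coll in colls) {
    if (inherits(coll, "metabolite_record")) coll <- list(coll)
    for (r in coll) {
      stopifnot(inherits(r, "metabolite_record"))
      records[[length(records) + 1L]] <- r
    }
  }
  keys <- vapply(records, function(r)
    paste(r$name, paste(format_exact(r$mz_values), collapse = "#"),
          sep = "\r"), character(1))
  conflicts <- character(0)
  for (k in unique(keys[duplicated(keys)])) {
    grp <- records[keys == k]
    cc <- vapply(grp, function(r)
      paste(r$n_carbons_metabolite, r$n_carbons_fragment), character(1))
    if (length(unique(cc)) > 1L) conflicts <- c(conflicts, grp[[1]]$name)
  }
  if (length(conflicts))
    stop("merge conflict: duplicate records with differing carbon counts: ",
         paste(unique(conflicts), collapse = ", "), call. = FALSE)
  n0 <- length(records)
  # later occurrence wins: keep the last record for each key, in first-seen order
  last_idx <- tapply(seq_along(keys), keys, max)
  keep <- sort(as.integer(last_idx[match(unique(keys), names(last_idx))]))
  out <- records[keep]
  attr(out, "n_collapsed") <- n0 - length(out)
  out
}

#' Usable mass window of a fragment
#'
#' Estimates the monoisotopic mass `m0` (nearest integer to the smallest
#' observed m/e), the proton-loss position `m_minus1 = m0 - 1`, and the upper
#' bound `m_max = m0 + max_heavy_atoms` of the mass range from which
#' intensities enter the fit.
#'
#' @param record A [metabolite_record()].
#' @param max_heavy_atoms Heaviest isotopomer group expected; defaults to the
#'   fragment carbon count.
#' @param m0 Optional override of the monoisotopic integer mass (for spectra
#'   where the smallest observed peak is itself the proton-loss satellite).
#' @return An object of class `mass_window` with integer fields `m0`,
#'   `m_minus1`, `m_max`.
#' @examples
#' rec <- metabolite_record("Ala", c(259.15, 260.1), c(1, 2), 3, 3)
#' estimate_mass_window(rec)
#' @export
estimate_mass_window <- function(record, max_heavy_atoms = NULL, m0 = NULL) {
  stopifnot(inherits(record, "metabolite_record"))
  if (is.null(max_heavy_atoms)) max_heavy_atoms <- record$n_carbons_fragment
  if (is.null(m0)) m0 <- round(min(record$mz_values))
  m0 <- as.integer(m0)
  structure(list(m0 = m0, m_minus1 = m0 - 1L,
                 m_max = m0 + as.integer(max_heavy_atoms)),
            class = "mass_window")
}

#' @export
print.mass_window <- function(x, ...) {
  cat(sprintf("<mass_window> m0 = %d, m-1 = %d, m_max = %d\n",
              x$m0, x$m_minus1, x$m_max))
  invisible(x)
}

#' Map m/e readings to integer isotopomer offsets
#'
#' Each peak is assigned the offset `round(mz) - m0` (0 = monoisotopic).
#' Peaks below `m0` (e.g. the M-1 proton-loss satellite) or above `m_max`
#' are excluded from the fit and returned in the `excluded` field. Two m/e
#' readings rounding to the same integer are a format error.
#'
#' @param record A [metabolite_record()].
#' @param window A [mass_window()]; computed from the record if missing.
#' @param verbose Log excluded peaks via `message()`.
#' @return An object of class `observed_spectrum`: list with `offsets`
#'   (integer), `intensities` (matched), and `excluded` (data frame of
#'   dropped peaks with a `reason` column).
#' @export
map_offsets <- function(record, window = NULL, verbose = FALSE) {
  stopifnot(inherits(record, "metabolite_record"))
  if (is.null(window)) window <- estimate_mass_window(record)
  m_int <- round(record$mz_values)
  off <- as.integer(m_int - window$m0)
  drop_low <- off < 0L
  drop_high <- m_int > window$m_max
  keep <- !(drop_low | drop_high)
  if (anyDuplicated(off[keep])) {
    d <- off[keep][duplicated(off[keep])][1]
    clash <- record$mz_values[keep][off[keep] == d]
    stop(sprintf("m/e values %s round to the same mass offset %d",
                 paste(format(clash), collapse = " and "), d), call. = FALSE)
  }
  if (!any(keep))
    stop("no peaks fall inside the mass window", call. = FALSE)
  reason <- ifelse(drop_low,
                   ifelse(off == -1L, "below window (M-1 candidate)",
                          "below window"),
                   "above window")
  excluded <- data.frame(mz = record$mz_values[!keep],
                         intensity = record$intensities[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (verbose && nrow(excluded))
    for (i in seq_len(nrow(excluded)))
      message(sprintf("excluded peak m/e %.4g (%s)",
                      excluded$mz[i], excluded$reason[i]))
  structure(list(offsets = off[keep],
                 intensities = record$intensities[keep],
                 excluded = excluded),
            class = "observed_spectrum")
}
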