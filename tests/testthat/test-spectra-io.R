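ALA_LINE <- paste("Alanine (Ala)",
                  "259.15#260.1#261.1#262.1#263.1#264.1#265.1#",
                  "0.07#8.53#2.3#2.39#44.59#8.79#3.88#",
                  "3", "3", sep = "\t")

test_that("parse_ls_record reads the canonical alanine record", {
  rec <- parse_ls_record(ALA_LINE)
  expect_s3_class(rec, "metabolite_record")
  expect_equal(rec$name, "Alanine (Ala)")
  expect_length(rec$mz_values, 7)
  expect_length(rec$intensities, 7)
  expect_equal(rec$mz_values,
               c(259.15, 260.1, 261.1, 262.1, 263.1, 264.1, 265.1))
  expect_equal(rec$intensities, c(0.07, 8.53, 2.3, 2.39, 44.59, 8.79, 3.88))
  expect_equal(rec$n_carbons_metabolite, 3L)
  expect_equal(rec$n_carbons_fragment, 3L)
})

test_that("comma-locale decimals parse under both 'comma' and 'auto'", {
  line <- paste("Gly", "100,5#101,5#", "0,07#8,53#", "2", "2", sep = "\t")
  for (loc in c("comma", "auto")) {
    rec <- parse_ls_record(line, locale = loc)
    expect_equal(rec$intensities, c(0.07, 8.53), label = loc)
    expect_equal(rec$mz_values, c(100.5, 101.5), label = loc)
  }
})

test_that("single-point and malformed records are handled", {
  rec <- parse_ls_record(paste("x", "1#", "1#", "1", "1", sep = "\t"))
  expect_equal(rec$mz_values, 1)
  expect_equal(rec$intensities, 1)

  bad_len <- paste("x", "1#2#3#", "1#2#", "1", "1", sep = "\t")
  expect_error(parse_ls_record(bad_len), "3 values.*2")
  bad_tok <- paste("x", "1#2#", "1#oops#", "1", "1", sep = "\t")
  expect_error(parse_ls_record(bad_tok), "'oops' at position 2")
  expect_error(parse_ls_record("just a name"), "5 tab-separated fields")
  expect_error(parse_ls_record(paste("", "1#", "1#", "1", "1", sep = "\t")),
               "non-empty")
})

test_that("write -> parse round trip is bit-exact in both locales", {
  set.seed(404)
  for (rep in 1:25) {
    rec <- random_record()
    for (loc in c("dot", "comma")) {
      back <- parse_ls_record(write_ls_record(rec, locale = loc),
                              locale = ifelse(loc == "dot", "dot", "comma"))
      expect_identical(back$mz_values, rec$mz_values)
      expect_identical(back$intensities, rec$intensities)
      expect_identical(back$name, rec$name)
    }
    # cross-locale: comma-written record parses identically under auto
    back <- parse_ls_record(write_ls_record(rec, locale = "comma"),
                            locale = "auto")
    expect_identical(back$mz_values, rec$mz_values)
    expect_identical(back$intensities, rec$intensities)
  }
})

test_that("read_ls / write_ls round trip through files", {
  set.seed(405)
  recs <- replicate(3, random_record(), simplify = FALSE)
  path <- withr::local_tempfile(fileext = ".ls")
  write_ls(recs, path)
  back <- read_ls(path)
  expect_length(back, 3)
  for (i in 1:3) expect_identical(back[[i]], recs[[i]])

  empty <- withr::local_tempfile(fileext = ".ls")
  writeLines(c("", "; only a comment"), empty)
  expect_error(read_ls(empty), "no records")
})

test_that("the installed alanine fixture parses to the worked example", {
  path <- system.file("extdata", "alanine.ls", package = "mida")
  recs <- read_ls(path)
  expect_length(recs, 1)
  expect_identical(recs[[1]], alanine_record())
})

test_that("merge_records concatenates, collapses and detects conflicts", {
  set.seed(406)
  a1 <- random_record(name = "a1")
  a2 <- random_record(name = "a2")
  b1 <- random_record(name = "b1")
  b2 <- random_record(name = "b2")

  expect_identical(merge_records(list(a1, a2), list()),
                   merge_records(list(a1, a2)))
  m <- merge_records(list(a1, a2), list(a1, a2))
  expect_length(m, 2)
  expect_equal(attr(m, "n_collapsed"), 2)

  m4 <- merge_records(list(a1, a2), list(b1, b2))
  expect_equal(vapply(m4, `[[`, "", "name"),
               c(a1$name, a2$name, b1$name, b2$name))

  # same name + m/e, later wins (differing intensities only)
  a1b <- a1
  a1b$intensities <- a1$intensities + 1
  m <- merge_records(list(a1), list(a1b))
  expect_length(m, 1)
  expect_equal(m[[1]]$intensities, a1b$intensities)

  # same name + m/e but different carbon counts: conflict
  a1c <- a1
  a1c$n_carbons_fragment <- a1$n_carbons_fragment %% 6 + 1L
  expect_error(merge_records(list(a1), list(a1c)),
               paste0("merge conflict.*", a1$name))
})

test_that("estimate_mass_window rounds the lightest peak and honors overrides", {
  ala <- alanine_record()
  w <- estimate_mass_window(ala)
  expect_equal(w$m0, 259L)
  expect_equal(w$m_minus1, 258L)
  expect_equal(w$m_max, 262L)  # default: fragment carbons above m0
  expect_equal(estimate_mass_window(ala, max_heavy_atoms = 19)$m_max, 278L)
  expect_equal(estimate_mass_window(ala, m0 = 260)$m_minus1, 259L)

  flat <- metabolite_record("f", c(100.0, 101.0), c(1, 1), 1, 1)
  expect_equal(estimate_mass_window(flat)$m0, 100L)
  # window ignores the intensities entirely
  flat2 <- metabolite_record("f", c(100.0, 101.0), c(9, 0), 1, 1)
  expect_identical(estimate_mass_window(flat),
                   estimate_mass_window(flat2))
})

test_that("map_offsets aligns peaks and excludes out-of-window signals", {
  ala <- alanine_record()
  sp <- map_offsets(ala, estimate_mass_window(ala, max_heavy_atoms = 19))
  expect_equal(sp$offsets, 0:6)
  expect_equal(sp$intensities, ala$intensities)

  # with the default window the heavy peaks fall outside and are logged
  sp2 <- map_offsets(ala)
  expect_equal(sp2$offsets, 0:3)
  expect_equal(nrow(sp2$excluded), 3)
  expect_true(all(sp2$excluded$reason == "above window"))

  # an M-1 satellite is excluded with its own reason
  rec <- metabolite_record("m1", c(258.1, 259.1, 260.1, 261.1),
                           c(0.5, 10, 2, 1), 1, 1)
  w <- estimate_mass_window(rec, m0 = 259, max_heavy_atoms = 2)
  sp3 <- map_offsets(rec, w)
  expect_equal(sp3$offsets, 0:2)
  expect_equal(sp3$excluded$reason, "below window (M-1 candidate)")
  expect_message(map_offsets(rec, w, verbose = TRUE), "excluded peak")

  # colliding m/e readings are a format error
  dup <- metabolite_record("dup", c(100.1, 100.4), c(1, 2), 1, 1)
  expect_error(map_offsets(dup), "round to the same mass offset")

  # integer-valued peaks map to consecutive offsets
  k <- metabolite_record("k", 200:204, rep(1, 5), 4, 4)
  expect_equal(map_offsets(k)$offsets, 0:4)
})

test_that("metabolite_record enforces its invariants", {
  expect_error(metabolite_record("", 1, 1, 1, 1), "non-empty")
  expect_error(metabolite_record("x", c(1, 2), 1, 1, 1), "matched")
  expect_error(metabolite_record("x", c(2, 1), c(1, 1), 1, 1),
               "strictly increasing")
  expect_error(metabolite_record("x", c(1, 2), c(-1, 1), 1, 1),
               "non-negative")
  expect_error(metabolite_record("x", 1, 1, 0, 1), "positive integer")
  expect_error(metabolite_record("x", 1, 1, 1, 2.5), "positive integer")
})
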