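test_that("allele names parse, round-trip, and report resolution", {
  cases <- list(
    list(txt = "DRB1*14:54", locus = "DRB1", vals = c(14L, 54L),
         suffix = NA_character_, res = 2L),
    list(txt = "A*24:02:01:02L", locus = "A", vals = c(24L, 2L, 1L, 2L),
         suffix = "L", res = 4L),
    list(txt = "A*01", locus = "A", vals = 1L, suffix = NA_character_,
         res = 1L),
    list(txt = "C*04:09N", locus = "C", vals = c(4L, 9L), suffix = "N",
         res = 2L))
  for (cs in cases) {
    a <- parse_allele_name(cs$txt)
    expect_identical(a$locus, cs$locus)
    expect_identical(a$values, cs$vals)
    expect_identical(a$suffix, cs$suffix)
    expect_identical(allele_resolution(a), cs$res)
    expect_identical(format_allele(a), cs$txt)  # exact round-trip
  }
})

test_that("malformed allele names are rejected with a position", {
  for (bad in c("A*", "01:01", "A*01:", "A*01:xx", "A2", "A*01X",
                "DRB1*14:54:", ""))
    expect_error(parse_allele_name(bad), "malformed|single character")
})

test_that("leading zeros are preserved textually but compared numerically", {
  a <- parse_allele_name("A*02:01")
  b <- parse_allele_name("A*2:1")
  expect_true(hlapop:::allele_equal(a, b))
  expect_identical(format_allele(a), "A*02:01")
  expect_identical(format_allele(b), "A*2:1")
})

test_that("reduce_resolution truncates, preserves identity, warns on suffix loss", {
  expect_warning(r <- reduce_resolution("A*24:02:01:02L", 1),
                 "suffix 'L'.*lost")
  expect_identical(format_allele(r), "A*24")
  expect_identical(format_allele(reduce_resolution("DQB1*02:02", 2)),
                   "DQB1*02:02")
  expect_warning(r2 <- reduce_resolution("C*04:09N", 1),
                 "null allele.*merged")
  expect_identical(format_allele(r2), "C*04")
  expect_error(reduce_resolution("A*01", 0))
})

test_that("reduce_resolution is monotone: L then L' < L equals L' directly", {
  names <- c("A*24:02:01:02L", "B*44:02:01", "DRB1*14:54", "A*01")
  for (nm in names) for (L in 1:4) for (L2 in seq_len(L)) {
    via <- suppressWarnings(
      reduce_resolution(reduce_resolution(nm, L), L2))
    direct <- suppressWarnings(reduce_resolution(nm, L2))
    expect_identical(format_allele(via), format_allele(direct))
  }
})

test_that("transliteration substitutes, de-duplicates, preserves counts", {
  s <- gl_sample("A*01:01+A*02:01",
                 "A*01:01+A*02:01|A*01:02+A*02:01")
  m <- resolution_mapping(c("A*01:01", "A*01:02", "A*02:01"), 1)
  out <- transliterate_sample(s, m)
  expect_length(out$genotypes, 2L)
  expect_identical(serialize_genotype(out$genotypes[[1]]), "A*01+A*02")
  # the two candidates of individual 2 merge into one pair
  expect_length(out$genotypes[[2]]$candidates, 1L)
  expect_identical(serialize_genotype(out$genotypes[[2]]), "A*01+A*02")
  # identity mapping leaves the sample unchanged
  alle <- hlapop:::sample_alleles(s)
  id_map <- allele_mapping(stats::setNames(alle, alle))
  same <- transliterate_sample(s, id_map)
  expect_identical(lapply(same$genotypes, serialize_genotype),
                   lapply(s$genotypes, serialize_genotype))
})

test_that("transliteration errors on unmapped alleles, naming them", {
  s <- gl_sample("A*01:01+A*02:01")
  m <- allele_mapping(c("A*01:01" = "A*01"))
  expect_error(transliterate_sample(s, m), "A\\*02:01")
})

test_that("mappings reject non-idempotent chains and read/write as TSV", {
  expect_error(allele_mapping(c("A*01:01" = "A*01", "A*01" = "A*02")),
               "idempotent")
  m <- resolution_mapping(c("B*44:02", "B*44:03"), 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mapping(m, path)
  m2 <- read_mapping(path)
  expect_identical(m2$entries[names(m$entries)], m$entries)
})

test_that("common pool merges what any sample cannot distinguish", {
  # sample 2 reports only the broad B*44 group
  s1 <- gl_sample("B*44:02+B*44:03", "B*44:02+B*44:02")
  s2 <- gl_sample("B*44+B*44")
  pool <- build_common_pool(list(s1, s2))
  expect_identical(unname(pool$entries[c("B*44:02", "B*44:03", "B*44")]),
                   rep("B*44", 3L))

  # unsplit A*01 absorbs its splits; A*02:01 stays precise
  s3 <- gl_sample("A*01:01+A*01:02", "A*01:01+A*02:01")
  s4 <- gl_sample("A*01+A*02:01")
  pool2 <- build_common_pool(list(s3, s4))
  expect_identical(unname(pool2$entries[c("A*01:01", "A*01:02", "A*01")]),
                   rep("A*01", 3L))
  expect_identical(unname(pool2$entries[["A*02:01"]]), "A*02:01")

  # full-resolution identical samples: identity mapping
  s5 <- gl_sample("A*01:01+A*02:01")
  s6 <- gl_sample("A*02:01+A*02:01", "A*01:01+A*01:01")
  pool3 <- build_common_pool(list(s5, s6))
  expect_identical(pool3$entries[c("A*01:01", "A*02:01")],
                   c("A*01:01" = "A*01:01", "A*02:01" = "A*02:01"))
  expect_error(build_common_pool(list(s1, s5)), "different loci")
})

test_that("pool mapping applied to every sample yields a shared vocabulary", {
  samples <- list(gl_sample("B*44:02+B*44:03", "B*44:05+B*44:05"),
                  gl_sample("B*44+B*44:05"),
                  gl_sample("B*44:02+B*44:05", "B*44:03+B*44:03"))
  pool <- build_common_pool(samples)
  vocab <- lapply(samples, function(s)
    sort(unique(hlapop:::sample_alleles(transliterate_sample(s, pool)))))
  # oracle: exhaustive pairwise merge closure gives one B*44 class here
  expect_true(all(vapply(vocab, function(v)
    all(v %in% c("B*44")), logical(1))))
  # ambiguity sets never emptied, individual counts preserved
  for (s in samples) {
    out <- transliterate_sample(s, pool)
    expect_length(out$genotypes, length(s$genotypes))
    expect_true(all(vapply(out$genotypes, hlapop:::n_candidates,
                           integer(1)) >= 1L))
  }
})

test_that("non-PBR warning list screens alleles and ships >= 9 entries", {
  expect_gte(nrow(non_pbr_alleles()), 9L)
  w <- flag_non_pbr_distinctions("DRB1*14:54")
  expect_identical(w$populations, "All populations")
  expect_identical(nrow(flag_non_pbr_distinctions("B*07:02")), 0L)
  w2 <- flag_non_pbr_distinctions(c("DQB1*03:19", "C*07:18"))
  expect_identical(nrow(w2), 2L)
  expect_setequal(w2$populations,
                  c("Pan-European", "Pan-European/Chilean"))
})
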