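test_that("GL strings expand to the right candidate sets", {
  g1 <- parse_genotype_string("A*01:01+A*02:01")
  expect_length(g1$candidates, 1L)
  expect_identical(g1$source, "unambiguous")

  g2 <- parse_genotype_string("A*01:01/A*01:02+A*02:01")
  expect_length(g2$candidates, 2L)

  # '|' lists pairs explicitly: exactly 2, never the 4-pair cross-product
  g3 <- parse_genotype_string("A*01:01+A*02:01|A*01:02+A*02:02")
  expect_length(g3$candidates, 3L - 1L)
  expect_setequal(hlapop:::candidate_keys(g3),
                  c("A*01:01+A*02:01", "A*01:02+A*02:02"))

  # unordered pairs canonicalize: duplicates collapse
  g4 <- parse_genotype_string("A*02:01+A*01:01|A*01:01+A*02:01")
  expect_length(g4$candidates, 1L)

  # multi-locus with '^'
  g5 <- parse_genotype_string("A*01+A*02^B*07+B*08")
  expect_identical(g5$loci, c("A", "B"))
  expect_length(g5$candidates, 1L)
  expect_length(g5$candidates[[1]], 2L)
})

test_that("malformed genotype strings raise specific errors", {
  expect_error(parse_genotype_string("A*01:01"), "two '\\+'-separated")
  expect_error(parse_genotype_string("A*01:01+"), "two '\\+'-separated")
  expect_error(parse_genotype_string("A*01:01+B*07:02"), "mixed loci")
  expect_error(parse_genotype_string("A*01+A*02|"), "empty")
  expect_error(parse_genotype_string("A*01//A*02+A*03"), "empty allele")
})

test_that("serialization factors only when lossless and round-trips", {
  # shared allele: factoring is lossless
  g <- parse_genotype_string("A*01:01/A*01:02+A*02:01")
  expect_identical(serialize_genotype(g, "factored"),
                   "A*01:01/A*01:02+A*02:01")
  # {01:01+02:01, 01:02+02:02}: factoring would add spurious pairs
  g2 <- parse_genotype_string("A*01:01+A*02:01|A*01:02+A*02:02")
  f2 <- serialize_genotype(g2, "factored")
  expect_identical(f2, serialize_genotype(g2, "pair_list"))
  expect_true(grepl("|", f2, fixed = TRUE))
})

test_that("parse/serialize closure holds for random ambiguous genotypes", {
  set.seed(42)
  alleles <- sprintf("A*%02d:%02d", sample(1:30, 10), sample(1:60, 10))
  for (rep in 1:25) {
    n_cand <- sample(1:5, 1)
    cands <- unique(replicate(n_cand,
      list(sort(sample(alleles, 2, replace = TRUE))), simplify = FALSE))
    g <- hla_genotype("x", "A", lapply(cands, function(p) list(p[[1]])))
    for (style in c("pair_list", "factored")) {
      back <- parse_genotype_string(serialize_genotype(g, style))
      expect_setequal(hlapop:::candidate_keys(back),
                      hlapop:::candidate_keys(g))
    }
  }
})

test_that("MAC expansion is the full cross-product and knows its size", {
  tab <- read_mac_table(system.file("extdata", "mac_toy.tsv",
                                    package = "hlapop"))
  g <- expand_mac("A*01:XX + A*02:01", tab)
  expect_length(g$candidates, 2L)
  expect_identical(g$source, "code_expansion")

  g2 <- expand_mac("A*01:XX + A*02:YY", tab)
  expect_length(g2$candidates, 4L)

  expect_error(expand_mac("A*01:QQ + A*02:01", tab), "unknown.*'QQ'")

  # expansion size = product of side lengths minus duplicate unordered
  # pairs, checked against direct enumeration
  g3 <- expand_mac("A*01:XX + A*01:XX", tab)
  left <- c("A*01:01", "A*01:02")
  enum <- unique(apply(expand.grid(left, left, stringsAsFactors = FALSE),
                       1, function(p) paste(sort(p), collapse = "+")))
  expect_length(g3$candidates, length(enum))
})

test_that("spurious-pair counting measures code-expansion inflation", {
  tab <- read_mac_table(system.file("extdata", "mac_toy.tsv",
                                    package = "hlapop"))
  reported <- parse_genotype_string("A*01:01+A*02:01|A*01:02+A*02:05")
  expanded <- expand_mac("A*01:XX + A*02:YY", tab)  # 01/02 x 01/05 = 4
  expect_identical(count_spurious_pairs(reported, expanded), 2L)
  expect_identical(count_spurious_pairs(expanded, expanded), 0L)
  disjoint <- parse_genotype_string("A*03:01+A*03:02")
  expect_error(count_spurious_pairs(disjoint, expanded), "not contained")
})

test_that("spurious count is 0 iff the expansion is lossless", {
  tab <- list(XX = c("01", "02"))
  expanded <- expand_mac("A*01:XX + A*02:01", tab)
  lossless <- parse_genotype_string("A*01:01+A*02:01|A*01:02+A*02:01")
  expect_identical(count_spurious_pairs(lossless, expanded), 0L)
  partial <- parse_genotype_string("A*01:01+A*02:01")
  expect_gt(count_spurious_pairs(partial, expanded), 0L)
})

test_that("validation reports violations and strictness escalates", {
  ok <- gl_sample("A*01:01+A*02:01", "A*01:02+A*01:02")
  expect_true(validate_sample(ok)$ok ||
    any(grepl("relatives", validate_sample(ok)$violations)))

  md <- questionnaire_metadata(first_degree_relatives_excluded = TRUE,
                               n_individuals = 2)
  ok2 <- gl_sample("A*01:01+A*02:01", "A*01:02+A*01:02", metadata = md)
  expect_true(validate_sample(ok2)$ok)

  # NMDP code present under the strict pair-list policy
  tab <- list(XX = c("01", "02"))
  coded <- hla_sample(list(expand_mac("A*01:XX + A*02:01", tab, id = "c1")),
                      metadata = md)
  v <- validate_sample(coded, strict_pair_list = TRUE)
  expect_false(v$ok)
  expect_true(any(grepl("NMDP code", v$violations)))
  expect_error(validate_sample(coded, strict_pair_list = TRUE,
                               strict = TRUE), "NMDP")

  # duplicate ids rejected at construction
  g <- parse_genotype_string("A*01+A*01", id = "dup")
  expect_error(hla_sample(list(g, g)), "dup")

  # declared sample size mismatch
  md_bad <- questionnaire_metadata(first_degree_relatives_excluded = TRUE,
                                   n_individuals = 5)
  v2 <- validate_sample(gl_sample("A*01+A*02", metadata = md_bad))
  expect_true(any(grepl("declares 5", v2$violations)))
})

test_that("format conversion is loss-free and counts individuals", {
  tab_in <- withr::local_tempfile(fileext = ".csv")
  gl_out <- withr::local_tempfile(fileext = ".txt")
  tab_back <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,locus,genotype",
               "i1,A,A*01:01+A*02:01",
               "i2,A,A*01:01/A*01:02+A*02:01",
               "i3,A,A*01:01+A*01:01"), tab_in)
  expect_identical(convert_format(tab_in, "tabular", gl_out, "glstring"), 3L)
  expect_identical(convert_format(gl_out, "glstring", tab_back, "tabular"),
                   3L)
  a <- read_sample_tabular(tab_in)
  b <- read_sample_tabular(tab_back)
  expect_identical(lapply(a$genotypes, hlapop:::candidate_keys),
                   lapply(b$genotypes, hlapop:::candidate_keys))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,locus,genotype", "i1,A,A*01:01"), bad)
  expect_error(read_sample_tabular(bad), "row 1")
})
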