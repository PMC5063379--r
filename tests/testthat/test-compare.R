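# Worked examples of the classification cascade, then property checks:
# oracle equivalence, symmetry, level nesting, totality, transitivity.

sex_cl <- function(oid = "CL.A") {
  fix_codelist(oid = oid, name = "Sex", data_type = "integer",
               values = c("1", "2"),
               entry_codes = list("C0086582", "C0086287"))
}

test_that("classify_pair reproduces the worked examples of the cascade", {
  a <- fix_item("Sex", "integer", "C0150831", sex_cl("CL.A"), file = "a.xml")
  b <- fix_item("Sex", "integer", "C0150831", sex_cl("CL.B"), file = "b.xml")
  expect_identical(classify_pair(a, b), "IDENTICAL")

  # disjoint concept domains
  expect_identical(
    classify_pair(fix_item("A", codes = "C0000001", codelist = NULL),
                  fix_item("B", codes = "C0000002", codelist = NULL)),
    "DIFFERENT")

  # same concepts, corresponding entries, but shifted coded values
  cl_01 <- fix_codelist("CL.C", "Sex", "integer", c("0", "1"),
                        list("C0086582", "C0086287"))
  shifted <- fix_item("Sex", "integer", "C0150831", cl_01, file = "b.xml")
  expect_identical(classify_pair(a, shifted), "TRANSFORMABLE")

  # as above but the item data types mismatch
  str_cl <- fix_codelist("CL.D", "Sex", "string", c("0", "1"),
                         list("C0086582", "C0086287"))
  str_item <- fix_item("Sex", "string", "C0150831", str_cl, file = "b.xml")
  expect_identical(classify_pair(a, str_item), "SIMILAR")

  # names differ only by case -> still IDENTICAL
  b_upper <- b; b_upper$item$name <- "SEX"
  expect_identical(classify_pair(a, b_upper), "IDENTICAL")

  # value domains identical but different names -> MATCHING
  gender <- b; gender$item$name <- "Gender"
  expect_identical(classify_pair(a, gender), "MATCHING")

  # uncoded items are a contract violation
  expect_error(classify_pair(a, fix_item("X", codes = character())),
               "NOTCODED")
})

test_that("code-list correspondence handles absence, identity and multiset mismatch", {
  vac <- codelist_correspondence(NULL, NULL)
  expect_true(vac$concepts_match && vac$values_match &&
                vac$datatypes_match && vac$names_match)

  one <- codelist_correspondence(sex_cl(), NULL)
  expect_false(one$concepts_match)

  self <- codelist_correspondence(sex_cl("CL.A"), sex_cl("CL.B"))
  expect_true(self$concepts_match && self$values_match &&
                self$datatypes_match && self$names_match)
  expect_identical(self$bijection[, "a"], self$bijection[, "b"])

  shorter <- fix_codelist("CL.E", "Sex", "integer", c("1", "2", "3"),
                          list("C0086582", "C0086287", "C0000003"))
  expect_false(codelist_correspondence(sex_cl(), shorter)$concepts_match)

  # duplicated signatures must occur equally often (multiset, not set)
  dup_a <- fix_codelist("CL.F", "L", "integer", c("1", "2"),
                        list("C0000009", "C0000009"))
  dup_b <- fix_codelist("CL.G", "L", "integer", c("1", "2"),
                        list("C0000009", "C0000008"))
  expect_false(codelist_correspondence(dup_a, dup_b)$concepts_match)

  # within one signature, pairing is by ascending coded value
  perm_a <- fix_codelist("CL.H", "L", "integer", c("2", "1"),
                         list("C0000009", "C0000009"))
  perm_b <- fix_codelist("CL.I", "L", "integer", c("1", "2"),
                         list("C0000009", "C0000009"))
  corr <- codelist_correspondence(perm_a, perm_b)
  expect_true(corr$concepts_match && corr$values_match)
})

test_that("compare_all drives all pairs, including within-form duplicates", {
  # two files, one identical Sex item each -> a single IDENTICAL pair
  mk_sex_doc <- function(file) fix_doc(
    list(list(name = "Sex", codes = "C0150831", codelist = sex_cl("CL.1"))),
    file = file)
  res <- compare_all(list(mk_sex_doc("a.xml"), mk_sex_doc("b.xml")))
  expect_identical(nrow(res$pairs), 1L)
  expect_identical(res$counts_by_level[["IDENTICAL"]], 1L)

  # one form containing "Surgery" twice + one unrelated coded item
  surgery_cl <- fix_codelist("CL.1", "YesNo", "integer", c("0", "1"),
                             list("C0000010", "C0000011"))
  doc <- fix_doc(list(
    list(name = "Surgery", codes = "C0038895", codelist = surgery_cl),
    list(name = "Surgery", codes = "C0038895", codelist = surgery_cl),
    list(name = "Weight", codes = "C0005910")))
  res <- compare_all(doc)
  expect_identical(nrow(res$pairs), 3L)
  expect_identical(res$counts_by_level[["IDENTICAL"]], 1L)
  expect_identical(res$counts_by_level[["DIFFERENT"]], 2L)

  # four pairwise-distinct coded items + one uncoded
  doc <- fix_doc(list(
    list(name = "A", codes = "C0000001"), list(name = "B", codes = "C0000002"),
    list(name = "C", codes = "C0000003"), list(name = "D", codes = "C0000004"),
    list(name = "E", codes = character())))
  res <- compare_all(doc)
  expect_identical(nrow(res$pairs), 6L)
  expect_identical(unname(res$counts_by_level["DIFFERENT"]), 6L)
  expect_length(res$not_coded, 1L)

  expect_error(compare_all(list(odm_document("empty.xml"))),
               "no study metadata")
})

test_that("classify_pair agrees with an independent brute-force oracle", {
  set.seed(42)
  pool <- sprintf("C%07d", sample.int(9999999L, 12))
  n_agree <- 0L
  levels_seen <- character()
  for (i in 1:1000) {
    p <- rand_pair(pool)
    got <- classify_pair(p$a, p$b)
    expect_identical(got, oracle_classify(p$a, p$b),
                     label = sprintf("pair %d", i))
    levels_seen <- union(levels_seen, got)
    n_agree <- n_agree + 1L
  }
  expect_identical(n_agree, 1000L)
  # the generator exercises every coded level
  expect_setequal(levels_seen,
                  c("DIFFERENT", "SIMILAR", "TRANSFORMABLE", "MATCHING",
                    "IDENTICAL"))
})

test_that("classification is symmetric and provenance-blind at the top level", {
  set.seed(7)
  pool <- sprintf("C%07d", sample.int(9999999L, 10))
  for (i in 1:200) {
    p <- rand_pair(pool)
    expect_identical(classify_pair(p$a, p$b), classify_pair(p$b, p$a))
  }
  # a definition-identical copy with different provenance is IDENTICAL
  a <- rand_item(pool)
  while (!odmsim:::is_coded(a$item$concept)) a <- rand_item(pool)
  twin <- a; twin$file_name <- "elsewhere.xml"; twin$position <- 5L
  expect_identical(classify_pair(a, twin), "IDENTICAL")
})

test_that("levels nest: each level implies every lower gate", {
  set.seed(99)
  pool <- sprintf("C%07d", sample.int(9999999L, 10))
  for (i in 1:300) {
    p <- rand_pair(pool)
    lvl <- classify_pair(p$a, p$b)
    r <- odmsim:::rel_rank(lvl)
    cd_eq <- odmsim:::cd_equal(p$a$item$concept, p$b$item$concept)
    corr <- codelist_correspondence(p$a$value_domain$code_list,
                                    p$b$value_domain$code_list)
    if (r >= odmsim:::rel_rank("SIMILAR")) expect_true(cd_eq)
    if (r >= odmsim:::rel_rank("TRANSFORMABLE")) {
      expect_true(corr$concepts_match)
      expect_identical(p$a$item$data_type, p$b$item$data_type)
    }
    if (r >= odmsim:::rel_rank("MATCHING"))
      expect_true(isTRUE(corr$datatypes_match) && isTRUE(corr$values_match))
    if (r == odmsim:::rel_rank("IDENTICAL"))
      expect_identical(tolower(p$a$item$name), tolower(p$b$item$name))
  }
})

test_that("every coded pair gets exactly one level and counts are complete", {
  d <- withr::local_tempdir()
  gen <- synth_generate(synth_preset("cross_institution"), d)
  res <- compare_all(gen$docs)
  n <- length(res$coded)
  expect_identical(nrow(res$pairs), (n * (n - 1L)) %/% 2L)
  expect_identical(sum(res$counts_by_level), nrow(res$pairs))
  expect_true(all(res$pairs$relationship %in% relationship_levels[-1]))
  # every coded item appears in exactly n - 1 pairs
  appearances <- table(c(res$pairs$a, res$pairs$b))
  expect_true(all(appearances == n - 1L))
})

test_that("concept-domain equality is transitive across SIMILAR+ pairs", {
  set.seed(5)
  pool <- sprintf("C%07d", sample.int(9999999L, 6))
  items <- replicate(12, rand_item(pool), simplify = FALSE)
  at_least_similar <- function(x, y)
    odmsim:::rel_rank(classify_pair(x, y)) >= odmsim:::rel_rank("SIMILAR")
  for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12)
    if (at_least_similar(items[[i]], items[[j]]) &&
        at_least_similar(items[[j]], items[[k]]))
      expect_true(at_least_similar(items[[i]], items[[k]]))
})
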