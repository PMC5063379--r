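chemo_docs <- function() {
  mk <- function(file, form) fix_doc(
    list(list(name = "Chemotherapy", codes = "C3665472")),
    file = file, form = form, study = paste("Registry", form))
  list(mk("r1.xml", "Register 1"), mk("r2.xml", "Register 2"),
       mk("r3.xml", "Register 3"))
}

test_that("concept-identical items across three forms give one row with three marks", {
  res <- compare_all(chemo_docs())
  m <- build_matrix(res)
  expect_identical(nrow(m$counts), 1L)
  expect_identical(ncol(m$counts), 3L)
  expect_identical(unname(m$counts[1, ]), c(1L, 1L, 1L))
  expect_identical(rownames(m$counts), "Chemotherapy")
  expect_true(all(m$levels[1, ] == "IDENTICAL"))
})

test_that("a form holding a concept twice yields a split (count 2) cell", {
  twice <- fix_doc(list(
    list(name = "Surgery", codes = "C0038895"),
    list(name = "Surgery", codes = "C0038895")),
    file = "fin.xml", form = "Finnish registry")
  once <- function(file, form) fix_doc(
    list(list(name = "Surgery", codes = "C0038895")), file = file,
    form = form)
  res <- compare_all(list(twice, once("a.xml", "Registry A"),
                          once("b.xml", "Registry B")))
  m <- build_matrix(res)
  expect_identical(unname(m$counts[1, ]), c(2L, 1L, 1L))
  expect_identical(sum(m$counts[1, ]), length(m$rows[[1]]$members))
})

test_that("no shared concepts means an empty matrix; min_level filters rows", {
  res <- compare_all(fix_doc(list(
    list(name = "A", codes = "C0000001"),
    list(name = "B", codes = "C0000002"))))
  m <- build_matrix(res)
  expect_identical(nrow(m$counts), 0L)

  # SIMILAR-only group disappears when min_level = MATCHING
  cl_a <- fix_codelist("CL.A", "L", "integer", c("1", "2"),
                       list("C0000011", "C0000012"))
  cl_b <- fix_codelist("CL.B", "L", "integer", c("1", "2"),
                       list("C0000011", "C0000013"))
  res2 <- compare_all(list(
    fix_doc(list(list(name = "X", codes = "C0000009", codelist = cl_a)),
            file = "a.xml"),
    fix_doc(list(list(name = "X", codes = "C0000009", codelist = cl_b)),
            file = "b.xml")))
  expect_identical(nrow(build_matrix(res2, "SIMILAR")$counts), 1L)
  expect_identical(nrow(build_matrix(res2, "MATCHING")$counts), 0L)
  expect_error(build_matrix(res2, "DIFFERENT"), "min_level")
})

test_that("matrix rows and pair classifications are mutually consistent", {
  d <- withr::local_tempdir()
  gen <- synth_generate(synth_preset("cross_institution"), d)
  res <- compare_all(gen$docs)
  m <- build_matrix(res)
  lut <- odmsim:::pair_lookup(res)
  row_of <- rep(NA_integer_, length(res$items))
  for (r in seq_along(m$rows)) row_of[m$rows[[r]]$members] <- r
  for (i in res$coded) for (j in res$coded) {
    if (i >= j) next
    rel <- odmsim:::lookup_rel(lut, i, j)
    if (!is.na(row_of[i]) && identical(row_of[i], row_of[j])) {
      expect_gte(odmsim:::rel_rank(rel), odmsim:::rel_rank("SIMILAR"))
    } else {
      expect_lt(odmsim:::rel_rank(rel), odmsim:::rel_rank("SIMILAR"))
    }
  }
})

test_that("pair listings are grouped by level and list uncoded items separately", {
  surgery_cl <- fix_codelist("CL.1", "YesNo", "integer", c("0", "1"),
                             list("C0000010", "C0000011"))
  doc <- fix_doc(list(
    list(name = "Surgery", codes = "C0038895", codelist = surgery_cl),
    list(name = "Surgery", codes = "C0038895", codelist = surgery_cl),
    list(name = "Weight", codes = "C0005910"),
    list(name = "Freitext", codes = character(), data_type = "text")))
  res <- compare_all(doc)
  lst <- list_pairs_by_level(res)
  expect_identical(nrow(lst$by_level$IDENTICAL), 1L)
  expect_identical(nrow(lst$by_level$DIFFERENT), 2L)
  expect_identical(nrow(lst$by_level$SIMILAR), 0L)
  expect_identical(lst$not_coded$item, "Freitext")
  expect_identical(lst$by_level$IDENTICAL$a_codes, "C0038895")

  # all-uncoded input: no pairs at all, everything under NOTCODED
  res0 <- compare_all(fix_doc(list(
    list(name = "N1", codes = character()),
    list(name = "N2", codes = character()))))
  lst0 <- list_pairs_by_level(res0)
  expect_true(all(vapply(lst0$by_level, nrow, integer(1)) == 0L))
  expect_identical(nrow(lst0$not_coded), 2L)

  # a single coded item has no pairs
  res1 <- compare_all(fix_doc(list(list(name = "A", codes = "C0000001"))))
  expect_true(all(vapply(list_pairs_by_level(res1)$by_level, nrow,
                         integer(1)) == 0L))
})

test_that("csv export round-trips the matrix cell counts exactly", {
  res <- compare_all(chemo_docs())
  m <- build_matrix(res)
  lst <- list_pairs_by_level(res)
  s <- short_summary(chemo_docs())
  out <- withr::local_tempdir()
  files <- export_report(m, lst, s, res, format = "csv", dest = out)
  expect_true(file.exists(file.path(out, "comparable_matrix.csv")))
  back <- utils::read.csv(file.path(out, "comparable_matrix.csv"),
                          check.names = FALSE)
  expect_identical(back$item, "Chemotherapy")
  expect_identical(back$codes, "C3665472")
  counts_back <- as.integer(back[1, -(1:2)])
  expect_identical(counts_back, unname(m$counts[1, ]))
  expect_identical(colnames(back)[-(1:2)], colnames(m$counts))

  # an empty matrix exports to a header-only file
  empty_res <- compare_all(fix_doc(list(
    list(name = "A", codes = "C0000001"),
    list(name = "B", codes = "C0000002"))))
  out2 <- withr::local_tempdir()
  export_report(build_matrix(empty_res), list_pairs_by_level(empty_res),
                short_summary(fix_doc(list(list(name = "A",
                                                codes = "C0000001")))),
                empty_res, format = "csv", dest = out2)
  expect_identical(nrow(utils::read.csv(file.path(out2,
                                                  "comparable_matrix.csv"))),
                   0L)
})

test_that("html export renders one mark per occurrence with hover detail", {
  res <- compare_all(chemo_docs())
  m <- build_matrix(res)
  lst <- list_pairs_by_level(res)
  s <- short_summary(chemo_docs())
  out <- withr::local_tempfile(fileext = ".html")
  export_report(m, lst, s, res, format = "html", dest = out)
  html <- paste(readLines(out), collapse = "\n")
  expect_identical(
    lengths(regmatches(html, gregexpr("<span title=", html, fixed = TRUE))),
    3L)
  expect_match(html, "Chemotherapy \\[integer\\] codes: C3665472")
  expect_match(html, "<h2>Comparable Items</h2>")
})

test_that("the xlsx token is rejected with a clear message", {
  res <- compare_all(chemo_docs())
  expect_error(export_report(build_matrix(res), list_pairs_by_level(res),
                             short_summary(chemo_docs()), res,
                             format = "xlsx", dest = tempdir()),
               "not supported")
})
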