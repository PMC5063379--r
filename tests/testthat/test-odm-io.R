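sex_fixture <- system.file("extdata", "sex-minimal.xml", package = "odmsim")
subset_schema <- system.file("extdata", "odm-subset-synthetic.xsd",
                             package = "odmsim")

test_that("a minimal item definition with a UMLS alias parses correctly", {
  doc <- read_odm(sex_fixture)
  mv <- doc$studies[[1]]$metadata_versions[[1]]
  sex <- odmsim:::mv_item(mv, "I.1")
  expect_identical(sex$name, "Sex")
  expect_identical(sex$data_type, "integer")
  expect_identical(unclass(sex$concept), "C0150831")
  cl <- odmsim:::mv_codelist(mv, sex$codelist_oid)
  expect_identical(vapply(cl$items, function(x) x$coded_value, character(1)),
                   c("1", "2"))
  expect_identical(vapply(cl$items, function(x) x$decode, character(1)),
                   c("male", "female"))
})

test_that("degenerate and off-version inputs are handled", {
  empty <- withr::local_tempfile(fileext = ".xml")
  writeLines(character(), empty)
  expect_error(read_odm(empty), "not well-formed")
  rep <- validate_odm(empty)
  expect_false(rep$well_formed)
  expect_gte(validation_errors(rep), 1L)
  expect_match(rep$messages$location[1], "line 1")

  not_odm <- withr::local_tempfile(fileext = ".xml")
  writeLines("<foo/>", not_odm)
  expect_error(read_odm(not_odm), "expected <ODM>")

  old <- withr::local_tempfile(fileext = ".xml")
  writeLines(sub('ODMVersion="1.3.2"', 'ODMVersion="1.3.0"',
                 readLines(sex_fixture)), old)
  expect_warning(doc <- read_odm(old), "unsupported declared ODMVersion")
  expect_identical(doc$odm_version, "1.3.0")
  expect_length(doc$studies[[1]]$metadata_versions[[1]]$item_defs, 1L)
})

test_that("the structural check reports missing attributes, duplicate coded values and dangling refs", {
  lines <- readLines(sex_fixture)

  miss_dt <- withr::local_tempfile(fileext = ".xml")
  writeLines(sub('<ItemDef OID="I.1" Name="Sex" DataType="integer">',
                 '<ItemDef OID="I.1" Name="Sex">', lines, fixed = TRUE),
             miss_dt)
  rep <- validate_odm(miss_dt)
  expect_true(rep$well_formed)
  expect_identical(validation_errors(rep), 1L)
  msg <- rep$messages[rep$messages$severity == "error", ]
  expect_match(msg$location, "ItemDef\\[@OID='I.1'\\]")
  expect_match(msg$text, "missing DataType")

  dup_cv <- withr::local_tempfile(fileext = ".xml")
  writeLines(sub('CodedValue="2"', 'CodedValue="1"', lines, fixed = TRUE),
             dup_cv)
  rep <- validate_odm(dup_cv)
  expect_identical(validation_errors(rep), 1L)
  msg <- rep$messages[rep$messages$severity == "error", ]
  expect_match(msg$location, "CodeList\\[@OID='CL.1'\\]")
  expect_match(msg$text, "duplicated CodedValue '1'")

  dangle <- withr::local_tempfile(fileext = ".xml")
  writeLines(sub('CodeListOID="CL.1"', 'CodeListOID="CL.9"', lines,
                 fixed = TRUE), dangle)
  rep <- validate_odm(dangle)
  expect_identical(validation_errors(rep), 1L)
  expect_match(rep$messages$text[rep$messages$severity == "error"],
               "CodeListOID 'CL.9' does not resolve")

  # structurally invalid files are also grammar-invalid under the subset
  # schema (no false acceptance), and the pristine fixture passes both
  expect_false(validate_odm(miss_dt, schema_path = subset_schema)$schema_valid)
  clean <- validate_odm(sex_fixture, schema_path = subset_schema)
  expect_true(clean$schema_valid)
  expect_identical(validation_errors(clean), 0L)
})

test_that("validation reports serialise to JSON lines", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines(sub('<ItemDef OID="I.1" Name="Sex" DataType="integer">',
                 '<ItemDef OID="I.1" Name="Sex">',
                 readLines(sex_fixture), fixed = TRUE), bad)
  lines <- validation_jsonlines(validate_odm(bad))
  expect_length(lines, 1L)
  parsed <- jsonlite::fromJSON(lines[1])
  expect_identical(parsed$severity, "error")
  expect_match(parsed$text, "missing DataType")
})

test_that("parse(serialize(doc)) reproduces the document exactly", {
  d <- withr::local_tempdir()
  for (preset in c("versions", "routine_vs_trial", "cross_institution")) {
    gen <- synth_generate(synth_preset(preset), file.path(d, preset))
    for (k in seq_along(gen$files)) {
      back <- read_odm(gen$files[k])
      expect_identical(back, gen$docs[[k]], label = gen$files[k])
    }
  }
  # and the bundled fixture survives a write/re-read cycle
  doc <- read_odm(sex_fixture)
  out <- withr::local_tempfile(fileext = ".xml")
  write_odm(doc, out)
  expect_identical(read_odm(out, source_name = doc$source_name), doc)
})
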