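# Independent brute-force re-derivation of the classification cascade, used
# only as an oracle. Deliberately shares no code with the package: concept
# equality via setequal on trimmed codes, code-list fit via sorted signature
# strings, value agreement per signature via sorted value lists.

oracle_sigs <- function(cl)
  unname(vapply(cl$items, function(e)
    paste(sort(unique(trimws(unclass(e$concept)))), collapse = ","),
    character(1)))

oracle_classify <- function(a, b) {
  ca <- unique(trimws(unclass(a$item$concept)))
  cb <- unique(trimws(unclass(b$item$concept)))
  stopifnot(length(ca) > 0, length(cb) > 0)
  if (!setequal(ca, cb)) return("DIFFERENT")

  cla <- a$value_domain$code_list
  clb <- b$value_domain$code_list
  lists_fit <-
    if (is.null(cla) && is.null(clb)) TRUE
    else if (is.null(cla) || is.null(clb)) FALSE
    else identical(sort(oracle_sigs(cla)), sort(oracle_sigs(clb)))
  if (!lists_fit || a$item$data_type != b$item$data_type) return("SIMILAR")

  cl_names_same <- TRUE; cl_fine <- TRUE
  if (!is.null(cla)) {
    sa <- oracle_sigs(cla); sb <- oracle_sigs(clb)
    va <- unname(vapply(cla$items, function(e) trimws(e$coded_value),
                        character(1)))
    vb <- unname(vapply(clb$items, function(e) trimws(e$coded_value),
                        character(1)))
    values_same <- all(vapply(unique(sa), function(s)
      identical(sort(va[sa == s]), sort(vb[sb == s])), logical(1)))
    cl_fine <- values_same && (cla$data_type == clb$data_type)
    cl_names_same <- tolower(trimws(cla$name)) == tolower(trimws(clb$name))
  }
  if (!cl_fine) return("TRANSFORMABLE")
  if (tolower(trimws(a$item$name)) == tolower(trimws(b$item$name)) &&
      cl_names_same) return("IDENTICAL")
  "MATCHING"
}
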