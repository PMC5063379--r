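# Builders for in-code fixtures: quick items, code lists, documents and
# randomized resolved items for property-style tests.

fix_codelist <- function(oid = "CL.1", name = "Choices", data_type = "integer",
                         values = c("1", "2"),
                         entry_codes = list("C1000001", "C1000002")) {
  odm_codelist(oid, name, data_type,
               unname(mapply(function(v, cc) odm_codelist_item(v, concept = cc),
                             values, entry_codes, SIMPLIFY = FALSE)))
}

# A resolved item built directly (no document plumbing needed).
fix_item <- function(name = "Sex", data_type = "integer",
                     codes = "C0150831", codelist = NULL,
                     file = "a.xml", study = "Study A", form = "Form A",
                     group = "Main", position = 1L) {
  it <- odm_itemdef(paste0("I.", name), name, data_type, concept = codes,
                    codelist_oid = if (!is.null(codelist)) codelist$oid)
  vd <- structure(list(data_type = data_type, code_list = codelist),
                  class = "value_domain")
  resolved_item(it, vd, file, study, form, group, position)
}

# One-form document: items is a list of lists with fields name, data_type,
# codes (character vector, possibly empty), codelist (odm_codelist or NULL).
# Groups: optional list mapping group name -> vector of item indices.
fix_doc <- function(items, file = "fix.xml", study = "Study F",
                    form = "Form F", groups = NULL) {
  item_defs <- list(); code_lists <- list()
  for (k in seq_along(items)) {
    sp <- items[[k]]
    cl <- sp$codelist
    seen_cl <- vapply(code_lists, function(x) x$oid, character(1))
    if (!is.null(cl) && !(cl$oid %in% seen_cl))
      code_lists[[length(code_lists) + 1L]] <- cl
    item_defs[[k]] <- odm_itemdef(
      sprintf("I.%d", k), sp$name, sp$data_type %||% "integer",
      concept = sp$codes %||% character(),
      codelist_oid = if (!is.null(cl)) cl$oid)
  }
  if (is.null(groups)) groups <- list(Main = seq_along(items))
  group_defs <- lapply(seq_along(groups), function(gi)
    odm_itemgroupdef(sprintf("IG.%d", gi), names(groups)[gi],
                     sprintf("I.%d", groups[[gi]])))
  formdef <- odm_formdef("F.1", form,
                         vapply(group_defs, function(g) g$oid, character(1)))
  event <- odm_studyeventdef("SE.1", "Baseline", formdef$oid)
  mv <- odm_metadataversion("MV.1", "v1", list(event), list(formdef),
                            group_defs, item_defs, code_lists)
  odm_document(file, "1.3.2", list(odm_study("S.1", study, list(mv))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Randomized resolved item; the perturbation modes of rand_pair below drive
# all five coded levels.
rand_item <- function(pool) {
  dt <- sample(c("integer", "text", "string", "float"), 1)
  codes <- sample(pool, sample(1:2, 1))
  cl <- NULL
  if (stats::runif(1) < 0.6) {
    n <- sample(2:3, 1)
    cl <- fix_codelist(oid = paste0("CL.", paste(sample(letters, 6),
                                                 collapse = "")),
                       name = sample(c("Choices", "Options"), 1),
                       data_type = sample(c("integer", "string"), 1),
                       values = as.character(seq_len(n)),
                       entry_codes = as.list(sample(pool, n)))
  }
  fix_item(name = paste("Item", paste(sample(letters, 4), collapse = "")),
           data_type = dt, codes = codes, codelist = cl)
}

perturb_item <- function(a, pool) {
  mode <- sample(c("copy", "rename", "values", "cl_dtype", "item_dtype",
                   "entry_codes", "drop_cl", "codes"), 1)
  b <- a
  cl <- a$value_domain$code_list
  if (mode == "rename") {
    b$item$name <- paste0(a$item$name, " B")
  } else if (mode == "values" && !is.null(cl)) {
    cl$items <- lapply(cl$items, function(e) {
      e$coded_value <- paste0("9", e$coded_value); e })
  } else if (mode == "cl_dtype" && !is.null(cl)) {
    cl$data_type <- if (cl$data_type == "integer") "string" else "integer"
  } else if (mode == "item_dtype") {
    b$item$data_type <- if (a$item$data_type == "integer") "text" else "integer"
    b$value_domain$data_type <- b$item$data_type
  } else if (mode == "entry_codes" && !is.null(cl)) {
    cl$items[[1]]$concept <- concept_domain(sample(pool, 1))
  } else if (mode == "drop_cl") {
    cl <- NULL
  } else if (mode == "codes") {
    b$item$concept <- concept_domain(sample(pool, 1))
  }
  b$value_domain$code_list <- cl
  b$file_name <- "b.xml"
  b
}

rand_pair <- function(pool) {
  a <- rand_item(pool)
  b <- if (stats::runif(1) < 0.7) perturb_item(a, pool) else rand_item(pool)
  list(a = a, b = b)
}

# Randomized generator layout for ground-truth recovery tests.
random_synth_spec <- function(seed) {
  set.seed(seed)
  n_forms <- sample(2:4, 1)
  n_anchor <- sample(2:4, 1)
  forms <- vector("list", n_forms)
  forms[[1]] <- list(form_name = "Base", items = lapply(
    seq_len(n_anchor), function(i)
      synth_item(data_type = sample(c("integer", "text", "string"), 1),
                 with_codelist = stats::runif(1) < 0.7)))
  for (fi in seq.int(2L, n_forms)) {
    n_it <- sample(1:5, 1)
    forms[[fi]] <- list(form_name = paste("Form", fi), items = lapply(
      seq_len(n_it), function(i) {
        u <- stats::runif(1)
        if (u < 0.7) {
          ai <- sample(n_anchor, 1)
          lv <- c("DIFFERENT", "SIMILAR", "MATCHING", "IDENTICAL")
          if (forms[[1]]$items[[ai]]$with_codelist)
            lv <- c(lv, "TRANSFORMABLE")
          synth_item(level = sample(lv, 1), anchor = c(1L, ai))
        } else if (u < 0.82) {
          synth_item(level = "NOTCODED", with_codelist = FALSE)
        } else {
          synth_item(with_codelist = stats::runif(1) < 0.5)
        }
      }))
  }
  synth_spec(seed = seed, forms = forms)
}
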