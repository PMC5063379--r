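# Deterministic generator of ODM fixtures with planted pairwise
# relationships. Given a seed and a layout of forms/items, it emits ODM
# 1.3.2 files that pass validation and whose all-pairs comparison reproduces
# every planted level exactly — the ground truth for end-to-end testing.

SYNTH_DATATYPES <- c("integer", "text", "float", "string")

#' Declare one synthetic item
#'
#' @param name optional explicit item name (otherwise generated).
#' @param level planted relationship to the anchor: one of
#'   [relationship_levels]; `NULL` (with no anchor) means an independent item
#'   with its own fresh concept code.
#' @param anchor `c(form, item)` indices of the anchor item in an *earlier*
#'   form; required for levels above NOTCODED.
#' @param with_codelist should an independent item carry a code list?
#' @param data_type optional data type for an independent item.
#' @export
synth_item <- function(name = NULL, level = NULL, anchor = NULL,
                       with_codelist = TRUE, data_type = NULL) {
  list(name = name, level = level, anchor = anchor,
       with_codelist = isTRUE(with_codelist), data_type = data_type)
}

#' Declare a synthetic form-set specification
#'
#' Validates achievability of every planted relationship before anything is
#' emitted: anchors must point at an earlier, coded item; `TRANSFORMABLE`
#' requires an anchor with a code list (the level is about transforming coded
#' values); `IDENTICAL` cannot be requested together with an explicit item
#' name that differs from the anchor's.
#'
#' @param seed integer; same seed and layout give byte-identical files.
#' @param forms list of forms, each `list(form_name =, items = list(...))`
#'   with items from [synth_item()].
#' @param code_pool_size number of distinct synthetic concept codes
#'   available ("C" + 7 digits, UMLS-style).
#' @param codelist_entries entries per generated code list.
#' @return a `synth_spec`.
#' @export
synth_spec <- function(seed, forms, code_pool_size = 500L,
                       codelist_entries = 3L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (length(forms) == 0L) stop("synth_spec: at least one form required")
  for (fi in seq_along(forms)) {
    f <- forms[[fi]]
    if (is.null(f$form_name) || !nzchar(f$form_name))
      stop("synth_spec: every form needs a form_name")
    for (ii in seq_along(f$items)) {
      it <- f$items[[ii]]
      lvl <- it$level
      if (!is.null(lvl) && !(lvl %in% relationship_levels))
        stop(sprintf("synth_spec: unknown level '%s'", lvl))
      if (!is.null(it$anchor)) {
        if (is.null(lvl) || lvl == "NOTCODED")
          stop("synth_spec: an anchored item needs a coded planted level")
        af <- it$anchor[1]; ai <- it$anchor[2]
        if (af >= fi)
          stop("synth_spec: anchor must be in an earlier form")
        anc <- forms[[af]]$items[[ai]]
        if (is.null(anc))
          stop("synth_spec: anchor item does not exist")
        if (identical(anc$level, "NOTCODED"))
          stop("synth_spec: cannot plant a relationship against an uncoded anchor")
        if (!is.null(anc$anchor))
          stop("synth_spec: anchors must be independent items")
        if (lvl == "TRANSFORMABLE" && !anc$with_codelist)
          stop("synth_spec: TRANSFORMABLE requires an anchor with a code list")
        if (lvl == "IDENTICAL" && !is.null(it$name) && !is.null(anc$name) &&
            tolower(trimws(it$name)) != tolower(trimws(anc$name)))
          stop("synth_spec: IDENTICAL requested with differing names is unachievable")
        if (lvl == "MATCHING" && !is.null(it$name) && !is.null(anc$name) &&
            tolower(trimws(it$name)) == tolower(trimws(anc$name)))
          stop("synth_spec: MATCHING requires differing item names")
      } else if (!is.null(lvl) && !(lvl %in% c("NOTCODED")))
        stop(sprintf("synth_spec: level %s needs an anchor", lvl))
    }
  }
  structure(list(seed = as.integer(seed), forms = forms,
                 code_pool_size = as.integer(code_pool_size),
                 codelist_entries = as.integer(codelist_entries)),
            class = "synth_spec")
}

#' Generate the ODM files of a synthetic specification
#'
#' Emits one ODM 1.3.2 file per form (one study, one metadata version, one
#' study event, one item group each). Output is deterministic: the same spec
#' yields byte-identical files.
#'
#' @param spec a [synth_spec()].
#' @param dir output directory (created if needed).
#' @return list with `files` (paths in form order), `docs` (the in-memory
#'   documents), and `truth` (data frame of planted pairs: `a_form`,
#'   `a_item`, `b_form`, `b_item`, `level`).
#' @export
synth_generate <- function(spec, dir) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  pool <- sprintf("C%07d", sample.int(9999999L, spec$code_pool_size))
  next_code_i <- 0L
  fresh_code <- function() {
    next_code_i <<- next_code_i + 1L
    if (next_code_i > length(pool))
      stop("synth_generate: code pool exhausted; raise code_pool_size")
    pool[next_code_i]
  }

  # realized item definitions, indexed [[form]][[item]]
  realized <- vector("list", length(spec$forms))
  truth <- list()
  docs <- list(); files <- character()

  for (fi in seq_along(spec$forms)) {
    f <- spec$forms[[fi]]
    realized[[fi]] <- vector("list", length(f$items))
    item_defs <- list(); code_lists <- list(); item_oids <- character()
    for (ii in seq_along(f$items)) {
      s <- f$items[[ii]]
      oid <- sprintf("I.%d.%d", fi, ii)
      cl_oid <- sprintf("CL.%d.%d", fi, ii)
      if (is.null(s$anchor)) {
        # independent item
        nm <- s$name %||% sprintf("Item %d-%d", fi, ii)
        dt <- s$data_type %||% sample(SYNTH_DATATYPES, 1L)
        if (identical(s$level, "NOTCODED")) {
          def <- list(name = nm, data_type = dt, concept = character(),
                      codelist = NULL)
        } else {
          cl <- NULL
          if (s$with_codelist && dt == "integer") {
            cl <- list(name = paste("CL", nm), data_type = "integer",
                       values = as.character(seq_len(spec$codelist_entries)),
                       entry_codes = replicate(spec$codelist_entries,
                                               fresh_code()))
          } else if (s$with_codelist) {
            cl <- list(name = paste("CL", nm), data_type = dt,
                       values = paste0("v", seq_len(spec$codelist_entries)),
                       entry_codes = replicate(spec$codelist_entries,
                                               fresh_code()))
          }
          def <- list(name = nm, data_type = dt, concept = fresh_code(),
                      codelist = cl)
        }
      } else {
        anc <- realized[[s$anchor[1]]][[s$anchor[2]]]
        def <- anc  # start from a faithful copy
        lvl <- s$level
        if (lvl == "IDENTICAL") {
          # nothing to change
        } else if (lvl == "MATCHING") {
          def$name <- s$name %||% paste(anc$name, "alt")
        } else if (lvl == "TRANSFORMABLE") {
          def$codelist$values <- paste0("9", anc$codelist$values)
          if (!is.null(s$name)) def$name <- s$name
        } else if (lvl == "SIMILAR") {
          if (!is.null(anc$codelist)) {
            def$codelist$entry_codes[1] <- fresh_code()
          } else {
            def$data_type <- setdiff(SYNTH_DATATYPES, anc$data_type)[1]
          }
          if (!is.null(s$name)) def$name <- s$name
        } else if (lvl == "DIFFERENT") {
          def$concept <- fresh_code()
          if (!is.null(s$name)) def$name <- s$name
        }
        truth[[length(truth) + 1L]] <- data.frame(
          a_form = s$anchor[1], a_item = s$anchor[2],
          b_form = fi, b_item = ii, level = lvl, stringsAsFactors = FALSE)
      }
      realized[[fi]][[ii]] <- def

      cl_ref <- NULL
      if (!is.null(def$codelist)) {
        entries <- lapply(seq_along(def$codelist$values), function(k)
          odm_codelist_item(coded_value = def$codelist$values[k],
                            concept = def$codelist$entry_codes[k],
                            decode = paste("Choice", k)))
        code_lists[[length(code_lists) + 1L]] <-
          odm_codelist(cl_oid, def$codelist$name, def$codelist$data_type,
                       entries)
        cl_ref <- cl_oid
      }
      item_defs[[length(item_defs) + 1L]] <-
        odm_itemdef(oid, def$name, def$data_type, concept = def$concept,
                    codelist_oid = cl_ref)
      item_oids <- c(item_oids, oid)
    }

    fname <- sprintf("form_%02d_%s.xml", fi,
                     gsub("[^A-Za-z0-9]+", "_", f$form_name))
    group <- odm_itemgroupdef(sprintf("IG.%d", fi), "Main", item_oids)
    formdef <- odm_formdef(sprintf("F.%d", fi), f$form_name, group$oid)
    event <- odm_studyeventdef(sprintf("SE.%d", fi), "Baseline", formdef$oid)
    mv <- odm_metadataversion(sprintf("MV.%d", fi), "v1",
                              study_event_defs = list(event),
                              form_defs = list(formdef),
                              item_group_defs = list(group),
                              item_defs = item_defs,
                              code_lists = code_lists)
    study <- odm_study(sprintf("S.%d", fi),
                       sprintf("Synthetic study %d", fi), list(mv))
    doc <- odm_document(source_name = fname, odm_version = "1.3.2",
                        studies = list(study))
    path <- file.path(dir, fname)
    write_odm(doc, path)
    docs[[fi]] <- doc
    files <- c(files, path)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(a_form = integer(), a_item = integer(), b_form = integer(),
               b_item = integer(), level = character(),
               stringsAsFactors = FALSE)
  list(files = files, docs = docs, truth = truth)
}

#' Recover the classified level of every planted pair
#'
#' Runs [compare_all()] over a generated form set and returns the truth
#' table with a `recovered` column: the classified level, or `"NOTCODED"`
#' when the planted side was uncoded.
#'
#' @param gen the result of [synth_generate()].
#' @param docs optionally, documents re-read from disk (defaults to the
#'   in-memory ones).
#' @export
synth_recovered <- function(gen, docs = gen$docs) {
  result <- compare_all(docs)
  # one file per form, one item per position: provenance -> index
  key <- vapply(result$items, function(it)
    paste(it$file_name, it$position), character(1))
  idx <- function(form, item)
    match(paste(basename(gen$files[form]), item), key)
  lut <- pair_lookup(result)
  truth <- gen$truth
  truth$recovered <- vapply(seq_len(nrow(truth)), function(r) {
    ia <- idx(truth$a_form[r], truth$a_item[r])
    ib <- idx(truth$b_form[r], truth$b_item[r])
    if (ia %in% result$not_coded || ib %in% result$not_coded)
      return("NOTCODED")
    lookup_rel(lut, ia, ib)
  }, character(1))
  truth
}

#' Preset synthetic scenarios
#'
#' Small fixed specifications reproducing the method's use-case patterns:
#'
#' * `"versions"` — four versions of one form; a total-score item present
#'   identically in versions 1–3 and absent in 4, a dystonia item whose code
#'   list changes between versions (same concept domain, different value
#'   domain), and a stable diagnosis item.
#' * `"routine_vs_trial"` — routine clinical documentation vs trial
#'   documentation sharing four concepts at level MATCHING (lymph-node
#'   counts, ECOG status, ER status).
#' * `"cross_institution"` — oncology forms of two institutions sharing
#'   eight comparable concepts at mixed levels, plus unshared items.
#'
#' @param name one of `"versions"`, `"routine_vs_trial"`,
#'   `"cross_institution"`.
#' @param seed optional seed override.
#' @return a [synth_spec()].
#' @export
synth_preset <- function(name, seed = NULL) {
  specs <- list(
    versions = function() {
      v1 <- list(form_name = "Version 1", items = list(
        synth_item("Total Score", data_type = "integer",
                   with_codelist = FALSE),
        synth_item("Dystonia", data_type = "integer"),
        synth_item("Diagnosis", data_type = "text", with_codelist = FALSE)))
      plant <- function(nm, lvl, ai) synth_item(nm, level = lvl,
                                                anchor = c(1L, ai))
      synth_spec(seed %||% 20161013L, list(
        v1,
        list(form_name = "Version 2", items = list(
          plant("Total Score", "IDENTICAL", 1L),
          plant("Dystonia", "SIMILAR", 2L),
          plant("Diagnosis", "IDENTICAL", 3L))),
        list(form_name = "Version 3", items = list(
          plant("Total Score", "IDENTICAL", 1L),
          plant("Dystonia", "SIMILAR", 2L),
          plant("Diagnosis", "IDENTICAL", 3L))),
        list(form_name = "Version 4", items = list(
          plant("Dystonia", "SIMILAR", 2L),
          plant("Diagnosis", "IDENTICAL", 3L)))))
    },
    routine_vs_trial = function() {
      synth_spec(seed %||% 20161014L, list(
        list(form_name = "Routine Pathology Report", items = list(
          synth_item("Lymph Nodes Examined", data_type = "integer",
                     with_codelist = FALSE),
          synth_item("Positive Lymph Nodes", data_type = "integer",
                     with_codelist = FALSE),
          synth_item("ECOG Status", data_type = "integer"),
          synth_item("ER Status", data_type = "integer"),
          synth_item("Specimen ID", data_type = "string",
                     with_codelist = FALSE))),
        list(form_name = "Trial Baseline", items = list(
          synth_item("Number of Lymph Nodes examined", level = "MATCHING",
                     anchor = c(1L, 1L)),
          synth_item("Number of positive Lymph Nodes", level = "MATCHING",
                     anchor = c(1L, 2L)),
          synth_item("ECOG Performance Status", level = "MATCHING",
                     anchor = c(1L, 3L)),
          synth_item("Estrogen Receptor Status", level = "MATCHING",
                     anchor = c(1L, 4L)),
          synth_item("Visit Date", data_type = "date",
                     with_codelist = FALSE)))))
    },
    cross_institution = function() {
      a_items <- list(
        synth_item("Active Surveillance", data_type = "integer"),
        synth_item("Analgesics", data_type = "integer"),
        synth_item("Tumour Board Type", data_type = "integer"),
        synth_item("Irradiation", data_type = "integer"),
        synth_item("Chemotherapy", data_type = "integer"),
        synth_item("Diagnosis", data_type = "text", with_codelist = FALSE),
        synth_item("Birthdate", data_type = "date", with_codelist = FALSE),
        synth_item("Hormone Therapy", data_type = "integer"),
        synth_item("Local Patient ID", data_type = "string",
                   with_codelist = FALSE))
      plant <- function(nm, lvl, ai) synth_item(nm, level = lvl,
                                                anchor = c(1L, ai))
      b_items <- list(
        plant("Active Surveillance", "IDENTICAL", 1L),
        plant("Pain Medication", "MATCHING", 2L),
        plant("Tumour Board Type", "TRANSFORMABLE", 3L),
        plant("Radiotherapy", "MATCHING", 4L),
        plant("Chemotherapy", "SIMILAR", 5L),
        plant("Diagnosis", "IDENTICAL", 6L),
        plant("Date of Birth", "MATCHING", 7L),
        plant("Hormone Therapy", "IDENTICAL", 8L),
        synth_item("Ward", data_type = "string", with_codelist = FALSE))
      synth_spec(seed %||% 20161015L, list(
        list(form_name = "Hospital A Oncology", items = a_items),
        list(form_name = "Hospital B Oncology", items = b_items)))
    })
  if (!(name %in% names(specs)))
    stop(sprintf("unknown preset '%s' (known: %s)", name,
                 paste(names(specs), collapse = ", ")))
  specs[[name]]()
}

#' Read a synthetic specification from a YAML config file
#'
#' Schema: top-level keys `seed` (int), `code_pool_size`, `codelist_entries`
#' (optional ints) and `forms` — a list of `{form_name, items}` where each
#' item takes the fields of [synth_item()] (`anchor` as a two-element list
#' `[form, item]`).
#'
#' @param path YAML file path.
#' @return a [synth_spec()].
#' @export
read_synth_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  forms <- lapply(cfg$forms, function(f)
    list(form_name = f$form_name, items = lapply(f$items, function(it)
      synth_item(name = it$name, level = it$level,
                 anchor = if (!is.null(it$anchor)) as.integer(unlist(it$anchor)),
                 with_codelist = it$with_codelist %||% TRUE,
                 data_type = it$data_type))))
  synth_spec(seed = cfg$seed, forms = forms,
             code_pool_size = cfg$code_pool_size %||% 500L,
             codelist_entries = cfg$codelist_entries %||% 3L)
}
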