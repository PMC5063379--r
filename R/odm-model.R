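# In-memory model for the subset of ODM study metadata consumed by the
# comparison engine: items, item groups, forms, study events, code lists and
# the UMLS concept annotations attached to items and code-list entries.

#' ODM data-type tokens accepted by the model
#'
#' The enumerated `DataType` values of ODM item and code-list definitions that
#' the model recognises. `"float"` and `"double"` are distinct tokens and are
#' never conflated.
#'
#' @export
odm_data_types <- c("integer", "float", "text", "string", "date", "time",
                    "datetime", "boolean", "double")

#' Concept domain: the set of terminology codes annotating a data element
#'
#' Following ISO/IEC 11179 usage, the concept domain of an item (or of a
#' code-list entry) is the set of concept codes — here UMLS CUIs such as
#' `"C0150831"` — attached to it. Set semantics apply: duplicates collapse,
#' order is irrelevant, and the empty domain means "not coded". Codes are
#' trimmed of surrounding whitespace and compared case-sensitively (CUIs are
#' canonical uppercase identifiers, not prose).
#'
#' @param codes character vector of concept codes; may be empty.
#' @return a `concept_domain` object (a sorted, duplicate-free character
#'   vector).
#' @examples
#' concept_domain(c("C0150831", " C0150831 "))  # one code
#' @export
concept_domain <- function(codes = character()) {
  codes <- trimws(as.character(codes))
  if (any(!nzchar(codes)))
    stop("concept codes must be non-empty after trimming whitespace")
  structure(sort(unique(codes)), class = "concept_domain")
}

#' @export
print.concept_domain <- function(x, ...) {
  if (length(x) == 0L) cat("<concept domain: not coded>\n")
  else cat("<concept domain:", paste(unclass(x), collapse = ", "), ">\n")
  invisible(x)
}

# Order-insensitive set equality of two concept domains.
cd_equal <- function(a, b) {
  identical(unclass(concept_domain(a)), unclass(concept_domain(b)))
}

is_coded <- function(cd) length(cd) > 0L

`%||%` <- function(a, b) if (is.null(a)) b else a

check_data_type <- function(data_type, what) {
  if (!is.character(data_type) || length(data_type) != 1L ||
      !(data_type %in% odm_data_types))
    stop(sprintf("%s: DataType must be one of %s (got %s)", what,
                 paste(odm_data_types, collapse = ", "),
                 deparse(data_type)))
  data_type
}

check_oid <- function(oid, what) {
  if (!is.character(oid) || length(oid) != 1L || !nzchar(trimws(oid)))
    stop(sprintf("%s: OID must be a non-empty string", what))
  trimws(oid)
}

#' Code-list entry
#'
#' One permissible value of a code list: a coded value (the stored datum), an
#' optional decode (display) text and the concept codes annotating the entry.
#'
#' @param coded_value the stored value, non-empty after trimming.
#' @param concept a [concept_domain()] (or character vector of codes).
#' @param decode optional display string.
#' @export
odm_codelist_item <- function(coded_value, concept = concept_domain(),
                              decode = NULL) {
  coded_value <- trimws(as.character(coded_value))
  if (length(coded_value) != 1L || !nzchar(coded_value))
    stop("coded_value must be a non-empty string")
  structure(list(coded_value = coded_value,
                 concept = concept_domain(concept),
                 decode = decode),
            class = "odm_codelist_item")
}

#' Code-list definition
#'
#' @param oid identifier, unique within its metadata version.
#' @param name display name of the code list.
#' @param data_type one of [odm_data_types].
#' @param items non-empty list of [odm_codelist_item()] with distinct coded
#'   values.
#' @export
odm_codelist <- function(oid, name, data_type, items) {
  oid <- check_oid(oid, "CodeList")
  check_data_type(data_type, paste0("CodeList ", oid))
  if (length(items) == 0L)
    stop(sprintf("CodeList %s: must contain at least one code-list item", oid))
  vals <- vapply(items, function(it) it$coded_value, character(1))
  if (anyDuplicated(vals))
    stop(sprintf("CodeList %s: duplicated CodedValue %s", oid,
                 vals[duplicated(vals)][1]))
  structure(list(oid = oid, name = as.character(name),
                 data_type = data_type, items = items),
            class = "odm_codelist")
}

#' Item definition
#'
#' A single documentation field (e.g. "Sex"): a name, an ODM data type, the
#' concept domain collected from its UMLS aliases, and an optional reference
#' to a code list.
#'
#' @param oid identifier, unique within its metadata version.
#' @param name item name.
#' @param data_type one of [odm_data_types].
#' @param concept a [concept_domain()]; empty means the item is not coded.
#' @param codelist_oid optional OID of the referenced code list.
#' @param question_text optional question/prompt text.
#' @export
odm_itemdef <- function(oid, name, data_type, concept = concept_domain(),
                        codelist_oid = NULL, question_text = NULL) {
  oid <- check_oid(oid, "ItemDef")
  check_data_type(data_type, paste0("ItemDef ", oid))
  structure(list(oid = oid, name = as.character(name), data_type = data_type,
                 concept = concept_domain(concept),
                 codelist_oid = codelist_oid, question_text = question_text),
            class = "odm_itemdef")
}

#' Item-group definition
#' @param oid identifier.
#' @param name group name.
#' @param item_oids ordered character vector of referenced ItemDef OIDs.
#' @export
odm_itemgroupdef <- function(oid, name, item_oids = character()) {
  structure(list(oid = check_oid(oid, "ItemGroupDef"),
                 name = as.character(name),
                 item_oids = as.character(item_oids)),
            class = "odm_itemgroupdef")
}

#' Form definition
#' @param oid identifier.
#' @param name form name.
#' @param group_oids ordered character vector of referenced ItemGroupDef OIDs.
#' @export
odm_formdef <- function(oid, name, group_oids = character()) {
  structure(list(oid = check_oid(oid, "FormDef"), name = as.character(name),
                 group_oids = as.character(group_oids)),
            class = "odm_formdef")
}

#' Study-event definition
#' @param oid identifier.
#' @param name event name.
#' @param form_oids ordered character vector of referenced FormDef OIDs.
#' @export
odm_studyeventdef <- function(oid, name, form_oids = character()) {
  structure(list(oid = check_oid(oid, "StudyEventDef"),
                 name = as.character(name),
                 form_oids = as.character(form_oids)),
            class = "odm_studyeventdef")
}

check_unique_oids <- function(defs, what) {
  oids <- vapply(defs, function(d) d$oid, character(1))
  if (anyDuplicated(oids))
    stop(sprintf("%s: duplicated OID %s", what, oids[duplicated(oids)][1]))
  defs
}

#' Metadata version
#'
#' One `MetaDataVersion` block: the definition tables for study events, forms,
#' item groups, items and code lists, in document order. OIDs must be unique
#' per definition type; reference resolution is checked by [validate_odm()]
#' and at lookup time, not at construction, so that partially invalid
#' documents can still be represented.
#'
#' @param oid,name identifier and display name.
#' @param study_event_defs,form_defs,item_group_defs,item_defs,code_lists
#'   ordered lists of the respective definitions.
#' @export
odm_metadataversion <- function(oid, name, study_event_defs = list(),
                                form_defs = list(), item_group_defs = list(),
                                item_defs = list(), code_lists = list()) {
  structure(list(oid = check_oid(oid, "MetaDataVersion"),
                 name = as.character(name),
                 study_event_defs = check_unique_oids(study_event_defs,
                                                      "StudyEventDef"),
                 form_defs = check_unique_oids(form_defs, "FormDef"),
                 item_group_defs = check_unique_oids(item_group_defs,
                                                     "ItemGroupDef"),
                 item_defs = check_unique_oids(item_defs, "ItemDef"),
                 code_lists = check_unique_oids(code_lists, "CodeList")),
            class = "odm_metadataversion")
}

#' Study
#' @param oid identifier.
#' @param name study name.
#' @param metadata_versions ordered list of [odm_metadataversion()].
#' @export
odm_study <- function(oid, name, metadata_versions = list()) {
  structure(list(oid = check_oid(oid, "Study"), name = as.character(name),
                 metadata_versions = check_unique_oids(metadata_versions,
                                                       "MetaDataVersion")),
            class = "odm_study")
}

#' ODM document
#' @param source_name file name or label identifying the document's origin.
#' @param odm_version declared `ODMVersion` string.
#' @param studies ordered list of [odm_study()].
#' @export
odm_document <- function(source_name, odm_version = "1.3.2",
                         studies = list()) {
  structure(list(source_name = as.character(source_name),
                 odm_version = as.character(odm_version),
                 studies = check_unique_oids(studies, "Study")),
            class = "odm_document")
}

#' @export
print.odm_document <- function(x, ...) {
  cat(sprintf("<ODM document '%s' (ODMVersion %s): %d stud%s>\n",
              x$source_name, x$odm_version, length(x$studies),
              if (length(x$studies) == 1L) "y" else "ies"))
  for (st in x$studies)
    for (mv in st$metadata_versions)
      cat(sprintf("  study %s / %s: %d forms, %d item groups, %d items, %d code lists\n",
                  st$name, mv$name, length(mv$form_defs),
                  length(mv$item_group_defs), length(mv$item_defs),
                  length(mv$code_lists)))
  invisible(x)
}

mv_lookup <- function(defs, oid) {
  for (d in defs) if (d$oid == oid) return(d)
  NULL
}

mv_item     <- function(mv, oid) mv_lookup(mv$item_defs, oid)
mv_group    <- function(mv, oid) mv_lookup(mv$item_group_defs, oid)
mv_form     <- function(mv, oid) mv_lookup(mv$form_defs, oid)
mv_codelist <- function(mv, oid) mv_lookup(mv$code_lists, oid)

#' Value domain of an item
#'
#' The value domain of a data element is its data type together with the
#' optional code list it references. The code list is resolved within the
#' item's own metadata version; a dangling reference is an error.
#'
#' @param item an [odm_itemdef()].
#' @param version the [odm_metadataversion()] the item belongs to.
#' @return a `value_domain`: list with `data_type` and `code_list` (an
#'   [odm_codelist()] or `NULL`).
#' @export
value_domain_of <- function(item, version) {
  cl <- NULL
  if (!is.null(item$codelist_oid)) {
    cl <- mv_codelist(version, item$codelist_oid)
    if (is.null(cl))
      stop(sprintf("ItemDef %s references undefined CodeList OID '%s'",
                   item$oid, item$codelist_oid))
  }
  structure(list(data_type = item$data_type, code_list = cl),
            class = "value_domain")
}
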