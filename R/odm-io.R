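# Reading, validating and (for the consumed subset) writing CDISC ODM
# 1.3.1/1.3.2 study-metadata XML. Parsing and grammar validation go through
# xml2; the emitter is hand-written so that generated fixtures are
# byte-stable (fixed attribute order, fixed indentation).

ODM_SUPPORTED_VERSIONS <- c("1.3.1", "1.3.2")
ODM_NS <- "http://www.cdisc.org/ns/odm/v1.3"

read_xml_or_stop <- function(source) {
  doc <- tryCatch(xml2::read_xml(source),
                  error = function(e) stop(sprintf(
                    "not well-formed XML (%s): %s",
                    if (is.character(source)) basename(source) else "stream",
                    conditionMessage(e)), call. = FALSE))
  doc
}

local_name <- function(node) sub("^.*:", "", xml2::xml_name(node))

# Aliases whose Context is "UMLS" (case-insensitive) contribute one code each.
collect_umls_codes <- function(node) {
  aliases <- xml2::xml_find_all(node, "./Alias")
  ctx <- xml2::xml_attr(aliases, "Context")
  nm <- xml2::xml_attr(aliases, "Name")
  keep <- !is.na(ctx) & tolower(trimws(ctx)) == "umls" & !is.na(nm) &
    nzchar(trimws(nm))
  trimws(nm[keep])
}

first_translated_text <- function(node, parent) {
  tt <- xml2::xml_find_first(node, sprintf("./%s/TranslatedText", parent))
  if (inherits(tt, "xml_missing")) NULL else trimws(xml2::xml_text(tt))
}

#' Read an ODM study-metadata file into the data model
#'
#' Parses a CDISC ODM 1.3.1/1.3.2 XML document (default or prefixed ODM
#' namespace) into an [odm_document()]. Document order is preserved
#' throughout; UMLS aliases on `ItemDef` and `CodeListItem` elements are
#' collected into concept domains. Elements outside the consumed subset
#' (e.g. `ClinicalData`, administrative sections, `MeasurementUnit`) are
#' ignored. A declared `ODMVersion` other than 1.3.1/1.3.2 triggers a warning
#' and a best-effort parse.
#'
#' @param source path to an ODM XML file, or anything [xml2::read_xml()]
#'   accepts.
#' @param source_name label recorded on the returned document; defaults to
#'   the file's base name.
#' @return an [odm_document()].
#' @export
read_odm <- function(source, source_name = NULL) {
  doc <- read_xml_or_stop(source)
  root <- xml2::xml_root(doc)
  if (local_name(root) != "ODM")
    stop(sprintf("not an ODM document: root element is <%s>, expected <ODM>",
                 local_name(root)))
  xml2::xml_ns_strip(doc)
  if (is.null(source_name))
    source_name <- if (is.character(source)) basename(source) else "stream"

  odm_version <- xml2::xml_attr(root, "ODMVersion")
  if (is.na(odm_version)) odm_version <- ""
  if (!(odm_version %in% ODM_SUPPORTED_VERSIONS))
    warning(sprintf(
      "%s: unsupported declared ODMVersion '%s' (supported: %s); parsing best-effort",
      source_name, odm_version,
      paste(ODM_SUPPORTED_VERSIONS, collapse = ", ")), call. = FALSE)

  studies <- lapply(xml2::xml_find_all(root, "./Study"), function(st) {
    st_name <- xml2::xml_text(
      xml2::xml_find_first(st, "./GlobalVariables/StudyName"))
    if (is.na(st_name) || !nzchar(st_name))
      st_name <- xml2::xml_attr(st, "OID")
    mvs <- lapply(xml2::xml_find_all(st, "./MetaDataVersion"), parse_mv)
    odm_study(oid = xml2::xml_attr(st, "OID"), name = st_name,
              metadata_versions = mvs)
  })
  if (length(studies) == 0L)
    warning(sprintf("%s: no Study element found", source_name), call. = FALSE)
  odm_document(source_name = source_name, odm_version = odm_version,
               studies = studies)
}

parse_mv <- function(mv) {
  events <- lapply(xml2::xml_find_all(mv, "./StudyEventDef"), function(e)
    odm_studyeventdef(
      oid = xml2::xml_attr(e, "OID"), name = xml2::xml_attr(e, "Name"),
      form_oids = xml2::xml_attr(xml2::xml_find_all(e, "./FormRef"),
                                 "FormOID")))
  forms <- lapply(xml2::xml_find_all(mv, "./FormDef"), function(f)
    odm_formdef(
      oid = xml2::xml_attr(f, "OID"), name = xml2::xml_attr(f, "Name"),
      group_oids = xml2::xml_attr(xml2::xml_find_all(f, "./ItemGroupRef"),
                                  "ItemGroupOID")))
  groups <- lapply(xml2::xml_find_all(mv, "./ItemGroupDef"), function(g)
    odm_itemgroupdef(
      oid = xml2::xml_attr(g, "OID"), name = xml2::xml_attr(g, "Name"),
      item_oids = xml2::xml_attr(xml2::xml_find_all(g, "./ItemRef"),
                                 "ItemOID")))
  items <- lapply(xml2::xml_find_all(mv, "./ItemDef"), function(it) {
    clref <- xml2::xml_find_first(it, "./CodeListRef")
    odm_itemdef(
      oid = xml2::xml_attr(it, "OID"), name = xml2::xml_attr(it, "Name"),
      data_type = xml2::xml_attr(it, "DataType"),
      concept = concept_domain(collect_umls_codes(it)),
      codelist_oid = if (inherits(clref, "xml_missing")) NULL
                     else xml2::xml_attr(clref, "CodeListOID"),
      question_text = first_translated_text(it, "Question"))
  })
  codelists <- lapply(xml2::xml_find_all(mv, "./CodeList"), function(cl) {
    entries <- lapply(xml2::xml_find_all(cl, "./CodeListItem"), function(cli)
      odm_codelist_item(
        coded_value = xml2::xml_attr(cli, "CodedValue"),
        concept = concept_domain(collect_umls_codes(cli)),
        decode = first_translated_text(cli, "Decode")))
    odm_codelist(oid = xml2::xml_attr(cl, "OID"),
                 name = xml2::xml_attr(cl, "Name"),
                 data_type = xml2::xml_attr(cl, "DataType"),
                 items = entries)
  })
  odm_metadataversion(
    oid = xml2::xml_attr(mv, "OID"), name = xml2::xml_attr(mv, "Name"),
    study_event_defs = events, form_defs = forms, item_group_defs = groups,
    item_defs = items, code_lists = codelists)
}

# ---------------------------------------------------------------------------
# Validation

vr_message <- function(severity, location, text) {
  data.frame(severity = severity, location = location, text = text,
             stringsAsFactors = FALSE)
}

#' Validate an ODM file
#'
#' Always returns a report; findings never raise. Three layers run in turn:
#' well-formedness (XML parse), an optional grammar validation against a
#' user-supplied XSD, and a built-in structural check of the consumed ODM
#' subset (required attributes `OID`/`Name`/`DataType` present and valid, all
#' `*Ref` elements resolving within their metadata version, `CodedValue`
#' unique per code list). The official CDISC schemas are not shipped; pass
#' `schema_path` to enable grammar validation.
#'
#' @param source path to the file to validate.
#' @param schema_path optional path to an XSD for grammar validation.
#' @return an `odm_validation` report: list with `file_name`, `well_formed`,
#'   `schema_valid` (`TRUE`/`FALSE`, or `NA` for "not checked") and
#'   `messages` (data frame with columns severity, location, text).
#' @export
validate_odm <- function(source, schema_path = NULL) {
  file_name <- if (is.character(source)) basename(source) else "stream"
  msgs <- vr_message(character(), character(), character())
  doc <- tryCatch(xml2::read_xml(source), error = function(e) e)
  if (inherits(doc, "error")) {
    msgs <- rbind(msgs, vr_message("error", "line 1",
                                   paste("not well-formed XML:",
                                         conditionMessage(doc))))
    return(new_validation(file_name, FALSE, NA, msgs))
  }
  schema_valid <- NA
  if (!is.null(schema_path)) {
    schema <- xml2::read_xml(schema_path)
    ok <- xml2::xml_validate(doc, schema)
    schema_valid <- isTRUE(ok)
    for (err in attr(ok, "errors"))
      msgs <- rbind(msgs, vr_message("error", "schema", err))
  }

  root <- xml2::xml_root(doc)
  if (local_name(root) != "ODM") {
    msgs <- rbind(msgs, vr_message(
      "error", "/", sprintf("root element is <%s>, expected <ODM>",
                            local_name(root))))
    return(new_validation(file_name, TRUE, schema_valid, msgs))
  }
  xml2::xml_ns_strip(doc)
  ver <- xml2::xml_attr(root, "ODMVersion")
  if (is.na(ver) || !(ver %in% ODM_SUPPORTED_VERSIONS))
    msgs <- rbind(msgs, vr_message(
      "warning", "/ODM",
      sprintf("unsupported declared ODMVersion '%s' (supported: %s)",
              if (is.na(ver)) "" else ver,
              paste(ODM_SUPPORTED_VERSIONS, collapse = ", "))))
  msgs <- rbind(msgs, structural_check(root))
  new_validation(file_name, TRUE, schema_valid, msgs)
}

new_validation <- function(file_name, well_formed, schema_valid, messages) {
  rownames(messages) <- NULL
  structure(list(file_name = file_name, well_formed = well_formed,
                 schema_valid = schema_valid, messages = messages),
            class = "odm_validation")
}

#' Number of error-severity findings in a validation report
#' @param report an `odm_validation` report.
#' @export
validation_errors <- function(report) {
  sum(report$messages$severity == "error")
}

structural_check <- function(root) {
  msgs <- vr_message(character(), character(), character())
  err <- function(loc, txt) msgs <<- rbind(msgs, vr_message("error", loc, txt))
  studies <- xml2::xml_find_all(root, "./Study")
  for (si in seq_along(studies)) {
    st <- studies[[si]]
    st_oid <- xml2::xml_attr(st, "OID")
    st_loc <- sprintf("/ODM/Study[%d]", si)
    if (is.na(st_oid) || !nzchar(st_oid)) err(st_loc, "Study missing OID")
    mvs <- xml2::xml_find_all(st, "./MetaDataVersion")
    for (mi in seq_along(mvs)) {
      mv <- mvs[[mi]]
      loc <- sprintf("%s/MetaDataVersion[%d]", st_loc, mi)
      check_defs <- function(tag, need_datatype = FALSE) {
        defs <- xml2::xml_find_all(mv, paste0("./", tag))
        oids <- character()
        for (d in defs) {
          oid <- xml2::xml_attr(d, "OID")
          dloc <- sprintf("%s/%s[@OID='%s']", loc, tag,
                          if (is.na(oid)) "" else oid)
          if (is.na(oid) || !nzchar(oid))
            err(loc, sprintf("%s missing OID", tag))
          else oids <- c(oids, oid)
          if (is.na(xml2::xml_attr(d, "Name")))
            err(dloc, sprintf("%s missing Name", tag))
          if (need_datatype) {
            dt <- xml2::xml_attr(d, "DataType")
            if (is.na(dt))
              err(dloc, sprintf("%s missing DataType", tag))
            else if (!(dt %in% odm_data_types))
              err(dloc, sprintf("%s has invalid DataType '%s'", tag, dt))
          }
        }
        if (anyDuplicated(oids))
          err(loc, sprintf("duplicated %s OID %s", tag,
                           oids[duplicated(oids)][1]))
        oids
      }
      event_oids <- check_defs("StudyEventDef")
      form_oids  <- check_defs("FormDef")
      group_oids <- check_defs("ItemGroupDef")
      item_oids  <- check_defs("ItemDef", need_datatype = TRUE)
      cl_oids    <- check_defs("CodeList", need_datatype = TRUE)

      check_refs <- function(parent_tag, ref_tag, ref_attr, targets) {
        refs <- xml2::xml_find_all(mv, sprintf("./%s/%s", parent_tag, ref_tag))
        for (r in refs) {
          target <- xml2::xml_attr(r, ref_attr)
          if (is.na(target) || !(target %in% targets)) {
            parent_oid <- xml2::xml_attr(xml2::xml_parent(r), "OID")
            err(sprintf("%s/%s[@OID='%s']", loc, parent_tag,
                        if (is.na(parent_oid)) "" else parent_oid),
                sprintf("%s '%s' does not resolve", ref_attr,
                        if (is.na(target)) "" else target))
          }
        }
      }
      check_refs("StudyEventDef", "FormRef", "FormOID", form_oids)
      check_refs("FormDef", "ItemGroupRef", "ItemGroupOID", group_oids)
      check_refs("ItemGroupDef", "ItemRef", "ItemOID", item_oids)
      check_refs("ItemDef", "CodeListRef", "CodeListOID", cl_oids)

      for (cl in xml2::xml_find_all(mv, "./CodeList")) {
        cl_oid <- xml2::xml_attr(cl, "OID")
        cloc <- sprintf("%s/CodeList[@OID='%s']", loc,
                        if (is.na(cl_oid)) "" else cl_oid)
        clis <- xml2::xml_find_all(cl, "./CodeListItem")
        if (length(clis) == 0L)
          err(cloc, "CodeList has no CodeListItem")
        vals <- xml2::xml_attr(clis, "CodedValue")
        if (any(is.na(vals)))
          err(cloc, "CodeListItem missing CodedValue")
        vals <- vals[!is.na(vals)]
        if (anyDuplicated(vals))
          err(cloc, sprintf("duplicated CodedValue '%s'",
                            vals[duplicated(vals)][1]))
      }
    }
  }
  msgs
}

#' @export
print.odm_validation <- function(x, ...) {
  n_err <- validation_errors(x)
  cat(sprintf("<validation of %s: %s, %d error(s), %d warning(s)>\n",
              x$file_name,
              if (x$well_formed) "well-formed" else "NOT well-formed",
              n_err, sum(x$messages$severity == "warning")))
  if (!is.na(x$schema_valid))
    cat(sprintf("  schema: %s\n",
                if (x$schema_valid) "valid" else "INVALID"))
  for (i in seq_len(nrow(x$messages)))
    cat(sprintf("  [%s] %s: %s\n", x$messages$severity[i],
                x$messages$location[i], x$messages$text[i]))
  invisible(x)
}

#' Serialise a validation report as JSON lines
#'
#' One JSON object per message, suitable for machine consumption.
#' @param report an `odm_validation` report.
#' @return character vector of JSON lines.
#' @export
validation_jsonlines <- function(report) {
  m <- report$messages
  if (nrow(m) == 0L) return(character())
  vapply(seq_len(nrow(m)), function(i)
    jsonlite::toJSON(list(file = report$file_name,
                          severity = m$severity[i],
                          location = m$location[i],
                          text = m$text[i]), auto_unbox = TRUE),
    character(1))
}

# ---------------------------------------------------------------------------
# Emitter for the consumed subset (used by the fixture generator and for
# round-trip testing). Fixed attribute order and indentation keep output
# byte-stable across runs.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

emit_aliases <- function(codes, indent) {
  vapply(codes, function(code)
    sprintf('%s<Alias Context="UMLS" Name="%s"/>', indent, xml_escape(code)),
    character(1), USE.NAMES = FALSE)
}

#' Write an ODM document
#'
#' Serialises an [odm_document()] as ODM 1.3.2 XML covering the consumed
#' study-metadata subset. Output is deterministic: fixed attribute order,
#' two-space indentation, UTF-8, default ODM namespace.
#'
#' @param doc an [odm_document()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_odm <- function(doc, path) {
  L <- c('<?xml version="1.0" encoding="UTF-8"?>',
         sprintf('<ODM xmlns="%s" FileType="Snapshot" FileOID="%s" ODMVersion="%s">',
                 ODM_NS, xml_escape(doc$source_name),
                 xml_escape(doc$odm_version)))
  for (st in doc$studies) {
    L <- c(L, sprintf('  <Study OID="%s">', xml_escape(st$oid)),
           '    <GlobalVariables>',
           sprintf('      <StudyName>%s</StudyName>', xml_escape(st$name)),
           sprintf('      <StudyDescription>%s</StudyDescription>',
                   xml_escape(st$name)),
           sprintf('      <ProtocolName>%s</ProtocolName>',
                   xml_escape(st$name)),
           '    </GlobalVariables>')
    for (mv in st$metadata_versions) {
      L <- c(L, sprintf('    <MetaDataVersion OID="%s" Name="%s">',
                        xml_escape(mv$oid), xml_escape(mv$name)))
      for (e in mv$study_event_defs) {
        L <- c(L, sprintf('      <StudyEventDef OID="%s" Name="%s" Repeating="No" Type="Scheduled">',
                          xml_escape(e$oid), xml_escape(e$name)))
        for (i in seq_along(e$form_oids))
          L <- c(L, sprintf('        <FormRef FormOID="%s" OrderNumber="%d" Mandatory="No"/>',
                            xml_escape(e$form_oids[i]), i))
        L <- c(L, '      </StudyEventDef>')
      }
      for (f in mv$form_defs) {
        L <- c(L, sprintf('      <FormDef OID="%s" Name="%s" Repeating="No">',
                          xml_escape(f$oid), xml_escape(f$name)))
        for (i in seq_along(f$group_oids))
          L <- c(L, sprintf('        <ItemGroupRef ItemGroupOID="%s" OrderNumber="%d" Mandatory="No"/>',
                            xml_escape(f$group_oids[i]), i))
        L <- c(L, '      </FormDef>')
      }
      for (g in mv$item_group_defs) {
        L <- c(L, sprintf('      <ItemGroupDef OID="%s" Name="%s" Repeating="No">',
                          xml_escape(g$oid), xml_escape(g$name)))
        for (i in seq_along(g$item_oids))
          L <- c(L, sprintf('        <ItemRef ItemOID="%s" OrderNumber="%d" Mandatory="No"/>',
                            xml_escape(g$item_oids[i]), i))
        L <- c(L, '      </ItemGroupDef>')
      }
      for (it in mv$item_defs) {
        L <- c(L, sprintf('      <ItemDef OID="%s" Name="%s" DataType="%s">',
                          xml_escape(it$oid), xml_escape(it$name),
                          it$data_type))
        if (!is.null(it$question_text))
          L <- c(L, '        <Question>',
                 sprintf('          <TranslatedText xml:lang="en">%s</TranslatedText>',
                         xml_escape(it$question_text)),
                 '        </Question>')
        if (!is.null(it$codelist_oid))
          L <- c(L, sprintf('        <CodeListRef CodeListOID="%s"/>',
                            xml_escape(it$codelist_oid)))
        L <- c(L, emit_aliases(it$concept, "        "), '      </ItemDef>')
      }
      for (cl in mv$code_lists) {
        L <- c(L, sprintf('      <CodeList OID="%s" Name="%s" DataType="%s">',
                          xml_escape(cl$oid), xml_escape(cl$name),
                          cl$data_type))
        for (cli in cl$items) {
          L <- c(L, sprintf('        <CodeListItem CodedValue="%s">',
                            xml_escape(cli$coded_value)))
          if (!is.null(cli$decode))
            L <- c(L, '          <Decode>',
                   sprintf('            <TranslatedText xml:lang="en">%s</TranslatedText>',
                           xml_escape(cli$decode)),
                   '          </Decode>')
          L <- c(L, emit_aliases(cli$concept, "          "),
                 '        </CodeListItem>')
        }
        L <- c(L, '      </CodeList>')
      }
      L <- c(L, '    </MetaDataVersion>')
    }
    L <- c(L, '  </Study>')
  }
  L <- c(L, '</ODM>')
  writeLines(L, path, useBytes = TRUE)
  invisible(path)
}
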