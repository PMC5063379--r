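# Content summaries of a form set: per-group item counts ("Short Summary")
# and the structural reference tree of each file.

#' Short summary of a form set's content
#'
#' One row per (file, form, item group) in document order, with the number of
#' item references in that group as presented by that form, plus a total row
#' per form (item group `"(total)"`). Items referenced by several groups are
#' counted once per referencing group — the summary estimates documentation
#' effort as the form is filled in. Items without semantic codes are counted
#' like any other. Forms not referenced by any study event are summarised
#' too.
#'
#' @param docs list of [odm_document()] (or one document).
#' @return an `odm_short_summary`: data frame with columns `file`, `form`,
#'   `item_group`, `item_count`.
#' @export
short_summary <- function(docs) {
  if (inherits(docs, "odm_document")) docs <- list(docs)
  rows <- list()
  add <- function(file, form, grp, n)
    rows[[length(rows) + 1L]] <<- data.frame(
      file = file, form = form, item_group = grp, item_count = as.integer(n),
      stringsAsFactors = FALSE)
  for (doc in docs) {
    for (st in doc$studies) {
      for (mv in st$metadata_versions) {
        for (f in mv$form_defs) {
          total <- 0L
          for (g_oid in f$group_oids) {
            g <- mv_group(mv, g_oid)
            if (is.null(g))
              stop(sprintf("FormDef %s references undefined ItemGroup '%s'",
                           f$oid, g_oid))
            add(doc$source_name, f$name, g$name, length(g$item_oids))
            total <- total + length(g$item_oids)
          }
          add(doc$source_name, f$name, "(total)", total)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(), form = character(),
               item_group = character(), item_count = integer(),
               stringsAsFactors = FALSE)
  class(out) <- c("odm_short_summary", "data.frame")
  out
}

#' @export
print.odm_short_summary <- function(x, ...) {
  cat("Short summary (item groups and amount of items per form):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Structural summary of one ODM file
#'
#' Echoes the study / study-event / metadata-version metadata of a document
#' and the reference tree FormDef -> ItemGroupDef -> ItemDef -> CodeList with
#' per-node counts. Forms not referenced by any study event are still shown
#' (flagged as unreferenced); item groups, items and code lists unreachable
#' from every form are listed as orphans. Pure and idempotent: the same
#' document always yields an identical report.
#'
#' @param doc an [odm_document()].
#' @return an `odm_structure` report (nested list; see `print` and
#'   [structure_json()]).
#' @export
structure_summary <- function(doc) {
  studies <- lapply(doc$studies, function(st) {
    mvs <- lapply(st$metadata_versions, function(mv) {
      referenced <- new.env(parent = emptyenv())
      mark <- function(kind, oid) assign(paste(kind, oid), TRUE, referenced)
      seen <- function(kind, oid)
        exists(paste(kind, oid), referenced, inherits = FALSE)

      form_tree <- function(f) {
        groups <- lapply(f$group_oids, function(g_oid) {
          g <- mv_group(mv, g_oid)
          if (is.null(g)) stop(sprintf(
            "FormDef %s references undefined ItemGroup '%s'", f$oid, g_oid))
          mark("group", g_oid)
          items <- lapply(g$item_oids, function(it_oid) {
            it <- mv_item(mv, it_oid)
            if (is.null(it)) stop(sprintf(
              "ItemGroupDef %s references undefined Item '%s'", g$oid, it_oid))
            mark("item", it_oid)
            cl <- NULL
            if (!is.null(it$codelist_oid)) {
              mark("codelist", it$codelist_oid)
              cldef <- mv_codelist(mv, it$codelist_oid)
              if (!is.null(cldef))
                cl <- list(oid = cldef$oid, name = cldef$name,
                           n_entries = length(cldef$items))
            }
            list(oid = it$oid, name = it$name, data_type = it$data_type,
                 n_codes = length(it$concept), code_list = cl)
          })
          list(oid = g$oid, name = g$name, n_items = length(g$item_oids),
               items = items)
        })
        list(oid = f$oid, name = f$name, n_groups = length(f$group_oids),
             n_items = sum(vapply(groups, function(g) g$n_items, integer(1))),
             groups = groups)
      }

      event_form_oids <- unlist(lapply(mv$study_event_defs,
                                       function(e) e$form_oids))
      forms <- lapply(mv$form_defs, function(f) {
        node <- form_tree(f)
        node$referenced_by_event <- f$oid %in% event_form_oids
        node
      })
      orphans <- c(
        vapply(Filter(function(g) !seen("group", g$oid), mv$item_group_defs),
               function(g) paste0("ItemGroupDef ", g$oid), character(1)),
        vapply(Filter(function(it) !seen("item", it$oid), mv$item_defs),
               function(it) paste0("ItemDef ", it$oid), character(1)),
        vapply(Filter(function(cl) !seen("codelist", cl$oid), mv$code_lists),
               function(cl) paste0("CodeList ", cl$oid), character(1)))
      list(oid = mv$oid, name = mv$name,
           events = lapply(mv$study_event_defs, function(e)
             list(oid = e$oid, name = e$name, form_oids = e$form_oids)),
           counts = c(study_events = length(mv$study_event_defs),
                      forms = length(mv$form_defs),
                      item_groups = length(mv$item_group_defs),
                      items = length(mv$item_defs),
                      code_lists = length(mv$code_lists)),
           forms = forms, orphans = orphans)
    })
    list(oid = st$oid, name = st$name, metadata_versions = mvs)
  })
  structure(list(file = doc$source_name, odm_version = doc$odm_version,
                 studies = studies),
            class = "odm_structure")
}

#' @export
print.odm_structure <- function(x, ...) {
  cat(sprintf("Structure of %s (ODMVersion %s)\n", x$file, x$odm_version))
  for (st in x$studies) {
    cat(sprintf("Study %s (%s)\n", st$name, st$oid))
    for (mv in st$metadata_versions) {
      cn <- mv$counts
      cat(sprintf("  MetaDataVersion %s (%s): %d event(s), %d form(s), %d group(s), %d item(s), %d code list(s)\n",
                  mv$name, mv$oid, cn[["study_events"]], cn[["forms"]],
                  cn[["item_groups"]], cn[["items"]], cn[["code_lists"]]))
      for (e in mv$events)
        cat(sprintf("    StudyEvent %s -> forms: %s\n", e$name,
                    paste(e$form_oids, collapse = ", ")))
      for (f in mv$forms) {
        cat(sprintf("    Form %s [%d group(s), %d item(s)]%s\n", f$name,
                    f$n_groups, f$n_items,
                    if (f$referenced_by_event) "" else " (not referenced by any event)"))
        for (g in f$groups) {
          cat(sprintf("      Group %s [%d item(s)]\n", g$name, g$n_items))
          for (it in g$items)
            cat(sprintf("        Item %s (%s, %d code%s)%s\n", it$name,
                        it$data_type, it$n_codes,
                        if (it$n_codes == 1L) "" else "s",
                        if (is.null(it$code_list)) "" else
                          sprintf(" -> CodeList %s [%d entries]",
                                  it$code_list$name, it$code_list$n_entries)))
        }
      }
      if (length(mv$orphans))
        cat("    Orphans:", paste(mv$orphans, collapse = "; "), "\n")
    }
  }
  invisible(x)
}

#' Structural summary as JSON
#' @param report an `odm_structure` report.
#' @return a JSON string.
#' @export
structure_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
}
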