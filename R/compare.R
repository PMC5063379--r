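# Pairwise item-similarity classification and the all-pairs driver.
#
# Two data elements are compared first on their concept domains (the UMLS
# code sets), then on their value domains (data type + optional code list).
# The decision cascade assigns exactly one of five levels to every coded
# pair; uncoded items are excluded up front as NOTCODED.

#' Similarity levels, in increasing order
#'
#' `NOTCODED < DIFFERENT < SIMILAR < TRANSFORMABLE < MATCHING < IDENTICAL`.
#' NOTCODED applies to items, not pairs: an item without semantic codes is
#' excluded from pairwise comparison.
#'
#' @export
relationship_levels <- c("NOTCODED", "DIFFERENT", "SIMILAR", "TRANSFORMABLE",
                         "MATCHING", "IDENTICAL")

#' Encode similarity levels as an ordered factor
#' @param x character vector of level names.
#' @export
relationship <- function(x) {
  if (!all(x %in% relationship_levels))
    stop("unknown relationship level: ",
         paste(setdiff(x, relationship_levels), collapse = ", "))
  factor(x, levels = relationship_levels, ordered = TRUE)
}

rel_rank <- function(x) match(x, relationship_levels)

norm_name <- function(x) tolower(trimws(x))

#' A resolved item occurrence
#'
#' One occurrence of an item as referenced by a form: the item definition,
#' its resolved value domain, and the provenance that makes the occurrence
#' unique (the same ItemDef referenced twice in one form yields two resolved
#' items with distinct positions).
#'
#' @param item an [odm_itemdef()].
#' @param value_domain its [value_domain_of()] result.
#' @param file_name,study_name,form_name,group_name provenance labels.
#' @param position ordinal position within the form (>= 1).
#' @export
resolved_item <- function(item, value_domain, file_name, study_name,
                          form_name, group_name, position) {
  stopifnot(position >= 1)
  structure(list(item = item, value_domain = value_domain,
                 file_name = file_name, study_name = study_name,
                 form_name = form_name, group_name = group_name,
                 position = as.integer(position)),
            class = "resolved_item")
}

#' Resolve every item occurrence in a set of ODM documents
#'
#' Walks every (file, study, metadata version, form, item group, item
#' reference) chain in document order and returns one [resolved_item()] per
#' occurrence. Each (file, study, metadata version, form) combination is a
#' distinct form source, so multiple forms in one file — and multiple
#' metadata versions — are all compared.
#'
#' @param docs a list of [odm_document()] (a single document is accepted).
#' @return list of [resolved_item()].
#' @export
resolve_items <- function(docs) {
  if (inherits(docs, "odm_document")) docs <- list(docs)
  out <- list()
  for (doc in docs) {
    for (st in doc$studies) {
      for (mv in st$metadata_versions) {
        for (f in mv$form_defs) {
          pos <- 0L
          for (g_oid in f$group_oids) {
            g <- mv_group(mv, g_oid)
            if (is.null(g))
              stop(sprintf("FormDef %s references undefined ItemGroup '%s'",
                           f$oid, g_oid))
            for (it_oid in g$item_oids) {
              it <- mv_item(mv, it_oid)
              if (is.null(it))
                stop(sprintf("ItemGroupDef %s references undefined Item '%s'",
                             g$oid, it_oid))
              pos <- pos + 1L
              out[[length(out) + 1L]] <- resolved_item(
                item = it, value_domain = value_domain_of(it, mv),
                file_name = doc$source_name, study_name = st$name,
                form_name = f$name, group_name = g$name, position = pos)
            }
          }
        }
      }
    }
  }
  out
}

# Concept signature of a code-list entry: its code set, collapsed to a
# canonical string (empty set -> "").
cli_signature <- function(cli) paste(unclass(cli$concept), collapse = "\x1f")

#' Code-list correspondence
#'
#' Decides whether the code lists of two items "fit": with no code list on
#' either side the correspondence holds vacuously; with a code list on only
#' one side it fails; with both present it holds iff the *multiset* of
#' per-entry concept-code sets is identical on both sides (so duplicated
#' signatures must occur equally often — this is what makes a bijection of
#' corresponding entries possible). Within one concept signature, entries are
#' paired by ascending coded value, a deterministic and order-independent
#' tie-break. The remaining flags compare the paired entries' coded values
#' (case-sensitive, whitespace-trimmed), the code-list data types (exact
#' token equality) and the code-list names (case-insensitive).
#'
#' @param cl_a,cl_b [odm_codelist()] objects or `NULL` (no code list).
#' @return list with `concepts_match`, `bijection` (two-column index matrix,
#'   or `NULL`), `values_match`, `datatypes_match`, `names_match`; the last
#'   three are `NA` when `concepts_match` is `FALSE`.
#' @export
codelist_correspondence <- function(cl_a, cl_b) {
  if (is.null(cl_a) && is.null(cl_b))
    return(list(concepts_match = TRUE, bijection = NULL, values_match = TRUE,
                datatypes_match = TRUE, names_match = TRUE))
  if (is.null(cl_a) || is.null(cl_b))
    return(list(concepts_match = FALSE, bijection = NULL, values_match = NA,
                datatypes_match = NA, names_match = NA))
  sig_a <- unname(vapply(cl_a$items, cli_signature, character(1)))
  sig_b <- unname(vapply(cl_b$items, cli_signature, character(1)))
  if (!identical(sort(sig_a), sort(sig_b)))
    return(list(concepts_match = FALSE, bijection = NULL, values_match = NA,
                datatypes_match = NA, names_match = NA))
  val_a <- unname(vapply(cl_a$items, function(x) x$coded_value, character(1)))
  val_b <- unname(vapply(cl_b$items, function(x) x$coded_value, character(1)))
  bij <- NULL
  for (sig in unique(sig_a)) {
    ia <- which(sig_a == sig); ia <- ia[order(val_a[ia])]
    ib <- which(sig_b == sig); ib <- ib[order(val_b[ib])]
    bij <- rbind(bij, cbind(a = ia, b = ib))
  }
  bij <- bij[order(bij[, "a"]), , drop = FALSE]
  list(concepts_match = TRUE,
       bijection = bij,
       values_match = all(val_a[bij[, "a"]] == val_b[bij[, "b"]]),
       datatypes_match = cl_a$data_type == cl_b$data_type,
       names_match = norm_name(cl_a$name) == norm_name(cl_b$name))
}

#' Classify one pair of coded items
#'
#' The decision cascade, evaluated in order; the first failing gate fixes the
#' level:
#'
#' 1. concept domains differ -> `DIFFERENT`;
#' 2. code-list concept correspondence fails, or the item data types differ
#'    -> `SIMILAR`;
#' 3. otherwise at least `TRANSFORMABLE` (stored data can be mapped back and
#'    forth through the corresponding entries);
#' 4. if additionally the code-list data types are equal and the coded values
#'    of corresponding entries are equal -> `MATCHING` (data merges with no
#'    transformation);
#' 5. if additionally the item names and code-list names are equal
#'    case-insensitively -> `IDENTICAL`.
#'
#' Both items must be coded; comparing an uncoded item is a contract
#' violation (uncoded items are NOTCODED and are filtered before pairing).
#'
#' @param a,b [resolved_item()] objects with non-empty concept domains.
#' @return one of `"DIFFERENT"`, `"SIMILAR"`, `"TRANSFORMABLE"`,
#'   `"MATCHING"`, `"IDENTICAL"`.
#' @export
classify_pair <- function(a, b) {
  if (!is_coded(a$item$concept) || !is_coded(b$item$concept))
    stop("classify_pair() requires coded items; uncoded items are NOTCODED and must be filtered out")
  if (!cd_equal(a$item$concept, b$item$concept)) return("DIFFERENT")
  corr <- codelist_correspondence(a$value_domain$code_list,
                                  b$value_domain$code_list)
  if (!corr$concepts_match || a$item$data_type != b$item$data_type)
    return("SIMILAR")
  if (!(isTRUE(corr$datatypes_match) && isTRUE(corr$values_match)))
    return("TRANSFORMABLE")
  if (norm_name(a$item$name) == norm_name(b$item$name) &&
      isTRUE(corr$names_match))
    return("IDENTICAL")
  "MATCHING"
}

#' Compare every item against every other item in a form set
#'
#' Resolves all item occurrences across the given documents, marks items
#' without semantic codes as NOTCODED and excludes them, and classifies all
#' C(n, 2) pairs of the n remaining coded occurrences — including pairs
#' within one form and within one file.
#'
#' @param docs list of [odm_document()] (or a single document).
#' @return an `odm_comparison`: list with `items` (all resolved occurrences),
#'   `coded` / `not_coded` (index vectors into `items`), `pairs` (data frame
#'   with columns `a`, `b` — indices into `items` — and `relationship`), and
#'   `counts_by_level` (named integer vector over the five coded levels).
#' @export
compare_all <- function(docs) {
  items <- resolve_items(docs)
  if (length(items) == 0L)
    stop("no study metadata: the given documents contain no form items")
  coded <- which(vapply(items, function(x) is_coded(x$item$concept),
                        logical(1)))
  not_coded <- setdiff(seq_along(items), coded)
  n <- length(coded)
  n_pairs <- if (n >= 2L) (n * (n - 1L)) %/% 2L else 0L
  a_idx <- integer(n_pairs); b_idx <- integer(n_pairs)
  rel <- character(n_pairs)
  k <- 0L
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        k <- k + 1L
        a_idx[k] <- coded[i]; b_idx[k] <- coded[j]
        rel[k] <- classify_pair(items[[coded[i]]], items[[coded[j]]])
      }
    }
  }
  counts <- table(factor(rel, levels = relationship_levels[-1]))
  structure(list(items = items, coded = coded, not_coded = not_coded,
                 pairs = data.frame(a = a_idx, b = b_idx, relationship = rel,
                                    stringsAsFactors = FALSE),
                 counts_by_level = stats::setNames(as.integer(counts),
                                                   names(counts))),
            class = "odm_comparison")
}

#' @export
print.odm_comparison <- function(x, ...) {
  cat(sprintf("<ODM comparison: %d item occurrence(s), %d coded, %d not coded, %d pair(s)>\n",
              length(x$items), length(x$coded), length(x$not_coded),
              nrow(x$pairs)))
  for (lvl in rev(names(x$counts_by_level)))
    if (x$counts_by_level[[lvl]] > 0L)
      cat(sprintf("  %-13s %d\n", lvl, x$counts_by_level[[lvl]]))
  invisible(x)
}

#' @export
summary.odm_comparison <- function(object, ...) {
  forms <- unique(vapply(object$items, function(it)
    paste(it$file_name, it$form_name, sep = " / "), character(1)))
  cat(sprintf("Comparison of %d form(s):\n", length(forms)))
  for (f in forms) cat("  -", f, "\n")
  print(object)
  invisible(object)
}
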