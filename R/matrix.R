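# The comparable-items matrix and the per-level pair listings, plus exports.
#
# Rows of the matrix are groups of coded items sharing one exact concept
# domain (a well-defined equivalence: any pair at level SIMILAR or above has
# equal concept domains, so grouping by the domain itself is transitive and
# unambiguous). Columns are the forms of the input set; a cell counts the
# occurrences of the row's concept in that form, rendered as that many "x"
# marks — a form holding a concept twice gets two marks.

cd_signature <- function(cd) paste(unclass(cd), collapse = "\x1f")

pair_lookup <- function(result) {
  stats::setNames(result$pairs$relationship,
                  paste(result$pairs$a, result$pairs$b))
}

lookup_rel <- function(lut, i, j) {
  if (i == j) return("IDENTICAL")  # an occurrence vs itself
  unname(lut[paste(min(i, j), max(i, j))])
}

form_key <- function(it) paste(it$file_name, it$study_name, it$form_name,
                               sep = "\x1f")

#' Build the comparable-items matrix
#'
#' Groups the coded items of a comparison by exact concept domain, keeps
#' groups with at least two members whose best pairwise level reaches
#' `min_level`, and counts occurrences per (file, study, form) column. Each
#' cell also carries the best relationship between the row's representative
#' item (its first member in input order, which provides the row label) and
#' the items in that cell.
#'
#' @param result an `odm_comparison` from [compare_all()].
#' @param min_level minimum similarity level a group must reach to be shown;
#'   one of `"SIMILAR"`, `"TRANSFORMABLE"`, `"MATCHING"`, `"IDENTICAL"`.
#' @return a `comparable_matrix`: list with `rows` (per-group label, codes,
#'   member indices), `columns` (data frame file/study/form), `counts`
#'   (integer matrix), `levels` (character matrix of best per-cell
#'   relationship, `""` for empty cells).
#' @export
build_matrix <- function(result, min_level = "SIMILAR") {
  stopifnot(inherits(result, "odm_comparison"))
  if (!(min_level %in% relationship_levels) ||
      rel_rank(min_level) < rel_rank("SIMILAR"))
    stop("min_level must be one of SIMILAR, TRANSFORMABLE, MATCHING, IDENTICAL")
  items <- result$items
  # columns: all forms of the input set, in input order
  fkeys <- vapply(items, form_key, character(1))
  col_keys <- unique(fkeys)
  cols <- do.call(rbind, lapply(strsplit(col_keys, "\x1f", fixed = TRUE),
                                function(p) data.frame(file = p[1],
                                                       study = p[2],
                                                       form = p[3],
                                                       stringsAsFactors = FALSE)))
  if (is.null(cols))
    cols <- data.frame(file = character(), study = character(),
                       form = character(), stringsAsFactors = FALSE)

  lut <- pair_lookup(result)
  sigs <- vapply(result$coded, function(i) cd_signature(items[[i]]$item$concept),
                 character(1))
  groups <- list()
  for (sig in unique(sigs)) {
    members <- result$coded[sigs == sig]
    if (length(members) < 2L) next
    rels <- vapply(utils::combn(members, 2L, simplify = FALSE),
                   function(p) lookup_rel(lut, p[1], p[2]), character(1))
    if (max(rel_rank(rels)) < rel_rank(min_level)) next
    lead <- members[1]
    groups[[length(groups) + 1L]] <- list(
      label = items[[lead]]$item$name,
      codes = unclass(items[[lead]]$item$concept),
      members = members)
  }

  counts <- matrix(0L, nrow = length(groups), ncol = length(col_keys),
                   dimnames = list(vapply(groups, function(g) g$label,
                                          character(1)),
                                   paste(cols$file, cols$form, sep = ":")))
  levels_m <- matrix("", nrow = nrow(counts), ncol = ncol(counts),
                     dimnames = dimnames(counts))
  for (r in seq_along(groups)) {
    g <- groups[[r]]
    lead <- g$members[1]
    for (m in g$members) {
      cidx <- match(fkeys[m], col_keys)
      counts[r, cidx] <- counts[r, cidx] + 1L
      rel <- lookup_rel(lut, lead, m)
      if (levels_m[r, cidx] == "" ||
          rel_rank(rel) > rel_rank(levels_m[r, cidx]))
        levels_m[r, cidx] <- rel
    }
  }
  structure(list(rows = groups, columns = cols, counts = counts,
                 levels = levels_m, min_level = min_level),
            class = "comparable_matrix")
}

#' @export
print.comparable_matrix <- function(x, ...) {
  cat(sprintf("<comparable-items matrix: %d concept group(s) x %d form(s), min level %s>\n",
              nrow(x$counts), ncol(x$counts), x$min_level))
  if (nrow(x$counts)) print(x$counts)
  invisible(x)
}

#' Comparable-items matrix as a data frame
#'
#' Columns: `item` (representative name), `codes` (concept codes, space
#' separated), then one integer column per form.
#' @param x a `comparable_matrix`.
#' @param ... unused.
#' @export
as.data.frame.comparable_matrix <- function(x, ...) {
  base <- data.frame(
    item = vapply(x$rows, function(g) g$label, character(1)),
    codes = vapply(x$rows, function(g) paste(g$codes, collapse = " "),
                   character(1)),
    stringsAsFactors = FALSE)
  cbind(base, as.data.frame(x$counts, check.names = FALSE,
                            row.names = seq_len(nrow(x$counts))))
}

item_detail <- function(it) {
  sprintf("%s [%s] codes: %s (%s / %s / %s, pos %d)", it$item$name,
          it$item$data_type, paste(unclass(it$item$concept), collapse = " "),
          it$file_name, it$form_name, it$group_name, it$position)
}

#' Pair listings grouped by relationship level
#'
#' For each of the five coded levels, the pairs at that level with both
#' sides' provenance, names, data types and concept codes; items without
#' semantic annotation are listed separately so they can be reviewed
#' manually.
#'
#' @param result an `odm_comparison` from [compare_all()].
#' @return an `odm_pair_listings`: list with `by_level` (named list of data
#'   frames, one per coded level) and `not_coded` (data frame).
#' @export
list_pairs_by_level <- function(result) {
  stopifnot(inherits(result, "odm_comparison"))
  items <- result$items
  side <- function(idx, prefix) {
    df <- data.frame(
      file = vapply(idx, function(i) items[[i]]$file_name, character(1)),
      form = vapply(idx, function(i) items[[i]]$form_name, character(1)),
      group = vapply(idx, function(i) items[[i]]$group_name, character(1)),
      item = vapply(idx, function(i) items[[i]]$item$name, character(1)),
      data_type = vapply(idx, function(i) items[[i]]$item$data_type,
                         character(1)),
      codes = vapply(idx, function(i)
        paste(unclass(items[[i]]$item$concept), collapse = " "),
        character(1)),
      stringsAsFactors = FALSE)
    stats::setNames(df, paste(prefix, names(df), sep = "_"))
  }
  by_level <- lapply(stats::setNames(nm = relationship_levels[-1]),
                     function(lvl) {
    sel <- result$pairs$relationship == lvl
    cbind(side(result$pairs$a[sel], "a"), side(result$pairs$b[sel], "b"))
  })
  nc <- result$not_coded
  not_coded <- data.frame(
    file = vapply(nc, function(i) items[[i]]$file_name, character(1)),
    form = vapply(nc, function(i) items[[i]]$form_name, character(1)),
    group = vapply(nc, function(i) items[[i]]$group_name, character(1)),
    item = vapply(nc, function(i) items[[i]]$item$name, character(1)),
    data_type = vapply(nc, function(i) items[[i]]$item$data_type,
                       character(1)),
    stringsAsFactors = FALSE)
  structure(list(by_level = by_level, not_coded = not_coded),
            class = "odm_pair_listings")
}

#' @export
print.odm_pair_listings <- function(x, ...) {
  for (lvl in rev(names(x$by_level)))
    cat(sprintf("%-13s %d pair(s)\n", lvl, nrow(x$by_level[[lvl]])))
  cat(sprintf("%-13s %d item(s)\n", "NOTCODED", nrow(x$not_coded)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Exports

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df) {
  if (nrow(df) == 0L)
    return(c("<table>", paste0("<tr>", paste0("<th>",
                                              html_escape(names(df)),
                                              "</th>", collapse = ""),
                               "</tr>"), "</table>"))
  head <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  body <- vapply(seq_len(nrow(df)), function(i)
    paste0("<tr>", paste0("<td>",
                          html_escape(as.character(unlist(df[i, ]))),
                          "</td>", collapse = ""), "</tr>"),
    character(1))
  c("<table>", head, body, "</table>")
}

matrix_html <- function(matrix, result) {
  items <- result$items
  head <- paste0("<tr><th>item</th><th>codes</th>",
                 paste0("<th>", html_escape(paste(matrix$columns$file,
                                                  matrix$columns$form,
                                                  sep = ":")), "</th>",
                        collapse = ""), "</tr>")
  col_keys <- paste(matrix$columns$file, matrix$columns$study,
                    matrix$columns$form, sep = "\x1f")
  rows <- vapply(seq_along(matrix$rows), function(r) {
    g <- matrix$rows[[r]]
    cells <- vapply(seq_along(col_keys), function(cidx) {
      in_cell <- g$members[vapply(g$members, function(m)
        form_key(items[[m]]) == col_keys[cidx], logical(1))]
      marks <- paste(vapply(in_cell, function(m)
        sprintf('<span title="%s">x</span>',
                html_escape(item_detail(items[[m]]))), character(1)),
        collapse = " ")
      lvl <- matrix$levels[r, cidx]
      sprintf('<td%s>%s</td>',
              if (nzchar(lvl)) sprintf(' class="%s"', tolower(lvl)) else "",
              marks)
    }, character(1))
    paste0(sprintf('<tr><td title="%s">%s</td><td>%s</td>',
                   html_escape(item_detail(items[[g$members[1]]])),
                   html_escape(g$label),
                   html_escape(paste(g$codes, collapse = " "))),
           paste(cells, collapse = ""), "</tr>")
  }, character(1))
  c("<table>", head, rows, "</table>")
}

#' Export comparison reports to files
#'
#' Writes the short summary, the per-level pair listings, the not-coded item
#' list and the comparable-items matrix. `csv`/`tsv` write one file per
#' section into `dest` (a directory, created if needed); matrix cells are
#' integer occurrence counts (0 = empty). `html` writes one self-contained
#' page with all sections; matrix cells are rendered as repeated "x" marks
#' with per-item hover detail. The `xlsx` token is recognised but not
#' supported by this build.
#'
#' @param matrix a `comparable_matrix` from [build_matrix()].
#' @param listings an `odm_pair_listings` from [list_pairs_by_level()].
#' @param short an `odm_short_summary` from [short_summary()].
#' @param result the `odm_comparison` the above were built from (needed for
#'   per-item hover detail in html).
#' @param format one of `"csv"`, `"tsv"`, `"html"`.
#' @param dest destination directory (csv/tsv) or file/directory (html).
#' @return character vector of files written, invisibly.
#' @export
export_report <- function(matrix, listings, short, result,
                          format = c("csv", "tsv", "html"), dest) {
  if (identical(format, "xlsx") ||
      (length(format) == 1L && format == "xlsx"))
    stop("format 'xlsx' is not supported by this build; use csv, tsv or html")
  format <- match.arg(format)
  written <- character()
  if (format %in% c("csv", "tsv")) {
    if (!dir.exists(dest)) dir.create(dest, recursive = TRUE)
    sep <- if (format == "csv") "," else "\t"
    ext <- paste0(".", format)
    emit <- function(df, name) {
      path <- file.path(dest, paste0(name, ext))
      utils::write.table(df, path, sep = sep, row.names = FALSE, qmethod = "double")
      written <<- c(written, path)
    }
    emit(as.data.frame(short), "short_summary")
    for (lvl in names(listings$by_level))
      emit(listings$by_level[[lvl]], paste0("pairs_", tolower(lvl)))
    emit(listings$not_coded, "not_coded")
    emit(as.data.frame(matrix), "comparable_matrix")
  } else {
    path <- if (dir.exists(dest)) file.path(dest, "report.html") else dest
    L <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
           "<title>ODM form comparison</title>",
           "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 6px}</style>",
           "</head><body>",
           "<h1>ODM form comparison</h1>",
           "<h2>Short Summary</h2>", html_table(as.data.frame(short)))
    for (lvl in rev(names(listings$by_level)))
      L <- c(L, sprintf("<h2>%s (%d pairs)</h2>", lvl,
                        nrow(listings$by_level[[lvl]])),
             html_table(listings$by_level[[lvl]]))
    L <- c(L, sprintf("<h2>Not coded (%d items)</h2>",
                      nrow(listings$not_coded)),
           html_table(listings$not_coded),
           "<h2>Comparable Items</h2>", matrix_html(matrix, result),
           "</body></html>")
    writeLines(L, path, useBytes = TRUE)
    written <- path
  }
  invisible(written)
}
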