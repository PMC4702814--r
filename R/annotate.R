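cell_tags <- c(conserved = "conserved",
               acceptable_replacement = "acceptable",
               unacceptable_replacement = "unacceptable",
               gap = "gap")

#' Annotate an alignment with scored-cell classifications
#'
#' Produces plain-text and HTML renderings of a scored cleavage site. In
#' both, the cleavage position in the reference row is marked between the
#' P1 and P1' columns, and every scored homologue cell carries its
#' classification tag: \code{conserved}, \code{acceptable},
#' \code{unacceptable} or \code{gap} (the service's pink / orange / black
#' highlighting, as tags).
#'
#' @param alignment The \code{homologue_alignment} that was scored.
#' @param report The matching \code{conservation_report} from [score_site()].
#' @return List with elements \code{text} (character vector of lines) and
#'   \code{html} (single HTML string).
#' @export
annotate_alignment <- function(alignment, report) {
  stopifnot(inherits(alignment, "homologue_alignment"),
            inherits(report, "conservation_report"))
  if (!identical(alignment$reference_id,
                 report$request$substrate_accession))
    stop("report does not correspond to this alignment")
  if (!setequal(rownames(report$cells),
                setdiff(names(alignment$sequences), alignment$reference_id)))
    stop("report homologue rows do not match the alignment")

  cols <- report$columns
  p1_col <- cols[["P1"]]
  subsites <- subsite_names()
  width <- alignment$width
  ids <- names(alignment$sequences)
  id_w <- max(nchar(ids))

  # cleavage marker line: "/" after the P1 column
  marker <- rep(" ", width)
  for (i in seq_along(cols)) if (!is.na(cols[[i]])) marker[cols[[i]]] <- "."
  text <- c(sprintf("# cleavage of %s by %s after residue %d",
                    report$request$substrate_accession, report$peptidase,
                    report$request$p1_residue),
            sprintf("# scored subsites marked '.'; cleavage falls after column %s",
                    if (is.na(p1_col)) "?" else p1_col),
            paste(formatC("", width = id_w), paste(marker, collapse = "")))
  text <- c(text, paste(formatC(alignment$reference_id, width = id_w),
                        alignment$sequences[[alignment$reference_id]],
                        "<reference>"))
  for (h in rownames(report$cells)) {
    tags <- stats::na.omit(sprintf(
      "%s:%s", subsites[!is.na(report$cells[h, ])],
      cell_tags[report$cells[h, !is.na(report$cells[h, ])]]))
    text <- c(text, paste(formatC(h, width = id_w),
                          alignment$sequences[[h]],
                          paste(tags, collapse = " ")))
  }

  html <- annotate_html(alignment, report)
  list(text = text, html = html)
}

annotate_html <- function(alignment, report) {
  cols <- report$columns
  p1_col <- cols[["P1"]]
  subsites <- subsite_names()
  width <- alignment$width
  col_subsite <- rep(NA_character_, width)
  for (i in seq_along(cols))
    if (!is.na(cols[[i]])) col_subsite[cols[[i]]] <- subsites[[i]]

  row_html <- function(id) {
    chars <- strsplit(alignment$sequences[[id]], "")[[1]]
    is_ref <- identical(id, alignment$reference_id)
    spans <- vapply(seq_len(width), function(j) {
      ch <- chars[[j]]
      s <- col_subsite[[j]]
      cut <- if (!is.na(p1_col) && j == p1_col) "<span class=\"cleavage\">|</span>" else ""
      if (is.na(s))
        return(paste0(ch, cut))
      tag <- if (is_ref) "reference"
             else cell_tags[[report$cells[id, s]]]
      paste0(sprintf("<span class=\"%s\" data-subsite=\"%s\">%s</span>",
                     tag, s, ch), cut)
    }, character(1))
    sprintf("<tr><th>%s</th><td><code>%s</code></td></tr>",
            id, paste(spans, collapse = ""))
  }

  ids <- c(alignment$reference_id,
           setdiff(names(alignment$sequences), alignment$reference_id))
  paste0(
    "<table class=\"cleavage-alignment\">\n",
    sprintf("<caption>%s cleaved by %s after residue %d</caption>\n",
            report$request$substrate_accession, report$peptidase,
            report$request$p1_residue),
    paste(vapply(ids, row_html, character(1)), collapse = "\n"),
    "\n</table>"
  )
}
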