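#' Catalytic-type letters
#'
#' The one-letter codes used as the first character of clan, family and
#' holotype identifiers, with their human-readable names. Seven letters
#' denote a catalytic mechanism (aspartic, cysteine, glutamic, metallo,
#' serine, threonine, asparagine lyase); three more cover peptidases of
#' mixed type, peptidases of unknown type, and protein inhibitors.
#'
#' @return Named character vector mapping each code letter to its label.
#' @export
#' @examples
#' catalytic_types()[["A"]]
catalytic_types <- function() {
  c(A = "aspartic peptidase",
    C = "cysteine peptidase",
    G = "glutamic peptidase",
    M = "metallopeptidase",
    S = "serine peptidase",
    T = "threonine peptidase",
    N = "asparagine lyase",
    P = "mixed catalytic type",
    U = "unknown catalytic type",
    I = "protein inhibitor")
}

#' Identifier kinds
#'
#' The possible classifications of a parsed identifier.
#' @return Character vector of kind names.
#' @export
identifier_kinds <- function() {
  c("clan", "family", "holotype_peptidase", "non_peptidase_homologue",
    "pseudogene", "model_organism_unassigned")
}

merops_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "merops_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

parse_error <- function(text, rule) {
  merops_error(
    sprintf("cannot parse identifier '%s': %s", text, rule),
    "merops_parse_error"
  )
}

unknown_type_error <- function(text, letter) {
  merops_error(
    sprintf("identifier '%s': '%s' is not a catalytic-type letter (one of %s)",
            text, letter, paste(names(catalytic_types()), collapse = "")),
    "merops_unknown_type_error"
  )
}

new_merops_id <- function(kind, type_code, family = NA_character_,
                          subfamily = NA_character_, suffix = NA_character_,
                          number = NA_integer_, text) {
  structure(
    list(kind = kind, type_code = type_code, family = family,
         subfamily = subfamily, suffix = suffix, number = number,
         text = text),
    class = "merops_id"
  )
}

#' Parse a clan, family or holotype identifier
#'
#' Identifiers come in three shapes. A clan identifier is two letters, the
#' first a catalytic-type letter (e.g. \code{"AA"}). A family identifier is a
#' catalytic-type letter followed by a family number, optionally with a
#' subfamily letter (e.g. \code{"A1"}, \code{"S8A"}). A holotype identifier is
#' the family part zero-padded to three characters, a dot, and a
#' three-character suffix (e.g. cathepsin D is \code{"A01.009"}). A suffix
#' beginning with the digit 9 marks a non-peptidase homologue
#' (\code{"A01.971"}); a leading \code{P} marks a pseudogene
#' (\code{"A01.P01"}); a leading \code{A}, \code{B} or \code{C} marks an
#' unassigned peptidase from a model-organism proteome (\code{"M10.A01"}).
#'
#' Lower-case input is accepted and canonicalised; subfamily letters are
#' accepted in holotype form but normalised out (\code{"S08A.071"} parses to
#' \code{"S08.071"}).
#'
#' @param text A single identifier string.
#' @return A \code{merops_id} object with fields \code{kind},
#'   \code{type_code}, \code{family}, \code{subfamily}, \code{suffix},
#'   \code{number} and canonical \code{text}.
#' @export
#' @examples
#' parse_identifier("A01.009")$kind     # holotype_peptidase
#' parse_identifier("A01.971")$kind     # non_peptidase_homologue
#' parse_identifier("A01.P01")$kind     # pseudogene
#' parse_identifier("AA")$kind          # clan
parse_identifier <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    parse_error(paste(text, collapse = ","),
                "identifier must be a single string")
  raw <- text
  text <- toupper(trimws(text))
  if (!nzchar(text)) parse_error(raw, "identifier is empty")
  letters10 <- names(catalytic_types())

  # clan: exactly two letters
  if (grepl("^[A-Z]{2}$", text)) {
    first <- substr(text, 1L, 1L)
    if (!first %in% letters10) unknown_type_error(text, first)
    return(new_merops_id("clan", first, text = text))
  }

  # family: letter + 1-2 digits + optional subfamily letter
  m <- regmatches(text, regexec("^([A-Z])([0-9]{1,2})([A-Z]?)$", text))[[1]]
  if (length(m)) {
    if (!m[2] %in% letters10) unknown_type_error(text, m[2])
    fam <- paste0(m[2], as.integer(m[3]))
    sub <- if (nzchar(m[4])) m[4] else NA_character_
    return(new_merops_id("family", m[2], family = fam, subfamily = sub,
                         text = paste0(fam, if (!is.na(sub)) sub else "")))
  }

  # holotype form: family part, dot, suffix
  m <- regmatches(text, regexec(
    "^([A-Z])([0-9]{1,2})([A-Z]?)\\.([A-Z]?)([0-9]+)$", text))[[1]]
  if (!length(m)) {
    if (grepl("\\.", text) && !grepl("^[A-Z]", text))
      parse_error(raw, "holotype identifiers start with a catalytic-type letter")
    parse_error(raw, paste("expected a two-letter clan, a family",
                           "(letter + number), or a holotype (family.suffix)"))
  }
  if (!m[2] %in% letters10) unknown_type_error(text, m[2])
  fam_num <- as.integer(m[3])
  suffix_letter <- m[5]
  digits <- m[6]
  if (nzchar(suffix_letter)) {
    if (!suffix_letter %in% c("P", "A", "B", "C"))
      parse_error(raw, sprintf(
        "suffix letter '%s' is not one of P (pseudogene) or A/B/C (model organism)",
        suffix_letter))
    if (nchar(digits) > 2L)
      parse_error(raw, "suffix number has more than two digits after a letter")
  } else if (nchar(digits) > 3L) {
    parse_error(raw, "suffix number has more than three digits")
  }
  number <- as.integer(digits)
  suffix <- if (nzchar(suffix_letter)) {
    sprintf("%s%02d", suffix_letter, number)
  } else {
    sprintf("%03d", number)
  }
  kind <- suffix_kind(suffix)
  fam <- sprintf("%s%02d", m[2], fam_num)
  sub <- if (nzchar(m[4])) m[4] else NA_character_
  new_merops_id(kind, m[2], family = fam, subfamily = sub, suffix = suffix,
                number = number, text = paste0(fam, ".", suffix))
}

suffix_kind <- function(suffix) {
  first <- substr(suffix, 1L, 1L)
  if (first == "9") "non_peptidase_homologue"
  else if (first == "P") "pseudogene"
  else if (first %in% c("A", "B", "C")) "model_organism_unassigned"
  else "holotype_peptidase"
}

#' Classify an identifier
#'
#' Returns the kind of an identifier: \code{clan}, \code{family},
#' \code{holotype_peptidase}, \code{non_peptidase_homologue} (suffix starts
#' with 9), \code{pseudogene} (suffix starts with P) or
#' \code{model_organism_unassigned} (suffix starts with A, B or C).
#'
#' @param id A \code{merops_id} or an identifier string.
#' @return A single kind string; see [identifier_kinds()].
#' @export
#' @examples
#' classify_identifier("S08.071")   # holotype_peptidase
#' classify_identifier("M10.A01")   # model_organism_unassigned
classify_identifier <- function(id) {
  id <- as_merops_id(id)
  id$kind
}

#' Format an identifier in canonical form
#'
#' Holotype identifiers have the family number zero-padded to two digits and
#' the suffix padded to three characters (a letter counts as one of them), so
#' family \code{"A1"} holotype number 9 prints as \code{"A01.009"}.
#'
#' @param id A \code{merops_id} or an identifier string.
#' @return Canonical identifier text.
#' @export
#' @examples
#' format_identifier(parse_identifier("a1.9"))   # "A01.009"
format_identifier <- function(id) {
  id <- as_merops_id(id)
  id$text
}

#' Coerce to a merops_id
#'
#' @param x A \code{merops_id} (returned unchanged) or identifier string.
#' @return A \code{merops_id}.
#' @export
as_merops_id <- function(x) {
  if (inherits(x, "merops_id")) x else parse_identifier(x)
}

#' @export
format.merops_id <- function(x, ...) x$text

#' @export
print.merops_id <- function(x, ...) {
  label <- if (x$type_code %in% names(catalytic_types()))
    catalytic_types()[[x$type_code]] else "?"
  cat(sprintf("<merops_id> %s  [%s; %s]\n", x$text, x$kind, label))
  invisible(x)
}

#' @export
as.character.merops_id <- function(x, ...) x$text
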