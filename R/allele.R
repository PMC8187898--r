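#' Recognised HLA loci
#'
#' The four classical loci handled by this package: class I \code{A},
#' \code{B}, \code{C} and class II \code{DRB1}.
#'
#' @export
HLA_LOCI <- c("A", "B", "C", "DRB1")

#' Construct an HLA allele at two-field resolution
#'
#' An allele is identified by its locus and two numeric fields: the allele
#' group (e.g. \code{"04"}) and the specific protein (e.g. \code{"06"}).
#' Higher-resolution fields (synonymous / intronic variants) are outside the
#' unit of analysis and are not stored.
#'
#' @param locus One of \code{"A"}, \code{"B"}, \code{"C"}, \code{"DRB1"}.
#' @param field1 Allele-group field, a string of 2-4 digits.
#' @param field2 Protein field, a string of 2-4 digits.
#' @return An object of class \code{hla_allele}.
#' @seealso [parse_allele()]
#' @examples
#' hla_allele("DRB1", "04", "06")
#' @export
hla_allele <- function(locus, field1, field2) {
  locus <- as.character(locus)
  if (length(locus) != 1L || !locus %in% HLA_LOCI) {
    stop("unknown HLA locus: ", deparse(locus), call. = FALSE)
  }
  for (f in list(field1, field2)) {
    if (length(f) != 1L || !grepl("^[0-9]{2,4}$", f)) {
      stop("allele field must be a 2-4 digit string, got ", deparse(f),
           call. = FALSE)
    }
  }
  structure(
    list(locus = locus, field1 = as.character(field1),
         field2 = as.character(field2)),
    class = "hla_allele"
  )
}

#' Parse an HLA allele name
#'
#' Accepts the fully qualified form \code{"HLA-DRB1*04:06"}, the short form
#' \code{"DRB1*04:06"}, and the bare two-field form \code{"04:06"} when
#' \code{locus} is supplied. Names carrying more than two fields
#' (e.g. \code{"04:06:01"}) are truncated to two-field resolution with a
#' warning. Malformed names (missing colon, unknown locus, non-numeric
#' fields) raise an error naming the offending token.
#'
#' @param text A single allele name.
#' @param locus Optional locus. Required for bare \code{"04:06"} input; if
#'   given together with a locus-qualified name the two must agree.
#' @return An [hla_allele()] object.
#' @examples
#' parse_allele("HLA-DRB1*04:06")
#' parse_allele("A*24:02")
#' parse_allele("24:02", locus = "A")
#' @export
parse_allele <- function(text, locus = NULL) {
  if (inherits(text, "hla_allele")) return(text)
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop("allele name must be a single non-empty string", call. = FALSE)
  }
  raw <- trimws(text)
  body <- sub("^HLA-", "", raw)
  if (grepl("\\*", body)) {
    parts <- strsplit(body, "*", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      stop("malformed allele name ", sQuote(raw), call. = FALSE)
    }
    loc <- parts[1L]
    if (!loc %in% HLA_LOCI) {
      stop("unknown HLA locus ", sQuote(loc), " in ", sQuote(raw),
           call. = FALSE)
    }
    if (!is.null(locus) && !identical(as.character(locus), loc)) {
      stop("allele ", sQuote(raw), " does not match requested locus ",
           sQuote(locus), call. = FALSE)
    }
    fields_str <- parts[2L]
  } else {
    if (is.null(locus)) {
      stop("bare allele name ", sQuote(raw),
           " requires an explicit locus", call. = FALSE)
    }
    loc <- as.character(locus)
    if (!loc %in% HLA_LOCI) {
      stop("unknown HLA locus ", sQuote(loc), call. = FALSE)
    }
    fields_str <- body
  }
  if (!grepl(":", fields_str, fixed = TRUE)) {
    stop("malformed allele name ", sQuote(raw),
         ": expected colon-separated two-field resolution", call. = FALSE)
  }
  fields <- strsplit(fields_str, ":", fixed = TRUE)[[1L]]
  if (length(fields) > 2L) {
    warning("truncating ", sQuote(raw), " to two-field resolution",
            call. = FALSE)
    fields <- fields[1:2]
  }
  if (length(fields) != 2L || !all(grepl("^[0-9]{2,4}$", fields))) {
    stop("malformed allele fields in ", sQuote(raw), call. = FALSE)
  }
  hla_allele(loc, fields[1L], fields[2L])
}

#' @export
format.hla_allele <- function(x, ...) {
  sprintf("HLA-%s*%s:%s", x$locus, x$field1, x$field2)
}

#' @export
print.hla_allele <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.hla_allele <- function(x, ...) format(x)

#' Locus of an allele
#' @param allele An [hla_allele()] or allele name.
#' @return Locus string.
#' @export
allele_locus <- function(allele) parse_allele(allele)$locus

# internal: canonical string, accepting hla_allele or character
canonical_allele <- function(allele, locus = NULL) {
  format(parse_allele(allele, locus = locus))
}
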