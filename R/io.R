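# Parsing and serialization: plain text, JSON, PDB CRYST1.

#' Parse a unit cell from text or JSON
#'
#' Accepts whitespace- or comma-separated `"a b c alpha beta gamma"`, a JSON
#' array of six numbers, or a JSON object with fields `a, b, c, alpha, beta,
#' gamma`.  Lines starting with `CRYST1` are delegated to [parse_cryst1()].
#'
#' @param text a single character string.
#' @return A [unit_cell()].
#' @export
#' @examples
#' parse_cell("5.1 6.2 7.3 77 88 99")
#' parse_cell('{"a":5.1,"b":6.2,"c":7.3,"alpha":77,"beta":88,"gamma":99}')
parse_cell <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (startsWith(text, "CRYST1")) return(parse_cryst1(text))
  if (startsWith(text, "{") || startsWith(text, "[")) {
    x <- jsonlite::fromJSON(text)
    if (is.list(x)) {
      need <- c("a", "b", "c", "alpha", "beta", "gamma")
      if (!all(need %in% names(x))) {
        stop("JSON cell object must have fields a, b, c, alpha, beta, gamma",
             call. = FALSE)
      }
      return(unit_cell(as.numeric(x[need])))
    }
    return(unit_cell(as.numeric(x)))
  }
  vals <- suppressWarnings(as.numeric(strsplit(text, "[,[:space:]]+")[[1]]))
  if (length(vals) != 6L || any(is.na(vals))) {
    stop("cell text must contain exactly six numbers: a b c alpha beta gamma",
         call. = FALSE)
  }
  unit_cell(vals)
}

#' Parse a PDB CRYST1 record
#'
#' Fixed-column read of the unit-cell parameters: a in columns 7-15, b in
#' 16-24, c in 25-33 (Angstrom), alpha in 34-40, beta in 41-47, gamma in
#' 48-54 (degrees).  Trailing space-group and Z fields are ignored.
#'
#' @param line a single character string beginning `"CRYST1"`.
#' @return A [unit_cell()].
#' @export
#' @examples
#' parse_cryst1(
#'   "CRYST1   61.300   61.300  171.300  90.00  90.00  90.00 P 43 21 2     8")
parse_cryst1 <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  if (!startsWith(line, "CRYST1")) {
    stop("not a CRYST1 record: line must start with 'CRYST1'", call. = FALSE)
  }
  if (nchar(line) < 54L) {
    stop("truncated CRYST1 record: need at least 54 columns, got ",
         nchar(line), call. = FALSE)
  }
  spans <- list(a = c(7, 15), b = c(16, 24), c = c(25, 33),
                alpha = c(34, 40), beta = c(41, 47), gamma = c(48, 54))
  vals <- vapply(names(spans), function(f) {
    sp <- spans[[f]]
    v <- suppressWarnings(as.numeric(substr(line, sp[1], sp[2])))
    if (is.na(v)) {
      stop(sprintf("malformed CRYST1 field '%s' in columns %d-%d",
                   f, sp[1], sp[2]), call. = FALSE)
    }
    v
  }, numeric(1))
  unit_cell(vals)
}

#' Parse a 3x3 matrix from text or JSON
#'
#' Accepts nine numbers row-major (whitespace/comma/newline separated) or a
#' JSON nested array `[[...],[...],[...]]`.
#'
#' @param text a single character string.
#' @return A plain 3x3 numeric matrix.
#' @export
#' @examples
#' parse_matrix3("0 1 1  1 0 1  1 1 0")
#' parse_matrix3("[[1,0,0],[0,1,0],[1,1,2]]")
parse_matrix3 <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (startsWith(text, "[")) {
    x <- jsonlite::fromJSON(text)
    m <- if (is.matrix(x)) x else do.call(rbind, x)
    return(as_matrix3(m, "matrix"))
  }
  vals <- suppressWarnings(as.numeric(strsplit(text, "[,[:space:]]+")[[1]]))
  if (length(vals) != 9L || any(is.na(vals))) {
    stop("matrix text must contain exactly nine numbers, row-major",
         call. = FALSE)
  }
  as_matrix3(vals, "matrix")
}

#' Parse an S6 vector from text or JSON
#'
#' @param text six numbers, `"s1 s2 s3 s4 s5 s6"` or a JSON array, in the
#'   order `[b.c, a.c, a.b, a.d, b.d, c.d]`.
#' @return An [s6_vector()].
#' @export
parse_s6 <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (startsWith(text, "[")) return(s6_vector(jsonlite::fromJSON(text)))
  vals <- suppressWarnings(as.numeric(strsplit(text, "[,[:space:]]+")[[1]]))
  if (length(vals) != 6L || any(is.na(vals))) {
    stop("S6 text must contain exactly six numbers", call. = FALSE)
  }
  s6_vector(vals)
}
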