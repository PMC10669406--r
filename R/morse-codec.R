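#' International Morse code table
#'
#' Builds the character/element-sequence bijection used by the encoder and
#' decoder. Elements are the characters `"."` (dot, short opening) and `"-"`
#' (dash, long opening). The default table covers the letters `a`--`z`
#' (sequences of 1--4 elements) and the digits `0`--`9` (5 elements each),
#' i.e. the ITU standard. A custom table can be loaded from a plain-text
#' file with one `character sequence` pair per line (e.g. `a .-`).
#'
#' @param path Optional path to a plain-text code-table file. `NULL` gives
#'   the built-in ITU table.
#' @return An object of class `code_table` with components
#'   `char_to_elements` (named list of element vectors) and
#'   `elements_to_char` (named character vector keyed by the dot/dash
#'   string).
#' @export
#' @examples
#' tab <- morse_table()
#' tab$char_to_elements[["o"]]  # "-" "-" "-"
morse_table <- function(path = NULL) {
  if (is.null(path)) {
    codes <- .itu_codes
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "[[:space:]]+")
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad)) {
      stop("malformed code-table line(s): ", paste(lines[bad], collapse = "; "))
    }
    codes <- vapply(parts, `[[`, "", 2L)
    names(codes) <- tolower(vapply(parts, `[[`, "", 1L))
  }
  if (!all(grepl("^[.-]+$", codes))) {
    stop("code sequences must consist of '.' and '-' only")
  }
  if (anyDuplicated(names(codes)) || anyDuplicated(codes)) {
    stop("code table must be a bijection: duplicate character or sequence")
  }
  tab <- list(
    char_to_elements = lapply(strsplit(codes, ""), identity),
    elements_to_char = stats::setNames(names(codes), codes)
  )
  names(tab$char_to_elements) <- names(codes)
  class(tab) <- "code_table"
  tab
}

.itu_codes <- c(
  a = ".-",    b = "-...",  c = "-.-.",  d = "-..",   e = ".",
  f = "..-.",  g = "--.",   h = "....",  i = "..",    j = ".---",
  k = "-.-",   l = ".-..",  m = "--",    n = "-.",    o = "---",
  p = ".--.",  q = "--.-",  r = ".-.",   s = "...",   t = "-",
  u = "..-",   v = "...-",  w = ".--",   x = "-..-",  y = "-.--",
  z = "--..",
  `0` = "-----", `1` = ".----", `2` = "..---", `3` = "...--",
  `4` = "....-", `5` = ".....", `6` = "-....", `7` = "--...",
  `8` = "---..", `9` = "----."
)

#' Write a code table to a plain-text file
#'
#' @param table A `code_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_code_table <- function(table, path) {
  stopifnot(inherits(table, "code_table"))
  seqs <- vapply(table$char_to_elements, paste, "", collapse = "")
  writeLines(paste(names(seqs), seqs), path)
  invisible(path)
}

#' Encode text as Morse element sequences
#'
#' Encoding is case-insensitive; whitespace separates characters and is
#' dropped (no word-gap handling).
#'
#' @param text Character scalar to encode.
#' @param table A `code_table` (default: ITU).
#' @return A list with one element vector (of `"."`/`"-"`) per
#'   non-whitespace character, named by the character.
#' @export
#' @examples
#' encode_text("sos")
encode_text <- function(text, table = morse_table()) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(tolower(text), "")[[1]]
  chars <- chars[!grepl("[[:space:]]", chars)]
  unknown <- setdiff(unique(chars), names(table$char_to_elements))
  if (length(unknown) > 0L) {
    stop("unsupported character(s) for Morse encoding: ",
         paste(sQuote(unknown), collapse = ", "))
  }
  out <- table$char_to_elements[chars]
  names(out) <- chars
  out
}

#' Decode one Morse element sequence to a character
#'
#' @param elements Vector of `"."`/`"-"` elements.
#' @param table A `code_table`.
#' @return The decoded single character (lowercase).
#' @export
#' @examples
#' decode_elements(c("-", "-", "-"))  # "o"
decode_elements <- function(elements, table = morse_table()) {
  if (length(elements) == 0L) stop("cannot decode an empty element sequence")
  if (!all(elements %in% c(".", "-"))) {
    stop("elements must be '.' or '-'")
  }
  key <- paste(elements, collapse = "")
  ch <- table$elements_to_char[key]
  if (is.na(ch)) {
    stop("unknown Morse code sequence: ", sQuote(key))
  }
  unname(ch)
}
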