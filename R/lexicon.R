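#' Additive lexicon for E400--E499 emulsifiers, thickeners and stabilizers
#'
#' The lexicon maps each main-class additive code (E400--E499) to the
#' plaintext names, Norwegian/English spellings and common misspellings under
#' which it appears in ingredient lists, and carries a compiled regular
#' expression per additive. Matching is case-insensitive; the E-number form
#' allows an optional single space or hyphen between the "E" and the digits
#' (`E407`, `E 407`, `E-407`) and an optional subclass letter (`E472a`).
#' Word-boundary guards prevent false hits inside longer tokens such as
#' `E4070`.
#'
#' Subclass tokens (E472a--f, E470a/b, E407a, E479b) are not distinguished:
#' they are matched by, and reported as, their main class.
#'
#' @section Lump groups:
#' Additives with near-identical technological roles are merged before
#' enrichment testing: E40x = E400--E404 (alginates), E42x = E420--E422
#' (sugar alcohols), E45x = E450--E452 (phosphates), E47x = E470--E477
#' (fatty-acid derivatives). Pectin (E440) is kept separate. See [lump_ets()].
#'
#' @name lexicon
NULL

lump_ranges <- list(
  E40x = sprintf("E4%02d", 0:4),
  E42x = sprintf("E4%02d", 20:22),
  E45x = sprintf("E4%02d", 50:52),
  E47x = sprintf("E4%02d", 70:77)
)

regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

split_pipe <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(x, "|", fixed = TRUE), function(s) s[nzchar(s)])
}

# One compiled PCRE per additive: alternation of literal synonyms, an optional
# hand-written regex fragment (the carrageenan pattern style), and the
# E-number form with optional space/hyphen and subclass letter. The
# (?<![a-z0-9]) / (?![a-z0-9]) guards are case-insensitive boundaries.
build_pattern <- function(code, literals, pattern_extra, subclasses) {
  digits <- sub("^E", "", code)
  sub_cls <- if (nzchar(subclasses)) {
    sprintf("[%s]?", subclasses)
  } else {
    ""
  }
  enum <- sprintf("e[ -]?%s%s", digits, sub_cls)
  parts <- c(regex_escape(literals), enum)
  if (nzchar(pattern_extra)) parts <- c(pattern_extra, parts)
  sprintf("(?i)(?<![a-z0-9])(?:%s)(?![a-z0-9])", paste(parts, collapse = "|"))
}

#' Compile an additive definition table into a lexicon
#'
#' @param definitions A data frame with columns `code`, `name`, `synonyms`
#'   (pipe-separated), `misspellings` (pipe-separated, may be empty),
#'   `pattern_extra` (optional regex fragment), `subclasses` (subclass
#'   letters, e.g. `"abcdef"` for E472), `lump_group` (`"E40x"`, `"E42x"`,
#'   `"E45x"`, `"E47x"` or `"self"`) and `fate` (`"non_absorbed"` or
#'   `"absorbed"`, the additive's suggested fate in the human gut).
#' @param validate If `TRUE` (default), check that every synonym and
#'   misspelling is matched by its own entry and by no other entry, so that
#'   rendering any stored spelling round-trips through [detect_ets()].
#'
#' @return An object of class `ets_lexicon`: a list with `entries` (a tibble,
#'   one row per additive, with the compiled `pattern` column) and
#'   `subclass_map` (named character vector mapping subclass tokens such as
#'   `"E472a"` to their main class).
#' @examples
#' lex <- compile_lexicon(ets_definitions())
#' detect_ets("water, karagenan, sugar, E 407", lex)
#' @export
compile_lexicon <- function(definitions, validate = TRUE) {
  definitions <- tibble::as_tibble(definitions)
  needed <- c("code", "name", "synonyms", "misspellings", "pattern_extra",
              "subclasses", "lump_group", "fate")
  missing_cols <- setdiff(needed, names(definitions))
  if (length(missing_cols) > 0) {
    stop("definition table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(definitions) == 0) {
    return(structure(
      list(entries = definitions[0, ], subclass_map = character(0)),
      class = "ets_lexicon"
    ))
  }
  bad <- definitions$code[!grepl("^E4[0-9]{2}$", definitions$code)]
  if (length(bad) > 0) {
    stop("invalid additive code(s): ", paste(bad, collapse = ", "))
  }
  dup <- unique(definitions$code[duplicated(definitions$code)])
  if (length(dup) > 0) {
    stop("duplicate additive code(s): ", paste(dup, collapse = ", "))
  }

  for (col in c("synonyms", "misspellings", "pattern_extra", "subclasses")) {
    definitions[[col]][is.na(definitions[[col]])] <- ""
  }
  syn <- split_pipe(definitions$synonyms)
  mis <- split_pipe(definitions$misspellings)
  entries <- definitions |>
    dplyr::mutate(
      synonyms = syn,
      misspellings = mis,
      pattern = purrr::pmap_chr(
        list(.data$code, purrr::map2(.data$name, purrr::map2(syn, mis, c), c),
             .data$pattern_extra, .data$subclasses),
        function(code, lits, extra, sub) build_pattern(code, unlist(lits), extra, sub)
      )
    )

  subclass_map <- unlist(purrr::map2(entries$code, entries$subclasses, function(code, sub) {
    if (!nzchar(sub)) return(character(0))
    letters_i <- strsplit(sub, "")[[1]]
    stats::setNames(rep(code, length(letters_i)), paste0(code, letters_i))
  }))
  if (is.null(subclass_map)) subclass_map <- character(0)

  lex <- structure(
    list(entries = entries, subclass_map = subclass_map),
    class = "ets_lexicon"
  )
  if (validate) validate_lexicon(lex)
  lex
}

# every stored spelling must be matched by its own entry and only its own
validate_lexicon <- function(lex) {
  e <- lex$entries
  for (i in seq_len(nrow(e))) {
    spellings <- c(e$name[i], e$synonyms[[i]], e$misspellings[[i]])
    hits <- vapply(e$pattern, function(p) any(grepl(p, spellings, perl = TRUE)),
                   logical(1))
    if (!hits[i]) {
      stop("entry ", e$code[i], " does not match its own spellings")
    }
    other <- e$code[hits & e$code != e$code[i]]
    if (length(other) > 0) {
      stop("spellings of ", e$code[i], " also matched by: ",
           paste(other, collapse = ", "))
    }
  }
  invisible(lex)
}

#' Built-in additive definition table and default lexicon
#'
#' `ets_definitions()` returns the curated definition table shipped with the
#' package: the 59 main-class E400--E499 additives authorized in the EU, each
#' with plaintext names (English and Norwegian), common misspellings, its
#' lump group and its suggested gastrointestinal fate (non-absorbed additives
#' reach the colon largely intact). `ets_lexicon()` compiles it (cached).
#'
#' @param path Path to a tab-separated definition table; defaults to the
#'   table shipped with the package. Supplying a different file overrides
#'   the lexicon throughout the pipeline.
#' @return `ets_definitions()`: a tibble; `ets_lexicon()`: an `ets_lexicon`.
#' @export
ets_definitions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ets_lexicon.tsv", package = "etscan")
  }
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = character())
}

the_lexicon <- new.env(parent = emptyenv())

#' @rdname ets_definitions
#' @export
ets_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(the_lexicon$default)) {
      the_lexicon$default <- compile_lexicon(ets_definitions(), validate = FALSE)
    }
    return(the_lexicon$default)
  }
  compile_lexicon(ets_definitions(path))
}

#' @export
print.ets_lexicon <- function(x, ...) {
  cat("<ets_lexicon> ", nrow(x$entries), " additives (",
      paste(range(x$entries$code), collapse = "-"), "), ",
      length(x$subclass_map), " subclass tokens\n", sep = "")
  invisible(x)
}

#' Detect additives in a free-text ingredient list
#'
#' Scans one or more ingredient texts for every additive in the lexicon,
#' matching E-number forms, plaintext names and misspellings. An additive
#' listed several times in the same product (for instance in two
#' sub-ingredient lists) is counted once, and subclass tokens (E472a, E472b,
#' ...) are reported as their main class.
#'
#' @param ingredient_text Character vector of ingredient lists; `NA` is
#'   treated as empty text.
#' @param lexicon An [ets_lexicon()].
#' @return A list (one element per text) of sorted character vectors of
#'   main-class codes; unmatched text yields `character(0)`.
#' @examples
#' detect_ets("emulsifier E472a, stabiliser E472b, guar gum")
#' @export
detect_ets <- function(ingredient_text, lexicon = ets_lexicon()) {
  stopifnot(inherits(lexicon, "ets_lexicon"))
  txt <- as.character(ingredient_text)
  txt[is.na(txt)] <- ""
  txt <- tolower(txt)
  codes <- lexicon$entries$code
  if (length(codes) == 0 || length(txt) == 0) {
    return(rep(list(character(0)), length(txt)))
  }
  hit <- vapply(lexicon$entries$pattern,
                function(p) grepl(p, txt, perl = TRUE),
                logical(length(txt)))
  hit <- matrix(hit, nrow = length(txt))
  lapply(seq_along(txt), function(i) sort(codes[hit[i, ]]))
}

#' Merge near-identical additives into lump groups
#'
#' Projects main-class codes onto the lump groups used for enrichment
#' testing: E400--E404 become `E40x`, E420--E422 `E42x`, E450--E452 `E45x`
#' and E470--E477 `E47x`; every other code (including pectin, E440) maps to
#' itself. The mapping is idempotent: lump-group labels pass through
#' unchanged.
#'
#' @param code Character vector of main-class codes (or lump labels).
#' @return Character vector of lumped codes, same length as `code`.
#' @examples
#' lump_ets(c("E451", "E440", "E499"))
#' @export
lump_ets <- function(code) {
  code <- as.character(code)
  out <- code
  lump_labels <- names(lump_ranges)
  valid <- grepl("^E4[0-9]{2}$", code) | code %in% lump_labels
  if (any(!valid)) {
    stop("not a main-class E400-E499 code: ",
         paste(unique(code[!valid]), collapse = ", "))
  }
  for (lab in lump_labels) {
    out[code %in% lump_ranges[[lab]]] <- lab
  }
  out
}
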