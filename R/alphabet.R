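# IUPAC nucleotide alphabet used throughout: 4 determinate bases, 10
# ambiguity codes (2-, 3- and 4-fold) and 'n' for no-call positions.

IUPAC_MAP <- list(
  a = "a", c = "c", g = "g", t = "t",
  m = c("a", "c"), r = c("a", "g"), w = c("a", "t"),
  s = c("c", "g"), y = c("c", "t"), k = c("g", "t"),
  v = c("a", "c", "g"), h = c("a", "c", "t"),
  d = c("a", "g", "t"), b = c("c", "g", "t"),
  n = c("a", "c", "g", "t")
)

#' The 15-letter IUPAC nucleotide alphabet
#'
#' Lowercase symbols accepted everywhere in mitolac: the four determinate
#' bases, the ten ambiguity codes used to encode heteroplasmic calls, and
#' `n` for no-call positions.
#'
#' @return A character vector of 15 single-letter symbols.
#' @export
#' @examples
#' iupac_alphabet()
iupac_alphabet <- function() names(IUPAC_MAP)

#' Expand an IUPAC symbol into its determinate base set
#'
#' A determinate base maps to itself; an ambiguity code maps to the set of
#' bases it denotes (`m` means `a` or `c`; `v` means `a`, `c` or `g`); the
#' no-call symbol `n` maps to all four bases.
#'
#' @param code A single IUPAC symbol (case-insensitive).
#' @return Character vector of determinate bases the symbol can stand for.
#' @export
#' @examples
#' expand_symbol("m")
#' expand_symbol("v")
expand_symbol <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, nchar(code) == 1L)
  code <- tolower(code)
  bases <- IUPAC_MAP[[code]]
  if (is.null(bases)) {
    stop("'", code, "' is not an IUPAC nucleotide symbol; expected one of: ",
         paste(iupac_alphabet(), collapse = ""), call. = FALSE)
  }
  bases
}

# Multiplicity of each symbol (how many determinate bases it expands to).
iupac_multiplicity <- function() vapply(IUPAC_MAP, length, integer(1))

# Validate a residue string; returns lowercased residues or errors naming
# the first offending symbols and their 1-based positions.
validate_residues <- function(residues, id = "sequence") {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- tolower(residues)
  if (nchar(residues) < 1L) {
    stop("sequence '", id, "' is empty", call. = FALSE)
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% iupac_alphabet())
  if (length(bad)) {
    show <- utils::head(bad, 5L)
    stop("sequence '", id, "' contains non-IUPAC symbol(s): ",
         paste0("'", chars[show], "' at position ", show, collapse = ", "),
         call. = FALSE)
  }
  residues
}
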