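#' Standard genetic code with synonymous family structure
#'
#' Wraps the standard nuclear genetic code (from
#' [Biostrings::GENETIC_CODE]) into an object that records, for every
#' codon, its amino acid, and for every amino acid, its synonymous codon
#' family.  All codon-usage indices in this package are defined with
#' respect to such an object, so alternative codes (e.g. mitochondrial)
#' can be substituted by building one from another 64-entry codon table.
#'
#' @param codon_to_aa named character vector of length 64 mapping codons
#'   (DNA alphabet, e.g. `"ATG"`) to one-letter amino-acid symbols, with
#'   `"*"` for stop.  Defaults to the standard code.
#' @return An object of class `genetic_code`: a list with elements
#'   `codon_to_aa` (named character, 64 codons), `families` (named list,
#'   amino acid -> sorted codon vector), `sense_codons` (61 codons for
#'   the standard code), `stop_codons`, and `multi_family_codons`
#'   (sense codons whose amino acid has two or more synonyms).
#' @examples
#' gc <- standard_genetic_code()
#' gc$families[["K"]]   # lysine: AAA, AAG
#' @export
standard_genetic_code <- function(codon_to_aa = NULL) {
  if (is.null(codon_to_aa)) {
    codon_to_aa <- Biostrings::GENETIC_CODE
  }
  codon_to_aa <- toupper(gsub("U", "T", codon_to_aa))
  names(codon_to_aa) <- toupper(gsub("U", "T", names(codon_to_aa)))
  if (length(codon_to_aa) != 64L || anyDuplicated(names(codon_to_aa)))
    stop("genetic code must map exactly 64 distinct codons")
  codon_to_aa <- codon_to_aa[order(names(codon_to_aa))]
  sense <- names(codon_to_aa)[codon_to_aa != "*"]
  stops <- names(codon_to_aa)[codon_to_aa == "*"]
  fam <- split(sense, codon_to_aa[sense])
  fam <- lapply(fam, sort)
  multi <- unlist(fam[vapply(fam, length, 1L) >= 2L], use.names = FALSE)
  structure(
    list(codon_to_aa = codon_to_aa,
         families = fam,
         sense_codons = sense,
         stop_codons = stops,
         multi_family_codons = sort(multi)),
    class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> ", length(x$sense_codons), " sense codons, ",
      length(x$families), " amino acids, ",
      length(x$stop_codons), " stop codons\n", sep = "")
  invisible(x)
}

# Split a CDS string into codons, applying the package's tolerance policy:
# a trailing partial codon is trimmed with a warning (strict = TRUE raises).
# Returns a character vector of trinucleotides (possibly containing N).
split_codons <- function(seq, strict = FALSE) {
  seq <- toupper(gsub("U", "T", seq))
  if (!grepl("^[ACGTN]*$", seq))
    stop("sequence contains characters outside ACGT/N/U")
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    if (strict) stop("sequence length ", n, " is not divisible by 3")
    warning("trimming ", n %% 3L, " nt trailing partial codon")
    seq <- substr(seq, 1L, n - n %% 3L)
    n <- nchar(seq)
  }
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# Translate codons to amino acids under a genetic_code; codons with N -> NA.
translate_codons <- function(codons, code) {
  aa <- unname(code$codon_to_aa[codons])
  aa
}

#' Translate a CDS nucleotide sequence
#'
#' @param seq CDS string (ACGT/N; U accepted).
#' @param code a [standard_genetic_code()] object.
#' @param strict error on a length not divisible by 3 instead of trimming.
#' @return single amino-acid string (`*` for stop, `X` for codons with N).
#' @export
translate_cds <- function(seq, code = standard_genetic_code(), strict = FALSE) {
  codons <- split_codons(seq, strict = strict)
  aa <- translate_codons(codons, code)
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

rev_comp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""), ""))
}
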