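#' Codon usage frequency table
#'
#' Container for per-codon usage frequencies (raw counts, per-thousand, or
#' family fractions — the unit is recorded, and every index in this package
#' only ever uses frequencies *relative* to the synonymous family, so the
#' unit does not affect results).
#'
#' @param codon_freq named numeric vector: codon -> frequency (>= 0).
#'   Codons may use U or T; all 61 sense codons of `code` must be present.
#' @param source_label free-text provenance label.
#' @param unit unit of the frequencies (recorded only).
#' @param code a [standard_genetic_code()] object.
#' @return object of class `codon_usage_table` with elements `codon_freq`
#'   (named over the 61 sense codons, sorted), `source_label`, `unit`.
#' @export
codon_usage_table <- function(codon_freq, source_label = "unspecified",
                              unit = "arbitrary",
                              code = standard_genetic_code()) {
  names(codon_freq) <- toupper(gsub("U", "T", names(codon_freq)))
  codon_freq <- codon_freq[names(codon_freq) %in% code$sense_codons]
  missing <- setdiff(code$sense_codons, names(codon_freq))
  if (length(missing))
    stop("usage table lacks sense codons: ", paste(missing, collapse = ", "))
  if (any(!is.finite(codon_freq)) || any(codon_freq < 0))
    stop("codon frequencies must be finite and >= 0")
  codon_freq <- codon_freq[sort(code$sense_codons)]
  for (aa in names(code$families)) {
    if (all(codon_freq[code$families[[aa]]] == 0))
      stop("family ", aa, " has all-zero frequencies")
  }
  structure(list(codon_freq = codon_freq, source_label = source_label,
                 unit = unit),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("<codon_usage_table> ", length(x$codon_freq), " sense codons; unit=",
      x$unit, "; source=", x$source_label, "\n", sep = "")
  invisible(x)
}

#' Read a codon usage table from disk
#'
#' Two dialects are accepted.  A columnar (Kazusa-style) file: tab- or
#' whitespace-separated with a header naming at least `codon` plus one of
#' `count`, `per_thousand`, `fraction` (extra columns such as `amino_acid`
#' are ignored); the first available of count > per_thousand > fraction is
#' used.  Or the minimal two-column dialect: `codon<TAB>frequency` with or
#' without a header.
#'
#' @param path file path.
#' @param code genetic code object.
#' @return a [codon_usage_table()].
#' @export
read_usage_table <- function(path, code = standard_genetic_code()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  nm <- tolower(names(df))
  freq_col <- intersect(c("count", "per_thousand", "fraction", "frequency",
                          "freq"), nm)
  if ("codon" %in% nm && length(freq_col)) {
    codons <- toupper(df[[which(nm == "codon")[1]]])
    freq <- as.numeric(df[[which(nm == freq_col[1])[1]]])
    unit <- freq_col[1]
  } else {
    # headerless two-column fallback
    df <- utils::read.table(path, header = FALSE, sep = "",
                            stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(df) < 2) stop("cannot parse usage table: ", path)
    codons <- toupper(df[[1]])
    freq <- as.numeric(df[[2]])
    unit <- "unknown"
  }
  if (anyDuplicated(toupper(gsub("U", "T", codons))))
    stop("duplicate codon in usage table: ", path)
  codon_usage_table(stats::setNames(freq, codons),
                    source_label = basename(path), unit = unit, code = code)
}

#' Write a codon usage table as TSV
#'
#' Columnar dialect with `codon`, `amino_acid`, and the table's unit as the
#' frequency column name; round-trips through [read_usage_table()].
#'
#' @param table a [codon_usage_table()].
#' @param path output path.
#' @param code genetic code object.
#' @return `path`, invisibly.
#' @export
write_usage_table <- function(table, path, code = standard_genetic_code()) {
  unit <- if (table$unit %in% c("count", "per_thousand", "fraction"))
    table$unit else "frequency"
  df <- data.frame(codon = names(table$codon_freq),
                   amino_acid = unname(code$codon_to_aa[names(table$codon_freq)]),
                   freq = unname(table$codon_freq))
  names(df)[3] <- unit
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
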