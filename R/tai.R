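#' tRNA adaptation index parameters
#'
#' Holds tRNA gene copy numbers (tGCN) per anticodon and the wobble-pairing
#' penalty constants (s-values) used to weight non-Watson-Crick decoding
#' routes.  Defaults are the canonical published penalties; species-specific
#' re-optimization of s-values (as done by stAIcalc-style tools) is out of
#' scope — supply custom values instead.
#'
#' @param anticodon_counts named integer vector: anticodon (DNA or RNA
#'   alphabet, 5'->3') -> tRNA gene copy number (>= 0).  Anticodons absent
#'   from the vector are treated as count 0.
#' @param s_values named numeric vector of wobble penalties in \[0, 1\];
#'   see [default_s_values()].
#' @param bacterial if `TRUE`, the lysidine-modified CAU anticodon also
#'   decodes the isoleucine AUA codon with penalty `s["L-A:I"]`.
#' @return object of class `tai_params`.
#' @export
tai_params <- function(anticodon_counts, s_values = default_s_values(),
                       bacterial = FALSE) {
  names(anticodon_counts) <- toupper(gsub("U", "T", names(anticodon_counts)))
  if (!length(anticodon_counts) || all(anticodon_counts == 0))
    stop("at least one anticodon must have a positive copy number")
  if (any(anticodon_counts < 0) || any(!is.finite(anticodon_counts)))
    stop("anticodon counts must be finite and >= 0")
  if (anyDuplicated(names(anticodon_counts)))
    stop("duplicate anticodon")
  s <- default_s_values()
  s[names(s_values)] <- s_values
  if (any(s < 0 | s > 1)) stop("s-values must lie in [0, 1]")
  structure(list(anticodon_counts = anticodon_counts, s_values = s,
                 bacterial = isTRUE(bacterial)),
            class = "tai_params")
}

#' Canonical wobble-pairing penalties
#'
#' Selective constraints `s` for each wobble decoding route (0 = as good as
#' Watson-Crick, 1 = route unusable): anticodon G reading codon U (0.41),
#' inosine reading C (0.28), inosine reading A (0.9999), anticodon U reading
#' G (0.68), and lysidine-modified C reading the isoleucine A codon (0.89,
#' bacteria only).
#'
#' @return named numeric vector.
#' @export
default_s_values <- function() {
  c("G:U" = 0.41, "I:C" = 0.28, "I:A" = 0.9999, "U:G" = 0.68,
    "L-A:I" = 0.89)
}

#' Read a tRNA gene copy-number table
#'
#' TSV with columns `anticodon` and `count` (header required; extra columns
#' ignored).
#'
#' @param path file path.
#' @inheritParams tai_params
#' @return a [tai_params()] object.
#' @export
read_trna_table <- function(path, s_values = default_s_values(),
                            bacterial = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  nm <- tolower(names(df))
  if (!all(c("anticodon", "count") %in% nm))
    stop("tRNA table needs 'anticodon' and 'count' columns: ", path)
  tai_params(stats::setNames(as.numeric(df[[which(nm == "count")[1]]]),
                             toupper(df[[which(nm == "anticodon")[1]]])),
             s_values = s_values, bacterial = bacterial)
}

# Decoding routes for one codon under standard wobble rules: the
# Watson-Crick anticodon plus one wobble anticodon determined by the codon's
# third base.  Inosine is encoded genomically as A.
codon_decoding_routes <- function(codon, s) {
  wc <- rev_comp(codon)
  third <- substr(codon, 3L, 3L)
  wob_first <- switch(third, "T" = "G", "C" = "A", "A" = "A", "G" = "T")
  s_wob <- switch(third, "T" = s[["G:U"]], "C" = s[["I:C"]],
                  "A" = s[["I:A"]], "G" = s[["U:G"]])
  wob <- paste0(wob_first, substr(wc, 2L, 3L))
  data.frame(anticodon = c(wc, wob), s = c(0, s_wob),
             stringsAsFactors = FALSE)
}

#' Compute per-codon tAI weights from tRNA copy numbers
#'
#' For every sense codon the raw weight is the sum over recognizing
#' anticodons of `(1 - s) * tGCN`: the Watson-Crick anticodon (s = 0) plus
#' the standard wobble route for the codon's third base.  AUG is decoded by
#' its Watson-Crick anticodon only.  Weights are scaled by the maximum;
#' codons with zero raw weight receive the geometric mean of the nonzero
#' scaled weights.
#'
#' @param params a [tai_params()] object.
#' @param code genetic code object.
#' @return named numeric vector over sense codons, values in (0, 1].
#' @export
compute_tai_weights <- function(params, code = standard_genetic_code()) {
  stopifnot(inherits(params, "tai_params"))
  counts <- params$anticodon_counts
  s <- params$s_values
  getc <- function(ac) if (ac %in% names(counts)) counts[[ac]] else 0
  w <- vapply(code$sense_codons, function(codon) {
    if (codon == "ATG") {
      # initiator/elongator Met: Watson-Crick CAT only, no wobble route
      return(getc("CAT"))
    }
    routes <- codon_decoding_routes(codon, s)
    raw <- sum((1 - routes$s) * vapply(routes$anticodon, getc, 0))
    if (codon == "ATA" && params$bacterial)
      raw <- raw + (1 - s[["L-A:I"]]) * getc("CAT")
    raw
  }, 0)
  if (all(w == 0)) stop("all tAI weights are zero; check anticodon counts")
  W <- w / max(w)
  nz <- W > 0
  if (any(!nz)) W[!nz] <- exp(mean(log(W[nz])))
  W
}

#' Gene-level tRNA adaptation index
#'
#' Geometric mean of the tAI weight over all sense codons of the CDS (stop
#' codon and codons containing N excluded).
#'
#' @param seq CDS nucleotide sequence.
#' @param weights per-codon weights from [compute_tai_weights()].
#' @param code genetic code object.
#' @param strict error on a length not divisible by 3 instead of trimming.
#' @return tAI in (0, 1].
#' @export
compute_gene_tai <- function(seq, weights, code = standard_genetic_code(),
                             strict = FALSE) {
  codons <- split_codons(seq, strict = strict)
  codons <- codons[codons %in% code$sense_codons]
  if (!length(codons))
    stop("undefined index: no sense codons in sequence")
  if (anyNA(weights[codons]))
    stop("missing tAI weight for codon(s): ",
         paste(unique(codons[is.na(weights[codons])]), collapse = ", "))
  exp(mean(log(weights[codons])))
}
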