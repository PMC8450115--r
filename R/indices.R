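#' Codon adaptation index (CAI)
#'
#' Geometric mean of each codon's relative adaptiveness
#' `w_c = f(c) / max(f over the synonymous family)`, taken over the sense
#' codons of amino acids with two or more synonyms.  Methionine and
#' tryptophan (single-codon families), stop codons, and codons containing N
#' are excluded.  Zero-frequency codons get `w = 0.01` so the geometric
#' mean stays defined (the classic implementation's convention).
#'
#' @param seq CDS nucleotide sequence (ACGT/N; U accepted).
#' @param table a [codon_usage_table()].
#' @param code genetic code object.
#' @param strict error on a length not divisible by 3 instead of trimming.
#' @return CAI in (0, 1].
#' @export
compute_cai <- function(seq, table, code = standard_genetic_code(),
                        strict = FALSE) {
  stopifnot(inherits(table, "codon_usage_table"))
  codons <- split_codons(seq, strict = strict)
  known <- codons[!grepl("N", codons)]
  if (!all(known %in% names(code$codon_to_aa)))
    stop("unknown codon(s): ",
         paste(unique(setdiff(known, names(code$codon_to_aa))), collapse = ", "))
  eligible <- known[known %in% code$multi_family_codons]
  if (!length(eligible))
    stop("undefined index: no codons from multi-codon families")
  w <- relative_adaptiveness(table, code)
  exp(mean(log(w[eligible])))
}

# w_c = f(c)/max over family, floored at 0.01 for zero-frequency codons.
relative_adaptiveness <- function(table, code) {
  f <- table$codon_freq
  w <- f
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    w[fam] <- f[fam] / max(f[fam])
  }
  pmax(w, 0.01)
}

#' Codon bias index (CBI)
#'
#' Bennetzen-Hall statistic `(N_opt - N_ran) / (N_tot - N_ran)` where
#' `N_opt` counts codons in `optimal_set`, `N_tot` counts codons of
#' multi-codon families, and `N_ran` is the count expected if synonyms were
#' chosen uniformly at random: `sum over aa of n_aa * k_opt,aa / k_syn,aa`.
#' 1 means exclusively optimal codons; 0 means random expectation; negative
#' values mean optimal codons are avoided.
#'
#' @param seq CDS nucleotide sequence.
#' @param optimal_set character vector of optimal codons, at least one per
#'   multi-codon family (see [derive_optimal_set()]).
#' @param code genetic code object.
#' @param strict error on a length not divisible by 3 instead of trimming.
#' @return CBI in (-1, 1].
#' @export
compute_cbi <- function(seq, optimal_set, code = standard_genetic_code(),
                        strict = FALSE) {
  optimal_set <- toupper(gsub("U", "T", optimal_set))
  check_optimal_set(optimal_set, code)
  codons <- split_codons(seq, strict = strict)
  codons <- codons[codons %in% code$multi_family_codons]
  if (!length(codons))
    stop("undefined index: no codons from multi-codon families")
  n_tot <- length(codons)
  n_opt <- sum(codons %in% optimal_set)
  aa <- translate_codons(codons, code)
  n_ran <- 0
  for (a in unique(aa)) {
    fam <- code$families[[a]]
    n_ran <- n_ran + sum(aa == a) * sum(fam %in% optimal_set) / length(fam)
  }
  if (abs(n_tot - n_ran) < .Machine$double.eps * n_tot)
    stop("undefined index: N_tot equals random expectation N_ran")
  (n_opt - n_ran) / (n_tot - n_ran)
}

check_optimal_set <- function(optimal_set, code) {
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    if (length(fam) >= 2L && !any(fam %in% optimal_set))
      stop("optimal_set lacks a codon for family ", aa)
  }
  invisible(TRUE)
}

#' Derive the optimal-codon set from a usage table
#'
#' One codon per multi-codon family: the highest-frequency synonym, ties
#' broken by lexicographic codon order.  Deterministic by construction.
#'
#' @param table a [codon_usage_table()].
#' @param code genetic code object.
#' @return character vector of codons, one per multi-codon family, sorted.
#' @export
derive_optimal_set <- function(table, code = standard_genetic_code()) {
  stopifnot(inherits(table, "codon_usage_table"))
  f <- table$codon_freq
  out <- character(0)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]         # already sorted lexicographically
    if (length(fam) < 2L) next
    if (all(f[fam] == 0))
      stop("configuration error: family ", aa, " has all-zero frequencies")
    out <- c(out, fam[which.max(f[fam])])  # which.max takes first tie
  }
  sort(out)
}

#' Synonymous codon optimization of a CDS
#'
#' Replaces every sense codon by its family's optimal codon (single-codon
#' families are necessarily unchanged); a terminal stop codon is kept as
#' is.  The encoded protein is unchanged and the operation is idempotent.
#'
#' @param seq CDS nucleotide sequence; length must be a multiple of 3.
#' @param optimal_set one optimal codon per multi-codon family.
#' @param code genetic code object.
#' @param internal_stop `"error"` (default) or `"warn"` on a non-terminal
#'   stop codon.
#' @return optimized CDS string.
#' @export
optimize_sequence <- function(seq, optimal_set,
                              code = standard_genetic_code(),
                              internal_stop = c("error", "warn")) {
  internal_stop <- match.arg(internal_stop)
  optimal_set <- toupper(gsub("U", "T", optimal_set))
  check_optimal_set(optimal_set, code)
  codons <- split_codons(seq, strict = TRUE)
  aa <- translate_codons(codons, code)
  stops <- which(!is.na(aa) & aa == "*")
  if (length(stops) && any(stops != length(codons))) {
    msg <- paste("internal stop codon at codon position",
                 paste(stops[stops != length(codons)], collapse = ", "))
    if (internal_stop == "error") stop(msg) else warning(msg)
  }
  # family -> optimal codon lookup
  best <- stats::setNames(character(length(code$families)), names(code$families))
  for (a in names(code$families)) {
    fam <- code$families[[a]]
    best[a] <- if (length(fam) == 1L) fam else intersect(fam, optimal_set)[1]
  }
  out <- codons
  sense <- !is.na(aa) & aa != "*" & !grepl("N", codons)
  out[sense] <- best[aa[sense]]
  paste(out, collapse = "")
}

#' Per-gene codon-usage index table
#'
#' Computes CAI, CBI and gene tAI for every CDS in a named sequence set,
#' the one-stop entry point behind the `indices` workflow.
#'
#' @param seqs named character vector of CDS sequences (e.g. from
#'   [read_fasta()]).
#' @param table a [codon_usage_table()]; also used to derive the
#'   optimal-codon set unless `optimal_set` is given.
#' @param params a [tai_params()] object, or `NULL` to skip tAI.
#' @param optimal_set override the derived optimal-codon set.
#' @param code genetic code object.
#' @return data.frame with columns `gene_id`, `length_aa`, `cai`, `cbi`,
#'   `tai` (NA where an index is undefined; such genes are flagged in the
#'   `flag` column).
#' @export
codon_index_table <- function(seqs, table, params = NULL, optimal_set = NULL,
                              code = standard_genetic_code()) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("seqs must be uniquely named")
  if (is.null(optimal_set)) optimal_set <- derive_optimal_set(table, code)
  weights <- if (!is.null(params)) compute_tai_weights(params, code) else NULL
  one <- function(id) {
    s <- seqs[[id]]
    codons <- suppressWarnings(split_codons(s))
    aa <- translate_codons(codons, code)
    len <- sum(!is.na(aa) & aa != "*")
    idx <- function(f) tryCatch(f, error = function(e) NA_real_)
    cai <- idx(suppressWarnings(compute_cai(s, table, code)))
    cbi <- idx(suppressWarnings(compute_cbi(s, optimal_set, code)))
    tai <- if (is.null(weights)) NA_real_ else
      idx(suppressWarnings(compute_gene_tai(s, weights, code)))
    data.frame(gene_id = id, length_aa = len, cai = cai, cbi = cbi,
               tai = tai,
               flag = if (anyNA(c(cai, cbi))) "undefined-index" else "",
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(names(seqs), one))
  rownames(out) <- NULL
  out
}
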