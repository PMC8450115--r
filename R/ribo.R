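#' Default A-site offsets
#'
#' Community-standard +15 nt offset from the read 5' end for footprint
#' lengths 27-31 nt.  Reads whose length has no offset entry are discarded
#' (and counted) during A-site assignment.
#'
#' @param lengths read lengths to retain.
#' @param offset nt offset applied to each.
#' @return named numeric vector: read length -> offset.
#' @export
default_a_site_offsets <- function(lengths = 27:31, offset = 15) {
  stats::setNames(rep(offset, length(lengths)), lengths)
}

#' Assign footprints to A-site codons
#'
#' For each aligned footprint the A-site codon index is
#' `floor((five_prime_pos + offset(read_length)) / 3)` (0-based
#' coordinates).  Reads with an unknown gene, a read length without an
#' offset entry, or an A-site outside `[0, n_codons)` are dropped and
#' counted per category.
#'
#' @param footprints data.frame with columns `gene_id`, `five_prime_pos`
#'   (0-based nt within the CDS), `read_length` (nt), e.g. from
#'   [read_footprints()].
#' @param n_codons named integer vector: gene -> CDS length in codons
#'   (nt length / 3, stop codon included).
#' @param offsets named vector read length -> nt offset; see
#'   [default_a_site_offsets()].
#' @return object of class `occupancy_profiles`: list with `profiles`
#'   (named list of per-codon integer count vectors), `n_codons`, and
#'   `dropped` (named counts: `unknown_gene`, `bad_length`,
#'   `out_of_range`), plus `n_assigned`.
#' @export
assign_a_sites <- function(footprints, n_codons,
                           offsets = default_a_site_offsets()) {
  req <- c("gene_id", "five_prime_pos", "read_length")
  if (!all(req %in% names(footprints)))
    stop("footprints must have columns: ", paste(req, collapse = ", "))
  gene <- as.character(footprints$gene_id)
  known <- gene %in% names(n_codons)
  n_unknown <- sum(!known)
  if (n_unknown) message(n_unknown, " footprints reference unknown genes; skipped")
  off <- offsets[as.character(footprints$read_length)]
  has_off <- !is.na(off)
  n_badlen <- sum(has_off[known] == FALSE)
  keep <- known & has_off
  codon <- (footprints$five_prime_pos[keep] + off[keep]) %/% 3
  g <- gene[keep]
  in_range <- codon >= 0 & codon < n_codons[g]
  n_oor <- sum(!in_range)
  codon <- codon[in_range]
  g <- g[in_range]
  profiles <- lapply(stats::setNames(names(n_codons), names(n_codons)),
                     function(id) integer(n_codons[[id]]))
  if (length(g)) {
    sp <- split(codon, g)
    for (id in names(sp))
      profiles[[id]] <- tabulate(sp[[id]] + 1L, nbins = n_codons[[id]])
  }
  if (all(vapply(profiles, sum, 0) == 0))
    warning("empty profiles: every footprint was dropped or input was empty")
  structure(list(profiles = profiles, n_codons = n_codons,
                 dropped = c(unknown_gene = n_unknown, bad_length = n_badlen,
                             out_of_range = n_oor),
                 n_assigned = length(g)),
            class = "occupancy_profiles")
}

#' @export
print.occupancy_profiles <- function(x, ...) {
  cat("<occupancy_profiles> ", length(x$profiles), " genes, ",
      x$n_assigned, " assigned footprints, ", sum(x$dropped), " dropped\n",
      sep = "")
  invisible(x)
}

#' Pool occupancy profiles across replicates
#'
#' Element-wise sum of per-codon counts over replicate profile sets
#' covering the same genes (the merged-replicate convention used before
#' decoding-time estimation).
#'
#' @param profile_list list of `occupancy_profiles` objects.
#' @return a single `occupancy_profiles` object.
#' @export
pool_profiles <- function(profile_list) {
  stopifnot(length(profile_list) >= 1)
  base <- profile_list[[1]]
  for (p in profile_list[-1]) {
    if (!identical(names(p$profiles), names(base$profiles)))
      stop("profiles cover different gene sets")
    base$profiles <- Map(`+`, base$profiles, p$profiles)
    base$dropped <- base$dropped + p$dropped
    base$n_assigned <- base$n_assigned + p$n_assigned
  }
  base
}

#' Transcripts per kilobase million (TPM)
#'
#' `rate_g = count_g / (length_g / 1000)`; `TPM_g = 1e6 * rate_g / sum(rates)`.
#'
#' @param counts named numeric vector of read counts (>= 0).
#' @param lengths_nt named numeric vector of feature lengths in nt (> 0),
#'   covering every gene in `counts`.
#' @return named numeric vector summing to 1e6.
#' @export
compute_tpm <- function(counts, lengths_nt) {
  if (!all(names(counts) %in% names(lengths_nt)))
    stop("missing lengths for some genes")
  lengths_nt <- lengths_nt[names(counts)]
  if (any(lengths_nt <= 0)) stop("lengths must be > 0")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (all(counts == 0)) stop("undefined: all counts are zero")
  rate <- counts / (lengths_nt / 1000)
  1e6 * rate / sum(rate)
}

#' Ribosome density per gene
#'
#' Density is RPF TPM divided by mRNA TPM; genes whose mRNA TPM falls
#' below `min_mrna_tpm` get `NA` density and are excluded from downstream
#' statistics.
#'
#' @param rpf_tpm,mrna_tpm named numeric vectors over the same gene
#'   universe (order may differ).
#' @param min_mrna_tpm mRNA TPM floor below which density is undefined.
#' @return data.frame with columns `gene_id`, `rpf_tpm`, `mrna_tpm`,
#'   `density`.
#' @export
compute_ribosome_density <- function(rpf_tpm, mrna_tpm, min_mrna_tpm = 1) {
  genes <- intersect(names(rpf_tpm), names(mrna_tpm))
  if (!length(genes)) stop("disjoint gene sets")
  r <- rpf_tpm[genes]
  m <- mrna_tpm[genes]
  density <- ifelse(m >= min_mrna_tpm, r / m, NA_real_)
  data.frame(gene_id = genes, rpf_tpm = unname(r), mrna_tpm = unname(m),
             density = unname(density), stringsAsFactors = FALSE)
}

as_codon_list <- function(cds_seqs) {
  if (is.character(cds_seqs)) {
    lapply(cds_seqs, function(s) suppressWarnings(split_codons(s)))
  } else cds_seqs
}

#' Relative codon decoding time (RCDT)
#'
#' For each gene passing the coverage filter, per-codon counts at
#' non-trimmed positions are divided by their mean, giving relative
#' occupancies `r_i` with per-gene mean exactly 1.  The RCDT of codon `c`
#' is the mean of `r_i` over all non-trimmed positions carrying `c`,
#' pooled across retained genes (`aggregate = "pooled"`, default) or
#' averaged per gene first (`"gene_mean"`).  Stop codons and codons with N
#' never contribute.  A high RCDT means ribosomes dwell longer on that
#' codon relative to the gene average.
#'
#' @param profiles an `occupancy_profiles` object (see [assign_a_sites()]).
#' @param cds_seqs named character vector of CDS sequences, or a named
#'   list of codon vectors, consistent in length with the profiles.
#' @param filter list with `min_mean` (minimum mean reads per non-trimmed
#'   codon) and `min_total` (minimum total reads in the non-trimmed
#'   window) a gene must reach to be retained.
#' @param trim integer vector `c(head, tail)`: codons excluded at the CDS
#'   start and end (initiation/termination ramp).
#' @param aggregate `"pooled"` or `"gene_mean"`.
#' @param condition_label free-text label stored in the result.
#' @param stratum label for the CDS-length stratum this table covers.
#' @param min_occurrences codons observed at fewer non-trimmed positions
#'   than this are omitted (with a warning).
#' @return object of class `rcdt_table`: list with `condition_label`,
#'   `stratum`, `rcdt` (named numeric over observed sense codons),
#'   `n_occurrences`, `n_genes_used`, `coverage_filter`, `aggregate`.
#' @export
compute_rcdt <- function(profiles, cds_seqs,
                         filter = list(min_mean = 0.5, min_total = 64),
                         trim = c(head = 15, tail = 5),
                         aggregate = c("pooled", "gene_mean"),
                         condition_label = "unlabelled", stratum = "all",
                         min_occurrences = 1L,
                         code = standard_genetic_code()) {
  aggregate <- match.arg(aggregate)
  codon_list <- as_codon_list(cds_seqs)
  genes <- intersect(names(profiles$profiles), names(codon_list))
  sense <- code$sense_codons
  sums <- stats::setNames(numeric(length(sense)), sense)
  occs <- stats::setNames(integer(length(sense)), sense)
  gm_sums <- sums; gm_n <- occs
  n_used <- 0L
  head_trim <- trim[[1]]; tail_trim <- trim[[2]]
  for (id in genes) {
    counts <- profiles$profiles[[id]]
    codons <- codon_list[[id]]
    n <- length(counts)
    if (length(codons) != n)
      stop("profile/sequence length mismatch for gene ", id)
    lo <- head_trim + 1L
    hi <- n - tail_trim
    if (hi - lo + 1L < 3L) next
    win <- lo:hi
    total <- sum(counts[win])
    mu <- total / length(win)
    if (mu < filter$min_mean || total < filter$min_total) next
    n_used <- n_used + 1L
    r <- counts[win] / mu
    cw <- codons[win]
    ok <- cw %in% sense
    agg <- rowsum(r[ok], cw[ok])
    cods <- rownames(agg)
    cnt <- tabulate(factor(cw[ok], levels = cods), nbins = length(cods))
    sums[cods] <- sums[cods] + agg[, 1]
    occs[cods] <- occs[cods] + cnt
    if (aggregate == "gene_mean") {
      gm_sums[cods] <- gm_sums[cods] + agg[, 1] / cnt
      gm_n[cods] <- gm_n[cods] + 1L
    }
  }
  if (n_used == 0L) stop("no gene passes the coverage filter")
  seen <- occs >= min_occurrences & occs > 0L
  if (any(occs > 0 & !seen) || any(occs == 0))
    warning("codons omitted (unobserved or below min_occurrences): ",
            paste(sense[!seen], collapse = ", "))
  rcdt <- if (aggregate == "pooled") sums[seen] / occs[seen]
          else gm_sums[seen] / gm_n[seen]
  structure(list(condition_label = condition_label, stratum = stratum,
                 rcdt = rcdt, n_occurrences = occs[seen],
                 n_genes_used = n_used, coverage_filter = filter,
                 aggregate = aggregate, trim = trim),
            class = "rcdt_table")
}

#' @export
print.rcdt_table <- function(x, ...) {
  cat("<rcdt_table> condition=", x$condition_label, " stratum=", x$stratum,
      " codons=", length(x$rcdt), " genes=", x$n_genes_used, "\n", sep = "")
  invisible(x)
}

#' RCDT stratified by CDS length
#'
#' Applies [compute_rcdt()] independently to the genes of each CDS-length
#' stratum.  Bounds are exclusive, matching the "> L" / "< L" convention:
#' a gene belongs to stratum `c(lo, hi)` when `lo < length_aa < hi`.
#'
#' @inheritParams compute_rcdt
#' @param strata named list of `c(lo, hi)` bounds in amino acids, e.g.
#'   `list(long = c(600, Inf), short = c(0, 300))`.
#' @param ... passed on to [compute_rcdt()].
#' @return named list of `rcdt_table` objects; empty strata are dropped
#'   with a warning.
#' @export
compute_rcdt_stratified <- function(profiles, cds_seqs,
                                    strata = list(long = c(600, Inf),
                                                  short = c(0, 300)),
                                    ..., code = standard_genetic_code()) {
  codon_list <- as_codon_list(cds_seqs)
  len_aa <- vapply(codon_list, function(cod)
    sum(cod %in% code$sense_codons), 0L)
  out <- list()
  for (nm in names(strata)) {
    b <- strata[[nm]]
    keep <- names(len_aa)[len_aa > b[1] & len_aa < b[2]]
    keep <- intersect(keep, names(profiles$profiles))
    if (!length(keep)) {
      warning("stratum ", nm, " (", b[1], ", ", b[2], ") aa is empty; omitted")
      next
    }
    sub <- profiles
    sub$profiles <- profiles$profiles[keep]
    tab <- tryCatch(
      compute_rcdt(sub, codon_list[keep], ..., stratum = nm, code = code),
      error = function(e) {
        warning("stratum ", nm, ": ", conditionMessage(e)); NULL
      })
    if (!is.null(tab)) out[[nm]] <- tab
  }
  out
}

#' Per-codon RCDT difference between two tables
#'
#' @param a,b `rcdt_table` objects (e.g. mutant and wild type, or long and
#'   short CDS strata).
#' @return named numeric vector of `a - b` over the shared codon set.
#' @export
delta_rcdt <- function(a, b) {
  stopifnot(inherits(a, "rcdt_table"), inherits(b, "rcdt_table"))
  shared <- intersect(names(a$rcdt), names(b$rcdt))
  if (!length(shared)) stop("tables share no codons")
  a$rcdt[shared] - b$rcdt[shared]
}

#' Total assigned reads per gene
#'
#' @param profiles an `occupancy_profiles` object.
#' @return named numeric vector of per-gene footprint totals.
#' @export
profile_totals <- function(profiles) {
  vapply(profiles$profiles, sum, 0)
}
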