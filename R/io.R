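#' Read a multi-record FASTA of CDS sequences
#'
#' @param path FASTA file (wrapped lines fine).
#' @return named character vector; names are the first
#'   whitespace-delimited header token; sequences upper-cased.  Duplicate
#'   ids are an error; an empty file yields an empty vector with a
#'   warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id: ", paste(unique(dup), collapse = ", "))
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read footprint alignments
#'
#' Two dialects.  `tsv`: a header-validated three-column table
#' (`gene_id`, `five_prime_pos`, `read_length`) in transcript/CDS
#' coordinates (0-based 5' end).  `sam`: a SAM/BAM file whose reference
#' names are gene ids; unmapped, secondary and supplementary records are
#' skipped and counted; the 1-based POS is converted to a 0-based 5'
#' offset and the read length is taken from the query width.
#'
#' @param path input file.
#' @param dialect `"auto"` (by extension), `"tsv"`, or `"sam"`.
#' @return data.frame `gene_id`, `five_prime_pos`, `read_length`, with a
#'   `skipped` attribute counting discarded SAM records.
#' @export
read_footprints <- function(path, dialect = c("auto", "tsv", "sam")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) "sam"
               else "tsv"
  }
  if (dialect == "tsv") {
    df <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    req <- c("gene_id", "five_prime_pos", "read_length")
    if (!all(req %in% names(df)))
      stop("footprint TSV must have header columns: ",
           paste(req, collapse = ", "), " (got: ",
           paste(names(df), collapse = ", "), ")")
    bad <- which(!is.finite(df$five_prime_pos) | df$five_prime_pos < 0 |
                   !is.finite(df$read_length) | df$read_length <= 0)
    if (length(bad))
      stop("corrupt footprint record at data line ", bad[1], " of ", path)
    out <- df[req]
    out$gene_id <- as.character(out$gene_id)
    attr(out, "skipped") <- 0L
    return(out)
  }
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path
         else Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
  all_rec <- Rsamtools::countBam(bam)$records
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(flag = flags,
                                         what = c("rname", "pos", "qwidth")))[[1]]
  out <- data.frame(gene_id = as.character(res$rname),
                    five_prime_pos = res$pos - 1L,
                    read_length = res$qwidth, stringsAsFactors = FALSE)
  attr(out, "skipped") <- all_rec - nrow(out)
  out
}

#' Write footprints in the TSV dialect
#'
#' @param footprints data.frame `gene_id`, `five_prime_pos`, `read_length`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_footprints <- function(footprints, path) {
  data.table::fwrite(footprints[c("gene_id", "five_prime_pos",
                                  "read_length")],
                     path, sep = "\t")
  invisible(path)
}

# TSV writer shared by all tabular outputs: UTF-8, tab-separated, "NA" for
# missing, newline-terminated final line, no locale-dependent formatting.
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert an RCDT table to a data.frame
#'
#' @param tab an `rcdt_table`.
#' @param code genetic code object.
#' @return data.frame `codon`, `amino_acid`, `rcdt`, `n_occurrences`.
#' @export
rcdt_as_data_frame <- function(tab, code = standard_genetic_code()) {
  stopifnot(inherits(tab, "rcdt_table"))
  data.frame(codon = names(tab$rcdt),
             amino_acid = unname(code$codon_to_aa[names(tab$rcdt)]),
             rcdt = unname(tab$rcdt),
             n_occurrences = unname(tab$n_occurrences[names(tab$rcdt)]),
             stringsAsFactors = FALSE)
}

#' Write a simulated study to a run directory
#'
#' Materializes the output of [simulate_two_condition_study()] as plain
#' files: `cds.fasta`, `usage_table.tsv`, `trna_table.tsv`,
#' `proteome.tsv`, `truth.tsv`, `dwell.tsv`,
#' `footprints/<condition>/<replicate>.tsv`,
#' `mrna/<condition>/<replicate>.tsv`, and the resolved `config.json`.
#' This layout is what [run_pipeline()] consumes.
#'
#' @param study result of [simulate_two_condition_study()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- study$transcriptome
  write_fasta(sim$sequences, file.path(dir, "cds.fasta"))
  write_usage_table(sim$usage_table, file.path(dir, "usage_table.tsv"))
  tp <- synthetic_tai_params(sim$usage_table)
  write_tsv_table(data.frame(anticodon = names(tp$anticodon_counts),
                             count = unname(tp$anticodon_counts)),
                  file.path(dir, "trna_table.tsv"))
  write_tsv_table(study$proteome[c("gene_id", "length_aa", "abundance")],
                  file.path(dir, "proteome.tsv"))
  write_tsv_table(sim$truth, file.path(dir, "truth.tsv"))
  write_tsv_table(data.frame(codon = names(sim$dwell),
                             dwell = unname(sim$dwell)),
                  file.path(dir, "dwell.tsv"))
  for (cond in names(study$libraries)) {
    fdir <- file.path(dir, "footprints", cond)
    mdir <- file.path(dir, "mrna", cond)
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    for (rep in names(study$libraries[[cond]])) {
      lib <- study$libraries[[cond]][[rep]]
      write_footprints(lib$footprints, file.path(fdir, paste0(rep, ".tsv")))
      write_tsv_table(data.frame(gene_id = names(lib$mrna_counts),
                                 count = unname(lib$mrna_counts)),
                      file.path(mdir, paste0(rep, ".tsv")))
    }
  }
  cfg <- study$config
  echo <- cfg[c("n_genes", "length_meanlog", "length_sdlog", "length_range",
                "bias_shape1", "bias_shape2", "abundance", "conditions",
                "long_dwell", "depth", "mrna_depth", "read_lengths",
                "n_replicates", "seed")]
  echo$offsets <- as.list(cfg$offsets)
  jsonlite::write_json(echo, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
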