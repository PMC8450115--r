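#' Analysis run configuration
#'
#' All thresholds the pipeline applies live here, with the field's
#' conventional defaults: fold-change cut 2 with FDR 0.05 for the
#' differential calls, CBI cuts 0.3/0.15 for gene grouping, CDS-length
#' strata >600 and <300 aa for stratified decoding times, 500-gene
#' scanning windows.  Unknown keys are rejected.
#'
#' @param run_dir directory laid out as by [write_simulation()] (CDS
#'   FASTA, usage/tRNA tables, footprint and mRNA TSVs per
#'   condition/replicate, optional proteome table).
#' @param out_dir output directory for tables and the manifest.
#' @param offsets A-site offset table.
#' @param min_mrna_tpm mRNA TPM floor for defined ribosome density.
#' @param coverage RCDT coverage filter (`min_mean`, `min_total`).
#' @param trim RCDT head/tail codon trim.
#' @param window,step scanning-window size and step (genes).
#' @param fc_threshold,alpha differential-call cuts.
#' @param cbi_high,cbi_low,group_size gene-grouping parameters.
#' @param strata CDS-length strata (aa, exclusive bounds).
#' @param cond_a,cond_b condition labels for differential comparisons
#'   (fold change is b/a, mutant over reference).
#' @param seed integer seed for any stochastic stage.
#' @param sim a [sim_config()] for the `simulate` workflow, or `NULL`.
#' @return object of class `run_config`.
#' @export
run_config <- function(run_dir = NULL, out_dir = NULL,
                       offsets = default_a_site_offsets(),
                       min_mrna_tpm = 1,
                       coverage = list(min_mean = 0.5, min_total = 64),
                       trim = c(head = 15, tail = 5),
                       window = 500L, step = 1L,
                       fc_threshold = 2, alpha = 0.05,
                       cbi_high = 0.3, cbi_low = 0.15, group_size = 1000L,
                       strata = list(long = c(600, Inf), short = c(0, 300)),
                       cond_a = "baseline", cond_b = "fast",
                       seed = 1L, sim = NULL) {
  cfg <- structure(as.list(environment()), class = "run_config")
  if (cfg$fc_threshold <= 1) stop("fc_threshold must be > 1")
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("alpha must lie in (0, 1]")
  if (cfg$window < 3) stop("window must be >= 3")
  cfg
}

#' Apply overrides to a run_config, rejecting unknown keys
#'
#' @param cfg a [run_config()].
#' @param overrides named list of replacement values.
#' @return the updated config.
#' @export
update_run_config <- function(cfg, overrides) {
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  cfg
}

run_dir_layout <- function(run_dir) {
  fps <- list()
  mrs <- list()
  fdir <- file.path(run_dir, "footprints")
  if (dir.exists(fdir)) {
    for (cond in sort(list.dirs(fdir, recursive = FALSE, full.names = FALSE))) {
      fps[[cond]] <- sort(list.files(file.path(fdir, cond),
                                     full.names = TRUE))
      mdir <- file.path(run_dir, "mrna", cond)
      mrs[[cond]] <- if (dir.exists(mdir))
        sort(list.files(mdir, full.names = TRUE)) else character(0)
    }
  }
  list(fasta = file.path(run_dir, "cds.fasta"),
       usage = file.path(run_dir, "usage_table.tsv"),
       trna = file.path(run_dir, "trna_table.tsv"),
       proteome = file.path(run_dir, "proteome.tsv"),
       footprints = fps, mrna = mrs)
}

pipeline_log <- function(...) message("[codonflux] ", ...)

#' Run an analysis workflow end to end
#'
#' Composes the package's stages over a run directory.  Workflows:
#' `indices` (per-gene CAI/CBI/tAI), `density` (per-replicate TPM and
#' ribosome density), `rcdt` (pooled-replicate decoding times per
#' condition plus CDS-length strata), `diffdensity` (differential
#' ribosome density, b vs a), `windows` (scanning-window length-abundance
#' correlation along the tAI ranking, plus fold-change proportion and
#' mean-length curves when both conditions are present), `groups`
#' (CBI x length gene groups), `simulate` (generate a run directory from
#' `config$sim`), `full` (everything).  Each produced table is recorded
#' in a manifest with its checksum; stage failures abort with a
#' stage-labelled error.
#'
#' @param config a [run_config()].
#' @param workflow workflow name.
#' @return list with `manifest` (data.frame `file`, `md5`), `outputs`
#'   (named list of in-memory results), invisibly written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config,
                         workflow = c("full", "indices", "density", "rcdt",
                                      "diffdensity", "windows", "groups",
                                      "simulate")) {
  workflow <- match.arg(workflow)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("configuration error: out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  produced <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv_table(df, path)
    produced <<- c(produced, path)
    path
  }
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", label, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if (workflow == "simulate") {
    if (is.null(config$sim))
      stop("configuration error: workflow 'simulate' needs config$sim")
    study <- stage("simulate", simulate_two_condition_study(config$sim))
    stage("simulate", write_simulation(study, config$run_dir))
    outputs$study <- study
    produced <- list.files(config$run_dir, recursive = TRUE,
                           full.names = TRUE)
    return(finish_run(produced, out_dir, config, outputs))
  }

  if (is.null(config$run_dir) || !dir.exists(config$run_dir))
    stop("configuration error: run_dir missing or not a directory")
  lay <- run_dir_layout(config$run_dir)
  needs_fp <- workflow %in% c("density", "rcdt", "diffdensity", "full")
  if (needs_fp && !length(lay$footprints))
    stop("configuration error: workflow '", workflow,
         "' needs footprint inputs under ", config$run_dir)

  seqs <- stage("read", read_fasta(lay$fasta))
  code <- standard_genetic_code()
  n_codons <- stats::setNames(as.integer(nchar(seqs) %/% 3), names(seqs))
  len_nt <- stats::setNames(nchar(seqs), names(seqs))

  if (workflow %in% c("indices", "windows", "groups", "full")) {
    usage <- stage("indices", read_usage_table(lay$usage))
    params <- if (file.exists(lay$trna)) read_trna_table(lay$trna) else NULL
    idx <- stage("indices", codon_index_table(seqs, usage, params))
    pipeline_log("indices: ", nrow(idx), " genes, ",
                 sum(idx$flag != ""), " flagged")
    outputs$indices <- idx
    emit(idx, "indices.tsv")
  }

  dens_mats <- NULL
  if (needs_fp) {
    conds <- names(lay$footprints)
    profs <- list()
    dens <- list()
    for (cond in conds) {
      profs[[cond]] <- list()
      dens[[cond]] <- list()
      reps <- lay$footprints[[cond]]
      mreps <- lay$mrna[[cond]]
      for (i in seq_along(reps)) {
        fp <- stage("density", read_footprints(reps[i]))
        pr <- stage("density", assign_a_sites(fp, n_codons, config$offsets))
        profs[[cond]][[i]] <- pr
        if (workflow %in% c("density", "diffdensity", "full") &&
            length(mreps) >= i) {
          mc <- utils::read.table(mreps[i], header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
          mrna_counts <- stats::setNames(mc$count, mc$gene_id)
          rpf_tpm <- compute_tpm(profile_totals(pr), len_nt)
          mrna_tpm <- compute_tpm(mrna_counts, len_nt)
          dd <- compute_ribosome_density(rpf_tpm, mrna_tpm,
                                         config$min_mrna_tpm)
          dens[[cond]][[i]] <- dd
          nm <- sub("\\.tsv$", "", basename(reps[i]))
          emit(dd, paste0("expression_", cond, "_", nm, ".tsv"))
        }
      }
      pipeline_log("condition ", cond, ": ", length(reps), " replicates")
    }
    outputs$profiles <- profs

    if (workflow %in% c("rcdt", "full")) {
      for (cond in conds) {
        pooled <- stage("rcdt", pool_profiles(profs[[cond]]))
        tab <- stage("rcdt", compute_rcdt(
          pooled, seqs, filter = config$coverage, trim = config$trim,
          condition_label = cond, code = code))
        outputs$rcdt[[cond]] <- tab
        emit(rcdt_as_data_frame(tab, code), paste0("rcdt_", cond, ".tsv"))
        st <- stage("rcdt", suppressWarnings(compute_rcdt_stratified(
          pooled, seqs, strata = config$strata, filter = config$coverage,
          trim = config$trim, condition_label = cond, code = code)))
        for (nm in names(st)) {
          outputs$rcdt_strata[[cond]][[nm]] <- st[[nm]]
          emit(rcdt_as_data_frame(st[[nm]], code),
               paste0("rcdt_", cond, "_", nm, ".tsv"))
        }
      }
    }

    if (workflow %in% c("diffdensity", "full")) {
      a <- config$cond_a; b <- config$cond_b
      if (!all(c(a, b) %in% conds))
        stop("configuration error: conditions ", a, "/", b, " not in run dir")
      genes <- names(seqs)
      mat <- function(cond) {
        cols <- lapply(dens[[cond]], function(d)
          stats::setNames(d$density, d$gene_id)[genes])
        m <- do.call(cbind, cols)
        rownames(m) <- genes
        m
      }
      diff <- stage("diffdensity", differential_density(
        mat(a), mat(b), fc_threshold = config$fc_threshold,
        alpha = config$alpha))
      pipeline_log("diffdensity: ", nrow(diff$results), " genes tested, ",
                   length(diff$excluded), " excluded, down-share ",
                   signif(diff$significant_share[["down"]], 3))
      outputs$differential <- diff
      emit(diff$results, paste0("differential_", b, "_vs_", a, ".tsv"))
      dens_mats <- diff
    }
  }

  if (workflow %in% c("windows", "full")) {
    idx <- outputs$indices
    if (file.exists(lay$proteome)) {
      prot <- utils::read.table(lay$proteome, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
      tab <- merge(idx, prot[c("gene_id", "abundance")], by = "gene_id")
      ws <- stage("windows", scanning_window_correlation(
        tab, rank_by = "tai", x = "length_aa", y = "abundance",
        window = min(config$window, nrow(tab)), step = config$step,
        transform = "identity", transform_y = "log10"))
      outputs$windows_abundance <- ws
      emit(ws, "windows_length_abundance.tsv")
    }
    if (!is.null(dens_mats)) {
      ft <- merge(idx[c("gene_id", "length_aa")],
                  dens_mats$results[c("gene_id", "fold_change")],
                  by = "gene_id")
      w <- min(config$window, nrow(ft))
      pc <- stage("windows", proportion_curves(
        ft, window = w, step = config$step,
        thresholds = c(lo = 1 / config$fc_threshold,
                       hi = config$fc_threshold)))
      outputs$proportion_curves <- pc
      emit(pc$decreased, "proportion_decreased.tsv")
      emit(pc$increased, "proportion_increased.tsv")
      rml <- stage("windows", ranked_mean_length(ft, window = w,
                                                 step = config$step))
      outputs$ranked_mean_length <- rml
      emit(rml, "ranked_mean_length.tsv")
    }
  }

  if (workflow %in% c("groups", "full")) {
    idx <- outputs$indices
    grp <- stage("groups", tryCatch(
      suppressWarnings(group_genes_by_cbi_length(
        idx, cbi_high = config$cbi_high, cbi_low = config$cbi_low,
        group_size = min(config$group_size,
                         sum(idx$cbi >= config$cbi_high, na.rm = TRUE),
                         sum(idx$cbi <= config$cbi_low, na.rm = TRUE)))),
      error = function(e) { pipeline_log("groups skipped: ",
                                         conditionMessage(e)); NULL }))
    if (!is.null(grp)) {
      outputs$groups <- grp
      for (nm in names(grp))
        emit(data.frame(gene_id = grp[[nm]]), paste0("group_", nm, ".tsv"))
    }
  }

  finish_run(produced, out_dir, config, outputs)
}

finish_run <- function(produced, out_dir, config, outputs) {
  manifest <- data.frame(file = basename(produced),
                         md5 = unname(tools::md5sum(produced)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  meta <- list(tool = "codonflux",
               version = as.character(utils::packageVersion("codonflux")),
               timestamp = format(Sys.time(), tz = "UTC"),
               files = manifest)
  jsonlite::write_json(meta, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(manifest = manifest, outputs = outputs)
}
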