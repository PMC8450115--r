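#' Scanning-window Pearson correlation along a gene ranking
#'
#' Genes are sorted ascending by `rank_by` (stable; ties broken by
#' `gene_id`), then for every window of `window` consecutive genes,
#' advanced by `step`, the Pearson correlation between `transform(x)` and
#' `y` is computed on pairs where both are present.  Windows with fewer
#' than 3 complete pairs are skipped; zero-variance windows yield an NA
#' statistic rather than an error.  This is the machinery behind
#' "correlation between protein length and abundance as a function of
#' codon usage" style analyses.
#'
#' @param table data.frame with a `gene_id` column plus the named fields.
#' @param rank_by,x,y column names.
#' @param window window size in genes (>= 3).
#' @param step ranks advanced between successive windows (default 1, the
#'   smoothest "continuous" scan).
#' @param transform `"identity"` or `"log10"`, applied to `x`.
#' @param transform_y same, applied to `y`.
#' @param method correlation estimator, `"pearson"` (default) or
#'   `"spearman"`.
#' @return data.frame of window statistics: `window_index`,
#'   `center_metric` (mean of `rank_by` in the window), `statistic`,
#'   `n_effective`.
#' @export
scanning_window_correlation <- function(table, rank_by, x, y, window = 500L,
                                        step = 1L,
                                        transform = c("identity", "log10"),
                                        transform_y = c("identity", "log10"),
                                        method = c("pearson", "spearman")) {
  transform <- match.arg(transform)
  transform_y <- match.arg(transform_y)
  method <- match.arg(method)
  if (window < 3L) stop("window must be >= 3")
  d <- table[!is.na(table[[rank_by]]) & !is.na(table[[x]]) &
               !is.na(table[[y]]), , drop = FALSE]
  if (nrow(d) < window)
    stop("window (", window, ") exceeds the ", nrow(d),
         " genes with complete fields")
  d <- d[order(d[[rank_by]], d$gene_id), , drop = FALSE]
  tx <- if (transform == "log10") log10(d[[x]]) else d[[x]]
  ty <- if (transform_y == "log10") log10(d[[y]]) else d[[y]]
  starts <- seq(1L, nrow(d) - window + 1L, by = step)
  out <- lapply(seq_along(starts), function(k) {
    idx <- starts[k]:(starts[k] + window - 1L)
    ok <- is.finite(tx[idx]) & is.finite(ty[idx])
    if (sum(ok) < 3L) return(NULL)
    xs <- tx[idx][ok]; ys <- ty[idx][ok]
    stat <- if (stats::sd(xs) == 0 || stats::sd(ys) == 0) NA_real_
            else stats::cor(xs, ys, method = method)
    data.frame(window_index = k, center_metric = mean(d[[rank_by]][idx]),
               statistic = stat, n_effective = sum(ok))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(window_index = integer(0), center_metric = numeric(0),
                      statistic = numeric(0), n_effective = integer(0))
  rownames(out) <- NULL
  out
}

#' Correlation on a filtered gene subset
#'
#' Pearson (or Spearman) correlation between `x` and `y` on the genes
#' selected by `filter_expr`, the machinery behind "restricted to genes
#' with CBI above/below a cut" style comparisons.
#'
#' @inheritParams scanning_window_correlation
#' @param filter_expr an expression on the table's columns, e.g.
#'   `cbi > 0.5` (quoted or unquoted).
#' @return list with `r` (correlation) and `n` (genes used).
#' @export
subset_correlation <- function(table, filter_expr, x, y,
                               transform = c("identity", "log10"),
                               transform_y = c("identity", "log10"),
                               method = c("pearson", "spearman")) {
  transform <- match.arg(transform)
  transform_y <- match.arg(transform_y)
  method <- match.arg(method)
  e <- substitute(filter_expr)
  if (is.character(e)) e <- str2lang(filter_expr)
  keep <- eval(e, table, parent.frame())
  keep[is.na(keep)] <- FALSE
  d <- table[keep, , drop = FALSE]
  tx <- if (transform == "log10") log10(d[[x]]) else d[[x]]
  ty <- if (transform_y == "log10") log10(d[[y]]) else d[[y]]
  ok <- is.finite(tx) & is.finite(ty)
  if (sum(ok) < 3L) stop("filter leaves ", sum(ok), " genes (< 3)")
  list(r = stats::cor(tx[ok], ty[ok], method = method), n = sum(ok))
}

#' Group genes by codon bias and CDS length
#'
#' Within the high-CBI stratum (`cbi >= cbi_high`) and the low-CBI stratum
#' (`cbi <= cbi_low`), selects the `group_size` longest and the
#' `group_size` shortest genes by `length_aa` (ties broken by `gene_id`).
#'
#' @param table data.frame with `gene_id`, `length_aa`, `cbi`.
#' @param cbi_high,cbi_low CBI cuts defining the strata.
#' @param group_size genes per group.
#' @return named list of gene-id vectors: `long_high_cbi`, `long_low_cbi`,
#'   `short_high_cbi`, `short_low_cbi`.  When a stratum holds fewer than
#'   `2 * group_size` genes its long/short lists overlap; this is flagged
#'   with a warning.
#' @export
group_genes_by_cbi_length <- function(table, cbi_high = 0.3, cbi_low = 0.15,
                                      group_size = 1000L) {
  d <- table[!is.na(table$cbi) & !is.na(table$length_aa), , drop = FALSE]
  pick <- function(stratum, decreasing, label) {
    if (nrow(stratum) < group_size)
      stop("stratum for ", label, " holds ", nrow(stratum),
           " genes (< group_size = ", group_size, ")")
    o <- order(stratum$length_aa, stratum$gene_id)
    if (decreasing)
      o <- order(-stratum$length_aa, stratum$gene_id)
    stratum$gene_id[o][seq_len(group_size)]
  }
  hi <- d[d$cbi >= cbi_high, , drop = FALSE]
  lo <- d[d$cbi <= cbi_low, , drop = FALSE]
  out <- list(long_high_cbi = pick(hi, TRUE, "long_high_cbi"),
              long_low_cbi = pick(lo, TRUE, "long_low_cbi"),
              short_high_cbi = pick(hi, FALSE, "short_high_cbi"),
              short_low_cbi = pick(lo, FALSE, "short_low_cbi"))
  if (nrow(hi) < 2L * group_size || nrow(lo) < 2L * group_size)
    warning("a CBI stratum holds fewer than 2*group_size genes; ",
            "its long and short lists overlap")
  out
}

#' Differential ribosome density between two conditions
#'
#' Per gene: fold change `mean(b)/mean(a)`, a two-sample two-tailed t test
#' across replicates (Welch by default, pooled-variance Student optional),
#' Benjamini-Hochberg adjustment across tested genes, and an
#' up/down/not-significant call: down iff `fold_change < 1/fc_threshold`
#' and `fdr < alpha`; up iff `fold_change > fc_threshold` and
#' `fdr < alpha`.
#'
#' @param a_reps,b_reps numeric matrices (genes x replicates, >= 2
#'   columns) with identical rownames (gene ids); rows with any NA, or a
#'   zero mean in `a`, are flagged and excluded from testing.
#' @param fc_threshold fold-change cut (default 2).
#' @param alpha FDR cut (default 0.05).
#' @param var_equal `FALSE` for Welch (default), `TRUE` for the pooled
#'   Student test.
#' @return list with `results` (data.frame: `gene_id`, `mean_density_a`,
#'   `mean_density_b`, `fold_change`, `p_value`, `fdr`, `call`),
#'   `excluded` (gene ids not tested), and `significant_share` (named:
#'   `down`, `up` — the share of each direction among genes passing both
#'   cuts).
#' @export
differential_density <- function(a_reps, b_reps, fc_threshold = 2,
                                 alpha = 0.05, var_equal = FALSE) {
  if (is.null(rownames(a_reps)) || !identical(rownames(a_reps), rownames(b_reps)))
    stop("a_reps and b_reps must share identical rownames (gene ids)")
  if (ncol(a_reps) < 2L || ncol(b_reps) < 2L)
    stop("need >= 2 replicates per condition")
  genes <- rownames(a_reps)
  usable <- stats::complete.cases(a_reps) & stats::complete.cases(b_reps) &
    rowMeans(a_reps) != 0
  excluded <- genes[!usable]
  a <- a_reps[usable, , drop = FALSE]
  b <- b_reps[usable, , drop = FALSE]
  p <- vapply(seq_len(nrow(a)), function(i) {
    av <- a[i, ]; bv <- b[i, ]
    if (stats::sd(av) == 0 && stats::sd(bv) == 0) {
      # degenerate: no within-group variability
      return(if (mean(av) == mean(bv)) 1 else 0)
    }
    stats::t.test(bv, av, var.equal = var_equal)$p.value
  }, 0)
  fc <- rowMeans(b) / rowMeans(a)
  fdr <- stats::p.adjust(p, method = "BH")
  call <- rep("ns", length(fc))
  call[fc < 1 / fc_threshold & fdr < alpha] <- "down"
  call[fc > fc_threshold & fdr < alpha] <- "up"
  res <- data.frame(gene_id = rownames(a), mean_density_a = rowMeans(a),
                    mean_density_b = rowMeans(b), fold_change = fc,
                    p_value = p, fdr = fdr, call = call,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  nsig <- sum(res$call != "ns")
  share <- if (nsig > 0)
    c(down = sum(res$call == "down") / nsig, up = sum(res$call == "up") / nsig)
  else c(down = NA_real_, up = NA_real_)
  list(results = res, excluded = excluded, significant_share = share)
}

#' Proportion of decreased/increased genes along a length ranking
#'
#' Genes are ranked ascending by `length_aa`; in each scanning window the
#' fraction of genes with `fold_change < lo` (decreased) and
#' `fold_change > hi` (increased) is computed.
#'
#' @param table data.frame with `gene_id`, `length_aa`, `fold_change`.
#' @param window window size in genes.
#' @param step ranks advanced between windows.
#' @param thresholds `c(lo, hi)` fold-change cuts (default 0.5 and 2).
#' @return list of two window-statistic data.frames, `decreased` and
#'   `increased`, each with `window_index`, `center_metric` (mean
#'   `length_aa`), `statistic` (the proportion), `n_effective`.
#' @export
proportion_curves <- function(table, window = 500L, step = 1L,
                              thresholds = c(lo = 0.5, hi = 2)) {
  d <- table[!is.na(table$fold_change) & !is.na(table$length_aa), ,
             drop = FALSE]
  if (nrow(d) < window)
    stop("window (", window, ") exceeds the ", nrow(d),
         " genes with fold changes")
  d <- d[order(d$length_aa, d$gene_id), , drop = FALSE]
  starts <- seq(1L, nrow(d) - window + 1L, by = step)
  one <- function(pred) {
    out <- lapply(seq_along(starts), function(k) {
      idx <- starts[k]:(starts[k] + window - 1L)
      data.frame(window_index = k, center_metric = mean(d$length_aa[idx]),
                 statistic = mean(pred(d$fold_change[idx])),
                 n_effective = length(idx))
    })
    out <- do.call(rbind, out); rownames(out) <- NULL; out
  }
  list(decreased = one(function(f) f < thresholds[[1]]),
       increased = one(function(f) f > thresholds[[2]]))
}

#' Mean CDS length along a fold-change ranking
#'
#' Genes are ranked ascending by `log2(fold_change)` (greatest decrease
#' first); each window's statistic is the mean `length_aa`.
#'
#' @inheritParams proportion_curves
#' @return window-statistic data.frame (`statistic` = mean length in aa).
#' @export
ranked_mean_length <- function(table, window = 500L, step = 1L) {
  d <- table[!is.na(table$fold_change) & !is.na(table$length_aa) &
               table$fold_change > 0, , drop = FALSE]
  if (nrow(d) < window)
    stop("window (", window, ") exceeds the ", nrow(d), " usable genes")
  d <- d[order(log2(d$fold_change), d$gene_id), , drop = FALSE]
  starts <- seq(1L, nrow(d) - window + 1L, by = step)
  out <- lapply(seq_along(starts), function(k) {
    idx <- starts[k]:(starts[k] + window - 1L)
    data.frame(window_index = k,
               center_metric = mean(log2(d$fold_change[idx])),
               statistic = mean(d$length_aa[idx]), n_effective = length(idx))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
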