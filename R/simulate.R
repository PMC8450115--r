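#' Deterministic synthetic codon usage table
#'
#' A fully synthetic usage table (labelled as such) for self-contained
#' simulations: within each synonymous family, frequencies fall
#' geometrically from a family-specific "preferred" codon whose position
#' is rotated deterministically by the amino-acid letter, so the optimal
#' codon is not always the lexicographically first one.  Unit is
#' per-thousand under a uniform amino-acid composition.
#'
#' @param code genetic code object.
#' @return a [codon_usage_table()] with `source_label = "synthetic"`.
#' @export
synthetic_usage_table <- function(code = standard_genetic_code()) {
  freq <- stats::setNames(numeric(length(code$sense_codons)),
                          sort(code$sense_codons))
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    k <- length(fam)
    rot <- utf8ToInt(aa) %% k
    rank <- ((seq_len(k) - 1L + rot) %% k)      # 0 = preferred
    w <- 2^(-rank)
    freq[fam] <- w / sum(w) * 1000 / length(code$families)
  }
  codon_usage_table(freq, source_label = "synthetic", unit = "per_thousand",
                    code = code)
}

#' Synthetic tRNA parameters matched to a usage table
#'
#' Watson-Crick anticodon copy numbers proportional to each codon's
#' within-family frequency fraction (scaled by `scale`, rounded), so that
#' tAI weights rise with codon preference.  Labelled synthetic.
#'
#' @param table a [codon_usage_table()] (default the synthetic one).
#' @param scale copies for a codon carrying its whole family's usage.
#' @param code genetic code object.
#' @return a [tai_params()] object.
#' @export
synthetic_tai_params <- function(table = synthetic_usage_table(),
                                 scale = 12, code = standard_genetic_code()) {
  counts <- integer(0)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    frac <- table$codon_freq[fam] / sum(table$codon_freq[fam])
    cnt <- round(scale * frac)
    cnt[which.max(frac)] <- max(cnt[which.max(frac)], 1L)
    counts <- c(counts, stats::setNames(as.integer(cnt), rev_comp(fam)))
  }
  tai_params(counts[counts > 0])
}

#' Per-codon dwell times derived from usage preference
#'
#' Baseline decoding dwell inversely monotone with within-family
#' preference: `d_c = hi - (hi - lo) * f(c)/max(f over family)`, so the
#' most preferred synonym always has the shortest dwell (`lo`) and a
#' never-used synonym approaches `hi`.
#'
#' @param table a [codon_usage_table()].
#' @param range `c(lo, hi)` dwell bounds (arbitrary relative units).
#' @param code genetic code object.
#' @return named numeric vector over sense codons.
#' @export
dwell_from_usage <- function(table = synthetic_usage_table(),
                             range = c(0.5, 3),
                             code = standard_genetic_code()) {
  w <- relative_adaptiveness(table, code)
  d <- range[2] - (range[2] - range[1]) * w
  d[names(table$codon_freq)]
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic world: transcriptome shape
#' (CDS-length distribution, per-gene codon-optimality parameter
#' `p_opt`), proteome model (`log10 abundance = a - (b0 - b1*tai)*length
#' + Normal(0, sigma)` — a negative length effect that weakens as codon
#' optimality rises), codon dwell model, two-condition modifiers, and
#' sequencing depths.  All randomness is governed by `seed`
#' (sub-seeds for the proteome and each condition/replicate are drawn by
#' `sample.int(2^31 - 2, ...)` under the master seed).
#'
#' @param n_genes number of genes.
#' @param length_meanlog,length_sdlog lognormal CDS-length parameters in
#'   amino acids (median 400 by default).
#' @param length_range truncation bounds in aa (draws are redrawn until
#'   inside).
#' @param bias_shape1,bias_shape2 Beta parameters for per-gene `p_opt`
#'   (probability that each codon is the family's optimal one; the
#'   remaining mass is uniform over the whole family, so `p_opt = 0` is
#'   exactly uniform synonymous sampling and `p_opt = 1` fully optimal).
#' @param p_opt optional fixed value (scalar or per-gene vector)
#'   overriding the Beta draw.
#' @param usage_table reference [codon_usage_table()] defining the
#'   optimal pole.
#' @param dwell named per-codon baseline dwell vector (> 0); default
#'   derived from `usage_table` via [dwell_from_usage()].
#' @param abundance list `a`, `b0`, `b1`, `sigma`, `missing_rate` for the
#'   proteome model; `b0` must exceed `b1 * max(gene tAI)` (checked when
#'   the proteome is generated) so the planted length effect stays
#'   negative at low optimality and weakest, but still negative, at high.
#' @param conditions named list of condition modifier lists, each with
#'   `init_fold` (global initiation multiplier), `dwell_exponent`
#'   (codon dwells raised to this power: < 1 compresses the spread,
#'   accelerating rare codons preferentially), `global_speed` (uniform
#'   dwell multiplier), `length_pause` (per-gene uniform dwell multiplier
#'   `exp(length_pause * length_aa)`, the length-dependent elongation
#'   slowdown; an exponential rate so long genes can slow down without
#'   bound, as cumulative pausing feedback implies), `attenuation`
#'   (initiation damping
#'   `exp(-attenuation * length_aa * (1 - p_opt))`).
#' @param long_dwell list `threshold` (aa), `factor`: genes longer than
#'   `threshold` get all dwells multiplied by `factor` (the length-stratum
#'   dwell modifier).
#' @param depth mean ribosome footprints per eligible codon.
#' @param mrna_depth mean mRNA-seq reads per codon.
#' @param read_lengths named probability vector over footprint lengths.
#' @param offsets A-site offset table, see [default_a_site_offsets()].
#' @param n_replicates replicates per condition (>= 2).
#' @param seed master seed (integer).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       length_meanlog = log(400), length_sdlog = 0.55,
                       length_range = c(60, 3000),
                       bias_shape1 = 2, bias_shape2 = 2, p_opt = NULL,
                       usage_table = synthetic_usage_table(),
                       dwell = NULL,
                       abundance = list(a = 6, b0 = 2e-3, b1 = 2.5e-3,
                                        sigma = 0.2, missing_rate = 0),
                       conditions = list(
                         baseline = list(init_fold = 1, dwell_exponent = 1,
                                         global_speed = 1,
                                         length_pause = 0.002,
                                         attenuation = 0),
                         fast = list(init_fold = 1.3, dwell_exponent = 0.5,
                                     global_speed = 0.6,
                                     length_pause = 0, attenuation = 0)),
                       long_dwell = list(threshold = Inf, factor = 1),
                       depth = 5, mrna_depth = 5,
                       read_lengths = c("27" = 0.15, "28" = 0.5,
                                        "29" = 0.25, "30" = 0.1),
                       offsets = default_a_site_offsets(),
                       n_replicates = 4L, seed = 1L) {
  if (is.null(dwell)) dwell <- dwell_from_usage(usage_table)
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1) stop("config error: n_genes must be >= 1")
    if (length_range[1] < 1 || length_range[2] <= length_range[1])
      stop("config error: bad length_range")
    if (any(dwell <= 0)) stop("config error: dwells must be > 0")
    if (abundance$sigma < 0) stop("config error: sigma must be >= 0")
    if (abundance$b0 <= 0 || abundance$b1 < 0)
      stop("config error: need b0 > 0 and b1 >= 0 in the abundance model")
    if (depth <= 0 || mrna_depth <= 0)
      stop("config error: zero total depth")
    if (n_replicates < 2) stop("config error: n_replicates must be >= 2")
    if (abs(sum(read_lengths) - 1) > 1e-8)
      stop("config error: read_lengths must sum to 1")
    if (!all(names(read_lengths) %in% names(offsets)))
      stop("config error: every read length needs an A-site offset")
    if (!all(c("baseline") %in% names(conditions)))
      stop("config error: conditions must include 'baseline'")
    if (!is.null(p_opt) && any(p_opt < 0 | p_opt > 1))
      stop("config error: p_opt must lie in [0, 1]")
  })
  invisible(cfg)
}

derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(master)
  sample.int(2147483646L, n)
}

#' Simulate a transcriptome with planted codon-usage bias
#'
#' Each gene gets a CDS length from the truncated lognormal, a per-gene
#' optimality `p_opt`, a forced ATG start and TAA stop, and codons drawn
#' per position: the family's optimal codon with probability `p_opt`,
#' otherwise uniformly over the whole family.  Ground truth (realized
#' `p_opt`, gene tAI/CBI, planted mRNA abundance) is returned alongside.
#'
#' @param cfg a [sim_config()].
#' @return list with `sequences` (named character, stop included),
#'   `codon_list`, `truth` (data.frame: `gene_id`, `length_aa`, `p_opt`,
#'   `tai`, `cbi`, `mrna_mean`), `usage_table`, `tai_params`, `dwell`,
#'   `optimal_set`, `config`.
#' @export
simulate_transcriptome <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  code <- standard_genetic_code()
  set.seed(cfg$seed)
  n <- cfg$n_genes
  # truncated lognormal lengths (rejection sampling)
  len <- round(stats::rlnorm(n, cfg$length_meanlog, cfg$length_sdlog))
  bad <- which(len < cfg$length_range[1] | len > cfg$length_range[2])
  while (length(bad)) {
    len[bad] <- round(stats::rlnorm(length(bad), cfg$length_meanlog,
                                    cfg$length_sdlog))
    bad <- which(len < cfg$length_range[1] | len > cfg$length_range[2])
  }
  p_opt <- if (!is.null(cfg$p_opt)) rep_len(cfg$p_opt, n)
           else stats::rbeta(n, cfg$bias_shape1, cfg$bias_shape2)
  opt <- derive_optimal_set(cfg$usage_table, code)
  fams <- code$families
  aa_names <- names(fams)
  best <- vapply(aa_names, function(a) {
    fam <- fams[[a]]
    if (length(fam) == 1L) fam else intersect(fam, opt)[1]
  }, "")
  fam_sizes <- vapply(fams, length, 1L)
  gene_ids <- sprintf("g%04d", seq_len(n))
  # planted mRNA abundance: higher for codon-optimal and shorter genes
  # (the canonical expression/optimality coupling), lognormal noise on top
  mrna_mean <- stats::rlnorm(n, meanlog = 1 + 2 * p_opt - 2.5e-3 * len,
                             sdlog = 1)
  # one flat draw over all positions of all genes, then re-split per gene
  m <- len - 1L                          # positions after the forced ATG
  gidx <- rep.int(seq_len(n), m)
  N <- sum(m)
  fam_mat <- matrix("", length(aa_names), max(fam_sizes))
  for (j in seq_along(aa_names))
    fam_mat[j, seq_len(fam_sizes[j])] <- fams[[j]]
  ai <- sample.int(length(aa_names), N, replace = TRUE)
  use_opt <- stats::runif(N) < p_opt[gidx]
  u <- ceiling(stats::runif(N) * fam_sizes[ai])
  cods <- fam_mat[cbind(ai, u)]
  cods[use_opt] <- best[ai[use_opt]]
  codon_list <- lapply(split(cods, gidx), function(x) c("ATG", x, "TAA"))
  names(codon_list) <- gene_ids
  seqs <- vapply(codon_list, paste, "", collapse = "")
  weights <- compute_tai_weights(synthetic_tai_params(cfg$usage_table),
                                 code)
  # vectorized gene tAI / CBI over the flat position vector (ATG and TAA
  # contribute log-weight terms for tAI; CBI uses multi-codon families)
  logw <- log(weights)
  tai_sum <- rowsum(logw[cods], gidx)[, 1] + logw[["ATG"]]
  tai <- exp(tai_sum / len)
  multi <- cods %in% code$multi_family_codons
  k_syn <- fam_sizes[ai]
  k_opt <- vapply(seq_along(aa_names), function(j)
    sum(fams[[j]] %in% opt), 0)
  lev <- seq_len(n)
  n_tot <- as.numeric(tapply(multi, factor(gidx, levels = lev), sum,
                             default = 0))
  n_opt <- as.numeric(tapply(multi & cods %in% opt,
                             factor(gidx, levels = lev), sum, default = 0))
  n_ran <- as.numeric(tapply(ifelse(multi, k_opt[ai] / k_syn, 0),
                             factor(gidx, levels = lev), sum, default = 0))
  cbi <- (n_opt - n_ran) / (n_tot - n_ran)
  truth <- data.frame(gene_id = gene_ids, length_aa = len, p_opt = p_opt,
                      tai = unname(tai), cbi = unname(cbi),
                      mrna_mean = mrna_mean, stringsAsFactors = FALSE)
  list(sequences = seqs, codon_list = codon_list, truth = truth,
       usage_table = cfg$usage_table, dwell = cfg$dwell,
       optimal_set = opt, tai_weights = weights, config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a proteome from transcriptome ground truth
#'
#' `log10 abundance = a - (b0 - b1 * tai) * length_aa + Normal(0, sigma)`;
#' optionally masked missing-at-random to emulate MS detectability.
#'
#' @param sim result of [simulate_transcriptome()].
#' @param seed RNG seed (default: first sub-seed derived from the master).
#' @return data.frame `gene_id`, `length_aa`, `tai`, `cbi`, `abundance`
#'   (NA where masked), `log10_abundance_true`.
#' @export
simulate_proteome <- function(sim, seed = NULL) {
  cfg <- sim$config
  ab <- cfg$abundance
  if (is.null(seed)) seed <- derive_seeds(cfg$seed, 1L)[1]
  set.seed(seed)
  t <- sim$truth
  if (ab$b0 - ab$b1 * max(t$tai) <= 0)
    stop("config error: b0 must exceed b1 * max(tai) so the planted ",
         "length effect stays negative at every optimality")
  mu <- ab$a - (ab$b0 - ab$b1 * t$tai) * t$length_aa
  obs <- mu + stats::rnorm(nrow(t), 0, ab$sigma)
  abun <- 10^obs
  if (ab$missing_rate > 0)
    abun[stats::runif(nrow(t)) < ab$missing_rate] <- NA_real_
  data.frame(gene_id = t$gene_id, length_aa = t$length_aa, tai = t$tai,
             cbi = t$cbi, abundance = abun, log10_abundance_true = mu,
             stringsAsFactors = FALSE)
}

# Effective per-position dwell weights and per-gene rates for a condition.
condition_model <- function(sim, condition) {
  cfg <- sim$config
  if (!condition %in% names(cfg$conditions))
    stop("unknown condition: ", condition)
  mod <- cfg$conditions[[condition]]
  dwell <- (cfg$dwell^(mod$dwell_exponent %||% 1)) * (mod$global_speed %||% 1)
  list(mod = mod, dwell = dwell)
}

#' Simulate ribosome footprints (and paired mRNA counts) for one library
#'
#' Per-gene footprint totals are Poisson with mean proportional to
#' planted mRNA abundance x initiation rate x transit time (the sum of
#' effective dwells over eligible positions); positions are multinomial
#' with weights proportional to the effective codon dwell; read lengths
#' follow the configured distribution and 5' positions are back-computed
#' from the A-site offsets, so [assign_a_sites()] inverts the generator
#' exactly.  Eligible positions are those whose footprint fits inside the
#' CDS for every configured read length.
#'
#' @param sim result of [simulate_transcriptome()].
#' @param condition condition label (a name of `config$conditions`).
#' @param seed RNG seed for this library.
#' @return list with `footprints` (data.frame `gene_id`, `five_prime_pos`,
#'   `read_length`), `mrna_counts` (named vector), `truth` (list:
#'   `dwell_eff`, per-gene `expected_footprints`, `n_footprints`,
#'   `init`, `transit`), `condition`, `seed`.
#' @export
simulate_footprints <- function(sim, condition = "baseline",
                                seed = sim$config$seed) {
  cfg <- sim$config
  cm <- condition_model(sim, condition)
  set.seed(seed)
  t <- sim$truth
  n <- nrow(t)
  code <- standard_genetic_code()
  max_off <- max(cfg$offsets[names(cfg$read_lengths)])
  rl <- as.integer(names(cfg$read_lengths))
  amin <- ceiling(max_off / 3)
  tail_excl <- ceiling((max(rl) - min(cfg$offsets[names(cfg$read_lengths)])) / 3)
  init <- (cm$mod$init_fold %||% 1) *
    exp(-(cm$mod$attenuation %||% 0) * t$length_aa * (1 - t$p_opt))
  gene_pause <- exp((cm$mod$length_pause %||% 0) * t$length_aa)
  long_fac <- ifelse(t$length_aa > cfg$long_dwell$threshold,
                     cfg$long_dwell$factor, 1)
  pos_w <- vector("list", n)
  transit <- numeric(n)
  n_eligible <- numeric(n)
  for (i in seq_len(n)) {
    cods <- sim$codon_list[[i]]
    nc <- length(cods)
    lo <- amin + 1L                       # 1-based index of first eligible
    hi <- nc - tail_excl
    w <- cm$dwell[cods[lo:hi]]
    w[is.na(w)] <- mean(cm$dwell)         # stop/N codons: neutral dwell
    w <- w * gene_pause[i] * long_fac[i]
    pos_w[[i]] <- w
    transit[i] <- sum(w)
    n_eligible[i] <- hi - lo + 1L
  }
  expected <- t$mrna_mean * init * transit
  lambda <- expected / sum(expected) * cfg$depth * sum(n_eligible)
  n_reads <- stats::rpois(n, lambda)
  parts <- vector("list", n)
  for (i in seq_len(n)) {
    if (n_reads[i] == 0) next
    cnt <- stats::rmultinom(1, n_reads[i], pos_w[[i]])[, 1]
    codon_idx0 <- (amin + seq_along(cnt) - 1L)[cnt > 0]  # 0-based codon index
    reps <- cnt[cnt > 0]
    ci <- rep.int(codon_idx0, reps)
    lens <- rl[sample.int(length(rl), sum(reps), replace = TRUE,
                          prob = cfg$read_lengths)]
    parts[[i]] <- data.frame(
      gene_id = t$gene_id[i],
      five_prime_pos = 3L * ci - as.integer(cfg$offsets[as.character(lens)]),
      read_length = lens, stringsAsFactors = FALSE)
  }
  fp <- do.call(rbind, parts)
  if (is.null(fp))
    stop("config error: zero total depth (no footprints drawn)")
  rownames(fp) <- NULL
  len_nt <- (t$length_aa + 1L) * 3L
  mrna_expected <- t$mrna_mean * len_nt
  mrna_lambda <- mrna_expected / sum(mrna_expected) *
    cfg$mrna_depth * sum(len_nt) / 3
  mrna <- stats::setNames(stats::rpois(n, mrna_lambda), t$gene_id)
  list(footprints = fp,
       mrna_counts = mrna,
       truth = list(dwell_eff = cm$dwell,
                    expected_footprints = stats::setNames(lambda, t$gene_id),
                    n_footprints = stats::setNames(n_reads, t$gene_id),
                    init = stats::setNames(init, t$gene_id),
                    transit = stats::setNames(transit, t$gene_id)),
       condition = condition, seed = seed)
}

#' Simulate a replicated two-condition ribosome-profiling study
#'
#' Generates a transcriptome and proteome plus `n_replicates` footprint +
#' mRNA libraries for each configured condition, with sub-seeds derived
#' deterministically from the master seed.  The default condition pair
#' emulates a baseline strain versus one with globally elevated
#' initiation and accelerated elongation (rare codons preferentially
#' accelerated, length-dependent pausing removed).
#'
#' @param cfg a [sim_config()].
#' @return list with `transcriptome`, `proteome`, `libraries` (nested:
#'   condition -> replicate -> [simulate_footprints()] result), `seeds`,
#'   `config`.
#' @export
simulate_two_condition_study <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  sim <- simulate_transcriptome(cfg)
  conds <- names(cfg$conditions)
  n_seeds <- 1L + length(conds) * cfg$n_replicates
  seeds <- derive_seeds(cfg$seed, n_seeds)
  proteome <- simulate_proteome(sim, seed = seeds[1])
  libraries <- list()
  k <- 1L
  for (cond in conds) {
    libraries[[cond]] <- lapply(seq_len(cfg$n_replicates), function(r) {
      k <<- k + 1L
      simulate_footprints(sim, condition = cond, seed = seeds[k])
    })
    names(libraries[[cond]]) <- paste0("rep", seq_len(cfg$n_replicates))
  }
  list(transcriptome = sim, proteome = proteome, libraries = libraries,
       seeds = seeds, config = cfg)
}
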