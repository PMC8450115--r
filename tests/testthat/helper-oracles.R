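# Independent naive-loop oracles and tiny fixtures shared by the suite.
# The oracles deliberately re-derive every quantity codon by codon, without
# touching the package's vectorized/pooled implementations.

GC <- standard_genetic_code()

# --- naive index oracles -----------------------------------------------

naive_split <- function(seq) {
  seq <- toupper(gsub("U", "T", seq))
  n <- nchar(seq) %/% 3
  vapply(seq_len(n), function(i) substr(seq, 3 * i - 2, 3 * i), "")
}

naive_cai <- function(seq, table, code = GC) {
  logs <- c()
  for (cod in naive_split(seq)) {
    if (grepl("N", cod)) next
    aa <- code$codon_to_aa[[cod]]
    if (aa == "*") next
    fam <- code$families[[aa]]
    if (length(fam) < 2) next
    w <- table$codon_freq[[cod]] / max(table$codon_freq[fam])
    logs <- c(logs, log(max(w, 0.01)))
  }
  exp(mean(logs))
}

naive_cbi <- function(seq, optimal_set, code = GC) {
  n_opt <- 0; n_tot <- 0; n_ran <- 0
  for (cod in naive_split(seq)) {
    if (grepl("N", cod)) next
    aa <- code$codon_to_aa[[cod]]
    if (aa == "*") next
    fam <- code$families[[aa]]
    if (length(fam) < 2) next
    n_tot <- n_tot + 1
    if (cod %in% optimal_set) n_opt <- n_opt + 1
    n_ran <- n_ran + sum(fam %in% optimal_set) / length(fam)
  }
  (n_opt - n_ran) / (n_tot - n_ran)
}

naive_tai <- function(seq, weights, code = GC) {
  logs <- c()
  for (cod in naive_split(seq)) {
    if (grepl("N", cod)) next
    if (code$codon_to_aa[[cod]] == "*") next
    logs <- c(logs, log(weights[[cod]]))
  }
  exp(mean(logs))
}

# whole-window statistics recomputed from scratch on a materialized window
naive_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# --- fixtures -----------------------------------------------------------

# random toy gene: codon string of n sense codons drawn from the given pool
random_gene <- function(n, pool = GC$sense_codons) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

toy_usage <- synthetic_usage_table()
toy_optimal <- derive_optimal_set(toy_usage)
toy_params <- synthetic_tai_params(toy_usage)
toy_weights <- compute_tai_weights(toy_params)

# a small usage table where lysine AAA:AAG = 75:25, used by the frozen
# hand examples
hand_usage <- local({
  f <- toy_usage$codon_freq
  f["AAA"] <- 75; f["AAG"] <- 25
  codon_usage_table(f, source_label = "hand", unit = "count")
})

# multinomial occupancy profiles from planted per-codon dwell times;
# reads per gene ~ depth * n_codons over the non-trimmed window
planted_profiles <- function(codon_list, dwell, depth = 30,
                             trim = c(head = 15, tail = 5)) {
  profiles <- lapply(codon_list, function(cods) {
    n <- length(cods)
    win <- (trim[[1]] + 1):(n - trim[[2]])
    w <- dwell[cods[win]]
    w[is.na(w)] <- 1
    counts <- integer(n)
    counts[win] <- stats::rmultinom(1, round(depth * length(win)), w)[, 1]
    counts
  })
  structure(list(profiles = profiles,
                 n_codons = vapply(codon_list, length, 1L),
                 dropped = c(unknown_gene = 0L, bad_length = 0L,
                             out_of_range = 0L),
                 n_assigned = sum(vapply(profiles, sum, 0))),
            class = "occupancy_profiles")
}

# random codon_list fixture: n_genes genes of n_codons sense codons each,
# bracketed by ATG/TAA like the generator's output
random_codon_list <- function(n_genes, n_codons, pool = GC$sense_codons) {
  out <- lapply(seq_len(n_genes), function(i)
    c("ATG", sample(pool, n_codons - 2L, replace = TRUE), "TAA"))
  names(out) <- sprintf("g%04d", seq_len(n_genes))
  out
}
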