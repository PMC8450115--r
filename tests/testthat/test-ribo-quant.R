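# footprint -> occupancy -> TPM/density -> RCDT

test_that("A-site assignment applies the offset rule and drops out-of-range", {
  fp <- data.frame(gene_id = c("g1", "g1", "g1", "g2", "gX"),
                   five_prime_pos = c(0L, 285L, 3L, 0L, 0L),
                   read_length = c(28L, 28L, 40L, 29L, 28L))
  nc <- c(g1 = 100L, g2 = 50L)
  expect_message(pr <- assign_a_sites(fp, nc), "unknown")
  # (0 + 15) %/% 3 = 5
  expect_equal(pr$profiles$g1[5 + 1], 1L)
  # (285 + 15) %/% 3 = 100 >= n_codons -> dropped
  expect_equal(unname(pr$dropped["out_of_range"]), 1L)
  # read length 40 has no offset -> dropped
  expect_equal(unname(pr$dropped["bad_length"]), 1L)
  expect_equal(unname(pr$dropped["unknown_gene"]), 1L)
  expect_equal(pr$n_assigned, 2L)
})

test_that("occupancy counts are conserved against a brute-force recount", {
  set.seed(5)
  n_reads <- 1000
  fp <- data.frame(gene_id = "g1",
                   five_prime_pos = sample(0:284, n_reads, replace = TRUE),
                   read_length = sample(27:31, n_reads, replace = TRUE))
  nc <- c(g1 = 100L)
  pr <- assign_a_sites(fp, nc)
  # brute-force: recompute every A-site independently
  brute <- integer(100)
  dropped <- 0
  for (i in seq_len(n_reads)) {
    a <- (fp$five_prime_pos[i] + 15) %/% 3
    if (a < 100) brute[a + 1] <- brute[a + 1] + 1L else dropped <- dropped + 1
  }
  expect_identical(pr$profiles$g1, brute)
  expect_equal(sum(pr$profiles$g1) + unname(pr$dropped["out_of_range"]),
               n_reads)
})

test_that("TPM closed forms and normalization invariant", {
  expect_equal(unname(compute_tpm(c(g = 7), c(g = 300))), 1e6)
  # equal counts, lengths L and 2L -> 2/3 and 1/3 of a million
  tpm <- compute_tpm(c(a = 10, b = 10), c(a = 500, b = 1000))
  expect_equal(unname(tpm), c(2 / 3, 1 / 3) * 1e6, tolerance = 1e-12)
  set.seed(9)
  cts <- stats::setNames(rpois(50, 100), paste0("g", 1:50))
  lens <- stats::setNames(sample(300:3000, 50), paste0("g", 1:50))
  expect_equal(sum(compute_tpm(cts, lens)), 1e6, tolerance = 1e-6)
  expect_error(compute_tpm(c(a = 0, b = 0), c(a = 10, b = 10)), "undefined")
})

test_that("ribosome density is the element-wise TPM ratio with a floor", {
  set.seed(10)
  genes <- paste0("g", 1:50)
  rpf <- stats::setNames(runif(50, 1, 100), genes)
  mrna <- stats::setNames(runif(50, 0.5, 100), genes)
  d <- compute_ribosome_density(rpf, mrna, min_mrna_tpm = 1)
  for (i in seq_len(50)) {        # independent division loop
    expected <- if (mrna[genes[i]] >= 1) rpf[genes[i]] / mrna[genes[i]]
                else NA_real_
    expect_equal(d$density[d$gene_id == genes[i]], unname(expected))
  }
  expect_error(compute_ribosome_density(c(a = 1), c(b = 1)), "disjoint")
})

test_that("RCDT is 1 for uniform occupancy and respects the filter", {
  cl <- random_codon_list(5, 120)
  profiles <- lapply(cl, function(cods) rep(4L, length(cods)))
  pr <- structure(list(profiles = profiles,
                       n_codons = vapply(cl, length, 1L),
                       dropped = c(unknown_gene = 0L, bad_length = 0L,
                                   out_of_range = 0L),
                       n_assigned = sum(unlist(profiles))),
                  class = "occupancy_profiles")
  tab <- compute_rcdt(pr, cl, filter = list(min_mean = 0.5, min_total = 64))
  expect_true(all(abs(tab$rcdt - 1) < 1e-12))
  expect_equal(tab$n_genes_used, 5L)
  # a gene with insufficient reads is excluded
  profiles$g0001 <- rep(0L, length(cl$g0001))
  pr$profiles <- profiles
  tab2 <- compute_rcdt(pr, cl, filter = list(min_mean = 0.5, min_total = 64))
  expect_equal(tab2$n_genes_used, 4L)
  # no gene passing -> error
  expect_error(compute_rcdt(pr, cl,
                            filter = list(min_mean = 1e6, min_total = 1e9)),
               "no gene")
})

test_that("per-gene mean relative occupancy is exactly 1", {
  set.seed(21)
  cl <- random_codon_list(10, 150)
  pr <- planted_profiles(cl, stats::setNames(runif(61, 0.5, 3),
                                             GC$sense_codons), depth = 5)
  trim <- c(head = 15, tail = 5)
  for (id in names(cl)) {
    counts <- pr$profiles[[id]]
    win <- (trim[[1]] + 1):(length(counts) - trim[[2]])
    r <- counts[win] / mean(counts[win])
    expect_equal(mean(r), 1, tolerance = 1e-12)
  }
})

test_that("RCDT recovers a single planted slow codon", {
  set.seed(77)
  dwell <- stats::setNames(rep(1, 61), GC$sense_codons)
  dwell[["CGG"]] <- 2.0
  cl <- random_codon_list(200, 300)
  pr <- planted_profiles(cl, dwell, depth = 50)
  tab <- compute_rcdt(pr, cl)
  ratio <- tab$rcdt[["CGG"]] / median(tab$rcdt[names(tab$rcdt) != "CGG"])
  expect_gt(ratio, 1.9)
  expect_lt(ratio, 2.1)
})

test_that("stratified RCDT: single full stratum equals the plain table", {
  set.seed(31)
  cl <- random_codon_list(30, 200)
  pr <- planted_profiles(cl, stats::setNames(runif(61, 0.5, 3),
                                             GC$sense_codons), depth = 10)
  plain <- compute_rcdt(pr, cl)
  st <- compute_rcdt_stratified(pr, cl, strata = list(all = c(0, Inf)))
  expect_equal(st$all$rcdt, plain$rcdt, tolerance = 1e-12)
  # empty stratum warns and is omitted
  expect_warning(
    st2 <- compute_rcdt_stratified(pr, cl,
                                   strata = list(long = c(600, Inf),
                                                 short = c(0, 300))),
    "empty")
  expect_named(st2, "short")
})

test_that("delta_rcdt arithmetic and codon intersection", {
  mk <- function(v) structure(list(condition_label = "x", stratum = "all",
                                   rcdt = v,
                                   n_occurrences = stats::setNames(
                                     rep(10L, length(v)), names(v)),
                                   n_genes_used = 1L,
                                   coverage_filter = list(), aggregate = "pooled"),
                              class = "rcdt_table")
  a <- mk(c(AAA = 1.2, AAG = 0.8, TTT = 1.0))
  expect_equal(delta_rcdt(a, a), c(AAA = 0, AAG = 0, TTT = 0))
  b <- mk(c(AAA = 1.0, AAG = 0.6))
  expect_equal(delta_rcdt(a, b), c(AAA = 0.2, AAG = 0.2))
  expect_false("TTT" %in% names(delta_rcdt(a, b)))
  expect_error(delta_rcdt(a, mk(c(GGG = 1))), "share no codons")
})

test_that("planted relative-dwell shift is recovered by delta_rcdt", {
  # two planted dwell vectors whose *relative* profiles differ by a known
  # pattern: condition b compresses dwell deviations by half
  set.seed(55)
  dwell_a <- stats::setNames(runif(61, 0.5, 3), GC$sense_codons)
  dwell_b <- 1 + (dwell_a - mean(dwell_a)) * 0.5
  cl <- random_codon_list(150, 250)
  ta <- compute_rcdt(planted_profiles(cl, dwell_a, depth = 30), cl)
  tb <- compute_rcdt(planted_profiles(cl, dwell_b, depth = 30), cl)
  dl <- delta_rcdt(ta, tb)
  # slow codons get faster (positive delta), fast codons slower
  slow <- names(dwell_a)[dwell_a > quantile(dwell_a, 0.8)]
  fast <- names(dwell_a)[dwell_a < quantile(dwell_a, 0.2)]
  expect_true(all(dl[slow] > 0))
  expect_true(all(dl[fast] < 0))
})

test_that("replicate pooling sums counts and totals", {
  cl <- random_codon_list(3, 60)
  set.seed(3)
  d <- stats::setNames(rep(1, 61), GC$sense_codons)
  p1 <- planted_profiles(cl, d, depth = 2)
  p2 <- planted_profiles(cl, d, depth = 2)
  pooled <- pool_profiles(list(p1, p2))
  expect_equal(pooled$profiles$g0001, p1$profiles$g0001 + p2$profiles$g0001)
  expect_equal(pooled$n_assigned, p1$n_assigned + p2$n_assigned)
})
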