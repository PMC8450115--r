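# scanning windows, grouping, differential classification

make_feature_table <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(gene_id = sprintf("g%04d", 1:n),
             tai = runif(n, 0.2, 0.9),
             length_aa = sample(60:2000, n, replace = TRUE),
             abundance = 10^runif(n, 2, 6),
             cbi = runif(n, -0.2, 0.9),
             stringsAsFactors = FALSE)
}

test_that("a single window spanning all genes equals the whole-set Pearson r", {
  tab <- make_feature_table(200)
  ws <- scanning_window_correlation(tab, "tai", "length_aa", "abundance",
                                    window = 200, transform_y = "log10")
  expect_equal(nrow(ws), 1)
  expect_equal(ws$statistic,
               naive_pearson(tab$length_aa, log10(tab$abundance)),
               tolerance = 1e-12)
  expect_equal(ws$n_effective, 200)
})

test_that("exact linear dependence gives r = -1 in every window", {
  tab <- make_feature_table(300)
  tab$abundance <- -2 * tab$length_aa
  ws <- scanning_window_correlation(tab, "tai", "length_aa", "abundance",
                                    window = 50, step = 10)
  expect_true(all(abs(ws$statistic + 1) < 1e-12))
})

test_that("window statistics equal naive recomputation on materialized windows", {
  tab <- make_feature_table(800, seed = 3)
  w <- 100L; s <- 7L
  ws <- scanning_window_correlation(tab, "tai", "length_aa", "abundance",
                                    window = w, step = s,
                                    transform_y = "log10")
  ord <- tab[order(tab$tai, tab$gene_id), ]
  set.seed(4)
  for (k in sample(nrow(ws), 20)) {
    start <- (ws$window_index[k] - 1L) * s + 1L
    idx <- start:(start + w - 1L)
    expect_equal(ws$statistic[k],
                 naive_pearson(ord$length_aa[idx], log10(ord$abundance[idx])),
                 tolerance = 1e-12)
    expect_equal(ws$center_metric[k], mean(ord$tai[idx]), tolerance = 1e-12)
  }
})

test_that("window errors and degeneracies", {
  tab <- make_feature_table(50)
  expect_error(scanning_window_correlation(tab, "tai", "length_aa",
                                           "abundance", window = 51),
               "exceeds")
  tab$length_aa <- 500      # zero variance -> NA statistic, no exception
  ws <- scanning_window_correlation(tab, "tai", "length_aa", "abundance",
                                    window = 50)
  expect_true(is.na(ws$statistic))
})

test_that("subset_correlation matches the whole set and rejects tiny subsets", {
  tab <- make_feature_table(400, seed = 6)
  full <- subset_correlation(tab, tai > -Inf, "length_aa", "abundance",
                             transform_y = "log10")
  expect_equal(full$r, naive_pearson(tab$length_aa, log10(tab$abundance)),
               tolerance = 1e-12)
  expect_equal(full$n, 400)
  expect_error(subset_correlation(tab, tai > 100, "length_aa", "abundance"),
               "< 3")
  # string filter expressions work too (CLI path)
  hi <- subset_correlation(tab, "cbi > 0.5", "length_aa", "abundance",
                           transform_y = "log10")
  expect_equal(hi$n, sum(tab$cbi > 0.5))
})

test_that("CBI x length grouping satisfies its defining predicates", {
  tab <- make_feature_table(4000, seed = 8)
  grp <- group_genes_by_cbi_length(tab, cbi_high = 0.3, cbi_low = 0.15,
                                   group_size = 500)
  expect_true(all(lengths(grp) == 500))
  hi <- tab[tab$cbi >= 0.3, ]
  lo <- tab[tab$cbi <= 0.15, ]
  expect_true(all(tab$cbi[match(grp$long_high_cbi, tab$gene_id)] >= 0.3))
  expect_true(all(tab$cbi[match(grp$short_low_cbi, tab$gene_id)] <= 0.15))
  # the selected long genes dominate the stratum's length distribution
  cut_len <- sort(hi$length_aa, decreasing = TRUE)[500]
  expect_true(all(tab$length_aa[match(grp$long_high_cbi,
                                      tab$gene_id)] >= cut_len))
  expect_length(intersect(grp$long_high_cbi, grp$short_high_cbi), 0)
  # deterministic under equal lengths: falls back to gene_id order
  tab2 <- tab; tab2$length_aa <- 100
  g1 <- group_genes_by_cbi_length(tab2, group_size = 100)
  g2 <- group_genes_by_cbi_length(tab2[sample(nrow(tab2)), ],
                                  group_size = 100)
  expect_identical(g1$long_high_cbi, g2$long_high_cbi)
  expect_error(group_genes_by_cbi_length(tab, group_size = 1e6),
               "group_size")
})

test_that("differential density: identity inputs, BH hand example, partition", {
  set.seed(12)
  m <- matrix(runif(40, 0.5, 2), nrow = 10,
              dimnames = list(paste0("g", 1:10), NULL))
  res <- differential_density(m, m)
  expect_true(all(res$results$fold_change == 1))
  expect_true(all(res$results$call == "ns"))
  # BH step-up on {0.01, 0.02, 0.03, 0.04} with m = 4 -> all 0.04
  # (frozen hand application of the step-up rule)
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  # calls partition the tested set
  a <- matrix(rnorm(40, 10, 0.5), 10,
              dimnames = list(paste0("g", 1:10), NULL))
  b <- a * rep(c(0.2, 1, 5), length.out = 10)
  r2 <- differential_density(a, b)$results
  expect_equal(sum(r2$call == "down") + sum(r2$call == "up") +
                 sum(r2$call == "ns"), nrow(r2))
  # BH monotone non-decreasing in raw p order, <= 1
  o <- order(r2$p_value)
  expect_true(all(diff(r2$fdr[o]) >= -1e-12))
  expect_true(all(r2$fdr <= 1))
})

test_that("degenerate and excluded genes are handled by convention", {
  a <- matrix(c(1, 1, 1, 1,
                0, 0, 0, 0,
                2, 2, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("same", "zeroA", "diff"), NULL))
  b <- matrix(c(1, 1, 1, 1,
                1, 1, 1, 1,
                4, 4, 4, 4), nrow = 3, byrow = TRUE,
              dimnames = list(c("same", "zeroA", "diff"), NULL))
  res <- differential_density(a, b)
  expect_equal(res$excluded, "zeroA")
  r <- res$results
  expect_equal(r$p_value[r$gene_id == "same"], 1)    # equal, no variance
  expect_equal(r$p_value[r$gene_id == "diff"], 0)    # unequal, no variance
})

test_that("planted down/up mixture recovers its split among significant calls", {
  set.seed(19)
  n <- 2000
  ratio <- ifelse(runif(n) < 0.9, 0.4, 2.5)
  base <- runif(n, 0.5, 2)
  a <- matrix(rep(base, 4) * (1 + rnorm(4 * n, 0, 0.1)), n,
              dimnames = list(sprintf("g%04d", 1:n), NULL))
  b <- matrix(rep(base * ratio, 4) * (1 + rnorm(4 * n, 0, 0.1)), n,
              dimnames = list(sprintf("g%04d", 1:n), NULL))
  res <- differential_density(a, b, fc_threshold = 2, alpha = 0.05)
  share <- res$significant_share
  planted_down <- mean(ratio == 0.4)
  expect_lt(abs(share[["down"]] - planted_down), 0.05)
})

test_that("proportion curves: null, step construction, and mean length", {
  n <- 400
  tab <- data.frame(gene_id = sprintf("g%04d", 1:n),
                    length_aa = seq_len(n) + 59,
                    fold_change = 1, stringsAsFactors = FALSE)
  pc <- proportion_curves(tab, window = 100, step = 10)
  expect_true(all(pc$decreased$statistic == 0))
  expect_true(all(pc$increased$statistic == 0))
  # constructed step: longest half at fold 0.25
  tab$fold_change <- ifelse(tab$length_aa > median(tab$length_aa), 0.25, 1)
  pc2 <- proportion_curves(tab, window = 100, step = 1)
  expect_equal(pc2$decreased$statistic[1], 0)
  expect_equal(tail(pc2$decreased$statistic, 1), 1)
  expect_true(all(diff(pc2$decreased$statistic) >= 0))
  # constant lengths -> flat ranked-mean-length curve
  tab$length_aa <- 500
  rml <- ranked_mean_length(tab, window = 100, step = 5)
  expect_true(all(rml$statistic == 500))
  expect_error(ranked_mean_length(tab, window = 1000), "exceeds")
})
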