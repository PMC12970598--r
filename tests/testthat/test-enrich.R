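test_that("contingency cells count hits against the reference in the universe", {
  uni <- sprintf("g%03d", 1:100)
  hits <- uni[1:10]
  ref <- gene_set("ref", uni[6:15])  # overlap 5
  ct <- build_contingency(hits, ref, uni)
  expect_equal(c(ct$a, ct$b, ct$c, ct$d), c(5, 5, 5, 85))

  none <- build_contingency(uni[1:10], gene_set("r", uni[50:59]), uni)
  expect_equal(none$a, 0)

  outside <- build_contingency(uni[1:10], gene_set("r", c("zz1", "zz2")), uni)
  expect_equal(c(outside$a, outside$b, outside$c, outside$d), c(0, 10, 0, 90))

  expect_error(build_contingency(c("g001", "nope"), ref, uni),
               class = "edscreen_data_error")
})

test_that("two-sided exact test matches hand enumeration on known tables", {
  flat <- fisher_exact_2sided(list(a = 5, b = 5, c = 5, d = 5))
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p, 1)

  strong <- fisher_exact_2sided(list(a = 3, b = 1, c = 1, d = 3))
  expect_equal(strong$odds_ratio, 9)
  expect_equal(strong$p, 34 / 70, tolerance = 1e-12)

  anti <- fisher_exact_2sided(list(a = 0, b = 5, c = 5, d = 0))
  expect_equal(anti$odds_ratio, 0)
  expect_equal(anti$p, brute_fisher_p(0, 5, 5, 0), tolerance = 1e-12)

  expect_error(fisher_exact_2sided(list(a = 0, b = 0, c = 0, d = 0)),
               class = "edscreen_data_error")
})

test_that("exact p agrees with stats::fisher.test across random tables", {
  set.seed(41)
  for (i in 1:50) {
    t <- as.list(setNames(rpois(4, sample(c(2, 8, 20), 1)),
                          c("a", "b", "c", "d")))
    if (sum(unlist(t)) == 0) next
    ours <- fisher_exact_2sided(t)
    ref <- stats::fisher.test(matrix(unlist(t), 2, byrow = TRUE))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-7)
  }
})

test_that("odds-ratio zero-cell rules and the Haldane variant", {
  inf_or <- fisher_exact_2sided(list(a = 4, b = 0, c = 2, d = 4))
  expect_identical(inf_or$odds_ratio, Inf)
  expect_equal(inf_or$or_haldane, (4.5 * 4.5) / (0.5 * 2.5))
  both0 <- fisher_exact_2sided(list(a = 0, b = 3, c = 0, d = 3))
  expect_true(is.nan(both0$odds_ratio))
})

test_that("enrich_many adjusts across sets and finds a planted enrichment", {
  uni <- sprintf("g%03d", 1:200)
  hits <- uni[1:30]
  one <- enrich_many(hits, list(myset = uni[11:40]), uni)
  expect_equal(one$fdr, one$p)

  dup <- enrich_many(hits, list(s1 = uni[11:40], s2 = uni[11:40]), uni)
  expect_equal(dup$p[1], dup$p[2])
  expect_equal(dup$fdr[1], dup$fdr[2])

  set.seed(42)
  sets <- c(list(planted = c(uni[1:25], uni[150:154])),  # 25/30 hit overlap
            lapply(1:9, function(i) sample(uni, 30)))
  names(sets)[-1] <- sprintf("random%d", 1:9)
  res <- enrich_many(hits, sets, uni)
  expect_equal(res$set[which.min(res$p)], "planted")
  expect_error(enrich_many(hits, list(), uni), class = "edscreen_data_error")
})

test_that("average precision matches hand evaluation and tie rules", {
  expect_equal(precision_recall_auc(c(-3, -2, -1), c(1, 1, 0)), 1)
  expect_equal(precision_recall_auc(c(-2, -1), c(0, 1)), 0.5)
  expect_equal(precision_recall_auc(c(-.9, -.8, -.7, -.6), c(1, 0, 1, 0)),
               5 / 6)
  # invariant under strictly monotone transformation of scores
  set.seed(43)
  sc <- rnorm(40)
  lb <- rbinom(40, 1, 0.3)
  lb[1] <- 1
  expect_equal(precision_recall_auc(sc, lb),
               precision_recall_auc(atan(sc) * 3, lb))
  # ties broken by smaller p then gene id
  tied <- precision_recall_auc(c(-1, -1), c(0, 1), p = c(0.5, 0.1),
                               gene_id = c("b", "a"))
  expect_equal(tied, 1)
  expect_error(precision_recall_auc(1:3, c(0, 0, 0)),
               class = "edscreen_data_error")
})

test_that("permutation null p-values are near-uniform for fine tables", {
  set.seed(44)
  uni <- sprintf("g%04d", 1:1000)
  ref <- gene_set("ref", uni[1:150])
  ps <- replicate(500, {
    hits <- sample(uni, 200)
    fisher_exact_2sided(build_contingency(hits, ref, uni))$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("method comparison reports AUPRC and relative improvements", {
  tb <- tibble::tibble(gene = sprintf("g%02d", 1:20), context = "pan",
                       layer = "mrna", method = "bayesian", n_obs = 50L,
                       rho = seq(-0.9, 0.05, length.out = 20), rho_sd = 0.1,
                       z = -2, p = seq(0.001, 0.5, length.out = 20),
                       fdr = 0.05, status = "ok")
  ref <- gene_set("ref", sprintf("g%02d", 1:5))
  same <- compare_methods_auprc(list(a = tb, b = tb), ref)
  expect_true(all(same$improvement$improvement_pct == 0))
  expect_equal(nrow(same$auprc), 2)
  # 0.26 vs 0.20 -> +30%
  expect_equal(100 * (0.26 - 0.20) / 0.20, 30)
  tb2 <- tb[1:15, ]
  expect_error(compare_methods_auprc(list(a = tb, b = tb2), ref),
               class = "edscreen_data_error")
})

test_that("under contamination at small n the Bayesian ranking holds up", {
  # protein-style screens: per-gene pairwise-complete n varies (7..14 lines)
  # and half the observed entries are corrupted with wide noise; posterior
  # shrinkage pulls the unstable small-n nulls toward zero, so the Bayesian
  # ranking should beat Pearson's in a majority of replicates
  wins <- 0
  for (s in 1:5) {
    fx <- generate_synthetic_depmap(n_lineages = 2, lines_per_lineage = 7,
                                    n_genes = 60, n_planted_pan = 10,
                                    n_planted_lineage = 0,
                                    protein_missing_fraction = 0.35,
                                    mrna_protein_cor = 0.9, seed = 50 + s)
    al <- align_datasets(fx$expr_protein, fx$dep, fx$ann)
    ex <- unclass(al$expr)
    dp <- unclass(al$dep)
    set.seed(60 + s)  # corrupt half the observed entries per gene
    for (g in seq_len(nrow(ex))) {
      obs <- which(!is.na(ex[g, ]))
      idx <- sample(obs, length(obs) %/% 2)
      ex[g, idx] <- mean(ex[g, obs]) + 5 * sd(ex[g, obs]) * rnorm(length(idx))
      dp[g, idx] <- mean(dp[g, ]) + 5 * sd(dp[g, ]) * rnorm(length(idx))
    }
    expr <- omics_matrix(ex, "protein")
    dep <- dependency_matrix(dp)
    tb_b <- run_ed_screen(expr, dep, method = "bayesian",
                          config = mcmc_config(seed = s, min_pairs = 5))
    tb_p <- run_ed_screen(expr, dep, method = "pearson",
                          config = mcmc_config(seed = s, min_pairs = 5))
    ok <- tb_b$gene[tb_b$status == "ok" & tb_p$status == "ok"]
    tb_b <- tb_b[tb_b$gene %in% ok, ]
    tb_p <- tb_p[tb_p$gene %in% ok, ]
    lab <- function(tb) as.integer(tb$gene %in% fx$truth$gene)
    au_b <- precision_recall_auc(tb_b$rho, lab(tb_b), p = tb_b$p,
                                 gene_id = tb_b$gene)
    au_p <- precision_recall_auc(tb_p$rho, lab(tb_p), p = tb_p$p,
                                 gene_id = tb_p$gene)
    wins <- wins + (au_b >= au_p)
  }
  expect_gte(wins, 3)
})
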