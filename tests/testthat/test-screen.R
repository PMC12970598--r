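make_mats <- function(genes, lines, seed = 1) {
  set.seed(seed)
  e <- matrix(rnorm(length(genes) * length(lines)), length(genes),
              dimnames = list(genes, lines))
  d <- matrix(rnorm(length(genes) * length(lines)), length(genes),
              dimnames = list(genes, lines))
  list(expr = omics_matrix(e, "mrna"), dep = dependency_matrix(d))
}

test_that("align_datasets intersects cell lines and genes deterministically", {
  m1 <- make_mats(c("g1", "g2"), c("A", "B", "C"))
  m2 <- make_mats(c("g2", "g3"), c("B", "C", "D"), seed = 2)
  ann <- lineage_annotation(c("A", "B", "C", "D"), rep("lung", 4))
  al <- align_datasets(m1$expr, m2$dep, ann)
  expect_equal(colnames(al$expr), c("B", "C"))
  expect_equal(rownames(al$expr), "g2")
  expect_equal(rownames(al$dep), "g2")
  expect_equal(al$ann$cell_line, c("B", "C"))

  disjoint <- make_mats("g1", c("X", "Y"))
  expect_error(align_datasets(m1$expr, disjoint$dep, ann),
               "cell lines", class = "edscreen_data_error")
  other_genes <- make_mats(c("h1", "h2"), c("A", "B"))
  expect_error(align_datasets(m1$expr, other_genes$dep, ann),
               "genes", class = "edscreen_data_error")
})

test_that("lineage filter boundary is inclusive at min_cells", {
  ann <- lineage_annotation(sprintf("c%02d", 1:13),
                            c(rep("seven", 7), rep("six", 6)))
  kept <- suppressMessages(filter_lineages(ann, ann$cell_line, min_cells = 7))
  expect_equal(kept, "seven")
  all_kept <- suppressMessages(filter_lineages(ann, ann$cell_line, min_cells = 2))
  expect_equal(all_kept, c("seven", "six")[order(c("seven", "six"))])
  expect_error(filter_lineages(ann, ann$cell_line, min_cells = 1))
})

test_that("screen emits one row per gene per context with valid per-context FDR", {
  fx <- small_fixture(seed = 31)
  al <- align_datasets(fx$expr_mrna, fx$dep, fx$ann)
  lin <- suppressMessages(filter_lineages(al$ann, colnames(al$expr)))
  tb <- run_ed_screen(al$expr, al$dep, al$ann, contexts = c("pan", lin),
                      method = "pearson")
  expect_equal(nrow(tb), nrow(al$expr) * (1 + length(lin)))
  expect_equal(unname(table(tb$context)[c("pan", lin)]),
               rep(nrow(al$expr), 1 + length(lin)), ignore_attr = TRUE)
  for (ctx in unique(tb$context)) {
    sub <- tb[tb$context == ctx, ]
    expect_identical(sub$fdr, bh_fdr(sub$p))
  }
})

test_that("planted genes occupy the most-negative rho ranks", {
  fx <- generate_synthetic_depmap(n_lineages = 2, lines_per_lineage = 20,
                                  n_genes = 120, n_planted_pan = 12,
                                  n_planted_lineage = 0, seed = 32)
  al <- align_datasets(fx$expr_mrna, fx$dep, fx$ann)
  tb <- run_ed_screen(al$expr, al$dep, method = "pearson")
  top <- tb$gene[order(tb$rho)][1:12]
  expect_gte(sum(top %in% fx$truth$gene), 11)
})

test_that("bayesian screen rows match single fits at the derived seed", {
  fx <- small_fixture(seed = 33, n_genes = 12)
  al <- align_datasets(fx$expr_mrna, fx$dep, fx$ann)
  cfg <- mcmc_config(seed = 40)
  tb <- run_ed_screen(al$expr, al$dep, method = "bayesian", config = cfg)
  for (g in c(5L, 10L)) {
    seed_g <- edscreen:::gene_seeds(cfg$seed, 1, g)
    ps <- paired_sample(rownames(al$expr)[g], unclass(al$expr)[g, ],
                        unclass(al$dep)[g, ])
    f <- fit_bayesian_correlation(ps, config = mcmc_config(seed = seed_g))
    expect_equal(tb$rho[g], f$rho_mean, tolerance = 1e-12)
    expect_equal(tb$rho_sd[g], f$rho_sd, tolerance = 1e-12)
  }
})

test_that("degenerate genes keep their rows with status flags", {
  m <- make_mats(sprintf("g%d", 1:4), sprintf("c%d", 1:8), seed = 3)
  e <- unclass(m$expr)
  e["g2", ] <- 7  # constant expression
  expr <- omics_matrix(e, "mrna")
  tb <- run_ed_screen(expr, m$dep, method = "pearson",
                      config = light_config())
  expect_equal(nrow(tb), 4)
  expect_equal(tb$status[tb$gene == "g2"], "constant_input")
  expect_true(is.na(tb$rho[tb$gene == "g2"]))

  tiny <- make_mats(sprintf("g%d", 1:3), sprintf("c%d", 1:4), seed = 4)
  tb2 <- run_ed_screen(tiny$expr, tiny$dep, method = "bayesian",
                       config = light_config())
  expect_true(all(tb2$status == "low_n"))
  expect_true(all(is.na(tb2$rho)))
})

test_that("identically permuting cell lines leaves rho unchanged", {
  m <- make_mats(sprintf("g%d", 1:10), sprintf("c%d", 1:15), seed = 5)
  tb1 <- run_ed_screen(m$expr, m$dep, method = "pearson")
  perm <- c(8, 3, 11, 1, 14, 2, 15, 9, 4, 13, 5, 10, 6, 12, 7)
  expr2 <- omics_matrix(unclass(m$expr)[, perm], "mrna")
  dep2 <- dependency_matrix(unclass(m$dep)[, perm])
  tb2 <- run_ed_screen(expr2, dep2, method = "pearson")
  expect_equal(tb1$rho, tb2$rho)
})

test_that("protein screens report pairwise-complete n_obs per gene", {
  fx <- small_fixture(seed = 34)
  al <- align_datasets(fx$expr_protein, fx$dep, fx$ann)
  tb <- run_ed_screen(al$expr, al$dep, method = "pearson")
  miss <- rowSums(is.na(unclass(al$expr)))
  expect_equal(tb$n_obs, as.integer(ncol(al$expr) - miss))
  expect_equal(unique(tb$layer), "protein")
})

test_that("significance calls use strict thresholds in both directions", {
  tb <- tibble::tibble(
    gene = sprintf("g%d", 1:5), context = "pan", layer = "mrna",
    method = "bayesian", n_obs = 50L,
    rho = c(-0.30, -0.25, -0.60, 0.40, -0.40),
    rho_sd = 0.1, z = -3, p = 0.001,
    fdr = c(0.04, 0.01, 0.06, 0.01, 0.04),
    status = c("ok", "ok", "ok", "ok", "not_converged"))
  kept <- call_significant(tb)
  expect_equal(kept$gene, "g1")  # g2 boundary rho, g3 fdr, g4 sign, g5 status
  pos <- call_significant(tb, rho_min = 0.25)
  expect_equal(pos$gene, "g4")
})

test_that("specificity is rho_in minus the mean of other lineages", {
  tb <- tibble::tibble(
    gene = rep(c("A", "B", "C"), each = 3),
    context = rep(c("L1", "L2", "L3"), 3), layer = "mrna",
    method = "bayesian", n_obs = 20L,
    rho = c(-0.8, -0.1, -0.1, -0.3, -0.3, -0.3, -0.5, -0.2, -0.2),
    rho_sd = 0.1, z = -2, p = 0.01, fdr = 0.02, status = "ok")
  sp <- lineage_specificity(tb)
  expect_equal(sp$specificity[sp$gene == "A" & sp$lineage == "L1"], -0.7)
  expect_equal(sp$specificity[sp$gene == "B"], rep(0, 3))
  # gene with only two lineages: one other estimate -> undefined
  tb2 <- tb[tb$gene != "C" | tb$context != "L3", ]
  sp2 <- lineage_specificity(tb2)
  expect_false(any(sp2$defined[sp2$gene == "C"]))
  expect_true(all(is.na(sp2$specificity[sp2$gene == "C"])))
})

test_that("a gene planted in one lineage scores specific there only", {
  fx <- generate_synthetic_depmap(n_lineages = 4, lines_per_lineage = 50,
                                  n_genes = 80, n_planted_pan = 0,
                                  n_planted_lineage = 4, seed = 35)
  al <- align_datasets(fx$expr_mrna, fx$dep, fx$ann)
  lin <- suppressMessages(filter_lineages(al$ann, colnames(al$expr)))
  tb <- run_ed_screen(al$expr, al$dep, al$ann, contexts = lin,
                      method = "pearson")
  sp <- lineage_specificity(tb)
  tr <- fx$truth
  for (i in seq_len(nrow(tr))) {
    rec <- sp[sp$gene == tr$gene[i], ]
    expect_lt(rec$specificity[rec$lineage == tr$context[i]], -0.3)
    expect_gt(min(rec$specificity[rec$lineage != tr$context[i]]), -0.1)
  }
})

test_that("concordance classes follow the two layers' significance calls", {
  mk <- function(gene, rho, fdr, status = "ok")
    tibble::tibble(gene = gene, context = "pan", layer = "mrna",
                   method = "bayesian", n_obs = 50L, rho = rho, rho_sd = 0.1,
                   z = -3, p = fdr / 2, fdr = fdr, status = status)
  ged <- do.call(rbind, list(mk("TPA", -0.69, 1e-10), mk("MYB", -0.59, 0.01),
                             mk("NUL", -0.05, 0.8), mk("PRT", -0.1, 0.9),
                             mk("BAD", -0.5, 0.01, status = "constant_input")))
  ped <- do.call(rbind, list(mk("TPA", -0.71, 1e-10), mk("MYB", -0.05, 0.9),
                             mk("NUL", -0.02, 0.9), mk("PRT", -0.6, 0.001),
                             mk("BAD", -0.5, 0.01), mk("XTR", -0.4, 0.01)))
  cc <- classify_concordance(ged, ped)
  cls <- setNames(cc$class, cc$gene)
  expect_equal(cls[["TPA"]], "both")
  expect_equal(cls[["MYB"]], "mrna_only")
  expect_equal(cls[["NUL"]], "neither")
  expect_equal(cls[["PRT"]], "protein_only")
  expect_equal(cls[["BAD"]], "untested")  # unusable mRNA estimate
  expect_equal(cls[["XTR"]], "untested")  # absent from the mRNA layer
})
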