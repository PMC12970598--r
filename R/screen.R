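#' Align expression, dependency and lineage data
#'
#' Restricts the three sources to their common cell lines and the genes
#' present in both matrices, in deterministic (sorted) order. Run this before
#' [run_ed_screen()].
#'
#' @param expr An [omics_matrix()].
#' @param dep A [dependency_matrix()].
#' @param ann A [lineage_annotation()].
#' @return A list with elements `expr`, `dep`, `ann`, all restricted and
#'   ordered identically.
#' @export
align_datasets <- function(expr, dep, ann) {
  stopifnot(inherits(expr, "omics_matrix"), inherits(dep, "dependency_matrix"))
  lines <- sort(intersect(intersect(colnames(expr), colnames(dep)),
                          ann$cell_line))
  if (length(lines) == 0) {
    data_error("align_datasets: no cell lines shared by expression, dependency and annotation")
  }
  genes <- sort(intersect(rownames(expr), rownames(dep)))
  if (length(genes) == 0) {
    data_error("align_datasets: no genes shared by expression and dependency")
  }
  layer <- attr(expr, "layer")
  expr2 <- omics_matrix(unclass(expr)[genes, lines, drop = FALSE], layer)
  dep2 <- dependency_matrix(unclass(dep)[genes, lines, drop = FALSE])
  ann2 <- ann[ann$cell_line %in% lines, , drop = FALSE]
  ann2 <- ann2[order(ann2$cell_line), , drop = FALSE]
  list(expr = expr2, dep = dep2, ann = ann2)
}

#' Lineages with enough aligned cell lines
#'
#' Keeps lineages represented by at least `min_cells` aligned cell lines
#' (the boundary is inclusive: a lineage with exactly `min_cells` lines is
#' retained). Small lineages give unstable correlation estimates, hence the
#' default of 7.
#'
#' @param ann A [lineage_annotation()].
#' @param aligned_lines Character vector of cell-line ids retained by
#'   [align_datasets()].
#' @param min_cells Minimum aligned lines per lineage (>= 2).
#' @return Character vector of retained lineage names (sorted); per-lineage
#'   counts are reported via `message()`.
#' @export
filter_lineages <- function(ann, aligned_lines, min_cells = 7) {
  stopifnot(min_cells >= 2)
  sub <- ann[ann$cell_line %in% aligned_lines, , drop = FALSE]
  counts <- table(sub$lineage)
  kept <- sort(names(counts)[counts >= min_cells])
  message(sprintf("filter_lineages: %d/%d lineages with >= %d aligned lines (%s)",
                  length(kept), length(counts), min_cells,
                  paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                        collapse = ", ")))
  kept
}

#' Run the expression-driven dependency screen
#'
#' For every gene and requested context (the pan-lineage pool and/or single
#' lineages), builds the pairwise-complete paired sample of expression and
#' dependency over that context's cell lines, estimates the correlation with
#' the chosen method, and attaches a z statistic, p-value and
#' Benjamini-Hochberg FDR. Bayesian rows use the posterior mean/SD and the
#' posterior z test; Pearson/Spearman rows use the t-distribution transform.
#' Degenerate genes are kept with a status flag, so the output always has
#' one row per gene per context.
#'
#' @param expr,dep,ann Aligned inputs (see [align_datasets()]).
#' @param contexts Character vector: `"pan"` and/or lineage names present in
#'   `ann` (lineages should have passed [filter_lineages()]).
#' @param method `"bayesian"`, `"pearson"` or `"spearman"`.
#' @param prior,config Model settings for the Bayesian method; `config$seed`
#'   also seeds the per-gene chains deterministically, and
#'   `config$min_pairs` is the minimum complete pairs for any method.
#' @param fdr_scope `"context"` (BH within each context; default) or
#'   `"pooled"` (one BH across all rows).
#' @return A tibble (the ED table) with columns `gene`, `context`, `layer`,
#'   `method`, `n_obs`, `rho`, `rho_sd`, `z`, `p`, `fdr`, `status`. Rows
#'   with `status != "ok"` carry `NA` estimates.
#' @export
run_ed_screen <- function(expr, dep, ann = NULL, contexts = "pan",
                          method = c("bayesian", "pearson", "spearman"),
                          prior = prior_spec(), config = mcmc_config(),
                          fdr_scope = c("context", "pooled")) {
  method <- match.arg(method)
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(inherits(expr, "omics_matrix"), inherits(dep, "dependency_matrix"))
  if (!identical(rownames(expr), rownames(dep)) ||
      !identical(colnames(expr), colnames(dep))) {
    data_error("run_ed_screen: expr and dep are not aligned; run align_datasets() first")
  }
  lineage_ctx <- setdiff(contexts, "pan")
  if (length(lineage_ctx) > 0 && is.null(ann)) {
    usage_error("run_ed_screen: lineage contexts require a lineage annotation")
  }
  for (ctx in lineage_ctx) {
    if (!any(ann$lineage == ctx)) {
      data_error(sprintf("run_ed_screen: unknown context '%s'", ctx))
    }
  }
  layer <- attr(expr, "layer")
  X <- unclass(expr)
  Y <- unclass(dep)
  res <- vector("list", length(contexts))
  for (i in seq_along(contexts)) {
    ctx <- contexts[i]
    lines <- if (ctx == "pan") colnames(X) else
      intersect(colnames(X), ann$cell_line[ann$lineage == ctx])
    if (length(lines) == 0) {
      data_error(sprintf("run_ed_screen: context '%s' has no aligned cell lines", ctx))
    }
    res[[i]] <- screen_one_context(X[, lines, drop = FALSE],
                                   Y[, lines, drop = FALSE],
                                   ctx, i, layer, method, prior, config)
  }
  out <- dplyr::bind_rows(res)
  if (fdr_scope == "pooled") {
    out$fdr <- bh_fdr(out$p)
  } else {
    out <- dplyr::mutate(dplyr::group_by(out, .data$context),
                         fdr = bh_fdr(.data$p))
    out <- dplyr::ungroup(out)
    # restore row order: contexts in requested order, genes in matrix order
    out <- out[order(match(out$context, contexts),
                     match(out$gene, rownames(X))), ]
  }
  out <- dplyr::relocate(out, "gene", "context", "layer", "method", "n_obs",
                         "rho", "rho_sd", "z", "p", "fdr", "status")
  attr(out, "method") <- method
  attr(out, "layer") <- layer
  out
}

# One context: vectorized pairwise-complete sufficient statistics across all
# genes, then a single batched MCMC call for the non-degenerate ones.
screen_one_context <- function(X, Y, ctx, ctx_index, layer, method,
                               prior, config) {
  genes <- rownames(X)
  G <- length(genes)
  M <- !is.na(X) & !is.na(Y)
  X0 <- ifelse(M, X, 0)
  Y0 <- ifelse(M, Y, 0)
  n <- rowSums(M)
  sx <- rowSums(X0); sy <- rowSums(Y0)
  sxx <- rowSums(X0 * X0); syy <- rowSums(Y0 * Y0); sxy <- rowSums(X0 * Y0)
  # per-gene sample variances and correlation over complete pairs
  vx <- (sxx - sx^2 / pmax(n, 1)) / pmax(n - 1, 1)
  vy <- (syy - sy^2 / pmax(n, 1)) / pmax(n - 1, 1)
  r <- (sxy - sx * sy / pmax(n, 1)) / pmax(n - 1, 1) / sqrt(pmax(vx * vy, 0))

  status <- rep("ok", G)
  status[n < config$min_pairs] <- "low_n"
  const <- n >= config$min_pairs & (vx <= 0 | vy <= 0 | !is.finite(r))
  status[const] <- "constant_input"
  fit_idx <- which(status == "ok")

  rho <- rho_sd <- z <- p <- rep(NA_real_, G)
  if (method == "bayesian") {
    if (length(fit_idx) > 0) {
      suff <- cbind(n[fit_idx], 0, 0, n[fit_idx] - 1, n[fit_idx] - 1,
                    (n[fit_idx] - 1) * r[fit_idx])
      seeds <- gene_seeds(config$seed, ctx_index, fit_idx)
      pc <- prior_codes(prior)
      fits <- cpp_fit_batch(suff, seeds,
                            prior$mu_scale, prior$sigma_scale,
                            pc$rho_code, pc$shrink_k,
                            config$n_chains, config$n_iter, config$n_burnin,
                            config$thin, config$adapt, config$target_accept)
      conv <- is.finite(fits[, "rhat"]) & is.finite(fits[, "ess"]) &
        fits[, "rhat"] < config$rhat_threshold &
        fits[, "ess"] >= config$ess_threshold
      status[fit_idx[!conv]] <- "not_converged"
      ok <- fit_idx[conv]
      okf <- which(conv)
      rho[ok] <- fits[okf, "rho_mean"]
      rho_sd[ok] <- fits[okf, "rho_sd"]
      z[ok] <- rho[ok] / rho_sd[ok]
      p[ok] <- p_value_from_z_safe(z[ok])
    }
  } else {
    for (g in fit_idx) {
      keep <- M[g, ]
      rg <- if (method == "pearson") r[g] else {
        stats::cor(rank(X[g, keep], ties.method = "average"),
                   rank(Y[g, keep], ties.method = "average"))
      }
      if (!is.finite(rg)) { status[g] <- "constant_input"; next }
      tp <- cor_t_pvalue(rg, n[g])
      rho[g] <- rg
      z[g] <- tp[["stat"]]
      p[g] <- tp[["p"]]
    }
  }
  tibble::tibble(gene = genes, context = ctx, layer = layer, method = method,
                 n_obs = as.integer(n), rho = rho, rho_sd = rho_sd,
                 z = z, p = p, fdr = NA_real_, status = status)
}

# per-gene chain seed, derived so identical (seed, context position, gene
# position) always reproduces the same fit; kept within 32-bit integer range
gene_seeds <- function(seed, ctx_index, gene_index) {
  (as.numeric(seed) + 1000003 * (ctx_index - 1) + 131 * gene_index) %%
    2147483629
}

p_value_from_z_safe <- function(z) 2 * stats::pnorm(-abs(z))

#' Select significant expression-driven dependencies
#'
#' Keeps rows passing the screen's significance rule: `rho < rho_max` and
#' `fdr < fdr_max` (both strict) with status `"ok"`. Setting `rho_min`
#' instead selects positive correlations (genes whose *loss* of expression
#' confers vulnerability, the CYCLOPS-type pattern).
#'
#' @param table An ED table from [run_ed_screen()].
#' @param rho_max Upper bound on `rho` (negative; default -0.25).
#' @param fdr_max Upper bound on FDR (default 0.05).
#' @param rho_min If non-`NULL`, select `rho > rho_min` instead of
#'   `rho < rho_max`.
#' @return The subset of rows passing the rule.
#' @export
call_significant <- function(table, rho_max = -0.25, fdr_max = 0.05,
                             rho_min = NULL) {
  stopifnot(all(c("rho", "fdr", "status") %in% names(table)))
  keep <- table$status == "ok" & !is.na(table$fdr) & table$fdr < fdr_max
  keep <- keep & if (is.null(rho_min)) table$rho < rho_max
                 else table$rho > rho_min
  table[which(keep), , drop = FALSE]
}

#' Lineage-specificity scores
#'
#' For each (gene, lineage) with a usable estimate, the specificity score is
#' the gene's `rho` within that lineage minus its mean `rho` across all
#' other lineages with usable estimates. Strongly negative scores flag
#' dependencies restricted to one tissue. At least `min_other` other-lineage
#' estimates are required for a defined score.
#'
#' @param per_lineage An ED table of lineage contexts (no `"pan"` rows are
#'   used).
#' @param gene_id,lineage Optional filters restricting the output.
#' @param min_other Minimum number of other-lineage estimates (default 2).
#' @return A tibble with columns `gene`, `lineage`, `rho_in`,
#'   `rho_out_mean`, `specificity`, `n_other_lineages`, `defined`. Rows with
#'   too few other-lineage estimates have `defined = FALSE` and `NA` scores.
#' @export
lineage_specificity <- function(per_lineage, gene_id = NULL, lineage = NULL,
                                min_other = 2) {
  ok <- per_lineage[per_lineage$status == "ok" &
                      per_lineage$context != "pan", , drop = FALSE]
  if (nrow(ok) == 0) {
    data_error("lineage_specificity: no usable lineage-level estimates")
  }
  out <- dplyr::reframe(
    dplyr::group_by(ok, gene = .data$gene),
    lineage = .data$context,
    rho_in = .data$rho,
    rho_out_mean = (sum(.data$rho) - .data$rho) /
      pmax(dplyr::n() - 1L, 1L),
    n_other_lineages = dplyr::n() - 1L
  )
  out$defined <- out$n_other_lineages >= min_other
  out$rho_out_mean[!out$defined] <- NA_real_
  out$specificity <- out$rho_in - out$rho_out_mean
  if (!is.null(gene_id)) out <- out[out$gene %in% gene_id, , drop = FALSE]
  if (!is.null(lineage)) out <- out[out$lineage %in% lineage, , drop = FALSE]
  dplyr::relocate(out, "gene", "lineage", "rho_in", "rho_out_mean",
                  "specificity", "n_other_lineages", "defined")
}

#' Classify mRNA/protein concordance of expression-driven dependencies
#'
#' Per gene, compares the mRNA-layer and protein-layer screen calls in a
#' shared context and classifies the gene as significant in `both`,
#' `mrna_only`, `protein_only`, `neither`, or `untested` (absent from one
#' layer, or no usable estimate there).
#'
#' @param ged ED table of the mRNA layer.
#' @param ped ED table of the protein layer.
#' @param rho_max,fdr_max Significance rule, as in [call_significant()].
#' @param context Context label shared by both tables (default `"pan"`).
#' @return A tibble with columns `gene`, `context`, `ged_rho`, `ged_fdr`,
#'   `ped_rho`, `ped_fdr`, `class`.
#' @export
classify_concordance <- function(ged, ped, rho_max = -0.25, fdr_max = 0.05,
                                 context = "pan") {
  g <- ged[ged$context == context, c("gene", "rho", "fdr", "status")]
  p <- ped[ped$context == context, c("gene", "rho", "fdr", "status")]
  if (nrow(g) == 0 || nrow(p) == 0) {
    data_error(sprintf("classify_concordance: context '%s' missing from a table",
                       context))
  }
  names(g) <- c("gene", "ged_rho", "ged_fdr", "ged_status")
  names(p) <- c("gene", "ped_rho", "ped_fdr", "ped_status")
  m <- dplyr::full_join(g, p, by = "gene")
  sig <- function(rho, fdr) !is.na(rho) & !is.na(fdr) &
    rho < rho_max & fdr < fdr_max
  g_ok <- !is.na(m$ged_status) & m$ged_status == "ok"
  p_ok <- !is.na(m$ped_status) & m$ped_status == "ok"
  g_sig <- g_ok & sig(m$ged_rho, m$ged_fdr)
  p_sig <- p_ok & sig(m$ped_rho, m$ped_fdr)
  cls <- dplyr::case_when(
    !g_ok | !p_ok ~ "untested",
    g_sig & p_sig ~ "both",
    g_sig & !p_sig ~ "mrna_only",
    !g_sig & p_sig ~ "protein_only",
    TRUE ~ "neither"
  )
  tibble::tibble(gene = m$gene, context = context,
                 ged_rho = m$ged_rho, ged_fdr = m$ged_fdr,
                 ped_rho = m$ped_rho, ped_fdr = m$ped_fdr,
                 class = cls)
}
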