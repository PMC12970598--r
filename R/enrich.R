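#' Gene set
#'
#' @param name Set label.
#' @param members Character vector of gene identifiers (deduplicated,
#'   must be non-empty).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, members) {
  members <- unique(as.character(members))
  members <- members[nzchar(members)]
  if (length(members) == 0) data_error(sprintf("gene_set '%s' is empty", name))
  structure(list(name = name, members = members), class = "gene_set")
}

as_gene_set <- function(x, name = "set") {
  if (inherits(x, "gene_set")) x else gene_set(name, x)
}

#' Build the 2x2 contingency table of hits against a reference set
#'
#' Cells: `a` = hits in the reference set, `b` = hits outside it, `c` =
#' reference genes (within the universe) not hit, `d` = the remainder. The
#' reference is intersected with the universe before counting; the universe
#' is all genes quantified in the layer under test.
#'
#' @param hits Character vector of significant genes (must be a subset of
#'   `universe`).
#' @param reference A [gene_set()] or character vector.
#' @param universe Character vector of all tested genes.
#' @return An object of class `contingency_table` with fields `a`, `b`,
#'   `c`, `d`.
#' @export
build_contingency <- function(hits, reference, universe) {
  hits <- unique(as.character(hits))
  universe <- unique(as.character(universe))
  if (!all(hits %in% universe)) {
    data_error("build_contingency: hits must be a subset of the universe")
  }
  ref <- intersect(as_gene_set(reference)$members, universe)
  a <- length(intersect(hits, ref))
  b <- length(hits) - a
  c <- length(ref) - a
  d <- length(universe) - a - b - c
  structure(list(a = a, b = b, c = c, d = d), class = "contingency_table")
}

#' Two-sided Fisher's exact test of a 2x2 table
#'
#' Exact independence test: the p-value sums the hypergeometric
#' probabilities, over all tables with the observed margins, of every table
#' at most as probable as the observed one (the minimum-likelihood two-sided
#' rule, with a small relative tolerance for floating-point ties). The
#' reported odds ratio is the unconditional sample value `(a*d)/(b*c)`;
#' when `b*c = 0` it is `Inf` (or `0` when `a*d = 0` as well as
#' `NaN` when both products vanish). `or_haldane` adds 0.5 to every cell
#' for display; the p-value never uses that correction.
#'
#' @param table A `contingency_table` from [build_contingency()], or a list
#'   with fields `a`, `b`, `c`, `d`.
#' @return A list with `odds_ratio`, `or_haldane` and `p`.
#' @examples
#' fisher_exact_2sided(build_contingency("g1", gene_set("s", "g1"),
#'                                       c("g1", "g2", "g3")))
#' @export
fisher_exact_2sided <- function(table) {
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  N <- a + b + c + d
  if (N == 0) data_error("fisher_exact_2sided: empty table")
  m <- a + c          # reference genes in the universe
  k <- a + b          # hits
  lo <- max(0, k - (N - m))
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, N - m, k)
  p_obs <- dens[support == a]
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  p <- min(p, 1)
  ad <- a * d
  bc <- b * c
  or <- if (bc == 0 && ad == 0) NaN
        else if (bc == 0) Inf
        else ad / bc
  list(odds_ratio = or,
       or_haldane = ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)),
       p = p)
}

#' Enrichment of hits across many gene sets
#'
#' Applies [build_contingency()] and [fisher_exact_2sided()] to each set,
#' then Benjamini-Hochberg adjusts the p-values across sets. The screen's
#' reporting convention flags sets with `odds_ratio > 2` and `fdr < 0.05`
#' as enriched.
#'
#' @param hits Character vector of significant genes.
#' @param gene_sets A list of [gene_set()] objects (or character vectors;
#'   a named list supplies set names).
#' @param universe Character vector of all tested genes.
#' @return A tibble with columns `set`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p`, `fdr`.
#' @export
enrich_many <- function(hits, gene_sets, universe) {
  if (length(gene_sets) == 0) data_error("enrich_many: no gene sets supplied")
  if (inherits(gene_sets, "gene_set")) gene_sets <- list(gene_sets)
  nms <- names(gene_sets)
  rows <- lapply(seq_along(gene_sets), function(i) {
    gs <- as_gene_set(gene_sets[[i]],
                      name = if (!is.null(nms) && nzchar(nms[i])) nms[i]
                             else sprintf("set%d", i))
    ct <- build_contingency(hits, gs, universe)
    ft <- fisher_exact_2sided(ct)
    tibble::tibble(set = gs$name, a = ct$a, b = ct$b, c = ct$c, d = ct$d,
                   odds_ratio = ft$odds_ratio, p = ft$p)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- bh_fdr(out$p)
  out
}

#' Area under the precision-recall curve of a ranked gene list
#'
#' Genes are ranked by score ascending (most negative `rho` first, i.e.
#' strongest expression-driven dependency at the top) and the AUPRC is
#' computed as average precision: the mean, over positives, of the precision
#' at each positive's rank. Ties in score are broken by smaller `p`, then
#' lexicographic gene id, so the value is reproducible; step-function
#' average precision is used rather than trapezoidal interpolation, which
#' overestimates PR area.
#'
#' @param scores Numeric scores (finite), lower = stronger.
#' @param labels Binary labels (1 = in the reference set).
#' @param p Optional p-values used as the first tie-break.
#' @param gene_id Optional gene ids used as the final tie-break.
#' @return Average precision in `[0, 1]`.
#' @examples
#' precision_recall_auc(c(-.9, -.8, -.7, -.6), c(1, 0, 1, 0))  # 5/6
#' @export
precision_recall_auc <- function(scores, labels, p = NULL, gene_id = NULL) {
  stopifnot(length(scores) == length(labels))
  if (any(!is.finite(scores))) {
    data_error("precision_recall_auc: scores must be finite")
  }
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels)
  if (n_pos == 0) data_error("precision_recall_auc: no positive labels")
  if (is.null(p)) p <- rep(0, length(scores))
  if (is.null(gene_id)) gene_id <- sprintf("g%09d", seq_along(scores))
  ord <- order(scores, p, gene_id)
  lab <- labels[ord]
  cum_pos <- cumsum(lab)
  prec_at_pos <- cum_pos[lab == 1L] / which(lab == 1L)
  sum(prec_at_pos) / n_pos
}

#' Compare methods by AUPRC against a reference gene set
#'
#' For each method's ED table (and each context within it), ranks genes by
#' `rho` and evaluates the AUPRC for recovering the reference set, then
#' reports pairwise relative improvements
#' `100 * (AUPRC_a - AUPRC_b) / AUPRC_b`, per context and averaged over
#' contexts. Only rows with status `"ok"` are ranked; all methods must rank
#' the same genes in each context.
#'
#' @param tables Named list of ED tables, one per method.
#' @param reference A [gene_set()] or character vector of positives.
#' @param universe Optional character vector restricting the ranked genes.
#' @return A list with tibbles `auprc` (method, context, n_ranked, auprc)
#'   and `improvement` (method_a, method_b, context, improvement_pct;
#'   context `"(mean)"` averages over contexts).
#' @export
compare_methods_auprc <- function(tables, reference, universe = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1, !is.null(names(tables)))
  ref <- as_gene_set(reference)$members
  per <- list()
  for (m in names(tables)) {
    tb <- tables[[m]]
    tb <- tb[tb$status == "ok", , drop = FALSE]
    if (!is.null(universe)) tb <- tb[tb$gene %in% universe, , drop = FALSE]
    for (ctx in unique(tb$context)) {
      sub <- tb[tb$context == ctx, , drop = FALSE]
      key <- paste(m, ctx, sep = "\r")
      per[[key]] <- tibble::tibble(
        method = m, context = ctx, n_ranked = nrow(sub),
        auprc = precision_recall_auc(sub$rho,
                                     as.integer(sub$gene %in% ref),
                                     p = sub$p, gene_id = sub$gene))
    }
  }
  auprc <- dplyr::bind_rows(per)
  # identical gene universes per method within each context
  for (ctx in unique(auprc$context)) {
    ns <- auprc$n_ranked[auprc$context == ctx]
    gsets <- lapply(tables, function(tb) {
      sub <- tb[tb$status == "ok" & tb$context == ctx, , drop = FALSE]
      if (!is.null(universe)) sub <- sub[sub$gene %in% universe, , drop = FALSE]
      sort(sub$gene)
    })
    if (length(unique(gsets)) > 1) {
      data_error(sprintf(
        "compare_methods_auprc: methods rank different gene universes in context '%s'",
        ctx))
    }
  }
  methods <- names(tables)
  imp <- list()
  for (a in methods) for (b in setdiff(methods, a)) {
    for (ctx in unique(auprc$context)) {
      aa <- auprc$auprc[auprc$method == a & auprc$context == ctx]
      bb <- auprc$auprc[auprc$method == b & auprc$context == ctx]
      imp[[paste(a, b, ctx)]] <- tibble::tibble(
        method_a = a, method_b = b, context = ctx,
        improvement_pct = 100 * (aa - bb) / bb)
    }
    ma <- mean(auprc$auprc[auprc$method == a])
    mb <- mean(auprc$auprc[auprc$method == b])
    imp[[paste(a, b, "(mean)")]] <- tibble::tibble(
      method_a = a, method_b = b, context = "(mean)",
      improvement_pct = 100 * (ma - mb) / mb)
  }
  list(auprc = auprc, improvement = dplyr::bind_rows(imp))
}
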