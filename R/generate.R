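#' Generate a synthetic DepMap-like dataset with planted ground truth
#'
#' Emulates the structure of a cell-line panel: lineage-grouped cell lines,
#' an mRNA expression matrix on all lines, a protein matrix that copies mRNA
#' with added noise (attenuating correlations to a target mRNA-protein
#' correlation) and randomly masked entries, and a CERES-like dependency
#' matrix. Null genes get dependency independent of expression; planted
#' pan-lineage genes get dependency built from standardized expression with
#' Gaussian noise calibrated so the population expression-dependency
#' correlation equals `effect_rho`; planted lineage genes carry the effect
#' only within one assigned lineage. Everything is reproducible from `seed`.
#'
#' @param n_lineages Number of lineages (default 5).
#' @param lines_per_lineage Cell lines per lineage (default 20).
#' @param n_genes Total genes (default 500).
#' @param n_planted_pan Genes with a pan-lineage effect (default 25).
#' @param n_planted_lineage Genes with a single-lineage effect (default 10).
#' @param effect_rho Planted expression-dependency correlation, in
#'   `(-1, 0)` (default -0.8).
#' @param protein_missing_fraction Fraction of protein entries masked
#'   (default 0.3).
#' @param mrna_protein_cor Target mRNA-protein correlation (default 0.6).
#' @param seed Integer seed.
#' @return A list of class `synthetic_depmap` with elements `expr_mrna`,
#'   `expr_protein` ([omics_matrix()]), `dep` ([dependency_matrix()]),
#'   `ann` ([lineage_annotation()]), `truth` (tibble: `gene`, `context`,
#'   `slope`, `true_rho`) and `params`.
#' @examples
#' sd <- generate_synthetic_depmap(n_lineages = 2, lines_per_lineage = 8,
#'                                 n_genes = 40, n_planted_pan = 4,
#'                                 n_planted_lineage = 2, seed = 1)
#' sd$truth
#' @export
generate_synthetic_depmap <- function(n_lineages = 5, lines_per_lineage = 20,
                                      n_genes = 500, n_planted_pan = 25,
                                      n_planted_lineage = 10,
                                      effect_rho = -0.8,
                                      protein_missing_fraction = 0.3,
                                      mrna_protein_cor = 0.6, seed = 1) {
  stopifnot(n_lineages >= 1, lines_per_lineage >= 1, n_genes >= 1,
            n_planted_pan >= 0, n_planted_lineage >= 0,
            effect_rho > -1, effect_rho < 0,
            protein_missing_fraction >= 0, protein_missing_fraction < 1,
            mrna_protein_cor > 0, mrna_protein_cor <= 1)
  if (n_planted_pan + n_planted_lineage > n_genes) {
    usage_error("planted gene counts exceed n_genes")
  }
  set.seed(seed)
  L <- n_lineages * lines_per_lineage
  lines <- sprintf("ACH-%06d", seq_len(L))
  lineages <- sprintf("lineage_%02d", rep(seq_len(n_lineages),
                                          each = lines_per_lineage))
  genes <- sprintf("GENE%04d", seq_len(n_genes))

  planted_pan <- if (n_planted_pan > 0) genes[seq_len(n_planted_pan)] else character(0)
  planted_lin <- if (n_planted_lineage > 0)
    genes[n_planted_pan + seq_len(n_planted_lineage)] else character(0)
  lin_assign <- if (n_planted_lineage > 0)
    sprintf("lineage_%02d", 1 + (seq_len(n_planted_lineage) - 1) %% n_lineages)
  else character(0)

  # mRNA: gene-level baseline and spread, log-TPM-like
  base <- stats::rnorm(n_genes, mean = 6, sd = 1.5)
  spread <- stats::runif(n_genes, 0.5, 1.5)
  Z <- matrix(stats::rnorm(n_genes * L), n_genes, L,
              dimnames = list(genes, lines))
  mrna <- base + spread * Z

  # dependency: CERES-like location/scale per gene; planted genes mix in
  # standardized expression so the population correlation is effect_rho
  dep_mu <- stats::rnorm(n_genes, mean = -0.2, sd = 0.2)
  dep_sd <- stats::runif(n_genes, 0.2, 0.5)
  E <- matrix(stats::rnorm(n_genes * L), n_genes, L)
  core <- E
  rows_pan <- match(planted_pan, genes)
  if (length(rows_pan) > 0) {
    core[rows_pan, ] <- effect_rho * Z[rows_pan, , drop = FALSE] +
      sqrt(1 - effect_rho^2) * E[rows_pan, , drop = FALSE]
  }
  rows_lin <- match(planted_lin, genes)
  for (j in seq_along(rows_lin)) {
    in_lin <- lineages == lin_assign[j]
    core[rows_lin[j], in_lin] <- effect_rho * Z[rows_lin[j], in_lin] +
      sqrt(1 - effect_rho^2) * E[rows_lin[j], in_lin]
  }
  dep <- dep_mu + dep_sd * core
  dimnames(dep) <- list(genes, lines)

  # protein: attenuated copy of mRNA (target correlation), then masked
  cpr <- mrna_protein_cor
  W <- matrix(stats::rnorm(n_genes * L), n_genes, L)
  prot_base <- stats::rnorm(n_genes, mean = 0, sd = 1)
  prot <- prot_base + cpr * Z + sqrt(1 - cpr^2) * W
  dimnames(prot) <- list(genes, lines)
  if (protein_missing_fraction > 0) {
    mask <- matrix(stats::runif(n_genes * L) < protein_missing_fraction,
                   n_genes, L)
    prot[mask] <- NA_real_
  }

  truth <- tibble::tibble(
    gene = c(planted_pan, planted_lin),
    context = c(rep("pan", length(planted_pan)), lin_assign),
    slope = effect_rho * dep_sd[c(rows_pan, rows_lin)] /
      spread[c(rows_pan, rows_lin)],
    true_rho = effect_rho
  )
  params <- list(n_lineages = n_lineages,
                 lines_per_lineage = lines_per_lineage,
                 n_genes = n_genes, n_planted_pan = n_planted_pan,
                 n_planted_lineage = n_planted_lineage,
                 effect_rho = effect_rho,
                 protein_missing_fraction = protein_missing_fraction,
                 mrna_protein_cor = mrna_protein_cor, seed = seed)
  structure(list(expr_mrna = omics_matrix(mrna, "mrna"),
                 expr_protein = omics_matrix(prot, "protein"),
                 dep = dependency_matrix(dep),
                 ann = lineage_annotation(lines, lineages),
                 truth = truth, params = params),
            class = "synthetic_depmap")
}

#' Write a synthetic dataset to a directory
#'
#' Writes `expression_mrna.csv`, `expression_protein.csv`, `dependency.csv`
#' (DepMap orientation), `lineage.tsv`, `truth.tsv` and `params.yaml`.
#'
#' @param data A `synthetic_depmap` from [generate_synthetic_depmap()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_depmap <- function(data, dir) {
  stopifnot(inherits(data, "synthetic_depmap"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(data$expr_mrna, file.path(dir, "expression_mrna.csv"))
  write_matrix_csv(data$expr_protein, file.path(dir, "expression_protein.csv"))
  write_matrix_csv(data$dep, file.path(dir, "dependency.csv"))
  writeLines(c("cell_line\tlineage",
               paste(data$ann$cell_line, data$ann$lineage, sep = "\t")),
             file.path(dir, "lineage.tsv"))
  writeLines(c("gene\tcontext\tslope\ttrue_rho",
               paste(data$truth$gene, data$truth$context,
                     format_real(data$truth$slope),
                     format_real(data$truth$true_rho), sep = "\t")),
             file.path(dir, "truth.tsv"))
  yaml::write_yaml(data$params, file.path(dir, "params.yaml"))
  invisible(dir)
}
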