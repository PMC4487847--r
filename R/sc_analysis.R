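# Downstream cell-type separation statistics: normalization, bulk
# correlation saturation, Wilcoxon differential expression, CV-ratio
# heterogeneity, Spearman matrices, and the rank-based classifier score.

#' Normalize a molecule-count matrix
#'
#' Per-cell molecules-per-million with a pseudocount, log-transformed:
#' `log10(1 + 1e6 * count / cell_total)`. Cells with zero totals are
#' excluded with a warning. The denominator is the cell's molecule total
#' (the matrix contains unique molecules); `per = "reads"` with a vector
#' of per-cell read totals is available for read-based normalization.
#'
#' @param counts genes x cells count matrix (sparse or dense).
#' @param base logarithm base (default 10).
#' @param scale counts-per-what scale (default 1e6).
#' @param per `"molecules"` (denominator = column sums) or `"reads"`.
#' @param read_totals named per-cell read totals when `per = "reads"`.
#' @return genes x cells `dgCMatrix` of normalized values (zeros are
#'   preserved, so sparsity is kept).
#' @export
normalize_counts <- function(counts, base = 10, scale = 1e6,
                             per = c("molecules", "reads"),
                             read_totals = NULL) {
  per <- match.arg(per)
  m <- methods::as(counts, "CsparseMatrix")
  totals <- if (per == "reads") {
    if (is.null(read_totals)) stop("read_totals required when per='reads'")
    as.numeric(read_totals[colnames(m)])
  } else {
    Matrix::colSums(m)
  }
  zero <- totals <= 0 | is.na(totals)
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero totals excluded from normalization")
    m <- m[, !zero, drop = FALSE]
    totals <- totals[!zero]
  }
  # scale non-zero entries column-wise, then log(1 + x); both preserve zeros
  sf <- scale / totals
  m@x <- log(1 + m@x * rep.int(sf, diff(m@p)), base = base)
  m
}

#' Invert [normalize_counts()] back to per-cell proportions
#'
#' @param norm normalized matrix.
#' @param base,scale as used in the forward transform.
#' @return genes x cells matrix of proportions (columns sum to 1).
#' @export
denormalize_proportions <- function(norm, base = 10, scale = 1e6) {
  m <- methods::as(norm, "CsparseMatrix")
  m@x <- (base^m@x - 1) / scale
  sums <- Matrix::colSums(m)
  m@x <- m@x / rep.int(sums, diff(m@p))
  m
}

#' Per-gene median profile over a cell subset
#'
#' @param norm genes x cells normalized matrix.
#' @param cells character vector of cell ids (non-empty, all present).
#' @return named numeric vector (one median per gene).
#' @export
median_profile <- function(norm, cells) {
  if (length(cells) == 0L) stop("cell subset is empty")
  missing <- setdiff(cells, colnames(norm))
  if (length(missing))
    stop("cells not in matrix: ", paste(head(missing, 5), collapse = ", "))
  m <- as.matrix(norm[, cells, drop = FALSE])
  apply(m, 1L, median)
}

#' Pearson correlation between a single-cell median profile and bulk
#'
#' Only genes whose log-transformed single-cell median OR bulk value
#' exceeds `expr_floor` enter the correlation (genes silent in both would
#' otherwise inflate r).
#'
#' @param median_profile named per-gene vector (log scale, from
#'   [median_profile()]).
#' @param bulk named per-gene vector of log-transformed bulk expression
#'   (e.g. `log10(FPKM + 1)`).
#' @param expr_floor inclusion floor on the log values (default 0.5).
#' @return Pearson r over the qualifying shared genes (>= 3 required).
#' @export
bulk_correlation <- function(median_profile, bulk, expr_floor = 0.5) {
  shared <- intersect(names(median_profile), names(bulk))
  x <- median_profile[shared]
  y <- bulk[shared]
  keep <- x > expr_floor | y > expr_floor
  if (sum(keep) < 3L)
    stop("fewer than 3 genes pass the expression floor")
  cor(x[keep], y[keep], method = "pearson")
}

#' Saturation of the bulk correlation with cell number
#'
#' For each n, draws `reps` random cell subsets (without replacement by
#' default), builds the median profile of each, correlates it with the
#' bulk profile, and reports the median r and its SEM across draws.
#'
#' @param norm genes x cells normalized matrix.
#' @param bulk named log-transformed bulk vector.
#' @param n_cells_list subset sizes.
#' @param reps random draws per size (default 10).
#' @param seed optional RNG seed.
#' @param replacement sample cells with replacement?
#' @param cells candidate cell ids (default all columns).
#' @param expr_floor see [bulk_correlation()].
#' @return data.frame with `n_cells`, `median_r`, `sem`, `reps`.
#' @export
saturation_curve <- function(norm, bulk, n_cells_list, reps = 10L,
                             seed = NULL, replacement = FALSE,
                             cells = colnames(norm), expr_floor = 0.5) {
  if (!replacement && max(n_cells_list) > length(cells))
    stop("n_cells exceeds available cells when sampling without replacement")
  with_seed(seed, {
    rows <- lapply(sort(n_cells_list), function(n) {
      rs <- vapply(seq_len(reps), function(i) {
        sub <- sample(cells, n, replace = replacement)
        bulk_correlation(median_profile(norm, sub), bulk, expr_floor)
      }, numeric(1))
      data.frame(n_cells = n, median_r = median(rs),
                 sem = sd(rs) / sqrt(reps), reps = reps)
    })
    do.call(rbind, rows)
  })
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per-gene two-sided rank-sum test on normalized values. Genes constant
#' across both groups get p = 1 by convention. The signed score
#' `+/-(1 - p)` is positive for genes more highly expressed in group A
#' and negative for group B, and feeds pathway analysis directly.
#'
#' @param norm genes x cells normalized matrix.
#' @param cells_a,cells_b cell ids of the two groups (>= 2 cells each).
#' @param alpha significance level (default 0.05).
#' @return data.frame: `gene`, `p_value`, `direction` (`"groupA"` /
#'   `"groupB"`), `signed_score`, `significant` (p < alpha).
#' @export
wilcoxon_de <- function(norm, cells_a, cells_b, alpha = 0.05) {
  if (length(cells_a) < 2L || length(cells_b) < 2L)
    stop("both groups need at least 2 cells")
  a <- as.matrix(norm[, cells_a, drop = FALSE])
  b <- as.matrix(norm[, cells_b, drop = FALSE])
  genes <- rownames(norm)
  res <- lapply(seq_along(genes), function(g) {
    x <- a[g, ]; y <- b[g, ]
    if (max(c(x, y)) == min(c(x, y))) {
      p <- 1
      delta <- 0
    } else {
      p <- suppressWarnings(wilcox.test(x, y)$p.value)
      delta <- mean(x) - mean(y)
    }
    c(p = p, delta = delta)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  delta <- vapply(res, `[[`, numeric(1), "delta")
  direction <- ifelse(delta >= 0, "groupA", "groupB")
  data.frame(gene = genes, p_value = p, direction = direction,
             signed_score = ifelse(delta >= 0, 1, -1) * (1 - p),
             significant = p < alpha, stringsAsFactors = FALSE)
}

#' Coefficient-of-variation ratio between mixed and pure cell groups
#'
#' For each gene of a cell-type-specific set, computes CV = sd/mean within
#' the mixed-population cells and within the pure-population cells and
#' returns the log CV ratio. Mixing two types adds between-type variance,
#' so type-specific genes should show log-ratios above zero in the mixed
#' group.
#'
#' @param norm genes x cells normalized matrix.
#' @param gene_set genes to evaluate (all must be present).
#' @param mixed_cells,pure_cells cell-id vectors.
#' @return list with `table` (gene, cv_mixed, cv_pure, log_ratio),
#'   `fraction_positive`, and `excluded` (genes with a non-positive mean
#'   or zero pure CV, dropped with a message).
#' @export
cv_ratio <- function(norm, gene_set, mixed_cells, pure_cells) {
  missing <- setdiff(gene_set, rownames(norm))
  if (length(missing))
    stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  mm <- as.matrix(norm[gene_set, mixed_cells, drop = FALSE])
  pm <- as.matrix(norm[gene_set, pure_cells, drop = FALSE])
  cv <- function(m) apply(m, 1L, sd) / rowMeans(m)
  cv_m <- cv(mm); cv_p <- cv(pm)
  bad <- !is.finite(cv_m) | !is.finite(cv_p) | cv_p == 0 | cv_m == 0
  if (any(bad))
    message(sum(bad), " gene(s) excluded from CV ratio (zero mean or sd)")
  tab <- data.frame(gene = gene_set[!bad], cv_mixed = cv_m[!bad],
                    cv_pure = cv_p[!bad],
                    log_ratio = log(cv_m[!bad] / cv_p[!bad]),
                    stringsAsFactors = FALSE)
  list(table = tab,
       fraction_positive = mean(tab$log_ratio > 0),
       excluded = gene_set[bad])
}

#' Pairwise Spearman correlation matrix over differentially expressed genes
#'
#' Cells are correlated on their rank-ordered expression of the DE genes
#' (ties receive average ranks); the result is the standard input for
#' embedding/clustering (e.g. t-SNE), which is consumed externally.
#'
#' @param norm genes x cells normalized matrix.
#' @param de_genes differentially expressed genes (>= 2 required).
#' @return cells x cells symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(norm, de_genes) {
  de_genes <- intersect(de_genes, rownames(norm))
  if (length(de_genes) < 2L)
    stop("need at least 2 DE genes present in the matrix")
  m <- as.matrix(norm[de_genes, , drop = FALSE])
  cor(m, method = "spearman")
}

#' Rank-based cell-type classifier score
#'
#' Within each cell, all genes are ranked by expression (ties averaged).
#' With `a` = number of type-A-specific genes ranked above the average
#' rank and `b` = likewise for type B, the score is
#' `log2((a + 1) / (b + 1))` (the +1 keeps the log-ratio finite at this
#' sequencing depth, where zero counts are common): positive scores
#' indicate type A character, negative type B, and swapping the gene sets
#' exactly negates the score.
#'
#' @param norm genes x cells normalized matrix.
#' @param set_a,set_b disjoint, non-empty type-specific gene sets (all
#'   present in the matrix).
#' @param cells cells to score (default all).
#' @return data.frame: `cell`, `n_above_a`, `n_above_b`, `score`.
#' @export
classifier_score <- function(norm, set_a, set_b, cells = colnames(norm)) {
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop("both gene sets must be non-empty")
  if (length(intersect(set_a, set_b)))
    stop("gene sets must be disjoint: ",
         paste(intersect(set_a, set_b), collapse = ", "))
  missing <- setdiff(c(set_a, set_b), rownames(norm))
  if (length(missing))
    stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  m <- as.matrix(norm[, cells, drop = FALSE])
  n_genes <- nrow(m)
  mid <- (n_genes + 1) / 2
  ia <- match(set_a, rownames(m))
  ib <- match(set_b, rownames(m))
  out <- lapply(seq_along(cells), function(j) {
    r <- rank(m[, j])
    c(a = sum(r[ia] > mid), b = sum(r[ib] > mid))
  })
  a <- vapply(out, `[[`, numeric(1), "a")
  b <- vapply(out, `[[`, numeric(1), "b")
  data.frame(cell = cells, n_above_a = a, n_above_b = b,
             score = log2((a + 1) / (b + 1)), stringsAsFactors = FALSE)
}

#' Write the DE table and the signed-score pathway input
#'
#' `de_table.tsv` carries the full test output; `signed_scores.tsv` is the
#' two-column (gene, +/-(1-p)) table consumed by ontology/pathway tools.
#'
#' @param de a [wilcoxon_de()] result.
#' @param dir output directory.
#' @export
write_de_tables <- function(de, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv_file(de, file.path(dir, "de_table.tsv"))
  write_tsv_file(de[, c("gene", "signed_score")],
                 file.path(dir, "signed_scores.tsv"))
  invisible(dir)
}

#' Write a numeric matrix as TSV with row names
#'
#' @param m matrix (e.g. a Spearman matrix).
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE))
  write_tsv_file(df, path)
}
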