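# Normalization, bulk correlation, DE, CV ratios, Spearman, classifier.

toy_counts <- function() {
  m <- Matrix::Matrix(c(5, 0, 2,
                        0, 3, 1,
                        1, 2, 0), nrow = 3, byrow = TRUE, sparse = TRUE)
  dimnames(m) <- list(paste0("g", 1:3), paste0("c", 1:3))
  m
}

test_that("normalization is log10 molecules-per-million plus one", {
  one <- Matrix::Matrix(matrix(5, 1, 1), sparse = TRUE)
  dimnames(one) <- list("g1", "c1")
  n <- normalize_counts(one)
  expect_equal(n["g1", "c1"], log10(1 + 1e6), tolerance = 1e-12)
  # zeros stay zero
  n3 <- normalize_counts(toy_counts())
  expect_equal(n3["g2", "c1"], 0)
  # direct formula for one entry: 5 of 6 molecules in c1
  expect_equal(n3["g1", "c1"], log10(1 + 1e6 * 5 / 6), tolerance = 1e-12)
  # zero-total cells are excluded with a warning
  z <- cbind(toy_counts(), c4 = c(0, 0, 0))
  expect_warning(nz <- normalize_counts(z), "zero totals")
  expect_equal(ncol(nz), 3L)
})

test_that("normalization round-trips to the original proportions", {
  set.seed(12)
  m <- Matrix::Matrix(matrix(rpois(200, 3), 20, 10), sparse = TRUE)
  dimnames(m) <- list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:10))
  m <- m[, Matrix::colSums(m) > 0]
  norm <- normalize_counts(m)
  prop <- denormalize_proportions(norm)
  truth <- sweep(as.matrix(m), 2, colSums(as.matrix(m)), "/")
  expect_lt(max(abs(as.matrix(prop) - truth)), 1e-9)
})

test_that("median profile equals a sort-based oracle", {
  set.seed(4)
  m <- matrix(runif(35), 5, 7,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:7)))
  mp <- median_profile(m, colnames(m))
  oracle <- apply(m, 1, function(v) sort(v)[4])  # middle of 7
  expect_equal(mp, oracle)
  # single cell: its own profile; two cells: per-gene midpoint
  expect_equal(median_profile(m, "c1"), m[, "c1"])
  expect_equal(median_profile(m, c("c1", "c2")),
               (m[, "c1"] + m[, "c2"]) / 2)
  expect_error(median_profile(m, character(0)), "empty")
})

test_that("bulk correlation applies the 0.5 floor and matches the covariance formula", {
  set.seed(8)
  x <- setNames(runif(100, 0, 4), paste0("g", 1:100))
  expect_equal(bulk_correlation(x, x), 1)
  y_neg <- 4 - x
  expect_equal(bulk_correlation(x, y_neg), -1)
  y <- setNames(runif(100, 0, 4), names(x))
  r <- bulk_correlation(x, y, expr_floor = 0.5)
  keep <- x > 0.5 | y > 0.5
  xv <- x[keep]; yv <- y[keep]
  oracle <- sum((xv - mean(xv)) * (yv - mean(yv))) /
    sqrt(sum((xv - mean(xv))^2) * sum((yv - mean(yv))^2))
  expect_equal(r, oracle, tolerance = 1e-12)
  # genes silent on both sides are excluded: r changes if we zero some
  low <- setNames(rep(0.1, 100), names(x))
  expect_error(bulk_correlation(low, low), "floor")
})

test_that("saturation curve is reproducible, saturating, and type-specific", {
  sim <- default_sim()
  counting <- default_counting()
  norm <- normalize_counts(counting$counts)
  truth <- default_sim()$truth$barcodes
  ids <- barcode_ids(truth)
  a_cells <- intersect(ids[truth$is_real_cell & truth$type == "A"],
                       colnames(norm))
  bulk_a <- sim_bulk_profile(sim, "A")
  bulk_b <- sim_bulk_profile(sim, "B")
  lg <- function(b) setNames(log10(b$fpkm + 1), b$gene)
  sc <- saturation_curve(norm, lg(bulk_a), c(3, 10, 25), reps = 5,
                         seed = 77, cells = a_cells)
  sc2 <- saturation_curve(norm, lg(bulk_a), c(3, 10, 25), reps = 5,
                          seed = 77, cells = a_cells)
  expect_identical(sc, sc2)  # seeded reproducibility
  # median r grows (within SEM) with cell number
  expect_gt(sc$median_r[3] + sc$sem[3], sc$median_r[1] - sc$sem[1])
  # same-type bulk correlates better than cross-type at every n
  sx <- saturation_curve(norm, lg(bulk_b), c(3, 10, 25), reps = 5,
                         seed = 77, cells = a_cells)
  expect_true(all(sc$median_r > sx$median_r))
  # full population: deterministic single value
  all_r <- saturation_curve(norm, lg(bulk_a), length(a_cells), reps = 3,
                            seed = 1, cells = a_cells)
  expect_equal(all_r$sem, 0)
  expect_error(saturation_curve(norm, lg(bulk_a), length(a_cells) + 1,
                                cells = a_cells), "exceeds")
})

test_that("wilcoxon DE matches exact enumeration on a 3-vs-3 toy", {
  x <- c(1.3, 2.9, 4.1)
  y <- c(2.0, 3.5, 0.7)
  m <- rbind(g1 = c(x, y))
  colnames(m) <- paste0("c", 1:6)
  de <- wilcoxon_de(rbind(m, m), paste0("c", 1:3), paste0("c", 4:6))
  # enumeration oracle over all C(6,3) labelings of the pooled values
  pool <- c(x, y)
  u_obs <- sum(rank(pool)[1:3]) - 6  # Mann-Whitney U of group A
  combs <- utils::combn(6, 3)
  u_all <- apply(combs, 2, function(idx) sum(rank(pool)[idx]) - 6)
  p_oracle <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  expect_equal(de$p_value[1], p_oracle, tolerance = 1e-12)
})

test_that("wilcoxon DE direction, scores, and degenerate genes behave", {
  set.seed(21)
  m <- matrix(rnorm(40, 5), 2, 20,
              dimnames = list(c("up_in_a", "flat"), paste0("c", 1:20)))
  m["up_in_a", 1:10] <- m["up_in_a", 1:10] + 5
  m["flat", ] <- 2                      # constant across both groups
  de <- wilcoxon_de(m, paste0("c", 1:10), paste0("c", 11:20))
  expect_equal(de$p_value[de$gene == "flat"], 1)
  expect_false(de$significant[de$gene == "flat"])
  row_a <- de[de$gene == "up_in_a", ]
  expect_true(row_a$significant)
  expect_equal(row_a$direction, "groupA")
  expect_equal(row_a$signed_score, 1 - row_a$p_value)
  expect_true(all(abs(de$signed_score) < 1))
  # identical groups (same values, relabeled): nothing significant
  half <- matrix(rnorm(25), 5, 5)
  mm <- cbind(half, half)
  rownames(mm) <- paste0("g", 1:5); colnames(mm) <- paste0("c", 1:10)
  de0 <- wilcoxon_de(mm, paste0("c", 1:5), paste0("c", 6:10))
  expect_false(any(de0$significant))
  expect_error(wilcoxon_de(m, "c1", paste0("c", 2:4)), "at least 2")
})

test_that("wilcoxon DE controls type-I error on permuted nulls", {
  set.seed(31)
  m <- matrix(rnorm(1000 * 40), 1000, 40,
              dimnames = list(sprintf("g%04d", 1:1000), paste0("c", 1:40)))
  de <- wilcoxon_de(m, paste0("c", 1:20), paste0("c", 21:40))
  expect_lte(mean(de$significant), 0.07)
})

test_that("wilcoxon DE recovers planted markers with high power", {
  counting <- default_counting()
  sim <- default_sim()
  norm <- normalize_counts(counting$counts)
  truth <- sim$truth$barcodes
  ids <- barcode_ids(truth)
  a <- head(intersect(ids[truth$is_real_cell & truth$type == "A"],
                      colnames(norm)), 50)
  b <- head(intersect(ids[truth$is_real_cell & truth$type == "B"],
                      colnames(norm)), 50)
  de <- wilcoxon_de(norm, a, b)
  planted <- unlist(sim$marker_genes)
  expect_gte(mean(planted %in% de$gene[de$significant]), 0.9)
  # planted directions are recovered
  da <- de[de$gene %in% sim$marker_genes$A & de$significant, ]
  expect_true(all(da$direction == "groupA"))
})

test_that("CV ratio arithmetic matches a by-hand toy and detects mixing", {
  m <- rbind(g1 = c(1, 3, 2, 4), g2 = c(2, 6, 1, 3))
  colnames(m) <- paste0("c", 1:4)
  cvr <- cv_ratio(m, c("g1", "g2"), mixed_cells = paste0("c", 1:2),
                  pure_cells = paste0("c", 3:4))
  # g1: mixed sd/mean = sqrt(2)/2, pure sd/mean = sqrt(2)/3
  expect_equal(cvr$table$log_ratio[1],
               log((sqrt(2) / 2) / (sqrt(2) / 3)), tolerance = 1e-12)
  # g2: mixed sqrt(8)/4, pure sqrt(2)/2
  expect_equal(cvr$table$log_ratio[2],
               log((sqrt(8) / 4) / (sqrt(2) / 2)), tolerance = 1e-12)
  # mixed == pure -> all zero
  same <- cv_ratio(m, c("g1", "g2"), paste0("c", 1:4), paste0("c", 1:4))
  expect_true(all(same$table$log_ratio == 0))
  expect_error(cv_ratio(m, "missing_gene", "c1", "c2"), "absent")
})

test_that("type-specific genes gain CV in mixed lanes", {
  sim <- default_sim()
  counting <- default_counting()
  norm <- normalize_counts(counting$counts)
  truth <- sim$truth$barcodes
  ids <- barcode_ids(truth)
  mixed <- intersect(ids[truth$is_real_cell &
                           !truth$lane %in% c("L1", "L2")], colnames(norm))
  pure_a <- intersect(ids[truth$is_real_cell & truth$lane == "L1"],
                      colnames(norm))
  cvr <- cv_ratio(norm, intersect(sim$marker_genes$A, rownames(norm)),
                  mixed, pure_a)
  expect_gt(cvr$fraction_positive, 0.8)
})

test_that("spearman matrix equals rank-then-pearson and handles edge cases", {
  set.seed(14)
  m <- matrix(runif(30), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
  sm <- spearman_matrix(m, rownames(m))
  oracle <- cor(apply(m, 2, rank))
  expect_equal(sm, oracle, tolerance = 1e-12)
  expect_equal(diag(sm), setNames(rep(1, 6), colnames(m)))
  expect_true(isSymmetric(sm))
  # duplicated cell -> off-diagonal 1; rank-reversed cell -> -1
  m2 <- cbind(m, c7 = m[, "c1"], c8 = -m[, "c1"])
  sm2 <- spearman_matrix(m2, rownames(m2))
  expect_equal(sm2["c1", "c7"], 1)
  expect_equal(sm2["c1", "c8"], -1)
  expect_error(spearman_matrix(m, "g1"), "at least 2")
})

test_that("classifier score is antisymmetric and separates planted types", {
  m <- matrix(c(10, 9, 8, 1, 2, 3), 6, 1,
              dimnames = list(paste0("g", 1:6), "cellX"))
  cs <- classifier_score(m, paste0("g", 1:3), paste0("g", 4:6))
  expect_equal(cs$score, log2(4 / 1))  # all A above average, no B
  swapped <- classifier_score(m, paste0("g", 4:6), paste0("g", 1:3))
  expect_equal(swapped$score, -cs$score)
  expect_error(classifier_score(m, "g1", "g1"), "disjoint")
  expect_error(classifier_score(m, "g1", "nope"), "absent")

  sim <- default_sim()
  counting <- default_counting()
  norm <- normalize_counts(counting$counts)
  truth <- sim$truth$barcodes
  ids <- barcode_ids(truth)
  a <- intersect(ids[truth$is_real_cell & truth$type == "A"],
                 colnames(norm))
  b <- intersect(ids[truth$is_real_cell & truth$type == "B"],
                 colnames(norm))
  cs_a <- classifier_score(norm, sim$marker_genes$A, sim$marker_genes$B,
                           cells = a)
  cs_b <- classifier_score(norm, sim$marker_genes$A, sim$marker_genes$B,
                           cells = b)
  expect_gte(mean(cs_a$score > 0), 0.95)
  expect_gte(mean(cs_b$score < 0), 0.95)
})

test_that("DE and matrix exports are written and re-readable", {
  set.seed(2)
  m <- matrix(rnorm(100, 5), 10, 10,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:10)))
  de <- wilcoxon_de(m, paste0("c", 1:5), paste0("c", 6:10))
  dir <- withr::local_tempdir()
  write_de_tables(de, dir)
  back <- read.table(file.path(dir, "signed_scores.tsv"), header = TRUE,
                     sep = "\t")
  expect_equal(back$signed_score, de$signed_score, tolerance = 1e-6)
  write_matrix_tsv(spearman_matrix(m, rownames(m)),
                   file.path(dir, "sp.tsv"))
  sp <- read.table(file.path(dir, "sp.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(sp), 10L)
})
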