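# Read filtering, molecule collapse, chimera removal, count matrix.

test_that("mapping-flag filter keeps exactly the documented combinations", {
  reads <- rbind(
    make_reads(umi = "AAAAAAAA", position = 0, unique_tx = TRUE,
               also_genome = FALSE, strand_ok = TRUE),
    make_reads(umi = "AAAAAAAA", position = 0, unique_tx = TRUE,
               also_genome = TRUE, strand_ok = TRUE),
    make_reads(umi = "AAAAAAAA", position = 0, unique_tx = TRUE,
               also_genome = TRUE, strand_ok = FALSE),
    make_reads(umi = "AAAAAAAA", position = 0, unique_tx = FALSE,
               also_genome = FALSE, strand_ok = TRUE),
    make_reads(umi = "AAAAAAAA", position = 0, unique_tx = NA,
               also_genome = FALSE, strand_ok = TRUE))
  f <- filter_mapped_reads(reads)
  expect_equal(nrow(f$kept), 2L)
  expect_equal(unname(f$tally),
               c(2L, 1L, 1L, 1L))  # kept, multimapped, strand, missing
  expect_equal(sum(f$tally), nrow(reads))
})

test_that("collapse honors the Hamming and position boundaries inclusively", {
  # distance-2 UMIs at the same position merge
  r <- rbind(make_reads(umi = "AAAAAAAA", position = 100),
             make_reads(umi = "AAAAAATT", position = 100))
  expect_equal(nrow(collapse_molecules(r)$molecules), 1L)
  # distance-3 stays apart
  r3 <- rbind(make_reads(umi = "AAAAAAAA", position = 100),
              make_reads(umi = "AAAAATTT", position = 100))
  expect_equal(nrow(collapse_molecules(r3)$molecules), 2L)
  # position 100 vs 106 merges; 100 vs 107 does not
  p6 <- rbind(make_reads(umi = "AAAAAAAA", position = 100),
              make_reads(umi = "AAAAAAAA", position = 106))
  expect_equal(nrow(collapse_molecules(p6)$molecules), 1L)
  p7 <- rbind(make_reads(umi = "AAAAAAAA", position = 100),
              make_reads(umi = "AAAAAAAA", position = 107))
  expect_equal(nrow(collapse_molecules(p7)$molecules), 2L)
  # transitivity: A-B and B-C linked, A-C not directly, still one molecule
  chain <- rbind(make_reads(umi = "AAAAAAAA", position = 100),
                 make_reads(umi = "AAAAAATT", position = 104),
                 make_reads(umi = "AAAATTTT", position = 108))
  expect_equal(nrow(collapse_molecules(chain)$molecules), 1L)
  # representative is the lexicographically smallest (umi, position)
  mol <- collapse_molecules(chain)$molecules
  expect_equal(mol$umi, "AAAAAAAA")
  expect_equal(mol$position, 100L)
  expect_equal(mol$read_support, 3L)
})

test_that("collapse equals exhaustive pairwise connected components", {
  skip_if_not_installed("igraph")
  set.seed(123)
  for (rep in 1:30) {
    k <- sample(2:50, 1)
    umis <- rand_umis(k)
    pos <- sample(0:30, k, replace = TRUE)
    r <- make_reads(umi = umis, position = pos)
    got <- collapse_molecules(r)
    oracle <- oracle_components(umis, pos)
    expect_equal(nrow(got$molecules), length(unique(oracle)))
    # component sizes must match too
    expect_equal(sort(got$molecules$read_support),
                 sort(unname(c(table(oracle)))))
  }
})

test_that("collapse is idempotent on its own output", {
  set.seed(9)
  r <- make_reads(umi = rand_umis(40), position = sample(0:25, 40, TRUE))
  m1 <- collapse_molecules(r)$molecules
  back <- make_reads(umi = m1$umi, position = m1$position)
  m2 <- collapse_molecules(back)$molecules
  expect_equal(nrow(m2), nrow(m1))
  expect_equal(m2$umi, m1$umi)
  expect_equal(m2$position, m1$position)
})

test_that("chimera filter removes same-lane cross-cell clusters entirely", {
  two <- rbind(
    make_reads(cell_bc = "A", umi = "AAAAAAAA", position = 100),
    make_reads(cell_bc = "B", umi = "AAAAAAAA", position = 100))
  ms <- collapse_molecules(two)
  cf <- chimera_filter(ms)
  expect_equal(nrow(cf$molecules$molecules), 0L)
  expect_equal(nrow(cf$removed), 2L)
  expect_true(all(cf$removed$cluster_barcodes == "A,B"))

  # different lanes: both kept
  diff_lane <- rbind(
    make_reads(lane = "L1", cell_bc = "A", umi = "AAAAAAAA", position = 100),
    make_reads(lane = "L2", cell_bc = "B", umi = "AAAAAAAA", position = 100))
  cf2 <- chimera_filter(collapse_molecules(diff_lane))
  expect_equal(nrow(cf2$molecules$molecules), 2L)
  expect_equal(nrow(cf2$removed), 0L)

  # keep_dominant retains the best-supported barcode's molecule
  dom <- rbind(
    make_reads(cell_bc = "A", umi = rep("AAAAAAAA", 5), position = 100),
    make_reads(cell_bc = "B", umi = "AAAAAAAA", position = 100))
  cf3 <- chimera_filter(collapse_molecules(dom), keep_dominant = TRUE)
  expect_equal(cf3$molecules$molecules$cell_bc, "A")
  expect_equal(cf3$removed$cell_bc, "B")
})

test_that("every planted cross-cell duplicate is removed in a chimera-only run", {
  sim <- chimera_sim()
  res <- count_molecules(sim$mapped_reads)
  kept <- res$molecules$molecules
  rd <- sim$truth$reads
  # cross-cell duplicates: molecules actually observed under >= 2 cell
  # barcodes (a molecule whose only read was relocated leaves no
  # duplicate evidence and is out of reach of the removal rule)
  dupmol <- rd[, .(nbc = data.table::uniqueN(barcode)),
               by = mol_id][nbc >= 2L]$mol_id
  chim <- rd[is_chimera == TRUE & mol_id %in% dupmol]
  expect_gt(nrow(chim), 100)  # the run actually planted such duplicates
  win <- 6L + sim$config$position_jitter_max
  for (side in c("barcode", "barcode_true")) {
    hit <- merge(kept, chim[, .(lane, cell_bc = get(side), gene,
                                umi = umi_obs, tpos = position)],
                 by = c("lane", "cell_bc", "gene", "umi"))
    hit <- hit[abs(position - tpos) <= win]
    expect_equal(nrow(hit), 0L)
  }
})

test_that("chimera removal matches an independent per-lane oracle", {
  skip_if_not_installed("igraph")
  sim <- chimera_sim()
  kept_reads <- filter_mapped_reads(sim$mapped_reads)$kept
  lane1 <- kept_reads[lane == "L1"]
  ms <- collapse_molecules(lane1)
  cf <- chimera_filter(ms)
  mols <- ms$molecules
  removed_oracle <- rep(FALSE, nrow(mols))
  for (g in unique(mols$gene)) {
    idx <- which(mols$gene == g)
    memb <- oracle_components(mols$umi[idx], mols$position[idx])
    for (cmp in unique(memb)) {
      rows <- idx[memb == cmp]
      if (length(unique(mols$cell_bc[rows])) > 1L)
        removed_oracle[rows] <- TRUE
    }
  }
  expect_equal(nrow(cf$removed), sum(removed_oracle))
  key <- function(d) paste(d$cell_bc, d$gene, d$umi, d$position)
  expect_setequal(key(cf$removed), key(mols[removed_oracle]))
})

test_that("count matrix conserves molecules and honors fixed axes", {
  r <- rbind(make_reads(cell_bc = "X", umi = "AAAAAAAA", gene = "g1",
                        position = 0),
             make_reads(cell_bc = "X", umi = "GGGGGGGG", gene = "g2",
                        position = 0),
             make_reads(cell_bc = "Y", umi = "CCCCCCCC", gene = "g1",
                        position = 50))
  m <- build_count_matrix(collapse_molecules(r))
  expect_equal(sum(m), 3)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["g1", "L1:X"], 1)
  # fixed axes pad with zeros
  m2 <- build_count_matrix(collapse_molecules(r),
                           cells = c("L1:X", "L1:Y", "L1:Z"),
                           genes = c("g1", "g2", "g3"))
  expect_equal(dim(m2), c(3L, 3L))
  expect_equal(sum(m2), 3)
  expect_equal(sum(m2[, "L1:Z"]), 0)
  # empty set
  e <- build_count_matrix(collapse_molecules(make_reads(umi = character(0),
                                                        position = integer(0))))
  expect_equal(dim(e), c(0L, 0L))
})

test_that("counts round-trip through Matrix Market files", {
  sim <- zero_sim()
  res <- count_molecules(sim$mapped_reads)
  dir <- withr::local_tempdir()
  write_counts_mtx(res$counts, dir)
  back <- read_counts_mtx(dir)
  expect_equal(as.matrix(back), as.matrix(res$counts))
})

test_that("molecule counts never exceed kept reads and zero-noise is lossless", {
  sim <- default_sim()
  filt <- filter_mapped_reads(sim$mapped_reads)
  ms <- collapse_molecules(filt$kept)
  expect_lte(nrow(ms$molecules), nrow(filt$kept))
  cf <- chimera_filter(ms)
  expect_lte(nrow(cf$molecules$molecules), nrow(ms$molecules))

  zs <- zero_sim()
  zres <- count_molecules(zs$mapped_reads)
  tc <- truth_count_matrix(zs)
  obs <- build_count_matrix(zres$molecules, cells = colnames(tc),
                            genes = rownames(tc))
  expect_identical(as.matrix(obs), as.matrix(tc))
})

test_that("high UMI collision rates only ever undercount molecules", {
  cfg <- sim_config_zero_noise(n_wells = 200L, n_genes = 10L,
                               gene_length = 80L, markers_per_type = 2L,
                               molecules_meanlog = log(400),
                               molecules_sdlog = 0.2,
                               allow_umi_collisions = TRUE)
  sim <- simulate_run(cfg, seed = 99)
  res <- count_molecules(sim$mapped_reads)
  tc <- truth_count_matrix(sim)
  obs <- build_count_matrix(res$molecules, cells = colnames(tc),
                            genes = rownames(tc))
  expect_true(all(as.matrix(obs) <= as.matrix(tc)))
  expect_lt(sum(obs), sum(tc))  # collisions dense enough to bite
})
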