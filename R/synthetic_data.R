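# Seeded generative model of a full microwell run with planted ground
# truth: Poisson cell loading, Bernoulli bead fill with uniform barcode
# draws, two cell types with planted marker genes, log-normal library
# sizes, phantom barcodes as low-complexity emitters, PCR duplication,
# cross-cell chimeric reads, per-base substitution errors, and mapping
# position jitter (emulating aligner start-offset variation, the reason
# for the +/-6-base collapse window).

#' Configuration of a synthetic device run
#'
#' Defaults describe the reference experiment scale: a five-lane device
#' loaded at ~100 cells per 1,000 microwells, a 96 x 10 combinatorial
#' barcode pool, two cell types (one pure lane each plus mixed lanes),
#' ~2,000 molecules per cell, and phantom barcodes carrying ~1/200 of the
#' cell median molecule count but heavily PCR-duplicated -- phantoms are
#' low-complexity libraries, which is exactly what the downsampling cell
#' caller detects.
#'
#' @param n_wells total microwells across the device.
#' @param lambda_cells mean cells per well (Poisson).
#' @param bead_fill_prob probability a well holds a (single) bead; bead
#'   diameter excludes a second bead, so fill is Bernoulli.
#' @param n_lanes number of flow lanes; wells are split evenly.
#' @param pool a [build_pool()] result, or NULL to build a fresh
#'   [make_default_pool()] inside [simulate_run()]'s seed.
#' @param n_genes,gene_length synthetic annotation size.
#' @param markers_per_type planted marker genes per cell type.
#' @param marker_fold expression fold applied to a marker in its own type
#'   and divided out in the other type.
#' @param lane_mixture n_lanes x 2 matrix of type weights per lane;
#'   default: lane 1 pure type A, lane 2 pure type B, remaining lanes
#'   50:50 mixtures.
#' @param molecules_meanlog,molecules_sdlog log-normal molecules-per-cell
#'   parameters (median `exp(meanlog)`).
#' @param phantom_per_lane phantom barcodes per lane.
#' @param phantom_molecule_scale phantom molecule count relative to the
#'   cell median (default 1/200, the low end of the observed 200-300x
#'   deficit).
#' @param phantom_dup_mean mean extra PCR duplicates per phantom molecule.
#' @param pcr_duplicate_mean mean extra duplicates per cell molecule.
#' @param chimera_rate per-read probability of a cell-barcode swap within
#'   the lane (PCR jumping), preserving gene, UMI and position.
#' @param error_rate_barcode,error_rate_umi,error_rate_transcript per-base
#'   substitution rates.
#' @param multimap_rate,genome_overlap_rate,strand_violation_rate mapping
#'   flag rates: non-unique transcriptome hits, genome+transcriptome
#'   overlaps, and wrong-strand overlaps.
#' @param position_jitter_max maximum aligner start offset added per read.
#' @param umi_len UMI width.
#' @param r1_len,r2_len read lengths in cycles.
#' @param allow_umi_collisions if FALSE (default), planted molecules of
#'   the same cell and gene are redrawn until pairwise outside the
#'   collapse relation, so that a zero-noise run is exactly recoverable;
#'   TRUE plants raw uniform UMIs for studying collapse undercounting.
#' @return a `sim_config` object.
#' @export
sim_config <- function(n_wells = 1000L, lambda_cells = 0.1,
                       bead_fill_prob = 0.95, n_lanes = 5L, pool = NULL,
                       n_genes = 250L, gene_length = 500L,
                       markers_per_type = 25L, marker_fold = 4,
                       lane_mixture = NULL,
                       molecules_meanlog = log(2000),
                       molecules_sdlog = 0.3,
                       phantom_per_lane = 100L,
                       phantom_molecule_scale = 1 / 200,
                       phantom_dup_mean = 30,
                       pcr_duplicate_mean = 0.5,
                       chimera_rate = 0.01,
                       error_rate_barcode = 0.005,
                       error_rate_umi = 0.005,
                       error_rate_transcript = 0.005,
                       multimap_rate = 0.01,
                       genome_overlap_rate = 0.2,
                       strand_violation_rate = 0.05,
                       position_jitter_max = 3L,
                       umi_len = 8L, r1_len = 26L, r2_len = 60L,
                       allow_umi_collisions = FALSE) {
  if (is.null(lane_mixture)) {
    lane_mixture <- matrix(0.5, n_lanes, 2)
    lane_mixture[1, ] <- c(1, 0)
    if (n_lanes >= 2L) lane_mixture[2, ] <- c(0, 1)
  }
  probs <- c(bead_fill_prob, chimera_rate, error_rate_barcode,
             error_rate_umi, error_rate_transcript, multimap_rate,
             genome_overlap_rate, strand_violation_rate, lane_mixture)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (lambda_cells < 0) stop("lambda_cells must be >= 0")
  if (any(c(phantom_molecule_scale, marker_fold) <= 0))
    stop("scales must be > 0")
  if (nrow(lane_mixture) != n_lanes)
    stop("lane_mixture must have one row per lane")
  if (2L * markers_per_type > n_genes)
    stop("2 * markers_per_type must not exceed n_genes")
  tx_len <- r2_len - umi_len - 6L
  if (tx_len < 1L) stop("read 2 too short for UMI + lane barcode + transcript")
  if (gene_length < tx_len + position_jitter_max + 1L)
    stop("gene_length too short for the transcript window")
  structure(list(
    n_wells = as.integer(n_wells), lambda_cells = lambda_cells,
    bead_fill_prob = bead_fill_prob, n_lanes = as.integer(n_lanes),
    pool = pool, n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    markers_per_type = as.integer(markers_per_type),
    marker_fold = marker_fold, lane_mixture = lane_mixture,
    molecules_meanlog = molecules_meanlog,
    molecules_sdlog = molecules_sdlog,
    phantom_per_lane = as.integer(phantom_per_lane),
    phantom_molecule_scale = phantom_molecule_scale,
    phantom_dup_mean = phantom_dup_mean,
    pcr_duplicate_mean = pcr_duplicate_mean,
    chimera_rate = chimera_rate,
    error_rate_barcode = error_rate_barcode,
    error_rate_umi = error_rate_umi,
    error_rate_transcript = error_rate_transcript,
    multimap_rate = multimap_rate,
    genome_overlap_rate = genome_overlap_rate,
    strand_violation_rate = strand_violation_rate,
    position_jitter_max = as.integer(position_jitter_max),
    umi_len = as.integer(umi_len), r1_len = as.integer(r1_len),
    r2_len = as.integer(r2_len), tx_len = tx_len,
    allow_umi_collisions = allow_umi_collisions),
    class = "sim_config")
}

#' Zero-noise variant of a configuration
#'
#' Convenience: all error, duplication, chimera, phantom, jitter and
#' mapping-artifact rates set to zero, so every emitted read is one true
#' molecule and the pipeline must be lossless.
#'
#' @param ... overrides passed to [sim_config()].
#' @export
sim_config_zero_noise <- function(...) {
  args <- list(phantom_per_lane = 0L, phantom_dup_mean = 0,
               pcr_duplicate_mean = 0, chimera_rate = 0,
               error_rate_barcode = 0, error_rate_umi = 0,
               error_rate_transcript = 0, multimap_rate = 0,
               genome_overlap_rate = 0, strand_violation_rate = 0,
               position_jitter_max = 0L)
  override <- list(...)
  do.call(sim_config, utils::modifyList(args, override))
}

## Draw wells, cells and beads under the current RNG state.
draw_loading <- function(config) {
  n <- config$n_wells
  lanes <- paste0("L", rep(seq_len(config$n_lanes), length.out = n))
  lanes <- sort(lanes)
  wells <- data.table::data.table(
    well = seq_len(n), lane = lanes,
    n_cells = rpois(n, config$lambda_cells),
    bead = runif(n) < config$bead_fill_prob)
  wells[, barcode := NA_character_]
  wells[bead == TRUE,
        barcode := sample(barcodes_of(config), sum(bead), replace = TRUE)]
  wells
}

barcodes_of <- function(config) {
  if (is.null(config$pool)) stop("pool not materialized")
  config$pool$composites
}

#' Simulate well loading only
#'
#' Runs just the loading stage (Poisson cells, Bernoulli beads, uniform
#' barcode draws) -- cheap enough for distributional cross-checks against
#' the closed-form device model.
#'
#' @param config a [sim_config()]; a NULL pool is replaced by a
#'   [make_default_pool()].
#' @param seed RNG seed.
#' @return data.table of wells: well, lane, n_cells, bead, barcode.
#' @export
simulate_loading <- function(config = sim_config(), seed = NULL) {
  with_seed(seed, {
    if (is.null(config$pool)) config$pool <- make_default_pool()
    draw_loading(config)
  })
}

## Redraw UMI/position so that distinct planted molecules of one lane and
## gene sit pairwise outside the collapse relation -- including across
## barcodes, so the chimera filter cannot remove coincidental truth. This
## makes every pipeline loss attributable to planted artifacts.
resolve_collisions <- function(mols, config, max_iter = 50L) {
  pos_max <- config$gene_length - config$tx_len - config$position_jitter_max
  for (it in seq_len(max_iter)) {
    um <- dna_int_matrix(mols$umi)
    mols[, comp := 1L]
    mols[, n_in_grp := .N, by = .(lane, gene)]
    ## widen the window by the jitter so observed positions cannot drift
    ## two distinct molecules into the collapse relation
    win <- 6L + config$position_jitter_max
    mols[n_in_grp > 1L,
         comp := collapse_components(um[.I, , drop = FALSE], position,
                                     max_hamming = 2L, window = win),
         by = .(lane, gene)]
    mols[, dup := duplicated(comp), by = .(lane, gene)]
    n_bad <- sum(mols$dup)
    if (n_bad == 0L) break
    mols[dup == TRUE, `:=`(
      umi = random_dna(n_bad, config$umi_len),
      position = sample.int(pos_max, n_bad, replace = TRUE) - 1L)]
  }
  if (n_bad > 0L)
    stop("could not place collision-free molecules; group too dense")
  mols[, c("comp", "n_in_grp", "dup") := NULL]
  mols
}

#' Simulate a full device run with planted ground truth
#'
#' All randomness is drawn under `seed` (restored on exit), so identical
#' config + seed reproduce identical results byte for byte.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return a `sim_run` object with elements:
#'   `mapped_reads` (the mapped-read table the pipeline consumes),
#'   `truth` (wells, cells, molecules, reads with provenance, per-barcode
#'   summary with `is_real_cell`), `pool`, `lane_barcodes`, `genes`
#'   (names, sequences), `profiles` + `marker_genes`, and `config`.
#' @export
simulate_run <- function(config = sim_config(), seed = NULL) {
  with_seed(seed, {
    if (is.null(config$pool)) config$pool <- make_default_pool()
    pool <- config$pool
    lane_ids <- paste0("L", seq_len(config$n_lanes))
    lane_barcodes <- setNames(generate_barcodes(config$n_lanes, 6L), lane_ids)
    genes <- sprintf("g%03d", seq_len(config$n_genes))
    gene_seqs <- setNames(random_dna(config$n_genes, config$gene_length),
                          genes)

    ## expression profiles with planted two-sided markers
    nm <- config$markers_per_type
    base <- rgamma(config$n_genes, shape = 0.8) + 0.02
    marker_a <- genes[seq_len(nm)]
    marker_b <- genes[nm + seq_len(nm)]
    base[seq_len(2L * nm)] <- rgamma(2L * nm, shape = 2) + 0.5
    prof_a <- base; prof_b <- base
    prof_a[seq_len(nm)] <- base[seq_len(nm)] * config$marker_fold
    prof_a[nm + seq_len(nm)] <- base[nm + seq_len(nm)] / config$marker_fold
    prof_b[seq_len(nm)] <- base[seq_len(nm)] / config$marker_fold
    prof_b[nm + seq_len(nm)] <- base[nm + seq_len(nm)] * config$marker_fold
    profiles <- list(A = prof_a / sum(prof_a), B = prof_b / sum(prof_b))

    ## wells, cells, beads
    wells <- draw_loading(config)
    cells <- wells[rep(seq_len(.N), n_cells)]
    if (nrow(cells) == 0L) stop("no cells loaded; increase lambda or wells")
    cells <- cells[, .(well, lane, bead, barcode)]
    mix <- config$lane_mixture
    lane_idx <- match(cells$lane, lane_ids)
    cells[, type := ifelse(runif(.N) < mix[lane_idx, 1], "A", "B")]
    cells[, cell_id := sprintf("c%04d", seq_len(.N))]
    paired <- cells[bead == TRUE]

    ## molecules: bead-paired cells
    n_mol_cell <- pmax(1L, as.integer(round(
      rlnorm(nrow(paired), config$molecules_meanlog,
             config$molecules_sdlog))))
    mols <- paired[rep(seq_len(.N), n_mol_cell),
                   .(lane, barcode, cell_id, type)]
    mols[, gene := genes[unlist(lapply(seq_len(nrow(paired)), function(i)
      sample.int(config$n_genes, n_mol_cell[i], replace = TRUE,
                 prob = profiles[[paired$type[i]]])))]]
    mols[, origin := "cell"]
    mols[, dup_mean := config$pcr_duplicate_mean]

    ## phantom barcodes: few molecules, heavy duplication
    if (config$phantom_per_lane > 0L) {
      mean_prof <- (profiles$A + profiles$B) / 2
      lam <- exp(config$molecules_meanlog) * config$phantom_molecule_scale
      ph_list <- lapply(lane_ids, function(ln) {
        used <- unique(paired[lane == ln]$barcode)
        avail <- setdiff(pool$composites, used)
        if (config$phantom_per_lane > length(avail))
          stop("infeasible config: more phantom barcodes than unused pool ",
               "barcodes in lane ", ln)
        data.table::data.table(
          lane = ln,
          barcode = sample(avail, config$phantom_per_lane))
      })
      phantoms <- data.table::rbindlist(ph_list)
      n_mol_ph <- pmax(1L, rpois(nrow(phantoms), lam))
      ph_mols <- phantoms[rep(seq_len(.N), n_mol_ph)]
      ph_mols[, `:=`(cell_id = NA_character_, type = NA_character_,
                     gene = genes[sample.int(config$n_genes, .N,
                                             replace = TRUE,
                                             prob = mean_prof)],
                     origin = "phantom",
                     dup_mean = config$phantom_dup_mean)]
      mols <- rbind(mols, ph_mols)
    }

    ## UMI + position per molecule; keep same-group molecules separable
    pos_max <- config$gene_length - config$tx_len - config$position_jitter_max
    mols[, `:=`(umi = random_dna(.N, config$umi_len),
                position = sample.int(pos_max, .N, replace = TRUE) - 1L)]
    if (!config$allow_umi_collisions) mols <- resolve_collisions(mols, config)
    mols[, mol_id := sprintf("m%07d", seq_len(.N))]

    ## reads: molecule copies with PCR duplicates
    n_reads <- 1L + rpois(nrow(mols), mols$dup_mean)
    reads <- mols[rep(seq_len(.N), n_reads),
                  .(mol_id, lane, barcode, gene, umi, position, origin)]
    data.table::setnames(reads, "barcode", "barcode_true")
    reads[, read_id := sprintf("r%08d", seq_len(.N))]

    ## chimeras: cell-barcode swap within the lane, keeping gene/UMI/pos
    reads[, is_chimera := runif(.N) < config$chimera_rate]
    reads[, barcode := barcode_true]
    if (any(reads$is_chimera)) {
      for (ln in lane_ids) {
        cand <- unique(mols[lane == ln]$barcode)
        idx <- which(reads$is_chimera & reads$lane == ln)
        if (length(idx) == 0L || length(cand) < 2L) {
          reads[idx, is_chimera := FALSE]
          next
        }
        swap <- sample(cand, length(idx), replace = TRUE)
        for (tries in 1:20) {
          same <- swap == reads$barcode_true[idx]
          if (!any(same)) break
          swap[same] <- sample(cand, sum(same), replace = TRUE)
        }
        keep <- swap != reads$barcode_true[idx]
        reads[idx[!keep], is_chimera := FALSE]
        reads[idx[keep], barcode := swap[keep]]
      }
    }

    ## observed sequences: jitter + substitution errors
    reads[, position_obs := position +
            sample.int(config$position_jitter_max + 1L, .N,
                       replace = TRUE) - 1L]
    reads[, umi_obs := mutate_dna(umi, config$error_rate_umi)]
    reads[, barcode_obs := mutate_dna(barcode, config$error_rate_barcode)]
    reads[, lane_bc_obs := mutate_dna(lane_barcodes[lane],
                                      config$error_rate_barcode)]

    ## in-silico demultiplexing with 1-mismatch correction -> mapped table
    cellm <- match_barcode(reads$barcode_obs, pool$composites, 1L)
    lanem <- match_barcode(reads$lane_bc_obs, unname(lane_barcodes), 1L)
    assigned <- !is.na(cellm$match) & !is.na(lanem$match)
    reads[, status := ifelse(assigned, "assigned", "demux_lost")]
    reads[, barcode_assigned := cellm$match]
    reads[, lane_assigned := lane_ids[match(lanem$match,
                                            unname(lane_barcodes))]]

    n_r <- nrow(reads)
    reads[, `:=`(
      unique_tx = runif(n_r) >= config$multimap_rate,
      also_genome = runif(n_r) < config$genome_overlap_rate)]
    reads[, strand_ok := !also_genome | (runif(n_r) >=
                                           config$strand_violation_rate)]

    mapped <- reads[status == "assigned",
                    .(read_id, lane = lane_assigned,
                      cell_bc = barcode_assigned, umi = umi_obs, gene,
                      position = position_obs, strand = "+", unique_tx,
                      also_genome, strand_ok)]

    ## per-barcode truth summary
    bc_truth <- mols[, .(n_true_molecules = .N,
                         origin = origin[1L],
                         type = paste(sort(unique(stats::na.omit(type))),
                                      collapse = "+")),
                     by = .(lane, barcode)]
    bc_truth[, is_real_cell := origin == "cell"]
    bc_truth[type == "", type := NA_character_]

    structure(list(
      mapped_reads = mapped,
      truth = list(wells = wells, cells = cells,
                   molecules = mols[, .(mol_id, lane, barcode, cell_id,
                                        type, gene, umi, position, origin)],
                   reads = reads[, .(read_id, mol_id, lane, barcode_true,
                                     barcode, barcode_assigned, is_chimera,
                                     status, gene, position, position_obs,
                                     umi_obs, barcode_obs, lane_bc_obs)],
                   barcodes = bc_truth),
      pool = pool, lane_barcodes = lane_barcodes,
      genes = genes, gene_seqs = gene_seqs,
      profiles = profiles,
      marker_genes = list(A = marker_a, B = marker_b),
      config = config, seed = seed),
      class = "sim_run")
  })
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf(
    "sim_run: %d bead-paired cells, %d phantom barcodes, %d molecules, %d mapped reads\n",
    sum(x$truth$barcodes$is_real_cell),
    sum(!x$truth$barcodes$is_real_cell),
    nrow(x$truth$molecules), nrow(x$mapped_reads)))
  invisible(x)
}

#' Planted true count matrix of a simulated run
#'
#' @param sim a [simulate_run()] result.
#' @return genes x cells sparse matrix of true molecule counts per
#'   bead-paired barcode (`"lane:barcode"` columns).
#' @export
truth_count_matrix <- function(sim) {
  mols <- sim$truth$molecules[origin == "cell"]
  mols <- mols[, .(lane, cell_bc = barcode, gene)]
  ids <- paste(mols$lane, mols$cell_bc, sep = ":")
  cells <- sort(unique(ids))
  m <- Matrix::sparseMatrix(
    i = match(mols$gene, sim$genes), j = match(ids, cells),
    x = rep(1L, nrow(mols)),
    dims = c(length(sim$genes), length(cells)),
    dimnames = list(sim$genes, cells))
  methods::as(m, "CsparseMatrix")
}

#' Synthetic bulk expression profile of one cell type
#'
#' FPKM-like values proportional to the type's planted gene profile,
#' scaled to one million.
#'
#' @param sim a [simulate_run()] result.
#' @param type `"A"` or `"B"`.
#' @return data.frame with `gene` and `fpkm`.
#' @export
sim_bulk_profile <- function(sim, type = c("A", "B")) {
  type <- match.arg(type)
  data.frame(gene = sim$genes, fpkm = sim$profiles[[type]] * 1e6,
             stringsAsFactors = FALSE)
}

#' Write simulated outputs to disk
#'
#' Emits the mapped-read table, truth tables, whitelists, and (optionally)
#' paired FASTQ honoring the read structure: read 1 = composite cell
#' barcode + poly(dT) to `r1_len` cycles; read 2 = UMI + lane barcode +
#' transcript window (from the true start position; observed substitution
#' errors applied). Byte-stable for a given simulation.
#'
#' @param sim a [simulate_run()] result.
#' @param dir output directory (created).
#' @param formats subset of `"table"`, `"truth"`, `"fastq"`.
#' @param gzip compress FASTQ output?
#' @return named list of written paths.
#' @export
write_sim_outputs <- function(sim, dir,
                              formats = c("table", "truth"),
                              gzip = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- list()
  if ("table" %in% formats) {
    out$mapped_reads <- file.path(dir, "mapped_reads.tsv")
    write_mapped_table(sim$mapped_reads, out$mapped_reads)
  }
  if ("truth" %in% formats) {
    for (nm in c("barcodes", "molecules", "reads", "cells")) {
      fp <- file.path(dir, paste0("truth_", nm, ".tsv"))
      write_tsv_file(as.data.frame(sim$truth[[nm]]), fp)
      out[[paste0("truth_", nm)]] <- fp
    }
    out$cell_whitelist <- file.path(dir, "cell_whitelist.tsv")
    write_whitelist(setNames(sim$pool$composites,
                             sprintf("cb%04d",
                                     seq_along(sim$pool$composites))),
                    out$cell_whitelist)
    out$lane_whitelist <- file.path(dir, "lane_whitelist.tsv")
    write_whitelist(sim$lane_barcodes, out$lane_whitelist)
  }
  if ("fastq" %in% formats) {
    cfg <- sim$config
    full <- sim$truth$reads
    tx <- substr(sim$gene_seqs[full$gene],
                 full$position + 1L, full$position + cfg$tx_len)
    tx <- mutate_dna_fixed(tx, cfg$error_rate_transcript, sim$seed)
    r1 <- paste0(full$barcode_obs,
                 strrep("T", cfg$r1_len - nchar(full$barcode_obs[1L])))
    r2 <- paste0(full$umi_obs, full$lane_bc_obs, tx)
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    out$r1 <- file.path(dir, paste0("reads_R1", ext))
    out$r2 <- file.path(dir, paste0("reads_R2", ext))
    write_fastq_bs(full$read_id, r1, out$r1)
    write_fastq_bs(full$read_id, r2, out$r2)
  }
  out
}

## transcript errors must be reproducible independently of when FASTQ is
## written: use a sub-seed derived from the run seed
mutate_dna_fixed <- function(x, rate, seed) {
  if (rate <= 0) return(x)
  with_seed(if (is.null(seed)) NULL else seed + 104729L,
            mutate_dna(x, rate))
}

write_fastq_bs <- function(ids, seqs, path) {
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  Biostrings::writeXStringSet(
    dna, path, format = "fastq", compress = grepl("\\.gz$", path),
    qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
  invisible(path)
}
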