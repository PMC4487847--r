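# Cell-barcode calling by read downsampling.
#
# Real bead-paired cells yield complex libraries: downsampled to a common
# read total they retain nearly as many unique molecules as reads, while
# phantom barcodes (sequencing error, cross-talk, spurious capture, PCR
# jumping) are low-complexity and plateau at far fewer molecules. The
# distribution of log10 unique molecules at a fixed depth is therefore
# bimodal, and a two-class Otsu split with a bimodality guard separates
# cells from phantoms.

## unique molecules in a set of kept reads (collapse across genes)
count_unique_molecules <- function(reads, umi_hamming_max = 2L,
                                   position_window = 6L) {
  nrow(collapse_molecules(reads, umi_hamming_max,
                          position_window)$molecules)
}

#' Unique molecules after downsampling one barcode to a fixed depth
#'
#' Samples `depth` reads uniformly without replacement from one barcode's
#' kept reads, applies the molecule collapse, and counts molecules.
#'
#' @param reads kept mapped reads of a single (lane, barcode).
#' @param depth number of reads to sample; must not exceed the available
#'   reads (callers exclude the barcode at that depth instead).
#' @param seed optional RNG seed (restored on exit).
#' @param umi_hamming_max,position_window collapse parameters.
#' @return integer unique-molecule count.
#' @export
downsample_unique_molecules <- function(reads, depth, seed = NULL,
                                        umi_hamming_max = 2L,
                                        position_window = 6L) {
  reads <- data.table::as.data.table(reads)
  n <- nrow(reads)
  if (depth > n)
    stop("depth (", depth, ") exceeds available reads (", n, ")")
  with_seed(seed, {
    idx <- if (depth == n) seq_len(n) else sample.int(n, depth)
    count_unique_molecules(reads[idx], umi_hamming_max, position_window)
  })
}

#' Downsampling curve for one barcode
#'
#' @inheritParams downsample_unique_molecules
#' @param depths vector of read depths; depths above the barcode's total
#'   are skipped.
#' @return data.frame with `depth` and `unique_molecules`.
#' @export
downsample_curve <- function(reads, depths, seed = NULL,
                             umi_hamming_max = 2L, position_window = 6L) {
  reads <- data.table::as.data.table(reads)
  depths <- sort(depths[depths <= nrow(reads)])
  um <- vapply(seq_along(depths), function(i) {
    s <- if (is.null(seed)) NULL else seed + i
    downsample_unique_molecules(reads, depths[i], s,
                                umi_hamming_max, position_window)
  }, integer(1))
  data.frame(depth = depths, unique_molecules = um)
}

#' Call cell barcodes by downsampling and bimodal splitting
#'
#' Barcodes with zero molecules are excluded up front. At each grid depth,
#' every remaining barcode with at least that many reads is downsampled to
#' the depth and its log10 unique-molecule count enters a two-class Otsu
#' split. A split is accepted only when its between/total variance ratio
#' reaches `min_bimodality`; barcodes above the threshold vote cell,
#' barcodes below vote phantom, and barcodes with too few reads for the
#' depth vote phantom (their library could not sustain the depth). When
#' the qualifying values admit no split but some barcodes were excluded,
#' qualification itself is the evidence: qualifiers vote cell, the
#' excluded vote phantom. The final call is the majority vote across
#' depths. If no depth yields any vote the population is unimodal: status
#' `"no_split"` is returned and all barcodes are reported as one (cell)
#' population rather than arbitrarily partitioned.
#'
#' The depth grid is capped at the 10th-percentile barcode read total so
#' that "progressively downsampling to the same number of total reads"
#' keeps most barcodes comparable; if the cap undercuts the whole grid the
#' cap itself is used as the single depth.
#'
#' @param reads kept mapped reads for many barcodes (columns as in
#'   [read_mapped_table()]).
#' @param depth_grid candidate read depths.
#' @param seed optional RNG seed; calls are invariant to barcode input
#'   order (barcodes are processed in sorted order).
#' @param cap_quantile quantile of barcode read totals capping the grid.
#' @param min_bimodality minimum between/total variance ratio for an
#'   accepted split (unimodal samples reach ~0.6-0.7; genuine cell/phantom
#'   mixtures land near 0.9).
#' @param umi_hamming_max,position_window collapse parameters.
#' @param apply_chimera_filter if TRUE (default), the per-barcode
#'   full-data molecule counts (and hence the median ratio and the
#'   zero-molecule exclusion) are taken after [chimera_filter()],
#'   mirroring the pipeline order in which molecule filtering precedes
#'   cell identification; downsampled counts are per-barcode and are
#'   unaffected.
#' @return a `cell_calls` object: `table` (data.table: lane, cell_bc,
#'   total_reads, molecules, called_cell), `cell_barcodes`,
#'   `phantom_barcodes` (as `"lane:barcode"` ids), `thresholds` per depth,
#'   `median_ratio` (median cell molecules / median phantom molecules),
#'   and `status` (`"ok"` or `"no_split"`).
#' @export
call_cells <- function(reads, depth_grid = c(100L, 300L, 1000L, 3000L),
                       seed = NULL, cap_quantile = 0.10,
                       min_bimodality = 0.75, umi_hamming_max = 2L,
                       position_window = 6L, apply_chimera_filter = TRUE) {
  reads <- data.table::copy(data.table::as.data.table(reads))
  if (nrow(reads) == 0L) {
    return(structure(list(table = data.table::data.table(),
                          cell_barcodes = character(0),
                          phantom_barcodes = character(0),
                          thresholds = numeric(0), median_ratio = NA_real_,
                          status = "no_split"),
                     class = "cell_calls"))
  }
  reads[, cell_id := paste(lane, cell_bc, sep = ":")]
  data.table::setorder(reads, cell_id)

  molset <- collapse_molecules(reads, umi_hamming_max, position_window)
  if (apply_chimera_filter) molset <- chimera_filter(molset)$molecules
  full <- molset$molecules
  mol_tab <- full[, .(molecules = .N), by = .(lane, cell_bc)]
  mol_tab[, cell_id := paste(lane, cell_bc, sep = ":")]
  tot_tab <- reads[, .(total_reads = .N), by = cell_id]
  tab <- merge(mol_tab, tot_tab, by = "cell_id")
  tab <- tab[molecules > 0L]
  data.table::setorder(tab, cell_id)
  if (nrow(tab) < 2L) {
    return(structure(list(table = tab, cell_barcodes = tab$cell_id,
                          phantom_barcodes = character(0),
                          thresholds = numeric(0), median_ratio = NA_real_,
                          status = "no_split"),
                     class = "cell_calls"))
  }

  cap <- as.numeric(quantile(tab$total_reads, cap_quantile, type = 1))
  depths <- sort(depth_grid[depth_grid <= cap])
  if (length(depths) == 0L) depths <- max(1L, as.integer(floor(cap)))

  read_idx <- split(seq_len(nrow(reads)), reads$cell_id)
  n_bc <- nrow(tab)
  votes <- matrix(NA, n_bc, length(depths))
  thresholds <- setNames(rep(NA_real_, length(depths)), as.character(depths))
  with_seed(seed, {
    for (d in seq_along(depths)) {
      depth <- depths[d]
      qual <- which(tab$total_reads >= depth)
      if (length(qual) == 0L) next
      um <- vapply(qual, function(b) {
        idx <- read_idx[[tab$cell_id[b]]]
        take <- if (length(idx) == depth) idx else
          idx[sample.int(length(idx), depth)]
        count_unique_molecules(reads[take], umi_hamming_max,
                               position_window)
      }, integer(1))
      lg <- log10(um)
      sp <- otsu_split(lg)
      excl <- setdiff(seq_len(n_bc), qual)
      if (!is.na(sp$threshold) && sp$eta >= min_bimodality) {
        thresholds[d] <- sp$threshold
        votes[qual, d] <- as.numeric(lg > sp$threshold)
        votes[excl, d] <- 0
      } else if (length(excl) > 0L) {
        # qualifiers are one tight mode; reaching the depth at all is the
        # separating evidence
        votes[qual, d] <- 1
        votes[excl, d] <- 0
      }
    }
  })

  vote_n <- rowSums(!is.na(votes))
  if (all(vote_n == 0L)) {
    return(structure(list(table = cbind(tab, called_cell = TRUE),
                          cell_barcodes = tab$cell_id,
                          phantom_barcodes = character(0),
                          thresholds = thresholds, median_ratio = NA_real_,
                          status = "no_split"),
                     class = "cell_calls"))
  }
  frac <- rowMeans(votes, na.rm = TRUE)
  frac[vote_n == 0L] <- 0        # no qualifying depth: not a cell
  called <- frac >= 0.5
  tab[, called_cell := called]
  cells <- tab$cell_id[called]
  phantoms <- tab$cell_id[!called]
  median_ratio <- if (length(cells) && length(phantoms)) {
    median(tab$molecules[called]) / median(tab$molecules[!called])
  } else NA_real_
  structure(list(table = tab, cell_barcodes = cells,
                 phantom_barcodes = phantoms, thresholds = thresholds,
                 median_ratio = median_ratio, status = "ok"),
            class = "cell_calls")
}

#' @export
print.cell_calls <- function(x, ...) {
  cat(sprintf(
    "cell_calls (%s): %d cells, %d phantoms, median molecule ratio %.1f\n",
    x$status, length(x$cell_barcodes), length(x$phantom_barcodes),
    x$median_ratio))
  invisible(x)
}

#' Write cell-call outputs
#'
#' Emits `cell_calls.tsv` (barcode, total_reads, molecules, called_cell)
#' and `cell_calls.json` (thresholds, median ratio, status) in `dir`.
#'
#' @param calls a [call_cells()] result.
#' @param dir output directory.
#' @export
write_cell_calls <- function(calls, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv_file(as.data.frame(calls$table),
                 file.path(dir, "cell_calls.tsv"))
  jsonlite::write_json(
    list(status = calls$status,
         n_cells = length(calls$cell_barcodes),
         n_phantoms = length(calls$phantom_barcodes),
         thresholds = as.list(calls$thresholds),
         median_ratio = calls$median_ratio),
    file.path(dir, "cell_calls.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}
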