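# Mapped reads -> unique molecules -> cell x gene counts.
#
# Each mapped read carries an address (cell barcode, gene, UMI, mapping
# position). Reads whose UMIs are within Hamming distance 2 and whose
# positions are within six bases (inclusive) of each other are considered
# the same molecule; since that pairwise relation is not transitive, a
# connected-components merge is the only order-independent reading of
# "collapsed to a single molecule", and identical addresses are simply
# distance-0 edges of the same graph. Molecules observed under different
# cell barcodes in the same lane are treated as PCR chimeras and removed
# entirely.

MAPPED_READ_COLS <- c("lane", "cell_bc", "umi", "gene", "position",
                      "strand", "unique_tx", "also_genome", "strand_ok")

#' Read a mapped-read table
#'
#' The table stands in for aligner plus gene-assignment output: one row
#' per read with columns `lane`, `cell_bc`, `umi`, `gene`, `position`
#' (0-based leftmost mapped coordinate), `strand`, and the logical mapping
#' flags `unique_tx`, `also_genome`, `strand_ok`.
#'
#' @param path TSV file with header.
#' @return a data.table.
#' @export
read_mapped_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  missing <- setdiff(MAPPED_READ_COLS, names(dt))
  if (length(missing))
    stop("mapped-read table lacks columns: ", paste(missing, collapse = ", "))
  for (cc in c("unique_tx", "also_genome", "strand_ok"))
    dt[[cc]] <- as.logical(dt[[cc]])
  dt
}

#' Write a mapped-read table
#'
#' @param reads data.frame/data.table of mapped reads.
#' @param path output TSV path.
#' @export
write_mapped_table <- function(reads, path) {
  write_tsv_file(as.data.frame(reads), path)
}

#' Filter mapped reads by mapping-uniqueness and strand flags
#'
#' Keeps reads that mapped uniquely to the transcriptome; reads that also
#' hit the genome are kept only when the transcriptome hit has the
#' appropriate strand orientation. Records with missing flags are dropped
#' and tallied.
#'
#' @param reads mapped-read data.table (see [read_mapped_table()]).
#' @return list with `kept` (data.table) and `tally` (named integer vector
#'   of kept / rejection-reason counts).
#' @export
filter_mapped_reads <- function(reads) {
  reads <- data.table::as.data.table(reads)
  flags_na <- is.na(reads$unique_tx) | is.na(reads$also_genome) |
    is.na(reads$strand_ok)
  keep <- !flags_na & reads$unique_tx &
    (!reads$also_genome | reads$strand_ok)
  reason <- rep("kept", nrow(reads))
  reason[flags_na] <- "missing_flags"
  reason[!flags_na & !reads$unique_tx] <- "multimapped"
  reason[!flags_na & reads$unique_tx & reads$also_genome &
           !reads$strand_ok] <- "strand_violation"
  tally <- c(kept = sum(keep),
             multimapped = sum(reason == "multimapped"),
             strand_violation = sum(reason == "strand_violation"),
             missing_flags = sum(reason == "missing_flags"))
  list(kept = reads[keep], tally = tally)
}

#' Collapse reads into unique molecules
#'
#' Within each (lane, cell barcode, gene) group, reads are linked when
#' their UMIs are within `umi_hamming_max` substitutions AND their mapping
#' positions are within `position_window` bases (both inclusive); each
#' connected component is one molecule. The mapping position is the
#' aligner-reported leftmost coordinate; the position window absorbs
#' aligner start-offset variation, so no soft-clip adjustment is made.
#' The reported representative is the lexicographically smallest
#' (umi, position) of the component, which fixes output bytes without
#' affecting counts.
#'
#' @param reads kept mapped reads (post [filter_mapped_reads()]).
#' @param umi_hamming_max maximum UMI Hamming distance (default 2).
#' @param position_window maximum position difference in bases (default 6,
#'   inclusive).
#' @return a `molecule_set`: list with `molecules` (data.table: lane,
#'   cell_bc, gene, umi, position, read_support) and `params`.
#' @export
collapse_molecules <- function(reads, umi_hamming_max = 2L,
                               position_window = 6L) {
  dt <- data.table::copy(data.table::as.data.table(reads))
  if (nrow(dt) == 0L) {
    mols <- data.table::data.table(
      lane = character(0), cell_bc = character(0), gene = character(0),
      umi = character(0), position = integer(0), read_support = integer(0))
    return(structure(list(molecules = mols,
                          params = list(umi_hamming_max = umi_hamming_max,
                                        position_window = position_window)),
                     class = "molecule_set"))
  }
  if (length(unique(nchar(dt$umi))) != 1L)
    stop("UMIs must all have the same length")
  um <- dna_int_matrix(dt$umi)
  dt[, comp := 1L]
  dt[, n_in_grp := .N, by = .(lane, cell_bc, gene)]
  if (any(dt$n_in_grp > 1L)) {
    dt[n_in_grp > 1L,
       comp := collapse_components(um[.I, , drop = FALSE], position,
                                   umi_hamming_max, position_window),
       by = .(lane, cell_bc, gene)]
  }
  mols <- dt[, {
    o <- order(umi, position)[1L]
    list(umi = umi[o], position = position[o], read_support = .N)
  }, by = .(lane, cell_bc, gene, comp)]
  mols[, comp := NULL]
  data.table::setorder(mols, lane, cell_bc, gene, umi, position)
  structure(list(molecules = mols,
                 params = list(umi_hamming_max = umi_hamming_max,
                               position_window = position_window)),
            class = "molecule_set")
}

#' @export
print.molecule_set <- function(x, ...) {
  cat(sprintf("molecule_set: %d molecules, %d cells, %d genes\n",
              nrow(x$molecules),
              data.table::uniqueN(x$molecules[, .(lane, cell_bc)]),
              data.table::uniqueN(x$molecules$gene)))
  invisible(x)
}

#' Remove cross-barcode chimeric molecules
#'
#' Within one lane and gene, molecules from different cell barcodes that
#' satisfy the collapse criterion (UMI Hamming <= 2 and position within
#' six bases, using molecule representatives) are PCR chimeras: the
#' amplification joined a molecule's UMI and gene to the wrong cell
#' barcode, so the true cell of origin is unknowable. Every molecule of
#' such a cross-cell cluster is removed; `keep_dominant = TRUE` instead
#' retains, per cluster, the molecules of the barcode with the largest
#' read support (off by default).
#'
#' @param molset a [collapse_molecules()] result.
#' @param keep_dominant retain the best-supported barcode per cluster?
#' @return list with `molecules` (a filtered `molecule_set`) and `removed`
#'   (data.table of removed molecules with the barcodes of their cluster).
#' @export
chimera_filter <- function(molset, keep_dominant = FALSE) {
  stopifnot(inherits(molset, "molecule_set"))
  mols <- data.table::copy(molset$molecules)
  p <- molset$params
  if (nrow(mols) == 0L) {
    return(list(molecules = molset,
                removed = cbind(mols, cluster_barcodes = character(0))))
  }
  um <- dna_int_matrix(mols$umi)
  mols[, comp := 1L]
  mols[, n_in_grp := .N, by = .(lane, gene)]
  mols[n_in_grp > 1L,
       comp := collapse_components(um[.I, , drop = FALSE], position,
                                   p$umi_hamming_max, p$position_window),
       by = .(lane, gene)]
  mols[, removed := data.table::uniqueN(cell_bc) > 1L,
       by = .(lane, gene, comp)]
  if (keep_dominant) {
    mols[removed == TRUE, removed := {
      support <- tapply(read_support, cell_bc, sum)
      best <- names(support)[which.max(support)]
      cell_bc != best
    }, by = .(lane, gene, comp)]
  }
  removed <- mols[removed == TRUE]
  if (nrow(removed)) {
    removed[, cluster_barcodes := paste(sort(unique(cell_bc)),
                                        collapse = ","),
            by = .(lane, gene, comp)]
  } else {
    removed[, cluster_barcodes := character(0)]
  }
  kept <- mols[removed == FALSE,
               .(lane, cell_bc, gene, umi, position, read_support)]
  removed <- removed[, .(lane, cell_bc, gene, umi, position, read_support,
                         cluster_barcodes)]
  list(molecules = structure(list(molecules = kept, params = p),
                             class = "molecule_set"),
       removed = removed)
}

#' Build the cell x gene molecule-count matrix
#'
#' @param molset a `molecule_set` (typically after [chimera_filter()]).
#' @param cells,genes optional fixed axes (character vectors); defaults to
#'   the cells/genes observed in the molecule set. Cells are identified as
#'   `"<lane>:<cell_bc>"` since the same bead barcode in different lanes
#'   labels different cells.
#' @return a sparse `dgCMatrix`, genes in rows, cells in columns; entries
#'   are unique-molecule counts.
#' @export
build_count_matrix <- function(molset, cells = NULL, genes = NULL) {
  mols <- if (inherits(molset, "molecule_set")) molset$molecules else molset
  ids <- if (nrow(mols)) paste(mols$lane, mols$cell_bc, sep = ":") else character(0)
  if (is.null(cells)) cells <- sort(unique(ids))
  if (is.null(genes)) genes <- sort(unique(mols$gene))
  m <- Matrix::sparseMatrix(
    i = match(mols$gene, genes),
    j = match(ids, cells),
    x = rep(1L, nrow(mols)),
    dims = c(length(genes), length(cells)),
    dimnames = list(genes, cells))
  methods::as(m, "CsparseMatrix")
}

#' Write counts as a Matrix Market triple
#'
#' Emits `matrix.mtx`, `barcodes.tsv` (cell ids) and `genes.tsv` in `dir`.
#'
#' @param counts genes x cells sparse matrix.
#' @param dir output directory (created if needed).
#' @export
write_counts_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' Read a Matrix Market counts directory written by [write_counts_mtx()]
#'
#' @param dir directory containing matrix.mtx, barcodes.tsv, genes.tsv.
#' @return genes x cells sparse `dgCMatrix`.
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  methods::as(m, "CsparseMatrix")
}

#' Run the full molecule-counting stage
#'
#' Convenience chain: [filter_mapped_reads()] -> [collapse_molecules()] ->
#' [chimera_filter()] -> [build_count_matrix()].
#'
#' @param reads mapped-read table (data.table or path).
#' @inheritParams collapse_molecules
#' @inheritParams chimera_filter
#' @return list with `counts`, `molecules` (filtered molecule_set),
#'   `removed` (chimera log), and `tally` (read-filter tally).
#' @export
count_molecules <- function(reads, umi_hamming_max = 2L,
                            position_window = 6L, keep_dominant = FALSE) {
  if (is.character(reads)) reads <- read_mapped_table(reads)
  filt <- filter_mapped_reads(reads)
  molset <- collapse_molecules(filt$kept, umi_hamming_max, position_window)
  chi <- chimera_filter(molset, keep_dominant)
  list(counts = build_count_matrix(chi$molecules),
       molecules = chi$molecules,
       removed = chi$removed,
       tally = filt$tally)
}
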