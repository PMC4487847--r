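# Two-round combinatorial barcode pool: construction, validation, capture
# primer assembly, and whitelist / plate-map I/O.

#' Build a two-round combinatorial barcode pool
#'
#' Beads receive a first-round barcode in a multi-well plate, are pooled,
#' and then receive a second-round barcode primed off a universal anchor
#' sequence. Every first x second combination therefore exists in the final
#' pool, and the composite cell-identifying barcode physically present on a
#' bead (and in read 1) is `BC1 + anchor + BC2`.
#'
#' @param first_barcodes character vector of round-1 barcodes (one per well
#'   of the first plate), equal width, A/C/G/T only.
#' @param second_barcodes character vector of round-2 barcodes, equal width.
#' @param anchor the universal anchor sequence joining the two halves
#'   (6 bases in the reference design).
#' @return An object of class `barcode_pool` with elements
#'   `first_barcodes`, `second_barcodes`, `anchor` and `composites`.
#'   Composites are ordered row-major with the first-round index varying
#'   slowest.
#' @examples
#' p <- build_pool(c("AAAA", "CCCC"), c("GG", "TT"), anchor = "AC")
#' p$composites
#' @export
build_pool <- function(first_barcodes, second_barcodes, anchor) {
  check_round <- function(x, what) {
    if (length(x) == 0L) stop(what, " barcode list is empty", call. = FALSE)
    stopifnot_dna(x, what)
    if (length(unique(nchar(x))) != 1L)
      stop(what, " barcodes must all have the same length", call. = FALSE)
    dup <- unique(x[duplicated(x)])
    if (length(dup))
      stop("duplicate ", what, " barcodes: ",
           paste(dup, collapse = ", "), call. = FALSE)
    x
  }
  check_round(first_barcodes, "first-round")
  check_round(second_barcodes, "second-round")
  if (length(anchor) != 1L) stop("anchor must be a single string")
  stopifnot_dna(anchor, "anchor")

  grid <- expand.grid(bc2 = second_barcodes, bc1 = first_barcodes,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  composites <- paste0(grid$bc1, anchor, grid$bc2)
  structure(
    list(first_barcodes = first_barcodes,
         second_barcodes = second_barcodes,
         anchor = anchor,
         composites = composites),
    class = "barcode_pool")
}

#' @export
print.barcode_pool <- function(x, ...) {
  cat(sprintf(
    "barcode_pool: %d x %d rounds -> %d composites (BC1 %d nt + anchor %d nt + BC2 %d nt)\n",
    length(x$first_barcodes), length(x$second_barcodes),
    length(x$composites), nchar(x$first_barcodes[1]), nchar(x$anchor),
    nchar(x$second_barcodes[1])))
  invisible(x)
}

#' Validate the pairwise separation of a barcode pool
#'
#' Single-mismatch demultiplexing corrects every 1-error read unambiguously
#' if and only if all composite pairs are at Hamming distance >= 3, so the
#' default requirement is 3. The report lists every offending pair.
#'
#' @param pool a [build_pool()] result, or a character vector of composites.
#' @param min_pairwise_hamming required minimum pairwise distance.
#' @return list with `pass` (logical), `min_distance`, and `violations`
#'   (data.frame of composite pairs below the requirement).
#' @export
validate_pool <- function(pool, min_pairwise_hamming = 3L) {
  composites <- if (inherits(pool, "barcode_pool")) pool$composites else pool
  if (length(unique(nchar(composites))) != 1L)
    stop("composites must all have the same length")
  m <- dna_int_matrix(composites)
  n <- length(composites)
  viol_i <- integer(0); viol_j <- integer(0); viol_d <- integer(0)
  min_d <- nchar(composites[1L])
  # one row against all later rows; avoids an n x n allocation for big pools
  for (i in seq_len(max(n - 1L, 0L))) {
    rest <- (i + 1L):n
    d <- hamming_to_all(m[i, ], m[rest, , drop = FALSE])
    min_d <- min(min_d, d)
    low <- which(d < min_pairwise_hamming)
    if (length(low)) {
      viol_i <- c(viol_i, rep.int(i, length(low)))
      viol_j <- c(viol_j, rest[low])
      viol_d <- c(viol_d, d[low])
    }
  }
  violations <- data.frame(
    i = viol_i, j = viol_j,
    composite_i = composites[viol_i], composite_j = composites[viol_j],
    distance = as.integer(viol_d), stringsAsFactors = FALSE)
  list(pass = nrow(violations) == 0L,
       min_distance = as.integer(min_d),
       violations = violations)
}

#' Assemble a capture primer sequence
#'
#' The capture primer is, 5' to 3': T7 promoter sequence (TPS), partial
#' Illumina sequencing adapter (ISA), composite barcode (BC1 + anchor +
#' BC2), then oligo(dT). The TPS allows linear pre-amplification by in
#' vitro transcription; the ISA allows library enrichment by PCR.
#'
#' @param tps,isa 5' constant segments (non-empty).
#' @param composite_barcode composite cell-identifying barcode.
#' @param dT_length number of T bases in the oligo(dT) tail (>= 1).
#' @return the assembled primer sequence (character scalar).
#' @export
assemble_capture_primer <- function(tps, isa, composite_barcode, dT_length) {
  if (!nzchar(tps)) stop("tps must be non-empty")
  if (!nzchar(isa)) stop("isa must be non-empty")
  stopifnot_dna(c(tps, isa, composite_barcode), "primer segments")
  if (dT_length < 1L) stop("dT_length must be >= 1")
  paste0(tps, isa, composite_barcode, strrep("T", dT_length))
}

#' Recover barcode halves from an assembled capture primer
#'
#' Inverse of [assemble_capture_primer()] given the segment lengths.
#'
#' @param primer assembled primer sequence.
#' @param tps_len,isa_len,bc1_len,anchor_len,bc2_len segment widths.
#' @return list with `bc1`, `anchor`, `bc2`, `dT_length`.
#' @export
parse_capture_primer <- function(primer, tps_len, isa_len, bc1_len,
                                 anchor_len, bc2_len) {
  min_len <- tps_len + isa_len + bc1_len + anchor_len + bc2_len + 1L
  if (nchar(primer) < min_len)
    stop("primer shorter than the declared segments plus one dT base")
  off <- tps_len + isa_len
  bc1 <- substr(primer, off + 1L, off + bc1_len)
  anchor <- substr(primer, off + bc1_len + 1L, off + bc1_len + anchor_len)
  bc2_start <- off + bc1_len + anchor_len + 1L
  bc2 <- substr(primer, bc2_start, bc2_start + bc2_len - 1L)
  tail <- substr(primer, bc2_start + bc2_len, nchar(primer))
  if (!grepl("^T+$", tail))
    stop("primer tail after BC2 is not oligo(dT)")
  list(bc1 = bc1, anchor = anchor, bc2 = bc2, dT_length = nchar(tail))
}

#' Generate a random well-separated barcode set
#'
#' Greedy rejection sampling of fixed-width random barcodes such that all
#' pairwise Hamming distances are at least `min_hamming`. Draws from the
#' current RNG state; seed externally (e.g. `set.seed()`) for
#' reproducibility.
#'
#' @param n number of barcodes.
#' @param width barcode width in bases.
#' @param min_hamming required pairwise minimum distance (default 3 so that
#'   single-mismatch correction is collision-free).
#' @param max_tries candidate draws before giving up.
#' @return character vector of `n` barcodes.
#' @export
generate_barcodes <- function(n, width, min_hamming = 3L, max_tries = 10000L * n) {
  if (n < 1L) stop("n must be >= 1")
  kept <- character(0)
  mat <- matrix(integer(0), nrow = 0L, ncol = width)
  tries <- 0L
  while (length(kept) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n, " barcodes of width ", width,
           " at pairwise distance >= ", min_hamming)
    cand <- random_dna(1L, width)
    v <- utf8ToInt(cand)
    if (nrow(mat) == 0L || all(hamming_to_all(v, mat) >= min_hamming)) {
      kept <- c(kept, cand)
      mat <- rbind(mat, v)
    }
  }
  kept
}

#' Construct the reference 96 x 10 pool with generated barcodes
#'
#' The actual production barcode sequences are supplied as whitelists by
#' the user; this helper generates a structurally equivalent pool (96
#' first-round 8-mers, 10 second-round 6-mers, a 6-base anchor, composite
#' width 20 so that barcode plus 6 dT bases fill a 26-cycle read 1) with
#' all composites at pairwise Hamming distance >= 3. Uses the current RNG
#' state.
#'
#' @param n_first,n_second round sizes.
#' @param bc1_len,bc2_len,anchor_len segment widths in bases.
#' @return a `barcode_pool`.
#' @export
make_default_pool <- function(n_first = 96L, n_second = 10L, bc1_len = 8L,
                              bc2_len = 6L, anchor_len = 6L) {
  repeat {
    bc1 <- generate_barcodes(n_first, bc1_len, min_hamming = 3L)
    bc2 <- generate_barcodes(n_second, bc2_len, min_hamming = 3L)
    anchor <- random_dna(1L, anchor_len)
    pool <- build_pool(bc1, bc2, anchor)
    # segment-wise distance >= 3 guarantees composite distance >= 3, but
    # verify explicitly so the returned pool always carries the property
    if (validate_pool(pool, 3L)$pass) return(pool)
  }
}

#' Read a barcode whitelist
#'
#' Accepts headerless two-column TSV (`barcode_id`, `sequence`) or FASTA.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"fasta"`.
#' @return named character vector of sequences (names = ids).
#' @export
read_whitelist <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta)(\\.gz)?$", path)) "fasta" else "tsv"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readDNAStringSet(path)
    out <- as.character(seqs)
    names(out) <- sub(" .*", "", names(seqs))
  } else {
    tab <- read.table(path, sep = "\t", header = FALSE,
                      col.names = c("barcode_id", "sequence"),
                      colClasses = "character")
    out <- setNames(tab$sequence, tab$barcode_id)
  }
  stopifnot_dna(out, "whitelist")
  out
}

#' Write a barcode whitelist
#'
#' @param barcodes character vector of sequences; names are used as ids
#'   (defaults `bc0001`, ...).
#' @param path output file.
#' @param format `"tsv"` (headerless id/sequence) or `"fasta"`.
#' @export
write_whitelist <- function(barcodes, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  ids <- names(barcodes)
  if (is.null(ids)) ids <- sprintf("bc%04d", seq_along(barcodes))
  if (format == "fasta") {
    seqs <- Biostrings::DNAStringSet(unname(barcodes))
    names(seqs) <- ids
    Biostrings::writeXStringSet(seqs, path)
  } else {
    write.table(data.frame(ids, unname(barcodes)), path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Export plate maps for the two synthesis rounds
#'
#' One CSV row per well: synthesis round, well label, barcode. Round 1
#' fills a 96-well plate column-major (A1..H1, A2..); round 2 is a
#' 10-well strip.
#'
#' @param pool a `barcode_pool`.
#' @param path output CSV path.
#' @return the plate map data.frame, invisibly.
#' @export
write_plate_map <- function(pool, path) {
  n1 <- length(pool$first_barcodes)
  rows <- LETTERS[1:8]
  wells1 <- paste0(rows[((seq_len(n1) - 1L) %% 8L) + 1L],
                   ((seq_len(n1) - 1L) %/% 8L) + 1L)
  n2 <- length(pool$second_barcodes)
  map <- rbind(
    data.frame(round = 1L, well = wells1, barcode = pool$first_barcodes),
    data.frame(round = 2L, well = paste0("S", seq_len(n2)),
               barcode = pool$second_barcodes))
  write.table(map, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(map)
}
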