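# Paired-read parsing and single-mismatch barcode demultiplexing.
#
# Read 1 carries the composite cell-identifying barcode followed by
# poly(dT); read 2 carries an 8-base UMI, a 6-base lane-identifying
# barcode, and the transcript sequence. Both barcode classes tolerate a
# single mismatch against their whitelists.

#' Describe the paired-read layout
#'
#' @param r1_len read-1 length in cycles (26 in the reference protocol).
#' @param cell_bc_start 1-based offset of the cell barcode in read 1.
#' @param cell_bc_len composite cell-barcode width (BC1 + anchor + BC2).
#' @param umi_len UMI width at the start of read 2.
#' @param lane_bc_len lane-barcode width following the UMI in read 2.
#' @return a `read_structure` object; the transcript starts at
#'   `umi_len + lane_bc_len + 1` in read 2.
#' @export
read_structure <- function(r1_len = 26L, cell_bc_start = 1L,
                           cell_bc_len = 20L, umi_len = 8L,
                           lane_bc_len = 6L) {
  if (cell_bc_start + cell_bc_len - 1L > r1_len)
    stop("cell barcode span exceeds read 1 length")
  if (umi_len < 1L || lane_bc_len < 1L)
    stop("umi_len and lane_bc_len must be >= 1")
  structure(list(r1_len = as.integer(r1_len),
                 cell_bc_start = as.integer(cell_bc_start),
                 cell_bc_len = as.integer(cell_bc_len),
                 umi_len = as.integer(umi_len),
                 lane_bc_len = as.integer(lane_bc_len),
                 transcript_start = as.integer(umi_len + lane_bc_len + 1L)),
            class = "read_structure")
}

#' Match observed barcodes against a whitelist with mismatch tolerance
#'
#' An exact whitelist hit always wins. Otherwise the unique whitelist entry
#' within `max_mismatch` substitutions is taken as the corrected barcode;
#' if two or more entries tie at the minimal distance within tolerance the
#' observation is ambiguous (and dropped by [demultiplex()] rather than
#' randomly assigned); if none is within tolerance there is no match.
#'
#' @param observed character vector of observed sequences (may contain N;
#'   N counts as a mismatch to every base).
#' @param whitelist character vector (optionally named) of true barcodes,
#'   all the same width as the observations.
#' @param max_mismatch maximum substitutions tolerated (default 1).
#' @return data.frame with columns `observed`, `match` (corrected barcode
#'   or NA) and `status` in `exact`, `corrected`, `ambiguous`, `none`.
#' @export
match_barcode <- function(observed, whitelist, max_mismatch = 1L) {
  whitelist <- unname(whitelist)
  w <- unique(nchar(whitelist))
  if (length(w) != 1L) stop("whitelist entries must have equal width")
  if (any(nchar(observed) != w))
    stop("observed barcodes must have the whitelist width (", w, ")")
  uo <- unique(observed)
  hit <- match(uo, whitelist)
  status <- ifelse(is.na(hit), NA_character_, "exact")
  corrected <- whitelist[hit]
  todo <- which(is.na(hit))
  if (length(todo)) {
    wm <- dna_int_matrix(whitelist)
    for (i in todo) {
      d <- hamming_to_all(utf8ToInt(uo[i]), wm)
      dmin <- min(d)
      if (dmin > max_mismatch) {
        status[i] <- "none"
      } else if (sum(d == dmin) > 1L) {
        status[i] <- "ambiguous"
      } else {
        status[i] <- "corrected"
        corrected[i] <- whitelist[which.min(d)]
      }
    }
  }
  idx <- match(observed, uo)
  data.frame(observed = observed, match = corrected[idx],
             status = status[idx], stringsAsFactors = FALSE)
}

## Strip FASTQ title lines to bare ids (drop comment and /1 /2 suffixes).
fastq_ids <- function(titles) {
  sub("/[12]$", "", sub("[ \t].*", "", titles))
}

read_fastq_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    s <- Biostrings::readDNAStringSet(x, format = "fastq")
    setNames(as.character(s), names(s))
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("read%06d", seq_along(x))
    x
  } else {
    setNames(as.character(x), names(x))
  }
}

#' Demultiplex paired reads by lane and cell barcode
#'
#' Parses each pair under the read structure, drops reads whose UMI
#' contains N (`low_quality`: an undetermined UMI base corrupts molecule
#' counting), then matches the lane barcode and the full composite cell
#' barcode against their whitelists with single-mismatch tolerance.
#' Assigned reads carry the corrected (whitelist) barcodes. Every input
#' pair appears exactly once in the output with a status, so
#' assigned + rejected always equals the input count.
#'
#' @param r1,r2 FASTQ file paths (plain or gzip) or named character
#'   vectors of sequences; pairs must be in the same order.
#' @param structure a [read_structure()].
#' @param lane_whitelist,cell_whitelist barcode whitelists (named vectors
#'   accepted; names label lanes in the summary).
#' @param max_mismatch mismatch tolerance for both barcode classes.
#' @return list with `reads` (data.table: read_id, status, lane_bc,
#'   cell_bc, umi, transcript) and `summary` (total, per-status counts,
#'   per-lane assigned counts).
#' @export
demultiplex <- function(r1, r2, structure = read_structure(),
                        lane_whitelist, cell_whitelist, max_mismatch = 1L) {
  s1 <- read_fastq_seqs(r1)
  s2 <- read_fastq_seqs(r2)
  if (length(s1) != length(s2))
    stop("read 1 and read 2 inputs have different record counts (",
         length(s1), " vs ", length(s2), ")")
  id1 <- fastq_ids(names(s1))
  id2 <- fastq_ids(names(s2))
  bad <- which(id1 != id2)
  if (length(bad))
    stop("paired inputs are out of sync starting at read ", bad[1L],
         " (", id1[bad[1L]], " vs ", id2[bad[1L]], ")")
  if (any(nchar(s1) < structure$cell_bc_start + structure$cell_bc_len - 1L))
    stop("truncated read 1 record encountered")
  if (any(nchar(s2) < structure$umi_len + structure$lane_bc_len))
    stop("truncated read 2 record encountered")

  cell_obs <- substr(s1, structure$cell_bc_start,
                     structure$cell_bc_start + structure$cell_bc_len - 1L)
  umi <- substr(s2, 1L, structure$umi_len)
  lane_obs <- substr(s2, structure$umi_len + 1L,
                     structure$umi_len + structure$lane_bc_len)
  transcript <- substr(s2, structure$transcript_start, nchar(s2))

  n <- length(s1)
  status <- rep("assigned", n)
  status[grepl("N", umi, fixed = TRUE)] <- "low_quality"

  lane_bc <- rep(NA_character_, n)
  cell_bc <- rep(NA_character_, n)
  live <- status == "assigned"
  if (any(live)) {
    lm <- match_barcode(lane_obs[live], lane_whitelist, max_mismatch)
    lidx <- which(live)
    status[lidx[lm$status == "none"]] <- "no_lane"
    status[lidx[lm$status == "ambiguous"]] <- "ambiguous"
    lane_bc[lidx] <- lm$match
  }
  live <- status == "assigned"
  if (any(live)) {
    cm <- match_barcode(cell_obs[live], cell_whitelist, max_mismatch)
    cidx <- which(live)
    status[cidx[cm$status == "none"]] <- "no_cell"
    status[cidx[cm$status == "ambiguous"]] <- "ambiguous"
    cell_bc[cidx] <- cm$match
  }
  keep_bc <- status == "assigned"
  lane_bc[!keep_bc] <- NA_character_
  cell_bc[!keep_bc] <- NA_character_

  lane_names <- names(lane_whitelist)
  lane_label <- if (!is.null(lane_names)) {
    lane_names[match(lane_bc, unname(lane_whitelist))]
  } else lane_bc

  reads <- data.table::data.table(
    read_id = id1, status = status, lane_bc = lane_bc,
    lane = lane_label, cell_bc = cell_bc, umi = umi,
    transcript = transcript)
  assigned <- reads[status == "assigned"]
  summary <- list(
    total = n,
    by_status = as.list(table(status)),
    assigned_per_lane = if (nrow(assigned)) as.list(table(assigned$lane))
                        else list())
  list(reads = reads, summary = summary)
}

#' Write per-lane tagged FASTQ of transcript sequences
#'
#' Assigned reads are written one file per lane with the corrected
#' barcodes in the header comment using the stable grammar
#' `@<read_id> CB:<cell_bc> UB:<umi> LB:<lane_bc>`. Qualities are not
#' propagated by the pipeline and are written as a constant placeholder.
#'
#' @param demux result of [demultiplex()].
#' @param dir output directory.
#' @return character vector of written file paths.
#' @export
write_demux_fastq <- function(demux, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  assigned <- demux$reads[status == "assigned"]
  paths <- character(0)
  for (ln in sort(unique(assigned$lane))) {
    sub <- assigned[lane == ln]
    seqs <- Biostrings::DNAStringSet(sub$transcript)
    names(seqs) <- sprintf("%s CB:%s UB:%s LB:%s", sub$read_id,
                           sub$cell_bc, sub$umi, sub$lane_bc)
    fp <- file.path(dir, paste0("lane_", ln, ".fastq"))
    Biostrings::writeXStringSet(
      seqs, fp, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(sub$transcript))))
    paths <- c(paths, fp)
  }
  invisible(paths)
}

#' Write a demultiplexing summary table
#'
#' @param demux result of [demultiplex()].
#' @param path output TSV path.
#' @export
write_demux_summary <- function(demux, path) {
  st <- demux$summary$by_status
  pl <- demux$summary$assigned_per_lane
  tab <- rbind(
    data.frame(category = "total", key = "all",
               count = demux$summary$total),
    data.frame(category = "status", key = names(st),
               count = as.integer(unlist(st))),
    if (length(pl)) data.frame(category = "lane_assigned", key = names(pl),
                               count = as.integer(unlist(pl))))
  write_tsv_file(tab, path)
}
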