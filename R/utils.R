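# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package operations never disturb the global
#' random-number stream. A NULL seed evaluates `code` unchanged.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

## Encode equal-width DNA strings as an integer matrix (one row per string).
dna_int_matrix <- function(x) {
  n <- length(x)
  if (n == 0L) return(matrix(integer(0), nrow = 0L, ncol = 0L))
  w <- nchar(x[1L])
  if (any(nchar(x) != w)) stop("sequences must all have width ", w)
  matrix(utf8ToInt(paste(x, collapse = "")), nrow = n, ncol = w, byrow = TRUE)
}

## Dense pairwise Hamming distance between rows of an integer matrix.
hamming_matrix <- function(m) {
  k <- nrow(m)
  d <- matrix(0L, k, k)
  for (j in seq_len(ncol(m))) {
    d <- d + (outer(m[, j], m[, j], "!="))
  }
  d
}

## Hamming distance from one encoded sequence to every row of `m`.
hamming_to_all <- function(v, m) {
  .rowSums(m != rep(v, each = nrow(m)), nrow(m), length(v))
}

stopifnot_dna <- function(x, what) {
  bad <- !grepl("^[ACGT]+$", x)
  if (any(bad)) {
    stop(what, " must contain only A/C/G/T; offending entries: ",
         paste(head(x[bad], 5L), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

## Random fixed-width DNA strings under the current RNG state.
random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(DNA_BASES[sample.int(4L, n * width, replace = TRUE)],
              nrow = n, ncol = width)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## Apply per-base substitution errors to equal-width DNA strings.
mutate_dna <- function(x, rate) {
  n <- length(x)
  if (n == 0L || rate <= 0) return(x)
  w <- nchar(x[1L])
  cols <- lapply(seq_len(w), function(i) substring(x, i, i))
  for (i in seq_len(w)) {
    hit <- which(runif(n) < rate)
    if (length(hit)) {
      # substitute with one of the three other bases, uniformly
      shift <- sample.int(3L, length(hit), replace = TRUE)
      cur <- match(cols[[i]][hit], DNA_BASES)
      cols[[i]][hit] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
  }
  do.call(paste0, cols)
}

#' Connected components of the molecule-collapse relation
#'
#' Rows are reads (or molecules); two rows are linked when their UMIs are
#' within `max_hamming` substitutions AND their positions differ by at most
#' `window`. Positions are sorted and cut at gaps > window first, so only
#' plausibly linked blocks pay the dense pairwise cost.
#'
#' @param m integer matrix of encoded UMIs (one row per item).
#' @param pos integer vector of mapping positions.
#' @return integer component labels (1-based, in order of first appearance).
#' @noRd
collapse_components <- function(m, pos, max_hamming = 2L, window = 6L) {
  k <- length(pos)
  if (k == 0L) return(integer(0))
  if (k == 1L) return(1L)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(pos)
  po <- pos[ord]
  cut <- c(0L, which(diff(po) > window), k)
  for (b in seq_len(length(cut) - 1L)) {
    idx <- ord[(cut[b] + 1L):cut[b + 1L]]
    kk <- length(idx)
    if (kk < 2L) next
    d <- hamming_matrix(m[idx, , drop = FALSE])
    adj <- d <= max_hamming &
      abs(outer(pos[idx], pos[idx], "-")) <= window
    ut <- which(adj & upper.tri(adj), arr.ind = TRUE)
    for (e in seq_len(nrow(ut))) {
      a <- find(idx[ut[e, 1L]])
      bb <- find(idx[ut[e, 2L]])
      if (a != bb) parent[max(a, bb)] <- min(a, bb)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  match(roots, unique(roots))
}

#' Two-class Otsu split of a 1-D sample
#'
#' Finds the threshold minimising the pooled within-class variance
#' (equivalently maximising between-class variance). Returns the threshold,
#' the between/total variance ratio ("eta", in \[0,1\]) measuring how bimodal
#' the split is, and the class sizes. Degenerate inputs (fewer than two
#' distinct values) give an NA threshold.
#' @noRd
otsu_split <- function(x) {
  n <- length(x)
  if (n < 2L) return(list(threshold = NA_real_, eta = NA_real_))
  xs <- sort(x)
  if (xs[1L] == xs[n]) return(list(threshold = NA_real_, eta = NA_real_))
  cs <- cumsum(xs)
  css <- cumsum(xs^2)
  k <- which(xs[-n] < xs[-1L])        # splits between distinct values
  n1 <- k
  n2 <- n - k
  ss1 <- css[k] - cs[k]^2 / n1
  ss2 <- (css[n] - css[k]) - (cs[n] - cs[k])^2 / n2
  within <- ss1 + ss2
  best <- k[which.min(within)]
  thr <- (xs[best] + xs[best + 1L]) / 2
  total <- css[n] - cs[n]^2 / n
  eta <- if (total > 0) 1 - min(within) / total else NA_real_
  list(threshold = thr, eta = eta, n_low = best, n_high = n - best)
}

## Write a data.frame as headered TSV, byte-stable.
write_tsv_file <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  data.table::fread(path, sep = "\t", header = TRUE, ...)
}
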