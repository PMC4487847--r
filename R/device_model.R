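# Closed-form loading and barcoding statistics of the microwell device.

#' Expected number of uniquely labeled cells
#'
#' When `n_cells` bead-paired cells each draw one of `pool_size` barcodes
#' uniformly at random (with replacement), the expected number of cells
#' whose barcode is drawn by no other cell is
#' `n * (1 - 1/B)^(n - 1)`. For 100 cells and the 960-barcode pool this is
#' ~90, i.e. mRNA from approximately 90 of 100 captured cells is uniquely
#' labeled.
#'
#' @param n_cells number of bead-paired cells (>= 1).
#' @param pool_size number of distinct barcodes in the pool (>= 1).
#' @return expected count of uniquely labeled cells (real).
#' @examples
#' expected_unique_labels(100, 960)  # ~90.2
#' @export
expected_unique_labels <- function(n_cells, pool_size) {
  if (pool_size < 1L) stop("pool_size must be >= 1")
  if (n_cells < 1L) stop("n_cells must be >= 1")
  n_cells * (1 - 1 / pool_size)^(n_cells - 1)
}

#' Monte-Carlo estimate of unique labeling
#'
#' Simulation counterpart of [expected_unique_labels()]: repeatedly assigns
#' `n_cells` barcodes uniformly from the pool and counts cells whose
#' barcode occurs exactly once.
#'
#' @param n_cells,pool_size as in [expected_unique_labels()].
#' @param reps number of replicate assignments.
#' @param seed optional RNG seed (restored on exit).
#' @return list with `mean`, `se` (standard error of the mean) and `reps`.
#' @export
simulate_unique_labels <- function(n_cells, pool_size, reps = 1e5, seed = NULL) {
  with_seed(seed, {
    counts <- vapply(seq_len(reps), function(i) {
      draws <- sample.int(pool_size, n_cells, replace = TRUE)
      sum(tabulate(draws, nbins = pool_size) == 1L)
    }, integer(1))
    list(mean = mean(counts), se = sd(counts) / sqrt(reps), reps = reps)
  })
}

#' Fraction of wells containing more than one cell
#'
#' Cells land in microwells according to Poisson statistics with mean
#' `lambda_cells` per well. At a loading of ~100 cells per 1,000 wells
#' (lambda = 0.1) fewer than 5% of occupied wells contain more than one
#' cell. The default (`conditional = TRUE`) reports
#' `P(K >= 2) / P(K >= 1)`, the multi-cell fraction among occupied wells;
#' `conditional = FALSE` gives the unconditional `P(K >= 2)`.
#'
#' @param lambda_cells mean cells per well (> 0).
#' @param conditional condition on the well being occupied?
#' @return fraction in (0, 1).
#' @examples
#' multi_cell_fraction(0.1)  # 0.0492
#' @export
multi_cell_fraction <- function(lambda_cells, conditional = TRUE) {
  if (lambda_cells <= 0) stop("lambda_cells must be > 0")
  p_ge1 <- -expm1(-lambda_cells)                 # 1 - P(K = 0)
  p_ge2 <- p_ge1 - lambda_cells * exp(-lambda_cells)
  if (conditional) p_ge2 / p_ge1 else p_ge2
}

#' Monte-Carlo estimate of the multi-cell fraction
#'
#' @param lambda_cells mean cells per well.
#' @param n_wells number of simulated wells.
#' @param seed optional RNG seed.
#' @param conditional as in [multi_cell_fraction()].
#' @return list with `fraction`, `se` and the occupied-well count `n`.
#' @export
simulate_multi_cell_fraction <- function(lambda_cells, n_wells = 1e6,
                                         seed = NULL, conditional = TRUE) {
  with_seed(seed, {
    k <- rpois(n_wells, lambda_cells)
    if (conditional) {
      occ <- k[k >= 1L]
      p <- mean(occ >= 2L)
      list(fraction = p, se = sqrt(p * (1 - p) / length(occ)),
           n = length(occ))
    } else {
      p <- mean(k >= 2L)
      list(fraction = p, se = sqrt(p * (1 - p) / n_wells), n = n_wells)
    }
  })
}

#' Volume of a cylindrical microwell in picoliters
#'
#' @param diameter,height well dimensions in micrometers (> 0). The
#'   reference device uses 50 um for both, i.e. just under 100 pL.
#' @return volume in pL.
#' @examples
#' microwell_volume(50, 50)  # 98.17 pL
#' @export
microwell_volume <- function(diameter, height) {
  if (diameter <= 0 || height <= 0)
    stop("diameter and height must be > 0")
  pi * (diameter / 2)^2 * height * 1e-3   # um^3 -> pL
}

#' Occupancy and barcode-collision report for a device configuration
#'
#' Convenience bundle of the closed-form statistics, suitable for JSON
#' export (used by the `stats` CLI subcommand).
#'
#' @param lambda_cells mean cells per well.
#' @param n_wells number of wells in the device.
#' @param pool_size number of distinct barcodes.
#' @param n_cells number of bead-paired cells (defaults to the expected
#'   occupied-well count).
#' @param diameter,height well geometry in micrometers.
#' @return named list of statistics.
#' @export
loading_report <- function(lambda_cells, n_wells = 1000L, pool_size = 960L,
                           n_cells = NULL, diameter = 50, height = 50) {
  if (is.null(n_cells))
    n_cells <- round(n_wells * -expm1(-lambda_cells))
  list(
    lambda_cells = lambda_cells,
    n_wells = n_wells,
    pool_size = pool_size,
    n_cells = n_cells,
    expected_occupied_wells = n_wells * -expm1(-lambda_cells),
    multi_cell_fraction_occupied = multi_cell_fraction(lambda_cells),
    multi_cell_fraction_all = multi_cell_fraction(lambda_cells,
                                                  conditional = FALSE),
    expected_unique_labels = expected_unique_labels(n_cells, pool_size),
    unique_label_rate = expected_unique_labels(n_cells, pool_size) / n_cells,
    microwell_volume_pL = microwell_volume(diameter, height)
  )
}
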