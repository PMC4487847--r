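# Shared fixtures and independent oracles. Expensive simulations are
# memoised so every test file sees the same run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

## the default study-condition run (100 nominal cells, 500 phantoms, 1%
## chimeras, 0.5% barcode errors)
default_sim <- function() {
  fixture("default_sim", simulate_run(sim_config(), seed = 20260919))
}

default_kept <- function() {
  fixture("default_kept", filter_mapped_reads(default_sim()$mapped_reads)$kept)
}

default_counting <- function() {
  fixture("default_counting", count_molecules(default_sim()$mapped_reads))
}

default_calls <- function() {
  fixture("default_calls", call_cells(default_kept(), seed = 7))
}

## a small zero-noise run for identity checks
zero_sim <- function() {
  fixture("zero_sim", simulate_run(
    sim_config_zero_noise(n_wells = 300L, n_genes = 100L,
                          gene_length = 300L,
                          molecules_meanlog = log(200),
                          molecules_sdlog = 0.15),
    seed = 11))
}

## chimera-only run: chimeras planted, no sequencing errors, so the
## removal rule is exactly attributable
chimera_sim <- function() {
  fixture("chimera_sim", simulate_run(
    sim_config(n_wells = 500L, n_genes = 150L, phantom_per_lane = 50L,
               molecules_meanlog = log(500), pcr_duplicate_mean = 0.2,
               phantom_dup_mean = 10, chimera_rate = 0.02,
               error_rate_barcode = 0, error_rate_umi = 0,
               error_rate_transcript = 0, multimap_rate = 0,
               genome_overlap_rate = 0, strand_violation_rate = 0),
    seed = 301))
}

barcode_ids <- function(dt) paste(dt$lane, dt$barcode, sep = ":")

## quick constructor for mapped-read rows
make_reads <- function(lane = "L1", cell_bc = "AAAA", umi, gene = "g1",
                       position, strand = "+", unique_tx = TRUE,
                       also_genome = FALSE, strand_ok = TRUE) {
  data.table::data.table(lane = lane, cell_bc = cell_bc, umi = umi,
                         gene = gene, position = as.integer(position),
                         strand = strand, unique_tx = unique_tx,
                         also_genome = also_genome, strand_ok = strand_ok)
}

## independent Hamming distance (character-split, no package internals)
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## independent connected components of the collapse relation via igraph
oracle_components <- function(umis, positions, max_ham = 2, window = 6) {
  k <- length(umis)
  edges <- matrix(integer(0), ncol = 2)
  if (k > 1) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        if (abs(positions[i] - positions[j]) <= window &&
            oracle_hamming(umis[i], umis[j]) <= max_ham) {
          edges <- rbind(edges, c(i, j))
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

## partitions equal up to label permutation
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(match(a, unique(a)) == match(b, unique(b)))
}

## random UMIs for toy groups
rand_umis <- function(n, width = 8) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = ""), character(1))
}
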