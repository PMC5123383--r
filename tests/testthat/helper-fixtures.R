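# Shared fixtures: the three-gene five-read worked example and random
# mapping tables for property-style tests.

toy_blast_path <- function() {
  system.file("extdata", "toy_blast.tsv", package = "fuzzydea")
}

# the worked example as a possibility table (identity x coverage / 1e4)
toy_mappings <- function() {
  tibble::tribble(
    ~read_id, ~reference_id, ~identity, ~coverage,
    "read-1", "gene-1", 100, 100,
    "read-2", "gene-1", 100, 100,
    "read-2", "gene-2",  99,  80,
    "read-2", "gene-3",  95,  80,
    "read-3", "gene-1", 100, 100,
    "read-3", "gene-2", 100, 100,
    "read-4", "gene-1",  96,  90,
    "read-4", "gene-2",  97,  90,
    "read-4", "gene-3", 100, 100,
    "read-5", "gene-1",  95,  80,
    "read-5", "gene-2", 100, 100
  ) |>
    dplyr::transmute(read_id, reference_id,
                     possibility = identity * coverage / 1e4)
}

# Random mapping table under the generator convention: every read's best
# alignment has possibility exactly 1, decoys strictly below 1 and away
# from ties. Returns n_reads reads over at most n_genes genes.
random_mapping_table <- function(n_reads, n_genes) {
  genes <- paste0("g", seq_len(n_genes))
  rows <- lapply(seq_len(n_reads), function(i) {
    k <- sample(seq_len(min(n_genes, 3)), 1)
    hit <- sample(genes, k)
    tibble::tibble(
      read_id = sprintf("r%03d", i),
      reference_id = hit,
      possibility = c(1, runif(k - 1, 0.05, 0.95))
    )
  })
  dplyr::bind_rows(rows)
}

# random valid trapezoid as a one-row count table
random_trapezoid <- function(max_count = 50, gene = "g") {
  v <- sort(sample(0:max_count, 4, replace = TRUE))
  tibble::tibble(gene = gene, A = v[1], B = v[2], C = v[3], D = v[4])
}

small_sim <- function(...) {
  simulate_experiment(n_genes = 60, n_families = 10, mu_null = 40,
                      mu_de = c(200, 300), n_de_over = 3, n_de_under = 3,
                      ...)
}
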