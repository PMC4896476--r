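# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

# Small synthetic benchmark shared across module tests.
small_benchmark <- function() {
  cached("bench120", generate_benchmark(benchmark_spec(n = 120, seed = 11)))
}

# Workflow bundle trained on 80% of the small benchmark (separation split);
# the held-out 20% is available via small_benchmark_test().
small_bundle <- function() {
  cached("bundle120", {
    bm <- small_benchmark()
    sp <- split_dataset(bm, "S", seed = 42)
    train <- dplyr::filter(bm, id %in% sp$id[sp$subset == "train"])
    train_workflow(train, workflow = "PW-2", seed = 99)
  })
}

small_benchmark_test <- function() {
  cached("bench120_test", {
    bm <- small_benchmark()
    sp <- split_dataset(bm, "S", seed = 42)
    dplyr::filter(bm, id %in% sp$id[sp$subset == "test"])
  })
}

# Parent-pool-scale benchmark with the labeled-pool class counts
# (X 17, St 32, S 180, M 90, W 74, N 150).
parent_pool <- function() {
  cached("pool543", generate_benchmark(benchmark_spec(n = 543, seed = 607)))
}

# A handful of named real structures used across tests.
fixture_molecules <- function() {
  cached("mols", parse_molecules(tibble::tibble(
    id = c("ethanol", "ethane", "benzene", "mvk", "hexane", "octyl_bromide",
           "benzaldehyde", "phenol"),
    smiles = c("CCO", "CC", "c1ccccc1", "C=CC(=O)C", "CCCCCC", "CCCCCCCCBr",
               "O=Cc1ccccc1", "Oc1ccccc1"),
    potency = c("N", "N", "N", "St", "N", "M", "M", "N")
  )))
}

# Write a throwaway file and return its path.
tmp_file <- function(lines, ext = "csv") {
  path <- withr::local_tempfile(fileext = paste0(".", ext),
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
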