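make_matrix <- function(n_per_class = 20, seed = 1) {
  generate_descriptor_table(n_per_class, p_features = 8, n_informative = 3,
                            effect = 2, seed = seed)
}

test_that("t-test screening keeps separated features and drops flat ones", {
  n <- 20
  labels <- rep(c(1, -1), each = n)
  withr::with_seed(42, {
    strong <- c(rnorm(n, 10, 1), rnorm(n, 0, 1))   # |gap| = 10 sd
    flat <- rep(3, 2 * n)                           # identical in both classes
    noise <- rnorm(2 * n)
  })
  data <- tibble::tibble(strong = strong, flat = flat, noise = noise)
  sel <- select_by_ttest(data, labels, alpha = 0.05)
  expect_true("strong" %in% sel)
  expect_false("flat" %in% sel)
  expect_true("flat" %in% attr(sel, "excluded"))
  # oracle: the selected feature's Welch p-value really is below alpha
  p <- t.test(strong[labels == 1], strong[labels == -1],
              var.equal = FALSE)$p.value
  expect_lt(p, 0.05)
})

test_that("t-test screening is invariant to column order and label swap", {
  g <- make_matrix()
  sel1 <- select_by_ttest(g$data, g$labels)
  shuffled <- g$data[, c("id", sample(setdiff(names(g$data), "id")))]
  sel2 <- select_by_ttest(shuffled, g$labels)
  sel3 <- select_by_ttest(g$data, -g$labels)
  expect_setequal(sel1, sel2)
  expect_setequal(sel1, sel3)
})

test_that("t-test screening rejects degenerate class sizes", {
  g <- make_matrix(n_per_class = 5)
  labels <- c(1, rep(-1, 9))
  expect_error(select_by_ttest(g$data, labels),
               class = "skinqsar_degenerate_input_error")
})

test_that("CFS merit reduces to |correlation| at k = 1 and penalizes redundancy", {
  g <- make_matrix()
  x <- as.matrix(g$data[-1])
  f <- colnames(x)[1]
  expect_equal(cfs_merit(f, g$data, g$labels),
               abs(cor(x[, f], g$labels)))

  # duplicating a feature (r_ff = 1): merit 2r/sqrt(2 + 2) = r, i.e. no
  # gain over the singleton - redundancy cancels the extra relevance
  dup <- dplyr::mutate(g$data, f_dup = .data[[f]])
  m_single <- cfs_merit(f, g$data, g$labels)
  m_pair <- cfs_merit(c(f, "f_dup"), dup, g$labels)
  r <- abs(cor(x[, f], g$labels))
  expect_equal(m_pair, 2 * r / sqrt(2 + 2 * 1))   # plug r_ff = 1
  expect_equal(m_pair, m_single)

  # pure-noise subsets have merit near zero for large n
  noise <- generate_descriptor_table(500, 4, 0, effect = 0, seed = 9)
  expect_lt(cfs_merit(colnames(noise$data)[-1], noise$data, noise$labels), 0.1)
  expect_error(cfs_merit(character(0), g$data, g$labels),
               class = "skinqsar_value_error")
})

test_that("best-first search matches exhaustive search on small instances", {
  for (seed in c(3, 14, 27)) {
    g <- generate_descriptor_table(15, p_features = 7, n_informative = 2,
                                   effect = 1.5, seed = seed)
    feats <- setdiff(names(g$data), "id")
    fs <- reduce_best_first(g$data, g$labels, feats)
    subsets <- unlist(lapply(seq_along(feats), combn, x = feats,
                             simplify = FALSE), recursive = FALSE)
    best <- max(vapply(subsets, cfs_merit, numeric(1),
                       data = g$data, labels = g$labels))
    expect_equal(fs$merit, best, tolerance = 1e-10)
  }
})

test_that("best-first keeps exactly one copy of a duplicated feature", {
  g <- generate_descriptor_table(30, p_features = 2, n_informative = 1,
                                 effect = 3, seed = 5)
  data <- dplyr::mutate(g$data, f_copy = .data$f0001)
  fs <- reduce_best_first(data, g$labels, c("f0001", "f_copy", "f0002"))
  expect_equal(sum(c("f0001", "f_copy") %in% fs$features), 1)
})

test_that("a single informative candidate is returned as-is", {
  g <- generate_descriptor_table(20, p_features = 1, n_informative = 1,
                                 effect = 2, seed = 8)
  fs <- reduce_best_first(g$data, g$labels, "f0001")
  expect_equal(fs$features, "f0001")
  # its merit is at least every singleton's merit (trivially, the only one)
  expect_gte(fs$merit, cfs_merit("f0001", g$data, g$labels) - 1e-12)
})

test_that("the five descriptor-set recipes combine A, B, C as documented", {
  # disjoint groups A (4), B (3), C (2) on a synthetic matrix
  g <- generate_descriptor_table(25, p_features = 9, n_informative = 4,
                                 effect = 1.5, seed = 21)
  feats <- setdiff(names(g$data), "id")
  A <- feats[1:4]; B <- feats[5:7]; C <- feats[8:9]

  s5 <- build_descriptor_set(5, A, B, C, g$data, g$labels)
  expect_equal(length(s5$features), 9)           # plain union, no reduction

  s2 <- build_descriptor_set(2, A, B, C, g$data, g$labels)
  expect_true(all(B %in% s2$features))           # B always retained

  s3 <- build_descriptor_set(3, A, B, C, g$data, g$labels)
  expect_true(all(C %in% s3$features))           # C always retained

  s1 <- build_descriptor_set(1, A, B, C, g$data, g$labels)
  expect_true(all(s1$features %in% c(A, B)))

  s4 <- build_descriptor_set(4, A, B, C, g$data, g$labels)
  expect_true(all(s4$features %in% c(A, B)))

  expect_error(build_descriptor_set(6, A, B, C, g$data, g$labels),
               class = "skinqsar_value_error")
})

test_that("built-in descriptors are finite numerics keyed by molecule id", {
  mols <- fixture_molecules()
  desc <- compute_descriptors(mols)
  expect_equal(desc$id, mols$id)
  vals <- as.matrix(desc[-1])
  expect_true(all(is.finite(vals)))
  # benzene: 6 aromatic atoms, 1 ring, no halogens
  benz <- desc[desc$id == "benzene", ]
  expect_equal(benz$desc_n_aromatic, 6)
  expect_equal(benz$desc_n_ring, 1)
  expect_equal(benz$desc_n_halogen, 0)
})
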