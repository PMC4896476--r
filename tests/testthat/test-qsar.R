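test_that("variant codes round trip over the full 300-code grid", {
  grid <- expand.grid(m = 1:4, s = c("D", "S", "C"), d = 1:5,
                      cl = c("J48", "MLP", "RF", "SL", "SMO"),
                      stringsAsFactors = FALSE)
  codes <- paste0(grid$m, grid$s, grid$d, grid$cl)
  expect_equal(length(codes), 300)
  for (code in codes) {
    expect_identical(format_variant_code(parse_variant_code(code)), code)
  }
  parsed <- parse_variant_code("1D4RF")
  expect_equal(parsed$model_id, 1)
  expect_equal(parsed$split_method, "D")
  expect_equal(parsed$set_id, 4)
  expect_equal(parsed$classifier, "RF")
})

test_that("out-of-vocabulary variant codes are rejected", {
  for (bad in c("6Z9XX", "2C2XX", "0D1RF", "2C6RF", "2A2RF", "")) {
    expect_error(parse_variant_code(bad), class = "skinqsar_variant_code_error")
  }
})

test_that("model datasets pull the documented potency strata", {
  bm <- small_benchmark()
  cc <- tibble::deframe(class_counts(bm))

  m2 <- assemble_model_dataset(bm, 2)
  expect_equal(nrow(m2), sum(cc[c("X", "St", "S", "N")]))
  expect_setequal(unique(m2$potency), c("X", "St", "S", "N"))
  expect_setequal(unique(m2$label), c(1L, -1L))
  expect_true(all(m2$label[m2$potency == "N"] == -1))

  m3 <- assemble_model_dataset(bm, 3)
  expect_equal(nrow(m3), sum(cc[c("M", "N")]))
  m4 <- assemble_model_dataset(bm, 4)
  expect_equal(nrow(m4), sum(cc[c("W", "N")]))

  k <- 10
  m1 <- assemble_model_dataset(bm, 1, diverse_nonsens_k = k)
  expect_equal(nrow(m1), sum(cc[c("X", "St")]) + k)

  no_m <- dplyr::filter(bm, potency != "M")
  expect_error(assemble_model_dataset(no_m, 3), class = "skinqsar_value_error")
})

test_that("splits honor their contracts and are seed-reproducible", {
  mols <- tibble::tibble(id = sprintf("m%03d", 1:20),
                         label = rep(c(1, -1), each = 10))
  s <- split_dataset(mols, "S", seed = 1)
  tr <- s$id[s$subset == "train"]
  expect_equal(sum(tr %in% mols$id[mols$label == 1]), 8)
  expect_equal(sum(tr %in% mols$id[mols$label == -1]), 8)

  d <- split_dataset(mols, "D", seed = 1)
  expect_equal(sum(d$subset == "train"), 16)
  expect_equal(sum(d$subset == "test"), 4)
  expect_setequal(d$id, mols$id)

  mols100 <- tibble::tibble(id = sprintf("m%03d", 1:100),
                            label = rep(c(1, -1), 50))
  cv <- split_dataset(mols100, "C", seed = 1, n_folds = 10)
  expect_equal(nrow(cv), 100)
  expect_equal(anyDuplicated(cv$id), 0)
  expect_equal(as.integer(table(cv$fold)), rep(10L, 10))

  expect_identical(split_dataset(mols, "D", seed = 7),
                   split_dataset(mols, "D", seed = 7))
  expect_false(identical(split_dataset(mols, "D", seed = 7),
                         split_dataset(mols, "D", seed = 8)))

  one_class <- dplyr::mutate(mols, label = 1)
  expect_error(split_dataset(one_class, "D"),
               class = "skinqsar_degenerate_input_error")
})

test_that("a tree-ensemble variant separates two distant Gaussian clouds", {
  g <- generate_descriptor_table(100, p_features = 5, n_informative = 5,
                                 effect = 5, seed = 13)
  mols <- tibble::tibble(id = g$data$id, label = g$labels)
  v <- train_variant("2D1RF", mols, g$data, seed = 17)
  acc <- variant_accuracy(v, mols, g$data)
  expect_gte(acc, 0.95)
  expect_s3_class(glance(v), "tbl_df")
  expect_true(all(tidy(v)$term %in% setdiff(names(g$data), "id")))
})

test_that("every classifier family trains and predicts in {-1, +1}", {
  g <- generate_descriptor_table(30, p_features = 4, n_informative = 2,
                                 effect = 3, seed = 23)
  mols <- tibble::tibble(id = g$data$id, label = g$labels)
  for (cl in c("J48", "MLP", "RF", "SL", "SMO")) {
    v <- train_variant(paste0("2D1", cl), mols, g$data, seed = 29)
    votes <- predict(v, g$data)
    expect_true(all(votes %in% c(-1L, 1L)), info = cl)
  }
})

test_that("cross-validation variants record fold-wise accuracy", {
  g <- generate_descriptor_table(30, p_features = 4, n_informative = 2,
                                 effect = 3, seed = 31)
  mols <- tibble::tibble(id = g$data$id, label = g$labels)
  v <- train_variant("2C1RF", mols, g$data, seed = 37)
  expect_true(v$cv_accuracy >= 0 && v$cv_accuracy <= 1)
  expect_gte(v$cv_accuracy, 0.9)  # effect 3 separates cleanly
})

test_that("least-average-similarity selection finds the structural outliers", {
  pool <- parse_molecules(tibble::tibble(
    id = c("t1", "t2", "t3", "odd1", "odd2"),
    smiles = c("Cc1ccccc1", "Cc1ccccc1", "Cc1ccccc1",
               "OCC(O)CO", "CCCCCCCCCCCC"),
    potency = "N"
  ))
  picked <- select_diverse(pool, 2, mode = "least-average-similarity")
  expect_setequal(picked$id, c("odd1", "odd2"))

  expect_identical(select_diverse(pool, nrow(pool))$id, pool$id)

  # invariant to input order
  shuf <- pool[c(4, 2, 5, 1, 3), ]
  picked2 <- select_diverse(shuf, 2, mode = "least-average-similarity")
  expect_setequal(picked2$id, picked$id)
})

test_that("stratified-representative selection honors class quotas", {
  bm <- small_benchmark()
  quotas <- c(X = 2, St = 2, S = 5, M = 5, W = 5, N = 10)
  rts <- select_diverse(bm, mode = "stratified-representative",
                        quotas = quotas)
  cc <- tibble::deframe(class_counts(rts))
  expect_equal(cc[names(quotas)], quotas, ignore_attr = TRUE)
  expect_equal(nrow(rts), sum(quotas))

  expect_error(
    select_diverse(bm, mode = "stratified-representative",
                   quotas = c(X = 10000)),
    class = "skinqsar_value_error"
  )
})

test_that("Y-randomization separates real labels from permuted ones", {
  g <- generate_descriptor_table(50, p_features = 6, n_informative = 3,
                                 effect = 3, seed = 41)
  mols <- tibble::tibble(id = g$data$id, label = g$labels)
  yr <- y_randomize("2D1RF", mols, g$data, seed = 43)
  expect_equal(yr$runs, 10)                     # default run count
  expect_length(yr$randomized_accuracies, 10)
  # permutation null on balanced classes sits near 0.5
  expect_gt(mean(yr$randomized_accuracies), 0.3)
  expect_lt(mean(yr$randomized_accuracies), 0.7)
  # at these conditions the margin lands exactly on 0.2 (1.0 vs 0.8)
  expect_gte(yr$real_accuracy - max(yr$randomized_accuracies), 0.2 - 1e-9)
  expect_equal(nrow(tidy(yr)), 11)
})
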