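# Literal weight table used as an independent oracle in these tests:
# columns m2_S, m2_N, m3_S, m3_N, m4_S, m4_N, sim_S, sim_N, sim_NS,
# sim_NoMatch, sub_Present, sub_Absent.
ORACLE_WEIGHTS <- list(
  "KB-a" = c(1, 1, 0.4, 0.4, 0.3, 0.3, 1, 1, 0, 0, 1, 0.5),
  "KB-b" = c(1, 0.8, 0.8, 0.4, 0.3, 0.4, 1, 1, 0, 0, 1, 0.5),
  "KB-c" = c(1, 0.8, 0.6, 0.4, 0.3, 0.4, 1, 1, 0, 0, 1, 0.5),
  "KB-d" = c(1, 0.8, 0.4, 0.3, 0.3, 0.3, 1, 1, 0, 0, 1, 0.5)
)

vote_tbl <- function(m2, m3, m4, sim_value, sim_dir, sub) {
  tibble::tibble(
    component = c("m2", "m3", "m4", "similarity", "substructure"),
    value = c(m2, m3, m4, sim_value, sub),
    direction = c(NA, NA, NA, sim_dir, NA)
  )
}

oracle_score <- function(w, m2, m3, m4, sim_value, sim_dir, sub) {
  qsar <- m2 * w[if (m2 > 0) 1 else 2] +
    m3 * w[if (m3 > 0) 3 else 4] +
    m4 * w[if (m4 > 0) 5 else 6]
  sim <- sim_value * w[match(sim_dir, c("S", "N", "NS", "NoMatch")) + 6]
  sub_w <- sub * w[if (sub > 0) 11 else 12]
  qsar + sim + sub_w
}

test_that("the built-in schemes reproduce the tabulated weights cell-for-cell", {
  cols <- list(c("m2", "S"), c("m2", "N"), c("m3", "S"), c("m3", "N"),
               c("m4", "S"), c("m4", "N"), c("similarity", "S"),
               c("similarity", "N"), c("similarity", "NS"),
               c("similarity", "NoMatch"), c("substructure", "Present"),
               c("substructure", "Absent"))
  for (scheme in names(ORACLE_WEIGHTS)) {
    for (j in seq_along(cols)) {
      expect_equal(
        lookup_weight(scheme, cols[[j]][1], cols[[j]][2]),
        ORACLE_WEIGHTS[[scheme]][j],
        info = paste(scheme, cols[[j]][1], cols[[j]][2])
      )
    }
  }
  # spot checks straight from the table
  expect_equal(lookup_weight("KB-a", "substructure", "Absent"), 0.5)
  expect_equal(lookup_weight("KB-b", "m3", "S"), 0.8)
  expect_equal(lookup_weight("KB-b", "similarity", "NoMatch"), 0)
})

test_that("hand-summed consensus scores match", {
  all_s <- vote_tbl(1, 1, 1, 1, "S", 1)
  r <- consensus_score(all_s, "KB-b")
  expect_equal(r$score, 4.1)                  # 1 + 0.8 + 0.3 + 1 + 1
  expect_equal(r$label, "sensitizer")

  all_n <- vote_tbl(-1, -1, -1, 0, "NoMatch", -1)
  r2 <- consensus_score(all_n, "KB-b")
  expect_equal(r2$score, -2.1)                # -0.8 -0.4 -0.4 + 0 - 0.5
  expect_equal(r2$label, "non-sensitizer")
})

test_that("exact cancellation yields indeterminate under a custom scheme", {
  custom <- weight_scheme("KB-b")
  custom$weight <- 0
  custom$weight[custom$component == "m2" & custom$direction == "S"] <- 1
  custom$weight[custom$component == "m3" & custom$direction == "N"] <- 1
  r <- consensus_score(vote_tbl(1, -1, 1, 0, "NoMatch", 1), custom)
  expect_equal(r$score, 0)
  expect_equal(r$label, "indeterminate")
})

test_that("the full vote grid agrees with the brute-force oracle", {
  sims <- list(c(1, "S"), c(-1, "N"), c(0, "NS"), c(0, "NoMatch"))
  for (scheme in names(ORACLE_WEIGHTS)) {
    w <- ORACLE_WEIGHTS[[scheme]]
    for (m2 in c(-1, 1)) for (m3 in c(-1, 1)) for (m4 in c(-1, 1)) {
      for (sim in sims) for (sub in c(-1, 1)) {
        sv <- as.numeric(sim[1])
        r <- consensus_score(vote_tbl(m2, m3, m4, sv, sim[2], sub), scheme)
        expected <- oracle_score(w, m2, m3, m4, sv, sim[2], sub)
        expect_equal(r$score, round(expected, 10))
        expect_equal(r$label,
                     if (expected > 1e-9) "sensitizer"
                     else if (expected < -1e-9) "non-sensitizer"
                     else "indeterminate")
        # every reachable score with tenth-valued weights is a tenth
        expect_equal(r$score * 10, round(r$score * 10))
      }
    }
  }
})

test_that("flipping a vote upward never decreases the score", {
  withr::with_seed(19, {
    for (rep in 1:20) {
      m <- sample(c(-1, 1), 3, replace = TRUE)
      sub <- sample(c(-1, 1), 1)
      sim <- sample(list(c(1, "S"), c(-1, "N"), c(0, "NoMatch")), 1)[[1]]
      # equal direction-weights so that flipping is monotone
      ws <- weight_scheme("KB-a")
      base <- consensus_score(
        vote_tbl(m[1], m[2], m[3], as.numeric(sim[1]), sim[2], sub), ws)$score
      for (slot in 1:3) {
        if (m[slot] == -1) {
          m2 <- m; m2[slot] <- 1
          up <- consensus_score(
            vote_tbl(m2[1], m2[2], m2[3], as.numeric(sim[1]), sim[2], sub),
            ws)$score
          expect_gte(up, base)
        }
      }
    }
  })
})

test_that("scaling all weights leaves every label unchanged", {
  ws <- weight_scheme("KB-b")
  scaled <- ws
  scaled$weight <- scaled$weight * 3.7
  sims <- list(c(1, "S"), c(-1, "N"), c(0, "NoMatch"))
  for (m2 in c(-1, 1)) for (sub in c(-1, 1)) for (sim in sims) {
    v <- vote_tbl(m2, -1, 1, as.numeric(sim[1]), sim[2], sub)
    expect_equal(consensus_score(v, ws)$label,
                 consensus_score(v, scaled)$label)
  }
})

test_that("malformed component sets and schemes are rejected", {
  v <- vote_tbl(1, 1, 1, 1, "S", 1)
  expect_error(consensus_score(v[-1, ], "KB-b"),
               class = "skinqsar_incomplete_components_error")
  expect_error(consensus_score(v, "KB-z"),
               class = "skinqsar_unknown_scheme_error")
  bad <- v; bad$value[1] <- 0   # QSAR votes are strictly +/-1
  expect_error(consensus_score(bad, "KB-b"), class = "skinqsar_value_error")
  expect_error(lookup_weight("KB-a", "m2", "Present"),
               class = "skinqsar_key_error")
})

test_that("meta-integration learns concordant votes perfectly", {
  withr::with_seed(5, {
    votes <- matrix(sample(c(-1L, 1L), 400, replace = TRUE), ncol = 5,
                    dimnames = list(NULL,
                                    c("m2", "m3", "m4", "similarity",
                                      "substructure")))
  })
  labels <- votes[, "m2"]
  mm <- meta_integrate(votes, labels, method = "SMO", seed = 3)
  expect_equal(mm$cv_accuracy, 1)
  expect_equal(mm$n_folds, 10)                   # default fold count
  expect_true(all(predict(mm, votes) %in% c(-1L, 1L)))

  expect_error(meta_integrate(votes, rep(1, nrow(votes))),
               class = "skinqsar_degenerate_input_error")
  zero <- votes * 0L
  expect_warning(mz <- meta_integrate(zero, labels), "majority")
  expect_true(all(predict(mz, zero) %in% c(-1L, 1L)))
})

test_that("workflows score every molecule with all five components", {
  bundle <- small_bundle()
  test <- small_benchmark_test()
  res <- run_workflow(test, bundle)
  expect_s3_class(res, "consensus_results")
  expect_equal(nrow(res), nrow(test))
  for (col in c("m2", "m3", "m4", "similarity", "substructure")) {
    expect_true(all(!is.na(res[[col]])), info = col)
  }
  expect_true(all(res$label[res$score > 0] == "sensitizer"))
  expect_true(all(res$label[res$score < 0] == "non-sensitizer"))
})

test_that("ablation zeroes component groups as advertised", {
  bundle <- small_bundle()
  test <- small_benchmark_test()

  # substructure alone: +/-1 times a positive weight can never be zero
  only_sub <- run_workflow(test, bundle, ablate = c("qsar", "similarity"))
  expect_false(any(only_sub$label == "indeterminate"))
  expect_equal(only_sub$score,
               ifelse(only_sub$substructure > 0, 1, -0.5))  # KB-b pair (1, 0.5)

  # qsar ablated, molecule without similarity match and without alerts:
  # score = -0.5 (absent alert) under KB-b
  no_qsar <- run_workflow(test, bundle, ablate = "qsar")
  lonely <- no_qsar$sim_direction == "NoMatch" & no_qsar$substructure == -1
  if (any(lonely)) {
    expect_true(all(no_qsar$score[lonely] == -0.5))
    expect_true(all(no_qsar$label[lonely] == "non-sensitizer"))
  }
  expect_error(run_workflow(test, bundle, ablate = "nonsense"),
               class = "skinqsar_value_error")
})

test_that("a meta-model combiner never returns indeterminate", {
  bundle <- small_bundle()
  test <- small_benchmark_test()
  base <- run_workflow(test, bundle)
  votes <- as.matrix(base[, c("m2", "m3", "m4", "similarity", "substructure")])
  truth <- ifelse(is_sensitizer(test$potency[match(base$id, test$id)]), 1, -1)
  mm <- meta_integrate(votes, truth, method = "SMO", seed = 7)
  res <- run_workflow(test, bundle, scheme = mm)
  expect_false(any(res$label == "indeterminate"))
})
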