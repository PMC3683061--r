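test_that("subject matching intersects ids across sources", {
  mk <- function(ids) matrix(rnorm(length(ids) * 2), length(ids), 2,
                             dimnames = list(ids, NULL))
  labels <- stats::setNames(rep(c(1, -1), 3), sprintf("s%d", 1:6))
  b <- suppressMessages(match_subjects(demographics = mk(c("s1", "s2", "s3")),
                                       genotypes = mk(c("s2", "s1", "s9")),
                                       labels = labels))
  expect_equal(b$subject_ids, c("s1", "s2"))
  expect_equal(names(b$views), c("D", "G"))
  # identical id sets retain everything, in sorted order
  b2 <- suppressMessages(match_subjects(demographics = mk(c("s3", "s1", "s2")),
                                        images = mk(c("s1", "s2", "s3")),
                                        labels = labels))
  expect_equal(b2$subject_ids, c("s1", "s2", "s3"))
  expect_equal(rownames(b2$views$D), b2$subject_ids)
  expect_error(suppressMessages(match_subjects(demographics = mk("a"),
                                               genotypes = mk("b"),
                                               labels = c(a = 1, b = -1))),
               class = "pmfuse_error_empty_intersection")
})

test_that("engineered overlap of 100/90/80 sources with 75 common ids matches exactly", {
  set.seed(81)
  all_ids <- sprintf("x%03d", 1:130)
  common <- all_ids[1:75]
  mk <- function(ids) matrix(rnorm(length(ids)), length(ids), 1,
                             dimnames = list(ids, NULL))
  d_ids <- c(common, all_ids[76:100])          # 100
  g_ids <- c(common, all_ids[101:115])         # 90
  i_ids <- c(common, all_ids[116:120])         # 80
  labels <- stats::setNames(sample(c(1, -1), 130, replace = TRUE), all_ids)
  labels[common[1]] <- 1
  b <- suppressMessages(match_subjects(mk(d_ids), mk(g_ids), mk(i_ids), labels))
  expect_equal(length(b$subject_ids), 75)
  expect_setequal(b$subject_ids, common)
})

test_that("method_specs enumerates the seven non-empty modality subsets", {
  m <- method_specs()
  expect_length(m, 7)
  expect_setequal(m, c("D", "G", "I", "D+G", "D+I", "G+I", "D+G+I"))
})

test_that("one test yields two result groups per method with balanced training sets", {
  set.seed(82)
  b <- toy_bundle(n = 40, n_pos = 10, d_effect = 1, g_effect = 1, i_effect = 1)
  ev <- run_protocol(b, n_tests = 1, seed = 3)
  counts <- table(ev$results$method)
  expect_true(all(counts == 2))
  expect_equal(nrow(ev$results), 14)
  # balanced training: n_train = 2 * positives of the training half
  expect_true(all(ev$results$n_train %% 2 == 0))
  # every method within a (test, round) shares the same train/test sizes
  for (r in 1:2) {
    sub <- ev$results[ev$results$round == r, ]
    expect_equal(length(unique(sub$n_train)), 1)
    expect_equal(length(unique(sub$n_test)), 1)
    expect_equal(sub$n_test[1], 20)
  }
})

test_that("stratified half splits are disjoint, exhaustive and balanced", {
  set.seed(83)
  y <- c(rep(1, 11), rep(-1, 29))
  for (s in 1:20) {
    halves <- with_seed(s, pmfuse:::stratified_half_split(y))
    expect_length(intersect(halves$A, halves$B), 0)
    expect_setequal(c(halves$A, halves$B), seq_along(y))
    expect_lte(abs(sum(y[halves$A] > 0) - sum(y[halves$B] > 0)), 1)
    expect_lte(abs(sum(y[halves$A] < 0) - sum(y[halves$B] < 0)), 1)
    # odd class counts put the extra subject in half A
    expect_equal(sum(y[halves$A] > 0), 6)
    expect_equal(sum(y[halves$A] < 0), 15)
  }
})

test_that("the protocol is bit-identical under a fixed seed", {
  set.seed(84)
  b <- toy_bundle(n = 36, n_pos = 8, d_effect = 0.8, g_effect = 0.5, i_effect = 1)
  ev1 <- run_protocol(b, n_tests = 2, seed = 11)
  ev2 <- run_protocol(b, n_tests = 2, seed = 11)
  expect_identical(ev1$results, ev2$results)
  expect_identical(ev1$roc, ev2$roc)
  ev3 <- run_protocol(b, n_tests = 2, seed = 12)
  expect_false(identical(ev1$results$auc, ev3$results$auc))
})

test_that("20 result groups are produced at the default test count", {
  set.seed(85)
  b <- toy_bundle(n = 60, n_pos = 12, d_effect = 1, g_effect = 0.3, i_effect = 0.6)
  ev <- run_protocol(b, methods = c("D", "D+G"), n_tests = 10, seed = 2)
  expect_equal(sum(ev$results$method == "D"), 20)
  expect_equal(sum(ev$results$method == "D+G"), 20)
  expect_true(all(ev$results$auc >= 0 & ev$results$auc <= 1))
})

test_that("requesting a modality absent from the bundle fails loudly", {
  set.seed(86)
  ids <- sprintf("s%d", 1:20)
  b <- suppressMessages(match_subjects(
    demographics = matrix(rnorm(40), 20, 2, dimnames = list(ids, NULL)),
    labels = stats::setNames(rep(c(1, -1), 10), ids)))
  expect_error(run_protocol(b, methods = "G", n_tests = 1, seed = 1),
               class = "pmfuse_error_modality_mismatch")
})

test_that("method comparison reports matched means and paired significance", {
  set.seed(87)
  b <- toy_bundle(n = 50, n_pos = 12, d_effect = 1.5, g_effect = 0.1, i_effect = 0.1)
  ev <- run_protocol(b, methods = c("D", "G"), n_tests = 10, seed = 4)
  cm <- compare_methods(ev)
  expect_equal(nrow(cm$table), 2)
  expect_equal(cm$table$n_groups, c(20, 20))
  expect_equal(unname(diag(cm$p_values)), c(1, 1))
  expect_equal(cm$p_values["D", "G"], cm$p_values["G", "D"], tolerance = 1e-12)
})

test_that("a constant AUC advantage with small jitter is highly significant", {
  set.seed(88)
  base <- runif(20, 0.6, 0.7)
  mk_eval <- function(auc, method) {
    structure(list(results = data.frame(method = method,
                                        test = rep(1:10, each = 2),
                                        round = rep(1:2, 10), auc = auc,
                                        sensitivity_at_setpoint = 0.5),
                   roc = list(),
                   provenance = list(seed = 1, n_tests = 10, n_subjects = 40)),
              class = "pm_eval")
  }
  ev <- mk_eval(c(base, base + 0.05 + rnorm(20, 0, 1e-4)),
                rep(c("lo", "hi"), each = 20))
  cm <- compare_methods(ev)
  expect_lt(cm$p_values["hi", "lo"], 1e-6)
  expect_true(cm$significant["hi", "lo"])
})

test_that("comparing runs with different split provenance is refused", {
  set.seed(89)
  b <- toy_bundle(n = 30, n_pos = 8, d_effect = 1, g_effect = 1, i_effect = 1)
  ev1 <- run_protocol(b, methods = "D", n_tests = 2, seed = 1)
  ev2 <- run_protocol(b, methods = "G", n_tests = 2, seed = 2)
  expect_error(compare_methods(list(ev1, ev2)),
               class = "pmfuse_error_provenance_mismatch")
  # same provenance combines fine
  ev3 <- run_protocol(b, methods = "G", n_tests = 2, seed = 1)
  cm <- compare_methods(list(ev1, ev3))
  expect_setequal(cm$table$method, c("D", "G"))
})
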