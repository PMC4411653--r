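# Dataset assembly, grouped splitting, tuning, fitting and the
# short-sequence deleterious rule.

fake_rows <- function(n, label, prefix, freq = 0.001,
                      variant_class = "missense") {
  set.seed(nchar(prefix) + n)
  d <- as.data.frame(matrix(rnorm(n * 4), n, 4,
                            dimnames = list(NULL, paste0("f", 1:4))))
  d$group_key <- paste0(prefix, seq_len(n))
  d$transcript_id <- "TX1"
  d$frequency <- rep_len(freq, n)
  d$variant_class <- rep_len(variant_class, n)
  d
}

test_that("dataset assembly applies both frequency filters with provenance", {
  dmg <- fake_rows(10, "damaging", "d")
  dmg$frequency[3] <- 0.07           # common -> dropped from damaging
  tol <- fake_rows(10, "tolerated", "t", freq = 0.2)
  tol$frequency[5] <- 0.04           # rare -> dropped from tolerated
  ds <- assemble_dataset(dmg, tol)
  expect_s3_class(ds, "labeled_dataset")
  expect_equal(nrow(ds$rows), 18)
  expect_equal(ds$provenance$removed_freq_damaging, 1)
  expect_equal(ds$provenance$removed_freq_tolerated, 1)
  expect_false("d3" %in% ds$rows$group_key)
  expect_false("t5" %in% ds$rows$group_key)
  expect_equal(ds$provenance$initial - ds$provenance$removed_freq_damaging -
                 ds$provenance$removed_freq_tolerated -
                 ds$provenance$removed_syn - ds$provenance$removed_frscsd,
               ds$provenance$final)
})

test_that("synonymous rows are removed and counted", {
  dmg <- fake_rows(10, "damaging", "d")
  dmg$variant_class[1:3] <- "synonymous"
  tol <- fake_rows(4, "tolerated", "t", freq = 0.2)
  ds <- assemble_dataset(dmg, tol)
  expect_equal(ds$provenance$removed_syn, 3)
  expect_equal(sum(ds$rows$label == "damaging"), 7)
})

test_that("conflicting labels and duplicate tolerated rows are handled", {
  dmg <- fake_rows(5, "damaging", "x")
  tol <- fake_rows(5, "tolerated", "x", freq = 0.2)
  expect_error(assemble_dataset(dmg, tol), "both damaging and tolerated")

  tol2 <- fake_rows(6, "tolerated", "t", freq = 0.2)
  tol2$group_key[6] <- tol2$group_key[1]   # same variant from two sources
  ds <- assemble_dataset(fake_rows(5, "damaging", "d"), tol2)
  expect_equal(ds$provenance$removed_duplicate_tolerated, 1)
})

test_that("FR/SC/SD exclusion is applied only when requested", {
  dmg <- fake_rows(10, "damaging", "d")
  dmg$variant_class[1:4] <- "frameshift"
  tol <- fake_rows(10, "tolerated", "t", freq = 0.2)
  keep <- assemble_dataset(dmg, tol)
  drop <- assemble_dataset(dmg, tol, exclude_fr_sc_sd = TRUE)
  expect_equal(keep$provenance$removed_frscsd, 0)
  expect_equal(drop$provenance$removed_frscsd, 4)
  expect_equal(nrow(keep$rows) - nrow(drop$rows), 4)
})

test_that("grouped splits keep isoform rows together and hit the fraction", {
  rows <- fake_rows(100, "damaging", "g")
  sp <- split_grouped(rows, 0.7, seed = 1)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$test), 30)

  # a variant with 4 transcript rows never straddles the split
  multi <- do.call(rbind, rep(list(fake_rows(25, "damaging", "m")), 4))
  sp2 <- split_grouped(multi, 0.7, seed = 5)
  expect_length(intersect(sp2$train$group_key, sp2$test$group_key), 0)

  sp3a <- split_grouped(rows, 0.7, seed = 9)
  sp3b <- split_grouped(rows, 0.7, seed = 9)
  expect_identical(sp3a$train$group_key, sp3b$train$group_key)

  one <- fake_rows(3, "damaging", "s")
  one$group_key <- "only"
  expect_error(split_grouped(one, 0.7, seed = 1), "fewer than two")
})

test_that("class balancing caps the majority class near the target ratio", {
  dmg <- fake_rows(100, "damaging", "d")
  dmg$label <- "damaging"
  tol <- fake_rows(40, "tolerated", "t", freq = 0.2)
  tol$label <- "tolerated"
  b <- balance_classes(rbind(dmg, tol), max_ratio = 1.3, seed = 2)
  n <- table(b$label)
  expect_lte(max(n) / min(n), 1.3)
  expect_equal(min(n), 40)
})

test_that("the mtry heuristic and published defaults are as specified", {
  expect_equal(mtry_heuristic(50), 6L)   # floor(log2(50)) + 1
  expect_equal(mtry_heuristic(66), 7L)
  expect_equal(mtry_heuristic(50, trees = 250, mode = "literal"),
               as.integer(floor(log(250)) + 1))
  expect_equal(default_params(),
               list(w = 0.1, lambda = 12L, trees = 250L, mtry = 2L))
  g <- default_grid()
  expect_equal(sort(unique(g$trees)),
               c(5L, 10L, 50L, 100L, 150L, 200L, 250L, 300L, 350L))
  expect_equal(sort(unique(g$lambda)), c(4L, 8L, 12L, 16L, 20L))
  expect_equal(sort(unique(g$w)), c(0.1, 0.5))
})

test_that("fitting, scoring and determinism of the classifiers", {
  sim <- simulate_study(sim_config(n_genes = 8, mean_cds_codons = 120,
                                   n_variants = 200, seed = 21))
  f <- sim$features
  rf <- fit_classifier(data = f, method = "rf", trees = 100, mtry = 2,
                       seed = 1)
  expect_s3_class(rf, "pseaac_clf")
  expect_equal(rf$params$trees, 100)
  expect_equal(rf$params$mtry, 2)
  p <- predict(rf, f)
  expect_gt(mean(p$class == f$label), 0.5)
  expect_true(all(p$score >= 0 & p$score <= 1))
  expect_identical(ifelse(p$score >= 0.5, "damaging", "tolerated"), p$class)
  # posterior of the complementary class is the complement
  probs <- predict(rf$fit, f[rf$feature_order], type = "prob")
  expect_equal(rowSums(probs), rep(1, nrow(f)), ignore_attr = TRUE)
  # same row scored twice gives the same answer
  expect_identical(predict(rf, f[3, ]), predict(rf, f[3, ]))

  lr <- fit_classifier(data = f, method = "lr")
  expect_gt(mean(predict(lr, f, type = "class") == f$label), 0.5)
  expect_length(coef(lr), length(lr$feature_order) + 1)
  expect_error(coef(rf), "logistic")

  # scoring refuses a mismatched feature block
  f8 <- simulate_study(sim_config(n_genes = 8, mean_cds_codons = 120,
                                  n_variants = 30, seed = 22),
                       lambda = 8L)$features
  expect_error(predict(rf, f8[feature_names(8L)]), "lambda = 12")

  one_class <- f[f$label == "damaging", ]
  expect_error(fit_classifier(data = one_class, method = "rf"),
               "single class")
})

test_that("the short-sequence rule fires only below lambda + 1 residues", {
  p100 <- paste0("M", rand_aa(99))
  stop3 <- fake_cc(p100, substr(p100, 1, 2), class = "stop_gain", first = 3)
  r <- rule_score(stop3, lambda = 12)
  expect_equal(r$class, "damaging")
  expect_equal(r$score, 1.0)
  expect_equal(r$source, "rule")

  mid <- fake_cc(p100, paste0(substr(p100, 1, 49), "W", substring(p100, 51)),
                 first = 50)
  expect_null(rule_score(mid, lambda = 12))

  stop30 <- fake_cc(p100, substr(p100, 1, 29), class = "stop_gain",
                    first = 30)
  expect_null(rule_score(stop30, lambda = 12))  # snippet still >= 13 long

  expect_null(rule_score(fake_cc(p100, p100, class = "synonymous",
                                 first = 0)))
})

test_that("tuning returns a single-point grid verbatim and is deterministic", {
  sim <- simulate_study(sim_config(n_genes = 8, mean_cds_codons = 120,
                                   n_variants = 150, seed = 31))
  base <- sim$features
  encoder <- function(lambda, w) {
    if (lambda == 12L && w == 0.1) return(base)
    # re-encode under the requested PseAAC parameters
    simulate_study(sim$config, lambda = lambda, w = w)$features
  }
  point <- data.frame(trees = 60L, mtry = 2L, lambda = 12L, w = 0.1)
  got <- tune_classifier(encoder, grid = point, folds = 4, seed = 1)
  expect_equal(got$best, list(trees = 60L, mtry = 2L, lambda = 12L, w = 0.1))
  expect_true(is.finite(got$results$cv_accuracy))

  two <- data.frame(trees = c(60L, 60L), mtry = 2L, lambda = 12L,
                    w = c(0.1, 0.1))
  a <- tune_classifier(encoder, grid = two, folds = 4, seed = 7)
  b <- tune_classifier(encoder, grid = two, folds = 4, seed = 7)
  expect_identical(a$results$cv_accuracy, b$results$cv_accuracy)
})
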