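test_that("metrics match brute-force recomputation from prediction vectors", {
  # perfect and chance-level classifiers
  perfect <- classification_metrics(confusion_matrix(10, 10, 0, 0))
  expect_equal(unlist(perfect), c(SEN = 1, SPC = 1, ACC = 1, MCC = 1))
  chance <- classification_metrics(confusion_matrix(5, 5, 5, 5))
  expect_equal(chance$MCC, 0)
  expect_equal(chance$ACC, 0.5)

  set.seed(99)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    truth <- sample(c("pos", "neg"), n, replace = TRUE)
    pred <- sample(c("pos", "neg"), n, replace = TRUE)
    o <- metrics_oracle(pred, truth, "pos")
    if (o$TP + o$TN + o$FP + o$FN == 0) next
    m <- classification_metrics(confusion_matrix(o$TP, o$TN, o$FP, o$FN))
    expect_equal(m$SEN, o$SEN)
    expect_equal(m$SPC, o$SPC)
    expect_equal(m$ACC, o$ACC)
    expect_equal(m$MCC, o$MCC)
    if (!is.na(m$MCC)) expect_true(m$MCC >= -1 && m$MCC <= 1)
    expect_true(m$ACC >= 0 && m$ACC <= 1)
  }

  # undefined metrics are NA, never coerced to 0
  no_pos <- classification_metrics(confusion_matrix(0, 8, 0, 0))
  expect_true(is.na(no_pos$SEN))
  expect_true(is.na(no_pos$MCC))
  expect_error(confusion_matrix(0, 0, 0, 0), "all-zero")
  expect_error(confusion_matrix(-1, 2, 0, 0), "nonnegative")
})

test_that("well-separated sample groups cluster exactly and invariantly", {
  model <- make_model(p = 80, n_hubs = 2, hub_degree = 30,
                      background_edges = 0, seed = 8, effect_size = 5)
  dat <- sample_expression(model, n_per_class = 25, seed = 21)
  x <- dat$expression[model$shift_genes, ]
  cls <- dat$annotation$class
  cs <- cluster_two_groups(x, dat$annotation)
  agree <- max(mean((cs$cluster == 1) == (cls == "high")),
               mean((cs$cluster == 2) == (cls == "high")))
  expect_equal(agree, 1)
  # the shorter-surviving cluster is the high-risk one
  expect_identical(unname(cs$risk[cls == "high"][1]), "high")
  expect_lt(cs$logrank$p_value, 0.05)

  # permuting the samples permutes the assignment, nothing else
  perm <- sample(ncol(x))
  cs2 <- cluster_two_groups(x[, perm], dat$annotation)
  same <- mean((cs$cluster[perm] == 1) == (cs2$cluster == 1))
  expect_true(same %in% c(0, 1))

  # two identical sample pairs form the two clusters
  m4 <- cbind(a1 = c(1, 2, 3), a2 = c(1, 2, 3) + 1e-3,
              b1 = c(9, 1, 4), b2 = c(9, 1, 4) + 1e-3)
  rownames(m4) <- paste0("g", 1:3)
  cl4 <- cluster_two_groups(m4)$cluster
  expect_identical(unname(cl4[c("a1", "a2")]), rep(cl4[["a1"]], 2))
  expect_identical(unname(cl4[c("b1", "b2")]), rep(cl4[["b1"]], 2))
  expect_false(cl4[["a1"]] == cl4[["b1"]])

  expect_error(cluster_two_groups(matrix(1, 3, 5)), "constant")
  expect_error(cluster_two_groups(matrix(rnorm(6), 2, 3)), "4 samples")
})

test_that("log-rank matches the hand-computed observed-minus-expected table", {
  # identical curves: statistic ~ 0, p ~ 1
  ann0 <- make_ann(days = rep(c(100, 200, 300, 400), 2),
                   event = rep(c(TRUE, TRUE, FALSE, TRUE), 2))
  lr0 <- logrank(rep(c("a", "b"), each = 4), ann0)
  expect_lt(lr0$statistic, 1e-10)
  expect_equal(lr0$p_value, 1, tolerance = 1e-6)

  # 6 vs 6 worked example against the O/E oracle
  days <- c(6, 13, 21, 30, 31, 37, 38, 47, 49, 50, 63, 79)
  event <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
             TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  grp <- rep(c("treated", "control"), 6)
  ann <- make_ann(days, event)
  got <- logrank(grp, ann)
  want <- logrank_oe(days, event, grp)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-9)

  expect_error(logrank(rep("a", 12), ann), "two nonempty")
  expect_error(logrank(c(grp[-1], "c"), ann), "two groups")
})

test_that("log-rank p-values are calibrated under label permutation", {
  set.seed(17)
  ann <- make_ann(days = sample(50:2000, 60),
                  event = runif(60) < 0.7)
  pvals <- replicate(1000, {
    g <- sample(rep(c("a", "b"), 30))
    logrank(g, ann)$p_value
  })
  expect_gt(mean(pvals), 0.45)
  expect_lt(mean(pvals), 0.55)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.025)
})

test_that("random gene-set null is seeded and detects planted module signal", {
  model <- make_model(p = 300, n_hubs = 2, hub_degree = 30,
                      background_edges = 0, seed = 5, effect_size = 3)
  dat <- sample_expression(model, n_per_class = 80, seed = 11)
  mod <- model$shift_genes
  rn <- random_geneset_null(dat$expression, dat$annotation,
                            rownames(dat$expression), m = length(mod),
                            reps = 30, seed = 3, module_genes = mod)
  expect_length(rn$p_values, 30)
  expect_lt(rn$observed_p, rn$mean_p)

  rn2 <- random_geneset_null(dat$expression, dat$annotation,
                             rownames(dat$expression), m = length(mod),
                             reps = 30, seed = 3)
  expect_identical(rn$p_values, rn2$p_values)

  # degenerate: sampling all genes reproduces the "module" p every time
  small <- dat$expression[1:20, ]
  rall <- random_geneset_null(small, dat$annotation, rownames(small),
                              m = 20, reps = 5, seed = 1,
                              module_genes = rownames(small))
  expect_true(all(rall$p_values == rall$observed_p))

  expect_error(random_geneset_null(small, dat$annotation, rownames(small),
                                   m = 21, reps = 2, seed = 1), "exceeds")
})

test_that("svm-rfe consistently ranks informative genes first", {
  hits <- 0L
  for (run in 1:100) {
    set.seed(1000 + run)
    x <- matrix(rnorm(30 * 40), 30, 40,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:40)))
    labels <- rep(c("high", "low"), each = 20)
    x[c("g01", "g02"), labels == "high"] <-
      x[c("g01", "g02"), labels == "high"] + 3
    sel <- svm_rfe_select(x, labels, n_features = 2)
    if (setequal(sel, c("g01", "g02"))) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("svm-rfe edge cases: identity ranking, duplicates, size limits", {
  set.seed(3)
  x <- matrix(rnorm(10 * 30), 10, 30,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:30)))
  labels <- rep(c("high", "low"), each = 15)
  all_ranked <- svm_rfe_select(x, labels, n_features = 10)
  expect_setequal(all_ranked, rownames(x))

  # a duplicated gene gets the same weight: adjacent ranks, id order
  xd <- rbind(x, g11 = x["g03", ])
  ranked <- svm_rfe_select(xd, labels, n_features = 11)
  pos <- match(c("g03", "g11"), ranked)
  expect_equal(diff(pos), 1L)

  expect_error(svm_rfe_select(x, labels, n_features = 11), "exceeds")
  expect_error(svm_rfe_select(x, rep("high", 30), n_features = 2),
               "two classes")
})

test_that("re-sampling evaluation is reproducible, leak-free and calibrated", {
  model <- make_model(p = 40, n_hubs = 1, hub_degree = 10,
                      background_edges = 0, seed = 4, effect_size = 5)
  dat <- sample_expression(model, n_per_class = 30, seed = 6)
  x <- dat$expression
  labels <- dat$annotation$class

  r1 <- resample_evaluate(x, labels, reps = 2, seed = 11)
  r2 <- resample_evaluate(x, labels, reps = 2, seed = 11)
  expect_identical(r1$per_iteration, r2$per_iteration)
  expect_identical(r1$selected_genes, r2$selected_genes)

  # averages are the arithmetic means of the per-iteration values
  expect_equal(r1$averages$ACC, mean(r1$per_iteration$ACC), tolerance = 1e-12)
  expect_equal(r1$averages$MCC, mean(r1$per_iteration$MCC), tolerance = 1e-12)

  # strongly separated classes classify nearly perfectly
  r5 <- resample_evaluate(x, labels, reps = 5, seed = 23)
  expect_gte(r5$averages$ACC, 0.95)
  expect_gte(r5$averages$MCC, 0.9)

  # no leakage: replaying iteration 1 from its recorded seed reproduces the
  # signature from the training split alone
  it_seed <- r1$per_iteration$seed[1]
  set.seed(it_seed)
  idx_pos <- which(labels == "high"); idx_neg <- which(labels == "low")
  nmin <- min(length(idx_pos), length(idx_neg))
  idx_pos <- sort(sample(idx_pos, nmin)); idx_neg <- sort(sample(idx_neg, nmin))
  ntr <- floor(0.8 * nmin)
  tr <- c(sample(idx_pos, ntr), sample(idx_neg, ntr))
  genes <- svm_rfe_select(x[, tr],
                          factor(labels[tr], levels = c("low", "high")),
                          n_features = 30)
  expect_identical(r1$selected_genes[[1]], genes)

  few <- c(1:3, 31:33)
  expect_error(resample_evaluate(x[, few], labels[few], reps = 1, seed = 1),
               ">= 5 samples")
})
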