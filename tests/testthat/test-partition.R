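test_that("hubs are ranked by degree with lexicographic tie-breaks", {
  net <- network_from_edges(data.frame(
    gene_a = c(rep("a", 5), rep("b", 5), rep("c", 3), "d"),
    gene_b = c(paste0("x", 1:5), paste0("y", 1:5), paste0("z", 1:3), "x1")))
  # degrees: a 5, b 5, c 3, d 1, leaves 1-2
  expect_identical(suppressMessages(select_hubs(net, 2)), c("a", "b"))
  expect_identical(suppressMessages(select_hubs(net, 3)), c("a", "b", "c"))
  expect_error(select_hubs(net, 100), "choose k")

  star <- network_from_edges(
    data.frame(gene_a = "center", gene_b = paste0("l", 1:9)),
    nodes = c("center", paste0("l", 1:9), "isolated"))
  expect_identical(select_hubs(star, 1), "center")
})

test_that("initialized modules are the hub plus its direct neighbours", {
  net <- toy_partition_network()
  mods <- initialize_modules(net, c("g1", "g5", "g9"))
  expect_identical(mods[[1]]$members, c("g1", "g2", "g3", "g4"))
  expect_identical(mods[[2]]$members, c("g5", "g6", "g7", "g8"))
  expect_identical(mods[[3]]$members, c("g10", "g2", "g6", "g9"))
  expect_true(all(vapply(mods, function(m) m$hub %in% m$members, TRUE)))
  expect_error(initialize_modules(net, "nope"), "absent")

  # two hubs sharing a neighbour overlap exactly in it
  expect_identical(intersect(mods[[1]]$members, mods[[3]]$members), "g2")
})

test_that("seed sets are the maximal pairwise-disjoint collections", {
  net <- toy_partition_network()
  mods <- initialize_modules(net, c("g1", "g5", "g9"))
  sets <- enumerate_seed_sets(mods)
  expect_length(sets, 1L)
  expect_identical(sets[[1]], c(1L, 2L))

  # all pairwise overlapping: no seed set
  ovl <- lapply(list(c("a", "b"), c("b", "c"), c("c", "a")), function(m)
    structure(list(hub = m[1], members = m, hub_degree = 1L),
              class = "initialized_module"))
  expect_identical(enumerate_seed_sets(ovl), list())

  # three pairwise-disjoint modules form one seed set of size 3,
  # maximality removing its sub-pairs
  dis <- lapply(list(c("a", "b"), c("c", "d"), c("e", "f")), function(m)
    structure(list(hub = m[1], members = m, hub_degree = 1L),
              class = "initialized_module"))
  sets3 <- enumerate_seed_sets(dis)
  expect_length(sets3, 1L)
  expect_identical(sets3[[1]], 1:3)
  # the non-maximal enumeration keeps the pairs too
  expect_length(enumerate_seed_sets(dis, maximal = FALSE), 4L)
})

test_that("seed-set enumeration matches the exhaustive oracle", {
  set.seed(13)
  for (rep in 1:25) {
    mods <- random_module_system(sample(3:6, 1))
    if (length(mods) < 2) next
    got <- enumerate_seed_sets(mods)
    want <- seed_sets_oracle(lapply(mods, `[[`, "members"))
    canon <- function(sets) sort(vapply(sets, paste, "", collapse = ","))
    expect_identical(canon(got), canon(want))
  }
})

test_that("merging follows the overlap-greedy trace with documented tie-breaks", {
  net <- toy_partition_network()
  mods <- initialize_modules(net, c("g1", "g5", "g9"))
  part <- merge_remaining(c(1L, 2L), mods)
  expect_identical(part$modules$g1,
                   c("g1", "g10", "g2", "g3", "g4", "g6", "g9"))
  expect_identical(part$modules$g5, c("g5", "g6", "g7", "g8"))
  expect_equal(part$avg_overlap, 1.0)
  expect_identical(part$merge_log$hub, "g9")
  expect_identical(part$merge_log$target_seed, "g1")
  expect_true(part$merge_log$tie)        # overlap 1 with both seeds
  expect_equal(part$merge_log$overlap, 1)

  # empty remainder: seeds unchanged, E = 0
  p2 <- merge_remaining(c(1L, 2L), mods[1:2])
  expect_identical(p2$modules$g1, c("g1", "g2", "g3", "g4"))
  expect_equal(p2$avg_overlap, 0)
  expect_identical(nrow(p2$merge_log), 0L)

  # strict subset is absorbed without growing the seed
  sub <- structure(list(hub = "g2", members = c("g2", "g3"), hub_degree = 2L),
                   class = "initialized_module")
  p3 <- merge_remaining(c(1L, 2L), c(mods[1:2], list(sub)))
  expect_identical(p3$modules$g1, c("g1", "g2", "g3", "g4"))

  expect_error(merge_remaining(c(1L, 9L), mods), "not present")
})

test_that("zero-overlap remainders follow the orphan policy", {
  mods <- lapply(list(c("a1", "a2"), c("b1", "b2"), c("q1", "q2")), function(m)
    structure(list(hub = m[1], members = m, hub_degree = 1L),
              class = "initialized_module"))
  merged <- merge_remaining(c(1L, 2L), mods, orphan_policy = "merge")
  expect_true(merged$merge_log$orphan)
  expect_identical(merged$modules$a1, c("a1", "a2", "q1", "q2"))
  alone <- merge_remaining(c(1L, 2L), mods, orphan_policy = "standalone")
  expect_identical(alone$modules$q1, c("q1", "q2"))
  expect_length(alone$modules, 3L)
})

test_that("average overlap matches hand computation", {
  expect_equal(average_overlap(list(c("g1", "g2", "g3", "g4", "g6", "g9", "g10"),
                                    c("g5", "g6", "g7", "g8"))), 1.0)
  expect_equal(average_overlap(list(c("a"), c("b"), c("c"))), 0)
  m <- c("x", "y", "z")
  expect_equal(average_overlap(list(m, m, m)), 3)   # every pair overlaps fully
  expect_error(average_overlap(list(m)), "at least 2")

  set.seed(31)
  for (rep in 1:10) {
    mods <- lapply(1:sample(2:5, 1), function(i)
      sample(sprintf("u%02d", 1:15), sample(2:6, 1)))
    expect_equal(average_overlap(mods), avg_overlap_oracle(mods))
  }
})

test_that("the toy network partition matches exhaustive enumeration", {
  net <- toy_partition_network()
  res <- partition_network(net, k = 3)
  expect_length(res$best, 1L)
  best <- res$best[[1]]
  expect_identical(best$modules$g1,
                   c("g1", "g10", "g2", "g3", "g4", "g6", "g9"))
  expect_identical(best$modules$g5, c("g5", "g6", "g7", "g8"))
  expect_equal(best$avg_overlap, 1.0)
  expect_identical(nrow(res$e_table), 1L)

  # independent trace: enumerate every seed set with the oracle and replay
  # the merge by hand
  mods <- initialize_modules(net, suppressMessages(select_hubs(net, 3)))
  oracle_sets <- seed_sets_oracle(lapply(mods, `[[`, "members"))
  oracle_parts <- lapply(oracle_sets, merge_oracle, mods = mods)
  oracle_e <- vapply(oracle_parts, avg_overlap_oracle, 0)
  expect_equal(min(oracle_e), best$avg_overlap)
  expect_identical(oracle_parts[[which.min(oracle_e)]],
                   best$modules[order(names(best$modules))])
})

test_that("best partitions match the oracle on random module systems", {
  set.seed(57)
  tried <- 0L
  while (tried < 15L) {
    mods <- random_module_system(sample(4:6, 1), universe = 14L)
    if (length(mods) < 3) next
    sets <- enumerate_seed_sets(mods)
    if (length(sets) == 0) next
    tried <- tried + 1L
    parts <- lapply(sets, merge_remaining, all_mods = mods)
    e <- vapply(parts, `[[`, 0, "avg_overlap")
    oracle_sets <- seed_sets_oracle(lapply(mods, `[[`, "members"))
    oracle_parts <- lapply(oracle_sets, merge_oracle, mods = mods)
    oracle_e <- vapply(oracle_parts, avg_overlap_oracle, 0)
    expect_equal(min(e), min(oracle_e))
    # ties in E are real (several seed sets can attain the minimum); the
    # implementation's best partitions must coincide, as unordered module
    # sets, with the oracle's best partitions
    canon <- function(mods_list)
      sort(vapply(mods_list, function(ms)
        paste(sort(vapply(ms, paste, "", collapse = ",")), collapse = "|"),
        ""))
    impl_best <- lapply(parts[e <= min(e) + 1e-12], `[[`, "modules")
    oracle_best <- oracle_parts[oracle_e <= min(oracle_e) + 1e-12]
    expect_identical(canon(impl_best), canon(oracle_best))
  }
})

test_that("partitions are deterministic, cover all module genes, and E is
           invariant under disjoint relabeling", {
  net <- toy_partition_network()
  r1 <- partition_network(net, k = 3)
  r2 <- partition_network(net, k = 3)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))

  mods <- initialize_modules(net, suppressMessages(select_hubs(net, 3)))
  all_members <- sort(unique(unlist(lapply(mods, `[[`, "members"))))
  covered <- sort(unique(unlist(r1$best[[1]]$modules)))
  expect_identical(covered, all_members)

  # disjoint relabeled copy scores the same E
  renamed <- net$edges
  renamed$gene_a <- paste0("copy_", renamed$gene_a)
  renamed$gene_b <- paste0("copy_", renamed$gene_b)
  rc <- partition_network(network_from_edges(renamed), k = 3)
  expect_equal(rc$best[[1]]$avg_overlap, r1$best[[1]]$avg_overlap)
})

test_that("planted two-hub structure is recovered exactly at scale", {
  model <- make_model(p = 30, n_hubs = 2, hub_degree = 8, seed = 42)
  dat <- sample_expression(model, n_per_class = 1000, seed = 7)
  scan <- suppressMessages(penalty_scan(dat$expression, k = 2))
  res <- partition_network(scan$network, k = 2)
  got <- lapply(res$best[[1]]$modules, sort)
  truth <- lapply(split(names(model$module_truth),
                        model$module_truth), sort)
  jac <- vapply(truth, function(tm)
    max(vapply(got, function(g)
      length(intersect(g, tm)) / length(union(g, tm)), 0)), 0)
  expect_true(all(jac >= 0.9))
  expect_equal(res$best[[1]]$avg_overlap, 0)
})

test_that("GMT output round-trips", {
  net <- toy_partition_network()
  best <- partition_network(net, k = 3)$best[[1]]
  f <- tempfile(fileext = ".gmt")
  write_gmt(best, f)
  back <- read_gmt(f)
  expect_identical(unname(back), unname(lapply(best$modules, as.character)))
  expect_identical(names(back), c("module_1", "module_2"))
})
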