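test_that("random root sequences are deterministic and landmark-ordered", {
  cat27 <- fixture_catalog()
  s1 <- random_root_sequence(cat27, 9, seed = 5)
  s2 <- random_root_sequence(cat27, 9, seed = 5)
  expect_identical(s1$ranks, s2$ranks)
  expect_false(identical(s1$ranks,
                         random_root_sequence(cat27, 9, seed = 6)$ranks))

  # landmark order: hatching never after a molt, molts in catalogue order
  for (seed in 1:20) {
    s <- random_root_sequence(cat27, sample(2:20, 1), seed = seed)
    r <- event_ranks(s)
    molts <- c("I", "O", "V", "Y", "AA")
    expect_true(all(r[["A"]] <= r[molts]))
    expect_true(all(diff(unname(r[molts])) >= 0))
  }

  one <- random_root_sequence(cat27, 1, seed = 1)
  expect_length(one$ranks, 1L)
  strict <- random_root_sequence(cat27, 27, seed = 1)
  expect_equal(lengths(strict$ranks), rep(1L, 27))
  expect_error(random_root_sequence(cat27, 28, seed = 1), "between 1 and")
})

test_that("apply_shift moves one event and is invertible", {
  cat6 <- plain_catalog(letters[1:6])
  s <- parse_sequence("a,b-c,d,e,f", cat6, "t")

  up <- apply_shift(s, "b", "late", 2)
  expect_equal(event_ranks(up)[["b"]], 4L)
  back <- apply_shift(up, "b", "early", 2)
  expect_equal(lapply(back$ranks, sort), lapply(s$ranks, sort))

  # singleton block travels as its own block and returns
  solo <- apply_shift(s, "d", "early", 2)
  expect_equal(event_ranks(solo)[["d"]], 1L)
  expect_equal(lapply(apply_shift(solo, "d", "late", 2)$ranks, sort),
               lapply(s$ranks, sort))

  clamped <- apply_shift(s, "e", "late", 10)
  expect_true(isTRUE(attr(clamped, "clamped")))
  expect_equal(event_ranks(clamped)[["e"]],
               length(clamped$ranks))

  expect_error(apply_shift(s, "z", "late", 1), "not placed")

  # only pairs involving the shifted event change
  code_before <- encode_sequence(s, cat6)
  code_after <- encode_sequence(up, cat6)
  differs <- which(code_before$state != code_after$state)
  expect_gt(length(differs), 0L)
  expect_true(all(code_before$first[differs] == "b" |
                    code_before$second[differs] == "b"))
})

test_that("tree simulation is seed-reproducible with a faithful shift log", {
  cat27 <- fixture_catalog()
  tree <- fixture_tree()
  root <- random_root_sequence(cat27, 9, seed = 3)

  none <- shift_model(shifts = tibble::tibble(
    child = character(0), event = character(0), direction = character(0),
    displacement = integer(0)))
  sim0 <- simulate_on_tree(tree, root, none)
  for (s in sim0$sequences$seq) expect_equal(s$ranks, root$ranks)

  m <- shift_model(n_shifts_per_branch = 1, seed = 9)
  simA <- simulate_on_tree(tree, root, m)
  simB <- simulate_on_tree(tree, root, m)
  expect_identical(lapply(simA$sequences$seq, `[[`, "ranks"),
                   lapply(simB$sequences$seq, `[[`, "ranks"))
  expect_identical(simA$truth, simB$truth)
  expect_equal(nrow(simA$truth), 10L)  # one per branch

  # a single planted shift affects exactly the subtended clade
  one <- shift_model(shifts = tibble::tibble(
    child = "Cladoceromorpha", event = "H", direction = "late",
    displacement = 1L))
  sim1 <- simulate_on_tree(tree, root, one)
  changed <- vapply(sim1$sequences$seq, function(s)
    !identical(s$ranks, root$ranks), TRUE)
  expect_equal(sim1$sequences$taxon[changed],
               c("Cyclestherida", "Cladocera"))
})

test_that("merge and loss noise stay within their advertised effects", {
  cat27 <- fixture_catalog()
  tree <- fixture_tree()
  root <- random_root_sequence(cat27, 9, seed = 3)
  noisy <- shift_model(n_shifts_per_branch = 0, merge_prob = 0.3,
                       loss_prob = 0.1, seed = 12)
  sim <- simulate_on_tree(tree, root, noisy)
  for (s in sim$sequences$seq) {
    expect_lte(length(s$ranks), length(root$ranks))
    expect_true(all(unlist(s$ranks) %in% event_labels(cat27)))
  }
  expect_error(shift_model(n_shifts_per_branch = 1), "seed is mandatory")
})

test_that("recovery metrics report perfect and empty inference correctly", {
  truth <- tibble::tibble(parent = "p", child = "c", event = "B",
                          direction = "late", displacement = 3L,
                          clamped = FALSE)
  set_tbl <- tibble::tibble(event = "B", direction = "late")
  perfect <- list("p->c" = structure(list(
    branch = "p->c", minimal_size = 1L,
    necessary = tibble::tibble(event = "B", direction = "late",
                               reference = list("C")),
    joint = tibble::tibble(events = list(), directions = list(),
                           reference = list()),
    n_sets = 1L, sets = list(set_tbl)), class = "shift_report"))
  m <- recovery_metrics(truth, perfect)
  expect_equal(m$summary$recall_necessary, 1)
  expect_equal(m$summary$precision_necessary, 1)

  empty <- perfect
  empty[["p->c"]]$necessary <- perfect[["p->c"]]$necessary[0, ]
  empty[["p->c"]]$sets <- list(set_tbl[0, ])
  m0 <- recovery_metrics(truth, empty)
  expect_equal(m0$summary$recall_necessary, 0)
  expect_equal(m0$summary$recall_any, 0)

  bad_truth <- truth
  bad_truth$child <- "elsewhere"
  expect_error(recovery_metrics(bad_truth, perfect), "absent from reports")
})

test_that("the packaged regression scenario replays identically", {
  sc <- regression_scenario()
  simA <- simulate_on_tree(sc$tree, sc$root_seq, sc$model)
  simB <- simulate_on_tree(sc$tree, sc$root_seq, sc$model)
  expect_identical(lapply(simA$node_sequences, `[[`, "ranks"),
                   lapply(simB$node_sequences, `[[`, "ranks"))
  expect_false(any(simA$truth$clamped))
  expect_true(all(simA$truth$displacement >= 3L))
  expect_equal(nrow(simA$truth), 10L)
})
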