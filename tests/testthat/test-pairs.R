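test_that("encoding scores pairs by relative timing with canonical orientation", {
  cat4 <- toy_catalog(4, hatching = "A")
  s <- parse_sequence("A,B-C,D", cat4, "toy")
  code <- encode_sequence(s, cat4)
  expect_equal(nrow(code), 6L)
  st <- function(f, sc) code$state[code$first == f & code$second == sc]
  expect_equal(st("A", "B"), 2L)
  expect_equal(st("A", "C"), 2L)
  expect_equal(st("A", "D"), 2L)
  expect_equal(st("B", "C"), 1L)
  expect_equal(st("B", "D"), 2L)
  expect_equal(st("C", "D"), 2L)

  all_sim <- parse_sequence("A-B-C-D", cat4, "toy")
  expect_true(all(encode_sequence(all_sim, cat4)$state == 1L))
})

test_that("a complete 27-event sequence encodes to 351 characters", {
  cat27 <- fixture_catalog()
  full <- dev_sequence("full", as.list(event_labels(cat27)), character(0), cat27)
  code <- encode_sequence(full, cat27)
  expect_equal(nrow(code), choose(27, 2))
  expect_equal(sum(is.na(code$state)), 0L)
  # missing events score unknown in all their pairs
  pen <- fixture_penilia(cat27)
  pcode <- encode_sequence(pen, cat27)
  expect_equal(sum(is.na(pcode$state)), 25 + 25 + 1)  # E, W pairs
})

test_that("linearized codes round-trip bit-exactly", {
  cat4 <- toy_catalog(4)
  s <- parse_sequence("A-B-C-D", cat4, "toy")
  code <- encode_sequence(s, cat4)
  expect_equal(linearize_code(code, collapse = TRUE), "111111")

  cat27 <- fixture_catalog()
  pen <- fixture_penilia(cat27)
  pcode <- encode_sequence(pen, cat27)
  lin <- linearize_code(pcode)
  expect_length(lin, 351L)
  back <- delinearize_code(lin, cat27, node = "Penilia_avirostris")
  expect_equal(back$state, pcode$state)
  expect_equal(linearize_code(back), lin)

  expect_error(delinearize_code("3", toy_catalog(2)), "invalid")
  expect_error(delinearize_code("012", toy_catalog(2)), "implies")
})

test_that("transitivity violations are detected and encodings are consistent", {
  cat3 <- toy_catalog(3)
  # a < b, b < c, c < a  (cycle)
  cyc <- delinearize_code(c("2", "0", "2"), cat3)  # A<B, C<A, B<C
  viol <- check_consistency(cyc)
  expect_equal(nrow(viol), 1L)
  expect_equal(sort(c(viol$a, viol$b, viol$c)), c("A", "B", "C"))

  unknowns <- delinearize_code(c("?", "?", "?"), cat3)
  expect_equal(nrow(check_consistency(unknowns)), 0L)

  set.seed(41)
  for (i in 1:25) {
    s <- random_sequence(plain_catalog(paste0("e", 1:8)), n_ranks = 4,
                         p_missing = 0.2)
    expect_equal(nrow(check_consistency(
      encode_sequence(s, plain_catalog(paste0("e", 1:8))))), 0L)
  }
})

test_that("derive_sequence inverts encode_sequence on ranks", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    cat_n <- plain_catalog(paste0("e", seq_len(n)))
    s <- random_sequence(cat_n, n_ranks = sample(1:n, 1), p_missing = 0.15)
    code <- encode_sequence(s, cat_n)
    if (length(unlist(s$ranks)) < 2) next
    d <- derive_sequence(code, cat_n, node = s$taxon)
    expect_equal(lapply(d$ranks, sort), lapply(s$ranks, sort))
    expect_equal(d$missing, s$missing)
  }
})

test_that("partially known tables derive the weakest consistent extension", {
  cat4 <- toy_catalog(4)
  code <- delinearize_code(c("2", "?", "?", "?", "?", "?"), cat4)  # A before B
  d <- derive_sequence(code, cat4)
  expect_equal(d$ranks, list("A", "B"))
  expect_equal(sort(d$missing), c("C", "D"))
  # derived sequences agree with every known input entry
  re <- encode_sequence(d, cat4)
  known <- !is.na(code$state)
  expect_equal(re$state[known], code$state[known])
})

test_that("inconsistent tables error unless repair is requested", {
  cat3 <- toy_catalog(3)
  cyc <- delinearize_code(c("2", "0", "2"), cat3)
  err <- tryCatch(derive_sequence(cyc, cat3), error = identity)
  expect_s3_class(err, "error")
  expect_equal(nrow(err$violations), 1L)

  rep <- derive_sequence(cyc, cat3, repair = TRUE)
  expect_true(attr(rep, "repaired"))
  # the cycle collapses into one simultaneity rank
  expect_equal(lapply(rep$ranks, sort), list(c("A", "B", "C")))
})
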