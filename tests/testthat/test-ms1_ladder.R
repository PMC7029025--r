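annotated_table1 <- function() {
  annotate_peaks(table1_peaks(), anchor = list(mz = 1008.6832, carbons = 13))
}

test_that("the published six-peak list forms one family with the expected edges", {
  fams <- detect_ladders(table1_peaks())
  expect_length(fams, 1)
  f <- fams[[1]]
  expect_equal(nrow(f$members), 6)
  e <- f$edges
  key <- function(from_mz, to_mz, kind) {
    m <- f$members
    any(e$kind == kind &
          e$from == m$id[abs(m$mz - from_mz) < 1e-6] &
          e$to == m$id[abs(m$mz - to_mz) < 1e-6])
  }
  expect_true(key(994.6701, 1008.6832, "CH2"))
  expect_true(key(1008.6832, 1022.6963, "CH2"))
  expect_true(key(1022.6963, 1036.7073, "CH2"))
  expect_true(key(1040.7147, 1054.7286, "CH2"))
  expect_true(key(1022.6963, 1040.7147, "WATER"))
  expect_true(key(1036.7073, 1054.7286, "WATER"))
  expect_equal(nrow(e), 6)
  # every reported residual is within its tolerance
  expect_true(all(e$residual <= 0.03))
})

test_that("degenerate peak lists give singleton families", {
  one <- peak_list(rt = 10, mz = 1000)
  fams <- detect_ladders(one)
  expect_length(fams, 1)
  expect_equal(nrow(fams[[1]]$edges), 0)
  two <- peak_list(rt = c(10, 11), mz = c(1000, 1001))
  expect_length(detect_ladders(two), 2)
  expect_error(detect_ladders(one, ch2_tol = 0), "positive")
})

test_that("water edges drive the topology calls and RT is only corroboration", {
  f <- classify_topology_ms1(detect_ladders(table1_peaks())[[1]])
  m <- f$members
  expect_identical(m$topology[abs(m$mz - 994.6701) < 1e-6], "cyclic")
  expect_identical(m$topology[abs(m$mz - 1036.7073) < 1e-6], "cyclic")
  expect_identical(m$topology[abs(m$mz - 1040.7147) < 1e-6], "linear")
  expect_identical(m$topology[abs(m$mz - 1054.7286) < 1e-6], "linear")
  expect_length(f$warnings, 0)

  # linear candidate eluting later than its cyclic partner earns a warning
  late <- peak_list(rt = c(10, 11), mz = c(1000, 1018.0106))
  f2 <- classify_topology_ms1(detect_ladders(late)[[1]])
  expect_identical(sort(f2$members$topology), c("cyclic", "linear"))
  expect_match(f2$warnings, "does not elute earlier", all = FALSE)

  # CH2 chain without water edges: all cyclic candidates
  chain <- peak_list(rt = 1:3, mz = 1000 + 14.01565 * (0:2))
  f3 <- classify_topology_ms1(detect_ladders(chain)[[1]])
  expect_true(all(f3$members$topology == "cyclic"))
})

test_that("tail carbons propagate from the anchor along CH2 and water edges", {
  fams <- annotated_table1()
  rep1 <- family_report(fams[[1]])
  expect_equal(rep1$tail_carbons, c(12, 13, 14, 15, 14, 15))
  expect_equal(rep1$nominal_offset[rep1$type == "cyclic"], c(0, 14, 28, 42))
  expect_identical(rep1$designation, c("A", "B", "C", "D", "C_L", "D_L"))

  # single-member family anchored directly
  f <- classify_topology_ms1(detect_ladders(peak_list(rt = 5, mz = 900))[[1]])
  f <- infer_tail_lengths(f, list(id = f$members$id[1], carbons = 12))
  expect_equal(f$members$tail_carbons, 12L)
  expect_error(infer_tail_lengths(f, list(id = "nope", carbons = 12)),
               "not a member")
})

test_that("conflicting propagation paths raise an error naming the cycle", {
  # two paths to the same endpoint: nine CH2-sized steps vs seven
  # water-sized steps, each within tolerance but differing by 9 carbons
  total <- 7 * 18.0105646 + 0.067
  mz <- c(1000, 1000 + cumsum(rep(total / 9, 9)),
          1000 + cumsum(rep(total / 7, 7))[-7])
  pk <- peak_list(rt = seq_along(mz), mz = sort(mz))
  f <- classify_topology_ms1(detect_ladders(pk)[[1]])
  anchor_id <- f$members$id[which.min(f$members$mz)]
  expect_error(infer_tail_lengths(f, list(id = anchor_id, carbons = 12)),
               "inconsistent tail-carbon propagation")
})

test_that("edge conflicts keep the smaller-residual partner", {
  pk <- peak_list(rt = c(1, 2, 3), mz = c(1000, 1014.0157, 1014.0357),
                  id = c("x", "best", "worse"))
  fams <- detect_ladders(pk)
  f <- fams[[1]]
  expect_setequal(f$members$id, c("x", "best"))
  expect_equal(nrow(f$edges), 1)
  expect_identical(f$edges$to, "best")
  expect_identical(fams[[2]]$members$id, "worse")
})

test_that("annotation is invariant under permutation of the input rows", {
  ref <- family_report(annotated_table1()[[1]])
  pk <- table1_peaks()
  set.seed(41)
  for (i in 1:5) {
    shuffled <- pk[sample(nrow(pk)), , drop = FALSE]
    fams <- annotate_peaks(shuffled, anchor = list(mz = 1008.6832, carbons = 13))
    expect_equal(family_report(fams[[1]]), ref, ignore_attr = TRUE)
  }
})

test_that("designation, mass and tail order agree within each topology class", {
  fams <- annotated_table1()
  m <- fams[[1]]$members
  for (cls in c("cyclic", "linear")) {
    sub <- m[m$topology == cls, , drop = FALSE]
    sub <- sub[order(sub$mz), , drop = FALSE]
    expect_false(is.unsorted(sub$designation))
    expect_false(is.unsorted(sub$tail_carbons))
  }
})

test_that("an unpartnered linear member is lettered by its tail count", {
  # CH2 chain whose heaviest member is later revealed linear by MS2 only;
  # with no cyclic water partner the letter comes from the tail count
  pk <- peak_list(rt = c(5, 6, 7), mz = 1000 + 14.0157 * (0:2),
                  id = c("p12", "p13", "p14"))
  f <- classify_topology_ms1(detect_ladders(pk)[[1]])
  f <- infer_tail_lengths(f, list(id = "p12", carbons = 12))
  lin_spec <- lipopeptide_spec("LLLVDLL", 14, "linear")
  sp <- simulate_ms2(lin_spec, seed = 3)
  sp$precursor_mz <- 1000 + 2 * 14.0157
  f <- apply_ms2_evidence(f, list(sp))
  expect_identical(f$members$topology[f$members$id == "p14"], "linear")
  expect_match(f$warnings, "MS2 takes precedence", all = FALSE)
  f <- assign_designations(f)
  expect_identical(f$members$designation[f$members$id == "p14"], "C_L")
  expect_match(f$warnings, "no cyclic water partner", all = FALSE)
})
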