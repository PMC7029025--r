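test_that("ring opening adds exactly one water", {
  expect_equal(ring_open(0), 18.0105646, tolerance = 1e-6)
  expect_equal(ring_open(994.6701), 1012.6807, tolerance = 1e-4)
  expect_equal(ring_open(1036.7073), 1054.7179, tolerance = 1e-4)
})

test_that("the b/y table carries the acyl tail on b ions only", {
  sp <- lipopeptide_spec("LLLVDLL", 12, "linear")
  ft <- fragment_table(sp)
  expect_equal(nrow(ft), 12)  # 2 x (7 - 1)
  leu <- 6 * ORA$C + 11 * ORA$H + ORA$N + ORA$O
  tail12 <- 12 * ORA$C + 24 * ORA$H + 3 * ORA$O
  b2 <- 2 * leu + (tail12 - ORA$water) + ORA$proton
  y2 <- 2 * leu + ORA$water + ORA$proton
  expect_equal(ft$mz[ft$series == "b" & ft$index == 2], b2, tolerance = 1e-9)
  expect_equal(ft$mz[ft$series == "b" & ft$index == 2], 425.33738,
               tolerance = 1e-4)
  expect_equal(ft$mz[ft$series == "y" & ft$index == 2], y2, tolerance = 1e-9)
  expect_equal(ft$mz[ft$series == "y" & ft$index == 2], 245.18596,
               tolerance = 1e-4)
  # y ions are tail-independent
  ft15 <- fragment_table(lipopeptide_spec("LLLVDLL", 15, "linear"))
  expect_equal(ft15$mz[ft15$series == "y"], ft$mz[ft$series == "y"],
               tolerance = 1e-12)
  expect_error(fragment_table(lipopeptide_spec("L", 12, "linear")),
               "at least 2 residues")
})

test_that("cyclic fragment tables are the linear ones plus the ring-opened parent", {
  set.seed(51)
  for (i in 1:20) {
    sp <- random_spec()
    if (nchar(sp$sequence) < 2) next
    lin <- fragment_table(lipopeptide_spec(sp$sequence, sp$tail_carbons, "linear"))
    cyc <- fragment_table(lipopeptide_spec(sp$sequence, sp$tail_carbons, "cyclic"))
    expect_equal(cyc[cyc$series %in% c("b", "y"), c("series", "index", "mz")],
                 lin[, c("series", "index", "mz")], ignore_attr = TRUE)
    ring <- cyc[cyc$series == "ring_opened_parent", ]
    expect_equal(nrow(ring), 1)
    expect_equal(ring$mz,
                 spec_mz(lipopeptide_spec(sp$sequence, sp$tail_carbons, "linear")),
                 tolerance = 1e-9)
  }
})

test_that("b and y ions are complementary to the protonated linear mass", {
  set.seed(52)
  for (i in 1:100) {
    sp <- random_spec()
    if (nchar(sp$sequence) < 2) next
    lin <- lipopeptide_spec(sp$sequence, sp$tail_carbons, "linear")
    ft <- fragment_table(lin)
    n <- nchar(sp$sequence)
    target <- protonated_mz(assemble_neutral(lin)) + 1.00727646
    for (idx in seq_len(n - 1)) {
      b <- ft$mz[ft$series == "b" & ft$index == idx]
      y <- ft$mz[ft$series == "y" & ft$index == n - idx]
      expect_equal(b + y, target, tolerance = 1e-9)
    }
  }
  # hand-checked instance: b5 + y2 of the C12 heptapeptide
  ft <- fragment_table(lipopeptide_spec("LLLVDLL", 12, "linear"))
  expect_equal(ft$mz[ft$series == "b" & ft$index == 5] +
                 ft$mz[ft$series == "y" & ft$index == 2],
               997.70275, tolerance = 1e-4)
})

test_that("spectrum matching is greedy, capped and monotone in tolerance", {
  sp <- lipopeptide_spec("LLLVDLL", 12, "linear")
  ft <- fragment_table(sp)
  parent <- spec_mz(sp)

  exact <- data.frame(mz = ft$mz, intensity = 1)
  expect_equal(match_spectrum(parent, exact, sp)$coverage, 1.0)

  shifted <- data.frame(mz = ft$mz + 0.5, intensity = 1)
  expect_equal(match_spectrum(parent, shifted, sp, frag_tol = 0.2)$coverage, 0.0)

  half <- data.frame(mz = ft$mz[seq(1, 12, by = 2)], intensity = 1)
  expect_equal(match_spectrum(parent, half, sp)$coverage, 0.5)

  empty <- match_spectrum(parent, data.frame(mz = numeric(), intensity = numeric()), sp)
  expect_equal(empty$coverage, 0)
  expect_identical(empty$topology_call, "inconclusive")

  set.seed(53)
  jittered <- data.frame(mz = ft$mz + rnorm(12, 0, 0.05), intensity = 1)
  covs <- vapply(c(0.01, 0.05, 0.1, 0.2),
                 function(tol) match_spectrum(parent, jittered, sp,
                                              frag_tol = tol)$coverage, 0)
  expect_false(is.unsorted(covs))
  # every matched delta within tolerance
  m <- match_spectrum(parent, jittered, sp, frag_tol = 0.1)
  expect_true(all(abs(m$matched$delta) <= 0.1))
})

test_that("the +18 Da daughter ion identifies cyclic precursors", {
  # the published daughter (1012.79 for parent 994.67) sits 0.11 Da above
  # the exact +H2O value and must still classify cyclic at the default 0.2
  expect_identical(
    topology_test(994.67, data.frame(mz = 1012.79, intensity = 1)), "cyclic")
  sp <- lipopeptide_spec("LLLVDLL", 14, "linear")
  ft <- fragment_table(sp)
  expect_identical(
    topology_test(spec_mz(sp), data.frame(mz = ft$mz, intensity = 1)), "linear")
  expect_identical(
    topology_test(994.67, data.frame(mz = numeric(), intensity = numeric())),
    "inconclusive")
  expect_error(topology_test(994.67, NULL, daughter_tol = -1), "positive")
})

test_that("MS2 evidence takes precedence over MS1 in reconciliation", {
  expect_identical(reconcile_topology("cyclic", "cyclic")$topology, "cyclic")
  expect_identical(reconcile_topology("linear", "inconclusive")$topology, "linear")
  conflict <- reconcile_topology("cyclic", "linear")
  expect_identical(conflict$topology, "linear")
  expect_match(conflict$note, "conflict")
})
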