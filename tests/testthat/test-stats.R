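test_that("pool_counts sums counts and presence per cohort", {
  counts <- rbind(A = c(5, 5, 5, 5, 0, 0, 0, 0),
                  B = c(1, 0, 2, 0, 3, 0, 0, 4))
  colnames(counts) <- c(paste0("CN", 1:4), paste0("CR", 1:4))
  cm <- make_cm(counts)
  pools <- pool_counts(cm)
  expect_equal(pools$n_ref, c(20L, 3L))
  expect_equal(pools$n_cmp, c(0L, 7L))
  expect_equal(pools$present_cmp, c(0L, 2L))
  expect_equal(attr(pools, "N_ref"), 23)
  expect_equal(attr(pools, "N_cmp"), 7)

  # single-record matrix: totals are the record's own pooled counts
  one <- make_cm(counts[1, , drop = FALSE])
  p1 <- pool_counts(one)
  expect_equal(attr(p1, "N_ref"), p1$n_ref)
  expect_equal(attr(p1, "N_cmp"), p1$n_cmp)

  # 100-protein matrix against an independent summation oracle
  set.seed(31)
  big <- make_cm(matrix(rpois(800, 6), 100, 8))
  expect_equal(attr(pool_counts(big), "N_ref"),
               sum(big$counts[, 1:4]))
})

test_that("compute_rsc applies the pseudocount and sign convention", {
  # symmetric counts and totals give rsc exactly +1
  expect_equal(compute_rsc(10, 10, 100, 100)$rsc, 1)
  # comparison-unique protein, equal totals: hand arithmetic -22.25/1.25
  res <- compute_rsc(21, 0, 1000, 1000)
  expect_equal(res$raw_ratio, 1.25 / 22.25)
  expect_equal(res$rsc, -22.25 / 1.25, tolerance = 1e-12)
  expect_equal(res$rsc, -17.8, tolerance = 1e-3)
  # the calibrated-ratio worked example: CN 0, CR 21, r = 1.12 -> ~19.9
  expect_equal(compute_rsc(0, 21, 1.12, 1)$rsc, 19.9, tolerance = 0.05)
  expect_error(compute_rsc(1, 1, 0, 10))
})

test_that("rsc monotonicity, |rsc| >= 1 and group-swap antisymmetry hold", {
  set.seed(41)
  for (i in 1:200) {
    n_ref <- rpois(1, 20); n_cmp <- rpois(1, 20)
    N_ref <- n_ref + rpois(1, 2000) + 1; N_cmp <- n_cmp + rpois(1, 2000) + 1
    fwd <- compute_rsc(n_ref, n_cmp, N_ref, N_cmp)
    rev <- compute_rsc(n_cmp, n_ref, N_cmp, N_ref)
    expect_gte(abs(fwd$rsc), 1)
    expect_equal(rev$raw_ratio, 1 / fwd$raw_ratio, tolerance = 1e-12)
    if (abs(fwd$rsc) > 1)
      expect_equal(rev$rsc, -fwd$rsc, tolerance = 1e-9)
    if (fwd$raw_ratio >= 1) expect_equal(fwd$rsc, fwd$raw_ratio)
    else expect_equal(fwd$rsc, -1 / fwd$raw_ratio)
    # strictly increasing in n_cmp, decreasing in n_ref
    expect_gt(compute_rsc(n_ref, n_cmp + 1, N_ref, N_cmp)$raw_ratio,
              fwd$raw_ratio)
    expect_lt(compute_rsc(n_ref + 1, n_cmp, N_ref, N_cmp)$raw_ratio,
              fwd$raw_ratio)
    # Fisher p invariant under group swap
    expect_equal(fisher_count_test(n_ref, N_ref, n_cmp, N_cmp),
                 fisher_count_test(n_cmp, N_cmp, n_ref, N_ref),
                 tolerance = 1e-12)
  }
})

test_that("total-ratio calibration recovers the group scale", {
  # single printed row: r = 12.1 * 2.25 / 24.25
  r1 <- calibrate_total_ratio(1, 23, 12.1)
  expect_equal(as.numeric(r1), 12.1 * 2.25 / 24.25, tolerance = 1e-12)
  # noiseless rows generated from a known scale are recovered exactly,
  # including negative-inverse rows
  set.seed(51)
  r_star <- 1.37
  n_ref <- rpois(20, 10); n_cmp <- rpois(20, 10)
  rsc <- compute_rsc(n_ref, n_cmp, r_star, 1)$rsc
  r_hat <- calibrate_total_ratio(n_ref, n_cmp, rsc)
  expect_equal(as.numeric(r_hat), r_star, tolerance = 1e-12)
})

test_that("two-sided Fisher matches hand-enumerated and oracle values", {
  expect_equal(fisher_count_test(1, 10, 1, 10), 1)
  expect_equal(fisher_count_test(2, 2, 0, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_count_test(0, 5, 0, 7), 1)   # degenerate margin
  # spot-check against the independent enumeration oracle and fisher.test
  set.seed(61)
  for (i in 1:200) {
    Nr <- sample(1:12, 1); Nc <- sample(1:12, 1)
    a <- sample(0:Nr, 1); b <- sample(0:Nc, 1)
    p <- fisher_count_test(a, Nr, b, Nc)
    expect_equal(p, fisher_enum_oracle(a, Nr, Nc = Nc, b = b),
                 tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(
      matrix(c(a, Nr - a, b, Nc - b), 2, byrow = TRUE))$p.value,
      tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(71)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_naive_oracle(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p))
  }
})

test_that("selection applies both criteria strictly", {
  rec <- make_records(n_ref = 10, n_cmp = 30,
                      rsc = c(2.5, 1.9, 2.5, 2.01),
                      p = c(0.04, 0.04, 0.06, 0.049), selected = FALSE)
  out <- select_differential(rec)
  expect_identical(out$selected, c(TRUE, FALSE, FALSE, TRUE))
  # q-gated alternative
  rec$q_value <- c(0.2, 0.2, 0.2, 0.01)
  out <- select_differential(rec, selection_policy(use_adjusted = TRUE))
  expect_identical(out$selected, c(FALSE, FALSE, FALSE, TRUE))

  # recount oracle on 1,000 synthetic records
  set.seed(81)
  big <- make_records(n_ref = rpois(1000, 10) + 1,
                      n_cmp = rpois(1000, 10) + 1,
                      rsc = runif(1000, -6, 6),
                      p = runif(1000), selected = FALSE)
  big$rsc[abs(big$rsc) < 1] <- 1
  out <- select_differential(big)
  expect_equal(sum(out$selected),
               sum(big$p_value < 0.05 & abs(big$rsc) > 2))
})

test_that("categorization partitions selected records exhaustively", {
  common <- make_records(n_ref = c(4, 9), n_cmp = c(9, 4), rsc = c(2.2, -2.2))
  out <- categorize(common)
  expect_identical(out$category, c("common_enriched", "common_diminished"))
  summ <- partition_summary(out)
  expect_identical(unname(summ[c("unique_to_ref", "unique_to_cmp")]),
                   c(0L, 0L))

  # the reference-unique worked table: all n_cmp = 0
  tab <- reference_tables()
  t1 <- tab[tab$table == "unique_to_ref", ]
  rec <- make_records(n_ref = t1$n_ref, n_cmp = t1$n_cmp,
                      rsc = t1$rsc_printed)
  expect_true(all(categorize(rec)$category == "unique_to_ref"))

  # planted composition is reproduced and conserved
  planted <- rbind(
    make_records(n_ref = 5, n_cmp = 0, rsc = rep(-3, 88)),
    make_records(n_ref = 0, n_cmp = 5, rsc = rep(3, 67)),
    make_records(n_ref = 5, n_cmp = 15, rsc = rep(3, 115)),
    make_records(n_ref = 15, n_cmp = 5, rsc = rep(-3, 83)))
  planted$accession <- sprintf("U%04d", seq_len(nrow(planted)))
  summ <- partition_summary(categorize(planted))
  expect_identical(unname(summ), c(88L, 67L, 115L, 83L, 353L))
  expect_equal(sum(summ[1:4]), summ[["total"]])

  expect_error(categorize(make_records(0, 0, 1)), "zero pooled counts")
})

test_that("presence breakdown counts detection multiplicity", {
  # proteins present in (4,4,4,4,3,3,3,2,2,1) of 4 comparison samples
  pres <- c(4, 4, 4, 4, 3, 3, 3, 2, 2, 1)
  counts <- matrix(0L, 11, 8)
  counts[, 1:4] <- 1L
  for (i in seq_along(pres)) counts[i, 4 + seq_len(pres[i])] <- 2L
  # row 11 undetected in the comparison group
  cm <- make_cm(counts)
  bd <- presence_breakdown(cm, rownames(cm$counts), "CR")
  expect_equal(unname(bd$fractions), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(bd$n_detected, 10)
  expect_equal(bd$n_undetected, 1)

  all_in <- presence_breakdown(cm, rownames(cm$counts), "CN")
  expect_equal(unname(all_in$fractions[4]), 1)
  expect_error(presence_breakdown(cm, "nope", "CR"), "unknown accession")
})

test_that("differential_analysis assembles a coherent record set", {
  sim <- simulate_counts(synthetic_config(n_proteins = 120, seed = 91,
                                          n_contaminants = 0, n_decoys = 0,
                                          n_cdna_like = 0))
  diff <- quiet_diff(sim$matrix)
  expect_true(all(abs(diff$rsc) >= 1))
  expect_true(all(diff$q_value >= diff$p_value))
  expect_true(all(diff$p_value > 0 & diff$p_value <= 1))
  expect_equal(nrow(diff) + attr(diff, "n_dropped"),
               nrow(sim$matrix$counts))
  summ <- partition_summary(diff)
  expect_equal(sum(summ[1:4]), summ[["total"]])
  expect_equal(summ[["total"]], sum(diff$selected))
})
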