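# reference "ACGA": one CpG at position 2; frame columns 1..4
.tt_frame <- function(b1, b2) {
  ref <- make_ref("ACGA")
  make_frame(ref, "ACGA", r = paste0("-", b1, b2, "-"))
}

test_that("the calling truth table is exhaustive over aligned base pairs", {
  alphabet <- c("A", "C", "G", "T", "N", "-")
  for (b1 in alphabet) {
    for (b2 in alphabet) {
      got <- call_cpg(.tt_frame(b1, b2), "r", 2L)
      expected <- if (b2 != "G") "X" else if (b1 == "C") "M" else if (b1 == "T") "U" else "X"
      expect_equal(got, expected, info = paste0(b1, "/", b2))
    }
  }
})

test_that("calling requires the CpG guanine before looking 5'", {
  # mutated/unreadable pairs TA, TT, TN, CN carry no methylation information
  for (pair in list(c("T", "A"), c("T", "T"), c("T", "N"), c("C", "N"))) {
    expect_equal(call_cpg(.tt_frame(pair[1], pair[2]), "r", 2L), "X")
  }
})

test_that("a thymine insertion does not shift the call off the CpG", {
  # reference TTTCGA, read TTTTCGA: the extra T pushes the informative C into
  # an insertion column; the base 5' of the read's G is still a C
  ref <- make_ref("TTTCGA")
  aln <- make_frame(ref, "TTTC-GA", r = "TTTTCGA")
  expect_equal(call_cpg(aln, "r", 4L), "M")
  # and the unmethylated version still calls U
  aln_u <- make_frame(ref, "TTTC-GA", r = "TTTTTGA")
  expect_equal(call_cpg(aln_u, "r", 4L), "U")
})

test_that("a thymine deletion does not shift the call off the CpG", {
  ref <- make_ref("TTTCGA")
  aln <- make_frame(ref, "TTTCGA", r = "-TTCGA")
  expect_equal(call_cpg(aln, "r", 4L), "M")
})

test_that("calling a non-CpG position is an error", {
  expect_error(call_cpg(.tt_frame("C", "G"), "r", 1L), "not a CpG")
})

test_that("call_all covers clones x sites and handles missing coverage", {
  ref <- make_ref("ACGAACGA")        # CpGs at 2 and 6
  aln <- make_frame(ref, ref$converted,
                    full = "ACGAACGA",    # both methylated
                    half = "ACGA----")    # second site not covered
  calls <- call_all(aln)
  expect_equal(dim(calls$calls), c(2L, 2L))
  expect_equal(unname(calls$calls["full", ]), c("M", "M"))
  expect_equal(unname(calls$calls["half", ]), c("M", "X"))

  empty <- call_all(aln, character(0))
  expect_equal(nrow(empty$calls), 0L)
  expect_equal(empty$sites, c(2L, 6L))
})

test_that("per-site statistics are suppressed below five informative reads", {
  ref <- make_ref("ACGA")
  rows <- c(r1 = "ACGA", r2 = "ACGA", r3 = "ACGA", r4 = "ATGA", r5 = "ATGA")
  calls <- call_all(make_frame(ref, "ACGA", rows))
  s <- summarize_methylation(calls)
  # 3 M / 2 U over 5 informative reads -> reported
  expect_equal(s$per_site$n_informative, 5L)
  expect_equal(s$per_site$pct_methylated, 60)

  # with only 4 informative reads the site is suppressed
  rows4 <- c(r1 = "ACGA", r2 = "ACGA", r3 = "ACGA", r4 = "ATGA", r5 = "-NGA")
  s4 <- summarize_methylation(call_all(make_frame(ref, "ACGA", rows4)))
  expect_equal(s4$per_site$n_informative, 4L)
  expect_true(is.na(s4$per_site$pct_methylated))
  # the overall percentage still pools whatever is informative
  expect_equal(s4$overall_pct, 75)
})

test_that("overall and informative percentages follow their definitions", {
  ref <- make_ref("ACGAACGA")
  aln <- make_frame(ref, ref$converted,
                    a = "ACGAACGA", b = "ACGAACGA", c = "ACGAACGA")
  s <- summarize_methylation(call_all(aln))
  expect_equal(s$overall_pct, 100)
  expect_equal(s$informative_pct, 100)

  mixed <- make_frame(ref, ref$converted, a = "ACGAANGA", b = "ATGAACGA")
  sm <- summarize_methylation(call_all(mixed))
  expect_equal(sm$informative_pct, 100 * 3 / 4)
  expect_equal(sm$overall_pct, 100 * 2 / 3)
})

test_that("summaries are invariant under clone permutation", {
  cfg <- sim_config(seed = 8, n_clones = 12, ref_length = 160, n_cpg = 6)
  ref <- make_ref(simulate_reference(cfg)$sequence)
  res <- run_unique(ref, simulate_reads(ref, cfg)$reads, sort = FALSE)
  calls <- res$calls
  perm <- calls
  set.seed(1)
  ord <- sample(length(perm$clone_ids))
  perm$clone_ids <- perm$clone_ids[ord]
  perm$calls <- perm$calls[ord, , drop = FALSE]
  a <- summarize_methylation(calls)
  b <- summarize_methylation(perm)
  expect_equal(a$overall_pct, b$overall_pct)
  expect_equal(a$per_site, b$per_site)
})

test_that("sorting by methylation is descending, stable, and optional", {
  ref <- make_ref("ACGAACGA")
  aln <- make_frame(ref, ref$converted,
                    lo = "ATGAATGA",   # 0%
                    hi = "ACGAACGA",   # 100%
                    m1 = "ACGAATGA",   # 50%
                    m2 = "ATGAACGA")   # 50%, after m1 in input
  calls <- call_all(aln)
  sorted <- sort_by_methylation(calls)
  expect_equal(sorted$clone_ids, c("hi", "m1", "m2", "lo"))
  expect_equal(calls$clone_ids, c("lo", "hi", "m1", "m2"))  # opt-out keeps input order
})

test_that("simulated per-site methylation is recovered by the overall percentage", {
  cfg <- sim_config(seed = 23, n_clones = 50, n_cpg = 20, per_site_p = 0.3,
                    conv_failure = 0)
  ref <- make_ref(simulate_reference(cfg)$sequence)
  sim <- simulate_reads(ref, cfg)
  res <- run_unique(ref, sim$reads, filter = filter_config("unique", clonal_mode = "off"),
                    sort = FALSE)
  se <- sqrt(0.3 * 0.7 / (50 * 20))
  expect_lt(abs(res$summary$overall_pct / 100 - 0.3), 3 * se)
  # and the planted truth is recovered exactly in the absence of noise
  truth <- ifelse(sim$truth$meth == 1, "M", "U")
  expect_equal(unname(res$calls_all$calls[rownames(truth), ]), unname(truth))
})
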