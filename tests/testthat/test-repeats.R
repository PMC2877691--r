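test_that("methylated CpGs are extracted at consensus and non-consensus positions", {
  # consensus AACGTTGA: one consensus CpG (pos 3); converted = original
  ref <- make_ref("AACGTTGA")
  aln <- make_frame(ref, ref$converted,
                    cons = "AACGTTGA",   # CG at the consensus CpG
                    novel = "AATGCGGA",  # TG at consensus, CG where consensus has TG
                    none = "AATGTTGA")   # no C at all
  r1 <- extract_methylated_cpgs(aln, "cons")
  expect_equal(r1$meth_count, 1L)
  expect_true(r1$meth_positions$is_consensus_cpg)
  expect_equal(r1$meth_positions$ref_position, 3L)

  r2 <- extract_methylated_cpgs(aln, "novel")
  expect_equal(r2$meth_count, 1L)
  expect_false(r2$meth_positions$is_consensus_cpg)
  expect_equal(r2$meth_positions$ref_position, 5L)

  r3 <- extract_methylated_cpgs(aln, "none")
  expect_equal(r3$meth_count, 0L)
  expect_equal(nrow(r3$meth_positions), 0L)
})

test_that("an inserted CpG absent from the consensus is still counted", {
  ref <- make_ref("AATTAA")
  aln <- make_frame(ref, "AAT--TAA", novel = "AATCGTAA")
  r <- extract_methylated_cpgs(aln, "novel")
  expect_equal(r$meth_count, 1L)
  expect_false(r$meth_positions$is_consensus_cpg)
  expect_true(is.na(r$meth_positions$ref_position))
})

test_that("a CG split by an alignment gap still counts (read-space adjacency)", {
  ref <- make_ref("AATTGA")
  # read C at pos 3, deletion at 4, G at 5: read-space neighbours C,G
  aln <- make_frame(ref, "AATTGA", r = "AAC-GA")
  r <- extract_methylated_cpgs(aln, "r")
  expect_equal(r$meth_count, 1L)
})

test_that("repeat summaries tally counts, sort stably, and average rates", {
  mk <- function(id, count, span) {
    structure(list(read_id = id,
                   meth_positions = tibble::tibble(column = seq_len(count),
                                                   ref_position = seq_len(count),
                                                   is_consensus_cpg = rep(TRUE, count)),
                   meth_count = count, aligned_span = span,
                   per100bp = 100 * count / span),
              class = "bs_repeat_read")
  }
  s <- repeat_summaries(list(mk("a", 3L, 100L), mk("b", 5L, 100L), mk("c", 3L, 100L)))
  expect_equal(s$per_read$read_id, c("b", "a", "c"))
  expect_equal(s$histogram$meth_count, c(3L, 5L))
  expect_equal(s$histogram$n_reads, c(2L, 1L))
  expect_equal(sum(s$histogram$n_reads), 3L)

  one <- repeat_summaries(list(mk("a", 4L, 200L)))
  expect_equal(one$per_read$per100bp, 2)

  zero <- repeat_summaries(list(mk("a", 0L, 100L), mk("b", 0L, 100L)))
  expect_equal(zero$histogram$meth_count, 0L)
  expect_equal(zero$mean_per100bp, 0)

  expect_error(repeat_summaries(list()), "no repeat read")
})

test_that("consensus dinucleotide tallies classify CG/TG/CA/TA and N as other", {
  ref <- make_ref("AACGTACGTA")   # consensus CpGs at 3 and 7
  aln <- make_frame(ref, ref$converted,
                    r1 = "AACGTACGTA",  # CG, CG
                    r2 = "AATGTACATA",  # TG, CA
                    r3 = "AATATACNTA")  # TA, N -> other
  t <- tally_consensus_dinucleotides(aln)
  expect_equal(t$n_CG, 2L)
  expect_equal(t$n_TG, 1L)
  expect_equal(t$n_CA, 1L)
  expect_equal(t$n_TA, 1L)
  expect_equal(t$n_other, 1L)
})

test_that("the mutation-corrected estimator matches its closed form", {
  mk <- function(cg, tg, ca, ta = 0L) {
    structure(list(n_CG = cg, n_TG = tg, n_CA = ca, n_TA = ta, n_other = 0L),
              class = "bs_dinuc_tally")
  }
  # no CA mutations observed: reduces to the naive estimate
  expect_equal(yang_overall_methylation(mk(50L, 50L, 0L)), 50)
  expect_equal(yang_overall_methylation(mk(50L, 50L, 0L)),
               naive_overall_methylation(mk(50L, 50L, 0L)))
  # closed form: 100 * CG / (CG + TG - CA)
  expect_equal(yang_overall_methylation(mk(80L, 20L, 5L)), 100 * 80 / 95)
  # over-correction clamps at zero unmethylated, with a warning
  expect_warning(v <- yang_overall_methylation(mk(10L, 2L, 5L)), "clamp")
  expect_equal(v, 100)
  # no informative observations is an error
  expect_error(yang_overall_methylation(mk(0L, 0L, 9L)), "no informative")
  # optional TA-aware correction
  expect_equal(yang_overall_methylation(mk(80L, 20L, 5L, 5L), use_ta = TRUE),
               100 * 80 / 90)
})

test_that("counts are invariant to read order and consensus flags partition hits", {
  cfg <- sim_config(seed = 19, n_clones = 12, ref_length = 200, n_cpg = 8,
                    per_site_p = 0.7)
  ref <- make_ref(simulate_reference(cfg)$sequence)
  sim <- simulate_reads(ref, cfg)
  res1 <- run_repeat(ref, sim$reads)
  res2 <- run_repeat(ref, sim$reads[rev(seq_len(12)), ])
  t1 <- res1$tally
  t2 <- res2$tally
  expect_equal(t1[c("n_CG", "n_TG", "n_CA", "n_TA", "n_other")],
               t2[c("n_CG", "n_TG", "n_CA", "n_TA", "n_other")])
  for (r in res1$repeat_reads) {
    expect_equal(sum(r$meth_positions$is_consensus_cpg) +
                   sum(!r$meth_positions$is_consensus_cpg),
                 r$meth_count)
  }
})

test_that("the corrected estimator recovers planted methylation where the naive one is biased", {
  p <- 0.9
  m <- 0.05
  cfg <- sim_config(seed = 29, n_clones = 50, n_cpg = 20, ref_length = 400,
                    per_site_p = p, conv_failure = 0.01, mutation_rate = m)
  ref <- make_ref(simulate_reference(cfg)$sequence)
  sim <- simulate_reads(ref, cfg)
  res <- run_repeat(ref, sim$reads)
  se <- sqrt(p * (1 - p) / (50 * 20))
  expect_lt(abs(res$yang_pct / 100 - p), 3 * se)
  # naive estimate is biased low by roughly the strand mutation rate
  expect_lt(res$naive_pct, res$yang_pct)
  expect_gt(p - res$naive_pct / 100, 3 * se)
})
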