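# reference with 2 CpGs (pos 2, 6) and 2 non-CpG cytosines (pos 9, 11):
# original ACGAACGACACA -> converted ACGAACGATATA
.clonal_ref <- function() make_ref("ACGAACGACACA")

.pattern_of <- function(rows) {
  ref <- .clonal_ref()
  aln <- make_frame(ref, ref$converted, rows)
  calls <- call_all(aln)
  cytosine_patterns(aln, calls)
}

test_that("cytosine patterns capture calls, conversion status and artifacts", {
  ref <- .clonal_ref()
  aln <- make_frame(ref, ref$converted,
                    meth_conv = "ACGAACGATATA",  # all M, fully converted
                    artifact = "ACGAACGACATA",   # unconverted C at position 9
                    with_n = "ACGAANGATATA")     # N at the second CpG
  calls <- call_all(aln)
  p1 <- cytosine_pattern(aln, "meth_conv", calls)
  expect_equal(p1$positions, c(2L, 6L, 9L, 11L))
  expect_equal(p1$symbols, c("M", "M", "t", "t"))
  expect_false(any(p1$mask))

  p2 <- cytosine_pattern(aln, "artifact", calls)
  expect_equal(p2$symbols, c("M", "M", "C", "t"))

  p3 <- cytosine_pattern(aln, "with_n", calls)
  expect_equal(p3$symbols[2], "X")
  expect_true(p3$mask[2])
})

test_that("pattern matching wildcards N positions and is symmetric", {
  pats <- .pattern_of(c(a = "ACGAACGATATA", b = "ACGAACGATATA",
                        n = "ACGAANGATATA", diff = "ATGAACGATATA"))
  expect_true(patterns_match(pats[[1]], pats[[2]]))
  # N at a cytosine is ignored: a and n still match
  expect_true(patterns_match(pats[[1]], pats[[3]]))
  expect_true(patterns_match(pats[[3]], pats[[1]]))
  # a real CpG difference breaks the match
  expect_false(patterns_match(pats[[1]], pats[[4]]))
  q <- pats[[1]]
  q$positions <- q$positions[-1]
  q$symbols <- q$symbols[-1]
  q$mask <- q$mask[-1]
  expect_error(patterns_match(pats[[1]], q), "position sets")
})

test_that("identical patterns without artifacts are kept in suggested mode, collapsed in strict", {
  # ten fully methylated + ten fully unmethylated identical clones
  rows <- c(setNames(rep("ACGAACGATATA", 10), paste0("m", 1:10)),
            setNames(rep("ATGAATGATATA", 10), paste0("u", 1:10)))
  pats <- .pattern_of(rows)
  sugg <- classify_clonal(pats, "suggested")
  expect_equal(sum(sugg$kept), 20L)
  expect_setequal(unique(sugg$reason[sugg$kept]),
                  c("kept_representative", "kept_cpg_only_match"))
  strict <- classify_clonal(pats, "strict")
  expect_equal(sum(strict$kept), 2L)
  expect_equal(strict$read_id[strict$kept], c("m1", "u1"))  # first of each group
  off <- classify_clonal(pats, "off")
  expect_true(all(off$kept))
})

test_that("a shared conversion artifact marks clones for removal in both modes", {
  rows <- c(a = "ACGAACGACATA", b = "ACGAACGACATA", c = "ACGAACGACATA")
  for (mode in c("suggested", "strict")) {
    dec <- classify_clonal(.pattern_of(rows), mode)
    expect_equal(sum(dec$kept), 1L)
    expect_equal(dec$read_id[dec$kept], "a")
    expect_equal(dec$reason[!dec$kept], rep("removed_clonal", 2))
  }
})

test_that("N-wildcarding composes with the shared-artifact rule", {
  # identical except an N at one cytosine; both carry the artifact at pos 9
  rows <- c(a = "ACGAACGACATA", b = "ACGAACGACANA")
  dec <- classify_clonal(.pattern_of(rows), "suggested")
  expect_equal(sum(dec$kept), 1L)
  expect_equal(dec$reason, c("kept_representative", "removed_clonal"))
})

test_that("strict removals contain suggested removals on random inputs", {
  cfg <- sim_config(seed = 31, n_clones = 25, ref_length = 200, n_cpg = 6,
                    per_site_p = 0.5, conv_failure = 0.05, clonal_fraction = 0.4)
  ref <- make_ref(simulate_reference(cfg)$sequence)
  sim <- simulate_reads(ref, cfg)
  oriented <- lapply(seq_len(25), function(i) {
    orient_and_trim(sim$reads$read_id[i], sim$reads$sequence[i], ref)
  })
  aln <- build_alignment(oriented, ref, "stitched")
  pats <- cytosine_patterns(aln, call_all(aln))
  removed <- function(mode) {
    d <- classify_clonal(pats, mode)
    d$read_id[!d$kept]
  }
  expect_true(all(removed("suggested") %in% removed("strict")))
  expect_length(removed("off"), 0L)
})

test_that("clonal classification is idempotent on the kept set", {
  cfg <- sim_config(seed = 37, n_clones = 20, ref_length = 200, n_cpg = 6,
                    per_site_p = 0.5, conv_failure = 0.05, clonal_fraction = 0.5)
  ref <- make_ref(simulate_reference(cfg)$sequence)
  sim <- simulate_reads(ref, cfg)
  oriented <- lapply(seq_len(20), function(i) {
    orient_and_trim(sim$reads$read_id[i], sim$reads$sequence[i], ref)
  })
  aln <- build_alignment(oriented, ref, "stitched")
  pats <- cytosine_patterns(aln, call_all(aln))
  names(pats) <- vapply(pats, `[[`, character(1), "read_id")
  for (mode in c("suggested", "strict")) {
    d1 <- classify_clonal(pats, mode)
    kept <- d1$read_id[d1$kept]
    d2 <- classify_clonal(pats[kept], mode)
    expect_true(all(d2$kept))
  }
})

test_that("suggested mode removes exactly the planted duplicates that share an artifact", {
  cfg <- sim_config(seed = 42, n_clones = 30, ref_length = 300, n_cpg = 10,
                    per_site_p = 0.5, conv_failure = 0.05, clonal_fraction = 0.4)
  ref <- make_ref(simulate_reference(cfg)$sequence)
  sim <- simulate_reads(ref, cfg)
  res <- run_unique(ref, sim$reads, sort = FALSE)
  passed <- res$quality$read_id[res$quality$passed]
  expected_removed <- expected_clonal_removals(sim$truth, passed)
  got_removed <- res$clonal$read_id[!res$clonal$kept]
  expect_gt(length(expected_removed), 0L)
  expect_setequal(got_removed, expected_removed)
})
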