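#' Simulation configuration for synthetic bisulfite clone datasets
#'
#' Defaults emulate a typical subcloned bisulfite-PCR experiment: a 400 bp
#' amplicon with 20 CpG sites, 50 sequenced clones, per-site methylation
#' probability 0.3, and a 2% bisulfite conversion failure rate (98%
#' conversion). Noise channels are off by default and switched on per
#' scenario: sequencing substitutions, unresolved bases (N), thymine
#' insertion/deletion artifacts at T-homopolymers, clonal PCR duplication,
#' cloning-vector flanks, random read orientation, and (for repeat-mode
#' datasets) per-strand CG-to-TG mutation at consensus CpG sites.
#'
#' @param seed Integer seed driving all randomness.
#' @param ref_length Reference length in bp.
#' @param n_cpg Number of CpG sites to plant.
#' @param n_clones Number of clones (reads).
#' @param per_site_p Methylation probability per CpG site; scalar or vector
#'   of length `n_cpg`.
#' @param conv_failure Probability that a non-CpG cytosine escapes
#'   conversion (conversion artifact).
#' @param seq_error Per-base substitution probability.
#' @param n_rate Per-base probability of an unresolved (N) basecall.
#' @param tstretch_indel Per-T-homopolymer (length >= 4) probability of a
#'   one-T insertion or deletion.
#' @param clonal_fraction Probability that a clone is a PCR duplicate of an
#'   earlier clone's converted molecule.
#' @param vector_flank Length (bp) of random vector sequence appended at
#'   each read end.
#' @param revcomp_fraction Probability a read is reported reverse-
#'   complemented.
#' @param mutation_rate Per-strand, per-consensus-CpG CG-to-TG mutation
#'   probability (repeat-mode datasets).
#' @return A list of class `bs_sim_config`.
#' @export
sim_config <- function(seed = 1L, ref_length = 400L, n_cpg = 20L, n_clones = 50L,
                       per_site_p = 0.3, conv_failure = 0.02, seq_error = 0,
                       n_rate = 0, tstretch_indel = 0, clonal_fraction = 0,
                       vector_flank = 0L, revcomp_fraction = 0.5,
                       mutation_rate = 0) {
  probs <- c(per_site_p, conv_failure, seq_error, n_rate, tstretch_indel,
             clonal_fraction, revcomp_fraction, mutation_rate)
  stopifnot(all(probs >= 0 & probs <= 1), n_cpg >= 1, n_clones >= 1)
  if (ref_length < 4L * n_cpg) {
    stop("ref_length must be at least 4 * n_cpg", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), ref_length = as.integer(ref_length),
         n_cpg = as.integer(n_cpg), n_clones = as.integer(n_clones),
         per_site_p = per_site_p, conv_failure = conv_failure,
         seq_error = seq_error, n_rate = n_rate,
         tstretch_indel = tstretch_indel, clonal_fraction = clonal_fraction,
         vector_flank = as.integer(vector_flank),
         revcomp_fraction = revcomp_fraction, mutation_rate = mutation_rate),
    class = "bs_sim_config"
  )
}

#' Simulate a reference (or consensus) sequence
#'
#' Generates a random sequence of the requested length containing exactly
#' `n_cpg` CpG dinucleotides; when `tstretch_indel > 0` a T-homopolymer of
#' length >= 4 is guaranteed to be present. Deterministic given the seed.
#'
#' @param cfg A [sim_config()].
#' @return A list `(id, sequence)` suitable for [convert_reference()].
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "bs_sim_config"))
  set.seed(cfg$seed)
  L <- cfg$ref_length
  for (attempt in 1:50) {
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # scrub accidental CpGs (only planted ones are wanted)
    cg <- which(chars[-L] == "C" & chars[-1] == "G")
    while (length(cg) > 0) {
      chars[cg + 1L] <- sample(c("A", "T"), length(cg), replace = TRUE)
      cg <- which(chars[-L] == "C" & chars[-1] == "G")
    }
    forbidden <- integer(0)
    if (cfg$tstretch_indel > 0) {
      s <- sample(seq(2L, L - 5L), 1L)
      chars[s:(s + 3L)] <- "T"
      forbidden <- (s - 1L):(s + 4L)
    }
    # plant CpGs at spaced positions, keeping clear of the T-stretch
    cand <- setdiff(seq(2L, L - 2L), forbidden)
    sites <- integer(0)
    cand <- sample(cand)
    for (p in cand) {
      if (length(sites) == cfg$n_cpg) break
      if (all(abs(sites - p) >= 3L)) sites <- c(sites, p)
    }
    if (length(sites) < cfg$n_cpg) next
    sites <- sort(sites)
    chars[sites] <- "C"
    chars[sites + 1L] <- "G"
    seq <- paste(chars, collapse = "")
    n_found <- length(gregexpr("CG", seq, fixed = TRUE)[[1]])
    if (n_found == cfg$n_cpg) {
      return(list(id = sprintf("sim_ref_seed%d", cfg$seed), sequence = seq))
    }
  }
  stop("could not satisfy reference constraints; relax n_cpg or ref_length",
       call. = FALSE)
}

# apply one-T insertions/deletions at T-homopolymers >= 4
.apply_t_indels <- function(chars, prob) {
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values == "T" & r$lengths >= 4L)
  if (length(runs) == 0L) return(chars)
  hit <- runs[stats::runif(length(runs)) < prob]
  for (k in rev(hit)) {  # right-to-left keeps indices valid
    if (stats::runif(1) < 0.5) {
      chars <- append(chars, "T", after = starts[k])
    } else {
      chars <- chars[-starts[k]]
    }
  }
  chars
}

#' Simulate bisulfite-converted clone reads with ground truth
#'
#' Each clone draws per-site methylation states, then the bisulfite rules are
#' applied to the reference: methylated CpG cytosines stay C, unmethylated
#' ones read T, and non-CpG cytosines convert to T except for conversion
#' failures (rate `conv_failure`), which remain C and are recorded as planted
#' artifacts. Repeat-mode mutations (rate `mutation_rate`, per strand) turn
#' the CpG cytosine reading into T (sequenced-strand CG-to-TG) or the guanine
#' into A (opposite-strand mutation, surfacing as CA/TA). Clonal duplicates
#' copy an earlier clone's converted molecule (methylation, artifacts and
#' mutations included) before per-read noise: T-indels at T-homopolymers,
#' substitution errors, N basecalls, vector flanks, and random orientation.
#'
#' @param ref A `bs_reference` built from [simulate_reference()] output (or
#'   any reference).
#' @param cfg A [sim_config()].
#' @return A list of class `bs_sim`: `reads` (tibble `read_id`, `sequence`,
#'   `source`) and `truth`, a list with `meth` (clones x sites 0/1 matrix,
#'   dimnames read ids x site positions), `duplicate_of` (named character,
#'   `NA` for originals), `artifact_pos` (named list of reference positions
#'   of planted conversion artifacts), `seq_strand_mut` / `opp_strand_mut`
#'   (clones x sites 0/1 matrices), `orientation` (named character).
#' @export
simulate_reads <- function(ref, cfg) {
  stopifnot(inherits(ref, "bs_reference"), inherits(cfg, "bs_sim_config"))
  set.seed(cfg$seed + 1L)
  n_cpg <- length(ref$cpg_pos)
  p_site <- rep_len(cfg$per_site_p, n_cpg)
  ids <- sprintf("clone_%03d", seq_len(cfg$n_clones))
  ref_chars <- strsplit(ref$original, "", fixed = TRUE)[[1]]

  meth <- matrix(0L, cfg$n_clones, n_cpg, dimnames = list(ids, ref$cpg_pos))
  smut <- matrix(0L, cfg$n_clones, n_cpg, dimnames = list(ids, ref$cpg_pos))
  omut <- matrix(0L, cfg$n_clones, n_cpg, dimnames = list(ids, ref$cpg_pos))
  dup_of <- stats::setNames(rep(NA_character_, cfg$n_clones), ids)
  artifacts <- stats::setNames(vector("list", cfg$n_clones), ids)
  orientation <- stats::setNames(rep("forward", cfg$n_clones), ids)
  molecules <- vector("list", cfg$n_clones)

  for (j in seq_len(cfg$n_clones)) {
    if (j > 1L && stats::runif(1) < cfg$clonal_fraction) {
      tmpl <- sample.int(j - 1L, 1L)
      molecules[[j]] <- molecules[[tmpl]]
      meth[j, ] <- meth[tmpl, ]
      smut[j, ] <- smut[tmpl, ]
      omut[j, ] <- omut[tmpl, ]
      artifacts[[j]] <- artifacts[[tmpl]]
      dup_of[j] <- ids[tmpl]
    } else {
      m <- stats::rbinom(n_cpg, 1L, p_site)
      sm <- stats::rbinom(n_cpg, 1L, cfg$mutation_rate)
      om <- stats::rbinom(n_cpg, 1L, cfg$mutation_rate)
      chars <- ref_chars
      chars[ref$cpg_pos] <- ifelse(sm == 1L, "T", ifelse(m == 1L, "C", "T"))
      chars[ref$cpg_pos + 1L] <- ifelse(om == 1L, "A", "G")
      art <- ref$noncpg_c_pos[stats::runif(length(ref$noncpg_c_pos)) < cfg$conv_failure]
      chars[ref$noncpg_c_pos] <- "T"
      chars[art] <- "C"
      meth[j, ] <- m
      smut[j, ] <- sm
      omut[j, ] <- om
      artifacts[[j]] <- art
      molecules[[j]] <- chars
    }
  }

  seqs <- character(cfg$n_clones)
  for (j in seq_len(cfg$n_clones)) {
    chars <- molecules[[j]]
    if (cfg$tstretch_indel > 0) chars <- .apply_t_indels(chars, cfg$tstretch_indel)
    if (cfg$seq_error > 0) {
      hit <- which(stats::runif(length(chars)) < cfg$seq_error)
      for (k in hit) {
        chars[k] <- sample(setdiff(c("A", "C", "G", "T"), chars[k]), 1L)
      }
    }
    if (cfg$n_rate > 0) {
      chars[stats::runif(length(chars)) < cfg$n_rate] <- "N"
    }
    s <- paste(chars, collapse = "")
    if (cfg$vector_flank > 0L) {
      fl <- function() paste(sample(c("A", "C", "G", "T"), cfg$vector_flank,
                                    replace = TRUE), collapse = "")
      s <- paste0(fl(), s, fl())
    }
    if (stats::runif(1) < cfg$revcomp_fraction) {
      s <- revcomp(s)
      orientation[j] <- "reverse"
    }
    seqs[j] <- s
  }

  structure(
    list(
      reads = tibble::tibble(read_id = ids, sequence = seqs, source = "fasta"),
      truth = list(meth = meth, duplicate_of = dup_of, artifact_pos = artifacts,
                   seq_strand_mut = smut, opp_strand_mut = omut,
                   orientation = orientation)
    ),
    class = "bs_sim"
  )
}
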