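# Pileups, SNV calling, coding-effect classification, density, sweeps.

mk_aln <- function(read_id, orf_id, pos, cigar, seq) {
  data.table::data.table(read_id = read_id, flag = 0L, orf_id = orf_id,
                         pos = pos, mapq = 60L, cigar = cigar, seq = seq,
                         nm = 0L, is_primary = TRUE)
}

test_that("pileup honors CIGAR semantics", {
  refs <- c(o1 = "ACGTACGTACGTACGTACGT")
  pu <- build_pileup(mk_aln("r1", "o1", 0L, "10M", "ACGTACGTAC"), refs)
  expect_equal(nrow(pu), 10L)
  expect_equal(pu$depth, rep(1L, 10))
  expect_equal(pu$pos, 1:10)
  ref_counts <- mapply(function(p, b) pu[[b]][pu$pos == p],
                       1:10, strsplit("ACGTACGTAC", "")[[1]])
  expect_equal(unname(ref_counts), rep(1L, 10))

  # 5M2D5M: deletion sites 6-7 get no base
  pu <- build_pileup(mk_aln("r2", "o1", 0L, "5M2D5M", "ACGTAGTACG"), refs)
  expect_setequal(pu$pos, c(1:5, 8:12))

  # insertion consumes read only: 3M2I3M covers reference sites 1-6
  pu <- build_pileup(mk_aln("r3", "o1", 0L, "3M2I3M", "ACGTTTAC"), refs)
  expect_equal(pu$pos, 1:6)
  expect_equal(pu$T[pu$pos == 4], 1L)  # read base after the insertion

  expect_error(build_pileup(mk_aln("r4", "o1", 15L, "10M", "ACGTACGTAC"),
                            refs), "r4")
})

test_that("pileup alt fraction matches a planted frequency", {
  cfg <- sim_config(seed = 41, n_taxon_groups = 1, orfs_per_group = 5,
                    samples = four_sample_sheet(lib = 15000L),
                    subpop_divergence = 0, error_rate = 0,
                    snv_spec = list(planted_snv("g01_orf0003", 99,
                                                freq_mid = 0.5,
                                                freq_late = 0.5)))
  b <- simulate_bundle(cfg)
  pu <- build_pileup(b$alignments$MB1, b$references)
  site <- pu[pu$orf_id == "g01_orf0003" & pu$pos == 99]
  sv <- b$truth$snvs[[1]]
  alt <- site[[sv$alt_allele]]
  ci <- stats::qbinom(c(0.005, 0.995), site$depth, 0.5)
  expect_gte(alt, ci[1])
  expect_lte(alt, ci[2])
  expect_equal(site$A + site$C + site$G + site$T, site$depth)
})

test_that("call thresholds behave as documented", {
  refs <- c(o1 = paste0("ATG", strrep("GAT", 9), "TAA"))
  mk_pileup <- function(depth, alt) {
    data.table::data.table(orf_id = "o1", pos = 5L, A = alt,
                           C = 0L, G = 0L, T = 0L, depth = depth)
  }
  # reference base at pos 5 is A? pos5 of ATGGATGAT... = "A"; use pos 6 (T)
  pu <- data.table::data.table(orf_id = "o1", pos = 6L, A = 6L, C = 0L,
                               G = 0L, T = 14L, depth = 20L)
  calls <- call_snvs(pu, refs)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$af, 0.3)
  expect_equal(calls$ref, "T")
  expect_equal(calls$alt, "A")

  low_depth <- data.table::data.table(orf_id = "o1", pos = 6L, A = 2L,
                                      C = 0L, G = 0L, T = 1L, depth = 3L)
  expect_equal(nrow(call_snvs(low_depth, refs)), 0L)

  low_alt <- data.table::data.table(orf_id = "o1", pos = 6L, A = 1L,
                                    C = 0L, G = 0L, T = 19L, depth = 20L)
  expect_equal(nrow(call_snvs(low_alt, refs)), 0L)

  multi <- data.table::data.table(orf_id = "o1", pos = 6L, A = 5L, C = 5L,
                                  G = 0L, T = 10L, depth = 20L)
  expect_equal(nrow(call_snvs(multi, refs)), 2L)
})

test_that("classify_effect: examples and the 576-case brute-force oracle", {
  refs <- c(o1 = "ATGGATTGGTAA")
  # GAT -> GAC at codon position 3: synonymous (Asp)
  expect_equal(classify_effect("o1", 6L, "C", refs)$effect, "SYN")
  # GAT -> TAT at codon position 1: Asp -> Tyr
  expect_equal(classify_effect("o1", 4L, "T", refs)$effect, "NONSYN")
  # TGG -> TGA: stop gain is nonsynonymous
  expect_equal(classify_effect("o1", 9L, "A", refs)$effect, "NONSYN")

  # full enumeration: every codon x every single-base substitution
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  for (codon in codons) {
    for (p in 1:3) {
      for (alt in setdiff(bases, substr(codon, p, p))) {
        got <- classify_effect("x", p, alt,
                               stats::setNames(codon, "x"))$effect
        mutated <- codon
        substr(mutated, p, p) <- alt
        want <- if (Biostrings::GENETIC_CODE[[codon]] ==
                      Biostrings::GENETIC_CODE[[mutated]]) "SYN" else
                        "NONSYN"
        expect_identical(got, want)
      }
    }
  }

  # incomplete trailing codon -> NA
  expect_true(is.na(classify_effect("y", 4L, "A",
                                    c(y = "ATGCC"))$effect))
})

test_that("clean data yields zero calls; error-driven false calls respect
           the binomial bound", {
  clean <- simulate_bundle(sim_config(
    seed = 43, n_taxon_groups = 1, orfs_per_group = 20,
    samples = four_sample_sheet(lib = 20000L), subpop_divergence = 0,
    error_rate = 0))
  pu <- build_pileup(clean$alignments$MB1, clean$references)
  expect_equal(nrow(call_snvs(pu, clean$references)), 0L)

  eps <- 0.001
  noisy <- simulate_bundle(sim_config(
    seed = 44, n_taxon_groups = 1, orfs_per_group = 20,
    samples = four_sample_sheet(lib = 20000L), subpop_divergence = 0,
    error_rate = eps))
  pu <- build_pileup(noisy$alignments$MB1, noisy$references)
  calls <- call_snvs(pu, noisy$references, sample = "MB1")
  # analytic bound: per site, P(alt calls) <= 3 * P(Binom(d, eps/3) >= max(
  # min_alt, ceil(min_af * d))); sum over covered sites
  thresh <- pmax(2L, ceiling(0.05 * pu$depth))
  bound <- sum(3 * stats::pbinom(thresh - 1L, pu$depth, eps / 3,
                                 lower.tail = FALSE))
  expect_lte(nrow(calls), bound + 3 * sqrt(bound) + 3)
})

test_that("snv_density uses eligible-ORF denominators and flags missing", {
  calls <- data.frame(orf_id = c("a1", "a1", "a2"), pos = c(3L, 9L, 3L),
                      ref = "A", alt = "G",
                      sample = "s1", stringsAsFactors = FALSE)
  refs <- c(a1 = strrep("A", 100), a2 = strrep("A", 100),
            b1 = strrep("A", 100))
  ann <- data.frame(orf_id = c("a1", "a2", "b1"),
                    taxon_group = c("ga", "ga", "gb"), genus = "x",
                    label = "y", stringsAsFactors = FALSE)
  pu <- data.table::data.table(
    orf_id = rep(c("a1", "a2"), each = 100), pos = rep(1:100, 2),
    A = 10L, C = 0L, G = 0L, T = 0L, depth = 10L)
  d <- snv_density(calls, list(s1 = pu), ann, refs)
  expect_equal(d$density[d$taxon_group == "ga"], 3 / 2)
  expect_true(is.na(d$density[d$taxon_group == "gb"]))  # no eligible ORFs
})

test_that("allele trajectories average within stage and flag sweeps", {
  sheet <- four_sample_sheet()
  refs <- c(o1 = strrep("A", 30))
  pu_at <- function(af, depth = 100L) {
    data.table::data.table(orf_id = "o1", pos = 6L,
                           A = as.integer(round(depth * (1 - af))), C = 0L,
                           G = as.integer(round(depth * af)), T = 0L,
                           depth = depth)
  }
  pileups <- list(MB1 = pu_at(0.30), MB2 = pu_at(0.95),
                  MB3 = pu_at(0.30), MB4 = pu_at(0.95))
  calls <- do.call(rbind, lapply(names(pileups), function(s) {
    call_snvs(pileups[[s]], refs, sample = s)
  }))
  traj <- allele_trajectories(calls, pileups, sheet)
  expect_equal(nrow(traj), 1L)
  expect_equal(traj$af_mid, 0.30)
  expect_equal(traj$af_late, 0.95)
  expect_true(traj$sweep)

  # af 0.6 -> 0.95 fails sweep_lo
  pileups2 <- list(MB1 = pu_at(0.60), MB2 = pu_at(0.95),
                   MB3 = pu_at(0.60), MB4 = pu_at(0.95))
  calls2 <- do.call(rbind, lapply(names(pileups2), function(s) {
    call_snvs(pileups2[[s]], refs, sample = s)
  }))
  traj2 <- allele_trajectories(calls2, pileups2, sheet)
  expect_false(traj2$sweep)

  # a stage with no coverage keeps a missing frequency, never imputed
  pileups3 <- list(MB1 = pu_at(0.30), MB2 = pu_at(0, depth = 0L),
                   MB3 = pu_at(0.30), MB4 = pu_at(0, depth = 0L))
  calls3 <- call_snvs(pileups3$MB1, refs, sample = "MB1")
  traj3 <- allele_trajectories(calls3, pileups3, sheet)
  expect_true(is.na(traj3$af_late))
  expect_false(traj3$sweep)
})
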