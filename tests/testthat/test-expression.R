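# Counting, TMM, dispersion, the NB exact test, BH and the DE driver.

test_that("count_reads counts once per read with the documented tie-break", {
  mk <- function(read_id, orf_id, nm) {
    data.table::data.table(read_id = read_id, flag = 0L, orf_id = orf_id,
                           pos = 0L, mapq = 60L, cigar = "50M", seq = "A",
                           nm = nm, is_primary = TRUE)
  }
  ann <- data.frame(orf_id = c("a", "b"), taxon_group = "g", genus = "g",
                    label = "x", stringsAsFactors = FALSE)
  aln <- mk(c("r1", "r2", "r3", "r4"), c("a", "a", "a", "b"), 0L)
  cm <- count_reads(list(s1 = aln), ann)
  expect_equal(cm$counts[, "s1"], c(a = 3L, b = 1L))
  expect_equal(unname(cm$lib_sizes["s1"]), 4L)

  # duplicate read: smaller NM wins; NM tie -> lexicographically smaller ORF
  dup <- rbind(mk("r1", "b", 1L), mk("r1", "a", 2L),
               mk("r2", "b", 2L), mk("r2", "a", 2L))
  cm <- count_reads(list(s1 = dup), ann)
  expect_equal(cm$counts[, "s1"], c(a = 1L, b = 1L))

  empty <- mk(character(), character(), integer())
  cm <- count_reads(list(s1 = empty), ann)
  expect_true(all(cm$counts == 0L))
})

test_that("TMM factors: identity, scaling absorption, and edgeR agreement", {
  set.seed(42)
  base <- rnbinom(500, mu = 50, size = 5) + 1L
  m <- cbind(s1 = base, s2 = base, s3 = base)
  expect_equal(unname(tmm_factors(m)), rep(1, 3))

  m2 <- cbind(s1 = base, s2 = 2L * base, s3 = base)
  expect_equal(unname(tmm_factors(m2)), rep(1, 3), tolerance = 1e-12)

  # one sample with 5% of ORFs hogging 80% of counts: its factor < 1,
  # and all factors agree with the reference implementation
  skew <- base
  heavy <- 1:25
  skew[heavy] <- round(0.8 * sum(base) / 25 / 0.2)
  m3 <- cbind(s1 = base, s2 = base, s3 = skew, s4 = base)
  f <- tmm_factors(m3)
  expect_lt(f[["s3"]], 1)
  skip_if_not_installed("edgeR")
  f_ref <- edgeR::calcNormFactors(m3, method = "TMM")
  expect_equal(unname(f), unname(f_ref), tolerance = 0.02)

  expect_equal(prod(tmm_factors(m3))^(1 / 4), 1, tolerance = 1e-12)
  expect_error(tmm_factors(cbind(s1 = base, s2 = 0L * base)), "zero")
})

test_that("common dispersion recovery and explicit bypass", {
  set.seed(7)
  pois <- matrix(rpois(2000 * 4, lambda = rep(exp(rnorm(2000, 4, 1)), 4)),
                 ncol = 4)
  est <- estimate_common_dispersion(pois, c("A", "A", "B", "B"))
  expect_lt(est$phi_common, 0.02)

  mu <- exp(rnorm(5000, 4, 1))
  nb <- matrix(rnbinom(5000 * 4, mu = rep(mu, 4), size = 10), ncol = 4)
  est <- estimate_common_dispersion(nb, c("A", "A", "B", "B"))
  expect_gte(est$phi_common, 0.08)
  expect_lte(est$phi_common, 0.12)

  sup <- estimate_common_dispersion(nb, c("A", "A", "B", "B"), phi = 0.42)
  expect_equal(sup$phi_common, 0.42)
  expect_equal(sup$method, "supplied")

  expect_error(estimate_common_dispersion(nb, c("A", "B", "C", "D")),
               "supply phi")

  # tagwise estimates exist per gene, are non-negative, and concentrate
  # around the common value under a homogeneous simulation
  small <- nb[1:300, ]
  tw <- estimate_common_dispersion(small, c("A", "A", "B", "B"),
                                   tagwise = TRUE)
  expect_length(tw$phi_tagwise, 300L)
  expect_true(all(tw$phi_tagwise >= 0))
  expect_lt(abs(stats::median(tw$phi_tagwise) - tw$phi_common), 0.05)
})

test_that("exact test: stated examples, symmetry and oracle equivalence", {
  expect_equal(exact_test_nb(10, 10, 0.1), 1.0)
  expect_equal(exact_test_nb(0, 0, 0.1), 1.0)
  expect_equal(exact_test_nb(0, 20, 0), 2 * 0.5^20)
  expect_error(exact_test_nb(-1, 5, 0.1), "negative")

  # symmetry: swapping groups (with sizes) leaves p unchanged
  for (phi in c(0, 0.05, 0.5)) {
    expect_equal(exact_test_nb(3, 17, phi, 2, 1),
                 exact_test_nb(17, 3, phi, 1, 2))
  }

  # spot equivalence against the dnbinom brute force (full sweep is in the
  # acceptance suite)
  for (phi in c(0, 0.01, 0.1, 1)) {
    for (t in c(1, 7, 30)) {
      for (a in 0:t) {
        expect_equal(exact_test_nb(a, t - a, phi, 2, 2),
                     brute_force_exact_p(a, t - a, phi, 2, 2),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("BH adjustment matches the step-up formula and is order-stable", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  set.seed(9)
  p <- runif(200)^2
  expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  perm <- sample(200)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
})

test_that("differential_expression: null data, planted signs and modes", {
  set.seed(5)
  base <- rnbinom(300, mu = 100, size = 10) + 1L
  m <- cbind(MB1 = base, MB2 = base, MB3 = base, MB4 = base)
  rownames(m) <- sprintf("orf%03d", 1:300)
  cm <- count_matrix(m)
  de <- differential_expression(cm, "N", phi = 0.1)
  expect_equal(sum(de$significant), 0L)
  expect_true(all(de$fdr >= de$p_value))
  expect_true(all(de$p_value >= 0 & de$p_value <= 1))

  # planted effects: sign recovery on a small world
  cfg <- sim_config(seed = 21, n_taxon_groups = 2, orfs_per_group = 100,
                    samples = four_sample_sheet(lib = 100000L),
                    group_bloom_log2fc = c(0, 0))
  cmP <- simulate_counts(cfg)
  truth <- attr(cmP, "truth")
  deP <- differential_expression(cmP, "N")
  j <- match(deP$orf_id, truth$orf_id)
  planted <- truth$true_log2fc[j] != 0
  agree <- sign(deP$log2fc[planted]) == sign(truth$true_log2fc[j][planted])
  expect_gte(mean(agree), 0.95)

  # a group doubling in abundance with unchanged physiology: flagged by
  # taxon_proportion mode, not (beyond nominal) by groupwise mode
  cfgB <- sim_config(seed = 22, n_taxon_groups = 2, orfs_per_group = 150,
                     samples = four_sample_sheet(lib = 100000L),
                     de_fraction = 0, group_bloom_log2fc = c(1, 0),
                     dispersion = 0.05)
  cmB <- simulate_counts(cfgB)
  prop <- differential_expression(cmB, "N", mode = "taxon_proportion")
  expect_true(prop$significant[prop$orf_id == "centric diatom"])
  grp <- differential_expression(cmB, "N", mode = "groupwise",
                                 taxon_group = "centric diatom")
  expect_lte(mean(grp$significant), 0.05)

  expect_error(differential_expression(
    cm, list(depleted = "MB9", replete = "MB1")), "MB9")
  empty_sheet <- cm
  expect_error(differential_expression(cm, "Fe"), "empty")
})
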