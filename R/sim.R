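# Synthetic bloom-community metatranscriptomes with planted truth.
#
# The generator emulates the nutrient-manipulation design: barrels sampled
# mid bloom (nutrient replete) and late bloom (depleted), negative-binomial
# ORF expression with planted log2 fold changes, taxon groups whose total
# abundance changes over the bloom, a reference-diverged subpopulation per
# taxon group whose mixing weight changes between stages (producing
# percent-identity shifts), planted SNVs with stage-specific allele
# frequencies, and uniform per-base sequencing error.

BASES <- c("A", "C", "G", "T")

TAXON_LABELS <- c("centric diatom", "pennate diatom", "dinoflagellate",
                  "chlorophyte", "haptophyte", "pelagophyte", "virus",
                  "other")

MARKER_LABELS <- c("NRT2", "GSII", "ISIP1", "ISIP2", "ISIP3", "thiC",
                   "flavodoxin", "ferredoxin", "ferritin", "LHC")

# Evaluate expr with a locally-set RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Stable 31-bit polynomial string hash, so per-sample RNG streams depend on
# the sample name and root seed only (adding a sample never perturbs others).
hash_string <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483629
  as.integer(h)
}

stream_seed <- function(root_seed, name) {
  as.integer((as.numeric(root_seed) * 48271 + hash_string(name)) %% 2147483629)
}

#' Planted SNV specification
#'
#' Describes one single-nucleotide variant to plant in simulated reads, with
#' an allele-frequency trajectory across bloom stages (so sweeps --- variants
#' rising to dominance late bloom --- can be planted directly).
#'
#' @param orf_id Target ORF id.
#' @param position 1-based position within the ORF.
#' @param freq_mid,freq_late Alternate-allele frequency in mid/late samples,
#'   both in `[0, 1]`.
#' @param ref_allele,alt_allele Bases in `{A,C,G,T}`; `NA` (default) resolves
#'   the reference base from the generated sequence and picks the next base
#'   in alphabet order as the alternate.
#' @return A `planted_snv` list.
#' @export
planted_snv <- function(orf_id, position, freq_mid, freq_late,
                        ref_allele = NA, alt_allele = NA) {
  stopifnot(position >= 1, freq_mid >= 0, freq_mid <= 1,
            freq_late >= 0, freq_late <= 1)
  if (!is.na(ref_allele) && !is.na(alt_allele) && ref_allele == alt_allele) {
    stop("ref and alt alleles must differ")
  }
  structure(list(orf_id = orf_id, position = as.integer(position),
                 ref_allele = ref_allele, alt_allele = alt_allele,
                 freq_by_condition = c(mid = freq_mid, late = freq_late)),
            class = "planted_snv")
}

#' Simulation configuration
#'
#' Collects all knobs of the synthetic bloom community. Defaults describe a
#' small but complete world: four taxon groups of which the diatoms bloom
#' (abundance up late), 10% of ORFs nutrient-responsive at |log2FC| = 3, NB
#' dispersion 0.1 (typical biological replicate variability), one diverged
#' subpopulation per group at 5% divergence whose mixing weight drops from
#' 0.8 mid bloom to 0.2 late bloom (the strain closest to the reference wins
#' the bloom), and a 0.1% uniform sequencing error rate.
#'
#' @param seed Root RNG seed.
#' @param n_taxon_groups,orfs_per_group Community size.
#' @param orf_length ORF length in nt, a multiple of 3.
#' @param samples Sample table: `sample`, `experiment` (`N`/`Fe`), `barrel`,
#'   `stage` (`mid`/`late`), `condition` (`replete`/`depleted`),
#'   `library_size`. Defaults to the eight-barrel-sample design with 25,000
#'   reads each.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param expr_sdlog Log-normal sd of per-ORF baseline abundances; 0 gives
#'   uniform expression (useful for coverage-controlled experiments).
#' @param de_fraction Fraction of ORFs with a planted depletion effect.
#' @param de_log2fc Magnitude of planted effects (sign random per ORF).
#' @param group_bloom_log2fc Per-group mid-to-late abundance log2 change;
#'   `NULL` assigns +2 to diatom groups, +0.5 to dinoflagellates, +1 to
#'   viruses, 0 elsewhere.
#' @param subpop_divergence Substitutions/site of the diverged subpopulation,
#'   in `[0, 0.3]`.
#' @param subpop_mix Named vector `c(mid=, late=)`: mixing weight of the
#'   diverged subpopulation per stage.
#' @param snv_spec List of [planted_snv()] objects.
#' @param label_log2fc Optional named numeric vector: functional label to
#'   planted depletion log2FC (e.g. `c(NRT2 = 3, GSII = -2)`); overrides the
#'   random planted effect on ORFs carrying those labels.
#' @param error_rate Per-base substitution error rate, in `[0, 0.05]`.
#' @param read_length Read length (>= 30, <= `orf_length`).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_taxon_groups = 4L,
                       orfs_per_group = 50L,
                       orf_length = 300L,
                       samples = NULL,
                       dispersion = 0.1,
                       expr_sdlog = 1,
                       de_fraction = 0.1,
                       de_log2fc = 3,
                       group_bloom_log2fc = NULL,
                       subpop_divergence = 0.05,
                       subpop_mix = c(mid = 0.8, late = 0.2),
                       snv_spec = list(),
                       label_log2fc = NULL,
                       error_rate = 0.001,
                       read_length = 100L) {
  if (orf_length %% 3 != 0) stop("orf_length must be divisible by 3")
  if (read_length < 30L) stop("read_length must be >= 30")
  if (read_length > orf_length) stop("read_length must be <= orf_length")
  if (subpop_divergence < 0 || subpop_divergence > 0.3) {
    stop("subpop_divergence must be in [0, 0.3]")
  }
  if (error_rate < 0 || error_rate > 0.05) {
    stop("error_rate must be in [0, 0.05]")
  }
  subpop_mix <- unlist(subpop_mix)
  if (is.null(names(subpop_mix)) && length(subpop_mix) == 2L) {
    names(subpop_mix) <- c("mid", "late")
  }
  if (any(subpop_mix < 0 | subpop_mix > 1) ||
      !all(c("mid", "late") %in% names(subpop_mix))) {
    stop("subpop_mix must be c(mid=, late=) weights in [0, 1]")
  }
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (is.null(samples)) {
    samples <- default_sample_sheet()
    samples$library_size <- 25000L
  }
  if (any(samples$library_size <= 0)) stop("library_size must be > 0")
  validate_sample_sheet(samples)
  group_label <- TAXON_LABELS[(seq_len(n_taxon_groups) - 1L) %%
                                length(TAXON_LABELS) + 1L]
  if (is.null(group_bloom_log2fc)) {
    group_bloom_log2fc <- ifelse(
      group_label %in% c("centric diatom", "pennate diatom"), 2,
      ifelse(group_label == "dinoflagellate", 0.5,
             ifelse(group_label == "virus", 1, 0)))
  }
  if (length(group_bloom_log2fc) != n_taxon_groups) {
    stop("group_bloom_log2fc must have one value per taxon group")
  }
  structure(list(
    seed = as.integer(seed), n_taxon_groups = as.integer(n_taxon_groups),
    orfs_per_group = as.integer(orfs_per_group),
    orf_length = as.integer(orf_length), samples = samples,
    dispersion = dispersion, expr_sdlog = expr_sdlog,
    de_fraction = de_fraction,
    de_log2fc = de_log2fc, group_bloom_log2fc = group_bloom_log2fc,
    group_label = group_label,
    subpop_divergence = subpop_divergence, subpop_mix = subpop_mix,
    snv_spec = snv_spec, label_log2fc = label_log2fc,
    error_rate = error_rate,
    read_length = as.integer(read_length)
  ), class = "sim_config")
}

#' Generate reference ORFs and annotation
#'
#' Draws `orfs_per_group * n_taxon_groups` random ORFs: ATG start, internal
#' codons from the 61 sense codons (so frame-1 translation has no internal
#' stop), TAA terminal codon. The annotation assigns each group a taxon
#' label and a genus, and tags the first ten ORFs of every group with the
#' marker gene families (NRT2, GSII, ISIP1-3, thiC, flavodoxin, ferredoxin,
#' ferritin, LHC); remaining ORFs get anonymous family labels.
#'
#' @param config A [sim_config()].
#' @return List with `references` (named character vector) and `annotation`
#'   (data.frame `orf_id`, `taxon_group`, `genus`, `label`).
#' @export
generate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  n_orfs <- config$n_taxon_groups * config$orfs_per_group
  n_codons <- config$orf_length %/% 3L
  refs <- with_seed(config$seed, {
    vapply(seq_len(n_orfs), function(i) {
      body <- sample(sense, n_codons - 2L, replace = TRUE)
      paste0("ATG", paste(body, collapse = ""), "TAA")
    }, character(1))
  })
  group <- rep(seq_len(config$n_taxon_groups), each = config$orfs_per_group)
  ids <- sprintf("g%02d_orf%04d", group,
                 rep(seq_len(config$orfs_per_group),
                     config$n_taxon_groups))
  names(refs) <- ids
  idx <- rep(seq_len(config$orfs_per_group), config$n_taxon_groups)
  label <- sprintf("fam%04d", idx)
  label[idx <= length(MARKER_LABELS)] <- MARKER_LABELS[idx[idx <=
                                                             length(MARKER_LABELS)]]
  annotation <- data.frame(
    orf_id = ids,
    taxon_group = config$group_label[group],
    genus = sprintf("Genus%02d", group),
    label = label,
    stringsAsFactors = FALSE
  )
  list(references = refs, annotation = annotation)
}

#' Mutate a sequence at a fixed per-site substitution rate
#'
#' Each site is independently substituted with probability `rate` to a
#' uniformly chosen different base; length is preserved. Used to create the
#' diverged subpopulation references.
#'
#' @param seq A DNA string.
#' @param rate Substitution probability per site, in `[0, 0.3]`.
#' @param seed RNG seed (local; global RNG state is untouched).
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, rate, seed) {
  if (rate < 0 || rate > 0.3) stop("rate must be in [0, 0.3]")
  if (rate == 0) return(seq)
  with_seed(seed, {
    chars <- strsplit(seq, "")[[1]]
    hit <- which(stats::runif(length(chars)) < rate)
    if (length(hit)) {
      chars[hit] <- vapply(chars[hit], function(b) {
        sample(setdiff(BASES, b), 1L)
      }, character(1))
    }
    paste(chars, collapse = "")
  })
}

# Planted truth: per-ORF baseline abundance, DE effect, and resolved SNVs.
build_truth <- function(config, refgen) {
  ids <- names(refgen$references)
  n <- length(ids)
  truth <- with_seed(stream_seed(config$seed, "truth"), {
    baseline <- stats::rlnorm(n, meanlog = 0, sdlog = config$expr_sdlog)
    n_de <- round(config$de_fraction * n)
    de_idx <- sample.int(n, n_de)
    lfc <- numeric(n)
    lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * config$de_log2fc
    list(baseline = baseline, true_log2fc = lfc)
  })
  if (!is.null(config$label_log2fc)) {
    hit <- match(refgen$annotation$label, names(config$label_log2fc))
    truth$true_log2fc[!is.na(hit)] <-
      config$label_log2fc[hit[!is.na(hit)]]
  }
  group <- match(refgen$annotation$taxon_group, config$group_label)
  snvs <- lapply(config$snv_spec, function(sv) {
    seq <- refgen$references[[sv$orf_id]]
    if (is.null(seq)) stop("planted SNV names unknown ORF: ", sv$orf_id)
    if (sv$position > nchar(seq)) stop("planted SNV position beyond ORF end")
    ref_base <- substr(seq, sv$position, sv$position)
    if (!is.na(sv$ref_allele) && sv$ref_allele != ref_base) {
      stop("planted SNV ref allele disagrees with reference at ",
           sv$orf_id, ":", sv$position)
    }
    sv$ref_allele <- ref_base
    if (is.na(sv$alt_allele)) {
      sv$alt_allele <- BASES[match(ref_base, BASES) %% 4L + 1L]
    }
    if (sv$alt_allele == ref_base) stop("alt allele equals reference base")
    sv
  })
  data.frame(
    orf_id = ids, taxon_group = refgen$annotation$taxon_group,
    group_index = group, baseline = truth$baseline,
    true_log2fc = truth$true_log2fc, stringsAsFactors = FALSE
  ) -> tab
  list(orf = tab, snvs = snvs)
}

# Draw one sample's per-ORF counts (NB expression, then a multinomial of
# exactly library_size reads). Called with the sample's RNG stream active;
# generate_reads() draws these same counts before laying out reads, so
# simulate_counts() and the full read simulation agree exactly.
draw_sample_counts <- function(config, orf_tab, sample_row) {
  mu <- orf_tab$baseline *
    2^(if (sample_row$condition == "depleted") orf_tab$true_log2fc else 0) *
    2^(if (sample_row$stage == "late")
      config$group_bloom_log2fc[orf_tab$group_index] else 0)
  lib <- sample_row$library_size
  mu <- mu / sum(mu) * lib
  expr <- if (config$dispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  } else {
    stats::rpois(length(mu), mu)
  }
  if (sum(expr) == 0) expr <- rep(1, length(mu))
  as.vector(stats::rmultinom(1, lib, expr / sum(expr)))
}

#' Simulate a count matrix directly
#'
#' Draws per-sample ORF counts from the same RNG streams as the full read
#' simulation but skips read layout, so statistical experiments that only
#' need counts run in milliseconds. The counts equal what
#' [simulate_bundle()] plus [count_reads()] on the truth alignments would
#' produce.
#'
#' @param config A [sim_config()].
#' @return A `count_matrix` with the per-ORF truth table attached as
#'   attribute `"truth"`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  refgen <- generate_references(config)
  truth <- build_truth(config, refgen)
  counts <- vapply(seq_len(nrow(config$samples)), function(i) {
    row <- config$samples[i, ]
    with_seed(stream_seed(config$seed, row$sample),
              draw_sample_counts(config, truth$orf, row))
  }, integer(nrow(truth$orf)))
  counts <- matrix(as.integer(counts), nrow = nrow(truth$orf),
                   dimnames = list(truth$orf$orf_id,
                                   config$samples$sample))
  cm <- count_matrix(counts, annotation = refgen$annotation,
                     sample_sheet = config$samples)
  attr(cm, "truth") <- truth$orf
  cm
}

# Simulate one sample: reads (character vector), truth alignments
# (data.table in read_sam() layout) and the realized per-ORF template use.
generate_reads <- function(config, refgen, truth, diverged, sample_row) {
  L <- config$orf_length
  rl <- config$read_length
  stage <- sample_row$stage
  cond <- sample_row$condition
  lib <- sample_row$library_size
  orf_tab <- truth$orf
  n <- nrow(orf_tab)
  with_seed(stream_seed(config$seed, sample_row$sample), {
    counts <- draw_sample_counts(config, orf_tab, sample_row)
    orf_idx <- rep.int(seq_len(nrow(orf_tab)), counts)
    starts <- if (L == rl) rep(0L, lib) else
      sample.int(L - rl + 1L, lib, replace = TRUE) - 1L
    from_subpop <- stats::runif(lib) < config$subpop_mix[[stage]]
    template <- ifelse(from_subpop, diverged[orf_idx],
                       refgen$references[orf_idx])
    win <- substr(template, starts + 1L, starts + rl)
    read_mat <- matrix(unlist(strsplit(win, ""), use.names = FALSE),
                       ncol = rl, byrow = TRUE)
    # planted SNVs: flip covered reads to the alt allele at the trajectory
    # frequency for this stage
    orf_ids <- orf_tab$orf_id[orf_idx]
    for (sv in truth$snvs) {
      covered <- which(orf_ids == sv$orf_id & starts < sv$position &
                         starts + rl >= sv$position)
      if (!length(covered)) next
      f <- sv$freq_by_condition[[stage]]
      flip <- covered[stats::runif(length(covered)) < f]
      col <- sv$position - starts[flip]
      read_mat[cbind(flip, col)] <- sv$alt_allele
      keep_ref <- setdiff(covered, flip)
      col <- sv$position - starts[keep_ref]
      read_mat[cbind(keep_ref, col)] <- sv$ref_allele
    }
    if (config$error_rate > 0) {
      hit <- which(stats::runif(length(read_mat)) < config$error_rate)
      if (length(hit)) {
        shift <- sample.int(3L, length(hit), replace = TRUE)
        read_mat[hit] <- BASES[(match(read_mat[hit], BASES) - 1L + shift) %%
                                 4L + 1L]
      }
    }
    ref_win <- substr(refgen$references[orf_idx], starts + 1L, starts + rl)
    ref_mat <- matrix(unlist(strsplit(ref_win, ""), use.names = FALSE),
                      ncol = rl, byrow = TRUE)
    nm <- as.integer(rowSums(read_mat != ref_mat))
    reads <- do.call(paste0, as.data.frame(read_mat,
                                           stringsAsFactors = FALSE))
    read_ids <- sprintf("%s_read%06d", sample_row$sample, seq_len(lib))
    aln <- data.table::data.table(
      read_id = read_ids, flag = 0L, orf_id = orf_ids, pos = starts,
      mapq = 60L, cigar = paste0(rl, "M"), seq = reads, nm = nm,
      is_primary = TRUE
    )
    list(reads = stats::setNames(reads, read_ids), alignments = aln,
         from_subpop = from_subpop, expr = counts)
  })
}

#' Simulate a full bloom-community bundle
#'
#' Runs reference generation, subpopulation divergence and per-sample read
#' simulation; samples use independent RNG streams derived from the root
#' seed and the sample name, so the bundle is deterministic and adding a
#' sample leaves the others byte-identical.
#'
#' @param config A [sim_config()].
#' @return A `sim_bundle` list: `references`, `diverged_references`,
#'   `annotation`, `truth` (per-ORF table, resolved planted SNVs, per-read
#'   subpopulation origin), `reads` and `alignments` per sample, and the
#'   `config`.
#' @export
simulate_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  refgen <- generate_references(config)
  truth <- build_truth(config, refgen)
  diverged <- vapply(seq_along(refgen$references), function(i) {
    mutate_sequence(refgen$references[[i]], config$subpop_divergence,
                    stream_seed(config$seed,
                                paste0("div:", names(refgen$references)[i])))
  }, character(1))
  names(diverged) <- names(refgen$references)
  reads <- list(); alignments <- list(); origin <- list()
  for (i in seq_len(nrow(config$samples))) {
    row <- config$samples[i, ]
    sim <- generate_reads(config, refgen, truth, diverged, row)
    reads[[row$sample]] <- sim$reads
    alignments[[row$sample]] <- sim$alignments
    origin[[row$sample]] <- sim$from_subpop
  }
  structure(list(
    references = refgen$references, diverged_references = diverged,
    annotation = refgen$annotation,
    truth = list(orf = truth$orf, snvs = truth$snvs, origin = origin),
    reads = reads, alignments = alignments, config = config
  ), class = "sim_bundle")
}

#' Write a simulated bundle to disk
#'
#' Emits the plain-text artifacts a real run would start from: reference
#' FASTA, per-sample FASTQ and truth SAM, annotation and truth TSVs, and the
#' sample sheet.
#'
#' @param bundle A `sim_bundle` from [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$references, file.path(dir, "references.fasta"))
  write_annotation(bundle$annotation, file.path(dir, "annotation.tsv"))
  utils::write.table(bundle$config$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$orf, file.path(dir, "truth_orfs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ref_len <- stats::setNames(nchar(bundle$references),
                             names(bundle$references))
  for (s in names(bundle$reads)) {
    write_fastq(bundle$reads[[s]], file.path(dir, paste0(s, ".fastq")))
    write_sam(bundle$alignments[[s]], ref_len,
              file.path(dir, paste0(s, ".sam")))
  }
  if (length(bundle$truth$snvs)) {
    snv_tab <- do.call(rbind, lapply(bundle$truth$snvs, function(sv) {
      data.frame(orf_id = sv$orf_id, position = sv$position,
                 ref = sv$ref_allele, alt = sv$alt_allele,
                 freq_mid = sv$freq_by_condition[["mid"]],
                 freq_late = sv$freq_by_condition[["late"]],
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(snv_tab, file.path(dir, "truth_snvs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
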