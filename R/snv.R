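# Gene-level selection: pileup construction from alignments, SNV calling,
# synonymous/nonsynonymous classification under the standard genetic code,
# per-taxon SNV density, and allele-frequency trajectories with sweep flags.

#' Build a base-count pileup from alignments
#'
#' For every covered ORF site, counts of A/C/G/T contributed by reads whose
#' M operations cover the site. CIGAR semantics are honored: D consumes
#' reference without a base, I consumes read only, S consumes read only.
#' Ungapped `<L>M` alignments take a vectorized fast path.
#'
#' @param aln Alignment table ([read_sam()] layout) for one sample; must
#'   carry `seq`.
#' @param references Named character vector of ORF sequences.
#' @return `data.table` with columns `orf_id`, `pos` (1-based), `A`, `C`,
#'   `G`, `T`, `depth`.
#' @export
build_pileup <- function(aln, references) {
  aln <- data.table::as.data.table(aln)
  aln <- aln[aln$is_primary]
  if (nrow(aln) == 0L) {
    return(data.table::data.table(orf_id = character(), pos = integer(),
                                  A = integer(), C = integer(),
                                  G = integer(), T = integer(),
                                  depth = integer()))
  }
  ref_len <- nchar(references)[aln$orf_id]
  simple <- grepl("^[0-9]+M$", aln$cigar)
  parts <- list()
  if (any(simple)) {
    sub <- aln[simple]
    width <- nchar(sub$seq)
    if (any(sub$pos + width > ref_len[simple])) {
      bad <- which(sub$pos + width > ref_len[simple])[1]
      stop("alignment overruns reference end: ", sub$read_id[bad])
    }
    parts[[1]] <- data.table::data.table(
      orf_id = rep(sub$orf_id, width),
      pos = unlist(lapply(seq_len(nrow(sub)), function(i) {
        seq.int(sub$pos[i] + 1L, sub$pos[i] + width[i])
      }), use.names = FALSE),
      base = unlist(strsplit(sub$seq, ""), use.names = FALSE)
    )
  }
  if (any(!simple)) {
    gap <- aln[!simple]
    ops <- parse_cigar(gap$cigar)
    gparts <- lapply(seq_len(nrow(gap)), function(i) {
      tab <- ops[[i]]
      ref_pos <- gap$pos[i]   # 0-based
      read_pos <- 0L
      pos_out <- integer(); base_out <- character()
      chars <- strsplit(gap$seq[i], "")[[1]]
      for (j in seq_len(nrow(tab))) {
        len <- tab$len[j]
        op <- tab$op[j]
        if (op == "M") {
          pos_out <- c(pos_out, seq.int(ref_pos + 1L, ref_pos + len))
          base_out <- c(base_out, chars[read_pos + seq_len(len)])
          ref_pos <- ref_pos + len
          read_pos <- read_pos + len
        } else if (op == "D") {
          ref_pos <- ref_pos + len
        } else {
          read_pos <- read_pos + len   # I and S consume read only
        }
      }
      if (ref_pos > nchar(references)[[gap$orf_id[i]]]) {
        stop("alignment overruns reference end: ", gap$read_id[i])
      }
      data.table::data.table(orf_id = gap$orf_id[i], pos = pos_out,
                             base = base_out)
    })
    parts[[length(parts) + 1L]] <- data.table::rbindlist(gparts)
  }
  bases <- data.table::rbindlist(parts)
  counts <- bases[, list(n = .N), by = c("orf_id", "pos", "base")]
  wide <- data.table::dcast(counts, orf_id + pos ~ base, value.var = "n",
                            fill = 0L)
  for (b in c("A", "C", "G", "T")) {
    if (!b %in% names(wide)) wide[, (b) := 0L]
  }
  wide <- wide[, c("orf_id", "pos", "A", "C", "G", "T"), with = FALSE]
  wide[, "depth" := wide$A + wide$C + wide$G + wide$T]
  data.table::setorderv(wide, c("orf_id", "pos"))
  wide[]
}

#' Call SNVs from a pileup
#'
#' A site yields one call per alternate allele with `depth >= min_depth`,
#' `alt_count >= min_alt` and `alt_count/depth >= min_af`; multi-allelic
#' sites emit multiple calls. Each call is classified synonymous or
#' nonsynonymous via [classify_effect()].
#'
#' @param pileup Result of [build_pileup()].
#' @param references Named character vector of ORF sequences (frame 1).
#' @param min_depth,min_alt,min_af Calling thresholds.
#' @param sample Sample name recorded in the output.
#' @return data.frame: `orf_id`, `pos` (1-based), `ref`, `alt`, `sample`,
#'   `depth`, `alt_count`, `af`, `codon_index`, `codon_pos`, `codon_ref`,
#'   `codon_alt`, `effect`.
#' @export
call_snvs <- function(pileup, references, min_depth = 4L, min_alt = 2L,
                      min_af = 0.05, sample = "sample") {
  empty <- data.frame(orf_id = character(), pos = integer(),
                      ref = character(), alt = character(),
                      sample = character(), depth = integer(),
                      alt_count = integer(), af = numeric(),
                      codon_index = integer(), codon_pos = integer(),
                      codon_ref = character(), codon_alt = character(),
                      effect = character(), stringsAsFactors = FALSE)
  pu <- pileup[pileup$depth >= min_depth]
  if (nrow(pu) == 0L) return(empty)
  ref_base <- substr(references[pu$orf_id], pu$pos, pu$pos)
  calls <- list()
  for (b in c("A", "C", "G", "T")) {
    cnt <- pu[[b]]
    hit <- which(ref_base != b & cnt >= min_alt &
                   cnt / pu$depth >= min_af)
    if (!length(hit)) next
    calls[[b]] <- data.frame(
      orf_id = pu$orf_id[hit], pos = pu$pos[hit], ref = ref_base[hit],
      alt = b, sample = sample, depth = pu$depth[hit],
      alt_count = cnt[hit], af = cnt[hit] / pu$depth[hit],
      stringsAsFactors = FALSE
    )
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  out <- out[order(out$orf_id, out$pos, out$alt), , drop = FALSE]
  eff <- classify_effect(out$orf_id, out$pos, out$alt, references)
  out <- cbind(out, eff)
  rownames(out) <- NULL
  out
}

#' Classify a substitution as synonymous or nonsynonymous
#'
#' Substitutes the alternate base into the codon containing the position
#' (frame 1) and translates both codons with the standard genetic code;
#' identical amino acids are synonymous, anything else (including stop gain
#' or loss) is nonsynonymous. Positions falling in an incomplete trailing
#' codon classify as `NA`.
#'
#' @param orf_id,pos,alt Vectors describing substitutions (`pos` 1-based).
#' @param references Named character vector of ORF sequences.
#' @return data.frame: `codon_index`, `codon_pos`, `codon_ref`, `codon_alt`,
#'   `effect` (`"SYN"`, `"NONSYN"` or `NA`).
#' @export
classify_effect <- function(orf_id, pos, alt, references) {
  codon_index <- (pos - 1L) %/% 3L + 1L
  codon_pos <- (pos - 1L) %% 3L + 1L
  start <- (codon_index - 1L) * 3L + 1L
  seqs <- references[orf_id]
  codon_ref <- substr(seqs, start, start + 2L)
  incomplete <- nchar(codon_ref) < 3L
  codon_alt <- codon_ref
  substr(codon_alt, codon_pos, codon_pos) <- alt
  aa_ref <- translate_codon(codon_ref)
  aa_alt <- translate_codon(codon_alt)
  effect <- ifelse(incomplete, NA_character_,
                   ifelse(aa_ref == aa_alt, "SYN", "NONSYN"))
  data.frame(codon_index = codon_index, codon_pos = codon_pos,
             codon_ref = codon_ref, codon_alt = codon_alt, effect = effect,
             stringsAsFactors = FALSE)
}

translate_codon <- function(codon) {
  out <- rep(NA_character_, length(codon))
  ok <- nchar(codon) == 3L & !grepl("[^ACGT]", codon)
  out[ok] <- unname(Biostrings::GENETIC_CODE[codon[ok]])
  out
}

#' Per-taxon SNV density
#'
#' `density = distinct called sites / eligible ORFs` for a taxon group in a
#' sample; an ORF is eligible when its mean coverage in that sample is at
#' least `min_depth`. Groups with zero eligible ORFs report a missing (not
#' zero) density.
#'
#' @param calls SNV call table (possibly several samples bound together).
#' @param pileups Named list (per sample) of pileups, for the coverage
#'   denominator.
#' @param annotation ORF annotation with `taxon_group`.
#' @param references Named character vector of ORF sequences (lengths give
#'   mean coverage).
#' @param min_depth Eligibility threshold on mean per-site coverage.
#' @return data.frame: `taxon_group`, `sample`, `n_snvs`, `n_orfs`,
#'   `density`.
#' @export
snv_density <- function(calls, pileups, annotation, references,
                        min_depth = 4L) {
  out <- list()
  for (s in names(pileups)) {
    pu <- pileups[[s]]
    cov <- pu[, list(total = sum(depth)), by = "orf_id"]
    cov[, "mean_cov" := cov$total / nchar(references)[cov$orf_id]]
    eligible <- cov$orf_id[cov$mean_cov >= min_depth]
    grp <- annotation$taxon_group[match(eligible, annotation$orf_id)]
    n_orfs <- table(grp)
    cs <- calls[calls$sample == s & calls$orf_id %in% eligible, ,
                drop = FALSE]
    sites <- unique(cs[, c("orf_id", "pos")])
    sgrp <- annotation$taxon_group[match(sites$orf_id, annotation$orf_id)]
    n_snvs <- table(sgrp)
    for (g in sort(unique(annotation$taxon_group))) {
      no <- if (g %in% names(n_orfs)) as.integer(n_orfs[[g]]) else 0L
      ns <- if (g %in% names(n_snvs)) as.integer(n_snvs[[g]]) else 0L
      out[[length(out) + 1L]] <- data.frame(
        taxon_group = g, sample = s, n_snvs = ns, n_orfs = no,
        density = if (no > 0L) ns / no else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Allele-frequency trajectories and sweep flags
#'
#' Takes the union of called sites across samples, averages per-site allele
#' frequencies over the mid and over the late samples of each experiment,
#' and flags a sweep when the allele rises from `af_mid <= sweep_lo` to
#' `af_late >= sweep_hi`. Sites uncovered at one stage keep a missing
#' frequency (never imputed) and cannot be flagged.
#'
#' @param calls Combined call table across samples.
#' @param pileups Named per-sample pileups, used to recover the frequency of
#'   a called allele in samples where it was not itself called (including
#'   zero when covered).
#' @param sample_sheet Sample sheet mapping samples to experiment/stage.
#' @param sweep_hi,sweep_lo Sweep thresholds.
#' @return data.frame: `orf_id`, `pos`, `ref`, `alt`, `experiment`,
#'   `af_mid`, `af_late`, `delta_af`, `sweep`.
#' @export
allele_trajectories <- function(calls, pileups, sample_sheet,
                                sweep_hi = 0.9, sweep_lo = 0.5) {
  sites <- unique(calls[, c("orf_id", "pos", "ref", "alt")])
  if (nrow(sites) == 0L) {
    return(data.frame(orf_id = character(), pos = integer(),
                      ref = character(), alt = character(),
                      experiment = character(), af_mid = numeric(),
                      af_late = numeric(), delta_af = numeric(),
                      sweep = logical(), stringsAsFactors = FALSE))
  }
  # per-sample af at every union site, from the pileup (NA when uncovered)
  af_by_sample <- lapply(names(pileups), function(s) {
    pu <- pileups[[s]]
    m <- merge(data.table::as.data.table(sites), pu,
               by = c("orf_id", "pos"), all.x = TRUE)
    alt_cnt <- m[["A"]] * (m$alt == "A") + m[["C"]] * (m$alt == "C") +
      m[["G"]] * (m$alt == "G") + m[["T"]] * (m$alt == "T")
    data.table::data.table(orf_id = m$orf_id, pos = m$pos, ref = m$ref,
                           alt = m$alt, sample = s,
                           af = ifelse(is.na(m$depth) | m$depth == 0,
                                       NA_real_, alt_cnt / m$depth))
  })
  aft <- data.table::rbindlist(af_by_sample)
  sheet <- sample_sheet[match(aft$sample, sample_sheet$sample), ]
  aft[, "experiment" := sheet$experiment]
  aft[, "stage" := sheet$stage]
  agg <- aft[!is.na(aft$experiment),
             list(af = mean(af, na.rm = TRUE)),
             by = c("orf_id", "pos", "ref", "alt", "experiment", "stage")]
  agg$af[is.nan(agg$af)] <- NA_real_
  wide <- data.table::dcast(agg, orf_id + pos + ref + alt + experiment ~
                              stage, value.var = "af")
  for (col in c("mid", "late")) {
    if (!col %in% names(wide)) wide[, (col) := NA_real_]
  }
  out <- data.frame(
    orf_id = wide$orf_id, pos = wide$pos, ref = wide$ref, alt = wide$alt,
    experiment = wide$experiment, af_mid = wide$mid, af_late = wide$late,
    stringsAsFactors = FALSE
  )
  out$delta_af <- out$af_late - out$af_mid
  out$sweep <- !is.na(out$af_mid) & !is.na(out$af_late) &
    out$af_mid <= sweep_lo & out$af_late >= sweep_hi
  out[order(out$orf_id, out$pos, out$alt, out$experiment), , drop = FALSE]
}
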