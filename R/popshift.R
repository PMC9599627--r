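# Population-level selection: per-read percent identity to the reference,
# per-sample identity histograms, and the replicated identity-shift table
# (ORFs significantly differentially expressed, at least min_identity
# percent identical to the reference, shifting in the same direction across
# replicate barrels).

#' Percent identity of alignments
#'
#' `pid = 100 * (1 - NM / aligned_columns)`, where aligned columns are the
#' summed M, I and D operation lengths (soft clips excluded); clamped to
#' `[0, 100]`.
#'
#' @param aln Alignment table ([read_sam()] layout), or a CIGAR character
#'   vector when `nm` is given.
#' @param nm Edit distances when `aln` is a CIGAR vector.
#' @return Numeric vector of percent identities.
#' @export
percent_identity <- function(aln, nm = NULL) {
  if (is.null(nm)) {
    cigar <- aln$cigar
    nm <- aln$nm
  } else {
    cigar <- aln
  }
  simple <- grepl("^[0-9]+M$", cigar)
  cols <- integer(length(cigar))
  cols[simple] <- as.integer(sub("M$", "", cigar[simple]))
  if (any(!simple)) cols[!simple] <- cigar_aligned_columns(cigar[!simple])
  if (any(cols == 0L)) stop("alignment with zero aligned columns")
  pmin(pmax(100 * (1 - nm / cols), 0), 100)
}

#' Per-sample percent-identity summaries
#'
#' Computes per-(ORF, sample) read counts and mean percent identity, and a
#' per-(reference group, sample) histogram over 1-point bins on `[50, 100]`
#' (left-closed, right-open; the final bin `[99, 100]` is closed; reads
#' below 50 land in an underflow bucket).
#'
#' @param alignments Named list (per sample) of alignment tables, or one
#'   table.
#' @param annotation ORF annotation (groups ORFs for the histograms); `NULL`
#'   puts everything in one group.
#' @param bin_width Histogram bin width in percentage points.
#' @return List with `per_orf` (data.frame `orf_id`, `sample`, `n_reads`,
#'   `mean_pid`) and `histogram` (data.frame `reference_group`, `sample`,
#'   `bin_start`, `bin_end`, `count`).
#' @export
pid_histogram <- function(alignments, annotation = NULL, bin_width = 1.0) {
  if (data.table::is.data.table(alignments) || is.data.frame(alignments)) {
    alignments <- list(sample = alignments)
  }
  per_orf <- list(); hist_out <- list()
  breaks <- seq(50, 100, by = bin_width)
  for (s in names(alignments)) {
    aln <- data.table::as.data.table(alignments[[s]])
    aln <- aln[aln$is_primary]
    if (nrow(aln) == 0L) next
    pid <- percent_identity(aln)
    dt <- data.table::data.table(orf_id = aln$orf_id, pid = pid)
    po <- dt[, list(n_reads = .N, mean_pid = mean(pid)), by = "orf_id"]
    po[, "sample" := s]
    per_orf[[s]] <- po
    grp <- if (is.null(annotation)) rep("all", nrow(dt)) else {
      g <- annotation$taxon_group[match(dt$orf_id, annotation$orf_id)]
      g[is.na(g)] <- "unannotated"
      g
    }
    # [b, b+w) bins; pid == 100 folded into the last bin
    bin <- findInterval(dt$pid, breaks, rightmost.closed = TRUE)
    hd <- data.table::data.table(reference_group = grp, bin = bin)
    hc <- hd[, list(count = .N), by = c("reference_group", "bin")]
    hc[, "bin_start" := ifelse(bin == 0L, -Inf, breaks[pmax(bin, 1L)])]
    hc[, "bin_end" := ifelse(bin == 0L, 50, breaks[pmax(bin, 1L)] +
                               bin_width)]
    hc[, "sample" := s]
    hist_out[[s]] <- hc[, c("reference_group", "sample", "bin_start",
                            "bin_end", "count"), with = FALSE]
  }
  list(
    per_orf = as.data.frame(data.table::rbindlist(per_orf))[
      , c("orf_id", "sample", "n_reads", "mean_pid")],
    histogram = as.data.frame(data.table::rbindlist(hist_out))
  )
}

#' Conserved percent-identity shift table
#'
#' For each ORF with at least `min_reads` reads in every involved sample,
#' the identity shift per replicate barrel is `mean_pid(late) -
#' mean_pid(mid)`; an ORF is retained when all barrel deltas share one sign
#' (a zero delta breaks consistency), its overall mean identity is at least
#' `min_identity`, and it is significantly differentially expressed
#' (FDR < `alpha`). Output is sorted by `|mean_delta_pid|` descending.
#'
#' @param pid_summaries Result of [pid_histogram()] (the `per_orf` part is
#'   used), or the `per_orf` data.frame itself.
#' @param de_results DE table from [differential_expression()].
#' @param replicate_pairs Named list mapping barrel id to `c(mid, late)`
#'   sample names, e.g. `list(B1 = c("MB1", "MB2"), B3 = c("MB3", "MB4"))`.
#' @param min_identity Minimum overall mean percent identity.
#' @param alpha FDR threshold.
#' @param min_reads Per-ORF, per-sample read floor.
#' @return data.frame of retained records: `orf_id`, `log2fc`, per-barrel
#'   deltas, `mean_delta_pid`, `mean_pid`, `fdr`, plus the three filter
#'   flags; attribute `"all_orfs"` carries the unfiltered table.
#' @export
conserved_shift_table <- function(pid_summaries, de_results, replicate_pairs,
                                  min_identity = 60.0, alpha = 0.05,
                                  min_reads = 10L) {
  per_orf <- if (is.data.frame(pid_summaries)) pid_summaries else
    pid_summaries$per_orf
  samples_needed <- unlist(replicate_pairs)
  unknown <- setdiff(samples_needed, unique(per_orf$sample))
  if (length(unknown)) {
    stop("replicate_pairs names unknown sample(s): ",
         paste(unknown, collapse = ", "))
  }
  po <- data.table::as.data.table(per_orf)
  po <- po[po$sample %in% samples_needed & po$n_reads >= min_reads]
  cover <- po[, list(n_samples = .N, mean_pid = sum(mean_pid * n_reads) /
                       sum(n_reads)), by = "orf_id"]
  eligible <- cover$orf_id[cover$n_samples == length(samples_needed)]
  if (!length(eligible)) {
    empty <- data.frame(orf_id = character(), log2fc = numeric(),
                        mean_delta_pid = numeric(), mean_pid = numeric(),
                        fdr = numeric(), consistent = logical(),
                        passes_identity = logical(), significant = logical(),
                        stringsAsFactors = FALSE)
    attr(empty, "all_orfs") <- empty
    return(empty)
  }
  wide <- lapply(names(replicate_pairs), function(b) {
    pair <- replicate_pairs[[b]]
    mid <- po[po$sample == pair[1]]
    late <- po[po$sample == pair[2]]
    d <- late$mean_pid[match(eligible, late$orf_id)] -
      mid$mean_pid[match(eligible, mid$orf_id)]
    stats::setNames(data.frame(d), paste0("delta_", b))
  })
  tab <- data.frame(orf_id = eligible, do.call(cbind, wide),
                    stringsAsFactors = FALSE)
  deltas <- as.matrix(tab[, -1, drop = FALSE])
  tab$mean_delta_pid <- rowMeans(deltas)
  tab$consistent <- apply(deltas, 1, function(d) {
    all(d > 0) || all(d < 0)
  })
  tab$mean_pid <- cover$mean_pid[match(tab$orf_id, cover$orf_id)]
  tab$passes_identity <- tab$mean_pid >= min_identity
  m <- match(tab$orf_id, de_results$orf_id)
  tab$log2fc <- de_results$log2fc[m]
  tab$fdr <- de_results$fdr[m]
  tab$significant <- !is.na(tab$fdr) & tab$fdr < alpha
  out <- tab[tab$consistent & tab$passes_identity & tab$significant, ,
             drop = FALSE]
  out <- out[order(-abs(out$mean_delta_pid)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_orfs") <- tab
  out
}
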