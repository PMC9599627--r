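# File formats and coordinate conventions.
#
# Internal coordinates are 0-based half-open everywhere; the SAM and VCF
# boundaries are the single place where 1-based coordinates appear.

#' Parse CIGAR strings
#'
#' Splits CIGAR strings of the supported alphabet (M, I, D, S) into
#' per-operation tables.
#'
#' @param cigar Character vector of CIGAR strings (no `*`).
#' @return A list (one element per input) of data.frames with columns
#'   `op` and `len`.
#' @examples
#' parse_cigar("50M2I48M")[[1]]
#' @export
parse_cigar <- function(cigar) {
  lapply(cigar, function(cg) {
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDS]", cg))[[1]]
    if (length(lens) != length(ops) || length(ops) == 0L) {
      stop("malformed CIGAR: ", cg)
    }
    data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
  })
}

#' Aligned-column count of a CIGAR
#'
#' Number of alignment columns: the sum of M, I and D operation lengths.
#' Soft-clipped bases are unaligned and excluded.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector.
#' @export
cigar_aligned_columns <- function(cigar) {
  vapply(parse_cigar(cigar), function(tab) {
    sum(tab$len[tab$op %in% c("M", "I", "D")])
  }, integer(1))
}

# Read-consuming length (M, I, S) of each CIGAR; used for bounds checks.
cigar_read_length <- function(cigar) {
  vapply(parse_cigar(cigar), function(tab) {
    sum(tab$len[tab$op %in% c("M", "I", "S")])
  }, integer(1))
}

#' Read a SAM file of ORF alignments
#'
#' Parses the subset of SAM the pipeline consumes: QNAME, FLAG, RNAME, POS,
#' MAPQ, CIGAR, SEQ and the `NM:i` tag. Unmapped records (FLAG 0x4) are
#' dropped; 1-based POS is converted to the internal 0-based convention;
#' secondary (0x100) and supplementary (0x800) records are flagged
#' non-primary.
#'
#' @param path Path to a SAM text file.
#' @param on_missing_nm Policy when a mapped record lacks an `NM:i` tag:
#'   `"fail"` (default) stops naming the record, `"skip"` drops it.
#' @return A `data.table` with columns `read_id`, `flag`, `orf_id`, `pos`
#'   (0-based), `mapq`, `cigar`, `seq`, `nm`, `is_primary`.
#' @export
read_sam <- function(path, on_missing_nm = c("fail", "skip")) {
  on_missing_nm <- match.arg(on_missing_nm)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(data.table::data.table(
      read_id = character(), flag = integer(), orf_id = character(),
      pos = integer(), mapq = integer(), cigar = character(),
      seq = character(), nm = integer(), is_primary = logical()
    ))
  }
  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:10)
  aln <- data.table::data.table(
    read_id = fields[[1]],
    flag = as.integer(fields[[2]]),
    orf_id = fields[[3]],
    pos = as.integer(fields[[4]]) - 1L,
    mapq = as.integer(fields[[5]]),
    cigar = fields[[6]],
    seq = fields[[10]]
  )
  nm <- suppressWarnings(as.integer(sub(".*\tNM:i:([0-9]+).*", "\\1",
                                        paste0("\t", lines))))
  aln[, "nm" := nm]
  aln <- aln[bitwAnd(aln$flag, 4L) == 0L]
  missing_nm <- is.na(aln$nm)
  if (any(missing_nm)) {
    if (on_missing_nm == "fail") {
      stop("mapped record without NM tag: ", aln$read_id[which(missing_nm)[1]])
    }
    aln <- aln[!missing_nm]
  }
  aln[, "is_primary" := bitwAnd(aln$flag, 0x900L) == 0L]
  aln[]
}

#' Write alignments as SAM
#'
#' Inverse of [read_sam()] for the supported field subset; emits `@SQ`
#' header lines and converts the internal 0-based `pos` back to 1-based.
#'
#' @param aln Alignment table as returned by [read_sam()].
#' @param ref_lengths Named integer vector of reference ORF lengths.
#' @param path Output path.
#' @export
write_sam <- function(aln, ref_lengths, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths))
  )
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
    aln$read_id, aln$flag, aln$orf_id, aln$pos + 1L, aln$mapq,
    aln$cigar, aln$seq, aln$nm
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write FASTA
#'
#' Thin wrappers over Biostrings returning plain named character vectors;
#' the writer wraps sequence lines at 60 columns.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @param seqs Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

# FASTQ writer with constant placeholder qualities (the simulator does not
# model base quality); reader returns the sequences only.
write_fastq <- function(seqs, path) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", names(seqs)), unname(seqs), "+", qual))
  writeLines(lines, path)
  invisible(path)
}

read_fastq <- function(path) {
  lines <- readLines(path)
  ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  stats::setNames(lines[seq(2L, length(lines), by = 4L)], ids)
}

#' Default bloom sample sheet
#'
#' The eight-sample design of the nitrogen and iron depletion experiments:
#' barrels B1/B3 (nitrogen) and B2/B4 (iron), each sampled mid bloom
#' (nutrient replete) and late bloom. MB6 (the late sample of the unchelated
#' iron-replete barrel) is excluded from differential expression by default.
#'
#' @return data.frame with columns `sample`, `experiment`, `barrel`,
#'   `stage`, `condition`, `include_in_de`.
#' @export
default_sample_sheet <- function() {
  data.frame(
    sample = paste0("MB", 1:8),
    experiment = rep(c("N", "Fe"), each = 4),
    barrel = c("B1", "B1", "B3", "B3", "B2", "B2", "B4", "B4"),
    stage = rep(c("mid", "late"), 4),
    condition = c("replete", "depleted", "replete", "depleted",
                  "replete", "replete", "replete", "depleted"),
    include_in_de = c(rep(TRUE, 5), FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

validate_sample_sheet <- function(sheet, samples = NULL) {
  req <- c("sample", "experiment", "barrel", "stage", "condition",
           "include_in_de")
  missing <- setdiff(req, names(sheet))
  if (length(missing)) stop("sample sheet lacks columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(sheet$sample)) stop("duplicate sample names in sheet")
  if (!all(sheet$condition %in% c("replete", "depleted"))) {
    stop("condition must be 'replete' or 'depleted'")
  }
  if (!all(sheet$stage %in% c("mid", "late"))) {
    stop("stage must be 'mid' or 'late'")
  }
  if (!is.null(samples)) {
    unknown <- setdiff(samples, sheet$sample)
    if (length(unknown)) stop("samples absent from sheet: ",
                              paste(unknown, collapse = ", "))
  }
  invisible(sheet)
}

#' Read/write the ORF annotation table
#'
#' Tab-separated with columns `orf_id`, `taxon_group`, `genus`, `label`
#' (gene family / functional label).
#'
#' @param path File path.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("orf_id", "taxon_group", "genus", "label")
  if (!all(req %in% names(ann))) {
    stop("annotation lacks columns: ",
         paste(setdiff(req, names(ann)), collapse = ", "))
  }
  ann
}

#' @param annotation Annotation data.frame.
#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write SNV calls as VCF 4.2
#'
#' One record per (ORF, position, alternate allele); CHROM is the ORF id and
#' POS the 1-based position within the ORF. INFO carries the coding effect
#' (`EFF=SYN|NONSYN|NA`) and the codon change; per-sample fields are
#' `DP:AD:AF` with AD as `ref,alt` depths.
#'
#' @param calls SNV call table from [call_snvs()] (long format, one row per
#'   site x sample).
#' @param references Named character vector of ORF sequences; used to verify
#'   the REF allele.
#' @param path Output path.
#' @export
write_vcf <- function(calls, references, path) {
  samples <- sort(unique(calls$sample))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Coding effect\">",
    "##INFO=<ID=CODON,Number=1,Type=String,Description=\"Codon change\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=2,Type=Integer,Description=\"Ref,alt depths\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Alt frequency\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  if (nrow(calls) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  calls <- data.table::as.data.table(calls)
  ref_base <- substr(references[calls$orf_id], calls$pos, calls$pos)
  bad <- which(ref_base != calls$ref)
  if (length(bad)) {
    stop("REF allele mismatch with reference sequence at ",
         calls$orf_id[bad[1]], ":", calls$pos[bad[1]])
  }
  key <- calls[, list(
    eff = effect[1],
    codon = paste0(codon_ref[1], ">", codon_alt[1])
  ), by = c("orf_id", "pos", "ref", "alt")]
  fmt <- calls[, list(gt = sprintf("%d:%d,%d:%.4g", depth, depth - alt_count,
                                   alt_count, af)),
               by = c("orf_id", "pos", "ref", "alt", "sample")]
  recs <- vapply(seq_len(nrow(key)), function(i) {
    k <- key[i]
    gts <- vapply(samples, function(s) {
      g <- fmt[fmt$orf_id == k$orf_id & fmt$pos == k$pos & fmt$alt == k$alt &
                 fmt$sample == s, ]
      if (nrow(g)) g$gt[1] else "./.:.,.:."
    }, character(1))
    paste(c(k$orf_id, k$pos, ".", k$ref, k$alt, ".", "PASS",
            sprintf("EFF=%s;CODON=%s", k$eff, k$codon), "DP:AD:AF", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()]
#'
#' Minimal reader for the subset this package emits; returns the long-format
#' call table (one row per site x sample with data).
#'
#' @param path VCF path.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  chrom_line <- lines[startsWith(lines, "#CHROM")]
  samples <- strsplit(chrom_line, "\t")[[1]][-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  out <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    info <- f[8]
    eff <- sub(".*EFF=([^;]+).*", "\\1", info)
    for (j in seq_along(samples)) {
      gt <- f[9 + j]
      if (startsWith(gt, "./.")) next
      parts <- strsplit(gt, ":")[[1]]
      ad <- as.integer(strsplit(parts[2], ",")[[1]])
      out[[length(out) + 1L]] <- data.frame(
        orf_id = f[1], pos = as.integer(f[2]), ref = f[4], alt = f[5],
        sample = samples[j], depth = as.integer(parts[1]), alt_count = ad[2],
        af = as.numeric(parts[3]), effect = eff, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(orf_id = character(), pos = integer(),
                      ref = character(), alt = character(),
                      sample = character(), depth = integer(),
                      alt_count = integer(), af = numeric(),
                      effect = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
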