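# Nutrient-status expression indices. Marker pairs with opposing responses
# to limitation give within-taxon expression ratios usable as status
# indicators: NRT2 (nitrate transporter, up under N depletion) over GSII
# (glutamine synthetase II, up in the presence of nitrate) for nitrogen,
# and the summed iron-starvation-induced proteins ISIP1+ISIP2+ISIP3 over
# thiC (thiamine biosynthesis, up under Fe repletion) for iron, plus the
# two comparison ratios flavodoxin:ferredoxin and ISIP2:ferritin.

MARKER_INDEX_SETS <- list(
  N_index = list(numerator = "NRT2", denominator = "GSII"),
  Fe_index = list(numerator = c("ISIP1", "ISIP2", "ISIP3"),
                  denominator = "thiC"),
  flav_fd = list(numerator = "flavodoxin", denominator = "ferredoxin"),
  isip2_ferritin = list(numerator = "ISIP2", denominator = "ferritin")
)

# Restrict a count matrix to a scope (taxon group or genus) and return
# within-scope TMM-normalized CPM.
scope_cpm <- function(x, scope_type = c("taxon_group", "genus"), scope) {
  scope_type <- match.arg(scope_type)
  ann <- x$annotation
  if (is.null(ann)) stop("biomarker scopes need annotation")
  ids <- ann$orf_id[ann[[scope_type]] == scope]
  counts <- x$counts[rownames(x$counts) %in% ids, , drop = FALSE]
  if (nrow(counts) == 0L) stop("no ORFs in scope ", scope)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("scope has a zero-count sample")
  f <- if (ncol(counts) >= 2L) {
    tmm_factors(count_matrix(counts, lib_sizes = lib))
  } else stats::setNames(1, colnames(counts))
  sweep(counts, 2, lib * f / 1e6, "/")
}

#' Summed marker expression within a scope
#'
#' Within-scope TMM-adjusted CPM summed over ORFs whose functional label is
#' in `labels`; normalization uses group-wise (within-scope) library sizes,
#' so taxon abundance changes cancel.
#'
#' @param x A `count_matrix` with annotation.
#' @param scope Taxon group or genus name.
#' @param labels Character vector of functional labels.
#' @param scope_type `"taxon_group"` or `"genus"`.
#' @return Named numeric vector: expression per sample (0 with a warning
#'   when no ORF carries a label).
#' @export
marker_expression <- function(x, scope, labels,
                              scope_type = c("taxon_group", "genus")) {
  scope_type <- match.arg(scope_type)
  cpm <- scope_cpm(x, scope_type, scope)
  if (length(labels) == 0L) {
    return(stats::setNames(rep(0, ncol(cpm)), colnames(cpm)))
  }
  ann <- x$annotation
  ids <- ann$orf_id[ann[[scope_type]] == scope & ann$label %in% labels]
  ids <- intersect(ids, rownames(cpm))
  if (length(ids) == 0L) {
    warning("no ORFs labeled {", paste(labels, collapse = ","),
            "} in scope ", scope)
    return(stats::setNames(rep(0, ncol(cpm)), colnames(cpm)))
  }
  colSums(cpm[ids, , drop = FALSE])
}

#' Nutrient-status indices
#'
#' Computes `log2((numerator + c) / (denominator + c))` per sample for the
#' four marker ratios (`N_index` = NRT2:GSII, `Fe_index` = ISIP1+2+3:thiC,
#' `flav_fd`, `isip2_ferritin`) within a taxon-group or genus scope. The
#' pseudocount `c` (in CPM units) bounds the index when a marker is
#' undetected. With `use_nr = TRUE` the N-index numerator also accepts
#' nitrate reductase (`NR`) labels.
#'
#' @param x A `count_matrix` with annotation.
#' @param scope Scope name.
#' @param scope_type `"taxon_group"` or `"genus"`.
#' @param pseudocount Pseudocount in CPM.
#' @param indices Which indices to compute.
#' @param use_nr Accept `NR` as an additional N-index numerator label.
#' @param label_map Optional named list rebinding canonical marker names to
#'   annotation vocabularies, e.g. `list(NRT2 = c("NRT2", "NRT2.1"))`.
#' @return data.frame: `sample`, `scope`, `index_name`, `numerator_expr`,
#'   `denominator_expr`, `log2_ratio`, `n_orfs_numerator`,
#'   `n_orfs_denominator`.
#' @export
nutrient_indices <- function(x, scope, scope_type = c("taxon_group", "genus"),
                             pseudocount = 1.0,
                             indices = names(MARKER_INDEX_SETS),
                             use_nr = FALSE, label_map = NULL) {
  scope_type <- match.arg(scope_type)
  resolve <- function(labels) {
    if (is.null(label_map)) return(labels)
    unlist(lapply(labels, function(l) {
      if (l %in% names(label_map)) label_map[[l]] else l
    }))
  }
  ann <- x$annotation
  out <- lapply(indices, function(nm) {
    spec <- MARKER_INDEX_SETS[[nm]]
    num_labels <- spec$numerator
    if (nm == "N_index" && use_nr) num_labels <- c(num_labels, "NR")
    num_labels <- resolve(num_labels)
    den_labels <- resolve(spec$denominator)
    num <- marker_expression(x, scope, num_labels, scope_type)
    den <- marker_expression(x, scope, den_labels, scope_type)
    n_num <- sum(ann[[scope_type]] == scope & ann$label %in% num_labels)
    n_den <- sum(ann[[scope_type]] == scope & ann$label %in% den_labels)
    data.frame(sample = names(num), scope = scope, index_name = nm,
               numerator_expr = unname(num), denominator_expr = unname(den),
               log2_ratio = log2((unname(num) + pseudocount) /
                                   (unname(den) + pseudocount)),
               n_orfs_numerator = n_num, n_orfs_denominator = n_den,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Relative nutrient status between two samples
#'
#' Reports the index difference (b minus a) per scope and index with a
#' qualitative call: `more_depleted` when the index rose by more than the
#' margin `delta`, `more_replete` when it fell by more, otherwise
#' `indistinguishable`. Only relative calls are made --- the indices carry
#' no absolute replete/deplete threshold.
#'
#' @param indices Index table from [nutrient_indices()] (may cover many
#'   samples).
#' @param sample_a,sample_b Sample names; the call describes `sample_b`
#'   relative to `sample_a`.
#' @param delta Indistinguishability margin in log2 units.
#' @return data.frame: `scope`, `index_name`, `index_a`, `index_b`,
#'   `difference`, `call`.
#' @export
relative_status <- function(indices, sample_a, sample_b, delta = 0.5) {
  a <- indices[indices$sample == sample_a, , drop = FALSE]
  b <- indices[indices$sample == sample_b, , drop = FALSE]
  key <- merge(a[, c("scope", "index_name", "log2_ratio")],
               b[, c("scope", "index_name", "log2_ratio")],
               by = c("scope", "index_name"), suffixes = c("_a", "_b"))
  if (nrow(key) == 0L) {
    return(data.frame(scope = character(), index_name = character(),
                      index_a = numeric(), index_b = numeric(),
                      difference = numeric(), call = character(),
                      stringsAsFactors = FALSE))
  }
  diff <- key$log2_ratio_b - key$log2_ratio_a
  call <- ifelse(diff > delta, "more_depleted",
                 ifelse(diff < -delta, "more_replete", "indistinguishable"))
  data.frame(scope = key$scope, index_name = key$index_name,
             index_a = key$log2_ratio_a, index_b = key$log2_ratio_b,
             difference = diff, call = call, stringsAsFactors = FALSE)
}
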