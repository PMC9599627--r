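# Count matrices and two-group differential expression under the negative
# binomial model: TMM between-sample normalization, conditional-likelihood
# (qCML-style) dispersion estimation on library-size-equalized pseudo-counts,
# the two-group NB exact test, and Benjamini-Hochberg FDR.

#' Build a count matrix from alignments
#'
#' Each primary-aligned read contributes one count to its ORF. A read with
#' several primary records (e.g. mapped against multiple references) is
#' counted once, on the record with the smallest edit distance; NM ties are
#' broken by the lexicographically smallest ORF id, so counting is
#' deterministic.
#'
#' @param alignments Either one alignment table ([read_sam()] layout) for a
#'   single sample, or a named list of them (one per sample).
#' @param annotation ORF annotation data.frame (`orf_id`, `taxon_group`,
#'   `genus`, `label`); ORFs absent from it are still counted and flagged.
#' @param sample_sheet Optional sample sheet; defaults to
#'   [default_sample_sheet()] restricted to the supplied samples.
#' @return A `count_matrix`: list with `counts` (ORF x sample integer
#'   matrix), `lib_sizes`, `samples` (sheet rows), `annotation`.
#' @export
count_reads <- function(alignments, annotation, sample_sheet = NULL) {
  if (data.table::is.data.table(alignments) || is.data.frame(alignments)) {
    alignments <- list(sample = alignments)
  }
  per_sample <- lapply(alignments, function(aln) {
    aln <- data.table::as.data.table(aln)
    aln <- aln[aln$is_primary]
    if (nrow(aln) == 0L) return(stats::setNames(integer(), character()))
    data.table::setorderv(aln, c("read_id", "nm", "orf_id"))
    aln <- aln[!duplicated(aln$read_id)]
    tab <- aln[, list(n = .N), by = "orf_id"]
    stats::setNames(tab$n, tab$orf_id)
  })
  orf_ids <- sort(unique(c(annotation$orf_id,
                           unlist(lapply(per_sample, names)))))
  counts <- vapply(per_sample, function(v) {
    out <- integer(length(orf_ids))
    out[match(names(v), orf_ids)] <- as.integer(v)
    out
  }, integer(length(orf_ids)))
  counts <- matrix(counts, nrow = length(orf_ids),
                   dimnames = list(orf_ids, names(per_sample)))
  unannotated <- setdiff(orf_ids, annotation$orf_id)
  if (length(unannotated)) {
    warning(length(unannotated), " counted ORF(s) missing from annotation")
  }
  count_matrix(counts, annotation = annotation, sample_sheet = sample_sheet)
}

#' Construct a count matrix container
#'
#' @param counts Non-negative integer matrix, ORFs x samples.
#' @param annotation ORF annotation data.frame.
#' @param sample_sheet Sample sheet; defaults to [default_sample_sheet()]
#'   rows matching the column names.
#' @param lib_sizes Optional explicit library sizes (defaults to column
#'   sums; group-wise analyses override them with within-group sums).
#' @export
count_matrix <- function(counts, annotation = NULL, sample_sheet = NULL,
                         lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (is.null(sample_sheet)) {
    sheet <- default_sample_sheet()
    sample_sheet <- sheet[sheet$sample %in% colnames(counts), , drop = FALSE]
    if (nrow(sample_sheet) == 0L) {
      sample_sheet <- data.frame(sample = colnames(counts),
                                 experiment = NA, barrel = NA, stage = NA,
                                 condition = NA, include_in_de = TRUE,
                                 stringsAsFactors = FALSE)
    }
  }
  structure(list(counts = counts, lib_sizes = lib_sizes,
                 samples = sample_sheet, annotation = annotation),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "ORFs x", ncol(x$counts),
      "samples\n")
  cat("library sizes:", paste(x$lib_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample scaling factors. The reference
#' column is the sample whose 75th count-fraction percentile is closest to
#' the mean across samples. For each sample, log ratios M and average log
#' abundances A are computed over ORFs positive in both sample and
#' reference; the most extreme `trim_m` of M and `trim_a` of A (each side)
#' are trimmed, and the factor is two to the precision-weighted mean M
#' (binomial asymptotic variance weights). Factors are rescaled to geometric
#' mean one.
#'
#' @param x A `count_matrix` or plain counts matrix.
#' @param trim_m,trim_a Two-sided trim fractions for M and A.
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(x, trim_m = 0.30, trim_a = 0.05) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  lib <- if (inherits(x, "count_matrix")) x$lib_sizes else colSums(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  if (any(lib == 0)) stop("sample with zero library size")
  f75 <- apply(counts, 2, function(col) stats::quantile(col / sum(col), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  factors <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  stats::setNames(factors, colnames(counts))
}

tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  p_o <- obs / n_obs; p_r <- ref / n_ref
  m <- log2(p_o / p_r)
  a <- 0.5 * log2(p_o * p_r)
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}

# Quantile-to-quantile NB count adjustment: maps a count observed at mean
# input_mean to the equivalent quantile at output_mean, averaging gamma and
# normal approximations (upper-tail formulation for counts above the mean).
q2q_nbinom <- function(x, input_mean, output_mean, dispersion) {
  eps <- 1e-10
  x <- pmax(x, 0)
  input_mean <- pmax(input_mean, eps)
  output_mean <- pmax(output_mean, eps)
  ri <- 1 + dispersion * input_mean
  ro <- 1 + dispersion * output_mean
  vi <- input_mean * ri
  vo <- output_mean * ro
  q_norm <- output_mean + (x - input_mean) / sqrt(vi) * sqrt(vo)
  shape_i <- input_mean^2 / vi
  shape_o <- output_mean^2 / vo
  upper <- x >= input_mean
  p <- numeric(length(x))
  q_gam <- numeric(length(x))
  p[upper] <- stats::pgamma(x[upper], shape = shape_i[upper],
                            scale = (vi / input_mean)[upper],
                            lower.tail = FALSE)
  q_gam[upper] <- stats::qgamma(p[upper], shape = shape_o[upper],
                                scale = (vo / output_mean)[upper],
                                lower.tail = FALSE)
  p[!upper] <- stats::pgamma(x[!upper], shape = shape_i[!upper],
                             scale = (vi / input_mean)[!upper])
  q_gam[!upper] <- stats::qgamma(p[!upper], shape = shape_o[!upper],
                                 scale = (vo / output_mean)[!upper])
  pmax((q_norm + q_gam) / 2, 0)
}

# Pseudo-counts at a common library size, given a dispersion: per-gene rates
# are estimated per group and counts are quantile-adjusted from their
# expected scale to the common scale.
equalize_lib_sizes <- function(counts, groups, eff_lib, dispersion) {
  common <- exp(mean(log(eff_lib)))
  pseudo <- counts
  for (g in unique(groups)) {
    sel <- groups == g
    rate <- rowSums(counts[, sel, drop = FALSE]) / sum(eff_lib[sel])
    for (j in which(sel)) {
      pseudo[, j] <- q2q_nbinom(counts[, j], rate * eff_lib[j],
                                rate * common, dispersion)
    }
  }
  list(pseudo = pseudo, common_lib = common)
}

# Summed NB conditional log-likelihood (conditioning on group totals) at
# equalized library sizes; y is the pseudo-count matrix, rows = genes.
cond_loglik <- function(y, groups, phi) {
  if (phi <= 0) phi <- 1e-8
  r <- 1 / phi
  ll <- 0
  for (g in unique(groups)) {
    sel <- groups == g
    n <- sum(sel)
    if (n < 2L) next
    yg <- y[, sel, drop = FALSE]
    z <- rowSums(yg)
    ll <- ll + sum(rowSums(lgamma(yg + r)) + lgamma(n * r) -
                     lgamma(z + n * r) - n * lgamma(r))
  }
  ll
}

#' Estimate the common NB dispersion by conditional likelihood
#'
#' Counts are quantile-adjusted to equalized effective library sizes, and
#' the common dispersion maximizes the conditional log-likelihood given
#' group totals, over a log-spaced grid on `[1e-6, 10]` refined by
#' golden-section search. Pseudo-count computation and maximization are
#' iterated until the estimate stabilizes. Optional tagwise estimates
#' shrink per-gene likelihoods toward the common value with a prior weight
#' equivalent to `prior_df` degrees of freedom.
#'
#' @param x A `count_matrix` or counts matrix.
#' @param groups Factor/vector of group membership per sample.
#' @param eff_lib Effective library sizes (library size x TMM factor);
#'   defaults to TMM-adjusted sizes.
#' @param phi Optional fixed dispersion: returned unchanged (bypass).
#' @param tagwise Also compute per-gene shrunken dispersions.
#' @param prior_df Prior degrees of freedom for tagwise shrinkage.
#' @return List `phi_common`, `phi_tagwise` (or NULL), `method`.
#' @export
estimate_common_dispersion <- function(x, groups, eff_lib = NULL, phi = NULL,
                                       tagwise = FALSE, prior_df = 10) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (!is.null(phi)) {
    return(list(phi_common = phi, phi_tagwise = NULL, method = "supplied"))
  }
  groups <- as.character(groups)
  if (max(table(groups)) < 2L) {
    stop("no group has >= 2 replicates; supply phi explicitly")
  }
  if (is.null(eff_lib)) {
    lib <- colSums(counts)
    eff_lib <- lib * tmm_factors(counts)
  }
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  phi_hat <- 0.1
  for (iter in 1:2) {
    eq <- equalize_lib_sizes(counts, groups, eff_lib, phi_hat)
    obj <- function(log_phi) cond_loglik(eq$pseudo, groups, exp(log_phi))
    grid <- log(exp(seq(log(1e-6), log(10), length.out = 25)))
    vals <- vapply(grid, obj, numeric(1))
    i <- which.max(vals)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    phi_hat <- exp(golden_section(obj, lo, hi, tol = 1e-4))
  }
  out <- list(phi_common = phi_hat, phi_tagwise = NULL, method = "qCML")
  if (tagwise) {
    eq <- equalize_lib_sizes(counts, groups, eff_lib, phi_hat)
    n_genes <- nrow(eq$pseudo)
    # per-gene CL plus prior_df "pseudo-genes" worth of the average CL
    avg_cl <- function(phi) cond_loglik(eq$pseudo, groups, phi) / n_genes
    grid_phi <- exp(seq(log(1e-6), log(10), length.out = 41))
    avg_vals <- vapply(grid_phi, avg_cl, numeric(1))
    resid_df <- length(groups) - length(unique(groups))
    w <- prior_df / max(resid_df, 1)
    phi_tag <- vapply(seq_len(n_genes), function(i) {
      yi <- eq$pseudo[i, , drop = FALSE]
      vals <- vapply(seq_along(grid_phi), function(k) {
        cond_loglik(yi, groups, grid_phi[k]) + w * avg_vals[k]
      }, numeric(1))
      grid_phi[which.max(vals)]
    }, numeric(1))
    names(phi_tag) <- rownames(counts)
    out$phi_tagwise <- phi_tag
    out$method <- "qCML-tagwise"
  }
  out
}

golden_section <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c); fd <- f(d)
  while (abs(b - a) > tol) {
    if (fc > fd) {
      b <- d; d <- c; fd <- fc
      c <- b - gr * (b - a); fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + gr * (b - a); fd <- f(d)
    }
  }
  (a + b) / 2
}

#' Two-group exact test under the negative binomial
#'
#' Conditions on the total of the pooled (library-size-equalized) group
#' counts. With per-sample dispersion `phi` and `n_a`, `n_b` samples per
#' group, the group sums are NB with sizes `n_a/phi`, `n_b/phi`, and the
#' conditional distribution of the split is negative hypergeometric
#' (independent of the mean). The two-sided p-value sums the probabilities
#' of all splits no more probable than the observed one; `phi = 0`
#' degenerates to the exact binomial test. A split counts as "no more
#' probable" up to a relative tolerance of 1e-10, so exact symmetry ties are
#' honored.
#'
#' @param a,b Pooled group counts (non-negative scalars).
#' @param phi NB dispersion (per sample).
#' @param n_a,n_b Number of samples pooled in each group.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
exact_test_nb <- function(a, b, phi, n_a = 1L, n_b = 1L) {
  if (a < 0 || b < 0) stop("negative counts")
  t <- round(a + b)
  a <- round(a)
  if (t == 0) return(1)
  k <- 0:t
  if (phi <= 0) {
    logp <- stats::dbinom(k, t, n_a / (n_a + n_b), log = TRUE)
  } else {
    ra <- n_a / phi; rb <- n_b / phi
    logp <- lgamma(k + ra) - lgamma(k + 1) - lgamma(ra) +
      lgamma(t - k + rb) - lgamma(t - k + 1) - lgamma(rb)
    logp <- logp - log_sum_exp(logp)
  }
  obs <- logp[a + 1L]
  p <- sum(exp(logp[logp <= obs + 1e-10]))
  min(p, 1)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} min(1, p_(j) * n / j)`,
#' returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (same length/order).
#' @export
bh_adjust <- function(p) {
  n <- length(p)
  if (n == 0L) return(numeric())
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Two-group differential expression (NB exact test)
#'
#' Runs the full classic pipeline on one contrast: minimum-count filter,
#' TMM normalization, qCML common dispersion (unless supplied), library-size
#' equalization, per-ORF exact test and BH FDR. The log2 fold change is
#' oriented depleted over replete: positive means upregulated under
#' nutrient limitation.
#'
#' Modes: `"global"` tests ORFs against full library sizes; `"groupwise"`
#' restricts to one taxon group with library sizes recomputed as within-
#' group sums (normalizing away the group's abundance change, isolating
#' physiology); `"taxon_proportion"` first aggregates counts to taxon group
#' x sample and tests group proportions against full library sizes.
#'
#' @param x A `count_matrix` with annotation (for the taxon modes).
#' @param contrast `"N"` or `"Fe"`, resolved through the sample sheet
#'   (depleted vs replete samples with `include_in_de`), or a list
#'   `list(depleted = c(...), replete = c(...))` of sample names.
#' @param mode `"global"`, `"groupwise"` or `"taxon_proportion"`.
#' @param taxon_group For `mode = "groupwise"`: the group to test (if
#'   omitted, all groups are tested and results concatenated).
#' @param phi Optional fixed dispersion.
#' @param min_total Minimum total count across the contrast for an ORF to be
#'   tested (default 5).
#' @param alpha Significance threshold recorded in the `significant` flag.
#' @return data.frame: `orf_id`, `taxon_group` (groupwise modes), `log2fc`,
#'   `mean_expr` (average log2 CPM), `p_value`, `fdr`, `significant`,
#'   `contrast`, `mode`.
#' @export
differential_expression <- function(x, contrast, mode = c(
  "global", "groupwise", "taxon_proportion"), taxon_group = NULL,
  phi = NULL, min_total = 5, alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "count_matrix"))
  sel <- resolve_contrast(x, contrast)
  contrast_name <- if (is.character(contrast)) contrast else "custom"

  if (mode == "groupwise" && is.null(taxon_group)) {
    groups <- unique(x$annotation$taxon_group)
    out <- lapply(groups, function(g) {
      differential_expression(x, contrast, mode = "groupwise",
                              taxon_group = g, phi = phi,
                              min_total = min_total, alpha = alpha)
    })
    return(do.call(rbind, out))
  }

  counts <- x$counts[, c(sel$depleted, sel$replete), drop = FALSE]
  ann <- x$annotation
  if (mode == "taxon_proportion") {
    if (is.null(ann)) stop("taxon_proportion mode needs annotation")
    grp <- ann$taxon_group[match(rownames(counts), ann$orf_id)]
    grp[is.na(grp)] <- "unannotated"
    counts <- rowsum(counts, grp)
    lib <- colSums(x$counts[, colnames(counts), drop = FALSE])
    tax_col <- rownames(counts)
  } else if (mode == "groupwise") {
    if (is.null(ann)) stop("groupwise mode needs annotation")
    ids <- ann$orf_id[ann$taxon_group == taxon_group]
    counts <- counts[rownames(counts) %in% ids, , drop = FALSE]
    lib <- colSums(counts)
    tax_col <- rep(taxon_group, nrow(counts))
  } else {
    lib <- x$lib_sizes[colnames(counts)]
    tax_col <- if (!is.null(ann)) {
      ann$taxon_group[match(rownames(counts), ann$orf_id)]
    } else rep(NA_character_, nrow(counts))
  }
  if (any(lib == 0)) stop("sample with zero library size in contrast")

  groups <- c(rep("depleted", length(sel$depleted)),
              rep("replete", length(sel$replete)))
  tested <- rowSums(counts) >= min_total
  y <- counts[tested, , drop = FALSE]
  tax_col <- tax_col[tested]
  if (nrow(y) == 0L) {
    return(data.frame(orf_id = character(), taxon_group = character(),
                      log2fc = numeric(), mean_expr = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      significant = logical(), contrast = character(),
                      mode = character(), stringsAsFactors = FALSE))
  }
  f <- tmm_factors(count_matrix(y, lib_sizes = lib))
  eff_lib <- lib * f
  disp <- estimate_common_dispersion(y, groups, eff_lib = eff_lib, phi = phi)
  phi_use <- disp$phi_common
  eq <- equalize_lib_sizes(y, groups, eff_lib, phi_use)
  dep <- groups == "depleted"
  a <- rowSums(eq$pseudo[, dep, drop = FALSE])
  b <- rowSums(eq$pseudo[, !dep, drop = FALSE])
  n_a <- sum(dep); n_b <- sum(!dep)
  p <- vapply(seq_along(a), function(i) {
    exact_test_nb(a[i], b[i], phi_use, n_a, n_b)
  }, numeric(1))
  fdr <- bh_adjust(p)
  # fold change from normalized fractions with a half-count pseudo-fraction
  frac_a <- a / (n_a * eq$common_lib)
  frac_b <- b / (n_b * eq$common_lib)
  pseudo <- 0.5 / eq$common_lib
  log2fc <- log2((frac_a + pseudo) / (frac_b + pseudo))
  cpm <- sweep(y, 2, eff_lib / 1e6, "/")
  mean_expr <- rowMeans(log2(cpm + 0.5))
  data.frame(
    orf_id = rownames(y), taxon_group = tax_col, log2fc = log2fc,
    mean_expr = mean_expr, p_value = p, fdr = fdr,
    significant = fdr < alpha, contrast = contrast_name, mode = mode,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# Resolve a contrast name (N / Fe) or explicit sample list against the
# sample sheet; errors if either side is empty or names unknown samples.
resolve_contrast <- function(x, contrast) {
  if (is.list(contrast)) {
    unknown <- setdiff(c(contrast$depleted, contrast$replete),
                       colnames(x$counts))
    if (length(unknown)) stop("unknown sample(s) in contrast: ",
                              paste(unknown, collapse = ", "))
    sel <- contrast
  } else {
    sheet <- x$samples
    rows <- sheet[sheet$experiment %in% contrast & sheet$include_in_de &
                    sheet$sample %in% colnames(x$counts), , drop = FALSE]
    sel <- list(depleted = rows$sample[rows$condition == "depleted"],
                replete = rows$sample[rows$condition == "replete"])
  }
  if (length(sel$depleted) == 0L || length(sel$replete) == 0L) {
    stop("contrast has an empty depleted or replete sample set")
  }
  sel
}
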