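# End-to-end orchestration: simulate -> count -> de -> pidshift -> snv ->
# cluster -> biomarker -> report, from a single validated config, with a
# run manifest (config hash, per-file checksums, seeds) for provenance.
# All intermediates are plain text so every stage is independently
# inspectable.

PIPELINE_STAGES <- c("simulate", "count", "de", "pidshift", "snv",
                     "cluster", "biomarker", "report")

#' Default pipeline configuration
#'
#' The demo world: eight barrel samples (N experiment barrels B1/B3, Fe
#' experiment barrels B2/B4; MB6 excluded from DE), 2,000 ORFs across four
#' taxon groups, 25,000 reads per sample, and a handful of planted sweep
#' SNVs. Any part can be overridden by the supplied list.
#'
#' @param seed Root seed.
#' @param overrides Named list merged over the defaults (one level deep).
#' @return Config list.
#' @export
default_pipeline_config <- function(seed = 1L, overrides = list()) {
  cfg <- list(
    seed = as.integer(seed),
    sim = list(n_taxon_groups = 4L, orfs_per_group = 500L,
               orf_length = 300L, library_size = 25000L,
               dispersion = 0.1, de_fraction = 0.1, de_log2fc = 3,
               subpop_divergence = 0.05,
               subpop_mix = c(mid = 0.8, late = 0.2),
               error_rate = 0.001, read_length = 100L,
               n_planted_snvs = 10L),
    de = list(min_total = 5, alpha = 0.05),
    pidshift = list(min_identity = 60, alpha = 0.05, min_reads = 10L),
    snv = list(min_depth = 4L, min_alt = 2L, min_af = 0.05,
               sweep_hi = 0.9, sweep_lo = 0.5),
    cluster = list(k = 4L, min_shared = 3L, inflation = 1.5,
                   min_members = 10L, min_abs_lfc = 2.5),
    biomarker = list(pseudocount = 1.0, delta = 0.5)
  )
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  cfg
}

validation_error <- function(...) {
  stop(structure(class = c("bloomshift_validation_error", "error",
                           "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Schema check; runs before any stage.
validate_config <- function(config) {
  req <- c("seed", "sim", "de", "pidshift", "snv", "cluster", "biomarker")
  missing <- setdiff(req, names(config))
  if (length(missing)) {
    validation_error("config lacks section(s): ",
                     paste(missing, collapse = ", "))
  }
  if (!is.numeric(config$seed)) validation_error("seed must be numeric")
  samples <- config$sim$samples
  if (!is.null(samples)) {
    validate_sample_sheet(samples)
  } else {
    samples <- default_sample_sheet()
  }
  for (cn in config$de$contrasts %||% c("N", "Fe")) {
    if (is.list(cn)) {
      unknown <- setdiff(unlist(cn), samples$sample)
      if (length(unknown)) {
        validation_error("contrast names unknown sample(s): ",
                         paste(unknown, collapse = ", "))
      }
    }
  }
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full pipeline
#'
#' Executes the requested stages in dependency order against `out_dir`,
#' writing plain-text outputs per stage, a JSON report aggregating DE
#' counts per taxon and condition, the shift table, SNV densities, retained
#' clusters and biomarker indices, and a run manifest with a config hash
#' and per-file MD5 checksums. Stage failures are recorded in the manifest
#' before the error propagates.
#'
#' @param config Config list (see [default_pipeline_config()]) or path to a
#'   JSON file.
#' @param out_dir Output directory.
#' @param stages Subset of stages to run (later stages read earlier
#'   stages' in-memory results, so run prefixes of the stage list).
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = PIPELINE_STAGES) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(config$sim$subpop_mix)) {
      config$sim$subpop_mix <- unlist(config$sim$subpop_mix)
    }
  }
  validate_config(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "bloomshift", version = as.character(
      utils::packageVersion("bloomshift")),
    config_hash = config_hash(config), seed = config$seed,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stages = list()
  )
  state <- new.env(parent = emptyenv())
  on.exit(write_manifest(manifest, state, out_dir))

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible())
    t0 <- Sys.time()
    result <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      stop(e)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      2))
    result
  }

  run_stage("simulate", function() {
    sim_args <- config$sim
    n_snv <- sim_args$n_planted_snvs %||% 0L
    sim_args$n_planted_snvs <- NULL
    lib <- sim_args$library_size %||% 25000L
    sim_args$library_size <- NULL
    if (is.null(sim_args$samples)) {
      sim_args$samples <- default_sample_sheet()
      sim_args$samples$library_size <- lib
    }
    sim_args$seed <- config$seed
    cfg <- do.call(sim_config, sim_args)
    if (n_snv > 0L) {
      cfg <- plant_demo_snvs(cfg, n_snv)
    }
    bundle <- simulate_bundle(cfg)
    write_bundle(bundle, file.path(out_dir, "sim"))
    stage_log("simulate", length(bundle$references), " ORFs, ",
              sum(vapply(bundle$reads, length, integer(1))), " reads")
    state$bundle <- bundle
  })

  run_stage("count", function() {
    b <- state$bundle
    cm <- count_reads(b$alignments, b$annotation,
                      sample_sheet = b$config$samples)
    utils::write.table(
      data.frame(orf_id = rownames(cm$counts), cm$counts,
                 check.names = FALSE),
      file.path(out_dir, "counts.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    stage_log("count", nrow(cm$counts), " ORFs x ", ncol(cm$counts),
              " samples")
    state$cm <- cm
  })

  run_stage("de", function() {
    cm <- state$cm
    de <- list()
    for (cn in c("N", "Fe")) {
      ok <- tryCatch({resolve_contrast(cm, cn); TRUE},
                     error = function(e) FALSE)
      if (!ok) next
      for (md in c("global", "groupwise", "taxon_proportion")) {
        tab <- differential_expression(
          cm, cn, mode = md, min_total = config$de$min_total %||% 5,
          alpha = config$de$alpha %||% 0.05, phi = config$de$phi)
        de[[paste(cn, md, sep = "_")]] <- tab
        utils::write.table(tab[, setdiff(names(tab), "members")],
                           file.path(out_dir,
                                     sprintf("de_%s_%s.tsv", cn, md)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      stage_log("de", cn, ": ", sum(de[[paste0(cn, "_global")]]$significant),
                " significant ORFs (global, FDR<0.05)")
    }
    state$de <- de
  })

  run_stage("pidshift", function() {
    b <- state$bundle
    pid <- pid_histogram(b$alignments, b$annotation)
    utils::write.table(pid$histogram, file.path(out_dir,
                                                "pid_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    shifts <- list()
    sheet <- b$config$samples
    for (cn in c("N", "Fe")) {
      de_tab <- state$de[[paste0(cn, "_global")]]
      if (is.null(de_tab)) next
      rows <- sheet[sheet$experiment == cn, , drop = FALSE]
      pairs <- list()
      for (barrel in unique(rows$barrel)) {
        br <- rows[rows$barrel == barrel, ]
        if (all(c("mid", "late") %in% br$stage)) {
          pairs[[barrel]] <- c(br$sample[br$stage == "mid"][1],
                               br$sample[br$stage == "late"][1])
        }
      }
      if (!length(pairs)) next
      tab <- conserved_shift_table(
        pid, de_tab, pairs,
        min_identity = config$pidshift$min_identity %||% 60,
        alpha = config$pidshift$alpha %||% 0.05,
        min_reads = config$pidshift$min_reads %||% 10L)
      shifts[[cn]] <- tab
      utils::write.table(tab, file.path(out_dir,
                                        sprintf("shift_table_%s.tsv", cn)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      stage_log("pidshift", cn, ": ", nrow(tab), " conserved-shift ORFs")
    }
    state$pid <- pid
    state$shifts <- shifts
  })

  run_stage("snv", function() {
    b <- state$bundle
    sc <- config$snv
    pileups <- lapply(b$alignments, build_pileup, references = b$references)
    calls <- data.table::rbindlist(lapply(names(pileups), function(s) {
      call_snvs(pileups[[s]], b$references,
                min_depth = sc$min_depth %||% 4L,
                min_alt = sc$min_alt %||% 2L,
                min_af = sc$min_af %||% 0.05, sample = s)
    }))
    calls <- as.data.frame(calls)
    write_vcf(calls, b$references, file.path(out_dir, "snvs.vcf"))
    density <- snv_density(calls, pileups, b$annotation, b$references,
                           min_depth = sc$min_depth %||% 4L)
    utils::write.table(density, file.path(out_dir, "snv_density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    traj <- allele_trajectories(calls, pileups, b$config$samples,
                                sweep_hi = sc$sweep_hi %||% 0.9,
                                sweep_lo = sc$sweep_lo %||% 0.5)
    utils::write.table(traj, file.path(out_dir, "snv_trajectories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage_log("snv", nrow(unique(calls[, c("orf_id", "pos", "alt")])),
              " distinct variants, ", sum(traj$sweep), " sweep flags")
    state$snv <- list(calls = calls, density = density, traj = traj)
  })

  run_stage("cluster", function() {
    b <- state$bundle
    cc <- config$cluster
    peptides <- translate_orfs(b$references)
    graph <- kmer_similarity_graph(peptides, k = cc$k %||% 4L,
                                   min_shared = cc$min_shared %||% 3L)
    part <- mcl(graph, inflation = cc$inflation %||% 1.5)
    tab <- cluster_de(part, de_n = state$de$N_groupwise,
                      de_fe = state$de$Fe_groupwise,
                      annotation = b$annotation,
                      min_members = cc$min_members %||% 10L,
                      min_abs_lfc = cc$min_abs_lfc %||% 2.5,
                      alpha = config$de$alpha %||% 0.05)
    membership <- data.frame(orf_id = names(part$membership),
                             cluster_id = unname(part$membership))
    utils::write.table(membership, file.path(out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tab[, setdiff(names(tab), "members")],
                       file.path(out_dir, "cluster_de.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage_log("cluster", length(part$clusters), " clusters, ",
              sum(tab$retained), " retained")
    state$clusters <- tab
  })

  run_stage("biomarker", function() {
    b <- state$bundle
    cm <- state$cm
    groups <- unique(b$annotation$taxon_group)
    idx <- do.call(rbind, lapply(groups, function(g) {
      tryCatch(nutrient_indices(
        cm, g, pseudocount = config$biomarker$pseudocount %||% 1.0),
        error = function(e) NULL)
    }))
    utils::write.table(idx, file.path(out_dir, "biomarker_indices.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stage_log("biomarker", nrow(idx), " index values")
    state$biomarkers <- idx
  })

  run_stage("report", function() {
    report <- list()
    if (!is.null(state$de)) {
      counts <- list()
      for (nm in grep("_global$", names(state$de), value = TRUE)) {
        tab <- state$de[[nm]]
        sig <- tab[tab$significant, , drop = FALSE]
        counts[[nm]] <- list(
          n_tested = nrow(tab), n_significant = nrow(sig),
          up_depleted_by_taxon = as.list(table(
            sig$taxon_group[sig$log2fc > 0])),
          up_replete_by_taxon = as.list(table(
            sig$taxon_group[sig$log2fc < 0]))
        )
      }
      report$de <- counts
    }
    if (!is.null(state$shifts)) {
      report$pidshift <- lapply(state$shifts, function(tab) {
        list(n_conserved = nrow(tab),
             mean_delta_pid = if (nrow(tab)) mean(tab$mean_delta_pid)
             else NA)
      })
    }
    if (!is.null(state$snv)) {
      report$snv <- list(
        n_variants = nrow(unique(
          state$snv$calls[, c("orf_id", "pos", "alt")])),
        n_sweeps = sum(state$snv$traj$sweep),
        density = state$snv$density
      )
    }
    if (!is.null(state$clusters)) {
      report$clusters <- list(
        n_clusters = nrow(state$clusters),
        n_retained = sum(state$clusters$retained))
    }
    if (!is.null(state$biomarkers)) {
      report$biomarkers <- state$biomarkers
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, na = "null",
                         digits = 10)
    stage_log("report", "sections: ", paste(names(report), collapse = ", "))
    state$report <- report
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  invisible(manifest)
}

# ORF peptides: frame-1 translation with the terminal stop stripped.
translate_orfs <- function(references) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(references)))
  stats::setNames(sub("\\*$", "", aa), names(references))
}

# Plant n sweep-style SNVs on distinct ORFs: frequency 0.3 mid -> 0.95 late.
plant_demo_snvs <- function(cfg, n) {
  n_orfs <- cfg$n_taxon_groups * cfg$orfs_per_group
  group <- rep(seq_len(cfg$n_taxon_groups), each = cfg$orfs_per_group)
  ids <- sprintf("g%02d_orf%04d", group,
                 rep(seq_len(cfg$orfs_per_group), cfg$n_taxon_groups))
  pick <- with_seed(stream_seed(cfg$seed, "demo_snvs"),
                    sample(ids, min(n, n_orfs)))
  cfg$snv_spec <- lapply(seq_along(pick), function(i) {
    planted_snv(pick[i], position = 50L + 3L * i, freq_mid = 0.3,
                freq_late = 0.95)
  })
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = 12), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(manifest, state, out_dir) {
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  sums <- tools::md5sum(files)
  manifest$files <- as.list(stats::setNames(unname(sums),
                                            sub(paste0("^", out_dir, "/?"),
                                                "", files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
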