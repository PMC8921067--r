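## End-to-end orchestration: assign -> abundance -> phenotype -> diff.
## Every stage reads/writes the package's plain-text formats; a JSON
## manifest (inputs, parameters, seed, output hashes) makes reruns
## hash-checkable.

pipeline_defaults <- function() {
  list(rank = "species", fold_threshold = 5, detection_limit = 0,
       control = "control", seed = 1L, phylotype_correction = FALSE)
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes assignment (MTA), abundance (relative abundance, rank
#' aggregation, copy-number renormalization), phenotype profiling (CPI) and
#' differential analysis, writing every result table as TSV plus a JSON
#' manifest whose input/output hashes fully determine a rerun.
#'
#' Configuration fields (list or YAML/JSON path): `ref_fasta`, `lineage`,
#' `asv_fasta`, `counts`, `metadata`, `copy_number`, `bpm`, `outdir`;
#' optional `identity` (precomputed identity TSV instead of the built-in
#' aligner), `rank` (default "species"), `fold_threshold` (default 5,
#' must be > 1), `detection_limit` (default 0), `control` (default
#' "control"), `seed` (recorded in the manifest; the analysis itself is
#' deterministic).
#'
#' Phylotype-level differential analysis runs on uncorrected relative
#' abundances by default; rank-level analyses are copy-number corrected.
#'
#' @param config named list or path to a YAML/JSON config file.
#' @return Object of class `scfa_pipeline`: tables, output paths and the
#'   manifest (invisibly printed).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)

  required <- c("ref_fasta", "lineage", "asv_fasta", "counts", "metadata",
                "copy_number", "bpm", "outdir")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop_input("[config] missing field(s): %s", paste(missing, collapse = ", "))
  }
  input_fields <- c("ref_fasta", "lineage", "asv_fasta", "counts",
                    "metadata", "copy_number", "bpm",
                    if (!is.null(cfg$identity)) "identity")
  for (f in input_fields) {
    if (!file.exists(cfg[[f]])) {
      stop_input("[config] input '%s' does not exist: %s", f, cfg[[f]])
    }
  }
  if (cfg$fold_threshold <= 1) stop_input("[config] fold_threshold must be > 1")
  cfg$rank <- match.arg(cfg$rank, RANKS)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  ## ---- load inputs ----
  inputs <- with_stage("load", {
    lineage <- read_lineage_tsv(cfg$lineage)
    ref_db <- structure(list(
      strains = lineage,
      sequences = read_fasta(cfg$ref_fasta),
      genomes = NULL), class = "ref_db")
    if (!all(lineage$strain_id %in% names(ref_db$sequences))) {
      stop_input("lineage strains missing from reference FASTA")
    }
    list(ref_db = ref_db,
         asv = read_fasta(cfg$asv_fasta),
         meta = read_metadata_tsv(cfg$metadata),
         cn = read_cn_tsv(cfg$copy_number),
         bpm = read_bpm_tsv(cfg$bpm))
  })
  counts <- with_stage("load", read_counts_tsv(cfg$counts, meta = inputs$meta))

  ## ---- assign ----
  assignments <- with_stage("assign", {
    hits <- if (!is.null(cfg$identity)) read_identity_tsv(cfg$identity) else NULL
    stage_msg("assign", "MTA over %d ASVs x %d references", length(inputs$asv),
              length(inputs$ref_db$sequences))
    assign_taxonomy(inputs$asv, inputs$ref_db, hits = hits)
  })

  ## ---- abundance ----
  ab <- with_stage("abundance", {
    rel <- to_relative(counts)
    agg <- aggregate_to_rank(rel, assignments, rank = cfg$rank)
    corrected <- copy_number_renormalize(agg, inputs$cn, rank = cfg$rank)
    stage_msg("abundance", "%d phylotypes -> %d taxa at rank '%s'",
              nrow(rel$mat), nrow(agg$mat), cfg$rank)
    list(rel = rel, agg = agg, corrected = corrected)
  })

  ## ---- phenotype ----
  phen <- with_stage("phenotype", {
    probs <- phenotype_probability_table(rownames(ab$corrected$mat),
                                         inputs$bpm, rank = cfg$rank)
    cpi <- cpi_matrix(ab$corrected, probs)
    stage_msg("phenotype", "CPI over %d samples x %d phenotypes",
              nrow(cpi), ncol(cpi))
    list(probs = probs, cpi = cpi)
  })

  ## ---- diff + diversity ----
  res <- with_stage("diff", {
    alpha <- apply(ab$rel$mat, 2L, shannon_diversity)
    bc <- bray_curtis_matrix(ab$rel)
    ord <- pcoa(bc)
    diff_phylotype <- differential_table(
      ab$rel, control = cfg$control, fold_threshold = cfg$fold_threshold,
      detection_limit = cfg$detection_limit)
    diff_rank <- differential_table(
      ab$corrected, control = cfg$control,
      fold_threshold = cfg$fold_threshold,
      detection_limit = cfg$detection_limit)
    diff_cpi <- differential_table(
      phen$cpi, control = cfg$control, fold_threshold = cfg$fold_threshold,
      detection_limit = cfg$detection_limit)
    list(alpha = alpha, bc = bc, ord = ord,
         diff_phylotype = diff_phylotype, diff_rank = diff_rank,
         diff_cpi = diff_cpi,
         summary = modulation_summary(diff_phylotype))
  })

  ## ---- write outputs ----
  paths <- with_stage("write", {
    p <- list(
      assignments = file.path(cfg$outdir, "assignments.tsv"),
      relative = file.path(cfg$outdir, "relative_phylotype.tsv"),
      corrected = file.path(cfg$outdir,
                            sprintf("relative_%s_corrected.tsv", cfg$rank)),
      probabilities = file.path(cfg$outdir, "phenotype_probabilities.tsv"),
      cpi = file.path(cfg$outdir, "cpi.tsv"),
      alpha = file.path(cfg$outdir, "alpha_diversity.tsv"),
      bray_curtis = file.path(cfg$outdir, "bray_curtis.tsv"),
      pcoa = file.path(cfg$outdir, "pcoa.tsv"),
      diff_phylotype = file.path(cfg$outdir, "differential_phylotype.tsv"),
      diff_rank = file.path(cfg$outdir,
                            sprintf("differential_%s.tsv", cfg$rank)),
      diff_cpi = file.path(cfg$outdir, "differential_cpi.tsv"),
      summary = file.path(cfg$outdir, "modulation_summary.tsv")
    )
    write_tsv(as.data.frame(assignments), p$assignments)
    write_counts_tsv(ab$rel, p$relative)
    write_counts_tsv(ab$corrected, p$corrected)
    probs_df <- data.frame(taxon = rownames(phen$probs$p),
                           n_genomes = phen$probs$n_genomes,
                           round(as.data.frame(phen$probs$p), 6),
                           stringsAsFactors = FALSE, check.names = FALSE)
    write_tsv(probs_df, p$probabilities)
    write_cpi_tsv(phen$cpi, p$cpi)
    write_tsv(data.frame(sample_id = names(res$alpha),
                         shannon = round(res$alpha, 6)), p$alpha)
    bc_df <- data.frame(sample_id = rownames(res$bc),
                        round(as.data.frame(res$bc), 6), check.names = FALSE)
    write_tsv(bc_df, p$bray_curtis)
    k <- min(2L, ncol(res$ord$coords))
    ord_df <- data.frame(sample_id = rownames(res$ord$coords),
                         round(as.data.frame(res$ord$coords[, seq_len(k),
                                                            drop = FALSE]), 6),
                         check.names = FALSE)
    write_tsv(ord_df, p$pcoa)
    write_tsv(res$diff_phylotype, p$diff_phylotype)
    write_tsv(res$diff_rank, p$diff_rank)
    write_tsv(res$diff_cpi, p$diff_cpi)
    write_tsv(res$summary, p$summary)
    p
  })

  manifest <- list(
    package = "scfaprof",
    version = as.character(utils::packageVersion("scfaprof")),
    parameters = cfg[c("rank", "fold_threshold", "detection_limit",
                       "control", "seed")],
    inputs = lapply(setNames(input_fields, input_fields), function(f) {
      list(path = cfg[[f]], md5 = unname(tools::md5sum(cfg[[f]])))
    }),
    outputs = lapply(paths, function(pp) {
      list(path = pp, md5 = unname(tools::md5sum(pp)))
    })
  )
  manifest_path <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  stage_msg("done", "wrote %d artifacts to %s", length(paths) + 1L, cfg$outdir)

  structure(list(config = cfg, assignments = assignments,
                 relative = ab$rel, corrected = ab$corrected,
                 probabilities = phen$probs, cpi = phen$cpi,
                 alpha = res$alpha, bray_curtis = res$bc, pcoa = res$ord,
                 diff_phylotype = res$diff_phylotype,
                 diff_rank = res$diff_rank, diff_cpi = res$diff_cpi,
                 summary = res$summary, paths = paths,
                 manifest = manifest, manifest_path = manifest_path),
            class = "scfa_pipeline")
}

#' @export
print.scfa_pipeline <- function(x, ...) {
  cat("scfaprof pipeline run\n")
  cat(sprintf("  %d ASVs -> %d taxa at rank '%s'; %d samples\n",
              nrow(x$assignments), nrow(x$corrected$mat), x$config$rank,
              ncol(x$relative$mat)))
  cat(sprintf("  CPI: %d phenotypes; differential contrasts vs '%s'\n",
              ncol(x$cpi), x$config$control))
  cat("Modulation summary (phylotype level):\n")
  print(x$summary)
  invisible(x)
}

#' @export
summary.scfa_pipeline <- function(object, ...) {
  cat(sprintf("Mean Shannon diversity: %.3f\n", mean(object$alpha)))
  sig <- object$diff_rank[object$diff_rank$p_value <= 0.05, ]
  cat(sprintf("Significant rank-level contrasts (p <= 0.05): %d\n", nrow(sig)))
  print(object$summary)
  invisible(object)
}
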