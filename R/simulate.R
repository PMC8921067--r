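## Seeded simulation of the culture experiment: one control plus SCFA
## conditions, technical replicates per condition, per-strain planted
## fold-change effects, Dirichlet-multinomial read counts with 16S
## copy-number bias.

#' Configuration for a simulated supplementation experiment
#'
#' Defaults mirror the reference study design: unsupplemented control plus
#' nine SCFA conditions, four technical replicates each, sequencing depth
#' 100,000 reads per sample, tenfold planted effects on 10% of strains.
#' The baseline log-normal (sdlog 0.6) places the most abundant of ~30
#' strains near 9% of the community, matching the most abundant species
#' group observed in control cultures; overdispersion 0.001 yields ~30%
#' CV on minor taxa across replicates.
#'
#' @param conditions condition labels; must include `control`.
#' @param control label of the control condition.
#' @param replicates replicates per condition (>= 2).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   strain abundances (shared across conditions).
#' @param affected_fraction fraction of strains receiving a planted effect
#'   in each non-control condition.
#' @param multiplier_bounds log-uniform bounds of the planted effect
#'   multiplier (both > 0; equal bounds give a fixed multiplier).
#' @param depth reads per sample (>= 1000).
#' @param overdispersion Dirichlet overdispersion theta >= 0;
#'   `Var(p_i) = p_i (1 - p_i) theta` across replicate cultures; 0 gives a
#'   plain multinomial.
#' @param seed integer seed.
#' @return Validated list of class `effect_config`.
#' @export
effect_config <- function(conditions = c("control", scfa_conditions()),
                          control = "control",
                          replicates = 4L,
                          baseline_meanlog = 0,
                          baseline_sdlog = 0.6,
                          affected_fraction = 0.1,
                          multiplier_bounds = c(10, 10),
                          depth = 100000L,
                          overdispersion = 0.001,
                          seed = 1L) {
  if (!control %in% conditions) {
    stop_input("control label '%s' is not among the conditions", control)
  }
  if (anyDuplicated(conditions)) stop_input("condition labels must be unique")
  if (replicates < 2) stop_input("`replicates` must be >= 2")
  if (depth < 1000) stop_input("`depth` must be >= 1000")
  if (length(multiplier_bounds) != 2 || any(multiplier_bounds <= 0)) {
    stop_input("`multiplier_bounds` must be two values > 0")
  }
  check_fraction(affected_fraction, "`affected_fraction`")
  if (overdispersion < 0) stop_input("`overdispersion` must be >= 0")
  if (baseline_sdlog < 0) stop_input("`baseline_sdlog` must be >= 0")
  structure(list(conditions = conditions, control = control,
                 replicates = as.integer(replicates),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 affected_fraction = affected_fraction,
                 multiplier_bounds = sort(as.numeric(multiplier_bounds)),
                 depth = as.integer(depth),
                 overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "effect_config")
}

#' Simulate a multi-condition replicate culture experiment
#'
#' Baseline strain abundances are drawn once (log-normal) and shared across
#' conditions. In each non-control condition a random subset of strains has
#' its abundance multiplied by a planted log-uniform multiplier. Each
#' replicate's true cell composition is a Dirichlet perturbation of the
#' condition composition (culture-to-culture variation); sequencing reads
#' are then drawn multinomially at the configured depth with weights
#' proportional to cell abundance times the strain's 16S copy number, so
#' raw counts carry the copy-number bias that the pipeline corrects.
#'
#' @param ref_db a `ref_db` object.
#' @param cfg an [effect_config()].
#' @param bpm optional `bpm`; when supplied, ground-truth CPI expectations
#'   are computed per sample from true cell compositions and genome bits.
#' @return List with `counts` (an [abund_table()] in counts mode, strains x
#'   samples, with condition/replicate metadata) and `truth` (class
#'   `ground_truth`: `multipliers` condition x strain, control row all 1;
#'   `true_props` strain x sample cell compositions; `cpi` sample x
#'   phenotype expectations in percent, or NULL).
#' @export
simulate_experiment <- function(ref_db, cfg, bpm = NULL) {
  stopifnot(inherits(cfg, "effect_config"))
  strains <- ref_db$strains$strain_id
  n <- length(strains)
  copy_number <- ref_db$strains$copy_number

  with_seed(cfg$seed, {
    baseline <- rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
    names(baseline) <- strains

    mult <- matrix(1, nrow = length(cfg$conditions), ncol = n,
                   dimnames = list(cfg$conditions, strains))
    for (cond in setdiff(cfg$conditions, cfg$control)) {
      k <- round(cfg$affected_fraction * n)
      if (k > 0) {
        idx <- sample.int(n, k)
        lo <- log(cfg$multiplier_bounds[1]); hi <- log(cfg$multiplier_bounds[2])
        mult[cond, idx] <- exp(runif(k, lo, hi))
      }
    }

    sample_ids <- as.vector(t(outer(cfg$conditions, seq_len(cfg$replicates),
                                    function(a, b) paste(a, b, sep = "_"))))
    meta <- data.frame(
      sample_id = sample_ids,
      condition = rep(cfg$conditions, each = cfg$replicates),
      replicate = rep(seq_len(cfg$replicates), times = length(cfg$conditions)),
      stringsAsFactors = FALSE
    )

    counts <- matrix(0L, nrow = n, ncol = nrow(meta),
                     dimnames = list(strains, meta$sample_id))
    true_props <- matrix(0, nrow = n, ncol = nrow(meta),
                         dimnames = list(strains, meta$sample_id))
    theta <- cfg$overdispersion
    for (i in seq_len(nrow(meta))) {
      p <- baseline * mult[meta$condition[i], ]
      p <- p / sum(p)
      pi_rep <- if (theta > 0) rdirichlet1(p * (1 - theta) / theta) else p
      true_props[, i] <- pi_rep
      w <- pi_rep * copy_number
      counts[, i] <- rmultinom(1L, cfg$depth, w / sum(w))[, 1L]
    }

    cpi <- NULL
    if (!is.null(bpm)) {
      bits <- bpm$mat[match(paste0("G_", strains), rownames(bpm$mat)), ,
                      drop = FALSE]
      if (anyNA(bits)) stop_input("bpm lacks genomes for some strains")
      cpi <- 100 * t(true_props) %*% bits   # sample x phenotype, percent
    }

    list(
      counts = abund_table(counts, meta = meta, mode = "counts"),
      truth = structure(list(multipliers = mult, true_props = true_props,
                             cpi = cpi, control = cfg$control),
                        class = "ground_truth")
    )
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  planted <- sum(x$multipliers != 1)
  cat(sprintf("Ground truth: %d conditions x %d strains, %d planted effects\n",
              nrow(x$multipliers), ncol(x$multipliers), planted))
  invisible(x)
}

#' Write a complete simulated study to disk
#'
#' Generates a reference database, a binary phenotype matrix and a
#' simulated experiment, and writes every pipeline input as tab-delimited
#' text (plus the ASV FASTA, whose sequences are the strain phylotypes).
#'
#' @param dir output directory (created if needed).
#' @param n_species,strains_per_species reference database dimensions.
#' @param cfg an [effect_config()].
#' @param phenotypes,prevalence,coherence passed to
#'   [generate_phenotype_matrix()].
#' @param seed master seed; sub-seeds for database, BPM and experiment are
#'   derived from it.
#' @return Invisibly, a named list of written file paths plus the in-memory
#'   objects (`ref_db`, `bpm_obj`, `experiment`).
#' @export
write_simulation <- function(dir, n_species = 10, strains_per_species = 3,
                             cfg = effect_config(),
                             phenotypes = default_phenotypes("fermentation"),
                             prevalence = 0.5, coherence = 1, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  db <- generate_reference_database(n_species, strains_per_species,
                                    seed = seed)
  b <- generate_phenotype_matrix(db, phenotypes, prevalence, coherence,
                                 seed = seed + 1L)
  cfg$seed <- seed + 2L
  exp <- simulate_experiment(db, cfg, bpm = b)

  paths <- list(
    ref_fasta = file.path(dir, "reference.fasta"),
    asv_fasta = file.path(dir, "asv.fasta"),
    lineage = file.path(dir, "lineage.tsv"),
    copy_number = file.path(dir, "copy_number.tsv"),
    bpm = file.path(dir, "bpm.tsv"),
    counts = file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv")
  )
  write_fasta(db$sequences, paths$ref_fasta)
  write_fasta(db$sequences, paths$asv_fasta)    # ASVs = observed phylotypes
  write_lineage_tsv(db$strains, paths$lineage)
  write_cn_tsv(copy_number_table(db), paths$copy_number)
  write_bpm_tsv(b, paths$bpm)
  write_counts_tsv(exp$counts, paths$counts)
  write_metadata_tsv(exp$counts$meta, paths$metadata)
  write_ground_truth_tsv(exp$truth, paths$ground_truth)

  invisible(c(paths, list(ref_db = db, bpm_obj = b, experiment = exp)))
}
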