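## Synthetic reference database: strain-level 16S phylotypes nested in
## species groups, one reference genome per strain, species-level 16S copy
## numbers. Emulates the statistical structure of a curated 16S database
## plus a reference genome collection, at desk scale.

BASES <- c("A", "C", "G", "T")

mutate_positions <- function(seq_vec, n_sub) {
  if (n_sub == 0) return(seq_vec)
  pos <- sample.int(length(seq_vec), n_sub)
  seq_vec[pos] <- vapply(seq_vec[pos], function(b) {
    sample(setdiff(BASES, b), 1L)
  }, character(1), USE.NAMES = FALSE)
  seq_vec
}

hamming <- function(a, b) sum(a != b)

#' Generate a synthetic 16S reference database
#'
#' Builds `n_species` species groups, each holding `strains_per_species`
#' strain-level phylotypes, with a nested genus/family/... taxonomy, a
#' fixed-length V3-V4-like amplicon sequence per strain, a species-level
#' 16S copy number shared by its strains, and one reference genome per
#' strain (same lineage).
#'
#' Within a species, strain sequences carry 1-5 substitutions relative to
#' the species consensus; between species, sequences differ at >= 3% of
#' positions (enforced by construction with a redraw loop).
#'
#' @param n_species number of species groups (>= 2).
#' @param strains_per_species strains (phylotypes) per species (>= 1).
#' @param seed integer seed; identical seeds reproduce the database
#'   byte-for-byte.
#' @param seq_length amplicon length in nt (default 450, V3-V4-like).
#' @param copy_number_range integer bounds for the per-species 16S copy
#'   number, drawn uniformly (default 1-7, the scale of rrnDB species means).
#' @param min_divergence minimum between-species sequence divergence as a
#'   fraction of positions (default 0.03).
#' @return An object of class `ref_db`: list with `strains` (data.frame of
#'   strain_id, the seven lineage ranks, copy_number), `sequences` (named
#'   character vector by strain_id) and `genomes` (data.frame of genome_id,
#'   strain_id and lineage ranks).
#' @export
#' @examples
#' db <- generate_reference_database(3, 2, seed = 1)
#' nrow(db$strains)
generate_reference_database <- function(n_species, strains_per_species, seed,
                                        seq_length = 450L,
                                        copy_number_range = c(1L, 7L),
                                        min_divergence = 0.03) {
  if (!is.numeric(n_species) || n_species < 2) {
    stop_input("`n_species` must be >= 2")
  }
  if (!is.numeric(strains_per_species) || strains_per_species < 1) {
    stop_input("`strains_per_species` must be >= 1")
  }
  n_species <- as.integer(n_species)
  strains_per_species <- as.integer(strains_per_species)
  L <- as.integer(seq_length)
  ## consensus pairs need a 10-substitution margin so that strain sequences
  ## (<= 5 substitutions each from their consensus) also stay >= 3% apart
  min_diff <- ceiling(min_divergence * L) + 10L

  with_seed(seed, {
    n_genera <- max(1L, ceiling(n_species / 3))
    genus_of_species <- rep(seq_len(n_genera), length.out = n_species)
    ## strictly nested higher ranks built by pairing adjacent groups
    fam <- ceiling(seq_len(n_genera) / 2)
    ord <- ceiling(fam / 2)
    cls <- ceiling(ord / 2)
    phy <- ceiling(cls / 2)

    root <- sample(BASES, L, replace = TRUE)
    genus_anc <- lapply(seq_len(n_genera), function(g) {
      mutate_positions(root, round(0.10 * L))
    })

    ## species consensus sequences; redraw any pair closer than min_diff
    consensus <- lapply(seq_len(n_species), function(s) {
      mutate_positions(genus_anc[[genus_of_species[s]]], round(0.04 * L))
    })
    for (iter in seq_len(200L)) {
      clash <- FALSE
      for (i in seq_len(n_species - 1L)) {
        for (j in seq((i + 1L), n_species)) {
          if (hamming(consensus[[i]], consensus[[j]]) < min_diff) {
            consensus[[j]] <- mutate_positions(
              genus_anc[[genus_of_species[j]]], round(0.04 * L))
            clash <- TRUE
          }
        }
      }
      if (!clash) break
      if (iter == 200L) {
        stop_input("could not construct species consensus sequences with >= %.0f%% divergence",
                   100 * min_divergence)
      }
    }

    genus_name <- sprintf("Genus%02d", seq_len(n_genera))
    species_name <- sprintf("%s_sp%03d", genus_name[genus_of_species],
                            seq_len(n_species))
    copy_number <- sample(seq(copy_number_range[1], copy_number_range[2]),
                          n_species, replace = TRUE)

    strain_rows <- list()
    seqs <- character(0)
    for (s in seq_len(n_species)) {
      for (k in seq_len(strains_per_species)) {
        sid <- sprintf("%s_str%d", species_name[s], k)
        repeat {
          sq <- mutate_positions(consensus[[s]], sample(1:5, 1L))
          sq <- paste(sq, collapse = "")
          if (!sq %in% seqs) break       # keep phylotype sequences distinct
        }
        seqs[sid] <- sq
        g <- genus_of_species[s]
        strain_rows[[sid]] <- data.frame(
          strain_id = sid,
          domain = "Bacteria",
          phylum = sprintf("Phylum%02d", phy[g]),
          class = sprintf("Class%02d", cls[g]),
          order = sprintf("Order%02d", ord[g]),
          family = sprintf("Family%02d", fam[g]),
          genus = genus_name[g],
          species = species_name[s],
          copy_number = copy_number[s],
          stringsAsFactors = FALSE
        )
      }
    }
    strains <- do.call(rbind, strain_rows)
    rownames(strains) <- NULL

    genomes <- strains[c("strain_id", RANKS)]
    genomes <- cbind(genome_id = paste0("G_", strains$strain_id), genomes)
    rownames(genomes) <- NULL

    structure(list(strains = strains, sequences = seqs, genomes = genomes),
              class = "ref_db")
  })
}

#' @export
print.ref_db <- function(x, ...) {
  cat(sprintf("Synthetic 16S reference database: %d strains, %d species, %d genomes\n",
              nrow(x$strains), length(unique(x$strains$species)),
              nrow(x$genomes)))
  cat(sprintf("Sequence length: %d nt; copy numbers %d-%d\n",
              nchar(x$sequences[[1]]), min(x$strains$copy_number),
              max(x$strains$copy_number)))
  invisible(x)
}

## Species-level copy-number table derived from a reference database.
#' Copy-number table of a reference database
#'
#' Extracts the species-level mean 16S copy numbers (rrnDB-style) from a
#' synthetic reference database.
#'
#' @param ref_db a `ref_db` object.
#' @param rank rank at which to average (default "species").
#' @return A `cn_table` data.frame with columns rank, name, mean_copies.
#' @export
copy_number_table <- function(ref_db, rank = "species") {
  rank <- match.arg(rank, RANKS)
  agg <- aggregate(ref_db$strains$copy_number,
                   by = list(name = ref_db$strains[[rank]]), FUN = mean)
  out <- data.frame(rank = rank, name = agg$name, mean_copies = agg$x,
                    stringsAsFactors = FALSE)
  cn_table(out)
}

#' Construct/validate a copy-number table
#'
#' @param df data.frame with columns rank, name, mean_copies (all >= 1).
#' @return The validated data.frame with class `cn_table`.
#' @export
cn_table <- function(df) {
  need <- c("rank", "name", "mean_copies")
  if (!all(need %in% names(df))) {
    stop_input("copy-number table needs columns %s", paste(need, collapse = ", "))
  }
  if (any(df$mean_copies < 1)) stop_input("copy numbers must be >= 1")
  structure(df[need], class = c("cn_table", "data.frame"))
}
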