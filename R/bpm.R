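## Binary phenotype matrix (BPM): reference genomes x metabolic phenotypes,
## entries 1 = complete pathway present, 0 = absent, plus the genome ->
## lineage mapping used to pool genomes under (possibly multi-name) taxa.

#' Construct/validate a binary phenotype matrix
#'
#' @param mat integer matrix, genomes x phenotypes, entries strictly 0/1,
#'   rownames = genome ids, colnames = phenotype names.
#' @param lineage data.frame with column `genome_id` plus the seven lineage
#'   ranks; every genome in `mat` must have a row.
#' @return Object of class `bpm`.
#' @export
bpm <- function(mat, lineage) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop_input("BPM matrix needs genome rownames and phenotype colnames")
  }
  if (!all(mat %in% c(0L, 1L))) {
    bad <- which(!(mat %in% c(0L, 1L)))[1]
    stop_input("BPM entries must be 0/1 (offending genome %s, phenotype %s)",
               rownames(mat)[(bad - 1L) %% nrow(mat) + 1L],
               colnames(mat)[(bad - 1L) %/% nrow(mat) + 1L])
  }
  if (!"genome_id" %in% names(lineage)) {
    stop_input("BPM lineage table needs a genome_id column")
  }
  missing <- setdiff(rownames(mat), lineage$genome_id)
  if (length(missing) > 0) {
    stop_input("unknown genome(s) without lineage: %s",
               paste(head(missing, 5), collapse = ", "))
  }
  lin <- lineage[match(rownames(mat), lineage$genome_id), , drop = FALSE]
  lin_frame <- as_lineage_frame(lin[RANKS])   # validates completeness
  storage.mode(mat) <- "integer"
  structure(list(mat = mat,
                 lineage = cbind(genome_id = lin$genome_id, lin_frame,
                                 stringsAsFactors = FALSE)),
            class = "bpm")
}

#' Generate a synthetic binary phenotype matrix
#'
#' Draws a species-level majority state per phenotype with the given
#' prevalence, then assigns each genome its species' state, flipped with
#' probability `1 - coherence`. `coherence = 1` makes pathway presence a
#' strict species-level trait; lower values model strain-variable pathway
#' content.
#'
#' @param ref_db a `ref_db` object supplying the genomes and lineages.
#' @param phenotypes character vector of phenotype names.
#' @param prevalence probability a species carries the phenotype; scalar or
#'   one value per phenotype.
#' @param coherence probability a genome follows its species' majority state.
#' @param seed integer seed.
#' @return Object of class `bpm`.
#' @export
#' @examples
#' db <- generate_reference_database(3, 2, seed = 1)
#' b <- generate_phenotype_matrix(db, c("butyrate", "B12"), 0.5, 1, seed = 2)
#' dim(b$mat)
generate_phenotype_matrix <- function(ref_db,
                                      phenotypes = default_phenotypes("fermentation"),
                                      prevalence = 0.5, coherence = 1,
                                      seed = 1) {
  check_fraction(prevalence, "`prevalence`")
  check_fraction(coherence, "`coherence`")
  if (length(phenotypes) < 1) stop_input("need at least one phenotype")
  prevalence <- rep_len(prevalence, length(phenotypes))

  genomes <- ref_db$genomes
  species <- unique(genomes$species)
  with_seed(seed, {
    mat <- matrix(0L, nrow = nrow(genomes), ncol = length(phenotypes),
                  dimnames = list(genomes$genome_id, phenotypes))
    for (j in seq_along(phenotypes)) {
      majority <- rbinom(length(species), 1L, prevalence[j])
      names(majority) <- species
      state <- majority[genomes$species]
      flip <- rbinom(nrow(genomes), 1L, 1 - coherence)
      mat[, j] <- as.integer(xor(state == 1L, flip == 1L))
    }
    bpm(mat, genomes)
  })
}

#' @export
print.bpm <- function(x, ...) {
  cat(sprintf("Binary phenotype matrix: %d genomes x %d phenotypes (density %.2f)\n",
              nrow(x$mat), ncol(x$mat), mean(x$mat)))
  invisible(x)
}
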