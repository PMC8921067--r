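## Phenotype profiling: propagate binary genome phenotypes to (possibly
## multi-name) taxa as pooled probabilities, then weight by relative
## abundance into per-sample Community Phenotype Indices (CPI, 0-100%).

#' Phenotype probabilities of one taxon
#'
#' Pools every reference genome whose lineage at the analysis rank matches
#' any constituent name of the (possibly "/"-joined) taxon, and returns
#' the mean of each binary phenotype over that pool. Multi-name taxa pool
#' their constituents' genomes unweighted: the multi-name encodes
#' assignment ambiguity, not mixture proportions. A taxon with no matching
#' genome returns NA probabilities (an explicit missing marker, never a
#' silent 0).
#'
#' @param taxon taxon name at the analysis rank, e.g. "spA" or "spA/spB".
#' @param bpm a [bpm()] object.
#' @param rank analysis rank (default "species").
#' @return Named numeric vector of probabilities (NA if no genomes), with
#'   attribute `n_genomes`.
#' @export
phenotype_probability <- function(taxon, bpm, rank = "species") {
  stopifnot(inherits(bpm, "bpm"))
  rank <- match.arg(rank, RANKS)
  parts <- split_multi_name(taxon)
  idx <- which(bpm$lineage[[rank]] %in% parts)
  if (length(idx) == 0) {
    p <- setNames(rep(NA_real_, ncol(bpm$mat)), colnames(bpm$mat))
  } else {
    p <- colMeans(bpm$mat[idx, , drop = FALSE])
  }
  attr(p, "n_genomes") <- length(idx)
  p
}

#' Phenotype probability table over a taxon set
#'
#' @param taxa character vector of taxon names at the analysis rank.
#' @param bpm a [bpm()] object.
#' @param rank analysis rank.
#' @return Object of class `prob_table`: list with `p` (taxa x phenotypes
#'   matrix, NA rows marking taxa without reference genomes) and
#'   `n_genomes` (named integer vector of supporting genome counts).
#' @export
phenotype_probability_table <- function(taxa, bpm, rank = "species") {
  if (anyDuplicated(taxa)) stop_input("taxon names must be unique")
  res <- lapply(taxa, phenotype_probability, bpm = bpm, rank = rank)
  p <- do.call(rbind, res)
  rownames(p) <- taxa
  n_genomes <- vapply(res, attr, integer(1), which = "n_genomes")
  names(n_genomes) <- taxa
  structure(list(p = p, n_genomes = n_genomes, rank = rank),
            class = "prob_table")
}

#' @export
print.prob_table <- function(x, ...) {
  cat(sprintf("Phenotype probabilities: %d taxa x %d phenotypes (%d taxa without genomes)\n",
              nrow(x$p), ncol(x$p), sum(x$n_genomes == 0)))
  invisible(x)
}

#' Community Phenotype Index of one sample
#'
#' CPI is the abundance-weighted sum of taxon phenotype probabilities,
#' scaled to percent: the predicted fraction of community cells carrying
#' the phenotype. Taxa without reference genomes (NA probability) are
#' excluded and the remaining abundances re-closed before the sum; the
#' excluded mass is reported in the `excluded_mass` attribute.
#'
#' @param abundances named relative abundances of one sample (summing to 1
#'   over taxa with defined and missing probabilities together).
#' @param probs named phenotype probabilities over the same taxa (NA =
#'   missing).
#' @return CPI in percent `[0, 100]` with attribute `excluded_mass`.
#' @export
#' @examples
#' compute_cpi(c(a = 0.5, b = 0.3, c = 0.2), c(a = 1, b = 0.5, c = 0))  # 65
compute_cpi <- function(abundances, probs) {
  if (is.null(names(abundances)) || is.null(names(probs))) {
    stop_input("abundances and probabilities must be named by taxon")
  }
  probs <- probs[names(abundances)]
  ok <- !is.na(probs)
  if (!any(ok)) stop_input("no taxon with a defined phenotype probability")
  excluded <- sum(abundances[!ok])
  a <- abundances[ok]
  total <- sum(a)
  if (total <= 0) stop_input("taxa with defined probabilities have zero abundance")
  cpi <- 100 * sum(probs[ok] * a / total)
  attr(cpi, "excluded_mass") <- excluded
  cpi
}

#' CPI table over all samples and phenotypes
#'
#' @param table a relative-mode `abund_table` whose taxa match the rows of
#'   `probs`.
#' @param probs a `prob_table` from [phenotype_probability_table()].
#' @return Object of class `cpi_table`: samples x phenotypes matrix of CPI
#'   percentages, with attributes `excluded_mass` (per sample) and `meta`
#'   (sample metadata, when present).
#' @export
cpi_matrix <- function(table, probs) {
  stopifnot(inherits(table, "abund_table"), inherits(probs, "prob_table"))
  if (table$mode != "relative") {
    stop_input("CPI requires a relative-mode abundance table")
  }
  taxa <- rownames(table$mat)
  missing <- setdiff(taxa, rownames(probs$p))
  if (length(missing) > 0) {
    stop_input("probability table lacks taxa: %s",
               paste(head(missing, 5), collapse = ", "))
  }
  p <- probs$p[taxa, , drop = FALSE]
  out <- matrix(NA_real_, nrow = ncol(table$mat), ncol = ncol(p),
                dimnames = list(colnames(table$mat), colnames(p)))
  excluded <- setNames(numeric(ncol(table$mat)), colnames(table$mat))
  for (s in seq_len(ncol(table$mat))) {
    for (j in seq_len(ncol(p))) {
      cpi <- tryCatch(compute_cpi(table$mat[, s], p[, j]), error = function(e) {
        stop_input("sample '%s', phenotype '%s': %s",
                   colnames(table$mat)[s], colnames(p)[j], conditionMessage(e))
      })
      out[s, j] <- as.numeric(cpi)
      excluded[s] <- attr(cpi, "excluded_mass")
    }
  }
  structure(out, excluded_mass = excluded, meta = table$meta,
            class = c("cpi_table", "matrix"))
}

#' @export
print.cpi_table <- function(x, ...) {
  cat(sprintf("CPI table: %d samples x %d phenotypes (percent)\n",
              nrow(x), ncol(x)))
  print(round(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE], 2))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
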