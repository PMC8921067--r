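## Abundance tables: taxa x samples matrices in counts or relative mode,
## with per-sample condition/replicate metadata. Relative-mode columns are
## closed (sum to 1).

#' Construct/validate an abundance table
#'
#' @param mat numeric matrix, taxa in rows, samples in columns, both
#'   dimensions named; no negative entries. In relative mode every sample
#'   column must sum to 1 within 1e-9.
#' @param meta optional data.frame with columns sample_id, condition,
#'   replicate covering every sample.
#' @param mode "counts" or "relative".
#' @return Object of class `abund_table` (list with `mat`, `meta`, `mode`).
#' @export
abund_table <- function(mat, meta = NULL, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop_input("abundance matrix needs taxon rownames and sample colnames")
  }
  if (any(mat < 0)) stop_input("abundance values must be non-negative")
  if (mode == "relative") {
    sums <- colSums(mat)
    off <- abs(sums - 1) > 1e-9
    if (any(off)) {
      stop_input("relative-mode sample(s) not summing to 1: %s",
                 paste(colnames(mat)[off], collapse = ", "))
    }
  }
  if (!is.null(meta)) {
    need <- c("sample_id", "condition", "replicate")
    if (!all(need %in% names(meta))) {
      stop_input("metadata needs columns %s", paste(need, collapse = ", "))
    }
    if (!all(colnames(mat) %in% meta$sample_id)) {
      stop_input("metadata is missing sample(s): %s",
                 paste(setdiff(colnames(mat), meta$sample_id), collapse = ", "))
    }
    meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(mat = mat, meta = meta, mode = mode), class = "abund_table")
}

#' @export
print.abund_table <- function(x, ...) {
  cat(sprintf("Abundance table (%s): %d taxa x %d samples\n",
              x$mode, nrow(x$mat), ncol(x$mat)))
  if (!is.null(x$meta)) {
    cat("Conditions:", paste(unique(x$meta$condition), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a counts table to relative abundance
#'
#' @param table an `abund_table` in counts mode.
#' @return The table in relative mode (each sample closed to sum 1).
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abund_table"))
  if (table$mode == "relative") return(table)
  sums <- colSums(table$mat)
  zero <- sums <= 0
  if (any(zero)) {
    stop_input("sample(s) with zero total count: %s",
               paste(colnames(table$mat)[zero], collapse = ", "))
  }
  abund_table(sweep(table$mat, 2L, sums, "/"), meta = table$meta,
              mode = "relative")
}

## Resolve each (possibly "/"-joined) taxon name to a mean copy number.
lookup_copy_numbers <- function(names_at_rank, cn, rank, fallback) {
  cn_rank <- cn[cn$rank == rank, , drop = FALSE]
  if (nrow(cn_rank) == 0) {
    stop_input("copy-number table has no entries at rank '%s'", rank)
  }
  grand_mean <- mean(cn_rank$mean_copies)
  used_fallback <- character(0)
  copies <- vapply(names_at_rank, function(nm) {
    parts <- split_multi_name(nm)
    found <- cn_rank$mean_copies[match(parts, cn_rank$name)]
    found <- found[!is.na(found)]
    if (length(found) == 0) {
      used_fallback <<- c(used_fallback, nm)
      grand_mean
    } else {
      mean(found)   # multi-name taxa average their constituents' means
    }
  }, numeric(1))
  if (length(used_fallback) > 0 && !fallback) {
    stop_input("no copy number at rank '%s' for taxa: %s",
               rank, paste(unique(used_fallback), collapse = ", "))
  }
  attr(copies, "fallback_taxa") <- unique(used_fallback)
  copies
}

#' Renormalize relative abundances by 16S copy number
#'
#' Divides every taxon's abundance by the mean 16S copy number of its name
#' at the chosen rank and re-closes each sample to sum 1, converting
#' read-fraction abundances into cell-fraction abundances. Multi-name
#' ("/"-joined) taxa use the mean over their constituent names' entries.
#' Taxa without a copy-number entry fall back to the table's grand mean
#' (reported in the `fallback_taxa` attribute) unless `fallback = FALSE`,
#' in which case they raise an error listing the taxa.
#'
#' @param table an `abund_table` (counts tables are converted to relative
#'   first).
#' @param cn a [cn_table()].
#' @param rank rank of the copy-number averaging (default "species").
#' @param assignments optional `mta_table` mapping the table's taxon ids
#'   (ASV ids) to rank names; when NULL the taxon ids are taken to be rank
#'   names already (e.g. after [aggregate_to_rank()]).
#' @param fallback use the grand-mean fallback for missing taxa?
#' @return Relative-mode `abund_table`, with attribute `fallback_taxa`.
#' @export
copy_number_renormalize <- function(table, cn, rank = "species",
                                    assignments = NULL, fallback = TRUE) {
  stopifnot(inherits(table, "abund_table"), inherits(cn, "cn_table"))
  rank <- match.arg(rank, RANKS)
  rel <- to_relative(table)
  taxa <- rownames(rel$mat)
  names_at_rank <- if (is.null(assignments)) {
    taxa
  } else {
    nm <- assignments[[rank]][match(taxa, assignments$asv_id)]
    if (anyNA(nm)) {
      stop_input("no assignment at rank '%s' for taxa: %s", rank,
                 paste(taxa[is.na(nm)], collapse = ", "))
    }
    nm
  }
  copies <- lookup_copy_numbers(names_at_rank, cn, rank, fallback)
  mat <- rel$mat / as.vector(copies)   # rows recycle over columns
  mat <- sweep(mat, 2L, colSums(mat), "/")
  out <- abund_table(mat, meta = rel$meta, mode = "relative")
  fb <- attr(copies, "fallback_taxa")
  if (length(fb) > 0) attr(out, "fallback_taxa") <- fb
  out
}

#' Aggregate an abundance table to a taxonomic rank
#'
#' Sums taxa sharing the same (possibly "/"-joined) name at the chosen
#' rank; per-sample totals are conserved.
#'
#' @param table an `abund_table` whose taxa are ASV/phylotype ids.
#' @param assignments an `mta_table` from [assign_taxonomy()] covering
#'   every taxon.
#' @param rank target rank.
#' @return `abund_table` in the same mode with rank names as taxon ids.
#' @export
aggregate_to_rank <- function(table, assignments, rank = "species") {
  stopifnot(inherits(table, "abund_table"))
  rank <- match.arg(rank, RANKS)
  taxa <- rownames(table$mat)
  keys <- assignments[[rank]][match(taxa, assignments$asv_id)]
  if (anyNA(keys)) {
    stop_input("unassigned taxa at rank '%s': %s", rank,
               paste(taxa[is.na(keys)], collapse = ", "))
  }
  agg <- rowsum(table$mat, group = keys, reorder = TRUE)
  abund_table(agg, meta = table$meta, mode = table$mode)
}

#' Count taxa observed above a detection threshold
#'
#' Number of taxa whose mean abundance over the selected samples strictly
#' exceeds the threshold (zero counts read as below the detection limit).
#'
#' @param table an `abund_table`.
#' @param samples sample ids (or a logical/integer column selector);
#'   default all samples.
#' @param threshold detection threshold (>= 0), strict inequality.
#' @return Integer count.
#' @export
count_observed <- function(table, samples = NULL, threshold = 0) {
  stopifnot(inherits(table, "abund_table"))
  if (threshold < 0) stop_input("`threshold` must be >= 0")
  mat <- table$mat
  if (!is.null(samples)) {
    mat <- mat[, samples, drop = FALSE]
  }
  if (ncol(mat) == 0) stop_input("empty sample subset")
  sum(rowMeans(mat) > threshold)
}
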