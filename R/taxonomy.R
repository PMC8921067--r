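## Multi-taxonomy approach (MTA): each ASV collects every reference hit
## whose identity exceeds M - (1 - M)/4, where M is its best identity, and
## receives the "/"-joined consensus of the accepted lineages.

check_sequence <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop_input("%s must be a non-empty nucleotide string", what)
  }
  if (grepl("[^ACGT]", x)) {
    stop_input("%s contains characters outside A/C/G/T", what)
  }
  invisible(x)
}

#' Pairwise global-alignment identity of two nucleotide sequences
#'
#' Aligns the two sequences globally under unit mismatch and gap costs
#' (i.e. the alignment minimizing edit distance) and returns
#' matches / alignment length, with gap columns counting against identity.
#'
#' @param seq_a,seq_b non-empty strings over A/C/G/T.
#' @return Identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
#' @examples
#' pairwise_identity("ACGT", "ACGA")  # 0.75
pairwise_identity <- function(seq_a, seq_b) {
  check_sequence(seq_a, "`seq_a`")
  check_sequence(seq_b, "`seq_b`")
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = sub_mat,
    gapOpening = 0, gapExtension = 1)
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::pattern(aln)))
}

#' Identities of many ASVs against a reference database
#'
#' Batch form of [pairwise_identity()]: aligns every ASV against every
#' reference strain sequence. For large references a precomputed identity
#' table (see [read_identity_tsv()]) can be used instead.
#'
#' @param asv_seqs named character vector of ASV sequences.
#' @param ref_db a `ref_db` object.
#' @return data.frame of `AlignmentHit`s: asv_id, strain_id, identity.
#' @export
compute_identities <- function(asv_seqs, ref_db) {
  if (is.null(names(asv_seqs)) || anyDuplicated(names(asv_seqs))) {
    stop_input("ASV sequences must have unique names")
  }
  for (s in asv_seqs) check_sequence(s, "ASV sequence")
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1)
  asv_set <- Biostrings::DNAStringSet(asv_seqs)
  hits <- vector("list", length(ref_db$sequences))
  for (j in seq_along(ref_db$sequences)) {
    aln <- Biostrings::pairwiseAlignment(
      asv_set, ref_db$sequences[[j]], type = "global",
      substitutionMatrix = sub_mat, gapOpening = 0, gapExtension = 1)
    ident <- Biostrings::nmatch(aln) /
      nchar(as.character(Biostrings::pattern(aln)))
    hits[[j]] <- data.frame(asv_id = names(asv_seqs),
                            strain_id = names(ref_db$sequences)[j],
                            identity = ident, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$asv_id, -out$identity, out$strain_id), ]
  rownames(out) <- NULL
  out
}

#' The MTA acceptance threshold
#'
#' For a best identity `M`, reference hits with identity strictly greater
#' than `M - (1 - M)/4` are accepted into the multi-taxonomy assignment.
#'
#' @param M best identity fraction in `[0, 1]`.
#' @return Threshold `M - (1 - M)/4` (can be negative for small `M`, in
#'   which case every hit is accepted).
#' @export
#' @examples
#' compute_mta_threshold(0.98)  # 0.975
compute_mta_threshold <- function(M) {
  if (!is.numeric(M) || anyNA(M) || any(M < 0) || any(M > 1)) {
    stop_input("`M` must lie in [0, 1]")
  }
  M - (1 - M) / 4
}

#' Multi-taxonomy assignment of one ASV
#'
#' Sorts the hits by identity, takes the maximum as `M`, accepts every hit
#' with identity strictly above `M - (1 - M)/4` -- always including the
#' maximal hit(s), so an ASV keeps its best match even at the `M = 1`
#' boundary where the threshold equals `M` -- and merges the accepted
#' references' lineages into a "/"-joined consensus.
#'
#' @param asv_id identifier of the ASV.
#' @param hits data.frame with columns strain_id, identity (one row per
#'   reference hit for this ASV); must be non-empty.
#' @param ref_db a `ref_db` supplying lineages of the hit strains.
#' @return List of class `mta` with asv_id, M, tau, accepted_refs
#'   (character vector, best first) and lineage (named character vector).
#' @export
assign_multi_taxonomy <- function(asv_id, hits, ref_db) {
  if (is.null(hits) || nrow(hits) == 0) {
    stop_input("ASV '%s' has no reference hits: unassigned", asv_id)
  }
  if (any(hits$identity < 0 | hits$identity > 1)) {
    stop_input("hit identities must lie in [0, 1]")
  }
  M <- max(hits$identity)
  tau <- compute_mta_threshold(M)
  keep <- hits$identity > tau | hits$identity == M
  acc <- hits[keep, , drop = FALSE]
  acc <- acc[order(-acc$identity, acc$strain_id), , drop = FALSE]
  idx <- match(acc$strain_id, ref_db$strains$strain_id)
  if (anyNA(idx)) {
    stop_input("hit strain(s) absent from reference database: %s",
               paste(acc$strain_id[is.na(idx)], collapse = ", "))
  }
  lineage <- merge_lineages(ref_db$strains[idx, RANKS, drop = FALSE])
  structure(list(asv_id = asv_id, M = M, tau = tau,
                 accepted_refs = acc$strain_id, lineage = lineage),
            class = "mta")
}

#' @export
print.mta <- function(x, ...) {
  cat(sprintf("MTA assignment %s: M = %.4f, tau = %.4f, %d accepted ref(s)\n",
              x$asv_id, x$M, x$tau, length(x$accepted_refs)))
  cat("  ", paste(x$lineage, collapse = "; "), "\n")
  invisible(x)
}

#' Multi-taxonomy assignment of an ASV set
#'
#' Applies [assign_multi_taxonomy()] to every ASV. ASVs without any hit are
#' reported unassigned (NA ranks) with a warning rather than dropped.
#'
#' @param asv_seqs named character vector of ASV sequences, or NULL when
#'   `hits` is precomputed and covers all ASVs.
#' @param ref_db a `ref_db` object.
#' @param hits optional precomputed hit table (asv_id, strain_id, identity);
#'   computed with [compute_identities()] when absent.
#' @return data.frame of class `mta_table`: asv_id, M, tau, accepted_refs
#'   (";"-joined) and one column per rank with "/"-joined names.
#' @export
assign_taxonomy <- function(asv_seqs, ref_db, hits = NULL) {
  if (is.null(hits)) {
    hits <- compute_identities(asv_seqs, ref_db)
  }
  ids <- if (!is.null(asv_seqs)) names(asv_seqs) else unique(hits$asv_id)
  rows <- lapply(ids, function(id) {
    h <- hits[hits$asv_id == id, , drop = FALSE]
    if (nrow(h) == 0) {
      warning(sprintf("ASV '%s' has no reference hits: unassigned", id),
              call. = FALSE)
      out <- data.frame(asv_id = id, M = NA_real_, tau = NA_real_,
                        accepted_refs = NA_character_,
                        stringsAsFactors = FALSE)
      out[RANKS] <- NA_character_
      return(out)
    }
    a <- assign_multi_taxonomy(id, h, ref_db)
    out <- data.frame(asv_id = id, M = a$M, tau = a$tau,
                      accepted_refs = paste(a$accepted_refs, collapse = ";"),
                      stringsAsFactors = FALSE)
    out[RANKS] <- as.list(a$lineage)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("mta_table", "data.frame"))
}
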