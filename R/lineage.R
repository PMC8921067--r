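## Lineages are named character vectors (or data.frame rows) over the seven
## ranks in taxonomic_ranks(). Multi-names within a rank are "/"-joined.

as_lineage_frame <- function(lineages) {
  if (is.data.frame(lineages)) {
    lf <- lineages
  } else if (is.list(lineages)) {
    lf <- do.call(rbind, lapply(lineages, function(x) {
      as.data.frame(as.list(x), stringsAsFactors = FALSE)
    }))
  } else if (is.character(lineages)) {         # a single lineage vector
    lf <- as.data.frame(as.list(lineages), stringsAsFactors = FALSE)
  } else {
    stop_input("lineages must be a data.frame, list, or named character vector")
  }
  missing_ranks <- setdiff(RANKS, names(lf))
  if (length(missing_ranks) > 0) {
    stop_input("lineage is incomplete: missing rank(s) %s",
               paste(missing_ranks, collapse = ", "))
  }
  lf <- lf[RANKS]
  bad <- vapply(lf, function(col) anyNA(col) | any(!nzchar(col)), logical(1))
  if (any(bad)) {
    stop_input("lineage has empty or NA names at rank(s) %s",
               paste(RANKS[bad], collapse = ", "))
  }
  lf
}

#' Merge lineages into a "/"-joined consensus lineage
#'
#' Combines the lineages of all reference sequences accepted for one ASV.
#' At every rank the distinct names are deduplicated, sorted alphabetically
#' and joined with `"/"`; a rank where all inputs agree keeps its single
#' name. Inputs whose names are themselves already "/"-joined are split
#' first, so merging is idempotent and order-invariant.
#'
#' @param lineages a data.frame with one column per rank (see
#'   [taxonomic_ranks()]), a list of named character vectors, or a single
#'   named character vector.
#' @return Named character vector over the seven ranks.
#' @export
#' @examples
#' merge_lineages(data.frame(
#'   domain = "Bacteria", phylum = "Firmicutes", class = "Clostridia",
#'   order = "Lachnospirales", family = "Lachnospiraceae", genus = "Blautia",
#'   species = c("Blautia obeum", "Blautia wexlerae")
#' ))["species"]
merge_lineages <- function(lineages) {
  lf <- as_lineage_frame(lineages)
  out <- vapply(RANKS, function(r) {
    parts <- unique(unlist(strsplit(lf[[r]], "/", fixed = TRUE)))
    paste(sort(parts), collapse = "/")
  }, character(1))
  names(out) <- RANKS
  out
}

## Split a possibly "/"-joined name into its constituent names.
split_multi_name <- function(name) {
  unique(unlist(strsplit(name, "/", fixed = TRUE)))
}

lineage_to_string <- function(lf) {
  apply(as_lineage_frame(lf)[RANKS], 1L, paste, collapse = ";")
}

lineage_from_string <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  n <- lengths(parts)
  if (any(n != length(RANKS))) {
    stop_input("lineage string must have %d ';'-separated ranks (got %s)",
               length(RANKS), paste(unique(n[n != length(RANKS)]), collapse = ","))
  }
  lf <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(lf) <- RANKS
  as_lineage_frame(lf)
}
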