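## Readers/writers for the pipeline's plain-text interchange formats:
## FASTA for sequences, tab-delimited UTF-8 TSV with a header row for all
## tables ('.' decimal separator), '#mode=' comment line on abundance
## tables, YAML/JSON for configuration.

#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (ids = first header token),
#'   input order preserved. Duplicate ids are rejected.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) stop_input("empty FASTA file: %s", path)
  first <- nonempty[1]
  if (!startsWith(lines[first], ">")) {
    stop_input("malformed FASTA record at line %d of %s: expected '>'",
               first, path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop_input("duplicate FASTA id(s): %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  setNames(as.character(set), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) stop_input("sequences must be named")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 70L)
  invisible(path)
}

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(comment, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      stop_input("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", "))
    }
  }
  df
}

#' Read/write lineage tables
#'
#' Lineage TSVs have columns `strain_id` and `lineage`
#' (domain;phylum;class;order;family;genus;species).
#'
#' @param path file path.
#' @return data.frame with strain_id plus one column per rank.
#' @export
read_lineage_tsv <- function(path) {
  df <- read_tsv(path, required = c("strain_id", "lineage"))
  if (anyDuplicated(df$strain_id)) stop_input("%s: duplicate strain ids", path)
  lf <- lineage_from_string(df$lineage)
  cbind(data.frame(strain_id = df$strain_id, stringsAsFactors = FALSE), lf)
}

#' @rdname read_lineage_tsv
#' @param strains data.frame with strain_id and the seven rank columns.
#' @export
write_lineage_tsv <- function(strains, path) {
  write_tsv(data.frame(strain_id = strains$strain_id,
                       lineage = lineage_to_string(strains[RANKS]),
                       stringsAsFactors = FALSE), path)
}

#' Read/write copy-number tables
#'
#' Columns: rank, name, mean_copies (all >= 1).
#'
#' @param path file path.
#' @return A [cn_table()].
#' @export
read_cn_tsv <- function(path) {
  df <- read_tsv(path, required = c("rank", "name", "mean_copies"))
  df$mean_copies <- as.numeric(df$mean_copies)
  if (anyNA(df$mean_copies)) stop_input("%s: non-numeric mean_copies", path)
  cn_table(df)
}

#' @rdname read_cn_tsv
#' @param cn a `cn_table`.
#' @export
write_cn_tsv <- function(cn, path) write_tsv(cn, path)

#' Read/write binary phenotype matrices
#'
#' BPM TSVs have columns genome_id, lineage (";"-separated ranks), then one
#' column per phenotype with cells strictly "0" or "1".
#'
#' @param path file path.
#' @return A [bpm()] object.
#' @export
read_bpm_tsv <- function(path) {
  df <- read_tsv(path, required = c("genome_id", "lineage"))
  phen <- setdiff(names(df), c("genome_id", "lineage"))
  if (length(phen) == 0) stop_input("%s: no phenotype columns", path)
  mat <- matrix(NA_integer_, nrow(df), length(phen),
                dimnames = list(df$genome_id, phen))
  for (ph in phen) {
    cell <- df[[ph]]
    bad <- !(cell %in% c("0", "1"))
    if (any(bad)) {
      stop_input("%s: non-binary BPM cell '%s' (genome %s, phenotype %s)",
                 path, cell[bad][1], df$genome_id[bad][1], ph)
    }
    mat[, ph] <- as.integer(cell)
  }
  lin <- lineage_from_string(df$lineage)
  bpm(mat, cbind(data.frame(genome_id = df$genome_id,
                            stringsAsFactors = FALSE), lin))
}

#' @rdname read_bpm_tsv
#' @param x a `bpm` object.
#' @export
write_bpm_tsv <- function(x, path) {
  df <- data.frame(genome_id = rownames(x$mat),
                   lineage = lineage_to_string(x$lineage[RANKS]),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x$mat))
  write_tsv(df, path)
}

#' Read/write abundance (count) tables
#'
#' Abundance TSVs carry a `#mode=counts` or `#mode=relative` comment line,
#' then a header row (`taxon_id` followed by sample ids) and one row per
#' taxon. Counts round-trip as exact integers.
#'
#' @param path file path.
#' @param meta optional metadata data.frame attached to the result.
#' @return An [abund_table()].
#' @export
read_counts_tsv <- function(path, meta = NULL) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  first <- readLines(path, n = 1L)
  mode <- if (grepl("^#mode=", first)) sub("^#mode=", "", first) else "counts"
  if (!mode %in% c("counts", "relative")) {
    stop_input("%s: unknown mode '%s'", path, mode)
  }
  df <- read_tsv(path, required = "taxon_id")
  samples <- setdiff(names(df), "taxon_id")
  if (length(samples) == 0) stop_input("%s: no sample columns", path)
  mat <- sapply(df[samples], as.numeric)
  mat <- matrix(mat, nrow = nrow(df), dimnames = list(df$taxon_id, samples))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop_input("%s: non-numeric value (taxon %s, sample %s)", path,
               df$taxon_id[bad[1]], samples[bad[2]])
  }
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop_input("%s: negative value (taxon %s, sample %s)", path,
               df$taxon_id[bad[1]], samples[bad[2]])
  }
  abund_table(mat, meta = meta, mode = mode)
}

#' @rdname read_counts_tsv
#' @param table an `abund_table`.
#' @export
write_counts_tsv <- function(table, path) {
  stopifnot(inherits(table, "abund_table"))
  df <- data.frame(taxon_id = rownames(table$mat), stringsAsFactors = FALSE)
  mat <- table$mat
  if (table$mode == "relative") {
    df <- cbind(df, format(as.data.frame(mat), digits = 15, trim = TRUE,
                           scientific = FALSE))
  } else {
    df <- cbind(df, as.data.frame(mat))
  }
  write_tsv(df, path, comment = paste0("#mode=", table$mode))
}

#' Read/write sample metadata
#'
#' Columns: sample_id, condition, replicate.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_metadata_tsv <- function(path) {
  df <- read_tsv(path, required = c("sample_id", "condition", "replicate"))
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$sample_id)) stop_input("%s: duplicate sample ids", path)
  df
}

#' @rdname read_metadata_tsv
#' @param meta metadata data.frame.
#' @export
write_metadata_tsv <- function(meta, path) {
  write_tsv(meta[c("sample_id", "condition", "replicate")], path)
}

#' Read a precomputed identity table
#'
#' Pluggable identity provider for large references: columns asv_id,
#' strain_id, identity (fraction in 0-1).
#'
#' @param path file path.
#' @return data.frame of alignment hits.
#' @export
read_identity_tsv <- function(path) {
  df <- read_tsv(path, required = c("asv_id", "strain_id", "identity"))
  df$identity <- as.numeric(df$identity)
  if (anyNA(df$identity) || any(df$identity < 0) || any(df$identity > 1)) {
    stop_input("%s: identities must be fractions in [0, 1]", path)
  }
  df
}

#' Write/read ground truth from a simulation
#'
#' Long-form TSV with columns condition, strain_id, multiplier, followed by
#' per-sample true cell proportions and (when present) true CPI
#' expectations in companion files `<path>` (multipliers),
#' `<path base>_props.tsv` and `<path base>_cpi.tsv`.
#'
#' @param truth a `ground_truth` object.
#' @param path path of the multiplier TSV.
#' @return Invisibly, the written paths.
#' @export
write_ground_truth_tsv <- function(truth, path) {
  m <- truth$multipliers
  long <- data.frame(
    condition = rep(rownames(m), times = ncol(m)),
    strain_id = rep(colnames(m), each = nrow(m)),
    multiplier = as.vector(m),
    stringsAsFactors = FALSE
  )
  write_tsv(long, path)
  base <- sub("\\.tsv$", "", path)
  props_path <- paste0(base, "_props.tsv")
  props <- data.frame(strain_id = rownames(truth$true_props),
                      stringsAsFactors = FALSE)
  props <- cbind(props, format(as.data.frame(truth$true_props), digits = 15,
                               trim = TRUE, scientific = FALSE))
  write_tsv(props, props_path)
  paths <- c(path, props_path)
  if (!is.null(truth$cpi)) {
    cpi_path <- paste0(base, "_cpi.tsv")
    cpi <- data.frame(sample_id = rownames(truth$cpi), stringsAsFactors = FALSE)
    cpi <- cbind(cpi, format(as.data.frame(truth$cpi), digits = 15,
                             trim = TRUE, scientific = FALSE))
    write_tsv(cpi, cpi_path)
    paths <- c(paths, cpi_path)
  }
  invisible(paths)
}

#' Read a pipeline configuration
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`) file whose keys mirror the
#' [run_pipeline()] configuration fields.
#'
#' @param path config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_input("unsupported config format '.%s' (use YAML or JSON)", ext)
  }
}

#' Write a CPI table as TSV (percent, 4 decimals)
#'
#' @param x a `cpi_table`.
#' @param path output path.
#' @export
write_cpi_tsv <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), stringsAsFactors = FALSE)
  df <- cbind(df, round(as.data.frame(unclass(x)), 4))
  write_tsv(df, path)
}
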