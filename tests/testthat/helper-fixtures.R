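# Fixtures are built in code: a hand-written three-species lineage frame,
# small seeded reference databases, and a tiny deterministic abundance
# table shared across abundance/phenotype tests.

fix_lineage <- function(species, genus = "Blautia") {
  data.frame(
    domain = "Bacteria", phylum = "Firmicutes", class = "Clostridia",
    order = "Lachnospirales", family = "Lachnospiraceae", genus = genus,
    species = species, stringsAsFactors = FALSE
  )
}

# Minimal ref_db with explicit lineages/sequences, no generator involved.
fix_ref_db <- function() {
  strains <- cbind(
    data.frame(strain_id = c("s1", "s2", "s3"), stringsAsFactors = FALSE),
    fix_lineage(c("obeum", "wexlerae", "obeum")),
    data.frame(copy_number = c(4, 4, 4))
  )
  structure(list(
    strains = strains,
    sequences = c(s1 = "ACGTACGT", s2 = "ACGTACGA", s3 = "ACGTACGG"),
    genomes = cbind(data.frame(genome_id = paste0("G_", strains$strain_id),
                               strain_id = strains$strain_id,
                               stringsAsFactors = FALSE),
                    fix_lineage(c("obeum", "wexlerae", "obeum")))
  ), class = "ref_db")
}

fix_meta <- function(conditions = c("control", "butyrate"), replicates = 2) {
  data.frame(
    sample_id = as.vector(t(outer(conditions, seq_len(replicates), paste,
                                  sep = "_"))),
    condition = rep(conditions, each = replicates),
    replicate = rep(seq_len(replicates), length(conditions)),
    stringsAsFactors = FALSE
  )
}

fix_counts <- function() {
  meta <- fix_meta()
  mat <- matrix(c(10, 30, 60,
                  20, 20, 60,
                  60, 30, 10,
                  50, 40, 10),
                nrow = 3, dimnames = list(c("t1", "t2", "t3"),
                                          meta$sample_id))
  abund_table(mat, meta = meta, mode = "counts")
}

# Random closed composition (uniform on the simplex).
rdirichlet_test <- function(k) {
  g <- rgamma(k, 1)
  g / sum(g)
}

# Independent brute-force MTA filter used as the oracle: no shared code
# with assign_multi_taxonomy.
brute_force_accept <- function(identities) {
  M <- max(identities)
  tau <- M - (1 - M) / 4
  names(identities)[identities > tau | identities == M]
}
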