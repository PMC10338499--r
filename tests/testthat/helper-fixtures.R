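# shared fixture builders; everything is generated in code at test time

# quick in-memory catalog from ligand/receptor vectors
quick_catalog <- function(lig, rec, src = "src", species = "human",
                          evidence = "predicted") {
  lrtalk::lr_catalog(
    tibble::tibble(ligand = lig, receptor = rec, sources = src,
                   evidence = evidence, id_flag = FALSE),
    species = species, source_names = src
  )
}

# random catalog of n distinct pairs drawn from a universe of gene labels
random_catalog <- function(n, universe_size = 100, src = "src",
                           species = "human") {
  stopifnot(n <= universe_size)
  idx <- sample.int(universe_size, n)
  quick_catalog(sprintf("L%03d", idx), sprintf("R%03d", idx), src = src,
                species = species)
}

# write a small LR source CSV, returning its path
write_lr_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, paste0("lr_", paste(sample(letters, 6), collapse = ""),
                                ".csv"))
  readr::write_csv(df, path, progress = FALSE)
  path
}

# independent scalar rank: position of each gene in a sample, descending,
# average ties, computed by counting rather than rank()
oracle_rank_scores <- function(x) {
  G <- length(x)
  pos <- vapply(seq_len(G), function(i) {
    higher <- sum(x > x[i])
    ties <- sum(x == x[i])
    higher + (1 + ties) / 2 # average position among the tied block
  }, numeric(1))
  10 * (G - pos + 1) / G
}

# scalar interaction strength, element by element
oracle_is <- function(r1, r2) (r1 + r2) * (10 - abs(r1 - r2))

# write a per-method prediction CSV
write_pred_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, paste0("pred_", paste(sample(letters, 6), collapse = ""),
                                ".csv"))
  readr::write_csv(df, path, progress = FALSE)
  path
}

# a small curated-interaction data frame
curated_fixture <- function() {
  tibble::tibble(
    gene_a = c("PDCD1", "CTLA4", "CD274", "TGFB1", "IL6"),
    gene_b = c("CD274", "CD80", "PDCD1", "TGFBR1", "IL6R"),
    tumor_cell = "tumor cell",
    immune_cell = c("CD8+ T cell", "CD4+ T cell", "CD8+ T cell",
                    "regulatory T cell", "macrophage"),
    interaction_type = c("direct", "direct", "direct", "indirect", "indirect"),
    species = "human",
    cancer_type = c("skin cancer", "lung cancer", "skin cancer",
                    "breast cancer", "breast cancer"),
    cancer_subtype = "subtype",
    experiment = "Western blot",
    description = "curated record",
    pmid = c("10000001", "10000002", "10000003", "10000004", "10000005")
  )
}
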