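# the five output CSV schemas; internal column -> output header
.schemas <- list(
  integrated_lr = c("ligand", "receptor", "function", "sources", "evidence"),
  curated_tic = c("gene_a", "gene_b", "tumor_cell", "immune_cell",
                  "interaction_type", "species", "cancer_type",
                  "cancer_subtype", "experiment", "description", "pmid"),
  predicted_bulk_tic = c("gene_a", "gene_b", "tumor_cell", "immune_cell",
                         "cancer_type", "interaction_strength", "p_value"),
  predicted_bulk_lr = c("ligand", "receptor", "function", "evidence",
                        "cancer_type", "interaction_strength", "p_value"),
  predicted_sc = c("ligand", "receptor", "sender_cell", "receiver_cell",
                   "method", "evidence", "dataset", "cancer_type")
)

# aliases: internal result-column names accepted for each schema column
.schema_aliases <- c(
  gene_a = "gene1", gene_b = "gene2",
  interaction_strength = "summary_is",
  `function` = "primary_group",
  sender_cell = "sender", receiver_cell = "receiver"
)

#' Output schema names
#'
#' @return Character vector of the named CSV schemas [write_outputs()]
#'   accepts.
#' @export
output_schemas <- function() names(.schemas)

#' Write results in one of the standard CSV schemas
#'
#' Renders a result table into one of the fixed-column CSV layouts
#' (see [output_schemas()]): integrated ligand-receptor catalog, curated
#' interactions, bulk-scored interactions against curated or catalog
#' references, and single-cell consensus predictions. Column order is fixed
#' per schema; known internal result columns (`gene1`/`gene2`,
#' `summary_is`, `primary_group`, `sender`/`receiver`) are mapped
#' automatically and absent columns are filled from `defaults` or left
#' empty. Files are UTF-8, RFC 4180 comma-separated.
#'
#' @param x Data frame of results.
#' @param schema One of [output_schemas()].
#' @param path Output file path.
#' @param defaults Named list of constant values for schema columns missing
#'   from `x` (e.g. `list(cancer_type = "breast cancer")`).
#' @return `path`, invisibly.
#' @export
write_outputs <- function(x, schema, path, defaults = list()) {
  if (!schema %in% names(.schemas)) {
    stop("unknown schema '", schema, "'; valid schemas: ",
         paste(names(.schemas), collapse = ", "), call. = FALSE)
  }
  cols <- .schemas[[schema]]
  x <- as.data.frame(x)
  out <- lapply(cols, function(col) {
    if (col %in% names(x)) return(x[[col]])
    alias <- if (col %in% names(.schema_aliases)) .schema_aliases[[col]] else NULL
    if (!is.null(alias) && alias %in% names(x)) return(x[[alias]])
    if (col %in% names(defaults)) return(rep(defaults[[col]], length.out = max(nrow(x), 0)))
    rep(NA, max(nrow(x), 0))
  })
  names(out) <- cols
  readr::write_csv(tibble::as_tibble(out), path, na = "", progress = FALSE)
  invisible(path)
}

#' Controlled vocabularies
#'
#' Loads the editable controlled vocabularies shipped with the package:
#' the three interaction-type categories, the 14 immune-cell labels, and
#' the functional-group vocabulary. Users can point `path` at their own
#' YAML to extend the lists.
#'
#' @param path YAML file; defaults to the copy shipped in the package.
#' @return Named list of character vectors.
#' @export
load_vocab <- function(path = system.file("extdata", "controlled_vocab.yaml",
                                          package = "lrtalk")) {
  yaml::read_yaml(path)
}

#' Read a curated tumor-immune interaction table
#'
#' Curated interactions are experimentally verified records of signaling
#' between tumor and immune cells, in three categories: `direct` (physical
#' tumor-immune contact), `secretory` (secreted molecule binding a
#' receptor) and `indirect` (intracellular interactions essential to tumor
#' immunity). Rows whose interaction type falls outside this vocabulary, or
#' whose PMID is present but not a positive integer, are rejected and
#' reported.
#'
#' @param path CSV with the curated-table columns (see the `curated_tic`
#'   schema in [output_schemas()]).
#' @param columns Optional named list remapping schema roles to the file's
#'   column names.
#' @return Tibble of validated records with attributes `rejected` (the
#'   rejected rows with reasons) and `summary` (counts by interaction type,
#'   cancer type and immune cell).
#' @export
read_curated <- function(path, columns = list()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  cols <- .schemas$curated_tic
  mapping <- stats::setNames(cols, cols)
  for (role in names(columns)) mapping[[role]] <- columns[[role]]
  if (!mapping[["interaction_type"]] %in% names(raw)) {
    stop("curated table is missing the interaction_type column ('",
         mapping[["interaction_type"]], "')", call. = FALSE)
  }
  df <- tibble::as_tibble(lapply(mapping, function(src) {
    if (src %in% names(raw)) as.character(raw[[src]]) else
      rep(NA_character_, nrow(raw))
  }))

  type_ok <- df$interaction_type %in% c("direct", "secretory", "indirect")
  pmid_num <- suppressWarnings(as.numeric(df$pmid))
  pmid_ok <- is.na(df$pmid) | df$pmid == "" |
    (!is.na(pmid_num) & pmid_num > 0 & pmid_num == round(pmid_num))
  ok <- type_ok & pmid_ok
  rejected <- df[!ok, ]
  if (nrow(rejected) > 0) {
    rejected$reason <- ifelse(!type_ok[!ok],
                              paste0("unknown interaction_type '",
                                     df$interaction_type[!ok], "'"),
                              "PMID is not a positive integer")
    message(sprintf("rejected %d curated row(s): %s", nrow(rejected),
                    paste(utils::head(rejected$reason, 3), collapse = "; ")))
  }
  df <- df[ok, ]
  attr(df, "rejected") <- rejected
  attr(df, "summary") <- list(
    by_type = table(df$interaction_type),
    by_cancer = table(df$cancer_type),
    by_immune_cell = table(df$immune_cell)
  )
  df
}

#' Assemble a run configuration
#'
#' Central defaults for the pipeline thresholds: the permutation count, the
#' significance level (with a relaxed `"small-cohort"` profile for small
#' sample sizes), the bulk-cohort and single-cell admission thresholds, the
#' gene zero-fraction filter and the functional-group priority order. A
#' YAML file and direct overrides are merged over the defaults.
#'
#' @param path Optional YAML config file.
#' @param profile `"default"` (alpha 0.05) or `"small-cohort"` (alpha 0.1).
#' @param ... Named overrides applied last.
#' @return Named list of configuration values.
#' @export
run_config <- function(path = NULL, profile = c("default", "small-cohort"),
                       ...) {
  profile <- match.arg(profile)
  cfg <- list(
    alpha = if (profile == "small-cohort") 0.1 else 0.05,
    n_perm = 1000,
    min_samples = 6,
    min_cells = 500,
    zero_fraction_max = 0.30,
    group_priority = lr_groups(),
    seed = NULL
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  stopifnot(cfg$alpha > 0, cfg$alpha <= 1, cfg$n_perm >= 1,
            cfg$min_samples >= 1, cfg$min_cells >= 1,
            cfg$zero_fraction_max >= 0, cfg$zero_fraction_max < 1)
  cfg
}
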