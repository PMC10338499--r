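#' Functional group vocabulary for ligand-receptor pairs
#'
#' The ten functional groups used to classify ligand-receptor pairs, in the
#' default priority order (first match wins when a pair qualifies for several
#' groups). Pairs matching none of the groups fall into `"other"`, which is
#' not part of this vocabulary.
#'
#' @return Character vector of the ten group labels.
#' @export
#' @examples
#' lr_groups()
lr_groups <- function() {
  c(
    "notch signaling", "antigen binding", "neuropeptide", "hormone",
    "growth factor", "interferon", "interleukin", "tumor necrosis factor",
    "chemokine", "cytokine"
  )
}

#' Construct a ligand-receptor catalog
#'
#' An `lr_catalog` is a tibble of deduplicated, directed ligand-receptor
#' pairs for one species, carrying multi-source provenance and an evidence
#' subclass per pair. `(ligand, receptor)` is an ordered key: `(A, B)` and
#' `(B, A)` are distinct pairs because the ligand and receptor roles are not
#' interchangeable.
#'
#' @param pairs Data frame with columns `ligand`, `receptor` and optionally
#'   `sources` (";"-separated source names), `evidence`
#'   (`"manually_curated"` or `"predicted"`), `id_flag` (logical; `TRUE` for
#'   pairs whose gene identifiers could not be mapped and retain their
#'   original symbol).
#' @param species `"human"` or `"mouse"`.
#' @param source_names Character vector of contributing source datasets.
#' @return A tibble of class `lr_catalog` with attributes `species` and
#'   `source_names`.
#' @export
lr_catalog <- function(pairs, species = c("human", "mouse"),
                       source_names = character()) {
  species <- match.arg(species)
  pairs <- tibble::as_tibble(pairs)
  required <- c("ligand", "receptor")
  missing_cols <- setdiff(required, names(pairs))
  if (length(missing_cols) > 0) {
    stop("catalog is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"sources" %in% names(pairs)) {
    pairs$sources <- if (length(source_names)) source_names[[1]] else ""
  }
  if (!"evidence" %in% names(pairs)) pairs$evidence <- "predicted"
  if (!"id_flag" %in% names(pairs)) pairs$id_flag <- FALSE
  if (!"primary_group" %in% names(pairs)) pairs$primary_group <- NA_character_
  if (!"all_groups" %in% names(pairs)) pairs$all_groups <- NA_character_
  key <- paste(pairs$ligand, pairs$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (ligand, receptor) pairs in catalog", call. = FALSE)
  }
  bad_ev <- setdiff(unique(pairs$evidence), c("manually_curated", "predicted"))
  if (length(bad_ev) > 0) {
    stop("evidence must be 'manually_curated' or 'predicted', got: ",
         paste(bad_ev, collapse = ", "), call. = FALSE)
  }
  pairs <- pairs[order(pairs$ligand, pairs$receptor, method = "radix"), ]
  structure(
    pairs,
    species = species,
    source_names = unique(source_names),
    class = c("lr_catalog", class(tibble::tibble()))
  )
}

#' @export
print.lr_catalog <- function(x, ...) {
  cat(sprintf(
    "<lr_catalog> %d %s ligand-receptor pairs from %d source(s): %s\n",
    nrow(x), attr(x, "species"), length(attr(x, "source_names")),
    paste(attr(x, "source_names"), collapse = ", ")
  ))
  NextMethod()
}

# interpret an evidence column as curated / predicted
.parse_evidence <- function(x) {
  curated_tokens <- c(
    "manually_curated", "manually curated", "curated", "experimental",
    "literature", "literature supported", "true", "yes", "1"
  )
  tolower(trimws(as.character(x))) %in% curated_tokens
}

.guess_delim <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Load one ligand-receptor source table
#'
#' Reads a CSV/TSV table of ligand-receptor pairs from one source resource
#' into an [lr_catalog()]. Gene symbols can be mapped to canonical
#' identifiers (typically Ensembl gene IDs) through `id_map`; genes missing
#' from the map keep their original symbol and are flagged via `id_flag`.
#' Duplicate pairs within the file are collapsed (curated evidence wins).
#'
#' Evidence is assigned per row when the file has an evidence column
#' (values such as "curated", "experimental", "yes" mark curated support);
#' otherwise the whole source is declared curated or predicted through the
#' `curated` argument, mirroring resources that assign evidence at the
#' identification-method level.
#'
#' @param path Path to a delimited file with at least ligand and receptor
#'   columns.
#' @param source_name Name recorded as this catalog's provenance.
#' @param species `"human"` or `"mouse"`.
#' @param columns Named list mapping the canonical roles `ligand`,
#'   `receptor` and optionally `evidence` to column names in the file.
#' @param curated Logical; evidence label for the whole source when the file
#'   has no evidence column.
#' @param id_map Optional data frame with columns `symbol` and `gene_id`
#'   used to translate gene symbols to canonical IDs. Never fetched at
#'   runtime; always user-supplied.
#' @param delim Field delimiter; guessed from the file extension by default.
#' @return An [lr_catalog()]. The attribute `load_report` records row counts:
#'   rows read, malformed rows dropped (empty/NA gene fields), duplicates
#'   collapsed, and genes left unmapped.
#' @export
load_lr_source <- function(path, source_name, species = c("human", "mouse"),
                           columns = list(ligand = "ligand",
                                          receptor = "receptor"),
                           curated = FALSE, id_map = NULL, delim = NULL) {
  species <- match.arg(species)
  if (is.null(delim)) delim <- .guess_delim(path)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  for (role in c("ligand", "receptor")) {
    if (is.null(columns[[role]]) || !columns[[role]] %in% names(raw)) {
      stop(sprintf("source '%s': required column '%s' (mapped from role '%s') not found",
                   source_name, columns[[role]] %||% "<unset>", role),
           call. = FALSE)
    }
  }
  if (nrow(raw) == 0) {
    warning(sprintf("source '%s' is empty; returning an empty catalog",
                    source_name), call. = FALSE)
    empty <- tibble::tibble(ligand = character(), receptor = character(),
                            sources = character(), evidence = character(),
                            id_flag = logical())
    cat <- lr_catalog(empty, species, source_name)
    attr(cat, "load_report") <- list(n_rows = 0L, n_malformed = 0L,
                                     n_duplicates = 0L, n_unmapped = 0L)
    return(cat)
  }

  lig <- trimws(raw[[columns$ligand]])
  rec <- trimws(raw[[columns$receptor]])
  malformed <- is.na(lig) | is.na(rec) | lig == "" | rec == ""
  n_malformed <- sum(malformed)
  lig <- lig[!malformed]
  rec <- rec[!malformed]

  if (!is.null(columns$evidence) && columns$evidence %in% names(raw)) {
    curated_row <- .parse_evidence(raw[[columns$evidence]])[!malformed]
  } else {
    curated_row <- rep(isTRUE(curated), length(lig))
  }

  n_unmapped <- 0L
  id_flag <- rep(FALSE, length(lig))
  if (!is.null(id_map)) {
    stopifnot(all(c("symbol", "gene_id") %in% names(id_map)))
    map <- stats::setNames(as.character(id_map$gene_id),
                           as.character(id_map$symbol))
    for (v in c("lig", "rec")) {
      sym <- get(v)
      hit <- sym %in% names(map)
      id_flag <- id_flag | !hit
      sym[hit] <- unname(map[sym[hit]])
      assign(v, sym)
    }
    n_unmapped <- sum(id_flag)
  }

  key <- paste(lig, rec, sep = "\r")
  first <- !duplicated(key)
  curated_any <- tapply(curated_row, key, any)
  flag_any <- tapply(id_flag, key, any)
  pairs <- tibble::tibble(
    ligand = lig[first],
    receptor = rec[first],
    sources = source_name,
    evidence = ifelse(unname(curated_any[key[first]]),
                      "manually_curated", "predicted"),
    id_flag = unname(flag_any[key[first]])
  )
  cat <- lr_catalog(pairs, species, source_name)
  attr(cat, "load_report") <- list(
    n_rows = nrow(raw),
    n_malformed = n_malformed,
    n_duplicates = length(key) - sum(first),
    n_unmapped = n_unmapped
  )
  if (n_malformed > 0) {
    message(sprintf("source '%s': dropped %d row(s) with empty gene fields",
                    source_name, n_malformed))
  }
  cat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge ligand-receptor catalogs from multiple sources
#'
#' Computes the union of pairs across catalogs of the same species. Source
#' provenance accumulates; a pair is labeled `manually_curated` if at least
#' one contributing source marks it curated, `predicted` otherwise. The
#' merge is idempotent, commutative and associative.
#'
#' @param catalogs List of [lr_catalog()] objects sharing one species.
#' @return A merged [lr_catalog()].
#' @export
merge_catalogs <- function(catalogs) {
  stopifnot(is.list(catalogs), length(catalogs) >= 1)
  if (!all(vapply(catalogs, inherits, logical(1), "lr_catalog"))) {
    stop("all elements must be lr_catalog objects", call. = FALSE)
  }
  species <- unique(vapply(catalogs, attr, character(1), "species"))
  if (length(species) != 1) {
    stop("cannot merge catalogs of different species: ",
         paste(species, collapse = ", "), call. = FALSE)
  }
  all_pairs <- dplyr::bind_rows(lapply(catalogs, function(x) {
    tibble::as_tibble(x)[, c("ligand", "receptor", "sources", "evidence",
                             "id_flag")]
  }))
  merged <- all_pairs |>
    dplyr::group_by(.data$ligand, .data$receptor) |>
    dplyr::summarise(
      sources = paste(sort(unique(unlist(strsplit(.data$sources, ";",
                                                  fixed = TRUE)))),
                      collapse = ";"),
      evidence = if (any(.data$evidence == "manually_curated"))
        "manually_curated" else "predicted",
      id_flag = any(.data$id_flag),
      .groups = "drop"
    )
  source_names <- sort(unique(unlist(lapply(catalogs, attr, "source_names"))))
  lr_catalog(merged, species, source_names)
}

#' Read a two-column gene-to-group annotation table
#'
#' @param path TSV with two columns: gene identifier and group label.
#' @param groups Allowed group vocabulary; labels outside it are an error.
#' @return Named list mapping each gene to its character vector of groups.
#' @export
read_group_annotation <- function(path, groups = lr_groups()) {
  tab <- readr::read_tsv(path, col_names = c("gene", "group"),
                         show_col_types = FALSE, progress = FALSE,
                         col_types = "cc")
  bad <- setdiff(unique(tab$group), groups)
  if (length(bad) > 0) {
    stop("annotation contains labels outside the group vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  split(tab$group, tab$gene) |> lapply(unique)
}

#' Read gene sets in GMT format as a gene-to-group annotation
#'
#' Each GMT row is `group<TAB>description<TAB>gene1<TAB>gene2...`; the file
#' is inverted into a gene -> groups map.
#'
#' @inheritParams read_group_annotation
#' @return Named list mapping each gene to its character vector of groups.
#' @export
read_gmt_annotation <- function(path, groups = lr_groups()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  labels <- vapply(parts, `[[`, character(1), 1)
  bad <- setdiff(unique(labels), groups)
  if (length(bad) > 0) {
    stop("GMT contains labels outside the group vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  gene <- unlist(lapply(parts, function(p) if (length(p) > 2) p[-(1:2)] else character()))
  grp <- rep(labels, vapply(parts, function(p) max(length(p) - 2L, 0L),
                            integer(1)))
  split(grp, gene) |> lapply(unique)
}

#' Classify ligand-receptor pairs into functional groups
#'
#' A pair belongs to a functional group when BOTH its ligand and its
#' receptor are annotated to that group; all such groups are retained in
#' `all_groups`, and `primary_group` is the first match in `priority`
#' (defaulting to the order of [lr_groups()]). Pairs matching no group are
#' assigned to `"other"`. Genes absent from the annotation map contribute no
#' groups.
#'
#' @param catalog An [lr_catalog()].
#' @param annotation Named list mapping gene identifiers to character
#'   vectors of group labels, as returned by [read_group_annotation()] or
#'   [read_gmt_annotation()].
#' @param priority Character vector: a permutation of the ten-group
#'   vocabulary giving the tie-break order for `primary_group`.
#' @return The catalog with `primary_group` and `all_groups`
#'   (";"-separated, in priority order) filled in.
#' @export
classify_pairs <- function(catalog, annotation, priority = lr_groups()) {
  stopifnot(inherits(catalog, "lr_catalog"))
  if (!setequal(priority, lr_groups()) || length(priority) != length(lr_groups())) {
    stop("priority must be a permutation of the ten-group vocabulary",
         call. = FALSE)
  }
  get_groups <- function(g) {
    a <- annotation[[g]]
    if (is.null(a)) character() else a
  }
  n_missing <- sum(!unique(c(catalog$ligand, catalog$receptor)) %in%
                     names(annotation))
  if (n_missing > 0) {
    message(sprintf("%d gene(s) absent from the annotation map (treated as unannotated)",
                    n_missing))
  }
  res <- vapply(seq_len(nrow(catalog)), function(i) {
    shared <- intersect(get_groups(catalog$ligand[i]),
                        get_groups(catalog$receptor[i]))
    shared <- priority[priority %in% shared]
    if (length(shared) == 0) {
      c("other", "")
    } else {
      c(shared[[1]], paste(shared, collapse = ";"))
    }
  }, character(2))
  catalog$primary_group <- res[1, ]
  catalog$all_groups <- res[2, ]
  catalog
}

#' Exclusive set-intersection statistics across catalogs
#'
#' For every non-empty subset of the supplied catalogs, counts the pairs
#' present in exactly that subset of sources (the semantics of an UpSet
#' plot). The exclusive counts partition the merged catalog, so they sum to
#' its size.
#'
#' @param catalogs Named list of two or more [lr_catalog()] objects of one
#'   species; names label the sources (falling back to each catalog's own
#'   source names).
#' @return Tibble with columns `sources` ("&"-joined subset label),
#'   `degree` (subset size) and `n_pairs` (exclusive count), one row per
#'   non-empty subset, sorted by degree then label. Attributes:
#'   `per_source_totals` (named pair counts per catalog), `shared_by_all`
#'   and `merged_size`.
#' @export
intersection_stats <- function(catalogs) {
  if (!is.list(catalogs) || length(catalogs) < 2) {
    stop("intersection_stats needs at least 2 catalogs; merge or supply more",
         call. = FALSE)
  }
  species <- unique(vapply(catalogs, attr, character(1), "species"))
  if (length(species) != 1) stop("catalogs must share one species", call. = FALSE)
  labels <- names(catalogs)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(catalogs, function(x) {
      paste(attr(x, "source_names"), collapse = "+")
    }, character(1))
  }
  if (anyDuplicated(labels)) stop("catalog labels must be unique", call. = FALSE)

  keysets <- lapply(catalogs, function(x) paste(x$ligand, x$receptor, sep = "\r"))
  universe <- unique(unlist(keysets))
  member <- vapply(keysets, function(k) universe %in% k, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  signature <- apply(member, 1, function(row) paste(which(row), collapse = ","))

  k <- length(catalogs)
  subsets <- unlist(lapply(seq_len(k), function(d) {
    utils::combn(k, d, simplify = FALSE)
  }), recursive = FALSE)
  out <- tibble::tibble(
    sources = vapply(subsets, function(s) paste(labels[s], collapse = "&"),
                     character(1)),
    degree = vapply(subsets, length, integer(1)),
    n_pairs = vapply(subsets, function(s) {
      sum(signature == paste(s, collapse = ","))
    }, integer(1))
  )
  attr(out, "per_source_totals") <- stats::setNames(
    vapply(keysets, length, integer(1)), labels)
  attr(out, "shared_by_all") <- out$n_pairs[out$degree == k]
  attr(out, "merged_size") <- length(universe)
  out
}
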