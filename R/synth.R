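#' Simulate a bulk FPKM expression matrix with planted interacting pairs
#'
#' Background abundances are log-normal on the FPKM scale (a standard
#' stand-in for bulk RNA-seq abundance distributions). Optional zero
#' inflation sets background entries to zero independently with probability
#' `zero_inflation`, which is what triggers the zero-fraction gene filter
#' downstream. Planted pairs are pairs of genes forced above the
#' `planted_quantile` of their sample's background values in a fixed
#' fraction of samples; because the interaction-strength statistic is
#' rank-based, quantile forcing (not additive shifts) is the mechanism that
#' matters. Planted genes are exempt from zero inflation so the planting
#' survives filtering.
#'
#' Identical arguments and seed give identical output.
#'
#' @param n_genes Number of genes (>= 10).
#' @param n_samples Number of samples (>= 6, the bulk-cohort admission
#'   threshold).
#' @param n_planted_pairs Number of planted gene pairs (uses `2 *
#'   n_planted_pairs` distinct genes).
#' @param planted_quantile Background expression quantile the planted genes
#'   are forced above; default 0.9 (top decile).
#' @param planted_sample_frac Fraction of samples in which each planted
#'   pair is forced; default 0.9.
#' @param zero_inflation Per-entry probability that a background value is
#'   zeroed; default 0.
#' @param meanlog,sdlog Log-normal background parameters; defaults 1 and 1.
#' @param seed Integer seed; mandatory.
#' @return List with `expr` (FPKM matrix, genes x samples) and `planted`
#'   (tibble of planted `gene1`, `gene2`).
#' @export
make_expression <- function(n_genes = 200, n_samples = 20,
                            n_planted_pairs = 0, planted_quantile = 0.9,
                            planted_sample_frac = 0.9, zero_inflation = 0,
                            meanlog = 1, sdlog = 1, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_genes >= 10, n_samples >= 6,
            planted_quantile > 0, planted_quantile <= 1,
            planted_sample_frac > 0, planted_sample_frac <= 1,
            zero_inflation >= 0, zero_inflation < 1)
  if (2 * n_planted_pairs > n_genes) {
    stop("planted pairs require more genes than the matrix has", call. = FALSE)
  }
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  samples <- sprintf("S%03d", seq_len(n_samples))
  expr <- matrix(stats::rlnorm(n_genes * n_samples, meanlog, sdlog),
                 nrow = n_genes, dimnames = list(genes, samples))

  planted_idx <- if (n_planted_pairs > 0) {
    sample.int(n_genes, 2 * n_planted_pairs)
  } else integer()
  if (zero_inflation > 0) {
    zero <- matrix(stats::runif(n_genes * n_samples) < zero_inflation,
                   nrow = n_genes)
    zero[planted_idx, ] <- FALSE
    expr[zero] <- 0
  }

  planted <- tibble::tibble(gene1 = character(), gene2 = character())
  if (n_planted_pairs > 0) {
    i1 <- planted_idx[seq_len(n_planted_pairs)]
    i2 <- planted_idx[n_planted_pairs + seq_len(n_planted_pairs)]
    n_force <- max(1L, round(planted_sample_frac * n_samples))
    bg_idx <- setdiff(seq_len(n_genes), planted_idx)
    for (p in seq_len(n_planted_pairs)) {
      force_samples <- sample.int(n_samples, n_force)
      for (s in force_samples) {
        bg <- expr[bg_idx, s]
        thr <- stats::quantile(bg, planted_quantile, names = FALSE)
        span <- max(bg) - min(bg) + 1
        expr[c(i1[p], i2[p]), s] <- thr + stats::runif(2, 0.1, 1) * span
      }
    }
    planted <- tibble::tibble(gene1 = genes[i1], gene2 = genes[i2])
  }
  list(expr = expr, planted = planted)
}

# parse a subset signature like "A+B" against source names
.parse_subset <- function(sig, sources) {
  parts <- strsplit(sig, "+", fixed = TRUE)[[1]]
  bad <- setdiff(parts, sources)
  if (length(bad) > 0) {
    stop("overlap subset refers to unknown source(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(parts)) {
    stop("overlap subset repeats a source: ", sig, call. = FALSE)
  }
  parts
}

#' Simulate ligand-receptor source catalogs with prescribed overlaps
#'
#' Builds one catalog per source such that the exclusive intersection
#' structure across sources exactly matches `overlaps`: a named integer
#' vector whose names are "+"-joined subsets of `sources` and whose values
#' are the number of pairs present in exactly that subset (UpSet
#' semantics). Subsets not named contribute zero pairs.
#'
#' @param sources Character vector of source names.
#' @param overlaps Named non-negative integer vector of exclusive subset
#'   counts, e.g. `c(A = 10, B = 5, "A+B" = 3)`.
#' @param species `"human"` or `"mouse"`.
#' @param curated_sources Sources whose pairs are labeled manually curated.
#' @param seed Integer seed; mandatory.
#' @return List with `catalogs` (named list of [lr_catalog()]) and
#'   `manifest` (tibble of `ligand`, `receptor`, `subset`).
#' @export
make_lr_catalogs <- function(sources, overlaps,
                             species = c("human", "mouse"),
                             curated_sources = character(), seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  species <- match.arg(species)
  stopifnot(length(sources) >= 1, !anyDuplicated(sources))
  if (is.null(names(overlaps)) || any(!nzchar(names(overlaps)))) {
    stop("overlaps must be a named vector of subset counts", call. = FALSE)
  }
  if (any(overlaps < 0) || any(overlaps != round(overlaps))) {
    stop("overlap counts must be non-negative integers", call. = FALSE)
  }
  subsets <- lapply(names(overlaps), .parse_subset, sources = sources)
  if (anyDuplicated(vapply(subsets, function(s) paste(sort(s), collapse = "+"),
                           character(1)))) {
    stop("overlaps names the same subset more than once", call. = FALSE)
  }
  set.seed(seed)
  n_total <- sum(overlaps)
  lig <- sprintf("LG%05d", seq_len(n_total))
  rec <- sprintf("RC%05d", sample.int(n_total))
  subset_of <- rep(names(overlaps), overlaps)

  manifest <- tibble::tibble(ligand = lig, receptor = rec, subset = subset_of)
  catalogs <- lapply(sources, function(src) {
    in_src <- vapply(subsets, function(s) src %in% s, logical(1))
    rows <- subset_of %in% names(overlaps)[in_src]
    lr_catalog(
      tibble::tibble(
        ligand = lig[rows], receptor = rec[rows], sources = src,
        evidence = if (src %in% curated_sources) "manually_curated"
          else "predicted",
        id_flag = FALSE
      ),
      species = species, source_names = src
    )
  })
  names(catalogs) <- sources
  list(catalogs = catalogs, manifest = manifest)
}

#' Simulate per-method cell-cell communication prediction tables
#'
#' Emulates the structure of multi-algorithm prediction outputs: a planted
#' core of communications shared by every method and scored from a high
#' distribution, plus method-specific noise communications scored from a
#' lower (by default overlapping) distribution. With the default score
#' ranges the planted core tends to the top of every method's ranking
#' without being perfectly separated, which is the regime consensus
#' evaluation is meant for; setting disjoint ranges produces perfect
#' separation.
#'
#' @param n_methods Number of mock methods (>= 2).
#' @param n_shared Number of planted communications shared by all methods.
#' @param n_noise Number of method-specific noise communications per
#'   method.
#' @param planted_score_range,noise_score_range Uniform score ranges for
#'   planted and noise predictions; defaults `c(4, 10)` and `c(0, 6)`.
#' @param n_cell_types Number of cell-type labels to draw senders/receivers
#'   from.
#' @param method_names Optional method labels.
#' @param seed Integer seed; mandatory.
#' @return List with `records` (tibble shaped like [load_predictions()]
#'   output, including within-method `percentile`) and `planted` (tibble of
#'   the shared communications).
#' @export
make_predictions <- function(n_methods = 5, n_shared = 30, n_noise = 70,
                             planted_score_range = c(4, 10),
                             noise_score_range = c(0, 6),
                             n_cell_types = 4, method_names = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_methods >= 2, n_shared >= 0, n_noise >= 0,
            n_shared + n_noise > 0)
  if (is.null(method_names)) method_names <- sprintf("method%d", seq_len(n_methods))
  stopifnot(length(method_names) == n_methods)
  set.seed(seed)
  cells <- sprintf("cell_type_%d", seq_len(n_cell_types))
  new_comm <- function(n, prefix) {
    tibble::tibble(
      ligand = sprintf("%s_L%04d", prefix, seq_len(n)),
      receptor = sprintf("%s_R%04d", prefix, seq_len(n)),
      sender = sample(cells, n, replace = TRUE),
      receiver = sample(cells, n, replace = TRUE)
    )
  }
  shared <- new_comm(n_shared, "core")
  recs <- lapply(seq_len(n_methods), function(i) {
    noise <- new_comm(n_noise, sprintf("m%d", i))
    df <- dplyr::bind_rows(shared, noise)
    df$score <- c(
      stats::runif(n_shared, planted_score_range[1], planted_score_range[2]),
      stats::runif(n_noise, noise_score_range[1], noise_score_range[2])
    )
    df$method <- method_names[i]
    df$dataset <- "synthetic"
    df$percentile <- .percentile_rank(df$score)
    df
  })
  list(records = dplyr::bind_rows(recs), planted = shared)
}
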