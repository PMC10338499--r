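#' Read a bulk expression matrix
#'
#' Expects a delimited genes-by-samples table with a header row of sample
#' identifiers and gene identifiers in the first column, values on the FPKM
#' scale.
#'
#' @param path Path to a TSV/CSV file.
#' @param delim Field delimiter; guessed from the extension by default.
#' @return Numeric matrix (genes x samples) with gene identifiers as row
#'   names.
#' @export
read_expression <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- .guess_delim(path)
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  .validate_expression(m)
  m
}

.validate_expression <- function(m) {
  if (anyDuplicated(rownames(m))) {
    stop("duplicate gene identifiers in expression matrix", call. = FALSE)
  }
  if (anyNA(m)) stop("expression matrix contains missing values", call. = FALSE)
  if (any(m < 0)) stop("FPKM values must be non-negative", call. = FALSE)
  invisible(m)
}

#' Log-normalize an FPKM matrix
#'
#' Applies `log2(FPKM + 0.05)`. The interaction-strength statistic depends
#' only on within-sample ranks, which any strictly increasing transform
#' preserves, so scoring is identical on FPKM and normalized values; the
#' normalized view is for storage, reporting and plotting.
#'
#' @param m Non-negative FPKM matrix.
#' @param pseudocount Offset added before the log; default 0.05.
#' @return Matrix of `log2(m + pseudocount)` values.
#' @export
normalize_expression <- function(m, pseudocount = 0.05) {
  .validate_expression(m)
  log2(m + pseudocount)
}

#' Filter genes by their fraction of zero samples
#'
#' Excludes genes whose expression is zero in MORE than
#' `zero_fraction_max` of samples (strict inequality: a gene at exactly the
#' threshold is retained). Apply to the FPKM matrix, where zeros are
#' meaningful.
#'
#' @param m FPKM matrix (genes x samples).
#' @param zero_fraction_max Maximum tolerated zero fraction; default 0.30.
#' @return The matrix restricted to retained genes, with attribute
#'   `n_removed`.
#' @export
filter_genes <- function(m, zero_fraction_max = 0.30) {
  if (ncol(m) < 1) stop("expression matrix has no samples", call. = FALSE)
  zero_frac <- rowMeans(m == 0)
  keep <- zero_frac <= zero_fraction_max
  if (!any(keep)) {
    stop("all genes removed by the zero-fraction filter; nothing to score",
         call. = FALSE)
  }
  out <- m[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-sample normalized rank transform
#'
#' Within each sample, genes are ranked in descending order of expression
#' (position 1 = highest) and positions are rescaled to
#' `r = 10 * (G - pos + 1) / G` for `G` genes, so the top-expressed gene
#' scores 10 and the lowest `10 / G`. Ties receive the average position, so
#' equal expression always yields equal rank scores.
#'
#' @param m Expression matrix (FPKM or log-normalized; ranks are identical).
#' @return Matrix of rank scores in `(0, 10]`, same dimensions as `m`.
#' @export
rank_transform <- function(m) {
  G <- nrow(m)
  if (G < 2) {
    stop("rank transform needs at least 2 genes; ranking a single gene is degenerate",
         call. = FALSE)
  }
  pos <- apply(m, 2, function(x) rank(-x, ties.method = "average"))
  10 * (G - pos + 1) / G
}

#' Rank-based interaction strength of a gene pair
#'
#' For rank scores `r1`, `r2` on the 0-10 scale,
#' `IS = (r1 + r2) * (10 - |r1 - r2|)`: the first factor rewards jointly
#' high expression, the second penalizes discordant ranks. The score is
#' symmetric in its arguments, bounded in `[0, 200]`, and attains 200 only
#' at `r1 = r2 = 10`.
#'
#' @param r1,r2 Numeric vectors of rank scores in `(0, 10]` (recycled).
#' @return Numeric vector of interaction strengths.
#' @export
#' @examples
#' interaction_strength(10, 10) # 200
#' interaction_strength(5, 5)   # 100
interaction_strength <- function(r1, r2) {
  if (any(r1 <= 0 | r1 > 10) || any(r2 <= 0 | r2 > 10)) {
    stop("rank scores must lie in (0, 10]; an unscaled rank may have leaked in",
         call. = FALSE)
  }
  (r1 + r2) * (10 - abs(r1 - r2))
}

# summary (mean over samples) interaction strength for index pairs i1, i2
# against a rank matrix; no domain checks, internal hot path
.pair_summary_is <- function(rk, i1, i2) {
  a <- rk[i1, , drop = FALSE]
  b <- rk[i2, , drop = FALSE]
  rowMeans((a + b) * (10 - abs(a - b)))
}

# Draw n_perm unordered random gene pairs (distinct genes within a draw),
# excluding the observed pair in either orientation. Vectorized scheme:
#   i1 <- sample.int(G, n_perm, replace = TRUE)
#   i2 <- sample.int(G - 1, n_perm, replace = TRUE); i2 <- i2 + (i2 >= i1)
# then any draw colliding with the observed pair is redrawn one at a time
# with sample.int(G, 2) until it differs.
.draw_null_pairs <- function(G, n_perm, exclude) {
  i1 <- sample.int(G, n_perm, replace = TRUE)
  i2 <- sample.int(G - 1L, n_perm, replace = TRUE)
  i2 <- i2 + (i2 >= i1)
  hit <- (i1 == exclude[1] & i2 == exclude[2]) |
    (i1 == exclude[2] & i2 == exclude[1])
  for (j in which(hit)) {
    repeat {
      d <- sample.int(G, 2L)
      if (!setequal(d, exclude)) break
    }
    i1[j] <- d[1]
    i2[j] <- d[2]
  }
  cbind(i1, i2)
}

#' Score gene pairs on a bulk expression matrix with permutation p-values
#'
#' Computes the per-sample interaction strength of each gene pair, its
#' dataset-level summary (the arithmetic mean over samples), and a
#' permutation p-value. The null distribution for a pair is built from
#' `n_perm` random gene pairs drawn uniformly from the retained gene
#' universe (two distinct genes per draw, the observed pair excluded),
#' scored and aggregated identically; sample labels are never permuted, so
#' each sample's rank structure is preserved. The default upper-tail
#' p-value with add-one correction is
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`, so `p` is never zero.
#'
#' Pairs are processed in input row order with a single RNG stream seeded
#' once from `seed`, so a run is fully reproducible. Pairs whose genes are
#' absent from the matrix (e.g. removed by [filter_genes()]) are skipped
#' and reported in the `skipped` attribute.
#'
#' @param m Expression matrix, already gene-filtered; FPKM or normalized.
#' @param pairs Data frame (or 2-column matrix) whose first two columns are
#'   the gene identifiers of each pair.
#' @param n_perm Number of random pairs in the null; default 1000.
#' @param seed Integer seed; mandatory, for reproducibility.
#' @param alternative `"greater"` (default) tests for unusually strong
#'   interaction; `"less"` for unusually weak.
#' @param min_samples Minimum number of samples the matrix must have
#'   (default 6, the admission threshold for bulk cohorts).
#' @return Tibble with columns `gene1`, `gene2`, `summary_is`, `p_value`,
#'   `n_perm`, `n_samples`, and a list-column `per_sample_is`. Attributes:
#'   `skipped` (pairs with absent genes), `seed`.
#' @export
score_pairs <- function(m, pairs, n_perm = 1000, seed,
                        alternative = c("greater", "less"),
                        min_samples = 6) {
  alternative <- match.arg(alternative)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required: permutation results must be reproducible",
         call. = FALSE)
  }
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  if (ncol(m) < min_samples) {
    stop(sprintf("matrix has %d samples; at least %d are required",
                 ncol(m), min_samples), call. = FALSE)
  }
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2) stop("pairs needs two gene columns", call. = FALSE)
  g1 <- as.character(pairs[[1]])
  g2 <- as.character(pairs[[2]])
  present <- g1 %in% rownames(m) & g2 %in% rownames(m) & g1 != g2
  skipped <- tibble::tibble(
    gene1 = g1[!present], gene2 = g2[!present],
    reason = ifelse(g1[!present] == g2[!present], "self-pair",
                    "gene absent from filtered matrix")
  )
  if (nrow(skipped) > 0) {
    message(sprintf("skipping %d pair(s) with absent or identical genes",
                    nrow(skipped)))
  }
  g1 <- g1[present]
  g2 <- g2[present]

  rk <- rank_transform(m)
  G <- nrow(rk)
  set.seed(seed)

  n <- length(g1)
  summary_is <- numeric(n)
  p_value <- numeric(n)
  per_sample <- vector("list", n)
  for (t in seq_len(n)) {
    i <- match(g1[t], rownames(rk))
    j <- match(g2[t], rownames(rk))
    is_vec <- interaction_strength(rk[i, ], rk[j, ])
    obs <- mean(is_vec)
    nul <- .draw_null_pairs(G, n_perm, exclude = c(i, j))
    null_sum <- .pair_summary_is(rk, nul[, 1], nul[, 2])
    k <- if (alternative == "greater") sum(null_sum >= obs) else
      sum(null_sum <= obs)
    summary_is[t] <- obs
    p_value[t] <- (1 + k) / (n_perm + 1)
    per_sample[[t]] <- stats::setNames(is_vec, colnames(m))
  }
  out <- tibble::tibble(
    gene1 = g1, gene2 = g2,
    summary_is = summary_is, p_value = p_value,
    n_perm = as.integer(n_perm), n_samples = ncol(m),
    per_sample_is = per_sample
  )
  attr(out, "skipped") <- skipped
  attr(out, "seed") <- seed
  attr(out, "alternative") <- alternative
  out
}

#' Score curated interactions and catalog pairs against one cohort
#'
#' Runs [score_pairs()] on two reference sets — experimentally verified
#' (curated) interactions and ligand-receptor catalog pairs — and reports
#' how many of each pass the significance threshold. Small cohorts
#' conventionally use a relaxed `alpha` (the `"small-cohort"` profile of
#' [run_config()] sets 0.1 instead of 0.05).
#'
#' @param m Filtered expression matrix.
#' @param curated_pairs Data frame of gene pairs from a curated-interaction
#'   table (first two columns are the interacting genes).
#' @param lr_pairs An [lr_catalog()] or data frame with `ligand`/`receptor`
#'   columns.
#' @param alpha Significance threshold on the permutation p-value.
#' @param n_perm,seed,min_samples Passed to [score_pairs()].
#' @return List with elements `curated` and `lr` (scored tibbles with a
#'   `significant` column), `n_significant` (named counts) and `alpha`.
#' @export
score_reference_sets <- function(m, curated_pairs, lr_pairs, alpha = 0.05,
                                 n_perm = 1000, seed, min_samples = 6) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (inherits(lr_pairs, "lr_catalog")) {
    lr_pairs <- tibble::as_tibble(lr_pairs)[, c("ligand", "receptor")]
  }
  if (NROW(curated_pairs) == 0 || NROW(lr_pairs) == 0) {
    stop("reference sets must be non-empty", call. = FALSE)
  }
  score_one <- function(p) {
    s <- score_pairs(m, p, n_perm = n_perm, seed = seed,
                     min_samples = min_samples)
    s$significant <- s$p_value < alpha
    s
  }
  curated <- score_one(curated_pairs)
  lr <- score_one(lr_pairs)
  list(
    curated = curated,
    lr = lr,
    n_significant = c(curated = sum(curated$significant),
                      lr = sum(lr$significant)),
    alpha = alpha
  )
}
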