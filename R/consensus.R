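# communication key: one string per (ligand, receptor, sender, receiver)
.comm_key <- function(df) {
  paste(df$ligand, df$receptor, df$sender, df$receiver, sep = "|")
}

# within-method percentile rank of scores, in (0, 1]; a single row gets 1
.percentile_rank <- function(score) {
  rank(score, ties.method = "average") / length(score)
}

#' Load per-method cell-cell communication prediction tables
#'
#' Reads one CSV per prediction method into a shared record layout keyed by
#' (ligand, receptor, sender cell, receiver cell). Method-native
#' communication scores are incomparable across methods, so each record also
#' carries its within-method percentile rank (1 = that method's strongest
#' prediction), which is the only score used in cross-method arithmetic.
#'
#' @param paths Character vector of CSV paths, one per method.
#' @param method_names Method labels, same length as `paths`.
#' @param columns Named list mapping the roles `ligand`, `receptor`,
#'   `sender`, `receiver`, `score` (and optionally `dataset`) to the files'
#'   column names.
#' @return Tibble of prediction records with columns `ligand`, `receptor`,
#'   `sender`, `receiver`, `score`, `method`, `dataset`, `percentile`.
#'   Rows with non-numeric scores are rejected (attribute `rejected`).
#' @export
load_predictions <- function(paths, method_names,
                             columns = list(ligand = "ligand",
                                            receptor = "receptor",
                                            sender = "sender",
                                            receiver = "receiver",
                                            score = "score")) {
  stopifnot(length(paths) == length(method_names))
  rejected <- list()
  recs <- lapply(seq_along(paths), function(i) {
    raw <- readr::read_csv(paths[i], show_col_types = FALSE, progress = FALSE)
    need <- c("ligand", "receptor", "sender", "receiver", "score")
    for (role in need) {
      if (is.null(columns[[role]]) || !columns[[role]] %in% names(raw)) {
        stop(sprintf("method '%s': required column '%s' (role '%s') not found",
                     method_names[i], columns[[role]] %||% "<unset>", role),
             call. = FALSE)
      }
    }
    df <- tibble::tibble(
      ligand = as.character(raw[[columns$ligand]]),
      receptor = as.character(raw[[columns$receptor]]),
      sender = as.character(raw[[columns$sender]]),
      receiver = as.character(raw[[columns$receiver]]),
      score = suppressWarnings(as.numeric(raw[[columns$score]])),
      method = method_names[i],
      dataset = if (!is.null(columns$dataset) &&
                    columns$dataset %in% names(raw))
        as.character(raw[[columns$dataset]]) else NA_character_
    )
    bad <- is.na(df$score)
    if (any(bad)) {
      rejected[[method_names[i]]] <<- df[bad, ]
      message(sprintf("method '%s': rejected %d row(s) with non-numeric scores",
                      method_names[i], sum(bad)))
      df <- df[!bad, ]
    }
    if (nrow(df) == 0) {
      stop(sprintf("method '%s' has no valid prediction rows", method_names[i]),
           call. = FALSE)
    }
    key <- .comm_key(df)
    if (anyDuplicated(key)) {
      stop(sprintf("method '%s': duplicate communication key(s): %s",
                   method_names[i],
                   paste(utils::head(unique(key[duplicated(key)]), 3),
                         collapse = "; ")),
           call. = FALSE)
    }
    df$percentile <- .percentile_rank(df$score)
    df
  })
  out <- dplyr::bind_rows(recs)
  attr(out, "rejected") <- rejected
  out
}

#' Integrate predictions from multiple methods into a consensus
#'
#' Groups prediction records by their communication key, counts the number
#' of supporting methods, and aggregates each key's within-method
#' percentile ranks into a consensus rank (their mean over supporting
#' methods). The result is filtered to `support >= min_support` and sorted
#' by support (descending), consensus rank (descending), then key
#' (lexicographic), so output is deterministic and invariant to input file
#' order.
#'
#' @param records Prediction records from [load_predictions()] (or any
#'   tibble with `ligand`, `receptor`, `sender`, `receiver`, `method`,
#'   `percentile`).
#' @param min_support Minimum number of methods that must predict a
#'   communication for it to enter the consensus; default 2.
#' @return Tibble with columns `ligand`, `receptor`, `sender`, `receiver`,
#'   `support`, `consensus_rank`, `methods` (";"-joined supporting method
#'   names).
#' @export
integrate_predictions <- function(records, min_support = 2) {
  n_methods <- length(unique(records$method))
  if (n_methods < 2) {
    stop("at least 2 methods are required for consensus integration",
         call. = FALSE)
  }
  if (min_support > n_methods) {
    stop(sprintf("min_support (%d) exceeds the number of methods (%d)",
                 min_support, n_methods), call. = FALSE)
  }
  out <- records |>
    dplyr::group_by(.data$ligand, .data$receptor, .data$sender,
                    .data$receiver) |>
    dplyr::summarise(
      support = dplyr::n_distinct(.data$method),
      consensus_rank = mean(.data$percentile),
      methods = paste(sort(unique(.data$method)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$support >= min_support)
  out[order(-out$support, -out$consensus_rank, out$ligand, out$receptor,
            out$sender, out$receiver, method = "radix"), ]
}

# sort a (key, score) table into a ranked list: score descending, stable,
# lexicographic key as the final tie-break
.sort_ranked <- function(keys, scores) {
  ord <- order(-scores, keys, method = "radix")
  list(keys = keys[ord], scores = scores[ord])
}

#' Weighted Kolmogorov-Smirnov enrichment score of a key set in a ranked list
#'
#' Classic GSEA running-sum statistic. Walking down the list (ordered by
#' score, descending), hits increment the running sum by
#' `|score|^weight_exponent` normalized over the in-set total, misses
#' decrement it by `1 / (N - Nh)`; the enrichment score (ES) is the
#' running-sum value at its extremum of largest magnitude. ES lies in
#' `[-1, 1]`; a set equal to the whole list scores 1; a set concentrated at
#' the bottom scores negative. Significance comes from `n_perm` random sets
#' of the same size drawn from the list (set-membership permutation — there
#' are no sample labels here), upper tail for positive ES and lower tail
#' for negative, with add-one correction.
#'
#' @param keys Character vector of unique list elements.
#' @param scores Numeric scores aligned with `keys` (need not be pre-sorted;
#'   sorting is score-descending with lexicographic key tie-break).
#' @param gene_set Character vector: the set to test. Elements outside the
#'   list are ignored; an empty intersection is an error.
#' @param weight_exponent Exponent on `|score|`; 1 is the classic GSEA
#'   weighting, 0 gives the unweighted Kolmogorov-Smirnov statistic.
#' @param n_perm Number of set-membership permutations; 0 skips the
#'   p-value.
#' @param seed Integer seed; required when `n_perm > 0`.
#' @return List of class `lr_enrichment`: `es`, `p_value`, `set_size`,
#'   `list_size`, `leading_edge` (keys driving the extremum), `running`
#'   (the running-sum vector), `n_perm`.
#' @export
enrichment_score <- function(keys, scores, gene_set, weight_exponent = 1,
                             n_perm = 0, seed = NULL) {
  if (anyDuplicated(keys)) {
    stop("ranked list contains duplicate keys", call. = FALSE)
  }
  stopifnot(length(keys) == length(scores))
  ranked <- .sort_ranked(keys, scores)
  in_set <- ranked$keys %in% gene_set
  if (!any(in_set)) {
    stop("gene set has empty intersection with the ranked list", call. = FALSE)
  }
  es_of <- function(hit) {
    N <- length(hit)
    Nh <- sum(hit)
    w <- abs(ranked$scores)^weight_exponent
    inc <- numeric(N)
    denom_hit <- sum(w[hit])
    if (denom_hit == 0) {
      # all in-set scores are exactly zero: fall back to equal hit weights
      inc[hit] <- 1 / Nh
    } else {
      inc[hit] <- w[hit] / denom_hit
    }
    if (N > Nh) inc[!hit] <- -1 / (N - Nh)
    running <- cumsum(inc)
    i_max <- which.max(abs(running))
    list(es = running[i_max], running = running, peak = i_max)
  }
  obs <- es_of(in_set)

  p_value <- NA_real_
  if (n_perm > 0) {
    if (is.null(seed)) {
      stop("a seed is required for permutation p-values", call. = FALSE)
    }
    set.seed(seed)
    Nh <- sum(in_set)
    N <- length(in_set)
    null_es <- vapply(seq_len(n_perm), function(i) {
      hit <- logical(N)
      hit[sample.int(N, Nh)] <- TRUE
      es_of(hit)$es
    }, numeric(1))
    k <- if (obs$es >= 0) sum(null_es >= obs$es) else sum(null_es <= obs$es)
    p_value <- (1 + k) / (n_perm + 1)
  }

  leading <- if (obs$es >= 0) {
    ranked$keys[seq_len(obs$peak)][in_set[seq_len(obs$peak)]]
  } else {
    idx <- seq(obs$peak, length(in_set))
    ranked$keys[idx][in_set[idx]]
  }
  structure(
    list(es = obs$es, p_value = p_value, set_size = sum(in_set),
         list_size = length(in_set), leading_edge = leading,
         running = obs$running, n_perm = n_perm),
    class = "lr_enrichment"
  )
}

#' @export
print.lr_enrichment <- function(x, ...) {
  cat(sprintf("<enrichment> ES = %.4f (set %d / list %d)", x$es,
              x$set_size, x$list_size))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g (%d perms)", x$p_value, x$n_perm))
  cat("\n")
  invisible(x)
}

#' Fraction of a key set falling in the top of a ranked list
#'
#' With `k = ceiling(fraction * N)` for a list of `N` keys, returns
#' `|set ∩ top-k| / |set ∩ list|` — the occupancy of the set in the top
#' fraction of the list. With the default `fraction = 0.5` this is the
#' top-50% occupancy used to ask whether consensus communications sit in
#' the upper half of each individual method's ranking.
#'
#' @inheritParams enrichment_score
#' @param fraction Top fraction of the list to consider, in `(0, 1]`.
#' @return A number in `[0, 1]`.
#' @export
top_fraction_occupancy <- function(keys, scores, gene_set, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  if (anyDuplicated(keys)) {
    stop("ranked list contains duplicate keys", call. = FALSE)
  }
  ranked <- .sort_ranked(keys, scores)
  in_list <- sum(gene_set %in% ranked$keys)
  if (in_list == 0) {
    stop("gene set has empty intersection with the ranked list", call. = FALSE)
  }
  k <- ceiling(fraction * length(ranked$keys))
  sum(gene_set %in% ranked$keys[seq_len(k)]) / in_list
}

#' Evaluate a consensus set against every contributing method
#'
#' For each method, ranks that method's predictions by its native score and
#' measures how the consensus communications concentrate at the top: the
#' running-sum enrichment score with permutation p-value, and the top-50%
#' occupancy.
#'
#' @param records Prediction records from [load_predictions()] or
#'   [make_predictions()].
#' @param consensus Consensus table from [integrate_predictions()].
#' @param n_perm,seed Permutation settings for [enrichment_score()].
#' @param fraction Top fraction for [top_fraction_occupancy()].
#' @param weight_exponent Passed to [enrichment_score()].
#' @return Tibble with one row per method: `method`, `es`, `p_value`,
#'   `occupancy`, `n_predictions`, `n_set_in_list`.
#' @export
evaluate_consensus <- function(records, consensus, n_perm = 1000, seed,
                               fraction = 0.5, weight_exponent = 1) {
  set_keys <- .comm_key(consensus)
  methods <- sort(unique(records$method))
  rows <- lapply(seq_along(methods), function(i) {
    df <- records[records$method == methods[i], ]
    keys <- .comm_key(df)
    enr <- enrichment_score(keys, df$score, set_keys,
                            weight_exponent = weight_exponent,
                            n_perm = n_perm, seed = seed + i)
    occ <- top_fraction_occupancy(keys, df$score, set_keys, fraction)
    tibble::tibble(method = methods[i], es = enr$es, p_value = enr$p_value,
                   occupancy = occ, n_predictions = nrow(df),
                   n_set_in_list = enr$set_size)
  })
  dplyr::bind_rows(rows)
}
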