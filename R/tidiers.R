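#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a relation-index report into long form
#'
#' One row per (disease pair, index), with the observed value and, when the
#' report carries a null, its empirical p-value.
#'
#' @param x A [relation_indices()] result.
#' @param ... Unused.
#' @return A tibble with columns `disease_a`, `disease_b`, `index`
#'   ("I"/"J"/"M"), `value`, and `p_value` when available.
#' @method tidy relation_index_report
#' @export
tidy.relation_index_report <- function(x, ...) {
  long <- tibble::tibble(
    disease_a = rep(x$disease_a, 3L),
    disease_b = rep(x$disease_b, 3L),
    index = rep(c("I", "J", "M"), each = nrow(x)),
    value = c(as.numeric(x$i_ab), x$j_ab, x$m_ab))
  if (!is.null(x$p_i)) {
    long$p_value <- c(x$p_i, x$p_j, x$p_m)
  }
  long[order(match(long$disease_a, x$disease_a),
             match(long$disease_b, x$disease_b)), ]
}

#' @rdname tidy.relation_index_report
#' @method glance relation_index_report
#' @export
glance.relation_index_report <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_null = if (!is.null(x$n_null)) x$n_null[1] else NA_integer_,
    seed = if (!is.null(x$seed)) x$seed[1] else NA_integer_,
    n_significant_i = if (!is.null(x$p_i)) sum(x$p_i <= 0.05) else
      NA_integer_)
}

#' Tidy a connectivity report
#'
#' @param x A [score_connectivity()] result.
#' @param ... Unused.
#' @return `tidy()`: a one-row tibble with the observed statistics and
#'   p-value. `glance()`: a one-row summary including the null mean.
#' @method tidy connectivity_report
#' @export
tidy.connectivity_report <- function(x, ...) {
  tibble::tibble(
    diseases = paste(x$disease_ids, collapse = "|"),
    n_genes = x$n_genes,
    n_connected_pairs = x$n_connected_pairs,
    n_links = x$n_links,
    statistic = x$statistic,
    observed = x$observed,
    p_value = x$p_value)
}

#' @rdname tidy.connectivity_report
#' @method glance connectivity_report
#' @export
glance.connectivity_report <- function(x, ...) {
  tibble::tibble(
    observed = x$observed, p_value = x$p_value, n_null = x$n_null,
    null_mean = mean(x$null$values), null_max = max(x$null$values),
    seed = x$seed)
}

#' Tidy a null distribution
#'
#' @param x A `relation_index_null` or `connectivity_null`.
#' @param ... Unused.
#' @return `tidy()`: one row per replicate. `glance()`: one-row summary
#'   (n, seed, per-statistic means).
#' @method tidy associome_null
#' @export
tidy.associome_null <- function(x, ...) {
  if (inherits(x, "relation_index_null")) {
    dplyr::bind_cols(tibble::tibble(replicate = seq_len(x$n)), x$values)
  } else {
    dplyr::bind_cols(tibble::tibble(replicate = seq_len(x$n)), x$stats)
  }
}

#' @rdname tidy.associome_null
#' @method glance associome_null
#' @export
glance.associome_null <- function(x, ...) {
  v <- tidy(x)
  v$replicate <- NULL
  out <- tibble::as_tibble(as.list(colMeans(v, na.rm = TRUE)))
  names(out) <- paste0("mean_", names(out))
  dplyr::bind_cols(tibble::tibble(n = x$n, seed = x$seed), out)
}
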