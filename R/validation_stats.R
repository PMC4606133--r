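# Edge-overlap validation of distinct subgraphs against reference networks:
# per-subgraph overlap rates, at-least-one-edge enrichment, and one-sided
# t-tests comparing same-name versus other-network subgraph groups.

#' Edge overlapping rate of a subgraph with a reference network
#'
#' Number of subgraph edges present in the reference divided by the
#' subgraph's edge count (undirected comparison). Node identifier namespaces
#' must already be harmonized by the caller.
#'
#' @param subgraph a `ppi_graph` (or module / labeled graph) with >= 1 edge.
#' @param reference a `ppi_graph`.
#' @return Rate in \[0, 1\].
#' @export
edge_overlap_rate <- function(subgraph, reference) {
  sk <- edge_keys(subgraph)
  if (length(sk) == 0) stop("edge overlap rate is undefined for an empty subgraph")
  mean(sk %in% edge_keys(reference))
}

#' Fraction of subgraphs with at least one overlapping edge
#'
#' @param subgraphs nonempty list of subgraphs.
#' @param reference a `ppi_graph`.
#' @return Fraction in \[0, 1\].
#' @export
fraction_with_overlap <- function(subgraphs, reference) {
  stopifnot(length(subgraphs) >= 1)
  rk <- edge_keys(reference)
  mean(vapply(subgraphs, function(s) any(edge_keys(s) %in% rk), TRUE))
}

#' One-sided two-sample t-test of overlap rates
#'
#' Tests whether the mean of `rates_same` exceeds the mean of `rates_other`
#' (alternative: greater). Welch's unequal-variance statistic by default; set
#' `var_equal = TRUE` for the pooled Student variant. When both groups are
#' (numerically) constant the t statistic is degenerate: the returned
#' p-value is then 0.5 for equal means (flagged via the `"degenerate"`
#' attribute), 0 when the first mean is larger and 1 when smaller.
#'
#' @param rates_same,rates_other numeric vectors, each with >= 2 values.
#' @param var_equal pooled-variance Student t-test instead of Welch.
#' @return One-sided p-value in \[0, 1\].
#' @export
compare_groups <- function(rates_same, rates_other, var_equal = FALSE) {
  stopifnot(length(rates_same) >= 2, length(rates_other) >= 2)
  p <- tryCatch(
    t.test(rates_same, rates_other, alternative = "greater",
           var.equal = var_equal)$p.value,
    error = function(e) NA_real_)
  if (is.na(p)) {
    ms <- mean(rates_same)
    mo <- mean(rates_other)
    p <- if (ms > mo) 0 else if (ms < mo) 1 else 0.5
    attr(p, "degenerate") <- TRUE
  }
  p
}

#' Overlap report across query networks and reference networks
#'
#' For every reference network (named by the network it represents) and every
#' query network with a different name, compares the overlap rates of the
#' reference's same-name distinct subgraphs against the query network's
#' distinct subgraphs with a one-sided t-test; the same-name cell is `NA`.
#' Also reports per-subgraph rates and the per-network fraction of subgraphs
#' with at least one overlapping edge.
#'
#' @param distinct_by_network named list (network -> list of distinct
#'   subgraphs, each with >= 1 edge).
#' @param references named list (network name -> reference `ppi_graph`).
#' @param var_equal passed to [compare_groups()].
#' @return An object of class `overlap_report`: `rates` (data frame
#'   `network`, `subgraph_id`, `reference`, `rate`), `fraction` (matrix
#'   network x reference) and `p_values` (matrix query network x reference,
#'   `NA` diagonal).
#' @export
overlap_matrix <- function(distinct_by_network, references,
                           var_equal = FALSE) {
  stopifnot(length(distinct_by_network) >= 2, length(references) >= 1,
            !is.null(names(references)))
  nets <- names(distinct_by_network)
  refs <- names(references)
  rate_of <- function(net, ref) {
    vapply(distinct_by_network[[net]], edge_overlap_rate,
           reference = references[[ref]], FUN.VALUE = 0)
  }
  rows <- list()
  for (net in nets) {
    ids <- vapply(distinct_by_network[[net]], function(s)
      if (!is.null(s$id)) s$id else "", "")
    for (ref in refs) {
      r <- rate_of(net, ref)
      if (length(r) == 0) next
      rows[[length(rows) + 1L]] <-
        data.frame(network = net, subgraph_id = ids, reference = ref,
                   rate = r, stringsAsFactors = FALSE)
    }
  }
  rates <- do.call(rbind, rows)
  rownames(rates) <- NULL
  fraction <- matrix(NA_real_, length(nets), length(refs),
                     dimnames = list(nets, refs))
  for (net in nets) {
    if (length(distinct_by_network[[net]]) == 0) next
    for (ref in refs)
      fraction[net, ref] <- fraction_with_overlap(distinct_by_network[[net]],
                                                  references[[ref]])
  }
  p_values <- matrix(NA_real_, length(nets), length(refs),
                     dimnames = list(nets, refs))
  for (ref in refs) {
    if (!(ref %in% nets) || length(distinct_by_network[[ref]]) < 2) {
      warning(sprintf("reference '%s' has no same-name query network with >= 2 subgraphs; column skipped", ref))
      next
    }
    same <- rate_of(ref, ref)
    for (net in setdiff(nets, ref)) {
      if (length(distinct_by_network[[net]]) < 2) next
      p_values[net, ref] <- compare_groups(same, rate_of(net, ref),
                                           var_equal = var_equal)
    }
  }
  structure(list(rates = rates, fraction = fraction, p_values = p_values),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report: %d rate rows, %d x %d p-value matrix>\n",
              nrow(x$rates), nrow(x$p_values), ncol(x$p_values)))
  invisible(x)
}
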