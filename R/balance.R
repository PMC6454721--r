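#' Community balance index (CBI)
#'
#' Community-size-weighted mean fraction of balanced triads inside each
#' community:
#' \deqn{CBI = \sum_c n_c (1 - \#PPN_c / \#triads_c) / \sum_c n_c,}
#' where the census in community `c` is taken over the induced subgraph
#' (edges with both endpoints inside `c`). A community with no internal
#' triangles contributes a fully balanced term (its 0/0 is defined as 1): a
#' community with no triads violates no balance constraint. Values lie in
#' `[0, 1]`; multiply by 100 to report a percentage.
#'
#' @param net A [signed_network()].
#' @param partition A partition of the nodes: a data frame with columns
#'   `drug` and `community`, or an integer vector of community indices in
#'   node order.
#' @return A single number in `[0, 1]`.
#' @examples
#' toy <- fig1_toy()
#' cbi(toy, attr(toy, "partition"))
#' @export
cbi <- function(net, partition) {
  net <- as_signed_network(net)
  z <- partition_vector(partition, net$labels)
  per_community_balance(net$adjacency, z)$weighted_mean
}

# per-community triad balance terms; shared by cbi() and balance_report()
per_community_balance <- function(A, z) {
  ks <- sort(unique(z))
  if (length(ks) == 0) {
    stop_invalid("Degenerate partition: no communities.")
  }
  rows <- lapply(ks, function(c) {
    members <- which(z == c)
    nneg <- if (length(members) >= 3) {
      triangle_negative_counts(A[members, members, drop = FALSE])
    } else {
      integer(0)
    }
    n_tri <- length(nneg)
    n_ppn <- sum(nneg == 1L)
    tibble(
      community = c, n = length(members), triads = n_tri, ppn = n_ppn,
      balance = if (n_tri > 0) 1 - n_ppn / n_tri else 1,
      no_triads = n_tri == 0
    )
  })
  tab <- dplyr::bind_rows(rows)
  list(table = tab,
       weighted_mean = sum(tab$n * tab$balance) / sum(tab$n))
}

#' Within- and between-community balance report
#'
#' Summarizes how well a hard partition respects weak balance, combining the
#' global [cbi()] with the local interaction-ratio metrics. For each
#' community, over its \eqn{n_c(n_c-1)/2} internal pairs, \eqn{R_e^w} and
#' \eqn{R_d^w} are the fractions of pairs carrying an enhancive or degressive
#' interaction; the report gives
#' \itemize{
#'   \item `delta_w` \eqn{= \ln R_e^w - \ln R_d^w} (log-ratio of enhancive to
#'     degressive density; positive for strongly balanced communities,
#'     negative for weakly balanced ones),
#'   \item `sr_w` \eqn{= R_e^w + R_d^w} (how dense the community is),
#'   \item `dr_w` \eqn{= R_e^w - R_d^w} (which polarity dominates).
#' }
#' For each community pair, the same log-ratio over the \eqn{n_c n_d} cross
#' pairs gives `delta_b`; a well-separated pair joined mostly by degressive
#' edges has `delta_b < 0`.
#'
#' Log-ratios use a pseudo-count of 0.5 interactions
#' (\eqn{R = (count + 0.5)/pairs}) so that communities with zero edges of one
#' polarity still yield finite values; `sr_w` and `dr_w` use the raw ratios.
#' Communities with fewer than two members have no internal pairs; their
#' `delta_w`/`sr_w`/`dr_w` are reported as `NA` and flagged.
#'
#' @inheritParams cbi
#' @return A `balance_report`: list with elements `cbi` (fraction in
#'   `[0, 1]`), `communities` (per-community tibble) and `pairs`
#'   (between-community tibble with `delta_b`).
#' @export
balance_report <- function(net, partition) {
  net <- as_signed_network(net)
  A <- net$adjacency
  z <- partition_vector(partition, net$labels)
  bal <- per_community_balance(A, z)
  ks <- bal$table$community

  within <- lapply(ks, function(c) {
    members <- which(z == c)
    n <- length(members)
    pairs <- n * (n - 1) / 2
    if (pairs == 0) {
      return(tibble(community = c, pairs = 0L, enhancive = 0L, degressive = 0L,
                    delta_w = NA_real_, sr_w = NA_real_, dr_w = NA_real_,
                    undefined = TRUE))
    }
    sub <- A[members, members, drop = FALSE]
    e <- sum(sub > 0) / 2
    d <- sum(sub < 0) / 2
    tibble(
      community = c, pairs = as.integer(pairs),
      enhancive = as.integer(e), degressive = as.integer(d),
      delta_w = log((e + 0.5) / pairs) - log((d + 0.5) / pairs),
      sr_w = (e + d) / pairs,
      dr_w = (e - d) / pairs,
      undefined = FALSE
    )
  })
  communities <- dplyr::left_join(bal$table, dplyr::bind_rows(within),
                                  by = "community")

  pairs_tbl <- if (length(ks) >= 2) {
    combos <- utils::combn(ks, 2)
    dplyr::bind_rows(lapply(seq_len(ncol(combos)), function(i) {
      ci <- combos[1, i]; cj <- combos[2, i]
      mi <- which(z == ci); mj <- which(z == cj)
      cross <- A[mi, mj, drop = FALSE]
      np <- length(mi) * length(mj)
      e <- sum(cross > 0)
      d <- sum(cross < 0)
      tibble(
        community_a = ci, community_b = cj, pairs = as.integer(np),
        enhancive = as.integer(e), degressive = as.integer(d),
        delta_b = log((e + 0.5) / np) - log((d + 0.5) / np)
      )
    }))
  } else {
    tibble(community_a = integer(0), community_b = integer(0),
           pairs = integer(0), enhancive = integer(0), degressive = integer(0),
           delta_b = numeric(0))
  }

  structure(
    list(cbi = bal$weighted_mean, communities = communities, pairs = pairs_tbl),
    class = "balance_report"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> CBI = %.4f (%.2f%%), %d communities\n",
              x$cbi, 100 * x$cbi, nrow(x$communities)))
  print(x$communities, ...)
  invisible(x)
}

#' @rdname balance_report
#' @param x A `balance_report`.
#' @param ... Unused.
#' @export
tidy.balance_report <- function(x, ...) {
  x$communities
}

#' @rdname balance_report
#' @export
glance.balance_report <- function(x, ...) {
  tibble(
    cbi = x$cbi,
    k = nrow(x$communities),
    mean_delta_w = mean(x$communities$delta_w, na.rm = TRUE),
    mean_delta_b = if (nrow(x$pairs)) mean(x$pairs$delta_b) else NA_real_
  )
}

#' @rdname balance_report
#' @param object A `balance_report`.
#' @export
autoplot.balance_report <- function(object, ...) {
  ks <- object$communities$community
  diag_df <- tibble(community_a = ks, community_b = ks,
                    delta = object$communities$delta_w)
  off <- object$pairs
  off_df <- dplyr::bind_rows(
    tibble(community_a = off$community_a, community_b = off$community_b,
           delta = off$delta_b),
    tibble(community_a = off$community_b, community_b = off$community_a,
           delta = off$delta_b)
  )
  df <- dplyr::bind_rows(diag_df, off_df)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$community_a),
                                   y = factor(.data$community_b),
                                   fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "community", y = "community",
                  fill = expression(Delta)) +
    ggplot2::theme_minimal()
}

# normalize a partition (tibble drug/community, or vector) to an integer
# vector aligned with `labels`
partition_vector <- function(partition, labels) {
  if (is.data.frame(partition)) {
    if (!all(c("drug", "community") %in% names(partition))) {
      stop_invalid("Partition table needs columns `drug` and `community`.")
    }
    idx <- match(labels, as.character(partition$drug))
    if (anyNA(idx)) {
      stop_invalid(sprintf(
        "Partition does not cover all nodes; missing: %s.",
        paste(head(labels[is.na(idx)], 5), collapse = ", ")
      ))
    }
    z <- as.integer(partition$community[idx])
  } else {
    z <- as.integer(partition)
    if (length(z) != length(labels)) {
      stop_invalid("Partition vector length must equal the number of nodes.")
    }
  }
  if (anyNA(z)) stop_invalid("Partition contains missing community indices.")
  z
}
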