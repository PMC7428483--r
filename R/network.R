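#' Pairwise Pearson correlation matrix
#'
#' Computes the node-by-node Pearson product-moment correlation matrix of an
#' ROI time-series matrix. Every node must have nonzero variance.
#'
#' @param ts A [roi_timeseries()] with at least 3 volumes.
#' @return An object of class `correlation_matrix`: symmetric matrix with
#'   unit diagonal and the node ids as dimnames.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  m <- unclass(ts)
  if (nrow(m) < 3) stop("at least 3 volumes required for correlation")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0]
    stop(sprintf("zero-variance node(s): %s", paste(bad, collapse = ", ")))
  }
  C <- stats::cor(m)
  diag(C) <- 1
  structure(C, class = c("correlation_matrix", "matrix", "array"))
}

#' Proportional threshold: correlation matrix to binary graph
#'
#' Ranks the `N(N-1)/2` upper-triangle correlations descending by signed
#' value (most positive first) and keeps the top `L = floor(p * N(N-1)/2)`
#' pairs as undirected links, so every subject's graph has an identical link
#' budget. Ties at the cutoff rank (vanishingly rare on real-valued data)
#' are broken deterministically in lexicographic (row, column) order.
#'
#' @param C A [correlation_matrix()] (or any symmetric numeric matrix).
#' @param p Proportion of pairs to keep, in (0, 1]; default 0.25.
#' @param ranking `"signed"` (default: rank by the correlation value) or
#'   `"absolute"` (rank by magnitude).
#' @return An object of class `adjacency_matrix`: binary symmetric matrix
#'   with zero diagonal and attribute `link_count`.
#' @export
proportional_threshold <- function(C, p = 0.25, ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1)
    stop("p must lie in (0, 1]")
  C <- unclass(C)
  N <- nrow(C)
  ut <- upper.tri(C)
  vals <- C[ut]
  if (ranking == "absolute") vals <- abs(vals)
  L <- floor(p * N * (N - 1) / 2)
  A <- matrix(0L, N, N, dimnames = dimnames(C))
  if (L > 0) {
    # order() is stable, and upper.tri indexing is column-major, i.e. already
    # lexicographic in (j, i); decreasing sort keeps that order within ties
    keep <- order(vals, decreasing = TRUE)[seq_len(L)]
    ut_idx <- which(ut)
    A[ut_idx[keep]] <- 1L
    A <- A + t(A)
  }
  structure(A, link_count = L, class = c("adjacency_matrix", "matrix", "array"))
}

#' Node degrees
#'
#' The degree of a node is the number of links connecting it to the rest of
#' the graph; the degrees sum to twice the link count.
#'
#' @param A An [proportional_threshold()] adjacency matrix.
#' @return Named integer vector of degrees.
#' @export
node_degrees <- function(A) {
  A <- unclass(A)
  stats::setNames(as.integer(rowSums(A)), rownames(A))
}

.network_members <- function(parc, label) {
  idx <- which(parc$network == label)
  if (length(idx) == 0) stop(sprintf("unknown or empty network label '%s'", label))
  idx
}

#' Within-network connectivity
#'
#' The mean full degree over the member nodes of a subnetwork. A node's full
#' degree counts all of its links — to nodes inside and outside the
#' subnetwork — so this statistic reflects the subnetwork's overall
#' engagement with the whole graph.
#'
#' @param A An adjacency matrix whose node order matches `parc`.
#' @param parc A [parcellation()].
#' @param label Network label, e.g. `"DMN"`.
#' @return Mean degree (real, in \[0, N-1\]).
#' @export
within_network_connectivity <- function(A, parc, label) {
  stopifnot(nrow(unclass(A)) == nrow(parc))
  idx <- .network_members(parc, label)
  mean(node_degrees(A)[idx])
}

#' Between-network connectivity
#'
#' The number of links with one endpoint in each of two disjoint
#' subnetworks — an indication of the degree of information flow between
#' them.
#'
#' @inheritParams within_network_connectivity
#' @param label_a,label_b Two distinct network labels with disjoint members.
#' @return Integer link count in \[0, |A|*|B|\].
#' @export
between_network_connectivity <- function(A, parc, label_a, label_b) {
  stopifnot(nrow(unclass(A)) == nrow(parc))
  if (identical(label_a, label_b)) stop("labels must be distinct")
  ia <- .network_members(parc, label_a)
  ib <- .network_members(parc, label_b)
  if (length(intersect(ia, ib)) > 0) stop("network member sets overlap")
  as.integer(sum(unclass(A)[ia, ib]))
}

#' Per-subject, per-condition subnetwork metrics
#'
#' Runs the full graph pipeline — correlation matrix, proportional threshold,
#' degree statistics — for each (subject, condition) time series and returns
#' a tidy table of within-network connectivity for each network of interest
#' plus the between-network link count for the first pair. Because the
#' threshold is proportional, every row's graph has the identical link
#' budget.
#'
#' @param ts_list Nested list: `ts_list[[subject]][[condition]]` is a
#'   [roi_timeseries()].
#' @param parc A [parcellation()] matching the node count.
#' @param p Threshold proportion (default 0.25).
#' @param networks Labels of the networks of interest (default
#'   `c("DMN", "FPN")`); within-connectivity is computed per label and
#'   between-connectivity for the first two.
#' @param ranking Passed to [proportional_threshold()].
#' @return Data frame with columns `subject`, `condition`, `metric`,
#'   `value`; metrics are `within_<label>` and `between_<A>_<B>`.
#' @export
subject_condition_metrics <- function(ts_list, parc, p = 0.25,
                                      networks = c("DMN", "FPN"),
                                      ranking = "signed") {
  if (length(networks) < 2) stop("need at least two networks of interest")
  rows <- list()
  for (subj in names(ts_list)) {
    for (cond in names(ts_list[[subj]])) {
      ts <- ts_list[[subj]][[cond]]
      if (ncol(ts) != nrow(parc))
        stop(sprintf("subject %s/%s: %d nodes but parcellation has %d",
                     subj, cond, ncol(ts), nrow(parc)))
      A <- proportional_threshold(correlation_matrix(ts), p, ranking = ranking)
      vals <- c(
        stats::setNames(
          vapply(networks, function(l) within_network_connectivity(A, parc, l),
                 numeric(1)),
          sprintf("within_%s", networks)),
        stats::setNames(
          between_network_connectivity(A, parc, networks[1], networks[2]),
          sprintf("between_%s_%s", networks[1], networks[2])))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, condition = cond, metric = names(vals),
        value = unname(vals), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
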