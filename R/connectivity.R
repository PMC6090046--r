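#' Band-limited instantaneous phase via the analytic signal
#'
#' Each column is transformed to the frequency domain, bins outside
#' `[f_low, f_high)` and all negative frequencies are zeroed, in-band
#' positive bins are doubled, and the inverse transform yields the analytic
#' signal whose argument is the instantaneous phase. The frequency-domain
#' selection is exactly zero-phase, so it cannot introduce the phase
#' distortion that would bias the phase lag index.
#'
#' @param x Numeric matrix, samples x channels (one epoch), or a vector.
#' @param sampling_rate Sampling frequency in Hz.
#' @param f_low,f_high Band edges in Hz, `[f_low, f_high)`.
#' @return Matrix of instantaneous phase in radians, samples x channels.
#' @export
analytic_phase <- function(x, sampling_rate, f_low = 0.5, f_high = 48) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (f_low <= 0 || f_high <= f_low || f_high > sampling_rate / 2) {
    stop("band must satisfy 0 < f_low < f_high <= Nyquist")
  }
  freq <- (0:(n - 1L)) * sampling_rate / n
  keep <- freq >= f_low & freq < f_high & seq_len(n) <= floor(n / 2) + 1L
  if (!any(keep)) stop("no spectral bins inside [", f_low, ", ", f_high, ") Hz")
  X <- stats::mvfft(x)
  X[!keep, ] <- 0
  X[keep, ] <- 2 * X[keep, ]
  z <- stats::mvfft(X, inverse = TRUE) / n
  Arg(z)
}

#' Phase lag index between two phase series
#'
#' PLI = | mean over samples of sign(sin(phase_a - phase_b)) |. It measures
#' the asymmetry of the distribution of instantaneous phase differences
#' around zero: consistently lagged (or leading) signals score near 1,
#' while zero-lag synchronization -- the signature of volume conduction and
#' field spread in source-reconstructed MEG -- scores 0. Samples with
#' sin(delta phi) = 0 contribute 0 to the mean.
#'
#' @param phase_a,phase_b Instantaneous-phase vectors (radians), equal
#'   length >= 2.
#' @return Scalar in `[0, 1]`.
#' @examples
#' ph <- runif(1000, -pi, pi)
#' pli_pair(ph, ph)             # 0: zero lag is invisible
#' pli_pair(ph + pi / 2, ph)    # 1: constant quarter-cycle lag
#' @export
pli_pair <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b)) {
    stop("phase series differ in length (", length(phase_a), " vs ",
         length(phase_b), ")")
  }
  if (length(phase_a) < 2L) stop("need at least 2 samples")
  abs(mean(sign(sin(phase_a - phase_b))))
}

#' Broadband PLI connectivity matrix
#'
#' Per epoch, every ROI series is band-limited to `[f_low, f_high)` and its
#' instantaneous phase extracted via the analytic signal; the PLI is then
#' computed for all ROI pairs and the per-epoch matrices are averaged.
#' Computing per epoch and then averaging (rather than on concatenated
#' data) keeps the epoch as the unit of analysis, consistent with the
#' band-power metrics.
#'
#' @param epochs An `epoch_array` from [segment_epochs()].
#' @param f_low,f_high Analysis band in Hz (default broadband 0.5-48).
#' @return Symmetric ROI x ROI matrix of PLI values in `[0, 1]` with zero
#'   diagonal, class `connectivity_matrix`.
#' @export
pli_matrix <- function(epochs, f_low = 0.5, f_high = 48) {
  stopifnot(inherits(epochs, "epoch_array"))
  n_epochs <- dim(epochs)[1]
  n_rois <- dim(epochs)[2]
  if (n_epochs < 1L) stop("need at least one epoch")
  if (n_rois < 2L) stop("need at least two ROIs")
  fs <- attr(epochs, "sampling_rate")

  acc <- matrix(0, n_rois, n_rois)
  for (e in seq_len(n_epochs)) {
    ep <- matrix(epochs[e, , , drop = FALSE], nrow = n_rois)  # rois x samples
    ph <- analytic_phase(t(ep), fs, f_low, f_high)            # samples x rois
    S <- sin(ph)
    C <- cos(ph)
    for (a in seq_len(n_rois - 1L)) {
      idx <- (a + 1L):n_rois
      # sign(sin(phi_b - phi_a)) for all b > a, vectorized over samples
      d <- S[, idx, drop = FALSE] * C[, a] - C[, idx, drop = FALSE] * S[, a]
      acc[a, idx] <- acc[a, idx] + abs(colMeans(sign(d)))
    }
  }
  m <- acc / n_epochs
  m <- m + t(m)
  diag(m) <- 0
  structure(m, class = c("connectivity_matrix", "matrix"))
}

validate_connectivity <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (any(matrix < 0) || any(matrix > 1)) stop("PLI values must lie in [0, 1]")
  if (any(diag(matrix) != 0)) stop("connectivity diagonal must be zero")
  if (!isTRUE(all.equal(matrix, t(matrix), check.attributes = FALSE))) {
    stop("connectivity matrix must be symmetric")
  }
  invisible(matrix)
}

#' Mean PLI of each ROI to all other ROIs
#'
#' Row mean of the connectivity matrix excluding the diagonal entry; the
#' per-ROI connectivity-strength metric.
#'
#' @param matrix A `connectivity_matrix` (ROI x ROI, zero diagonal).
#' @return Numeric vector, one mean per ROI.
#' @export
roi_mean_pli <- function(matrix) {
  validate_connectivity(matrix)
  n <- nrow(matrix)
  if (n < 2L) stop("need at least two ROIs")
  rowSums(matrix) / (n - 1)
}

#' Minimum spanning tree of the PLI network
#'
#' The ROIs are the nodes of a complete graph whose edge weights are the
#' inverted PLI values (1/PLI), so the strongest functional connections
#' carry the smallest weights and the minimum spanning tree is the
#' highest-connectivity backbone of the network. Pairs with PLI = 0 receive
#' a surrogate weight far above every real weight, so such edges are chosen
#' only if nothing else can connect the graph.
#'
#' @param matrix A `connectivity_matrix`.
#' @return An [igraph][igraph::igraph-package] tree with `n - 1` edges;
#'   edge attributes `weight` (1/PLI) and `pli`. Edges are inserted in
#'   lexicographic (i, j) order so the tree is deterministic for a given
#'   matrix, including under ties.
#' @export
mst_from_pli <- function(matrix) {
  validate_connectivity(matrix)
  n <- nrow(matrix)
  if (n < 2L) stop("need at least two ROIs")
  ut <- upper.tri(matrix)
  pli <- matrix[ut]
  if (all(pli == 0)) stop("degenerate input: all PLI values are zero")
  w <- ifelse(pli > 0, 1 / pli, max(1 / pli[pli > 0]) * n * n)
  pairs <- which(ut, arr.ind = TRUE)       # already ordered with i < j
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2], weight = w, pli = pli),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  igraph::mst(g, weights = igraph::E(g)$weight)
}

#' Betweenness centrality on a spanning tree
#'
#' For each node, the fraction of the `(N-1)(N-2)/2` unordered pairs of
#' other nodes whose (unique) tree path passes through it. The star center
#' scores 1 and every leaf scores 0. Hop counts are used for path finding;
#' on a tree the paths are unique, so edge weights cannot change them.
#'
#' @param tree An igraph tree, e.g. from [mst_from_pli()].
#' @return Numeric vector of centralities in `[0, 1]`, in vertex order.
#' @export
tree_betweenness <- function(tree) {
  stopifnot(igraph::is_igraph(tree))
  n <- igraph::vcount(tree)
  if (!igraph::is_connected(tree)) stop("input graph is disconnected")
  if (igraph::ecount(tree) != n - 1L) {
    stop("input is not a tree: expected ", n - 1L, " edges, found ",
         igraph::ecount(tree))
  }
  if (n < 3L) return(rep(0, n))
  bc <- igraph::betweenness(tree, directed = FALSE, weights = NA)
  unname(bc / ((n - 1) * (n - 2) / 2))
}

#' Edge list of a spanning tree
#'
#' @param tree An igraph tree from [mst_from_pli()].
#' @return data.frame with columns `roi_a`, `roi_b`, `weight` (1/PLI) and,
#'   when present, `pli`.
#' @export
tree_edges <- function(tree) {
  el <- igraph::as_edgelist(tree)
  out <- data.frame(roi_a = as.integer(el[, 1]), roi_b = as.integer(el[, 2]),
                    weight = igraph::E(tree)$weight)
  if (!is.null(igraph::E(tree)$pli)) out$pli <- igraph::E(tree)$pli
  out
}
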