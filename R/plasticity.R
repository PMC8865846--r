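#' Spike-timing-dependent plasticity kernel
#'
#' Pair-based additive STDP kernel. Two presets are provided: the broad
#' `"symmetric"` kernel measured between CA3 pyramidal cells (both branches
#' potentiate; `A+ = A- = 80` pA, `tau = 62.5` ms, `w_max = 20` nS) and the
#' classical `"asymmetric"` Hebbian kernel (`A+ = 400`, `A- = -400` pA,
#' `tau = 20` ms, `w_max = 40` nS).
#'
#' Kernel amplitudes are given in pA while synaptic weights are peak
#' conductances in nS; the mapping is the single conversion constant
#' `unit_scale` (nS of weight increment per pA of kernel amplitude, default
#' `1e-3`, i.e. an 80 pA coincident-pair amplitude increments the weight by
#' 0.08 nS).
#'
#' `scale` is the population-level multiplier applied to the learned weights
#' at the end of learning (0.62 for the symmetric, 1.27 for the asymmetric
#' preset), tuned so that the offline network operates in its physiological
#' regime; [learn_weights()] applies it by default.
#'
#' @param preset `"symmetric"` or `"asymmetric"`.
#' @param A_plus,A_minus Amplitudes in pA (`A_minus` signed).
#' @param tau_plus,tau_minus Decay time constants in ms.
#' @param w_max Upper weight crop in nS.
#' @param w_init Initial weight in nS.
#' @param unit_scale nS of weight increment per pA of amplitude; the
#'   default (1.1e-3) is calibrated once so that the baseline network
#'   operates just above its sharp-wave ignition threshold at E-E scale 1.
#' @param scale Post-learning multiplier.
#' @return An object of class `stdp_kernel`.
#' @export
stdp_kernel <- function(preset = c("symmetric", "asymmetric"),
                        A_plus = NULL, A_minus = NULL, tau_plus = NULL,
                        tau_minus = NULL, w_max = NULL, w_init = 0.1,
                        unit_scale = 1.1e-3, scale = NULL) {
  preset <- match.arg(preset)
  def <- if (preset == "symmetric") {
    list(A_plus = 80, A_minus = 80, tau_plus = 62.5, tau_minus = 62.5,
         w_max = 20, scale = 0.62)
  } else {
    list(A_plus = 400, A_minus = -400, tau_plus = 20, tau_minus = 20,
         w_max = 40, scale = 1.27)
  }
  k <- list(preset = preset,
            A_plus = A_plus %||% def$A_plus,
            A_minus = A_minus %||% def$A_minus,
            tau_plus = tau_plus %||% def$tau_plus,
            tau_minus = tau_minus %||% def$tau_minus,
            w_max = w_max %||% def$w_max,
            w_init = w_init, unit_scale = unit_scale,
            scale = scale %||% def$scale)
  stopifnot(k$tau_plus > 0, k$tau_minus > 0, k$w_max > k$w_init, k$w_init >= 0)
  structure(k, class = "stdp_kernel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' STDP weight change for a single spike pair
#'
#' Evaluates the pair contribution for a pre/post time difference
#' `delta_t = t_post - t_pre` (ms): `A+ exp(-delta_t / tau+)` for
#' `delta_t > 0`, `A- exp(delta_t / tau-)` for `delta_t < 0`, and a single
#' update of `A+` for an exact tie. Returned on the pA amplitude scale (not
#' yet converted to nS).
#'
#' @param delta_t Time difference(s) `t_post - t_pre` in ms.
#' @param kernel An [stdp_kernel()].
#' @return Weight increment(s), pA scale.
#' @export
stdp_weight_change <- function(delta_t, kernel) {
  ifelse(delta_t > 0, kernel$A_plus * exp(-delta_t / kernel$tau_plus),
         ifelse(delta_t < 0, kernel$A_minus * exp(delta_t / kernel$tau_minus),
                kernel$A_plus))
}

#' Sample a random directed connectivity graph
#'
#' Each ordered pair (pre, post) is connected independently with probability
#' `p`; self-edges are excluded unless `allow_self`. Stored in compressed
#' sparse column form (0-based, ready for the C++ cores).
#'
#' @param n_pre,n_post Population sizes.
#' @param p Connection probability.
#' @param allow_self Keep self-edges (only meaningful when the two
#'   populations are the same cells).
#' @param seed Integer seed.
#' @return A `connectivity_graph`: list with `col_ptr` (length
#'   `n_post + 1`), `row_ind` (0-based presynaptic indices, sorted within
#'   each column), `n_pre`, `n_post`.
#' @export
sample_connectivity <- function(n_pre, n_post, p, allow_self = FALSE, seed = 1L) {
  if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) stop("invalid connection probability")
  set.seed(seed)
  cols <- vector("list", n_post)
  for (j in seq_len(n_post)) {
    excl_self <- !allow_self && j <= n_pre
    n_cand <- n_pre - excl_self
    k <- rbinom(1L, n_cand, p)
    if (k > 0) {
      pre <- sample.int(n_cand, k)
      if (excl_self) pre <- ifelse(pre >= j, pre + 1L, pre)
      cols[[j]] <- sort(pre) - 1L
    } else {
      cols[[j]] <- integer(0)
    }
  }
  structure(list(col_ptr = c(0L, cumsum(lengths(cols))),
                 row_ind = unlist(cols, use.names = FALSE) %||% integer(0),
                 n_pre = as.integer(n_pre), n_post = as.integer(n_post)),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat("connectivity_graph:", x$n_pre, "x", x$n_post, "with",
      length(x$row_ind), "edges\n")
  invisible(x)
}

#' Edge list of a connectivity graph
#' @param graph A `connectivity_graph`.
#' @return data.frame with 1-based `pre`, `post`.
#' @export
graph_edges <- function(graph) {
  n_per_col <- diff(graph$col_ptr)
  data.frame(pre = graph$row_ind + 1L,
             post = rep(seq_len(graph$n_post), n_per_col))
}

new_weight_matrix <- function(graph, w, w_max) {
  structure(list(graph = graph, w = as.numeric(w), w_max = w_max),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  nz <- x$w[x$w > 0]
  cat("weight_matrix:", x$graph$n_pre, "x", x$graph$n_post, "with",
      length(x$w), "edges,", length(nz), "nonzero;",
      if (length(nz)) sprintf("mean %.4f nS, max %.4f nS", mean(nz), max(nz))
      else "", "\n")
  invisible(x)
}

#' Convert a weight matrix to a sparse `dgCMatrix`
#' @param W A `weight_matrix`.
#' @return A [Matrix::sparseMatrix()] (`dgCMatrix`) of peak conductances, nS.
#' @export
as_sparse_matrix <- function(W) {
  g <- W$graph
  Matrix::sparseMatrix(i = g$row_ind, p = g$col_ptr, x = W$w,
                       dims = c(g$n_pre, g$n_post), index1 = FALSE)
}

#' Learn recurrent weights from exploration spike trains
#'
#' Applies the additive pair-based STDP rule with all-to-all spike pairing
#' over the full spike trains, restricted to the edges of a fixed sparse
#' connectivity graph. The implementation accumulates exponential pre- and
#' post-synaptic traces (equivalent to the explicit double sum over all
#' spike pairs when no clipping occurs); every update is applied at its
#' event time (potentiation at the postsynaptic, depression at the
#' presynaptic spike arrival) and immediately cropped to `[0, w_max]`.
#' Weights start from `kernel$w_init` and the learned matrix is multiplied
#' by `scale` at the end.
#'
#' @param spikes A `spike_train_set` from [generate_spike_trains()].
#' @param graph A `connectivity_graph` over the same population.
#' @param kernel An [stdp_kernel()].
#' @param scale Post-learning multiplier (default the kernel's).
#' @param w_start Optional per-edge starting weights in nS (unscaled), for
#'   sequential learning of several environments; default `kernel$w_init`
#'   everywhere.
#' @return A `weight_matrix` of peak conductances (nS) on the graph's
#'   edges; the pre-scale weights are kept in its `w_raw` element.
#' @export
learn_weights <- function(spikes, graph, kernel, scale = kernel$scale,
                          w_start = NULL) {
  stopifnot(inherits(spikes, "spike_train_set"),
            inherits(graph, "connectivity_graph"),
            inherits(kernel, "stdp_kernel"))
  if (spikes$n_cells != graph$n_pre || spikes$n_cells != graph$n_post)
    stop("spike trains and graph population size mismatch")
  cell <- rep(seq_along(spikes$spikes) - 1L, lengths(spikes$spikes))
  t_ms <- unlist(spikes$spikes, use.names = FALSE) * 1000
  o <- order(t_ms)
  w0 <- w_start %||% rep(kernel$w_init, length(graph$row_ind))
  stopifnot(length(w0) == length(graph$row_ind))
  w <- cpp_learn_stdp(t_ms[o], cell[o], spikes$n_cells,
                      graph$col_ptr, graph$row_ind, w0,
                      kernel$A_plus * kernel$unit_scale,
                      kernel$A_minus * kernel$unit_scale,
                      kernel$tau_plus, kernel$tau_minus, kernel$w_max)
  out <- new_weight_matrix(graph, w * scale, kernel$w_max * scale)
  out$w_raw <- w
  out
}

#' Scale recurrent weights
#'
#' Elementwise multiplication by a scalar; used for the post-learning
#' up-/down-scaling experiments. No clipping is reapplied.
#'
#' @param W A `weight_matrix`.
#' @param factor Dimensionless multiplier.
#' @export
scale_weights <- function(W, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1, factor >= 0)
  new_weight_matrix(W$graph, W$w * factor, W$w_max)
}

#' Binarize recurrent weights into two group means
#'
#' Splits the nonzero weights at the `1 - top_fraction` quantile into the
#' strongest `top_fraction` and the rest, and replaces every weight by its
#' group mean. Support and total summed weight are preserved; only the
#' distribution collapses to two values.
#'
#' @param W A `weight_matrix` with nonzero entries.
#' @param top_fraction Fraction forming the strong group (default 0.03).
#' @export
binarize_weights <- function(W, top_fraction = 0.03) {
  nz <- W$w > 0
  if (!any(nz)) stop("empty weight matrix")
  w <- W$w
  thr <- quantile(w[nz], 1 - top_fraction, names = FALSE)
  hi <- nz & w > thr
  lo <- nz & !hi
  if (any(hi)) w[hi] <- mean(W$w[hi])
  if (any(lo)) w[lo] <- mean(W$w[lo])
  new_weight_matrix(W$graph, w, W$w_max)
}

#' Shuffle postsynaptic identities (column shuffle)
#'
#' Permutes the columns of the weight matrix by a uniform random
#' permutation, destroying the global structure of the interactions while
#' preserving each neuron's outgoing weight multiset. Any weight landing on
#' the diagonal afterwards is set to zero (self-connections are never
#' allowed); the displaced mass is not redistributed.
#'
#' @param W A `weight_matrix` (square).
#' @param seed Integer seed.
#' @export
shuffle_postsynaptic <- function(W, seed) {
  g <- W$graph
  stopifnot(g$n_pre == g$n_post)
  set.seed(seed)
  perm <- sample.int(g$n_post)          # new column j <- old column perm[j]
  n_per_col <- diff(g$col_ptr)
  cols <- vector("list", g$n_post)
  wcols <- vector("list", g$n_post)
  for (j in seq_len(g$n_post)) {
    src <- perm[j]
    idx <- if (n_per_col[src] > 0)
      (g$col_ptr[src] + 1L):g$col_ptr[src + 1L] else integer(0)
    pre <- g$row_ind[idx]
    wj <- W$w[idx]
    wj[pre == j - 1L] <- 0            # re-zero the diagonal
    cols[[j]] <- pre
    wcols[[j]] <- wj
  }
  g2 <- structure(list(col_ptr = c(0L, cumsum(lengths(cols))),
                       row_ind = unlist(cols, use.names = FALSE),
                       n_pre = g$n_pre, n_post = g$n_post),
                  class = "connectivity_graph")
  new_weight_matrix(g2, unlist(wcols, use.names = FALSE), W$w_max)
}

#' Write / read a weight matrix as coordinate-format text
#'
#' Three-column text (`pre`, `post`, 1-based; `w` in nS) with a header line.
#' @param W A `weight_matrix`.
#' @param path File path.
#' @export
write_weight_matrix <- function(W, path) {
  e <- graph_edges(W$graph)
  e$w <- W$w
  con <- file(path, "w")
  writeLines(sprintf("# n_pre %d n_post %d w_max %.10g",
                     W$graph$n_pre, W$graph$n_post, W$w_max), con)
  write.table(e, con, row.names = FALSE, quote = FALSE, sep = "\t")
  close(con)
  invisible(path)
}

#' @rdname write_weight_matrix
#' @export
read_weight_matrix <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), " ")[[1]]
  n_pre <- as.integer(hdr[3]); n_post <- as.integer(hdr[5])
  w_max <- as.numeric(hdr[7])
  df <- read.table(path, header = TRUE, skip = 1)
  o <- order(df$post, df$pre)
  df <- df[o, ]
  counts <- tabulate(df$post, nbins = n_post)
  g <- structure(list(col_ptr = c(0L, cumsum(counts)),
                      row_ind = as.integer(df$pre) - 1L,
                      n_pre = n_pre, n_post = n_post),
                 class = "connectivity_graph")
  new_weight_matrix(g, df$w, w_max)
}
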