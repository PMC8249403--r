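#' Discretized conformational path
#'
#' Builds the path collective variable from an ordered set of conformations
#' (the path nodes). Node `m` of an `M`-node path sits at path parameter
#' `s_m = (m - 1) / (M - 1)`, so `s` runs from 0 at the first node to 1 at the
#' last.
#'
#' @param conformations an ordered list of [conformation()] objects, all with
#'   the same bead count, length `M >= 2`.
#' @return an object of class `"cv_path"` with elements `nodes` and
#'   `s_values`.
#' @examples
#' arm <- function(a) conformation(cbind(cos(a) * 1:4, sin(a) * 1:4, 0),
#'                                 rep(3, 4), rep(50, 4))
#' p <- make_path(lapply(c(0, 0.1, 0.2), arm))
#' p$s_values
#' @export
make_path <- function(conformations) {
  if (!is.list(conformations) || length(conformations) < 2)
    stopf("a path needs at least 2 conformations")
  if (!all(vapply(conformations, inherits, logical(1), "conformation")))
    stopf("all path nodes must be conformation objects")
  b <- vapply(conformations, n_beads, integer(1))
  if (length(unique(b)) != 1)
    stopf("all path nodes must have the same bead count (got %s)",
          paste(unique(b), collapse = ", "))
  m <- length(conformations)
  structure(list(nodes = conformations,
                 s_values = (seq_len(m) - 1) / (m - 1)),
            class = "cv_path")
}

#' @export
print.cv_path <- function(x, ...) {
  cat(sprintf("<cv_path> M = %d nodes, %d beads each, s in [0, 1]\n",
              length(x$nodes), n_beads(x$nodes[[1]])))
  invisible(x)
}

path_length <- function(path) length(path$nodes)

#' Equispaced path quadrature
#'
#' Approximates `integral_0^1 f(s) ds` from values of `f` at the `M`
#' equispaced path nodes by the M-node rule `(1/M) * sum_m f(s_m)`. This is
#' the rule used to discretize all integrals over the path parameter
#' (including the profile partition function), implemented exactly as stated
#' rather than as a trapezoid rule.
#'
#' @param node_values values `f(s_m)` at the path nodes, length `M >= 2`.
#' @return the quadrature value, a single number.
#' @examples
#' quadrature(seq(0, 1, length.out = 7))  # f(s) = s integrates to 0.5 exactly
#' @export
quadrature <- function(node_values) {
  if (length(node_values) < 2) stopf("quadrature needs at least 2 node values")
  sum(node_values) / length(node_values)
}

#' Progress variable of a conformation along a path
#'
#' The softmax-weighted progress coordinate of Branduardi-style path
#' collective variables, computed from RMSD distances to all path nodes:
#' `s(x) = sum_m (m-1) exp(-lambda d_m^2) / ((M-1) sum_m exp(-lambda d_m^2))`
#' with `d_m` the RMSD between the query conformation and node `m` after
#' optimal (Kabsch) superposition. For a conformation on top of node `k` and
#' well-separated nodes, `s` approaches `(k-1)/(M-1)`.
#'
#' @param conf a [conformation()] with the same bead count as the path nodes.
#' @param path a [make_path()] object.
#' @param lambda_cv softmax inverse length-scale in Angstrom^-2 (default 50,
#'   the value used for hexapeptide-scale systems).
#' @return the progress estimate, a number in `[0, 1]`.
#' @export
path_cv_value <- function(conf, path, lambda_cv = 50) {
  if (!inherits(conf, "conformation")) stopf("conf must be a conformation")
  if (!inherits(path, "cv_path")) stopf("path must be a cv_path")
  if (lambda_cv <= 0) stopf("lambda_cv must be positive")
  if (n_beads(conf) != n_beads(path$nodes[[1]]))
    stopf("bead count mismatch between conformation (%d) and path nodes (%d)",
          n_beads(conf), n_beads(path$nodes[[1]]))
  m <- path_length(path)
  d2 <- vapply(path$nodes, function(nd) rmsd_fitted(conf$positions, nd$positions)^2,
               numeric(1))
  # softmax in log space: weights exp(-lambda d^2), stabilized by the min d^2
  lw <- -lambda_cv * (d2 - min(d2))
  w <- exp(lw)
  sum((seq_len(m) - 1) * w) / ((m - 1) * sum(w))
}

#' Select path nodes from an ensemble by a scalar metric
#'
#' Picks `M` members of a conformational ensemble whose metric values (for
#' example the end-to-end distance) are closest to `M` equispaced targets
#' spanning the observed metric range, so that successive nodes are
#' approximately equally spaced in the metric.
#'
#' @param ensemble list of [conformation()] objects.
#' @param metric numeric vector of per-conformation metric values (finite),
#'   same length as `ensemble`.
#' @param M number of nodes to select, `2 <= M <= length(ensemble)`.
#' @return a [make_path()] built from the selected members (ordered by
#'   metric target); the indices of the chosen members are attached as
#'   attribute `"indices"`.
#' @export
select_nodes_by_metric <- function(ensemble, metric, M) {
  if (length(ensemble) < M) stopf("ensemble (%d) is smaller than M = %d",
                                  length(ensemble), M)
  if (M < 2) stopf("M must be at least 2")
  metric <- as.numeric(metric)
  if (length(metric) != length(ensemble)) stopf("metric length must match ensemble")
  if (!all(is.finite(metric))) stopf("metric values must be finite")
  targets <- seq(min(metric), max(metric), length.out = M)
  picked <- integer(M)
  avail <- seq_along(metric)
  for (k in seq_len(M)) {
    j <- avail[which.min(abs(metric[avail] - targets[k]))]
    picked[k] <- j
    avail <- setdiff(avail, j)  # without replacement so nodes are distinct
  }
  p <- make_path(ensemble[picked])
  attr(p, "indices") <- picked
  p
}
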