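#' Synthetic ground-truth free energies for the benchmark systems
#'
#' Closed-form free-energy profiles (in units of kBT, with beta = 1) used to
#' set the Boltzmann populations of the synthetic benchmark systems. The 1D
#' profile is a double well along the path parameter `s`:
#' `exp(-G(s)) = exp(-(19 s - 6)^2 / 8) + exp(-(19 s - 15)^2 / 18) / 3`,
#' and the 2D surface over the two rotation-model indices `(u, v)` is
#' `exp(-G(u, v)) = exp(-(u-6)^2/18 - (v-6)^2/10) + exp(-(u-15)^2/18 - (v-15)^2/10)`,
#' two basins at models (6, 6) and (15, 15) separated by a barrier of about
#' 2 kBT.
#'
#' @param s path parameter(s) in `[0, 1]` (vectorized).
#' @param u,v real-valued model indices on the 20 x 20 conformer grid
#'   (vectorized).
#' @return free energy value(s) in kBT.
#' @examples
#' ground_truth_1d(c(0, 6 / 19, 15 / 19))
#' ground_truth_2d(6, 6)
#' @export
ground_truth_1d <- function(s) {
  if (any(s < 0 | s > 1)) stopf("s must lie in [0, 1]")
  -log(exp(-(19 * s - 6)^2 / 8) + exp(-(19 * s - 15)^2 / 18) / 3)
}

#' @rdname ground_truth_1d
#' @export
ground_truth_2d <- function(u, v) {
  -log(exp(-(u - 6)^2 / 18 - (v - 6)^2 / 10) +
       exp(-(u - 15)^2 / 18 - (v - 15)^2 / 10))
}

#' Ground-truth profile at the path nodes
#'
#' Tabulates a ground-truth free energy at the `M` path nodes, for driving
#' the synthetic particle generator and for scoring recovered profiles. Only
#' free-energy differences are meaningful (the profile is gauge-free).
#'
#' @param kind one of `"hsp90_1d"` (the 1D double well evaluated at
#'   `s_m = (m-1)/(M-1)`), `"hsp90_2d_along_path"` (the 2D surface sliced
#'   along a CV line from [path_on_surface()]), or `"tabulated"` (explicit
#'   values).
#' @param M number of nodes (for the formula kinds).
#' @param values explicit node values in kBT (for `kind = "tabulated"`).
#' @param cv_id CV line for the 2D kind, see [path_on_surface()].
#' @return an object of class `"gt_profile"` with elements `kind`, `values`
#'   (length `M`, kBT) and `beta = 1`.
#' @export
ground_truth_profile <- function(kind = c("hsp90_1d", "hsp90_2d_along_path", "tabulated"),
                                 M = NULL, values = NULL, cv_id = "CV1") {
  kind <- match.arg(kind)
  vals <- switch(kind,
    hsp90_1d = {
      if (is.null(M)) stopf("M is required for kind 'hsp90_1d'")
      ground_truth_1d((seq_len(M) - 1) / (M - 1))
    },
    hsp90_2d_along_path = {
      if (is.null(M)) stopf("M is required for kind 'hsp90_2d_along_path'")
      uv <- path_on_surface(cv_id, M)
      ground_truth_2d(uv[, 1], uv[, 2])
    },
    tabulated = {
      if (is.null(values)) stopf("values are required for kind 'tabulated'")
      as.numeric(values)
    })
  if (!all(is.finite(vals))) stopf("ground-truth values must be finite")
  structure(list(kind = kind, values = vals, beta = 1), class = "gt_profile")
}

#' @export
print.gt_profile <- function(x, ...) {
  cat(sprintf("<gt_profile> kind = %s, M = %d nodes, range %.2f kBT\n",
              x$kind, length(x$values), diff(range(x$values))))
  invisible(x)
}

#' Boltzmann node populations of a profile
#'
#' @param profile a `gt_profile` or a numeric vector of node free energies
#'   in kBT.
#' @return normalized populations `exp(-G_m) / sum_k exp(-G_k)`.
#' @export
node_populations <- function(profile) {
  g <- if (inherits(profile, "gt_profile")) profile$values else as.numeric(profile)
  w <- exp(-(g - min(g)))
  w / sum(w)
}

#' CV lines across the 2D benchmark surface
#'
#' Returns `M` equispaced `(u, v)` points along one of the three benchmark
#' paths over the 20 x 20 conformer-model grid: `CV1` follows the diagonal
#' `u = v` (through both basins and the transition state), `CV2` holds
#' `u = 10` fixed while `v` varies, and `CV3` holds `v = 10` fixed while `u`
#' varies.
#'
#' @param cv_id one of `"CV1"`, `"CV2"`, `"CV3"`.
#' @param M number of points, `>= 2`.
#' @return an `M x 2` matrix with columns `u`, `v`.
#' @export
path_on_surface <- function(cv_id, M) {
  if (M < 2) stopf("M must be at least 2")
  t_seq <- seq(1, 20, length.out = M)
  uv <- switch(as.character(cv_id),
    CV1 = cbind(u = t_seq, v = t_seq),
    CV2 = cbind(u = rep(10, M), v = t_seq),
    CV3 = cbind(u = t_seq, v = rep(10, M)),
    stopf("unknown cv_id '%s' (expected CV1, CV2 or CV3)", cv_id))
  uv
}
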