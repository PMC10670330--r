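#' Scoring parameters for the similarity indices
#'
#' Bundles every tunable the twelve indices use, with the defaults the
#' package recommends.
#'
#' @param lambda_weight Weight \eqn{\lambda \in [0, 1]} balancing the local
#'   against the global closeness term in LGC and LGC*. Default 0.8, the
#'   value at which both indices peak across a range of networks.
#' @param katz_beta Damping factor \eqn{\beta > 0} of the Katz index.
#'   Must stay strictly below the reciprocal of the adjacency spectral
#'   radius (validated at scoring time). Default 0.01.
#' @param lp_epsilon Weight \eqn{\epsilon > 0} of the cubic term in the
#'   local-path index \eqn{A^2 + \epsilon A^3}. Default 0.001.
#' @param cn2d_beta Weight \eqn{\beta > 0} of the degree-normalised
#'   second-order term in CN2D. Default 0.1.
#' @param gc_form How the global closeness term combines pair closeness
#'   \eqn{C_{u,v}} with the network averages \eqn{CC} (clustering) and
#'   \eqn{d} (shortest path): `"product"` (default) gives
#'   \eqn{C_{u,v} \cdot CC / d}; `"inverse"` gives
#'   \eqn{C_{u,v} / (d \cdot CC)} and errors on triangle-free networks
#'   where \eqn{CC = 0}.
#' @param dense_cap Largest node count for which the dense-matrix indices
#'   (Katz, LP) are computed; beyond it they error with guidance, since the
#'   matrix inverse is cubic in n. Default 3000.
#' @return An object of class `index_params` (a validated list).
#' @examples
#' index_params(lambda_weight = 0.5)
#' @export
index_params <- function(lambda_weight = 0.8, katz_beta = 0.01,
                         lp_epsilon = 0.001, cn2d_beta = 0.1,
                         gc_form = c("product", "inverse"),
                         dense_cap = 3000L) {
  gc_form <- match.arg(gc_form)
  if (!is.numeric(lambda_weight) || length(lambda_weight) != 1L ||
      is.na(lambda_weight) || lambda_weight < 0 || lambda_weight > 1) {
    stop("`lambda_weight` must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(katz_beta) || katz_beta < 0) {
    stop("`katz_beta` must be a non-negative number", call. = FALSE)
  }
  if (!is.numeric(lp_epsilon) || lp_epsilon < 0) {
    stop("`lp_epsilon` must be a non-negative number", call. = FALSE)
  }
  if (!is.numeric(cn2d_beta) || cn2d_beta < 0) {
    stop("`cn2d_beta` must be a non-negative number", call. = FALSE)
  }
  structure(
    list(lambda_weight = lambda_weight, katz_beta = katz_beta,
         lp_epsilon = lp_epsilon, cn2d_beta = cn2d_beta,
         gc_form = gc_form, dense_cap = as.integer(dense_cap)),
    class = "index_params"
  )
}

#' @export
print.index_params <- function(x, ...) {
  cat(sprintf(
    "Index parameters: lambda = %g, katz beta = %g, lp epsilon = %g, cn2d beta = %g, gc form = %s\n",
    x$lambda_weight, x$katz_beta, x$lp_epsilon, x$cn2d_beta, x$gc_form))
  invisible(x)
}

as_index_params <- function(params) {
  if (inherits(params, "index_params")) return(params)
  if (is.null(params)) return(index_params())
  do.call(index_params, as.list(params))
}
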