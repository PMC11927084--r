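#' Behavioural parameters of the polarized-choice model
#'
#' Bundles the three behavioural constants of the update rule and the
#' homophily level used by the community (stochastic block model) variant.
#'
#' @param alpha In-group love: weight on conforming to same-group
#'   neighbours, in `[0, 1]`.
#' @param beta Out-group hate: weight on opposing other-group neighbours,
#'   in `[0, 1]`.
#' @param delta Inertia: the net social drive must exceed `delta` in
#'   magnitude before a node changes its current choice, in `[0, 1]`.
#' @param rho Homophily level in `(0, 1)`. `rho > 0.5` means individuals
#'   preferentially connect to (or attend to) their own group; `0.5` is
#'   neutral and reduces to the fully mixed case.
#'
#' @return An object of class `model_params`.
#' @examples
#' model_params(alpha = 0.8, beta = 0.4)
#' @export
model_params <- function(alpha, beta, delta = 0, rho = 0.5) {
  for (nm in c("alpha", "beta", "delta", "rho")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm))
  }
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]")
  if (beta < 0 || beta > 1) stop("'beta' must be in [0, 1]")
  if (delta < 0 || delta > 1) stop("'delta' must be in [0, 1]")
  if (rho <= 0 || rho >= 1) stop("'rho' must be in (0, 1)")
  structure(list(alpha = alpha, beta = beta, delta = delta, rho = rho),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "model_params: alpha = %g (in-group love), beta = %g (out-group hate),\n",
    x$alpha, x$beta))
  cat(sprintf("              delta = %g (inertia), rho = %g (homophily)\n",
              x$delta, x$rho))
  invisible(x)
}

as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  stop("expected a 'model_params' object; see ?model_params")
}
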