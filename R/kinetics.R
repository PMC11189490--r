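#' Per-gene transcription/splicing/degradation programme
#'
#' A gene's kinetic parameters for the two-species splicing model
#' du/dt = alpha - beta * u, ds/dt = beta * u - gamma * s, where `u` is
#' unspliced and `s` spliced abundance.  The transcription rate `alpha`
#' switches at lineage-segment boundaries (one value per segment), while the
#' splicing rate `beta` and degradation rate `gamma` are constant per gene.
#'
#' @param gene_id Single gene identifier.
#' @param alpha_by_segment Named non-negative numeric vector of transcription
#'   rates (molecules per unit time), one per lineage segment.
#' @param beta Splicing rate (1/unit time), strictly positive.
#' @param gamma Degradation rate (1/unit time), strictly positive and
#'   different from `beta` (the equal-rate case has a different closed form
#'   and is rejected).
#' @return An object of class `kinetic_gene_program`.
#' @seealso [solve_kinetics()]
#' @export
kinetic_gene_program <- function(gene_id, alpha_by_segment, beta = 1, gamma) {
  if (!is.character(gene_id) || length(gene_id) != 1L)
    stop("'gene_id' must be a single identifier")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a single positive rate")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("'gamma' must be a single positive rate")
  if (abs(gamma - beta) < 1e-12)
    stop("degenerate kinetics: gamma == beta is not supported by the closed-form solution")
  if (!is.numeric(alpha_by_segment) || length(alpha_by_segment) < 1L ||
      any(!is.finite(alpha_by_segment)) || any(alpha_by_segment < 0))
    stop("'alpha_by_segment' must be finite and non-negative")
  structure(
    list(gene_id = gene_id,
         alpha_by_segment = alpha_by_segment,
         beta = beta, gamma = gamma),
    class = "kinetic_gene_program"
  )
}

#' @export
print.kinetic_gene_program <- function(x, ...) {
  cat(sprintf("<kinetic_gene_program> %s: beta=%.3g gamma=%.3g, %d segment alphas\n",
              x$gene_id, x$beta, x$gamma, length(x$alpha_by_segment)))
  invisible(x)
}

#' Closed-form solution of the splicing-kinetics ODE
#'
#' Evaluates the analytic solution of du/dt = alpha - beta*u,
#' ds/dt = beta*u - gamma*s at elapsed time `tau`, starting from (`u0`,
#' `s0`) under a constant transcription rate `alpha`:
#' \deqn{u(\tau) = \alpha/\beta + (u_0 - \alpha/\beta) e^{-\beta\tau}}
#' \deqn{s(\tau) = s_0 e^{-\gamma\tau} + \frac{\alpha}{\gamma}(1 - e^{-\gamma\tau})
#'   + \frac{\alpha - \beta u_0}{\gamma - \beta}(e^{-\gamma\tau} - e^{-\beta\tau})}
#' Results are clipped at zero against floating-point underflow.
#'
#' @param program Optional [kinetic_gene_program()] supplying `beta`/`gamma`.
#' @param u0,s0 Non-negative initial unspliced/spliced abundances.
#' @param alpha Constant transcription rate over the interval.
#' @param tau Non-negative elapsed time(s); vectorised.
#' @param beta,gamma Rates, used when `program` is `NULL`.
#' @return A list with numeric components `u` and `s`, each the length of
#'   `tau` (after recycling of `u0`, `s0`, `alpha`).
#' @examples
#' p <- kinetic_gene_program("g1", c(root = 2), beta = 1, gamma = 0.5)
#' solve_kinetics(p, u0 = 0, s0 = 0, alpha = 2, tau = 1)
#' @export
solve_kinetics <- function(program = NULL, u0, s0, alpha, tau,
                           beta = NULL, gamma = NULL) {
  if (!is.null(program)) {
    stopifnot(inherits(program, "kinetic_gene_program"))
    beta <- program$beta
    gamma <- program$gamma
  }
  if (is.null(beta) || is.null(gamma))
    stop("supply either 'program' or both 'beta' and 'gamma'")
  if (beta <= 0 || gamma <= 0) stop("rates must be positive")
  if (abs(gamma - beta) < 1e-12)
    stop("degenerate kinetics: gamma == beta is not supported by the closed-form solution")
  if (any(tau < 0)) stop("'tau' must be non-negative")
  if (any(u0 < 0) || any(s0 < 0) || any(alpha < 0))
    stop("'u0', 's0' and 'alpha' must be non-negative")

  eb <- exp(-beta * tau)
  eg <- exp(-gamma * tau)
  u <- alpha / beta + (u0 - alpha / beta) * eb
  s <- s0 * eg + (alpha / gamma) * (1 - eg) +
    ((alpha - beta * u0) / (gamma - beta)) * (eg - eb)
  list(u = pmax(u, 0), s = pmax(s, 0))
}
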