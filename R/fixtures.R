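# Programmatic builders for the four worked example models.  These are the
# package's test data; all parameters default to the published values (with
# the documented association-ratio and volume conventions).

#' Build one of the bundled example networks
#'
#' Four multiscale networks are bundled:
#'
#' * `"feedforward"`: a 4-species, 8-reaction nonlinear feedforward cascade.
#'   \eqn{S_1} is produced constitutively; \eqn{S_1}, an \eqn{S_1 S_2}
#'   heterodimer and an \eqn{S_1 S_3} heterodimer catalyze production of
#'   \eqn{S_2}, \eqn{S_3} and \eqn{S_4}; every species degrades.  Synthesis
#'   and degradation of \eqn{S_1} and \eqn{S_3} are fast.  Combined rates:
#'   \eqn{\alpha_1\Omega = \alpha_3/\Omega = 2/\epsilon},
#'   \eqn{\beta_1 = \beta_3 = 1/\epsilon}, \eqn{\alpha_2 = \alpha_4/\Omega =
#'   2}, \eqn{\beta_2 = \beta_4 = 1}.
#' * `"negative_feedback"`: a 9-species, 16-reaction transcriptional
#'   negative feedback loop; the repressor R is produced through a fast
#'   feedforward module (cofactors E and F, intermediate Q, catalyzed by the
#'   protein P), dimerizes slowly and represses the gene.  All fast combined
#'   rates are \eqn{1/\epsilon}, all slow rates 1.
#' * `"oscillator"`: a 5-species, 9-reaction genetic oscillator with a fast
#'   reversible repressor-promoter binding (association ratio
#'   \eqn{K\Omega = 16} molecules\eqn{^{-1}}; promoter total 10;
#'   \eqn{\alpha_M = 10}, all other slow rates 1; binding/unbinding scaled by
#'   \eqn{1/\epsilon}).
#' * `"decoy"`: a transcriptional positive feedback loop where the
#'   transcription factor P binds a promoter site and N = 10 identical decoy
#'   sites (fast competitive reversible bindings; a complex-balanced fast
#'   subnetwork).  Two transcription presets: `preset = "low"`
#'   (\eqn{\alpha_0 = 4, \alpha_A = 10}) and `preset = "high"`
#'   (\eqn{\alpha_0 = 8, \alpha_A = 20}); \eqn{k_{fA}/\Omega = 2000},
#'   \eqn{k_{bA} = 100}, \eqn{k_{fD}/\Omega = 10^4}, \eqn{k_{bD} = 100},
#'   \eqn{\beta_P = 0.8}.
#'
#' Initial conditions: gene/promoter/decoy species start at their conserved
#' totals, \eqn{S_1} starts at its fast stationary mean in the feedforward
#' network, and everything else starts at zero.  The volume enters only
#' through the combined rate constants; `omega` rescales them consistently
#' (zeroth-order rates scale with \eqn{\Omega}, bimolecular with
#' \eqn{1/\Omega}).
#'
#' @param name one of `"feedforward"`, `"negative_feedback"`, `"oscillator"`,
#'   `"decoy"`.
#' @param eps timescale separation \eqn{\epsilon} (fast rates carry
#'   \eqn{1/\epsilon}); defaults: 0.01, 0.01, 0.1, 1.
#' @param omega system volume \eqn{\Omega} (default 1).
#' @param assoc association ratio \eqn{K\Omega} of the oscillator binding
#'   (molecules\eqn{^{-1}}, default 16).
#' @param preset decoy transcription preset, `"low"` or `"high"`.
#' @return a [reaction_network()] with fast/slow tags and an `example`
#'   attribute.
#' @export
build_example <- function(name = c("feedforward", "negative_feedback",
                                   "oscillator", "decoy"),
                          eps = NULL, omega = 1, assoc = 16,
                          preset = c("low", "high")) {
  name <- match.arg(name)
  preset <- match.arg(preset)
  if (is.null(eps)) eps <- switch(name, oscillator = 0.1, decoy = 1, 0.01)
  if (eps <= 0) stop("eps must be positive")
  net <- switch(name,
    feedforward = {
      reaction_network(
        tibble::tibble(name = c("S1", "S2", "S3", "S4"),
                       initial = c(round(2 * omega), 0, 0, 0)),
        list(
          rxn(products = c(S1 = 1), rate = 2 * omega / eps, timescale = "fast"),
          rxn(reactants = c(S1 = 1), rate = 1 / eps, timescale = "fast"),
          rxn(reactants = c(S1 = 1), products = c(S1 = 1, S2 = 1), rate = 2),
          rxn(reactants = c(S2 = 1), rate = 1),
          rxn(reactants = c(S1 = 1, S2 = 1), products = c(S1 = 1, S2 = 1, S3 = 1),
              rate = 2 / (eps * omega), timescale = "fast"),
          rxn(reactants = c(S3 = 1), rate = 1 / eps, timescale = "fast"),
          rxn(reactants = c(S1 = 1, S3 = 1), products = c(S1 = 1, S3 = 1, S4 = 1),
              rate = 2 / omega),
          rxn(reactants = c(S4 = 1), rate = 1)
        ), volume = omega)
    },
    negative_feedback = {
      reaction_network(
        tibble::tibble(name = c("G", "GR", "M", "P", "E", "Q", "F", "R", "RR"),
                       initial = c(1, 0, 0, 0, 0, 0, 0, 0, 0)),
        list(
          rxn(reactants = c(G = 1, RR = 1), products = c(GR = 1), rate = 1 / omega),
          rxn(reactants = c(GR = 1), products = c(G = 1, RR = 1), rate = 1),
          rxn(reactants = c(G = 1), products = c(G = 1, M = 1), rate = 1),
          rxn(reactants = c(M = 1), rate = 1),
          rxn(reactants = c(M = 1), products = c(M = 1, P = 1), rate = 1),
          rxn(reactants = c(P = 1), rate = 1),
          rxn(products = c(E = 1), rate = omega / eps, timescale = "fast"),
          rxn(reactants = c(E = 1), rate = 1 / eps, timescale = "fast"),
          rxn(reactants = c(E = 1, P = 1), products = c(E = 1, P = 1, Q = 1),
              rate = 1 / (eps * omega), timescale = "fast"),
          rxn(reactants = c(Q = 1), rate = 1 / eps, timescale = "fast"),
          rxn(products = c(F = 1), rate = omega / eps, timescale = "fast"),
          rxn(reactants = c(F = 1), rate = 1 / eps, timescale = "fast"),
          rxn(reactants = c(Q = 1, F = 1), products = c(Q = 1, F = 1, R = 1),
              rate = 1 / (eps * omega), timescale = "fast"),
          rxn(reactants = c(R = 1), rate = 1 / eps, timescale = "fast"),
          rxn(reactants = c(R = 2), products = c(RR = 1), rate = 1 / omega),
          rxn(reactants = c(RR = 1), products = c(R = 2), rate = 1)
        ), volume = omega)
    },
    oscillator = {
      reaction_network(
        tibble::tibble(name = c("DA", "DR", "M", "P", "R"),
                       initial = c(10, 0, 0, 0, 0)),
        list(
          rxn(reactants = c(DA = 1), products = c(DA = 1, M = 1), rate = 10),
          rxn(reactants = c(M = 1), rate = 1),
          rxn(reactants = c(M = 1), products = c(M = 1, P = 1), rate = 1),
          rxn(reactants = c(P = 1), rate = 1),
          rxn(reactants = c(P = 1), products = c(P = 1, R = 1), rate = 1),
          rxn(reactants = c(R = 1), rate = 1),
          rxn(reactants = c(DR = 1), products = c(DA = 1), rate = 1),
          rxn(reactants = c(DA = 1, R = 1), products = c(DR = 1),
              rate = assoc / (eps * omega), timescale = "fast"),
          rxn(reactants = c(DR = 1), products = c(DA = 1, R = 1),
              rate = 1 / eps, timescale = "fast")
        ), volume = omega)
    },
    decoy = {
      a0 <- if (preset == "low") 4 else 8
      aA <- if (preset == "low") 10 else 20
      reaction_network(
        tibble::tibble(name = c("P", "G0", "GA", "D", "DP"),
                       initial = c(0, 1, 0, 10, 0)),
        list(
          rxn(reactants = c(G0 = 1), products = c(G0 = 1, P = 1), rate = a0),
          rxn(reactants = c(GA = 1), products = c(GA = 1, P = 1), rate = aA),
          rxn(reactants = c(G0 = 1, P = 1), products = c(GA = 1),
              rate = 2000 / (eps * omega), timescale = "fast"),
          rxn(reactants = c(GA = 1), products = c(G0 = 1, P = 1),
              rate = 100 / eps, timescale = "fast"),
          rxn(reactants = c(D = 1, P = 1), products = c(DP = 1),
              rate = 10000 / (eps * omega), timescale = "fast"),
          rxn(reactants = c(DP = 1), products = c(D = 1, P = 1),
              rate = 100 / eps, timescale = "fast"),
          rxn(reactants = c(P = 1), rate = 0.8),
          rxn(reactants = c(DP = 1), products = c(D = 1), rate = 0.8),
          rxn(reactants = c(GA = 1), products = c(G0 = 1), rate = 0.8)
        ), volume = omega)
    })
  attr(net, "example") <- name
  net
}
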