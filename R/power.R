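# Trial-enrichment power calculations.
#
# A two-arm trial with a binary short-term progression endpoint compares the
# fraction of progressors under treatment vs control. Enriching enrollment
# with predicted progressors raises the control-arm event rate and, for a
# fixed relative risk reduction, widens the absolute arm difference, which
# shrinks the required sample size.

#' Configuration for a two-proportion trial power calculation
#'
#' @param p_control probability of progression in the control arm (the
#'   progressor prevalence of the enrolled population).
#' @param rrr relative risk reduction of the experimental therapeutic; the
#'   treated-arm progression probability is `p_control * (1 - rrr)`.
#' @param alpha two-sided type-I error rate.
#' @param power target power (1 - beta).
#' @return an object of class `power_calc_config`.
#' @examples
#' cfg <- power_calc_config(p_control = 0.5, rrr = 0.10)
#' required_sample_size(cfg)
#' @export
power_calc_config <- function(p_control, rrr, alpha = 0.05, power = 0.80) {
  if (!is.numeric(p_control) || p_control <= 0 || p_control >= 1) {
    config_error("p_control must lie in (0, 1)")
  }
  if (!is.numeric(rrr) || rrr >= 1) config_error("rrr must be < 1")
  if (rrr == 0) config_error("rrr = 0 implies no effect: required n is infinite")
  if (rrr < 0) config_error("rrr must lie in (0, 1)")
  p_treat <- p_control * (1 - rrr)
  if (p_treat <= 0 || p_treat >= 1) config_error("derived p_treat outside (0, 1)")
  if (alpha <= 0 || alpha >= 1) config_error("alpha must lie in (0, 1)")
  if (power <= 0 || power >= 1) config_error("power must lie in (0, 1)")
  structure(
    list(p_control = p_control, rrr = rrr, p_treat = p_treat,
         alpha = alpha, power = power),
    class = "power_calc_config"
  )
}

#' Required sample size for a two-arm trial with a progression endpoint
#'
#' Standard pooled-variance two-proportion z-test formula with 1:1
#' allocation:
#' \deqn{n_{arm} = \frac{\left(z_{1-\alpha/2}\sqrt{2\bar p\bar q} +
#'   z_{1-\beta}\sqrt{p_1 q_1 + p_2 q_2}\right)^2}{(p_1 - p_2)^2}}
#' where \eqn{\bar p} is the pooled proportion. The per-arm size is rounded
#' up before doubling.
#'
#' @param cfg a [power_calc_config()].
#' @return list with `n_per_arm` (ceiling) and `n_total` (both arms).
#' @export
required_sample_size <- function(cfg) {
  stopifnot(inherits(cfg, "power_calc_config"))
  p1 <- cfg$p_control
  p2 <- cfg$p_treat
  pbar <- (p1 + p2) / 2
  z_a <- stats::qnorm(1 - cfg$alpha / 2)
  z_b <- stats::qnorm(cfg$power)
  num <- (z_a * sqrt(2 * pbar * (1 - pbar)) +
            z_b * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2
  n_arm <- num / (p1 - p2)^2
  list(n_per_arm = ceiling(n_arm), n_total = 2 * ceiling(n_arm),
       n_per_arm_exact = n_arm)
}

#' Sample-size gain from enriching a trial with predicted progressors
#'
#' Recomputes the required sample size after raising the control-arm
#' progression probability to the enriched progressor prevalence (the
#' relative risk reduction is held fixed) and reports the ratio of enriched
#' to unenriched total sample size.
#'
#' @param cfg a [power_calc_config()] describing the unenriched trial.
#' @param enriched_p_control control-arm progression probability after
#'   enrichment; must exceed `cfg$p_control`.
#' @return list with `n_unenriched`, `n_enriched` (total sizes) and `ratio`
#'   (= enriched / unenriched).
#' @export
enrichment_gain <- function(cfg, enriched_p_control) {
  stopifnot(inherits(cfg, "power_calc_config"))
  if (!is.numeric(enriched_p_control) ||
      enriched_p_control <= cfg$p_control) {
    config_error("enriched prevalence must exceed the baseline prevalence")
  }
  cfg2 <- power_calc_config(enriched_p_control, cfg$rrr,
                            alpha = cfg$alpha, power = cfg$power)
  n0 <- required_sample_size(cfg)
  n1 <- required_sample_size(cfg2)
  list(n_unenriched = n0$n_total, n_enriched = n1$n_total,
       ratio = n1$n_total / n0$n_total)
}
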