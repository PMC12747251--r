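#' Penetrances under an additive genotype-relative-risk model
#'
#' Given disease prevalence K, risk-allele frequency p and per-allele
#' genotype relative risk r, solves for the penetrance set (f0, f1, f2) =
#' P(disease | 0/1/2 risk alleles) under Hardy-Weinberg genotype weights.
#' Two risk-scale parameterizations are available, matching the two
#' conventions of standard genetic-power calculators:
#' \itemize{
#'   \item \code{additive}: f1 = f0 r, f2 = f0 (2r - 1) (default);
#'   \item \code{multiplicative}: f1 = f0 r, f2 = f0 r^2.
#' }
#' f0 is solved from the prevalence constraint
#' q^2 f0 + 2pq f1 + p^2 f2 = K. Parameter sets driving any penetrance
#' above 1 are rejected with an error naming the offending value.
#'
#' @param K disease prevalence, in (0, 1).
#' @param p risk-allele frequency, in (0, 1).
#' @param grr per-allele genotype relative risk, > 0 (for \code{additive},
#'   >= 0.5 so f2 stays non-negative).
#' @param mode \code{"additive"} or \code{"multiplicative"}.
#' @return A list (class \code{penetrance_set}) with \code{f0}, \code{f1},
#'   \code{f2} and the genotype frequencies \code{g} = (q^2, 2pq, p^2).
#' @export
#' @examples
#' penetrances(0.005, 0.021, 1.32)
penetrances <- function(K, p, grr, mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  stopifnot(K > 0, K < 1, p > 0, p < 1, grr > 0)
  if (mode == "additive" && grr < 0.5)
    stop("additive mode needs grr >= 0.5 (f2 would be negative)")
  q <- 1 - p
  g <- c(q^2, 2 * p * q, p^2)
  mult <- if (mode == "additive") c(1, grr, 2 * grr - 1) else c(1, grr, grr^2)
  f0 <- K / sum(g * mult)
  f <- f0 * mult
  if (any(f > 1))
    stop("infeasible parameters: penetrance f",
         max(which(f > 1)) - 1L, " = ", signif(max(f), 4),
         " exceeds 1 (K = ", K, ", p = ", p, ", grr = ", grr, ")")
  structure(list(f0 = f[1], f1 = f[2], f2 = f[3], g = g, K = K, p = p,
                 grr = grr, mode = mode),
            class = "penetrance_set")
}

# expected genotype frequencies in cases and controls, via Bayes
case_control_geno_freqs <- function(pen) {
  pc <- pen$g * c(pen$f0, pen$f1, pen$f2) / pen$K
  pu <- pen$g * (1 - c(pen$f0, pen$f1, pen$f2)) / (1 - pen$K)
  list(cases = pc, controls = pu)
}

#' Analytic power of the 1-df trend test for a case/control design
#'
#' Computes the power of the Cochran-Armitage trend test (scores 0/1/2,
#' 1 degree of freedom) at significance level alpha: expected genotype
#' frequencies in cases and controls are derived from the penetrance model
#' by Bayes' rule, the induced non-centrality of the chi-square statistic
#' is computed for the design (n_cases, n_controls), and power is the
#' non-central chi-square tail probability beyond the central critical
#' value. This reproduces the genetic-association power calculation used
#' for study planning at a tag SNV.
#'
#' @param K,p,grr,mode as in \code{\link{penetrances}}.
#' @param alpha significance level, in (0, 1).
#' @param n_cases,n_controls numbers of cases and controls.
#' @return The power (scalar in [alpha, 1]).
#' @export
#' @examples
#' power_additive(K = 0.005, p = 0.021, grr = 1.32, alpha = 0.05,
#'                n_cases = 4360, n_controls = 4360)
power_additive <- function(K, p, grr, alpha, n_cases, n_controls,
                           mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, n_cases > 0, n_controls > 0)
  pen <- penetrances(K, p, grr, mode)
  fr <- case_control_geno_freqs(pen)
  ncp <- trend_ncp(fr$cases, fr$controls, n_cases, n_controls)
  crit <- stats::qchisq(1 - alpha, df = 1)
  1 - stats::pchisq(crit, df = 1, ncp = ncp)
}

# non-centrality of the 1-df trend chi-square for genotype frequency
# vectors (length 3, scores 0/1/2) in cases and controls
trend_ncp <- function(p_case, p_ctrl, n_cases, n_controls) {
  N <- n_cases + n_controls
  phi <- n_cases / N
  x <- 0:2
  m <- phi * p_case + (1 - phi) * p_ctrl
  num <- sum(x * (p_case - p_ctrl))^2
  den <- sum(x^2 * m) - sum(x * m)^2
  N * phi * (1 - phi) * num / den
}

#' Minimal case count reaching a target power
#'
#' Inverts \code{\link{power_additive}} by bracketed bisection: the
#' smallest integer number of cases (with controls = ratio x cases)
#' whose power reaches the target.
#'
#' @param K,p,grr,alpha,mode as in \code{\link{power_additive}}.
#' @param target_power in (alpha, 1).
#' @param ratio controls per case (default 1).
#' @return Minimal integer \code{n_cases} with
#'   \code{power_additive(...) >= target_power}.
#' @export
#' @examples
#' required_n(K = 0.005, p = 0.021, grr = 1.32, alpha = 0.05,
#'            target_power = 0.8)
required_n <- function(K, p, grr, alpha, target_power, ratio = 1,
                       mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  stopifnot(target_power > alpha, target_power < 1, ratio > 0)
  f <- function(n) power_additive(K, p, grr, alpha, n,
                                  max(1, round(ratio * n)), mode)
  lo <- 1L
  if (f(lo) >= target_power) return(lo)
  hi <- 2L
  while (f(hi) < target_power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > 1e9) stop("required sample size exceeds 1e9; check parameters")
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (f(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

#' Risk-allele vs protective-allele symmetry gap
#'
#' The same locus can be parameterized by the risk allele (frequency p,
#' GRR r) or by the complementary protective allele (frequency 1 - p,
#' GRR 1/r). Under the multiplicative parameterization the two give nearly
#' identical power; under the additive parameterization they can diverge,
#' especially at extreme allele frequencies. This helper computes both
#' powers and their gap, and warns when the gap exceeds one percentage
#' point, so the discrepancy is surfaced rather than hidden.
#'
#' @inheritParams power_additive
#' @return A list: \code{power_risk}, \code{power_protective},
#'   \code{gap_pp} (absolute gap in percentage points).
#' @export
power_symmetry_check <- function(K, p, grr, alpha, n_cases, n_controls,
                                 mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  pr <- power_additive(K, p, grr, alpha, n_cases, n_controls, mode)
  pp <- power_additive(K, 1 - p, 1 / grr, alpha, n_cases, n_controls, mode)
  gap <- abs(pr - pp) * 100
  if (gap > 1)
    warning(sprintf(paste0("risk/protective parameterizations disagree by ",
                           "%.1f percentage points under the %s model"),
                    gap, mode), call. = FALSE)
  list(power_risk = pr, power_protective = pp, gap_pp = gap)
}
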