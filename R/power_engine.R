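#' Multiplicative disease risk model
#'
#' Encodes the per-allele genotype relative risk (GRR) of a multiplicative
#' (log-additive) disease model: carrying g copies of the risk allele
#' multiplies disease risk by GRR^g. By default the rare-disease
#' approximation is used, so control allele frequencies equal population
#' frequencies; supplying a prevalence switches to the exact case/control
#' mixture at that prevalence.
#'
#' @param grr genotype relative risk per risk-allele copy; any positive
#'   value is accepted (GRR < 1 is equivalent to re-orienting the risk
#'   allele)
#' @param prevalence optional disease prevalence in (0, 1)
#' @return object of class `effect_model`
#' @export
effect_model <- function(grr, prevalence = NULL) {
  if (!is.numeric(grr) || length(grr) != 1 || !is.finite(grr) || grr <= 0) {
    stop("grr must be a single positive number")
  }
  if (!is.null(prevalence) &&
      (length(prevalence) != 1 || prevalence <= 0 || prevalence >= 1)) {
    stop("prevalence must lie in (0, 1)")
  }
  structure(list(grr = grr, prevalence = prevalence), class = "effect_model")
}

as_effect_model <- function(model) {
  if (inherits(model, "effect_model")) model else effect_model(model)
}

#' Expected case and control allele frequencies
#'
#' Under the rare-disease default, Bayes' rule on the multiplicative model
#' gives `p_case = p * GRR / (p * GRR + 1 - p)` and `p_control = p`. With a
#' prevalence K, case genotype probabilities are the Hardy-Weinberg
#' probabilities reweighted by GRR^g, and controls are the population minus
#' the cases at prevalence K.
#'
#' @param p risk-allele population frequency, vectorised over SNPs
#' @param model an [effect_model()] (or a bare GRR value)
#' @return list with numeric vectors `p_case` and `p_control`
#' @export
case_control_freqs <- function(p, model) {
  model <- as_effect_model(model)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  g <- model$grr
  if (is.null(model$prevalence)) {
    list(p_case = p * g / (p * g + 1 - p), p_control = p)
  } else {
    K <- model$prevalence
    hw0 <- (1 - p)^2; hw1 <- 2 * p * (1 - p); hw2 <- p^2
    eg <- hw0 + hw1 * g + hw2 * g^2     # E[GRR^g]
    f0 <- K / eg                        # baseline penetrance
    if (any(f0 * g^2 > 1 + 1e-12, na.rm = TRUE)) {
      stop("prevalence and grr imply a homozygote penetrance above 1")
    }
    p_case <- (hw1 * g + 2 * hw2 * g^2) / (2 * eg)
    p_control <- (hw1 * (1 - f0 * g) + 2 * hw2 * (1 - f0 * g^2)) /
      (2 * (1 - K))
    list(p_case = p_case, p_control = p_control)
  }
}

#' Non-centrality parameter of the 1-df allelic chi-square test
#'
#' NCP of the allele-count chi-square comparing case and control risk-allele
#' frequencies in a single case-control arm:
#' `ncp = (p_case - p_control)^2 / (pbar (1 - pbar) (1/(2 n_cases) + 1/(2 n_controls)))`
#' with `pbar` the sample-size-weighted pooled frequency under the
#' alternative. Returns 0 for monomorphic SNPs (p of 0 or 1), at GRR = 1,
#' and when either arm is empty. The NCP is exactly linear in sample size at
#' fixed frequencies, so per-arm NCPs can be summed across phases and
#' panels.
#'
#' @param p risk-allele frequency in the arm's source population
#'   (vectorised)
#' @param n_cases,n_controls case and control counts (individuals)
#' @param model an [effect_model()] (or bare GRR)
#' @return non-negative numeric vector of NCPs
#' @export
ncp_single <- function(p, n_cases, n_controls, model) {
  model <- as_effect_model(model)
  if (n_cases < 0 || n_controls < 0) stop("sample sizes must be non-negative")
  if (n_cases == 0 || n_controls == 0) return(rep(0, length(p)))
  cc <- case_control_freqs(p, model)
  pbar <- (n_cases * cc$p_case + n_controls * cc$p_control) /
    (n_cases + n_controls)
  v <- pbar * (1 - pbar) * (1 / (2 * n_cases) + 1 / (2 * n_controls))
  ncp <- ifelse(v > 0, (cc$p_case - cc$p_control)^2 / v, 0)
  ncp[p == 0 | p == 1] <- 0
  ncp
}

#' Asymptotic power from a chi-square non-centrality parameter
#'
#' `P[chisq(df, ncp) > q]` where `q` is the upper-alpha quantile of the
#' central chi-square. Both tail probabilities are evaluated on the upper
#' tail (survival function) so that power remains accurate at genome-wide
#' significance levels; at `ncp = 0` the size `alpha` is returned exactly.
#'
#' @param ncp non-negative non-centrality parameter (vectorised)
#' @param alpha two-sided significance threshold in (0, 1); default the
#'   genome-wide 5e-8
#' @param df degrees of freedom (default 1, the allelic test)
#' @return power in `[alpha, 1]`
#' @export
power_from_ncp <- function(ncp, alpha = 5e-8, df = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (any(ncp < 0, na.rm = TRUE)) stop("ncp must be non-negative")
  q <- stats::qchisq(alpha, df = df, lower.tail = FALSE)
  out <- stats::pchisq(q, df = df, ncp = ncp, lower.tail = FALSE)
  out[ncp == 0] <- alpha
  out
}

scenario_arms <- function(scenario) {
  rbind(scenario$phase1, scenario$phase2)
}

#' Power of a two-phase multi-panel study for one SNP
#'
#' Sums the per-arm NCPs over every (phase, panel) arm of the scenario and
#' converts the total to asymptotic power. With `risk_allele = "average"`
#' the powers obtained by treating each of the two alleles in turn as
#' risk-increasing are averaged, which makes the result orientation-free.
#'
#' @param freqs named numeric vector: frequency of `allele_a` per panel
#' @param scenario a [scenario()]
#' @param model an [effect_model()] (or bare GRR)
#' @param alpha,df significance threshold and test degrees of freedom
#' @param risk_allele `"average"`, `"a"` or `"b"`
#' @return power (scalar)
#' @export
snp_power <- function(freqs, scenario, model, alpha = 5e-8, df = 1,
                      risk_allele = c("average", "a", "b")) {
  risk_allele <- match.arg(risk_allele)
  model <- as_effect_model(model)
  arms <- scenario_arms(scenario)
  missing_panels <- setdiff(arms$panel, names(freqs))
  if (length(missing_panels)) {
    stop("scenario references panels absent from the SNP record: ",
         paste(unique(missing_panels), collapse = ", "))
  }
  total <- function(p_by_panel) {
    sum(vapply(seq_len(nrow(arms)), function(i) {
      ncp_single(p_by_panel[arms$panel[i]], arms$n_cases[i],
                 arms$n_controls[i], model)
    }, 0))
  }
  if (risk_allele == "a") {
    power_from_ncp(total(freqs), alpha, df)
  } else if (risk_allele == "b") {
    power_from_ncp(total(1 - freqs), alpha, df)
  } else {
    mean(c(power_from_ncp(total(freqs), alpha, df),
           power_from_ncp(total(1 - freqs), alpha, df)))
  }
}

#' Empirical power by genotype-level simulation
#'
#' Monte-Carlo oracle for the analytic NCP formulas. Case genotypes are
#' drawn from Hardy-Weinberg proportions reweighted by GRR^g (or from the
#' exact case mixture when the model carries a prevalence); control
#' genotypes from the corresponding control distribution. Each replicate's
#' 1-df allelic (allele-count) chi-square is compared against the central
#' upper-alpha quantile.
#'
#' @param p risk-allele population frequency (scalar)
#' @param n_cases,n_controls arm sizes (individuals)
#' @param model an [effect_model()] (or bare GRR)
#' @param alpha significance threshold
#' @param reps number of simulated studies
#' @param seed integer seed; identical seeds give identical estimates
#' @return list with `power`, its binomial `se`, `mean_stat` (the average
#'   chi-square across replicates, expected `df + ncp`) and `reps`
#' @export
monte_carlo_power <- function(p, n_cases, n_controls, model, alpha = 0.05,
                              reps = 50000, seed = 1) {
  model <- as_effect_model(model)
  if (reps < 1) stop("reps must be at least 1")
  g <- model$grr
  hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  if (is.null(model$prevalence)) {
    case_pr <- hw * g^(0:2)
    case_pr <- case_pr / sum(case_pr)
    ctrl_pr <- hw
  } else {
    K <- model$prevalence
    eg <- sum(hw * g^(0:2))
    f0 <- K / eg
    case_pr <- hw * g^(0:2) / eg
    ctrl_pr <- hw * (1 - f0 * g^(0:2)) / (1 - K)
  }
  set.seed(seed)
  gc <- stats::rmultinom(reps, n_cases, case_pr)
  gk <- stats::rmultinom(reps, n_controls, ctrl_pr)
  a1 <- as.numeric(gc[2, ] + 2 * gc[3, ])   # risk alleles in cases
  b1 <- as.numeric(gk[2, ] + 2 * gk[3, ])
  a0 <- 2 * n_cases - a1
  b0 <- 2 * n_controls - b1
  n <- 2 * (n_cases + n_controls)
  denom <- (a1 + b1) * (a0 + b0) * (a1 + a0) * (b1 + b0)
  stat <- ifelse(denom > 0, n * (a1 * b0 - a0 * b1)^2 / denom, 0)
  q <- stats::qchisq(alpha, df = 1, lower.tail = FALSE)
  pw <- mean(stat > q)
  list(power = pw, se = sqrt(pw * (1 - pw) / reps),
       mean_stat = mean(stat), reps = reps)
}
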