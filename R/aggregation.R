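#' Genome-wide per-SNP power under a two-phase scenario
#'
#' Computes, for every SNP in the table, the total NCP summed over all
#' (phase, panel) arms and the resulting asymptotic power, averaged over
#' both risk-allele orientations. SNPs are stratified by the minor allele
#' frequency in the reference panel and summarised as unweighted means
#' within each stratum and genome-wide.
#'
#' @param table a [freq_table()]
#' @param scen a [scenario()]
#' @param model an [effect_model()] (or bare GRR)
#' @param alpha,df significance threshold and chi-square degrees of freedom
#' @param strata a [maf_strata()]; its reference panel must be in the table
#' @return object of class `power_result`: list with `per_snp` (data.frame
#'   `snp_id`, `maf_ref`, `stratum`, `ncp_a`, `ncp_b`, `power`), `strata`
#'   (data.frame `stratum`, `n`, `mean_power`), `genome_mean`, and the
#'   scenario/model descriptors
#' @export
genome_power <- function(table, scen, model, alpha = 5e-8, df = 1,
                         strata = maf_strata()) {
  model <- as_effect_model(model)
  arms <- scenario_arms(scen)
  missing_panels <- setdiff(unique(arms$panel), table$panels)
  if (length(missing_panels)) {
    stop("scenario panels absent from the frequency table: ",
         paste(missing_panels, collapse = ", "))
  }
  if (!strata$reference_panel %in% table$panels) {
    stop("stratum reference panel absent from the frequency table: ",
         strata$reference_panel)
  }
  used <- unique(arms$panel)
  if (anyNA(table$freq[, used])) {
    stop("missing frequencies in scenario panels; drop or impute them first")
  }
  ncp_a <- numeric(n_snps(table))
  ncp_b <- numeric(n_snps(table))
  for (i in seq_len(nrow(arms))) {
    p <- table$freq[, arms$panel[i]]
    ncp_a <- ncp_a + ncp_single(p, arms$n_cases[i], arms$n_controls[i], model)
    ncp_b <- ncp_b + ncp_single(1 - p, arms$n_cases[i], arms$n_controls[i],
                                model)
  }
  power <- (power_from_ncp(ncp_a, alpha, df) +
              power_from_ncp(ncp_b, alpha, df)) / 2
  maf_ref <- minor_freq(table$freq[, strata$reference_panel])
  bins <- assign_strata(maf_ref, strata)
  per_snp <- data.frame(
    snp_id = table$snps$snp_id, maf_ref = maf_ref, stratum = bins,
    ncp_a = ncp_a, ncp_b = ncp_b, power = power,
    stringsAsFactors = FALSE)
  n_by <- tapply(power, bins, length)
  mean_by <- tapply(power, bins, mean)
  strata_df <- data.frame(
    stratum = strata$labels,
    n = ifelse(is.na(n_by[strata$labels]), 0L,
               as.integer(n_by[strata$labels])),
    mean_power = as.numeric(mean_by[strata$labels]),
    stringsAsFactors = FALSE)
  structure(list(per_snp = per_snp, strata = strata_df,
                 genome_mean = mean(power),
                 scenario = scen$name, grr = model$grr, alpha = alpha),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("power_result: scenario '%s', GRR = %g, alpha = %g\n",
              x$scenario, x$grr, x$alpha))
  cat(sprintf("genome-wide mean power over %d SNPs: %.4f\n",
              nrow(x$per_snp), x$genome_mean))
  print(x$strata, row.names = FALSE)
  invisible(x)
}

align_powers <- function(power_a, power_b) {
  if (length(power_a) != length(power_b)) {
    stop("power vectors have different lengths")
  }
  if (!is.null(names(power_a)) && !is.null(names(power_b))) {
    if (!setequal(names(power_a), names(power_b))) {
      stop("power vectors cover different SNP sets")
    }
    power_b <- power_b[names(power_a)]
  }
  list(a = unname(power_a), b = unname(power_b))
}

per_snp_power <- function(x) {
  if (inherits(x, "power_result")) {
    stats::setNames(x$per_snp$power, x$per_snp$snp_id)
  } else {
    x
  }
}

#' Classify SNPs by reaching a power threshold under two scenarios
#'
#' Splits the SNP set into four categories: at least the threshold power in
#' both scenarios, in scenario A only, in scenario B only, or in neither.
#'
#' @param power_a,power_b per-SNP power vectors (optionally named by
#'   `snp_id`, in which case the sets are aligned) or [genome_power()]
#'   results
#' @param threshold power threshold (default 0.80)
#' @return data.frame with `category`, `n`, `fraction`; fractions sum to 1
#' @export
gain_categories <- function(power_a, power_b, threshold = 0.80) {
  al <- align_powers(per_snp_power(power_a), per_snp_power(power_b))
  hit_a <- al$a >= threshold
  hit_b <- al$b >= threshold
  n <- c(both = sum(hit_a & hit_b),
         a_only = sum(hit_a & !hit_b),
         b_only = sum(!hit_a & hit_b),
         neither = sum(!hit_a & !hit_b))
  data.frame(category = names(n), n = as.integer(n),
             fraction = as.numeric(n) / length(al$a),
             stringsAsFactors = FALSE)
}

# frequency, in both panels, of the allele that is minor in the reference
# panel (ties at exactly 0.5 broken toward allele_a); NULL rows excluded
anchored_minor_freqs <- function(table, panel_ref, panel_alt) {
  for (pn in c(panel_ref, panel_alt)) {
    if (!pn %in% table$panels) stop("panel absent from table: ", pn)
  }
  f_ref <- table$freq[, panel_ref]
  f_alt <- table$freq[, panel_alt]
  minor_is_a <- f_ref <= 0.5
  list(ref = ifelse(minor_is_a, f_ref, 1 - f_ref),
       alt = ifelse(minor_is_a, f_alt, 1 - f_alt),
       mono_both = (f_ref == 0 | f_ref == 1) & (f_alt == 0 | f_alt == 1))
}

#' Compare the reference-panel minor allele's frequency across two panels
#'
#' For each SNP the minor allele is fixed in the reference panel and its
#' frequency compared with the frequency of that same allele in the other
#' panel; anchoring to one allele deliberately ignores allele flips (where
#' the reference minor allele is the major allele elsewhere). SNPs
#' monomorphic in both panels are excluded.
#'
#' @param table a [freq_table()]
#' @param panel_ref,panel_alt panel names
#' @param tol frequencies within `tol` of each other count as equal
#'   (default 0: exact ties, which are common for finite-chromosome
#'   estimates)
#' @return data.frame with classes `less_common_in_ref`, `equal`,
#'   `more_common_in_ref`, `excluded` and their counts and fractions of the
#'   included SNPs
#' @export
freq_difference_classes <- function(table, panel_ref, panel_alt, tol = 0) {
  an <- anchored_minor_freqs(table, panel_ref, panel_alt)
  keep <- !an$mono_both & !is.na(an$ref) & !is.na(an$alt)
  d <- an$alt[keep] - an$ref[keep]
  n <- c(less_common_in_ref = sum(d > tol),
         equal = sum(abs(d) <= tol),
         more_common_in_ref = sum(d < -tol))
  data.frame(
    class = c(names(n), "excluded"),
    n = as.integer(c(n, sum(!keep))),
    fraction = c(as.numeric(n) / max(sum(keep), 1), NA),
    stringsAsFactors = FALSE)
}

#' Power change as a function of cross-panel allele-frequency difference
#'
#' Bins SNPs by the frequency difference of the reference-panel minor
#' allele (`f_alt - f_ref`, in half-open bins `[lo, hi)`) and reports, per
#' bin, the SNP count, the mean power change from scenario A to scenario B,
#' and the bin's contribution to the aggregate power change (sum of the
#' per-SNP change divided by the number of included SNPs).
#'
#' @param table a [freq_table()]
#' @param power_a,power_b per-SNP power vectors aligned with the table
#'   (or [genome_power()] results)
#' @param panel_ref,panel_alt panels defining the frequency difference
#' @param bin_width bin width on the difference axis (default 0.05)
#' @return list with `bins` (data.frame `lo`, `hi`, `n`, `mean_dpower`,
#'   `contribution`), `net_gain` (mean power change over included SNPs) and
#'   `n_included`
#' @export
gain_by_difference <- function(table, power_a, power_b, panel_ref,
                               panel_alt, bin_width = 0.05) {
  al <- align_powers(per_snp_power(power_a), per_snp_power(power_b))
  if (length(al$a) != n_snps(table)) {
    stop("power vectors and frequency table cover different SNP sets")
  }
  an <- anchored_minor_freqs(table, panel_ref, panel_alt)
  keep <- !an$mono_both & !is.na(an$ref) & !is.na(an$alt)
  d <- an$alt[keep] - an$ref[keep]
  dp <- (al$b - al$a)[keep]
  lo_edge <- floor(min(d) / bin_width) * bin_width
  hi_edge <- floor(max(d) / bin_width) * bin_width + bin_width
  edges <- seq(lo_edge, hi_edge, by = bin_width)
  idx <- findInterval(d, edges, rightmost.closed = FALSE)
  nb <- length(edges) - 1
  n_in <- tabulate(idx, nbins = nb)
  sum_dp <- vapply(seq_len(nb), function(j) sum(dp[idx == j]), 0)
  bins <- data.frame(
    lo = edges[-length(edges)], hi = edges[-1], n = n_in,
    mean_dpower = ifelse(n_in > 0, sum_dp / n_in, NA_real_),
    contribution = sum_dp / length(d))
  list(bins = bins, net_gain = mean(dp), n_included = length(d))
}

#' Write per-SNP power results as TSV
#' @param result a [genome_power()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_power_result <- function(result, path) {
  per <- result$per_snp
  out <- data.frame(
    snp_id = per$snp_id,
    maf_ref = sprintf("%.6f", per$maf_ref),
    stratum = as.character(per$stratum),
    ncp = sprintf("%.6g", (per$ncp_a + per$ncp_b) / 2),
    power = sprintf("%.6g", per$power),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
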