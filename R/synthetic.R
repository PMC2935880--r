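#' Synthetic population panel model
#'
#' Parameters of one simulated population: its divergence F from the shared
#' ancestral pool under the Balding-Nichols model (an F_ST analogue), and
#' the number of chromosomes used to estimate its allele frequencies
#' (0 means the exact, infinite-sample frequency is kept).
#'
#' @param name panel name
#' @param divergence drift parameter F in `[0, 1)`
#' @param chromosomes non-negative integer; 0 keeps exact frequencies
#' @return object of class `panel_model`
#' @export
panel_model <- function(name, divergence = 0, chromosomes = 0) {
  if (divergence < 0 || divergence >= 1) {
    stop("divergence F must lie in [0, 1)")
  }
  if (chromosomes < 0) stop("chromosomes must be non-negative")
  structure(list(name = name, divergence = divergence,
                 chromosomes = as.integer(chromosomes)),
            class = "panel_model")
}

#' Ancestral allele-frequency spectrum
#'
#' Distribution the ancestral frequency of each simulated SNP is drawn
#' from. The neutral-like default has density proportional to 1/x on a
#' bounded support, mimicking the excess of rare alleles under neutrality;
#' `beta` and `uniform` alternatives are available (the beta is truncated
#' to the support).
#'
#' @param kind `"neutral_1_over_x"`, `"beta"` or `"uniform"`
#' @param shape1,shape2 beta parameters (used for `kind = "beta"`)
#' @param fmin,fmax support bounds, `0 < fmin <= fmax < 1` (equal bounds
#'   give a point mass, handy for conditioning on a fixed ancestral
#'   frequency)
#' @return object of class `ancestral_spectrum`
#' @export
ancestral_spectrum <- function(kind = c("neutral_1_over_x", "beta",
                                        "uniform"),
                               shape1 = 0.5, shape2 = 0.5,
                               fmin = 0.001, fmax = 0.999) {
  kind <- match.arg(kind)
  if (fmin <= 0 || fmax >= 1 || fmin > fmax) {
    stop("need 0 < fmin <= fmax < 1")
  }
  structure(list(kind = kind, shape1 = shape1, shape2 = shape2,
                 fmin = fmin, fmax = fmax),
            class = "ancestral_spectrum")
}

#' Draw ancestral frequencies from a spectrum
#' @param n number of draws
#' @param spectrum an [ancestral_spectrum()]
#' @return numeric vector in `[fmin, fmax]`
#' @export
sample_spectrum <- function(n, spectrum = ancestral_spectrum()) {
  u <- stats::runif(n)
  with(spectrum, switch(
    kind,
    # inverse CDF of the 1/x density on [fmin, fmax]
    neutral_1_over_x = fmin * (fmax / fmin)^u,
    uniform = fmin + u * (fmax - fmin),
    beta = {
      plo <- stats::pbeta(fmin, shape1, shape2)
      phi <- stats::pbeta(fmax, shape1, shape2)
      stats::qbeta(plo + u * (phi - plo), shape1, shape2)
    }))
}

#' Simulate drifted multi-population allele frequencies
#'
#' For each SNP an ancestral frequency q is drawn from the spectrum; each
#' panel's frequency is then drawn independently (star topology) from the
#' Balding-Nichols distribution
#' `Beta(q (1 - F) / F, (1 - q)(1 - F) / F)`, whose mean is q and whose
#' spread grows with the panel's divergence F (F = 0 keeps exactly q). If a
#' panel declares a finite chromosome count, its true frequency is replaced
#' by a binomial finite-sample estimate on that many chromosomes.
#'
#' @param n_snps number of SNPs to simulate
#' @param panels list of [panel_model()]s
#' @param spectrum an [ancestral_spectrum()]
#' @param seed integer seed; identical seeds give identical tables
#' @return a [freq_table()] tagged `"synthetic"`, with an extra column
#'   `ancestral` in `$snps` holding the ancestral draw
#' @export
simulate_panels <- function(n_snps, panels, spectrum = ancestral_spectrum(),
                            seed = NULL) {
  if (n_snps < 1) stop("n_snps must be at least 1")
  if (inherits(panels, "panel_model")) panels <- list(panels)
  if (!is.null(seed)) set.seed(seed)
  q <- sample_spectrum(n_snps, spectrum)
  fr <- matrix(NA_real_, n_snps, length(panels))
  chrom <- integer(length(panels))
  nm <- character(length(panels))
  for (j in seq_along(panels)) {
    pm <- panels[[j]]
    f <- pm$divergence
    fr[, j] <- if (f == 0) q else {
      stats::rbeta(n_snps, q * (1 - f) / f, (1 - q) * (1 - f) / f)
    }
    if (pm$chromosomes > 0) {
      fr[, j] <- stats::rbinom(n_snps, pm$chromosomes, fr[, j]) /
        pm$chromosomes
    }
    chrom[j] <- pm$chromosomes
    nm[j] <- pm$name
  }
  colnames(fr) <- nm
  snps <- data.frame(
    snp_id = sprintf("snp%07d", seq_len(n_snps)),
    chrom = "1", pos = seq_len(n_snps),
    allele_a = "A", allele_b = "B",
    ancestral = q, stringsAsFactors = FALSE)
  freq_table(snps, fr,
             chromosomes = stats::setNames(
               ifelse(chrom > 0, chrom, NA_integer_), nm),
             source = "synthetic")
}

#' Apply SNP-array-like ascertainment toward a reference panel
#'
#' Retains SNPs whose minor allele frequency in the reference panel is at
#' least `min_maf`, emulating genotyping arrays' bias toward variants
#' common in the (European) discovery panel. `min_maf = 0` is the identity
#' (sequencing-like, ascertainment-free input).
#'
#' @param table a [freq_table()]
#' @param reference_panel panel the array was designed against
#' @param min_maf minimum reference-panel MAF retained
#' @return filtered `freq_table`
#' @export
apply_ascertainment <- function(table, reference_panel, min_maf) {
  if (!reference_panel %in% table$panels) {
    stop("panel absent from table: ", reference_panel)
  }
  maf <- minor_freq(table$freq[, reference_panel])
  subset_snps(table, !is.na(maf) & maf >= min_maf)
}

#' Replace true frequencies by finite-founder binomial estimates
#'
#' Each frequency p becomes X / chromosomes with X ~ Binomial(chromosomes,
#' p), emulating estimation from a fixed number of founder chromosomes per
#' panel (e.g. 100, i.e. 50 founders). Estimates are unbiased; low-frequency
#' alleles are lost (estimated monomorphic) with probability
#' `(1 - p)^chromosomes`.
#'
#' @param table a [freq_table()]
#' @param chromosomes chromosomes per panel (>= 2)
#' @param seed integer seed
#' @return a `freq_table` tagged `"estimated"` with the chromosome count in
#'   its metadata
#' @export
estimate_from_founders <- function(table, chromosomes, seed = NULL) {
  if (chromosomes < 2) stop("chromosomes must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  fr <- table$freq
  ok <- !is.na(fr)
  fr[ok] <- stats::rbinom(sum(ok), chromosomes, fr[ok]) / chromosomes
  out <- freq_table(table$snps, fr,
                    chromosomes = stats::setNames(
                      rep(as.integer(chromosomes), length(table$panels)),
                      table$panels),
                    source = "estimated")
  out
}

#' Fabricate a reported-association catalog with matching frequencies
#'
#' Generates n association records (risk allele, odds ratio, trait) whose
#' odds ratios and reference risk-allele frequencies are drawn uniformly
#' from the stated ranges, together with a frequency table for the
#' underlying unique SNPs across the given panels (drifted from the drawn
#' frequency by each panel's divergence). `n_duplicated` SNPs are reported
#' twice under different traits, mirroring catalogs where some loci are
#' associated with several diseases.
#'
#' @param n number of association records
#' @param panels list of [panel_model()]s
#' @param or_range odds-ratio range (uniform draw)
#' @param maf_range risk-allele frequency range (uniform draw)
#' @param n_duplicated how many SNPs appear twice across traits
#' @param seed integer seed
#' @return list with `associations` (data.frame of n records) and `table`
#'   (a [freq_table()] of the `n - n_duplicated` unique SNPs)
#' @export
simulate_associations <- function(n, panels, or_range = c(1.1, 1.3),
                                  maf_range = c(0.05, 0.5),
                                  n_duplicated = 0, seed = NULL) {
  if (n < 0 || n_duplicated < 0 || n_duplicated > n %/% 2) {
    stop("need 0 <= n_duplicated <= n/2")
  }
  if (inherits(panels, "panel_model")) panels <- list(panels)
  if (!is.null(seed)) set.seed(seed)
  n_unique <- n - n_duplicated
  if (n == 0) {
    return(list(associations = data.frame(
      snp_id = character(), risk_allele = character(),
      odds_ratio = numeric(), trait = character(),
      stringsAsFactors = FALSE), table = NULL))
  }
  p0 <- stats::runif(n_unique, maf_range[1], maf_range[2])
  risk_is_a <- sample(c(TRUE, FALSE), n_unique, replace = TRUE)
  snp_id <- sprintf("assoc%05d", seq_len(n_unique))
  fr <- matrix(NA_real_, n_unique, length(panels))
  nm <- vapply(panels, `[[`, "", "name")
  for (j in seq_along(panels)) {
    f <- panels[[j]]$divergence
    pj <- if (f == 0) p0 else {
      stats::rbeta(n_unique, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
    }
    if (panels[[j]]$chromosomes > 0) {
      pj <- stats::rbinom(n_unique, panels[[j]]$chromosomes, pj) /
        panels[[j]]$chromosomes
    }
    # table stores the frequency of allele_a
    fr[, j] <- ifelse(risk_is_a, pj, 1 - pj)
  }
  colnames(fr) <- nm
  snps <- data.frame(snp_id = snp_id, chrom = "1",
                     pos = seq_len(n_unique),
                     allele_a = "A", allele_b = "B",
                     stringsAsFactors = FALSE)
  tab <- freq_table(snps, fr, source = "synthetic")
  rec_idx <- c(seq_len(n_unique),
               if (n_duplicated > 0) seq_len(n_duplicated))
  associations <- data.frame(
    snp_id = snp_id[rec_idx],
    risk_allele = ifelse(risk_is_a[rec_idx], "A", "B"),
    odds_ratio = stats::runif(n, or_range[1], or_range[2]),
    trait = sprintf("trait_%03d", seq_len(n)),
    stringsAsFactors = FALSE)
  list(associations = associations, table = tab)
}
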