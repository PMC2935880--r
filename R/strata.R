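#' Minor-allele-frequency strata anchored to a reference panel
#'
#' Defines the bins used to stratify genome-wide power summaries by the
#' minor allele frequency (MAF) observed in a reference panel. The default
#' layout separates monomorphic sites (MAF exactly 0), rare sites below 1%,
#' the low-frequency band 1-5% (closed on both ends), 5-10% and common sites
#' above 10%.
#'
#' @param reference_panel panel whose MAF defines the stratum (default CEU)
#' @param breaks increasing interior breakpoints in (0, 0.5]
#' @return object of class `maf_strata` with the bin labels in order
#' @export
maf_strata <- function(reference_panel = "CEU",
                       breaks = c(0.01, 0.05, 0.10)) {
  if (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0 | breaks > 0.5)) {
    stop("breaks must be strictly increasing within (0, 0.5]")
  }
  k <- length(breaks)
  labels <- c(
    "monomorphic",
    sprintf("(0,%g)", breaks[1]),
    sprintf("[%g,%g]", breaks[1], breaks[2]))
  if (k > 2) {
    labels <- c(labels, sprintf("(%g,%g]", breaks[-c(1, k)], breaks[-(1:2)]))
  }
  labels <- c(labels, sprintf("(%g,0.5]", breaks[k]))
  structure(list(reference_panel = reference_panel, breaks = breaks,
                 labels = labels),
            class = "maf_strata")
}

#' Assign minor allele frequencies to strata
#'
#' Bin conventions: `maf == 0` is monomorphic; `(0, b1)` is open;
#' `[b1, b2]` is closed on both ends; each later bin `(b, b']` is half-open
#' on the left. Together the bins partition `[0, 0.5]`.
#'
#' @param maf numeric vector of minor allele frequencies in `[0, 0.5]`
#' @param strata a [maf_strata()]
#' @return factor with the strata labels as levels
#' @export
assign_strata <- function(maf, strata = maf_strata()) {
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE)) {
    stop("minor allele frequencies must lie in [0, 0.5]")
  }
  br <- strata$breaks
  idx <- rep(NA_integer_, length(maf))
  idx[maf == 0] <- 1L
  idx[maf > 0 & maf < br[1]] <- 2L
  lo <- br[1]
  for (j in seq_along(br)[-1]) {
    idx[maf >= lo & maf <= br[j] & is.na(idx)] <- j + 1L
    lo <- br[j]
  }
  idx[is.na(idx) & maf > br[length(br)]] <- length(br) + 2L
  factor(strata$labels[idx], levels = strata$labels)
}

#' Minor allele frequency of the designated allele
#' @param f frequency of `allele_a`
#' @return `pmin(f, 1 - f)`
#' @export
minor_freq <- function(f) pmin(f, 1 - f)

#' Flag monomorphic SNPs per panel
#'
#' A SNP is monomorphic in a panel when the frequency of `allele_a` is
#' exactly 0 or 1 there. Counts per panel are additionally stratified by the
#' reference-panel MAF bins, summarising how array ascertainment and drift
#' deplete polymorphism outside the reference population.
#'
#' @param table a [freq_table()]
#' @param strata a [maf_strata()]; counts are omitted (`NULL`) when its
#'   reference panel is absent from the table
#' @return list with `flags` (SNP x panel logical matrix, `NA` where the
#'   frequency is missing) and `counts` (panel x stratum integer matrix)
#' @export
annotate_monomorphic <- function(table, strata = maf_strata()) {
  flags <- table$freq == 0 | table$freq == 1
  counts <- NULL
  if (strata$reference_panel %in% table$panels) {
    bins <- assign_strata(minor_freq(table$freq[, strata$reference_panel]),
                          strata)
    counts <- t(sapply(table$panels, function(pn) {
      tab <- table(bins[which(flags[, pn])])
      as.integer(tab[strata$labels])
    }))
    counts[is.na(counts)] <- 0L
    dimnames(counts) <- list(table$panels, strata$labels)
  }
  list(flags = flags, counts = counts)
}

#' Keep SNPs polymorphic in at least one panel
#'
#' Retains exactly the records whose frequency lies strictly inside (0, 1)
#' in at least one panel. Idempotent.
#'
#' @param table a [freq_table()]
#' @return filtered `freq_table`
#' @export
filter_polymorphic_any <- function(table) {
  poly <- table$freq > 0 & table$freq < 1
  keep <- rowSums(poly, na.rm = TRUE) > 0
  subset_snps(table, keep)
}
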