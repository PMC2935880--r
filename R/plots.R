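#' Plot mean power against the reference-panel MAF stratum
#'
#' One line per supplied result (e.g. the same scenario at several effect
#' sizes, or several phase-2 panels at one effect size).
#'
#' @param ... one or more [genome_power()] results
#' @param labels legend labels (defaults to each result's scenario name)
#' @param main plot title
#' @return invisibly, the matrix of stratum means that was drawn
#' @export
plot_power_by_maf <- function(..., labels = NULL, main = "Power by MAF stratum") {
  results <- list(...)
  if (!length(results)) stop("supply at least one power result")
  strata_labels <- results[[1]]$strata$stratum
  m <- sapply(results, function(r) r$strata$mean_power)
  m <- matrix(m, nrow = length(strata_labels))
  labels <- labels %||% vapply(results, function(r)
    sprintf("%s, GRR=%g", r$scenario, r$grr), "")
  graphics::matplot(seq_len(nrow(m)), m, type = "b", pch = 19, lty = 1,
                    xaxt = "n", ylim = c(0, 1), xlab = "MAF stratum",
                    ylab = "mean power", main = main)
  graphics::axis(1, at = seq_len(nrow(m)), labels = strata_labels,
                 cex.axis = 0.8)
  graphics::legend("topleft", legend = labels, col = seq_len(ncol(m)),
                   lty = 1, pch = 19, bty = "n", cex = 0.8)
  invisible(m)
}

#' Histogram of SNP counts by cross-panel frequency difference
#'
#' Bars show the SNP count per frequency-difference bin from
#' [gain_by_difference()], coloured by the sign of the mean power change in
#' the bin (red = power gained by moving phase 2 to the alternative panel,
#' blue = power lost).
#'
#' @param gbd a [gain_by_difference()] result
#' @param main plot title
#' @return `gbd`, invisibly
#' @export
plot_gain_histogram <- function(gbd, main = "Power change by frequency difference") {
  b <- gbd$bins
  col <- ifelse(is.na(b$mean_dpower), "grey",
                ifelse(b$mean_dpower > 0, "firebrick",
                       ifelse(b$mean_dpower < 0, "steelblue", "grey")))
  graphics::barplot(b$n, names.arg = sprintf("%.2f", b$lo), col = col,
                    border = NA, las = 2, cex.names = 0.7,
                    xlab = "frequency difference (alt - ref, anchored minor allele)",
                    ylab = "SNPs", main = main)
  graphics::legend("topright", fill = c("firebrick", "steelblue"),
                   legend = c("mean power gain", "mean power loss"),
                   bty = "n", cex = 0.8)
  invisible(gbd)
}
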