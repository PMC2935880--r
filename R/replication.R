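#' Sample size needed to replicate an association at a target power
#'
#' Finds the smallest even total sample size N (N/2 cases, N/2 controls;
#' the 1:1 ratio is fixed) whose analytic 1-df allelic-test power reaches
#' the target at the given nominal significance level. The power function
#' is monotone in N, so the solution is bracketed by doubling and refined
#' by bisection over even N; the returned N satisfies
#' `power(N) >= target > power(N - 2)`.
#'
#' @param p risk-allele frequency in the target population
#' @param model an [effect_model()] (or bare GRR / reported odds ratio)
#' @param alpha nominal significance threshold (default 0.05, replication
#'   of a pre-specified hypothesis)
#' @param target required power (default 0.80)
#' @param n_cap largest total sample size considered (default 150,000)
#' @return list with `n` (even integer, or `NA`), `power` (at `n`, or at
#'   the cap when capped) and `status`: `"ok"`, `"monomorphic"` (p of 0 or
#'   1 cannot ever replicate) or `"capped"` (target unreachable at
#'   `n_cap`; `power` then reports the power at the cap)
#' @export
required_sample_size <- function(p, model, alpha = 0.05, target = 0.80,
                                 n_cap = 150000) {
  model <- as_effect_model(model)
  if (target <= 0 || target >= 1) stop("target power must lie in (0, 1)")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  pw <- function(n_total) {
    power_from_ncp(ncp_single(p, n_total / 2, n_total / 2, model),
                   alpha = alpha, df = 1)
  }
  if (p == 0 || p == 1) {
    return(list(n = NA_integer_, power = NA_real_, status = "monomorphic"))
  }
  cap <- 2L * (as.integer(n_cap) %/% 2L)
  if (pw(cap) < target) {
    return(list(n = NA_integer_, power = pw(cap), status = "capped"))
  }
  if (pw(2) >= target) {
    return(list(n = 2L, power = pw(2), status = "ok"))
  }
  # bisect on k = N/2 with pw(2*lo) < target <= pw(2*hi)
  lo <- 1L
  hi <- cap %/% 2L
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (pw(2 * mid) >= target) hi <- mid else lo <- mid
  }
  list(n = 2L * hi, power = pw(2 * hi), status = "ok")
}

#' Read a reported-association table
#'
#' TSV with header columns `snp_id`, `risk_allele`, `odds_ratio` and
#' optionally `trait` and `source`. The reported odds ratio is used as the
#' GRR of the multiplicative model.
#'
#' @param path TSV file
#' @return data.frame of association records
#' @export
read_association_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("snp_id", "risk_allele", "odds_ratio")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop("association table is missing columns: ",
         paste(miss, collapse = ", "))
  }
  if (any(d$odds_ratio <= 0)) stop("odds ratios must be positive")
  if (is.null(d$trait)) d$trait <- NA_character_
  d
}

#' Write an association table as TSV
#' @param associations data.frame with `snp_id`, `risk_allele`,
#'   `odds_ratio` and optional `trait`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_association_table <- function(associations, path) {
  utils::write.table(associations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Replication sample sizes for reported associations across panels
#'
#' For each reported association and each population panel, computes the
#' total 1:1 case-control sample size required to replicate the reported
#' effect at the target power, using the panel's frequency of the declared
#' risk allele. Summarises, relative to a reference panel, how many
#' associations could be replicated more efficiently (smaller minimum N) in
#' some other panel, how many only less efficiently, and how many need at
#' least `size_threshold` samples in the reference panel itself.
#'
#' @param associations data.frame as from [read_association_table()]
#' @param table a [freq_table()] containing every association SNP
#' @param panels panels to evaluate (default: all panels in the table)
#' @param reference_panel panel the comparisons are relative to
#' @param alpha,target,n_cap passed to [required_sample_size()]
#' @param size_threshold reference-panel N at or above which an association
#'   counts as "large" (default 2,500)
#' @return list with `cells` (long data.frame: association x panel with
#'   `n`, `power`, `status`), `wide` (character matrix, `N`, `"NA"` or
#'   `"cap:<power>"`, shaped associations x panels) and `summary`
#' @export
replication_report <- function(associations, table, panels = NULL,
                               reference_panel = "CEU", alpha = 0.05,
                               target = 0.80, n_cap = 150000,
                               size_threshold = 2500) {
  panels <- panels %||% table$panels
  if (is.null(associations$trait)) associations$trait <- NA_character_
  if (!reference_panel %in% panels) {
    stop("reference panel ", reference_panel, " not among the panels")
  }
  idx <- match(associations$snp_id, table$snps$snp_id)
  if (anyNA(idx)) {
    stop("association SNPs absent from the frequency table: ",
         paste(associations$snp_id[is.na(idx)], collapse = ", "))
  }
  is_a <- associations$risk_allele == table$snps$allele_a[idx]
  is_b <- associations$risk_allele == table$snps$allele_b[idx]
  if (any(!is_a & !is_b)) {
    bad <- associations$snp_id[!is_a & !is_b][1]
    stop("risk allele matches neither table allele for SNP ", bad)
  }
  cells <- do.call(rbind, lapply(seq_len(nrow(associations)), function(i) {
    model <- effect_model(associations$odds_ratio[i])
    do.call(rbind, lapply(panels, function(pn) {
      fa <- table$freq[idx[i], pn]
      p <- if (is_a[i]) fa else 1 - fa
      res <- required_sample_size(p, model, alpha = alpha, target = target,
                                  n_cap = n_cap)
      data.frame(record = i, snp_id = associations$snp_id[i],
                 trait = associations$trait[i] %||% NA_character_,
                 panel = pn, n = res$n, power = res$power,
                 status = res$status, stringsAsFactors = FALSE)
    }))
  }))
  fmt <- ifelse(cells$status == "ok", as.character(cells$n),
                ifelse(cells$status == "capped",
                       sprintf("cap:%.4f", cells$power), "NA"))
  wide <- matrix(fmt, nrow = nrow(associations), byrow = TRUE,
                 dimnames = list(paste(associations$snp_id,
                                       associations$trait, sep = "|"),
                                 panels))
  per_record <- lapply(seq_len(nrow(associations)), function(i) {
    cc <- cells[cells$record == i, ]
    ref <- cc[cc$panel == reference_panel, ]
    others <- cc[cc$panel != reference_panel & cc$status == "ok", ]
    min_other <- if (nrow(others)) min(others$n) else NA_integer_
    ref_n <- if (ref$status == "ok") ref$n else NA_integer_
    data.frame(ref_n = ref_n, ref_status = ref$status,
               min_other_n = min_other)
  })
  per_record <- do.call(rbind, per_record)
  comparable <- !is.na(per_record$min_other_n)
  # reference capped or monomorphic: any finite N elsewhere is a gain
  gain <- comparable &
    (is.na(per_record$ref_n) | per_record$min_other_n < per_record$ref_n)
  loss <- !is.na(per_record$ref_n) &
    (!comparable | per_record$min_other_n > per_record$ref_n)
  equal <- comparable & !is.na(per_record$ref_n) &
    per_record$min_other_n == per_record$ref_n
  summary <- list(
    n_associations = nrow(associations),
    n_unique_snps = length(unique(associations$snp_id)),
    n_gain = sum(gain), frac_gain = mean(gain),
    n_loss = sum(loss), frac_loss = mean(loss),
    n_equal = sum(equal),
    n_ref_large = sum(!is.na(per_record$ref_n) &
                        per_record$ref_n >= size_threshold) +
      sum(per_record$ref_status == "capped"),
    size_threshold = size_threshold,
    reference_panel = reference_panel)
  list(cells = cells, wide = wide, summary = summary,
       per_record = cbind(associations, per_record))
}

#' Write a replication report as TSV (associations x panels)
#' @param report a [replication_report()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_replication_report <- function(report, path) {
  out <- data.frame(association = rownames(report$wide),
                    report$wide, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
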