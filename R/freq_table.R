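#' Construct a per-panel allele-frequency table
#'
#' A `freq_table` holds, for each SNP, the identities of its two alleles and
#' the frequency of `allele_a` in each population panel. All downstream power
#' calculations are anchored to `allele_a`: the frequency of `allele_b` in any
#' panel is `1 - freq_a` under the biallelic assumption.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b`. `snp_id` must be unique; `allele_a != allele_b` per row.
#' @param freq numeric matrix, one row per SNP (in `snps` order) and one
#'   column per panel, holding the frequency of `allele_a` in `[0, 1]`.
#'   `NA` marks an explicitly missing frequency.
#' @param chromosomes optional named integer vector: number of chromosomes
#'   the frequency estimate of each panel is based on (`NA` = unknown/exact).
#' @param source provenance tag: `"observed"`, `"estimated"` or `"synthetic"`.
#' @return An object of class `freq_table` with components `snps`, `freq`
#'   (dimnames `snp_id` x panel), `panels`, `chromosomes` and `source`.
#' @seealso [read_frequency_table()], [write_frequency_table()]
#' @export
freq_table <- function(snps, freq, chromosomes = NULL,
                       source = c("observed", "estimated", "synthetic")) {
  source <- match.arg(source)
  freq <- as.matrix(freq)
  if (is.null(colnames(freq))) {
    stop("'freq' must have panel names as column names")
  }
  panels <- colnames(freq)
  storage.mode(freq) <- "double"
  rownames(freq) <- snps$snp_id
  if (is.null(chromosomes)) {
    chromosomes <- stats::setNames(rep(NA_integer_, length(panels)), panels)
  } else {
    chromosomes <- stats::setNames(as.integer(chromosomes[panels]), panels)
  }
  out <- structure(
    list(snps = snps, freq = freq, panels = panels,
         chromosomes = chromosomes, source = source),
    class = "freq_table")
  validate_freq_table(out)
  out
}

validate_freq_table <- function(x) {
  req <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  miss <- setdiff(req, names(x$snps))
  if (length(miss)) {
    stop("frequency table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(x$snps$snp_id)) {
    dup <- x$snps$snp_id[duplicated(x$snps$snp_id)][1]
    stop("duplicate SNP id in frequency table: ", dup)
  }
  if (any(x$snps$allele_a == x$snps$allele_b)) {
    bad <- x$snps$snp_id[x$snps$allele_a == x$snps$allele_b][1]
    stop("allele_a equals allele_b for SNP ", bad)
  }
  if (nrow(x$freq) != nrow(x$snps)) {
    stop("frequency matrix and SNP metadata disagree on the number of SNPs")
  }
  bad <- which(!is.na(x$freq) & (x$freq < 0 | x$freq > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(x$freq))
    stop(sprintf(
      "frequency outside [0,1] for SNP %s in panel %s: %g",
      x$snps$snp_id[i[1]], x$panels[i[2]], x$freq[bad[1]]))
  }
  invisible(x)
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table: %d SNPs x %d panels (%s)\n",
              nrow(x$freq), length(x$panels), x$source))
  cat("panels:", paste(x$panels, collapse = ", "), "\n")
  chr <- x$chromosomes[!is.na(x$chromosomes)]
  if (length(chr)) {
    cat("chromosomes:",
        paste(sprintf("%s=%d", names(chr), chr), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.freq_table <- function(x) dim(x$freq)

#' Number of SNPs in a frequency table
#' @param table a [freq_table()]
#' @return integer SNP count
#' @export
n_snps <- function(table) nrow(table$freq)

#' Subset a frequency table by SNP index
#' @param table a [freq_table()]
#' @param i logical or integer index over SNP records
#' @return a `freq_table` with the selected records
#' @export
subset_snps <- function(table, i) {
  freq_table(table$snps[i, , drop = FALSE],
             table$freq[i, , drop = FALSE],
             chromosomes = table$chromosomes,
             source = table$source)
}

#' Read a per-panel allele-frequency table
#'
#' Two input formats are supported. The native TSV dialect has a header line
#' with columns `snp_id`, `chrom`, `pos`, `allele_a`, `allele_b`, followed by
#' one column per panel (named exactly as the panel) holding the frequency of
#' `allele_a`. Lines starting with `#` carry optional metadata
#' (`#source: ...`, `#chromosomes: PANEL=N,...`). Alternatively a VCF is
#' read with [vcfR::read.vcfR()] and per-panel frequencies are computed as
#' allele counts of REF (`allele_a`) over non-missing called chromosomes per
#' panel; this requires a `panel_map` covering every VCF sample.
#'
#' @param path path to a TSV or VCF file
#' @param format `"tsv"` or `"vcf"`
#' @param panel_map for VCF input: a data.frame with columns `sample` and
#'   `panel`, or a named character vector `sample -> panel`
#' @return a [freq_table()]
#' @export
read_frequency_table <- function(path, format = c("tsv", "vcf"),
                                 panel_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    read_frequency_tsv(path)
  } else {
    if (is.null(panel_map)) {
      stop("a panel_map (sample -> panel) is required for VCF input")
    }
    geno <- read_vcf_genotypes(path)
    genotype_frequencies(geno, panel_map)
  }
}

read_frequency_tsv <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  source <- "observed"
  chromosomes <- NULL
  for (m in lines[meta_idx]) {
    if (grepl("^#source:", m)) {
      source <- trimws(sub("^#source:", "", m))
    } else if (grepl("^#chromosomes:", m)) {
      kv <- strsplit(trimws(sub("^#chromosomes:", "", m)), ",")[[1]]
      parts <- strsplit(kv, "=")
      chromosomes <- stats::setNames(
        as.integer(vapply(parts, `[`, "", 2)),
        vapply(parts, `[`, "", 1))
    }
  }
  body <- if (length(meta_idx)) lines[-meta_idx] else lines
  # remember original line numbers so parse errors point at the file
  body_lineno <- setdiff(seq_along(lines), meta_idx)
  if (length(body) < 1) stop("no header line in ", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  req <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  if (!identical(header[seq_along(req)], req)) {
    stop("TSV header must start with: ", paste(req, collapse = ", "))
  }
  panels <- header[-seq_along(req)]
  if (!length(panels)) stop("TSV has no panel columns")
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    stop(sprintf("malformed row at line %d of %s: expected %d fields, found %d",
                 body_lineno[-1][bad], path, length(header), nf[bad]))
  }
  cells <- do.call(rbind, rows)
  snps <- data.frame(
    snp_id = cells[, 1], chrom = cells[, 2],
    pos = as.integer(cells[, 3]),
    allele_a = cells[, 4], allele_b = cells[, 5],
    stringsAsFactors = FALSE)
  fr <- cells[, -seq_along(req), drop = FALSE]
  suppressWarnings(storage.mode(fr) <- "double")
  bad_num <- which(is.na(fr) & cells[, -seq_along(req), drop = FALSE] != "NA")
  if (length(bad_num)) {
    i <- arrayInd(bad_num[1], dim(fr))
    stop(sprintf("malformed frequency at line %d of %s (panel %s)",
                 body_lineno[-1][i[1]], path, panels[i[2]]))
  }
  colnames(fr) <- panels
  freq_table(snps, fr, chromosomes = chromosomes,
             source = match.arg(source, c("observed", "estimated", "synthetic")))
}

#' Write a frequency table in the native TSV dialect
#'
#' Frequencies are printed at 6 decimals; provenance (source tag and
#' per-panel chromosome counts) is stored in `#`-prefixed metadata lines so
#' that a write/read round trip preserves it.
#'
#' @param table a [freq_table()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_frequency_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#source: %s", table$source), con)
  chr <- table$chromosomes[!is.na(table$chromosomes)]
  if (length(chr)) {
    writeLines(sprintf("#chromosomes: %s",
                       paste(sprintf("%s=%d", names(chr), chr),
                             collapse = ",")), con)
  }
  writeLines(paste(c("snp_id", "chrom", "pos", "allele_a", "allele_b",
                     table$panels), collapse = "\t"), con)
  fr <- table$freq
  txt <- matrix(sprintf("%.6f", fr), nrow = nrow(fr))
  txt[is.na(fr)] <- "NA"
  body <- do.call(paste, c(
    list(table$snps$snp_id, table$snps$chrom, table$snps$pos,
         table$snps$allele_a, table$snps$allele_b),
    lapply(seq_len(ncol(txt)), function(j) txt[, j]),
    sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

as_panel_map <- function(panel_map) {
  if (is.data.frame(panel_map)) {
    if (!all(c("sample", "panel") %in% names(panel_map))) {
      stop("panel_map data.frame needs columns 'sample' and 'panel'")
    }
    stats::setNames(as.character(panel_map$panel),
                    as.character(panel_map$sample))
  } else {
    if (is.null(names(panel_map))) stop("panel_map vector must be named by sample")
    panel_map
  }
}

#' Read diploid genotypes from a VCF
#'
#' Reads a biallelic VCF into an allele-count (dosage) matrix: the number of
#' `allele_a` (REF) copies per sample, `NA` for missing calls. Multiallelic
#' sites are rejected with a counted warning, keeping the table strictly
#' biallelic.
#'
#' @param path VCF file (v4.x, plain or bgzipped)
#' @return list with `snps` (metadata data.frame), `geno` (SNP x sample
#'   integer matrix of REF-allele dosages) and `samples`
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic site(s) rejected")
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(gt[keep, , drop = FALSE], ncol = ncol(gt),
               dimnames = list(NULL, colnames(gt)))
  id <- fix[keep, "ID"]
  noid <- is.na(id) | id == "."
  id[noid] <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])[noid]
  snps <- data.frame(
    snp_id = id,
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    allele_a = fix[keep, "REF"],
    allele_b = fix[keep, "ALT"],
    stringsAsFactors = FALSE)
  # REF dosage per call; any "." in the call marks the genotype missing
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                dimnames = list(snps$snp_id, colnames(gt)))
  ok <- !is.na(gt) & !grepl(".", gt, fixed = TRUE)
  dos[ok] <- nchar(gsub("[^0]", "", gt[ok]))
  list(snps = snps, geno = dos, samples = colnames(gt))
}

#' Per-panel allele frequencies from a genotype matrix
#'
#' @param genotypes as returned by [read_vcf_genotypes()]
#' @param panel_map sample-to-panel mapping (data.frame or named vector)
#' @return a [freq_table()] with source `"observed"`; the denominator per
#'   panel is the number of non-missing called chromosomes
#' @export
genotype_frequencies <- function(genotypes, panel_map) {
  pm <- as_panel_map(panel_map)
  missing_samples <- setdiff(genotypes$samples, names(pm))
  if (length(missing_samples)) {
    stop("samples absent from panel_map: ",
         paste(missing_samples, collapse = ", "))
  }
  panel_of <- pm[genotypes$samples]
  panels <- unique(unname(panel_of))
  fr <- sapply(panels, function(pn) {
    g <- genotypes$geno[, panel_of == pn, drop = FALSE]
    called <- 2L * rowSums(!is.na(g))
    ifelse(called > 0, rowSums(g, na.rm = TRUE) / called, NA_real_)
  })
  fr <- matrix(fr, ncol = length(panels), dimnames = list(NULL, panels))
  chrom <- 2L * table(factor(panel_of, levels = panels))
  freq_table(genotypes$snps, fr,
             chromosomes = stats::setNames(as.integer(chrom), panels),
             source = "observed")
}

#' Recompute frequencies from a random founder subset of each panel
#'
#' Draws `n_founders` samples per panel without replacement and recomputes
#' allele frequencies from exactly `2 * n_founders` chromosomes, equalising
#' the precision of the per-panel estimates (the smallest panel dictates the
#' founder count in typical use).
#'
#' @param genotypes as returned by [read_vcf_genotypes()]
#' @param panel_map sample-to-panel mapping
#' @param n_founders founders drawn per panel
#' @param seed integer seed; identical seeds give identical tables
#' @return a [freq_table()] with `chromosomes = 2 * n_founders` per panel
#' @export
subsample_founders <- function(genotypes, panel_map, n_founders, seed) {
  pm <- as_panel_map(panel_map)
  missing_samples <- setdiff(genotypes$samples, names(pm))
  if (length(missing_samples)) {
    stop("samples absent from panel_map: ",
         paste(missing_samples, collapse = ", "))
  }
  panel_of <- pm[genotypes$samples]
  panels <- unique(unname(panel_of))
  set.seed(seed)
  keep <- character(0)
  for (pn in panels) {
    ss <- genotypes$samples[panel_of == pn]
    if (length(ss) < n_founders) {
      stop(sprintf("panel %s has %d samples, fewer than n_founders = %d",
                   pn, length(ss), n_founders))
    }
    keep <- c(keep, if (length(ss) == n_founders) ss else
      ss[sample.int(length(ss), n_founders)])
  }
  sub <- list(snps = genotypes$snps,
              geno = genotypes$geno[, keep, drop = FALSE],
              samples = keep)
  out <- genotype_frequencies(sub, pm[keep])
  out$chromosomes[] <- 2L * as.integer(n_founders)
  out
}
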