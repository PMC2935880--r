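# fixtures are built in code: small frequency tables, genotype sets and a
# toy VCF, so no binary data ships with the package

make_table <- function(freq, panels = colnames(freq), source = "synthetic") {
  freq <- as.matrix(freq)
  colnames(freq) <- panels
  n <- nrow(freq)
  snps <- data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = "1", pos = seq_len(n),
    allele_a = "A", allele_b = "G",
    stringsAsFactors = FALSE)
  freq_table(snps, freq, source = source)
}

write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1", "0/1"), collapse = "\t"),
    paste(c("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
            "0/0", "0/0", "0/1", "./."), collapse = "\t"))
  writeLines(lines, path)
  path
}

toy_panel_map <- data.frame(
  sample = c("s1", "s2", "s3", "s4"),
  panel = c("P1", "P1", "P2", "P2"),
  stringsAsFactors = FALSE)

# genotype set shaped like read_vcf_genotypes() output
make_genotypes <- function(geno, samples = colnames(geno)) {
  n <- nrow(geno)
  colnames(geno) <- samples
  list(snps = data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)), chrom = "1",
    pos = seq_len(n), allele_a = "A", allele_b = "G",
    stringsAsFactors = FALSE),
    geno = geno, samples = samples)
}
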