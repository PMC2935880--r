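run_pipeline <- function(dir, seed = 23) {
  dir.create(dir, showWarnings = FALSE)
  freq <- file.path(dir, "freq.tsv")
  power_cli(c("simulate", "--n-snps", "3000",
              "--panels", "CEU:0.01,YRI:0.15",
              "--seed", as.character(seed),
              "--ascertain-panel", "CEU", "--min-maf", "0.01",
              "--chromosomes", "100",
              "--out", freq))
  per_snp <- file.path(dir, "per_snp.tsv")
  summary <- file.path(dir, "summary.json")
  power_cli(c("run", "--freq", freq, "--scenario", "20000:YRI",
              "--grr", "1.2", "--ref-panel", "CEU",
              "--out", per_snp, "--summary", summary))
  tab <- read_frequency_table(freq)
  sim <- simulate_associations(
    12, list(panel_model("CEU", 0), panel_model("YRI", 0.15)),
    n_duplicated = 2, seed = seed)
  assoc <- file.path(dir, "assoc.tsv")
  afreq <- file.path(dir, "afreq.tsv")
  write_association_table(sim$associations, assoc)
  write_frequency_table(sim$table, afreq)
  rep_tsv <- file.path(dir, "replication.tsv")
  rep_json <- file.path(dir, "replication.json")
  power_cli(c("replicate", "--assoc", assoc, "--freq", afreq,
              "--ref-panel", "CEU",
              "--out", rep_tsv, "--summary", rep_json))
  c(freq, per_snp, summary, assoc, afreq, rep_tsv, rep_json)
}
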