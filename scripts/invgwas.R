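#!/usr/bin/env Rscript

# Thin command-line wrapper over the invgwas package.
#
#   Rscript scripts/invgwas.R simulate --out DIR [--n-lines N] [--seed S]
#   Rscript scripts/invgwas.R run      --out DIR [--n-perm N]  [--seed S]
#
# `simulate` writes a synthetic panel (VCF + TSVs); `run` executes the full
# scenario pipeline (run_scenario) into the output directory.  Every other
# stage of the pipeline maps 1:1 to an exported function; see the package
# documentation.

suppressPackageStartupMessages({
  library(optparse)
  library(invgwas)
})

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args)) args[1] else ""
if (!cmd %in% c("simulate", "run")) {
  message("usage: invgwas.R {simulate|run} --out DIR [options]")
  quit(status = 2)
}

parser <- OptionParser(option_list = list(
  make_option("--out", type = "character", default = "invgwas_out"),
  make_option("--n-lines", type = "integer", default = 200L, dest = "n_lines"),
  make_option("--n-variants", type = "integer", default = 400L,
              dest = "n_variants"),
  make_option("--n-perm", type = "integer", default = 25L, dest = "n_perm"),
  make_option("--seed", type = "integer", default = 1L)
))
o <- parse_args(parser, args = args[-1])

sim_cfg <- sim_config(n_lines = o$n_lines, n_variants = o$n_variants,
                      seed = o$seed)

if (cmd == "simulate") {
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_panel(sim_cfg)
  tm <- simulate_traits(sim$panel, sim$karyotypes, sim$covariates,
                        trait_sim_config(seed = o$seed))
  write_genotypes(sim$panel, file.path(o$out, "genotypes.vcf"))
  write_karyotypes(sim$karyotypes, file.path(o$out, "karyotypes.tsv"))
  write_inversions(sim$inversions, file.path(o$out, "inversions.tsv"))
  write_traits(tm, file.path(o$out, "traits.tsv"))
  write.table(sim$covariates, file.path(o$out, "covariates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message("simulated panel written to ", o$out)
} else {
  cfg <- run_config(sim = sim_cfg, n_perm = o$n_perm, seed = o$seed,
                    out_dir = o$out)
  run_scenario(cfg)
  message("scenario artifacts written to ", o$out)
}
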