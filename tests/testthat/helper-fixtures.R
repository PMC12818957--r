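# Shared fixtures, built in code.  The cache keeps one simulation per key so
# several test files can reuse the same panel without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Hand-built 4-line x 3-variant panel: one common variant, one rare, one with
# a missing call.
toy_panel <- function() {
  dos <- matrix(c(0, 2, 2, 0,    # v1: p = 0.5
                  0, 0, 0, 2,    # v2: p = 0.25
                  2, 2, NA, 0),  # v3: missing 25%
                nrow = 4,
                dimnames = list(paste0("L", 1:4), NULL))
  genotype_panel(dos, data.frame(
    id = c("2L_100_A_T", "2L_5000_A_G", "2R_200_C_T"),
    arm = c("2L", "2L", "2R"), pos = c(100L, 5000L, 200L),
    ref = c("A", "A", "C"), alt = c("T", "G", "T"),
    stringsAsFactors = FALSE))
}

# Default-condition simulation at reduced variant density, reused widely.
small_sim <- function() cached("small_sim", {
  cfg <- sim_config(n_lines = 120,
                    genome = c("2L" = 23e6, "2R" = 21e6),
                    inversions = inversion_def("In(2L)t", "2L",
                                               2225744L, 13154180L),
                    inv_freq = 0.25, n_variants = 150L, seed = 101)
  sim <- simulate_panel(cfg)
  sim$cfg <- cfg
  sim
})

# Karyotype table over given ids with a fixed INV set.
toy_karyotypes <- function(ids, inv_ids, name = "In(2L)t") {
  call <- matrix(ifelse(ids %in% inv_ids, "INV", "STD"), ncol = 1,
                 dimnames = list(ids, name))
  karyotype_table(call)
}
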