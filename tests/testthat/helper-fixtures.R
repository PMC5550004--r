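# Shared fixtures, built once per test run and memoised in this environment.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

test_grid <- function(r = 1, seed = 1, D = 50) {
  memo(sprintf("grid_%g_%d_%d", r, seed, D), function()
    build_polar_grid(r, sample_slice(D, seed = seed)))
}

# full-resolution Gabor bank (expensive; share across tests and with the
# package-level cache used by simulate_runs)
test_bank <- function() memo("bank96", function() {
  b <- build_filter_bank(96)
  assign("96", b, envir = get("bank_cache", envir = asNamespace("facersa")))
  b
})

test_participant <- function(seed = 5) {
  memo(sprintf("participant_%d", seed), function()
    generate_participant(seed))
}

# row indices of mirror (same identity, L vs R) condition pairs in the
# 24-condition order f01_L, f01_R, f02_L, ...
mirror_pair_idx <- function() cbind(seq(1, 23, 2), seq(2, 24, 2))

# mean eccentricity per level of a 24-condition profile
profile_by_ecc <- function(profile, grid) {
  tapply(profile, rep(grid$faces$ecc_level, each = 2),
         mean)[c("sub", "typical", "caricature")]
}
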