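# Shared fixture builders and independent oracles.

# growth table from explicit per-strain efficiency vectors
make_growth_tbl <- function(values, genotypes = NULL, temperature = 39) {
  rows <- lapply(names(values), function(s) {
    eff <- values[[s]]
    tibble::tibble(
      strain_id = s,
      genotype = if (is.null(genotypes)) NA_character_ else genotypes[[s]],
      temperature_C = temperature,
      replicate = paste0("r", seq_along(eff)),
      day = "day_1",
      od_initial = 0.1,
      od_final = 0.1 + eff,
      duration_h = 24)
  })
  dplyr::bind_rows(rows)
}

# effect_estimate stand-in for classification tests
make_est <- function(effect, boot, locus = "L", nf = 1000, nr = 1000) {
  structure(list(locus = locus, background = NA_character_, effect = effect,
                 n_focal = nf, n_ref = nr, boot = boot,
                 ci = NULL, ci_level = NA_real_),
            class = "effect_estimate")
}

# brute-force Wilcoxon rank-sum p by enumerating all rank partitions
wilcox_oracle <- function(x, y, alternative) {
  nx <- length(x); ny <- length(y)
  comb <- c(x, y)
  r <- rank(comb)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  switch(alternative,
         greater = mean(u_all >= u_obs),
         less = mean(u_all <= u_obs),
         two_sided = mean(abs(u_all - mu) >= abs(u_obs - mu)))
}

# exact distribution of mean(resample of 2) - mean(resample of 2)
boot_enum_2 <- function(xf, xr) {
  stopifnot(length(xf) == 2, length(xr) == 2)
  means2 <- function(v) {
    vals <- c(v[1], mean(v), v[2])
    probs <- c(0.25, 0.5, 0.25)
    list(vals = vals, probs = probs)
  }
  f <- means2(xf); r <- means2(xr)
  d <- outer(f$vals, r$vals, `-`)
  p <- outer(f$probs, r$probs)
  agg <- tapply(as.vector(p), round(as.vector(d), 12), sum)
  list(vals = as.numeric(names(agg)), probs = as.numeric(agg))
}
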