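# Shared fixture builders: every fixture is generated in code at test time.

# small noise-free screen: nDrugs drugs, chosen models, 1 bio replicate
noiseFreeScreen <- function(nDrugs = 6, models = c("2D7d", "MG7d"),
                            seed = 42, bioReps = 1, ...) {
  tr <- makeTruth(nDrugs, models = models, seed = seed, noiseCv = 0,
                  gradientRow = 0, gradientCol = 0, edgeEffect = 1, ...)
  lay <- screenLayouts(tr, bioReps = bioReps)
  list(truth = tr, layouts = lay,
       plates = simulateScreen(tr, lay, seed = seed + 1))
}

# flat synthetic plate grid with optional multiplicative field
flatGrid <- function(value = 1000, field = NULL) {
  g <- matrix(value, 16, 24)
  if (!is.null(field)) g <- g * field
  g
}

# drugs x origins difference matrix -> centered-value long table with a
# zero reference arm, as rankProduct() consumes
makeCentered <- function(diffs, model = "MG7d", conc = NULL) {
  drugs <- rownames(diffs)
  if (is.null(conc)) conc <- 10^seq_len(ncol(diffs))
  rbind(
    data.frame(drug = rep(drugs, ncol(diffs)),
               concentration_uM = rep(conc, each = nrow(diffs)),
               model = model, estimate = as.vector(diffs)),
    data.frame(drug = rep(drugs, ncol(diffs)),
               concentration_uM = rep(conc, each = nrow(diffs)),
               model = "2D7d", estimate = 0))
}

# independent brute-force rank-product enumeration: all (n!)^k rank
# assignments, p = fraction of null RPs <= observed (used as the oracle
# against the package's permutation machinery)
bruteForceRankProductP <- function(obsRanks) {
  n <- nrow(obsRanks)
  k <- ncol(obsRanks)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  P <- perms(seq_len(n))
  combos <- expand.grid(rep(list(seq_along(P)), k))
  obsRP <- apply(obsRanks, 1, function(r) prod(r)^(1 / k))
  nullRP <- unlist(apply(combos, 1, function(ix) {
    m <- sapply(seq_len(k), function(j) P[[ix[j]]])
    apply(m, 1, function(r) prod(r)^(1 / k))
  }, simplify = FALSE))
  vapply(obsRP, function(x) mean(nullRP <= x * (1 + 1e-12)), 0)
}
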