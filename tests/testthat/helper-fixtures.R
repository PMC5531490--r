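# Shared fixtures for the test suite. All data are generated in code.

# Chain model where intermediate 1 shares the dark band (so its difference
# spectrum vanishes) and intermediate 2 absorbs far from it: at 400 nm the
# surface reads c2(t) * amplitude directly.
isolatedChainModel <- function(k1 = 100, k2 = 10, f = 0.1) {
  photocycleModel(
    intermediateNames = c("X1", "X2"),
    rateConstants = c(k1, k2),
    intermediateSpectra = rbind(c(700, 10, 1), c(400, 10, 1)),
    darkSpectrum = c(700, 10, 1),
    excitedFraction = f)
}

# Single-intermediate model, blue-shifted band, used for one-exponential
# recovery checks. Rate in s^-1.
oneStepModel <- function(rate = 1000, center = 410, darkCenter = 525,
                         f = 0.1) {
  photocycleModel("M", rate, c(center, 35, 1), c(darkCenter, 40, 1),
                  excitedFraction = f)
}

# Four-taxon additive distance matrix from a known unrooted tree
# ((A,B),(C,D)) with external branches a,b,c,d and internal branch e.
additiveFourTaxon <- function(a = 0.10, b = 0.15, c = 0.12, d = 0.08,
                              e = 0.05) {
  taxa <- c("A", "B", "C", "D")
  m <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  m["A", "B"] <- a + b
  m["A", "C"] <- a + e + c
  m["A", "D"] <- a + e + d
  m["B", "C"] <- b + e + c
  m["B", "D"] <- b + e + d
  m["C", "D"] <- c + d
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Balanced 4-taxon tree used for alignment simulation.
fourTaxonTree <- function(inner = 0.08, outer = 0.1) {
  ape::read.tree(text = sprintf("((A:%g,B:%g):%g,(C:%g,D:%g):%g);",
                                outer, outer, inner, outer, outer, inner))
}
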