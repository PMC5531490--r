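# p-distances, Poisson correction, neighbor-joining, bootstrap supports.

test_that("p-distance counts differing residues with pairwise deletion", {
  aln <- c(s1 = "ACDEF", s2 = "ACDEY", s3 = "ACDEF")
  p <- pDistance(aln)
  expect_equal(p["s1", "s2"], 0.2)
  expect_equal(p["s1", "s3"], 0)
  expect_equal(diag(p), c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(p, t(p))

  # gapped columns are dropped per pair
  g <- c(a = "AC-EF", b = "ACW-F", c = "ACWEF")
  pg <- pDistance(g)
  expect_equal(pg["a", "b"], 0)     # only columns 1,2,5 compared
  expect_equal(pg["a", "c"], 0)
  expect_equal(pg["b", "c"], 0)

  # a pair with no gap-free columns is an error naming the pair
  h <- c(x = "A---", y = "-CDE", z = "ACDE")
  expect_error(pDistance(h), "'x' and 'y'")
})

test_that("Poisson correction follows -ln(1 - p)", {
  mk <- function(p) matrix(c(0, p, p, 0), 2,
                           dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(poissonCorrect(mk(0))["a", "b"], 0)
  expect_equal(poissonCorrect(mk(0.5))["a", "b"], 0.6931, tolerance = 1e-4)
  expect_warning(d <- poissonCorrect(mk(0.999)), "saturation")
  expect_equal(d["a", "b"], 6.908, tolerance = 1e-4)
  expect_error(poissonCorrect(mk(1)), "undefined")

  # strictly increasing in p, and always d >= p
  p <- seq(0, 0.95, by = 0.05)
  d <- -log(1 - p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
  pm <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("a","b"), c("a","b")))
  expect_true(all(poissonCorrect(pm) >= pm))
})

test_that("3-taxon NJ reproduces the closed-form star tree", {
  taxa <- c("A", "B", "C")
  d <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, dimnames = list(taxa, taxa))
  tr <- njTree(d)
  pl <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(pl[["A"]], (0.3 + 0.4 - 0.5) / 2)
  expect_equal(pl[["B"]], (0.3 + 0.5 - 0.4) / 2)
  expect_equal(pl[["C"]], (0.4 + 0.5 - 0.3) / 2)
})

test_that("NJ recovers additive 4-taxon trees exactly", {
  d <- additiveFourTaxon(a = 0.10, b = 0.15, c = 0.12, d = 0.08, e = 0.05)
  # four-point condition confirms additivity of the fixture
  sums <- c(d["A","B"] + d["C","D"], d["A","C"] + d["B","D"],
            d["A","D"] + d["B","C"])
  expect_equal(sort(sums)[2], sort(sums)[3])
  expect_lt(sort(sums)[1], sort(sums)[2])

  tr <- njTree(d)
  # topology: AB|CD bipartition present (canonical key excludes taxon A)
  expect_true("C|D" %in% NaRtools:::bipartitionKeys(tr))
  # path lengths reproduce the input exactly (NJ consistency oracle)
  co <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(co, d, tolerance = 1e-12)
})

test_that("NJ path lengths reproduce any additive input (random trees)", {
  set.seed(8)
  for (r in 1:3) {
    tr0 <- ape::rtree(7, br = function(n) runif(n, 0.05, 0.4))
    tr0 <- ape::unroot(tr0)
    d <- ape::cophenetic.phylo(tr0)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    tr <- njTree(d)
    co <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_equal(co, d, tolerance = 1e-10)
    # independent cross-check: same topology as ape's NJ
    expect_equal(as.numeric(ape::dist.topo(tr, ape::nj(as.dist(d)))), 0)
  }
})

test_that("malformed distance matrices are rejected", {
  taxa <- c("A", "B", "C")
  asym <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3,
                 dimnames = list(taxa, taxa))
  expect_error(njTree(asym), "symmetric")
  expect_error(njTree(matrix(0, 2, 2, dimnames = list(c("a","b"), c("a","b")))),
               "3 taxa")
})

test_that("negative NJ branch lengths are clamped with raw values kept", {
  taxa <- c("A", "B", "C", "D")
  # near-degenerate matrix that forces a negative internal estimate
  d <- matrix(c(0, 0.1, 0.2, 0.2,
                0.1, 0, 0.2, 0.2,
                0.2, 0.2, 0, 0.01,
                0.2, 0.2, 0.01, 0), 4, dimnames = list(taxa, taxa))
  tr <- njTree(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are 100 for a fully supported split", {
  # 20 sites separate AB from CD; 20 shared sites keep p-distances away from
  # saturation; one site each distinguishes within the pairs
  aln <- c(A = paste0(strrep("A", 20), strrep("G", 20)),
           B = paste0(strrep("A", 20), strrep("G", 20)),
           C = paste0(strrep("W", 20), strrep("G", 20)),
           D = paste0(strrep("W", 20), strrep("G", 20)))
  substr(aln["A"], 21, 21) <- "C"
  substr(aln["C"], 22, 22) <- "E"
  tr <- bootstrapSupport(aln, nReplicates = 100, seed = 1)
  sup <- attr(tr, "supports")
  expect_identical(unname(sup), 100)
})

test_that("bootstrap is reproducible and invariant to taxon order", {
  tree <- fourTaxonTree()
  aln <- alignment(simulateAlignment(tree, 300, seed = 31))
  t1 <- bootstrapSupport(aln, nReplicates = 100, seed = 7)
  t2 <- bootstrapSupport(aln, nReplicates = 100, seed = 7)
  expect_identical(attr(t1, "supports"), attr(t2, "supports"))

  shuffled <- aln[c(3, 1, 4, 2)]
  t3 <- bootstrapSupport(shuffled, nReplicates = 100, seed = 7)
  expect_identical(sort(names(attr(t1, "supports"))),
                   sort(names(attr(t3, "supports"))))
  # the recovered topology contains the generating AB|CD split with strong
  # support at 300 sites (canonical key excludes taxon A)
  expect_gt(attr(t1, "supports")[["C|D"]], 90)
})

test_that("bootstrapped NJ recovers the generating topology", {
  set.seed(41)
  tr0 <- ape::unroot(ape::rtree(6, br = function(n) runif(n, 0.08, 0.3)))
  aln <- simulateAlignment(tr0, 1000, seed = 42)
  est <- njTree(poissonCorrect(pDistance(aln)))
  expect_equal(as.numeric(ape::dist.topo(est, tr0)), 0)
})
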