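#' Pairwise amino-acid p-distances
#'
#' Proportion of differing residues for every sequence pair, counted over the
#' columns where neither sequence of the pair has a gap (pairwise deletion;
#' set \code{completeDeletion = TRUE} to first drop every column containing a
#' gap in any sequence, as some workflows prefer).
#'
#' @param aln an aligned \code{AAStringSet}, a [SyntheticAlignment-class], or
#'   a named character vector of equal-length sequences.
#' @param completeDeletion drop all gapped columns up front instead of
#'   per-pair deletion.
#' @param gapChars characters treated as gaps.
#' @return symmetric numeric matrix of proportions with taxa dimnames, zero
#'   diagonal.
#' @export
pDistance <- function(aln, completeDeletion = FALSE, gapChars = c("-", ".")) {
  pDistanceFromMatrix(alignmentMatrix(aln), completeDeletion, gapChars)
}

alignmentMatrix <- function(aln) {
  if (is(aln, "SyntheticAlignment")) aln <- aln@alignment
  if (is(aln, "AAStringSet")) {
    if (length(unique(Biostrings::width(aln))) != 1L)
      stop("sequences must be aligned (equal width)")
    m <- do.call(rbind, strsplit(as.character(aln), ""))
    rownames(m) <- names(aln)
  } else if (is.character(aln)) {
    if (length(unique(nchar(aln))) != 1L)
      stop("sequences must be aligned (equal length)")
    m <- do.call(rbind, strsplit(aln, ""))
    rownames(m) <- names(aln)
  } else stop("unsupported alignment type")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("taxa names must be present and unique")
  m
}

#' Poisson correction of p-distances
#'
#' Converts observed proportions of differing residues into expected
#' substitutions per site under the equal-rates Poisson model,
#' \eqn{d = -\ln(1 - p)}. The transform is strictly increasing and always
#' \eqn{d \ge p}. Distances approaching saturation (p >= 0.99 by default)
#' trigger a warning; p >= 1 is an error (the distance is undefined).
#'
#' @param pMatrix symmetric matrix of p-distances (from [pDistance()]).
#' @param saturationWarn warn when any off-diagonal p exceeds this value.
#' @return matrix of corrected distances (substitutions/site).
#' @examples
#' poissonCorrect(matrix(c(0, .5, .5, 0), 2,
#'                dimnames = list(c("a","b"), c("a","b"))))  # 0.6931
#' @export
poissonCorrect <- function(pMatrix, saturationWarn = 0.99) {
  off <- pMatrix[row(pMatrix) != col(pMatrix)]
  if (any(off >= 1))
    stop("p-distance >= 1: Poisson correction undefined")
  if (any(off >= saturationWarn))
    warning("p-distance(s) >= ", saturationWarn,
            ": corrected distances are near saturation and unreliable")
  d <- -log(1 - pMatrix)
  dimnames(d) <- dimnames(pMatrix)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing
#' \eqn{Q_{ij} = (n-2) d_{ij} - r_i - r_j} (with \eqn{r} the row sums of the
#' current matrix) is joined; ties are broken deterministically by the lowest
#' index pair. Branch lengths use the standard NJ formulas; negative lengths
#' are clamped to zero (MEGA-compatible convention) with the raw values kept
#' in the \code{rawNegativeLengths} attribute.
#'
#' @param dm symmetric distance matrix with zero diagonal, unique taxa
#'   dimnames and at least 3 taxa.
#' @return an unrooted \code{phylo} tree (the 3-taxon case is the unique
#'   star tree with lengths \eqn{a = (d_{12} + d_{13} - d_{23})/2} etc.).
#' @export
njTree <- function(dm) {
  checkDistanceMatrix(dm)
  n0 <- nrow(dm)
  taxa <- rownames(dm)
  node <- as.list(paste0("T", seq_len(n0)))  # newick fragments per active node
  D <- unname(dm)
  active <- seq_len(n0)
  rawNeg <- numeric(0)
  clamp <- function(x) {
    if (x < 0) rawNeg <<- c(rawNeg, x)
    max(x, 0)
  }
  nwk <- function(i) node[[i]]
  while (length(active) > 3L) {
    m <- length(active)
    Dm <- D[active, active]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE][1L, ]
    i <- idx[1L]; j <- idx[2L]             # positions within `active`
    ai <- active[i]; aj <- active[j]
    dij <- Dm[i, j]
    vi <- clamp(0.5 * dij + (r[i] - r[j]) / (2 * (m - 2)))
    vj <- clamp(dij - (0.5 * dij + (r[i] - r[j]) / (2 * (m - 2))))
    # new node replaces position i; distances to the others
    others <- active[-c(i, j)]
    newD <- 0.5 * (D[ai, others] + D[aj, others] - dij)
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, others] <- newD; D[others, u] <- newD
    node[[u]] <- sprintf("(%s:%.12g,%s:%.12g)", nwk(ai), vi, nwk(aj), vj)
    active <- c(setdiff(active, c(ai, aj)), u)
  }
  a <- active
  d12 <- D[a[1L], a[2L]]; d13 <- D[a[1L], a[3L]]; d23 <- D[a[2L], a[3L]]
  v1 <- clamp((d12 + d13 - d23) / 2)
  v2 <- clamp((d12 + d23 - d13) / 2)
  v3 <- clamp((d13 + d23 - d12) / 2)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 nwk(a[1L]), v1, nwk(a[2L]), v2, nwk(a[3L]), v3)
  tr <- ape::read.tree(text = txt)
  tr$tip.label <- taxa[as.integer(sub("^T", "", tr$tip.label))]
  attr(tr, "rawNegativeLengths") <- rawNeg
  tr
}

checkDistanceMatrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be square")
  if (nrow(dm) < 3L) stop("at least 3 taxa are required")
  if (is.null(rownames(dm)) || anyDuplicated(rownames(dm)))
    stop("distance matrix needs unique taxa dimnames")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(dm < 0)) stop("distances must be non-negative")
  invisible(TRUE)
}

# Bipartition keys of the internal edges of an unrooted phylo: for each
# internal (non-root) node, the set of tips on its side of the edge,
# canonicalized to the side not containing the reference taxon.
bipartitionKeys <- function(tree, refTaxa = sort(tree$tip.label)) {
  nTip <- length(tree$tip.label)
  nNode <- tree$Nnode
  desc <- vector("list", nTip + nNode)
  for (i in seq_len(nTip)) desc[[i]] <- tree$tip.label[i]
  # postorder so children are filled before parents
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  root <- nTip + 1L
  keys <- character(0)
  nodes <- integer(0)
  for (v in seq_len(nNode) + nTip) {
    if (v == root) next
    side <- sort(desc[[v]])
    if (refTaxa[1L] %in% side) side <- sort(setdiff(refTaxa, side))
    if (length(side) < 2L || length(side) > length(refTaxa) - 2L) next  # trivial
    keys <- c(keys, paste(side, collapse = "|"))
    nodes <- c(nodes, v)
  }
  names(keys) <- nodes
  keys
}

#' NJ tree with nonparametric bootstrap supports
#'
#' Builds the full-data tree through the [pDistance()] ->
#' [poissonCorrect()] -> [njTree()] chain, then resamples alignment columns
#' with replacement \code{nReplicates} times (default 1000), rebuilds a tree
#' per replicate, and labels every internal edge of the full-data tree with
#' the percentage of replicate trees containing the same bipartition.
#' Supports are attached as integer \code{node.label}s, so
#' \code{ape::write.tree} emits the conventional Newick with supports.
#' Supports refer to taxon bipartitions, hence are invariant to the input
#' order of the sequences.
#'
#' @param aln alignment as accepted by [pDistance()].
#' @param nReplicates bootstrap replicates (default 1000).
#' @param seed integer RNG seed; a fixed seed reproduces supports exactly.
#' @param completeDeletion passed to [pDistance()].
#' @return the full-data \code{phylo} with \code{node.label} supports (root
#'   label empty) and an attribute \code{supports} mapping bipartition keys
#'   to percentages.
#' @export
bootstrapSupport <- function(aln, nReplicates = 1000L, seed = NULL,
                             completeDeletion = FALSE) {
  m <- alignmentMatrix(aln)
  if (!is.null(seed)) set.seed(as.integer(seed))
  buildFromMatrix <- function(mm) {
    p <- pDistanceFromMatrix(mm, completeDeletion)
    njTree(suppressWarnings(poissonCorrect(p)))
  }
  full <- buildFromMatrix(m)
  refTaxa <- sort(full$tip.label)
  fullKeys <- bipartitionKeys(full, refTaxa)
  counts <- stats::setNames(numeric(length(fullKeys)), fullKeys)
  nSites <- ncol(m)
  for (b in seq_len(nReplicates)) {
    cols <- sample.int(nSites, nSites, replace = TRUE)
    rep <- try(buildFromMatrix(m[, cols, drop = FALSE]), silent = TRUE)
    if (inherits(rep, "try-error")) next
    hit <- fullKeys %in% bipartitionKeys(rep, refTaxa)
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / nReplicates
  nTip <- length(full$tip.label)
  labs <- rep("", full$Nnode)
  labs[as.integer(names(fullKeys)) - nTip] <- as.character(round(support))
  full$node.label <- labs
  attr(full, "supports") <- support
  full
}

# pDistance on a pre-split character matrix (used by the bootstrap loop to
# avoid re-splitting strings every replicate).
pDistanceFromMatrix <- function(m, completeDeletion = FALSE,
                                gapChars = c("-", ".")) {
  if (completeDeletion) {
    keep <- colSums(matrix(m %in% gapChars, nrow = nrow(m))) == 0L
    if (!any(keep)) stop("complete deletion removed every column")
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m); taxa <- rownames(m)
  isGap <- matrix(m %in% gapChars, nrow = n)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !isGap[i, ] & !isGap[j, ]
    if (!any(ok))
      stop("sequences '", taxa[i], "' and '", taxa[j],
           "' share no gap-free columns")
    d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
  }
  d
}
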