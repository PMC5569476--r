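## Independent brute-force oracles the implementation is checked against.
## These deliberately share no code with the package internals.

## Filter cascade: per-candidate rule-by-rule loop.
oracleCascade <- function(cand, config, mask = NULL, neighbors = NULL) {
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- cand$maf[i] >= config$mafMin
    ok <- ok && cand$accuracy[i] > config$accuracyMin
    if (ok && !is.null(mask) && nrow(mask)) {
      for (j in seq_len(nrow(mask)))
        if (mask$chrom[j] == cand$chrom[i] &&
            cand$pos[i] >= mask$start[j] && cand$pos[i] <= mask$end[j])
          ok <- FALSE
    }
    if (ok && !is.null(neighbors) && nrow(neighbors)) {
      for (j in seq_len(nrow(neighbors)))
        if (neighbors$chrom[j] == cand$chrom[i] &&
            abs(neighbors$pos[j] - cand$pos[i]) <= config$flankBp)
          ok <- FALSE
    }
    ok <- ok && cand$het_rate[i] < config$hetMax
    if (config$dropMultiMapped) ok <- ok && !cand$multi_mapped[i]
    if (ok && !is.null(cand$design_score)) {
      thr <- if (cand$region_class[i] == "genic") config$scoreGenicMin
             else config$scoreIntergenicMin
      ok <- cand$design_score[i] > thr
    }
    keep[i] <- ok
  }
  cand[keep, , drop = FALSE]
}

## Maximum number of markers with pairwise adjacent gaps > minGap:
## dynamic programme over sorted positions.
oracleSpacingDP <- function(pos, minGap) {
  pos <- sort(pos)
  n <- length(pos)
  if (n == 0) return(0L)
  best <- rep(1L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (pos[i] - pos[j] > minGap && best[j] + 1L > best[i])
        best[i] <- best[j] + 1L
    }
  }
  max(best)
}

## 1-IBS distances by explicit allele-sharing loop.
oracleIBS <- function(cl) {
  share <- function(a, b) {
    da <- c(AA = 0, AB = 1, BB = 2)[a]
    db <- c(AA = 0, AB = 1, BB = 2)[b]
    1 - abs(da - db) / 2
  }
  n <- ncol(cl)
  out <- matrix(0, n, n, dimnames = list(colnames(cl), colnames(cl)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- c(); cnt <- 0
    for (l in seq_len(nrow(cl))) {
      if (cl[l, i] %in% c("AA", "AB", "BB") &&
          cl[l, j] %in% c("AA", "AB", "BB")) {
        s <- c(s, share(cl[l, i], cl[l, j])); cnt <- cnt + 1
      }
    }
    out[i, j] <- 1 - mean(s)
  }
  out
}

## REML by fine two-stage grid search plus direct (unrotated) GLS t-test.
oracleMlmP <- function(y, W, x, K) {
  n <- length(y)
  X <- cbind(W, x)
  negll <- function(lambda) {
    V <- lambda * K + diag(n)
    Vi <- solve(V)
    A <- t(X) %*% Vi %*% X
    beta <- solve(A, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    rss <- drop(t(r) %*% Vi %*% r)
    np <- n - ncol(X)
    0.5 * (np * log(rss) + determinant(V)$modulus[1] +
             determinant(A)$modulus[1])
  }
  lg <- seq(-12, 12, length.out = 300)
  v <- vapply(exp(lg), negll, numeric(1))
  l0 <- lg[which.min(v)]
  for (hw in c(0.2, 0.01, 5e-4)) {
    lg <- seq(l0 - hw, l0 + hw, length.out = 401)
    v <- vapply(exp(lg), negll, numeric(1))
    l0 <- lg[which.min(v)]
  }
  lam <- exp(l0)
  V <- lam * K + diag(n)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  df <- n - ncol(X)
  sigma2 <- drop(t(r) %*% Vi %*% r) / df
  se <- sqrt(sigma2 * solve(A)[ncol(X), ncol(X)])
  tt <- beta[ncol(X)] / se
  list(lambda = lam, p = 2 * stats::pt(-abs(tt), df))
}

## Hudson Fst (Bhatia ratio-of-averages), averaged over subpopulation pairs.
oracleHudsonFst <- function(dos, pops) {
  lv <- unique(pops)
  pairsFst <- c()
  for (a in seq_along(lv)) for (b in seq_along(lv)) {
    if (b <= a) next
    ia <- pops == lv[a]; ib <- pops == lv[b]
    p1 <- rowMeans(dos[, ia, drop = FALSE]) / 2
    p2 <- rowMeans(dos[, ib, drop = FALSE]) / 2
    n1 <- sum(ia); n2 <- sum(ib)
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) -
      p2 * (1 - p2) / (2 * n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    pairsFst <- c(pairsFst, sum(num) / sum(den))
  }
  mean(pairsFst)
}

## Random candidate instance for cascade property tests.
randomCandidateInstance <- function(n, config) {
  cand <- data.frame(
    id = sprintf("c%02d", seq_len(n)),
    chrom = sample(c("A01", "D01"), n, replace = TRUE),
    pos = sample.int(1e5, n),
    maf = stats::runif(n, 0, 0.5),
    het_rate = stats::runif(n, 0, 0.3),
    accuracy = stats::runif(n, 0.98, 1),
    design_score = stats::runif(n, 0.5, 1),
    region_class = sample(c("genic", "intergenic"), n, replace = TRUE),
    multi_mapped = stats::runif(n) < 0.15)
  cand <- cand[!duplicated(cand[c("chrom", "pos")]), , drop = FALSE]
  chroms <- unique(cand$chrom)
  mask <- data.frame(chrom = sample(chroms, 2, replace = TRUE),
                     start = sample.int(9e4, 2), end = NA)
  mask$end <- mask$start + sample.int(5e3, 2)
  neighbors <- data.frame(chrom = sample(chroms, 3, replace = TRUE),
                          pos = sample.int(1e5, 3))
  list(cand = cand, mask = mask, neighbors = neighbors)
}
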