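## Genotype calling from normalized (theta, R) intensities.
##
## The mixture is one-dimensional in theta: on Infinium-style data the
## genotype classes separate along the allele-contrast axis, while the total
## signal R carries presence/absence information only. R is therefore used
## to gate no-signal (NG) samples and to exclude them from fitting.

#' Calling configuration
#'
#' @param maxClusters Maximum number of theta clusters considered (1–5; an
#'   allotetraploid locus can show up to five genotype classes
#'   AAAA/AAAB/AABB/ABBB/BBBB).
#' @param mergeDeltaTheta Adjacent clusters closer than this in mean theta
#'   are merged during adjustment. Default 0.15: comfortably below the
#'   ~0.23 spacing of five canonical cluster means, so genuine tetraploid
#'   classes survive while sub-cluster artifacts collapse.
#' @param ngRMin Samples with `normR` below this have no usable signal and
#'   are called `NG`. Default 0.2.
#' @param assignMaxDistance Maximum standardized theta distance (in cluster
#'   standard deviations) to the nearest cluster; beyond it a sample is
#'   called `--` (off-cluster, e.g. In-Del). Default 4.
#' @param minClusterWeight Mixture components below this weight are dropped
#'   and the model refit with one fewer cluster. Default 0.02.
#' @param seed Retained for interface stability; the fit itself is
#'   deterministic (quantile-initialized EM).
#' @return A list of class `CallingConfig`.
#' @export
callingConfig <- function(maxClusters = 5, mergeDeltaTheta = 0.15,
                          ngRMin = 0.2, assignMaxDistance = 4,
                          minClusterWeight = 0.02, seed = 17) {
  stopifnot(maxClusters >= 1, maxClusters <= 5, mergeDeltaTheta > 0,
            ngRMin > 0, assignMaxDistance > 0, minClusterWeight >= 0)
  structure(list(maxClusters = maxClusters,
                 mergeDeltaTheta = mergeDeltaTheta, ngRMin = ngRMin,
                 assignMaxDistance = assignMaxDistance,
                 minClusterWeight = minClusterWeight, seed = seed),
            class = "CallingConfig")
}

## sd floor keeps the likelihood finite on noise-free (replicated-value) data
.SD_FLOOR <- 1e-3

## EM for a 1-D Gaussian mixture, deterministic. Two fixed starts guard
## against the classic failure of a single initialization on very uneven
## class sizes: means equally spaced over the data range (robust when the
## clusters span the theta axis) and means at data quantiles (robust when
## they do not).
.emRun <- function(x, mu, s, w, maxit = 200, tol = 1e-7) {
  n <- length(x)
  k <- length(mu)
  ll_old <- -Inf
  ll <- ll_old
  for (it in seq_len(maxit)) {
    logd <- vapply(seq_len(k), function(j)
      log(w[j]) + stats::dnorm(x, mu[j], s[j], log = TRUE), numeric(n))
    dim(logd) <- c(n, k)
    m <- apply(logd, 1, max)
    p <- exp(logd - m)
    rs <- rowSums(p)
    ll <- sum(m + log(rs))
    r <- p / rs
    nk <- colSums(r)
    w <- pmax(nk / n, 1e-12)
    w <- w / sum(w)
    live <- nk > 1e-8
    mu[live] <- colSums(r * x)[live] / nk[live]
    s2 <- colSums(r * outer(x, mu, "-")^2)
    s[live] <- sqrt(s2[live] / nk[live])
    s <- pmax(s, .SD_FLOOR)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(k = as.integer(k), mean = mu[ord], sd = s[ord], weight = w[ord],
       loglik = ll)
}

.gmm1d <- function(x, k, maxit = 200, tol = 1e-7) {
  if (k == 1) {
    mu <- mean(x)
    s <- max(sqrt(mean((x - mu)^2)), .SD_FLOOR)
    return(list(k = 1L, mean = mu, sd = s, weight = 1,
                loglik = sum(stats::dnorm(x, mu, s, log = TRUE))))
  }
  s0 <- rep(max(stats::sd(x) / k, .SD_FLOOR), k)
  w0 <- rep(1 / k, k)
  starts <- list(
    seq(min(x), max(x), length.out = k),
    stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE))
  fits <- lapply(starts, function(mu0)
    .emRun(x, mu0, s0, w0, maxit = maxit, tol = tol))
  fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
}

.bic <- function(fit, n) -2 * fit$loglik + (3 * fit$k - 1) * log(n)

#' Fit theta clusters for one marker
#'
#' Fits 1-D Gaussian mixtures with 1..`maxClusters` components to the theta
#' values of samples with adequate signal (`normR >= ngRMin`), selects the
#' component count by minimum BIC, then removes components below
#' `minClusterWeight` (renormalizing the rest); samples of a removed
#' micro-cluster fall outside `assignMaxDistance` of the surviving
#' clusters and are called `--`.
#'
#' @param theta,normR Numeric vectors over samples for one marker.
#' @param config A [callingConfig()].
#' @return Per-marker model list with elements `k`, `mean`, `sd`, `weight`,
#'   `bic`, `nUsed`, `failed`, plus label fields added by
#'   [adjustClusters()]. Markers with fewer than two usable samples are
#'   returned with `failed = TRUE`.
#' @examples
#' th <- rep(c(0.05, 0.5, 0.95), each = 20)
#' fitThetaClusters(th, rep(1, 60))$k  # 3
#' @export
fitThetaClusters <- function(theta, normR, config = callingConfig()) {
  usable <- which(normR >= config$ngRMin & !is.na(theta))
  if (length(usable) < 2)
    return(list(failed = TRUE, k = 0L, nUsed = length(usable)))
  x <- theta[usable]
  fits <- lapply(seq_len(config$maxClusters), .gmm1d, x = x)
  bics <- vapply(fits, .bic, numeric(1), n = length(x))
  best <- fits[[which.min(bics)]]
  ## Components below the weight floor are untrustworthy micro-clusters:
  ## remove them outright (their samples end up off-cluster, "--") rather
  ## than refitting, which would smear their mass into a neighbour.
  while (best$k > 1 && any(best$weight < config$minClusterWeight)) {
    j <- which.min(best$weight)
    best$mean <- best$mean[-j]
    best$sd <- best$sd[-j]
    best$weight <- best$weight[-j] / sum(best$weight[-j])
    best$k <- best$k - 1L
  }
  c(best, list(bic = .bic(best, length(x)), nUsed = length(x),
               failed = FALSE, merged = FALSE))
}

## Order-preserving assignment of genotype labels to cluster means: choose
## the size-k increasing subset of anchor positions minimizing total
## |mean - anchor| (ties -> lexicographically first subset).
.pickAnchors <- function(anchors, means) {
  k <- length(means)
  cmb <- utils::combn(length(anchors), k)
  costs <- apply(cmb, 2, function(ix) sum(abs(means - anchors[ix])))
  names(anchors)[cmb[, which.min(costs)]]
}

.assignLabels <- function(means) {
  k <- length(means)
  tetAnchors <- c(AAAA = 0, AAAB = 0.25, AABB = 0.5, ABBB = 0.75, BBBB = 1)
  dipAnchors <- c(AA = 0, AB = 0.5, BB = 1)
  tet <- .pickAnchors(tetAnchors, means)
  dip <- if (k <= 3) .pickAnchors(dipAnchors, means)
         else unname(c(AAAA = "AA", AAAB = "AA", AABB = "AB",
                       ABBB = "BB", BBBB = "BB")[tet])
  list(tetraploid = tet, diploid = dip)
}

#' Adjust a fitted cluster model
#'
#' Polyploid cluster adjustment: adjacent components whose mean thetas are
#' closer than `mergeDeltaTheta` are merged (weighted mean and pooled
#' spread), iterating until no pair qualifies — the automated analogue of
#' manually collapsing AAAA/AAAB or ABBB/BBBB sub-clusters. Remaining
#' clusters are relabeled by theta rank: a single cluster takes the nearest
#' homozygous/heterozygous class; two clusters become \{AA, AB\},
#' \{AB, BB\} or \{AA, BB\} by proximity to 0, 0.5 and 1; three become
#' \{AA, AB, BB\}. Models still holding more than three clusters are
#' flagged `complex` (distinct tetraploid classes that cannot be
#' diploidized by merging).
#'
#' Idempotent: re-adjusting an adjusted model changes nothing.
#'
#' @param model A model from [fitThetaClusters()].
#' @param config A [callingConfig()].
#' @return The adjusted model with `tetraploid`/`diploid` labels, `merged`
#'   and `complex` flags.
#' @export
adjustClusters <- function(model, config = callingConfig()) {
  if (isTRUE(model$failed)) return(model)
  mu <- model$mean; s <- model$sd; w <- model$weight
  merged <- isTRUE(model$merged)
  while (length(mu) > 1) {
    gaps <- diff(mu)
    j <- which.min(gaps)
    if (gaps[j] >= config$mergeDeltaTheta) break
    wj <- w[j] + w[j + 1]
    m2 <- (w[j] * (s[j]^2 + mu[j]^2) + w[j + 1] * (s[j + 1]^2 + mu[j + 1]^2)) / wj
    mnew <- (w[j] * mu[j] + w[j + 1] * mu[j + 1]) / wj
    snew <- sqrt(max(m2 - mnew^2, .SD_FLOOR^2))
    mu <- c(mu[seq_len(j - 1)], mnew, mu[-seq_len(j + 1)])
    s <- c(s[seq_len(j - 1)], snew, s[-seq_len(j + 1)])
    w <- c(w[seq_len(j - 1)], wj, w[-seq_len(j + 1)])
    merged <- TRUE
  }
  model$mean <- mu; model$sd <- s; model$weight <- w
  model$k <- length(mu)
  model$merged <- merged
  model$complex <- model$k > 3
  labs <- .assignLabels(mu)
  model$tetraploid <- labs$tetraploid
  model$diploid <- labs$diploid
  model
}

#' Call genotypes for one marker
#'
#' Samples with `normR` below `ngRMin` at a working marker are `NG`;
#' samples whose standardized theta distance to the nearest cluster exceeds
#' `assignMaxDistance` are `--`; everything else takes the nearest
#' cluster's diploidized label. Failed markers are `--` for all samples.
#'
#' @param model An adjusted model from [adjustClusters()].
#' @param theta,normR Numeric vectors over samples.
#' @param config A [callingConfig()].
#' @return Character vector of calls.
#' @export
callGenotypes <- function(model, theta, normR, config = callingConfig()) {
  n <- length(theta)
  if (isTRUE(model$failed)) return(rep("--", n))
  z <- abs(outer(theta, model$mean, "-")) /
    rep(pmax(model$sd, .SD_FLOOR), each = n)
  nearest <- max.col(-z, ties.method = "first")
  out <- model$diploid[nearest]
  out[z[cbind(seq_len(n), nearest)] > config$assignMaxDistance] <- "--"
  out[normR < config$ngRMin] <- "NG"
  out[is.na(theta)] <- "--"
  out
}

#' Classify the cluster pattern of a locus
#'
#' Maps a called locus onto the recurring cluster-graph taxonomy of
#' polyploid array data: `failed` (no sample called), `polyploid_adjusted`
#' (cluster merging occurred or >3 clusters remain), `partial_ng` (some
#' samples without signal), `monomorphic` (one cluster), `two_cluster`,
#' `three_cluster`. The listed order is the precedence used when several
#' predicates hold.
#'
#' @param model An adjusted model.
#' @param calls The calls for this marker.
#' @return A single pattern string.
#' @export
classifyLocusPattern <- function(model, calls) {
  if (isTRUE(model$failed) || all(calls == "--")) return("failed")
  if (isTRUE(model$merged) || isTRUE(model$complex))
    return("polyploid_adjusted")
  if (any(calls == "NG")) return("partial_ng")
  switch(as.character(model$k),
         "1" = "monomorphic",
         "2" = "two_cluster",
         "3" = "three_cluster",
         "polyploid_adjusted")
}

#' Call a full intensity matrix
#'
#' Fits, adjusts and calls every marker of an [IntensityExperiment-class],
#' returning a [GenotypeExperiment-class] whose `rowData` records the
#' cluster count, pattern class, merge flag and per-marker call rate, with
#' the full [ClusterModelSet-class] in `metadata(x)$clusterModels`.
#'
#' @param intensities An [IntensityExperiment-class].
#' @param config A [callingConfig()].
#' @return A [GenotypeExperiment-class].
#' @export
callGenotypeMatrix <- function(intensities, config = callingConfig()) {
  th <- thetaMatrix(intensities)
  nr <- normRMatrix(intensities)
  m <- nrow(th)
  callMat <- matrix("--", m, ncol(th), dimnames = dimnames(th))
  models <- vector("list", m)
  pattern <- character(m)
  for (i in seq_len(m)) {
    fit <- fitThetaClusters(th[i, ], nr[i, ], config)
    fit <- adjustClusters(fit, config)
    cl <- callGenotypes(fit, th[i, ], nr[i, ], config)
    callMat[i, ] <- cl
    pattern[i] <- classifyLocusPattern(fit, cl)
    models[[i]] <- fit
  }
  names(models) <- rownames(th)
  gt <- GenotypeExperiment(callMat,
                           rowData = S4Vectors::DataFrame(
                             rowData(intensities),
                             k = vapply(models, function(m) m$k, integer(1)),
                             pattern = pattern,
                             merged = vapply(models,
                                             function(m) isTRUE(m$merged),
                                             logical(1)),
                             callRate = .callRate(callMat, "marker")),
                           colData = colData(intensities))
  mset <- new("ClusterModelSet", models = models,
              config = unclass(config))
  S4Vectors::metadata(gt)$clusterModels <- mset
  gt
}
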