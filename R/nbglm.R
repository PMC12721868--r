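## Negative-binomial GLM machinery for the disome-enrichment interaction
## test: log-link IRLS at fixed dispersion, Cox-Reid adjusted profile
## likelihood for gene-wise dispersion, a parametric mean-dispersion trend
## and log-normal shrinkage toward it.

## IRLS fit of an NB GLM with log link, fixed dispersion alpha and
## log-size-factor offsets.  Returns coefficients, fitted means, the
## log-likelihood and the Cox-Reid term.
nbFit <- function(y, X, sf, alpha, maxit = 50L, tol = 1e-10) {
  off <- log(sf)
  mu <- pmax(y, 0.5)
  beta <- qr.solve(X, log(mu) - off)
  dev0 <- Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + off
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    W <- mu / (1 + alpha * mu)
    z <- eta - off + (y - mu) / mu
    XtW <- t(X * W)
    beta.new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) beta)
    beta.new <- drop(beta.new)
    dev <- -2 * sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
    if (abs(dev - dev0) < tol * (abs(dev) + 0.1) &&
        max(abs(beta.new - beta)) < 1e-8) { beta <- beta.new; break }
    beta <- beta.new
    dev0 <- dev
  }
  eta <- drop(X %*% beta) + off
  mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
  W <- mu / (1 + alpha * mu)
  ll <- sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  crm <- t(X * W) %*% X
  cr <- -0.5 * determinant(crm, logarithm = TRUE)$modulus
  list(beta = beta, mu = mu, ll = ll, cr = as.numeric(cr))
}

## Cox-Reid adjusted profile log-likelihood of log-dispersion.
aplFun <- function(logAlpha, y, X, sf) {
  f <- nbFit(y, X, sf, exp(logAlpha))
  f$ll + f$cr
}

## Gene-wise dispersion by maximising the CR-adjusted profile likelihood.
estimateDispersionGene <- function(y, X, sf,
                                   interval = log(c(1e-8, 30))) {
  opt <- optimize(aplFun, interval = interval, y = y, X = X, sf = sf,
                  maximum = TRUE, tol = 1e-2)
  exp(opt$maximum)
}

## Parametric mean-dispersion trend alpha(mu) = a0 + a1/mu, fitted as an
## iterated gamma GLM with identity link on the mean scale (gene-wise
## profile estimates are roughly mean-unbiased but strongly right-skewed,
## so a log-scale fit would bias the trend low); extreme-ratio outliers
## are dropped between iterations.
fitDispersionTrend <- function(alpha, baseMean) {
  use <- is.finite(alpha) & alpha > 1e-7 & baseMean > 1
  fallback <- c(a0 = max(mean(alpha[use]), 1e-6), a1 = 0)
  if (sum(use) < 10L) return(fallback)
  a <- alpha[use]; m <- baseMean[use]
  coefs <- c(fallback[["a0"]], 0)
  for (it in 1:4) {
    fit <- tryCatch(
      glm(a ~ I(1 / m), family = Gamma(link = "identity"),
          start = pmax(coefs, c(1e-6, 0))),
      error = function(e) NULL)
    if (is.null(fit)) return(fallback)
    newCoefs <- pmax(coef(fit), c(1e-8, 0))
    pred <- newCoefs[1] + newCoefs[2] / m
    ratio <- a / pred
    keep <- ratio > 1e-4 & ratio < 15
    if (all(keep) || sum(keep) < 10L ||
        max(abs(newCoefs - coefs) / pmax(coefs, 1e-8)) < 1e-4) {
      coefs <- newCoefs
      break
    }
    a <- a[keep]; m <- m[keep]
    coefs <- newCoefs
  }
  c(a0 = unname(coefs[1]), a1 = unname(coefs[2]))
}

#' Disome-enrichment interaction test
#'
#' Per-gene likelihood-ratio test of the fraction x genotype interaction
#' on a negative-binomial GLM: full model
#' \code{~ fraction + genotype + fraction:genotype} against the reduced
#' \code{~ fraction + genotype}, with median-of-ratios library-size
#' normalisation and gene-wise Cox-Reid dispersion estimates shrunk toward
#' a parametric mean-dispersion trend (a deliberate simplification of the
#' empirical-Bayes machinery of dedicated DE packages).  The monosome
#' fraction and the first genotype of \code{conditionPair} are the
#' reference levels, so a positive interaction log2 fold change means
#' disome enrichment in the second genotype.  P-values are BH-adjusted.
#'
#' @param se \code{SummarizedExperiment} with assay \code{counts} and
#'   colData columns \code{genotype}, \code{fraction}, \code{replicate}.
#' @param conditionPair c(reference genotype, treatment genotype).
#' @param priorDf weight (in pseudo-genes) of the trend in the dispersion
#'   shrinkage.
#' @return data.frame(gene, baseMean, lfc, stat, pvalue, padj); genes with
#'   all-zero counts are excluded.
#' @export
interactionDE <- function(se, conditionPair, priorDf = 10) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  keep <- cd$genotype %in% conditionPair
  if (!any(keep)) stop("conditionPair not found in colData genotype")
  counts <- SummarizedExperiment::assay(se, "counts")[, keep, drop = FALSE]
  cd <- cd[keep, , drop = FALSE]
  if (length(unique(cd$fraction)) != 2L)
    stop("both fractions are required")
  frac <- as.integer(cd$fraction != "monosome")
  geno <- as.integer(cd$genotype == conditionPair[2])
  X <- cbind(1, frac, geno, frac * geno)
  Xr <- X[, 1:3, drop = FALSE]

  nz <- rowSums(counts) > 0
  counts <- counts[nz, , drop = FALSE]

  ## median-of-ratios size factors
  logGeo <- rowMeans(log(counts))
  usable <- is.finite(logGeo)
  sf <- apply(counts[usable, , drop = FALSE], 2L, function(col)
    exp(median(log(col[col > 0]) - logGeo[usable][col > 0])))
  sf <- sf / exp(mean(log(sf)))

  baseMean <- rowMeans(sweep(counts, 2L, sf, "/"))
  n <- nrow(counts)
  alphaGene <- numeric(n)
  for (i in seq_len(n))
    alphaGene[i] <- estimateDispersionGene(counts[i, ], X, sf)

  trend <- fitDispersionTrend(alphaGene, baseMean)
  alphaTrend <- trend["a0"] + trend["a1"] / baseMean
  ## MAP dispersion: CR-adjusted profile likelihood plus a log-normal
  ## prior centred on the trend; prior width = spread of log residuals
  ## beyond the sampling noise expected at the model's residual df
  logRes <- log(pmax(alphaGene, 1e-8)) - log(alphaTrend)
  m <- ncol(counts); pcol <- ncol(X)
  sampVar <- trigamma((m - pcol) / 2)
  priorVar <- max(mad(logRes[is.finite(logRes)])^2 - sampVar, 0.25)
  priorSd <- sqrt(priorVar)
  alphaMap <- numeric(n)
  for (i in seq_len(n)) {
    post <- function(la)
      aplFun(la, counts[i, ], X, sf) +
        dnorm(la, mean = log(alphaTrend[i]), sd = priorSd, log = TRUE)
    opt <- optimize(post, interval = log(c(1e-8, 30)), maximum = TRUE,
                    tol = 1e-2)
    alphaMap[i] <- exp(opt$maximum)
  }
  ## dispersion outliers (far above the trend) keep their gene-wise value
  outlier <- is.finite(logRes) & logRes > 2 * sqrt(priorVar + sampVar)
  alphaMap[outlier] <- alphaGene[outlier]

  lfc <- stat <- pval <- numeric(n)
  for (i in seq_len(n)) {
    a <- alphaMap[i]
    ff <- nbFit(counts[i, ], X, sf, a)
    fr <- nbFit(counts[i, ], Xr, sf, a)
    stat[i] <- max(2 * (ff$ll - fr$ll), 0)
    lfc[i] <- ff$beta[4] / log(2)
    pval[i] <- pchisq(stat[i], df = 1L, lower.tail = FALSE)
  }
  data.frame(gene = rownames(counts), baseMean = baseMean,
             lfc = lfc, stat = stat, pvalue = pval,
             padj = p.adjust(pval, method = "BH"),
             dispersion = alphaMap, row.names = NULL,
             stringsAsFactors = FALSE)
}
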