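#' Default sympatric pair specification
#'
#' One pair per lake and non-planktivorous ecotype, oriented from the
#' planktivorous ecotype (the shared reference) to the other ecotype, so
#' divergence vectors are comparable across lakes.
#'
#' @param samples data.frame with lake and ecotype columns.
#' @return data.frame with columns lake, ecoFrom, ecoTo.
#' @export
defaultPairSpec <- function(samples) {
  out <- do.call(rbind, lapply(unique(samples$lake), function(lk) {
    ecos <- unique(samples$ecotype[samples$lake == lk])
    ref <- if ("planktivorous" %in% ecos) "planktivorous" else sort(ecos)[1]
    data.frame(lake = lk, ecoFrom = ref, ecoTo = setdiff(ecos, ref),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.angleDeg <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Compute divergence trajectories for sympatric ecotype pairs
#'
#' For each pair, the trajectory is the vector from the centroid of the
#' reference ecotype to the centroid of the derived ecotype in the supplied
#' score space. Returns lengths L per pair and the full matrices of pairwise
#' angles theta (degrees) and length differences |L_i - L_j|. When `scores`
#' is a [PcaResult-class], only its leading `k50` components (cumulative
#' explained variance > 50%) are used.
#'
#' @param scores matrix (rows = individuals) or [PcaResult-class].
#' @param samples data.frame aligned with score rows: lake, lineage, ecotype.
#' @param pairSpec data.frame(lake, ecoFrom, ecoTo); default
#'   [defaultPairSpec()].
#' @return A [TrajectorySet-class]. Pairs with identical centroids get NA
#'   angles with a warning.
#' @export
computeTrajectories <- function(scores, samples, pairSpec = NULL) {
  if (is(scores, "PcaResult"))
    scores <- pcaScores(scores)[, seq_len(k50(scores)), drop = FALSE]
  scores <- as.matrix(scores)
  if (is.null(pairSpec)) pairSpec <- defaultPairSpec(samples)
  nP <- nrow(pairSpec)
  d <- ncol(scores)
  vec <- matrix(NA_real_, nP, d)
  L <- numeric(nP)
  lin <- character(nP)
  for (i in seq_len(nP)) {
    selF <- samples$lake == pairSpec$lake[i] &
      samples$ecotype == pairSpec$ecoFrom[i]
    selT <- samples$lake == pairSpec$lake[i] &
      samples$ecotype == pairSpec$ecoTo[i]
    if (sum(selF) < 2 || sum(selT) < 2)
      stop("pair ", i, ": need >= 2 individuals per ecotype")
    vec[i, ] <- colMeans(scores[selT, , drop = FALSE]) -
      colMeans(scores[selF, , drop = FALSE])
    L[i] <- sqrt(sum(vec[i, ]^2))
    lin[i] <- as.character(samples$lineage[selF][1])
  }
  if (any(L == 0))
    warning("pair(s) with identical centroids: angle undefined, set NA")
  pairs <- data.frame(pair = paste0(pairSpec$lake, ":", pairSpec$ecoTo),
                      lake = pairSpec$lake, lineage = lin,
                      ecoFrom = pairSpec$ecoFrom, ecoTo = pairSpec$ecoTo,
                      type = paste(pairSpec$ecoFrom, pairSpec$ecoTo,
                                   sep = "-"),
                      stringsAsFactors = FALSE)
  theta <- matrix(0, nP, nP, dimnames = list(pairs$pair, pairs$pair))
  for (i in seq_len(nP)) for (j in seq_len(nP)) if (i != j)
    theta[i, j] <- .angleDeg(vec[i, ], vec[j, ])
  dL <- abs(outer(L, L, "-"))
  dimnames(dL) <- dimnames(theta)
  rep <- outer(pairs$type, pairs$type, "==")
  diag(rep) <- NA
  dimnames(rep) <- dimnames(theta)
  empty <- matrix(NA_real_, nP, nP, dimnames = dimnames(theta))
  rownames(vec) <- pairs$pair
  names(L) <- pairs$pair
  new("TrajectorySet", pairs = pairs, vectors = vec, L = L, theta = theta,
      dL = dL, pTheta = empty, pDL = empty, replicated = rep, nPerm = 0L)
}

#' Permutation test of trajectory angle and length differences
#'
#' For every pair-of-pairs, builds a null by residual randomization: the
#' residuals of the full group-centroid model are permuted across all
#' individuals of the two pairs and added back onto the fitted values of
#' the reduced model containing only pair locations; group centroids are
#' recomputed and theta and dL re-derived. The null therefore removes all
#' ecotype-divergence structure while preserving pair location and the
#' residual spread, so permuted divergence vectors have random directions
#' and noise-scale lengths. Permutations with an undefined angle
#' (zero-length vectors, possible only in degenerate noise-free data) are
#' counted as extreme, which makes the degenerate case conservatively
#' non-significant. The p-value is
#' `(1 + count(stat_perm >= stat_obs)) / (nPerm + 1)`. A comparison is
#' labelled parallel when both p-values exceed 0.05.
#'
#' @param trajset a [TrajectorySet-class] from [computeTrajectories()].
#' @param scores,samples the inputs used to build it.
#' @param nPerm number of permutations (>= 99).
#' @param seed integer seed; required for reproducibility.
#' @return The trajectory set with `pTheta` and `pDL` filled.
#' @export
trajectoryPermutationTest <- function(trajset, scores, samples,
                                      nPerm = 1000, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  if (nPerm < 99) stop("nPerm must be >= 99")
  if (is(scores, "PcaResult"))
    scores <- pcaScores(scores)[, seq_len(k50(scores)), drop = FALSE]
  scores <- as.matrix(scores)
  set.seed(as.integer(seed))
  pr <- trajset@pairs
  nP <- nrow(pr)
  idx <- lapply(seq_len(nP), function(i) list(
    from = which(samples$lake == pr$lake[i] &
                   samples$ecotype == pr$ecoFrom[i]),
    to = which(samples$lake == pr$lake[i] & samples$ecotype == pr$ecoTo[i])))
  pTheta <- pDL <- matrix(NA_real_, nP, nP,
                          dimnames = dimnames(trajset@theta))
  for (i in seq_len(nP - 1)) for (j in (i + 1):nP) {
    rows <- c(idx[[i]]$from, idx[[i]]$to, idx[[j]]$from, idx[[j]]$to)
    pairId <- factor(rep(c("i", "i", "j", "j"),
                         c(length(idx[[i]]$from), length(idx[[i]]$to),
                           length(idx[[j]]$from), length(idx[[j]]$to))))
    role <- factor(rep(c("from", "to", "from", "to"),
                       c(length(idx[[i]]$from), length(idx[[i]]$to),
                         length(idx[[j]]$from), length(idx[[j]]$to))))
    Y <- scores[rows, , drop = FALSE]
    X <- model.matrix(~ pairId)
    fitRed <- X %*% qr.coef(qr(X), Y)
    grp <- interaction(pairId, role)
    centroids <- rowsum(Y, grp) / as.vector(table(grp))
    res <- Y - centroids[as.character(grp), , drop = FALSE]
    stat <- function(Yp) {
      cen <- rowsum(Yp, grp) / as.vector(table(grp))
      vi <- cen["i.to", ] - cen["i.from", ]
      vj <- cen["j.to", ] - cen["j.from", ]
      c(.angleDeg(vi, vj),
        abs(sqrt(sum(vi^2)) - sqrt(sum(vj^2))))
    }
    obs <- c(trajset@theta[i, j], trajset@dL[i, j])
    geT <- geL <- 0L
    m <- nrow(Y)
    for (p in seq_len(nPerm)) {
      st <- stat(fitRed + res[sample.int(m), , drop = FALSE])
      # undefined permuted angle (degenerate zero-length vectors) counts
      # as extreme
      if (!is.na(obs[1]) && (is.na(st[1]) || st[1] >= obs[1]))
        geT <- geT + 1L
      if (is.na(st[2]) || st[2] >= obs[2]) geL <- geL + 1L
    }
    pTheta[i, j] <- pTheta[j, i] <-
      if (is.na(obs[1])) NA_real_ else (1 + geT) / (nPerm + 1)
    pDL[i, j] <- pDL[j, i] <- (1 + geL) / (nPerm + 1)
  }
  trajset@pTheta <- pTheta
  trajset@pDL <- pDL
  trajset@nPerm <- as.integer(nPerm)
  trajset
}

#' Contrast angles between replicated and non-replicated comparisons
#'
#' Replicated comparisons contrast two pairs of the same ecotype combination
#' (e.g. two benthivorous-planktivorous pairs from different lakes);
#' non-replicated comparisons mix combinations. Reports group means and
#' standard deviations of the pairwise angles and a two-sided Wilcoxon
#' rank-sum test.
#'
#' @param trajset a [TrajectorySet-class].
#' @return list: `meanReplicated`, `meanNonReplicated`, `sdReplicated`,
#'   `sdNonReplicated`, `difference` (non-replicated minus replicated),
#'   `p` (Wilcoxon), `nReplicated`, `nNonReplicated`.
#' @export
groupContrast <- function(trajset) {
  ut <- upper.tri(trajset@theta)
  th <- trajset@theta[ut]
  rp <- trajset@replicated[ut]
  a <- th[rp %in% TRUE]
  b <- th[rp %in% FALSE]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need >= 2 comparisons in each group")
  p <- if (all(c(a, b) == c(a, b)[1])) 1 else
    suppressWarnings(wilcox.test(a, b)$p.value)
  list(meanReplicated = mean(a), meanNonReplicated = mean(b),
       sdReplicated = sd(a), sdNonReplicated = sd(b),
       difference = mean(b) - mean(a), p = p,
       nReplicated = length(a), nNonReplicated = length(b))
}
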