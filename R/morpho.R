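#' Allometric size correction of linear traits
#'
#' Removes the allometric dependence of each trait on body size using
#' `log10 Y = log10 M + b (log10 Lm - log10 L)`, where M is the measured
#' value, L the individual's fork length and Lm the mean fork length of all
#' fish within the individual's lineage. The common slope b is estimated per
#' trait and lineage by ANCOVA of log10 M on log10 L with population (lake)
#' and ecotype as additive covariates.
#'
#' @param traits matrix individuals x traits of measured values (mm), > 0.
#' @param forkLength individual fork lengths (mm), > 0.
#' @param lake,ecotype,lineage factors/character per individual.
#' @return A [CorrectedTraits-class]; `correctedTraits()` returns Y on the
#'   original mm scale. Non-positive measurements are set to NA with a
#'   warning; groups (lake x ecotype) with fewer than 3 individuals are an
#'   error.
#' @examples
#' b <- simulateStudy(synthConfig(nSnps = 10, nGenes = 10, seed = 1))
#' s <- studySamples(b)
#' ct <- sizeCorrectTraits(traitMatrix(b), s$forkLength, s$lake, s$ecotype,
#'                         s$lineage)
#' head(correctedTraits(ct))
#' @export
sizeCorrectTraits <- function(traits, forkLength, lake, ecotype, lineage) {
  traits <- as.matrix(traits)
  if (is.null(colnames(traits)))
    colnames(traits) <- paste0("T", seq_len(ncol(traits)))
  bad <- !is.na(traits) & traits <= 0
  nDropped <- sum(bad)
  if (nDropped > 0) {
    warning(nDropped, " non-positive trait measurement(s) set to missing")
    traits[bad] <- NA
  }
  if (any(forkLength <= 0, na.rm = TRUE))
    stop("fork lengths must be positive")
  grp <- interaction(lake, ecotype, drop = TRUE)
  if (any(table(grp) < 3))
    stop("each lake x ecotype group needs at least 3 individuals")

  lineage <- as.character(lineage)
  lins <- unique(lineage)
  Lm <- vapply(lins, function(li) mean(forkLength[lineage == li]), 0)
  b <- matrix(NA_real_, length(lins), ncol(traits),
              dimnames = list(lins, colnames(traits)))
  Y <- traits
  logL <- log10(forkLength)
  for (li in lins) {
    sel <- lineage == li
    df <- data.frame(logL = logL[sel], lake = factor(lake[sel]),
                     ecotype = factor(ecotype[sel]))
    for (j in seq_len(ncol(traits))) {
      df$logM <- log10(traits[sel, j])
      form <- if (nlevels(df$lake) > 1 && nlevels(df$ecotype) > 1)
        logM ~ logL + lake + ecotype
      else if (nlevels(df$lake) > 1) logM ~ logL + lake
      else if (nlevels(df$ecotype) > 1) logM ~ logL + ecotype
      else logM ~ logL
      fit <- lm(form, data = df, na.action = na.omit)
      bj <- coef(fit)[["logL"]]
      if (is.na(bj)) {
        # no size variation to regress on: any slope leaves Y = M when
        # L = Lm; use 0 so the correction is the identity
        bj <- 0
      }
      b[li, j] <- bj
      Y[sel, j] <- 10^(log10(traits[sel, j]) +
                         b[li, j] * (log10(Lm[li]) - logL[sel]))
    }
  }
  new("CorrectedTraits", Y = Y, M = traits, L = as.numeric(forkLength),
      b = b, Lm = Lm, dropped = as.integer(nDropped))
}

#' Principal component analysis with a fixed sign convention
#'
#' Wraps the standard spectral decomposition; each component's sign is fixed
#' by making its largest-magnitude loading positive, so results are
#' deterministic across platforms. Missing cells are column-mean imputed
#' when `impute = TRUE` (with a message giving the count), otherwise an
#' error.
#'
#' @param x numeric matrix, rows = observations.
#' @param center,scale passed to the decomposition. With `scale = TRUE` a
#'   constant column is an error naming the column.
#' @param impute mean-impute missing cells first.
#' @return A [PcaResult-class]; `k50()` gives the smallest number of leading
#'   components whose cumulative explained variance exceeds 50%.
#' @export
runPca <- function(x, center = TRUE, scale = FALSE, impute = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 rows and 2 columns")
  nImp <- 0L
  if (anyNA(x)) {
    if (!impute) stop("missing values present; set impute = TRUE")
    nImp <- sum(is.na(x))
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
    }
    message(nImp, " missing cell(s) mean-imputed before PCA")
  }
  if (scale) {
    sds <- apply(x, 2, sd)
    if (any(sds == 0))
      stop("constant column(s) with scale = TRUE: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
  }
  pc <- prcomp(x, center = center, scale. = scale)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2
  expl <- ev / sum(ev)
  k <- as.integer(which(cumsum(expl) > 0.5)[1])
  new("PcaResult", scores = pc$x, loadings = pc$rotation, explained = expl,
      k50 = max(1L, k),
      center = if (isTRUE(center)) pc$center else rep(0, ncol(x)),
      scale = if (isTRUE(scale)) pc$scale else rep(1, ncol(x)),
      imputed = nImp)
}

# Refit dropping aliased terms until the model is full rank; returns the fit
# and the labels of dropped terms.
.fitDroppingAliased <- function(formula, data) {
  dropped <- character()
  repeat {
    fit <- lm(formula, data = data)
    cf <- coef(fit)
    if (!anyNA(cf)) return(list(fit = fit, dropped = dropped))
    asgn <- attr(model.matrix(fit), "assign")
    labs <- attr(terms(fit), "term.labels")
    badTerms <- unique(labs[asgn[is.na(cf)][asgn[is.na(cf)] > 0]])
    if (!length(badTerms)) return(list(fit = fit, dropped = dropped))
    dropped <- c(dropped, badTerms)
    formula <- stats::update.formula(
      formula, paste("~ . -", paste(badTerms, collapse = " - ")))
  }
}

# Type-II sums of squares by residual-sum-of-squares comparisons: for each
# term T, SS_T = RSS(all terms not containing T) - RSS(those terms plus T).
.typeIISS <- function(termLabels, data) {
  rss <- function(labs) {
    f <- if (length(labs))
      stats::reformulate(labs, response = "y") else y ~ 1
    sum(stats::residuals(lm(f, data = data))^2)
  }
  contains <- function(big, small) {
    all(strsplit(small, ":")[[1]] %in% strsplit(big, ":")[[1]])
  }
  rk <- function(labs) {
    f <- if (length(labs))
      stats::reformulate(labs, response = "y") else y ~ 1
    qr(model.matrix(f, data = data))$rank
  }
  full <- rss(termLabels)
  out <- dfT <- setNames(numeric(length(termLabels)), termLabels)
  for (tm in termLabels) {
    base <- termLabels[!vapply(termLabels, contains, TRUE, small = tm)]
    out[tm] <- max(0, rss(base) - rss(c(base, tm)))
    dfT[tm] <- rk(c(base, tm)) - rk(base)
  }
  list(ss = out, ssRes = full, dfTerm = dfT,
       dfRes = nrow(data) - rk(termLabels))
}

#' Partition trait variance into parallel and non-parallel components
#'
#' Fits `response ~ ecotype + lake + lineage + ecotype:lake +
#' ecotype:lineage` and reports the partial eta-squared effect size
#' `SS_term / (SS_term + SS_residual)` for every estimable term, using
#' Type-II sums of squares. The ecotype term captures parallel divergence;
#' the interactions capture lake- and lineage-specific (non-parallel)
#' divergence. The response is labelled "parallel-dominant" when the ecotype
#' effect size exceeds both interaction effect sizes.
#'
#' Terms fully aliased by the design (e.g. lineage when lakes are nested in
#' lineages) are dropped with a message and reported as NA.
#'
#' @param response numeric vector (one trait or one PC score column).
#' @param samples data.frame with columns ecotype, lake, lineage.
#' @return list with `eta2` (named vector over the five terms), `p` (term
#'   p-values), `dropped` (aliased terms) and `parallelDominant` (logical).
#' @export
traitAnovaEta2 <- function(response, samples) {
  df <- data.frame(y = as.numeric(response),
                   ecotype = factor(samples$ecotype),
                   lake = factor(samples$lake),
                   lineage = factor(samples$lineage))
  if (nlevels(df$ecotype) < 2 || nlevels(df$lake) < 2)
    stop("need at least 2 ecotypes and 2 lakes")
  termNames <- c("ecotype", "lake", "lineage", "ecotype:lake",
                 "ecotype:lineage")
  form <- y ~ ecotype + lake + lineage + ecotype:lake + ecotype:lineage
  if (nlevels(df$lineage) < 2)
    form <- y ~ ecotype + lake + ecotype:lake
  ft <- .fitDroppingAliased(form, df)
  if (length(ft$dropped))
    message("aliased term(s) dropped: ", paste(ft$dropped, collapse = ", "))
  labs <- attr(terms(ft$fit), "term.labels")
  t2 <- .typeIISS(labs, df)
  # sums of squares below numerical noise (relative to the total) are zero
  eps <- 1e-12 * sum((df$y - mean(df$y))^2)
  t2$ss[t2$ss < eps] <- 0
  if (t2$ssRes < eps) t2$ssRes <- 0
  eta2 <- p <- setNames(rep(NA_real_, length(termNames)), termNames)
  for (tn in labs) {
    den <- t2$ss[tn] + t2$ssRes
    eta2[tn] <- if (den > 0) t2$ss[tn] / den else 0
    dfT <- t2$dfTerm[tn]
    if (t2$ssRes > 0 && t2$dfRes > 0 && dfT > 0) {
      Fv <- (t2$ss[tn] / dfT) / (t2$ssRes / t2$dfRes)
      p[tn] <- pf(Fv, dfT, t2$dfRes, lower.tail = FALSE)
    }
  }
  eEco <- eta2["ecotype"]
  inter <- eta2[c("ecotype:lake", "ecotype:lineage")]
  inter <- inter[!is.na(inter)]
  pd <- !is.na(eEco) && (length(inter) == 0 || all(eEco > inter))
  list(eta2 = eta2, p = p,
       dropped = c(ft$dropped,
                   if (nlevels(df$lineage) < 2) c("lineage", "ecotype:lineage")),
       parallelDominant = pd)
}
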