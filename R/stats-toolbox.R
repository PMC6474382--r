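# Memory-performance scoring and the statistics toolbox: paired tests,
# BH-FDR channel topography, Greenhouse-Geisser repeated-measures ANOVA,
# and exact noncentral-t power / sample-size computation.

#' Memory performance change relative to baseline
#'
#' Expresses each recall test as a percentage of the participant's own
#' baseline recall (100 * test / baseline), per condition. The group
#' value is the mean of per-participant ratios (not the ratio of group
#' means). Participants with a zero baseline are excluded and reported
#' in the \code{"excluded"} attribute.
#'
#' @param scores data.frame with columns \code{participant},
#'   \code{condition}, \code{test}, \code{percent}; \code{test} must
#'   include \code{baselineTest}.
#' @param baselineTest name of the baseline test level.
#' @return List with \code{perParticipant} (participant, condition,
#'   test, change) and \code{group} (condition, test, mean change);
#'   attribute \code{"excluded"} on \code{perParticipant}.
#' @export
performanceChange <- function(scores, baselineTest = "baseline") {
  stopifnot(all(c("participant", "condition", "test", "percent") %in%
                  names(scores)))
  base <- scores[scores$test == baselineTest, ]
  key <- paste(scores$participant, scores$condition)
  bkey <- paste(base$participant, base$condition)
  bval <- stats::setNames(base$percent, bkey)[key]
  excluded <- unique(scores$participant[!is.na(bval) & bval == 0])
  ok <- !is.na(bval) & bval > 0 & scores$test != baselineTest
  per <- data.frame(participant = scores$participant[ok],
                    condition = scores$condition[ok],
                    test = scores$test[ok],
                    change = 100 * scores$percent[ok] / bval[ok])
  attr(per, "excluded") <- excluded
  grp <- stats::aggregate(change ~ condition + test, data = per, FUN = mean)
  list(perParticipant = per, group = grp)
}

#' Paired-sample Cohen's d
#'
#' Mean of the paired differences divided by their standard deviation.
#'
#' @param x,y paired numeric vectors (or \code{y = NULL} and \code{x}
#'   the differences).
#' @return Scalar d (0 when all differences are zero).
#' @export
cohensDPaired <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  s <- stats::sd(d)
  if (s == 0) return(0)
  mean(d) / s
}

#' Per-channel paired test with BH-FDR correction
#'
#' Paired-samples t-test at every channel followed by Benjamini-Hochberg
#' step-up control of the false discovery rate across channels at level
#' \code{alpha}. Channels with zero-variance differences get NA p-values
#' and are never declared significant.
#'
#' @param active,sham numeric matrices, participants x channels, same
#'   dimnames.
#' @param alpha FDR level.
#' @return data.frame: \code{channel}, \code{t}, \code{p}, \code{p_adj}
#'   (BH-adjusted), \code{significant}.
#' @export
channelTopographyTest <- function(active, sham, alpha = 0.05) {
  stopifnot(all(dim(active) == dim(sham)), nrow(active) >= 3L)
  channels <- colnames(active)
  res <- lapply(seq_len(ncol(active)), function(j) {
    # zero-variance differences (numerically constant) are flagged NA
    tryCatch({
      tt <- stats::t.test(active[, j], sham[, j], paired = TRUE)
      c(t = unname(tt$statistic), p = tt$p.value)
    }, error = function(e) c(t = NA_real_, p = NA_real_))
  })
  res <- do.call(rbind, res)
  padj <- stats::p.adjust(res[, "p"], method = "BH")
  data.frame(channel = channels, t = res[, "t"], p = res[, "p"],
             p_adj = padj,
             significant = !is.na(padj) & padj <= alpha)
}

orthonormalContrasts <- function(k) {
  C <- stats::contr.helmert(k)
  apply(C, 2, function(v) v / sqrt(sum(v^2)))
}

ggEpsilon <- function(M) {
  # M: subject x contrast scores for one within effect
  S <- stats::cov(M)
  d <- ncol(M)
  if (d == 1L) return(1)
  sum(diag(S))^2 / (d * sum(S^2))
}

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subjects two-factor ANOVA from long-format data. For each
#' effect (both main effects and the interaction) reports the F ratio on
#' uncorrected degrees of freedom, the Greenhouse-Geisser epsilon
#' computed from the covariance of orthonormal within-factor contrast
#' scores, the epsilon-corrected p-value, and partial eta-squared
#' (SS_effect / (SS_effect + SS_error)). Two-level factors have epsilon
#' exactly 1, so the corrected p equals the uncorrected one.
#'
#' @param data long-format data.frame.
#' @param dv name of the value column.
#' @param subject name of the participant column.
#' @param factors names of the two within-subject factor columns.
#' @return data.frame: \code{effect}, \code{F}, \code{df1}, \code{df2},
#'   \code{epsilon}, \code{p_uncorrected}, \code{p_gg}, \code{pes}.
#' @export
rmAnovaGG <- function(data, dv = "value", subject = "participant",
                      factors = c("A", "B")) {
  stopifnot(length(factors) == 2L,
            all(c(dv, subject, factors) %in% names(data)))
  sid <- factor(data[[subject]])
  fa <- factor(data[[factors[1]]])
  fb <- factor(data[[factors[2]]])
  y <- data[[dv]]
  s <- nlevels(sid); a <- nlevels(fa); b <- nlevels(fb)
  if (nrow(data) != s * a * b ||
      any(table(sid, fa, fb) != 1L))
    stop("design must be complete and balanced (one value per cell)")

  # subject x (a*b) cell matrix, cells ordered B within A
  Y <- array(NA_real_, c(s, a, b))
  Y[cbind(as.integer(sid), as.integer(fa), as.integer(fb))] <- y
  grand <- mean(Y)
  mS <- apply(Y, 1, mean); mA <- apply(Y, 2, mean)
  mB <- apply(Y, 3, mean)
  mSA <- apply(Y, c(1, 2), mean); mSB <- apply(Y, c(1, 3), mean)
  mAB <- apply(Y, c(2, 3), mean)

  ssA <- s * b * sum((mA - grand)^2)
  ssB <- s * a * sum((mB - grand)^2)
  ssAB <- s * sum((mAB - outer(mA, rep(1, b)) -
                     outer(rep(1, a), mB) + grand)^2)
  ssSA <- b * sum((mSA - outer(mS, rep(1, a)) -
                     outer(rep(1, s), mA) + grand)^2)
  ssSB <- a * sum((mSB - outer(mS, rep(1, b)) -
                     outer(rep(1, s), mB) + grand)^2)
  fit <- array(0, c(s, a, b))
  for (i in seq_len(s)) for (j in seq_len(a)) for (k in seq_len(b))
    fit[i, j, k] <- mSA[i, j] + mSB[i, k] + mAB[j, k] -
      mS[i] - mA[j] - mB[k] + grand
  ssSAB <- sum((Y - fit)^2)

  CA <- orthonormalContrasts(a); CB <- orthonormalContrasts(b)
  epsA <- ggEpsilon(mSA %*% CA)
  epsB <- ggEpsilon(mSB %*% CB)
  Ycells <- matrix(aperm(Y, c(1, 3, 2)), nrow = s)   # B fastest
  Cab <- kronecker(CA, CB)
  epsAB <- ggEpsilon(Ycells %*% Cab)

  mkRow <- function(name, ssE, dfE, ssErr, dfErr, eps) {
    Fv <- (ssE / dfE) / (ssErr / dfErr)
    data.frame(effect = name, F = Fv, df1 = dfE, df2 = dfErr,
               epsilon = eps,
               p_uncorrected = stats::pf(Fv, dfE, dfErr,
                                         lower.tail = FALSE),
               p_gg = stats::pf(Fv, eps * dfE, eps * dfErr,
                                lower.tail = FALSE),
               pes = ssE / (ssE + ssErr))
  }
  out <- rbind(
    mkRow(factors[1], ssA, a - 1, ssSA, (a - 1) * (s - 1), epsA),
    mkRow(factors[2], ssB, b - 1, ssSB, (b - 1) * (s - 1), epsB),
    mkRow(paste(factors, collapse = ":"), ssAB, (a - 1) * (b - 1),
          ssSAB, (a - 1) * (b - 1) * (s - 1), epsAB))
  rownames(out) <- NULL
  out
}

#' Paired descriptive tests
#'
#' The battery applied to paired condition comparisons: Wilcoxon
#' matched-pairs signed-rank test (exact for n <= 25 without ties,
#' normal approximation with continuity correction otherwise), paired
#' t-test, paired Cohen's d, and Spearman rank correlation (mid-rank
#' ties) between the two conditions.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return List with \code{wilcoxon} (V, p), \code{t} (t, df, p),
#'   \code{d}, \code{spearman} (r, p). With all-zero differences d is 0
#'   and the Wilcoxon entries are NA (flagged undefined).
#' @export
descriptiveTests <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  d <- x - y
  nz <- d[d != 0]
  wil <- list(V = NA_real_, p = NA_real_)
  if (length(nz) > 0L) {
    exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = exact,
                         correct = TRUE))
    wil <- list(V = unname(wt$statistic), p = wt$p.value)
  }
  tt <- tryCatch({
    tr <- stats::t.test(x, y, paired = TRUE)
    list(t = unname(tr$statistic), df = unname(tr$parameter),
         p = tr$p.value)
  }, error = function(e)
    list(t = NA_real_, df = length(x) - 1, p = NA_real_))
  sp <- if (stats::sd(x) > 0 && stats::sd(y) > 0) {
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    list(r = unname(ct$estimate), p = ct$p.value)
  } else list(r = NA_real_, p = NA_real_)
  list(wilcoxon = wil, t = tt, d = cohensDPaired(x, y), spearman = sp)
}

#' Exact power of a two-sided paired t-test
#'
#' Power of the two-sided one-sample t-test on paired differences with
#' effect size \code{d}, from the noncentral t distribution with
#' df = n - 1 and noncentrality d * sqrt(n).
#'
#' @param n number of pairs (>= 2).
#' @param d effect size (mean difference / SD of differences).
#' @param alpha two-sided significance level.
#' @return Power in [0, 1].
#' @export
powerPairedT <- function(n, d, alpha = 0.05) {
  stopifnot(n >= 2, alpha > 0, alpha < 1)
  tc <- stats::qt(1 - alpha / 2, n - 1)
  ncp <- d * sqrt(n)
  stats::pt(-tc, n - 1, ncp) + stats::pt(tc, n - 1, ncp,
                                         lower.tail = FALSE)
}

#' Smallest sample size reaching a target power (paired t)
#'
#' Searches n = 2, 3, ... for the first sample size whose exact
#' noncentral-t power (see [powerPairedT()]) reaches the requested
#' power.
#'
#' @param d effect size (> 0).
#' @param alpha two-sided significance level.
#' @param power target power in (alpha, 1).
#' @param nMax search cap; exceeding it raises an error (power
#'   unreachable at a practical n).
#' @return Smallest integer n with power >= \code{power}.
#' @examples
#' sampleSizePairedT(0.5, 0.05, 0.80)
#' @export
sampleSizePairedT <- function(d, alpha = 0.05, power = 0.92,
                              nMax = 1e5) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- 2L
  while (n <= nMax) {
    if (powerPairedT(n, d, alpha) >= power) return(n)
    n <- n + 1L
  }
  stop("requested power not reachable below nMax pairs")
}
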