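#' Univariate Cox proportional-hazards fit for one covariate
#'
#' Maximum-partial-likelihood fit of a single-covariate proportional
#' hazards model (Efron ties handling), returning the hazard ratio per
#' unit of the covariate, its Wald 95\% CI (computed on the log scale)
#' and the Wald p-value. Rows with missing covariate values are dropped
#' with a warning.
#'
#' @param values covariate vector (e.g. a feature's F5/F1 ratio).
#' @param times follow-up times (days).
#' @param events event indicators (1 = progression, 0 = censored).
#' @return List with \code{hazardRatio}, \code{ci95} (length-2),
#'   \code{pRaw}, \code{beta}, \code{se}, \code{n}, \code{nEvents}.
#' @examples
#' set.seed(1)
#' x <- rnorm(60); t <- rexp(60, 0.01 * exp(0.7 * x)); e <- rbinom(60, 1, 0.7)
#' coxUnivariate(x, t, e)$hazardRatio
#' @export
coxUnivariate <- function(values, times, events) {
  ok <- is.finite(values) & is.finite(times) & events %in% c(0, 1)
  if (!all(ok)) {
    warning(sum(!ok), " rows with missing values dropped")
    values <- values[ok]; times <- times[ok]; events <- events[ok]
  }
  if (sum(events) < 2) stop("inestimable: fewer than 2 events")
  if (length(unique(values)) < 2) stop("inestimable: constant covariate")
  fit <- survival::coxph(survival::Surv(times, events) ~ values,
                         ties = "efron")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  z <- qnorm(0.975)
  list(hazardRatio = exp(beta),
       ci95 = exp(c(beta - z * se, beta + z * se)),
       pRaw = 2 * pnorm(-abs(beta / se)),
       beta = beta, se = se,
       n = length(values), nEvents = sum(events))
}

#' Holm step-down multiplicity adjustment
#'
#' Step-down Holm correction: p-values are sorted ascending, the i-th is
#' multiplied by \eqn{m - i + 1}, a running maximum enforces
#' monotonicity, values are clamped at 1 and mapped back to input order.
#' Adjusted values are always \eqn{\ge} the raw ones.
#'
#' @param p numeric vector of p-values in \eqn{[0, 1]}.
#' @return Adjusted p-values in input order.
#' @examples
#' holmAdjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holmAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Univariate Cox screening of a delta-feature table
#'
#' Fits [coxUnivariate()] for every registry feature against PFS and
#' applies the Holm correction separately within the histogram and the
#' texture feature families (texture = GLCM + GLRLM + GLSZM + NGTDM),
#' mirroring a screening design in which the two families are tested as
#' separate hypothesis sets. Features whose fit is inestimable (constant
#' ratio, too few events after dropping missing values) carry \code{NA}.
#'
#' @param deltaTable a [DeltaFeatureTable-class].
#' @param survivalData data.frame with \code{patient_id, pfs_days,
#'   event} covering the table's patients.
#' @return A \code{CoxScreenResult}: data.frame with one row per feature
#'   (\code{feature, family, hazard_ratio, ci_low, ci_high, p_raw,
#'   p_adjusted}).
#' @export
coxScreen <- function(deltaTable, survivalData) {
  stopifnot(is(deltaTable, "DeltaFeatureTable"))
  m <- deltaTable@values
  sv <- survivalData[match(rownames(m), survivalData$patient_id), ]
  if (any(is.na(sv$patient_id))) stop("survival data missing for some patients")
  fits <- lapply(seq_len(ncol(m)), function(j) {
    tryCatch(suppressWarnings(
      coxUnivariate(m[, j], sv$pfs_days, sv$event)),
      error = function(e) NULL)
  })
  out <- data.frame(
    feature = REGISTRY$name,
    family = REGISTRY$family,
    hazard_ratio = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$hazardRatio, 1),
    ci_low = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$ci95[1], 1),
    ci_high = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$ci95[2], 1),
    p_raw = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$pRaw, 1),
    stringsAsFactors = FALSE
  )
  out$p_adjusted <- NA_real_
  for (fam in list("histogram", c("GLCM", "GLRLM", "GLSZM", "NGTDM"))) {
    idx <- out$family %in% fam & !is.na(out$p_raw)
    out$p_adjusted[idx] <- holmAdjust(out$p_raw[idx])
  }
  class(out) <- c("CoxScreenResult", "data.frame")
  out
}

#' Maximally selected log-rank risk split
#'
#' Identifies high- and low-risk groups from one covariate: every
#' midpoint between consecutive sorted unique covariate values (with
#' both sides meeting the minimum group size) is scored by the
#' two-sample log-rank statistic, the maximizing threshold is selected,
#' and the significance of that maximally selected statistic is assessed
#' by permuting the covariate against the survival outcomes. This is the
#' single-split decision surface of a conditional inference tree; the
#' permutation p-value accounts for the threshold optimization that a
#' naive log-rank p at the chosen cut would ignore.
#'
#' @param values covariate vector.
#' @param times follow-up times.
#' @param events event indicators (1/0).
#' @param alpha significance level for declaring a split (default 0.05).
#' @param nPerm number of covariate permutations (default 9999).
#' @param seed integer seed for the permutations (recorded in the
#'   result).
#' @param minGroup minimum size of each side of the split (default 5).
#' @return A \code{RiskSplit}: list with \code{splitFound},
#'   \code{threshold}, \code{group} (per-subject \code{"high"} /
#'   \code{"low"}; higher covariate = \code{"high"}), \code{statistic}
#'   (max log-rank chi-square), \code{permutationP}, \code{logrankP}
#'   (naive p at the chosen threshold), \code{reason} when no split,
#'   \code{seed}, \code{nPerm}.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(30, 0), rnorm(30, 3))
#' t <- rexp(60, 0.01 * ifelse(x > 1.5, 4, 1))
#' bestSplit(x, t, rep(1, 60), nPerm = 199, seed = 7)$threshold
#' @export
bestSplit <- function(values, times, events, alpha = 0.05, nPerm = 9999,
                      seed = 1, minGroup = 5) {
  ok <- is.finite(values) & is.finite(times) & events %in% c(0, 1)
  values <- values[ok]; times <- times[ok]; events <- events[ok]
  n <- length(values)
  noSplit <- function(reason)
    structure(list(splitFound = FALSE, threshold = NA_real_,
                   group = rep(NA_character_, n), statistic = NA_real_,
                   permutationP = NA_real_, logrankP = NA_real_,
                   reason = reason, seed = seed, nPerm = nPerm),
              class = "RiskSplit")
  if (n < 10) return(noSplit("fewer than 10 subjects"))
  if (sum(events) < 2) return(noSplit("fewer than 2 events"))

  pre <- logrankPrecompute(times, events)
  scan <- logrankScan(values, times, events, minGroup, pre)
  if (!length(scan$thresholds)) return(noSplit("no admissible threshold"))
  obs <- max(scan$stat)
  best <- which.max(scan$stat)
  thr <- scan$thresholds[best]

  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    xp <- sample(values)
    sp <- logrankScan(xp, times, events, minGroup, pre)
    if (length(sp$stat) && max(sp$stat) >= obs) exceed <- exceed + 1L
  }
  permP <- (1 + exceed) / (1 + nPerm)

  grp <- ifelse(values > thr, "high", "low")
  lrP <- pchisq(obs, df = 1, lower.tail = FALSE)
  structure(list(splitFound = permP <= alpha, threshold = thr,
                 group = grp, statistic = obs, permutationP = permP,
                 logrankP = lrP, reason = NULL, seed = seed,
                 nPerm = nPerm),
            class = "RiskSplit")
}

# Risk-set quantities shared by every threshold scan on one outcome set.
logrankPrecompute <- function(times, events) {
  dt <- sort(unique(times[events == 1]))
  atRisk <- outer(dt, times, "<=") * 1          # J x n
  dying <- outer(dt, times, "==") * rep(events, each = length(dt))
  nj <- rowSums(atRisk)
  dj <- rowSums(dying)
  list(atRisk = atRisk, dying = dying, nj = nj, dj = dj)
}

# Log-rank chi-square statistic at every admissible threshold,
# vectorized across thresholds (columns) and event times (rows).
logrankScan <- function(x, times, events, minGroup,
                        pre = logrankPrecompute(times, events)) {
  ux <- sort(unique(x))
  if (length(ux) < 2)
    return(list(thresholds = numeric(0), stat = numeric(0)))
  mids <- (ux[-1] + ux[-length(ux)]) / 2
  nLow <- vapply(mids, function(t) sum(x <= t), integer(1))
  keep <- nLow >= minGroup & (length(x) - nLow) >= minGroup
  mids <- mids[keep]
  if (!length(mids))
    return(list(thresholds = numeric(0), stat = numeric(0)))

  G <- outer(x, mids, "<=") * 1                 # n x K, group 1 = low
  nj <- pre$nj; dj <- pre$dj
  n1 <- pre$atRisk %*% G                        # J x K
  d1 <- pre$dying %*% G                         # J x K
  Ej <- n1 * (dj / nj)
  denom <- pmax(nj - 1, 1)
  Vj <- (dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj)) / denom
  U <- colSums(d1 - Ej)
  V <- colSums(Vj)
  stat <- ifelse(V > 0, U^2 / V, 0)
  list(thresholds = mids, stat = stat)
}

#' @export
print.RiskSplit <- function(x, ...) {
  if (x$splitFound)
    cat(sprintf("RiskSplit: threshold %.4g (high: %d, low: %d), max chi-sq %.2f, permutation p = %.4g\n",
                x$threshold, sum(x$group == "high"), sum(x$group == "low"),
                x$statistic, x$permutationP))
  else
    cat("RiskSplit: no significant split (", x$reason %||% "permutation p > alpha", ")\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kaplan-Meier curve and two-sample log-rank test
#'
#' \code{kmCurve} wraps the product-limit estimator with right
#' censoring; \code{logrankTest} the two-sided two-sample log-rank
#' chi-square test.
#'
#' @param times follow-up times.
#' @param events event indicators (1/0).
#' @return \code{kmCurve}: a \code{survival::survfit} object (step
#'   function via \code{summary}). \code{logrankTest}: list with
#'   \code{chisq}, \code{p}.
#' @examples
#' fit <- kmCurve(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' summary(fit, times = 2.5)$surv  # 0.5
#' @export
kmCurve <- function(times, events) {
  if (!length(times)) stop("empty group")
  survival::survfit(survival::Surv(times, events) ~ 1)
}

#' @rdname kmCurve
#' @param timesA,eventsA,timesB,eventsB the two groups' outcomes.
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  if (!length(timesA) || !length(timesB)) stop("empty group")
  grp <- c(rep(0L, length(timesA)), rep(1L, length(timesB)))
  tt <- c(timesA, timesB); ee <- c(eventsA, eventsB)
  sd <- survival::survdiff(survival::Surv(tt, ee) ~ grp)
  list(chisq = sd$chisq, p = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' RECIST 1.1 local response classification
#'
#' Classifies longest-diameter change from baseline: an increase of 20\%
#' or more is progressive disease (\code{PD}), a decrease of 30\% or
#' more is partial response (\code{PR}), anything between is stable
#' disease (\code{SD}). Both boundaries are inclusive.
#'
#' @param baselineDiameter,followupDiameter longest diameters in mm
#'   (vectorized; must be > 0).
#' @return Character vector in \code{\{"PD", "PR", "SD"\}}.
#' @examples
#' recistClassify(50, c(60, 35, 52))
#' @export
recistClassify <- function(baselineDiameter, followupDiameter) {
  if (any(baselineDiameter <= 0) || any(followupDiameter <= 0))
    stop("diameters must be > 0")
  change <- (followupDiameter - baselineDiameter) / baselineDiameter
  ifelse(change >= 0.20, "PD", ifelse(change <= -0.30, "PR", "SD"))
}
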