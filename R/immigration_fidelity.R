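#' Construct an immigration submodel
#'
#' @param betaAge numeric(A), log-scale age-class intercepts.
#' @param betaSex numeric(1), female effect (log scale).
#' @param alpha numeric(T-1), occasion random effects for occasions 2..T.
#' @param sigmaT their standard deviation.
#' @return an [ImmigrationModel-class].
#' @export
immigrationModel <- function(betaAge, betaSex = 0, alpha, sigmaT = 1) {
  new("ImmigrationModel", betaAge = betaAge, betaSex = betaSex,
      alpha = alpha, sigmaT = sigmaT)
}

#' Per-capita immigration rate for one cell
#'
#' Exponential of the log-linear predictor
#' `beta_age[a] + beta_sex * sex + alpha_t`.
#'
#' @param age age class.
#' @param sex 0 = male, 1 = female.
#' @param t occasion (2..T).
#' @param m an [ImmigrationModel-class].
#' @return the rate (> 0).
#' @export
immigrationRate <- function(age, sex, t, m) {
  if (t < 2 || t - 1 > length(m@alpha)) stop("occasion out of range (2..T)")
  exp(m@betaAge[age] + m@betaSex * sex + m@alpha[t - 1])
}

#' Poisson log-likelihood of the unmarked-capture counts
#'
#' `Imm[a,s,t] ~ Poisson(C[a,s,t] * I[a,s,t])` summed over cells for
#' occasions 2..T.  Cells with no captured individuals and no unmarked
#' captures contribute zero; unmarked captures in a cell with `C = 0` are
#' impossible under the model and raise an error.
#'
#' @param counts a [ClassCounts-class].
#' @param m an [ImmigrationModel-class].
#' @return the log-likelihood.
#' @export
immigrationLoglik <- function(counts, m) {
  A <- dim(counts@C)[1]; T <- dim(counts@C)[3]
  ll <- 0
  for (t in 2:T) for (s in 0:1) for (a in seq_len(A)) {
    C <- counts@C[a, s + 1, t]; Imm <- counts@Imm[a, s + 1, t - 1]
    if (C == 0) {
      if (Imm > 0)
        stop(sprintf("cell (age %d, sex %d, occasion %d): unmarked captures with C = 0",
                     a, s, t))
      next
    }
    ll <- ll + dpois(Imm, C * immigrationRate(a, s, t, m), log = TRUE)
  }
  ll
}

#' Derive emigration and site fidelity from immigration rates
#'
#' Under the balanced-flow assumption, emigration over interval t..t+1
#' equals the immigration rate at occasion t+1, and site fidelity is its
#' complement, `r = 1 - emigration`.  Cells with rate >= 1 would give
#' non-positive fidelity; they are clamped to a small floor and flagged
#' rather than failing.
#'
#' @param I immigration rates for occasions 2..T: a vector or an array whose
#'   last dimension indexes occasions 2..T (e.g. [A x 2 x (T-1)], or
#'   [draws x A x 2 x (T-1)] for draw-wise use).  Entry j of the occasion
#'   dimension is occasion j+1, which is exactly interval j, so the output
#'   arrays are aligned with intervals 1..T-1.
#' @param floor fidelity floor used when clamping (default 0.05).
#' @return list with `emigration`, `r`, and logical `flagged`, all shaped
#'   like `I`.
#' @export
deriveFidelity <- function(I, floor = 0.05) {
  flagged <- I >= 1
  r <- 1 - I
  r[flagged] <- floor
  list(emigration = I, r = r, flagged = flagged)
}

#' Emigration-adjusted survival
#'
#' Apparent survival is the product of true survival and site fidelity, so
#' dividing by fidelity removes the emigration bias:
#' `phi_adjusted = phi / r`, and the adjustment is
#' `Delta = phi_adjusted - phi`.  Values above 1 are retained but flagged.
#'
#' @param phi apparent survival (vector or array).
#' @param r site fidelity, same shape.
#' @param flagged optional logical mask of cells already flagged by
#'   clamping in [deriveFidelity()]; any non-positive `r` outside that mask
#'   is an error.
#' @return list with `phiAdjusted`, `delta`, and logical `flagged`
#'   (clamped cells or adjusted survival > 1).
#' @export
adjustSurvival <- function(phi, r, flagged = NULL) {
  if (!all(dim(phi) == dim(r)) || length(phi) != length(r))
    stop("phi and r must conform")
  if (is.null(flagged)) flagged <- array(FALSE, dim = dim(r) %||% length(r))
  if (any(r <= 0 & !flagged))
    stop("non-positive fidelity in an unflagged cell")
  phiAdj <- phi / r
  list(phiAdjusted = phiAdj, delta = phiAdj - phi,
       flagged = flagged | phiAdj > 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw-wise emigration adjustment of a fitted model
#'
#' Pairs the posterior draws of the apparent-survival cells with the draws
#' of the immigration rates (same iteration index; the two processes are
#' independent), derives fidelity, adjusts survival draw by draw so that
#' the credible intervals propagate both sources of uncertainty, and
#' summarizes each age x sex x interval cell.
#'
#' @param fit a [PosteriorResult-class] fitted with class counts.
#' @param floor fidelity floor for clamping (see [deriveFidelity()]).
#' @return an [AdjustedSurvival-class].
#' @export
adjustedSurvival <- function(fit, floor = 0.05) {
  phi <- phiCellDraws(fit)
  I <- immigrationRateDraws(fit)
  fid <- deriveFidelity(I, floor)
  adj <- adjustSurvival(phi, fid$r, fid$flagged)
  A <- dim(phi)[2]; Tm1 <- dim(phi)[4]
  rows <- expand.grid(age = seq_len(A), sex = 0:1, interval = seq_len(Tm1))
  summCell <- function(arr, a, s, t) summarizePosterior(arr[, a, s + 1, t])
  tab <- do.call(rbind, lapply(seq_len(nrow(rows)), function(k) {
    a <- rows$age[k]; s <- rows$sex[k]; t <- rows$interval[k]
    v <- c(summCell(phi, a, s, t), summCell(I, a, s, t),
           summCell(fid$r, a, s, t), summCell(adj$phiAdjusted, a, s, t),
           summCell(adj$delta, a, s, t))
    names(v) <- as.vector(outer(c("mean", "lower", "upper"),
                                c("phi", "I", "r", "phiAdj", "delta"),
                                function(x, y) paste0(y, "_", x)))
    clamped <- mean(fid$flagged[, a, s + 1, t])
    over1 <- mean(adj$phiAdjusted[, a, s + 1, t] > 1)
    data.frame(t(v), clampedFrac = clamped, adjAbove1Frac = over1)
  }))
  tab <- cbind(rows, tab)
  tab$flag <- ifelse(tab$clampedFrac > 0.5, "clamped",
                     ifelse(tab$phiAdj_mean > 1, "adj>1", ""))
  new("AdjustedSurvival", table = tab, floor = floor)
}

#' @rdname AdjustedSurvival-class
#' @export
setMethod("adjustmentTable", "AdjustedSurvival", function(x) x@table)

setMethod("show", "AdjustedSurvival", function(object) {
  tab <- object@table
  cat(sprintf("AdjustedSurvival: %d cells; mean adjustment Delta %.3f (range %.3f..%.3f)\n",
              nrow(tab), mean(tab$delta_mean), min(tab$delta_mean),
              max(tab$delta_mean)))
  nf <- sum(tab$flag != "")
  if (nf > 0) cat(sprintf("  %d flagged cells (%s)\n", nf,
                          paste(unique(tab$flag[tab$flag != ""]), collapse = ", ")))
})

#' Write the survival/adjustment results table
#'
#' Machine-readable twin of the survival and adjustment figures: one row per
#' age x sex x interval with posterior mean and 95% CI of apparent survival,
#' immigration rate, fidelity, adjusted survival and the adjustment, plus
#' flags.
#'
#' @param adj an [AdjustedSurvival-class].
#' @param path output CSV path.
#' @export
writeAdjustmentTable <- function(adj, path) {
  write.csv(adj@table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
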