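logMeanExp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Watanabe-Akaike information criterion
#'
#' From a draws x individuals matrix of pointwise capture-history
#' log-likelihoods: `lppd_i = log mean_d exp(ll_{d,i})`, the effective
#' parameter penalty `p_waic_i = var_d(ll_{d,i})` (sample variance, n-1
#' denominator), and `WAIC = -2 * sum(lppd_i - p_waic_i)`.
#'
#' @param pointwise numeric matrix, posterior draws x individuals.
#' @return list with `waic`, `lppd`, `pWaic`, and the per-individual
#'   `pointwise` contributions `-2 (lppd_i - p_waic_i)`.
#' @export
waic <- function(pointwise) {
  pointwise <- as.matrix(pointwise)
  if (nrow(pointwise) < 2) stop("WAIC needs at least 2 posterior draws")
  if (any(!is.finite(pointwise))) stop("non-finite pointwise log-likelihoods")
  lppd_i <- apply(pointwise, 2, logMeanExp)
  p_i <- apply(pointwise, 2, var)
  contrib <- -2 * (lppd_i - p_i)
  list(waic = sum(contrib), lppd = sum(lppd_i), pWaic = sum(p_i),
       pointwise = contrib)
}

#' WAIC difference with a 95% interval
#'
#' The WAIC difference between two models on the same individuals, with a
#' normal-approximation 95% interval built from the pointwise contribution
#' differences: `SE = sqrt(n * var(d_i))` where
#' `d_i = contrib_B_i - contrib_A_i`.  A difference is treated as meaningful
#' when the interval excludes zero.
#'
#' @param pointwiseA,pointwiseB per-individual WAIC contributions of the two
#'   models (same individuals, same order), as returned by [waic()].
#' @return named numeric: delta, lower, upper.
#' @export
deltaWaicCI <- function(pointwiseA, pointwiseB) {
  if (length(pointwiseA) != length(pointwiseB))
    stop("pointwise contribution vectors must match")
  d <- pointwiseB - pointwiseA
  delta <- sum(d)
  se <- sqrt(length(d) * var(d))
  c(delta = delta, lower = delta - 1.96 * se, upper = delta + 1.96 * se)
}

#' Model support weights
#'
#' `w_m = exp(-0.5 * deltaWAIC_m) / sum_k exp(-0.5 * deltaWAIC_k)`.
#'
#' @param waicValues numeric vector of WAIC values.
#' @return weights summing to 1.
#' @export
waicWeights <- function(waicValues) {
  d <- waicValues - min(waicValues)
  w <- exp(-0.5 * d)
  w / sum(w)
}

#' Rank the candidate detection structures by WAIC
#'
#' Fits the CJS model under each requested detection structure (survival held
#' at the full age/sex/time form throughout), computes WAIC from the
#' pointwise capture-history log-likelihoods, and tabulates the WAIC
#' difference from the top model with its 95% interval and the model support
#' weights.
#'
#' @param ds a filtered [CaptureDataset-class].
#' @param structures character vector of structures to compare (default all
#'   nine).
#' @param priors a [PriorSet-class].
#' @param chains,iter,burn,thin,seed sampler settings for the selection-length
#'   runs.
#' @param keepFits keep the per-structure [PosteriorResult-class] objects.
#' @return a [ModelComparison-class].
#' @export
selectDetectionModel <- function(ds, structures = DETECTION_STRUCTURES,
                                 priors = priorSet("prior1"), chains = 3,
                                 iter = 5000, burn = 2000, thin = 1,
                                 seed = 1, keepFits = FALSE) {
  bad <- setdiff(structures, DETECTION_STRUCTURES)
  if (length(bad)) stop(sprintf("unknown detection structure '%s'", bad[1]))
  fits <- list(); pointwise <- list(); werr <- list()
  rows <- lapply(seq_along(structures), function(k) {
    st <- structures[k]
    fit <- tryCatch(
      fitModel(ds, counts = NULL, structure = st, priors = priors,
               chains = chains, iter = iter, burn = burn, thin = thin,
               seed = seed + k),
      error = function(e) stop(sprintf("structure '%s': %s", st,
                                       conditionMessage(e)), call. = FALSE))
    w <- waic(pointwiseLoglik(fit))
    pointwise[[st]] <<- w$pointwise
    if (keepFits) fits[[st]] <<- fit
    data.frame(model = st, waic = w$waic, lppd = w$lppd, pWaic = w$pWaic,
               maxRhat = max(monitoredRhat(fit)), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$waic)
  tab <- tab[ord, , drop = FALSE]
  top <- tab$model[1]
  ci <- t(vapply(tab$model, function(mname) {
    if (mname == top) c(delta = 0, lower = NA_real_, upper = NA_real_)
    else deltaWaicCI(pointwise[[top]], pointwise[[mname]])
  }, numeric(3)))
  tab$deltaWaic <- ci[, "delta"]; tab$lower <- ci[, "lower"]
  tab$upper <- ci[, "upper"]
  tab$weight <- waicWeights(tab$waic)
  rownames(tab) <- NULL
  new("ModelComparison", table = tab, pointwise = pointwise, fits = fits)
}

#' @rdname ModelComparison-class
#' @export
setMethod("comparisonTable", "ModelComparison", function(x) x@table)

setMethod("show", "ModelComparison", function(object) {
  tab <- object@table
  cat(sprintf("ModelComparison over %d detection structures (top: %s)\n",
              nrow(tab), tab$model[1]))
  print(tab[, c("model", "deltaWaic", "lower", "upper", "weight")],
        digits = 4, row.names = FALSE)
})

#' Write the model-comparison table
#'
#' Delimited-text report with columns model, deltaWaic, lower, upper, weight.
#'
#' @param cmp a [ModelComparison-class].
#' @param path output CSV path.
#' @export
writeComparisonTable <- function(cmp, path) {
  write.csv(cmp@table[, c("model", "deltaWaic", "lower", "upper", "weight")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
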