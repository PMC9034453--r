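#' Construct a capture-history dataset
#'
#' Builds and validates a [CaptureDataset-class] from a binary detection
#' matrix and per-individual metadata.  First-capture occasions are derived
#' from the histories.
#'
#' @param y matrix of 0/1 detections, individuals x occasions.
#' @param site integer site index (1..S) or factor/character site labels.
#' @param sex integer vector, 0 = male, 1 = female.
#' @param ageAtFirst integer age class (1..`nAgeClasses`) at first capture.
#' @param nAgeClasses number of age classes (3 or 2).
#' @param individualId optional individual labels.
#' @param occasionLabels optional occasion (year) labels.
#' @param siteLevels optional full set of site names (allows sites with no
#'   individuals).
#' @param effort optional sites x occasions 0/1 trapping-effort mask
#'   (default: effort everywhere).
#' @return a validated `CaptureDataset`.
#' @export
captureDataset <- function(y, site, sex, ageAtFirst, nAgeClasses,
                           individualId = NULL, occasionLabels = NULL,
                           siteLevels = NULL, effort = NULL) {
  y <- as.matrix(y)
  dimnames(y) <- NULL
  storage.mode(y) <- "integer"
  n <- nrow(y); T <- ncol(y)
  if (n > 0 && any(rowSums(y) == 0)) {
    bad <- which(rowSums(y) == 0)[1]
    stop(sprintf("individual %s never captured (all-zero history)",
                 if (is.null(individualId)) bad else individualId[bad]))
  }
  f <- if (n > 0) apply(y == 1L, 1, which.max) else integer(0)
  if (is.null(siteLevels)) {
    if (is.numeric(site)) siteLevels <- as.character(seq_len(max(site, 1)))
    else siteLevels <- sort(unique(as.character(site)))
  }
  if (!is.numeric(site)) site <- match(as.character(site), siteLevels)
  if (anyNA(site)) stop("unknown site code")
  if (is.null(individualId)) individualId <- sprintf("ind%04d", seq_len(n))
  if (is.null(occasionLabels)) occasionLabels <- as.character(seq_len(T))
  if (is.null(effort))
    effort <- matrix(1L, length(siteLevels), T)
  storage.mode(effort) <- "integer"
  new("CaptureDataset", y = y, f = as.integer(f),
      individualId = as.character(individualId), site = as.integer(site),
      siteLevels = siteLevels, sex = as.integer(sex),
      ageAtFirst = as.integer(ageAtFirst), nAgeClasses = as.integer(nAgeClasses),
      occasionLabels = as.character(occasionLabels), effort = effort)
}

#' @rdname CaptureDataset-class
#' @export
setMethod("nIndividuals", "CaptureDataset", function(x) nrow(x@y))
#' @rdname CaptureDataset-class
#' @export
setMethod("nOccasions", "CaptureDataset", function(x) ncol(x@y))
#' @rdname CaptureDataset-class
#' @export
setMethod("nAgeClasses", "CaptureDataset", function(x) x@nAgeClasses)
#' @rdname CaptureDataset-class
#' @export
setMethod("captureHistories", "CaptureDataset", function(x) x@y)
#' @rdname CaptureDataset-class
#' @export
setMethod("firstCapture", "CaptureDataset", function(x) x@f)
#' @rdname CaptureDataset-class
#' @export
setMethod("occasionLabels", "CaptureDataset", function(x) x@occasionLabels)
#' @rdname CaptureDataset-class
#' @export
setMethod("indSex", "CaptureDataset", function(x) x@sex)
#' @rdname CaptureDataset-class
#' @export
setMethod("indSite", "CaptureDataset", function(x) x@site)
#' @rdname CaptureDataset-class
#' @export
setMethod("ageAtFirst", "CaptureDataset", function(x) x@ageAtFirst)
#' @rdname CaptureDataset-class
#' @export
setMethod("effortMask", "CaptureDataset", function(x) x@effort)

setMethod("show", "CaptureDataset", function(object) {
  cat(sprintf("CaptureDataset: %d individuals x %d occasions (%s..%s)\n",
              nrow(object@y), ncol(object@y),
              object@occasionLabels[1], utils::tail(object@occasionLabels, 1)))
  cat(sprintf("  %d age classes; %d sites; %d females, %d males\n",
              object@nAgeClasses, length(object@siteLevels),
              sum(object@sex == 1L), sum(object@sex == 0L)))
  cat(sprintf("  detections: %d; first captures per occasion: %s\n",
              sum(object@y), paste(tabulate(object@f, ncol(object@y)),
                                   collapse = " ")))
})

#' Read capture histories from delimited text
#'
#' Accepts two dialects.  Wide (canonical): one row per individual with
#' columns `id`, `site`, `sex`, `age`, then one 0/1 column per occasion.
#' Long: one row per capture with columns `id`, `site`, `sex`, `age`,
#' `occasion` (occasion index or year label); the age column holds the age
#' class observed at that capture and ages must be non-decreasing.
#'
#' @param path CSV file path.
#' @param nAgeClasses species age-class count (3 or 2).
#' @param occasionLabels occasion labels; required for the long dialect when
#'   `occasion` holds year labels, otherwise inferred.
#' @param effort optional effort mask (sites x occasions).
#' @return a validated [CaptureDataset-class].
#' @export
readCaptureTable <- function(path, nAgeClasses, occasionLabels = NULL,
                             effort = NULL) {
  if (!file.exists(path)) stop(sprintf("input file '%s' does not exist", path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  lc <- tolower(names(df))
  needed <- c("id", "site", "sex", "age")
  if (!all(needed %in% lc))
    stop("capture table must have columns id, site, sex, age")
  names(df)[match(needed, lc)] <- needed
  if ("occasion" %in% lc) {                      # long dialect
    names(df)[match("occasion", lc)] <- "occasion"
    if (is.null(occasionLabels))
      occasionLabels <- as.character(sort(unique(df$occasion)))
    occ <- match(as.character(df$occasion), occasionLabels)
    if (anyNA(occ))
      stop(sprintf("row %d: occasion '%s' not among occasion labels",
                   which(is.na(occ))[1], df$occasion[which(is.na(occ))[1]]))
    ids <- unique(df$id)
    T <- length(occasionLabels)
    y <- matrix(0L, length(ids), T)
    site <- sex <- age1 <- rep(NA, length(ids))
    for (k in seq_along(ids)) {
      rows <- df[df$id == ids[k], , drop = FALSE]
      o <- occ[df$id == ids[k]]
      ord <- order(o)
      validateAgeMonotonicity(rows$age[ord], individual = as.character(ids[k]),
                              occasions = o[ord])
      y[k, o] <- 1L
      site[k] <- rows$site[1]; sex[k] <- rows$sex[1]
      age1[k] <- rows$age[ord][1]
    }
    checkSexAge(sex, age1, nAgeClasses, ids)
    return(captureDataset(y, site, sex, age1, nAgeClasses,
                          individualId = as.character(ids),
                          occasionLabels = occasionLabels, effort = effort))
  }
  occCols <- setdiff(names(df), needed)          # wide dialect
  if (length(occCols) < 2) stop("wide capture table needs >= 2 occasion columns")
  y <- as.matrix(df[, occCols, drop = FALSE])
  if (!all(y %in% c(0, 1))) {
    bad <- which(apply(y, 1, function(r) !all(r %in% c(0, 1))))[1]
    stop(sprintf("row %d: non-binary detection entry", bad))
  }
  if (any(rowSums(y) == 0))
    stop(sprintf("row %d: individual never captured",
                 which(rowSums(y) == 0)[1]))
  if (is.null(occasionLabels)) occasionLabels <- occCols
  checkSexAge(df$sex, df$age, nAgeClasses, df$id)
  captureDataset(y, df$site, df$sex, df$age, nAgeClasses,
                 individualId = as.character(df$id),
                 occasionLabels = occasionLabels, effort = effort)
}

checkSexAge <- function(sex, age, nAgeClasses, ids) {
  if (!all(sex %in% c(0, 1)))
    stop(sprintf("individual %s: unknown sex code '%s' (expect 0/1)",
                 ids[!sex %in% c(0, 1)][1], sex[!sex %in% c(0, 1)][1]))
  bad <- !(age %in% seq_len(nAgeClasses))
  if (any(bad))
    stop(sprintf("individual %s: age class '%s' outside 1..%d",
                 ids[bad][1], age[bad][1], nAgeClasses))
  invisible(TRUE)
}

#' Write a capture-history dataset as wide CSV
#'
#' The written file round-trips through [readCaptureTable()].
#'
#' @param ds a [CaptureDataset-class].
#' @param path output CSV path.
#' @export
writeCaptureTable <- function(ds, path) {
  df <- data.frame(id = ds@individualId,
                   site = ds@siteLevels[ds@site],
                   sex = ds@sex, age = ds@ageAtFirst,
                   check.names = FALSE)
  y <- ds@y
  colnames(y) <- ds@occasionLabels
  write.csv(cbind(df, y), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate that observed age classes never decrease
#'
#' Age classifications can only increase through time; a recorded decrease is
#' a data error.
#'
#' @param ages per-capture observed age classes, in occasion order.
#' @param individual label used in the error message.
#' @param occasions occasion indices of the captures (for the message).
#' @return the ages, invisibly, if valid.
#' @export
validateAgeMonotonicity <- function(ages, individual = "?", occasions = seq_along(ages)) {
  if (length(ages) > 1) {
    d <- diff(ages)
    if (any(d < 0)) {
      k <- which(d < 0)[1]
      stop(sprintf(
        "individual %s: age class decreases from %d to %d between occasions %s and %s",
        individual, ages[k], ages[k + 1], occasions[k], occasions[k + 1]))
    }
  }
  invisible(ages)
}

#' Drop individuals first captured at the final occasion
#'
#' Individuals first caught at the last occasion carry no information about
#' survival; only individuals captured before the final trapping occasion are
#' retained for survival estimation.
#'
#' @param ds a [CaptureDataset-class].
#' @return the filtered dataset; a message reports the retained count.
#' @export
filterForSurvival <- function(ds) {
  keep <- ds@f < nOccasions(ds)
  if (!any(keep)) warning("no individuals captured before the final occasion")
  out <- new("CaptureDataset", y = ds@y[keep, , drop = FALSE],
             f = ds@f[keep], individualId = ds@individualId[keep],
             site = ds@site[keep], siteLevels = ds@siteLevels,
             sex = ds@sex[keep], ageAtFirst = ds@ageAtFirst[keep],
             nAgeClasses = ds@nAgeClasses, occasionLabels = ds@occasionLabels,
             effort = ds@effort)
  message(sprintf("retained %d of %d individuals captured before the final occasion",
                  sum(keep), length(keep)))
  out
}

#' Construct a ClassCounts object
#'
#' @param C integer array [A x 2 x T] of captured individuals per class.
#' @param Imm integer array [A x 2 x (T-1)] of captured unmarked individuals,
#'   occasions 2..T.
#' @param occasionLabels labels for the T occasions.
#' @return a validated [ClassCounts-class].
#' @export
classCounts <- function(C, Imm, occasionLabels = NULL) {
  if (is.null(occasionLabels)) occasionLabels <- as.character(seq_len(dim(C)[3]))
  storage.mode(C) <- "integer"; storage.mode(Imm) <- "integer"
  # a slot named "C" would partially match new()'s Class argument, so build
  # from the prototype and validate explicitly
  obj <- new("ClassCounts")
  obj@C <- C; obj@Imm <- Imm
  obj@occasionLabels <- as.character(occasionLabels)
  validObject(obj)
  obj
}

#' @rdname ClassCounts-class
#' @export
setMethod("totalCaptures", "ClassCounts", function(x) x@C)
#' @rdname ClassCounts-class
#' @export
setMethod("unmarkedCaptures", "ClassCounts", function(x) x@Imm)
#' @rdname ClassCounts-class
#' @export
setMethod("nOccasions", "ClassCounts", function(x) dim(x@C)[3])
#' @rdname ClassCounts-class
#' @export
setMethod("nAgeClasses", "ClassCounts", function(x) dim(x@C)[1])

setMethod("show", "ClassCounts", function(object) {
  cat(sprintf("ClassCounts: %d age classes x 2 sexes x %d occasions\n",
              dim(object@C)[1], dim(object@C)[3]))
  cat(sprintf("  total captures %d; unmarked captures (occ 2..T) %d\n",
              sum(object@C), sum(object@Imm)))
})

#' Tally per-class capture and unmarked-capture counts
#'
#' `C[a,s,t]` counts the distinct individuals of age class a and sex s
#' captured at occasion t (age advancing deterministically from the class at
#' first capture); `Imm[a,s,t]`, defined for occasions 2..T, counts those
#' whose first capture is t — the "captured unmarked individuals" response of
#' the immigration regression.  An individual is unmarked at its first
#' capture occasion and marked thereafter.
#'
#' @param ds a [CaptureDataset-class].
#' @return a [ClassCounts-class].
#' @export
computeClassCounts <- function(ds) {
  A <- ds@nAgeClasses; T <- nOccasions(ds); n <- nIndividuals(ds)
  C <- array(0L, c(A, 2, T))
  Imm <- array(0L, c(A, 2, T - 1))
  for (i in seq_len(n)) {
    ages <- ageTrajectory(ds@ageAtFirst[i], ds@f[i], T, A)
    s <- ds@sex[i] + 1L
    for (t in which(ds@y[i, ] == 1L)) {
      a <- ages[t]
      C[a, s, t] <- C[a, s, t] + 1L
      if (t == ds@f[i] && t >= 2L) Imm[a, s, t - 1] <- Imm[a, s, t - 1] + 1L
    }
  }
  classCounts(C, Imm, ds@occasionLabels)
}

#' Write and read class-count tables
#'
#' Long CSV with columns age, sex, occasion, C, Imm (Imm is NA at the first
#' occasion).
#'
#' @param counts a [ClassCounts-class].
#' @param path CSV path.
#' @export
writeClassCounts <- function(counts, path) {
  A <- dim(counts@C)[1]; T <- dim(counts@C)[3]
  g <- expand.grid(age = seq_len(A), sex = 0:1, occasion = seq_len(T))
  g$C <- counts@C[cbind(g$age, g$sex + 1, g$occasion)]
  g$Imm <- ifelse(g$occasion >= 2,
                  counts@Imm[cbind(g$age, g$sex + 1, pmax(g$occasion - 1, 1))],
                  NA)
  g$occasion <- counts@occasionLabels[g$occasion]
  write.csv(g, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeClassCounts
#' @export
readClassCounts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  labs <- unique(df$occasion)
  A <- max(df$age); T <- length(labs)
  C <- array(0L, c(A, 2, T)); Imm <- array(0L, c(A, 2, T - 1))
  occ <- match(df$occasion, labs)
  C[cbind(df$age, df$sex + 1, occ)] <- df$C
  keep <- occ >= 2
  Imm[cbind(df$age[keep], df$sex[keep] + 1, occ[keep] - 1)] <- df$Imm[keep]
  classCounts(C, Imm, as.character(labs))
}

#' Read a run configuration file
#'
#' YAML with keys `n_age_classes`, `occasion_labels`, and optionally
#' `effort` (a sites x occasions 0/1 matrix given as a list of rows),
#' `site_levels`, `detection_structures`, `prior`, and sampler settings.
#'
#' @param path YAML file path.
#' @return a named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$effort))
    cfg$effort <- do.call(rbind, lapply(cfg$effort, as.integer))
  # YAML reads a bare `Null` as the null value; it names the intercept-only
  # detection structure here
  if (!is.null(cfg$detection) &&
      ("structure" %in% names(cfg$detection)) &&
      is.null(cfg$detection$structure))
    cfg$detection$structure <- "Null"
  cfg
}
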