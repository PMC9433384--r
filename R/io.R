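#' Read a gene-level table
#'
#' Reads a tab-separated gene table with a mandatory header and columns
#' \code{gene_id}, \code{chi} (ribosome allocation count fraction),
#' \code{k} (translation speed, Da/min), \code{phi} (protein mass
#' fraction), \code{length} (amino acids), \code{is_ribosomal}, and
#' optionally \code{alpha} (degradation rate, 1/min; missing column means
#' no degradation, with a warning), \code{v} (amino acids/min), \code{a}
#' (mean amino-acid mass, Da) and \code{paralog_group}.  When \code{v} and
#' \code{a} are both present the identity \code{k = v * a} is checked.
#'
#' Mass-fraction calibration: proteomics intensity-derived fractions can be
#' calibrated by a power of protein length; \code{"length_pow_057"}
#' rescales \eqn{\phi_i \gets \phi_i L^{-0.57}} (a calibration independent
#' of ribosome-profiling data) and \code{"length_pow_1"} uses
#' \eqn{L^{-1}}; both renormalize afterwards.
#'
#' @param path TSV file path.
#' @param calibration one of \code{"none"}, \code{"length_pow_057"},
#'   \code{"length_pow_1"}.
#' @return data.frame of gene records (fraction columns each summing to 1).
#' @export
readGeneTable <- function(path, calibration = c("none", "length_pow_057",
                                                "length_pow_1")) {
  calibration <- match.arg(calibration)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("gene_id", "chi", "k", "phi", "length", "is_ribosomal")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  dup <- duplicated(df$gene_id)
  if (any(dup))
    stop("duplicate gene_id at line(s) ",
         paste(which(dup) + 1L, collapse = ", "))
  for (col in intersect(c("chi", "k", "alpha", "phi", "length", "v", "a"),
                        names(df))) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(x) & !is.na(df[[col]])
    if (any(bad))
      stop(sprintf("non-numeric value in column '%s' at line(s) %s", col,
                   paste(which(bad) + 1L, collapse = ", ")))
    if (any(x < 0, na.rm = TRUE))
      stop(sprintf("negative value in column '%s'", col))
    df[[col]] <- x
  }
  df$is_ribosomal <- as.logical(df$is_ribosomal)
  if (!"alpha" %in% names(df)) {
    warning("no 'alpha' column: assuming non-degradable proteins (alpha = 0)")
    df$alpha <- 0
  }
  if (all(c("v", "a") %in% names(df))) {
    relerr <- abs(df$k - df$v * df$a) / pmax(df$k, .Machine$double.xmin)
    if (any(relerr > 1e-9))
      stop("inconsistent speeds: k != v * a beyond 1e-9 relative")
  }
  for (col in c("chi", "phi")) {
    s <- sum(df[[col]])
    if (abs(s - 1) > 1e-6)
      stop(sprintf("fraction column '%s' sums to %.8g, expected 1", col, s))
  }
  p <- switch(calibration, none = 0, length_pow_057 = 0.57,
              length_pow_1 = 1)
  if (p > 0) {
    df$phi <- df$phi * df$length^(-p)
    df$phi <- df$phi / sum(df$phi)
  }
  df
}

#' Write a gene-level table
#'
#' Writes the tab-separated dialect read by [readGeneTable()], with full
#' numeric precision so a write/read round trip is lossless.
#'
#' @param records gene-record data.frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeGeneTable <- function(records, path) {
  df <- as.data.frame(records)
  df[] <- lapply(df, function(x)
    if (is.numeric(x)) format(x, digits = 17) else x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate ribosomal records into effective coarse-grained parameters
#'
#' The coarse-grained ribosomal protein's effective translation speed is
#' the allocation-weighted mean speed over ribosomal records (allocations
#' renormalized within the ribosomal set) and its degradation rate the
#' mass-fraction-weighted mean rate.  The effective ribosome mass is the
#' summed molecular mass (length x mean amino-acid mass) of detected
#' ribosomal proteins; when a \code{paralog_group} column is present, a
#' detected paralog pair contributes the average of its two masses once.
#'
#' @param records gene-record data.frame (as from [readGeneTable()]).
#' @return named vector \code{c(kR = , alphaR = , mR = )}.
#' @export
aggregateRibosomal <- function(records) {
  rb <- records[records$is_ribosomal, , drop = FALSE]
  if (nrow(rb) == 0L)
    stop("aggregation error: no ribosomal records")
  a <- if ("a" %in% names(rb)) rb$a else rep(110, nrow(rb))
  mass <- rb$length * a
  if ("paralog_group" %in% names(rb) && any(!is.na(rb$paralog_group))) {
    grp <- as.character(rb$paralog_group)
    grp[is.na(grp) | grp == ""] <- paste0(".single", seq_len(nrow(rb)))[
      is.na(rb$paralog_group) | rb$paralog_group == ""]
    mR <- sum(tapply(mass, grp, mean))
  } else {
    mR <- sum(mass)
  }
  alpha <- if ("alpha" %in% names(rb)) rb$alpha else rep(0, nrow(rb))
  c(kR = sum(rb$chi / sum(rb$chi) * rb$k),
    alphaR = sum(rb$phi / sum(rb$phi) * alpha),
    mR = mR)
}

#' Environment metrics from a gene table
#'
#' Computes, over non-ribosomal genes, the arithmetic means
#' \eqn{\langle k\rangle} and \eqn{\langle\alpha\rangle}, the correlation
#' indices \eqn{I_{\chi,k}} and \eqn{I_{\phi,\alpha}}, the weighted
#' averages \eqn{\langle k\rangle_\chi} and
#' \eqn{\langle\alpha\rangle_\phi}, and the ribosomal aggregates from
#' [aggregateRibosomal()].
#'
#' @param records gene-record data.frame.
#' @return named list of metrics.
#' @export
geneTableMetrics <- function(records) {
  nr <- records[!records$is_ribosomal, , drop = FALSE]
  if (nrow(nr) < 2L) stop("need at least 2 non-ribosomal genes")
  ct <- nr$chi / sum(nr$chi)
  pt <- nr$phi / sum(nr$phi)
  agg <- aggregateRibosomal(records)
  list(meanK = mean(nr$k), meanAlpha = mean(nr$alpha),
       IChiK = correlationIndex(ct, nr$k),
       IPhiAlpha = if (mean(nr$alpha) > 0)
         correlationIndex(pt, nr$alpha) else 0,
       kChi = sum(nr$k * ct), alphaPhi = sum(nr$alpha * pt),
       kR = unname(agg["kR"]), alphaR = unname(agg["alphaR"]),
       mREffective = unname(agg["mR"]),
       phiRibosomal = sum(records$phi[records$is_ribosomal]))
}

#' Growth rate from an OD600 time series
#'
#' Sliding 5-point linear regressions of ln(OD600) against time locate the
#' steepest stretch of the curve; all points belonging to windows whose
#' slope is at least 95\% of the maximum window slope are pooled (each
#' point used once) and a single regression over the pooled points gives
#' the growth rate.  The estimate is invariant to uniform time shifts and
#' to rescaling the OD values.
#'
#' @param times strictly increasing sampling times, min.
#' @param od positive OD600 readings.
#' @param window window width in points (default 5).
#' @param threshold fraction of the maximum window slope a window must
#'   reach to be included (default 0.95).
#' @return growth rate, 1/min.
#' @examples
#' t <- seq(0, 500, by = 5)
#' growthRateFromOD(t, 0.05 * exp(0.01 * t))  # 0.01
#' @export
growthRateFromOD <- function(times, od, window = 5L, threshold = 0.95) {
  if (length(times) != length(od)) stop("times and od lengths differ")
  if (length(times) < window)
    stop(sprintf("insufficient data: need at least %d points", window))
  if (any(od <= 0)) stop("domain error: OD values must be positive")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  y <- log(od)
  nW <- length(times) - window + 1L
  slopes <- vapply(seq_len(nW), function(i) {
    idx <- i:(i + window - 1L)
    tt <- times[idx]
    stats::cov(tt, y[idx]) / stats::var(tt)
  }, numeric(1))
  mx <- max(slopes)
  cut <- if (mx > 0) threshold * mx else mx
  sel <- which(slopes >= cut)
  pts <- sort(unique(unlist(lapply(sel, function(i) i:(i + window - 1L)))))
  tt <- times[pts]
  unname(stats::cov(tt, y[pts]) / stats::var(tt))
}

#' Read a growth-law dataset
#'
#' Comma-separated with header; columns \code{mu} (1/min), \code{phi_R},
#' optional \code{condition}.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readGrowthLawData <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mu", "phi_R") %in% names(df)))
    stop("growth-law CSV must have columns mu and phi_R")
  if (!is.numeric(df$mu) || !is.numeric(df$phi_R))
    stop("non-numeric values in mu/phi_R")
  df
}

#' Write a growth-law dataset
#'
#' @param data data.frame with columns \code{mu}, \code{phi_R} (and
#'   optionally \code{condition}).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeGrowthLawData <- function(data, path) {
  df <- as.data.frame(data)
  df[] <- lapply(df, function(x)
    if (is.numeric(x)) format(x, digits = 17) else x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an OD600 time series (CSV: time_min, od)
#'
#' @param path CSV file path.
#' @return data.frame with columns \code{time_min}, \code{od}.
#' @export
readODCurve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_min", "od") %in% names(df)))
    stop("OD CSV must have columns time_min and od")
  df
}

#' @rdname readODCurve
#' @param data data.frame with columns \code{time_min}, \code{od}.
#' @export
writeODCurve <- function(data, path) {
  df <- as.data.frame(data)
  df[] <- lapply(df, function(x)
    if (is.numeric(x)) format(x, digits = 17) else x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit result as JSON
#'
#' Serializes point estimates, 95\% confidence intervals, RMSE, sample
#' size, and any inversion settings for provenance.
#'
#' @param fit a [GrowthLawFit-class].
#' @param path output JSON path.
#' @param settings optional named list recorded verbatim (e.g. alphaR,
#'   alphaPhi, mR used for inversion).
#' @return \code{path}, invisibly.
#' @export
writeFitResult <- function(fit, path, settings = list()) {
  stopifnot(is(fit, "GrowthLawFit"))
  obj <- list(coefficients = as.list(curveCoefficients(fit)),
              ci95 = list(c1 = unname(confint95(fit)[1, ]),
                          c2 = unname(confint95(fit)[2, ]),
                          c3 = unname(confint95(fit)[3, ])),
              rmse = fitRMSE(fit), n = fit@nObs, settings = settings,
              package_version = as.character(utils::packageVersion(
                "riboGrowthLaw")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Materialize a synthetic study as files
#'
#' Writes one gene TSV and one OD CSV per condition plus a growth-law CSV
#' of the true (mu, phi_R) pairs — the small on-disk fixture set used by
#' the test suite and examples.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
writeStudyTables <- function(study, dir) {
  stopifnot(is(study, "SyntheticStudy"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nC <- length(study@states)
  genePaths <- odPaths <- character(nC)
  for (j in seq_len(nC)) {
    genePaths[j] <- file.path(dir, sprintf("condition%02d_genes.tsv", j))
    writeGeneTable(study@tables[[j]], genePaths[j])
    odPaths[j] <- file.path(dir, sprintf("condition%02d_od.csv", j))
    writeODCurve(study@odCurves[[j]], odPaths[j])
  }
  glPath <- file.path(dir, "growth_law.csv")
  writeGrowthLawData(
    data.frame(mu = vapply(study@states, growthRate, numeric(1)),
               phi_R = vapply(study@states, phiR, numeric(1))), glPath)
  invisible(list(genes = genePaths, od = odPaths, growthLaw = glPath))
}
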