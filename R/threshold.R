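#' Window correlations restricted to a spectral region
#'
#' Computes [windowCorrelations()] on the variables inside a ppm region, per
#' interval, keeping only windows that lie entirely inside the region. Used to
#' contrast the correlation structure of a metabolite-dominated region
#' against a noise-dominated one when choosing the clustering threshold.
#'
#' @param s a \linkS4class{SpectraSet}.
#' @param region a \code{RegionMask} (or anything [regionMask()] accepts).
#' @param st window size.
#' @param cm correlation method.
#' @return numeric vector of window average correlations, with the window
#'   anchor ppm values as the \code{"anchors"} attribute.
#' @export
regionWindowCorrs <- function(s, region, st = 4L,
                              cm = c("pearson", "spearman")) {
    cm <- match.arg(cm)
    if (!inherits(region, "RegionMask")) region <- regionMask(region)
    p <- ppm(s)
    vals <- numeric(0)
    anchors <- numeric(0)
    for (i in seq_len(nrow(region))) {
        idx <- which(p >= region[i, "lo"] & p <= region[i, "hi"])
        if (length(idx) < st) next
        sub <- SpectraSet(intensityMatrix(s)[, idx, drop = FALSE],
                          ppm = p[idx], sampleIds = sampleIds(s),
                          qcFlags = qcFlags(s))
        cs <- windowCorrelations(sub, st, cm)
        vals <- c(vals, rBar(cs))
        anchors <- c(anchors, ppmAnchor(cs))
    }
    if (!length(vals))
        stop("region contains fewer than st variables", call. = FALSE)
    attr(vals, "anchors") <- anchors
    vals
}

#' Data-driven selection of the correlation threshold
#'
#' Contrasts window correlations from a noise-dominated region against a
#' metabolite-dominated region and places the threshold at the point where
#' the empirical cumulative distribution of the noise correlations reaches 1
#' — i.e. at the top of the noise sample — so that, by construction, no
#' window lying entirely inside the noise region exceeds the threshold.
#'
#' The selected value is rounded up at the \code{digits}-th decimal (default
#' 3, the customary reporting precision for correlation thresholds), which
#' guarantees strict clearance of the noise maximum. An optional
#' \code{quantile} below 1 gives a robustified variant that tolerates a
#' fraction of extreme noise windows.
#'
#' @param noise numeric vector of noise-region window correlations (from
#'   [regionWindowCorrs()]).
#' @param signal numeric vector of signal-region window correlations.
#' @param quantile noise quantile defining the threshold (default 1 = the
#'   maximum).
#' @param digits decimal at which the threshold is rounded up (default 3).
#' @param noiseRegion,signalRegion optional \code{RegionMask}s recorded in
#'   the result for provenance.
#' @return a \linkS4class{CtSelection}; extract the threshold with
#'   [selectedCt()]. The \code{signalSurvival} slot reports the fraction of
#'   signal-region windows at or above the threshold (a sensitivity
#'   diagnostic: a low value warns that the threshold also suppresses
#'   metabolic signal).
#' @examples
#' selectCt(noise = c(0.1, 0.2, 0.3), signal = c(0.85, 0.9, 0.95))
#' @export
selectCt <- function(noise, signal, quantile = 1, digits = 3L,
                     noiseRegion = NULL, signalRegion = NULL) {
    if (!length(noise) || !length(signal))
        stop("both correlation samples must be nonempty", call. = FALSE)
    q <- as.numeric(stats::quantile(noise, quantile, names = FALSE, type = 7))
    ct <- ceiling(q * 10^digits) / 10^digits
    ct <- min(ct, 1)
    emptyRegion <- matrix(numeric(0), ncol = 2L,
                          dimnames = list(NULL, c("lo", "hi")))
    asRegion <- function(r) {
        if (is.null(r)) return(emptyRegion)
        if (!inherits(r, "RegionMask")) r <- regionMask(r)
        matrix(as.numeric(r), ncol = 2L,
               dimnames = list(NULL, c("lo", "hi")))
    }
    methods::new("CtSelection", ct = ct,
                 noiseCorrs = as.numeric(noise),
                 signalCorrs = as.numeric(signal),
                 noiseRegion = asRegion(noiseRegion),
                 signalRegion = asRegion(signalRegion),
                 signalSurvival = mean(signal >= ct),
                 quantile = quantile)
}
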