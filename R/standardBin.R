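#' Parameters of equidistant ("standard") binning
#'
#' @param width_ppm bin width in ppm (default 0.005).
#' @param int aggregation statistic, as in [jbaParams()] (default sum: the
#'   area under each bin replaces the individual intensities).
#' @return a validated parameter list of class \code{SbParams}.
#' @export
sbParams <- function(width_ppm = 0.005,
                     int = c("sum", "mean", "median", "max")) {
    int <- match.arg(int)
    if (!is.numeric(width_ppm) || width_ppm <= 0)
        stop("width_ppm must be > 0", call. = FALSE)
    structure(list(width_ppm = width_ppm, int = int), class = "SbParams")
}

#' Equidistant binning baseline
#'
#' Partitions the axis into half-open intervals \code{[lo, lo + width)}
#' anchored at the lowest ppm; every nonempty interval becomes a cluster,
#' so the bins partition the variable set exactly (no loss, no overlap).
#'
#' @param s a \linkS4class{SpectraSet}.
#' @param p an [sbParams()] record.
#' @return a \linkS4class{BinnedSet} with \code{binMethod() == "SB"}.
#' @examples
#' s <- SpectraSet(matrix(rnorm(40), 4), ppm = seq(0.40, 0.49, by = 0.01))
#' standardBin(s, sbParams(width_ppm = 0.05))  # 2 bins of 5 variables
#' @export
standardBin <- function(s, p = sbParams()) {
    stopifnot(inherits(p, "SbParams"))
    pv <- ppm(s)
    ## guard against representation error putting a grid point just below its
    ## bin edge
    binOf <- floor((pv - pv[1L]) / p$width_ppm + 1e-9)
    starts <- which(!duplicated(binOf))
    ends <- c(starts[-1L] - 1L, length(pv))
    z <- .standardize(intensityMatrix(s), "pearson")
    clusters <- list(
        start_idx = starts, end_idx = ends,
        seed_idx = rep(NA_integer_, length(starts)),
        r_bar = vapply(seq_along(starts), function(i)
            if (ends[i] > starts[i]) .meanPairCor(z, starts[i]:ends[i])
            else NA_real_, 1),
        members = lapply(seq_along(starts), function(i) starts[i]:ends[i]))
    .binnedFromClusters(clusters, s, "SB", p, p$int)
}
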