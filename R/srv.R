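#' Parameters of statistical recoupling of variables (SRV)
#'
#' @param minsize minimum number of variables a segment must contain to be
#'   retained as a cluster (default 10, the number of points sampling a
#'   well-defined singlet at typical resolution).
#' @param int aggregation statistic, as in [jbaParams()].
#' @param super_r Pearson threshold above which neighbouring retained clusters
#'   are aggregated into superclusters (default 0.90).
#' @return a validated parameter list of class \code{SrvParams}.
#' @seealso [runSRV()]
#' @export
srvParams <- function(minsize = 10L, int = c("sum", "mean", "median", "max"),
                      super_r = 0.90) {
    int <- match.arg(int)
    minsize <- as.integer(minsize)
    if (minsize < 2L) stop("minsize must be >= 2", call. = FALSE)
    if (super_r < 0 || super_r > 1)
        stop("super_r must lie in [0, 1]", call. = FALSE)
    structure(list(minsize = minsize, int = int, super_r = super_r),
              class = "SrvParams")
}

#' Spectral dependency landscape
#'
#' For each pair of adjacent variables along the chemical-shift axis, the
#' covariance/correlation ratio \code{cov(x_i, x_{i+1}) / cor(x_i, x_{i+1})}
#' (Pearson, n-1 denominator), which algebraically equals
#' \code{sd(x_i) * sd(x_{i+1})}. Peaks of the landscape follow intensity
#' peaks; its local minima mark cluster edges. Degenerate pairs (a
#' zero-variance member, or exactly zero correlation) are assigned 0, forcing
#' an edge at dead regions.
#'
#' @param s a \linkS4class{SpectraSet} with at least 3 samples.
#' @return numeric vector of length \code{nVariables(s) - 1}, aligned to the
#'   lower-ppm member of each pair.
#' @export
dependencyLandscape <- function(s) {
    if (nSamples(s) < 3L)
        stop("at least 3 samples are required", call. = FALSE)
    x <- intensityMatrix(s)
    v <- ncol(x)
    n <- nrow(x)
    ctr <- sweep(x, 2L, colMeans(x), `-`)
    covs <- colSums(ctr[, -v, drop = FALSE] * ctr[, -1L, drop = FALSE]) /
        (n - 1)
    sds <- sqrt(colSums(ctr^2) / (n - 1))
    cors <- covs / (sds[-v] * sds[-1L])
    out <- covs / cors
    out[!is.finite(out) | cors == 0] <- 0
    unname(out)
}

#' Segment spectra into clusters at dependency-landscape minima
#'
#' Cluster edges are the strict interior local minima of
#' [dependencyLandscape()] (plateaus: one edge at the run's lowest-ppm
#' position; runs touching the landscape ends never qualify, since the axis
#' ends are already implicit edges).
#' The boundary sits between the minimum pair's two variables, i.e. after the
#' lower-ppm member. Segments with at least \code{minsize} variables become
#' clusters; smaller segments are neglected.
#'
#' @param s a \linkS4class{SpectraSet}.
#' @param p an [srvParams()] record.
#' @return a \linkS4class{BinnedSet} with \code{binMethod() == "SRV"}
#'   (before superclustering; see [superClusters()] and [runSRV()]).
#' @export
srvClusters <- function(s, p = srvParams()) {
    stopifnot(inherits(p, "SrvParams"))
    d <- dependencyLandscape(s)
    v <- nVariables(s)
    minima <- .extremeRuns(d, "min", interior = TRUE)
    ## boundary after variable index m for each landscape minimum at m
    bounds <- sort(unique(c(0L, minima, v)))
    starts <- utils::head(bounds, -1L) + 1L
    ends <- bounds[-1L]
    keep <- (ends - starts + 1L) >= p$minsize
    starts <- starts[keep]
    ends <- ends[keep]
    z <- .standardize(intensityMatrix(s), "pearson")
    clusters <- list(
        start_idx = starts, end_idx = ends,
        seed_idx = rep(NA_integer_, length(starts)),
        r_bar = vapply(seq_along(starts), function(i)
            .meanPairCor(z, starts[i]:ends[i]), 1),
        members = lapply(seq_along(starts), function(i) starts[i]:ends[i]))
    .binnedFromClusters(clusters, s, "SRV", p, p$int)
}

#' Aggregate neighbouring correlated SRV clusters into superclusters
#'
#' Clusters adjacent in the retained list whose aggregated intensity vectors
#' have Pearson correlation above \code{super_r} are merged, iterating to a
#' fixpoint, so that a multiplet split across several segments is represented
#' by one supercluster. The merged member set is the union of the parents'
#' members; variables in discarded segments between them are not re-included.
#'
#' @param s the source \linkS4class{SpectraSet}.
#' @param b an SRV \linkS4class{BinnedSet} from [srvClusters()].
#' @param p an [srvParams()] record.
#' @return a \linkS4class{BinnedSet}.
#' @export
superClusters <- function(s, b, p = srvParams()) {
    stopifnot(inherits(p, "SrvParams"))
    rd <- clusterInfo(b)
    clusters <- list(start_idx = rd$start_idx, end_idx = rd$end_idx,
                     seed_idx = rd$seed_idx, r_bar = rd$r_bar,
                     members = as.list(rd$members))
    x <- intensityMatrix(s)
    z <- .standardize(x, "pearson")
    clusters <- .mergePass(clusters, x, z, ppm(s), p$int, "pearson",
                           p$super_r, Inf, "list")
    .binnedFromClusters(clusters, s, "SRV", binParams(b), p$int)
}

#' Run the full SRV pipeline
#'
#' [srvClusters()] followed by [superClusters()].
#'
#' @inheritParams srvClusters
#' @return a \linkS4class{BinnedSet} with \code{binMethod() == "SRV"}.
#' @export
runSRV <- function(s, p = srvParams()) {
    superClusters(s, srvClusters(s, p), p)
}
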