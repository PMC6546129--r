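# Correlation machinery shared by the binning methods.
#
# All correlation work runs on a column-standardized copy Z of the
# samples-by-variables matrix: cor(x_i, x_j) = crossprod(Z[, i], Z[, j]).
# A zero-variance variable gets an all-zero Z column, which implements the
# convention that its pairwise correlations are 0 (a constant column carries
# no metabolic covariance and must never seed or join a cluster). Spearman
# mode rank-transforms each column first, so Spearman = Pearson on ranks and
# the same machinery serves both.

# Standardize columns so that crossprod(Z) is the correlation matrix.
.standardize <- function(x, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    x <- as.matrix(x)
    if (method == "spearman")
        x <- apply(x, 2L, rank)
    n <- nrow(x)
    ctr <- sweep(x, 2L, colMeans(x), `-`)
    ss <- sqrt(colSums(ctr^2))
    ss[ss == 0] <- Inf          # zero-variance -> zero column -> cor 0
    sweep(ctr, 2L, ss, `/`)
}

# Lag-L correlations: c[i] = cor(x_i, x_{i+L}), length V - L.
.lagCor <- function(z, L) {
    v <- ncol(z)
    colSums(z[, seq_len(v - L), drop = FALSE] *
            z[, (L + 1L):v, drop = FALSE])
}

# Mean of all pairwise correlations among the variables in `idx` (>= 2).
.meanPairCor <- function(z, idx) {
    k <- length(idx)
    r <- crossprod(z[, idx, drop = FALSE])
    (sum(r) - sum(diag(r))) / (k * (k - 1))
}

#' Sliding-window average-correlation spectrum
#'
#' Scans the spectra from low to high ppm with a window of \code{st} adjacent
#' variables (step one) and computes, for each window, the mean of all
#' \code{st*(st-1)/2} pairwise correlations among the window's variables. The
#' result can be displayed like a spectrum ("pseudo-NMR spectrum"): windows
#' sitting on a metabolite peak have high average correlation because all
#' member variables are driven by the same underlying concentration, whereas
#' windows in noise regions do not.
#'
#' @param s a \linkS4class{SpectraSet} with at least 3 samples.
#' @param st window size (also the minimum cluster size downstream), >= 2.
#' @param cm correlation method, \code{"pearson"} or \code{"spearman"}.
#' @return a \linkS4class{CorrelationSpectrum} with one value per window,
#'   anchored at the window's first (lowest-ppm) variable.
#' @details Zero-variance variables contribute 0-valued correlation pairs.
#'   The implementation computes lag-1 .. lag-(st-1) correlation vectors once
#'   and combines them with rolling sums, which is algebraically identical to
#'   the brute-force loop over all pairs in every window but linear in the
#'   number of variables.
#' @examples
#' set.seed(1)
#' s <- SpectraSet(matrix(rnorm(200), 20), ppm = seq(1, 1.09, by = 0.01))
#' windowCorrelations(s, st = 4)
#' @export
windowCorrelations <- function(s, st, cm = c("pearson", "spearman")) {
    cm <- match.arg(cm)
    st <- as.integer(st)
    v <- nVariables(s)
    if (st < 2L) stop("st must be >= 2", call. = FALSE)
    if (st > v) stop("st exceeds the number of variables", call. = FALSE)
    if (nSamples(s) < 3L)
        stop("at least 3 samples are required for correlations",
             call. = FALSE)
    z <- .standardize(intensityMatrix(s), cm)
    nwin <- v - st + 1L
    tot <- numeric(nwin)
    for (L in seq_len(st - 1L)) {
        cl <- .lagCor(z, L)
        ## window i needs sum of cl[i .. i + st - 1 - L]
        w <- st - L
        cs <- c(0, cumsum(cl))
        tot <- tot + (cs[(seq_len(nwin)) + w] - cs[seq_len(nwin)])
    }
    rbar <- tot / (st * (st - 1) / 2)
    ## clamp tiny numerical excursions
    rbar <- pmin(1, pmax(-1, rbar))
    methods::new("CorrelationSpectrum",
                 ppmAnchor = ppm(s)[seq_len(nwin)], rBar = rbar,
                 st = st, method = cm)
}

# Runs of equal values that are strict local extrema of a vector.
# Returns the index of the first element of each qualifying run.
# type = "max": run value strictly greater than both flanking run values
# (runs at the vector ends compare only to their single neighbour);
# type = "min": mirrored. With interior = TRUE, runs touching the vector ends
# never qualify (both flanks must exist) — used for segmentation edges, where
# the axis ends are already implicit boundaries.
.extremeRuns <- function(x, type = c("max", "min"), interior = FALSE) {
    type <- match.arg(type)
    r <- rle(x)
    k <- length(r$values)
    if (k == 0L) return(integer(0))
    if (k == 1L) return(if (interior) integer(0) else 1L)
    starts <- cumsum(c(1L, r$lengths[-k]))
    left <- c(NA, r$values[-k])
    right <- c(r$values[-1L], NA)
    ok <- if (type == "max") {
        (is.na(left) | r$values > left) & (is.na(right) | r$values > right)
    } else {
        (is.na(left) | r$values < left) & (is.na(right) | r$values < right)
    }
    if (interior) ok <- ok & !is.na(left) & !is.na(right)
    starts[ok]
}
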