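#' @include AllGenerics.R
NULL

#' SpectraSet: a set of pJRES spectra on a common chemical-shift axis
#'
#' Container for a samples-by-variables intensity matrix together with its ppm
#' axis. Internally the data live in a \link[SummarizedExperiment]{SummarizedExperiment}
#' with spectral variables as rows (rowData column \code{ppm}) and samples as
#' columns (colData column \code{qc}); the user-facing accessors present the
#' matrix in the samples-by-variables orientation used throughout NMR
#' metabonomics.
#'
#' Invariants enforced by the validity method:
#' \itemize{
#'   \item \code{ppm} is numeric, finite, strictly increasing, no duplicates
#'     (readers sort decreasing axes into increasing order);
#'   \item no missing intensities;
#'   \item one qc flag per sample.
#' }
#'
#' The increasing-ppm orientation fixes the spectroscopic vocabulary used by
#' every scanning operation: "downfield" means higher ppm, "upfield" lower ppm.
#'
#' @slot .dummy unused; all data are carried by the SummarizedExperiment
#'   representation.
#' @aliases SpectraSet-class
#' @seealso [readSpectra()], [applyMask()], [runJBA()]
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
    rd <- SummarizedExperiment::rowData(object)
    if (!"ppm" %in% colnames(rd))
        return("rowData must contain a 'ppm' column")
    p <- rd$ppm
    if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)))
        return("ppm must be finite numeric")
    if (anyDuplicated(p))
        return("duplicate ppm values")
    if (is.unsorted(p, strictly = TRUE))
        return("ppm must be strictly increasing")
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        return("assay 'intensity' missing")
    if (anyNA(SummarizedExperiment::assay(object, "intensity")))
        return("missing intensities are not allowed")
    cd <- SummarizedExperiment::colData(object)
    if (!"qc" %in% colnames(cd) || !is.logical(cd$qc) || anyNA(cd$qc))
        return("colData must contain a complete logical 'qc' column")
    TRUE
})

#' Construct a SpectraSet
#'
#' @param intensity numeric matrix, samples in rows, spectral variables in
#'   columns.
#' @param ppm numeric vector of chemical shifts, one per variable. May be
#'   decreasing (the usual plotting order of NMR spectra); it is stored
#'   increasing and the columns of \code{intensity} are reordered to match.
#' @param sampleIds character vector of sample identifiers; defaults to the
#'   rownames of \code{intensity} or \code{sample_1 ...}.
#' @param qcFlags logical vector marking pooled QC samples (default all
#'   \code{FALSE}).
#'
#' @return a \linkS4class{SpectraSet}.
#' @examples
#' x <- matrix(rnorm(20), nrow = 4)
#' s <- SpectraSet(x, ppm = seq(1.00, 1.04, by = 0.01))
#' nVariables(s)
#' @export
SpectraSet <- function(intensity, ppm, sampleIds = NULL, qcFlags = NULL) {
    intensity <- as.matrix(intensity)
    storage.mode(intensity) <- "double"
    if (length(ppm) != ncol(intensity))
        stop("length(ppm) must equal ncol(intensity)", call. = FALSE)
    if (anyNA(intensity))
        stop("missing intensities are not allowed", call. = FALSE)
    if (anyDuplicated(ppm))
        stop("duplicate ppm values", call. = FALSE)
    ord <- order(ppm)
    ppm <- as.numeric(ppm[ord])
    intensity <- intensity[, ord, drop = FALSE]
    if (is.null(sampleIds))
        sampleIds <- if (!is.null(rownames(intensity))) rownames(intensity)
                     else paste0("sample_", seq_len(nrow(intensity)))
    sampleIds <- as.character(sampleIds)
    if (length(sampleIds) != nrow(intensity) || anyDuplicated(sampleIds))
        stop("sampleIds must be unique, one per sample", call. = FALSE)
    dimnames(intensity) <- NULL
    if (is.null(qcFlags)) qcFlags <- rep(FALSE, nrow(intensity))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = t(intensity)),
        rowData = S4Vectors::DataFrame(ppm = ppm),
        colData = S4Vectors::DataFrame(qc = as.logical(qcFlags),
                                       row.names = sampleIds))
    methods::new("SpectraSet", se)
}

#' BinnedSet: binned spectra plus the clusters that produced them
#'
#' Output container shared by all three binning methods. Rows of the underlying
#' SummarizedExperiment are clusters (rowData columns: \code{start_idx},
#' \code{end_idx}, \code{n_variables}, \code{ppm_start}, \code{ppm_end},
#' \code{seed_idx}, \code{seed_ppm}, \code{r_bar}, and the member-variable
#' index list \code{members}); columns are samples. \code{metadata} records the
#' method label and the full parameter list.
#'
#' Clusters are ordered by starting ppm and their member index sets are
#' pairwise disjoint. \code{seed_idx}/\code{seed_ppm} are \code{NA} for
#' methods without seeds (SRV, SB). \code{r_bar} is the mean of all pairwise
#' correlations among member variables (\code{NA} for singleton clusters).
#'
#' @aliases BinnedSet-class
#' @seealso [runJBA()], [runSRV()], [standardBin()], [writeBins()]
#' @export
setClass("BinnedSet", contains = "SummarizedExperiment")

setValidity("BinnedSet", function(object) {
    rd <- SummarizedExperiment::rowData(object)
    need <- c("start_idx", "end_idx", "n_variables", "ppm_start", "ppm_end",
              "seed_idx", "seed_ppm", "r_bar", "members")
    if (!all(need %in% colnames(rd)))
        return(paste("rowData must contain:", paste(need, collapse = ", ")))
    md <- S4Vectors::metadata(object)
    if (is.null(md$method) || !md$method %in% c("JBA", "SRV", "SB"))
        return("metadata$method must be one of JBA, SRV, SB")
    if (nrow(rd) > 0L) {
        if (is.unsorted(rd$ppm_start))
            return("clusters must be ordered by start ppm")
        mem <- unlist(rd$members, use.names = FALSE)
        if (anyDuplicated(mem))
            return("cluster member index sets must be pairwise disjoint")
        if (any(rd$start_idx > rd$end_idx))
            return("start_idx must be <= end_idx")
    }
    TRUE
})

# Internal constructor: `clusters` is a data.frame-like with columns start_idx,
# end_idx, seed_idx (NA allowed), r_bar, and a list column `members`; Y is the
# samples-by-clusters aggregated intensity matrix.
.BinnedSet <- function(clusters, Y, sampleIds, ppm, method, params,
                       qcFlags = NULL) {
    n <- length(clusters$start_idx)
    members <- IRanges::IntegerList(clusters$members)
    rd <- S4Vectors::DataFrame(
        start_idx = as.integer(clusters$start_idx),
        end_idx = as.integer(clusters$end_idx),
        n_variables = lengths(members),
        ppm_start = if (n) ppm[clusters$start_idx] else numeric(0),
        ppm_end = if (n) ppm[clusters$end_idx] else numeric(0),
        seed_idx = as.integer(clusters$seed_idx),
        seed_ppm = if (n) ifelse(is.na(clusters$seed_idx), NA_real_,
                                 ppm[ifelse(is.na(clusters$seed_idx), 1L,
                                            clusters$seed_idx)])
                   else numeric(0),
        r_bar = as.numeric(clusters$r_bar),
        members = members,
        row.names = if (n) paste0("cluster_", seq_len(n)) else NULL)
    if (is.null(qcFlags)) qcFlags <- rep(FALSE, length(sampleIds))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = t(Y)),
        rowData = rd,
        colData = S4Vectors::DataFrame(qc = as.logical(qcFlags),
                                       row.names = sampleIds),
        metadata = list(method = method, params = params))
    methods::new("BinnedSet", se)
}

#' CorrelationSpectrum: sliding-window average correlations
#'
#' The "pseudo-NMR spectrum" scanned for peak seeds: for each window of
#' \code{st} adjacent spectral variables, the mean of all \code{st*(st-1)/2}
#' pairwise correlations, anchored at the window's first (lowest-ppm)
#' variable.
#'
#' @slot ppmAnchor numeric, ppm of each window's first variable.
#' @slot rBar numeric, average correlation per window, in [-1, 1] (windows
#'   containing zero-variance variables contribute 0-valued pairs).
#' @slot st integer window size.
#' @slot method correlation method, \code{"pearson"} or \code{"spearman"}.
#' @aliases CorrelationSpectrum-class
#' @seealso [windowCorrelations()], [findSeeds()]
#' @export
setClass("CorrelationSpectrum",
         representation(ppmAnchor = "numeric", rBar = "numeric",
                        st = "integer", method = "character"))

setValidity("CorrelationSpectrum", function(object) {
    if (length(object@ppmAnchor) != length(object@rBar))
        return("ppmAnchor and rBar must have equal length")
    if (any(object@rBar > 1 + 1e-8 | object@rBar < -1 - 1e-8))
        return("rBar values must lie in [-1, 1]")
    if (object@st < 2L) return("st must be >= 2")
    TRUE
})

#' CtSelection: result of the data-driven correlation-threshold choice
#'
#' @slot ct selected correlation threshold.
#' @slot noiseCorrs window correlations from the noise-dominated region.
#' @slot signalCorrs window correlations from the metabolite-dominated region.
#' @slot noiseRegion,signalRegion the ppm intervals used (2-column matrices).
#' @slot signalSurvival fraction of signal-region windows with correlation at
#'   or above \code{ct} (sensitivity diagnostic).
#' @slot quantile quantile of the noise sample used (1 = maximum, the point
#'   where the empirical noise CDF reaches 1).
#' @aliases CtSelection-class
#' @seealso [selectCt()]
#' @export
setClass("CtSelection",
         representation(ct = "numeric", noiseCorrs = "numeric",
                        signalCorrs = "numeric", noiseRegion = "matrix",
                        signalRegion = "matrix", signalSurvival = "numeric",
                        quantile = "numeric"))

## ---- accessors --------------------------------------------------------------

#' @rdname pjresbin-generics
#' @export
setMethod("ppm", "SpectraSet", function(x)
    SummarizedExperiment::rowData(x)$ppm)

#' @rdname pjresbin-generics
#' @export
setMethod("intensityMatrix", "SpectraSet", function(x) {
    m <- t(SummarizedExperiment::assay(x, "intensity"))
    rownames(m) <- colnames(x)
    m
})

#' @rdname pjresbin-generics
#' @export
setMethod("intensityMatrix", "BinnedSet", function(x) {
    m <- t(SummarizedExperiment::assay(x, "intensity"))
    rownames(m) <- colnames(x)
    m
})

#' @rdname pjresbin-generics
#' @export
setMethod("sampleIds", "SpectraSet", function(x) colnames(x))

#' @rdname pjresbin-generics
#' @export
setMethod("sampleIds", "BinnedSet", function(x) colnames(x))

#' @rdname pjresbin-generics
#' @export
setMethod("qcFlags", "SpectraSet", function(x)
    SummarizedExperiment::colData(x)$qc)

#' @rdname pjresbin-generics
#' @export
setMethod("qcFlags", "BinnedSet", function(x)
    SummarizedExperiment::colData(x)$qc)

#' @rdname pjresbin-generics
#' @export
setMethod("nVariables", "SpectraSet", function(x) nrow(x))

#' @rdname pjresbin-generics
#' @export
setMethod("nSamples", "SpectraSet", function(x) ncol(x))

#' @rdname pjresbin-generics
#' @export
setMethod("nSamples", "BinnedSet", function(x) ncol(x))

#' @rdname pjresbin-generics
#' @export
setMethod("clusterInfo", "BinnedSet", function(x)
    SummarizedExperiment::rowData(x))

#' @rdname pjresbin-generics
#' @export
setMethod("binMethod", "BinnedSet", function(x)
    S4Vectors::metadata(x)$method)

#' @rdname pjresbin-generics
#' @export
setMethod("binParams", "BinnedSet", function(x)
    S4Vectors::metadata(x)$params)

#' @rdname pjresbin-generics
#' @export
setMethod("rBar", "CorrelationSpectrum", function(x) x@rBar)

#' @rdname pjresbin-generics
#' @export
setMethod("ppmAnchor", "CorrelationSpectrum", function(x) x@ppmAnchor)

## ---- show methods -----------------------------------------------------------

setMethod("show", "SpectraSet", function(object) {
    p <- ppm(object)
    cat("SpectraSet:", ncol(object), "samples x", nrow(object),
        "spectral variables\n")
    if (length(p))
        cat(sprintf("  ppm range: %.4f .. %.4f (median step %.5g)\n",
                    min(p), max(p), stats::median(diff(p))))
    nqc <- sum(qcFlags(object))
    if (nqc) cat("  QC samples:", nqc, "\n")
})

setMethod("show", "BinnedSet", function(object) {
    cat("BinnedSet (", binMethod(object), "): ", nrow(object),
        " clusters x ", ncol(object), " samples\n", sep = "")
    rd <- SummarizedExperiment::rowData(object)
    if (nrow(rd)) {
        cat(sprintf("  cluster sizes: %d .. %d variables (median %g)\n",
                    min(rd$n_variables), max(rd$n_variables),
                    stats::median(rd$n_variables)))
        cat(sprintf("  ppm coverage: %.4f .. %.4f\n",
                    min(rd$ppm_start), max(rd$ppm_end)))
    }
})

setMethod("show", "CorrelationSpectrum", function(object) {
    cat("CorrelationSpectrum:", length(object@rBar), "windows (st =",
        object@st, ",", object@method, ")\n")
    if (length(object@rBar))
        cat(sprintf("  r_bar range: %.3f .. %.3f\n", min(object@rBar),
                    max(object@rBar)))
})

setMethod("show", "CtSelection", function(object) {
    cat(sprintf("CtSelection: ct = %.3f (noise quantile %g)\n",
                object@ct, object@quantile))
    cat(sprintf("  noise windows: %d (max %.3f); signal windows: %d (%.1f%% >= ct)\n",
                length(object@noiseCorrs), max(object@noiseCorrs),
                length(object@signalCorrs), 100 * object@signalSurvival))
})

#' @rdname CtSelection-class
#' @param x a \code{CtSelection}.
#' @export
selectedCt <- function(x) {
    stopifnot(methods::is(x, "CtSelection"))
    x@ct
}
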