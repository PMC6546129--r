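#' Read a spectra matrix from delimited text
#'
#' Expected layout: header row = chemical shifts in ppm (first field is the
#' sample-id column label and may be anything non-numeric, e.g.
#' \code{sample_id} or empty), one row per sample, first column = sample
#' identifier, remaining cells = intensities. Decreasing ppm axes (the usual
#' presentation order of NMR spectra) are reversed to the internal increasing
#' orientation.
#'
#' @param path path to a CSV or TSV file.
#' @param dialect \code{"csv"} or \code{"tsv"}; by default guessed from the
#'   file extension.
#' @return a \linkS4class{SpectraSet}.
#' @details Missing intensities are rejected (there is no imputation: upstream
#'   processing should have produced a complete matrix). Duplicate ppm values
#'   or a non-numeric header are format errors.
#' @seealso [writeSpectra()], [applyMask()]
#' @export
readSpectra <- function(path, dialect = c("auto", "csv", "tsv")) {
    dialect <- match.arg(dialect)
    sep <- switch(dialect,
                  csv = ",",
                  tsv = "\t",
                  auto = if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE))
                      "\t" else ",")
    header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
    if (length(header) < 3L)
        stop("spectra file must have >= 2 variables", call. = FALSE)
    ppmv <- suppressWarnings(as.numeric(header[-1L]))
    if (anyNA(ppmv))
        stop("format error: header row must be numeric ppm values",
             call. = FALSE)
    if (anyDuplicated(ppmv))
        stop("format error: duplicate ppm values in header", call. = FALSE)
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            colClasses = list(character = 1L),
                            data.table = FALSE, showProgress = FALSE)
    if (nrow(dt) < 2L)
        stop("spectra file must have >= 2 samples", call. = FALSE)
    ids <- as.character(dt[[1L]])
    x <- as.matrix(dt[, -1L, drop = FALSE])
    storage.mode(x) <- "double"
    if (anyNA(x))
        stop("data error: missing intensities in spectra file", call. = FALSE)
    SpectraSet(x, ppm = ppmv, sampleIds = ids)
}

#' Write a SpectraSet to delimited text
#'
#' Inverse of [readSpectra()]: header row of ppm values (full double
#' precision, so that a read/write round trip is lossless), one row per
#' sample.
#'
#' @param s a \linkS4class{SpectraSet}.
#' @param path output file path.
#' @param dialect \code{"csv"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeSpectra <- function(s, path, dialect = c("csv", "tsv")) {
    dialect <- match.arg(dialect)
    sep <- if (dialect == "csv") "," else "\t"
    x <- intensityMatrix(s)
    ## %.17g round-trips doubles exactly; fwrite's numeric formatting does not
    chr <- matrix(sprintf("%.17g", x), nrow = nrow(x))
    body <- data.table::as.data.table(chr)
    data.table::setnames(body, sprintf("%.17g", ppm(s)))
    out <- cbind(data.table::data.table(sample_id = sampleIds(s)), body)
    data.table::fwrite(out, path, sep = sep, quote = FALSE)
    invisible(path)
}

#' Region masks on the chemical-shift axis
#'
#' A \code{RegionMask} is a set of closed ppm intervals, normalized (sorted,
#' overlapping or touching intervals merged), used to exclude solvent/EDTA
#' regions or to select analysis windows.
#'
#' @param intervals a 2-column matrix or a list of length-2 numeric vectors of
#'   \code{c(lo, hi)} ppm bounds (either order).
#' @return an object of class \code{RegionMask}: a 2-column numeric matrix
#'   (columns \code{lo}, \code{hi}).
#' @examples
#' regionMask(list(c(4.50, 5.00), c(4.90, 5.10)))  # merged to [4.5, 5.1]
#' @export
regionMask <- function(intervals) {
    if (is.matrix(intervals)) {
        m <- intervals
    } else if (is.numeric(intervals) && length(intervals) == 2L) {
        m <- matrix(intervals, nrow = 1L)
    } else {
        m <- do.call(rbind, lapply(intervals, function(iv) {
            stopifnot(length(iv) == 2L)
            as.numeric(iv)
        }))
    }
    if (is.null(m) || nrow(m) == 0L) {
        m <- matrix(numeric(0), ncol = 2L)
    } else {
        m <- t(apply(m, 1L, sort))
        m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
        ## merge overlapping/touching closed intervals
        keep <- list(m[1L, ])
        if (nrow(m) > 1L) for (i in 2:nrow(m)) {
            last <- keep[[length(keep)]]
            if (m[i, 1L] <= last[2L]) {
                keep[[length(keep)]] <- c(last[1L], max(last[2L], m[i, 2L]))
            } else keep[[length(keep) + 1L]] <- m[i, ]
        }
        m <- do.call(rbind, keep)
    }
    colnames(m) <- c("lo", "hi")
    class(m) <- c("RegionMask", class(m))
    m
}

#' @rdname regionMask
#' @param s a \linkS4class{SpectraSet}.
#' @param mask a \code{RegionMask} (or anything [regionMask()] accepts).
#' @param mode \code{"exclude"} drops variables whose ppm falls in any
#'   interval; \code{"select"} keeps only those. Intervals are closed on both
#'   ends, matching the inclusive region notation customary in NMR.
#' @return \code{applyMask}: a \linkS4class{SpectraSet} restricted to the
#'   surviving variables (ordering preserved).
#' @export
applyMask <- function(s, mask, mode = c("exclude", "select")) {
    mode <- match.arg(mode)
    if (!inherits(mask, "RegionMask")) mask <- regionMask(mask)
    p <- ppm(s)
    inside <- rep(FALSE, length(p))
    if (nrow(mask)) for (i in seq_len(nrow(mask)))
        inside <- inside | (p >= mask[i, "lo"] & p <= mask[i, "hi"])
    keep <- if (mode == "exclude") !inside else inside
    if (sum(keep) < 2L)
        stop("data error: fewer than 2 variables remain after masking",
             call. = FALSE)
    SpectraSet(intensityMatrix(s)[, keep, drop = FALSE], ppm = p[keep],
               sampleIds = sampleIds(s), qcFlags = qcFlags(s))
}

#' Write a cluster table
#'
#' One row per cluster with columns \code{cluster_id}, \code{ppm_start},
#' \code{ppm_end}, \code{n_variables}, \code{seed_ppm} (empty for methods
#' without seeds), \code{mean_window_correlation}, followed by one aggregated
#' intensity column per sample, in a deterministic order.
#'
#' @param b a \linkS4class{BinnedSet}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @seealso [readBins()]
#' @export
writeBins <- function(b, path) {
    rd <- clusterInfo(b)
    y <- intensityMatrix(b)
    n <- nrow(rd)
    dt <- data.table::data.table(
        cluster_id = if (n) seq_len(n) else integer(0),
        ppm_start = if (n) sprintf("%.17g", rd$ppm_start) else character(0),
        ppm_end = if (n) sprintf("%.17g", rd$ppm_end) else character(0),
        n_variables = if (n) rd$n_variables else integer(0),
        seed_ppm = if (n) ifelse(is.na(rd$seed_ppm), "",
                                 sprintf("%.17g", rd$seed_ppm))
                   else character(0),
        mean_window_correlation = if (n) sprintf("%.17g", rd$r_bar)
                                  else character(0))
    body <- data.table::as.data.table(
        matrix(sprintf("%.17g", t(y)), nrow = n, ncol = length(sampleIds(b))))
    data.table::setnames(body, sampleIds(b))
    data.table::fwrite(cbind(dt, body), path, quote = FALSE)
    invisible(path)
}

#' Read a cluster table written by [writeBins()]
#'
#' @param path path to the CSV.
#' @return a data.frame with the cluster columns plus one intensity column per
#'   sample (\code{seed_ppm} is \code{NA} where empty).
#' @export
readBins <- function(path) {
    dt <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
    if (nrow(dt) && is.character(dt$seed_ppm))
        dt$seed_ppm <- suppressWarnings(as.numeric(dt$seed_ppm))
    dt
}

#' Read an external metabolite-concentration table
#'
#' Layout: first column = sample id, remaining columns = one metabolite each
#' (header = metabolite name), cells = concentrations (e.g. GC-MS peak areas).
#'
#' @param path CSV path.
#' @return a list with elements \code{concentrations} (samples x metabolites
#'   numeric matrix, rownames = sample ids) and \code{metaboliteNames}.
#' @seealso [crossCorrelate()]
#' @export
readMetaboliteTable <- function(path) {
    dt <- data.table::fread(path, colClasses = list(character = 1L),
                            data.table = FALSE, showProgress = FALSE)
    ids <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    list(concentrations = m, metaboliteNames = colnames(m))
}
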