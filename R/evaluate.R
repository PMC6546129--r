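# Cross-correlation of binned features with external metabolite
# concentrations, paired method comparison, and PCA diagnostics.

# Feature matrix + per-feature ppm interval from either container.
.featureTable <- function(features) {
    if (methods::is(features, "BinnedSet")) {
        rd <- clusterInfo(features)
        list(x = intensityMatrix(features),
             lo = rd$ppm_start, hi = rd$ppm_end,
             mid = (rd$ppm_start + rd$ppm_end) / 2,
             ids = sampleIds(features))
    } else if (methods::is(features, "SpectraSet")) {
        p <- ppm(features)
        list(x = intensityMatrix(features), lo = p, hi = p, mid = p,
             ids = sampleIds(features))
    } else stop("features must be a BinnedSet or a SpectraSet",
                call. = FALSE)
}

#' Cross-correlate features with external metabolite concentrations
#'
#' Spearman correlations between every feature (binned cluster or
#' full-resolution variable) and every metabolite over the shared samples.
#' Per metabolite, the reported coefficient is the maximum over features —
#' restricted to the metabolite's resonance window(s) when \code{match}
#' provides them; a metabolite with no feature in its window is flagged
#' not detected (ND). The maximum (not maximum absolute) is used because
#' concentrations and resonance intensities are positively related.
#'
#' @param features a \linkS4class{BinnedSet} or \linkS4class{SpectraSet}.
#' @param met a metabolite table as returned by [readMetaboliteTable()], or a
#'   samples-by-metabolites numeric matrix with sample ids as rownames.
#' @param match optional named list mapping metabolite names to ppm windows
#'   (anything [regionMask()] accepts); a feature matches when its ppm
#'   interval overlaps a window.
#' @return a list of class \code{CrossCorResult}: \code{table} (data.frame
#'   with \code{metabolite}, \code{r_best}, \code{ppm_best},
#'   \code{detected}), \code{correlations} (features x metabolites Spearman
#'   matrix) and \code{n_shared} samples.
#' @export
crossCorrelate <- function(features, met, match = NULL) {
    ft <- .featureTable(features)
    conc <- if (is.list(met) && !is.null(met$concentrations))
        met$concentrations else as.matrix(met)
    shared <- intersect(ft$ids, rownames(conc))
    if (length(shared) < 3L)
        stop("data error: fewer than 3 shared samples", call. = FALSE)
    fx <- ft$x[base::match(shared, ft$ids), , drop = FALSE]
    mx <- conc[shared, , drop = FALSE]
    cc <- stats::cor(fx, mx, method = "spearman")
    mets <- colnames(mx)
    if (is.null(mets)) mets <- paste0("metabolite_", seq_len(ncol(mx)))
    res <- data.frame(metabolite = mets, r_best = NA_real_,
                      ppm_best = NA_real_, detected = FALSE)
    for (j in seq_along(mets)) {
        inWin <- rep(TRUE, nrow(cc))
        if (!is.null(match) && mets[j] %in% names(match)) {
            win <- regionMask(match[[mets[j]]])
            inWin <- rep(FALSE, nrow(cc))
            for (k in seq_len(nrow(win)))
                inWin <- inWin | (ft$hi >= win[k, "lo"] &
                                  ft$lo <= win[k, "hi"])
        }
        if (!any(inWin)) next   # ND
        r <- cc[inWin, j]
        best <- which.max(r)
        res$r_best[j] <- r[best]
        res$ppm_best[j] <- ft$mid[inWin][best]
        res$detected[j] <- TRUE
    }
    structure(list(table = res, correlations = cc,
                   n_shared = length(shared)),
              class = "CrossCorResult")
}

#' @export
print.CrossCorResult <- function(x, ...) {
    cat("CrossCorResult:", nrow(x$table), "metabolites x",
        nrow(x$correlations), "features (", x$n_shared, "shared samples )\n")
    nd <- sum(!x$table$detected)
    if (nd) cat("  not detected (ND):", nd, "\n")
    print(utils::head(x$table, 10L))
    invisible(x)
}

#' Paired signed-rank comparison of two methods' correlation profiles
#'
#' Two-sided Wilcoxon signed-rank test on per-metabolite best correlation
#' coefficients paired by metabolite. Pairs with a missing coefficient (a
#' metabolite not detected under one method) are dropped, as are zero
#' differences (standard signed-rank practice). The exact distribution is
#' used for up to 25 informative pairs when the absolute differences are
#' untied; otherwise the normal approximation with continuity correction.
#'
#' @param a,b numeric coefficient vectors of equal length (NA = not
#'   detected).
#' @return a list with \code{statistic} (V), \code{p.value}, \code{n.used}
#'   (informative pairs), \code{exact}, and \code{degenerate} (TRUE with
#'   \code{p.value = NA} when no nonzero differences remain).
#' @examples
#' compareMethodsPaired(c(.9, .8, .85, .7, .95, .6),
#'                      c(.7, .75, .8, .5, .9, .55))
#' @export
compareMethodsPaired <- function(a, b) {
    if (length(a) != length(b))
        stop("coefficient vectors must be paired (equal length)",
             call. = FALSE)
    if (length(a) < 5L)
        stop("at least 5 metabolite pairs are required", call. = FALSE)
    keep <- !(is.na(a) | is.na(b))
    d <- a[keep] - b[keep]
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L)
        return(list(statistic = NA_real_, p.value = NA_real_, n.used = 0L,
                    exact = NA, degenerate = TRUE))
    exact <- n <= 25L && !anyDuplicated(abs(d))
    wt <- suppressWarnings(
        stats::wilcox.test(d, alternative = "two.sided", mu = 0,
                           exact = exact, correct = TRUE))
    list(statistic = unname(wt$statistic), p.value = wt$p.value,
         n.used = n, exact = exact, degenerate = FALSE)
}

#' PCA diagnostics of a feature matrix
#'
#' Column-wise scaling (\code{"mean_center"}, or \code{"unit_variance"} =
#' mean-centre then divide by the column standard deviation, dropping
#' zero-variance columns with a warning), singular value decomposition,
#' scores, loadings, the cumulative explained-variance curve over the first
#' \code{n_pc} components (squared singular values over their total), and
#' the 95\% Hotelling T-squared ellipse for the first two scores — the
#' standard QC display for metabolic-profiling runs.
#'
#' @param features a \linkS4class{BinnedSet}, \linkS4class{SpectraSet} or
#'   samples-by-features numeric matrix.
#' @param scaling \code{"mean_center"} or \code{"unit_variance"}.
#' @param n_pc number of principal components to report (>= 2, less than the
#'   number of samples).
#' @return a list of class \code{PcaDiagnostics}: \code{scores},
#'   \code{loadings}, \code{var_explained}, \code{cum_var},
#'   \code{hotelling} (list with semi-axis lengths \code{a}, \code{b} and
#'   critical value \code{t2}), \code{scaling}, \code{n_dropped}.
#' @export
pcaDiagnostics <- function(features,
                           scaling = c("mean_center", "unit_variance"),
                           n_pc = 10L) {
    scaling <- match.arg(scaling)
    x <- if (is.matrix(features)) features else .featureTable(features)$x
    n_pc <- as.integer(n_pc)
    if (n_pc < 2L) stop("n_pc must be >= 2", call. = FALSE)
    if (nrow(x) <= n_pc)
        stop("n_pc must be smaller than the number of samples",
             call. = FALSE)
    sds <- apply(x, 2L, stats::sd)
    dropped <- 0L
    if (scaling == "unit_variance") {
        bad <- sds == 0
        if (any(bad)) {
            warning(sum(bad), " zero-variance column(s) dropped before ",
                    "unit-variance scaling")
            x <- x[, !bad, drop = FALSE]
            sds <- sds[!bad]
            dropped <- sum(bad)
        }
    }
    if (ncol(x) < 2L)
        stop("data error: fewer than 2 non-degenerate columns", call. = FALSE)
    x <- sweep(x, 2L, colMeans(x), `-`)
    if (scaling == "unit_variance") x <- sweep(x, 2L, sds, `/`)
    pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
    varex <- pc$sdev^2 / sum(pc$sdev^2)
    k <- min(n_pc, length(varex))
    n <- nrow(x)
    t2 <- 2 * (n - 1) / (n - 2) * stats::qf(0.95, 2, n - 2)
    hot <- list(a = sqrt(stats::var(pc$x[, 1L]) * t2),
                b = sqrt(stats::var(pc$x[, 2L]) * t2),
                t2 = t2)
    structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                   loadings = pc$rotation[, seq_len(k), drop = FALSE],
                   var_explained = varex[seq_len(k)],
                   cum_var = cumsum(varex)[seq_len(k)],
                   hotelling = hot, scaling = scaling,
                   n_dropped = dropped),
              class = "PcaDiagnostics")
}

#' @export
print.PcaDiagnostics <- function(x, ...) {
    cat("PcaDiagnostics (", x$scaling, "): ", nrow(x$scores), " samples, ",
        length(x$cum_var), " PCs\n", sep = "")
    cat("  cumulative variance:",
        paste(sprintf("%.3f", x$cum_var), collapse = " "), "\n")
    invisible(x)
}
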