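#' Parameters of the correlation-guided binning algorithm
#'
#' @param st integer window size and minimum (pre-merge) cluster size, >= 2.
#'   Should cover the narrowest well-resolved peak at the data's digital
#'   resolution; 4 suits typical pJRES plasma spectra.
#' @param ct correlation threshold in [-1, 1]: the minimum average pairwise
#'   correlation a window/cluster must reach to count as a metabolic signal.
#'   Choose it with [selectCt()] (noise vs signal region contrast) or set it
#'   explicitly.
#' @param cm correlation method used throughout (windows, expansion,
#'   neighbour merging): \code{"pearson"} or \code{"spearman"}.
#' @param int aggregation statistic turning a cluster's member intensities
#'   into one feature per sample: \code{"sum"} (default), \code{"mean"},
#'   \code{"median"} or \code{"max"}.
#' @param merge_r correlation threshold above which adjacent clusters are
#'   integrated into one (split-peak repair), default 0.90.
#' @param merge_gap_ppm maximum ppm gap between clusters eligible for merging;
#'   the default 0 restricts merging to index-adjacent clusters. A small
#'   positive value lets fragments separated by 1-2 unclustered points (peak
#'   misalignment) merge; the merged cluster spans the gap.
#' @return a validated parameter list of class \code{JbaParams}.
#' @seealso [runJBA()]
#' @export
jbaParams <- function(st = 4L, ct = NA_real_,
                      cm = c("pearson", "spearman"),
                      int = c("sum", "mean", "median", "max"),
                      merge_r = 0.90, merge_gap_ppm = 0) {
    cm <- match.arg(cm)
    int <- match.arg(int)
    st <- as.integer(st)
    if (st < 2L) stop("st must be >= 2", call. = FALSE)
    if (!is.na(ct) && (ct < -1 || ct > 1))
        stop("ct must lie in [-1, 1]", call. = FALSE)
    if (merge_r < 0 || merge_r > 1)
        stop("merge_r must lie in [0, 1]", call. = FALSE)
    if (merge_gap_ppm < 0)
        stop("merge_gap_ppm must be >= 0", call. = FALSE)
    structure(list(st = st, ct = ct, cm = cm, int = int, merge_r = merge_r,
                   merge_gap_ppm = merge_gap_ppm),
              class = "JbaParams")
}

#' Detect seed windows in a correlation spectrum
#'
#' Seeds are windows whose average correlation reaches the threshold and is a
#' local maximum: each is taken as the optimal size-\code{st} cluster of the
#' underlying peak, to be grown by [expandSeed()]. A plateau (maximal run of
#' equal values strictly above both flanking values) yields one seed at its
#' lowest-ppm anchor; runs at the spectrum ends compare only to their single
#' neighbour.
#'
#' @param cs a \linkS4class{CorrelationSpectrum}.
#' @param ct correlation threshold.
#' @return integer vector of window anchor indices (1-based, increasing ppm).
#' @export
findSeeds <- function(cs, ct) {
    stopifnot(methods::is(cs, "CorrelationSpectrum"))
    anchors <- .extremeRuns(cs@rBar, "max")
    sort(anchors[cs@rBar[anchors] >= ct])
}

# Directional admissibility of a candidate variable (increasing-ppm indices).
# side = "down" (downfield, higher ppm, growing right) or "up" (upfield,
# lower ppm, growing left). c1 is the lag-1 correlation vector
# (c1[i] = cor(v_i, v_{i+1})). A candidate passes when it correlates at least
# as strongly with its neighbour toward the cluster as with its neighbour
# away from it; a missing away-neighbour (spectrum edge) passes.
.sideRule <- function(c1, i, v, side) {
    if (side == "down") {          # toward-cluster neighbour is v_{i-1}
        if (i >= v) return(TRUE)   # no v_{i+1}
        c1[i] <= c1[i - 1L]
    } else {                       # toward-cluster neighbour is v_{i+1}
        if (i <= 1L) return(TRUE)  # no v_{i-1}
        c1[i] >= c1[i - 1L]
    }
}

#' Expand a seed window into a cluster
#'
#' Grows the size-\code{st} seed window symmetrically, alternating a downfield
#' (higher-ppm) candidate with an upfield one. A candidate variable joins only
#' while (i) the cluster's average pairwise correlation stays at or above
#' \code{ct} and (ii) the candidate correlates at least as strongly with its
#' neighbour toward the cluster as with its neighbour away from it
#' (the directional monotonicity expected on a peak flank). A side closes
#' permanently at its first failure, at the spectrum edge, or at a variable
#' already claimed by a stronger seed.
#'
#' @param s a \linkS4class{SpectraSet}.
#' @param seed anchor index of the seed window (from [findSeeds()]).
#' @param p a [jbaParams()] record with a finite \code{ct}.
#' @param occupied integer vector of variable indices already claimed by
#'   previously expanded clusters. If the seed window itself intersects
#'   \code{occupied} the seed is dropped (returns \code{NULL}).
#' @return a list describing the cluster (\code{start_idx}, \code{end_idx},
#'   \code{seed_idx}, \code{r_bar}, \code{members}), or \code{NULL} for a
#'   dropped seed.
#' @export
expandSeed <- function(s, seed, p, occupied = integer(0)) {
    stopifnot(inherits(p, "JbaParams"), !is.na(p$ct))
    z <- .standardize(intensityMatrix(s), p$cm)
    c1 <- .lagCor(z, 1L)
    .expandSeed(z, c1, seed, p, occupied, ppm(s))
}

# Worker: z and c1 precomputed by the caller (runJBA computes them once).
.expandSeed <- function(z, c1, seed, p, occupied, ppmv) {
    v <- ncol(z)
    lo <- seed
    hi <- seed + p$st - 1L
    if (any(lo:hi %in% occupied)) return(NULL)
    occ <- logical(v)
    occ[occupied] <- TRUE
    members <- lo:hi
    ## incremental all-pairs mean: track the sum of pairwise correlations
    rmat <- crossprod(z[, members, drop = FALSE])
    pairSum <- (sum(rmat) - sum(diag(rmat))) / 2
    npairs <- p$st * (p$st - 1L) / 2
    openDown <- TRUE
    openUp <- TRUE
    while (openDown || openUp) {
        for (side in c("down", "up")) {
            if (side == "down" && !openDown) next
            if (side == "up" && !openUp) next
            cand <- if (side == "down") hi + 1L else lo - 1L
            admissible <- cand >= 1L && cand <= v && !occ[cand] &&
                .sideRule(c1, cand, v, side)
            if (admissible) {
                add <- sum(crossprod(z[, members, drop = FALSE], z[, cand]))
                k <- length(members)
                newRbar <- (pairSum + add) / (npairs + k)
                admissible <- newRbar >= p$ct
                if (admissible) {
                    pairSum <- pairSum + add
                    npairs <- npairs + k
                    if (side == "down") hi <- cand else lo <- cand
                    members <- lo:hi
                }
            }
            if (!admissible) {
                if (side == "down") openDown <- FALSE else openUp <- FALSE
            }
        }
    }
    list(start_idx = lo, end_idx = hi, seed_idx = seed,
         r_bar = pairSum / npairs, members = list(lo:hi))
}

#' Aggregate a cluster's member intensities into one value per sample
#'
#' @param s a \linkS4class{SpectraSet}.
#' @param members integer vector of member variable indices (or a cluster
#'   list as returned by [expandSeed()]).
#' @param int aggregation statistic: \code{"sum"}, \code{"mean"},
#'   \code{"median"} or \code{"max"}.
#' @return numeric vector, one aggregated intensity per sample.
#' @export
aggregateIntensity <- function(s, members,
                               int = c("sum", "mean", "median", "max")) {
    int <- match.arg(int)
    if (is.list(members)) members <- unlist(members$members)
    .aggregate(intensityMatrix(s), members, int)
}

.aggregate <- function(x, members, int) {
    xm <- x[, members, drop = FALSE]
    switch(int,
           sum = rowSums(xm),
           mean = rowMeans(xm),
           median = apply(xm, 1L, stats::median),
           max = apply(xm, 1L, max))
}

# Shared merge engine.
# clusters: list with vectors start_idx, end_idx, seed_idx, r_bar and list
# column members, ordered by start_idx.
# adjacency = "gap": eligible when the ppm gap between consecutive clusters
#   (beyond one nominal step) is <= gap_ppm; the merged cluster spans the gap
#   (contiguous fill). Used by the correlation-guided method.
# adjacency = "list": any consecutive pair in the retained list is eligible;
#   the merged member set is the union of the parents' members (discarded
#   gap variables are not re-included). Used for superclustering.
.mergePass <- function(clusters, x, z, ppmv, int, cm, merge_r, gap_ppm,
                       adjacency) {
    step <- stats::median(diff(ppmv))
    eps <- 1e-9
    repeat {
        n <- length(clusters$start_idx)
        if (n < 2L) break
        merged <- FALSE
        y <- do.call(cbind, lapply(clusters$members,
                                   function(m) .aggregate(x, m, int)))
        i <- 1L
        while (i < length(clusters$start_idx)) {
            eligible <- if (adjacency == "gap") {
                gap <- ppmv[clusters$start_idx[i + 1L]] -
                       ppmv[clusters$end_idx[i]] - step
                gap <= gap_ppm + eps
            } else TRUE
            if (eligible) {
                r <- stats::cor(y[, i], y[, i + 1L], method = cm)
                eligible <- !is.na(r) && r > merge_r
            }
            if (eligible) {
                newMembers <- if (adjacency == "gap")
                    clusters$start_idx[i]:clusters$end_idx[i + 1L]
                else sort(c(clusters$members[[i]],
                            clusters$members[[i + 1L]]))
                ## keep the seed of the more strongly correlated parent
                keepSeed <- if (is.na(clusters$r_bar[i + 1L]) ||
                                (!is.na(clusters$r_bar[i]) &&
                                 clusters$r_bar[i] >= clusters$r_bar[i + 1L]))
                    clusters$seed_idx[i] else clusters$seed_idx[i + 1L]
                clusters$start_idx[i] <- clusters$start_idx[i]
                clusters$end_idx[i] <- clusters$end_idx[i + 1L]
                clusters$seed_idx[i] <- keepSeed
                clusters$members[[i]] <- newMembers
                clusters$r_bar[i] <- if (length(newMembers) > 1L)
                    .meanPairCor(z, newMembers) else NA_real_
                idx <- setdiff(seq_along(clusters$start_idx), i + 1L)
                clusters <- list(start_idx = clusters$start_idx[idx],
                                 end_idx = clusters$end_idx[idx],
                                 seed_idx = clusters$seed_idx[idx],
                                 r_bar = clusters$r_bar[idx],
                                 members = clusters$members[idx])
                ## recompute intensities after the merge before moving on
                y <- do.call(cbind, lapply(clusters$members,
                                           function(m) .aggregate(x, m, int)))
                merged <- TRUE
            } else {
                i <- i + 1L
            }
        }
        if (!merged) break
    }
    clusters
}

#' Merge adjacent clusters that carry the same underlying signal
#'
#' Peak misalignment or overlap can split one peak into several clusters;
#' such fragments are detected by the correlation of their aggregated
#' intensity vectors and re-integrated. Passes run left to right and repeat
#' until no adjacent pair with ppm gap at most \code{merge_gap_ppm} (default:
#' index-adjacent only) has correlation above \code{merge_r}; intensities are
#' recomputed after every merge, so chains of mutually correlated fragments
#' collapse transitively.
#'
#' @param s the \linkS4class{SpectraSet} the clusters were derived from.
#' @param b a \linkS4class{BinnedSet}.
#' @param p a [jbaParams()] record (\code{merge_r}, \code{merge_gap_ppm},
#'   \code{cm}, \code{int} are used).
#' @return a \linkS4class{BinnedSet} with merged clusters.
#' @export
mergeNeighbours <- function(s, b, p) {
    stopifnot(inherits(p, "JbaParams"))
    rd <- clusterInfo(b)
    clusters <- list(start_idx = rd$start_idx, end_idx = rd$end_idx,
                     seed_idx = rd$seed_idx, r_bar = rd$r_bar,
                     members = as.list(rd$members))
    x <- intensityMatrix(s)
    z <- .standardize(x, p$cm)
    clusters <- .mergePass(clusters, x, z, ppm(s), p$int, p$cm,
                           p$merge_r, p$merge_gap_ppm, "gap")
    .binnedFromClusters(clusters, s, binMethod(b), binParams(b), p$int)
}

.binnedFromClusters <- function(clusters, s, method, params, int) {
    x <- intensityMatrix(s)
    n <- length(clusters$start_idx)
    Y <- if (n) do.call(cbind, lapply(clusters$members,
                                      function(m) .aggregate(x, m, int)))
         else matrix(numeric(0), nrow = nSamples(s), ncol = 0L)
    .BinnedSet(clusters, Y, sampleIds(s), ppm(s), method, params,
               qcFlags = qcFlags(s))
}

#' Run the full correlation-guided binning pipeline
#'
#' Orchestrates [windowCorrelations()] (sliding-window average correlations,
#' low to high ppm), [findSeeds()] (local maxima at or above \code{ct}),
#' [expandSeed()] for every seed in order of decreasing window correlation
#' (ties broken toward lower ppm; variables claimed by stronger seeds are
#' unavailable and a seed whose window is already partly claimed is dropped),
#' intensity aggregation, and [mergeNeighbours()].
#'
#' @param s a \linkS4class{SpectraSet}.
#' @param p a [jbaParams()] record; \code{p$ct} must be set (use
#'   [selectCt()] for a data-driven choice).
#' @return a \linkS4class{BinnedSet} with \code{binMethod() == "JBA"}.
#' @examples
#' spec <- plasmaLikeScenario(nSamples = 40, seed = 7)
#' sim <- generateSpectra(spec)
#' ## threshold from the scenario's designated regions, then bin
#' ct <- selectCt(
#'   regionWindowCorrs(sim$spectra, spec$regions$noise, st = 4),
#'   regionWindowCorrs(sim$spectra, spec$regions$signal, st = 4))
#' b <- runJBA(sim$spectra, jbaParams(st = 4, ct = selectedCt(ct)))
#' b
#' @export
runJBA <- function(s, p = jbaParams()) {
    stopifnot(inherits(p, "JbaParams"))
    if (is.na(p$ct))
        stop("ct is not set; choose it with selectCt() or set it explicitly",
             call. = FALSE)
    cs <- windowCorrelations(s, p$st, p$cm)
    seeds <- findSeeds(cs, p$ct)
    x <- intensityMatrix(s)
    z <- .standardize(x, p$cm)
    c1 <- .lagCor(z, 1L)
    ## strongest evidence first; ties toward lower ppm
    seeds <- seeds[order(-cs@rBar[seeds], seeds)]
    occupied <- integer(0)
    built <- list()
    for (sd in seeds) {
        cl <- .expandSeed(z, c1, sd, p, occupied, ppm(s))
        if (is.null(cl)) next
        occupied <- c(occupied, cl$start_idx:cl$end_idx)
        built[[length(built) + 1L]] <- cl
    }
    if (length(built)) {
        ord <- order(vapply(built, `[[`, 1L, "start_idx"))
        built <- built[ord]
        clusters <- list(
            start_idx = vapply(built, `[[`, 1L, "start_idx"),
            end_idx = vapply(built, `[[`, 1L, "end_idx"),
            seed_idx = vapply(built, `[[`, 1L, "seed_idx"),
            r_bar = vapply(built, `[[`, 1, "r_bar"),
            members = lapply(built, function(cl) cl$members[[1L]]))
    } else {
        clusters <- list(start_idx = integer(0), end_idx = integer(0),
                         seed_idx = integer(0), r_bar = numeric(0),
                         members = list())
    }
    clusters <- .mergePass(clusters, x, z, ppm(s), p$int, p$cm,
                           p$merge_r, p$merge_gap_ppm, "gap")
    .binnedFromClusters(clusters, s, "JBA", p, p$int)
}
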