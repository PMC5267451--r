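#' Match calls to simulated truth SV
#'
#' A call is a candidate true positive when it covers at least
#' \code{minFraction} of a truth SV of the same type (insertions: breakpoints
#' within \code{insWindow} bp).  Candidates are matched one-to-one, greedily by
#' descending fraction with a deterministic positional tie-break, so two calls
#' covering the same truth SV yield exactly one true positive.
#'
#' @param calls,truth \code{SVCallSet}s.
#' @param minFraction matching threshold (default 0.5).
#' @param mode \code{"truth"}: fraction of the truth SV covered (default);
#'   \code{"reciprocal"}: threshold must hold in both directions.
#' @param insWindow insertion breakpoint window, bp.
#' @return \code{data.frame} with columns \code{call}, \code{truth} (indices)
#'   and \code{fraction}.
#' @export
matchCallsToTruth <- function(calls, truth, minFraction = 0.5,
                              mode = c("truth", "reciprocal"),
                              insWindow = 25) {
    mode <- match.arg(mode)
    stopifnot(is(calls, "SVCallSet"), is(truth, "SVCallSet"))
    grC <- svCalls(calls)
    grT <- svCalls(truth)
    cand <- .pairCandidates(grC, grT, minOverlap = 1, insWindow = insWindow,
                            requireSample = FALSE)
    if (nrow(cand)) {
        frac <- overlapFractionOfTruth(grC[cand$i], grT[cand$j],
                                       insWindow = insWindow, mode = mode)
        cand$score <- frac
        cand <- cand[frac >= minFraction, , drop = FALSE]
    }
    sel <- .greedySelect(cand, grC, grT)
    data.frame(call = sel$i, truth = sel$j, fraction = sel$score)
}

#' Precision of a call set
#'
#' True positives divided by total calls.  With zero calls the precision is
#' undefined and reported as NA, not 0.
#'
#' @param nTruePositive,nCalls counts.
#' @return fraction, or NA when \code{nCalls} is 0.
#' @export
svPrecision <- function(nTruePositive, nCalls) {
    if (any(nTruePositive > nCalls))
        stop("more true positives than calls")
    ifelse(nCalls == 0, NA_real_, nTruePositive / nCalls)
}

#' Sensitivity of a call set
#'
#' True positives divided by the number of simulated truth variants.
#'
#' @param nTruePositive,nTruth counts; \code{nTruth} must be positive.
#' @return fraction.
#' @export
svSensitivity <- function(nTruePositive, nTruth) {
    if (any(nTruth == 0))
        stop("sensitivity undefined: no truth variants")
    if (any(nTruePositive > nTruth))
        stop("more true positives than truth variants")
    nTruePositive / nTruth
}

## per-type TP/call/truth counts for one replicate
.benchmarkCounts <- function(calls, truth, minFraction, mode, insWindow,
                             types) {
    m <- matchCallsToTruth(calls, truth, minFraction, mode, insWindow)
    tpType <- svType(truth)[m$truth]
    vapply(types, function(tp) {
        c(n_truth = sum(svType(truth) == tp),
          n_calls = sum(svType(calls) == tp),
          n_tp = sum(tpType == tp))
    }, numeric(3))
}

#' Benchmark call sets against replicated simulated truth
#'
#' Computes precision and sensitivity per method and SV type across simulation
#' replicates.  The default averaging follows the ratio-of-means convention:
#' precision is the average number of true positives divided by the average
#' number of calls (and likewise sensitivity over the average number of truth
#' variants); \code{average = "mean_of_ratios"} averages the per-replicate
#' ratios instead.
#'
#' @param truthReps list of truth \code{SVCallSet}s, one per replicate.
#' @param callsByMethod named list; each element is a list of call
#'   \code{SVCallSet}s parallel to \code{truthReps}.
#' @param minFraction,mode,insWindow see \code{\link{matchCallsToTruth}}.
#' @param average \code{"ratio_of_means"} (default) or
#'   \code{"mean_of_ratios"}.
#' @return \code{data.frame} with one row per method and SV type: mean counts,
#'   \code{precision} and \code{sensitivity}.  The per-replicate counts are
#'   attached as attribute \code{"replicates"}.
#' @export
evaluateScenario <- function(truthReps, callsByMethod, minFraction = 0.5,
                             mode = c("truth", "reciprocal"), insWindow = 25,
                             average = c("ratio_of_means",
                                         "mean_of_ratios")) {
    mode <- match.arg(mode)
    average <- match.arg(average)
    stopifnot(is.list(truthReps), is.list(callsByMethod),
              !is.null(names(callsByMethod)))
    nrep <- length(truthReps)
    if (!all(lengths(callsByMethod) == nrep))
        stop("every method needs one call set per truth replicate")
    types <- sort(unique(unlist(lapply(truthReps, svType))))
    perRep <- list()
    for (meth in names(callsByMethod)) {
        for (r in seq_len(nrep)) {
            cnt <- .benchmarkCounts(callsByMethod[[meth]][[r]],
                                    truthReps[[r]], minFraction, mode,
                                    insWindow, types)
            perRep[[length(perRep) + 1L]] <- data.frame(
                method = meth, replicate = r, svtype = types,
                n_truth = cnt["n_truth", ], n_calls = cnt["n_calls", ],
                n_tp = cnt["n_tp", ], row.names = NULL)
        }
    }
    rep_df <- do.call(rbind, perRep)
    agg <- do.call(rbind, lapply(split(
        rep_df, list(rep_df$method, rep_df$svtype), sep = "\r"),
        function(d) {
            prec <- if (average == "ratio_of_means")
                svPrecision(mean(d$n_tp), mean(d$n_calls))
            else mean(svPrecision(d$n_tp, d$n_calls), na.rm = TRUE)
            sens <- if (average == "ratio_of_means")
                svSensitivity(mean(d$n_tp), mean(d$n_truth))
            else mean(svSensitivity(d$n_tp, d$n_truth))
            data.frame(method = d$method[1], svtype = d$svtype[1],
                       n_truth = mean(d$n_truth), n_calls = mean(d$n_calls),
                       n_tp = mean(d$n_tp), precision = prec,
                       sensitivity = sens)
        }))
    rownames(agg) <- NULL
    agg <- agg[order(agg$method, agg$svtype), , drop = FALSE]
    rownames(agg) <- NULL
    attr(agg, "replicates") <- rep_df
    agg
}
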