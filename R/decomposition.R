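# Decomposition of close-neighbour co-expression into chromatin,
# shared-promoter and transcriptional-interference components.
#
# The chromatin effect is estimated from the orientations whose geometry
# rules out promoter sharing and read-through at long range: the average
# co-expression of divergent and convergent pairs beyond the distance split,
# minus the random-pair background.  Uni-directional pairs are excluded from
# this estimate because read-through can couple them even at long range.

#' Chromatin-mediated co-expression effect
#'
#' \code{(meanBiLong + meanConvLong)/2 - randomMean}: the excess correlation
#' of distant divergent/convergent direct neighbours over random pairs,
#' attributed to shared chromatin environments.
#'
#' @param meanBiLong Mean co-expression of long-distance bi-directional pairs.
#' @param meanConvLong Mean co-expression of long-distance convergent pairs.
#' @param randomMean Mean co-expression of random gene pairs.
#' @return Numeric chromatin effect.
#' @export
chromatinEffect <- function(meanBiLong, meanConvLong, randomMean) {
    (meanBiLong + meanConvLong) / 2 - randomMean
}

#' Promoter-sharing fraction of close bi-directional co-expression
#'
#' \code{(meanBiShort - chromatinEffect)/meanBiShort}: the share of close
#' bi-directional pairs' co-expression not explained by the chromatin
#' effect, attributed to transcription from a shared promoter region.
#' Undefined (NA, with a warning) when \code{meanBiShort <= 0}.
#'
#' @param meanBiShort Mean co-expression of close bi-directional pairs.
#' @param chromatinEffect Chromatin effect (see \code{\link{chromatinEffect}}).
#' @return Fraction (at most 1).
#' @export
promoterFraction <- function(meanBiShort, chromatinEffect) {
    if (meanBiShort <= 0) {
        warning("promoter fraction undefined: close bi-directional mean <= 0")
        return(NA_real_)
    }
    (meanBiShort - chromatinEffect) / meanBiShort
}

#' Interference fraction of chromatin-mediated co-expression
#'
#' \code{(chromatinEffect - meanConvShort)/chromatinEffect}: the relative
#' reduction of the chromatin-mediated co-expression observed in close
#' convergent pairs, attributed to transcriptional interference at the 3'
#' ends.  Undefined (NA, with a warning) when \code{chromatinEffect <= 0}.
#'
#' @param chromatinEffect Chromatin effect.
#' @param meanConvShort Mean co-expression of close convergent pairs.
#' @return Fraction.
#' @export
interferenceFraction <- function(chromatinEffect, meanConvShort) {
    if (chromatinEffect <= 0) {
        warning("interference fraction undefined: chromatin effect <= 0")
        return(NA_real_)
    }
    (chromatinEffect - meanConvShort) / chromatinEffect
}

.decomposeFromMeans <- function(biLong, convLong, randomMean,
                                biShort, convShort,
                                rounding = c("full", "printed"),
                                se = list()) {
    rounding <- match.arg(rounding)
    inputs <- list(mean_bi_long = biLong, mean_conv_long = convLong,
                   mean_bi_short = biShort, mean_conv_short = convShort,
                   random_mean = randomMean)
    if (rounding == "printed") {
        # round as the published arithmetic does: group means to the printed
        # precision (3 decimals; the close bi-directional mean to 2), and
        # the chromatin effect to 2 decimals before it feeds the ratios
        biLong <- round(biLong, 3); convLong <- round(convLong, 3)
        randomMean <- round(randomMean, 3); convShort <- round(convShort, 3)
        biShort <- round(biShort, 2)
    }
    ce <- if (anyNA(c(biLong, convLong, randomMean))) NA_real_
          else chromatinEffect(biLong, convLong, randomMean)
    if (rounding == "printed" && !is.na(ce)) ce <- round(ce, 2)
    pf <- if (!is.na(biShort) && !is.na(ce) && biShort > 0)
        promoterFraction(biShort, ce)
    else {
        warning("promoter fraction undefined: close bi-directional mean ",
                "missing, non-positive, or chromatin effect missing")
        NA_real_
    }
    if (!is.na(ce) && ce > 0 && !is.na(convShort)) {
        iff <- interferenceFraction(ce, convShort)
        vif <- (ce - (convShort - randomMean)) / ce
    } else {
        warning("interference fraction undefined: chromatin effect missing ",
                "or <= 0, or close convergent mean missing")
        iff <- NA_real_; vif <- NA_real_
    }
    new("DecompositionResult",
        chromatinEffect = ce, promoterFraction = pf,
        interferenceFraction = iff, variantInterferenceFraction = vif,
        inputsUsed = inputs, rounding = rounding, se = se)
}

#' Decompose co-expression from pipeline group statistics
#'
#' Chains \code{\link{chromatinEffect}}, \code{\link{promoterFraction}} and
#' \code{\link{interferenceFraction}} on the orientation-by-distance group
#' means (see \code{\link{groupMeans}}) and the random background.  In
#' \code{"printed"} rounding mode the feeding quantities are first rounded
#' to the precision at which such tables are typically printed (3 decimals;
#' close bi-directional mean and chromatin effect to 2), so that published
#' desk arithmetic can be reproduced exactly; \code{"full"} uses the raw
#' means.  Delta-method standard errors are attached when the group table
#' carries SEMs.  A baseline-consistent interference variant, using
#' \code{meanConvShort - randomMean} in the numerator of the suppressed
#' term, is always reported alongside the as-printed formula.
#'
#' @param stats Output of \code{\link{groupMeans}} (with short/long classes).
#' @param background A \code{\link{randomBackground}} result, or a single
#'   numeric random mean.
#' @param rounding \code{"full"} (default) or \code{"printed"}.
#' @return A \code{\linkS4class{DecompositionResult}}.
#' @export
decomposeCoexpression <- function(stats, background,
                                  rounding = c("full", "printed")) {
    rounding <- match.arg(rounding)
    pick <- function(lbl, col = "mean_r") {
        v <- stats[stats$group_label == lbl, col]
        if (!length(v)) NA_real_ else v
    }
    randomMean <- if (is.list(background)) background$mean_r else background
    randomSem <- if (is.list(background) && !is.null(background$sem_r))
        background$sem_r else NA_real_
    biLong <- pick("bidirectional_long"); convLong <- pick("convergent_long")
    biShort <- pick("bidirectional_short"); convShort <- pick("convergent_short")
    se <- list()
    if ("sem_r" %in% colnames(stats) && !anyNA(c(
            pick("bidirectional_long", "sem_r"),
            pick("convergent_long", "sem_r"),
            pick("bidirectional_short", "sem_r"),
            pick("convergent_short", "sem_r"), randomSem))) {
        sBL <- pick("bidirectional_long", "sem_r")
        sCL <- pick("convergent_long", "sem_r")
        sBS <- pick("bidirectional_short", "sem_r")
        sCS <- pick("convergent_short", "sem_r")
        ce <- chromatinEffect(biLong, convLong, randomMean)
        seCe <- sqrt((sBL^2 + sCL^2) / 4 + randomSem^2)
        # promoter fraction p = 1 - ce/m: dp/dce = -1/m, dp/dm = ce/m^2
        sePf <- sqrt((seCe / biShort)^2 + (ce * sBS / biShort^2)^2)
        # interference f = 1 - m_cv/ce: df/dm = -1/ce, df/dce = m_cv/ce^2
        seIf <- sqrt((sCS / ce)^2 + (convShort * seCe / ce^2)^2)
        se <- list(chromatin_effect = seCe, promoter_fraction = sePf,
                   interference_fraction = seIf)
    }
    .decomposeFromMeans(biLong, convLong, randomMean, biShort, convShort,
                        rounding = rounding, se = se)
}

#' Decompose co-expression from five explicit means
#'
#' Standalone entry point: supply the five feeding quantities directly
#' (long bi-directional, long convergent, random, short bi-directional,
#' short convergent means) to reproduce desk arithmetic without running the
#' pipeline.
#'
#' @param meanBiLong,meanConvLong,randomMean,meanBiShort,meanConvShort The
#'   five feeding means.
#' @param rounding \code{"full"} or \code{"printed"}.
#' @return A \code{\linkS4class{DecompositionResult}}.
#' @examples
#' decomposeMeans(0.060, 0.050, 0.014, 0.152, 0.024, rounding = "printed")
#' @export
decomposeMeans <- function(meanBiLong, meanConvLong, randomMean,
                           meanBiShort, meanConvShort,
                           rounding = c("full", "printed")) {
    .decomposeFromMeans(meanBiLong, meanConvLong, randomMean,
                        meanBiShort, meanConvShort,
                        rounding = match.arg(rounding))
}

setMethod("show", "DecompositionResult", function(object) {
    cat("DecompositionResult (rounding:", object@rounding, ")\n")
    cat(sprintf("  chromatin effect:      %.4f\n", object@chromatinEffect))
    cat(sprintf("  promoter fraction:     %.4f\n", object@promoterFraction))
    cat(sprintf("  interference fraction: %.4f (baseline-consistent: %.4f)\n",
                object@interferenceFraction,
                object@variantInterferenceFraction))
})

#' Convert a DecompositionResult to a plain list
#'
#' @param result A \code{DecompositionResult}.
#' @return Named list suitable for JSON serialisation.
#' @export
decompositionAsList <- function(result) {
    list(chromatin_effect = result@chromatinEffect,
         promoter_fraction = result@promoterFraction,
         interference_fraction = result@interferenceFraction,
         variant_interference_fraction = result@variantInterferenceFraction,
         inputs_used = result@inputsUsed,
         rounding = result@rounding,
         se = result@se)
}
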