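# Generics and accessors. Slots are never reached into from user code.

#' @rdname SampleProfile-class
#' @param x,object an object of the documented class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname SampleProfile-class
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' @rdname SampleProfile-class
#' @export
setGeneric("orfCounts", function(x) standardGeneric("orfCounts"))

#' @rdname SampleProfile-class
#' @export
setGeneric("totalAssigned", function(x) standardGeneric("totalAssigned"))

#' @rdname SampleProfile-class
#' @export
setGeneric("kogCounts", function(x) standardGeneric("kogCounts"))

#' @rdname ExtensionState-class
#' @export
setGeneric("consensusSequence", function(x) standardGeneric("consensusSequence"))

#' @rdname ExtensionState-class
#' @export
setGeneric("coverageVector", function(x) standardGeneric("coverageVector"))

#' @rdname ExtensionState-class
#' @export
setGeneric("iterationLog", function(x) standardGeneric("iterationLog"))

#' @rdname DistanceMatrix-class
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname DistanceMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname AnosimResult-class
#' @export
setGeneric("anosimR", function(x) standardGeneric("anosimR"))

#' @rdname AnosimResult-class
#' @export
setGeneric("anosimP", function(x) standardGeneric("anosimP"))

#' @rdname UpgmaTree-class
#' @export
setGeneric("asPhylo", function(x) standardGeneric("asPhylo"))

#' @rdname UpgmaTree-class
#' @export
setGeneric("mergeHeights", function(x) standardGeneric("mergeHeights"))

#' @rdname CommunitySpec-class
#' @export
setGeneric("taxonTable", function(x) standardGeneric("taxonTable"))

#' @rdname CommunitySpec-class
#' @export
setGeneric("sampleTable", function(x) standardGeneric("sampleTable"))

setMethod("sampleId", "SampleProfile", function(x) x@sampleId)
setMethod("conditionLabel", "SampleProfile", function(x) x@condition)
setMethod("orfCounts", "SampleProfile", function(x) x@orfCounts)
setMethod("totalAssigned", "SampleProfile", function(x) x@totalAssigned)
setMethod("kogCounts", "SampleProfile", function(x) x@kogCounts)

setMethod("consensusSequence", "ExtensionState", function(x) x@consensus)
setMethod("coverageVector", "ExtensionState", function(x) x@coverage)
setMethod("iterationLog", "ExtensionState", function(x) x@log)

setMethod("distances", "DistanceMatrix", function(x) x@d)
setMethod("sampleIds", "DistanceMatrix", function(x) rownames(x@d))

setMethod("anosimR", "AnosimResult", function(x) x@R)
setMethod("anosimP", "AnosimResult", function(x) x@pValue)

setMethod("asPhylo", "UpgmaTree", function(x) x@tree)
setMethod("mergeHeights", "UpgmaTree", function(x) x@heights)

setMethod("taxonTable", "CommunitySpec", function(x) x@taxa)
setMethod("sampleTable", "CommunitySpec", function(x) x@samples)

setMethod("show", "CommunitySpec", function(object) {
  cat("CommunitySpec:", nrow(object@taxa), "taxa,",
      nrow(object@samples), "samples\n")
  cat("  groups:", paste(unique(object@taxa$group), collapse = ", "), "\n")
  cat("  amplification sigma:", object@amplificationSigma,
      " error rate:", object@errorRate, "\n")
  cat("  reads: 2 x", object@readLength, "nt, insert",
      object@insertMean, "+/-", object@insertSd, "nt, seed", object@seed, "\n")
})

setMethod("show", "SampleProfile", function(object) {
  cat("SampleProfile", object@sampleId,
      sprintf("(replicate %s, condition %s)\n",
              object@replicateId, object@condition))
  cat("  ", object@totalAssigned, "assigned unique ORFs in",
      length(object@orfCounts), "groups\n")
  if (object@totalAssigned > 0) {
    fr <- round(object@orfCounts / object@totalAssigned, 3)
    for (g in names(fr)) cat(sprintf("    %-20s %5d  (%.3f)\n",
                                     g, object@orfCounts[[g]], fr[[g]]))
  }
})

setMethod("show", "ExtensionState", function(object) {
  cat("ExtensionState", object@seedId, "-", nchar(object@consensus),
      "nt consensus after", object@iteration, "iteration(s)\n")
  cat("  converged:", object@converged,
      " mean coverage:", round(mean(object@coverage), 1), "\n")
})

setMethod("show", "DistanceMatrix", function(object) {
  cat("DistanceMatrix (", object@metric, "on", object@features, "):",
      nrow(object@d), "samples\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "AnosimResult", function(object) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s, %d %s)\n",
              object@R, object@pValue,
              if (object@exhaustive) "exhaustive" else "sampled",
              object@nPermutations,
              if (object@exhaustive) "arrangements" else "permutations"))
  cat("  group sizes:",
      paste(sprintf("%s=%d", names(table(object@grouping)),
                    table(object@grouping)), collapse = ", "), "\n")
})

setMethod("show", "UpgmaTree", function(object) {
  cat("UpgmaTree:", length(object@tree$tip.label), "samples, root height",
      round(max(object@heights), 4), "\n")
})

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme (", object@type, "):",
      nrow(object@matrix), "x", ncol(object@matrix), "matrix, gap",
      object@gapOpen, "/", object@gapExtend,
      " lambda", object@lambda, " K", object@K, "\n")
})
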