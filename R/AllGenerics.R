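#' @importClassesFrom Matrix dgCMatrix
#' @importFrom Matrix drop0
NULL

#' Gene identifiers of an object
#' @param object a GeneNetwork or FixtureBundle.
#' @return character vector of gene ids.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneNetwork", function(object) rownames(object@adjacency))

#' Adjacency matrix of a GeneNetwork
#' @param object a GeneNetwork.
#' @return sparse symmetric 0/1 \code{dgCMatrix}.
#' @export
setGeneric("adjacencyMatrix", function(object) standardGeneric("adjacencyMatrix"))

#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "GeneNetwork", function(object) object@adjacency)

#' Number of nodes / edges
#' @param object a GeneNetwork.
#' @return integer.
#' @export
setGeneric("numNodes", function(object) standardGeneric("numNodes"))

#' @rdname numNodes
#' @export
setMethod("numNodes", "GeneNetwork", function(object) nrow(object@adjacency))

#' @rdname numNodes
#' @export
setGeneric("numEdges", function(object) standardGeneric("numEdges"))

#' @rdname numNodes
#' @export
setMethod("numEdges", "GeneNetwork",
          function(object) as.integer(length(object@adjacency@x) / 2))

setMethod("show", "GeneNetwork", function(object) {
    cat("GeneNetwork:", numNodes(object), "genes,", numEdges(object),
        "undirected edges\n")
})

#' Cell identifiers
#' @param object an SRProfile.
#' @return character vector.
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))

#' @rdname cellIds
#' @export
setMethod("cellIds", "SRProfile", function(object) object@cellIds)

#' Per-cell entropy rate (nats)
#' @param object an SRProfile.
#' @return named numeric vector.
#' @export
setGeneric("entropyRates", function(object) standardGeneric("entropyRates"))

#' @rdname entropyRates
#' @export
setMethod("entropyRates", "SRProfile",
          function(object) stats::setNames(object@sr, object@cellIds))

#' Maximum entropy rate of the underlying network (nats)
#' @param object an SRProfile.
#' @return scalar.
#' @export
setGeneric("maxSR", function(object) standardGeneric("maxSR"))

#' @rdname maxSR
#' @export
setMethod("maxSR", "SRProfile", function(object) object@maxSr)

#' Normalized entropy rate SR = Sr / maxSr, in (0, 1]
#' @param object an SRProfile.
#' @return named numeric vector.
#' @export
setGeneric("SR", function(object) standardGeneric("SR"))

#' @rdname SR
#' @export
setMethod("SR", "SRProfile",
          function(object) stats::setNames(object@srn, object@cellIds))

#' Base-2 logit of SR
#'
#' For an `SRProfile` this is an accessor; for a numeric vector it computes
#' `log2(x / (1 - x))` and errors on values outside the open interval (0, 1),
#' where the logit is infinite.
#'
#' @param object an SRProfile or a numeric vector with values in (0, 1).
#' @return numeric vector.
#' @export
setGeneric("logitSR", function(object) standardGeneric("logitSR"))

#' @rdname logitSR
#' @export
setMethod("logitSR", "SRProfile",
          function(object) stats::setNames(object@logitSr, object@cellIds))

#' @rdname logitSR
#' @export
setMethod("logitSR", "numeric", function(object) {
    if (any(!is.finite(object)) || any(object <= 0) || any(object >= 1))
        stop("logitSR is only defined on the open interval (0, 1); ",
             "values of 0 or 1 give an infinite logit")
    log2(object / (1 - object))
})

setMethod("show", "SRProfile", function(object) {
    cat("SRProfile:", length(object@cellIds), "cells; maxSr =",
        format(object@maxSr, digits = 6), "nats\n")
    if (length(object@srn))
        cat("  SR range: [", format(min(object@srn), digits = 4), ", ",
            format(max(object@srn), digits = 4), "]\n", sep = "")
})

#' Coerce an SRProfile to a data.frame
#'
#' Columns: cell_id, Sr, maxSr, SR, logitSR.
#' @param x an SRProfile.
#' @param ... ignored.
#' @return data.frame with one row per cell.
#' @export
as.data.frame.SRProfile <- function(x, ...) {
    data.frame(cell_id = x@cellIds, Sr = x@sr, maxSr = x@maxSr,
               SR = x@srn, logitSR = x@logitSr,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Number of potency states
#' @param object a PotencyModel.
#' @return integer K.
#' @export
setGeneric("numStates", function(object) standardGeneric("numStates"))

#' @rdname numStates
#' @export
setMethod("numStates", "PotencyModel", function(object) object@K)

#' Hard state labels (1 = lowest potency, K = highest)
#' @param object a PotencyModel.
#' @return integer vector per cell.
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))

#' @rdname stateLabels
#' @export
setMethod("stateLabels", "PotencyModel", function(object) object@labels)

#' State-membership posterior probabilities
#' @param object a PotencyModel.
#' @return cells x K matrix.
#' @export
setGeneric("statePosteriors", function(object) standardGeneric("statePosteriors"))

#' @rdname statePosteriors
#' @export
setMethod("statePosteriors", "PotencyModel", function(object) object@posteriors)

#' BIC per candidate number of states
#' @param object a PotencyModel.
#' @return named numeric vector (convention -2 loglik + p log n; minimized).
#' @export
setGeneric("bicTable", function(object) standardGeneric("bicTable"))

#' @rdname bicTable
#' @export
setMethod("bicTable", "PotencyModel", function(object) object@bicTable)

setMethod("show", "PotencyModel", function(object) {
    cat("PotencyModel:", object@K, "potency state(s) over",
        nrow(object@posteriors), "cells (", object@varModel,
        "variance model )\n")
    cat("  means:", paste(format(object@means, digits = 4), collapse = ", "),
        "\n")
    cat("  weights:", paste(format(object@weights, digits = 3),
                            collapse = ", "), "\n")
})

setMethod("show", "DiffusionResult", function(object) {
    cat("DiffusionResult:", nrow(object@components), "cells,",
        length(object@eigenvalues), "diffusion components (k =",
        object@kernelParams$k, ")\n")
    if (!is.na(object@rootIndex[1]) && length(object@dpt))
        cat("  root cell index:", object@rootIndex,
            "; max DPT:", format(max(object@dpt), digits = 4), "\n")
})

setMethod("show", "LandscapeResult", function(object) {
    k <- max(object@clusterLabels)
    cat("LandscapeResult:", nrow(object@coords), "cells,", k, "cluster(s),",
        sum(object@clusterLabels == 0L), "peripheral;",
        sum(object@cellStateTable$qualifies), "qualifying cell-state(s)\n")
})

setMethod("show", "GseaResult", function(object) {
    cat("GseaResult: maxES =", format(object@maxES, digits = 4),
        "; NES =", format(object@nes, digits = 4),
        "; P =", format(object@p, digits = 3),
        "(", object@nMC, "Monte-Carlo reshuffles )\n")
})

setMethod("show", "SignedSignature", function(object) {
    cat("SignedSignature:", sum(object@sign > 0), "up-,",
        sum(object@sign < 0), "downregulated genes\n")
})

setMethod("show", "FixtureBundle", function(object) {
    cat("FixtureBundle (seed ", object@seed, "): ", sep = "")
    if (numNodes(object@network) > 0)
        cat(numNodes(object@network), "network genes; ")
    if (length(object@expression))
        cat(nrow(object@expression), "x", ncol(object@expression),
            "expression matrix; ")
    if (!is.null(object@counts))
        cat("counts ", paste(dim(object@counts), collapse = " x "), "; ",
            sep = "")
    cat(nrow(object@groundTruth), "ground-truth rows\n")
})
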