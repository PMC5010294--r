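#' @import methods
NULL

#' The 20 standard amino acids, one-letter codes
#'
#' Alphabet order follows the packaged contact-energy table.
#' @export
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' ContactEnergyMatrix: pairwise residue contact potentials
#'
#' A 20 x 20 matrix of dimensionless pairwise contact energies between the
#' standard amino acids, indexed target (row) by partner (column). The
#' packaged matrix is a sequence-derived statistical potential; it is kept
#' exactly as printed in its source, including a handful of asymmetric
#' cells (see \code{\link{matrixAsymmetryReport}}).
#'
#' @slot energies numeric 20 x 20 matrix with dimnames \code{AA_STANDARD}.
#' @seealso \code{\link{loadContactEnergyMatrix}}, \code{\link{lookupEnergy}}
#' @export
setClass("ContactEnergyMatrix", representation(energies = "matrix"))

setValidity("ContactEnergyMatrix", function(object) {
    e <- object@energies
    if (!is.numeric(e) || !identical(dim(e), c(20L, 20L)))
        return("energies must be a numeric 20 x 20 matrix")
    if (!identical(rownames(e), AA_STANDARD) ||
        !identical(colnames(e), AA_STANDARD))
        return("dimnames must be the 20 standard amino acids in table order")
    if (any(!is.finite(e)))
        return("all 400 contact energies must be finite")
    TRUE
})

setMethod("show", "ContactEnergyMatrix", function(object) {
    e <- object@energies
    cat("ContactEnergyMatrix: 20 x 20 pairwise contact potentials\n")
    cat(sprintf("  range: [%.2f, %.2f]; min at (%s)\n",
                min(e), max(e),
                paste(AA_STANDARD[which(e == min(e), arr.ind = TRUE)[1, ]],
                      collapse = ",")))
    nasym <- nrow(matrixAsymmetryReport(object))
    cat(sprintf("  asymmetric unordered pairs: %d\n", nasym))
})

#' Accessor for the raw energy matrix
#' @param x a \code{ContactEnergyMatrix}
#' @return numeric 20 x 20 matrix (target rows, partner columns)
#' @export
energyMatrix <- function(x) {
    stopifnot(is(x, "ContactEnergyMatrix"))
    x@energies
}

#' PSEEConfig: parameters of the PSEE computation
#'
#' @slot contactRadius integer, number of sequence neighbours on each side
#'   of the target residue (neighbourhood size 2*CR). Default 9, the value
#'   selected by maximising disorder-classification MCC over CR 4..30.
#' @slot symmetrize logical, average the (a,b) and (b,a) contact energies
#'   instead of the as-printed row-major entry.
#' @slot clipExposure logical, truncate proportional exposure to [0,1].
#' @slot normalizeByCount logical, divide by the actual partner count near
#'   the termini instead of the constant 2*CR.
#' @export
setClass("PSEEConfig", representation(contactRadius = "integer",
                                      symmetrize = "logical",
                                      clipExposure = "logical",
                                      normalizeByCount = "logical"))

setValidity("PSEEConfig", function(object) {
    if (length(object@contactRadius) != 1L || is.na(object@contactRadius) ||
        object@contactRadius < 1L)
        return("contactRadius must be a single integer >= 1")
    TRUE
})

#' Construct a PSEEConfig
#'
#' @param contactRadius neighbourhood half-width CR (default 9)
#' @param symmetrize use symmetrized contact energies (default FALSE)
#' @param clipExposure clip proportional exposure to [0,1] (default TRUE)
#' @param normalizeByCount divide by actual partner count at termini
#'   (default FALSE: the divisor is always 2*CR)
#' @return a \code{PSEEConfig} object
#' @examples
#' pseeConfig()
#' pseeConfig(contactRadius = 4)
#' @export
pseeConfig <- function(contactRadius = 9L, symmetrize = FALSE,
                       clipExposure = TRUE, normalizeByCount = FALSE) {
    new("PSEEConfig", contactRadius = as.integer(contactRadius),
        symmetrize = symmetrize, clipExposure = clipExposure,
        normalizeByCount = normalizeByCount)
}

setMethod("show", "PSEEConfig", function(object) {
    cat(sprintf(paste0("PSEEConfig: CR=%d, symmetrize=%s, clipExposure=%s, ",
                       "normalizeByCount=%s\n"),
                object@contactRadius, object@symmetrize, object@clipExposure,
                object@normalizeByCount))
})

#' Accessor for the contact radius
#' @param x a \code{PSEEConfig}
#' @return integer contact radius
#' @export
contactRadius <- function(x) {
    stopifnot(is(x, "PSEEConfig"))
    x@contactRadius
}

#' DisorderClassifier: a trained probabilistic disorder model
#'
#' Wraps a support-vector machine with radial-basis kernel and calibrated
#' probability output, together with the feature schema, configuration and
#' seed it was trained under, so that prediction can refuse mismatched
#' inputs and training is reproducible.
#'
#' @slot model the fitted svm object
#' @slot schema the \code{featureSchema} used to build the feature matrix
#' @slot config a \code{list} with cost, gamma and decisionThreshold
#' @slot seed integer seed used for training
#' @slot version archive format version
#' @export
setClass("DisorderClassifier", representation(model = "ANY",
                                              schema = "list",
                                              config = "list",
                                              seed = "integer",
                                              version = "character"))

setMethod("show", "DisorderClassifier", function(object) {
    cat("DisorderClassifier (RBF-kernel SVM with probability output)\n")
    cat(sprintf("  features per residue: %d; window: %d; input width: %d\n",
                object@schema$width, object@schema$window,
                object@schema$width * object@schema$window))
    cat(sprintf("  cost=%g gamma=%g decisionThreshold=%g seed=%d\n",
                object@config$cost, object@config$gamma,
                object@config$decisionThreshold, object@seed))
})
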