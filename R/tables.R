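#' Load the packaged pairwise contact-energy matrix
#'
#' Reads the 20 x 20 sequence-derived residue contact potential shipped
#' with the package (plain tab-delimited text, human-diffable against its
#' printed source). Rows index the target residue, columns the contact
#' partner. The table is kept exactly as printed; a few cells are
#' asymmetric (see \code{\link{matrixAsymmetryReport}}).
#'
#' @param path path to a matrix file; defaults to the packaged resource.
#' @return a \code{\link{ContactEnergyMatrix}}
#' @examples
#' m <- loadContactEnergyMatrix()
#' energyMatrix(m)["C", "C"]   # -39.58, the cysteine-cysteine anomaly
#' @export
loadContactEnergyMatrix <- function(path = system.file(
        "extdata", "contact_energy.tsv", package = "PSEE")) {
    if (!nzchar(path) || !file.exists(path))
        .stopf("contact energy matrix resource not found: '%s'", path)
    tab <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
    m <- as.matrix(tab)
    if (!identical(dim(m), c(20L, 20L)) || any(!is.finite(m)))
        .stopf("corrupted contact energy matrix in '%s': expected 20 x 20 finite values",
               path)
    m <- m[AA_STANDARD, AA_STANDARD]
    new("ContactEnergyMatrix", energies = m)
}

#' Write a contact-energy matrix to delimited text
#'
#' Inverse of \code{\link{loadContactEnergyMatrix}}; the round trip is
#' value-exact.
#'
#' @param x a \code{ContactEnergyMatrix}
#' @param path output file path
#' @return invisibly, \code{path}
#' @export
writeContactEnergyMatrix <- function(x, path) {
    stopifnot(is(x, "ContactEnergyMatrix"))
    e <- energyMatrix(x)
    df <- data.frame(aa = rownames(e), e, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Look up a pairwise contact energy
#'
#' Returns the contact potential between a target and a partner residue.
#' The default is the as-printed row-major entry (target row, partner
#' column), matching how the PSEE formula indexes the matrix with the
#' target first; \code{symmetrize = TRUE} returns the arithmetic mean of
#' the (a,b) and (b,a) entries instead.
#'
#' @param matrix a \code{ContactEnergyMatrix}
#' @param target,partner one-letter amino-acid codes (case-insensitive)
#' @param symmetrize average the two ordered entries (default FALSE)
#' @return numeric contact energy (vectorized over target/partner)
#' @examples
#' m <- loadContactEnergyMatrix()
#' lookupEnergy(m, "C", "C")                     # -39.58
#' lookupEnergy(m, "Q", "V", symmetrize = TRUE)  # mean(0.38, -1.91)
#' @export
lookupEnergy <- function(matrix, target, partner, symmetrize = FALSE) {
    stopifnot(is(matrix, "ContactEnergyMatrix"))
    target <- .checkAA(target, "target amino acid")
    partner <- .checkAA(partner, "partner amino acid")
    e <- energyMatrix(matrix)
    v <- e[cbind(target, partner)]
    if (symmetrize) v <- (v + e[cbind(partner, target)]) / 2
    unname(v)
}

#' Report asymmetric cells of a contact-energy matrix
#'
#' Lists every unordered amino-acid pair whose two ordered entries differ
#' by more than \code{tol}, sorted by descending absolute difference.
#' Useful for auditing as-printed tables before opting into
#' symmetrization.
#'
#' @param matrix a \code{ContactEnergyMatrix}
#' @param tol numeric tolerance below which a pair counts as symmetric
#' @return data.frame with columns \code{aa1}, \code{aa2}, \code{delta}
#'   (aa1 < aa2 alphabetically; delta = |P(a,b) - P(b,a)|)
#' @export
matrixAsymmetryReport <- function(matrix, tol = 1e-9) {
    stopifnot(is(matrix, "ContactEnergyMatrix"))
    e <- energyMatrix(matrix)
    pairs <- t(utils::combn(AA_STANDARD, 2L))
    delta <- abs(e[pairs] - e[pairs[, c(2L, 1L)]])
    keep <- delta > tol
    out <- data.frame(aa1 = pmin(pairs[keep, 1L], pairs[keep, 2L]),
                      aa2 = pmax(pairs[keep, 1L], pairs[keep, 2L]),
                      delta = delta[keep], stringsAsFactors = FALSE)
    out[order(-out$delta), , drop = FALSE]
}

#' Load the accessible-surface-area normalization table
#'
#' Reference ASA per amino acid, in squared angstroms, for residue X in an
#' extended Gly-X-Gly tripeptide. Predicted ASA divided by this reference
#' gives the proportional exposure.
#'
#' @param path path to the table; defaults to the packaged resource.
#' @return named numeric vector of 20 reference areas
#' @examples
#' loadASANormalization()[["G"]]  # 104.0
#' @export
loadASANormalization <- function(path = system.file(
        "extdata", "asa_normalization.tsv", package = "PSEE")) {
    if (!nzchar(path) || !file.exists(path))
        .stopf("ASA normalization resource not found: '%s'", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    v <- stats::setNames(tab$asa_ref, tab$aa)
    if (length(v) != 20L || !setequal(names(v), AA_STANDARD) ||
        any(!is.finite(v)) || any(v <= 0))
        .stopf("corrupted ASA normalization table in '%s'", path)
    v[AA_STANDARD]
}

#' Load the hydrophobicity scale and hydrophobic/hydrophilic partition
#'
#' The binary partition assigns A, G, I, L, M, F, P, W, Y, V as
#' hydrophobic and R, N, D, C, Q, E, H, K, S, T as hydrophilic. The
#' numeric index shipped alongside is the Kyte-Doolittle hydropathy scale
#' (positive = hydrophobic).
#'
#' @param path path to the table; defaults to the packaged resource.
#' @return list with \code{index} (named numeric) and \code{partition}
#'   (named character, \code{"hydrophobic"}/\code{"hydrophilic"})
#' @export
loadHydrophobicity <- function(path = system.file(
        "extdata", "hydrophobicity.tsv", package = "PSEE")) {
    if (!nzchar(path) || !file.exists(path))
        .stopf("hydrophobicity resource not found: '%s'", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nrow(tab) != 20L || !setequal(tab$aa, AA_STANDARD) ||
        !all(tab$partition %in% c("hydrophobic", "hydrophilic")))
        .stopf("corrupted hydrophobicity table in '%s'", path)
    idx <- match(AA_STANDARD, tab$aa)
    list(index = stats::setNames(tab$index[idx], AA_STANDARD),
         partition = stats::setNames(tab$partition[idx], AA_STANDARD))
}
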