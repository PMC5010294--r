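#' Specification for synthetic labelled disorder datasets
#'
#' Describes sequences built from alternating ordered and disordered
#' segments. Ordered segments draw residues from a hydrophobic-biased
#' composition and low-mean relative exposure (buried core); disordered
#' segments draw from a hydrophilic-biased composition and high-mean
#' exposure (solvent-facing). Per-residue exposure is Beta-distributed,
#' so it always lies in [0,1]; predicted ASA is exposure times the
#' residue's Gly-X-Gly reference area, which makes proportional exposure
#' recover the sampled value exactly.
#'
#' Default exposure means are 0.25 (ordered; the conventional burial cut
#' at 25 percent relative exposure) and 0.67 (disordered). Default
#' compositions put 70 percent of the weight on the ten hydrophobic
#' residues in ordered segments and 30 percent in disordered ones.
#'
#' @param nSequences number of sequences (default 40)
#' @param lengthRange inclusive range of sequence lengths (default
#'   80..160)
#' @param segmentLengthRange inclusive range of segment lengths (default
#'   10..40)
#' @param orderedComposition,disorderedComposition named weight vectors
#'   over the 20 amino acids, each summing to 1
#' @param orderedExposure,disorderedExposure Beta shape pairs
#'   \code{c(shape1, shape2)} for per-residue exposure
#' @param seed integer seed; fully determines the generated dataset
#' @return a list of class \code{"SyntheticSpec"}
#' @export
syntheticSpec <- function(nSequences = 40L,
                          lengthRange = c(80L, 160L),
                          segmentLengthRange = c(10L, 40L),
                          orderedComposition = NULL,
                          disorderedComposition = NULL,
                          orderedExposure = c(2.5, 7.5),
                          disorderedExposure = c(6.7, 3.3),
                          seed = 7L) {
    if (nSequences < 1L) .stopf("nSequences must be >= 1")
    if (length(lengthRange) != 2L || lengthRange[1L] > lengthRange[2L] ||
        lengthRange[1L] < 1L)
        .stopf("invalid sequence length range")
    if (segmentLengthRange[1L] < 1L ||
        segmentLengthRange[1L] > segmentLengthRange[2L])
        .stopf("invalid segment length range")
    hydro <- loadHydrophobicity()$partition
    defaultComp <- function(hydroWeight) {
        w <- ifelse(hydro == "hydrophobic", hydroWeight / 10,
                    (1 - hydroWeight) / 10)
        stats::setNames(w, names(hydro))
    }
    if (is.null(orderedComposition)) orderedComposition <- defaultComp(0.7)
    if (is.null(disorderedComposition))
        disorderedComposition <- defaultComp(0.3)
    for (w in list(orderedComposition, disorderedComposition)) {
        if (!setequal(names(w), AA_STANDARD) || any(w < 0) ||
            abs(sum(w) - 1) > 1e-8)
            .stopf("composition weights must cover the 20 amino acids and sum to 1")
    }
    for (sh in list(orderedExposure, disorderedExposure))
        if (length(sh) != 2L || any(sh <= 0))
            .stopf("exposure parameters must be two positive Beta shapes")
    structure(list(nSequences = as.integer(nSequences),
                   lengthRange = as.integer(lengthRange),
                   segmentLengthRange = as.integer(segmentLengthRange),
                   orderedComposition = orderedComposition[AA_STANDARD],
                   disorderedComposition = disorderedComposition[AA_STANDARD],
                   orderedExposure = orderedExposure,
                   disorderedExposure = disorderedExposure,
                   seed = as.integer(seed)),
              class = "SyntheticSpec")
}

#' Generate a labelled synthetic disorder dataset
#'
#' Each sequence is a concatenation of alternating ordered/disordered
#' segments (the starting state alternates across sequences); residues
#' and per-residue exposures are drawn from the state's composition and
#' Beta distribution, exposure is converted to predicted ASA via the
#' reference-area table, and the matching O/D annotation track is
#' emitted. Output is fully determined by the spec's seed.
#'
#' @param spec a \code{\link{syntheticSpec}}
#' @return list of class \code{"SyntheticDisorderDataset"} with
#'   \code{records} (each a list: id, sequence, asa, exposure, pBur,
#'   labels) and the generating \code{spec}
#' @export
generateDataset <- function(spec = syntheticSpec()) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    asaRef <- loadASANormalization()
    set.seed(spec$seed)
    records <- lapply(seq_len(spec$nSequences), function(k) {
        L <- sample(spec$lengthRange[1L]:spec$lengthRange[2L], 1L)
        state <- if (k %% 2L == 1L) "O" else "D"
        res <- character(0); lab <- character(0); expo <- numeric(0)
        while (length(res) < L) {
            n <- sample(spec$segmentLengthRange[1L]:
                        spec$segmentLengthRange[2L], 1L)
            n <- min(n, L - length(res))
            comp <- if (state == "O") spec$orderedComposition
                    else spec$disorderedComposition
            sh <- if (state == "O") spec$orderedExposure
                  else spec$disorderedExposure
            res <- c(res, sample(AA_STANDARD, n, replace = TRUE,
                                 prob = comp))
            expo <- c(expo, stats::rbeta(n, sh[1L], sh[2L]))
            lab <- c(lab, rep(state, n))
            state <- if (state == "O") "D" else "O"
        }
        asa <- expo * unname(asaRef[res])
        list(id = sprintf("syn%03d", k),
             sequence = paste(res, collapse = ""), asa = asa,
             exposure = expo, pBur = 1 - expo, labels = lab)
    })
    structure(list(records = records, spec = spec),
              class = "SyntheticDisorderDataset")
}

#' Write a synthetic dataset bundle to disk
#'
#' Emits the same formats the readers consume: a FASTA of sequences, one
#' ASA file per sequence (two-column), and a FASTA-like O/D annotation
#' file.
#'
#' @param dataset a \code{generateDataset} result
#' @param dir output directory (created if needed)
#' @return invisibly, a list of written paths
#' @export
writeDatasetBundle <- function(dataset, dir) {
    stopifnot(inherits(dataset, "SyntheticDisorderDataset"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    seqs <- Biostrings::AAStringSet(vapply(dataset$records, `[[`, "",
                                           "sequence"))
    names(seqs) <- vapply(dataset$records, `[[`, "", "id")
    fa <- file.path(dir, "sequences.fasta")
    writeFasta(seqs, fa)
    ann <- file.path(dir, "annotation.txt")
    writeLines(unlist(lapply(dataset$records, function(r)
        c(paste0(">", r$id), paste(r$labels, collapse = "")))), ann)
    asaPaths <- vapply(dataset$records, function(r) {
        p <- file.path(dir, paste0(r$id, ".asa"))
        writeLines(sprintf("%d %.6f", seq_along(r$asa), r$asa), p)
        p
    }, "")
    invisible(list(fasta = fa, annotation = ann, asa = asaPaths))
}

#' Generate per-residue feature tables for a synthetic dataset
#'
#' Fills every schema column with label-correlated Gaussian noise except
#' the \code{terminal} and \code{psee} columns, which are genuinely
#' computed (terminal indicator from position, PSEE from the generated
#' sequence and burial), so classifier tests exercise the real pipeline
#' geometry. Setting \code{labelCorrelation = 0} makes every noise
#' column uninformative, leaving PSEE as the only real signal.
#'
#' @param dataset a \code{generateDataset} result
#' @param schema a \code{\link{featureSchema}}
#' @param seed integer seed for the noise columns
#' @param labelCorrelation shift added to noise columns for disordered
#'   residues (default 0.2)
#' @param config \code{\link{pseeConfig}} used for the PSEE column
#' @param matrix contact-energy matrix used for the PSEE column
#' @return named list of L x F numeric matrices, one per sequence,
#'   columns named after the schema
#' @export
generateFeatureTable <- function(dataset, schema = fullFeatureSchema(),
                                 seed = 7L, labelCorrelation = 0.2,
                                 config = pseeConfig(),
                                 matrix = loadContactEnergyMatrix()) {
    stopifnot(inherits(dataset, "SyntheticDisorderDataset"))
    set.seed(as.integer(seed))
    energies <- energyMatrix(matrix)
    out <- lapply(dataset$records, function(r) {
        L <- length(r$labels)
        m <- matrix(stats::rnorm(L * schema$width), L, schema$width)
        colnames(m) <- schema$feature_names
        shift <- ifelse(r$labels == "D", labelCorrelation, -labelCorrelation)
        m <- m + shift
        if ("terminal" %in% schema$feature_names)
            m[, "terminal"] <- terminalIndicator(seq_len(L), L)
        m[, "psee"] <- .pseeValues(.residues(r$sequence), r$pBur, config,
                                   energies)
        m
    })
    names(out) <- vapply(dataset$records, `[[`, "", "id")
    out
}
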