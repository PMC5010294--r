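#' Proportional exposure of a residue
#'
#' Predicted accessible surface area divided by the residue's reference
#' area in an extended Gly-X-Gly tripeptide. Predicted ASA can exceed the
#' reference, so by default the ratio is clipped to [0,1] to keep the
#' complementary burial a proportion.
#'
#' @param aa one-letter amino-acid code(s)
#' @param predictedASA predicted ASA in squared angstroms (>= 0)
#' @param table ASA normalization table from
#'   \code{\link{loadASANormalization}}
#' @param clip truncate the ratio to [0,1] (default TRUE)
#' @return numeric proportional exposure
#' @examples
#' proportionalExposure("G", 104)  # 1
#' @export
proportionalExposure <- function(aa, predictedASA,
                                 table = loadASANormalization(),
                                 clip = TRUE) {
    aa <- .checkAA(aa)
    if (any(!is.finite(predictedASA)) || any(predictedASA < 0))
        .stopf("predicted ASA must be finite and non-negative")
    p <- predictedASA / unname(table[aa])
    if (clip) p <- pmin(pmax(p, 0), 1)
    p
}

#' Proportional burial, the complement of proportional exposure
#'
#' @param pExp proportional exposure in [0,1]
#' @return 1 - pExp
#' @export
proportionalBurial <- function(pExp) {
    if (any(!is.finite(pExp)) || any(pExp < 0) || any(pExp > 1))
        .stopf("proportional exposure must lie in [0,1]")
    1 - pExp
}

# Core PSEE recurrence for one sequence. Positions whose residue is
# outside the standard alphabet get NA and are skipped both as targets
# and as partners.
.pseeValues <- function(res, pBur, config, energies) {
    L <- length(res)
    cr <- config@contactRadius
    std <- res %in% AA_STANDARD
    psee <- rep(NA_real_, L)
    for (i in seq_len(L)) {
        if (!std[i]) next
        nb <- setdiff(max(1L, i - cr):min(L, i + cr), i)
        nb <- nb[std[nb]]
        if (config@symmetrize) {
            pij <- (energies[cbind(res[i], res[nb])] +
                    energies[cbind(res[nb], res[i])]) / 2
        } else {
            pij <- energies[cbind(res[i], res[nb])]
        }
        div <- if (config@normalizeByCount) max(length(nb), 1L) else 2 * cr
        psee[i] <- pBur[i] * sum(pij * pBur[nb]) / div
    }
    psee
}

#' Per-residue position specific estimated energy (PSEE)
#'
#' For each residue i, PSEE(i) = pBur(i) * sum over the neighbourhood
#' N_i of P(AA_i, AA_j) * pBur(j) / (2*CR), where N_i spans the CR
#' positions on either side of i (excluding i, truncated at the sequence
#' ends) and P is the pairwise contact-energy matrix. Negative PSEE is
#' energetically favourable (structured); less negative or positive PSEE
#' marks unstable, disorder-prone positions. The divisor is the constant
#' 2*CR even in truncated terminal neighbourhoods unless
#' \code{normalizeByCount} is set in the config.
#'
#' Positions with a non-standard residue code (X, B, Z, U, ...) get
#' \code{NA} PSEE and are excluded both as targets and as partners; a
#' warning is emitted (use \code{strict = TRUE} to reject the sequence
#' outright). A diagnostic warning is also emitted when any |PSEE|
#' exceeds \code{magnitudeWarn} (cysteine-rich stretches can produce
#' extreme values because of the very large C-C potential); the values
#' are still returned, exclusion is the caller's decision.
#'
#' @param sequence amino-acid sequence (single string or character vector)
#' @param pBur per-residue proportional burial in [0,1], same length
#' @param config a \code{\link{pseeConfig}} (default: CR 9, as-printed
#'   lookup, constant divisor)
#' @param matrix a \code{\link{ContactEnergyMatrix}}
#' @param strict reject sequences containing non-standard residues
#' @param magnitudeWarn diagnostic threshold on |PSEE| (default 10)
#' @return data.frame with columns \code{position}, \code{aa},
#'   \code{p_bur}, \code{psee}
#' @examples
#' m <- loadContactEnergyMatrix()
#' p <- pseeProfile(strrep("A", 30), rep(1, 30), pseeConfig(9), m)
#' p$psee[15]  # -1.65, the A-A diagonal potential
#' @export
pseeProfile <- function(sequence, pBur, config = pseeConfig(),
                        matrix = loadContactEnergyMatrix(),
                        strict = FALSE, magnitudeWarn = 10) {
    stopifnot(is(config, "PSEEConfig"), is(matrix, "ContactEnergyMatrix"))
    res <- .residues(sequence)
    L <- length(res)
    if (L < 1L) .stopf("sequence must contain at least one residue")
    if (length(pBur) != L)
        .stopf("length mismatch: %d residues but %d burial values", L,
               length(pBur))
    if (any(!is.finite(pBur)) || any(pBur < 0) || any(pBur > 1))
        .stopf("proportional burial values must lie in [0,1]")
    nonstd <- unique(res[!res %in% AA_STANDARD])
    if (length(nonstd)) {
        if (strict)
            .stopf("sequence contains non-standard residue(s): %s",
                   paste(nonstd, collapse = ", "))
        warning(sprintf(
            "non-standard residue(s) %s: positions marked unavailable",
            paste(nonstd, collapse = ", ")), call. = FALSE)
    }
    psee <- .pseeValues(res, pBur, config, energyMatrix(matrix))
    if (any(abs(psee) > magnitudeWarn, na.rm = TRUE))
        warning(sprintf("|PSEE| exceeds %g at %d position(s)",
                        magnitudeWarn, sum(abs(psee) > magnitudeWarn,
                                           na.rm = TRUE)), call. = FALSE)
    data.frame(position = seq_len(L), aa = res, p_bur = pBur, psee = psee,
               stringsAsFactors = FALSE)
}

#' Full per-residue profile from sequence plus predicted ASA
#'
#' Convenience wrapper: converts predicted ASA to proportional
#' exposure/burial with the reference-area table, then computes PSEE.
#'
#' @inheritParams pseeProfile
#' @param predictedASA per-residue predicted ASA in squared angstroms
#' @param asaTable table from \code{\link{loadASANormalization}}
#' @param ... passed to \code{\link{pseeProfile}}
#' @return data.frame with columns \code{position}, \code{aa}, \code{asa},
#'   \code{p_exp}, \code{p_bur}, \code{psee}
#' @export
residueProfile <- function(sequence, predictedASA, config = pseeConfig(),
                           matrix = loadContactEnergyMatrix(),
                           asaTable = loadASANormalization(), ...) {
    res <- .residues(sequence)
    std <- res %in% AA_STANDARD
    pExp <- rep(NA_real_, length(res))
    pExp[std] <- proportionalExposure(res[std], predictedASA[std], asaTable,
                                      clip = config@clipExposure)
    pBur <- ifelse(std, 1 - pExp, 0)  # placeholder burial; position skipped
    prof <- pseeProfile(res, pBur, config, matrix, ...)
    data.frame(position = prof$position, aa = prof$aa, asa = predictedASA,
               p_exp = pExp, p_bur = ifelse(std, pBur, NA_real_),
               psee = prof$psee, stringsAsFactors = FALSE)
}

#' Mean PSEE per annotation class, with midpoint threshold
#'
#' Arithmetic mean of the PSEE values in each label class (for example
#' ordered/disordered, or helix/beta/coil), with per-class counts.
#' Positions with unavailable PSEE or label \code{"X"} (unknown) are
#' excluded. When exactly two classes remain, the midpoint threshold
#' equidistant from the two class means is also returned.
#'
#' @param psee per-residue PSEE values (NA = unavailable), or a profile
#'   data.frame with a \code{psee} column
#' @param labels per-residue class labels, same length
#' @return list with \code{class_means} (named numeric),
#'   \code{class_counts} (named integer) and \code{threshold} (numeric or
#'   NA when not exactly two classes)
#' @examples
#' meanPseeByLabel(c(-1, -2, 0, 1), c("O", "O", "D", "D"))
#' @export
meanPseeByLabel <- function(psee, labels) {
    if (is.data.frame(psee)) psee <- psee$psee
    if (length(psee) != length(labels))
        .stopf("length mismatch: %d PSEE values but %d labels",
               length(psee), length(labels))
    labels <- as.character(labels)
    usable <- !is.na(psee) & !is.na(labels) & labels != "X"
    classes <- sort(unique(labels[!is.na(labels) & labels != "X"]))
    if (!length(classes) || !any(usable))
        .stopf("no usable residues: every position is unavailable or 'X'")
    means <- counts <- stats::setNames(numeric(length(classes)), classes)
    for (cl in classes) {
        sel <- usable & labels == cl
        if (!any(sel))
            .stopf("class '%s' has zero usable residues", cl)
        means[cl] <- mean(psee[sel])
        counts[cl] <- sum(sel)
    }
    thr <- if (length(classes) == 2L)
        midpointThreshold(means[1L], means[2L]) else NA_real_
    list(class_means = means, class_counts = as.integer(counts) |>
             stats::setNames(classes), threshold = unname(thr))
}

#' Midpoint threshold between two class means
#'
#' The separation value equidistant from both means.
#'
#' @param meanA,meanB finite class means
#' @return (meanA + meanB) / 2
#' @export
midpointThreshold <- function(meanA, meanB) {
    if (!is.finite(meanA) || !is.finite(meanB))
        .stopf("class means must be finite")
    (meanA + meanB) / 2
}

#' Threshold classification of residues by PSEE
#'
#' PSEE at or below the threshold falls on the energetically favourable
#' side and is called ordered (\code{"O"}); above it, disordered
#' (\code{"D"}). The boundary is deterministically assigned to the
#' ordered class. Unavailable PSEE gives \code{NA}.
#'
#' @param psee per-residue PSEE values
#' @param threshold finite separation threshold t(PSEE)
#' @return character vector of \code{"O"}/\code{"D"}/\code{NA}
#' @export
classifyByThreshold <- function(psee, threshold) {
    if (!is.finite(threshold)) .stopf("threshold must be finite")
    ifelse(is.na(psee), NA_character_,
           ifelse(psee <= threshold, "O", "D"))
}

#' Region-level mean PSEE with disorder length strata
#'
#' Averages PSEE over 1-based inclusive regions and tags disordered
#' regions with a length stratum: \code{"<=5"}, \code{"6-20"},
#' \code{"21-40"} or \code{">=41"} residues. Short disordered regions
#' (potential binding sites) tend to sit close to the ordered side of the
#' separation threshold.
#'
#' @param psee per-residue PSEE values, or a profile data.frame
#' @param regions data.frame with columns \code{start}, \code{end},
#'   \code{label} (\code{"O"} ordered / \code{"D"} disordered)
#' @return data.frame with \code{start}, \code{end}, \code{label},
#'   \code{length}, \code{mean_psee}, \code{stratum} (NA for ordered)
#' @export
regionMeanPsee <- function(psee, regions) {
    if (is.data.frame(psee)) psee <- psee$psee
    L <- length(psee)
    stopifnot(is.data.frame(regions),
              all(c("start", "end", "label") %in% names(regions)))
    if (nrow(regions) == 0L) .stopf("no regions supplied")
    bad <- regions$start < 1 | regions$end > L | regions$start > regions$end
    if (any(bad))
        .stopf("invalid region bounds (start %d, end %d) for length %d",
               regions$start[which(bad)[1L]], regions$end[which(bad)[1L]], L)
    len <- regions$end - regions$start + 1L
    mean_psee <- mapply(function(s, e) mean(psee[s:e], na.rm = TRUE),
                        regions$start, regions$end)
    stratum <- ifelse(regions$label == "D",
                      cut(len, c(0, 5, 20, 40, Inf),
                          labels = c("<=5", "6-20", "21-40", ">=41")) |>
                          as.character(),
                      NA_character_)
    data.frame(start = regions$start, end = regions$end,
               label = regions$label, length = len, mean_psee = mean_psee,
               stratum = stratum, stringsAsFactors = FALSE)
}

#' Sweep the contact radius and pick the best by MCC
#'
#' For each candidate CR, recomputes every PSEE profile, takes the
#' ordered/disordered class means and their midpoint threshold, classifies
#' by that threshold, and scores the classification against the supplied
#' labels with balanced accuracy, precision and MCC. The best CR is the
#' one maximising MCC; ties go to the smallest CR (cheaper neighbourhood).
#'
#' @param dataset list of records, each a list with \code{sequence},
#'   \code{pBur} and \code{labels} (per-residue \code{"O"}/\code{"D"}/
#'   \code{"X"}); \code{\link{generateDataset}} output is accepted
#'   directly
#' @param crRange integer vector of candidate contact radii (the
#'   reference sweep uses 4..30)
#' @param matrix a \code{ContactEnergyMatrix}
#' @param symmetrize,normalizeByCount forwarded to \code{\link{pseeConfig}}
#' @return list with \code{sweep} (data.frame: cr, mean_ordered,
#'   mean_disordered, threshold, acc, ppv, mcc) and \code{best_cr}
#' @export
sweepContactRadius <- function(dataset, crRange = 4:30,
                               matrix = loadContactEnergyMatrix(),
                               symmetrize = FALSE, normalizeByCount = FALSE) {
    crRange <- sort(unique(as.integer(crRange)))
    if (!length(crRange)) .stopf("empty contact-radius range")
    recs <- if (!is.null(dataset$records)) dataset$records else dataset
    labels <- unlist(lapply(recs, `[[`, "labels"), use.names = FALSE)
    present <- setdiff(unique(labels), c("X", NA))
    if (!setequal(present, c("O", "D")))
        .stopf("dataset must contain both ordered and disordered residues (found: %s)",
               paste(present, collapse = ", "))
    energies <- energyMatrix(matrix)
    rows <- lapply(crRange, function(cr) {
        cfg <- pseeConfig(cr, symmetrize = symmetrize,
                          normalizeByCount = normalizeByCount)
        psee <- unlist(lapply(recs, function(r)
            .pseeValues(.residues(r$sequence), r$pBur, cfg, energies)),
            use.names = FALSE)
        ms <- meanPseeByLabel(psee, labels)
        pred <- classifyByThreshold(psee, ms$threshold)
        ok <- !is.na(pred) & labels %in% c("O", "D")
        cc <- confusionCounts(pred[ok], labels[ok])
        data.frame(cr = cr, mean_ordered = ms$class_means[["O"]],
                   mean_disordered = ms$class_means[["D"]],
                   threshold = ms$threshold, acc = balancedAccuracy(cc),
                   ppv = precisionPPV(cc), mcc = mcc(cc))
    })
    sweep <- do.call(rbind, rows)
    best <- sweep$cr[which.max(sweep$mcc)]  # which.max takes first = smallest CR
    list(sweep = sweep, best_cr = best)
}

#' Mean PSEE per amino-acid type
#'
#' Aggregates PSEE values by residue identity, for correlation against a
#' hydrophobicity scale.
#'
#' @param aa per-residue amino-acid codes
#' @param psee per-residue PSEE values (NA excluded)
#' @return named numeric vector of per-amino-acid mean PSEE
#' @export
meanPseeByAminoAcid <- function(aa, psee) {
    aa <- .residues(aa)
    ok <- !is.na(psee) & aa %in% AA_STANDARD
    tapply(psee[ok], factor(aa[ok], levels = AA_STANDARD), mean) |>
        unlist()
}

#' Pearson correlation between mean PSEE and hydrophobicity
#'
#' Hydrophobic residues bury into the core and accrue favourable
#' (negative) contact energy, so the correlation between per-amino-acid
#' mean PSEE and a hydrophobicity index is expected to be strongly
#' negative.
#'
#' @param perAAMeanPsee named numeric vector, amino acid -> mean PSEE
#' @param hydro table from \code{\link{loadHydrophobicity}}
#' @return Pearson correlation coefficient
#' @export
hydrophobicityCorrelation <- function(perAAMeanPsee,
                                      hydro = loadHydrophobicity()) {
    aa <- .checkAA(names(perAAMeanPsee))
    ok <- is.finite(perAAMeanPsee)
    aa <- aa[ok]
    x <- as.numeric(perAAMeanPsee[ok])
    if (length(aa) < 3L)
        .stopf("need mean PSEE for at least 3 amino acids")
    y <- unname(hydro$index[aa])
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        .stopf("correlation undefined for constant input")
    stats::cor(x, y)
}
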