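#' Terminal-residue indicator feature
#'
#' Encodes proximity to the sequence ends: the five N-terminal positions
#' get -1.0, -0.8, -0.6, -0.4, -0.2, the five C-terminal positions get
#' +0.2, +0.4, +0.6, +0.8, +1.0, and interior positions 0.0. For
#' sequences shorter than 10 residues, where both rules would apply, the
#' N-terminal value wins for the first ceiling(L/2) positions.
#'
#' @param position 1-based residue position(s)
#' @param length sequence length L
#' @return numeric indicator in [-1, 1]
#' @examples
#' terminalIndicator(c(1, 50, 100), 100)  # -1, 0, 1
#' @export
terminalIndicator <- function(position, length) {
    if (length < 1L) .stopf("sequence length must be >= 1")
    if (any(position < 1L | position > length))
        .stopf("position out of range 1..%d", length)
    nval <- ifelse(position <= 5L, -1 + (position - 1L) * 0.2, NA_real_)
    cval <- ifelse(position >= length - 4L,
                   0.2 + (position - (length - 4L)) * 0.2, NA_real_)
    out <- numeric(length(position))
    both <- !is.na(nval) & !is.na(cval)
    out[!is.na(nval) & is.na(cval)] <- nval[!is.na(nval) & is.na(cval)]
    out[is.na(nval) & !is.na(cval)] <- cval[is.na(nval) & !is.na(cval)]
    out[both] <- ifelse(position[both] <= ceiling(length / 2),
                        nval[both], cval[both])
    out
}

#' Define a per-residue feature schema
#'
#' Names and order of the per-residue features (PSEE must come last) and
#' the odd sliding-window width used to aggregate neighbouring residues'
#' features into one vector per residue.
#'
#' @param featureNames ordered character vector of feature names; the
#'   last entry must be \code{"psee"}
#' @param window odd window width (default 21: the target plus 10
#'   residues on either side)
#' @return list with \code{feature_names}, \code{width} (F),
#'   \code{window} (w); the assembled vector length is w * F
#' @seealso \code{\link{fullFeatureSchema}}
#' @export
featureSchema <- function(featureNames, window = 21L) {
    window <- as.integer(window)
    if (window < 1L || window %% 2L == 0L)
        .stopf("window must be a positive odd integer")
    featureNames <- as.character(featureNames)
    if (!length(featureNames) || utils::tail(featureNames, 1L) != "psee")
        .stopf("feature schema must end with the 'psee' feature")
    list(feature_names = featureNames, width = length(featureNames),
         window = window)
}

#' The full 57-feature per-residue schema
#'
#' One amino-acid encoding, seven physicochemical properties, twenty
#' PSSM columns, three secondary-structure probabilities, one predicted
#' relative surface area, two torsion-angle fluctuations, one PSSM
#' monogram, twenty PSSM bigrams, the terminal indicator, and PSEE last:
#' 57 features per residue, 21 x 57 = 1197 per windowed vector. The
#' externally sourced blocks (PSSM, secondary structure, torsion,
#' mono/bigram) are accepted from user-supplied feature tables; only the
#' terminal indicator and PSEE are computed here.
#'
#' @param window odd window width (default 21)
#' @return a \code{\link{featureSchema}} with width 57
#' @export
fullFeatureSchema <- function(window = 21L) {
    nm <- c("aa_code", paste0("physchem_", 1:7), paste0("pssm_", AA_STANDARD),
            paste0("ss_", c("helix", "beta", "coil")), "rsa",
            paste0("torsion_", c("phi", "psi")), "monogram",
            paste0("bigram_", AA_STANDARD), "terminal", "psee")
    featureSchema(nm, window)
}

#' Assemble sliding-window feature vectors
#'
#' Row i of the result concatenates the F-wide per-residue feature blocks
#' of positions i-(w-1)/2 .. i+(w-1)/2 in order; positions outside the
#' sequence contribute zero blocks (zero padding; the terminal-indicator
#' feature already encodes proximity to the ends).
#'
#' @param perResidueFeatures numeric L x F matrix (or data.frame), one
#'   row per residue, columns in schema order
#' @param schema a \code{\link{featureSchema}} with width F
#' @return numeric L x (w*F) matrix
#' @export
assembleWindowedFeatures <- function(perResidueFeatures, schema) {
    x <- as.matrix(perResidueFeatures)
    storage.mode(x) <- "double"
    Fw <- schema$width
    if (ncol(x) != Fw)
        .stopf("feature table has %d columns but schema width is %d",
               ncol(x), Fw)
    L <- nrow(x)
    w <- schema$window
    half <- (w - 1L) %/% 2L
    out <- matrix(0, L, w * Fw)
    for (k in seq_len(w)) {
        off <- k - 1L - half
        src <- seq_len(L) + off
        ok <- src >= 1L & src <= L
        out[ok, (k - 1L) * Fw + seq_len(Fw)] <- x[src[ok], , drop = FALSE]
    }
    colnames(out) <- paste0(rep(schema$feature_names, w), "_w",
                            rep(seq_len(w) - 1L - half, each = Fw))
    out
}

#' Classifier configuration
#'
#' @param cost SVM misclassification cost C (default 0.5, from the
#'   reference grid search)
#' @param gamma RBF kernel width (default 0.0078125 = 2^-7)
#' @param decisionThreshold raw disorder-probability cutoff in (0,1)
#'   (default 0.79, the Youden-optimal operating point of the reference
#'   predictor)
#' @return list with the three validated parameters
#' @export
classifierConfig <- function(cost = 0.5, gamma = 0.0078125,
                             decisionThreshold = 0.79) {
    if (cost <= 0 || gamma <= 0)
        .stopf("cost and gamma must be positive")
    if (decisionThreshold <= 0 || decisionThreshold >= 1)
        .stopf("decisionThreshold must lie strictly inside (0,1)")
    list(cost = cost, gamma = gamma, decisionThreshold = decisionThreshold)
}

#' Train the probabilistic disorder classifier
#'
#' Fits a support-vector machine with radial-basis kernel and calibrated
#' (sigmoid-fit) probability output on windowed feature vectors. Rows
#' whose label is \code{"X"} are dropped. Training is reproducible given
#' the seed (the seed drives the internal cross-validation folds of the
#' probability calibration).
#'
#' @param features numeric matrix, one row per residue (typically from
#'   \code{\link{assembleWindowedFeatures}})
#' @param labels per-residue labels, \code{"O"}/\code{"D"} (or \code{"X"}
#'   to exclude)
#' @param schema the \code{\link{featureSchema}} the rows were built with
#' @param config a \code{\link{classifierConfig}}
#' @param seed integer seed
#' @return a \code{\link{DisorderClassifier}}
#' @export
trainDisorderClassifier <- function(features, labels,
                                    schema = fullFeatureSchema(),
                                    config = classifierConfig(),
                                    seed = 1L) {
    x <- as.matrix(features)
    labels <- as.character(labels)
    if (nrow(x) != length(labels))
        .stopf("feature rows (%d) and labels (%d) differ", nrow(x),
               length(labels))
    keep <- labels %in% c("O", "D")
    x <- x[keep, , drop = FALSE]
    y <- factor(labels[keep], levels = c("O", "D"))
    if (nlevels(droplevels(y)) < 2L)
        .stopf("training data must contain both ordered and disordered residues")
    if (ncol(x) != schema$width * schema$window)
        .stopf("feature width %d does not match schema (w*F = %d)",
               ncol(x), schema$width * schema$window)
    set.seed(as.integer(seed))
    fit <- e1071::svm(x, y, kernel = "radial", cost = config$cost,
                      gamma = config$gamma, probability = TRUE,
                      scale = FALSE)
    new("DisorderClassifier", model = fit, schema = schema, config = config,
        seed = as.integer(seed), version = "1")
}

#' Predict per-residue disorder
#'
#' Returns the raw calibrated disorder probability, the rescaled
#' probability, and the binary label. A residue is called disordered when
#' its raw probability reaches the decision threshold, equivalently when
#' its rescaled probability reaches 0.5.
#'
#' @param object a \code{\link{DisorderClassifier}}
#' @param features numeric matrix with the training feature width
#' @param decisionThreshold optional override of the stored threshold
#' @return data.frame with \code{raw_prob}, \code{rescaled_prob},
#'   \code{label} (\code{"O"}/\code{"D"})
#' @export
predictDisorder <- function(object, features, decisionThreshold = NULL) {
    stopifnot(is(object, "DisorderClassifier"))
    x <- as.matrix(features)
    want <- object@schema$width * object@schema$window
    if (ncol(x) != want)
        .stopf("feature width %d does not match the model schema (%d)",
               ncol(x), want)
    th <- if (is.null(decisionThreshold)) object@config$decisionThreshold
          else decisionThreshold
    pr <- stats::predict(object@model, x, probability = TRUE)
    raw <- attr(pr, "probabilities")[, "D"]
    data.frame(raw_prob = unname(raw),
               rescaled_prob = rescaleProbability(unname(raw), th),
               label = ifelse(raw >= th, "D", "O"),
               stringsAsFactors = FALSE)
}

#' Youden-J optimal probability threshold
#'
#' Scans candidate thresholds (midpoints between consecutive distinct
#' sorted probabilities, plus 0 and 1) and returns the one maximising
#' sensitivity + specificity, where a residue is called positive
#' (disordered) when its probability is at or above the threshold. Ties
#' are broken towards higher specificity, then towards the lower
#' threshold.
#'
#' @param probabilities per-residue disorder probabilities
#' @param labels per-residue truth, \code{"O"}/\code{"D"}
#' @return list with \code{threshold} and \code{j} (the Youden statistic
#'   sensitivity + specificity - 1 at that threshold)
#' @export
youdenOptimalThreshold <- function(probabilities, labels) {
    labels <- as.character(labels)
    keep <- labels %in% c("O", "D") & !is.na(probabilities)
    p <- probabilities[keep]
    y <- labels[keep]
    npos <- sum(y == "D"); nneg <- sum(y == "O")
    if (npos == 0L || nneg == 0L)
        .stopf("both classes must be present to optimise the threshold")
    s <- sort(unique(p))
    cand <- unique(c(0, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2, 1))
    best <- NULL
    for (t in cand) {
        sens <- sum(p >= t & y == "D") / npos
        spec <- sum(p < t & y == "O") / nneg
        cur <- c(sens + spec, spec, -t)
        if (is.null(best) ||
            cur[1L] > best$key[1L] + 1e-12 ||
            (abs(cur[1L] - best$key[1L]) <= 1e-12 &&
             (cur[2L] > best$key[2L] + 1e-12 ||
              (abs(cur[2L] - best$key[2L]) <= 1e-12 && t < best$threshold))))
            best <- list(threshold = t, key = cur,
                         j = sens + spec - 1)
        }
    list(threshold = best$threshold, j = best$j)
}

#' Piecewise-linear probability rescaling around a threshold
#'
#' Maps the raw probability range [0, theta) linearly onto [0, 0.5) and
#' [theta, 1] onto [0.5, 1], so that the decision threshold lands at 0.5
#' and binary calls read naturally off the rescaled scale. Continuous and
#' strictly monotone for any theta in (0,1).
#'
#' @param p raw probability in [0,1] (vectorized)
#' @param threshold theta in (0,1) (default 0.79)
#' @return rescaled probability in [0,1]
#' @examples
#' rescaleProbability(0.79, 0.79)  # 0.5
#' @export
rescaleProbability <- function(p, threshold = 0.79) {
    if (threshold <= 0 || threshold >= 1)
        .stopf("threshold must lie strictly inside (0,1)")
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        .stopf("probabilities must lie in [0,1]")
    ifelse(p < threshold, p * 0.5 / threshold,
           0.5 + (p - threshold) * 0.5 / (1 - threshold))
}

#' Invert the probability rescaling
#'
#' @param q rescaled probability in [0,1]
#' @param threshold theta in (0,1)
#' @return raw probability p with rescaleProbability(p, threshold) = q
#' @export
unrescaleProbability <- function(q, threshold = 0.79) {
    if (threshold <= 0 || threshold >= 1)
        .stopf("threshold must lie strictly inside (0,1)")
    if (any(!is.finite(q)) || any(q < 0) || any(q > 1))
        .stopf("probabilities must lie in [0,1]")
    ifelse(q < 0.5, q * threshold / 0.5,
           threshold + (q - 0.5) * (1 - threshold) / 0.5)
}

#' Save / load a disorder classifier archive
#'
#' The archive records the format version, schema, config and seed next
#' to the model parameters; loading refuses archives whose version is
#' unknown, and prediction refuses feature matrices whose width does not
#' match the stored schema.
#'
#' @param object a \code{DisorderClassifier}
#' @param path archive file path
#' @return \code{saveDisorderClassifier}: invisibly, \code{path};
#'   \code{readDisorderClassifier}: the restored classifier
#' @export
saveDisorderClassifier <- function(object, path) {
    stopifnot(is(object, "DisorderClassifier"))
    saveRDS(list(version = object@version, schema = object@schema,
                 config = object@config, seed = object@seed,
                 model = object@model), path)
    invisible(path)
}

#' @rdname saveDisorderClassifier
#' @export
readDisorderClassifier <- function(path) {
    a <- readRDS(path)
    if (!is.list(a) || !identical(a$version, "1"))
        .stopf("unrecognised classifier archive version in '%s'", path)
    new("DisorderClassifier", model = a$model, schema = a$schema,
        config = a$config, seed = a$seed, version = a$version)
}
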