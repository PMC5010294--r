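# Independent brute-force oracles and shared fixtures.

# Explicit-neighbourhood PSEE: scalar double loop, no vectorization.
oracle_psee <- function(res, pBur, cr, energies, symmetrize = FALSE,
                        normalizeByCount = FALSE) {
    L <- length(res)
    out <- rep(NA_real_, L)
    for (i in seq_len(L)) {
        if (!(res[i] %in% PSEE::AA_STANDARD)) next
        acc <- 0
        npart <- 0L
        for (j in seq(i - cr, i + cr)) {
            if (j < 1 || j > L || j == i) next
            if (!(res[j] %in% PSEE::AA_STANDARD)) next
            pij <- if (symmetrize)
                (energies[res[i], res[j]] + energies[res[j], res[i]]) / 2
            else energies[res[i], res[j]]
            acc <- acc + pij * pBur[j]
            npart <- npart + 1L
        }
        div <- if (normalizeByCount) max(npart, 1L) else 2 * cr
        out[i] <- pBur[i] * acc / div
    }
    out
}

# Pairwise rank-statistic AUC: ties count one half.
oracle_auc <- function(prob, truth) {
    pos <- prob[truth == "D"]
    neg <- prob[truth == "O"]
    tot <- 0
    for (p in pos) for (n in neg)
        tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
    tot / (length(pos) * length(neg))
}

# Exhaustive Youden search over the candidate grid, loops only.
oracle_youden <- function(prob, truth) {
    s <- sort(unique(prob))
    cand <- c(0, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, 1)
    cand <- unique(cand)
    best <- NULL
    for (t in cand) {
        sens <- mean(prob[truth == "D"] >= t)
        spec <- mean(prob[truth == "O"] < t)
        if (is.null(best) || sens + spec > best$ss + 1e-12 ||
            (abs(sens + spec - best$ss) <= 1e-12 &&
             (spec > best$spec + 1e-12 ||
              (abs(spec - best$spec) <= 1e-12 && t < best$threshold))))
            best <- list(threshold = t, ss = sens + spec, spec = spec)
    }
    best
}

random_sequence <- function(L) {
    paste(sample(PSEE::AA_STANDARD, L, replace = TRUE), collapse = "")
}

predictor_names <- c("DisPredict2", "DisPredict", "SPINE-D", "Espritz",
                     "MFDp", "MFDp2", "IUPred-L", "IUPred-S")

# Published 8-predictor benchmark tables: metric values and the printed
# per-metric ranks, cumulative scores and final ranks.
benchmark_tables <- list(
    dd73 = list(
        metrics = data.frame(predictor = predictor_names,
            acc = c(0.832, 0.829, 0.822, 0.715, 0.828, 0.821, 0.742, 0.708),
            ppv = c(0.857, 0.806, 0.766, 0.817, 0.796, 0.873, 0.812, 0.787),
            mcc = c(0.680, 0.663, 0.639, 0.494, 0.658, 0.675, 0.532, 0.471),
            auc = c(0.902, 0.890, 0.890, 0.826, 0.883, 0.889, 0.806, 0.798)),
        rank_acc = c(1, 2, 4, 7, 3, 5, 6, 8),
        rank_ppv = c(2, 5, 8, 3, 6, 1, 4, 7),
        rank_mcc = c(1, 3, 5, 7, 4, 2, 6, 8),
        rank_auc = c(1, 2, 2, 6, 5, 4, 7, 8),
        s_c = c(5, 12, 19, 23, 18, 12, 23, 31),
        final = c(1, 2, 4, 5, 3, 2, 5, 6),
        final_ties = "dense",
        print_self_consistent = TRUE),
    casp8 = list(
        metrics = data.frame(predictor = predictor_names,
            acc = c(0.807, 0.810, 0.849, 0.797, 0.806, 0.774, 0.722, 0.766),
            ppv = c(0.628, 0.529, 0.504, 0.636, 0.634, 0.758, 0.700, 0.624),
            mcc = c(0.600, 0.551, 0.576, 0.592, 0.601, 0.622, 0.531, 0.551),
            auc = c(0.894, 0.875, 0.910, 0.893, 0.894, 0.888, 0.810, 0.853)),
        rank_acc = c(3, 2, 1, 5, 4, 6, 8, 7),
        rank_ppv = c(5, 7, 8, 3, 4, 1, 2, 6),
        rank_mcc = c(2, 6, 5, 4, 3, 1, 8, 6),
        rank_auc = c(2, 6, 1, 4, 2, 5, 8, 7),
        s_c = c(12, 21, 15, 16, 13, 13, 26, 26),
        final = c(1, 6, 4, 5, 2, 2, 7, 7),
        final_ties = "competition",
        print_self_consistent = FALSE),
    casp9 = list(
        metrics = data.frame(predictor = predictor_names,
            acc = c(0.699, 0.718, 0.745, 0.683, 0.651, 0.616, 0.561, 0.633),
            ppv = c(0.471, 0.389, 0.346, 0.466, 0.361, 0.399, 0.259, 0.466),
            mcc = c(0.407, 0.385, 0.385, 0.386, 0.299, 0.276, 0.147, 0.386),
            auc = c(0.823, 0.809, 0.840, 0.827, 0.756, 0.751, 0.572, 0.827)),
        rank_acc = c(3, 2, 1, 4, 5, 7, 8, 6),
        rank_ppv = c(1, 4, 7, 2, 6, 3, 8, 5),
        rank_mcc = c(1, 3, 3, 2, 5, 7, 8, 6),
        rank_auc = c(3, 4, 1, 2, 5, 6, 8, 7),
        s_c = c(8, 13, 12, 10, 21, 23, 32, 24),
        final = c(1, 4, 3, 2, 5, 6, 8, 7),
        final_ties = "competition",
        print_self_consistent = FALSE),
    casp10 = list(
        metrics = data.frame(predictor = predictor_names,
            acc = c(0.719, 0.734, 0.774, 0.674, 0.677, 0.636, 0.569, 0.635),
            ppv = c(0.347, 0.249, 0.269, 0.441, 0.359, 0.453, 0.238, 0.331),
            mcc = c(0.370, 0.320, 0.366, 0.374, 0.336, 0.332, 0.160, 0.278),
            auc = c(0.839, 0.810, 0.840, 0.829, 0.818, 0.815, 0.604, 0.664)),
        rank_acc = c(3, 2, 1, 5, 4, 6, 8, 7),
        rank_ppv = c(4, 7, 6, 2, 3, 1, 8, 5),
        rank_mcc = c(2, 6, 3, 1, 4, 5, 8, 7),
        rank_auc = c(2, 6, 1, 3, 4, 5, 8, 7),
        s_c = c(11, 21, 11, 11, 15, 17, 32, 26),
        final = c(1, 6, 1, 1, 4, 5, 8, 7),
        final_ties = "competition",
        print_self_consistent = TRUE))
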