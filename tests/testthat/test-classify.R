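test_that("terminal indicator steps through the 5+5 terminal scheme", {
    expect_equal(terminalIndicator(1:5, 100), c(-1, -0.8, -0.6, -0.4, -0.2))
    expect_equal(terminalIndicator(96:100, 100), c(0.2, 0.4, 0.6, 0.8, 1))
    expect_equal(terminalIndicator(c(6, 50, 95), 100), c(0, 0, 0))
    # short sequences: N-terminal values win for the first ceiling(L/2)
    expect_equal(terminalIndicator(1:7, 7),
                 c(-1, -0.8, -0.6, -0.4, 0.6, 0.8, 1))
    expect_equal(terminalIndicator(1:4, 4), c(-1, -0.8, 0.8, 1))
    expect_error(terminalIndicator(0, 10), "range")
    expect_error(terminalIndicator(11, 10), "range")
})

test_that("windowed feature assembly has the published geometry", {
    schema <- fullFeatureSchema()
    expect_equal(schema$width, 57L)
    expect_equal(schema$window, 21L)
    x <- matrix(rnorm(8 * 57), 8, 57)
    w <- assembleWindowedFeatures(x, schema)
    expect_equal(dim(w), c(8L, 1197L))
})

test_that("windowed assembly zero-pads termini and is translation invariant", {
    schema <- featureSchema(c("x", "psee"), 3L)
    w <- assembleWindowedFeatures(matrix(c(1, 2), 1, 2), schema)
    expect_equal(as.numeric(w), c(0, 0, 1, 2, 0, 0))
    # constant table: all interior rows identical
    const <- matrix(rep(c(3, 4), each = 10), 10, 2)
    wc <- assembleWindowedFeatures(const, featureSchema(c("a", "psee"), 5L))
    interior <- wc[3:8, ]
    expect_true(all(apply(interior, 2, function(col) length(unique(col)) == 1)))
    expect_error(assembleWindowedFeatures(matrix(0, 3, 3), schema),
                 "schema width")
    expect_error(featureSchema(c("a", "b"), 4L), "odd")
    expect_error(featureSchema(c("psee", "a")), "psee")
})

test_that("an impulse feature stays local to its window", {
    schema <- featureSchema(c("f", "psee"), 7L)
    L <- 30L
    x <- matrix(0, L, 2)
    k <- 17L
    x[k, ] <- 1
    w <- assembleWindowedFeatures(x, schema)
    nz <- which(rowSums(abs(w)) > 0)
    expect_equal(nz, (k - 3L):(k + 3L))
})

test_that("probability rescaling pivots the threshold to 0.5", {
    expect_equal(rescaleProbability(0.79, 0.79), 0.5)
    expect_equal(rescaleProbability(0, 0.79), 0)
    expect_equal(rescaleProbability(1, 0.79), 1)
    expect_equal(rescaleProbability(0.895, 0.79), 0.75)
    expect_error(rescaleProbability(1.2, 0.5), "\\[0,1\\]")
    expect_error(rescaleProbability(0.5, 1), "\\(0,1\\)")
})

test_that("rescaling is continuous, strictly monotone, and invertible", {
    set.seed(99)
    p <- runif(10000)
    th <- runif(10000, 0.01, 0.99)
    q <- mapply(rescaleProbability, p, th)
    expect_true(all(q >= 0 & q <= 1))
    expect_equal(mapply(unrescaleProbability, q, th), p, tolerance = 1e-12)
    # monotone + continuous per threshold on a fine grid
    for (t in c(0.1, 0.5, 0.79, 0.95)) {
        g <- seq(0, 1, by = 1e-3)
        r <- rescaleProbability(g, t)
        expect_true(all(diff(r) > 0))
        expect_lt(max(abs(diff(r))), 2e-2)   # no jumps beyond slope * step
        expect_equal(rescaleProbability(t, t), 0.5)
    }
})

test_that("Youden threshold matches exhaustive candidate search", {
    expect_equal(youdenOptimalThreshold(c(0.2, 0.3, 0.7, 0.9),
                                        c("O", "O", "D", "D"))$threshold, 0.5)
    inv <- youdenOptimalThreshold(c(0.9, 0.1), c("O", "D"))
    expect_lte(inv$j, 1)
    tie <- youdenOptimalThreshold(c(0.5, 0.5), c("O", "D"))
    expect_lte(tie$j, 1)
    expect_error(youdenOptimalThreshold(c(0.1, 0.9), c("D", "D")), "both")
    set.seed(31)
    for (i in 1:100) {
        n <- sample(4:50, 1)
        prob <- round(runif(n), 2)   # duplicates force tie-breaking
        truth <- sample(c("O", "D"), n, replace = TRUE)
        if (length(unique(truth)) < 2) truth[1:2] <- c("O", "D")
        got <- youdenOptimalThreshold(prob, truth)
        want <- oracle_youden(prob, truth)
        expect_equal(got$threshold, want$threshold)
        expect_equal(got$j, want$ss - 1)
    }
})

make_toy_features <- function(n, seed, shift = 3) {
    set.seed(seed)
    lab <- rep(c("O", "D"), length.out = n)
    x <- matrix(rnorm(n * 4), n, 4)
    x[lab == "D", 1] <- x[lab == "D", 1] + shift
    list(x = x, lab = lab)
}

toy_schema <- featureSchema(c("f1", "f2", "f3", "psee"), 1L)

test_that("classifier training is reproducible and fits separable data", {
    toy <- make_toy_features(80, 1, shift = 6)
    cfg <- classifierConfig(cost = 1, gamma = 0.25, decisionThreshold = 0.5)
    m1 <- trainDisorderClassifier(toy$x, toy$lab, toy_schema, cfg, seed = 3)
    m2 <- trainDisorderClassifier(toy$x, toy$lab, toy_schema, cfg, seed = 3)
    p1 <- predictDisorder(m1, toy$x)
    p2 <- predictDisorder(m2, toy$x)
    expect_identical(p1$raw_prob, p2$raw_prob)
    expect_equal(mean(p1$label == toy$lab), 1)
    expect_error(trainDisorderClassifier(toy$x, rep("O", 80), toy_schema,
                                         cfg), "both")
    expect_error(trainDisorderClassifier(toy$x[, 1:2], toy$lab, toy_schema,
                                         cfg), "schema")
})

test_that("predictions keep the raw/rescaled/label invariant", {
    toy <- make_toy_features(80, 2, shift = 2)
    cfg <- classifierConfig(decisionThreshold = 0.6)
    mod <- trainDisorderClassifier(toy$x, toy$lab, toy_schema, cfg, seed = 5)
    pred <- predictDisorder(mod, toy$x)
    expect_true(all((pred$label == "D") == (pred$raw_prob >= 0.6)))
    expect_true(all((pred$label == "D") == (pred$rescaled_prob >= 0.5)))
    expect_true(all(pred$rescaled_prob >= 0 & pred$rescaled_prob <= 1))
    expect_error(predictDisorder(mod, toy$x[, 1:3]), "schema")
})

test_that("classifier archives round-trip and refuse schema mismatches", {
    toy <- make_toy_features(60, 4, shift = 4)
    cfg <- classifierConfig()
    mod <- trainDisorderClassifier(toy$x, toy$lab, toy_schema, cfg, seed = 2)
    tmp <- withr::local_tempfile(fileext = ".rds")
    saveDisorderClassifier(mod, tmp)
    back <- readDisorderClassifier(tmp)
    expect_identical(predictDisorder(back, toy$x)$raw_prob,
                     predictDisorder(mod, toy$x)$raw_prob)
    expect_error(predictDisorder(back, cbind(toy$x, 0)), "schema")
    bad <- withr::local_tempfile(fileext = ".rds")
    saveRDS(list(version = "99"), bad)
    expect_error(readDisorderClassifier(bad), "version")
})
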