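toggle <- function(...) GRNModel(c("a = NOT b", "b = NOT a"), ...)


test_that("normalized Hill activation hits its anchor points", {
    expect_equal(hillActivation(0), 0)
    expect_equal(hillActivation(1), 1)
    ## at x = k: raw value 1/2, normalized by (1 + k^n) -> 0.625 for n=2, k=0.5
    expect_equal(hillActivation(0.5, n = 2, k = 0.5), 0.625)
    ## monotone on [0, 1]
    x <- seq(0, 1, 0.01)
    expect_true(all(diff(hillActivation(x)) > 0))
})

test_that("rule homologues follow AND/OR/NOT semantics", {
    m <- GRNModel(c("a = a AND NOT b", "b = b"))
    expect_equal(unname(ruleHomologue(m, c(1, 0))[1]), 1)   # a AND NOT b
    expect_equal(unname(ruleHomologue(m, c(1, 1))[1]), 0)
    ## OR as probabilistic sum: 1 - (1-h(a))(1-h(b))
    m2 <- GRNModel(c("a = a OR b", "b = b"))
    h <- function(x) hillActivation(x, 2, 0.5)
    x <- c(0.3, 0.7)
    expect_equal(unname(ruleHomologue(m2, x)[1]),
                 1 - (1 - h(0.3)) * (1 - h(0.7)))
    ## parentheses and NOT distribution
    m3 <- GRNModel(c("a = NOT (a AND b)", "b = b"))
    expect_equal(unname(ruleHomologue(m3, x)[1]), 1 - h(0.3) * h(0.7))
})

test_that("rule parsing rejects malformed models", {
    expect_error(GRNModel("a = NOT c"), "unknown gene")
    expect_error(GRNModel("a = (a AND"), "unbalanced|unexpected")
    expect_error(GRNModel(c("a = a", "a = NOT a")), "duplicate")
    expect_error(GRNModel("a = a", hillK = 2), "hillK")
})

test_that("deterministic dynamics hold fixed points and converge on the toggle", {
    ## sigma = 0 at a fixed point: constant trajectory
    m <- GRNModel("a = a", noiseSd = 0)
    tr <- simulateTrajectory(m, 1, 100)   # x = 1 is a fixed point: h(1) = 1
    expect_true(all(tr == 1))
    ## pure self-activation from 0 stays absorbed at 0
    tr0 <- simulateTrajectory(m, 0, 100)
    expect_true(all(tr0 == 0))

    ## mutual repression from an asymmetric start reaches the high-a state
    mt <- toggle(noiseSd = 0)
    tr2 <- simulateTrajectory(mt, c(0.9, 0.1), 5000)
    expect_gt(tr2[5000, "a"], 0.9)
    expect_lt(tr2[5000, "b"], 0.1)

    ## independent ODE oracle at the same endpoint
    ode <- deSolve::ode(
        y = c(a = 0.9, b = 0.1), times = seq(0, 50, 0.5),
        func = function(t, y, p) {
            h <- function(x) hillActivation(x, 2, 0.5)
            list(c((1 - h(y["b"])) - y["a"], (1 - h(y["a"])) - y["b"]))
        }, parms = NULL)
    expect_equal(unname(tr2[5000, ]), unname(ode[nrow(ode), c("a", "b")]),
                 tolerance = 1e-3)

    ## halving dt changes the endpoint by < 1e-3
    mfine <- toggle(noiseSd = 0, dt = 0.005)
    tr3 <- simulateTrajectory(mfine, c(0.9, 0.1), 10000)
    expect_lt(max(abs(tr2[5000, ] - tr3[10000, ])), 1e-3)

    ## seeded noise is reproducible
    mn <- toggle(noiseSd = 0.05)
    expect_identical(simulateTrajectory(mn, c(0.5, 0.5), 50, seed = 7),
                     simulateTrajectory(mn, c(0.5, 0.5), 50, seed = 7))
    expect_error(simulateTrajectory(mn, c(1.5, 0), 10), "\\[0,1\\]")
})

test_that("sampled cells stay in the unit cube and recover the two attractors", {
    m <- toggle(noiseSd = 0.1)
    a <- sampleCells(m, c(0.5, 0.5), nCells = 400, nSteps = 2000, seed = 1)
    expect_equal(dim(a), c(400, 2))
    expect_true(all(xData(a) >= 0 & xData(a) <= 1))
    expect_true(all(c("sim_time", "trajectory_id") %in% colnames(obsTable(a))))
    b <- sampleCells(m, c(0.5, 0.5), nCells = 400, nSteps = 2000, seed = 1)
    expect_identical(xData(a), xData(b))

    ## late-sampled cells cluster into the two attractor populations
    late <- a[obsTable(a)$sim_time > 500, ]
    Xl <- as.matrix(xData(late))            # columns follow varNames: a, b
    truth <- as.integer(Xl[, 1] > Xl[, 2])
    ## two dense blobs at the hypercube corners: a wide neighborhood and a
    ## sub-unit resolution keep each attractor in one community (duplicated
    ## corner states trigger the kernel-width fallback warning)
    g <- suppressWarnings(buildNeighborGraph(Xl, k = 30))
    cl <- louvainCluster(g, resolution = 0.3, seed = 0)
    expect_gte(length(unique(cl@labels)), 2)
    ari <- mclust::adjustedRandIndex(cl@labels, truth)
    expect_gte(ari, 0.8)
})
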