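#' @include AnnMatrix-class.R
NULL

#' Boolean gene-regulatory network model
#'
#' A literature-curated boolean network made continuous for ODE/SDE
#' simulation: every literal `g` in a rule is replaced by the normalized
#' Hill activation \eqn{h(x) = x^n/(x^n + k^n) \cdot (1 + k^n)} (so that
#' h(0) = 0 and h(1) = 1), `NOT a` by \eqn{1 - h(x_a)}, `a AND b` by the
#' product, and `a OR b` by the probabilistic sum
#' \eqn{1 - (1 - \cdot)(1 - \cdot)}.  States evolve by the
#' Euler–Maruyama update
#' \eqn{x \leftarrow \mathrm{clamp}(x + \tau (B(x) - x) + \sqrt{\tau}\,
#' \sigma\, \eta,\ 0,\ 1)}.
#'
#' The model text format is one line per gene, `gene = expression`, with
#' operators `AND`, `OR`, `NOT` and parentheses; `#` starts a comment.
#'
#' @slot genes Ordered gene names.
#' @slot rules Parsed per-gene rule expressions.
#' @slot ruleText The source lines.
#' @slot hillN Hill exponent n (>= 1).
#' @slot hillK Hill threshold k in (0, 1).
#' @slot dt Integration step tau (> 0).
#' @slot noiseSd Additive Gaussian noise sigma (>= 0).
#' @slot seed Default simulation seed.
#' @aliases GRNModel-class
#' @exportClass GRNModel
setClass("GRNModel",
    representation(genes = "character", rules = "list",
                   ruleText = "character", hillN = "numeric",
                   hillK = "numeric", dt = "numeric", noiseSd = "numeric",
                   seed = "integer"))

setValidity("GRNModel", function(object) {
    msg <- character(0)
    if (length(object@rules) != length(object@genes))
        msg <- c(msg, "one rule per gene required")
    if (object@hillN < 1) msg <- c(msg, "hillN must be >= 1")
    if (object@hillK <= 0 || object@hillK >= 1)
        msg <- c(msg, "hillK must lie in (0, 1)")
    if (object@dt <= 0) msg <- c(msg, "dt must be positive")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GRNModel", function(object) {
    cat(sprintf("GRNModel: %d genes (n = %g, k = %g, dt = %g, sigma = %g)\n",
                length(object@genes), object@hillN, object@hillK,
                object@dt, object@noiseSd))
    for (i in seq_along(object@genes))
        cat(" ", object@ruleText[i], "\n")
})

#' @describeIn GRNModel-class Construct a model from rule lines.
#' @param rules Character vector of `gene = expression` lines (or one
#'   string with newlines).
#' @param hillN,hillK,dt,noiseSd,seed Model parameters (defaults 2, 0.5,
#'   0.01, 0.01, 0).
#' @export
GRNModel <- function(rules, hillN = 2, hillK = 0.5, dt = 0.01,
                     noiseSd = 0.01, seed = 0) {
    lines <- unlist(strsplit(rules, "\n", fixed = TRUE))
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stopf("no rules given")
    parts <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", lines))
    bad <- vapply(parts, length, integer(1)) != 3
    if (any(bad))
        stopf("malformed rule line(s): %s", paste(lines[bad], collapse = "; "))
    genes <- vapply(parts, `[`, character(1), 2)
    if (anyDuplicated(genes))
        stopf("duplicate rule for gene(s): %s",
              paste(unique(genes[duplicated(genes)]), collapse = ", "))
    exprs <- vapply(parts, `[`, character(1), 3)
    asts <- lapply(exprs, parseRule, genes = genes)
    new("GRNModel", genes = genes, rules = asts, ruleText = lines,
        hillN = hillN, hillK = hillK, dt = dt, noiseSd = noiseSd,
        seed = as.integer(seed))
}

#' @describeIn GRNModel-class Read a model from a plain-text rule file.
#' @param path Path of a rule file.
#' @param ... Passed on to `GRNModel()`.
#' @export
readGRNModel <- function(path, ...) {
    GRNModel(readLines(path), ...)
}

## --- recursive-descent parser: expr := term (OR term)*;
##     term := factor (AND factor)*; factor := NOT factor | (expr) | gene
parseRule <- function(text, genes) {
    tokens <- regmatches(text,
        gregexpr("[A-Za-z_][A-Za-z0-9_]*|\\(|\\)", text))[[1]]
    if (!length(tokens)) stopf("empty rule expression: '%s'", text)
    pos <- 1L
    peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
    advance <- function() { t <- peek(); pos <<- pos + 1L; t }
    parseExpr <- function() {
        args <- list(parseTerm())
        while (identical(toupper(peek()), "OR")) {
            advance()
            args[[length(args) + 1L]] <- parseTerm()
        }
        if (length(args) == 1) args[[1]] else list(op = "or", args = args)
    }
    parseTerm <- function() {
        args <- list(parseFactor())
        while (identical(toupper(peek()), "AND")) {
            advance()
            args[[length(args) + 1L]] <- parseFactor()
        }
        if (length(args) == 1) args[[1]] else list(op = "and", args = args)
    }
    parseFactor <- function() {
        t <- peek()
        if (is.na(t)) stopf("unexpected end of rule: '%s'", text)
        if (toupper(t) == "NOT") {
            advance()
            return(list(op = "not", arg = parseFactor()))
        }
        if (t == "(") {
            advance()
            e <- parseExpr()
            if (!identical(advance(), ")"))
                stopf("unbalanced parentheses in rule: '%s'", text)
            return(e)
        }
        if (t == ")") stopf("unexpected ')' in rule: '%s'", text)
        advance()
        g <- match(t, genes)
        if (is.na(g)) stopf("unknown gene '%s' in rule: '%s'", t, text)
        list(op = "lit", gene = g)
    }
    ast <- parseExpr()
    if (pos <= length(tokens))
        stopf("trailing tokens in rule: '%s'", text)
    ast
}

#' Normalized Hill activation
#'
#' \eqn{h(x) = \frac{x^n}{x^n + k^n} (1 + k^n)}: a sigmoidal relaxation
#' of a boolean input with h(0) = 0 and h(1) = 1.
#'
#' @param x State value(s) in [0, 1].
#' @param n Hill exponent.
#' @param k Hill threshold.
#' @return Activation value(s).
#' @export
hillActivation <- function(x, n = 2, k = 0.5) {
    x^n / (x^n + k^n) * (1 + k^n)
}

evalRule <- function(node, S, hillN, hillK) {
    switch(node$op,
        lit = hillActivation(S[, node$gene, drop = TRUE], hillN, hillK),
        not = 1 - evalRule(node$arg, S, hillN, hillK),
        and = {
            out <- evalRule(node$args[[1]], S, hillN, hillK)
            for (i in seq_along(node$args)[-1])
                out <- out * evalRule(node$args[[i]], S, hillN, hillK)
            out
        },
        or = {
            out <- 1 - evalRule(node$args[[1]], S, hillN, hillK)
            for (i in seq_along(node$args)[-1])
                out <- out * (1 - evalRule(node$args[[i]], S, hillN, hillK))
            1 - out
        },
        stopf("unknown rule node '%s'", node$op))
}

#' Continuous homologue of the boolean rules
#'
#' Evaluates the Hill-transformed boolean update \eqn{B(x)} of every
#' gene at the given state(s).
#'
#' @param m A [GRNModel-class].
#' @param x State vector in `[0,1]^G`, or a cells-by-genes state matrix.
#' @return A vector (or matrix) of update targets in [0, 1].
#' @export
ruleHomologue <- function(m, x) {
    single <- is.null(dim(x))
    S <- if (single) matrix(x, nrow = 1) else as.matrix(x)
    if (ncol(S) != length(m@genes))
        stopf("state has %d columns but the model has %d genes",
              ncol(S), length(m@genes))
    out <- vapply(m@rules, evalRule, numeric(nrow(S)), S = S,
                  hillN = m@hillN, hillK = m@hillK)
    if (nrow(S) == 1) out <- matrix(out, nrow = 1)
    if (single) drop(out) else out
}

checkState <- function(x0, G) {
    if (length(x0) != G) stopf("x0 must have length %d", G)
    if (any(x0 < 0 | x0 > 1)) stopf("x0 must lie in [0,1]^G")
}

#' Simulate one network trajectory
#'
#' Euler–Maruyama integration of the continuous boolean network from a
#' given initial state, with states clamped to `[0, 1]` after every
#' step.  Seeded: identical inputs give identical trajectories.
#'
#' @param m A [GRNModel-class].
#' @param x0 Initial state in `[0,1]^G`.
#' @param nSteps Number of integration steps.
#' @param seed Seed (default: the model's seed).
#' @return An `nSteps`-by-G matrix of states (row t = state after t
#'   steps), with gene names as column names.
#' @export
simulateTrajectory <- function(m, x0, nSteps, seed = m@seed) {
    G <- length(m@genes)
    checkState(x0, G)
    set.seed(seed)
    out <- matrix(NA_real_, nSteps, G, dimnames = list(NULL, m@genes))
    x <- matrix(as.numeric(x0), 1, G)
    sq <- sqrt(m@dt) * m@noiseSd
    for (t in seq_len(nSteps)) {
        B <- ruleHomologue(m, x)
        x <- x + m@dt * (B - x)
        if (m@noiseSd > 0) x <- x + sq * matrix(stats::rnorm(G), 1, G)
        x[x < 0] <- 0; x[x > 1] <- 1
        out[t, ] <- x
    }
    out
}

#' Sample single-cell snapshots from a network
#'
#' Runs `nCells` independent noisy trajectories from `x0`; each cell is
#' the state of its trajectory at a time step drawn uniformly from
#' `[1, nSteps]`, mimicking an unsynchronized population.
#'
#' @inheritParams simulateTrajectory
#' @param nCells Number of cells (>= 1).
#' @return An [AnnMatrix-class] (`nCells` x G, values in [0, 1]) with
#'   obs columns `sim_time` and `trajectory_id`.
#' @export
sampleCells <- function(m, x0, nCells, nSteps, seed = m@seed) {
    G <- length(m@genes)
    checkState(x0, G)
    if (nCells < 1) stopf("nCells must be >= 1")
    set.seed(seed)
    ts <- sample.int(nSteps, nCells, replace = TRUE)
    S <- matrix(rep(as.numeric(x0), each = nCells), nCells, G)
    out <- matrix(NA_real_, nCells, G)
    sq <- sqrt(m@dt) * m@noiseSd
    for (t in seq_len(nSteps)) {
        B <- ruleHomologue(m, S)
        S <- S + m@dt * (B - S)
        if (m@noiseSd > 0)
            S <- S + sq * matrix(stats::rnorm(nCells * G), nCells, G)
        S[S < 0] <- 0; S[S > 1] <- 1
        hit <- ts == t
        if (any(hit)) out[hit, ] <- S[hit, , drop = FALSE]
    }
    AnnMatrix(out, obsNames = paste0("cell", seq_len(nCells)),
              varNames = m@genes,
              obs = data.frame(sim_time = ts,
                               trajectory_id = seq_len(nCells)),
              uns = list(grn_params = list(hill_n = m@hillN, hill_k = m@hillK,
                                           dt = m@dt, noise_sd = m@noiseSd,
                                           seed = as.numeric(seed),
                                           n_steps = as.numeric(nSteps))))
}
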