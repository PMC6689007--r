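#' Infer discrete potency states from logit-SR values
#'
#' Fits one-dimensional Gaussian mixtures with K = 1..`kMax` components to
#' the base-2 logit of the normalized entropy rate and selects K by the
#' Bayesian Information Criterion (convention `BIC = -2 loglik + p log n`,
#' minimized; equivalent to the maximizing convention of mclust, which
#' performs the fits). States are relabeled by ascending mean, so state K is
#' the highest-potency state. Fitting is deterministic given the data
#' (hierarchical model-based initialization); `seed` is fixed for
#' reproducibility of any stochastic fallback path.
#'
#' @param y numeric vector of logit-SR values (finite).
#' @param kMax maximum number of candidate states (default 6).
#' @param seed integer seed.
#' @param varModel "V" for unequal component variances (default) or "E" for
#'   a shared variance.
#' @return a [PotencyModel-class].
#' @importFrom mclust Mclust mclustBIC
#' @examples
#' set.seed(1)
#' y <- c(rnorm(100, -4, 0.5), rnorm(100, 0, 0.5), rnorm(100, 4, 0.5))
#' m <- inferPotencyStates(y, seed = 7)
#' numStates(m)  # 3
#' @export
inferPotencyStates <- function(y, kMax = 6L, seed = 42L,
                               varModel = c("V", "E")) {
    varModel <- match.arg(varModel)
    y <- as.numeric(y)
    if (any(!is.finite(y))) stop("logit-SR values must be finite")
    if (length(y) < 10L * kMax)
        stop("need at least 10 * kMax observations (", 10L * kMax,
             "); got ", length(y))
    if (stats::sd(y) == 0)
        stop("all values identical; mixture variance is degenerate")
    set.seed(as.integer(seed))
    fits <- lapply(seq_len(kMax), function(k) {
        suppressWarnings(tryCatch(
            Mclust(y, G = k, modelNames = varModel, verbose = FALSE),
            error = function(e) NULL))
    })
    n <- length(y)
    bic <- vapply(fits, function(f) {
        if (is.null(f) || is.na(f$loglik)) return(NA_real_)
        # p: k means + k weights - 1 + (k or 1) variances
        k <- f$G
        p <- k + (k - 1L) + if (varModel == "V") k else 1L
        -2 * f$loglik + p * log(n)
    }, numeric(1))
    names(bic) <- paste0("K", seq_len(kMax))
    if (all(is.na(bic))) stop("no mixture model could be fitted")
    best <- which.min(bic)
    fit <- fits[[best]]
    pars <- fit$parameters
    means <- as.numeric(pars$mean)
    sds <- sqrt(if (length(pars$variance$sigmasq) == 1L)
        rep(pars$variance$sigmasq, fit$G) else pars$variance$sigmasq)
    wts <- as.numeric(pars$pro)
    ord <- order(means)
    z <- fit$z
    if (is.null(z)) z <- matrix(1, n, 1L)
    z <- z[, ord, drop = FALSE]
    z <- z / rowSums(z)
    labels <- max.col(z, ties.method = "first")
    new("PotencyModel",
        K = as.integer(fit$G),
        means = means[ord], sds = sds[ord], weights = wts[ord],
        bicTable = bic,
        posteriors = unname(z),
        labels = as.integer(labels),
        logLik = as.numeric(fit$loglik),
        varModel = varModel)
}

#' Assign potency states to new logit-SR values
#'
#' Posterior membership `P(state k | y) \propto weight_k N(y; mean_k, sd_k)`;
#' the hard label is the argmax, with ties resolved to the lower state index.
#'
#' @param model a fitted [PotencyModel-class].
#' @param y numeric vector of logit-SR values.
#' @return list with `labels` (integer) and `posteriors` (cells x K matrix).
#' @export
assignState <- function(model, y) {
    stopifnot(is(model, "PotencyModel"))
    y <- as.numeric(y)
    dens <- vapply(seq_len(model@K), function(k)
        model@weights[k] * stats::dnorm(y, model@means[k], model@sds[k]),
        numeric(length(y)))
    dens <- matrix(dens, nrow = length(y))
    # guard against underflow far in the tails: fall back to nearest mean
    zero <- rowSums(dens) == 0
    if (any(zero)) {
        nearest <- vapply(y[zero], function(v)
            which.min(abs(v - model@means)), integer(1))
        dens[cbind(which(zero), nearest)] <- 1
    }
    post <- dens / rowSums(dens)
    list(labels = max.col(post, ties.method = "first"),
         posteriors = post)
}
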