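#' Fit the Bayesian linear measurement transformation
#'
#' Automatic segmentation masks carry a systematic, approximately linear size
#' bias relative to ground truth. This fits, per size metric, the Bayesian
#' linear model
#' \deqn{truth_i \sim Normal(m \cdot auto_i + n, \sigma)}
#' with weakly informative priors `m, n ~ Normal(0, 20)` and a Half-Cauchy
#' prior on `sigma`, by MCMC (JAGS). All post-warmup draws from every chain
#' are retained, so the total posterior sample count is
#' `chains * draws_per_chain` (12000 with the defaults).
#'
#' @param auto_values metric values measured on automatic masks.
#' @param truth_values matching ground-truth values (same length, >= 3).
#' @param metric name of the size metric (bookkeeping).
#' @param chains MCMC chains (default 4).
#' @param draws_per_chain retained draws per chain after warm-up (default
#'   3000).
#' @param warmup adaptation + burn-in iterations (default 1000).
#' @param prior_sd prior SD of slope and intercept (default 20).
#' @param sigma_scale Half-Cauchy scale for `sigma` (default 10; weakly
#'   informative for um-scale residuals).
#' @param seed integer seed; fits are reproducible given the seed.
#' @return A `correction_model`: list with `metric`, `draws` (data.frame
#'   with columns chain, draw, m, n_intercept, sigma), `chains`,
#'   `draws_per_chain`, `rhat` (split-Rhat per parameter). Warns if any
#'   split-Rhat exceeds 1.05.
#' @export
fit_correction_model <- function(auto_values, truth_values, metric = "width",
                                 chains = 4, draws_per_chain = 3000,
                                 warmup = 1000, prior_sd = 20,
                                 sigma_scale = 10, seed = 1) {
  if (length(auto_values) != length(truth_values))
    stop("`auto_values` and `truth_values` must have equal length")
  if (length(auto_values) < 3) stop("need at least 3 pairs")
  if (any(!is.finite(auto_values)) || any(!is.finite(truth_values)))
    stop("non-finite input values")

  # Sampled on centered x for mixing: with q = n0 + m * xbar the likelihood
  # decouples m and q, and the prior q | m ~ Normal(m * xbar, prior_sd) is
  # exactly equivalent (unit Jacobian) to n0 ~ Normal(0, prior_sd).
  model_str <- "model {
    for (i in 1:N) { y[i] ~ dnorm(m * xc[i] + q, tau) }
    m ~ dnorm(0, prec_mn)
    q ~ dnorm(m * xbar, prec_mn)
    n0 <- q - m * xbar
    sigma ~ dt(0, prec_sig, 1) T(1.0E-9,)
    tau <- 1 / (sigma * sigma)
  }"
  ols <- stats::lm.fit(cbind(auto_values, 1), truth_values)$coefficients
  xbar <- mean(auto_values)
  inits <- lapply(seq_len(chains), function(ch) list(
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = as.integer(seed %% 2^20 * 1000 + ch),
    m = unname(ols[1]), q = unname(ols[2] + ols[1] * xbar), sigma = 0.1
  ))
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = truth_values, xc = auto_values - xbar, xbar = xbar,
                N = length(auto_values),
                prec_mn = 1 / prior_sd^2, prec_sig = 1 / sigma_scale^2),
    inits = inits, n.chains = chains,
    n.adapt = max(100, floor(warmup / 2)), quiet = TRUE
  )
  update(jm, max(0, warmup - max(100, floor(warmup / 2))),
         progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("m", "n0", "sigma"),
                              n.iter = draws_per_chain,
                              progress.bar = "none")
  mats <- lapply(samp, as.matrix)
  draws <- do.call(rbind, lapply(seq_along(mats), function(ch) {
    data.frame(chain = ch, draw = seq_len(nrow(mats[[ch]])),
               m = mats[[ch]][, "m"], n_intercept = mats[[ch]][, "n0"],
               sigma = mats[[ch]][, "sigma"])
  }))
  rownames(draws) <- NULL
  rhat <- vapply(c("m", "n_intercept", "sigma"), function(p)
    split_rhat(matrix(draws[[p]], ncol = chains)), numeric(1))
  if (any(rhat > 1.05, na.rm = TRUE))
    warning("split-Rhat > 1.05 for: ",
            paste(names(rhat)[rhat > 1.05], collapse = ", "),
            "; consider more warmup")
  structure(list(metric = metric, draws = draws, chains = chains,
                 draws_per_chain = draws_per_chain, rhat = rhat),
            class = "correction_model")
}

# Split-Rhat: halve each chain, then classic potential scale reduction.
split_rhat <- function(chain_matrix) {
  n <- nrow(chain_matrix)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  halves <- cbind(chain_matrix[seq_len(half), , drop = FALSE],
                  chain_matrix[(n - half + 1):n, , drop = FALSE])
  mns <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(mns)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "correction_model [%s]: %d draws (%d chains x %d)\n",
    x$metric, nrow(x$draws), x$chains, x$draws_per_chain))
  cat(sprintf("  m = %.4f, n = %.4f, sigma = %.4f (posterior means)\n",
              mean(x$draws$m), mean(x$draws$n_intercept),
              mean(x$draws$sigma)))
  invisible(x)
}

#' Apply a fitted measurement transformation
#'
#' For each input value, draws `K` (m, n) pairs jointly (rows of the
#' posterior draw table, uniformly with replacement, preserving posterior
#' correlation) and computes `m * x + n`. The per-cell summary is the median
#' of the K transformed values. No observation noise is added; `sigma` is
#' diagnostic only.
#'
#' @param model a [fit_correction_model()] result.
#' @param values metric values to transform.
#' @param K posterior pairs per value (default 250).
#' @param seed integer seed.
#' @return A `transformed_measurements` object: list with `values` (inputs),
#'   `transformed` (K x length(values) matrix), `summary` (per-value
#'   medians), `K`.
#' @export
apply_correction <- function(model, values, K = 250, seed = 1) {
  stopifnot(inherits(model, "correction_model"))
  if (K <= 0) stop("`K` must be positive")
  nd <- nrow(model$draws)
  if (K > nd) stop("`K` exceeds the number of posterior draws")
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  out <- vapply(values, function(x) {
    idx <- sample.int(nd, K, replace = TRUE)
    model$draws$m[idx] * x + model$draws$n_intercept[idx]
  }, numeric(K))
  out <- matrix(out, nrow = K)
  structure(list(values = values, transformed = out,
                 summary = apply(out, 2, median), K = K),
            class = "transformed_measurements")
}

#' @export
print.transformed_measurements <- function(x, ...) {
  cat(sprintf(
    "transformed_measurements: %d value(s), %d posterior pairs each\n",
    length(x$values), x$K))
  invisible(x)
}

#' Save / load a correction model as columnar CSV
#'
#' The model file stores the posterior draws with header
#' `chain, draw, m, n_intercept, sigma`.
#'
#' @param model a `correction_model`.
#' @param path CSV path.
#' @return `path` (write) or a `correction_model` (read).
#' @export
write_correction_model <- function(model, path) {
  stopifnot(inherits(model, "correction_model"))
  utils::write.csv(model$draws, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_correction_model
#' @param metric metric name to attach on read.
#' @export
read_correction_model <- function(path, metric = "width") {
  draws <- utils::read.csv(path)
  need <- c("chain", "draw", "m", "n_intercept", "sigma")
  if (!all(need %in% names(draws)))
    stop("not a correction model file: needs columns ",
         paste(need, collapse = ", "))
  chains <- length(unique(draws$chain))
  structure(list(metric = metric, draws = draws, chains = chains,
                 draws_per_chain = nrow(draws) / chains,
                 rhat = NULL),
            class = "correction_model")
}

#' Kullback-Leibler divergence between two empirical samples
#'
#' Discrete KL(P || Q) over a shared histogram: bins span the pooled range,
#' bin count by the Freedman-Diaconis rule on the pooled sample (minimum 10),
#' and a small additive epsilon before normalization keeps the estimate
#' finite on disjoint supports.
#'
#' @param sample_p test sample (P).
#' @param sample_q reference sample (Q), e.g. ground-truth-derived values.
#' @param eps smoothing constant (default 1e-10).
#' @param min_bins minimum histogram bins (default 10).
#' @return Non-negative finite scalar.
#' @export
kl_divergence <- function(sample_p, sample_q, eps = 1e-10, min_bins = 10) {
  if (!length(sample_p) || !length(sample_q)) stop("empty input sample")
  pooled <- c(sample_p, sample_q)
  rng <- range(pooled)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  nb <- max(min_bins, grDevices::nclass.FD(pooled))
  breaks <- seq(rng[1], rng[2], length.out = nb + 1)
  hp <- tabulate(findInterval(sample_p, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = nb)
  hq <- tabulate(findInterval(sample_q, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = nb)
  p <- (hp + eps); p <- p / sum(p)
  q <- (hq + eps); q <- q / sum(q)
  sum(p * log(p / q))
}

#' Compare groups with the Levene-gated ANOVA/Kruskal flow
#'
#' Brown-Forsythe (median-centered Levene) test for equality of variances;
#' if its p-value exceeds 0.05 a one-way ANOVA is run, otherwise a
#' Kruskal-Wallis test.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @param alpha variance-test threshold (default 0.05).
#' @return A `distribution_comparison`: list with `levene_p`, `chosen_test`
#'   (`"anova"` or `"kruskal"`), `test_p`, `group_sizes`.
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  lev <- car::leveneTest(values ~ grp, center = median)
  levene_p <- lev[["Pr(>F)"]][1]
  if (is.na(levene_p)) levene_p <- 1  # identical groups: no variance to test
  if (levene_p > alpha) {
    fit <- stats::aov(values ~ grp)
    test_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    if (is.na(test_p)) test_p <- 1  # zero between- and within-group variance
    chosen <- "anova"
  } else {
    test_p <- stats::kruskal.test(values, grp)$p.value
    chosen <- "kruskal"
  }
  structure(list(levene_p = levene_p, chosen_test = chosen, test_p = test_p,
                 group_sizes = vapply(groups, length, integer(1))),
            class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat(sprintf(
    "distribution_comparison: Levene p = %.4g -> %s, p = %.4g (n = %s)\n",
    x$levene_p, x$chosen_test, x$test_p,
    paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}
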