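#' Box-Cox variance-stabilizing transformation
#'
#' Transforms non-negative per-codon coverage toward normality:
#' y = ((x + c)^lambda - 1) / lambda for lambda != 0, and ln(x + c) for
#' lambda = 0, with pseudocount c guarding zeros. In `"auto"` mode lambda
#' maximizes the Gaussian profile log-likelihood over \[-2, 2\] (grid search
#' refined by golden section).
#'
#' @param values Non-negative numeric vector.
#' @param pseudocount Offset added before transforming, default 0.5.
#' @param lambda Either a number or `"auto"`.
#' @return A list of class `boxcox_result`: `lambda`, `transformed`,
#'   `pseudocount`.
#' @examples
#' boxcox_transform(rpois(100, 10), lambda = 0)$lambda
#' @export
boxcox_transform <- function(values, pseudocount = 0.5, lambda = "auto") {
  stopifnot(is.numeric(values), all(is.finite(values)))
  x <- values + pseudocount
  if (any(x <= 0)) {
    stop("domain-error: values + pseudocount must be positive", call. = FALSE)
  }
  bc <- function(l) if (abs(l) < 1e-12) log(x) else (x^l - 1) / l
  if (identical(lambda, "auto")) {
    # profile log-likelihood: -n/2 log sigma^2(lambda) + (lambda-1) sum log x
    n <- length(x)
    slx <- sum(log(x))
    ll <- function(l) {
      y <- bc(l)
      v <- mean((y - mean(y))^2)
      if (v <= 0) return(-Inf)
      -n / 2 * log(v) + (l - 1) * slx
    }
    grid <- seq(-2, 2, by = 0.1)
    lg <- vapply(grid, ll, numeric(1))
    i <- which.max(lg)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-6)
    lambda <- opt$maximum
  }
  structure(list(lambda = lambda, transformed = bc(lambda),
                 pseudocount = pseudocount),
            class = "boxcox_result")
}

#' Assemble the codon-level predictor matrix
#'
#' Joins a per-codon response with named feature tracks and downstream-lag
#' terms: Lag_k at codon i is the response at codon i + k (the A + k site).
#' Codons missing any predictor or lag are dropped; the number of dropped
#' rows is recorded. Feature tracks that are entirely missing are dropped
#' with a warning; constant tracks are retained but flagged.
#'
#' @param response Numeric vector of (transformed) per-codon values, or a
#'   [feature_track()].
#' @param features Named list of [feature_track()]s or equal-length numeric
#'   vectors, or a long track tibble whose `feature` column names the
#'   predictors.
#' @param n_lags Number of downstream lags of the response, default 3.
#' @return A tibble of class `predictor_matrix` with `codon_index`,
#'   `response`, feature columns and `Lag1..Lagk`; attributes `n_dropped`
#'   and `zero_variance` (names of constant columns).
#' @export
build_predictor_matrix <- function(response, features = list(), n_lags = 3L) {
  if (is.data.frame(response)) response <- track_values(response)
  n <- length(response)
  if (is.data.frame(features)) {
    features <- split(features, features$feature)
  }
  feats <- lapply(features, function(f) if (is.data.frame(f)) track_values(f) else as.numeric(f))
  if (length(feats)) {
    if (any(lengths(feats) != n)) {
      stop("all feature tracks must match the response length ", n, call. = FALSE)
    }
    all_na <- vapply(feats, function(v) all(is.na(v)), logical(1))
    if (any(all_na)) {
      warning("dropping all-missing feature track(s): ",
              paste(names(feats)[all_na], collapse = ","), call. = FALSE)
      feats <- feats[!all_na]
    }
  }
  tbl <- tibble::tibble(codon_index = seq_len(n) - 1L, response = response)
  for (nm in names(feats)) tbl[[nm]] <- feats[[nm]]
  for (k in seq_len(n_lags)) {
    tbl[[paste0("Lag", k)]] <- c(response[-seq_len(k)], rep(NA_real_, k))
  }
  keep <- stats::complete.cases(tbl)
  out <- tbl[keep, , drop = FALSE]
  if (!nrow(out)) stop("empty-design-error: no complete rows", call. = FALSE)
  pred_cols <- setdiff(names(out), c("codon_index", "response"))
  zv <- pred_cols[vapply(pred_cols, function(cn) stats::var(out[[cn]]) == 0, logical(1))]
  attr(out, "n_dropped") <- n - nrow(out)
  attr(out, "zero_variance") <- zv
  class(out) <- c("predictor_matrix", class(out))
  out
}

pm_predictors <- function(X) setdiff(names(X), c("codon_index", "response"))

fit_terms <- function(X, terms) {
  fml <- if (length(terms)) {
    stats::reformulate(sprintf("`%s`", terms), response = "response")
  } else {
    response ~ 1
  }
  stats::lm(fml, data = X)
}

#' Ordinary least squares on the predictor matrix
#'
#' Fits the per-codon linear model with intercept by least squares and
#' returns estimates, standard errors, t statistics and two-sided p-values
#' for each term, plus the Gaussian AIC (log-likelihood constant included,
#' so values are comparable with mainstream statistical software).
#'
#' @param X A [build_predictor_matrix()] result.
#' @param terms Character vector of predictor names (default: all).
#' @return An object of class `kinfit` (see [tidy.kinfit()],
#'   [glance.kinfit()]).
#' @export
ols_fit <- function(X, terms = pm_predictors(X)) {
  stopifnot(all(terms %in% pm_predictors(X)))
  if (nrow(X) <= length(terms) + 1L) {
    stop("need n > number of terms + 1", call. = FALSE)
  }
  fit <- fit_terms(X, terms)
  if (any(is.na(stats::coef(fit)))) {
    stop("singular-design-error: rank-deficient design (",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ","),
         ")", call. = FALSE)
  }
  structure(list(fit = fit, terms = terms, aic = stats::AIC(fit),
                 n = nrow(X)),
            class = "kinfit")
}

#' @export
print.kinfit <- function(x, ...) {
  cat("<kinfit> n =", x$n, "| terms:",
      if (length(x$terms)) paste(x$terms, collapse = ", ") else "(intercept only)",
      "| AIC =", format(x$aic, digits = 6), "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a per-codon regression fit
#'
#' @param x A [ols_fit()] / [stepwise_aic()] result.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `t_value`,
#'   `p_value` (the classic regression-report columns).
#' @export
tidy.kinfit <- function(x, ...) {
  cf <- stats::coef(summary(x$fit))
  tibble::tibble(term = gsub("`", "", rownames(cf)),
                 estimate = unname(cf[, "Estimate"]),
                 std_error = unname(cf[, "Std. Error"]),
                 t_value = unname(cf[, "t value"]),
                 p_value = unname(cf[, "Pr(>|t|)"]))
}

#' One-row summary of a per-codon regression fit
#'
#' @inheritParams tidy.kinfit
#' @return A tibble with `n`, `n_terms`, `r_squared`, `sigma`, `aic`.
#' @export
glance.kinfit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(n = x$n, n_terms = length(x$terms),
                 r_squared = s$r.squared, sigma = s$sigma, aic = x$aic)
}

#' Write a model report TSV
#'
#' Mirrors the usual regression-table columns (term, estimate, std_error,
#' t_value, p_value) and appends the model AIC as a comment line.
#'
#' @param fit A `kinfit`.
#' @param path Output path.
#' @export
write_model_report <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# AIC\t%.6f\tn\t%d", fit$aic, fit$n), con)
  utils::write.table(as.data.frame(tidy(fit)), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Stepwise model selection by AIC
#'
#' Starting from the full model, repeatedly applies the single add or drop
#' move that most decreases the Gaussian AIC until no move improves it
#' (both directions). Ties break deterministically: drops before adds, then
#' predictor name order.
#'
#' @param X A [build_predictor_matrix()] result.
#' @param scope Candidate predictors (default: all).
#' @param trace Print each move.
#' @return A `kinfit` for the selected model.
#' @export
stepwise_aic <- function(X, scope = pm_predictors(X), trace = FALSE) {
  # perfectly collinear columns cannot enter lm together; drop by name order
  usable <- sort(scope)  # name order fixes which of two aliased columns survives
  repeat {
    fit <- fit_terms(X, usable)
    na_terms <- names(which(is.na(stats::coef(fit))))
    if (!length(na_terms)) break
    drop_nm <- sort(gsub("`", "", na_terms), decreasing = TRUE)[1]
    usable <- setdiff(usable, drop_nm)
    if (trace) message("dropping aliased predictor: ", drop_nm)
  }
  current <- sort(usable)
  aic_cur <- stats::AIC(fit_terms(X, current))
  repeat {
    drops <- sort(current)
    adds <- sort(setdiff(usable, current))
    moves <- c(lapply(drops, function(t) setdiff(current, t)),
               lapply(adds, function(t) sort(c(current, t))))
    names(moves) <- c(if (length(drops)) paste0("- ", drops),
                      if (length(adds)) paste0("+ ", adds))
    if (!length(moves)) break
    aics <- vapply(moves, function(tr) stats::AIC(fit_terms(X, tr)), numeric(1))
    best <- which.min(aics)  # first minimum: drops (name order) before adds
    if (aics[best] < aic_cur - 1e-10) {
      if (trace) message(names(moves)[best], "  AIC ", round(aics[best], 3))
      current <- moves[[best]]
      aic_cur <- aics[best]
    } else break
  }
  ols_fit(X, current)
}

#' Cumulative-sum profile of transformed coverage
#'
#' Standardizes the transformed values (subtract mean, divide by SD) and
#' cumulatively sums them. Under pure noise the curve is a random walk
#' bridge pinned to 0 at its end; sustained regional slowdowns bend it away
#' from 0. A zero-variance input yields a flagged all-zero curve.
#'
#' @param transformed Finite numeric vector (e.g. ln or Box-Cox coverage).
#' @param gene_id Label carried into the result.
#' @return A list of class `cumsum_profile`: `curve`, `standardized`,
#'   `degenerate`, `gene_id`.
#' @export
cumsum_profile <- function(transformed, gene_id = "gene") {
  stopifnot(is.numeric(transformed), all(is.finite(transformed)))
  s <- stats::sd(transformed)
  if (!is.finite(s) || s == 0) {
    z <- rep(0, length(transformed))
    return(structure(list(curve = z, standardized = z, degenerate = TRUE,
                          gene_id = gene_id), class = "cumsum_profile"))
  }
  z <- (transformed - mean(transformed)) / s
  structure(list(curve = cumsum(z), standardized = z, degenerate = FALSE,
                 gene_id = gene_id), class = "cumsum_profile")
}

#' @export
print.cumsum_profile <- function(x, ...) {
  cat("<cumsum_profile> ", x$gene_id, ": ", length(x$curve), " codons, max |curve| = ",
      format(max(abs(x$curve)), digits = 4),
      if (x$degenerate) " (degenerate)", "\n", sep = "")
  invisible(x)
}

#' Plot cumulative-sum curves
#'
#' @param object A `cumsum_profile`.
#' @param ... Further `cumsum_profile`s to overlay (e.g. the second variant).
#' @return A ggplot object.
#' @export
autoplot.cumsum_profile <- function(object, ...) {
  profs <- c(list(object), list(...))
  df <- dplyr::bind_rows(lapply(profs, function(p) {
    tibble::tibble(gene_id = p$gene_id, codon_index = seq_along(p$curve) - 1L,
                   cumsum = p$curve)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon_index, y = .data$cumsum,
                                   colour = .data$gene_id)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "codon (0-based)", y = "cumulative sum of standardized values",
                  colour = "gene") +
    ggplot2::theme_minimal()
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D = sup |ECDF_a - ECDF_b| with the asymptotic Kolmogorov p-value at
#' effective sample size n_a n_b / (n_a + n_b).
#'
#' @param a,b Nonempty numeric vectors.
#' @return A tibble with `D` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  tibble::tibble(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Compare the cumulative-sum curves of two variants
#'
#' Builds the cumulative-sum profile of each variant's transformed coverage
#' and compares the two curves' value sets with the two-sample KS test. This
#' operationalizes the variant-vs-variant comparison of regional translation
#' kinetics; the choice of curve values as the KS operands is a documented
#' convention (see the methods vignette).
#'
#' @param a,b Transformed per-codon vectors (or `cumsum_profile`s).
#' @return A list of class `cumsum_comparison`: both profiles plus `ks_D`,
#'   `ks_p`, `null_kind = "variant-vs-variant"`.
#' @export
cumsum_compare <- function(a, b) {
  pa <- if (inherits(a, "cumsum_profile")) a else cumsum_profile(a, gene_id = "a")
  pb <- if (inherits(b, "cumsum_profile")) b else cumsum_profile(b, gene_id = "b")
  ks <- ks_two_sample(pa$curve, pb$curve)
  structure(list(profile_a = pa, profile_b = pb, ks_D = ks$D, ks_p = ks$p_value,
                 null_kind = "variant-vs-variant"),
            class = "cumsum_comparison")
}

#' @export
print.cumsum_comparison <- function(x, ...) {
  cat("<cumsum_comparison> ", x$profile_a$gene_id, " vs ", x$profile_b$gene_id,
      ": KS D = ", format(x$ks_D, digits = 4), ", p = ",
      format(x$ks_p, digits = 4), "\n", sep = "")
  invisible(x)
}

# simulate n_sims standardized-Gaussian cumulative-sum curves of length n;
# returns matrix (n x n_sims)
simulate_null_curves <- function(n, n_sims) {
  m <- matrix(stats::rnorm(n * n_sims), nrow = n)
  m <- scale(m)  # per-column standardization, as cumsum_profile does
  apply(m, 2, cumsum)
}

#' Test a coverage profile against simulated white noise
#'
#' Simulates `n_sims` standard-Gaussian sequences of the same length,
#' builds their cumulative-sum profiles, and reports the fraction whose
#' maximum |curve| reaches the observed one (the empirical p-value of the
#' null hypothesis that the observed transformed coverage is white noise),
#' plus the KS statistic between the observed curve and the pooled simulated
#' curve values.
#'
#' @param transformed Transformed per-codon vector (or a `cumsum_profile`).
#' @param n_sims Number of simulated sequences, at least 100 (default 1000).
#' @param seed Integer seed for the simulation.
#' @return A list of class `white_noise_test`: `p_empirical`, `observed_max`,
#'   `ks_D`, `ks_p`, `n_sims`, `degenerate`, `null_kind = "white-noise"`.
#' @export
white_noise_test <- function(transformed, n_sims = 1000L, seed = 1L) {
  stopifnot(n_sims >= 100L)
  prof <- if (inherits(transformed, "cumsum_profile")) transformed
          else cumsum_profile(transformed)
  if (prof$degenerate) {
    return(structure(list(p_empirical = 1, observed_max = 0, ks_D = NA_real_,
                          ks_p = NA_real_, n_sims = n_sims, degenerate = TRUE,
                          null_kind = "white-noise"),
                     class = "white_noise_test"))
  }
  n <- length(prof$curve)
  obs <- max(abs(prof$curve))
  curves <- withr::with_seed(seed, simulate_null_curves(n, n_sims))
  sim_max <- apply(abs(curves), 2, max)
  ks <- ks_two_sample(prof$curve, as.numeric(curves))
  structure(list(p_empirical = mean(sim_max >= obs), observed_max = obs,
                 ks_D = ks$D, ks_p = ks$p_value, n_sims = n_sims,
                 degenerate = FALSE, null_kind = "white-noise"),
            class = "white_noise_test")
}

#' @export
print.white_noise_test <- function(x, ...) {
  cat("<white_noise_test> empirical p = ", format(x$p_empirical, digits = 4),
      " (", x$n_sims, " sims; max |curve| = ", format(x$observed_max, digits = 4),
      if (x$degenerate) "; degenerate", ")\n", sep = "")
  invisible(x)
}
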