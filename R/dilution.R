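#' Construct a serial-dilution well-count series
#'
#' Limiting-dilution PCR quantitation scores each well (parallel PCR
#' reaction) as positive or negative for amplification; under Poisson
#' seeding a well is negative exactly when zero amplifiable template
#' molecules entered it. A series records, per dilution level, the fold
#' dilution relative to the stock, the number of wells and the number of
#' negative wells.
#'
#' @param dilution_factor numeric vector, fold dilution of each level
#'   relative to the stock (strictly increasing, >= 1).
#' @param n_wells,n_negative integer vectors per level;
#'   `0 <= n_negative <= n_wells`.
#' @param molecule_class optional label (`"crossover"` / `"parental"`).
#' @return object of class `dilution_series` (a data.frame).
#' @export
dilution_series <- function(dilution_factor, n_wells, n_negative,
                            molecule_class = NA_character_) {
  if (length(dilution_factor) < 1L ||
      length(dilution_factor) != length(n_wells) ||
      length(n_wells) != length(n_negative)) {
    abort_data("levels must supply equal-length factor/wells/negatives")
  }
  if (any(dilution_factor < 1) || is.unsorted(dilution_factor, strictly = TRUE)) {
    abort_data("`dilution_factor` must be strictly increasing and >= 1")
  }
  if (any(n_negative < 0) || any(n_negative > n_wells) || any(n_wells < 1)) {
    abort_data("need 0 <= n_negative <= n_wells, n_wells >= 1")
  }
  structure(
    data.frame(level = seq_along(dilution_factor),
               dilution_factor = as.numeric(dilution_factor),
               n_wells = as.integer(n_wells),
               n_negative = as.integer(n_negative),
               molecule_class = molecule_class,
               stringsAsFactors = FALSE),
    class = c("dilution_series", "data.frame")
  )
}

#' Simulate serial-dilution well outcomes under Poisson seeding
#'
#' Emulates the bench protocol: a stock containing amplifiable molecules is
#' serially diluted (two-fold by default, the standard consecutive-reaction
#' scheme) and a fixed number of parallel PCR wells is run at each level.
#' Each well at level with dilution factor `f` is positive with probability
#' `1 - exp(-lambda/f)` where `lambda = true_molecules_per_ul *
#' input_volume` is the per-well mean at the stock.
#'
#' @param true_molecules_per_ul true amplifiable molecule concentration
#'   (must be > 0).
#' @param fold fold dilution between consecutive levels (> 1; default 2).
#' @param n_levels number of dilution levels (level 1 = stock, factor 1).
#' @param wells_per_level parallel PCR wells per level (default 20).
#' @param input_volume volume seeded per well, in the same units (default 1).
#' @param seed integer seed.
#' @param molecule_class optional label carried into the series.
#' @return a [dilution_series()] with simulated `n_negative` and the true
#'   stock mean attached as attribute `"true_lambda"`.
#' @export
make_dilution_series <- function(true_molecules_per_ul, fold = 2,
                                 n_levels = 8L, wells_per_level = 20L,
                                 input_volume = 1, seed = 1L,
                                 molecule_class = NA_character_) {
  if (!is.numeric(true_molecules_per_ul) || true_molecules_per_ul <= 0) {
    abort_data("`true_molecules_per_ul` must be > 0")
  }
  if (fold <= 1) abort_data("`fold` must be > 1")
  n_levels <- assert_count(n_levels, "n_levels", min = 1L)
  wells_per_level <- assert_count(wells_per_level, "wells_per_level", min = 1L)
  lambda0 <- true_molecules_per_ul * input_volume
  f <- fold^(seq_len(n_levels) - 1L)
  with_seed(seed, {
    p_neg <- exp(-lambda0 / f)
    n_neg <- rbinom(n_levels, wells_per_level, p_neg)
    out <- dilution_series(f, rep(wells_per_level, n_levels), n_neg,
                           molecule_class = molecule_class)
    attr(out, "true_lambda") <- lambda0
    out
  })
}

#' Single-level Poisson estimate of amplifiable molecules
#'
#' At one dilution level the fraction of negative wells estimates the
#' Poisson zero class: per-well mean `-log(n_negative/n_wells)`, scaled by
#' the dilution factor to the mean per well of undiluted stock. A level
#' with zero negative wells has no finite single-level estimate; use
#' [estimate_lambda_joint()] across levels instead.
#'
#' @param n_negative,n_wells well counts at the level
#'   (`1 <= n_negative <= n_wells`).
#' @param dilution_factor fold dilution of the level relative to stock.
#' @return estimated mean molecules per well at the stock concentration.
#' @examples
#' estimate_lambda_single(5, 20, dilution_factor = 8)  # 8 * log(4)
#' @export
estimate_lambda_single <- function(n_negative, n_wells, dilution_factor = 1) {
  n_negative <- assert_count(n_negative, "n_negative")
  n_wells <- assert_count(n_wells, "n_wells", min = 1L)
  if (dilution_factor < 1) abort_data("`dilution_factor` must be >= 1")
  if (n_negative > n_wells) abort_data("n_negative > n_wells")
  if (n_negative == 0L) {
    abort_data(paste("all wells positive: single-level estimate is infinite;",
                     "use estimate_lambda_joint() across levels"),
               class = "hotspotkit_all_positive")
  }
  -log(n_negative / n_wells) * dilution_factor
}

# binomial log-likelihood of the negative-well counts at stock mean lambda
# (constant choose() terms dropped)
dilution_loglik <- function(lambda, series) {
  if (lambda < 0) return(-Inf)
  mu <- lambda / series$dilution_factor
  n_pos <- series$n_wells - series$n_negative
  ll <- -series$n_negative * mu
  pos_term <- ifelse(n_pos > 0,
                     n_pos * log1p(-exp(-mu)),
                     0)
  if (lambda == 0 && any(n_pos > 0)) return(-Inf)
  sum(ll + pos_term)
}

#' Joint most-probable-number estimate across dilution levels
#'
#' Maximises the product of binomial likelihoods
#' `Binom(n_negative; n_wells, exp(-lambda/f))` over the levels of a
#' serial-dilution series — the classical most-probable-number (MPN)
#' construction — and attaches a profile-likelihood 95% interval
#' (chi-square(1) cutoff 3.84). With a single informative level the joint
#' MLE reduces to [estimate_lambda_single()] exactly.
#'
#' Degenerate series are handled one-sidedly: all wells negative gives
#' `lambda_hat = 0` with an upper bound only; all wells positive gives an
#' infinite point estimate with a lower bound only.
#'
#' @param series a [dilution_series()].
#' @param conf_level confidence level for the profile interval.
#' @return list of class `molecule_estimate`: `lambda_hat` (mean molecules
#'   per well at stock), `ci_low`, `ci_high`, `loglik`.
#' @export
estimate_lambda_joint <- function(series, conf_level = 0.95) {
  stopifnot(inherits(series, "dilution_series"))
  cut <- qchisq(conf_level, df = 1) / 2
  ll <- function(l) dilution_loglik(l, series)
  all_neg <- all(series$n_negative == series$n_wells)
  all_pos <- all(series$n_negative == 0L)

  if (all_neg) {
    # no positives: MLE at 0, one-sided upper bound where loglik drops by cut
    upper <- uniroot(function(l) ll(l) - (ll(0) - cut),
                     lower = 0, upper = 1e3 * max(series$dilution_factor))$root
    est <- list(lambda_hat = 0, ci_low = 0, ci_high = upper, loglik = ll(0))
    class(est) <- "molecule_estimate"
    return(est)
  }
  if (all_pos) {
    # no negatives: likelihood increases to 0 as lambda -> Inf
    lower <- uniroot(function(l) ll(l) + cut,
                     lower = 1e-12, upper = 1e6 * max(series$dilution_factor))$root
    est <- list(lambda_hat = Inf, ci_low = lower, ci_high = Inf, loglik = 0)
    class(est) <- "molecule_estimate"
    return(est)
  }

  # bracket the optimum on log(lambda)
  opt <- optimize(function(x) ll(exp(x)),
                  interval = log(c(1e-8, 1e4 * max(series$dilution_factor))),
                  maximum = TRUE, tol = 1e-12)
  lambda_hat <- exp(opt$maximum)
  ll_max <- opt$objective

  drop_fun <- function(l) ll(l) - (ll_max - cut)
  ci_low <- if (drop_fun(1e-12) > 0) 0 else {
    uniroot(drop_fun, lower = 1e-12, upper = lambda_hat, tol = 1e-10)$root
  }
  up <- lambda_hat
  while (drop_fun(up) > 0) up <- up * 4
  ci_high <- uniroot(drop_fun, lower = lambda_hat, upper = up, tol = 1e-10)$root

  est <- list(lambda_hat = lambda_hat, ci_low = ci_low, ci_high = ci_high,
              loglik = ll_max)
  class(est) <- "molecule_estimate"
  est
}

#' @export
print.molecule_estimate <- function(x, ...) {
  cat(sprintf("MPN estimate: %.4g molecules/well at stock (95%% CI %.4g-%.4g)\n",
              x$lambda_hat, x$ci_low, x$ci_high))
  invisible(x)
}

#' Recombination rate from crossover and parental molecule numbers
#'
#' Combines the MPN estimates for crossover-specific and parental-specific
#' amplifications of the same sperm DNA sample into a rate:
#' `cM = 100 * lambda_CO / (lambda_CO + lambda_parental)`.
#'
#' @param crossover_est,parental_est `molecule_estimate` objects from
#'   [estimate_lambda_joint()], or bare numerics.
#' @return recombination rate in cM.
#' @export
rate_from_molecules <- function(crossover_est, parental_est) {
  lam <- function(x) if (inherits(x, "molecule_estimate")) x$lambda_hat else x
  co <- lam(crossover_est)
  par <- lam(parental_est)
  if (co < 0 || par < 0) abort_data("molecule numbers must be >= 0")
  if (co == 0 && par == 0) abort_data("rate undefined: no molecules of either class")
  if (par == 0) abort_data("rate undefined: zero parental molecules")
  100 * co / (co + par)
}

#' Read a dilution-series table from TSV
#'
#' Expected columns: `level_index`, `dilution_factor`, `n_wells`,
#' `n_negative`, `molecule_class`; one series per molecule class.
#'
#' @param path TSV file path (comment lines starting `#` ignored).
#' @return named list of [dilution_series()], one per molecule class.
#' @export
read_dilution_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("dilution_factor", "n_wells", "n_negative", "molecule_class")
  if (!all(need %in% names(df))) {
    abort_data(paste("dilution TSV needs columns:", paste(need, collapse = ", ")))
  }
  out <- lapply(split(df, df$molecule_class), function(d) {
    d <- d[order(d$dilution_factor), ]
    dilution_series(d$dilution_factor, d$n_wells, d$n_negative,
                    molecule_class = d$molecule_class[1])
  })
  out
}
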