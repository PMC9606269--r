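#' Binomial incomplete-labeling probability
#'
#' Probability that an N-mer particle carries exactly `m` functional
#' fluorophores when each subunit is labeled independently with efficiency
#' `p_f`: \eqn{P_{Nm} = \binom{N}{m} p_f^m (1-p_f)^{N-m}}. An N-mer labeled on
#' `m` subunits photobleaches in `m` steps, so incomplete labeling makes true
#' oligomers masquerade as lower orders (and makes fully unlabeled particles
#' invisible).
#'
#' @param order Integer oligomer order N (number of subunits), N >= 0.
#' @param observed Integer m, the number of labeled subunits, 0 <= m <= N.
#' @param p_f Per-subunit labeling efficiency in (0, 1].
#' @return A probability (vectorised over `order`/`observed`).
#' @examples
#' binomial_label_prob(2, 2, 0.8) # 0.64: dimer labeled on both subunits
#' @export
binomial_label_prob <- function(order, observed, p_f) {
  assert_probability(p_f, "p_f")
  if (any(observed > order)) {
    abort("`observed` (m) cannot exceed `order` (N).")
  }
  if (any(order < 0) || any(observed < 0)) {
    abort("`order` and `observed` must be non-negative integers.")
  }
  dbinom(observed, size = order, prob = p_f)
}

#' Observation matrix of the incomplete-labeling model
#'
#' Builds the linear system mapping true particle fractions to observed
#' bleaching-step fractions. With visibility conditioning (the default),
#' entry \code{A[m, i]} is the probability that an order-i particle shows m
#' steps *given that it is visible* (at least one labeled subunit):
#' \deqn{A_{mi} = \binom{i}{m} p_f^m (1-p_f)^{i-m} / (1 - (1-p_f)^i).}
#' Columns then sum to 1. With `conditional = FALSE` the raw binomial
#' probabilities are used and each column sums to the visible fraction
#' \eqn{1-(1-p_f)^i}.
#'
#' @param p_f Per-subunit labeling efficiency in (0, 1].
#' @param n_max Largest oligomer order carried by the model (default 5:
#'   monomer through pentamer).
#' @param conditional Condition on particle visibility? (default TRUE).
#' @return An `n_max` x `n_max` matrix, rows = observed steps m, columns =
#'   true order i; zero above the diagonal in the (m, i) sense (a particle
#'   cannot show more steps than subunits).
#' @export
observation_matrix <- function(p_f, n_max = 5, conditional = TRUE) {
  assert_probability(p_f, "p_f")
  if (n_max < 1) abort("`n_max` must be >= 1.")
  A <- matrix(0, n_max, n_max,
              dimnames = list(steps = seq_len(n_max), order = seq_len(n_max)))
  for (i in seq_len(n_max)) {
    m <- seq_len(i)
    col <- dbinom(m, size = i, prob = p_f)
    if (conditional) col <- col / (1 - (1 - p_f)^i)
    A[m, i] <- col
  }
  A
}

#' Forward model: true fractions to observed step fractions
#'
#' Maps a true particle-fraction vector x over orders 1..n_max to the
#' expected observed bleaching-step fractions R over m = 1..n_max. Particles
#' with zero labeled subunits are undetectable, so (by default) the output is
#' normalized over visible particles: \eqn{R_m \propto \sum_i x_i P_{im}}.
#'
#' @param fractions Numeric vector of true particle fractions (sums to 1).
#' @param p_f Per-subunit labeling efficiency in (0, 1].
#' @param conditional If TRUE (default) renormalize over visible particles so
#'   the result sums to 1; if FALSE return fractions of *all* particles (the
#'   invisible mass is simply missing and the vector sums to less than 1).
#' @return Named numeric vector of observed step fractions, m = 1..n_max.
#' @examples
#' forward_observe(c(0, 1, 0, 0, 0), p_f = 0.8) # dimers: 1/3 one-step, 2/3 two-step
#' @export
forward_observe <- function(fractions, p_f, conditional = TRUE) {
  assert_fractions(fractions, what = "fractions")
  assert_probability(p_f, "p_f")
  n_max <- length(fractions)
  A_u <- observation_matrix(p_f, n_max, conditional = FALSE)
  r <- drop(A_u %*% fractions)
  if (conditional) r <- r / sum(r)
  setNames(r, seq_len(n_max))
}

observed_to_fractions <- function(observed, n_max) {
  if (is.data.frame(observed)) {
    if (!all(c("m", "count") %in% names(observed))) {
      abort("A histogram data frame must have columns `m` and `count`.")
    }
    counts <- numeric(n_max)
    keep <- observed$m >= 1 & observed$m <= n_max
    counts[observed$m[keep]] <- observed$count[keep]
  } else {
    if (length(observed) > n_max) {
      abort("`observed` is longer than `n_max`.")
    }
    counts <- c(observed, numeric(n_max - length(observed)))
  }
  if (any(counts < 0)) abort("Observed counts must be non-negative.")
  total <- sum(counts)
  if (total <= 0) abort("Observed histogram is empty: nothing to correct.")
  list(fractions = counts / total, total = total, counts = counts)
}

solve_one <- function(r_obs, A, p_f, conditional) {
  n_max <- ncol(A)
  fit <- pracma::lsqnonneg(A, r_obs)
  w <- fit$x
  if (conditional) {
    vis <- 1 - (1 - p_f)^seq_len(n_max)
    x <- w / vis
  } else {
    x <- w
  }
  if (sum(x) <= 0) abort("Degenerate solution: all corrected fractions zero.")
  list(x = x / sum(x), residual = sqrt(sum((A %*% w - r_obs)^2)))
}

#' Correct an observed step histogram for incomplete labeling
#'
#' Inverts the binomial incomplete-labeling model: solves
#' \eqn{A x = R} for the true particle fractions x given the
#' observed bleaching-step fractions R, by non-negative least squares
#' followed by renormalization (guaranteeing a valid distribution even on
#' noisy histograms; when the NNLS solution is interior it coincides with the
#' direct solve). Optionally attaches percentile bootstrap confidence
#' intervals obtained by multinomial resampling of the histogram.
#'
#' @param observed Either a histogram tibble with columns `m` (steps) and
#'   `count`, or a numeric vector of counts (or fractions) over m = 1..n_max.
#' @param p_f Per-subunit labeling efficiency in (0, 1].
#' @param n_max Largest oligomer order (default 5).
#' @param conditional Use the visibility-conditioned model (default TRUE).
#' @param bootstrap Number of bootstrap resamples B for confidence intervals
#'   (0 = none). Requires `observed` to carry counts (not bare fractions).
#' @param conf_level Bootstrap interval coverage (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `oligomer_correction`: use [tidy()] for the
#'   per-order corrected fractions (with CIs when bootstrapped), [glance()]
#'   for diagnostics (residual norm, condition number of A, n), and
#'   [autoplot()] to compare observed and corrected distributions.
#' @examples
#' r <- forward_observe(c(0.435, 0.467, 0.049, 0.049, 0), p_f = 0.8)
#' tidy(correct_stoichiometry(r * 1000, p_f = 0.8))
#' @export
correct_stoichiometry <- function(observed, p_f, n_max = 5,
                                  conditional = TRUE, bootstrap = 0,
                                  conf_level = 0.95, seed = NULL) {
  assert_probability(p_f, "p_f")
  obs <- observed_to_fractions(observed, n_max)
  A <- observation_matrix(p_f, n_max, conditional = conditional)
  kappa_A <- kappa(A, exact = TRUE)
  if (kappa_A > 1e6) {
    warn(sprintf(
      "Observation matrix is ill-conditioned (condition number %.3g); corrected fractions for high orders are unreliable at this labeling efficiency.",
      kappa_A))
  }
  sol <- solve_one(obs$fractions, A, p_f, conditional)

  corrected <- tibble(order = seq_len(n_max), fraction = sol$x)
  ci <- NULL
  if (bootstrap > 0) {
    total <- round(obs$total)
    if (total < length(which(obs$counts > 0))) {
      abort("Bootstrap requires `observed` to be counts, not fractions.")
    }
    boots <- with_seed_if(seed, {
      draws <- rmultinom(bootstrap, size = total, prob = obs$fractions)
      apply(draws, 2, function(cts) {
        solve_one(cts / sum(cts), A, p_f, conditional)$x
      })
    })
    qs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
    ci <- t(apply(boots, 1, quantile, probs = qs, names = FALSE))
    corrected$ci_low <- ci[, 1]
    corrected$ci_high <- ci[, 2]
  }

  structure(
    list(
      corrected = corrected,
      observed = tibble(m = seq_len(n_max), fraction = obs$fractions,
                        count = obs$counts),
      p_f = p_f,
      n_max = n_max,
      conditional = conditional,
      residual_norm = sol$residual,
      condition_indicator = kappa_A,
      n_particles = obs$total,
      bootstrap = bootstrap,
      conf_level = conf_level
    ),
    class = "oligomer_correction"
  )
}

#' @export
print.oligomer_correction <- function(x, ...) {
  cat(sprintf(
    "Oligomer correction (P_f = %.3g, orders 1..%d, %s model)\n",
    x$p_f, x$n_max, if (x$conditional) "visibility-conditioned" else "unconditional"))
  cat(sprintf("  particles: %s   residual: %.3g   condition: %.3g\n",
              format(x$n_particles, big.mark = ","),
              x$residual_norm, x$condition_indicator))
  print(x$corrected, ...)
  invisible(x)
}

#' @rdname correct_stoichiometry
#' @param x An `oligomer_correction` object.
#' @param ... Unused.
#' @export
tidy.oligomer_correction <- function(x, ...) {
  x$corrected
}

#' @rdname correct_stoichiometry
#' @exportS3Method generics::glance
glance.oligomer_correction <- function(x, ...) {
  tibble(
    n_particles = x$n_particles,
    p_f = x$p_f,
    n_max = x$n_max,
    residual_norm = x$residual_norm,
    condition_indicator = x$condition_indicator,
    conditional = x$conditional
  )
}

#' Particle fractions to subunit ("entity") fractions
#'
#' Re-weights a particle-level oligomer distribution by subunit count: the
#' fraction of receptor *entities* (protomers) residing in order-i particles
#' is \eqn{E_i = i x_i / \sum_j j x_j}. A 50/50 monomer/dimer particle mix,
#' for instance, has two thirds of its subunits inside dimers.
#'
#' @param fractions Particle-fraction vector over orders 1..n_max (sums to 1).
#' @return Named numeric vector of entity fractions (sums to 1).
#' @export
particle_to_entity <- function(fractions) {
  assert_fractions(fractions, what = "fractions")
  w <- seq_along(fractions) * fractions
  setNames(w / sum(w), seq_along(fractions))
}

#' Group oligomer orders into summary classes
#'
#' Sums a fraction vector within named groups of orders, e.g. the
#' conventional monomer / dimer / oligomer (orders >= 3) split.
#'
#' @param fractions Fraction vector over orders 1..n_max.
#' @param grouping Named list mapping group name to the integer orders it
#'   contains; must cover every order exactly once. Default:
#'   `list(monomer = 1, dimer = 2, oligomer = 3:n_max)`.
#' @return A tibble with columns `group` and `fraction`; fractions preserve
#'   the input total.
#' @export
group_fractions <- function(fractions, grouping = NULL) {
  n_max <- length(fractions)
  if (is.null(grouping)) {
    grouping <- list(monomer = 1, dimer = 2)
    if (n_max >= 3) grouping$oligomer <- 3:n_max
  }
  covered <- sort(unlist(grouping, use.names = FALSE))
  if (!identical(as.integer(covered), seq_len(n_max))) {
    abort("`grouping` must cover each order 1..n_max exactly once.")
  }
  tibble(
    group = names(grouping),
    fraction = unname(purrr::map_dbl(grouping, ~ sum(fractions[.x])))
  )
}

#' Receptors per cell from particle density
#'
#' Converts a measured surface particle density into a per-cell receptor
#' count: density x cell surface area, reported rounded (by default to the
#' nearest ten, matching the precision such counts are usually quoted at).
#'
#' @param density Particle density in particles per square micron.
#' @param cell_area Cell surface area in square microns (default 1200, a
#'   typical COS-7 cell).
#' @param round_to Rounding granularity (default 10; use 1 for the raw
#'   product).
#' @return Receptor count per cell.
#' @examples
#' receptors_per_cell(0.22, 1200) # ~260
#' @export
receptors_per_cell <- function(density, cell_area = 1200, round_to = 10) {
  if (any(density < 0) || cell_area <= 0) {
    abort("`density` must be >= 0 and `cell_area` > 0.")
  }
  round(density * cell_area / round_to) * round_to
}

#' Expression level relative to a physiological reference
#'
#' Ratio of a measured receptor quantity (e.g. Bmax in pmol/mg total
#' protein) to a reference density from native tissue.
#'
#' @param bmax Measured receptor quantity.
#' @param reference Reference quantity in the same units; must be > 0.
#' @return The fold ratio `bmax / reference`.
#' @export
fold_over_reference <- function(bmax, reference) {
  if (any(reference <= 0)) abort("`reference` must be > 0.")
  bmax / reference
}

#' @exportS3Method ggplot2::autoplot
autoplot.oligomer_correction <- function(object, ...) {
  dat <- bind_rows(
    object$observed %>%
      select(order = "m", fraction = "fraction") %>%
      mutate(which = "observed steps"),
    object$corrected %>%
      select("order", "fraction",
             dplyr::any_of(c("ci_low", "ci_high"))) %>%
      mutate(which = "corrected")
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(
    x = factor(.data$order), y = .data$fraction, fill = .data$which)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::labs(x = "oligomer order / observed steps", y = "fraction",
                  fill = NULL) +
    ggplot2::theme_minimal()
  if ("ci_low" %in% names(dat)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25,
      na.rm = TRUE)
  }
  p
}
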