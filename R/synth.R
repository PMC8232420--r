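# Synthetic DILI cohort generator.
#
# The stated world: 432 DILI vs 220 no-DILI drugs; class-conditional AMW
# from a shifted log-normal (shift 6.0) whose (meanlog, sdlog) are solved
# in closed form from the class means 7.99 / 7.49 and the threshold-7.4
# operating point sensitivity 0.64 / specificity 0.71; an MLOGP-like
# lipophilicity feature correlated with class; independent nuisance
# features; Most/Less subclasses with the Most log-mean shifted up; ATC
# strata whose separability heterogeneity comes from preferential
# assignment of correctly/incorrectly screened drugs. The no-DILI
# operating point (mean above 7.4 yet 71% of mass below it) forces a heavy
# right tail: that is a property of the stated numbers, not a tuning
# choice.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# closed-form calibration of one class: shifted log-normal with given mean
# and P(X >= threshold)
.solve_amw_class <- function(mean, p_ge, threshold = 7.4, shift = 6.0) {
  if (mean <= shift) stop("class mean must exceed the distribution shift")
  Mb <- log(mean - shift)
  L <- log(threshold - shift)
  z <- stats::qnorm(1 - p_ge)
  disc <- z^2 + 2 * (Mb - L)
  if (disc < 0) stop("AMW calibration has no real solution")
  r1 <- z + sqrt(disc); r2 <- z - sqrt(disc)
  sigma <- if (r1 > 0) r1 else r2
  if (sigma <= 0) stop("AMW calibration yields non-positive sdlog")
  c(meanlog = Mb - sigma^2 / 2, sdlog = sigma)
}

#' Specification of a synthetic screening cohort
#'
#' Defaults encode the published cohort: class sizes 432:220, class AMW
#' means 7.99 (DILI) and 7.49 (no-DILI), threshold-7.4 operating point
#' 64% sensitivity / 71% specificity (the calibration target of the
#' generator, frozen here), Most fraction 175/432 with the Most log-mean
#' shifted up by `most_shift` (the Less shift is solved so the overall
#' DILI mean is preserved). `separation` scales the gap between the class
#' log-means around their pooled value (1 = calibrated world).
#'
#' @param n_dili,n_nodili class sizes.
#' @param amw_shift shift of the shifted log-normal AMW model.
#' @param amw_mean_dili,amw_mean_nodili class AMW means.
#' @param sens,spec the threshold operating point used for calibration.
#' @param threshold AMW screening boundary.
#' @param separation multiplier on the class log-mean separation.
#' @param most_fraction fraction of DILI drugs with Most-concern label.
#' @param most_shift log-mean shift of the Most subclass.
#' @param mlogp_dili,mlogp_nodili `c(mean, sd)` of the class-conditional
#'   normal MLOGP model.
#' @param n_noise_features count of class-independent standard-normal
#'   features.
#' @param noise_correlation pairwise correlation among noise features
#'   (equicorrelated via a shared factor).
#' @param atc_spec data.frame with columns `code`, `weight` (relative
#'   category size; code `"none"` = no ATC annotation) and `w_correct`
#'   (assignment affinity for drugs the AMW screen classifies correctly;
#'   > 1 makes a category easier than average, < 1 harder).
#' @param years range of approval years assigned uniformly.
#' @param seed default seed used by [generate_cohort()].
#' @return object of class `generator_spec` (a list).
#' @export
generator_spec <- function(n_dili = 432L, n_nodili = 220L,
                           amw_shift = 6.0,
                           amw_mean_dili = 7.99, amw_mean_nodili = 7.49,
                           sens = 0.64, spec = 0.71, threshold = 7.4,
                           separation = 1.0,
                           most_fraction = 175 / 432, most_shift = 0.10,
                           mlogp_dili = c(2.5, 1.5),
                           mlogp_nodili = c(0.5, 1.8),
                           n_noise_features = 5L, noise_correlation = 0,
                           atc_spec = default_atc_spec(),
                           years = 2010:2019, seed = 1L) {
  if (n_dili < 0 || n_nodili < 0) stop("class sizes must be >= 0")
  p1 <- .solve_amw_class(amw_mean_dili, sens, threshold, amw_shift)
  p0 <- .solve_amw_class(amw_mean_nodili, 1 - spec, threshold, amw_shift)
  if (separation != 1.0) {
    mid <- (p1[["meanlog"]] + p0[["meanlog"]]) / 2
    p1[["meanlog"]] <- mid + separation * (p1[["meanlog"]] - mid)
    p0[["meanlog"]] <- mid + separation * (p0[["meanlog"]] - mid)
  }
  # subclass shifts preserving the DILI mean: p*e^d_most+(1-p)*e^-d_less=1
  p <- most_fraction
  arg <- (1 - p * exp(most_shift)) / (1 - p)
  if (!is.finite(arg) || arg <= 0 || arg > 1)
    stop("most_shift too large for the given most_fraction")
  d_less <- -log(arg)
  structure(list(
    n_dili = as.integer(n_dili), n_nodili = as.integer(n_nodili),
    amw_shift = amw_shift, threshold = threshold,
    amw_dili = p1, amw_nodili = p0,
    amw_mean_dili = amw_mean_dili, amw_mean_nodili = amw_mean_nodili,
    most_fraction = most_fraction, most_shift = most_shift,
    less_shift = d_less,
    mlogp_dili = mlogp_dili, mlogp_nodili = mlogp_nodili,
    n_noise_features = as.integer(n_noise_features),
    noise_correlation = noise_correlation,
    atc_spec = atc_spec, years = years, seed = as.integer(seed)
  ), class = "generator_spec")
}

#' Default ATC stratum specification
#'
#' Fourteen first-level categories plus a `"none"` bucket (drugs without
#' annotation). Categories emulating the easy strata (B, J, M, S) attract
#' correctly screened drugs (`w_correct` 2, giving per-category accuracy
#' near 0.85-0.9), the hard strata (C, G, R, V) attract misclassified ones
#' (`w_correct` 0.7, accuracy near 0.5), the rest are neutral.
#' Assignment conditions on the drug's screen outcome and therefore leaves
#' the marginal AMW distributions untouched.
#'
#' @return data.frame with columns `code`, `weight`, `w_correct`.
#' @export
default_atc_spec <- function() {
  data.frame(
    code = c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P", "R",
             "S", "V", "none"),
    weight = c(6, 2, 6, 2, 2, 1, 6, 4, 3, 8, 1, 3, 3, 1, 20),
    w_correct = c(1, 2, 0.7, 1, 0.7, 1, 2, 1, 2, 1, 1, 0.7, 2, 0.7, 1),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic screening cohort
#'
#' Draws a cohort from a [generator_spec()]: per-drug AMW from the
#' class-conditional shifted log-normal (Most/Less subclasses with
#' shifted log-means), a class-correlated MLOGP feature, independent noise
#' features, ATC codes and approval years. Ground-truth generating
#' parameters are returned for recovery tests, including the Bayes
#' boundary (lower crossing of the class posteriors) and the
#' population-optimal single Gini split computed from the generating
#' distributions.
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed; defaults to `spec$seed`. Fully determines the
#'   output.
#' @return list with `records` (data.frame: id, dili_class, dili_label,
#'   atc_codes, year), `features` (data.frame: AMW, MLOGP, noise columns),
#'   and `ground_truth` (list of generating parameters).
#' @export
generate_cohort <- function(spec = generator_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_dili + spec$n_nodili
  .with_seed(seed, {
    n_most <- round(spec$n_dili * spec$most_fraction)
    subclass <- c(rep("Most", n_most), rep("Less", spec$n_dili - n_most),
                  rep("No", spec$n_nodili))
    label <- as.integer(subclass != "No")

    meanlog <- ifelse(subclass == "Most",
                      spec$amw_dili[["meanlog"]] + spec$most_shift,
               ifelse(subclass == "Less",
                      spec$amw_dili[["meanlog"]] - spec$less_shift,
                      spec$amw_nodili[["meanlog"]]))
    sdlog <- ifelse(label == 1L, spec$amw_dili[["sdlog"]],
                    spec$amw_nodili[["sdlog"]])
    amw <- spec$amw_shift + stats::rlnorm(n, meanlog, sdlog)

    mlogp_par <- rbind(spec$mlogp_nodili, spec$mlogp_dili)
    mlogp <- stats::rnorm(n, mlogp_par[label + 1L, 1],
                          mlogp_par[label + 1L, 2])

    feats <- data.frame(AMW = amw, MLOGP = mlogp)
    if (spec$n_noise_features > 0L) {
      rho <- spec$noise_correlation
      shared <- stats::rnorm(n)
      for (j in seq_len(spec$n_noise_features)) {
        eps <- stats::rnorm(n)
        feats[[paste0("noise", j)]] <-
          if (rho > 0) sqrt(rho) * shared + sqrt(1 - rho) * eps else eps
      }
    }

    correct <- as.integer(amw >= spec$threshold) == label
    as_ <- spec$atc_spec
    atc <- vapply(seq_len(n), function(i) {
      w <- as_$weight *
        (if (correct[i]) as_$w_correct else 1 / as_$w_correct)
      sample(as_$code, 1L, prob = w)
    }, "")
    atc[atc == "none"] <- ""

    year <- sample(spec$years, n, replace = TRUE)

    records <- normalize_drug_table(data.frame(
      id = sprintf("SYN%04d", seq_len(n)),
      name = sprintf("synthetic-%04d", seq_len(n)),
      dili_class = subclass,
      atc_codes = atc,
      year = year,
      stringsAsFactors = FALSE
    ))

    pi1 <- spec$n_dili / n
    f1 <- function(x) stats::dlnorm(x - spec$amw_shift,
                                    spec$amw_dili[["meanlog"]],
                                    spec$amw_dili[["sdlog"]])
    f0 <- function(x) stats::dlnorm(x - spec$amw_shift,
                                    spec$amw_nodili[["meanlog"]],
                                    spec$amw_nodili[["sdlog"]])
    post <- function(x) pi1 * f1(x) - (1 - pi1) * f0(x)
    bayes <- tryCatch(
      stats::uniroot(post, c(spec$amw_shift + 0.01, spec$threshold + 2))$root,
      error = function(e) NA_real_)
    gini_pop <- function(t) {
      P1 <- stats::plnorm(t - spec$amw_shift, spec$amw_dili[["meanlog"]],
                          spec$amw_dili[["sdlog"]])
      P0 <- stats::plnorm(t - spec$amw_shift, spec$amw_nodili[["meanlog"]],
                          spec$amw_nodili[["sdlog"]])
      wL <- pi1 * P1 + (1 - pi1) * P0
      if (wL <= 0 || wL >= 1) return(0)
      pL <- pi1 * P1 / wL
      pR <- pi1 * (1 - P1) / (1 - wL)
      wL * (1 - wL) * (pL - pR)^2
    }
    grid <- seq(spec$amw_shift + 0.01, spec$threshold + 3, by = 0.005)
    gini_opt <- grid[which.max(vapply(grid, gini_pop, 0))]

    list(records = records, features = feats,
         ground_truth = list(
           amw_dili = spec$amw_dili, amw_nodili = spec$amw_nodili,
           amw_shift = spec$amw_shift, threshold = spec$threshold,
           bayes_boundary = bayes, gini_optimal_split = gini_opt,
           seed = seed))
  })
}

#' Generate random molecular formulas in an AMW window
#'
#' Rejection sampler over small element-count vectors on C, H, N, O, S, F,
#' Cl, Br; a formula is accepted when its AMW (computed with the package's
#' own mass table) falls in `target_amw_range`. Exercises the formula ->
#' composition -> AMW path end to end.
#'
#' @param n number of formulas.
#' @param target_amw_range length-2 numeric, inclusive AMW window.
#' @param seed integer seed.
#' @param masses mass table.
#' @param max_attempts rejection budget before failing.
#' @return character vector of `n` Hill formulas.
#' @export
generate_formulas <- function(n, target_amw_range = c(6, 12), seed = 1L,
                              masses = atomic_masses(),
                              max_attempts = 10000L * max(n, 1L)) {
  stopifnot(length(target_amw_range) == 2L,
            target_amw_range[1] <= target_amw_range[2])
  if (target_amw_range[2] < masses[["H"]])
    stop("unattainable AMW range: below the mass of hydrogen")
  if (n == 0L) return(character(0))
  .with_seed(seed, {
    out <- character(0)
    attempts <- 0L
    while (length(out) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not reach the target AMW range in ", max_attempts,
             " attempts")
      counts <- c(C = sample(1:20, 1), H = sample(0:30, 1),
                  N = sample(0:4, 1), O = sample(0:5, 1),
                  S = sample(0:2, 1), F = sample(0:3, 1),
                  Cl = sample(0:3, 1), Br = sample(0:2, 1))
      counts <- counts[counts > 0]
      if (length(counts) == 0L) next
      cmp <- composition(counts)
      a <- amw(cmp, masses)
      if (a >= target_amw_range[1] && a <= target_amw_range[2])
        out <- c(out, hill_formula(cmp))
    }
    out
  })
}
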