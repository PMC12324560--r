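#' Specification of a synthetic cohort
#'
#' Bundles the dimensions and acquisition parameters of a simulated
#' resting-state study: number of subjects, regions, sessions, frames per
#' session, repetition time, the family-size distribution, and the master
#' seed from which all component substreams (cohort, SC, time series,
#' targets) are derived. Defaults emulate a large young-adult twin/sibling
#' cohort: 4 sessions of 1200 frames at TR = 0.72 s over 274 regions, ages
#' uniform on 22-37, family sizes 1-4 with weights 0.4/0.3/0.2/0.1.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_regions number of parcellation regions (default 274).
#' @param n_sessions resting-state sessions per subject (default 4).
#' @param frames_per_session frames per session (default 1200, >= 16).
#' @param tr repetition time in seconds (default 0.72).
#' @param family_weights named probability weights over family sizes
#'   `1..k`; names are the sizes.
#' @param age_range uniform age range in years (default `c(22, 37)`).
#' @param seed master integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, n_regions = 274L, n_sessions = 4L,
                        frames_per_session = 1200L, tr = 0.72,
                        family_weights = c("1" = 0.4, "2" = 0.3,
                                           "3" = 0.2, "4" = 0.1),
                        age_range = c(22, 37), seed = 1L) {
  if (n_subjects < 1L) stop("n_subjects must be at least 1")
  if (frames_per_session < 16L) stop("frames_per_session must be at least 16")
  if (tr <= 0) stop("tr must be positive")
  if (is.null(names(family_weights)) ||
      anyNA(suppressWarnings(as.integer(names(family_weights)))))
    stop("family_weights must be named by integer family sizes")
  if (any(!is.finite(family_weights)) || any(family_weights < 0) ||
      sum(family_weights) <= 0)
    stop("family_weights must be nonnegative with positive sum")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_regions = as.integer(n_regions),
                 n_sessions = as.integer(n_sessions),
                 frames_per_session = as.integer(frames_per_session),
                 tr = tr, family_weights = family_weights,
                 age_range = age_range, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("Cohort spec: %d subjects, %d regions, %d x %d frames ",
                     "(TR %g s), seed %d\n"),
              x$n_subjects, x$n_regions, x$n_sessions, x$frames_per_session,
              x$tr, x$seed))
  invisible(x)
}

#' Generate a synthetic cohort table
#'
#' Samples family sizes from the spec's distribution until the cohort is
#' full (the last family is trimmed to fit), draws ages uniformly on the
#' spec's range, assigns balanced sexes, and optionally flags a hold-out
#' partition of exactly `holdout_n` subjects (families are kept intact where
#' possible; the last hold-out family may be split to reach the exact count,
#' which is safe because the hold-out is never pooled with the main
#' analysis). Deterministic for a fixed spec seed.
#'
#' @param spec a [cohort_spec()].
#' @param holdout_n number of subjects to flag as hold-out (default 0), e.g.
#'   a separate partition used to derive target scores without leakage.
#' @return data.frame with columns `subject_id`, `family_id`, `sex`, `age`,
#'   `holdout`.
#' @export
generate_cohort <- function(spec, holdout_n = 0L) {
  stopifnot(inherits(spec, "cohort_spec"))
  holdout_n <- as.integer(holdout_n)
  if (holdout_n < 0L || holdout_n >= spec$n_subjects)
    stop("holdout_n must be in [0, n_subjects)")
  with_seed(substream_seed(spec$seed, "cohort"), {
    n <- spec$n_subjects
    sizes_pool <- as.integer(names(spec$family_weights))
    sizes <- integer(0)
    while (sum(sizes) < n) {
      k <- sample(sizes_pool, 1L, prob = spec$family_weights)
      sizes <- c(sizes, k)
    }
    excess <- sum(sizes) - n
    if (excess > 0) {
      sizes[length(sizes)] <- sizes[length(sizes)] - excess
      sizes <- sizes[sizes > 0L]
    }
    fam <- rep(seq_along(sizes), sizes)
    sex <- sample_vec(rep(c("F", "M"), length.out = n))
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    holdout <- rep(FALSE, n)
    if (holdout_n > 0L) {
      fam_order <- sample_vec(seq_along(sizes))
      picked <- integer(0)
      total <- 0L
      for (f in fam_order) {
        if (total + sizes[f] <= holdout_n) {
          picked <- c(picked, which(fam == f))
          total <- total + sizes[f]
        }
        if (total == holdout_n) break
      }
      if (total < holdout_n) {
        remaining <- setdiff(seq_len(n), picked)
        picked <- c(picked, remaining[seq_len(holdout_n - total)])
      }
      holdout[picked] <- TRUE
    }
    data.frame(subject_id = sprintf("sub-%04d", seq_len(n)),
               family_id = sprintf("fam-%04d", fam),
               sex = sex, age = age, holdout = holdout,
               stringsAsFactors = FALSE)
  })
}

# Prim's minimum spanning tree over a distance matrix; returns edge index pairs
mst_edges <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  edges <- matrix(0L, n - 1L, 2L)
  best_d <- d[1L, ]
  best_from <- rep(1L, n)
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_d[cand])]
    edges[k, ] <- c(best_from[j], j)
    in_tree[j] <- TRUE
    upd <- !in_tree & d[j, ] < best_d
    best_d[upd] <- d[j, upd]
    best_from[upd] <- j
  }
  edges
}

#' Generate per-subject structural connectomes
#'
#' Places regions uniformly in a 100 mm cube, builds a connected group
#' template whose edge probability and weight decay with Euclidean distance
#' (emulating the short-connection bias of fiber-density connectomes, so
#' distance-binned consensus thresholding has a real confound to correct),
#' and derives per-subject matrices as noisy perturbations of the template:
#' multiplicative log-normal weight noise plus random edge drop/add at rates
#' scaled by `noise_level`. `noise_level = 0` returns the template for every
#' subject. All outputs are symmetric, nonnegative, zero-diagonal.
#'
#' @param spec a [cohort_spec()].
#' @param noise_level nonnegative perturbation scale (default 0.2).
#' @return List with `template` (`R x R`), `subjects` (named list of `R x R`
#'   matrices), `coords` (`R x 3`), `distances` (`R x R`).
#' @export
generate_sc <- function(spec, noise_level = 0.2) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (noise_level < 0) stop("noise_level must be nonnegative")
  with_seed(substream_seed(spec$seed, "sc"), {
    r <- spec$n_regions
    coords <- matrix(stats::runif(r * 3, 0, 100), r, 3L)
    d <- as.matrix(stats::dist(coords))
    lambda <- max(d) / 2.5
    p <- exp(-d / lambda)
    diag(p) <- 0
    up <- upper.tri(p)
    present <- matrix(FALSE, r, r)
    present[up] <- stats::runif(sum(up)) < p[up]
    present <- present | t(present)
    for (e in seq_len(nrow(mst <- mst_edges(d))))    # guarantee connectivity
      present[mst[e, 1L], mst[e, 2L]] <- present[mst[e, 2L], mst[e, 1L]] <- TRUE
    wbase <- exp(-d / lambda) * matrix(stats::rlnorm(r * r, 0, 0.25), r, r)
    wbase <- (wbase + t(wbase)) / 2
    template <- ifelse(present, wbase, 0)
    diag(template) <- 0
    ids <- sprintf("sub-%04d", seq_len(spec$n_subjects))
    subjects <- lapply(seq_len(spec$n_subjects), function(i) {
      A <- template
      if (noise_level > 0) {
        mult <- matrix(stats::rlnorm(r * r, 0, noise_level), r, r)
        mult[lower.tri(mult)] <- t(mult)[lower.tri(mult)]
        A <- A * mult
        drop_p <- min(0.5 * noise_level, 0.3)
        edge_ix <- which(up & template > 0)
        dropped <- edge_ix[stats::runif(length(edge_ix)) < drop_p]
        add_ix <- which(up & template == 0)
        added <- add_ix[stats::runif(length(add_ix)) < drop_p * p[add_ix]]
        A[dropped] <- 0
        A[added] <- exp(-d[added] / lambda)
        A[lower.tri(A)] <- t(A)[lower.tri(A)]
      }
      diag(A) <- 0
      A
    })
    names(subjects) <- ids
    list(template = template, subjects = subjects, coords = coords,
         distances = d)
  })
}

#' Generate a graph-spectrally structured BOLD time series
#'
#' Simulates one subject's parcellated signal with a controlled graph power
#' profile: per-harmonic coefficient series (a slow oscillation drawn inside
#' 0.01-0.08 Hz mixed with AR(1) noise, rho = `ar_rho`, so the temporal
#' spectrum has energy both inside and outside the fALFF band) are scaled so
#' that the expected graph-spectral energy splits between the low band
#' (harmonics below the cutoff) and the high band as `band_energy` states,
#' then rotated to region space through the harmonics of `sc`. With
#' `band_energy = c(low = 1, high = 0)` the high-pass filtered output is
#' exactly zero.
#'
#' @param sc structural connectome weight matrix whose harmonics define the
#'   bands (typically the group template), or a [graph_spectrum()].
#' @param spec a [cohort_spec()] (sessions, frames, TR).
#' @param band_energy proportions `c(low = ..., high = ...)` summing to 1.
#' @param seed integer seed for this subject's draw.
#' @param ar_rho AR(1) coefficient of the noise component (default 0.3).
#' @param slow_fraction fraction of each coefficient's variance carried by
#'   the slow oscillation (default 0.5).
#' @param subject_id label stored in the output.
#' @return A [parcellated_ts()] of size `(n_sessions * frames_per_session) x R`.
#' @export
generate_timeseries <- function(sc, spec, band_energy = c(low = 0.5, high = 0.5),
                                seed = 1L, ar_rho = 0.3, slow_fraction = 0.5,
                                subject_id = NA_character_) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (abs(sum(band_energy) - 1) > 1e-8 || any(band_energy < 0))
    stop("band_energy must be nonnegative and sum to 1")
  gs <- if (inherits(sc, "graph_spectrum")) sc
        else graph_spectrum(normalized_laplacian(sc))
  r <- length(gs$eigenvalues)
  c0 <- gs$cutoff
  n_low <- c0
  n_high <- r - c0
  amp <- c(rep(sqrt(band_energy[["low"]] / n_low), n_low),
           rep(sqrt(band_energy[["high"]] / n_high), n_high))
  tt <- spec$n_sessions * spec$frames_per_session
  with_seed(seed, {
    f_slow <- stats::runif(r, 0.01, 0.08)
    phase <- stats::runif(r, 0, 2 * pi)
    tgrid <- seq_len(tt) * spec$tr
    slow <- sqrt(2) * cos(outer(tgrid, 2 * pi * f_slow) +
                          matrix(phase, tt, r, byrow = TRUE))
    innov <- matrix(stats::rnorm(tt * r, 0, sqrt(1 - ar_rho^2)), tt, r)
    noise <- apply(innov, 2L, function(e)
      stats::filter(e, ar_rho, method = "recursive"))
    xhat <- (sqrt(slow_fraction) * slow + sqrt(1 - slow_fraction) * noise) *
      matrix(amp, tt, r, byrow = TRUE)
    zero <- amp == 0
    if (any(zero)) xhat[, zero] <- 0    # exact band placement
    X <- igft(xhat, gs)
    parcellated_ts(X, tr = spec$tr,
                   session_lengths = rep(spec$frames_per_session,
                                         spec$n_sessions),
                   subject_id = subject_id)
  })
}

#' Specify a synthetic behavioral target
#'
#' Describes how one target column is generated from precomputed features: a
#' standardized linear combination of the basis feature (weights drawn once
#' per seed) explains `signal_fraction` of the target variance, the rest is
#' Gaussian noise. Binary targets threshold the latent score at its median.
#' `spectral_band` records which graph-frequency band carries the effect; if
#' the feature list contains a band-specific variant named
#' `"<basis>_<band>"`, it is used as the basis.
#'
#' @param target_name name of the generated column.
#' @param feature_basis one of `mean`, `sd`, `mssd`, `falff`, `fc`, `psd`,
#'   `sdi`, `coupled_fc`, `decoupled_fc`.
#' @param signal_fraction proportion of target variance explained, in `[0, 1)`.
#' @param spectral_band `"broadband"`, `"low"`, or `"high"`.
#' @param binary generate a binary (sex-like) target.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(target_name, feature_basis, signal_fraction,
                        spectral_band = c("broadband", "low", "high"),
                        binary = FALSE) {
  spectral_band <- match.arg(spectral_band)
  if (!feature_basis %in% FEATURE_NAMES)
    stop("unknown feature_basis '", feature_basis, "'")
  if (signal_fraction < 0 || signal_fraction >= 1)
    stop("signal_fraction must be in [0, 1)")
  structure(list(target_name = target_name, feature_basis = feature_basis,
                 signal_fraction = signal_fraction,
                 spectral_band = spectral_band, binary = binary),
            class = "effect_spec")
}

#' Append synthetic targets to a cohort table
#'
#' For each [effect_spec()], draws basis weights once, forms the standardized
#' latent score from the named feature matrix, and mixes it with independent
#' Gaussian noise so the realized signal fraction matches the nominal one
#' (within sampling error; +/- 0.05 at n >= 400). Binary targets are the
#' latent score thresholded at its median (balanced classes).
#'
#' @param cohort cohort data.frame (rows = subjects, in feature-row order).
#' @param features named list of `n x p` feature matrices (names are feature
#'   names, e.g. `"fc"`).
#' @param effects list of [effect_spec()] objects (or a single one).
#' @param seed integer seed.
#' @return The cohort with one new column per effect.
#' @export
generate_targets <- function(cohort, features, effects, seed = 1L) {
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  out <- cohort
  n <- nrow(cohort)
  for (k in seq_along(effects)) {
    ef <- effects[[k]]
    stopifnot(inherits(ef, "effect_spec"))
    base_name <- if (ef$spectral_band != "broadband" &&
                     !is.null(features[[paste(ef$feature_basis,
                                              ef$spectral_band, sep = "_")]]))
      paste(ef$feature_basis, ef$spectral_band, sep = "_")
    else ef$feature_basis
    X <- features[[base_name]]
    if (is.null(X)) stop("features does not contain basis '", base_name, "'")
    X <- as.matrix(X)
    if (nrow(X) != n) stop("feature rows must match cohort rows")
    with_seed(substream_seed(seed, paste0("target_", ef$target_name)), {
      Xs <- scale(X)
      Xs[, attr(Xs, "scaled:scale") == 0] <- 0
      w <- stats::rnorm(ncol(X))
      score <- as.numeric(Xs %*% w)
      score <- if (stats::sd(score) > 0) as.numeric(scale(score))
               else stats::rnorm(n)
      noise <- as.numeric(scale(stats::rnorm(n)))
      latent <- sqrt(ef$signal_fraction) * score +
        sqrt(1 - ef$signal_fraction) * noise
      out[[ef$target_name]] <- if (ef$binary)
        factor(ifelse(latent > stats::median(latent), "pos", "neg"))
      else latent
    })
  }
  out
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining the generator: cohort table, structural
#' connectomes, per-subject time series (all driven by named substreams of
#' the spec's master seed), feature extraction for the requested bases, and
#' target generation. The group-template harmonics define the graph bands.
#'
#' @param spec a [cohort_spec()].
#' @param effects list of [effect_spec()] (may be empty).
#' @param band_energy graph-band energy split for the BOLD generator.
#' @param noise_level SC perturbation scale.
#' @param holdout_n subjects flagged as hold-out.
#' @param features character vector of feature names to precompute (defaults
#'   to the bases named by `effects`).
#' @return List: `cohort` (with targets), `sc`, `ts` (named list of
#'   `parc_ts`), `spectrum`, `features` (named list of matrices), `spec`.
#' @export
simulate_study <- function(spec, effects = list(),
                           band_energy = c(low = 0.5, high = 0.5),
                           noise_level = 0.2, holdout_n = 0L,
                           features = NULL) {
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  cohort <- generate_cohort(spec, holdout_n = holdout_n)
  sc <- generate_sc(spec, noise_level = noise_level)
  gs <- graph_spectrum(normalized_laplacian(sc$template))
  ts_list <- lapply(seq_len(spec$n_subjects), function(i)
    generate_timeseries(gs, spec, band_energy = band_energy,
                        seed = substream_seed(spec$seed, paste0("ts_", i)),
                        subject_id = cohort$subject_id[i]))
  names(ts_list) <- cohort$subject_id
  want <- features %||%
    unique(vapply(effects, function(e) e$feature_basis, character(1)))
  feats <- lapply(want, function(f) extract_features(ts_list, f, spectrum = gs))
  names(feats) <- want
  if (length(effects))
    cohort <- generate_targets(cohort, feats, effects,
                               seed = substream_seed(spec$seed, "targets"))
  list(cohort = cohort, sc = sc, ts = ts_list, spectrum = gs,
       features = feats, spec = spec)
}

#' Cross-fit oracle recovery of a synthetic effect
#'
#' Estimates how much of a generated target's variance the generating
#' feature matrix recovers out of sample: k-fold cross-fit ridge regression
#' (penalty chosen by inner cross-validation), averaging the held-out
#' R-squared over folds. Used to confirm that targets built with a nominal
#' signal fraction are recoverable at that level.
#'
#' @param x `n x p` generating feature matrix.
#' @param y numeric target.
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @return Mean held-out R-squared across folds.
#' @export
oracle_recovery <- function(x, y, k = 5L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  fold <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  mean(vapply(seq_len(k), function(f) {
    tr <- fold != f
    sc <- fit_scaler(x[tr, , drop = FALSE])
    xs <- apply_scaler(x, sc)
    cvf <- with_seed(seed + f,
      glmnet::cv.glmnet(xs[tr, , drop = FALSE], y[tr], alpha = 0, nfolds = 5))
    pr <- stats::predict(cvf, xs[!tr, , drop = FALSE], s = "lambda.min")
    r_squared(y[!tr], pr)
  }, numeric(1)))
}
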