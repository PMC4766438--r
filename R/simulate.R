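# Seeded generators: ground-truth tuning profiles, multi-study distorted
# datasets, and imaging traces. All generators are pure functions of their
# arguments (seed included); no hidden state survives a call.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_inchikeys <- function(n) {
  keys <- character(0)
  while (length(keys) < n) {
    k <- paste0(paste(sample(LETTERS, 14, replace = TRUE), collapse = ""), "-",
                paste(sample(LETTERS, 10, replace = TRUE), collapse = ""), "-",
                sample(LETTERS, 1))
    keys <- unique(c(keys, k))
  }
  keys[seq_len(n)]
}

#' Simulate a ground-truth response profile
#'
#' Draws a latent `[0, 1]` odorant-response profile for one responding
#' unit. `tuning_shape` sets the kurtosis regime: `"one-hot"` mimics a
#' narrowly tuned unit (a single strong ligand, high lifetime kurtosis),
#' `"exponential"` a realistic skewed profile (a few good ligands, many
#' weak ones), `"uniform"` a broadly tuned unit (excess kurtosis near
#' -1.2).
#'
#' @param n_odorants Number of odorants (>= 5).
#' @param tuning_shape `"exponential"`, `"uniform"` or `"one-hot"`.
#' @param seed Integer seed; identical arguments give identical output.
#' @return Tibble `inchikey` (synthetic keys), `response` in `[0, 1]`.
#' @export
simulate_ground_truth <- function(n_odorants = 60,
                                  tuning_shape = c("exponential", "uniform", "one-hot"),
                                  seed = 1) {
  tuning_shape <- match.arg(tuning_shape)
  if (n_odorants < 5) abort("need at least 5 odorants")
  with_seed(seed, {
    keys <- random_inchikeys(n_odorants)
    values <- switch(tuning_shape,
      uniform = runif(n_odorants),
      exponential = { x <- rexp(n_odorants); x / max(x) },
      `one-hot` = c(1, rep(0, n_odorants - 1)))
    tibble::tibble(inchikey = keys, response = values)
  })
}

# monotone increasing transforms on [0, 1], normalized to [0, 1]
transform_catalog <- c("identity", "linear", "exponential", "sigmoid",
                       "asymptotic", "asymptotic_offset")

sample_transform <- function(family) {
  if (family == "random") {
    family <- sample(setdiff(transform_catalog, "identity"), 1)
  }
  params <- switch(family,
    identity = list(),
    linear = list(b = runif(1, 0.5, 2)),
    exponential = list(b = runif(1, 0.8, 3) * sample(c(1, -1), 1)),
    sigmoid = list(x0 = runif(1, 0.3, 0.7), k = runif(1, 0.08, 0.25)),
    asymptotic = list(lambda = runif(1, 1, 4)),
    asymptotic_offset = list(lambda = runif(1, 1, 4),
                             c0 = runif(1, -0.2, 0.1)),
    abort(paste0("unknown transform family: ", family)))
  g <- transform_fun(family, params)
  list(family = family, params = params, fun = g)
}

transform_fun <- function(family, p) {
  raw <- switch(family,
    identity = function(x) x,
    linear = function(x) p$b * x,
    exponential = function(x) (exp(p$b * x) - 1) / (exp(p$b) - 1),
    sigmoid = function(x) 1 / (1 + exp(-(x - p$x0) / p$k)),
    asymptotic = function(x) 1 - exp(-p$lambda * x),
    asymptotic_offset = function(x) 1 - exp(-p$lambda * (x - p$c0)))
  function(x) {
    y <- raw(x); y0 <- raw(0); y1 <- raw(1)
    (y - y0) / (y1 - y0)
  }
}

#' Simulate multiple studies measuring one ground-truth profile
#'
#' Emulates the heterogeneity the merging algorithm has to undo: each study
#' observes a subset of the odorants, reports responses through its own
#' monotone distortion of the shared ground truth (the generative
#' assumption behind pairwise merging: rank order is preserved across
#' techniques), with additive Gaussian noise on the transformed scale and
#' an optional spontaneous-firing-rate offset added to all values (the SFR
#' pseudo-odorant is included so merges treat it like any odorant).
#'
#' Subsets are built as a shared core of `round(overlap_fraction *
#' n_odorants)` odorants plus a disjoint share of the rest per study, so
#' every pair of studies overlaps in exactly the core.
#'
#' @param truth Output of [simulate_ground_truth()].
#' @param n_studies Number of studies (>= 2).
#' @param overlap_fraction Fraction of odorants every pair shares.
#' @param transform_family One of `"random"`, `"identity"`, `"linear"`,
#'   `"exponential"`, `"sigmoid"`, `"asymptotic"`, `"asymptotic_offset"`;
#'   `"random"` samples a distinct family per study.
#' @param noise_sd Gaussian noise sd on the transformed (`[0, 1]`) scale.
#' @param sfr_offset Baseline offset added to every response.
#' @param seed Integer seed.
#' @return List of class `study_simulation`: `studies` (named list of
#'   tibbles `study_id`, `inchikey`, `response`), `truth`, `meta` (tibble
#'   `study_id`, `family`, `params`, `n_odorants`), `min_pairwise_overlap`,
#'   `low_overlap` (flag: some pair shares fewer than 5 odorants).
#' @export
simulate_studies <- function(truth, n_studies = 3, overlap_fraction = 0.6,
                             transform_family = "random", noise_sd = 0.05,
                             sfr_offset = 0, seed = 1) {
  stopifnot(n_studies >= 2)
  n <- nrow(truth)
  with_seed(seed + 1L, {
    core_n <- round(overlap_fraction * n)
    idx <- sample.int(n)
    core <- idx[seq_len(core_n)]
    rest <- idx[-seq_len(core_n)]
    shares <- split(rest, rep_len(seq_len(n_studies), length(rest)))
    studies <- list()
    meta <- list()
    for (s in seq_len(n_studies)) {
      tr <- sample_transform(transform_family)
      rows <- sort(c(core, shares[[s]] %||% integer(0)))
      vals <- tr$fun(truth$response[rows]) + rnorm(length(rows), 0, noise_sd)
      id <- sprintf("study_%02d", s)
      studies[[id]] <- tibble::tibble(
        study_id = id,
        inchikey = c(truth$inchikey[rows], SFR_KEY),
        response = c(vals, tr$fun(0) + rnorm(1, 0, noise_sd)) + sfr_offset)
      meta[[id]] <- tibble::tibble(study_id = id, family = tr$family,
                                   params = list(tr$params),
                                   n_odorants = length(rows))
    }
    min_overlap <- core_n # by construction every pair shares exactly the core
    structure(list(studies = studies, truth = truth,
                   meta = dplyr::bind_rows(meta),
                   min_pairwise_overlap = min_overlap,
                   low_overlap = min_overlap < 5),
              class = "study_simulation")
  })
}

#' Write a simulated multi-study set to disk
#'
#' Emits one dataset file per study in the canonical exchange format plus
#' `truth.tsv`, mirroring what a small curated repository of raw datasets
#' would look like.
#'
#' @param sim A `study_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(sim$studies)) {
    ds <- as_study_dataset(sim$studies[[id]], study_id = id, unit_id = "simulated")
    write_study_dataset(ds, file.path(dir, paste0(id, "_simulated.tsv")))
  }
  readr::write_tsv(
    tibble::tibble(InChIKey = sim$truth$inchikey,
                   Response = fmt_response(sim$truth$response)),
    file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' Simulate calcium-imaging traces with known response magnitudes
#'
#' Generates raw fluorescence traces for several animals:
#' baseline + exponential photobleaching decay + a boxcar response in the
#' post-onset window + Gaussian noise, with a linear within-session decline
#' (drift) multiplying the injected magnitudes and periodic
#' reference-odorant and solvent-control presentations -- the structure the
#' trace pipeline ([process_traces()]) is built to invert. Injected
#' magnitudes are returned as ground truth.
#'
#' @param n_animals Number of animals.
#' @param n_tests Test-odorant presentations per animal.
#' @param magnitudes Injected response magnitudes (percent of baseline
#'   fluorescence): `NULL` (default) draws each presentation's magnitude
#'   from a continuous uniform distribution on `[0, magnitude_max]` --
#'   real odorant panels span a continuum of response strengths, and a
#'   continuous distribution avoids rank ties when recovery is scored by
#'   correlation -- or a numeric pool sampled per presentation (e.g.
#'   `c(0, 5, 10, 20)` for a discrete-level design).
#' @param magnitude_max Upper end of the continuous magnitude range.
#' @param decay_A,decay_B,decay_C Bleaching decay parameters (amplitude in
#'   raw fluorescence units, rate in seconds, offset).
#' @param f_base Baseline fluorescence (arbitrary units).
#' @param noise_sd Gaussian noise sd in raw units (0.5 = 0.5% of a
#'   baseline of 100).
#' @param drift_end Multiplier the signal declines to by the session end
#'   (1 = no drift).
#' @param reference_magnitude Injected magnitude of the reference odorant.
#' @param seed Integer seed.
#' @param protocol A [stimulus_protocol()].
#' @return List of class `trace_simulation`: `traces` (long tibble as
#'   [read_traces()] returns) and `truth` (tibble `animal_id`,
#'   `stimulus_id`, `order`, `role`, `magnitude`, `magnitude_drifted`).
#' @export
simulate_traces <- function(n_animals = 8, n_tests = 12,
                            magnitudes = NULL, magnitude_max = 20,
                            decay_A = 10, decay_B = 8, decay_C = 0,
                            f_base = 100, noise_sd = 0.5, drift_end = 0.8,
                            reference_magnitude = 10, seed = 1,
                            protocol = stimulus_protocol()) {
  t <- frame_times(protocol)
  onset <- protocol$onsets[1]
  box <- as.numeric(t >= onset & t < onset + protocol$response_window)
  with_seed(seed + 2L, {
    traces <- list(); truth <- list()
    for (a in seq_len(n_animals)) {
      animal <- sprintf("animal_%02d", a)
      # presentation plan: solvent first, a reference every 4 tests
      roles <- c("solvent", "reference")
      stim <- c("solvent", "reference")
      mags <- c(0, reference_magnitude)
      for (k in seq_len(n_tests)) {
        roles <- c(roles, "test")
        stim <- c(stim, sprintf("odor_%02d", k))
        mags <- c(mags, if (is.null(magnitudes)) {
          runif(1, 0, magnitude_max)
        } else if (length(magnitudes) == 1) {
          magnitudes
        } else sample(magnitudes, 1))
        if (k %% 4 == 0) {
          roles <- c(roles, "reference")
          stim <- c(stim, "reference")
          mags <- c(mags, reference_magnitude)
        }
        if (k %% 6 == 0) {
          roles <- c(roles, "solvent")
          stim <- c(stim, "solvent")
          mags <- c(mags, 0)
        }
      }
      n_pres <- length(roles)
      drift <- seq(1, drift_end, length.out = n_pres)
      for (i in seq_len(n_pres)) {
        mag_eff <- mags[i] * drift[i]
        f <- f_base + decay_A * exp(-t / decay_B) + decay_C +
          mag_eff * box + rnorm(length(t), 0, noise_sd)
        traces[[length(traces) + 1]] <- tibble::tibble(
          animal_id = animal, stimulus_id = stim[i], role = roles[i],
          order = i, frame = seq_along(t), time = t, value = f)
        truth[[length(truth) + 1]] <- tibble::tibble(
          animal_id = animal, stimulus_id = stim[i], order = i,
          role = roles[i], magnitude = mags[i], magnitude_drifted = mag_eff)
      }
    }
    structure(list(traces = dplyr::bind_rows(traces),
                   truth = dplyr::bind_rows(truth),
                   protocol = protocol),
              class = "trace_simulation")
  })
}
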