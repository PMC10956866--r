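#' Describe one cell population of a synthetic sample
#'
#' A synthetic sample is a mixture of populations, each a bivariate Gaussian
#' on the (transformed fluorescence, back-scatter) plane. This is the
#' minimal model that reproduces the unimodal blobs with bright tails seen
#' in real edited-pool profiles: a CRISPR-edited pool is a non-fluorescent
#' unedited majority plus a fluorescent edited subpopulation.
#'
#' @param weight mixture fraction in \[0, 1\].
#' @param fluo_mean,fluo_sd fluorescence location/scale on the transformed
#'   (asinh) scale.
#' @param bsc_mean,bsc_sd back-scatter location/scale in linear instrument
#'   units.
#' @param fluo_bsc_corr fluorescence/back-scatter correlation in (-1, 1).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(weight, fluo_mean, fluo_sd, bsc_mean, bsc_sd,
                            fluo_bsc_corr = 0.2) {
  bad <- function(msg) sg_stop("sortgate_error_invalid_spec", msg)
  if (!is.numeric(weight) || length(weight) != 1 || weight < 0 || weight > 1) {
    bad("population weight must be in [0, 1]")
  }
  if (!is.numeric(fluo_sd) || fluo_sd <= 0) bad("fluo_sd must be > 0")
  if (!is.numeric(bsc_sd) || bsc_sd <= 0) bad("bsc_sd must be > 0")
  if (!is.numeric(fluo_bsc_corr) || abs(fluo_bsc_corr) >= 1) bad("|fluo_bsc_corr| must be < 1")
  structure(list(weight = weight, fluo_mean = fluo_mean, fluo_sd = fluo_sd,
                 bsc_mean = bsc_mean, bsc_sd = bsc_sd,
                 fluo_bsc_corr = fluo_bsc_corr),
            class = "population_spec")
}

#' Generative parameters for one synthetic sample
#'
#' @param sample_id sample name.
#' @param populations list of [population_spec()]s; weights must sum to 1
#'   within 1e-9.
#' @param n_events number of events to draw.
#' @param concentration cell concentration in cells/mL (drives simulated
#'   event rates during a sort session); typical small-scale preps run near
#'   2e6 cells/mL.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(sample_id, populations, n_events = 50000,
                        concentration = 2e6, seed = 1L) {
  bad <- function(msg) sg_stop("sortgate_error_invalid_spec", msg)
  if (!length(populations) || !all(vapply(populations, inherits, TRUE, "population_spec"))) {
    bad("populations must be a non-empty list of population_spec objects")
  }
  w <- sum(vapply(populations, `[[`, 0, "weight"))
  if (abs(w - 1) > 1e-9) bad(sprintf("population weights sum to %.12g, not 1", w))
  if (!is.numeric(n_events) || length(n_events) != 1 || n_events < 0 ||
      n_events != round(n_events)) bad("n_events must be a non-negative integer")
  if (!is.numeric(concentration) || concentration <= 0) bad("concentration must be > 0")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) bad("seed must be a finite integer")
  structure(list(sample_id = as.character(sample_id)[1],
                 populations = populations,
                 n_events = as.integer(n_events),
                 concentration = concentration,
                 seed = as.integer(seed)),
            class = "sample_spec")
}

#' Simulate the profiled events of one synthetic sample
#'
#' Draws per-population event counts from a multinomial on the mixture
#' weights, samples each population from its bivariate Gaussian on the
#' transformed scale, and shuffles the rows so no downstream operation can
#' depend on population blocks. Output is deterministic given the spec's
#' seed. Channels are named `FL1` (tagged `asinh`) and `BSC` (tagged
#' `linear`); the true component index of every event is attached as
#' attribute `component` for test oracles.
#'
#' @param spec a [sample_spec()].
#' @return An [event_table()] with `spec$n_events` rows.
#' @export
simulate_sample <- function(spec) {
  if (!inherits(spec, "sample_spec")) {
    sg_stop("sortgate_error_invalid_spec", "spec must be a sample_spec")
  }
  n <- spec$n_events
  withr::with_seed(spec$seed, {
    w <- vapply(spec$populations, `[[`, 0, "weight")
    counts <- if (n > 0) as.integer(rmultinom(1, n, w)) else integer(length(w))
    xs <- vector("list", length(counts))
    for (k in seq_along(counts)) {
      p <- spec$populations[[k]]
      if (counts[k] == 0L) {
        xs[[k]] <- cbind(matrix(numeric(0), ncol = 2), integer(0))
        next
      }
      sigma <- matrix(c(p$fluo_sd^2,
                        p$fluo_bsc_corr * p$fluo_sd * p$bsc_sd,
                        p$fluo_bsc_corr * p$fluo_sd * p$bsc_sd,
                        p$bsc_sd^2), 2, 2)
      xy <- MASS::mvrnorm(counts[k], mu = c(p$fluo_mean, p$bsc_mean), Sigma = sigma)
      if (counts[k] == 1L) xy <- matrix(xy, nrow = 1)
      xs[[k]] <- cbind(xy, rep.int(k, counts[k]))
    }
    all <- do.call(rbind, xs)
    ord <- if (n > 0) sample.int(n) else integer(0)
    all <- all[ord, , drop = FALSE]
    values <- all[, 1:2, drop = FALSE]
    colnames(values) <- c("FL1", "BSC")
    tab <- event_table(values, sample_id = spec$sample_id,
                       transform_tags = c(FL1 = "asinh", BSC = "linear"))
    attr(tab, "component") <- as.integer(all[, 3])
    tab
  })
}

# Shared study-condition defaults for the panel generator.
panel_defaults <- function() {
  list(unedited_fluo_mean = 0.5, unedited_fluo_sd = 0.25,
       edited_fluo_sd = 0.4,
       bsc_mean = 5e5, bsc_sd = 7.5e4, corr = 0.2,
       edit_fraction_range = c(0.02, 0.60),
       edited_fluo_mean_range = c(1.2, 5.0))
}

#' Build the spec of one two-population edited-pool sample
#'
#' Convenience constructor used by [make_panel()]: a non-fluorescent
#' unedited majority plus an edited subpopulation that is brighter in
#' fluorescence but shares the back-scatter distribution (tagging does not
#' change cell size).
#'
#' @param sample_id sample name.
#' @param edit_fraction fraction of edited (fluorescent) cells.
#' @param edited_fluo_mean transformed-scale fluorescence mean of the edited
#'   component.
#' @param n_events,concentration,seed passed to [sample_spec()].
#' @return A [sample_spec()].
#' @export
panel_sample_spec <- function(sample_id, edit_fraction, edited_fluo_mean,
                              n_events = 50000, concentration = 2e6, seed = 1L) {
  d <- panel_defaults()
  sample_spec(
    sample_id,
    populations = list(
      population_spec(1 - edit_fraction, d$unedited_fluo_mean, d$unedited_fluo_sd,
                      d$bsc_mean, d$bsc_sd, d$corr),
      population_spec(edit_fraction, edited_fluo_mean, d$edited_fluo_sd,
                      d$bsc_mean, d$bsc_sd, d$corr)),
    n_events = n_events, concentration = concentration, seed = seed)
}

#' Generate a deterministic panel of synthetic sample specs
#'
#' Emulates a batch of gene-tagging samples with per-gene variation: the
#' edited fraction spans 2-60% and the edited fluorescence mean increases
#' strictly across the panel from dim to bright, so each sample has a unique
#' fluorescence signature.
#'
#' @param n_samples number of samples (a sorting batch is typically 12).
#' @param seed integer seed; sample `i` receives seed `seed + i`.
#' @param n_events events per sample.
#' @return List of [sample_spec()]s, named by sample id.
#' @export
make_panel <- function(n_samples = 12, seed = 1L, n_events = 50000) {
  if (!is.numeric(n_samples) || n_samples < 1) {
    sg_stop("sortgate_error_invalid_spec", "n_samples must be >= 1")
  }
  n_samples <- as.integer(n_samples)
  d <- panel_defaults()
  fracs <- seq(d$edit_fraction_range[1], d$edit_fraction_range[2], length.out = n_samples)
  means <- seq(d$edited_fluo_mean_range[1], d$edited_fluo_mean_range[2], length.out = n_samples)
  specs <- lapply(seq_len(n_samples), function(i) {
    panel_sample_spec(sprintf("S%02d", i), fracs[i], means[i],
                      n_events = n_events, seed = as.integer(seed) + i)
  })
  names(specs) <- vapply(specs, `[[`, "", "sample_id")
  specs
}
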