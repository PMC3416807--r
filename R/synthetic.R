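#' Specification of one synthetic task network
#'
#' Describes how to simulate the foci corpus of one task-related network:
#' experiments scatter their foci around planted true activation centers
#' with isotropic Gaussian jitter, plus a fraction of uniform noise foci
#' anywhere in the mask. Isotropic Gaussian jitter mirrors the ALE kernel's
#' own spatial-uncertainty model, which makes parameter recovery
#' interpretable.
#'
#' @param name Network (task) label.
#' @param true_centers Matrix (n x 3) or length-3 vector of planted center
#'   mm coordinates.
#' @param jitter_sd Isotropic jitter standard deviation, mm (> 0).
#' @param n_experiments Number of experiments to simulate.
#' @param foci_per_experiment Foci per experiment.
#' @param noise_fraction Proportion of each experiment's foci drawn uniformly
#'   over the mask instead of around a center, in `[0, 1]`.
#' @param seed RNG seed for this network.
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(name, true_centers, jitter_sd = 4,
                         n_experiments = 15, foci_per_experiment = 10,
                         noise_fraction = 0.15, seed = 1L) {
  true_centers <- rbind_coords(true_centers)
  if (jitter_sd <= 0) abort("`jitter_sd` must be > 0")
  if (noise_fraction < 0 || noise_fraction > 1)
    abort("`noise_fraction` must be in [0, 1]")
  if (n_experiments < 1 || foci_per_experiment < 1)
    abort("need at least 1 experiment and 1 focus per experiment")
  structure(list(name = name, true_centers = true_centers,
                 jitter_sd = jitter_sd, n_experiments = n_experiments,
                 foci_per_experiment = foci_per_experiment,
                 noise_fraction = noise_fraction, seed = as.integer(seed)),
            class = "network_spec")
}

# uniform draw over the mask: uniform in-mask voxel, then uniform within it
runif_in_mask <- function(n, mask) {
  in_idx <- which(mask$mask)
  vox <- arrayInd(sample(in_idx, n, replace = TRUE), dim(mask$values))
  ctr <- voxel_to_mm(mask, vox)
  jit <- matrix(runif(3 * n, -0.5, 0.5), ncol = 3)
  ctr + sweep(jit, 2, mask$voxel_size, "*")
}

rjitter_in_mask <- function(center, sd, mask, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    p <- center + rnorm(3, sd = sd)
    if (in_mask(mask, p)) return(p)
  }
  abort("could not draw an in-mask focus; is the center near the mask edge?")
}

#' Simulate one task network's foci corpus
#'
#' Each experiment places `round(noise_fraction * foci_per_experiment)` foci
#' uniformly over the mask and the remainder around the planted centers:
#' when there are at least as many signal foci as centers, every center is
#' used at least once and the rest are assigned to centers uniformly at
#' random. Jitter draws falling outside the mask are redrawn. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [network_spec()].
#' @param mask A `volume_map` whose mask is the sampling region.
#' @return A foci tibble (columns `network`, `study_id`, `experiment_id`,
#'   `domain`, `x`, `y`, `z`).
#' @export
generate_network <- function(spec, mask) {
  if (!inherits(spec, "network_spec")) abort("`spec` must be a network_spec")
  if (!all(in_mask(mask, spec$true_centers)))
    abort("all true_centers must lie inside the mask")
  n_c <- nrow(spec$true_centers)
  with_rng(spec$seed, {
    purrr::map_dfr(seq_len(spec$n_experiments), function(e) {
      n_f <- spec$foci_per_experiment
      n_noise <- round(spec$noise_fraction * n_f)
      n_sig <- n_f - n_noise
      pts <- NULL
      if (n_sig > 0) {
        which_c <- if (n_sig >= n_c)
          c(seq_len(n_c), sample.int(n_c, n_sig - n_c, replace = TRUE))
        else sample.int(n_c, n_sig)
        pts <- t(vapply(which_c, function(ci)
          rjitter_in_mask(spec$true_centers[ci, ], spec$jitter_sd, mask),
          numeric(3)))
      }
      if (n_noise > 0) pts <- rbind(pts, runif_in_mask(n_noise, mask))
      tibble(network = spec$name,
             study_id = sprintf("%s_study_%02d", spec$name, e),
             experiment_id = sprintf("%s_exp_%02d", spec$name, e),
             domain = spec$name, x = pts[, 1], y = pts[, 2], z = pts[, 3])
    })
  })
}

#' Default private-center layout for the hub scenario
#'
#' Places up to 8 well-separated centers at the corners of a cube of
#' half-side `half` around `center`.
#' @param n Number of centers (<= 8).
#' @param half Half-side of the cube, mm.
#' @param center Cube center, mm.
#' @return An n x 3 matrix.
#' @export
corner_centers <- function(n, half = 18, center = c(0, 0, 0)) {
  if (n > 8) abort("corner_centers supports at most 8 centers")
  g <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))[seq_len(n), ,
                                                            drop = FALSE]
  sweep(g * half, 2, center, "+")
}

#' Planted-hub multi-network scenario
#'
#' Generates `n_networks` synthetic task networks that all share one planted
#' "hub" center while each also carries one private center absent from every
#' other network — the ground-truth analogue of a set of task networks whose
#' thresholded maps overlap 100% only at shared integrative regions.
#'
#' @param n_networks Number of networks (default 8).
#' @param hub_center mm coordinate shared by all networks.
#' @param mask Analysis mask (`volume_map`); default [toy_mask()].
#' @param private_centers Optional n x 3 matrix of private centers, one per
#'   network; default well-separated cube corners via [corner_centers()].
#' @param jitter_sd,n_experiments,foci_per_experiment,noise_fraction Passed
#'   to [network_spec()] for every network.
#' @param seed Base seed; network i uses `seed + i`.
#' @return A list of class `hub_scenario` with elements `foci` (one tibble,
#'   `network` column), `hub_center`, `private_centers`, `mask`, `specs`.
#' @export
generate_hub_scenario <- function(n_networks = 8, hub_center = c(0, 0, 0),
                                  mask = toy_mask(),
                                  private_centers = NULL,
                                  jitter_sd = 4, n_experiments = 15,
                                  foci_per_experiment = 10,
                                  noise_fraction = 0.15, seed = 1L) {
  if (n_networks < 2) abort("need at least 2 networks")
  if (is.null(private_centers))
    private_centers <- corner_centers(n_networks, center = hub_center)
  private_centers <- rbind_coords(private_centers)
  if (nrow(private_centers) != n_networks)
    abort("need one private center per network")
  d <- as.matrix(dist(rbind(private_centers, hub_center)))
  diag(d) <- Inf
  if (min(d) <= 4 * jitter_sd)
    abort("centers closer than 4 * jitter_sd; increase separation")
  specs <- lapply(seq_len(n_networks), function(i)
    network_spec(name = sprintf("net%02d", i),
                 true_centers = rbind(hub_center, private_centers[i, ]),
                 jitter_sd = jitter_sd, n_experiments = n_experiments,
                 foci_per_experiment = foci_per_experiment,
                 noise_fraction = noise_fraction, seed = seed + i))
  foci <- bind_rows(lapply(specs, generate_network, mask = mask))
  structure(list(foci = foci, hub_center = as.numeric(hub_center),
                 private_centers = private_centers, mask = mask,
                 specs = specs),
            class = "hub_scenario")
}

#' @export
print.hub_scenario <- function(x, ...) {
  cat(sprintf("<hub_scenario> %d networks, %d foci, hub at (%g, %g, %g)\n",
              length(x$specs), nrow(x$foci),
              x$hub_center[1], x$hub_center[2], x$hub_center[3]))
  invisible(x)
}

#' Specification of a synthetic study corpus
#'
#' Describes a binary study-by-term and study-by-region incidence corpus:
#' each study carries each term independently with probability `p_term`, and
#' activates each target region with probability `p_act_given_term` if it
#' carries `target_term` and `p_act_given_notterm` otherwise — the planted
#' ground truth for forward/reverse Bayesian inference.
#'
#' @param n_studies Number of studies.
#' @param terms Character vector of term names.
#' @param p_term Per-term base rate (scalar or named vector over `terms`).
#' @param regions Character vector of region names (default one region).
#' @param target_term Term driving activation (default first of `terms`).
#' @param p_act_given_term,p_act_given_notterm Activation probabilities for
#'   each region conditional on the target term.
#' @param seed RNG seed.
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_studies, terms, p_term = 0.3,
                        regions = "region_1", target_term = terms[1],
                        p_act_given_term = 0.8, p_act_given_notterm = 0.1,
                        seed = 1L) {
  if (length(p_term) == 1L) p_term <- setNames(rep(p_term, length(terms)),
                                               terms)
  probs <- c(p_term, p_act_given_term, p_act_given_notterm)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must be in [0, 1]")
  if (!target_term %in% terms) abort("`target_term` must be one of `terms`")
  structure(list(n_studies = as.integer(n_studies), terms = terms,
                 p_term = p_term, regions = regions,
                 target_term = target_term,
                 p_act_given_term = p_act_given_term,
                 p_act_given_notterm = p_act_given_notterm,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Simulate a binary study corpus
#'
#' @param spec A [corpus_spec()].
#' @return A tibble with `study_id`, one 0/1 column per term and one 0/1
#'   column per region; attributes `terms` and `regions` name the column
#'   groups. Deterministic given `spec$seed`.
#' @export
generate_corpus <- function(spec) {
  if (!inherits(spec, "corpus_spec")) abort("`spec` must be a corpus_spec")
  with_rng(spec$seed, {
    out <- tibble(study_id = sprintf("study_%05d", seq_len(spec$n_studies)))
    for (tm in spec$terms)
      out[[tm]] <- as.integer(runif(spec$n_studies) < spec$p_term[[tm]])
    has_t <- out[[spec$target_term]] == 1L
    for (rg in spec$regions) {
      p <- ifelse(has_t, spec$p_act_given_term, spec$p_act_given_notterm)
      out[[rg]] <- as.integer(runif(spec$n_studies) < p)
    }
    attr(out, "terms") <- spec$terms
    attr(out, "regions") <- spec$regions
    out
  })
}
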