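# Shared synthetic scenarios. The expensive ones (full 8-network hub
# recovery, planted MACM) are computed once per test run and cached.

.scenario_cache <- new.env(parent = emptyenv())

small_grid <- function(extent = 24, voxel = 2) toy_mask(extent, voxel)

# Full planted-hub pipeline at the default study conditions.
hub_results <- function() {
  if (!is.null(.scenario_cache$hub)) return(.scenario_cache$hub)
  scen <- generate_hub_scenario(seed = 1)
  g <- scen$mask
  nets <- unique(scen$foci$network)
  thr <- lapply(setNames(nets, nets), function(nm) {
    fc <- scen$foci[scen$foci$network == nm, ]
    p <- ale_params(n_permutations = 200, seed = 100L + match(nm, nets))
    a <- ale_map(fc, g, p, quiet = TRUE)
    threshold_map(a, build_null(fc, g, p), p)
  })
  ov <- probability_overlap(thr)
  .scenario_cache$hub <- list(scen = scen, thresholded = thr, overlap = ov,
                              conjunction = conjunction(ov))
  .scenario_cache$hub
}

# Planted MACM structure: one group of experiments co-activates hub + B,
# a disjoint control group activates only C. Noise-free so ground-truth
# selection is exact.
macm_scenario <- function() {
  g <- toy_mask()
  hub <- c(0, 0, 0); b <- c(18, 18, 18); c_ctr <- c(-18, -18, -18)
  co <- generate_network(
    network_spec("coact", rbind(hub, b), jitter_sd = 4, n_experiments = 8,
                 foci_per_experiment = 10, noise_fraction = 0, seed = 11),
    g)
  ctl <- generate_network(
    network_spec("control", c_ctr, jitter_sd = 4, n_experiments = 7,
                 foci_per_experiment = 10, noise_fraction = 0, seed = 12),
    g)
  list(grid = g, foci = dplyr::bind_rows(co, ctl),
       hub = hub, region_b = b, region_c = c_ctr,
       coact_ids = unique(co$experiment_id),
       seed_roi = sphere_map(g, hub, 10))
}

macm_results <- function() {
  if (!is.null(.scenario_cache$macm)) return(.scenario_cache$macm)
  sc <- macm_scenario()
  p <- ale_params(n_permutations = 200, seed = 21)
  .scenario_cache$macm <- list(
    scenario = sc,
    result = macm_map(sc$foci, list(seed = sc$seed_roi), sc$grid, p))
  .scenario_cache$macm
}

# Planted two-group similarity design: 4 networks around centers {A, B},
# 4 around {C, D}, and one reference network sharing a center with each
# group. Unthresholded ALE maps only (no permutation nulls needed).
similarity_maps <- function() {
  if (!is.null(.scenario_cache$rsa)) return(.scenario_cache$rsa)
  g <- toy_mask()
  a <- c(18, 18, 18); b <- c(-18, 18, 18)
  c_ctr <- c(-18, -18, -18); d <- c(18, -18, -18)
  specs <- c(
    lapply(1:4, function(i)
      network_spec(sprintf("grp1_%d", i), rbind(a, b), seed = 30 + i)),
    lapply(1:4, function(i)
      network_spec(sprintf("grp2_%d", i), rbind(c_ctr, d), seed = 40 + i)),
    list(network_spec("reference", rbind(a, c_ctr), seed = 50)))
  maps <- lapply(specs, function(sp)
    ale_map(generate_network(sp, g), g, ale_params(), quiet = TRUE))
  names(maps) <- vapply(specs, `[[`, character(1), "name")
  .scenario_cache$rsa <- list(grid = g, maps = maps,
                              group = c(rep(1, 4), rep(2, 4)))
  .scenario_cache$rsa
}

# Average fraction of in-mask voxels with uncorrected p < alpha when the
# observed foci are themselves uniform draws (type-I calibration).
null_calibration <- function(n_runs = 10, n_perm = 200, alpha = 0.05) {
  g <- toy_mask()
  mean(vapply(seq_len(n_runs), function(r) {
    spec <- network_spec("unif", c(0, 0, 0), jitter_sd = 4,
                         n_experiments = 5, foci_per_experiment = 8,
                         noise_fraction = 1, seed = 500L + r)
    fc <- generate_network(spec, g)
    p <- ale_params(n_permutations = n_perm, seed = 600L + r)
    a <- ale_map(fc, g, p, quiet = TRUE)
    nl <- build_null(fc, g, p)
    mean(null_pvalue(nl, a$values[g$mask]) < alpha)
  }, numeric(1)))
}
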