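#' Default desk-scale study configuration
#'
#' The configuration of the full synthetic study as nested lists, the same
#' schema [run_study()] reads from YAML: a planted-hub scenario (8 networks,
#' 15 experiments of 10 foci each, 4 mm jitter) on a 64 mm toy mask at 2 mm
#' resolution, the standard ALE chain (FWHM 10 mm, FDR q = 0.05, cluster
#' extent > 100 mm^3), overlap/conjunction, MACM seeded at the conjunction,
#' network similarity, and a small synthetic term corpus.
#'
#' @param seed Master seed; every stage's RNG derives from it.
#' @return A nested configuration list.
#' @export
default_study_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    mask = list(extent_mm = 64, voxel_size = 2),
    synthetic = list(n_networks = 8, hub_center = c(0, 0, 0), jitter_sd = 4,
                     n_experiments = 15, foci_per_experiment = 10,
                     noise_fraction = 0.15),
    ale = list(fwhm = 10, n_permutations = 200, q_fdr = 0.05,
               min_cluster_mm3 = 100, connectivity = 26),
    overlap = list(low_fraction = 0.2),
    macm = list(enabled = TRUE, require_all = FALSE, dilate_mm = 0),
    similarity = list(enabled = TRUE, reference = "net01"),
    corpus = list(enabled = TRUE, n_studies = 500,
                  terms = c("pain", "touch", "attention"),
                  p_term = 0.3, p_act_given_term = 0.8,
                  p_act_given_notterm = 0.1)
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
      merge_config(base[[k]], user[[k]]) else user[[k]]
  }
  base
}

hclust_to_list <- function(hc) {
  build <- function(i) {
    if (i < 0) return(list(name = hc$labels[-i]))
    list(height = hc$height[i],
         children = list(build(hc$merge[i, 1]), build(hc$merge[i, 2])))
  }
  build(nrow(hc$merge))
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(network = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  write_tsv_file(df, path)
}

#' Run the full synthetic study pipeline
#'
#' One-command orchestration: synthetic foci generation, per-network ALE
#' with permutation-null FDR thresholding, probabilistic overlap,
#' conjunction and low-overlap maps, MACM seeded at the conjunction,
#' network similarity (1 - r distances, spectral reordering, Ward
#' dendrogram, classical MDS, reference centrality profile), optional term
#' statistics on a synthetic corpus, and a JSON provenance report with
#' every parameter, seed, stage wall time and output file hash. Any stage
#' failure aborts with the stage name; files already written are renamed
#' with a `.partial` suffix.
#'
#' @param config Path to a YAML configuration file, or a nested list; keys
#'   missing from the config fall back to [default_study_config()]. Instead
#'   of `synthetic`, a `foci` section (`files`: named per-network foci
#'   paths, `dialect`, `mask`: NIfTI path) runs the pipeline on real foci
#'   tables.
#' @param out_dir Output directory (created if needed).
#' @return The provenance report, invisibly (class `study_report`).
#' @export
run_study <- function(config = NULL, out_dir = tempfile("alemaps_study_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_study_config(), config %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stages <- list()
  out <- function(name) file.path(out_dir, name)
  note <- function(path) { written <<- c(written, path); path }

  run_stage <- function(name, code) {
    t0 <- Sys.time()
    res <- tryCatch(force(code), error = function(e) {
      for (f in written) if (file.exists(f))
        file.rename(f, paste0(f, ".partial"))
      abort(sprintf("stage \"%s\" failed: %s", name, conditionMessage(e)))
    })
    stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  # -- inputs: synthetic scenario or real foci files ------------------------
  scen <- NULL
  inputs <- run_stage("inputs", {
    if (!is.null(cfg$foci)) {
      mask <- read_volume(cfg$foci$mask)
      foci <- bind_rows(purrr::imap(cfg$foci$files, function(f, nm)
        mutate(read_foci_table(f, cfg$foci$dialect %||% "sleuth_text"),
               network = nm)))
      list(mask = mask, foci = foci)
    } else {
      mask <- toy_mask(cfg$mask$extent_mm, cfg$mask$voxel_size)
      # the stage block evaluates in run_study's own frame, so a plain
      # assignment lands in the right environment
      scen <- generate_hub_scenario(
        n_networks = cfg$synthetic$n_networks,
        hub_center = unlist(cfg$synthetic$hub_center),
        mask = mask, jitter_sd = cfg$synthetic$jitter_sd,
        n_experiments = cfg$synthetic$n_experiments,
        foci_per_experiment = cfg$synthetic$foci_per_experiment,
        noise_fraction = cfg$synthetic$noise_fraction,
        seed = cfg$seed)
      note(write_foci_table(scen$foci, out("foci.csv"), "csv"))
      list(mask = mask, foci = scen$foci)
    }
  })
  mask <- inputs$mask
  networks <- unique(inputs$foci$network)

  # -- per-network ALE + thresholding ---------------------------------------
  thresholded <- run_stage("ale_networks", {
    maps <- purrr::imap(
      setNames(split(inputs$foci, inputs$foci$network)[networks], networks),
      function(fc, nm) {
        i <- match(nm, networks)
        params <- ale_params(
          fwhm = cfg$ale$fwhm, n_permutations = cfg$ale$n_permutations,
          q_fdr = cfg$ale$q_fdr, min_cluster_mm3 = cfg$ale$min_cluster_mm3,
          connectivity = cfg$ale$connectivity, seed = cfg$seed + 1000L + i)
        a <- ale_map(fc, mask, params, quiet = TRUE)
        thr <- threshold_map(a, build_null(fc, mask, params), params)
        note(write_volume(a, out(sprintf("ale_%s.nii", nm))))
        note(write_volume(thr, out(sprintf("thresholded_%s.nii", nm))))
        list(ale = a, thr = thr)
      })
    maps
  })
  ale_maps <- purrr::map(thresholded, "ale")
  thr_maps <- purrr::map(thresholded, "thr")

  # -- overlap / conjunction / low-overlap ----------------------------------
  conj <- run_stage("overlap", {
    ov <- probability_overlap(thr_maps)
    cj <- conjunction(ov)
    lo <- low_overlap_region(ov, cfg$overlap$low_fraction)
    note(write_volume(ov, out("overlap.nii")))
    note(write_volume(cj, out("conjunction.nii")))
    note(write_volume(lo, out("low_overlap.nii")))
    cj
  })

  # -- MACM seeded at the conjunction ---------------------------------------
  macm <- NULL
  if (isTRUE(cfg$macm$enabled) && any(conj$values != 0)) {
    macm <- run_stage("macm", {
      params <- ale_params(
        fwhm = cfg$ale$fwhm, n_permutations = cfg$ale$n_permutations,
        q_fdr = cfg$ale$q_fdr, min_cluster_mm3 = cfg$ale$min_cluster_mm3,
        connectivity = cfg$ale$connectivity, seed = cfg$seed + 2000L)
      m <- macm_map(inputs$foci, list(seed = conj), mask, params,
                    require_all = isTRUE(cfg$macm$require_all),
                    dilate_mm = cfg$macm$dilate_mm %||% 0)
      note(write_volume(m$ale, out("macm_ale.nii")))
      note(write_volume(m$thresholded, out("macm_thresholded.nii")))
      note(write_tsv_file(m$selection, out("macm_selection.tsv")))
      m
    })
  }

  # -- network similarity ----------------------------------------------------
  similarity <- NULL
  if (isTRUE(cfg$similarity$enabled)) {
    similarity <- run_stage("similarity", {
      D <- distance_matrix(vectorize_maps(ale_maps))
      ord <- reorder_matrix(D)
      tree <- ward_dendrogram(D)
      emb <- mds_embed(D, d = 2)
      ref <- cfg$similarity$reference %||% rownames(D)[1]
      prof <- centrality_profile(D, ref)
      note(write_matrix_tsv(D, out("distance.tsv")))
      note(write_tsv_file(tibble(position = seq_along(ord),
                                 network = names(ord)),
                          out("reordering.tsv")))
      jsonlite::write_json(hclust_to_list(tree), out("dendrogram.json"),
                           auto_unbox = TRUE, digits = NA)
      note(out("dendrogram.json"))
      note(write_tsv_file(tidy(emb), out("mds.tsv")))
      note(write_tsv_file(prof, out("centrality.tsv")))
      list(D = D, order = ord, tree = tree, mds = emb, profile = prof)
    })
  }

  # -- term statistics -------------------------------------------------------
  terms <- NULL
  if (isTRUE(cfg$corpus$enabled)) {
    terms <- run_stage("term_stats", {
      cs <- corpus_spec(
        n_studies = cfg$corpus$n_studies,
        terms = unlist(cfg$corpus$terms), p_term = cfg$corpus$p_term,
        p_act_given_term = cfg$corpus$p_act_given_term,
        p_act_given_notterm = cfg$corpus$p_act_given_notterm,
        seed = cfg$seed + 3000L)
      corpus <- generate_corpus(cs)
      ph <- phenotype_map(corpus)
      fwd <- forward_inference(corpus, cs$target_term)
      rev <- reverse_inference(corpus, cs$target_term)
      note(write_tsv_file(corpus, out("corpus.tsv")))
      note(write_matrix_tsv(ph$ln_j, out("ln_jaccard.tsv")))
      note(write_tsv_file(ph$edges, out("phenotype_edges.tsv")))
      note(write_tsv_file(left_join(fwd, rev, by = "region"),
                          out("inference.tsv")))
      list(phenotype = ph, forward = fwd, reverse = rev)
    })
  }

  # -- provenance report -----------------------------------------------------
  report <- list(
    package_version = as.character(utils::packageVersion("alemaps")),
    config = cfg, stages = stages,
    outputs = lapply(setNames(nm = basename(written)), function(b)
      unname(tools::md5sum(file.path(out_dir, b)))))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  structure(list(report = report, out_dir = out_dir,
                 thresholded = thr_maps, conjunction = conj,
                 macm = macm, similarity = similarity, terms = terms,
                 scenario = scen),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d stages in %s\n",
              length(x$report$stages), x$out_dir))
  for (nm in names(x$report$stages))
    cat(sprintf("  %-14s %6.1f s\n", nm, x$report$stages[[nm]]$seconds))
  invisible(x)
}
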