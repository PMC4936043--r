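#' Pipeline configuration
#'
#' Describes one end-to-end run: input loci (a directory of FASTA
#' alignments or a [simulation_config()]), the occupancy tiers, the
#' rate-series geometry, the bootstrap settings and the clade hypotheses.
#'
#' @param out_dir Output directory for all derived files.
#' @param input_dir Directory of per-locus FASTA alignments; mutually
#'   exclusive with `simulation`.
#' @param simulation A [simulation_config()] used to generate the input
#'   collection; mutually exclusive with `input_dir`.
#' @param occupancy_fractions Ascending occupancy tiers; each becomes a
#'   supermatrix with `min_taxa = ceiling(fraction * n_taxa)`. The middle
#'   tier (second of three, as in a 50/75/90 design) is the one carried
#'   into the rate series and the RCFV screen.
#' @param block_size Loci per block for the block series.
#' @param cut_points Cumulative cut points; `NULL` means multiples of
#'   `block_size` up to four, capped below the locus count.
#' @param bootstrap_replicates Bootstrap replicates per matrix (0 skips
#'   tree inference and trajectories).
#' @param hypotheses Path to a hypothesis file, or a named list of
#'   [clade_hypothesis()] objects; `NULL` skips trajectories.
#' @param model_tag Model label written into partition files.
#' @param seed Integer master seed; per-matrix bootstrap seeds are derived
#'   from it, so the whole run is a pure function of inputs + config.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input_dir = NULL, simulation = NULL,
                            occupancy_fractions = c(0.5, 0.75, 0.9),
                            block_size = 50L, cut_points = NULL,
                            bootstrap_replicates = 100L,
                            hypotheses = NULL, model_tag = "WAG",
                            seed = 1L) {
  if (is.null(input_dir) == is.null(simulation))
    stop("provide exactly one of 'input_dir' or 'simulation'")
  if (!is.null(simulation)) stopifnot(inherits(simulation, "simulation_config"))
  stopifnot(length(occupancy_fractions) >= 1,
            all(occupancy_fractions > 0), all(occupancy_fractions <= 1),
            !is.unsorted(occupancy_fractions, strictly = TRUE),
            block_size >= 1, bootstrap_replicates >= 0)
  structure(list(out_dir = out_dir, input_dir = input_dir,
                 simulation = simulation,
                 occupancy_fractions = occupancy_fractions,
                 block_size = as.integer(block_size),
                 cut_points = cut_points,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 hypotheses = hypotheses, model_tag = model_tag,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Accepts the fields of [pipeline_config()]; a `simulation:` mapping is
#' passed to [simulation_config()].
#'
#' @param path Path to a YAML file.
#' @param ... Overrides applied on top of the file's values.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation))
    raw$simulation <- do.call(simulation_config, raw$simulation)
  over <- list(...)
  raw[names(over)] <- over
  do.call(pipeline_config, raw)
}

# write one matrix's full file set, returning the paths
write_matrix_files <- function(collection, label, dir, model_tag) {
  sm <- concatenate_loci(collection)
  paths <- c(
    fasta = file.path(dir, paste0(label, ".fasta")),
    phylip = file.path(dir, paste0(label, ".phy")),
    partitions = file.path(dir, paste0(label, ".partitions.txt")))
  write_fasta_alignment(sm, paths[["fasta"]])
  write_phylip(sm, paths[["phylip"]])
  write_raxml_partitions(sm, model_tag, paths[["partitions"]])
  list(supermatrix = sm, paths = paths)
}

#' Run the full matrix-engineering workflow
#'
#' Stages: (1) load or simulate the orthogroup collection; (2) build one
#' supermatrix per occupancy tier; (3) rank the middle tier's loci by
#' conservation and derive the cumulative and block series — with the
#' default three tiers, four cuts and a locus count between 250 and 300 at
#' block size 50 this yields the classic 13-matrix layout; (4) infer
#' column-bootstrap NJ trees for every rate-series matrix (middle tier
#' included); (5) RCFV screen of the middle tier; (6) support trajectories
#' for every hypothesis, the cumulative series ending at the full middle
#' matrix. A JSON manifest listing every artifact with its MD5 checksum,
#' the resolved settings and the seed is written last; identical inputs
#' and seed give identical checksums.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, complete = FALSE, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      write_manifest(manifest, config)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  collection <- stage("input", {
    if (!is.null(config$input_dir)) read_orthogroup_dir(config$input_dir)
    else {
      ds <- generate_dataset(config$simulation,
                             dir = file.path(config$out_dir, "simulated"))
      ds$collection
    }
  })
  n_univ <- length(collection$taxon_universe)

  mats <- stage("occupancy", {
    min_taxa <- ceiling(config$occupancy_fractions * n_univ)
    out <- list()
    for (i in seq_along(min_taxa)) {
      label <- sprintf("matrix%d", i)
      coll <- filter_by_min_taxa(collection, min_taxa[i])
      wf <- write_matrix_files(coll, label, config$out_dir, config$model_tag)
      out[[label]] <- list(collection = coll, supermatrix = wf$supermatrix,
                           paths = wf$paths, min_taxa = min_taxa[i])
    }
    rep <- occupancy_table(collection)
    write_occupancy_report(rep, file.path(config$out_dir, "occupancy.tsv"))
    out
  })
  mid_label <- names(mats)[min(2L, length(mats))]
  mid <- mats[[mid_label]]

  series <- stage("rate_series", {
    ranking <- rank_by_conservation(mid$collection)
    write_ranking(ranking, file.path(config$out_dir, "conservation_ranks.tsv"))
    n <- length(mid$collection$loci)
    cuts <- config$cut_points
    if (is.null(cuts)) {
      cuts <- config$block_size * seq_len(4L)
      cuts <- cuts[cuts < n]
      if (length(cuts) == 0) cuts <- max(1L, n %/% 2L)
    }
    cum <- cumulative_submatrices(mid$collection, cuts, ranking = ranking)
    blk <- block_submatrices(mid$collection, config$block_size,
                             ranking = ranking)
    sdir <- file.path(config$out_dir, "rate_series")
    dir.create(sdir, showWarnings = FALSE)
    members <- c(cum$members, blk$members)
    sm <- lapply(names(members), function(lb)
      write_matrix_files(members[[lb]], lb, sdir, config$model_tag)$supermatrix)
    names(sm) <- names(members)
    list(ranking = ranking, cumulative = cum, block = blk,
         supermatrices = sm, cuts = cuts)
  })

  rcfv_rep <- stage("rcfv", {
    rep <- rcfv(mid$supermatrix)
    write_rcfv_report(rep, file.path(config$out_dir,
                                     paste0("rcfv_", mid_label, ".tsv")))
    rep
  })

  tree_sets <- NULL
  if (config$bootstrap_replicates > 0) {
    tree_sets <- stage("bootstrap", {
      tdir <- file.path(config$out_dir, "trees")
      dir.create(tdir, showWarnings = FALSE)
      targets <- c(series$supermatrices,
                   stats::setNames(list(mid$supermatrix), mid_label))
      out <- list()
      for (i in seq_along(targets)) {
        lb <- names(targets)[i]
        trs <- bootstrap_trees(targets[[i]], config$bootstrap_replicates,
                               seed = config$seed + i)
        write_tree_set(trs, file.path(tdir, paste0(lb, ".boot.nwk")))
        out[[lb]] <- trs
      }
      out
    })
  }

  trajectories <- NULL
  if (!is.null(tree_sets) && !is.null(config$hypotheses)) {
    trajectories <- stage("trajectory", {
      hyps <- config$hypotheses
      if (is.character(hyps)) hyps <- read_hypotheses(hyps)
      cum_labels <- c(names(series$cumulative$members), mid_label)
      blk_labels <- names(series$block$members)
      out <- list()
      for (h in hyps) {
        tc <- support_trajectory(tree_sets[cum_labels], h)
        tb <- support_trajectory(tree_sets[blk_labels], h)
        write_trajectory(tc, file.path(config$out_dir, sprintf(
          "trajectory_%s_cumulative.tsv", h$hypothesis_id)))
        write_trajectory(tb, file.path(config$out_dir, sprintf(
          "trajectory_%s_block.tsv", h$hypothesis_id)))
        out[[h$hypothesis_id]] <- list(cumulative = tc, block = tb)
      }
      out
    })
  }

  manifest$complete <- TRUE
  manifest$n_taxa <- n_univ
  manifest$n_input_loci <- length(collection$loci)
  manifest$occupancy_matrices <- lapply(mats, function(m)
    list(min_taxa = m$min_taxa, n_loci = length(m$collection$loci),
         n_columns = m$supermatrix$n_columns))
  manifest$middle_matrix <- mid_label
  manifest$cut_points <- series$cuts
  manifest$block_sizes <- unname(series_sizes(series$block))
  manifest$matrix_labels <- c(names(mats), names(series$supermatrices))
  manifest$n_matrices <- length(manifest$matrix_labels)
  manifest$rcfv_total <- rcfv_rep$total
  manifest$bootstrap_replicates <- config$bootstrap_replicates
  write_manifest(manifest, config)
  invisible(manifest)
}

write_manifest <- function(manifest, config) {
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$files <- lapply(files, function(f)
    list(path = sub(paste0("^", config$out_dir, "/?"), "", f),
         md5 = unname(tools::md5sum(f))))
  cfg <- config
  cfg$simulation <- if (!is.null(cfg$simulation))
    cfg$simulation[setdiff(names(cfg$simulation), "tree")] else NULL
  manifest$config <- cfg[setdiff(names(unclass(cfg)), "hypotheses")]
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
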