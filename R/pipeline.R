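#' Pipeline configuration
#'
#' One configuration object drives the full stage graph
#' (simulate -> align/detect -> search -> ancestry -> zones -> associate ->
#' paralogs -> phylo -> motif). Every stage parameter object appears once,
#' named; the canonical detection and search defaults (100 bp window, 70%
#' identity, cutoffs 4, word size 6, E <= 1e-6, 1 Mb association window,
#' >= 5 synteny species, 500 kb zones, 50 bp marker flanks, 50% gap
#' trimming, 10,000 bootstrap replicates) live in the respective `*_params`
#' constructors.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @param focal_pairs list of two character pairs: the clade-1 and clade-2
#'   reference pairs used for de novo detection (reference species first).
#' @param aligner an [aligner_params()].
#' @param detect a [detect_params()].
#' @param search a [search_params()].
#' @param assoc an [assoc_params()].
#' @param zone_size zone size (bp).
#' @param flank marker flank (bp).
#' @param gap_threshold supermatrix column gap-trim threshold.
#' @param motif consensus motif to scan.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(),
                            focal_pairs = list(c("zeb", "tet"),
                                               c("fugu", "seab")),
                            aligner = aligner_params(),
                            detect = detect_params(),
                            search = search_params(),
                            assoc = assoc_params(),
                            zone_size = 500000L, flank = 50L,
                            gap_threshold = 0.5, motif = "TAATTA") {
  sim$seed <- as.integer(seed)
  assoc$seed <- derive_seed(seed, "bootstrap")
  structure(list(seed = as.integer(seed), sim = sim, focal_pairs = focal_pairs,
                 aligner = aligner, detect = detect, search = search,
                 assoc = assoc, zone_size = as.integer(zone_size),
                 flank = as.integer(flank), gap_threshold = gap_threshold,
                 motif = motif),
            class = "pipeline_config")
}

.pipeline_stages <- c("simulate", "detect", "search", "ancestry", "zones",
                      "associate", "paralogs", "phylo", "motif")

#' Save / load a pipeline configuration as YAML
#'
#' Every parameter appears once, named, under its stage section; loading
#' restores the typed parameter objects.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file.
#' @return `save_config()` returns `path` invisibly; `load_config()` a
#'   [pipeline_config()].
#' @export
save_config <- function(config, path) {
  plain <- unclass(config)
  plain$sim <- unclass(plain$sim)
  # named atomic vectors must become maps or YAML drops the names
  plain$sim$cne_rate_scale <- as.list(config$sim$cne_rate_scale)
  for (p in c("aligner", "detect", "search", "assoc"))
    plain[[p]] <- unclass(plain[[p]])
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  div <- y$sim$divergence_events
  pipeline_config(
    seed = y$seed,
    sim = do.call(sim_config, c(y$sim[setdiff(names(y$sim),
                                              c("divergence_events",
                                                "cne_rate_scale"))],
                                list(cne_rate_scale = unlist(y$sim$cne_rate_scale),
                                     divergence_events =
                                       if (is.null(div)) NULL else
                                         as.data.frame(div)))),
    focal_pairs = lapply(y$focal_pairs, unlist),
    aligner = do.call(aligner_params, y$aligner),
    detect = do.call(detect_params, y$detect),
    search = do.call(search_params, y$search),
    assoc = do.call(assoc_params, y$assoc[setdiff(names(y$assoc), "seed")]),
    zone_size = y$zone_size, flank = y$flank,
    gap_threshold = y$gap_threshold, motif = y$motif)
}

#' Run the CNE pipeline end to end
#'
#' Executes the requested stages in dependency order on a simulated cohort
#' and returns all intermediate results. When `out_dir` is given, stage
#' outputs are written there together with a JSON run manifest (config
#' hash, per-stage output file hashes, seeds, runtimes); deterministic
#' stages reproduce identical hashes for identical config and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param stages stages to run (upstream dependencies are added
#'   automatically); default all.
#' @param prev a previous [run_pipeline()] result whose upstream outputs are
#'   reused instead of recomputation (poor man's caching for partial
#'   reruns).
#' @return list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         stages = NULL, prev = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- stages %||% .pipeline_stages
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  # upstream stages not requested are reused from `prev` when available and
  # recomputed otherwise (the `is.null(res$...)` guards below)
  res <- prev %||% list()
  manifest <- list(config_hash = .obj_hash(config), stages = list())
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    manifest$stages[[name]] <<- list(runtime_s = round(proc.time()[["elapsed"]] - t0, 2))
    value
  }
  if ("simulate" %in% stages || is.null(res$cohort))
    res$cohort <- tick("simulate", simulate_cohort(config$sim))
  co <- res$cohort
  fp1 <- config$focal_pairs[[1]]; fp2 <- config$focal_pairs[[2]]
  if ("detect" %in% stages || is.null(res$zcne)) {
    res$zcne <- tick("detect", detect_cnes(co$genomes, fp1[1], fp1[2],
                                           config$detect, config$aligner,
                                           config$search))
    res$fcne <- detect_cnes(co$genomes, fp2[1], fp2[2], config$detect,
                            config$aligner, config$search)
  }
  if ("search" %in% stages || is.null(res$presence))
    res$presence <- tick("search", build_presence_matrix(
      list(res$zcne, res$fcne), co$genomes, config$search))
  aparams <- ancestry_params(co$tree$clade1, co$tree$clade2,
                             co$tree$outgroup_ids, co$tree$vertebrate_ids,
                             config$zone_size)
  res$ancestry_params <- aparams
  if ("ancestry" %in% stages || is.null(res$atcnes)) {
    res$atcnes <- tick("ancestry", {
      at <- infer_ancestral_set(res$zcne, res$fcne, res$presence, aparams)
      at <- categorize_origin(at, res$presence, aparams)
      conservation_score(at, res$presence, co$genomes)
    })
    res$losses <- loss_rates(res$atcnes, res$presence,
                             c(co$tree$clade1, co$tree$clade2))
  }
  if ("zones" %in% stages || is.null(res$zones))
    res$zones <- tick("zones", zone_profile(res$atcnes, co$genomes, fp1[1],
                                            aparams, res$presence))
  genes_by_species <- lapply(co$genomes, function(g) g$genes)
  if ("associate" %in% stages || is.null(res$associations)) {
    res$associations <- tick("associate", {
      a <- associate_cnes(res$atcnes, res$presence, genes_by_species,
                          co$orthology, config$assoc)
      classify_targets(a, co$truth$vcne_target_orthogroups)
    })
    res$bootstrap <- bootstrap_null(
      res$associations, co$genomes[[fp1[1]]]$genes, co$orthology,
      co$truth$vcne_target_orthogroups, config$assoc, ref_species = fp1[1])
  }
  if ("paralogs" %in% stages || is.null(res$clusters)) {
    res$clusters <- tick("paralogs", {
      # self-search runs per reference group, as pairs split across the two
      # reference sets cannot be seen from either alone
      out <- list()
      for (ref in c(fp1[1], fp2[1])) {
        sub <- res$atcnes[res$atcnes$ref_species == ref, , drop = FALSE]
        if (nrow(sub) < 2) next
        pairs <- self_hits(sub, co$genomes, config$search)
        cl <- paralogy_clusters(pairs, res$associations, co$orthology, ref)
        if (nrow(cl)) {
          cl$cluster_id <- paste(ref, cl$cluster_id, sep = "_")
          cl$reference <- ref
          out[[ref]] <- cl
        }
      }
      if (length(out)) {
        cl <- do.call(rbind, out)
        rownames(cl) <- NULL
        cl
      } else {
        data.frame(cluster_id = character(), members = character(),
                   n_members = integer(), anchor_orthogroups = character(),
                   origin = character(), reference = character(),
                   stringsAsFactors = FALSE)
      }
    })
  }
  if ("phylo" %in% stages || is.null(res$tree_nj)) {
    res$phylo <- tick("phylo", {
      teleosts <- c(co$tree$clade1, co$tree$clade2)
      zat <- res$atcnes[res$atcnes$ref_species == fp1[1], , drop = FALSE]
      hc <- count_hits_matrix(zat, co$genomes, config$search)
      markers <- universal_single_copy(hc, teleosts)
      universal_gar <- universal_single_copy(hc, c(teleosts, co$tree$outgroup_ids))
      sm <- NULL; tree <- NULL
      if (length(markers) >= 1) {
        seqs <- extract_marker_seqs(markers, zat, res$presence, co$genomes,
                                    config$flank)
        seqs <- lapply(seqs, function(s) s[names(s) %in% teleosts])
        sm <- build_supermatrix(seqs, config$gap_threshold)
        if (nrow(sm$matrix) >= 4) tree <- nj_tree(sm)
      }
      list(markers = markers, markers_with_outgroup = universal_gar,
           supermatrix = sm, tree = tree)
    })
    res$tree_nj <- res$phylo$tree
  }
  if ("motif" %in% stages || is.null(res$motif)) {
    res$motif <- tick("motif", {
      zat <- res$atcnes[res$atcnes$ref_species == fp1[1], , drop = FALSE]
      sc <- scan_consensus(cne_sequences(zat, co$genomes), config$motif)
      c(sc, positional_distribution(sc$occurrences))
    })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_run(res, config, out_dir)
    manifest$outputs <- .hash_dir(out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res$manifest <- manifest
  res$config <- config
  res
}

.obj_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(x, file = f)
  unname(tools::md5sum(f))
}

.hash_dir <- function(dir) {
  files <- sort(setdiff(list.files(dir, recursive = TRUE), "manifest.json"))
  setNames(as.list(unname(tools::md5sum(file.path(dir, files)))), files)
}

.write_run <- function(res, config, out_dir) {
  wt <- function(df, name) write.table(df, file.path(out_dir, name),
                                       sep = "\t", quote = FALSE, row.names = FALSE)
  cne_bed <- function(cs) {
    data.frame(chrom = cs$chrom, start = cs$start, end = cs$end,
               name = cs$id, score = round(1000 * cs$mean_identity),
               strand = cs$strand, stringsAsFactors = FALSE)
  }
  write_bed(cne_bed(res$zcne), file.path(out_dir, "zcne.bed"))
  write_bed(cne_bed(res$fcne), file.path(out_dir, "fcne.bed"))
  wt(res$zcne, "zcne.tsv"); wt(res$fcne, "fcne.tsv")
  write_presence_matrix(res$presence, file.path(out_dir, "presence.tsv"))
  at <- res$atcnes
  at$conservation_score <- round(at$conservation_score, 6)
  at$mean_identity <- round(at$mean_identity, 6)
  wt(at, "atcnes.tsv")
  wt(res$losses, "loss_rates.tsv")
  wt(res$zones, "zones.tsv")
  assoc <- res$associations
  assoc$proximity_rank <- round(assoc$proximity_rank, 6)
  wt(assoc, "associations.tsv")
  wt(res$clusters, "paralogy_clusters.tsv")
  if (!is.null(res$tree_nj))
    ape::write.tree(res$tree_nj, file.path(out_dir, "nj_tree.nwk"))
  if (!is.null(res$phylo$supermatrix))
    write_supermatrix(res$phylo$supermatrix, file.path(out_dir, "supermatrix.phy"))
  occ <- res$motif$occurrences
  occ$relative_position <- round(occ$relative_position, 6)
  wt(occ, "motif_occurrences.tsv")
  invisible(out_dir)
}
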